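DESIGN_FEATURES <- c(MULTIPLIER_NAMES, "tissue_area")

#' Build the full-factorial experiment design
#'
#' One row per (profile, tissue size, drug condition) combination, ordered
#' by profile, then size, then condition. The nine *effective* multipliers
#' are the profile multipliers with the drug's conductance factors folded
#' onto the mapped channels (Nav1.5 -> m_gNa, Cav1.2 -> m_gCaL; the hERG
#' factor acts in simulation but has no corresponding varied feature).
#'
#' @param profiles data.frame with `profile_id` and the nine multiplier
#'   columns (e.g. accepted rows from [calibrate_population()]).
#' @param sizes tissue size labels (must map onto geometry areas).
#' @param conditions subset of `basal, flecainide, verapamil, isoproterenol`.
#' @param areas named areas (cm^2) for the size labels.
#' @return unlabeled design data.frame (add a `label` column after
#'   simulation).
#' @export
build_design <- function(profiles, sizes = c("normal", "dilated"),
                         conditions = c("basal", "flecainide", "verapamil",
                                        "isoproterenol"),
                         areas = c(normal = 16, dilated = 20.25,
                                   desk_normal = 16, desk_dilated = 20.25)) {
  stopifnot(nrow(profiles) > 0, length(sizes) > 0, length(conditions) > 0)
  if (anyDuplicated(profiles$profile_id))
    stop("validation error: duplicate profile_id in profiles")
  stopifnot(all(MULTIPLIER_NAMES %in% names(profiles)),
            all(sizes %in% names(areas)))
  lib <- drug_library()
  cond_drug <- c(basal = "none", flecainide = "flecainide",
                 verapamil = "verapamil", isoproterenol = "isoproterenol")
  stopifnot(all(conditions %in% names(cond_drug)))
  rows <- list()
  for (i in seq_len(nrow(profiles))) {
    for (sz in sizes) {
      for (cond in conditions) {
        f <- drug_factors(lib[[cond_drug[[cond]]]])
        m <- as.numeric(profiles[i, MULTIPLIER_NAMES])
        names(m) <- MULTIPLIER_NAMES
        m["m_gNa"] <- m["m_gNa"] * f[["gNa"]]
        m["m_gCaL"] <- m["m_gCaL"] * f[["gCaL"]]
        rows[[length(rows) + 1]] <-
          data.frame(profile_id = profiles$profile_id[i], t(m),
                     tissue = sz, condition = cond,
                     tissue_area = unname(areas[sz]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train the inducibility random forest
#'
#' Stratified 80/20 train/test split, k-fold cross-validation on the
#' training portion, then a forest fit on the full training portion.
#' Features are the nine effective multipliers plus tissue area.
#'
#' @param table labeled design table (factor or character `label` column
#'   with classes `induced` / `non_inducible`).
#' @param train_frac training fraction in (0, 1).
#' @param k CV folds.
#' @param seed split/forest seed.
#' @param ntree forest size.
#' @param features feature columns (drop entries to ablate).
#' @return object of class `af_classifier`: `forest`, `importances`
#'   (normalized, sum 1), `cv_scores`, `holdout_accuracy`, `split_seed`, ...
#' @export
train_classifier <- function(table, train_frac = 0.8, k = 5, seed = 1,
                             ntree = 500, features = DESIGN_FEATURES) {
  stopifnot(train_frac > 0, train_frac < 1, all(features %in% names(table)))
  y <- factor(as.character(table$label),
              levels = c("non_inducible", "induced"))
  if (nlevels(droplevels(y)) < 2)
    stop("degenerate-label error: table contains a single outcome class")
  x <- table[, features, drop = FALSE]
  set.seed(seed)
  # stratified split
  tr_idx <- unlist(lapply(levels(y), function(lv) {
    ii <- which(y == lv)
    sample(ii, round(train_frac * length(ii)))
  }))
  tr_idx <- sort(tr_idx)
  xtr <- x[tr_idx, , drop = FALSE]; ytr <- droplevels(y[tr_idx])
  xte <- x[-tr_idx, , drop = FALSE]; yte <- y[-tr_idx]
  # k-fold CV on the training portion (stratified fold assignment)
  fold <- integer(length(ytr))
  for (lv in levels(ytr)) {
    ii <- sample(which(ytr == lv))
    fold[ii] <- rep_len(seq_len(k), length(ii))
  }
  cv_scores <- vapply(seq_len(k), function(f) {
    fit <- randomForest::randomForest(xtr[fold != f, , drop = FALSE],
                                      ytr[fold != f], ntree = ntree)
    mean(predict(fit, xtr[fold == f, , drop = FALSE]) == ytr[fold == f])
  }, 0)
  forest <- randomForest::randomForest(xtr, ytr, ntree = ntree,
                                       importance = TRUE)
  holdout <- mean(predict(forest, xte) == yte)
  imp <- randomForest::importance(forest, type = 2)[, 1]
  imp <- pmax(imp, 0); imp <- imp / sum(imp)
  structure(list(forest = forest, importances = imp,
                 cv_scores = cv_scores, cv_mean = mean(cv_scores),
                 cv_sd = sd(cv_scores), holdout_accuracy = holdout,
                 split_seed = seed, train_idx = tr_idx,
                 features = features, classes = levels(y)),
            class = "af_classifier")
}

#' Predict inducibility for design rows
#' @param clf an `af_classifier`.
#' @param rows data.frame with the classifier's feature columns.
#' @return data.frame: `label`, `p_induced`, `p_non_inducible`.
#' @export
predict_inducibility <- function(clf, rows) {
  stopifnot(inherits(clf, "af_classifier"))
  if (!all(clf$features %in% names(rows)))
    stop("schema error: missing feature column(s): ",
         paste(setdiff(clf$features, names(rows)), collapse = ", "))
  x <- rows[, clf$features, drop = FALSE]
  pr <- predict(clf$forest, x, type = "prob")
  lab <- colnames(pr)[max.col(pr, ties.method = "first")]
  data.frame(label = lab,
             p_induced = if ("induced" %in% colnames(pr))
               pr[, "induced"] else 0,
             p_non_inducible = if ("non_inducible" %in% colnames(pr))
               pr[, "non_inducible"] else 0)
}

#' Extract interpretable decision paths (sunburst structure)
#'
#' Fits a single CART tree of depth <= `max_depth` (Gini impurity) on the
#' full labeled table, enumerates every root-to-leaf path as an ordered
#' list of `{feature, threshold, direction}` conditions, and builds the
#' nested ring (sunburst) structure: ring i holds the depth-i split
#' variables, leaves carry the outcome label.
#'
#' @param table labeled design table.
#' @param max_depth maximum tree depth.
#' @param features feature columns.
#' @param cp,minsplit,minbucket rpart growth controls.
#' @return object of class `decision_paths`: `tree` (rpart), `paths`,
#'   `sunburst` (nested list, JSON-exportable), `root`.
#' @export
extract_decision_paths <- function(table, max_depth = 7,
                                   features = DESIGN_FEATURES,
                                   cp = 1e-4, minsplit = 10, minbucket = 5) {
  y <- factor(as.character(table$label),
              levels = c("non_inducible", "induced"))
  dat <- cbind(table[, features, drop = FALSE], label = y)
  fit <- rpart::rpart(label ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = cp, minsplit = minsplit,
                        minbucket = minbucket, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  parsed <- parse_rpart(fit)
  structure(list(tree = fit, paths = parsed$paths,
                 sunburst = parsed$sunburst, root = parsed$root),
            class = "decision_paths")
}

# With maxcompete = maxsurrogate = 0 every internal node owns exactly one
# row of fit$splits, in frame order.
parse_rpart <- function(fit) {
  fr <- fit$frame
  labels <- attr(fit, "ylevels")
  internal <- which(fr$var != "<leaf>")
  if (!length(internal)) {
    leaf_lab <- labels[fr$yval[1]]
    return(list(paths = list(), root = NULL,
                sunburst = list(name = leaf_lab, leaf = TRUE,
                                label = leaf_lab, n = fr$n[1])))
  }
  sp <- fit$splits
  node_ids <- as.integer(rownames(fr))
  split_of <- setNames(seq_along(internal), node_ids[internal])
  info <- function(node) {
    r <- which(node_ids == node)
    if (fr$var[r] == "<leaf>")
      return(list(leaf = TRUE, label = labels[fr$yval[r]], n = fr$n[r]))
    k <- split_of[[as.character(node)]]
    list(leaf = FALSE, feature = as.character(fr$var[r]), n = fr$n[r],
         threshold = unname(sp[k, "index"]), ncat = unname(sp[k, "ncat"]))
  }
  paths <- list()
  build <- function(node, conds) {
    nd <- info(node)
    if (nd$leaf) {
      paths[[length(paths) + 1]] <<-
        list(conditions = conds, leaf_label = nd$label, support = nd$n)
      return(list(name = "leaf", leaf = TRUE, label = nd$label, n = nd$n))
    }
    # ncat = -1: left child takes x < threshold; ncat = +1: x >= threshold
    dir_left <- if (nd$ncat < 0) "<" else ">="
    dir_right <- if (nd$ncat < 0) ">=" else "<"
    cond_row <- function(dir)
      data.frame(feature = nd$feature, threshold = nd$threshold,
                 direction = dir)
    left <- build(2 * node, rbind(conds, cond_row(dir_left)))
    right <- build(2 * node + 1, rbind(conds, cond_row(dir_right)))
    list(name = nd$feature, leaf = FALSE, threshold = nd$threshold, n = nd$n,
         children = list(left = left, right = right),
         left_direction = dir_left)
  }
  empty <- data.frame(feature = character(0), threshold = numeric(0),
                      direction = character(0))
  sb <- build(1, empty)
  root_info <- info(1)
  list(paths = paths, sunburst = sb,
       root = list(feature = root_info$feature,
                   threshold = root_info$threshold))
}

#' Decision path taken by a single row
#' @param dp a `decision_paths` object.
#' @param row one-row data.frame with the feature columns.
#' @return the matching path element (`conditions`, `leaf_label`, `support`).
#' @export
row_path <- function(dp, row) {
  for (p in dp$paths) {
    ok <- TRUE
    cs <- p$conditions
    for (i in seq_len(nrow(cs))) {
      v <- row[[cs$feature[i]]]
      ok <- ok && if (cs$direction[i] == "<") v < cs$threshold[i]
                  else v >= cs$threshold[i]
      if (!ok) break
    }
    if (ok) return(p)
  }
  stop("row matched no decision path (schema mismatch?)")
}

#' Write the sunburst structure as nested JSON
#' @param dp a `decision_paths` object.
#' @param path output file.
#' @export
write_sunburst <- function(dp, path) {
  jsonlite::write_json(dp$sunburst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.af_classifier <- function(x, ...) {
  cat("Inducibility random forest:", x$forest$ntree, "trees |",
      "held-out accuracy", round(x$holdout_accuracy, 3), "|",
      sprintf("CV %.3f +- %.3f", x$cv_mean, x$cv_sd), "\n")
  cat("Top features:", paste(names(sort(x$importances,
                                        decreasing = TRUE))[1:3],
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.decision_paths <- function(x, ...) {
  cat("CART decision paths:", length(x$paths), "leaves; root split on",
      x$root$feature, "at", signif(x$root$threshold, 4), "\n")
  invisible(x)
}
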