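#' Full-scale pipeline configuration
#'
#' Defaults mirror the study conditions of the pipeline: nine-parameter
#' variation over -50%..+100%, 500 LHS candidates, a 15-beat 1 Hz
#' calibration strip of 8 x 256 nodes with probe cells 500/620/748,
#' 400 x 400 / 450 x 450 planes at dx = 0.01 cm, 1 us fidelity time step,
#' three S1 at 1 Hz plus an adaptive S2, 2 s observation window, and an
#' 80/20 + 5-fold random-forest stage. Running this configuration at full
#' scale with the detailed ionic model is a substantial compute job; see
#' [desk_config()] for the surrogate desk scale.
#'
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    model = "detailed",
    cell_base = baseline_parameters(),
    surrogate_base = surrogate_parameters(),
    population = list(n_lhs = 500, n_keep = Inf, seed = 1,
                      range = c(0.5, 2),
                      probe_cells = c(500, 620, 748)),
    strip = list(nx = 8L, ny = 256L, dx = 0.01, dt = 0.001,
                 n_beats = 15, cl = 1000, n_last = 5,
                 stim_columns = 2, stim_dur = 3, amp_factor = 2),
    tissue = list(D_base = 0.0019, dt = 0.001, dt_out = 1,
                  movie_stride = 1L,
                  geometries = c("normal", "dilated")),
    protocol = list(n_s1 = 3, cl = 1000, s2_coupling = NULL, s2_offset = 10,
                    amplitude = 2, duration = 3, obs_window = 2000),
    reentry = list(link_radius = 10, max_gap = 2, min_rotations = 1),
    ml = list(train_frac = 0.8, k = 5, seed = 1, ntree = 500,
              max_depth = 7)
  ), class = "run_config")
}

#' Desk-scale configuration (surrogate model)
#'
#' Same pipeline on the two-variable surrogate with coarse grids: a
#' 8 x 256 calibration strip at dx = 0.025 cm, 100 x 100 / 112 x 112
#' planes of the same areas as the full-scale geometries, dt = 30 us
#' (admissible for the surrogate's Rush-Larsen gate), movies spatially
#' strided by 2 for phase analysis. The diffusion baseline is calibrated so
#' the surrogate's planar conduction velocity is ~65 cm/s at dx = 0.01 cm.
#' The S2 coupling offset is 60 ms and the observation window 1.5 s -- the
#' desk-scale vulnerable-window calibration discussed in the methods
#' vignette.
#'
#' @param n_lhs LHS candidates for the population stage.
#' @param n_keep accepted profiles carried into the simulation grid.
#' @param seed population seed.
#' @return `run_config` list.
#' @export
desk_config <- function(n_lhs = 120, n_keep = 20, seed = 1) {
  cfg <- default_config()
  cfg$model <- "surrogate"
  cfg$population$n_lhs <- n_lhs
  cfg$population$n_keep <- n_keep
  cfg$population$seed <- seed
  cfg$strip$dx <- 0.025
  cfg$strip$dt <- 0.02
  cfg$tissue$D_base <- 0.006
  cfg$tissue$dt <- 0.03
  cfg$protocol$s2_offset <- 60
  cfg$protocol$obs_window <- 1500
  cfg$tissue$movie_stride <- 2L
  cfg$tissue$geometries <- c("desk_normal", "desk_dilated")
  cfg
}

#' Validate a configuration
#' @param config a `run_config`.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  with(config, {
    stopifnot(model %in% c("surrogate", "detailed"),
              population$n_lhs >= 1,
              all(population$range == c(0.5, 2)) ||
                population$range[1] < population$range[2],
              strip$nx >= 2, strip$ny >= 8, strip$dx > 0, strip$dt > 0,
              strip$n_last <= strip$n_beats,
              tissue$D_base > 0, tissue$dt > 0, tissue$dt_out > 0,
              protocol$n_s1 >= 1, protocol$duration < protocol$cl,
              protocol$obs_window > 0,
              ml$train_frac > 0, ml$train_frac < 1, ml$k >= 2)
  })
  invisible(config)
}

#' Run the end-to-end pipeline
#'
#' Stages in order: `population` (LHS + strip calibration),
#' `simulate` (S1-S2 grid over accepted profiles x sizes x conditions, with
#' reentry labeling), `train` (random forest + decision paths). Each stage
#' consumes the previous one's output; pass `prior` to resume. When
#' `out_dir` is given, stage outputs are written as CSV/JSON plus a run
#' manifest.
#'
#' @param config a `run_config` (see [desk_config()]).
#' @param stages subset of `c("population", "simulate", "train")`.
#' @param out_dir optional output directory.
#' @param prior a previous [run_pipeline()] result to resume from.
#' @param conditions drug conditions for the simulation grid.
#' @param quiet suppress progress messages.
#' @return list: `population`, `profiles`, `design`, `classifier`,
#'   `paths`, `manifest`.
#' @export
run_pipeline <- function(config = desk_config(),
                         stages = c("population", "simulate", "train"),
                         out_dir = NULL, prior = NULL,
                         conditions = c("basal", "flecainide", "verapamil",
                                        "isoproterenol"),
                         quiet = FALSE) {
  validate_config(config)
  say <- function(...) if (!quiet) message(...)
  res <- prior %||% list()
  res$manifest <- list(started = format(Sys.time()),
                       model = config$model,
                       seed = config$population$seed,
                       geometries = config$tissue$geometries,
                       stages = stages)
  t0 <- proc.time()[["elapsed"]]

  if ("population" %in% stages) {
    say("population: LHS n = ", config$population$n_lhs)
    cand <- lhs_sample(config$population$n_lhs, 9,
                       seed = config$population$seed,
                       range = config$population$range)
    pop <- calibrate_population(cand, gen_constraint_box(),
                                probe_cells = config$population$probe_cells,
                                model = config$model, config = config)
    res$population <- pop
    acc <- pop[pop$accepted, , drop = FALSE]
    say("population: accepted ", nrow(acc), "/", nrow(pop))
    n_keep <- min(config$population$n_keep, nrow(acc))
    if (n_keep < 1)
      stop("population stage accepted no profiles; widen constraints or n_lhs")
    res$profiles <- acc[seq_len(n_keep), , drop = FALSE]
  }

  if ("simulate" %in% stages) {
    if (is.null(res$profiles))
      stop("missing upstream output: run the 'population' stage first")
    lib <- drug_library()
    cond_drug <- c(basal = "none", flecainide = "flecainide",
                   verapamil = "verapamil", isoproterenol = "isoproterenol")
    design <- build_design(res$profiles,
                           sizes = config$tissue$geometries,
                           conditions = conditions)
    labels <- character(nrow(design))
    rot <- numeric(nrow(design))
    maint <- logical(nrow(design))
    for (i in seq_len(nrow(design))) {
      prof <- res$profiles[res$profiles$profile_id ==
                             design$profile_id[i], ]
      mult <- as.numeric(prof[1, MULTIPLIER_NAMES])
      names(mult) <- MULTIPLIER_NAMES
      drug <- lib[[cond_drug[[as.character(design$condition[i])]]]]
      if (drug$name == "none") drug <- NULL
      an <- tryCatch({
        sim <- run_s1s2(mult, build_geometry(as.character(design$tissue[i])),
                        drug = drug, protocol = config$protocol,
                        model = config$model, config = config)
        analyze_reentry(sim,
                        link_radius = config$reentry$link_radius,
                        max_gap = config$reentry$max_gap,
                        min_rotations = config$reentry$min_rotations)
      }, error = function(e) {
        # a tissue rendered inexcitable (e.g. by channel block) cannot
        # sustain an arrhythmia; record it as non-inducible
        say("simulate: row ", i, " not excitable (", conditionMessage(e), ")")
        list(outcome = list(induced = FALSE, maintained = FALSE,
                            n_tracks = 0L), tracks = list())
      })
      induced <- isTRUE(an$outcome$induced)
      labels[i] <- if (induced) "induced" else "non_inducible"
      maint[i] <- isTRUE(an$outcome$maintained)
      rot[i] <- if (length(an$tracks))
        max(vapply(an$tracks, `[[`, 0, "rotations")) else 0
      if (i %% 20 == 0) say("simulate: ", i, "/", nrow(design))
    }
    design$label <- factor(labels, levels = c("non_inducible", "induced"))
    design$maintained <- maint
    design$max_rotations <- rot
    res$design <- design
    say("simulate: induced ", sum(labels == "induced"), "/", nrow(design))
  }

  if ("train" %in% stages) {
    if (is.null(res$design))
      stop("missing upstream output: run the 'simulate' stage first")
    res$classifier <- train_classifier(res$design,
                                       train_frac = config$ml$train_frac,
                                       k = config$ml$k,
                                       seed = config$ml$seed,
                                       ntree = config$ml$ntree)
    res$paths <- extract_decision_paths(res$design,
                                        max_depth = config$ml$max_depth)
  }

  res$manifest$wall_s <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$population))
      write.csv(res$population, file.path(out_dir, "population.csv"),
                row.names = FALSE)
    if (!is.null(res$design))
      write.csv(res$design, file.path(out_dir, "design.csv"),
                row.names = FALSE)
    if (!is.null(res$classifier))
      jsonlite::write_json(
        list(importances = as.list(res$classifier$importances),
             cv_scores = res$classifier$cv_scores,
             holdout_accuracy = res$classifier$holdout_accuracy),
        file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(res$paths))
      write_sunburst(res$paths, file.path(out_dir, "sunburst.json"))
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
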