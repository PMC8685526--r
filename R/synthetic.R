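#' Surrogate excitable-cell parameters (two-variable model)
#'
#' A Mitchell-Schaeffer-type two-variable excitable model used as a fast
#' drop-in for the detailed atrial myocyte: it supports reentry, has
#' interpretable action-potential-duration control, and runs a 100x100 sheet
#' in seconds. State is `(v, h)` with normalized voltage `v`; the observation
#' map to millivolts is `Vm = -80 + 140 v |v|` (sign-preserving quadratic,
#' which gives the square two-variable AP a realistic early-repolarization
#' profile).
#'
#' Population-multiplier hooks: `m_gNa` scales `1/tau_in` (upstroke/
#' excitability), `m_gK1` and `m_gKur` jointly scale `1/tau_out`
#' (repolarization; geometric mean), `m_gCaL` scales `tau_close` (plateau
#' duration), `m_D` scales the tissue diffusion coefficient, and the
#' remaining multipliers are no-ops. Drug factors on Nav1.5 and Cav1.2 enter
#' through the same hooks.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants, ms.
#' @param v_gate dimensionless recovery threshold in (0, 1).
#' @return object of class `surrogate_parameters`.
#' @export
surrogate_parameters <- function(tau_in = 0.3, tau_out = 3,
                                 tau_open = 120, tau_close = 190,
                                 v_gate = 0.13) {
  stopifnot(tau_in > 0, tau_out > 0, tau_open > 0, tau_close > 0,
            v_gate > 0, v_gate < 1)
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate),
            class = "surrogate_parameters")
}

# Apply multiplier hooks (and drug conductance factors) to surrogate params.
surrogate_effective <- function(params, multipliers = NULL,
                                drug_factors = c(gNa = 1, gKr = 1, gCaL = 1)) {
  m <- setNames(rep(1, 9), MULTIPLIER_NAMES)
  if (!is.null(multipliers)) m[names(multipliers)] <- multipliers
  f_na <- unname(drug_factors["gNa"]) %na1%
    1
  f_cal <- unname(drug_factors["gCaL"]) %na1% 1
  surrogate_parameters(
    tau_in = params$tau_in / (m[["m_gNa"]] * f_na),
    tau_out = params$tau_out / sqrt(m[["m_gK1"]] * m[["m_gKur"]]),
    tau_open = params$tau_open,
    tau_close = params$tau_close * (m[["m_gCaL"]] * f_cal),
    v_gate = params$v_gate)
}

`%na1%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Surrogate cell right-hand side
#'
#' `dv/dt = h v^2 (1 - v)/tau_in - v/tau_out + i_stim`; the gate `h`
#' relaxes toward 1 with `tau_open` below `v_gate` and toward 0 with
#' `tau_close` above it, giving an exact Rush-Larsen form.
#'
#' @param state numeric `c(v, h)`.
#' @param params [surrogate_parameters()].
#' @param i_stim normalized stimulus (1/ms), depolarizing positive.
#' @return list with `dvdt`, `winf`, `wtau` (for the single gate).
#' @export
surrogate_cell <- function(state, params, i_stim = 0) {
  stopifnot(inherits(params, "surrogate_parameters"))
  cell_derivatives(state, params, i_stim)
}

#' Stand-in biomarker constraint box for chronic-AF atrial myocytes
#'
#' SYNTHETIC ranges: plausible chronic-AF atrial action-potential biomarker
#' bounds shipped as a stand-in for an experimental calibration table, read
#' from `inst/extdata/constraints_caf_synthetic.csv`. They are a
#' documented placeholder, not measured data; replace with a real table via
#' [read_constraints()] when one is available. A seed applies a small
#' deterministic jitter (up to 2% of each bound's width) for robustness
#' testing.
#'
#' @param seed optional integer jitter seed.
#' @return a [biomarker_constraints()] object.
#' @export
gen_constraint_box <- function(seed = NULL) {
  path <- system.file("extdata", "constraints_caf_synthetic.csv",
                      package = "afpop")
  box <- read_constraints(path)
  if (!is.null(seed)) {
    set.seed(seed)
    for (b in names(box)) {
      w <- box[[b]]["max"] - box[[b]]["min"]
      box[[b]] <- box[[b]] + runif(2, -0.02, 0.02) * w * c(1, 1)
      if (box[[b]]["min"] > box[[b]]["max"]) box[[b]] <- rev(box[[b]])
    }
    box <- do.call(biomarker_constraints, lapply(box, function(x)
      setNames(as.numeric(x), c("min", "max"))))
  }
  box
}

#' Generate an action-potential trace with closed-form biomarkers
#'
#' Piecewise waveform: rest, an instantaneous upstroke to `peak`, then a
#' linear or exponential return toward rest, chosen so the analytic APD90
#' equals `apd90`. The analytic values of all six biomarkers are returned
#' alongside, making this an oracle for [compute_biomarkers()].
#'
#' @param rest,peak resting and peak potential, mV.
#' @param apd90 action-potential duration at 90% repolarization, ms.
#' @param shape `"linear"` or `"exp"`.
#' @param t_rest leading rest segment before each upstroke, ms.
#' @param n_beats,cl number of concatenated beats and cycle length (ms).
#' @param dt_out sample period, ms.
#' @return list: `t`, `vm`, `stim_times` (upstroke instants),
#'   `biomarkers` (analytic), `shape`.
#' @export
gen_ap_trace <- function(rest = -80, peak = 20, apd90 = 270,
                         shape = c("linear", "exp"), t_rest = 100,
                         n_beats = 1, cl = NULL, dt_out = 1) {
  shape <- match.arg(shape)
  stopifnot(peak > rest, apd90 > 0)
  apa <- peak - rest
  if (shape == "linear") {
    T_dec <- apd90 / 0.9
    apd20 <- apd90 * (20 / 90)
    apd50 <- apd90 * (50 / 90)
    decay <- function(tau) ifelse(tau >= T_dec, rest,
                                  peak - apa * tau / T_dec)
    beat_len <- t_rest + T_dec + 50
  } else {
    tauc <- apd90 / log(10)
    apd20 <- tauc * log(1 / 0.8)
    apd50 <- tauc * log(2)
    decay <- function(tau) rest + apa * exp(-tau / tauc)
    beat_len <- t_rest + apd90 * 2
  }
  cl <- cl %||% beat_len
  stopifnot(cl >= beat_len)
  t <- seq(0, n_beats * cl, by = dt_out)
  vm <- rep(rest, length(t))
  ups <- t_rest + (seq_len(n_beats) - 1) * cl
  for (u in ups) {
    in_ap <- t >= u & t < u + cl - t_rest
    vm[in_ap] <- decay(t[in_ap] - u)
  }
  v20 <- peak - 0.2 * apa
  # stimulus onsets lead the upstroke (as a real pacing artifact would), so
  # each beat window contains its own upstroke sample
  list(t = t, vm = vm, stim_times = ups - min(2, t_rest),
       biomarkers = c(APD20 = apd20, APD50 = apd50, APD90 = apd90,
                      APA = apa, RMP = rest, V20 = v20),
       shape = shape)
}

#' Generate a rotating-spiral voltage movie with known singularities
#'
#' `Vm(x, y, t) = rest + amp * (1 + cos(theta(x, y) - 2 pi f t))` where
#' `theta` is the sum of the centers' angular fields (each weighted by its
#' chirality). Ground-truth singularity positions, charges (in the
#' convention recovered by [phase_map()] + [detect_singularities()]) and the
#' rotation count are emitted alongside.
#'
#' @param nx,ny grid size (rows, cols).
#' @param centers data.frame with columns `x`, `y` (node coords, 1-based)
#'   and `chirality` (+1 / -1); may have zero rows.
#' @param f rotation frequency, rotations per second.
#' @param duration_ms movie length.
#' @param dt_out frame period, ms.
#' @param rest,amp affine mV scaling.
#' @return list: `movie` (array nx x ny x nt), `t`, `truth` (data.frame
#'   x, y, charge, rotations), `f`.
#' @export
gen_spiral_movie <- function(nx, ny, centers, f = 5, duration_ms = 600,
                             dt_out = 1, rest = -80, amp = 55) {
  stopifnot(nrow(centers) == 0 ||
              (all(centers$x >= 1 & centers$x <= nx) &&
                 all(centers$y >= 1 & centers$y <= ny)))
  t <- seq(0, duration_ms, by = dt_out)
  theta <- matrix(0, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  if (nrow(centers) > 0)
    for (k in seq_len(nrow(centers)))
      theta <- theta + centers$chirality[k] *
        atan2(ys - centers$y[k], xs - centers$x[k])
  movie <- array(0, dim = c(nx, ny, length(t)))
  for (i in seq_along(t))
    movie[, , i] <- rest + amp * (1 + cos(theta - 2 * pi * f * t[i] / 1000))
  rot <- f * duration_ms / 1000
  truth <- if (nrow(centers) > 0)
    data.frame(x = centers$x, y = centers$y,
               charge = -centers$chirality, rotations = rot)
  else data.frame(x = numeric(0), y = numeric(0), charge = numeric(0),
                  rotations = numeric(0))
  list(movie = movie, t = t, truth = truth, f = f)
}

#' A threshold rule for labeling synthetic outcome tables
#'
#' Clauses are AND-combinations of `{feature, threshold, direction}` terms
#' (direction `">"` or `"<"`); a row is labeled induced when any clause
#' holds. `label_noise` flips labels independently with that probability.
#'
#' @param clauses list of data.frames with columns feature, threshold,
#'   direction.
#' @param label_noise flip probability in \[0, 0.5).
#' @export
generator_rule <- function(clauses, label_noise = 0) {
  stopifnot(label_noise >= 0, label_noise < 0.5)
  for (cl in clauses) {
    stopifnot(all(c("feature", "threshold", "direction") %in% names(cl)),
              all(cl$direction %in% c(">", "<")))
    bad <- setdiff(cl$feature, c(MULTIPLIER_NAMES, "tissue_area"))
    if (length(bad)) stop("rule feature(s) outside design schema: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(clauses = clauses, label_noise = label_noise),
            class = "generator_rule")
}

rule_clause <- function(...) {
  terms <- list(...)
  data.frame(feature = vapply(terms, `[[`, "", 1),
             threshold = vapply(terms, function(x) as.numeric(x[[2]]), 0),
             direction = vapply(terms, `[[`, "", 3))
}

#' The two induced-AF archetype clusters as a preset rule
#'
#' Encodes two ionic archetypes associated with inducibility: (high gK1,
#' low D, high Ko, high gNa, low gKur) OR (low gK1, low Ko, high INaK,
#' high gCaL, high IKCa, high gNa). The gK1 threshold is 1.0912 (a +9.12%
#' conductance change expressed as a multiplier); the supporting
#' thresholds sit at the mid-range value 1.25.
#' @return a [generator_rule()].
#' @export
rule_archetypes <- function() {
  generator_rule(list(
    rule_clause(list("m_gK1", 1.0912, ">"), list("m_D", 1.25, "<"),
                list("m_K_o", 1.25, ">"), list("m_gNa", 1.25, ">"),
                list("m_gKur", 1.25, "<")),
    rule_clause(list("m_gK1", 1.0912, "<"), list("m_K_o", 1.25, "<"),
                list("m_iNaK", 1.25, ">"), list("m_gCaL", 1.25, ">"),
                list("m_iKCa", 1.25, ">"), list("m_gNa", 1.25, ">"))))
}

apply_rule <- function(rule, df) {
  hit <- rep(FALSE, nrow(df))
  for (cl in rule$clauses) {
    ok <- rep(TRUE, nrow(df))
    for (i in seq_len(nrow(cl))) {
      x <- df[[cl$feature[i]]]
      ok <- ok & if (cl$direction[i] == ">") x > cl$threshold[i]
                 else x < cl$threshold[i]
    }
    hit <- hit | ok
  }
  hit
}

#' Generate a rule-labeled outcome table (ML-stage fixture)
#'
#' Multipliers are uniform on \[0.5, 2\] (or LHS), tissue sizes and drug
#' conditions uniform over their vocabularies, labels from a known threshold
#' rule plus optional label noise. Because the rule is known, classifier
#' rule-recovery can be tested exactly.
#'
#' @param n rows (>= 10).
#' @param rule a [generator_rule()], or the string `"archetypes"` for the
#'   preset two-cluster rule of [rule_archetypes()].
#' @param seed integer seed (everything is deterministic given it).
#' @param lhs use Latin-hypercube instead of iid uniform multipliers.
#' @return data.frame in the design-row schema with a `label` column and
#'   attribute `degenerate` flagging an all-one-class table.
#' @export
gen_outcome_table <- function(n, rule, seed, lhs = FALSE) {
  stopifnot(n >= 10)
  if (is.character(rule) && rule %in% c("archetypes", "paper_clusters"))
    rule <- rule_archetypes()
  stopifnot(inherits(rule, "generator_rule"))
  set.seed(seed)
  m <- if (lhs) lhs_sample(n, 9, seed = seed)
       else matrix(runif(n * 9, 0.5, 2), n, 9,
                   dimnames = list(NULL, MULTIPLIER_NAMES))
  df <- as.data.frame(m)
  df$profile_id <- sprintf("syn%04d", seq_len(n))
  df$tissue <- sample(c("normal", "dilated"), n, replace = TRUE)
  df$condition <- sample(c("basal", "flecainide", "verapamil",
                           "isoproterenol"), n, replace = TRUE)
  df$tissue_area <- ifelse(df$tissue == "dilated", 20.25, 16)
  lab <- apply_rule(rule, df)
  if (rule$label_noise > 0)
    lab <- xor(lab, runif(n) < rule$label_noise)
  df$label <- factor(ifelse(lab, "induced", "non_inducible"),
                     levels = c("non_inducible", "induced"))
  df <- df[, c("profile_id", MULTIPLIER_NAMES, "tissue", "condition",
               "tissue_area", "label")]
  degenerate <- length(unique(df$label)) < 2
  if (degenerate) warning("degenerate rule: table has a single label class")
  attr(df, "degenerate") <- degenerate
  df
}
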