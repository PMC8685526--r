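#' Baseline ionic parameters of the human atrial myocyte model
#'
#' Maximum conductances (nS/pF), pump/exchanger scales, SR-handling scales and
#' extracellular concentrations (mM) of the detailed atrial myocyte model
#' (Courtemanche-family formulation extended with an SK current). These are
#' the *non-remodeled* values; see [apply_caf_remodeling()] for the
#' chronic-AF rescaling applied before any population variation.
#'
#' @param ... named overrides of individual fields.
#' @return An object of class `baseline_parameters` (named list).
#' @examples
#' p <- baseline_parameters()
#' p$gNa
#' @export
baseline_parameters <- function(...) {
  p <- list(
    gNa = 7.8,            # fast Na+ conductance
    gK1 = 0.09,           # inward rectifier
    gCaL = 0.12375,       # L-type Ca2+
    gKur = 1.0,           # scale on the voltage-dependent IKur conductance
    gKCa = 0.005,         # SK (Ca2+-activated K+)
    iNaK_max = 0.59933874,
    gto = 0.1652,
    gKr = 0.029411765,
    gNCX_scale = 1.0,     # Na+/Ca2+ exchanger scale
    serca_scale = 1.0,    # SERCA uptake Vmax scale
    plb_scale = 1.0,      # phospholamban/SERCA ratio (raises uptake Km)
    sln_scale = 1.0,      # sarcolipin/SERCA ratio (raises uptake Km)
    Na_o = 140,           # mM
    K_o = 5.4,            # mM
    Cm = 100              # pF
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown baseline parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  validate_baseline(p)
  structure(p, class = "baseline_parameters")
}

validate_baseline <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("invalid parameter: all baseline fields must be strictly positive ",
         "finite numbers (offending: ",
         paste(names(num)[!is.finite(num) | num <= 0], collapse = ", "), ")")
  invisible(p)
}

#' Apply chronic-AF electrical remodeling to baseline parameters
#'
#' Fixed conductance rescalings representing chronic-AF remodeling of the
#' atrial myocyte: ICaL x0.45, Ito x0.38, IKur x0.62, IK1 x1.62,
#' NCX x1.50, SERCA x0.84, PLB/SERCA x1.18, SLN/SERCA x0.60. All other
#' fields (including the SK conductance, which the remodeling set does not
#' touch) are returned unchanged.
#'
#' @param base a [baseline_parameters()] object.
#' @return a remodeled `baseline_parameters` copy.
#' @export
apply_caf_remodeling <- function(base) {
  validate_baseline(base)
  out <- base
  out$gCaL <- base$gCaL * 0.45
  out$gto <- base$gto * 0.38
  out$gKur <- base$gKur * 0.62
  out$gK1 <- base$gK1 * 1.62
  out$gNCX_scale <- base$gNCX_scale * 1.50
  out$serca_scale <- base$serca_scale * 0.84
  out$plb_scale <- base$plb_scale * 1.18
  out$sln_scale <- base$sln_scale * 0.60
  structure(out, class = "baseline_parameters")
}

#' Construct an ionic profile (nine population multipliers)
#'
#' A profile is a nine-element record of dimensionless multipliers over the
#' remodeled baseline, each in \[0.5, 2\] (i.e. -50% to +100% variation):
#' `m_gNa, m_iNaK, m_gK1, m_gCaL, m_gKur, m_iKCa, m_Na_o, m_K_o, m_D`.
#'
#' @param profile_id identifier.
#' @param multipliers named numeric vector with the nine multiplier names;
#'   missing entries default to 1.
#' @return an `ionic_profile` object.
#' @export
ionic_profile <- function(profile_id, multipliers = NULL) {
  m <- setNames(rep(1, 9), MULTIPLIER_NAMES)
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), MULTIPLIER_NAMES)
    if (length(bad)) stop("unknown multiplier(s): ", paste(bad, collapse = ", "))
    m[names(multipliers)] <- multipliers
  }
  if (any(m < 0.5 - 1e-12 | m > 2 + 1e-12))
    stop("multiplier out of range [0.5, 2]: ",
         paste(names(m)[m < 0.5 | m > 2], collapse = ", "))
  structure(list(profile_id = profile_id, multipliers = m),
            class = "ionic_profile")
}

#' Scale baseline parameters by a population profile
#'
#' Applies the six conductance/pump multipliers and the two extracellular
#' concentration multipliers onto `base`; the diffusion multiplier `m_D` does
#' not touch the cell parameters and is carried through as attribute `"m_D"`
#' for the tissue stage. Remodeling-first convention: call
#' [apply_caf_remodeling()] before this.
#'
#' @param base a [baseline_parameters()] object.
#' @param profile an [ionic_profile()] object.
#' @return scaled `baseline_parameters` with attribute `m_D`.
#' @export
scale_profile <- function(base, profile) {
  validate_baseline(base)
  stopifnot(inherits(profile, "ionic_profile"))
  m <- profile$multipliers
  out <- base
  out$gNa <- base$gNa * m[["m_gNa"]]
  out$iNaK_max <- base$iNaK_max * m[["m_iNaK"]]
  out$gK1 <- base$gK1 * m[["m_gK1"]]
  out$gCaL <- base$gCaL * m[["m_gCaL"]]
  out$gKur <- base$gKur * m[["m_gKur"]]
  out$gKCa <- base$gKCa * m[["m_iKCa"]]
  out$Na_o <- base$Na_o * m[["m_Na_o"]]
  out$K_o <- base$K_o * m[["m_K_o"]]
  out <- structure(out, class = "baseline_parameters")
  attr(out, "m_D") <- m[["m_D"]]
  out
}

# Pack baseline parameters into the C++ engine's parameter vector.
# Fixed model constants (gKs, backgrounds, Cao, NCX/SERCA reference values)
# live here; the remodeling/population scales multiply onto them.
crn_engine_params <- function(base) {
  c(gNa = base$gNa,
    gK1 = base$gK1,
    gto = base$gto,
    gKur_scale = base$gKur,
    gKr = base$gKr,
    gKs = 0.12941176,
    gCaL = base$gCaL,
    gKCa = base$gKCa,
    INaK_max = base$iNaK_max,
    INaCa_max = 1600 * base$gNCX_scale,
    Iup_max = 0.005 * base$serca_scale,
    Kup = 0.00092 * base$plb_scale * base$sln_scale,
    Nao = base$Na_o,
    Ko = base$K_o,
    Cao = 1.8,
    gbCa = 0.001131,
    gbNa = 0.0006744375,
    ipCa_max = 0.275)
}

# Published resting state of the detailed model (control conditions); used
# as the integration starting point everywhere.
crn_initial_state <- function() {
  c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775,
    oa = 0.03043, oi = 0.9992, ua = 0.004966, ui = 0.9986,
    xr = 3.296e-5, xs = 0.01869, d = 1.367e-4, f = 0.9996,
    fca = 0.7755, u = 0, vrel = 1, w = 0.9992,
    Nai = 11.17, Ki = 139.0, Cai = 1.013e-4,
    Caup = 1.488, Carel = 1.488)
}

crn_gate_names <- function() {
  c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fca", "u", "vrel", "w")
}

#' Evaluate the cell model right-hand side
#'
#' Returns the membrane-potential derivative, steady-state/time-constant
#' pairs `(w_inf, tau)` for every Hodgkin-Huxley gate (enabling Rush-Larsen
#' integration) and forward-Euler derivatives for the concentration states.
#' Sign convention: a depolarizing stimulus is positive and
#' `dVm/dt = -(I_ion - I_stim)/Cm`.
#'
#' @param state named numeric state vector (see [crn_initial_state()] for the
#'   detailed model; `c(v, h)` for the surrogate).
#' @param params a [baseline_parameters()] object (detailed model) or a
#'   [surrogate_parameters()] object.
#' @param i_stim stimulus current density (pA/pF for the detailed model,
#'   1/ms in normalized units for the surrogate).
#' @return list with `dvdt`, `winf`, `wtau`, `dconc`.
#' @export
cell_derivatives <- function(state, params, i_stim = 0) {
  if (any(is.na(state) | !is.finite(state))) {
    nm <- names(state) %||% as.character(seq_along(state))
    stop("numerical-state error: non-finite value in state variable(s) ",
         paste(nm[is.na(state) | !is.finite(state)], collapse = ", "))
  }
  if (inherits(params, "surrogate_parameters")) {
    out <- cpp_cell_rhs(0L, as.numeric(state), as.numeric(unlist(params)),
                        i_stim)
    names(out$winf) <- names(out$wtau) <- "h"
  } else {
    validate_baseline(params)
    out <- cpp_cell_rhs(1L, as.numeric(state), crn_engine_params(params),
                        i_stim)
    names(out$winf) <- names(out$wtau) <- crn_gate_names()
    names(out$dconc) <- c("Nai", "Ki", "Cai", "Caup", "Carel")
  }
  out
}

# -- diastolic threshold -----------------------------------------------------

# Bisection on single-stimulus amplitude to 1% relative tolerance.
# An action potential is scored when Vm exceeds -20 mV within the window.
# Results are memoised per parameter vector within the session.
.threshold_cache <- new.env(parent = emptyenv())

find_diastolic_threshold <- function(params, stim_dur = 3, window_ms = 400,
                                     dt = NULL, tol = 0.01) {
  eng <- engine_spec(params)
  key <- paste0(eng$model, ":", paste(signif(eng$cpar, 10), collapse = ","),
                ":", stim_dur)
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  dt <- dt %||% eng$dt_default
  fires <- function(amp) {
    run <- cpp_cell_run(eng$model, eng$cpar, eng$state0, window_ms,
                        50, stim_dur, amp, dt, 1)
    max(eng$to_mv(run$vm)) > -20
  }
  hi <- eng$amp_guess
  tries <- 0
  while (!fires(hi)) {
    hi <- hi * 2; tries <- tries + 1
    if (tries > 12) stop("no stimulus amplitude elicits an action potential")
  }
  lo <- 0
  while ((hi - lo) > tol * hi) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .threshold_cache[[key]] <- hi
  hi
}

# Normalised engine view of either cell model: C++ model id, packed params,
# resting state, mV mapping, sensible dt and an amplitude scale for the
# threshold search.
engine_spec <- function(params) {
  if (inherits(params, "surrogate_parameters")) {
    list(model = 0L, cpar = as.numeric(unlist(params)),
         state0 = c(0, 1),
         # sign-preserving quadratic observation map: triangulates early
         # repolarization so the surrogate AP has realistic APD20/APD90
         to_mv = function(v) -80 + 140 * v * abs(v),
         dt_default = 0.02, amp_guess = 0.1)
  } else {
    validate_baseline(params)
    list(model = 1L, cpar = crn_engine_params(params),
         state0 = as.numeric(crn_initial_state()),
         to_mv = identity, dt_default = 0.02, amp_guess = 10)
  }
}

#' Run a paced single-cell simulation
#'
#' Pacing with `n_beats` stimuli at cycle length `cl`; by default the
#' stimulus is 3 ms at twice the diastolic threshold (found by bisection and
#' cached). The voltage trace is sampled at 1 kHz regardless of the
#' integration step.
#'
#' @param params [baseline_parameters()] or [surrogate_parameters()].
#' @param n_beats number of stimuli (>= 1).
#' @param cl cycle length, ms.
#' @param stim list with `duration` (ms) and `amplitude`; `amplitude = NULL`
#'   means twice diastolic threshold.
#' @param dt integration step, ms.
#' @param dt_out output sampling period, ms (default 1 = 1 kHz).
#' @param repol_threshold_mv repolarization must fall below this before each
#'   next stimulus, otherwise the trace is flagged (`repol_failure`).
#' @return list of class `vm_trace`: `t`, `vm` (mV), `stim_times`,
#'   `state_final`, `gate_range`, `repol_failure`.
#' @export
run_paced_cell <- function(params, n_beats, cl = 1000,
                           stim = list(duration = 3, amplitude = NULL),
                           dt = NULL, dt_out = 1,
                           repol_threshold_mv = -60) {
  stopifnot(n_beats >= 1, cl > stim$duration)
  eng <- engine_spec(params)
  dt <- dt %||% eng$dt_default
  amp <- stim$amplitude %||%
    (2 * find_diastolic_threshold(params, stim_dur = stim$duration, dt = dt))
  starts <- (seq_len(n_beats) - 1) * cl
  run <- cpp_cell_run(eng$model, eng$cpar, eng$state0, n_beats * cl,
                      starts, stim$duration, amp, dt, dt_out)
  vm <- eng$to_mv(run$vm)
  # repolarization check in the 20 ms before each later stimulus
  repol_fail <- FALSE
  for (s in starts[-1]) {
    idx <- run$t >= (s - 20) & run$t < s
    if (any(idx) && min(vm[idx]) > repol_threshold_mv) repol_fail <- TRUE
  }
  structure(list(t = run$t, vm = vm, stim_times = starts,
                 stim = list(duration = stim$duration, amplitude = amp),
                 state_final = run$state_final,
                 gate_range = cbind(min = run$gate_min, max = run$gate_max),
                 repol_failure = repol_fail),
            class = "vm_trace")
}

#' @export
print.vm_trace <- function(x, ...) {
  cat("Paced voltage trace:", length(x$t), "samples,",
      length(x$stim_times), "stimuli, Vm in [",
      round(min(x$vm), 1), ",", round(max(x$vm), 1), "] mV",
      if (x$repol_failure) "(repolarization failure)" else "", "\n")
  invisible(x)
}
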