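#' Pore-block factor
#'
#' Simple pore-channel block: the conductance factor `1/(1 + conc/ic50)`,
#' where IC50 is the concentration that halves the channel current.
#'
#' @param conc drug concentration, uM (>= 0); vectorized.
#' @param ic50 half-maximal inhibitory concentration, uM (> 0).
#' @return factor in (0, 1] multiplied onto the target conductance.
#' @export
pore_block_factor <- function(conc, ic50) {
  if (any(conc < 0)) stop("negative drug concentration")
  if (any(ic50 <= 0)) stop("ic50 must be positive")
  1 / (1 + conc / ic50)
}

#' Agonist (conductance-enhancing) factor
#'
#' Saturating form `1 + conc/(conc + ec50)`: unity at zero dose, 1.5 at
#' `conc = ec50`, doubling at saturation -- the scaling used for the
#' beta-agonist effect on the L-type Ca2+ conductance. A linear alternative
#' `1 + conc/ec50` is available for sensitivity analyses.
#'
#' @param conc concentration, uM (>= 0); vectorized.
#' @param ec50 half-saturation concentration, uM (> 0).
#' @param form `"saturating"` (default) or `"linear"`.
#' @return factor >= 1.
#' @export
agonist_factor <- function(conc, ec50, form = c("saturating", "linear")) {
  form <- match.arg(form)
  if (any(conc < 0)) stop("negative drug concentration")
  if (any(ec50 <= 0)) stop("ec50 must be positive")
  if (form == "saturating") 1 + conc / (conc + ec50) else 1 + conc / ec50
}

DRUG_CHANNELS <- c("Nav1.5-peak" = "gNa", "hERG" = "gKr", "Cav1.2" = "gCaL")

#' Construct a drug specification
#'
#' @param name label.
#' @param concentration uM (>= 0).
#' @param targets list of `list(channel, half_max, mode)` with channel one of
#'   `"Nav1.5-peak"`, `"hERG"`, `"Cav1.2"`, `half_max` the IC50/EC50 in uM,
#'   and mode `"block"` or `"enhance"`.
#' @export
drug_spec <- function(name, concentration, targets = list()) {
  stopifnot(concentration >= 0)
  for (tg in targets) {
    if (!tg$channel %in% names(DRUG_CHANNELS))
      stop("configuration error: unknown channel label '", tg$channel, "'")
    stopifnot(tg$half_max > 0, tg$mode %in% c("block", "enhance"))
  }
  structure(list(name = name, concentration = concentration,
                 targets = targets), class = "drug_spec")
}

#' The studied drug library
#'
#' Flecainide (0.2 uM; Nav1.5 IC50 6.7, hERG 0.7, Cav1.2 20), verapamil
#' (0.5 uM; 1.0 / 0.7 / 0.1) and isoproterenol (80 uM; Cav1.2 EC50 20,
#' enhancing; no Nav1.5/hERG effect), plus a zero-dose `"none"` entry for
#' the basal condition. Concentrations are stated in uM (the source table's
#' mM entries reinterpreted: 2.0e-4 mM = 0.2 uM etc., the physiologically
#' sensible reading).
#' @return named list of [drug_spec()] objects.
#' @export
drug_library <- function() {
  list(
    none = drug_spec("none", 0),
    flecainide = drug_spec("flecainide", 0.2, list(
      list(channel = "Nav1.5-peak", half_max = 6.7, mode = "block"),
      list(channel = "hERG", half_max = 0.7, mode = "block"),
      list(channel = "Cav1.2", half_max = 20, mode = "block"))),
    verapamil = drug_spec("verapamil", 0.5, list(
      list(channel = "Nav1.5-peak", half_max = 1.0, mode = "block"),
      list(channel = "hERG", half_max = 0.7, mode = "block"),
      list(channel = "Cav1.2", half_max = 0.1, mode = "block"))),
    isoproterenol = drug_spec("isoproterenol", 80, list(
      list(channel = "Cav1.2", half_max = 20, mode = "enhance"))))
}

#' Per-channel conductance factors of a drug
#'
#' @param drug a [drug_spec()].
#' @param agonist_form passed to [agonist_factor()].
#' @return named numeric `c(gNa=, gKr=, gCaL=)`, 1 where untargeted.
#' @export
drug_factors <- function(drug, agonist_form = "saturating") {
  stopifnot(inherits(drug, "drug_spec"))
  f <- c(gNa = 1, gKr = 1, gCaL = 1)
  for (tg in drug$targets) {
    par <- DRUG_CHANNELS[[tg$channel]]
    fac <- if (tg$mode == "block")
      pore_block_factor(drug$concentration, tg$half_max)
    else agonist_factor(drug$concentration, tg$half_max, agonist_form)
    f[par] <- f[par] * fac
  }
  f
}

#' Apply a drug to cell parameters
#'
#' Multiplies each target channel's conductance by its pore-block or agonist
#' factor (channel mapping: Nav1.5-peak -> gNa, hERG -> gKr,
#' Cav1.2 -> gCaL); untargeted parameters are unchanged. Multiplicative, so
#' it commutes with [scale_profile()].
#'
#' @param params a [baseline_parameters()] object.
#' @param drug a [drug_spec()].
#' @return modified `baseline_parameters` (attributes preserved).
#' @export
apply_drug <- function(params, drug, agonist_form = "saturating") {
  validate_baseline(params)
  f <- drug_factors(drug, agonist_form)
  out <- params
  out$gNa <- params$gNa * f[["gNa"]]
  out$gKr <- params$gKr * f[["gKr"]]
  out$gCaL <- params$gCaL * f[["gCaL"]]
  attributes(out) <- attributes(params)
  out
}
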