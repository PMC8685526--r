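#' Build a tissue geometry
#'
#' `"normal"` is a 16 cm^2 square sheet (400 x 400 nodes, dx = 0.01 cm);
#' `"dilated"` is 20.25 cm^2 (450 x 450 nodes). The `desk_*` labels are
#' coarse desk-scale counterparts with the same areas (100 x 100 and
#' 112 x 112 nodes). A custom geometry is given as `list(nx, ny, dx)`.
#'
#' @param size either a label (`"normal"`, `"dilated"`, `"desk_normal"`,
#'   `"desk_dilated"`) or a `list(nx, ny, dx)`.
#' @return object of class `tissue_geometry`: `nx`, `ny`, `dx` (cm),
#'   `area` (cm^2), `label`.
#' @export
build_geometry <- function(size = "normal") {
  if (is.list(size)) {
    stopifnot(size$nx >= 8, size$ny >= 8, size$dx > 0)
    g <- list(nx = as.integer(size$nx), ny = as.integer(size$ny),
              dx = size$dx, label = "custom")
  } else {
    g <- switch(size,
      normal       = list(nx = 400L, ny = 400L, dx = 0.01, label = "normal"),
      dilated      = list(nx = 450L, ny = 450L, dx = 0.01, label = "dilated"),
      desk_normal  = list(nx = 100L, ny = 100L, dx = 0.04,
                          label = "desk_normal"),
      desk_dilated = list(nx = 112L, ny = 112L, dx = 0.0402,
                          label = "desk_dilated"),
      stop("unknown geometry label: ", size))
  }
  g$area <- (g$nx * g$dx) * (g$ny * g$dx)
  structure(g, class = "tissue_geometry")
}

#' Rush-Larsen gating update
#'
#' Exact exponential relaxation of a Hodgkin-Huxley gate with frozen rates
#' over one step: `w_inf + (w - w_inf) exp(-dt/tau)`. Vectorized.
#'
#' @param w gate value(s) in \[0, 1\].
#' @param w_inf steady state.
#' @param tau time constant, ms (> 0).
#' @param dt step, ms (> 0).
#' @export
rush_larsen_step <- function(w, w_inf, tau, dt) {
  if (any(tau <= 0)) stop("numerical-parameter error: tau must be positive")
  if (any(dt <= 0)) stop("numerical-parameter error: dt must be positive")
  w_inf + (w - w_inf) * exp(-dt / tau)
}

# Largest step <= dt that divides the output period exactly, so that
# movie/probe sampling is exactly on the 1 kHz grid.
snap_dt <- function(dt, dt_out = 1) dt_out / ceiling(dt_out / dt)

#' Forward-Euler stability bound for the diffusion step
#' @param dx node spacing, cm.
#' @param D diffusion coefficient, cm^2/ms.
#' @param safety multiplicative safety margin.
#' @return largest admissible dt, ms.
#' @export
stability_dt <- function(dx, D, safety = 0.9) {
  if (D <= 0) return(Inf)
  safety * dx^2 / (4 * D)
}

#' Construct a tissue state
#'
#' @param geometry a [tissue_geometry()].
#' @param params cell parameters ([surrogate_parameters()] or
#'   [baseline_parameters()]); every node starts from the model's resting
#'   state.
#' @return object of class `tissue_state`: `vm` (nx x ny, mV), `cells`
#'   (per-node full state matrix), `t`, plus the engine view.
#' @export
tissue_state <- function(geometry, params) {
  eng <- engine_spec(params)
  n <- geometry$nx * geometry$ny
  cells <- matrix(eng$state0, length(eng$state0), n)
  structure(list(vm = matrix(eng$to_mv(cells[1, ]), geometry$nx,
                             geometry$ny),
                 cells = cells, t = 0, geometry = geometry, engine = eng),
            class = "tissue_state")
}

#' Advance a tissue state by one monodomain step (reference implementation)
#'
#' Forward Euler with the 5-point Laplacian and no-flux (mirrored) borders
#' for voltage, Rush-Larsen for gates, forward Euler for concentrations.
#' This is the plain-R reference used for contract and symmetry tests; long
#' runs go through the compiled driver inside [run_s1s2()], which follows
#' the identical update order.
#'
#' @param state a [tissue_state()].
#' @param D_eff effective diffusion coefficient, cm^2/ms.
#' @param dt step, ms; refused (with a suggestion) if it violates the
#'   stability bound.
#' @param i_stim optional nx x ny stimulus matrix (model stimulus units).
#' @return the advanced `tissue_state`.
#' @export
step_monodomain <- function(state, D_eff, dt, i_stim = NULL) {
  g <- state$geometry
  bound <- stability_dt(g$dx, D_eff)
  if (dt > bound)
    stop(sprintf("stability bound violated: dt = %g ms > %g ms; use dt <= %g",
                 dt, bound, bound))
  eng <- state$engine
  n <- g$nx * g$ny
  cells <- state$cells
  v <- matrix(cells[1, ], g$nx, g$ny)
  # mirrored-ghost Laplacian
  up <- v[c(2, seq_len(g$nx - 1)), ]
  dn <- v[c(seq_len(g$nx)[-1], g$nx - 1), ]
  lf <- v[, c(2, seq_len(g$ny - 1))]
  rt <- v[, c(seq_len(g$ny)[-1], g$ny - 1)]
  lap <- (up + dn + lf + rt - 4 * v) / g$dx^2
  newcells <- cells
  for (c0 in seq_len(n)) {
    st <- cells[, c0]
    stim <- if (is.null(i_stim)) 0 else i_stim[c0]
    rhs <- cpp_cell_rhs(eng$model, st, eng$cpar, stim)
    ngate <- length(rhs$winf)
    newcells[1, c0] <- st[1] + dt * (D_eff * lap[c0] + rhs$dvdt)
    newcells[2:(1 + ngate), c0] <-
      rush_larsen_step(st[2:(1 + ngate)], rhs$winf, rhs$wtau, dt)
    if (length(rhs$dconc))
      newcells[(2 + ngate):nrow(cells), c0] <-
        st[(2 + ngate):nrow(cells)] + dt * rhs$dconc
  }
  if (any(!is.finite(newcells[1, ]))) {
    bad <- which(!is.finite(newcells[1, ]))[1]
    stop(sprintf("numerical blowup at node (%d, %d), t = %g ms",
                 (bad - 1) %% g$nx + 1, (bad - 1) %/% g$nx + 1, state$t))
  }
  state$cells <- newcells
  state$vm <- matrix(eng$to_mv(newcells[1, ]), g$nx, g$ny)
  state$t <- state$t + dt
  state
}

#' Measure planar conduction velocity on a strip
#'
#' Runs a planar wave from the left-edge column band and reports CV from the
#' activation-time difference (crossing of -40 mV on the upstroke) between
#' two probe columns at least 1 cm apart.
#'
#' @param params cell parameters (either model).
#' @param D_eff diffusion coefficient, cm^2/ms.
#' @param geometry strip geometry (default 8 x 256 at dx = 0.01 cm).
#' @param dt integration step (capped by the stability bound).
#' @return conduction velocity, cm/s.
#' @export
measure_cv <- function(params, D_eff,
                       geometry = build_geometry(list(nx = 8, ny = 256,
                                                      dx = 0.01)),
                       dt = 0.02) {
  if (D_eff <= 0) stop("propagation failure: D_eff must be positive")
  eng <- engine_spec(params)
  g <- geometry
  dt <- snap_dt(min(dt, stability_dt(g$dx, D_eff)), 0.1)
  # planar wave => width-uniform solution; integrate the collapsed cable
  len <- max(g$nx, g$ny); wid <- 1L
  n <- len * wid
  state0 <- matrix(eng$state0, length(eng$state0), n)
  mask <- stim_mask_band(len, wid, 1:2)
  eff <- c(eng, list(params = params))
  amp <- 2 * find_tissue_threshold(eff, D_eff, g$dx)
  # probe columns >= 1 cm apart, away from the stimulated edge
  ja <- max(3, round(len * 0.2))
  jb <- ja + ceiling(1 / g$dx)
  if (jb > len - 2) stop("strip too short for 1 cm probe separation")
  probes0 <- c(ja - 1, jb - 1)
  total <- (jb * g$dx * 1.2) / 0.01 + 60   # generous upper bound, ms
  run <- cpp_tissue_run(eng$model, eng$cpar, state0, len, wid, g$dx,
                        D_eff, dt, total, 1, 3, amp, list(mask),
                        as.integer(probes0), total + 1, 0.1, 1L)
  if (run$blowup) stop("numerical blowup during CV measurement")
  act <- apply(run$probe_vm, 2, function(vv) {
    vmv <- eng$to_mv(vv)
    i <- which(vmv >= -40)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(run$probe_t[1])
    approx(vmv[(i - 1):i], run$probe_t[(i - 1):i], -40)$y
  })
  if (any(is.na(act)) || diff(act) <= 0)
    stop("propagation failure: wave did not reach the distal probe")
  dist_cm <- (jb - ja) * g$dx
  1000 * dist_cm / diff(act)
}

# Diastolic threshold of a left-edge band stimulus in coupled tissue:
# diffusion into resting neighbors raises the threshold well above the
# isolated cell's, so it is bisected (1% tolerance) on a short strip with
# the target dx and D_eff. Success = propagation to half the strip.
# Memoised per (model, params, dx, D_eff, duration).
.tissue_thr_cache <- new.env(parent = emptyenv())

find_tissue_threshold <- function(eff, D_eff, dx, stim_dur = 3,
                                  stim_columns = 2, tol = 0.01) {
  key <- paste0(eff$model, ":", paste(signif(eff$cpar, 8), collapse = ","),
                ":", signif(dx, 6), ":", signif(D_eff, 6), ":", stim_dur)
  hit <- .tissue_thr_cache[[key]]
  if (!is.null(hit)) return(hit)
  nx <- 64L; ny <- 1L   # width-collapsed cable (planar-symmetric band)
  dt <- snap_dt(min(0.02, stability_dt(dx, D_eff)))
  state0 <- matrix(eff$state0, length(eff$state0), nx * ny)
  mask <- stim_mask_band(nx, ny, seq_len(stim_columns))
  probe <- as.integer(nx %/% 2)
  fires <- function(amp) {
    run <- cpp_tissue_run(eff$model, eff$cpar, state0, nx, ny, dx, D_eff,
                          dt, 80, 1, stim_dur, amp, list(mask), probe,
                          100, 1, 1L)
    vv <- eff$to_mv(run$probe_vm[, 1])
    if (run$blowup || any(!is.finite(vv)))
      stop("profile is not excitable in tissue: band stimulus overdrives ",
           "without propagating")
    max(vv) > -20
  }
  hi <- find_diastolic_threshold(eff$params, stim_dur = stim_dur)
  tries <- 0
  while (!fires(hi)) {
    hi <- hi * 2; tries <- tries + 1
    if (tries > 8)
      stop("profile is not excitable in tissue: no band stimulus propagates")
  }
  lo <- hi / 2
  while ((hi - lo) > tol * hi) {
    mid <- (hi + lo) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .tissue_thr_cache[[key]] <- hi
  hi
}

# Node mask of the inferior-left quadrant (rows >= nx/2, cols < ny/2).
s2_quadrant_mask <- function(nx, ny) {
  rows <- seq(floor(nx / 2) + 1, nx)
  cols <- seq_len(floor(ny / 2))
  as.integer(outer(rows - 1, (cols - 1) * nx, `+`))
}

#' Run the S1-S2 induction protocol on a 2D sheet
#'
#' `n_s1` planar conditioning beats from the left-edge column band at cycle
#' length `cl`, then one premature S2 in the inferior-left quadrant at the
#' coupling interval. Default coupling is adaptive: the profile's APD90
#' plus 10 ms after the last S1 onset (targeting the vulnerable window); a
#' fixed value can be supplied. The voltage movie is stored at 1 kHz from
#' just before S2 (spatially strided if requested) for phase analysis.
#'
#' @param multipliers named nine-multiplier vector (an accepted profile row).
#' @param geometry a [tissue_geometry()].
#' @param drug a [drug_spec()] or `NULL`.
#' @param protocol list: `n_s1`, `cl`, `s2_coupling` (ms or `NULL` =
#'   adaptive, APD90 + `s2_offset`), `amplitude` (multiple of diastolic
#'   threshold; `s2_amplitude` overrides it for S2), `duration` (ms),
#'   `obs_window` (ms after S2).
#' @param model `"surrogate"` or `"detailed"`.
#' @param config pipeline configuration ([default_config()]).
#' @return object of class `sim_result`: `movie` (mV, nx' x ny' x frames),
#'   `movie_t`, `dt_out`, `stride`, `s2_time`, `geometry`, `blowup`, ...
#' @export
run_s1s2 <- function(multipliers, geometry, drug = NULL,
                     protocol = list(), model = c("surrogate", "detailed"),
                     config = desk_config()) {
  model <- match.arg(model)
  pr <- utils::modifyList(list(n_s1 = 3, cl = 1000, s2_coupling = NULL,
                               s2_offset = 10, amplitude = 2,
                               s2_amplitude = NULL, duration = 3,
                               obs_window = 2000), protocol)
  stopifnot(pr$duration < pr$cl, pr$n_s1 >= 1)
  eff <- effective_cell(multipliers, drug, model, config)
  D_eff <- config$tissue$D_base * multipliers[["m_D"]]
  dt <- snap_dt(min(config$tissue$dt, stability_dt(geometry$dx, D_eff)),
                config$tissue$dt_out)
  g <- geometry
  n <- g$nx * g$ny
  state0 <- matrix(eff$state0, length(eff$state0), n)
  thr <- find_tissue_threshold(eff, D_eff, g$dx, stim_dur = pr$duration)
  amp <- pr$amplitude * thr

  coupling <- pr$s2_coupling
  if (is.null(coupling)) {
    apd <- profile_apd90(eff, config)
    coupling <- apd + pr$s2_offset
  }
  if (coupling <= 0) stop("s2_coupling must be positive")
  s1_starts <- (seq_len(pr$n_s1) - 1) * pr$cl
  s2_time <- s1_starts[pr$n_s1] + coupling
  total <- s2_time + pr$obs_window
  s1_mask <- stim_mask_columns(g$nx, g$ny, 1:2)
  s2_mask <- s2_quadrant_mask(g$nx, g$ny)
  stride <- config$tissue$movie_stride
  movie_start <- s2_time   # the analysis window opens at S2
  run <- cpp_tissue_run(eff$model, eff$cpar, state0, g$nx, g$ny, g$dx,
                        D_eff, dt, total,
                        c(s1_starts, s2_time),
                        rep(pr$duration, pr$n_s1 + 1),
                        c(rep(amp, pr$n_s1),
                          (pr$s2_amplitude %||% pr$amplitude) * thr),
                        c(rep(list(s1_mask), pr$n_s1), list(s2_mask)),
                        integer(0), movie_start, config$tissue$dt_out,
                        as.integer(stride))
  movie <- eff$to_mv(run$movie)
  dim(movie) <- dim(run$movie)
  structure(list(movie = movie, movie_t = run$movie_t,
                 dt_out = config$tissue$dt_out, stride = stride,
                 s2_time = s2_time, coupling = coupling,
                 geometry = g, protocol = pr, D_eff = D_eff,
                 model = model, drug = if (is.null(drug)) "none" else
                   drug$name,
                 blowup = run$blowup, blowup_node = run$blowup_node),
            class = "sim_result")
}

# Steady-ish APD90 of the effective cell model (paced 0D, last beat);
# memoised per parameter vector.
.apd_cache <- new.env(parent = emptyenv())
profile_apd90 <- function(eff, config, n_beats = 6, cl = 1000) {
  key <- paste0(eff$model, ":", paste(signif(eff$cpar, 10), collapse = ","))
  hit <- .apd_cache[[key]]
  if (!is.null(hit)) return(hit)
  amp <- 2 * find_diastolic_threshold(eff$params)
  starts <- (seq_len(n_beats) - 1) * cl
  run <- cpp_cell_run(eff$model, eff$cpar, eff$state0, n_beats * cl,
                      starts, 3, amp, engine_spec(eff$params)$dt_default, 1)
  bio <- compute_biomarkers(list(t = run$t, vm = eff$to_mv(run$vm)),
                            stim_times = starts, n_last = 1)
  .apd_cache[[key]] <- unname(bio["APD90"])
  .apd_cache[[key]]
}

#' @export
print.sim_result <- function(x, ...) {
  cat("S1-S2 simulation (", x$geometry$label, ", ", x$model, ", drug ",
      x$drug, "): S2 at ", round(x$s2_time), " ms, movie ",
      paste(dim(x$movie), collapse = " x "),
      if (x$blowup) " [NUMERICAL FAILURE]" else "", "\n", sep = "")
  invisible(x)
}
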