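#' Latin-hypercube sample of candidate multipliers
#'
#' For each dimension exactly one sample falls in each of the `n`
#' equal-width strata of `range` (the -50%..+100% variation window by
#' default). Bit-reproducible for a given seed.
#'
#' @param n number of candidates (>= 1).
#' @param dims number of varied parameters (default 9).
#' @param seed integer seed.
#' @param range lower/upper multiplier bounds.
#' @return `n x dims` matrix; when `dims == 9`, columns carry the canonical
#'   multiplier names.
#' @export
lhs_sample <- function(n, dims = 9, seed = 1, range = c(0.5, 2)) {
  if (n <= 0) stop("n must be a positive count")
  if (dims <= 0) stop("dims must be a positive count")
  set.seed(seed)
  u <- lhs::randomLHS(n, dims)
  m <- range[1] + u * (range[2] - range[1])
  if (dims == 9) colnames(m) <- MULTIPLIER_NAMES
  m
}

#' Biomarker constraint box
#'
#' Per-biomarker `{min, max}` acceptance bounds with the same units as the
#' biomarkers (ms for durations, mV for potentials).
#'
#' @param ... one named `c(min=, max=)` pair per biomarker
#'   (`APD20, APD50, APD90, APA, RMP, V20`); omitted biomarkers are
#'   unconstrained.
#' @export
biomarker_constraints <- function(...) {
  box <- list(...)
  bad <- setdiff(names(box), BIOMARKER_NAMES)
  if (length(bad)) stop("unknown biomarker(s): ", paste(bad, collapse = ", "))
  for (b in names(box)) {
    stopifnot(all(c("min", "max") %in% names(box[[b]])))
    if (box[[b]]["min"] > box[[b]]["max"])
      stop("constraint min > max for ", b)
  }
  structure(box, class = "biomarker_constraints")
}

#' Read / write a constraint table (CSV: biomarker, min, max)
#' @param path CSV path.
#' @return a [biomarker_constraints()] object.
#' @export
read_constraints <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("biomarker", "min", "max") %in% names(df)))
  do.call(biomarker_constraints,
          setNames(lapply(seq_len(nrow(df)), function(i)
            c(min = df$min[i], max = df$max[i])), df$biomarker))
}

#' @rdname read_constraints
#' @param box a [biomarker_constraints()] object.
#' @export
write_constraints <- function(box, path) {
  df <- data.frame(biomarker = names(box),
                   min = vapply(box, `[[`, 0, "min"),
                   max = vapply(box, `[[`, 0, "max"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

in_constraints <- function(bio, box) {
  for (b in names(box)) {
    v <- bio[[b]]
    if (is.na(v) || v < box[[b]]["min"] || v > box[[b]]["max"]) return(FALSE)
  }
  TRUE
}

#' Action-potential biomarkers from a paced voltage trace
#'
#' Computes per-beat biomarkers on the last `n_last` beats and averages:
#' APDx is the time from the maximum-upstroke instant to x% repolarization
#' of that beat's amplitude; APA = peak - RMP; RMP is the minimum Vm in the
#' diastolic window (up to 100 ms) before the upstroke; V20 is Vm at the
#' time offset APD20 after the upstroke.
#'
#' @param trace a `vm_trace` (or any list with `t`, `vm`).
#' @param stim_times stimulus onset times, ms (defaults to the trace's own).
#' @param n_last number of final beats to average (default 5).
#' @return named numeric of class `ap_biomarkers`.
#' @export
compute_biomarkers <- function(trace, stim_times = NULL, n_last = 5) {
  stim_times <- stim_times %||% trace$stim_times
  stopifnot(!is.null(stim_times), n_last <= length(stim_times))
  t <- trace$t; vm <- trace$vm
  bounds <- c(stim_times, max(t) + 1e-9)
  beats <- seq(length(stim_times) - n_last + 1, length(stim_times))
  per_beat <- lapply(beats, function(k) {
    w <- which(t >= bounds[k] & t < bounds[k + 1])
    if (length(w) < 3) stop("no AP: beat ", k, " window has too few samples")
    dv <- diff(vm[w]) / diff(t[w])
    iu <- which.max(dv)
    t_up <- t[w][iu + 1]                       # first sample after max rise
    dia <- which(t >= bounds[k] - 100 & t <= t_up)
    rmp <- min(vm[dia])
    after <- w[t[w] >= t_up]
    peak <- max(vm[after])
    apa <- peak - rmp
    if (apa < 30) stop("no AP detected in beat ", k,
                       " (amplitude ", round(apa, 1), " mV)")
    ipk <- after[which.max(vm[after])]
    apd <- function(frac) {
      target <- peak - frac * apa
      seg <- seq(ipk, max(w))
      below <- which(vm[seg] <= target)
      if (!length(below)) return(NA_real_)
      i2 <- seg[below[1]]
      if (i2 == seg[1]) return(t[i2] - t_up)
      i1 <- i2 - 1
      tc <- t[i1] + (t[i2] - t[i1]) * (vm[i1] - target) / (vm[i1] - vm[i2])
      tc - t_up
    }
    a20 <- apd(0.2); a50 <- apd(0.5); a90 <- apd(0.9)
    v20 <- if (is.na(a20)) NA_real_ else approx(t[w], vm[w], t_up + a20)$y
    c(APD20 = a20, APD50 = a50, APD90 = a90, APA = apa, RMP = rmp, V20 = v20)
  })
  out <- colMeans(do.call(rbind, per_beat))
  structure(out, class = "ap_biomarkers")
}

# Map the published strip linear index convention (row*256 + column over an
# 8 x 256 row-major grid) onto the engine grid. The strip is simulated
# transposed (propagation axis first, so the stencil loop runs along
# contiguous memory): engine nx = strip length, ny = strip width, and the
# engine's column-major linear index col + row*length coincides with the
# published row*length + column convention.
strip_probe_index <- function(idx, width = 8, len = 256) {
  row <- idx %/% len
  col <- idx %% len
  stopifnot(all(row < width), all(col < len))
  col + row * len           # 0-based engine index on the transposed grid
}

#' Calibrate a candidate population against biomarker constraints
#'
#' Each candidate profile is simulated on a thin paced strip (default
#' 8 x 256 nodes, planar S1 from the left-edge column band, 15 beats at
#' 1 Hz), biomarkers are computed at the probe cells from the last 5 beats,
#' and the candidate is accepted iff *every* probe cell satisfies *every*
#' bound. Candidates whose simulation fails numerically are rejected with
#' reason `"numerical"`; the batch never aborts.
#'
#' @param candidates matrix/data.frame of multipliers (one row per
#'   candidate, the nine canonical columns), e.g. from [lhs_sample()].
#' @param constraints a [biomarker_constraints()] object.
#' @param probe_cells strip linear indices (row*256 + column convention).
#' @param model `"surrogate"` or `"detailed"`.
#' @param config pipeline configuration, see [default_config()]; the
#'   `strip` and `tissue` sections are used.
#' @return data.frame: profile_id, the nine multipliers, `accepted`,
#'   `reason`, and per-probe biomarker columns (`c<idx>_<biomarker>`).
#' @export
calibrate_population <- function(candidates,
                                 constraints = gen_constraint_box(),
                                 probe_cells = c(500, 620, 748),
                                 model = c("surrogate", "detailed"),
                                 config = desk_config()) {
  model <- match.arg(model)
  m <- as.matrix(as.data.frame(candidates)[, MULTIPLIER_NAMES, drop = FALSE])
  sc <- config$strip
  probes0 <- strip_probe_index(probe_cells, sc$nx, sc$ny)
  n <- nrow(m)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    bio <- tryCatch(
      strip_biomarkers(m[i, ], probes0, model, config),
      error = function(e) e)
    if (inherits(bio, "error")) {
      acc <- FALSE
      reason <- if (grepl("not excitable", conditionMessage(bio)))
        "not_excitable" else "numerical"
      bio <- matrix(NA_real_, length(probe_cells), 6,
                    dimnames = list(NULL, BIOMARKER_NAMES))
    } else {
      acc <- all(apply(bio, 1, function(b) in_constraints(as.list(b),
                                                          constraints)))
      reason <- if (acc) "" else "constraints"
    }
    flat <- as.numeric(t(bio))
    names(flat) <- paste0("c", rep(probe_cells, each = 6), "_",
                          rep(BIOMARKER_NAMES, length(probe_cells)))
    rows[[i]] <- c(list(profile_id = sprintf("p%04d", i)),
                   as.list(m[i, ]), list(accepted = acc, reason = reason),
                   as.list(flat))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

# Paced-strip simulation of one candidate; returns probes x biomarkers.
# The strip runs transposed (see strip_probe_index): length first. Because
# the S1 band spans the full strip width, the solution is uniform across
# the width (mirror borders preserve planar symmetry exactly), so the
# engine integrates the width-collapsed cable -- bitwise identical probe
# traces at an eighth of the cost; probe indices reduce to their column.
strip_biomarkers <- function(multipliers, probes0, model, config) {
  sc <- config$strip
  len <- sc$ny; wid <- 1L
  probes0 <- probes0 %% len
  eff <- effective_cell(multipliers, drug = NULL, model, config)
  D_eff <- config$tissue$D_base * multipliers[["m_D"]]
  dt <- snap_dt(min(sc$dt, stability_dt(sc$dx, D_eff)))
  n <- len * wid
  state0 <- matrix(eff$state0, length(eff$state0), n)
  mask <- stim_mask_band(len, wid, seq_len(sc$stim_columns))
  amp <- sc$amp_factor * find_tissue_threshold(eff, D_eff, sc$dx,
                                               stim_dur = sc$stim_dur,
                                               stim_columns = sc$stim_columns)
  starts <- (seq_len(sc$n_beats) - 1) * sc$cl
  total_ms <- sc$n_beats * sc$cl
  run <- cpp_tissue_run(eff$model, eff$cpar, state0, len, wid, sc$dx,
                        D_eff, dt, total_ms,
                        starts, rep(sc$stim_dur, length(starts)),
                        rep(amp, length(starts)),
                        rep(list(mask), length(starts)),
                        probes0, total_ms + 1, 1, 1L)
  if (run$blowup) stop("numerical blowup in strip run")
  bio <- t(vapply(seq_along(probes0), function(q) {
    tr <- list(t = run$probe_t, vm = eff$to_mv(run$probe_vm[, q]))
    unclass(compute_biomarkers(tr, stim_times = starts, n_last = sc$n_last))
  }, numeric(6)))
  colnames(bio) <- BIOMARKER_NAMES
  bio
}

# 0-based node mask for a band of the *first* grid dimension (the
# propagation axis): rows `band` across every column of the second dim.
stim_mask_band <- function(nx, ny, band) {
  as.integer(outer(band - 1, (seq_len(ny) - 1) * nx, `+`))
}

# 0-based node mask for a set of columns (full height): the left-edge
# S1 band of the square planes.
stim_mask_columns <- function(nx, ny, cols) {
  as.integer(outer(seq_len(nx) - 1, (cols - 1) * nx, `+`))
}

# Build the effective cell-model view for one profile (+ optional drug):
# model id, packed C++ params, resting state, mV map, params object.
effective_cell <- function(multipliers, drug, model, config) {
  f <- if (is.null(drug)) c(gNa = 1, gKr = 1, gCaL = 1) else drug_factors(drug)
  if (model == "surrogate") {
    p <- surrogate_effective(config$surrogate_base, multipliers, f)
    es <- engine_spec(p)
  } else {
    prof <- ionic_profile("tmp", multipliers[MULTIPLIER_NAMES])
    p <- scale_profile(apply_caf_remodeling(config$cell_base), prof)
    if (!is.null(drug)) p <- apply_drug(p, drug)
    es <- engine_spec(p)
  }
  c(es, list(params = p))
}
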