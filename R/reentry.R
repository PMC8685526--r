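# Analytic signal via FFT (columns of x are signals). Standard construction:
# zero the negative frequencies, double the positive ones.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  nt <- nrow(x)
  h <- numeric(nt)
  if (nt %% 2 == 0) {
    h[c(1, nt / 2 + 1)] <- 1
    h[2:(nt / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nt + 1) / 2)] <- 2
  }
  X <- mvfft(x)
  mvfft(X * h, inverse = TRUE) / nt
}

#' Phase maps of a voltage movie (Hilbert transform)
#'
#' Per node, the phase is the argument of the analytic signal of the
#' mean-subtracted Vm over the analysis window; no band-pass is applied.
#' Nodes with (numerically) constant signal get `NA` phase and are excluded
#' from singularity detection.
#'
#' @param movie nx x ny x nt voltage array (mV).
#' @param window optional `c(t0, t1)` (ms) selecting the analysis window;
#'   default: the whole movie.
#' @param t frame times (ms); default `0:(nt-1)`.
#' @param chunk nodes per FFT block (memory control).
#' @return list of class `phase_movie`: `phase` (nx x ny x nt', in
#'   (-pi, pi]), `t`.
#' @export
phase_map <- function(movie, window = NULL, t = NULL, chunk = 4000) {
  d <- dim(movie)
  t <- t %||% (seq_len(d[3]) - 1)
  keep <- if (is.null(window)) seq_len(d[3])
          else which(t >= window[1] & t <= window[2])
  nt <- length(keep)
  if (nt < 8) stop("analysis window too short for a meaningful phase")
  n <- d[1] * d[2]
  x <- matrix(movie, n, d[3])[, keep, drop = FALSE]
  x <- t(x)                              # nt x nodes
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  const <- apply(x, 2, function(v) max(abs(v)) < 1e-9)
  ph <- matrix(NA_real_, nt, n)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(n, i0 + chunk - 1)
    ph[, i0:i1] <- Arg(analytic_signal(x[, i0:i1, drop = FALSE]))
  }
  ph[, const] <- NA_real_
  structure(list(phase = array(t(ph), dim = c(d[1], d[2], nt)),
                 t = t[keep]),
            class = "phase_movie")
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # keep the (-pi, pi] convention
  y[y == -pi] <- pi
  y
}

#' Detect phase singularities in one phase frame
#'
#' A singularity is a 2x2 plaquette around which the discrete line integral
#' of wrapped phase differences equals +-2 pi (a point surrounded by all
#' phases 0..2 pi); its charge is the integral's sign. Plaquettes touching
#' an undefined (NA) node are skipped.
#'
#' @param frame nx x ny phase matrix in (-pi, pi].
#' @return data.frame with `x`, `y` (plaquette centers, node units) and
#'   `charge` (+-1); zero rows when none.
#' @export
detect_singularities <- function(frame) {
  nx <- nrow(frame); ny <- ncol(frame)
  a <- frame[-nx, -ny]   # (i, j)
  b <- frame[-1, -ny]    # (i+1, j)
  cc <- frame[-1, -1]    # (i+1, j+1)
  d <- frame[-nx, -1]    # (i, j+1)
  w <- wrap_pi(b - a) + wrap_pi(cc - b) + wrap_pi(d - cc) + wrap_pi(a - d)
  w[is.na(w)] <- 0
  hit <- which(abs(w) > 6, arr.ind = TRUE)  # |w| == 2*pi up to roundoff
  if (!nrow(hit))
    return(data.frame(x = numeric(0), y = numeric(0), charge = integer(0)))
  data.frame(x = hit[, 1] + 0.5, y = hit[, 2] + 0.5,
             charge = as.integer(sign(w[hit])))
}

# Vectorized all-frames singularity detection (same plaquette rule as
# detect_singularities, computed once over the 3D phase array).
detect_singularities_movie <- function(phase_arr) {
  d <- dim(phase_arr)
  a <- phase_arr[-d[1], -d[2], , drop = FALSE]
  b <- phase_arr[-1, -d[2], , drop = FALSE]
  cc <- phase_arr[-1, -1, , drop = FALSE]
  dd <- phase_arr[-d[1], -1, , drop = FALSE]
  w <- wrap_pi(b - a) + wrap_pi(cc - b) + wrap_pi(dd - cc) + wrap_pi(a - dd)
  w[is.na(w)] <- 0
  hit <- which(abs(w) > 6, arr.ind = TRUE)
  out <- rep(list(data.frame(x = numeric(0), y = numeric(0),
                             charge = integer(0))), d[3])
  if (nrow(hit)) {
    sp <- data.frame(x = hit[, 1] + 0.5, y = hit[, 2] + 0.5,
                     charge = as.integer(sign(w[hit])), frame = hit[, 3])
    for (k in unique(sp$frame))
      out[[k]] <- sp[sp$frame == k, c("x", "y", "charge")]
  }
  out
}

#' Link singularities over time into rotor tracks
#'
#' Greedy nearest-neighbor linking of same-charge singularities within
#' `link_radius` nodes per step, tolerating gaps up to `max_gap` frames.
#' Each track's rotation count is the median absolute unwrapped phase
#' advance over a ring of radius 3 nodes around the track centroid, divided
#' by 2 pi; tracks with fewer than `min_rotations` rotations are discarded.
#'
#' @param sp_frames list (one per frame) of singularity data.frames from
#'   [detect_singularities()].
#' @param phases the `phase_movie` the singularities came from.
#' @param dt_out frame period, ms.
#' @param link_radius linking radius, nodes.
#' @param max_gap tolerated missing frames.
#' @param min_rotations survival threshold (>= 1 full rotation).
#' @return list of `rotor_track` objects: `points` (t, x, y, charge),
#'   `rotations`, `chirality`.
#' @export
track_rotors <- function(sp_frames, phases, dt_out = 1, link_radius = 10,
                         max_gap = 2, min_rotations = 1) {
  open <- list()    # each: list(rows = list of c(t, frame, x, y, charge), ...)
  done <- list()
  for (k in seq_along(sp_frames)) {
    sp <- sp_frames[[k]]
    used <- rep(FALSE, nrow(sp))
    # try to extend each open track with the nearest same-charge SP
    for (ti in seq_along(open)) {
      tr <- open[[ti]]
      if (k - tr$last_frame > max_gap + 1) next
      cand <- which(!used & sp$charge == tr$charge)
      if (!length(cand)) next
      last <- tr$rows[[length(tr$rows)]]
      dd <- sqrt((sp$x[cand] - last[3])^2 + (sp$y[cand] - last[4])^2)
      j <- cand[which.min(dd)]
      if (min(dd) <= link_radius) {
        tr$rows[[length(tr$rows) + 1]] <-
          c(phases$t[k], k, sp$x[j], sp$y[j], sp$charge[j])
        tr$last_frame <- k
        open[[ti]] <- tr
        used[j] <- TRUE
      }
    }
    # retire stale tracks
    stale <- vapply(open, function(tr) k - tr$last_frame > max_gap, TRUE)
    done <- c(done, open[stale])
    open <- open[!stale]
    # new tracks for unmatched SPs
    for (j in which(!used)) {
      open[[length(open) + 1]] <-
        list(rows = list(c(phases$t[k], k, sp$x[j], sp$y[j], sp$charge[j])),
             last_frame = k, charge = sp$charge[j])
    }
  }
  done <- c(done, open)
  out <- list()
  for (tr in done) {
    pm <- do.call(rbind, tr$rows)
    tr$points <- data.frame(t = pm[, 1], frame = pm[, 2], x = pm[, 3],
                            y = pm[, 4], charge = as.integer(pm[, 5]))
    rot <- track_rotations(tr, phases)
    if (!is.na(rot) && rot >= min_rotations)
      out[[length(out) + 1]] <-
        structure(list(points = tr$points[, c("t", "x", "y", "charge")],
                       rotations = rot, chirality = tr$charge),
                  class = "rotor_track")
  }
  out
}

# Median |unwrapped phase advance| / 2pi over a ring of radius 3 nodes
# around the track centroid, within the track's lifetime.
track_rotations <- function(tr, phases, radius = 3) {
  d <- dim(phases$phase)
  f0 <- min(tr$points$frame); f1 <- max(tr$points$frame)
  if (f1 - f0 < 2) return(0)
  cx <- mean(tr$points$x); cy <- mean(tr$points$y)
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  rx <- pmin(pmax(round(cx + radius * cos(ang)), 1), d[1])
  ry <- pmin(pmax(round(cy + radius * sin(ang)), 1), d[2])
  pts <- unique(cbind(rx, ry))
  adv <- apply(pts, 1, function(p) {
    th <- phases$phase[p[1], p[2], f0:f1]
    if (any(is.na(th))) return(NA_real_)
    sum(wrap_pi(diff(th)))
  })
  adv <- adv[!is.na(adv)]
  if (!length(adv)) return(NA_real_)
  median(abs(adv)) / (2 * pi)
}

#' Classify the arrhythmia outcome of an S1-S2 run
#'
#' `induced` is true when at least one rotor track survives the
#' full-rotation filter in the post-S2 window; `maintained` additionally
#' requires the tissue to be non-quiescent (any node above `quiescent_mv`)
#' in the final `tail_ms` of the observation window.
#'
#' @param tracks list of surviving `rotor_track`s (from [track_rotors()]).
#' @param movie the analyzed voltage movie (mV).
#' @param movie_t frame times, ms.
#' @param quiescent_mv quiescence threshold, mV.
#' @param tail_ms tail window length, ms.
#' @return list of class `af_outcome`: `induced`, `maintained`, `n_tracks`.
#' @export
classify_outcome <- function(tracks, movie, movie_t,
                             quiescent_mv = -60, tail_ms = 200) {
  induced <- length(tracks) >= 1
  tail_idx <- which(movie_t >= max(movie_t) - tail_ms)
  active <- any(movie[, , tail_idx] > quiescent_mv)
  structure(list(induced = induced,
                 maintained = induced && active,
                 n_tracks = length(tracks)),
            class = "af_outcome")
}

#' Full reentry analysis of an S1-S2 simulation
#'
#' Phase-maps the post-S2 movie, detects and tracks singularities, applies
#' the full-rotation survival filter and the outcome rule.
#'
#' @param sim a `sim_result` from [run_s1s2()].
#' @param link_radius,max_gap,min_rotations see [track_rotors()].
#' @return list: `outcome` (`af_outcome`), `tracks`, `n_sp_frames`.
#' @export
analyze_reentry <- function(sim, link_radius = 10, max_gap = 2,
                            min_rotations = 1) {
  if (sim$blowup)
    return(list(outcome = structure(list(induced = NA, maintained = NA,
                                         n_tracks = NA_integer_),
                                    class = "af_outcome"),
                tracks = list(), n_sp_frames = 0))
  keep <- sim$movie_t >= sim$s2_time
  # singularities can only live while the tissue is active, so the phase
  # window is clipped 50 ms past the last electrically active frame
  active <- apply(sim$movie, 3, max) > -60
  t_act <- if (any(active & keep)) max(sim$movie_t[active & keep])
           else sim$s2_time
  t_end <- min(max(sim$movie_t), t_act + 50)
  t_end <- max(t_end, sim$s2_time + 64)   # floor for a usable analytic signal
  ph <- phase_map(sim$movie, window = c(sim$s2_time, t_end),
                  t = sim$movie_t)
  sps <- detect_singularities_movie(ph$phase)
  # scale the link radius to the movie's spatial stride
  lr <- max(2, link_radius / sim$stride)
  tracks <- track_rotors(sps, ph, dt_out = sim$dt_out, link_radius = lr,
                         max_gap = max_gap, min_rotations = min_rotations)
  outcome <- classify_outcome(tracks, sim$movie[, , keep, drop = FALSE],
                              sim$movie_t[keep])
  list(outcome = outcome, tracks = tracks,
       n_sp_frames = sum(vapply(sps, nrow, 0L) > 0))
}

#' Export singularity tracks as a flat table
#' @param tracks list of `rotor_track`s.
#' @return data.frame (t, x, y, charge, track_id, rotations).
#' @export
tracks_table <- function(tracks) {
  if (!length(tracks))
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      charge = integer(0), track_id = integer(0),
                      rotations = numeric(0)))
  do.call(rbind, lapply(seq_along(tracks), function(i)
    cbind(tracks[[i]]$points, track_id = i,
          rotations = tracks[[i]]$rotations)))
}

#' @export
print.af_outcome <- function(x, ...) {
  cat("AF outcome: induced =", x$induced, "| maintained =", x$maintained,
      "| surviving tracks =", x$n_tracks, "\n")
  invisible(x)
}
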