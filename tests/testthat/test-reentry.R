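test_that("phase of a pure oscillation advances 2 pi per cycle", {
  f <- 4; t <- 0:999
  movie <- array(rep(sin(2 * pi * f * t / 1000), each = 4), c(2, 2, 1000))
  ph <- phase_map(movie, t = t)
  th <- ph$phase[1, 1, ]
  adv <- sum(afpop:::wrap_pi(diff(th)))
  expect_equal(adv / (2 * pi), f * 0.999, tolerance = 0.02)
})

test_that("constant nodes get the undefined marker and never host SPs", {
  t <- 0:499
  movie <- array(0, c(4, 4, 500))
  movie[] <- rep(cos(2 * pi * 5 * t / 1000), each = 16)
  movie[2, 2, ] <- -80                       # one dead node
  ph <- phase_map(movie, t = t)
  expect_true(all(is.na(ph$phase[2, 2, ])))
  expect_true(all(!is.na(ph$phase[1, 1, ])))
  sps <- detect_singularities(ph$phase[, , 100])
  expect_equal(nrow(sps), 0)
})

test_that("a pure angular field winds exactly once around its center", {
  nx <- 41; ny <- 41; x0 <- 20.5; y0 <- 20.5
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  frame <- atan2(ys - y0, xs - x0)
  sp <- detect_singularities(frame)
  expect_equal(nrow(sp), 1)
  expect_lt(max(abs(c(sp$x - x0, sp$y - y0))), 1.5)
  expect_equal(sp$charge, 1L)
  # uniform frame: no singularities
  expect_equal(nrow(detect_singularities(matrix(0.3, 20, 20))), 0)
})

test_that("mirrored spiral pairs carry opposite charges summing to zero", {
  g <- gen_spiral_movie(80, 60, data.frame(x = c(25.5, 55.5), y = c(30.5, 30.5),
                                           chirality = c(1, -1)),
                        f = 4, duration_ms = 700)
  ph <- phase_map(g$movie, t = g$t)
  sp <- detect_singularities(ph$phase[, , 300])
  expect_equal(nrow(sp), 2)
  expect_setequal(sp$charge, c(-1L, 1L))
  expect_equal(sum(sp$charge), 0)
  # positions within 2 nodes of the generator's truth
  for (k in 1:2) {
    d <- sqrt((sp$x - g$truth$x[k])^2 + (sp$y - g$truth$y[k])^2)
    expect_lt(min(d), 2)
  }
})

test_that("SP detection is invariant to a constant voltage offset", {
  g <- gen_spiral_movie(50, 50, data.frame(x = 25.5, y = 25.5, chirality = 1),
                        f = 5, duration_ms = 500)
  ph1 <- phase_map(g$movie, t = g$t)
  ph2 <- phase_map(g$movie + 35, t = g$t)
  expect_equal(detect_singularities(ph1$phase[, , 200]),
               detect_singularities(ph2$phase[, , 200]))
})

test_that("phase recovery matches the generator field away from the core", {
  g <- gen_spiral_movie(60, 60, data.frame(x = 30.5, y = 30.5, chirality = 1),
                        f = 5, duration_ms = 600)
  ph <- phase_map(g$movie, t = g$t)
  k <- 300
  xs <- matrix(seq_len(60), 60, 60)
  ys <- matrix(rep(seq_len(60), each = 60), 60, 60)
  expected <- 2 * pi * g$f * g$t[k] / 1000 -
    atan2(ys - 30.5, xs - 30.5)   # recovered-phase convention
  resid <- afpop:::wrap_pi(ph$phase[, , k] - expected)
  resid <- afpop:::wrap_pi(resid - median(resid))   # free global constant
  core <- sqrt((xs - 30.5)^2 + (ys - 30.5)^2) < 5
  expect_lt(sqrt(mean(resid[!core]^2)), 0.2)
})

test_that("rotor tracking counts rotations and enforces the survival filter", {
  g <- gen_spiral_movie(60, 60, data.frame(x = 30.5, y = 30.5, chirality = 1),
                        f = 5, duration_ms = 600)   # exactly 3 rotations
  ph <- phase_map(g$movie, t = g$t)
  sps <- lapply(seq_along(ph$t), function(k)
    detect_singularities(ph$phase[, , k]))
  trk <- track_rotors(sps, ph)
  expect_length(trk, 1)
  expect_equal(trk[[1]]$rotations, 3, tolerance = 0.05 * 3)
  expect_equal(trk[[1]]$chirality, g$truth$charge[1])
  expect_true(all(diff(trk[[1]]$points$t) > 0))
  # half a rotation does not survive
  gh <- gen_spiral_movie(60, 60, data.frame(x = 30.5, y = 30.5, chirality = 1),
                         f = 5, duration_ms = 100)
  phh <- phase_map(gh$movie, t = gh$t)
  spsh <- lapply(seq_along(phh$t), function(k)
    detect_singularities(phh$phase[, , k]))
  expect_length(track_rotors(spsh, phh), 0)
  # two far-apart singularities stay distinct tracks
  g2 <- gen_spiral_movie(90, 60, data.frame(x = c(20.5, 70.5), y = c(30.5, 30.5),
                                            chirality = c(1, -1)),
                         f = 5, duration_ms = 600)
  ph2 <- phase_map(g2$movie, t = g2$t)
  sps2 <- lapply(seq_along(ph2$t), function(k)
    detect_singularities(ph2$phase[, , k]))
  expect_length(track_rotors(sps2, ph2), 2)
})

test_that("halving the frame rate changes rotation counts by < 5%", {
  g <- gen_spiral_movie(60, 60, data.frame(x = 30.5, y = 30.5, chirality = 1),
                        f = 5, duration_ms = 800)
  rot_at <- function(step) {
    idx <- seq(1, length(g$t), by = step)
    ph <- phase_map(g$movie[, , idx], t = g$t[idx])
    sps <- lapply(seq_along(ph$t), function(k)
      detect_singularities(ph$phase[, , k]))
    trk <- track_rotors(sps, ph, dt_out = step)
    trk[[1]]$rotations
  }
  expect_equal(rot_at(2), rot_at(1), tolerance = 0.05)
})

test_that("the outcome rule distinguishes no-, transient- and sustained reentry", {
  nx <- 20; nt <- 500
  quiet <- array(-80, c(nx, nx, nt))
  active <- quiet; active[5, 5, ] <- 0
  t <- seq_len(nt) - 1
  fake_track <- function(rot) structure(
    list(points = data.frame(t = 0:99, x = 10, y = 10, charge = 1),
         rotations = rot, chirality = 1), class = "rotor_track")
  o0 <- classify_outcome(list(), quiet, t)
  expect_false(o0$induced); expect_false(o0$maintained)
  o1 <- classify_outcome(list(fake_track(5)), active, t)
  expect_true(o1$induced); expect_true(o1$maintained)
  expect_equal(o1$n_tracks, 1L)
  # induced but not maintained: the track existed, the tissue died out
  o2 <- classify_outcome(list(fake_track(1.5)), quiet, t)
  expect_true(o2$induced); expect_false(o2$maintained)
})
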