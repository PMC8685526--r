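test_that("geometries carry the stated node counts and areas", {
  gn <- build_geometry("normal")
  expect_equal(c(gn$nx, gn$ny), c(400L, 400L))
  expect_equal(gn$area, 16)
  expect_equal(gn$dx, sqrt(16) / 400)   # side length / node count
  gd <- build_geometry("dilated")
  expect_equal(c(gd$nx, gd$ny), c(450L, 450L))
  expect_equal(gd$area, 20.25)
  gc <- build_geometry(list(nx = 60, ny = 80, dx = 0.02))
  expect_equal(gc$area, (60 * 0.02) * (80 * 0.02))
  expect_error(build_geometry("huge"), "unknown geometry")
})

test_that("Rush-Larsen is the exact exponential relaxation", {
  expect_equal(rush_larsen_step(0.4, 0.4, 7, 0.5), 0.4)
  expect_lt(abs(rush_larsen_step(0.2, 0.9, 3, 1e-9) - 0.2), 1e-9)
  expect_equal(rush_larsen_step(0, 1, 1, 1), 1 - exp(-1), tolerance = 1e-15)
  expect_error(rush_larsen_step(0.5, 0.5, -1, 0.1), "tau")
  w <- runif(50); wi <- runif(50)
  out <- rush_larsen_step(w, wi, runif(50, 0.5, 50), 0.02)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("step_monodomain refuses unstable steps and keeps invariants", {
  g <- build_geometry(list(nx = 8, ny = 8, dx = 0.02))
  st <- tissue_state(g, surrogate_parameters())
  expect_error(step_monodomain(st, D_eff = 0.006, dt = 1), "stability")
  # uniform field: diffusion term identically zero -> same as isolated cell
  st1 <- step_monodomain(st, D_eff = 0.006, dt = 0.01)
  expect_equal(max(st1$vm) - min(st1$vm), 0)
  # mirror-symmetric stimulus keeps the field mirror-symmetric
  stim <- matrix(0, 8, 8); stim[, 1:2] <- 0.5; stim <- stim + stim[, 8:1]
  s <- tissue_state(g, surrogate_parameters())
  for (k in 1:100) s <- step_monodomain(s, 0.006, 0.01,
                                        i_stim = if (k <= 3) stim else NULL)
  expect_equal(s$vm, s$vm[, 8:1], tolerance = 1e-12)
  expect_gt(max(s$vm), -80)   # the stimulus actually did something
})

test_that("the reference step and the compiled driver agree", {
  g <- build_geometry(list(nx = 8, ny = 10, dx = 0.02))
  sp <- surrogate_parameters()
  eng <- afpop:::engine_spec(sp)
  n <- g$nx * g$ny
  dt <- 0.01
  mask <- afpop:::stim_mask_columns(g$nx, g$ny, 1:2)
  run <- afpop:::cpp_tissue_run(0L, eng$cpar,
                                matrix(eng$state0, 2, n), g$nx, g$ny, g$dx,
                                0.004, dt, 20 * dt, 0, 20 * dt, 0.3,
                                list(mask), integer(0), 0, dt, 1L)
  st <- tissue_state(g, sp)
  stim <- matrix(0, g$nx, g$ny); stim[mask + 1] <- 0.3
  for (k in 1:20) st <- step_monodomain(st, 0.004, dt, i_stim = stim)
  final_cpp <- matrix(run$state_final[1, ], g$nx, g$ny)
  expect_equal(matrix(st$cells[1, ], g$nx, g$ny),
               final_cpp, tolerance = 1e-12)
})

test_that("a resting unstimulated plane stays at rest", {
  sp <- surrogate_parameters()
  eng <- afpop:::engine_spec(sp)
  run <- afpop:::cpp_tissue_run(0L, eng$cpar, matrix(eng$state0, 2, 400),
                                20L, 20L, 0.04, 0.006, 0.025, 1000,
                                numeric(0), numeric(0), numeric(0), list(),
                                integer(0), 0, 1, 1L)
  vm <- eng$to_mv(run$movie)
  expect_lt(max(abs(vm - vm[1, 1, 1])), 0.5)
  # movie contract: 1 ms frames, geometry-shaped
  expect_equal(unique(round(diff(run$movie_t), 9)), 1)
  expect_equal(dim(run$movie)[1:2], c(20L, 20L))
})

test_that("conduction velocity scales as sqrt(D)", {
  sp <- surrogate_parameters()
  cv1 <- measure_cv(sp, 0.003)
  cv2 <- measure_cv(sp, 0.006)
  expect_equal(cv2 / cv1, sqrt(2), tolerance = 0.05)
  expect_error(measure_cv(sp, 0), "propagation failure")
})

test_that("single-cell APD90 is converged in dt", {
  sp <- surrogate_parameters()
  apd <- function(dt) {
    tr <- run_paced_cell(sp, 4, cl = 1000, dt = dt)
    unname(compute_biomarkers(tr, n_last = 1)["APD90"])
  }
  expect_lt(abs(apd(0.02) - apd(0.01)) / apd(0.01), 0.01)
})

test_that("S1-only and post-repolarization S2 runs do not reenter", {
  cfg <- desk_config()
  g <- build_geometry(list(nx = 48, ny = 48, dx = 0.04))
  # S2 amplitude zero: activity extinguishes after the last planar beat
  sim0 <- run_s1s2(all_ones(), g, protocol = list(n_s1 = 1, s2_coupling = 250,
                                                  s2_amplitude = 0,
                                                  obs_window = 900),
                   model = "surrogate", config = cfg)
  an0 <- analyze_reentry(sim0)
  expect_false(an0$outcome$induced)
  expect_equal(an0$outcome$n_tracks, 0L)
  # S2 far beyond APD90: a plain planar beat, no reentry
  sim1 <- run_s1s2(all_ones(), g, protocol = list(n_s1 = 1, s2_coupling = 800,
                                                  obs_window = 900),
                   model = "surrogate", config = cfg)
  an1 <- analyze_reentry(sim1)
  expect_false(an1$outcome$induced)
  # movie timestamps exactly 1 ms apart
  expect_equal(unique(round(diff(sim1$movie_t), 9)), 1)
})

test_that("cross-field S2 in the vulnerable window spawns a phase singularity", {
  cfg <- desk_config()
  sim <- run_s1s2(all_ones(), build_geometry("desk_normal"),
                  protocol = cfg$protocol, model = "surrogate", config = cfg)
  an <- analyze_reentry(sim)
  expect_gt(an$n_sp_frames, 0)
  expect_true(an$outcome$induced)
})
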