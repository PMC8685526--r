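test_that("LHS sampling is stratified, bounded and seed-reproducible", {
  m <- lhs_sample(500, 9, seed = 42)
  expect_equal(dim(m), c(500, 9))
  expect_true(all(m >= 0.5 & m <= 2))
  expect_identical(colnames(m), afpop:::MULTIPLIER_NAMES)
  expect_identical(m, lhs_sample(500, 9, seed = 42))
  expect_false(identical(m, lhs_sample(500, 9, seed = 43)))
  # exactly one sample per stratum, every dimension
  s <- lhs_sample(16, 3, seed = 7)
  for (d in 1:3) {
    occ <- table(cut(s[, d], breaks = seq(0.5, 2, length.out = 17)))
    expect_true(all(occ == 1))
  }
  one <- lhs_sample(1, 4, seed = 1)
  expect_equal(dim(one), c(1, 4))
  expect_true(all(one >= 0.5 & one <= 2))
  expect_error(lhs_sample(0, 3), "positive")
})

test_that("biomarkers match the closed-form piecewise-linear waveform", {
  # rest -80, instant jump to +20, linear return over 300 ms
  g <- gen_ap_trace(rest = -80, peak = 20, apd90 = 270, shape = "linear")
  bio <- compute_biomarkers(g, n_last = 1)
  expect_equal(unname(bio["APA"]), 100, tolerance = 1e-9)
  expect_lt(abs(bio["APD90"] - 270), 1.01)   # one output sample
  expect_lt(abs(bio["APD50"] - 150), 1.01)
  expect_lt(abs(bio["APD20"] - 60), 1.01)
  expect_equal(unname(bio["RMP"]), -80)
  # averaging two identical beats equals one
  g2 <- gen_ap_trace(n_beats = 2, cl = 600)
  b1 <- compute_biomarkers(g2, n_last = 1)
  b2 <- compute_biomarkers(g2, n_last = 2)
  expect_equal(unclass(b1), unclass(b2), tolerance = 1e-9)
})

test_that("a flat trace raises a 'no AP' error naming the beat", {
  flat <- list(t = 0:1000, vm = rep(-80, 1001))
  expect_error(compute_biomarkers(flat, stim_times = 100, n_last = 1),
               "no AP")
})

test_that("probe-cell convention places 500/620/748 in strip rows 1-2", {
  idx <- c(500, 620, 748)
  rows <- idx %/% 256
  cols <- idx %% 256
  expect_true(all(rows %in% 1:2))
  expect_true(all(cols >= 2))   # away from the stimulated edge band
  expect_equal(afpop:::strip_probe_index(idx), cols + rows * 256)
})

test_that("calibration accepts by constraint box and survives failures", {
  cfg <- tiny_config()
  cand <- rbind(all_ones(),
                c(1.2, 1, 1.1, 0.9, 1, 1, 1, 1, 1.2),
                c(2, 2, 2, 0.5, 0.5, 2, 1, 1, 2),    # extreme, short APD
                c(0.5, 1, 2, 0.8, 2, 1, 1, 1, 0.6))  # weakly excitable
  colnames(cand) <- afpop:::MULTIPLIER_NAMES
  free <- biomarker_constraints()   # unconstrained
  pop_free <- calibrate_population(cand, free, model = "surrogate",
                                   config = cfg)
  expect_equal(nrow(pop_free), 4)
  ok <- pop_free$reason %in% c("", "constraints")
  expect_true(all(pop_free$accepted[ok]))   # every numerically-sane row passes
  # impossible box rejects everything
  impossible <- biomarker_constraints(APD90 = c(min = 4000, max = 5000))
  pop_no <- calibrate_population(cand, impossible, model = "surrogate",
                                 config = cfg)
  expect_false(any(pop_no$accepted))
  # the default chronic-AF box contains the all-ones surrogate profile
  pop_def <- calibrate_population(cand[1, , drop = FALSE],
                                  gen_constraint_box(),
                                  model = "surrogate", config = cfg)
  expect_true(pop_def$accepted[1])
  expect_equal(pop_def$profile_id, "p0001")   # order preserved
})

test_that("acceptance is monotone under widening constraints", {
  cfg <- tiny_config()
  cand <- lhs_sample(8, 9, seed = 5)
  narrow <- biomarker_constraints(APD90 = c(min = 180, max = 230),
                                  APA = c(min = 95, max = 120))
  wide <- biomarker_constraints(APD90 = c(min = 150, max = 280),
                                APA = c(min = 85, max = 130))
  acc_n <- calibrate_population(cand, narrow, model = "surrogate",
                                config = cfg)$accepted
  acc_w <- calibrate_population(cand, wide, model = "surrogate",
                                config = cfg)$accepted
  expect_true(all(acc_w[acc_n]))
})

test_that("constraint CSV round-trips through read/write", {
  box <- gen_constraint_box()
  tmp <- tempfile(fileext = ".csv")
  write_constraints(box, tmp)
  box2 <- read_constraints(tmp)
  expect_equal(unclass(box2), unclass(box), tolerance = 1e-12)
  expect_error(biomarker_constraints(APD90 = c(min = 10, max = 5)),
               "min > max")
})
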