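test_that("chronic-AF remodeling rescales exactly the listed currents", {
  base <- baseline_parameters()
  caf <- apply_caf_remodeling(base)
  expect_equal(caf$gCaL, base$gCaL * 0.45)
  expect_equal(caf$gto, base$gto * 0.38)
  expect_equal(caf$gKur, base$gKur * 0.62)
  expect_equal(caf$gK1, base$gK1 * 1.62)
  expect_equal(caf$gNCX_scale, 1.50)
  expect_equal(caf$serca_scale, 0.84)
  expect_equal(caf$plb_scale, 1.18)
  expect_equal(caf$sln_scale, 0.60)
  # untouched fields
  expect_equal(caf$Na_o, base$Na_o)
  expect_equal(caf$gNa, base$gNa)
  expect_equal(caf$gKCa, base$gKCa)  # SK is not in the remodeling set
  bad <- base; bad$gNa <- -1
  expect_error(apply_caf_remodeling(bad), "invalid parameter")
})

test_that("profile scaling is multiplicative, identity at all-ones, and range-checked", {
  base <- apply_caf_remodeling(baseline_parameters())
  id <- scale_profile(base, ionic_profile("id"))
  expect_equal(unclass(id)[names(base)], unclass(base)[names(base)])
  expect_equal(attr(id, "m_D"), 1)
  # deterministic / bit-stable
  id2 <- scale_profile(apply_caf_remodeling(baseline_parameters()),
                       ionic_profile("id"))
  expect_identical(unlist(unclass(id)), unlist(unclass(id2)))
  half <- scale_profile(base, ionic_profile("h", c(m_gNa = 0.5)))
  expect_equal(half$gNa, base$gNa * 0.5)
  thr <- scale_profile(base, ionic_profile("t", c(m_gK1 = 1.0912)))
  expect_equal(thr$gK1, base$gK1 * 1.0912)
  expect_error(ionic_profile("bad", c(m_gNa = 2.5)), "out of range")
  expect_error(ionic_profile("bad", c(m_foo = 1)), "unknown multiplier")
})

test_that("the resting cell drifts below tolerance after equilibration", {
  base <- baseline_parameters()
  eng <- afpop:::engine_spec(base)
  run <- afpop:::cpp_cell_run(1L, eng$cpar, eng$state0, 60000, numeric(0),
                              3, 0, 0.02, 1)
  # drift of Vm over the last second, in mV/ms
  tail_v <- utils::tail(run$vm, 1000)
  drift <- abs(diff(range(tail_v))) / 1000
  expect_lt(drift, 0.01)
  # gate fixed point: w == w_inf leaves the gate unchanged
  rhs <- cell_derivatives(run$state_final, base, 0)
  st <- run$state_final
  st[2:16] <- rhs$winf
  rhs2 <- cell_derivatives(st, base, 0)
  expect_equal(rush_larsen_step(rhs2$winf, rhs2$winf, rhs2$wtau, 0.02),
               rhs2$winf)
  # depolarizing stimulus sign convention
  expect_gt(cell_derivatives(run$state_final, base, 30)$dvdt,
            cell_derivatives(run$state_final, base, 0)$dvdt)
  expect_gt(cell_derivatives(run$state_final, base, 30)$dvdt, 0)
})

test_that("cell_derivatives rejects non-finite states naming the variable", {
  st <- crn_initial_state()
  st["Cai"] <- NaN
  expect_error(cell_derivatives(st, baseline_parameters()), "Cai")
})

test_that("paced runs: beat count, quiescence at zero amplitude, gates in [0,1]", {
  base <- apply_caf_remodeling(baseline_parameters())
  tr <- run_paced_cell(base, n_beats = 15, cl = 1000)
  # 15 upstrokes: count threshold crossings of -40 mV from below
  up <- sum(diff(tr$vm > -40) == 1)
  expect_equal(up, 15)
  expect_false(tr$repol_failure)
  expect_true(all(tr$gate_range[, "min"] >= 0))
  expect_true(all(tr$gate_range[, "max"] <= 1))
  quiet <- run_paced_cell(base, n_beats = 3, cl = 1000,
                          stim = list(duration = 3, amplitude = 0))
  expect_lt(max(quiet$vm) - min(quiet$vm), 5)
})

test_that("diastolic threshold from bisection separates capture from failure", {
  base <- apply_caf_remodeling(baseline_parameters())
  thr <- afpop:::find_diastolic_threshold(base)
  fire <- run_paced_cell(base, 1, stim = list(duration = 3,
                                              amplitude = 2 * thr))
  fail <- run_paced_cell(base, 1, stim = list(duration = 3,
                                              amplitude = 0.5 * thr))
  expect_gt(max(fire$vm), -20)
  expect_lt(max(fail$vm), -40)
})

test_that("refractoriness: an early S2 is blocked, a late one captures", {
  base <- apply_caf_remodeling(baseline_parameters())
  eng <- afpop:::engine_spec(base)
  amp <- 2 * afpop:::find_diastolic_threshold(base)
  early <- afpop:::cpp_cell_run(1L, eng$cpar, eng$state0, 800,
                                c(0, 10), 3, amp, 0.02, 1)
  late <- afpop:::cpp_cell_run(1L, eng$cpar, eng$state0, 800,
                               c(0, 600), 3, amp, 0.02, 1)
  expect_equal(sum(diff(early$vm > -40) == 1), 1)
  expect_equal(sum(diff(late$vm > -40) == 1), 2)
})

test_that("APD90 responds monotonically to gCaL and gK1", {
  base <- apply_caf_remodeling(baseline_parameters())
  apd <- function(mult) {
    p <- scale_profile(base, ionic_profile("x", mult))
    bio <- compute_biomarkers(run_paced_cell(p, 5, cl = 1000), n_last = 1)
    unname(bio["APD90"])
  }
  a_cal <- vapply(c(0.5, 1, 2), function(m) apd(c(m_gCaL = m)), 0)
  expect_true(all(diff(a_cal) > 0))     # more ICaL -> longer APD
  a_k1 <- vapply(c(0.5, 1, 2), function(m) apd(c(m_gK1 = m)), 0)
  expect_true(all(diff(a_k1) < 0))      # more IK1 -> shorter APD
})
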