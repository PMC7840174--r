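test_that("identical params, epochs and seed give a bit-identical trace", {
  p <- synth_params(amp_pA = 10, noise_sd_pA = 2, seed = 7)
  a <- simulate_trace(p, std_epoch())
  b <- simulate_trace(p, std_epoch())
  expect_identical(a$current, b$current)
  expect_identical(a$time, b$time)
  p2 <- p; p2$seed <- 8
  expect_false(identical(simulate_trace(p2, std_epoch())$current, a$current))
})

test_that("measured plateau effect matches the closed-form kernel mean", {
  # drug window = last 8 bins of [300, 660) -> 120-360 s after onset
  expected <- 15 * kernel_window_mean(120, 360, tau_on = 30)
  p <- synth_params(amp_pA = 15, noise_sd_pA = 0.05, seed = 21)
  tr <- simulate_trace(p, std_epoch())
  call <- classify_trace(tr)[[1]]
  expect_equal(call$effect_pA, expected, tolerance = 0.01)
  expect_lt(abs(call$effect_pA - 15), 1)
  expect_identical(call$direction, "outward")
})

test_that("AR(1) noise keeps the stationary marginal SD", {
  p <- synth_params(amp_pA = 0, noise_sd_pA = 2, ar1 = 0.8, seed = 5)
  tr <- simulate_trace(p, std_epoch(), duration_s = 6000)
  expect_equal(sd(tr$current), 2, tolerance = 0.1)
})

test_that("degenerate mixture p_none = 1 yields only non-responders", {
  spec <- cohort_spec(n_cells = 10, p_outward = 0, p_inward = 0, p_none = 1,
                      seed = 3)
  coh <- simulate_cohort(spec, std_epoch(), duration_s = 720)
  expect_true(all(coh$truth$class == "none"))
  expect_true(all(coh$truth$true_amp_pA == 0))
})

test_that("second-application amplitude follows the desensitization rule", {
  proto <- rbind(std_epoch(100), std_epoch(1000, t_on = 1560, t_off = 1920))
  spec <- cohort_spec(n_cells = 5, p_outward = 1, p_inward = 0, p_none = 0,
                      desens_threshold_nM = 100, desens_frac = 0.14, seed = 9)
  coh <- simulate_cohort(spec, proto, duration_s = 2220)
  for (id in unique(coh$truth$cell_id)) {
    tt <- coh$truth[coh$truth$cell_id == id, ]
    base_amp <- tt$true_amp_pA[1] / hill_factor(100, spec$ec50_nM, spec$hill_n)
    expect_equal(tt$true_amp_pA[2],
                 0.14 * base_amp * hill_factor(1000, spec$ec50_nM, spec$hill_n))
  }
  # below threshold, no desensitization
  proto10 <- rbind(std_epoch(10), std_epoch(10, t_on = 1560, t_off = 1920))
  coh10 <- simulate_cohort(cohort_spec(n_cells = 3, p_outward = 1,
                                       p_inward = 0, p_none = 0, seed = 9),
                           proto10, duration_s = 2220)
  expect_equal(coh10$truth$true_amp_pA[coh10$truth$epoch == 2],
               coh10$truth$true_amp_pA[coh10$truth$epoch == 1])
})

test_that("cohort class counts stay within binomial bounds", {
  spec <- cohort_spec(n_cells = 86, seed = 17)
  coh <- simulate_cohort(spec, std_epoch(10), duration_s = 720)
  per_cell <- coh$truth[coh$truth$epoch == 1, ]
  n_out <- sum(per_cell$class == "outward")
  n_in <- sum(per_cell$class == "inward")
  # 95% binomial bounds computed from the spec probabilities
  expect_gte(n_out, qbinom(0.025, 86, 44 / 86))
  expect_lte(n_out, qbinom(0.975, 86, 44 / 86))
  expect_gte(n_in, qbinom(0.025, 86, 15 / 86))
  expect_lte(n_in, qbinom(0.975, 86, 15 / 86))
  # determinism
  coh2 <- simulate_cohort(cohort_spec(n_cells = 86, seed = 17),
                          std_epoch(10), duration_s = 720)
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$traces[[5]]$current, coh2$traces[[5]]$current)
})

test_that("mean measured plateau converges to amp_mean x Hill factor", {
  spec <- cohort_spec(n_cells = 500, p_outward = 1, p_inward = 0, p_none = 0,
                      amp_mean_out = 20, amp_sd_out = 3, seed = 23)
  coh <- simulate_cohort(spec, std_epoch(10), duration_s = 720)
  effects <- vapply(coh$traces,
                    function(tr) classify_trace(tr)[[1]]$effect_pA,
                    numeric(1))
  expected <- 20 * hill_factor(10, spec$ec50_nM, spec$hill_n) *
    kernel_window_mean(120, 360, 30)
  expect_lt(abs(mean(effects) - expected),
            3 * sd(effects) / sqrt(length(effects)))
})

test_that("invalid cohort probabilities are rejected", {
  expect_error(cohort_spec(p_outward = 0.5, p_inward = 0.5, p_none = 0.1),
               class = "spec_error")
  expect_error(synth_params(recovery_frac = 1.2), class = "spec_error")
  expect_error(synth_params(tau_on_s = 0), class = "spec_error")
})

test_that("overlapping epochs are rejected by the simulator", {
  p <- synth_params(seed = 1)
  bad <- rbind(std_epoch(10, 100, 400), std_epoch(10, 300, 600))
  expect_error(simulate_trace(p, bad), class = "epoch_error")
})
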