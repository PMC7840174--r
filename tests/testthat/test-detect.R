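test_that("bin_trace means, partial-bin rule, and ramp closed form", {
  hz <- 10
  ep <- std_epoch(10, 30, 300)

  # constant 40 pA trace, 600 s -> 20 bins of 40
  t <- (seq_len(600 * hz) - 1) / hz
  b <- bin_trace(ihold_trace("c", t, rep(40, length(t)), epochs = ep), 30)
  expect_length(b$bin_means, 20)
  expect_true(all(b$bin_means == 40))

  # 615 s -> trailing 15 s dropped
  t2 <- (seq_len(615 * hz) - 1) / hz
  b2 <- bin_trace(ihold_trace("c", t2, rep(40, length(t2)), epochs = ep), 30)
  expect_length(b2$bin_means, 20)

  # linear ramp: bin mean = ramp at the mean sample time of the bin
  cur <- 40 + 0.02 * t
  b3 <- bin_trace(ihold_trace("c", t, cur, epochs = ep), 30)
  starts <- (0:19) * 30
  expected <- 40 + 0.02 * (starts + (30 - 1 / hz) / 2)
  expect_equal(b3$bin_means, expected)

  # too short for two bins
  expect_error(bin_trace(ihold_trace("c", (0:299) / 10, rnorm(300, 40),
                                     epochs = std_epoch(10, 1, 20)), 30),
               class = "window_error")
})

test_that("classify_response is sign-symmetric and guards degenerate input", {
  p <- synth_params(amp_pA = 12, noise_sd_pA = 2, seed = 31)
  tr <- simulate_trace(p, std_epoch())
  call <- classify_trace(tr)[[1]]
  neg <- tr
  neg$current <- -neg$current
  call_neg <- classify_trace(neg)[[1]]
  expect_equal(call_neg$effect_pA, -call$effect_pA)
  expect_equal(call_neg$p_value, call$p_value)
  expect_identical(call$direction, "outward")
  expect_identical(call_neg$direction, "inward")

  # constant trace: zero variance in both windows, equal means
  flat <- ihold_trace("f", (0:9599) / 10, rep(40, 9600), epochs = std_epoch())
  fc <- classify_trace(flat)[[1]]
  expect_identical(fc$direction, "none")
  expect_equal(fc$p_value, 1)
})

test_that("short pressure epochs are flagged truncated, short baselines error", {
  ep <- std_epoch(100, t_on = 300, t_off = 420, delivery = "pressure")
  p <- synth_params(amp_pA = 10, noise_sd_pA = 1, tau_on_s = 10, seed = 41)
  tr <- simulate_trace(p, ep, duration_s = 720)
  call <- classify_trace(tr)[[1]]
  expect_true(call$truncated)
  expect_identical(diff(call$drug_window) + 1L, 4L)  # 2 min = 4 bins
  expect_identical(call$direction, "outward")

  early <- drug_epoch("N/OFQ", 10, 60, 420)   # only 2 baseline bins
  tr2 <- simulate_trace(p, early, duration_s = 720)
  expect_error(classify_response(bin_trace(tr2), 1), class = "window_error")

  # secondary magnitude criterion suppresses small significant effects
  small <- synth_params(amp_pA = 1, noise_sd_pA = 0.05, seed = 43)
  tr3 <- simulate_trace(small, std_epoch())
  cfg <- detection_config(min_effect_pA = 1.5)
  expect_identical(classify_response(bin_trace(tr3), 1, cfg)$direction, "none")
  expect_identical(classify_response(bin_trace(tr3), 1)$direction, "outward")
})

test_that("sliding_window on a noise-free step gives one run over the epoch", {
  sw <- sliding_window(bin_trace(step_trace(15)), 1)
  expect_true(any(sw$significant))
  runs <- rle(sw$significant)
  expect_identical(sum(runs$values), 1L)           # a single contiguous run
  expect_gte(sw$max_consecutive, 8)
  sig <- sw$window_starts[sw$significant]
  expect_true(any(sig >= sw$onset_bin & sig < sw$onset_bin + 12))
  # self-comparison window (baseline vs itself) is never significant
  self_idx <- which(sw$window_starts == sw$baseline_start)
  expect_equal(sw$raw_p[self_idx], 1)
  # Bonferroni invariant
  expect_equal(sw$corrected_p,
               pmin(1, sw$raw_p * length(sw$raw_p)))
})

test_that("max consecutive run matches a brute-force scan", {
  brute <- function(v) {
    best <- run <- 0L
    for (x in v) {
      run <- if (x) run + 1L else 0L
      best <- max(best, run)
    }
    best
  }
  set.seed(59)
  for (i in 1:50) {
    v <- runif(sample(1:40, 1)) < 0.4
    expect_identical(clampresp:::max_true_run(v), brute(v))
  }
})

test_that("window_histogram aggregates onset-aligned proportions", {
  expect_identical(nrow(window_histogram(list())), 0L)
  mk <- function(sig, onset) structure(
    list(cell_id = "x", window_starts = seq_along(sig), significant = sig,
         onset_bin = onset), class = "sliding_window_result")
  one <- window_histogram(list(mk(rep(TRUE, 4), 2L)))
  expect_true(all(one$prop_significant == 1))
  two <- window_histogram(list(mk(c(TRUE, FALSE, FALSE, FALSE), 1L),
                               mk(c(FALSE, TRUE, FALSE, FALSE), 1L)))
  expect_equal(two$prop_significant, c(0.5, 0.5, 0, 0))
  # step-responder cohort: proportions rise after onset, fall after offset
  swr <- lapply(1:4, function(i) sliding_window(bin_trace(step_trace(15)), 1))
  h <- window_histogram(swr)
  during <- h$offset_bins >= 0 & h$offset_bins <= 4
  before <- h$offset_bins < -8
  expect_true(all(h$prop_significant[during] == 1))
  expect_true(all(h$prop_significant[before] == 0))
})

test_that("desensitization_ratio is the signed effect ratio", {
  mk_call <- function(effect, id = "c1") structure(
    list(cell_id = id, effect_pA = effect), class = "response_call")
  expect_equal(desensitization_ratio(mk_call(10), mk_call(10)), 1)
  expect_equal(desensitization_ratio(mk_call(10), mk_call(0)), 0)
  expect_equal(desensitization_ratio(mk_call(-10), mk_call(-1.4)), 0.14)
  expect_error(desensitization_ratio(mk_call(0), mk_call(5)),
               class = "domain_error")
  expect_error(desensitization_ratio(mk_call(10, "a"), mk_call(5, "b")),
               class = "domain_error")
})

test_that("summarize_cohort counts, percentages and grouping", {
  s <- summarize_cohort(calls_fixture(44, 16, 26))
  expect_identical(s$n_total, 86L)
  expect_identical(s$n_responsive, 60L)
  expect_equal(s$pct_responsive, 70)
  expect_equal(s$pct_outward_responsive, 73)
  expect_equal(s$pct_outward_all, 51)
  expect_equal(s$mean_effect_outward, 10)
  expect_equal(s$mean_effect_inward, -10)

  # empty input -> zero counts, NA percentages
  empty <- summarize_cohort(list())
  expect_identical(empty$n_total, 0L)
  expect_true(is.na(empty$pct_responsive))

  # grouped by projection
  both <- rbind(calls_fixture(8, 0, 4, projection = "mPFC"),
                calls_fixture(1, 4, 1, projection = "pACC"))
  g <- summarize_cohort(both, keys = "projection")
  expect_identical(nrow(g), 2L)
  expect_equal(g$pct_outward_all[g$projection == "mPFC"], 67)
  expect_equal(g$pct_inward_all[g$projection == "pACC"], 67)
})
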