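test_that("onset detection follows the sustained-run criterion", {
  mk <- function(p) data.frame(bin_start_ms = seq(4000, by = 200,
                                                  length.out = length(p)),
                               p = p)
  cfg <- dpa_config()
  # significant everywhere: onset at span start
  expect_equal(detect_onset(mk(rep(0.01, 10)), cfg)$onset_ms, 4000)
  # [ns ns sig sig sig ns ...] -> 4400
  expect_equal(detect_onset(mk(c(.5, .5, .01, .01, .01, .5, .5)), cfg)$onset_ms,
               4400)
  # an isolated early significant bin does not qualify
  expect_equal(detect_onset(mk(c(.01, .5, .01, .01, .01)), cfg)$onset_ms, 4400)
  # no run: missing onset
  out <- detect_onset(mk(c(.01, .01, .5, .01, .01, .5)), cfg)
  expect_true(is.na(out$onset_ms))
  # NA p-values never count as significant
  expect_true(is.na(detect_onset(mk(c(.01, NA, .01, .01, NA, .01)),
                                 cfg)$onset_ms))
  # k is configurable
  expect_equal(detect_onset(mk(c(.5, .01, .01, .5)),
                            dpa_config(k_consecutive = 2))$onset_ms, 4200)
})

test_that("per-bin WLS matches an independent lm() oracle", {
  # 4 participants, counts (factual, illusory) out of N = 20
  yf <- c(15, 16, 14, 17)
  binned <- data.frame(participant_id = sprintf("P%d", 1:4),
                       bin_start_ms = 4000, y_factual = yf,
                       y_illusory = 20 - yf)
  got <- fit_bin_models(binned, dpa_config())
  # oracle: explicit weighted regression on the 8 elog points
  ef <- empirical_logit(yf, 20)
  ei <- empirical_logit(20 - yf, 20)
  df <- data.frame(elog = c(ef$elog, ei$elog),
                   target = rep(c("factual", "illusory"), each = 4),
                   w = c(ef$weight, ei$weight))
  or <- summary(lm(elog ~ target, data = df, weights = w))$coefficients
  expect_equal(got$estimate, -unname(or["targetillusory", "Estimate"]),
               tolerance = 1e-10)
  expect_equal(got$se, unname(or["targetillusory", "Std. Error"]),
               tolerance = 1e-10)
  expect_equal(abs(got$t), abs(unname(or["targetillusory", "t value"])),
               tolerance = 1e-10)
  expect_equal(got$df, 6)
})

test_that("identical factual and illusory counts give a null bin", {
  binned <- data.frame(participant_id = sprintf("P%d", 1:5),
                       bin_start_ms = 4000, y_factual = 8, y_illusory = 8)
  got <- fit_bin_models(binned, dpa_config())
  expect_equal(got$estimate, 0)
  expect_gte(got$p, 0.5)
})

test_that("bins with fewer than two participants are untestable", {
  binned <- data.frame(participant_id = "P1", bin_start_ms = c(4000, 4200),
                       y_factual = c(9, 9), y_illusory = c(1, 1))
  got <- fit_bin_models(binned, dpa_config())
  expect_true(all(got$untestable))
  expect_true(all(is.na(got$p)))
})

test_that("zero between-trial variance collapses the bootstrap distribution", {
  ds <- deterministic_dataset(onset = 5000)
  fit <- dpa(ds, config = dpa_config(n_boot = 40, seed = 3))
  b <- fit$fits$negative$boot
  expect_equal(b$n_missing, 0L)
  expect_equal(unique(b$onsets), 5000)
  expect_equal(b$mean_ms, fit$fits$negative$point_onset_ms)
  expect_equal(b$ci_high_ms - b$ci_low_ms, 0)
})

test_that("bootstrap is reproducible under a fixed seed and stable across seeds", {
  ds <- simulate_gaze(sim_config(conditions = "negative",
                                 true_onset_ms = c(negative = 5000),
                                 asymptote = 0.45, seed = 8))
  f1 <- dpa(ds, config = dpa_config(n_boot = 100, seed = 11))
  f2 <- dpa(ds, config = dpa_config(n_boot = 100, seed = 11))
  expect_identical(f1$fits$negative$boot$onsets, f2$fits$negative$boot$onsets)
  f3 <- dpa(ds, config = dpa_config(n_boot = 100, seed = 12))
  expect_false(identical(f1$fits$negative$boot$onsets,
                         f3$fits$negative$boot$onsets))
  # on a strong-effect dataset, means differ by less than one bin
  expect_lt(abs(f1$fits$negative$boot$mean_ms - f3$fits$negative$boot$mean_ms),
            200)
})

test_that("alternative resampling units run and stay on the bin grid", {
  ds <- simulate_gaze(sim_config(conditions = "negative",
                                 true_onset_ms = c(negative = 5000),
                                 n_participants = 8,
                                 n_items_per_condition = 5, seed = 8))
  for (unit in c("participants", "bin_samples")) {
    fit <- dpa(ds, config = dpa_config(n_boot = 30, seed = 5,
                                       resample_unit = unit))
    on <- fit$fits$negative$boot$onsets
    on <- on[!is.na(on)]
    expect_true(all(on %in% seq(4000, 7800, by = 200)), info = unit)
  }
})

test_that("difference of a distribution with itself is identically zero", {
  a <- make_boot(rep(c(4800, 5000, 5200), 20), "a")
  d <- dpa_difference(a, a)
  expect_true(all(d$diffs == 0))
  expect_equal(d$mean_ms, 0)
  expect_false(d$excludes_zero)
})

test_that("a constant shift moves the whole difference distribution", {
  b <- make_boot(rep(c(4800, 5000), 30), "b")
  a <- make_boot(b$onsets + 400, "a")
  d <- dpa_difference(a, b)
  expect_equal(d$mean_ms, 400)
  expect_equal(c(d$ci_low_ms, d$ci_high_ms), c(400, 400))
  expect_true(d$excludes_zero)
})

test_that("missing onsets drop pairs, and fully-missing differences stay undefined", {
  a <- make_boot(c(5000, NA, 5200, 5400), "a")
  b <- make_boot(c(4800, 4800, NA, 5000), "b")
  d <- dpa_difference(a, b)
  expect_equal(d$n_pairs, 2L)
  expect_equal(d$n_dropped, 2L)
  expect_equal(d$diffs, c(200, 400))
  e <- suppressWarnings(dpa_difference(make_boot(rep(NA_real_, 4)),
                                       make_boot(rep(NA_real_, 4))))
  expect_true(is.na(e$mean_ms))
  expect_false(isTRUE(e$excludes_zero))
})

test_that("unequal bootstrap sizes are refused", {
  expect_error(dpa_difference(make_boot(rep(5000, 10)),
                              make_boot(rep(5000, 20))),
               "n_boot")
})

test_that("between-language differences recover a simulated lag with L1 - L2 direction", {
  cfg_l1 <- sim_config(conditions = "negative",
                       true_onset_ms = c(negative = 6300), language = "L1",
                       seed = 15)
  cfg_l2 <- sim_config(conditions = "negative",
                       true_onset_ms = c(negative = 5100), language = "L2",
                       seed = 16)
  dcfg <- dpa_config(n_boot = 200, seed = 17)
  f1 <- dpa(simulate_gaze(cfg_l1), config = dcfg)
  f2 <- dpa(simulate_gaze(cfg_l2), config = dpa_config(n_boot = 200, seed = 18))
  d <- between_language_difference(f1, f2, "negative")
  # positive mean = slower divergence in the first (L1) dataset
  expect_gt(d$mean_ms, 0)
  expect_equal(d$mean_ms, 1200, tolerance = 200 / 1200)
  expect_match(d$label, "^L1 negative - L2 negative$")
  # identical inputs give a zero-mean difference
  same <- between_language_difference(f1, f1, "negative")
  expect_equal(same$mean_ms, 0)
})

test_that("condition contrasts cover all pairs and order by recovered onset", {
  ds <- small_sim(seed = 18)
  fit <- dpa(ds, config = quick_dpa(n_boot = 40))
  cc <- condition_contrasts(fit)
  expect_length(cc, 3L)
  for (d in cc) {
    if (!is.na(d$mean_ms)) expect_gte(d$mean_ms, 0)
  }
})

test_that("fit and summary expose a coherent surface", {
  ds <- small_sim(seed = 19)
  fit <- dpa(ds, config = quick_dpa(n_boot = 20))
  s <- summary(fit)
  expect_setequal(s$condition, c("positive", "negative", "nobody"))
  expect_true(all(is.na(s$mean_ms) | (s$ci_low_ms <= s$mean_ms &
                                        s$mean_ms <= s$ci_high_ms)))
  ct <- coef(fit)
  expect_equal(nrow(ct), 3 * 20)   # 3 conditions x 20 bins
  expect_output(print(fit), "Divergence point analysis")
  expect_error(onset_distribution(fit, "nope"), "no such condition")
})
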