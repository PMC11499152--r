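test_that("window descriptives reduce constructed cells correctly", {
  props <- data.frame(participant_id = c("P1", "P2", "P3"),
                      trial_id = 1:3, condition = "negative",
                      window = "anticipation", role = "factual",
                      pct = c(50, 60, 70))
  d <- window_descriptives(props)
  row <- d[d$aggregation == "trials", ]
  expect_equal(row$mean_pct, 60)
  expect_equal(row$sd_pct, 10)
  expect_equal(row$n, 3L)
  # a single-trial cell has SD 0 (not NA)
  one <- window_descriptives(props[1, ])
  expect_equal(one$sd_pct, c(0, 0))
})

test_that("descriptives are invariant to trial order and cover both aggregations", {
  ds <- small_sim(seed = 4)
  pr <- suppressMessages(proportions_by_window(ds))
  d1 <- window_descriptives(pr)
  d2 <- window_descriptives(pr[rev(seq_len(nrow(pr))), ])
  expect_equal(d1, d2)
  expect_setequal(unique(d1$aggregation), c("trials", "participants"))
  # anticipation block has one row per condition x role
  ant <- d1[d1$aggregation == "trials" & d1$window == "anticipation", ]
  expect_equal(nrow(ant), 3 * 2)
})

test_that("accuracy summarises per condition to two decimals", {
  tr <- data.frame(condition = rep("negative", 640),
                   response_correct = c(rep(TRUE, 639), FALSE))
  a <- accuracy_summary(tr)
  expect_equal(a$accuracy_pct, 99.84)
  tr2 <- data.frame(condition = rep(c("positive", "nobody"), each = 4),
                    language = "L1",
                    response_correct = c(rep(TRUE, 4), TRUE, TRUE, TRUE, FALSE))
  a2 <- accuracy_summary(tr2)
  expect_equal(a2$accuracy_pct[a2$condition == "positive"], 100)
  expect_equal(a2$accuracy_pct[a2$condition == "nobody"], 75)
  expect_true("language" %in% names(a2))
  # trial order is irrelevant
  expect_equal(accuracy_summary(tr2[sample(8), ]), a2)
})

test_that("fixation totals are sample counts times the period", {
  ds <- deterministic_dataset(onset = 5000, period = 100)
  tot <- fixation_totals(ds, window = "anticipation")
  # anticipation 4000-7000: 10 illusory samples then 20 factual, x 100 ms
  f <- tot[tot$target == "factual", ]
  i <- tot[tot$target == "illusory", ]
  expect_true(all(f$fix_total_ms == 2000))
  expect_true(all(i$fix_total_ms == 1000))
  expect_equal(nrow(tot), 2 * nrow(ds$trials))
})

test_that("proficiency correlations match the closed-form Pearson oracle", {
  # participants engineered to fixed anticipation proportions
  lay <- aoi_layout()
  counts <- c(2, 1, 4, 3, 5)   # factual out of 10 AOI samples
  prof <- 1:5
  trials <- data.frame(participant_id = sprintf("P%d", 1:5), trial_id = 1:5,
                       condition = "negative", factual_side = "left")
  samples <- do.call(rbind, lapply(1:5, function(i) {
    role <- rep(c("factual", "illusory"), c(counts[i], 10 - counts[i]))
    data.frame(participant_id = sprintf("P%d", i), trial_id = i,
               t = seq(4000, by = 100, length.out = 10), x = 0, y = 0,
               role = factor(role, levels = c("factual", "illusory",
                                              "elsewhere")))
  }))
  ds <- gazedpa:::new_gaze_dataset(
    trials = trials, samples = samples,
    participants = data.frame(participant_id = sprintf("P%d", 1:5),
                              proficiency = prof))
  got <- proficiency_correlation(ds)
  # textbook Pearson on (prof, pct): pct = 10 * counts
  x <- prof; y <- 10 * counts
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle, tolerance = 1e-12)
  expect_equal(got$r, 0.8)
  expect_equal(got$n, 5L)
  # perfect linear relation
  ds$participants$proficiency <- 10 * counts
  expect_equal(proficiency_correlation(ds)$r, 1)
})

test_that("a positive proficiency-asymptote coupling yields a positive correlation", {
  ds <- simulate_gaze(sim_config(n_participants = 24,
                                 n_items_per_condition = 8,
                                 conditions = "negative",
                                 true_onset_ms = c(negative = 4600),
                                 proficiency_asymptote_r = 0.9, seed = 61))
  got <- proficiency_correlation(ds)
  expect_gt(got$r, 0.3)
  expect_lt(got$p, 0.05)
})

test_that("paired sample size reproduces canonical values and is minimal", {
  expect_identical(paired_sample_size(d = 0.5, alpha = 0.05, power = 0.8,
                                      tails = 2), 34L)
  expect_identical(paired_sample_size(d = 2.0), 5L)
  for (d in c(0.3, 0.5, 1.0)) {
    n <- paired_sample_size(d)
    expect_gte(paired_power(n, d), 0.8)
    expect_lt(paired_power(n - 1, d), 0.8)
    # independent oracle: stats::power.t.test
    n_oracle <- ceiling(stats::power.t.test(delta = d, sd = 1, power = 0.8,
                                            type = "paired")$n)
    expect_equal(n, n_oracle)
  }
})

test_that("paired sample size is monotone in effect size and power", {
  ds <- c(0.2, 0.4, 0.6, 1.0)
  ns <- vapply(ds, paired_sample_size, 0L)
  expect_true(all(diff(ns) <= 0))          # nonincreasing in d
  pws <- c(0.5, 0.8, 0.9, 0.99)
  ns2 <- vapply(pws, function(p) paired_sample_size(0.5, power = p), 0L)
  expect_true(all(diff(ns2) >= 0))         # nondecreasing in power
  expect_error(paired_sample_size(1e-4, n_max = 1000), "unreachable")
})

test_that("the fixation mixed model recovers a constructed target effect", {
  set.seed(99)
  n <- 32; m <- 20; beta <- -300
  g <- expand.grid(p = seq_len(n), i = seq_len(m),
                   target = c("factual", "illusory"))
  bp <- rnorm(n, 0, 120)[g$p]
  bi <- rnorm(m, 0, 80)[g$i]
  tot <- data.frame(participant_id = sprintf("P%02d", g$p),
                    item_id = g$i, trial_id = seq_len(nrow(g)),
                    condition = "negative",
                    target = factor(g$target, levels = c("factual",
                                                         "illusory")),
                    fix_total_ms = 1500 + bp + bi +
                      beta * (g$target == "illusory") +
                      rnorm(nrow(g), 0, 200))
  fit <- suppressWarnings(fit_fixation_lmm(
    tot, formula = "fix_total_ms ~ target + (1 + target | participant_id) + (1 | item_id)"))
  est <- fit$coefficients["targetillusory", "beta"]
  expect_equal(est, beta, tolerance = 0.2)
  expect_lt(est, 0)  # factual preference = negative illusory coefficient
})

test_that("the mixed model stays null when the target has no effect", {
  reps <- 40
  tvals <- vapply(seq_len(reps), function(r) {
    set.seed(300 + r)
    g <- expand.grid(p = 1:6, i = 1:4, target = c("factual", "illusory"))
    tot <- data.frame(participant_id = sprintf("P%d", g$p), item_id = g$i,
                      condition = "negative",
                      target = factor(g$target),
                      fix_total_ms = 1500 + rnorm(6, 0, 100)[g$p] +
                        rnorm(nrow(g), 0, 200))
    fit <- suppressWarnings(fit_fixation_lmm(
      tot, formula = "fix_total_ms ~ target + (1 | participant_id) + (1 | item_id)"))
    fit$coefficients["targetillusory", "t"]
  }, 0)
  expect_gte(mean(abs(tvals) < 2), 0.9)
})

test_that("the maximal model falls back with a warning on singular fits", {
  ds <- small_sim(seed = 41)
  tot <- fixation_totals(ds)
  w <- capture_warnings(fit <- fit_fixation_lmm(tot))
  expect_true(any(grepl("simplified|singular", w)))
  expect_true(fit$simplified)
  expect_true(all(c("beta", "se", "t") %in% names(fit$coefficients)))
})
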