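#' Configuration for the blank-screen visual-world simulator
#'
#' Defines the generative model behind [simulate_gaze()]. Defaults mirror a
#' webcam blank-screen negation experiment: 32 participants, three sentence
#' conditions (`positive`, `negative`, `nobody`), 20 items per condition,
#' 8,000 ms trials with picture preview over 0-4,000 ms, audio over a blank
#' screen during 4,000-7,000 ms, and pictures back on screen from 7,000 ms.
#'
#' The probability that a gaze sample lands on the factual picture follows a
#' logistic ramp in time from `baseline_p_factual` up to `asymptote`. So
#' that the onset parameter really is the first moment of divergence, the
#' ramp is a half-logistic anchored at the trial's true onset
#' `true_onset_ms[condition] + participant offset + item offset` (offsets
#' are mean-zero Gaussian in ms, truncated to the trial): the factual
#' probability sits exactly at baseline until the onset and rises as
#' `2 * plogis(ramp_slope * (t - onset)) - 1` of the baseline-to-asymptote
#' distance afterwards. The default slope makes the 10-90% rise span
#' 600 ms. The probability of a look to the illusory picture declines
#' complementarily from `baseline_p_illusory`, so total picture-directed
#' probability is constant and the remainder is `elsewhere` (the blank
#' background). During the preview window the factual and illusory
#' probabilities are forced equal, reflecting even screening of both
#' pictures.
#'
#' @param n_participants Number of participants (default 32).
#' @param n_items_per_condition Items (picture pairs) per condition (default 20).
#' @param conditions Condition labels; must match `names(true_onset_ms)`.
#' @param true_onset_ms Named vector of ground-truth divergence onsets (ms).
#' @param ramp_slope Logistic slope (per ms). The 10-90% rise span of the
#'   half-logistic is `(logit(0.95) - logit(0.55)) / ramp_slope` ms; the
#'   default gives 600 ms.
#' @param asymptote Upper probability of a factual look once the ramp is
#'   complete. Must satisfy `asymptote <= baseline_p_factual + baseline_p_illusory`
#'   so the illusory probability can decline complementarily without going
#'   negative. The default 0.50 gives a conditional (factual of
#'   factual + illusory) plateau of ~71%, which reproduces published
#'   anticipation-window fixation proportions in the 55-63% range once
#'   averaged over the window (see the vignette).
#' @param baseline_p_factual,baseline_p_illusory Pre-onset probabilities of a
#'   look to each picture region; their sum must be at most 1.
#' @param participant_onset_sd_ms,item_onset_sd_ms SDs of the additive
#'   Gaussian onset offsets (ms). Defaults are calibrated so that the
#'   heterogeneity-induced group-level divergence stays below the per-bin
#'   detection threshold until one bin before the true onset, keeping
#'   `true_onset_ms` interpretable as the group divergence onset at 200 ms
#'   resolution (see the package vignette).
#' @param sample_period_ms Gaze sampling period (default 50 ms, i.e. a
#'   ~20 Hz webcam tracker).
#' @param trial_duration_ms Trial length (default 8,000 ms).
#' @param audio_onset_ms End of preview / start of the blank-screen audio
#'   (default 4,000 ms).
#' @param accuracy_p Probability of a correct button response per trial.
#' @param proficiency_mean,proficiency_sd,proficiency_min,proficiency_max
#'   Parameters of the bounded-normal L2 proficiency score (defaults match a
#'   placement-test profile: mean 43, range 36-47 out of 50).
#' @param proficiency_asymptote_r Coupling in \[0, 1\] between a participant's
#'   proficiency and their asymptote (0 = none). Positive values induce a
#'   positive proficiency-anticipation correlation for exercising the
#'   correlation stage.
#' @param dropout_rate Probability that any gaze sample is lost (track loss).
#'   No default other than 0 is claimed to be faithful to webcam data.
#' @param language Language label attached to the dataset (e.g. `"L1"`).
#' @param layout [aoi_layout()] used to place simulated gaze coordinates.
#' @param seed Integer seed; the simulator is bit-reproducible given the seed.
#' @return An object of class `gazedpa_sim_config`.
#' @seealso [simulate_gaze()]
#' @export
sim_config <- function(n_participants = 32,
                       n_items_per_condition = 20,
                       conditions = c("positive", "negative", "nobody"),
                       true_onset_ms = c(positive = 4600, negative = 6300,
                                         nobody = 5900),
                       ramp_slope = (log(19) - log(11 / 9)) / 600,
                       asymptote = 0.50,
                       baseline_p_factual = 0.35,
                       baseline_p_illusory = 0.35,
                       participant_onset_sd_ms = 100,
                       item_onset_sd_ms = 50,
                       sample_period_ms = 50,
                       trial_duration_ms = 8000,
                       audio_onset_ms = 4000,
                       accuracy_p = 0.995,
                       proficiency_mean = 43, proficiency_sd = 2.5,
                       proficiency_min = 36, proficiency_max = 47,
                       proficiency_asymptote_r = 0,
                       dropout_rate = 0,
                       language = "L1",
                       layout = aoi_layout(),
                       seed = 1L) {
  cfg <- list(
    n_participants = check_count(n_participants, "n_participants"),
    n_items_per_condition = check_count(n_items_per_condition,
                                        "n_items_per_condition"),
    conditions = as.character(conditions),
    true_onset_ms = true_onset_ms,
    ramp_slope = ramp_slope,
    asymptote = check_prob(asymptote, "asymptote", open_zero = TRUE),
    baseline_p_factual = check_prob(baseline_p_factual, "baseline_p_factual"),
    baseline_p_illusory = check_prob(baseline_p_illusory, "baseline_p_illusory"),
    participant_onset_sd_ms = participant_onset_sd_ms,
    item_onset_sd_ms = item_onset_sd_ms,
    sample_period_ms = check_count(sample_period_ms, "sample_period_ms"),
    trial_duration_ms = check_count(trial_duration_ms, "trial_duration_ms"),
    audio_onset_ms = audio_onset_ms,
    accuracy_p = check_prob(accuracy_p, "accuracy_p"),
    proficiency_mean = proficiency_mean, proficiency_sd = proficiency_sd,
    proficiency_min = proficiency_min, proficiency_max = proficiency_max,
    proficiency_asymptote_r = check_prob(proficiency_asymptote_r,
                                         "proficiency_asymptote_r"),
    dropout_rate = check_prob(dropout_rate, "dropout_rate"),
    language = as.character(language),
    layout = layout,
    seed = seed
  )
  if (!is.numeric(cfg$ramp_slope) || cfg$ramp_slope <= 0) {
    stop("'ramp_slope' must be a positive rate per ms", call. = FALSE)
  }
  if (is.null(names(cfg$true_onset_ms)) ||
      !setequal(names(cfg$true_onset_ms), cfg$conditions)) {
    stop("'true_onset_ms' must be a named vector covering every condition",
         call. = FALSE)
  }
  cfg$true_onset_ms <- cfg$true_onset_ms[cfg$conditions]
  if (any(cfg$true_onset_ms < 0 | cfg$true_onset_ms > cfg$trial_duration_ms)) {
    stop("true onsets must lie inside [0, trial_duration_ms]", call. = FALSE)
  }
  if (cfg$baseline_p_factual + cfg$baseline_p_illusory > 1) {
    stop("baseline_p_factual + baseline_p_illusory must be <= 1", call. = FALSE)
  }
  if (cfg$asymptote < cfg$baseline_p_factual) {
    stop("'asymptote' must be >= 'baseline_p_factual'", call. = FALSE)
  }
  if (cfg$asymptote > cfg$baseline_p_factual + cfg$baseline_p_illusory) {
    stop("'asymptote' may not exceed baseline_p_factual + baseline_p_illusory ",
         "(the illusory probability would go negative)", call. = FALSE)
  }
  if (cfg$participant_onset_sd_ms < 0 || cfg$item_onset_sd_ms < 0) {
    stop("onset SDs must be >= 0", call. = FALSE)
  }
  if (cfg$audio_onset_ms < 0 || cfg$audio_onset_ms >= cfg$trial_duration_ms) {
    stop("'audio_onset_ms' must lie inside the trial", call. = FALSE)
  }
  stopifnot(inherits(layout, "gazedpa_aoi_layout"))
  structure(cfg, class = "gazedpa_sim_config")
}

#' @export
print.gazedpa_sim_config <- function(x, ...) {
  cat("Blank-screen simulation config (", x$language, ")\n", sep = "")
  cat("  ", x$n_participants, " participants x ", x$n_items_per_condition,
      " items x ", length(x$conditions), " conditions; ",
      x$trial_duration_ms, " ms trials @ ", x$sample_period_ms, " ms\n", sep = "")
  cat("  true onsets:",
      paste(sprintf("%s = %g", names(x$true_onset_ms), x$true_onset_ms),
            collapse = ", "), "ms\n")
  cat("  ramp: ", signif(x$ramp_slope, 3), "/ms (10-90% span ",
      round((log(19) - log(11 / 9)) / x$ramp_slope), " ms), ",
      x$baseline_p_factual, " -> ", x$asymptote, "\n", sep = "")
  invisible(x)
}

# per-sample role probabilities; t, tau, asym are equal-length vectors.
# Exposed internally so tests can assert the probability curves sum to 1.
# Half-logistic: exactly baseline before tau, so tau IS the divergence onset.
role_probs <- function(t, tau, cfg, asym = cfg$asymptote) {
  bf <- cfg$baseline_p_factual
  bi <- cfg$baseline_p_illusory
  frac <- pmax(2 * plogis(cfg$ramp_slope * (t - tau)) - 1, 0)
  rise <- (asym - bf) * frac
  pf <- bf + rise
  pil <- bi - rise
  pre <- t < cfg$audio_onset_ms
  eq <- (bf + bi) / 2
  pf[pre] <- eq
  pil[pre] <- eq
  cbind(factual = pf, illusory = pil, elsewhere = 1 - pf - pil)
}

#' Simulate a blank-screen visual-world dataset with known onsets
#'
#' Generates one trial per participant x condition x item with a
#' counterbalanced factual side, a gaze-sample stream at the configured
#' sampling period, a near-ceiling button response, and a bounded-normal
#' proficiency score per participant. Every downstream stage of the package
#' can be validated against the configuration's ground-truth divergence
#' onsets.
#'
#' Gaze coordinates are drawn uniformly inside the role's picture rectangle
#' (or uniformly over the off-picture screen area for `elsewhere` looks), so
#' re-deriving roles from coordinates with [assign_roles()] reproduces the
#' generated roles exactly.
#'
#' @param config A [sim_config()].
#' @return A `gaze_dataset`: list with `trials`, `samples`, `participants`
#'   data frames plus the `config` and its AOI `layout`. `trials` carries the
#'   per-trial ground-truth onset in `true_onset_ms`; `participants` carries
#'   the ground-truth onset offset.
#' @examples
#' cfg <- sim_config(n_participants = 4, n_items_per_condition = 3, seed = 7)
#' ds <- simulate_gaze(cfg)
#' ds
#' @export
simulate_gaze <- function(config = sim_config()) {
  stopifnot(inherits(config, "gazedpa_sim_config"))
  with_seed(config$seed, simulate_gaze_impl(config))
}

simulate_gaze_impl <- function(cfg) {
  n <- cfg$n_participants
  m <- cfg$n_items_per_condition
  conds <- cfg$conditions
  pid <- sprintf("P%02d", seq_len(n))

  # participant-level draws
  prof_raw <- rnorm(n, cfg$proficiency_mean, cfg$proficiency_sd)
  proficiency <- pmin(pmax(round(prof_raw), cfg$proficiency_min),
                      cfg$proficiency_max)
  p_off <- rnorm(n, 0, cfg$participant_onset_sd_ms)
  i_off <- rnorm(m, 0, cfg$item_onset_sd_ms)
  # optional shared participant effect linking proficiency and asymptote
  r <- cfg$proficiency_asymptote_r
  z <- if (cfg$proficiency_sd > 0) (prof_raw - cfg$proficiency_mean) / cfg$proficiency_sd else rep(0, n)
  asym_p <- cfg$asymptote + r * 0.08 * z
  asym_p <- pmin(pmax(asym_p, cfg$baseline_p_factual),
                 cfg$baseline_p_factual + cfg$baseline_p_illusory)

  trials <- expand.grid(item_id = seq_len(m), condition = conds,
                        p_idx = seq_len(n), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  ntr <- nrow(trials)
  trials$participant_id <- pid[trials$p_idx]
  trials$trial_id <- seq_len(ntr)
  trials$language <- cfg$language
  # counterbalanced factual side: alternates over items, flipped across
  # participants so each item appears on both sides across the sample
  trials$factual_side <- ifelse((trials$item_id + trials$p_idx) %% 2 == 0,
                                "left", "right")
  tau <- cfg$true_onset_ms[trials$condition] + p_off[trials$p_idx] +
    i_off[trials$item_id]
  trials$true_onset_ms <- pmin(pmax(tau, 0), cfg$trial_duration_ms)
  trials$audio_duration_ms <- round(runif(ntr, 2500, 3000))
  correct <- runif(ntr) < cfg$accuracy_p
  trials$response_correct <- correct
  trials$response_side <- ifelse(correct, trials$factual_side,
                                 ifelse(trials$factual_side == "left",
                                        "right", "left"))
  trials$rt_ms <- round(rlnorm(ntr, log(900), 0.35))

  # gaze-sample stream
  tgrid <- seq(0, cfg$trial_duration_ms - cfg$sample_period_ms,
               by = cfg$sample_period_ms)
  nt <- length(tgrid)
  t_s <- rep(tgrid, times = ntr)
  row_s <- rep(seq_len(ntr), each = nt)
  P <- role_probs(t_s, trials$true_onset_ms[row_s], cfg,
                  asym = asym_p[trials$p_idx[row_s]])
  stopifnot(all(P >= -1e-12), all(abs(rowSums(P) - 1) < 1e-12))
  u <- runif(length(t_s))
  role <- ifelse(u < P[, 1L], "factual",
                 ifelse(u < P[, 1L] + P[, 2L], "illusory", "elsewhere"))

  side_s <- trials$factual_side[row_s]
  xy <- place_samples(role, side_s, cfg$layout)
  samples <- data.frame(participant_id = trials$participant_id[row_s],
                        trial_id = trials$trial_id[row_s],
                        t = t_s, x = xy$x, y = xy$y,
                        role = factor(role, levels = c("factual", "illusory",
                                                       "elsewhere")))
  if (cfg$dropout_rate > 0) {
    samples <- samples[runif(nrow(samples)) >= cfg$dropout_rate, , drop = FALSE]
    rownames(samples) <- NULL
  }

  participants <- data.frame(participant_id = pid, language = cfg$language,
                             proficiency = proficiency,
                             onset_offset_ms = p_off)
  trials$p_idx <- NULL
  trials <- trials[, c("participant_id", "trial_id", "item_id", "condition",
                       "language", "factual_side", "audio_duration_ms",
                       "response_side", "response_correct", "rt_ms",
                       "true_onset_ms")]
  new_gaze_dataset(trials = trials, samples = samples,
                   participants = participants, config = cfg,
                   layout = cfg$layout)
}

# draw a coordinate for each sample consistent with its role
place_samples <- function(role, factual_side, layout) {
  nS <- length(role)
  x <- numeric(nS); y <- numeric(nS)
  rect_of <- function(side) if (identical(side, "left")) layout$left_rect else layout$right_rect
  target_side <- ifelse(role == "factual", factual_side,
                        ifelse(factual_side == "left", "right", "left"))
  # keep a 0.1 px margin so rounding below cannot cross the AOI boundary
  for (side in c("left", "right")) {
    rct <- rect_of(side)
    k <- which(role != "elsewhere" & target_side == side)
    x[k] <- rct[1] + 0.1 + runif(length(k)) * (rct[3] - 0.2)
    y[k] <- rct[2] + 0.1 + runif(length(k)) * (rct[4] - 0.2)
  }
  # elsewhere: uniform over the screen, rejecting (rounded) points inside
  # either rectangle
  k <- which(role == "elsewhere")
  while (length(k)) {
    x[k] <- round(runif(length(k)) * layout$screen_w, 1)
    y[k] <- round(runif(length(k)) * layout$screen_h, 1)
    inside <- in_rect(x[k], y[k], layout$left_rect, layout$padding_px) |
      in_rect(x[k], y[k], layout$right_rect, layout$padding_px)
    k <- k[inside]
  }
  list(x = unname(round(x, 1)), y = unname(round(y, 1)))
}
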