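# shared fixtures, built in code

small_sim <- function(seed = 101, ...) {
  simulate_gaze(sim_config(n_participants = 8, n_items_per_condition = 5,
                           seed = seed, ...))
}

quick_dpa <- function(n_boot = 50, seed = 99, ...) {
  dpa_config(n_boot = n_boot, seed = seed, ...)
}

# a dpa_boot object with known onsets, for difference-distribution tests
make_boot <- function(onsets, label = "x") {
  ok <- !is.na(onsets)
  structure(list(onsets = onsets, n_boot = length(onsets),
                 n_missing = sum(!ok),
                 mean_ms = if (any(ok)) mean(onsets[ok]) else NA_real_,
                 ci_low_ms = if (any(ok)) unname(quantile(onsets[ok], 0.025)) else NA_real_,
                 ci_high_ms = if (any(ok)) unname(quantile(onsets[ok], 0.975)) else NA_real_,
                 label = label, ci_probs = c(2.5, 97.5)),
            class = "dpa_boot")
}

# deterministic hand-built dataset: every trial identical, factual looks
# start exactly at `onset` and continue to trial end, illusory before that
deterministic_dataset <- function(n_participants = 4, n_trials = 6,
                                  onset = 5000, period = 100) {
  lay <- aoi_layout()
  tgrid <- seq(0, 8000 - period, by = period)
  trials <- expand.grid(trial = seq_len(n_trials), p = seq_len(n_participants))
  trials <- data.frame(participant_id = sprintf("P%02d", trials$p),
                       trial_id = seq_len(nrow(trials)),
                       condition = "negative", factual_side = "left",
                       language = "L1", response_correct = TRUE,
                       stringsAsFactors = FALSE)
  nt <- length(tgrid)
  role <- ifelse(tgrid >= onset, "factual", "illusory")
  samples <- data.frame(
    participant_id = rep(trials$participant_id, each = nt),
    trial_id = rep(trials$trial_id, each = nt),
    t = rep(tgrid, nrow(trials)),
    x = unname(ifelse(rep(role, nrow(trials)) == "factual",
                      lay$left_rect[1] + 10, lay$right_rect[1] + 10)),
    y = unname(lay$left_rect[2] + 10),
    role = factor(rep(role, nrow(trials)),
                  levels = c("factual", "illusory", "elsewhere")),
    stringsAsFactors = FALSE)
  gazedpa:::new_gaze_dataset(trials = trials, samples = samples,
                             layout = lay)
}
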