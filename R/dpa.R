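#' Configuration for divergence point analysis
#'
#' @param bin_width_ms Time-bin width in ms (default 200).
#' @param k_consecutive Number of consecutive significant bins required to
#'   call an onset (default 3, i.e. a preference sustained for 600 ms at the
#'   default bin width).
#' @param alpha Per-bin significance level (default 0.05).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param ci Percentile CI bounds in percent (default `c(2.5, 97.5)`).
#' @param span Analysis span `c(start, end)` in ms, binned from its start
#'   (default `[4000, 8000)`: the anticipation and integration windows,
#'   anchored at audio onset).
#' @param one_sided Per-bin test sidedness. The default `TRUE` tests
#'   factual > illusory, matching the onset criterion of *more* looks to the
#'   factual; set `FALSE` for a two-sided test.
#' @param resample_unit What the bootstrap resamples: `"trials"` (default;
#'   trials with replacement within participant x condition strata,
#'   preserving per-bin structure), `"participants"` (participants with
#'   replacement), or `"bin_samples"` (the individual gaze samples within
#'   each participant x bin cell).
#' @param missing_onset_policy Resamples in which no qualifying run exists
#'   carry no onset; `"exclude"` (the only policy) drops them from the mean
#'   and CI and reports their count.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `gazedpa_dpa_config`.
#' @export
dpa_config <- function(bin_width_ms = 200, k_consecutive = 3, alpha = 0.05,
                       n_boot = 2000, ci = c(2.5, 97.5),
                       span = c(4000, 8000), one_sided = TRUE,
                       resample_unit = c("trials", "participants",
                                         "bin_samples"),
                       missing_onset_policy = "exclude", seed = NULL) {
  resample_unit <- match.arg(resample_unit)
  missing_onset_policy <- match.arg(missing_onset_policy, "exclude")
  cfg <- list(bin_width_ms = check_count(bin_width_ms, "bin_width_ms"),
              k_consecutive = check_count(k_consecutive, "k_consecutive"),
              alpha = check_prob(alpha, "alpha", open_zero = TRUE),
              n_boot = check_count(n_boot, "n_boot"),
              ci = as.numeric(ci), span = as.numeric(span),
              one_sided = isTRUE(one_sided),
              resample_unit = resample_unit,
              missing_onset_policy = missing_onset_policy, seed = seed)
  if (length(cfg$ci) != 2L || any(cfg$ci < 0 | cfg$ci > 100) ||
      cfg$ci[1] >= cfg$ci[2]) {
    stop("'ci' must be increasing percentiles in [0, 100]", call. = FALSE)
  }
  if (length(cfg$span) != 2L || cfg$span[1] >= cfg$span[2] ||
      (cfg$span[2] - cfg$span[1]) %% cfg$bin_width_ms != 0) {
    stop("'span' must be c(start, end) with bin_width_ms dividing its length",
         call. = FALSE)
  }
  structure(cfg, class = "gazedpa_dpa_config")
}

#' @export
print.gazedpa_dpa_config <- function(x, ...) {
  cat("DPA config: ", x$bin_width_ms, " ms bins over [", x$span[1], ", ",
      x$span[2], ") ms; onset = first of ", x$k_consecutive,
      " consecutive bins with p < ", x$alpha,
      if (x$one_sided) " (one-sided factual > illusory)" else " (two-sided)",
      "\n  bootstrap: ", x$n_boot, " resamples of ", x$resample_unit,
      ", percentile CI at (", x$ci[1], ", ", x$ci[2], ")%\n", sep = "")
  invisible(x)
}

# Vectorised per-bin weighted empirical-logit tests.
# Yf, Yi: participants x bins count matrices (looks to factual / illusory).
# Observations per bin: one elog per participant x target; elog_illusory is
# the mirror image of elog_factual with the same variance, so the WLS fit of
# elog on the target indicator reduces to weighted group means.
wls_bins <- function(Yf, Yi, alpha = 0.05, one_sided = TRUE) {
  N <- Yf + Yi
  valid <- N > 0
  elF <- matrix(0, nrow(Yf), ncol(Yf))
  w <- matrix(0, nrow(Yf), ncol(Yf))
  elF[valid] <- log((Yf[valid] + 0.5) / (Yi[valid] + 0.5))
  w[valid] <- 1 / (1 / (Yf[valid] + 0.5) + 1 / (Yi[valid] + 0.5))
  Sw <- colSums(w)
  n_part <- colSums(valid)
  muF <- ifelse(Sw > 0, colSums(w * elF) / Sw, NA_real_)
  estimate <- 2 * muF                      # factual minus illusory group mean
  rss <- 2 * (colSums(w * elF^2) - ifelse(Sw > 0, Sw * muF^2, 0))
  nobs <- 2L * n_part
  dfree <- nobs - 2L
  sigma2 <- ifelse(dfree > 0, pmax(rss, 0) / dfree, NA_real_)
  se <- suppressWarnings(sqrt(2 * sigma2 / Sw))
  tval <- rep(NA_real_, length(estimate))
  pos_se <- which(is.finite(se) & se > 0)
  tval[pos_se] <- estimate[pos_se] / se[pos_se]
  zero_se <- which(is.finite(se) & se == 0)  # no residual variance
  tval[zero_se] <- sign(estimate[zero_se]) * Inf
  tval[zero_se][estimate[zero_se] == 0] <- 0
  p <- rep(NA_real_, length(estimate))
  fin <- which(is.finite(tval) & dfree > 0)
  p[fin] <- if (one_sided) {
    pt(tval[fin], dfree[fin], lower.tail = FALSE)
  } else {
    2 * pt(abs(tval[fin]), dfree[fin], lower.tail = FALSE)
  }
  inf <- which(is.infinite(tval))
  p[inf] <- if (one_sided) ifelse(tval[inf] > 0, 0, 1) else 0
  deg <- which(tval == 0 & !(seq_along(tval) %in% fin))  # 0/0 cells
  p[deg] <- if (one_sided) 0.5 else 1
  untestable <- n_part < 2L
  p[which(untestable)] <- NA_real_
  data.frame(estimate = estimate, se = se, t = tval, df = dfree, p = p,
             n_participants = n_part, untestable = untestable)
}

#' Per-bin weighted empirical-logit models
#'
#' For each time bin, fits a weighted least-squares model of the empirical
#' logit on a two-level fixation-target indicator (factual vs illusory),
#' with one observation per participant x target and inverse-variance
#' weights, and tests whether looks to the factual exceed looks to the
#' illusory.
#'
#' @param binned Participant-level binned counts as returned by
#'   [bin_counts()] (columns `participant_id`, `bin_start_ms`, `y_factual`,
#'   `y_illusory`; a `condition` column, if present, must be constant).
#' @param config A [dpa_config()]; supplies `alpha` and sidedness.
#' @return Data frame with one row per bin: `bin_start_ms`, `estimate`
#'   (elog difference factual - illusory), `se`, `t`, `df`, `p`,
#'   `n_participants`, `untestable` (fewer than 2 contributing
#'   participants).
#' @export
fit_bin_models <- function(binned, config = dpa_config()) {
  check_cols(binned, c("participant_id", "bin_start_ms", "y_factual",
                       "y_illusory"), "binned counts")
  if ("condition" %in% names(binned) &&
      length(unique(binned$condition)) > 1L) {
    stop("fit_bin_models() expects a single condition; split first",
         call. = FALSE)
  }
  pid <- factor(binned$participant_id)
  bins <- sort(unique(binned$bin_start_ms))
  bidx <- match(binned$bin_start_ms, bins)
  Yf <- matrix(0, nlevels(pid), length(bins))
  Yi <- matrix(0, nlevels(pid), length(bins))
  ij <- cbind(as.integer(pid), bidx)
  Yf[ij] <- Yf[ij] + binned$y_factual
  Yi[ij] <- Yi[ij] + binned$y_illusory
  res <- wls_bins(Yf, Yi, alpha = config$alpha, one_sided = config$one_sided)
  cbind(bin_start_ms = bins, res)
}

#' Detect the divergence onset from per-bin test results
#'
#' The onset is the left edge of the first bin of the first run of at least
#' `k_consecutive` consecutive bins whose p-value is below `alpha` — i.e. the
#' first moment at which significantly more looks go to the factual than to
#' the illusory picture, sustained for `k_consecutive * bin_width_ms` ms
#' (600 ms by default). A missing onset (no qualifying run) is a valid
#' outcome, returned as `NA`.
#'
#' @param results Data frame from [fit_bin_models()] (needs `bin_start_ms`
#'   and `p`); rows are sorted by bin internally.
#' @param config A [dpa_config()].
#' @return List with `onset_ms` (`NA` if no qualifying run) and
#'   `qualifying_run_start_bin` (index into the sorted bins, `NA` if none).
#' @examples
#' res <- data.frame(bin_start_ms = seq(4000, 5000, 200),
#'                   p = c(.2, .2, .01, .01, .01, .4))
#' detect_onset(res)
#' @export
detect_onset <- function(results, config = dpa_config()) {
  check_cols(results, c("bin_start_ms", "p"), "bin test results")
  o <- order(results$bin_start_ms)
  p <- results$p[o]
  sig <- !is.na(p) & p < config$alpha
  k <- config$k_consecutive
  onset <- NA_real_; start <- NA_integer_
  if (length(sig) >= k) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= k)
    if (length(hit)) {
      start <- ends[hit[1L]] - r$lengths[hit[1L]] + 1L
      onset <- results$bin_start_ms[o][start]
    }
  }
  list(onset_ms = onset, qualifying_run_start_bin = start)
}

# trial x bin count matrices for one condition
trial_bin_matrices <- function(samples, trials, span, width) {
  nb <- (span[2] - span[1]) %/% width
  keep <- samples$t >= span[1] & samples$t < span[2] & !is.na(samples$role) &
    samples$role != "elsewhere"
  s <- samples[keep, , drop = FALSE]
  tkey <- trial_key(trials$participant_id, trials$trial_id)
  ti <- match(trial_key(s$participant_id, s$trial_id), tkey)
  ok <- !is.na(ti)
  s <- s[ok, , drop = FALSE]; ti <- ti[ok]
  bin <- 1L + (s$t - span[1]) %/% width
  ij <- (ti - 1L) * nb + bin
  Yf <- matrix(tabulate(ij[s$role == "factual"], nbins = nrow(trials) * nb),
               nrow = nrow(trials), byrow = TRUE)
  Yi <- matrix(tabulate(ij[s$role == "illusory"], nbins = nrow(trials) * nb),
               nrow = nrow(trials), byrow = TRUE)
  list(Yf = Yf, Yi = Yi, pid = factor(trials$participant_id),
       bins = span[1] + width * (seq_len(nb) - 1L))
}

boot_onsets_condition <- function(mats, config) {
  pid <- mats$pid
  idx_by_p <- split(seq_along(pid), pid)
  np <- length(idx_by_p)
  n_per <- lengths(idx_by_p)
  onsets <- rep(NA_real_, config$n_boot)
  for (b in seq_len(config$n_boot)) {
    if (config$resample_unit == "trials") {
      rows <- unlist(lapply(idx_by_p, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      g <- pid[rows]
      Yf <- rowsum(mats$Yf[rows, , drop = FALSE], g)
      Yi <- rowsum(mats$Yi[rows, , drop = FALSE], g)
    } else if (config$resample_unit == "participants") {
      ps <- sample.int(np, np, replace = TRUE)
      rows <- unlist(idx_by_p[ps], use.names = FALSE)
      g <- rep(seq_len(np), times = n_per[ps])
      Yf <- rowsum(mats$Yf[rows, , drop = FALSE], g)
      Yi <- rowsum(mats$Yi[rows, , drop = FALSE], g)
    } else { # bin_samples: resample the N AOI samples within each cell
      Yf0 <- rowsum(mats$Yf, pid); Yi0 <- rowsum(mats$Yi, pid)
      N <- Yf0 + Yi0
      Yf <- matrix(0, nrow(Yf0), ncol(Yf0))
      pos <- N > 0
      Yf[pos] <- rbinom(sum(pos), N[pos], Yf0[pos] / N[pos])
      Yi <- N - Yf
    }
    fit <- wls_bins(Yf, Yi, alpha = config$alpha, one_sided = config$one_sided)
    sig <- !is.na(fit$p) & fit$p < config$alpha
    r <- rle(sig)
    hit <- which(r$values & r$lengths >= config$k_consecutive)
    if (length(hit)) {
      ends <- cumsum(r$lengths)
      onsets[b] <- mats$bins[ends[hit[1L]] - r$lengths[hit[1L]] + 1L]
    }
  }
  onsets
}

#' Divergence point analysis
#'
#' The core estimator: for each condition, gaze samples are binned into
#' `bin_width_ms` bins over the analysis span, each bin is tested with a
#' weighted empirical-logit model of looks to the factual vs the illusory
#' picture, and the divergence point is the left edge of the first of
#' `k_consecutive` consecutive significant bins. The sampling distribution
#' of that onset is obtained by a stratified nonparametric bootstrap
#' (default: trials resampled with replacement within participant x
#' condition strata), the whole bin-fit-and-detect procedure being repeated
#' `n_boot` times; the distribution is summarised by its mean over
#' non-missing onsets and a percentile confidence interval. Resamples with
#' no qualifying run are excluded from the mean and CI and counted.
#'
#' @param data A `gaze_dataset` with role-labelled samples (see
#'   [simulate_gaze()], [assign_roles()]), or a samples data frame plus
#'   `trials`.
#' @param conditions Conditions to analyse; default all non-filler
#'   conditions present.
#' @param config A [dpa_config()].
#' @param trials Trial table when `data` is a samples data frame.
#' @return An object of class `dpa`: per condition, the per-bin test table,
#'   the point-estimate onset, and the bootstrap distribution (onsets, mean,
#'   percentile CI, missing count). Methods: [print.dpa()], [summary.dpa()],
#'   [coef.dpa()], [plot.dpa()], plus [onset_distribution()] and
#'   [dpa_difference()] for contrasts.
#' @examples
#' cfg <- sim_config(n_participants = 6, n_items_per_condition = 4,
#'                   conditions = "positive",
#'                   true_onset_ms = c(positive = 5000), seed = 2)
#' fit <- dpa(simulate_gaze(cfg), config = dpa_config(n_boot = 20, seed = 9))
#' fit
#' @export
dpa <- function(data, conditions = NULL, config = dpa_config(),
                trials = NULL) {
  stopifnot(inherits(config, "gazedpa_dpa_config"))
  xs <- as_analysis_tables(data, trials)
  conds <- conditions %||% unique(as.character(xs$trials$condition))
  miss <- setdiff(conds, unique(as.character(xs$trials$condition)))
  if (length(miss)) stop("condition not in data: ", miss[1L], call. = FALSE)
  language <- if (!is.null(xs$trials$language)) {
    as.character(xs$trials$language[1L])
  } else NA_character_

  fit_one <- function(cond) {
    tr <- xs$trials[xs$trials$condition == cond, , drop = FALSE]
    mats <- trial_bin_matrices(xs$samples, tr, config$span,
                               config$bin_width_ms)
    Yf0 <- rowsum(mats$Yf, mats$pid)
    Yi0 <- rowsum(mats$Yi, mats$pid)
    bin_tests <- cbind(bin_start_ms = mats$bins,
                       wls_bins(Yf0, Yi0, config$alpha, config$one_sided))
    point <- detect_onset(bin_tests, config)
    onsets <- boot_onsets_condition(mats, config)
    ok <- !is.na(onsets)
    list(condition = cond, bin_tests = bin_tests,
         point_onset_ms = point$onset_ms,
         boot = list(onsets = onsets, n_boot = config$n_boot,
                     n_missing = sum(!ok),
                     mean_ms = if (any(ok)) mean(onsets[ok]) else NA_real_,
                     ci_low_ms = if (any(ok)) unname(quantile(onsets[ok], config$ci[1] / 100)) else NA_real_,
                     ci_high_ms = if (any(ok)) unname(quantile(onsets[ok], config$ci[2] / 100)) else NA_real_))
  }
  fits <- with_seed(config$seed, lapply(conds, fit_one))
  names(fits) <- conds
  structure(list(fits = fits, conditions = conds, config = config,
                 language = language,
                 n_participants = length(unique(xs$trials$participant_id)),
                 call = match.call()),
            class = "dpa")
}

#' Summarise a divergence point analysis
#'
#' @param object,x A `dpa` fit.
#' @param ... Unused.
#' @return `summary.dpa()` returns a data frame with one row per condition:
#'   point-estimate onset, bootstrap mean, percentile CI bounds, and the
#'   number of resamples without a qualifying onset.
#' @export
summary.dpa <- function(object, ...) {
  rows <- lapply(object$fits, function(f) {
    data.frame(condition = f$condition, language = object$language,
               onset_ms = f$point_onset_ms, mean_ms = f$boot$mean_ms,
               ci_low_ms = f$boot$ci_low_ms, ci_high_ms = f$boot$ci_high_ms,
               n_boot = f$boot$n_boot, n_missing = f$boot$n_missing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname summary.dpa
#' @export
print.dpa <- function(x, ...) {
  cat("Divergence point analysis",
      if (!is.na(x$language)) paste0(" (", x$language, ")"), "\n", sep = "")
  cat("  ", x$n_participants, " participants; ", x$config$n_boot,
      " bootstrap resamples of ", x$config$resample_unit, "; ",
      x$config$bin_width_ms, " ms bins over [", x$config$span[1], ", ",
      x$config$span[2], ") ms\n", sep = "")
  s <- summary(x)
  for (i in seq_len(nrow(s))) {
    if (is.na(s$mean_ms[i])) {
      cat(sprintf("  %-10s no qualifying onset in any resample\n",
                  s$condition[i]))
    } else {
      cat(sprintf("  %-10s M = %.0f ms, %g%% CI %.0f-%.0f ms (%d/%d resamples without onset)\n",
                  s$condition[i], s$mean_ms[i], diff(x$config$ci),
                  s$ci_low_ms[i], s$ci_high_ms[i], s$n_missing[i],
                  s$n_boot[i]))
    }
  }
  invisible(x)
}

#' Per-bin test results of a DPA fit
#'
#' @param object A `dpa` fit.
#' @param ... Unused.
#' @return Data frame of per-bin estimates stacked across conditions.
#' @export
coef.dpa <- function(object, ...) {
  out <- do.call(rbind, lapply(object$fits, function(f) {
    cbind(condition = f$condition, f$bin_tests)
  }))
  rownames(out) <- NULL
  out
}

#' Extract one condition's bootstrap onset distribution
#'
#' @param fit A `dpa` fit.
#' @param condition Condition name.
#' @return An object of class `dpa_boot` with fields `onsets` (length
#'   `n_boot`, `NA` for resamples without a qualifying onset), `mean_ms`,
#'   `ci_low_ms`, `ci_high_ms`, `n_boot`, `n_missing` and a `label`.
#' @export
onset_distribution <- function(fit, condition) {
  stopifnot(inherits(fit, "dpa"))
  if (!condition %in% names(fit$fits)) {
    stop("no such condition in fit: ", condition, call. = FALSE)
  }
  f <- fit$fits[[condition]]
  structure(c(f$boot,
              list(label = paste0(if (!is.na(fit$language))
                paste0(fit$language, " ") else "", condition),
                ci_probs = fit$config$ci)),
            class = "dpa_boot")
}

#' @export
print.dpa_boot <- function(x, ...) {
  cat("Bootstrap onset distribution: ", x$label, "\n", sep = "")
  if (is.na(x$mean_ms)) {
    cat("  no qualifying onset in any of ", x$n_boot, " resamples\n", sep = "")
  } else {
    cat(sprintf("  M = %.0f ms, %g%% CI %.0f-%.0f ms; %d/%d resamples without onset\n",
                x$mean_ms, diff(x$ci_probs %||% c(2.5, 97.5)),
                x$ci_low_ms, x$ci_high_ms, x$n_missing, x$n_boot))
  }
  invisible(x)
}
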