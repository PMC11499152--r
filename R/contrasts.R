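#' Difference distribution between two bootstrap onset distributions
#'
#' Subtracts two bootstrap divergence-point distributions resample-by-
#' resample (pairing by resample index; the two bootstraps are independent
#' draws) and summarises the differences by their mean and percentile CI.
#' A contrast is flagged significant when the CI excludes zero.
#'
#' Resample pairs in which either onset is missing are dropped and counted.
#' If no pair survives (e.g. both inputs come from flat, signal-free data),
#' the distribution is flagged undefined: mean and CI are `NA` and
#' `excludes_zero` is `NA`, never `TRUE`.
#'
#' @param a,b `dpa_boot` objects from [onset_distribution()], with equal
#'   `n_boot`. The difference is `a - b`, so a positive mean says `a`
#'   diverges later (is slower) than `b`.
#' @param ci Percentile bounds (default taken from `a`).
#' @return An object of class `dpa_diff`: `diffs`, `mean_ms`, `ci_low_ms`,
#'   `ci_high_ms`, `excludes_zero`, `n_pairs`, `n_dropped`, `label`.
#' @export
dpa_difference <- function(a, b, ci = NULL) {
  stopifnot(inherits(a, "dpa_boot"), inherits(b, "dpa_boot"))
  if (a$n_boot != b$n_boot) {
    stop("onset distributions have unequal n_boot (", a$n_boot, " vs ",
         b$n_boot, "); rerun dpa() with equal n_boot", call. = FALSE)
  }
  ci <- ci %||% a$ci_probs %||% c(2.5, 97.5)
  diffs <- a$onsets - b$onsets
  ok <- !is.na(diffs)
  res <- list(diffs = diffs[ok], n_pairs = sum(ok),
              n_dropped = sum(!ok), ci_probs = ci,
              label = paste(a$label, "-", b$label))
  if (res$n_pairs == 0L) {
    warning("no resample pair carries an onset in both distributions; ",
            "difference undefined", call. = FALSE)
    res <- c(res, list(mean_ms = NA_real_, ci_low_ms = NA_real_,
                       ci_high_ms = NA_real_, excludes_zero = NA))
  } else {
    lo <- unname(quantile(res$diffs, ci[1] / 100))
    hi <- unname(quantile(res$diffs, ci[2] / 100))
    res <- c(res, list(mean_ms = mean(res$diffs), ci_low_ms = lo,
                       ci_high_ms = hi,
                       excludes_zero = !(lo <= 0 && hi >= 0)))
  }
  structure(res, class = "dpa_diff")
}

#' @export
print.dpa_diff <- function(x, ...) {
  cat("Divergence-point difference: ", x$label, "\n", sep = "")
  if (is.na(x$mean_ms)) {
    cat("  undefined (no resample pair with onsets in both distributions)\n")
  } else {
    cat(sprintf("  M = %.0f ms, %g%% CI %.0f-%.0f ms (%s; %d pairs, %d dropped)\n",
                x$mean_ms, diff(x$ci_probs %||% c(2.5, 97.5)),
                x$ci_low_ms, x$ci_high_ms,
                if (isTRUE(x$excludes_zero)) "CI excludes zero"
                else "CI contains zero", x$n_pairs, x$n_dropped))
  }
  invisible(x)
}

#' All pairwise condition contrasts of a DPA fit
#'
#' @param fit A `dpa` fit.
#' @param pairs Optional list of 2-element character vectors `c(a, b)`;
#'   default all unordered pairs, later-onset condition first so means are
#'   positive when the named ordering holds.
#' @return Named list of [dpa_difference()] objects (`a_minus_b` names).
#' @export
condition_contrasts <- function(fit, pairs = NULL) {
  stopifnot(inherits(fit, "dpa"))
  conds <- fit$conditions
  if (is.null(pairs)) {
    pairs <- list()
    if (length(conds) >= 2) {
      cmb <- utils::combn(conds, 2, simplify = FALSE)
      pairs <- lapply(cmb, function(p) {
        m1 <- fit$fits[[p[1]]]$boot$mean_ms
        m2 <- fit$fits[[p[2]]]$boot$mean_ms
        if (!is.na(m1) && !is.na(m2) && m1 < m2) rev(p) else p
      })
    }
  }
  out <- lapply(pairs, function(p) {
    dpa_difference(onset_distribution(fit, p[1]), onset_distribution(fit, p[2]))
  })
  names(out) <- vapply(pairs, function(p) paste(p[1], p[2], sep = "_minus_"),
                       "")
  out
}

#' Between-language divergence-point difference
#'
#' Subtracts the onset distribution of one language's condition from the
#' other's, pairing resamples by index. The direction is `lang1 - lang2`
#' (conventionally L1 - L2), so a positive mean says divergence is slower in
#' `lang1`.
#'
#' @param fit_lang1,fit_lang2 `dpa` fits for the two language datasets.
#' @param condition Condition to compare (present in both fits).
#' @return A [dpa_difference()] object.
#' @export
between_language_difference <- function(fit_lang1, fit_lang2, condition) {
  dpa_difference(onset_distribution(fit_lang1, condition),
                 onset_distribution(fit_lang2, condition))
}
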