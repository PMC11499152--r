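#' Fixation-proportion timecourse curves
#'
#' One panel per condition: mean proportion of looks to the factual and the
#' illusory picture per time bin, with shaded 95% confidence bands
#' (normal-approximation across participant means), vertical lines at the
#' window boundaries, and — when a `dpa` fit is supplied — the bootstrap
#' divergence point with its percentile-CI whiskers.
#'
#' @param data A `gaze_dataset` or role-labelled samples data frame.
#' @param fit Optional `dpa` fit whose onsets are superimposed.
#' @param trials Trial table when `data` is raw samples.
#' @param bin_width_ms Bin width for the curves (default 200 ms).
#' @param spec A [window_spec()]; also sets the plotted span.
#' @param denominator `"aoi_only"` or `"all_samples"` (see
#'   [proportions_by_window()]).
#' @param conditions Conditions to plot (default all).
#' @return Invisibly, the binned means that were drawn.
#' @export
plot_fixation_curves <- function(data, fit = NULL, trials = NULL,
                                 bin_width_ms = 200, spec = window_spec(),
                                 denominator = c("aoi_only", "all_samples"),
                                 conditions = NULL) {
  denominator <- match.arg(denominator)
  span <- c(spec$preview[1], spec$integration[2])
  binned <- bin_counts(data, trials = trials, bin_width_ms = bin_width_ms,
                       span = span)
  conds <- conditions %||% unique(binned$condition)
  denom <- if (denominator == "aoi_only") {
    binned$y_factual + binned$y_illusory
  } else {
    binned$n_total
  }
  ok <- denom > 0
  pf <- binned$y_factual[ok] / denom[ok]
  pi_ <- binned$y_illusory[ok] / denom[ok]
  b <- binned[ok, , drop = FALSE]

  old <- par(mfrow = c(1, length(conds)), mar = c(4, 4, 2, 1))
  on.exit(par(old), add = TRUE)
  curves <- list()
  for (cond in conds) {
    sel <- b$condition == cond
    agg <- function(v) {
      m <- tapply(v[sel], b$bin_start_ms[sel], mean)
      s <- tapply(v[sel], b$bin_start_ms[sel], sd)
      n <- tapply(v[sel], b$bin_start_ms[sel], length)
      list(t = as.numeric(names(m)) + bin_width_ms / 2, m = m,
           half = 1.96 * s / sqrt(n))
    }
    f <- agg(pf); il <- agg(pi_)
    plot(NA, xlim = span, ylim = c(0, 1), xlab = "time (ms)",
         ylab = "fixation proportion", main = cond)
    band <- function(a, col) {
      polygon(c(a$t, rev(a$t)), c(a$m - a$half, rev(a$m + a$half)),
              col = adjustcolor(col, 0.2), border = NA)
      lines(a$t, a$m, col = col, lwd = 2)
    }
    band(f, "steelblue"); band(il, "darkorange")
    abline(v = c(spec$anticipation[1], spec$integration[1]), lty = 3,
           col = "grey40")
    if (!is.null(fit) && cond %in% names(fit$fits)) {
      bo <- fit$fits[[cond]]$boot
      if (!is.na(bo$mean_ms)) {
        segments(bo$ci_low_ms, 0.5, bo$ci_high_ms, 0.5, lwd = 2)
        points(bo$mean_ms, 0.5, pch = 19, cex = 1.2)
      }
    }
    if (cond == conds[1L]) {
      legend("topleft", c("factual", "illusory"), lwd = 2, bty = "n",
             col = c("steelblue", "darkorange"), cex = 0.8)
    }
    curves[[cond]] <- list(factual = f, illusory = il)
  }
  invisible(curves)
}

#' Histogram of a DPA fit's bootstrap onset distributions
#'
#' One panel per condition: the bootstrap onsets (a diagnostic that makes
#' multimodal onset distributions visible), the distribution mean, and the
#' percentile-CI whiskers.
#'
#' @param x A `dpa` fit.
#' @param conditions Conditions to plot (default all).
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.dpa <- function(x, conditions = NULL, ...) {
  conds <- conditions %||% x$conditions
  old <- par(mfrow = c(1, length(conds)), mar = c(4, 4, 2, 1))
  on.exit(par(old), add = TRUE)
  bw <- x$config$bin_width_ms
  for (cond in conds) {
    bo <- x$fits[[cond]]$boot
    on <- bo$onsets[!is.na(bo$onsets)]
    if (!length(on)) {
      plot(NA, xlim = x$config$span, ylim = c(0, 1), xlab = "onset (ms)",
           ylab = "resamples", main = cond)
      mtext("no qualifying onsets", cex = 0.8)
      next
    }
    brks <- seq(x$config$span[1] - bw / 2, x$config$span[2] + bw / 2, bw)
    h <- hist(on, breaks = brks, plot = FALSE)
    hist(on, breaks = brks, col = "grey80", border = "white",
         xlab = "onset (ms)", main = cond, ...)
    y <- max(h$counts) * 1.02
    segments(bo$ci_low_ms, y, bo$ci_high_ms, y, lwd = 2)
    points(bo$mean_ms, y, pch = 19)
  }
  invisible(x)
}

#' Histogram of a divergence-point difference distribution
#'
#' The bootstrap differences with the distribution mean, percentile-CI
#' whiskers, and a dotted vertical line at zero difference.
#'
#' @param x A `dpa_diff` object.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.dpa_diff <- function(x, ...) {
  if (!length(x$diffs)) {
    plot(NA, xlim = c(-1, 1), ylim = c(0, 1), xlab = "difference (ms)",
         ylab = "resamples", main = x$label)
    mtext("difference undefined", cex = 0.8)
    return(invisible(x))
  }
  h <- hist(x$diffs, breaks = 20, plot = FALSE)
  hist(x$diffs, breaks = 20, col = "grey80", border = "white",
       xlab = "difference in divergence points (ms)", main = x$label, ...)
  abline(v = 0, lty = 3)
  y <- max(h$counts) * 1.02
  segments(x$ci_low_ms, y, x$ci_high_ms, y, lwd = 2)
  points(x$mean_ms, y, pch = 19)
  invisible(x)
}
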