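#' Trial window segmentation
#'
#' The blank-screen trial divides into three analysis windows: `preview`
#' (pictures on screen, no audio), `anticipation` (blank screen, audio
#' playing) and `integration` (pictures back on screen). Windows are
#' half-open on the right except the last, which includes the trial end.
#'
#' @param preview,anticipation,integration Two-element numeric vectors
#'   `c(start, end)` in ms. Defaults: `[0, 4000)`, `[4000, 7000)`,
#'   `[7000, 8000]`.
#' @return An object of class `gazedpa_window_spec`.
#' @export
window_spec <- function(preview = c(0, 4000),
                        anticipation = c(4000, 7000),
                        integration = c(7000, 8000)) {
  w <- list(preview = as.numeric(preview),
            anticipation = as.numeric(anticipation),
            integration = as.numeric(integration))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || any(!is.finite(w[[nm]])) ||
        w[[nm]][1] >= w[[nm]][2]) {
      stop("window '", nm, "' must be c(start, end) with start < end",
           call. = FALSE)
    }
  }
  b <- unlist(w, use.names = FALSE)
  if (is.unsorted(b[c(1, 2, 3, 4, 5, 6)]) ||
      w$preview[2] > w$anticipation[1] || w$anticipation[2] > w$integration[1]) {
    stop("windows must be disjoint and ordered", call. = FALSE)
  }
  structure(w, class = "gazedpa_window_spec")
}

#' @export
print.gazedpa_window_spec <- function(x, ...) {
  cat("Trial windows (ms):\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-12s [%g, %g%s\n", nm, x[[nm]][1], x[[nm]][2],
                if (nm == "integration") "]" else ")"))
  }
  invisible(x)
}

#' Assign timestamps to trial windows
#'
#' Membership is half-open, so a boundary timestamp belongs to the later
#' window (4,000 ms is `anticipation`); the trial-final boundary belongs to
#' `integration`.
#'
#' @param t Numeric vector of timestamps (ms since trial onset).
#' @param spec A [window_spec()].
#' @return Factor with levels `preview`, `anticipation`, `integration`.
#' @examples
#' assign_window(c(3500, 4000, 7200))
#' @export
assign_window <- function(t, spec = window_spec()) {
  stopifnot(inherits(spec, "gazedpa_window_spec"))
  if (any(t < spec$preview[1] | t > spec$integration[2], na.rm = TRUE)) {
    stop("timestamp outside the trial (", spec$preview[1], "-",
         spec$integration[2], " ms)", call. = FALSE)
  }
  lab <- ifelse(t < spec$anticipation[1], "preview",
                ifelse(t < spec$integration[1], "anticipation", "integration"))
  factor(lab, levels = c("preview", "anticipation", "integration"))
}

#' Bin role-labelled gaze samples into fixed-width time bins
#'
#' Counts looks to the factual and the illusory picture per 200 ms bin
#' (default), per participant x condition, optionally split by trial. Bins
#' are anchored at the start of the analysis span and are half-open
#' `[start, start + width)`. Sample totals are conserved: the counts sum to
#' the number of in-span samples.
#'
#' @param data A `gaze_dataset`, or a samples data frame with a `role`
#'   column (then `trials` must be given to supply conditions).
#' @param trials Trial table when `data` is a samples data frame.
#' @param bin_width_ms Bin width in ms (default 200).
#' @param span `c(start, end)` of the analysis span in ms; `bin_width_ms`
#'   must divide its length. Default `[4000, 8000)`, the anticipation plus
#'   integration windows.
#' @param by_trial Keep trial-level counts instead of aggregating to
#'   participant x condition cells.
#' @return Data frame with `participant_id`, `condition` (and `trial_id`,
#'   `item_id` if `by_trial`), `bin_start_ms`, `bin_end_ms`, `y_factual`,
#'   `y_illusory`, `n_total` (all in-span samples including `elsewhere`).
#' @export
bin_counts <- function(data, trials = NULL, bin_width_ms = 200,
                       span = c(4000, 8000), by_trial = FALSE) {
  xs <- as_analysis_tables(data, trials)
  samples <- xs$samples; trials <- xs$trials
  if (length(span) != 2L || span[1] >= span[2]) {
    stop("'span' must be c(start, end) with start < end", call. = FALSE)
  }
  len <- span[2] - span[1]
  if (len %% bin_width_ms != 0) {
    stop("'bin_width_ms' must divide the span length", call. = FALSE)
  }
  nb <- len %/% bin_width_ms
  edges <- span[1] + bin_width_ms * (seq_len(nb) - 1L)

  keep <- samples$t >= span[1] & samples$t < span[2] & !is.na(samples$role)
  s <- samples[keep, , drop = FALSE]
  if (!nrow(s)) stop("no samples fall inside the span", call. = FALSE)
  key <- trial_key(s$participant_id, s$trial_id)
  tkey <- trial_key(trials$participant_id, trials$trial_id)
  m <- match(key, tkey)
  if (anyNA(m)) stop("samples reference unknown trials", call. = FALSE)

  cell <- if (by_trial) {
    factor(tkey, levels = tkey)[m]
  } else {
    ckey <- paste(trials$participant_id, trials$condition, sep = "\r")
    factor(ckey, levels = unique(ckey))[m]
  }
  bin <- factor(edges[1L + (s$t - span[1]) %/% bin_width_ms], levels = edges)
  role <- factor(as.character(s$role),
                 levels = c("factual", "illusory", "elsewhere"))
  tab <- table(cell = cell, bin = bin, role = role)

  grid <- expand.grid(bin = seq_len(nb), cell = seq_len(nlevels(cell)),
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(cell = levels(cell)[grid$cell],
                    bin_start_ms = edges[grid$bin],
                    bin_end_ms = edges[grid$bin] + bin_width_ms,
                    y_factual = as.vector(t(tab[, , "factual"])),
                    y_illusory = as.vector(t(tab[, , "illusory"])),
                    stringsAsFactors = FALSE)
  out$n_total <- out$y_factual + out$y_illusory + as.vector(t(tab[, , "elsewhere"]))
  if (by_trial) {
    i <- match(out$cell, tkey)
    out <- cbind(trials[i, c("participant_id", "trial_id", "condition"),
                        drop = FALSE],
                 if ("item_id" %in% names(trials)) trials[i, "item_id", drop = FALSE],
                 out[, c("bin_start_ms", "bin_end_ms", "y_factual",
                         "y_illusory", "n_total")])
  } else {
    parts <- strsplit(out$cell, "\r", fixed = TRUE)
    out <- cbind(data.frame(participant_id = vapply(parts, `[`, "", 1L),
                            condition = vapply(parts, `[`, "", 2L),
                            stringsAsFactors = FALSE),
                 out[, c("bin_start_ms", "bin_end_ms", "y_factual",
                         "y_illusory", "n_total")])
  }
  rownames(out) <- NULL
  out
}

# normalise inputs to list(trials, samples with role)
as_analysis_tables <- function(data, trials = NULL) {
  if (inherits(data, "gaze_dataset")) {
    samples <- data$samples
    trials <- data$trials
  } else {
    samples <- data
    if (is.null(trials)) stop("'trials' required when passing raw samples",
                              call. = FALSE)
  }
  if (!"role" %in% names(samples)) {
    stop("samples carry no 'role' column; run assign_roles() first",
         call. = FALSE)
  }
  nonfiller <- is.na(trials$condition) | trials$condition != "filler"
  list(samples = samples, trials = trials[nonfiller, , drop = FALSE])
}

#' Weighted empirical logit of a binned count
#'
#' The empirical logit with the 0.5 bias correction,
#' `elog = log((y + 0.5) / (N - y + 0.5))`, finite for all counts including
#' `y = 0` and `y = N`, with its approximate sampling variance
#' `var = 1/(y + 0.5) + 1/(N - y + 0.5)`. Per-bin linear models weight each
#' observation by the inverse of that variance (`weight = 1/var`).
#'
#' @param y Successes (e.g. looks to the factual picture) per cell.
#' @param n Number of trials/samples per cell (`y <= n`). Cells with
#'   `n == 0` yield `NA` (flagged missing rather than an error, for batch
#'   use).
#' @return Data frame with columns `elog`, `var`, `weight`.
#' @examples
#' empirical_logit(c(5, 0, 10), 10)
#' @export
empirical_logit <- function(y, n) {
  if (length(n) == 1L) n <- rep(n, length(y))
  if (length(y) != length(n)) stop("'y' and 'n' must have equal length",
                                   call. = FALSE)
  if (any(y < 0 | y > n, na.rm = TRUE)) {
    stop("'y' must satisfy 0 <= y <= n", call. = FALSE)
  }
  ok <- !is.na(y) & !is.na(n) & n >= 1
  elog <- v <- rep(NA_real_, length(y))
  elog[ok] <- log((y[ok] + 0.5) / (n[ok] - y[ok] + 0.5))
  v[ok] <- 1 / (y[ok] + 0.5) + 1 / (n[ok] - y[ok] + 0.5)
  data.frame(elog = elog, var = v, weight = 1 / v)
}

#' Per-trial fixation proportions by window
#'
#' Computes, for every trial and window, the percentage of looks to the
#' factual and to the illusory picture. Two denominators are available:
#' `aoi_only` divides by factual + illusory looks (so the two roles sum to
#' 100% per trial), `all_samples` divides by every in-window sample
#' including looks elsewhere on the blank screen.
#'
#' @param data A `gaze_dataset` or role-labelled samples data frame.
#' @param trials Trial table when `data` is a samples data frame.
#' @param spec A [window_spec()].
#' @param denominator `"aoi_only"` (default) or `"all_samples"`.
#' @return Data frame with one row per trial x window x role:
#'   `participant_id`, `trial_id`, `condition`, `window`, `role`, `pct`,
#'   `n_denom`. Trials whose denominator is zero in a window are excluded
#'   with a message giving the count.
#' @export
proportions_by_window <- function(data, trials = NULL, spec = window_spec(),
                                  denominator = c("aoi_only", "all_samples")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(spec, "gazedpa_window_spec"))
  xs <- as_analysis_tables(data, trials)
  s <- xs$samples[!is.na(xs$samples$role), , drop = FALSE]
  s <- s[s$t >= spec$preview[1] & s$t <= spec$integration[2], , drop = FALSE]
  if (!nrow(s)) stop("no samples inside the trial windows", call. = FALSE)
  win <- assign_window(s$t, spec)
  key <- trial_key(s$participant_id, s$trial_id)
  tkey <- trial_key(xs$trials$participant_id, xs$trials$trial_id)
  m <- match(key, tkey)
  if (anyNA(m)) stop("samples reference unknown trials", call. = FALSE)
  cell <- factor(m, levels = seq_len(nrow(xs$trials)))
  role <- factor(as.character(s$role),
                 levels = c("factual", "illusory", "elsewhere"))
  tab <- table(cell = cell, win = win, role = role)   # trials x 3 x 3
  sl <- function(r) {   # role slice as a matrix even for a single trial
    m <- tab[, , r, drop = FALSE]
    dim(m) <- dim(tab)[1:2]
    dimnames(m) <- dimnames(tab)[1:2]
    m
  }
  den <- if (denominator == "aoi_only") {
    sl("factual") + sl("illusory")
  } else {
    sl("factual") + sl("illusory") + sl("elsewhere")
  }
  out <- NULL
  n_zero <- 0L
  for (w in colnames(den)) {
    d <- den[, w]
    zero <- d == 0
    n_zero <- n_zero + sum(zero)
    keep <- which(!zero)
    if (!length(keep)) next
    for (r in c("factual", "illusory")) {
      out <- rbind(out, data.frame(
        participant_id = xs$trials$participant_id[keep],
        trial_id = xs$trials$trial_id[keep],
        condition = as.character(xs$trials$condition[keep]),
        window = w, role = r,
        pct = 100 * sl(r)[keep, w] / d[keep],
        n_denom = as.integer(d[keep]),
        stringsAsFactors = FALSE))
    }
  }
  if (n_zero > 0) {
    message(n_zero, " trial-window cell(s) with zero denominator excluded")
  }
  out$window <- factor(out$window,
                       levels = c("preview", "anticipation", "integration"))
  rownames(out) <- NULL
  out
}
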