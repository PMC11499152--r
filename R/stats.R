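#' Window-level descriptive statistics of fixation proportions
#'
#' Mean and SD of per-trial fixation percentages for every window x
#' condition x role cell. Because it is not always obvious whether such
#' descriptives should average over trials or over participant means, both
#' aggregations are returned, labelled in the `aggregation` column
#' (`"trials"`: mean/SD across all trials; `"participants"`: participant
#' means first, then mean/SD across participants).
#'
#' @param props Per-trial proportions from [proportions_by_window()].
#' @return Data frame keyed by (`aggregation`, `window`, `condition`,
#'   `role`) with `mean_pct`, `sd_pct` and `n`. Empty cells are omitted with
#'   a warning.
#' @export
window_descriptives <- function(props) {
  check_cols(props, c("participant_id", "condition", "window", "role", "pct"),
             "proportions table")
  agg_cells <- function(df, label) {
    sp <- split(df$pct, list(df$window, df$condition, df$role), sep = "\r")
    keys <- strsplit(names(sp), "\r", fixed = TRUE)
    keep <- lengths(sp) > 0
    if (any(!keep)) {
      warning(sum(!keep), " empty cell(s) omitted from descriptives (",
              label, ")", call. = FALSE)
    }
    data.frame(aggregation = label,
               window = vapply(keys[keep], `[`, "", 1L),
               condition = vapply(keys[keep], `[`, "", 2L),
               role = vapply(keys[keep], `[`, "", 3L),
               mean_pct = vapply(sp[keep], mean, 0),
               sd_pct = vapply(sp[keep], function(v)
                 if (length(v) > 1L) sd(v) else 0, 0),
               n = lengths(sp[keep]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  by_trial <- agg_cells(props, "trials")
  pm <- aggregate(pct ~ participant_id + window + condition + role,
                  data = props, FUN = mean)
  by_part <- agg_cells(pm, "participants")
  out <- rbind(by_trial, by_part)
  out[order(out$aggregation, out$window, out$condition, out$role), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Per-trial total fixation length by target
#'
#' Total looking time per trial and fixation target (factual / illusory)
#' within one window, computed as the number of in-window gaze samples in
#' that role times the sampling period. This is the outcome variable of
#' [fit_fixation_lmm()].
#'
#' @param data A `gaze_dataset` or role-labelled samples data frame.
#' @param trials Trial table when `data` is a samples data frame.
#' @param window Window name (default `"anticipation"`).
#' @param spec A [window_spec()].
#' @param sample_period_ms Sampling period; taken from the dataset's
#'   simulation config when available, otherwise inferred as the median
#'   timestamp step.
#' @return Data frame with `participant_id`, `trial_id`, `item_id` (if
#'   available), `condition`, `target`, `fix_total_ms`; one row per trial x
#'   target, zeros included.
#' @export
fixation_totals <- function(data, trials = NULL, window = "anticipation",
                            spec = window_spec(), sample_period_ms = NULL) {
  xs <- as_analysis_tables(data, trials)
  if (is.null(sample_period_ms)) {
    sample_period_ms <- if (inherits(data, "gaze_dataset") &&
                            !is.null(data$config)) {
      data$config$sample_period_ms
    } else {
      tt <- sort(unique(xs$samples$t))
      as.numeric(median(diff(tt)))
    }
  }
  window <- match.arg(window, c("preview", "anticipation", "integration"))
  bounds <- spec[[window]]
  s <- xs$samples[!is.na(xs$samples$role), , drop = FALSE]
  s <- s[s$t >= bounds[1] &
           (if (window == "integration") s$t <= bounds[2] else s$t < bounds[2]),
         , drop = FALSE]
  tkey <- trial_key(xs$trials$participant_id, xs$trials$trial_id)
  ti <- match(trial_key(s$participant_id, s$trial_id), tkey)
  counts <- table(factor(ti, levels = seq_len(nrow(xs$trials))),
                  factor(as.character(s$role),
                         levels = c("factual", "illusory")))
  out <- data.frame(
    participant_id = rep(xs$trials$participant_id, 2L),
    trial_id = rep(xs$trials$trial_id, 2L),
    condition = rep(as.character(xs$trials$condition), 2L),
    target = rep(c("factual", "illusory"), each = nrow(xs$trials)),
    fix_total_ms = c(counts[, "factual"], counts[, "illusory"]) *
      sample_period_ms,
    stringsAsFactors = FALSE)
  if ("item_id" %in% names(xs$trials)) {
    out$item_id <- rep(xs$trials$item_id, 2L)
  }
  out$target <- factor(out$target, levels = c("factual", "illusory"))
  out$condition <- factor(out$condition)
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of total fixation length
#'
#' Fits the fixation-duration contract: total fixation length per trial x
#' target as outcome, fixed effects of fixation target (factual vs
#' illusory) crossed with condition under treatment contrasts, and a
#' maximal random-effect structure (by-participant intercept and full
#' target x condition slopes; by-item intercept and target slope). The
#' numerical optimisation is delegated to `lmerTest`/`lme4` (REML). On
#' non-convergence or a singular fit the random structure is simplified
#' step by step, and the simplification is reported via a warning.
#'
#' With the factual level as reference, a preference for the factual
#' picture shows up as a negative coefficient for the illusory target
#' level.
#'
#' @param totals Data frame from [fixation_totals()].
#' @param formula Optional model formula overriding the maximal default.
#' @param reml Fit by REML (default `TRUE`).
#' @return An object of class `fixation_lmm`: list with the fitted `model`,
#'   the fixed-effect table `coefficients` (beta, SE, df, t, p), the
#'   `formula` actually used, and `simplified` (`TRUE` if a reduced random
#'   structure was needed).
#' @export
fit_fixation_lmm <- function(totals, formula = NULL, reml = TRUE) {
  check_cols(totals, c("participant_id", "condition", "target",
                       "fix_total_ms"), "fixation totals")
  if (length(unique(totals$participant_id)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  has_item <- "item_id" %in% names(totals)
  if (has_item && length(unique(totals$item_id)) < 2L) {
    stop("need at least 2 items", call. = FALSE)
  }
  candidates <- if (!is.null(formula)) {
    list(as.formula(formula))
  } else if (has_item) {
    list(fix_total_ms ~ target * condition +
           (1 + target * condition | participant_id) + (1 + target | item_id),
         fix_total_ms ~ target * condition +
           (1 + target | participant_id) + (1 | item_id),
         fix_total_ms ~ target * condition +
           (1 | participant_id) + (1 | item_id))
  } else {
    list(fix_total_ms ~ target * condition + (1 + target | participant_id),
         fix_total_ms ~ target * condition + (1 | participant_id))
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  model <- NULL; used <- NULL; simplified <- FALSE
  for (i in seq_along(candidates)) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(candidates[[i]], data = totals,
                                      REML = reml, control = ctrl)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      if (grepl("rank deficient|fewer observations|number of levels",
                conditionMessage(fit))) {
        stop("model misspecified for these data: ", conditionMessage(fit),
             call. = FALSE)
      }
      next
    }
    singular <- tryCatch(lme4::isSingular(fit, tol = 1e-4),
                         error = function(e) FALSE)
    if (!singular || i == length(candidates) || !is.null(formula)) {
      model <- fit; used <- candidates[[i]]
      simplified <- is.null(formula) && i > 1L
      if (singular) {
        warning("random-effect structure singular even after simplification",
                call. = FALSE)
      }
      break
    }
  }
  if (is.null(model)) stop("no candidate mixed model could be fitted",
                           call. = FALSE)
  if (simplified) {
    warning("maximal random structure did not converge cleanly; simplified to: ",
            deparse(used), call. = FALSE)
  }
  cf <- as.data.frame(summary(model)$coefficients)
  names(cf) <- c("beta", "se", "df", "t", "p")[seq_len(ncol(cf))]
  structure(list(model = model, coefficients = cf, formula = used,
                 simplified = simplified),
            class = "fixation_lmm")
}

#' @export
print.fixation_lmm <- function(x, ...) {
  cat("Mixed model of total fixation length (REML via lme4)\n")
  cat("  formula:", deparse(x$formula), "\n")
  if (x$simplified) cat("  note: random structure simplified\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Correlation of proficiency with anticipatory fixation proportions
#'
#' Pearson correlation, per condition, between participants' language
#' proficiency scores and their mean fixation percentage on the factual
#' picture in the anticipation window.
#'
#' @param data A `gaze_dataset` whose `participants` table has a
#'   `proficiency` column.
#' @param conditions Conditions to report (default all in the data).
#' @param spec A [window_spec()].
#' @param denominator Passed to [proportions_by_window()].
#' @param window Window whose factual proportions are used (default
#'   `"anticipation"`).
#' @return Data frame with one row per condition: `condition`, `r`, `p`,
#'   `n`. Conditions where either variable has zero variance get `NA` with a
#'   warning.
#' @export
proficiency_correlation <- function(data, conditions = NULL,
                                    spec = window_spec(),
                                    denominator = "aoi_only",
                                    window = "anticipation") {
  stopifnot(inherits(data, "gaze_dataset"))
  if (is.null(data$participants) ||
      !"proficiency" %in% names(data$participants)) {
    stop("dataset carries no participant proficiency scores", call. = FALSE)
  }
  props <- suppressMessages(
    proportions_by_window(data, spec = spec, denominator = denominator))
  props <- props[props$window == window & props$role == "factual", ,
                 drop = FALSE]
  conditions <- conditions %||% sort(unique(props$condition))
  rows <- lapply(conditions, function(cond) {
    pc <- props[props$condition == cond, , drop = FALSE]
    pm <- tapply(pc$pct, pc$participant_id, mean)
    prof <- data$participants$proficiency[
      match(names(pm), data$participants$participant_id)]
    ok <- is.finite(pm) & is.finite(prof)
    pm <- pm[ok]; prof <- prof[ok]
    if (length(pm) < 3L || sd(pm) == 0 || sd(prof) == 0) {
      warning("correlation undefined for condition '", cond,
              "' (zero variance or too few participants)", call. = FALSE)
      return(data.frame(condition = cond, r = NA_real_, p = NA_real_,
                        n = length(pm)))
    }
    ct <- cor.test(prof, pm, method = "pearson")
    data.frame(condition = cond, r = unname(ct$estimate), p = ct$p.value,
               n = length(pm))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Button-response accuracy per condition
#'
#' @param data A `gaze_dataset` or trial table with `condition` and
#'   `response_correct`.
#' @return Data frame per condition (and language, when present):
#'   `n_trials`, `n_correct`, `accuracy_pct` (to 2 decimals).
#' @export
accuracy_summary <- function(data) {
  trials <- if (inherits(data, "gaze_dataset")) data$trials else data
  check_cols(trials, c("condition", "response_correct"), "trials")
  trials <- trials[!is.na(trials$condition) & trials$condition != "filler", ,
                   drop = FALSE]
  keys <- if ("language" %in% names(trials)) {
    list(condition = trials$condition, language = trials$language)
  } else {
    list(condition = trials$condition)
  }
  agg <- aggregate(trials$response_correct,
                   by = keys,
                   FUN = function(v) c(n = length(v), k = sum(v)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    n_trials = agg$x[, "n"], n_correct = agg$x[, "k"])
  out$accuracy_pct <- round(100 * out$n_correct / out$n_trials, 2)
  out[order(out$condition), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Power of a paired (two dependent means) t-test
#'
#' @param n Sample size (number of pairs).
#' @param d Standardised effect size for dependent means (Cohen's dz).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power of the paired t-test with `n - 1` degrees of freedom and
#'   noncentrality `d * sqrt(n)`.
#' @seealso [paired_sample_size()]
#' @export
paired_power <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  dfree <- n - 1
  ncp <- d * sqrt(n)
  if (tails == 2) {
    q <- qt(1 - alpha / 2, dfree)
    pt(q, dfree, ncp = ncp, lower.tail = FALSE) + pt(-q, dfree, ncp = ncp)
  } else {
    q <- qt(1 - alpha, dfree)
    pt(q, dfree, ncp = ncp, lower.tail = FALSE)
  }
}

#' A-priori sample size for two dependent means
#'
#' Smallest integer `n` such that a paired t-test with `n - 1` degrees of
#' freedom and noncentrality `d * sqrt(n)` reaches the requested power,
#' found by iterating the noncentral-t power function over `n`. For a
#' medium effect `d = 0.5` at `alpha = 0.05` and power 0.80 (two-tailed)
#' this returns 34.
#'
#' @param d Effect size (Cohen's dz) for the paired comparison.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param tails 1 or 2 (default 2).
#' @param n_max Search bound; exceeding it raises an "unreachable power"
#'   error.
#' @return Required sample size (integer).
#' @examples
#' paired_sample_size(d = 0.5)          # 34
#' paired_sample_size(d = 2.0)          # 5
#' @export
paired_sample_size <- function(d, alpha = 0.05, power = 0.8, tails = 2,
                               n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2
  while (paired_power(n, d, alpha, tails) < power) {
    n <- n + 1
    if (n > n_max) {
      stop("requested power unreachable within n_max pairs", call. = FALSE)
    }
  }
  as.integer(n)
}
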