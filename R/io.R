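#' Write a gaze dataset to delimiter-separated files
#'
#' Writes `trials.csv`, `samples.csv` and (when present) `participants.csv`
#' into `dir`, plus a `config.json` echo of the simulation configuration if
#' the dataset carries one. Column names are stable and match what
#' [read_gaze_dataset()] expects.
#'
#' @param dataset A `gaze_dataset` (from [simulate_gaze()] or
#'   [read_gaze_dataset()]).
#' @param dir Output directory; created if absent.
#' @return Invisibly, the paths written.
#' @export
write_gaze_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gaze_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             samples = file.path(dir, "samples.csv"))
  write.csv(dataset$trials, paths[["trials"]], row.names = FALSE)
  write.csv(dataset$samples, paths[["samples"]], row.names = FALSE)
  if (!is.null(dataset$participants)) {
    paths <- c(paths, participants = file.path(dir, "participants.csv"))
    write.csv(dataset$participants, paths[["participants"]], row.names = FALSE)
  }
  if (!is.null(dataset$config)) {
    paths <- c(paths, config = file.path(dir, "config.json"))
    jsonlite::write_json(strip_classes(dataset$config), paths[["config"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(paths)
}

# turn nested classed lists into plain lists for JSON echo
strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Read a gaze dataset from delimiter-separated files
#'
#' Reads a trial table and a gaze-sample log (plus an optional participant
#' table) and validates them: required columns must be present (a missing
#' column raises a schema error naming it), timestamps must parse as
#' non-negative numbers (an unparseable value raises a row-level error naming
#' the file and line), and gaze coordinates must be finite.
#'
#' External logs with different column names can be ingested by supplying
#' `col_map`, a named character vector mapping the canonical names used here
#' to the names in the file, e.g. `c(t = "time_ms", x = "gaze_x")`.
#'
#' @param trials Path to the trial table, or a directory containing
#'   `trials.csv` / `samples.csv` (and optionally `participants.csv`).
#' @param samples Path to the sample log (ignored when `trials` is a
#'   directory).
#' @param participants Optional path to a participant table.
#' @param col_map Optional named character vector renaming file columns to
#'   the canonical schema.
#' @param quiet Suppress the row-count message.
#' @return A `gaze_dataset`: list with `trials`, `samples` and optionally
#'   `participants` data frames.
#' @export
read_gaze_dataset <- function(trials, samples = NULL, participants = NULL,
                              col_map = NULL, quiet = FALSE) {
  if (length(trials) == 1L && dir.exists(trials)) {
    dir <- trials
    trials <- file.path(dir, "trials.csv")
    samples <- file.path(dir, "samples.csv")
    pf <- file.path(dir, "participants.csv")
    if (is.null(participants) && file.exists(pf)) participants <- pf
  }
  for (p in c(trials, samples, participants)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  remap <- function(df) {
    if (is.null(col_map)) return(df)
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
    df
  }
  tr <- remap(read.csv(trials, stringsAsFactors = FALSE))
  check_cols(tr, c("participant_id", "trial_id", "condition"),
             paste0("trials file '", basename(trials), "'"))
  sm <- remap(read.csv(samples, stringsAsFactors = FALSE))
  check_cols(sm, c("participant_id", "trial_id", "t", "x", "y"),
             paste0("samples file '", basename(samples), "'"))

  sm$t <- parse_numeric(sm$t, "t", basename(samples))
  if (any(sm$t < 0)) {
    stop("negative timestamp at ", basename(samples), " line ",
         which(sm$t < 0)[1L] + 1L, call. = FALSE)
  }
  sm$x <- parse_numeric(sm$x, "x", basename(samples))
  sm$y <- parse_numeric(sm$y, "y", basename(samples))
  if (any(!is.finite(sm$x)) || any(!is.finite(sm$y))) {
    bad <- which(!is.finite(sm$x) | !is.finite(sm$y))[1L]
    stop("non-finite gaze coordinate at ", basename(samples), " line ",
         bad + 1L, call. = FALSE)
  }

  nonfiller <- tr$condition != "filler" & !is.na(tr$condition)
  if ("factual_side" %in% names(tr)) {
    if (any(nonfiller & (is.na(tr$factual_side) | tr$factual_side == ""))) {
      stop("factual_side missing for a non-filler trial", call. = FALSE)
    }
  }
  if ("audio_duration_ms" %in% names(tr)) {
    out <- nonfiller & !is.na(tr$audio_duration_ms) &
      (tr$audio_duration_ms < 2500 | tr$audio_duration_ms > 3000)
    if (any(out)) {
      warning(sum(out), " trial(s) with audio_duration_ms outside [2500, 3000]",
              call. = FALSE)
    }
  }
  if ("role" %in% names(sm)) {
    sm$role <- factor(sm$role, levels = c("factual", "illusory", "elsewhere"))
  }
  pt <- if (!is.null(participants)) {
    p <- remap(read.csv(participants, stringsAsFactors = FALSE))
    check_cols(p, "participant_id",
               paste0("participants file '", basename(participants), "'"))
    p
  }
  if (!quiet) {
    message("read ", nrow(tr), " trials, ", nrow(sm), " gaze samples",
            if (!is.null(pt)) paste0(", ", nrow(pt), " participants"))
  }
  new_gaze_dataset(trials = tr, samples = sm, participants = pt)
}

parse_numeric <- function(v, name, file) {
  if (is.numeric(v)) return(v)
  num <- suppressWarnings(as.numeric(v))
  bad <- is.na(num) & !is.na(v) & v != ""
  if (any(bad)) {
    stop("unparseable '", name, "' value '", v[which(bad)[1L]], "' at ",
         file, " line ", which(bad)[1L] + 1L, call. = FALSE)
  }
  num
}

new_gaze_dataset <- function(trials, samples, participants = NULL,
                             config = NULL, layout = NULL) {
  structure(list(trials = trials, samples = samples,
                 participants = participants, config = config,
                 layout = layout),
            class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  conds <- setdiff(unique(as.character(x$trials$condition)), "filler")
  cat("Blank-screen visual-world gaze dataset\n")
  cat("  ", length(unique(x$trials$participant_id)), " participants, ",
      nrow(x$trials), " trials, ", nrow(x$samples), " gaze samples\n", sep = "")
  cat("  conditions:", paste(conds, collapse = ", "), "\n")
  if (!is.null(x$config)) {
    tau <- x$config$true_onset_ms
    cat("  simulated (", x$config$language, "), true onsets: ",
        paste(sprintf("%s = %g ms", names(tau), tau), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
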