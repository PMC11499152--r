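# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 ||
      x != round(x)) {
    stop("'", name, "' must be a single positive integer", call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, open_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1 ||
      (open_zero && x == 0)) {
    stop("'", name, "' must be a probability in ", if (open_zero) "(0, 1]" else "[0, 1]",
         call. = FALSE)
  }
  as.numeric(x)
}

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error: column '", miss[1L], "' missing from ", what,
         call. = FALSE)
  }
  invisible(df)
}

# trial-level key used to join samples to trial metadata
trial_key <- function(participant_id, trial_id) {
  paste(participant_id, trial_id, sep = "\r")
}
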