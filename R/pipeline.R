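#' Run the full blank-screen DPA pipeline from one configuration
#'
#' Orchestrates an end-to-end run — simulate (or ingest), assign roles, bin,
#' divergence point analysis, condition and between-language contrasts,
#' descriptive statistics, mixed model, proficiency correlations, accuracy,
#' figures — writing tidy CSV tables, PNG figures and a machine-readable
#' JSON manifest into an output directory. Runs are deterministic given the
#' configured seed.
#'
#' @param config A list, or path to a YAML/JSON file, with elements:
#'   \describe{
#'     \item{seed}{integer; master seed for the run.}
#'     \item{output_dir}{where tables/figures/manifest are written.}
#'     \item{simulation}{either a single block of [sim_config()] arguments
#'       or a named list of blocks (one per language dataset). Exactly one
#'       of `simulation` / `inputs` must be present.}
#'     \item{inputs}{list with `trials`, `samples`, optionally
#'       `participants` file paths (or a single `dir`).}
#'     \item{layout}{[aoi_layout()] arguments, needed when ingested samples
#'       carry no `role` column.}
#'     \item{windows}{[window_spec()] arguments.}
#'     \item{dpa}{[dpa_config()] arguments.}
#'     \item{lmm}{`list(enabled =, windows =, formula =)` controlling the
#'       fixation-duration mixed model (default: enabled, anticipation and
#'       integration windows, maximal random structure).}
#'     \item{figures}{logical; write PNG figures (default `TRUE`).}
#'   }
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, the report bundle: per-dataset fits and tables, the
#'   contrast objects, and the manifest. Any stage failure aborts with an
#'   error naming the stage; outputs written before the failure are kept.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  has_sim <- !is.null(config$simulation)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in) {
    stop("config must contain exactly one of 'simulation' or 'inputs'",
         call. = FALSE)
  }
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  written <- character()
  emit_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    write.csv(df, path, row.names = FALSE)
    written <<- c(written, file)
  }
  figures <- config$figures %||% TRUE

  windows <- stage("windows", do.call(window_spec, config$windows %||% list()))
  dpa_args <- config$dpa %||% list()

  # ---- obtain datasets -------------------------------------------------
  datasets <- stage("data", {
    if (has_sim) {
      blocks <- config$simulation
      single <- any(c("n_participants", "true_onset_ms", "conditions",
                      "seed", "language") %in% names(blocks))
      if (single) blocks <- list(main = blocks)
      ds <- list()
      for (i in seq_along(blocks)) {
        blk <- blocks[[i]]
        if (!is.null(blk$true_onset_ms)) {
          blk$true_onset_ms <- unlist(blk$true_onset_ms)
        }
        if (!is.null(blk$layout) && !inherits(blk$layout, "gazedpa_aoi_layout")) {
          blk$layout <- do.call(aoi_layout, blk$layout)
        }
        if (is.null(blk$seed)) blk$seed <- seed + i
        if (is.null(blk$language)) blk$language <- names(blocks)[i]
        ds[[names(blocks)[i]]] <- simulate_gaze(do.call(sim_config, blk))
      }
      ds
    } else {
      inp <- config$inputs
      d <- if (!is.null(inp$dir)) {
        read_gaze_dataset(inp$dir, quiet = TRUE)
      } else {
        read_gaze_dataset(inp$trials, inp$samples, inp$participants,
                          col_map = unlist(inp$col_map), quiet = TRUE)
      }
      if (!"role" %in% names(d$samples)) {
        if (is.null(config$layout)) {
          stop("samples carry no roles and no 'layout' block is configured")
        }
        lay <- do.call(aoi_layout, config$layout)
        d$samples <- assign_roles(d$samples, d$trials, lay)
        d$layout <- lay
      }
      nm <- if (!is.null(d$trials$language)) as.character(d$trials$language[1L]) else "main"
      setNames(list(d), nm)
    }
  })

  # ---- per-dataset analyses -------------------------------------------
  bundle <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    tag <- if (length(datasets) > 1L) paste0(nm, "_") else ""

    props <- stage("proportions",
                   suppressMessages(proportions_by_window(d, spec = windows)))
    desc <- stage("descriptives",
                  suppressWarnings(window_descriptives(props)))
    emit_csv(desc, paste0(tag, "descriptives.csv"))

    acc <- stage("accuracy", accuracy_summary(d))
    emit_csv(acc, paste0(tag, "accuracy.csv"))

    dcfg <- stage("dpa_config", do.call(
      dpa_config, modifyList(list(seed = seed + 1000L + match(nm, names(datasets))),
                             dpa_args)))
    binned <- stage("binning",
                    bin_counts(d, bin_width_ms = dcfg$bin_width_ms,
                               span = dcfg$span))
    el <- empirical_logit(binned$y_factual,
                          binned$y_factual + binned$y_illusory)
    emit_csv(cbind(binned, el), paste0(tag, "binned.csv"))

    fit <- stage("dpa", dpa(d, config = dcfg))
    emit_csv(summary(fit), paste0(tag, "divergence_points.csv"))
    emit_csv(coef(fit), paste0(tag, "bin_tests.csv"))
    boots <- do.call(rbind, lapply(fit$conditions, function(cond) {
      data.frame(condition = cond, resample = seq_len(dcfg$n_boot),
                 onset_ms = fit$fits[[cond]]$boot$onsets)
    }))
    emit_csv(boots, paste0(tag, "bootstrap_onsets.csv"))

    contrasts <- stage("contrasts", condition_contrasts(fit))
    if (length(contrasts)) {
      ct <- do.call(rbind, lapply(names(contrasts), function(k) {
        x <- contrasts[[k]]
        data.frame(contrast = k, mean_ms = x$mean_ms, ci_low_ms = x$ci_low_ms,
                   ci_high_ms = x$ci_high_ms, excludes_zero = x$excludes_zero,
                   n_pairs = x$n_pairs, n_dropped = x$n_dropped)
      }))
      emit_csv(ct, paste0(tag, "condition_differences.csv"))
    }

    lmm_cfg <- config$lmm %||% list()
    lmms <- list()
    if (lmm_cfg$enabled %||% TRUE) {
      for (w in lmm_cfg$windows %||% c("anticipation", "integration")) {
        lmms[[w]] <- stage(paste0("lmm_", w), {
          tot <- fixation_totals(d, window = w, spec = windows)
          suppressWarnings(fit_fixation_lmm(tot, formula = lmm_cfg$formula))
        })
        cf <- lmms[[w]]$coefficients
        emit_csv(cbind(term = rownames(cf), cf),
                 paste0(tag, "lmm_", w, ".csv"))
      }
    }

    cors <- NULL
    if (!is.null(d$participants) &&
        "proficiency" %in% names(d$participants)) {
      cors <- stage("correlations",
                    suppressWarnings(proficiency_correlation(d, spec = windows)))
      emit_csv(cors, paste0(tag, "proficiency_correlations.csv"))
    }

    if (figures) {
      stage("figures", {
        fig <- function(file, w, h, code) {
          path <- file.path(out_dir, file)
          png(path, width = w, height = h)
          on.exit(dev.off(), add = TRUE)
          code
          written <<- c(written, file)
        }
        fig(paste0(tag, "fixation_curves.png"), 1100, 360,
            plot_fixation_curves(d, fit = fit, spec = windows,
                                 bin_width_ms = dcfg$bin_width_ms))
        fig(paste0(tag, "onset_histograms.png"), 1100, 360, plot(fit))
        for (k in names(contrasts)) {
          fig(paste0(tag, "diff_", k, ".png"), 500, 400,
              plot(contrasts[[k]]))
        }
      })
    }
    bundle[[nm]] <- list(dataset = d, proportions = props,
                         descriptives = desc, accuracy = acc, dpa = fit,
                         contrasts = contrasts, lmm = lmms,
                         correlations = cors)
  }

  # ---- between-language contrasts -------------------------------------
  if (length(datasets) >= 2L) {
    nms <- names(datasets)[1:2]
    shared <- intersect(bundle[[nms[1]]]$dpa$conditions,
                        bundle[[nms[2]]]$dpa$conditions)
    lang_conds <- intersect(config$between_language_conditions %||%
                              c("negative", "nobody"), shared)
    bl <- stage("between_language", lapply(lang_conds, function(cond) {
      between_language_difference(bundle[[nms[1]]]$dpa,
                                  bundle[[nms[2]]]$dpa, cond)
    }))
    names(bl) <- lang_conds
    if (length(bl)) {
      blt <- do.call(rbind, lapply(lang_conds, function(cond) {
        x <- bl[[cond]]
        data.frame(condition = cond, direction = x$label,
                   mean_ms = x$mean_ms, ci_low_ms = x$ci_low_ms,
                   ci_high_ms = x$ci_high_ms, excludes_zero = x$excludes_zero,
                   n_pairs = x$n_pairs, n_dropped = x$n_dropped)
      }))
      emit_csv(blt, "between_language_differences.csv")
      if (figures) {
        stage("figures_between_language", for (cond in lang_conds) {
          path <- file.path(out_dir, paste0("diff_language_", cond, ".png"))
          png(path, width = 500, height = 400)
          plot(bl[[cond]])
          dev.off()
          written <- c(written, basename(path))
        })
      }
    }
    bundle$between_language <- bl
  }

  # ---- manifest --------------------------------------------------------
  manifest <- list(seed = seed,
                   package = "gazedpa",
                   package_version = as.character(utils::packageVersion("gazedpa")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = strip_classes(config),
                   outputs = sort(unique(written)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}
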