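#' Area-of-interest layout for a two-picture display
#'
#' Describes the screen and the two lateral picture rectangles of a
#' blank-screen visual-world display. During the anticipation window the
#' screen is blank, but looks are scored against the *remembered* picture
#' positions, so the same rectangles are used throughout the trial.
#' Coordinates follow the web convention: origin at the top-left corner,
#' `y` increasing downward, units in pixels.
#'
#' Rectangle membership is half-open, `[x0, x0 + w) x [y0, y0 + h)`, so a
#' sample on a shared boundary can never be counted in two regions.
#'
#' @param screen_w,screen_h Screen size in pixels.
#' @param left_rect,right_rect Numeric vectors `c(x0, y0, w, h)` giving the
#'   top-left corner and size of each picture rectangle. Defaults place two
#'   300 x 300 px pictures symmetrically on a 1280 x 720 screen.
#' @param padding_px Optional margin added around each rectangle when scoring
#'   gaze samples (default 0; the bare picture area).
#' @return An object of class `gazedpa_aoi_layout`.
#' @examples
#' layout <- aoi_layout()
#' layout
#' @export
aoi_layout <- function(screen_w = 1280, screen_h = 720,
                       left_rect = c(x0 = 170, y0 = 210, w = 300, h = 300),
                       right_rect = c(x0 = 810, y0 = 210, w = 300, h = 300),
                       padding_px = 0) {
  as_rect <- function(r, name) {
    r <- as.numeric(r)
    if (length(r) != 4L || any(!is.finite(r)) || r[3] <= 0 || r[4] <= 0) {
      stop("'", name, "' must be c(x0, y0, w, h) with positive size", call. = FALSE)
    }
    names(r) <- c("x0", "y0", "w", "h")
    r
  }
  L <- as_rect(left_rect, "left_rect")
  R <- as_rect(right_rect, "right_rect")
  if (padding_px < 0) stop("'padding_px' must be >= 0", call. = FALSE)
  pad <- function(r) c(r[1] - padding_px, r[2] - padding_px,
                       r[3] + 2 * padding_px, r[4] + 2 * padding_px)
  Lp <- pad(L); Rp <- pad(R)
  overlap_x <- Lp[1] < Rp[1] + Rp[3] && Rp[1] < Lp[1] + Lp[3]
  overlap_y <- Lp[2] < Rp[2] + Rp[4] && Rp[2] < Lp[2] + Lp[4]
  if (overlap_x && overlap_y) {
    stop("left and right rectangles overlap (after padding)", call. = FALSE)
  }
  structure(list(screen_w = as.numeric(screen_w), screen_h = as.numeric(screen_h),
                 left_rect = L, right_rect = R, padding_px = as.numeric(padding_px)),
            class = "gazedpa_aoi_layout")
}

#' @export
print.gazedpa_aoi_layout <- function(x, ...) {
  cat("AOI layout (", x$screen_w, "x", x$screen_h, "px screen)\n", sep = "")
  fmt <- function(r) sprintf("(%g, %g) %g x %g px", r[1], r[2], r[3], r[4])
  cat("  left : ", fmt(x$left_rect), "\n", sep = "")
  cat("  right: ", fmt(x$right_rect), "\n", sep = "")
  if (x$padding_px > 0) cat("  padding:", x$padding_px, "px\n")
  invisible(x)
}

# half-open membership test, padding applied
in_rect <- function(x, y, rect, padding = 0) {
  x >= rect[1] - padding & x < rect[1] + rect[3] + padding &
    y >= rect[2] - padding & y < rect[2] + rect[4] + padding
}

#' Map gaze samples to factual / illusory / elsewhere roles
#'
#' Classifies each gaze sample by which remembered picture rectangle it falls
#' in, then relabels the two sides by the trial's `factual_side`: the
#' rectangle where the factual (correct) picture was shown becomes `factual`,
#' the other becomes `illusory`, and anything outside both is `elsewhere`.
#' Samples are used directly; no fixation-event parsing (dispersion or
#' velocity filtering) is applied, since the analysis works with proportions
#' of looks per time bin.
#'
#' @param samples Data frame of gaze samples with columns `participant_id`,
#'   `trial_id`, `t`, `x`, `y`.
#' @param trials Data frame with columns `participant_id`, `trial_id`,
#'   `factual_side` (`"left"` or `"right"`); additional columns are carried
#'   along for the join but not used.
#' @param layout An [aoi_layout()].
#' @return `samples` with a `role` column added (factor with levels
#'   `factual`, `illusory`, `elsewhere`). Samples from trials with no
#'   `factual_side` (e.g. fillers) get `NA` roles.
#' @examples
#' lay <- aoi_layout()
#' tr <- data.frame(participant_id = "P01", trial_id = 1, factual_side = "left")
#' sm <- data.frame(participant_id = "P01", trial_id = 1,
#'                  t = c(0, 50), x = c(320, 5), y = c(360, 5))
#' assign_roles(sm, tr, lay)$role
#' @export
assign_roles <- function(samples, trials, layout) {
  stopifnot(inherits(layout, "gazedpa_aoi_layout"))
  check_cols(samples, c("participant_id", "trial_id", "t", "x", "y"), "samples")
  check_cols(trials, c("participant_id", "trial_id", "factual_side"), "trials")
  side <- as.character(trials$factual_side)
  bad <- !is.na(side) & !side %in% c("left", "right")
  if (any(bad)) {
    stop("factual_side must be 'left' or 'right' (got '",
         side[which(bad)[1L]], "')", call. = FALSE)
  }
  key <- trial_key(samples$participant_id, samples$trial_id)
  tkey <- trial_key(trials$participant_id, trials$trial_id)
  m <- match(key, tkey)
  if (anyNA(m)) {
    stop("samples reference trials absent from the trial table", call. = FALSE)
  }
  s_side <- side[m]
  inL <- in_rect(samples$x, samples$y, layout$left_rect, layout$padding_px)
  inR <- in_rect(samples$x, samples$y, layout$right_rect, layout$padding_px)
  role <- rep("elsewhere", nrow(samples))
  role[(inL & s_side == "left") | (inR & s_side == "right")] <- "factual"
  role[(inL & s_side == "right") | (inR & s_side == "left")] <- "illusory"
  role[is.na(s_side)] <- NA_character_
  samples$role <- factor(role, levels = c("factual", "illusory", "elsewhere"))
  samples
}
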