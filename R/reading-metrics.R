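#' Word length class
#'
#' Words of 1-6 letters are "short", 7-11 letters "long"; lengths outside
#' 1-11 are unclassified (`NA`) and excluded from length analyses.
#'
#' @param n_chars Integer vector of word lengths.
#' @return Character vector "short"/"long"/`NA`.
#' @examples
#' word_length_class(c(5, 6, 7, 12)) # short short long NA
#' @export
word_length_class <- function(n_chars) {
  ifelse(n_chars >= 1 & n_chars <= 6, "short",
         ifelse(n_chars >= 7 & n_chars <= 11, "long", NA_character_))
}

#' Assign fixations to word regions of interest
#'
#' A fixation belongs to the word whose padded box contains its barycenter;
#' fixations in no padded box are unassigned (`NA`). Horizontal padding
#' defaults to half the inter-word space (half a character cell on each side)
#' and vertical padding to one line height; padded boxes must not overlap.
#' Consecutive fixations on the same word form one visit streak, numbered in
#' time order per word.
#'
#' @param fixations Fixation table from [segment_trajectory()] (ordered by
#'   time).
#' @param word_boxes Word geometry from [render_text()].
#' @param pad_x,pad_y Padding in px; `NULL` for the defaults above.
#' @return `fixations` with added columns `word_index`, `word`, and `visit`
#'   (visit-streak number within the word, `NA` when unassigned).
#' @export
assign_fixations <- function(fixations, word_boxes, pad_x = NULL, pad_y = NULL) {
  if (is.null(pad_x)) pad_x <- word_boxes$char_width[1] / 2
  if (is.null(pad_y)) pad_y <- word_boxes$height[1]
  x0 <- word_boxes$origin_x - pad_x
  x1 <- word_boxes$origin_x + word_boxes$n_chars * word_boxes$char_width + pad_x
  y0 <- word_boxes$origin_y - pad_y
  y1 <- word_boxes$origin_y + word_boxes$height + pad_y
  for (i in seq_along(x0)) {
    same_line <- which(word_boxes$line_index == word_boxes$line_index[i])
    overlap <- same_line[same_line != i & x0[same_line] < x1[i] &
                         x1[same_line] > x0[i]]
    if (length(overlap)) {
      stop("padded word boxes overlap: \"", word_boxes$text[i], "\" and \"",
           word_boxes$text[overlap[1]], "\"; reduce `pad_x`", call. = FALSE)
    }
  }
  widx <- rep(NA_integer_, nrow(fixations))
  for (k in seq_len(nrow(fixations))) {
    hit <- which(fixations$barycenter_x[k] >= x0 &
                 fixations$barycenter_x[k] < x1 &
                 fixations$barycenter_y[k] >= y0 &
                 fixations$barycenter_y[k] < y1)
    if (length(hit)) widx[k] <- hit[1]
  }
  fixations$word_index <- widx
  fixations$word <- ifelse(is.na(widx), NA_character_, word_boxes$text[widx])
  # visit streaks: a new visit starts whenever the assigned word changes
  visit <- rep(NA_integer_, nrow(fixations))
  counters <- integer(nrow(word_boxes))
  prev <- NA_integer_
  for (k in seq_len(nrow(fixations))) {
    w <- widx[k]
    if (is.na(w)) { prev <- NA_integer_; next }
    if (is.na(prev) || w != prev) counters[w] <- counters[w] + 1L
    visit[k] <- counters[w]
    prev <- w
  }
  fixations$visit <- visit
  fixations
}

#' First-fixation landing position on a word
#'
#' The landing position is the horizontal offset of the first fixation's
#' barycenter from the word's left edge, in continuous character units: the
#' first letter spans \[0, 1). Values may fall slightly outside
#' \[0, n_chars\] under ROI padding; `clip = TRUE` (the reporting default)
#' clips to that interval while the raw value is returned when `clip = FALSE`.
#'
#' @param word_box One row of word geometry.
#' @param barycenter_x X of the word's first fixation, px.
#' @param clip Clip to \[0, n_chars\]?
#' @return Landing position in character units.
#' @examples
#' wb <- data.frame(origin_x = 500, char_width = 20, n_chars = 7)
#' first_fixation_landing(wb, 530) # 1.5
#' @export
first_fixation_landing <- function(word_box, barycenter_x, clip = TRUE) {
  landing <- (barycenter_x - word_box$origin_x) / word_box$char_width
  if (clip) landing <- pmin(pmax(landing, 0), word_box$n_chars)
  landing
}

#' Word-level reading measures for one trial
#'
#' Joins segmented fixations to word geometry and reports, per word: the
#' first-fixation landing position (character units), the number of fixations
#' received, the number of visit streaks, and the word-length class.
#'
#' @param fixations Fixation table for one trial.
#' @param word_boxes Word geometry from [render_text()].
#' @param ... Passed to [assign_fixations()].
#' @return A data.frame with one row per word: `word`, `n_chars`,
#'   `length_class`, `first_landing` (`NA` for unfixated words),
#'   `n_fixations`, `n_visits`.
#' @export
word_fixation_metrics <- function(fixations, word_boxes, ...) {
  af <- assign_fixations(fixations, word_boxes, ...)
  out <- data.frame(word = word_boxes$text,
                    n_chars = word_boxes$n_chars,
                    length_class = word_length_class(word_boxes$n_chars),
                    first_landing = NA_real_,
                    n_fixations = 0L, n_visits = 0L,
                    stringsAsFactors = FALSE)
  for (w in seq_len(nrow(word_boxes))) {
    rows <- which(af$word_index == w)
    if (!length(rows)) next
    out$n_fixations[w] <- length(rows)
    out$n_visits[w] <- max(af$visit[rows])
    first <- rows[which.min(af$start_t[rows])]
    out$first_landing[w] <- first_fixation_landing(word_boxes[w, ],
                                                   af$barycenter_x[first])
  }
  out
}

#' Group density curve of first-fixation landing positions
#'
#' Kernel density of one word's per-subject first-fixation X positions
#' (character units), pooled within a decoder group. The bandwidth is
#' `bandwidth_factor` (default 0.4) times the reference rule
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (the nrd0 rule, [stats::bw.nrd0()]),
#' and the curve is scaled by the group size so that it integrates to the
#' number of subjects, making curves of unequal groups visually comparable.
#'
#' @param landings Numeric vector, one first-fixation position per subject.
#' @param group Group label stored on the result (e.g. "good", "poor").
#' @param group_size Number of subjects the curve represents (defaults to
#'   `length(landings)`).
#' @param bandwidth_factor Multiplier on the reference bandwidth.
#' @param n_grid Number of grid points.
#' @return A data.frame of class `density_curve` with columns `x` (character
#'   units) and `value`; attributes `bw`, `group`, `group_size`.
#' @export
first_fixation_density <- function(landings, group = "all",
                                   group_size = length(landings),
                                   bandwidth_factor = 0.4, n_grid = 512) {
  landings <- landings[!is.na(landings)]
  if (length(unique(landings)) < 2L) {
    stop("need at least two distinct landing positions for a density (group ",
         group, ")", call. = FALSE)
  }
  bw <- bandwidth_factor * stats::bw.nrd0(landings)
  d <- stats::density(landings, bw = bw, n = n_grid)
  out <- data.frame(x = d$x, value = d$y * group_size)
  attr(out, "bw") <- bw
  attr(out, "group") <- group
  attr(out, "group_size") <- group_size
  class(out) <- c("density_curve", "data.frame")
  out
}

#' Integrate a density curve
#'
#' Trapezoidal quadrature; a valid curve integrates to its group size (within
#' quadrature tolerance).
#'
#' @param curve A [first_fixation_density()] result.
#' @return The integral.
#' @export
density_integral <- function(curve) {
  sum(diff(curve$x) * (utils::head(curve$value, -1) + utils::tail(curve$value, -1)) / 2)
}
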