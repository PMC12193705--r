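#' Score a discontinuing item list (letter/syllable decoding)
#'
#' The letter-and-syllable decoding test presents up to `max_items` items in a
#' fixed order and is discontinued after `stop_run` consecutive incorrect
#' responses. The score is the number of correct responses among administered
#' items; the ceiling is `max_items` (85 in the study's test).
#'
#' Responses recorded beyond the stop point (e.g. from a lenient
#' administration) are trimmed with a warning and never change the score.
#'
#' @param correct Logical vector of item-by-item correctness, ordered by item.
#' @param max_items Maximum number of items.
#' @param stop_run Number of consecutive errors that stops the test.
#' @param trim_warning Warn when responses beyond the stop point are trimmed
#'   (set to `FALSE` when scoring simulated full-length response vectors).
#' @return A one-row data.frame: `test`, `items_administered`, `items_correct`
#'   (the score), `max_score`, `accuracy_pct`, `discontinued`.
#' @examples
#' score_discontinuing_list(rep(TRUE, 85))$items_correct # 85
#' @export
score_discontinuing_list <- function(correct, max_items = 85L, stop_run = 5L,
                                     trim_warning = TRUE) {
  stopifnot(is.logical(correct), max_items > 0, stop_run > 0)
  correct <- correct[seq_len(min(length(correct), max_items))]
  run <- 0L
  stop_at <- length(correct)
  discontinued <- FALSE
  for (i in seq_along(correct)) {
    run <- if (correct[i]) 0L else run + 1L
    if (run >= stop_run) { stop_at <- i; discontinued <- TRUE; break }
  }
  if (stop_at < length(correct) && trim_warning) {
    warning(sprintf("%d response(s) beyond the discontinuation point trimmed",
                    length(correct) - stop_at), call. = FALSE)
  }
  administered <- correct[seq_len(stop_at)]
  data.frame(test = "letters_syllables",
             items_administered = length(administered),
             items_correct = sum(administered),
             max_score = as.integer(max_items),
             accuracy_pct = 100 * mean(administered),
             discontinued = discontinued)
}

#' Score a timed reading test
#'
#' For the timed texts (meaningless 265-word text in 3 minutes, meaningful
#' text in 1 minute) and the 45-pseudoword list: accuracy is the percentage of
#' attempted items read correctly, fluency the number of items correctly read
#' per minute of the time limit.
#'
#' @param correct Logical vector over the items attempted before timeout.
#' @param time_limit_s Time limit in seconds (> 0).
#' @param test Label for the result row.
#' @return A one-row data.frame: `test`, `items_administered`,
#'   `items_correct`, `accuracy_pct`, `fluency_per_min`, `time_limit_s`.
#' @examples
#' timed_reading_result(rep(c(TRUE, FALSE), c(30, 10)), 180)
#' @export
timed_reading_result <- function(correct, time_limit_s,
                                 test = "meaningless_text") {
  stopifnot(is.logical(correct), time_limit_s > 0)
  if (length(correct) == 0L) {
    stop("no items administered before the time limit", call. = FALSE)
  }
  data.frame(test = test,
             items_administered = length(correct),
             items_correct = sum(correct),
             accuracy_pct = 100 * mean(correct),
             fluency_per_min = sum(correct) / (time_limit_s / 60),
             time_limit_s = time_limit_s)
}

#' Pre/post change scores
#'
#' The training outcome is the gain between pre- and post-test scores on the
#' test's native scale (score points for the decoding list, words/min for
#' fluency, percent for accuracy).
#'
#' @param pre,post Numeric vectors of per-subject scores, or result rows from
#'   the scoring functions (their `items_correct` is used); must describe the
#'   same test.
#' @param test Optional test label consistency check when `pre`/`post` are
#'   result data.frames.
#' @return Numeric vector of gains `post - pre`.
#' @export
change_scores <- function(pre, post, test = NULL) {
  if (is.data.frame(pre) && is.data.frame(post)) {
    if (!identical(pre$test, post$test)) {
      stop("pre and post results are from different tests (",
           paste(unique(pre$test), collapse = ","), " vs ",
           paste(unique(post$test), collapse = ","), ")", call. = FALSE)
    }
    if (!is.null(test) && !all(pre$test == test)) {
      stop("results are not from test ", test, call. = FALSE)
    }
    return(post$items_correct - pre$items_correct)
  }
  stopifnot(length(pre) == length(post))
  post - pre
}

#' Median split into good and poor decoders
#'
#' Dichotomises subjects at the median of a decoding score: strictly above
#' the median is "good", strictly below is "poor". Subjects exactly at the
#' median follow `tie_rule` (default "poor"); the rule in effect is recorded
#' as an attribute so reports can state it.
#'
#' @param scores Named numeric vector (names = subject ids) with at least two
#'   subjects.
#' @param tie_rule "poor" or "good".
#' @return Named character vector of labels with attributes `median` and
#'   `tie_rule`.
#' @examples
#' median_split(c(a = 10, b = 20, c = 30, d = 40))
#' @export
median_split <- function(scores, tie_rule = c("poor", "good")) {
  tie_rule <- match.arg(tie_rule)
  if (length(scores) < 2L) stop("need at least two subjects", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    stop("all scores identical: median split undefined", call. = FALSE)
  }
  med <- stats::median(scores)
  lab <- ifelse(scores > med, "good", ifelse(scores < med, "poor", tie_rule))
  names(lab) <- names(scores)
  attr(lab, "median") <- med
  attr(lab, "tie_rule") <- tie_rule
  lab
}
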