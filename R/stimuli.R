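#' Grapheme inventory for pseudoword construction
#'
#' The training material is built only from grapheme-phoneme correspondences
#' the children have already been taught in class, introduced progressively
#' across the six training sessions. An inventory records each grapheme, its
#' phoneme label, its class (consonant or vowel, simple or complex), and the
#' first session in which it may appear.
#'
#' @param grapheme Character vector of graphemes (possibly multi-letter,
#'   e.g. "ou", "ch").
#' @param phoneme Phoneme label per grapheme.
#' @param class One of "C" (simple consonant), "V" (simple vowel),
#'   "Cx" (complex consonant grapheme), "Vx" (complex vowel grapheme).
#' @param introduction_session First session (1-6) in which the grapheme may
#'   be used.
#' @return A data.frame of class `grapheme_inventory`.
#' @seealso [default_grapheme_inventory()]
#' @export
grapheme_inventory <- function(grapheme, phoneme, class, introduction_session) {
  if (length(grapheme) == 0L) {
    stop("grapheme inventory must be non-empty", call. = FALSE)
  }
  stopifnot(length(phoneme) == length(grapheme),
            length(class) == length(grapheme),
            length(introduction_session) == length(grapheme))
  if (any(is.na(phoneme) | !nzchar(phoneme))) {
    stop("every grapheme must map to a phoneme label", call. = FALSE)
  }
  stopifnot(all(class %in% c("C", "V", "Cx", "Vx")),
            all(introduction_session %in% 1:6))
  inv <- data.frame(grapheme = grapheme, phoneme = phoneme, class = class,
                    introduction_session = as.integer(introduction_session),
                    stringsAsFactors = FALSE)
  class(inv) <- c("grapheme_inventory", "data.frame")
  inv
}

#' Default French-like grapheme inventory
#'
#' A schematic first-grade progression: simple consonants and vowels first,
#' complex graphemes (digraphs, nasal vowels) from mid-training. It is a
#' synthetic stand-in with the structure of a French phonics curriculum, not
#' any published syllabus.
#'
#' @return A `grapheme_inventory`.
#' @export
default_grapheme_inventory <- function() {
  grapheme_inventory(
    grapheme = c("l", "m", "r", "p", "t", "s", "n", "d", "f", "b", "v", "c",
                 "a", "i", "o", "u", "e", "é",
                 "ch", "ou", "on", "an", "in", "gn"),
    phoneme = c("/l/", "/m/", "/R/", "/p/", "/t/", "/s/", "/n/", "/d/", "/f/",
                "/b/", "/v/", "/k/",
                "/a/", "/i/", "/o/", "/y/", "/@/", "/e/",
                "/S/", "/u/", "/o~/", "/a~/", "/e~/", "/nj/"),
    class = c(rep("C", 12), rep("V", 6), "Cx", "Vx", "Vx", "Vx", "Vx", "Cx"),
    introduction_session = c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4,
                             1, 1, 1, 2, 2, 3,
                             4, 4, 5, 5, 6, 6)
  )
}

# Sample one syllable as a vector of graphemes. Tiers follow the training
# material's three complexity levels: simple CV, CV with a complex grapheme,
# and CVC/CCV structures.
.sample_syllable <- function(inv, tier) {
  C  <- inv$grapheme[inv$class == "C"]
  V  <- inv$grapheme[inv$class == "V"]
  Cx <- inv$grapheme[inv$class == "Cx"]
  Vx <- inv$grapheme[inv$class == "Vx"]
  pick <- function(x) {
    if (length(x) == 0L) {
      stop("inventory too small: a required grapheme class is empty",
           call. = FALSE)
    }
    x[sample.int(length(x), 1L)]
  }
  switch(tier,
    "simple-CV" = c(pick(C), pick(V)),
    "complex-grapheme-CV" = {
      if (length(Cx) && (length(Vx) == 0L || stats::runif(1) < 0.5)) {
        c(pick(Cx), pick(V))
      } else if (length(Vx)) {
        c(pick(C), pick(Vx))
      } else c(pick(C), pick(V))
    },
    "complex-syllable" = {
      if (stats::runif(1) < 0.5) c(pick(C), pick(V), pick(C))  # CVC
      else c(pick(C), pick(C), pick(V))                        # CCV
    },
    stop("unknown complexity tier: ", tier, call. = FALSE)
  )
}

#' Build a pseudoword catalogue
#'
#' Generates the training catalogue of pronounceable pseudowords: by default
#' 20 monosyllabic, 60 bisyllabic and 40 trisyllabic items per training phase,
#' spanning three complexity tiers (simple CV syllables, CV with complex
#' graphemes, CVC/CCV syllables). Words are sampled from the inventory with a
#' seeded generator and are unique within the catalogue; candidates matching
#' `blocklist` (e.g. real French words) are rejected.
#'
#' @param inventory A [grapheme_inventory()].
#' @param counts Named integer vector `c(monosyllabic=, bisyllabic=, trisyllabic=)`.
#' @param seed Optional integer seed; the catalogue is a pure function of
#'   `(inventory, counts, seed)`.
#' @param blocklist Character vector of forbidden surfaces.
#' @return A data.frame of class `pseudoword_catalogue` with columns `surface`,
#'   `syllable_count`, `complexity_tier`, plus list-columns `graphemes` and
#'   `syllables`.
#' @examples
#' cat120 <- build_pseudoword_catalogue(default_grapheme_inventory(), seed = 1)
#' table(cat120$syllable_count)
#' @export
build_pseudoword_catalogue <- function(inventory,
                                       counts = c(monosyllabic = 20L,
                                                  bisyllabic = 60L,
                                                  trisyllabic = 40L),
                                       seed = NULL,
                                       blocklist = character()) {
  if (!inherits(inventory, "grapheme_inventory") || nrow(inventory) == 0L) {
    stop("`inventory` must be a non-empty grapheme_inventory", call. = FALSE)
  }
  counts <- counts[c("monosyllabic", "bisyllabic", "trisyllabic")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("`counts` must name non-negative monosyllabic/bisyllabic/trisyllabic",
         call. = FALSE)
  }
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }

  tiers <- c("simple-CV", "complex-grapheme-CV", "complex-syllable")
  seen <- new.env(parent = emptyenv())
  for (b in blocklist) assign(b, TRUE, envir = seen)

  out <- vector("list", sum(counts))
  k <- 0L
  for (nsyl in 1:3) {
    need <- counts[[nsyl]]
    if (need == 0L) next
    made <- 0L
    tries <- 0L
    max_tries <- 200L * need
    while (made < need) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(
          "inventory too small to generate %d unique %s pseudowords",
          need, names(counts)[nsyl]), call. = FALSE)
      }
      tier <- tiers[1L + (made %% length(tiers))]
      # progressive introduction: items cycle over target sessions and only
      # use graphemes taught by their target session, so every session of
      # the training has admissible material
      target_session <- 1L + ((made + tries) %% 6L)
      sub <- inventory[inventory$introduction_session <= target_session, ,
                       drop = FALSE]
      if (!any(sub$class == "C") || !any(sub$class == "V")) sub <- inventory
      syls <- replicate(nsyl, .sample_syllable(sub, tier), simplify = FALSE)
      graphemes <- unlist(syls)
      surface <- paste(graphemes, collapse = "")
      if (!is.null(seen[[surface]])) next
      assign(surface, TRUE, envir = seen)
      # label the tier from the realised structure (early-session items may
      # fall back to simpler syllables than requested)
      cls <- inventory$class[match(graphemes, inventory$grapheme)]
      tier_real <- if (any(lengths(syls) == 3L)) "complex-syllable"
        else if (any(cls %in% c("Cx", "Vx"))) "complex-grapheme-CV"
        else "simple-CV"
      made <- made + 1L
      k <- k + 1L
      out[[k]] <- list(surface = surface, syllable_count = nsyl,
                       complexity_tier = tier_real, graphemes = graphemes,
                       syllables = syls)
    }
  }
  cat_df <- data.frame(
    surface = vapply(out, `[[`, "", "surface"),
    syllable_count = vapply(out, `[[`, 0L, "syllable_count"),
    complexity_tier = vapply(out, `[[`, "", "complexity_tier"),
    stringsAsFactors = FALSE
  )
  cat_df$graphemes <- lapply(out, `[[`, "graphemes")
  cat_df$syllables <- lapply(out, `[[`, "syllables")
  class(cat_df) <- c("pseudoword_catalogue", "data.frame")
  cat_df
}

# First session at which every grapheme of an item has been introduced.
.item_intro_session <- function(graphemes, inventory) {
  idx <- match(graphemes, inventory$grapheme)
  if (anyNA(idx)) return(NA_integer_)
  max(inventory$introduction_session[idx])
}

#' Plan the trial mix of one training session
#'
#' Sessions 1-3 hold 10 written-pseudoword (WPW), 10 syllable (Sy) and
#' 10 oral-pseudoword (OPW) trials; sessions 4-6 hold 10 WPW, 5 Sy,
#' 5 sentence (SE) and 10 OPW trials. Stimuli are drawn only from material
#' whose graphemes have been introduced by the requested session.
#'
#' @param session_index Integer 1-6.
#' @param catalogue A [build_pseudoword_catalogue()] result.
#' @param inventory The [grapheme_inventory()] the catalogue was built from.
#' @param seed Optional integer seed.
#' @return A data.frame of class `session_plan` with columns `session`,
#'   `exercise_type` ("WPW", "Sy", "SE", "OPW") and `stimulus`.
#' @export
schedule_session <- function(session_index, catalogue,
                             inventory = default_grapheme_inventory(),
                             seed = NULL) {
  if (!is.numeric(session_index) || length(session_index) != 1L ||
      !(session_index %in% 1:6)) {
    stop("`session_index` must be an integer in 1..6", call. = FALSE)
  }
  session_index <- as.integer(session_index)
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }

  mix <- if (session_index <= 3L) c(WPW = 10L, Sy = 10L, SE = 0L, OPW = 10L)
         else c(WPW = 10L, Sy = 5L, SE = 5L, OPW = 10L)

  intro <- vapply(catalogue$graphemes, .item_intro_session, 0L,
                  inventory = inventory)
  avail <- catalogue$surface[!is.na(intro) & intro <= session_index]
  if (length(avail) == 0L) {
    stop("no catalogue items available for session ", session_index,
         call. = FALSE)
  }
  draw_words <- function(n) avail[sample.int(length(avail), n, replace = n > length(avail))]

  syl_pool <- unique(unlist(lapply(
    catalogue$syllables[!is.na(intro) & intro <= session_index],
    function(s) vapply(s, paste, "", collapse = "")
  )))
  draw_syll <- function(n) syl_pool[sample.int(length(syl_pool), n,
                                               replace = n > length(syl_pool))]
  draw_sent <- function(n) {
    if (n == 0L) return(character())
    vapply(seq_len(n), function(i) paste(draw_words(4L), collapse = " "), "")
  }

  plan <- data.frame(
    session = session_index,
    exercise_type = rep(names(mix), mix),
    stimulus = c(draw_words(mix[["WPW"]]), draw_syll(mix[["Sy"]]),
                 draw_sent(mix[["SE"]]), draw_words(mix[["OPW"]])),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("session_plan", "data.frame")
  plan
}

#' Fraction of decodable phonemes in a segmented sentence
#'
#' A sentence is admissible as training material only if more than 60% of its
#' phonemes are decodable, i.e. their grapheme has already been taught. The
#' package does not syllabify French automatically: the caller supplies the
#' grapheme segmentation as a character vector (spaces are ignored).
#'
#' @param graphemes Character vector of grapheme tokens, e.g.
#'   `c("l","e"," ","ch","a","t")`.
#' @param inventory A [grapheme_inventory()] of taught graphemes.
#' @param session Optional session index; only graphemes introduced by that
#'   session count as taught.
#' @return The decodable fraction in \[0, 1\].
#' @seealso [decodable_sentence()] for the strict > 0.60 admissibility rule.
#' @export
decodability_fraction <- function(graphemes, inventory, session = 6L) {
  toks <- graphemes[!graphemes %in% c(" ", "")]
  if (length(toks) == 0L) stop("empty sentence segmentation", call. = FALSE)
  taught <- inventory$grapheme[inventory$introduction_session <= session]
  mean(toks %in% taught)
}

#' Is a segmented sentence admissible as training material?
#'
#' Strictly more than 60% of phonemes must be decodable; a fraction of exactly
#' 0.60 is not admissible.
#'
#' @inheritParams decodability_fraction
#' @return Logical.
#' @export
decodable_sentence <- function(graphemes, inventory, session = 6L) {
  decodability_fraction(graphemes, inventory, session) > 0.60
}
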