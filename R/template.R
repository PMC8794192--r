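DEFAULT_CONSONANTS <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
                        "p", "r", "s", "t", "v", "z")
DEFAULT_VOWELS <- c("a", "e", "i", "o", "u")

#' Morphological template for generation-0 languages
#'
#' Generation-0 languages share one morphological skeleton: nouns are a CVC
#' stem plus a single-consonant plural suffix; verbs are a single-consonant
#' stem (one per event) plus a single-vowel ending that redundantly marks the
#' sentence's agent (double agent-marking, a minimal model of gender
#' agreement).
#'
#' @param consonants,vowels Character pools the concrete letters are drawn
#'   from. Defaults cover the letters attested in printed example languages.
#' @param noun_stem_vowels Pool for the medial vowel of noun stems; defaults
#'   to `vowels` (so ending vowels may also appear inside noun stems).
#' @return An object of class `morph_template`.
#' @details Distinctness constraints on each draw: the two noun stems differ,
#'   the three verb-stem consonants are pairwise distinct, the two
#'   agent-ending vowels differ, and the plural consonant differs from all
#'   verb-stem consonants (avoiding accidental homophony between a plural noun
#'   and noun + verb sequences that would corrupt type counts).
#' @export
morph_template <- function(consonants = DEFAULT_CONSONANTS,
                           vowels = DEFAULT_VOWELS,
                           noun_stem_vowels = vowels) {
  consonants <- unique(tolower(consonants))
  vowels <- unique(tolower(vowels))
  noun_stem_vowels <- unique(tolower(noun_stem_vowels))
  if (length(consonants) < 4L)
    stop("need at least 4 consonants (3 distinct verb stems + plural suffix)")
  if (length(vowels) < 2L)
    stop("need at least 2 vowels for distinct agent endings")
  if (length(noun_stem_vowels) < 1L)
    stop("need at least 1 noun-stem vowel")
  structure(list(consonants = consonants, vowels = vowels,
                 noun_stem_vowels = noun_stem_vowels),
            class = "morph_template")
}

#' Generate a structurally isomorphic generation-0 language
#'
#' Draws concrete letters for the template slots and builds the full 16-cell
#' language: `noun = stem (+ plural suffix when plural)`, `verb = event stem
#' consonant + agent ending vowel`. Every generated language has 28 word
#' tokens and 10 word types (4 noun forms, 6 verb forms), hence overall
#' type-token ratio 10/28.
#'
#' @param template A [morph_template()].
#' @param seed Integer seed; the same (template, seed) pair always yields the
#'   identical language.
#' @param label Optional language label.
#' @return An `iterlang_language`.
#' @examples
#' lang <- generate_initial_language(seed = 42)
#' ttr(lang)           # 10/28
#' ttr_ending(lang)    # 0.5: each event's endings look like {u, u, e, e}
#' @export
generate_initial_language <- function(template = morph_template(), seed,
                                      label = NULL) {
  stopifnot(inherits(template, "morph_template"))
  if (missing(seed) || !is.numeric(seed)) stop("`seed` must be an integer")
  withr::with_seed(as.integer(seed), {
    verb_stems <- sample(template$consonants, 3L)
    plural <- sample(setdiff(template$consonants, verb_stems), 1L)
    endings <- sample(template$vowels, 2L)
    draw_stem <- function() paste0(sample(template$consonants, 1L),
                                   sample(template$noun_stem_vowels, 1L),
                                   sample(template$consonants, 1L))
    noun_stems <- c(draw_stem(), draw_stem())
    while (noun_stems[2L] == noun_stems[1L]) noun_stems[2L] <- draw_stem()
  })
  m <- enumerate_meanings()
  noun <- paste0(noun_stems[as.integer(m$agent)],
                 ifelse(m$number == "pl", plural, ""))
  verb <- ifelse(m$event == "none", "",
                 paste0(verb_stems[pmax(as.integer(m$event) - 1L, 1L)],
                        endings[as.integer(m$agent)]))
  language(trimws(paste(noun, verb)), label = label)
}
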