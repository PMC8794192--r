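#' Positional morpheme extraction for verbs
#'
#' The verb stem carries the lexical meaning and is read off as the first
#' letter of the verb token; the ending carries agent-marking and is read off
#' as the last letter. For a one-letter verb, stem and ending coincide.
#' Extraction is positional by definition, not morphological segmentation.
#'
#' @param word Character vector of verb tokens (nonempty).
#' @return Single characters (stems resp. endings).
#' @examples
#' verb_stem("fu")    # "f"
#' verb_ending("fu")  # "u"
#' @export
verb_stem <- function(word) {
  if (any(is.na(word)) || any(!nzchar(word))) stop("empty verb token")
  substr(word, 1L, 1L)
}

#' @rdname verb_stem
#' @export
verb_ending <- function(word) {
  if (any(is.na(word)) || any(!nzchar(word))) stop("empty verb token")
  substr(word, nchar(word), nchar(word))
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming `a` into `b` (computed via [utils::adist()]). Vectorized
#' elementwise with recycling.
#'
#' @param a,b Character vectors.
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.integer(mapply(function(x, y) utils::adist(x, y), a, b,
                    USE.NAMES = FALSE))
}

#' Normalized Levenshtein distance
#'
#' Edit distance divided by the length of the longer string (the default) or
#' by the mean length, giving a value in \[0, 1\]. Spaces count as ordinary
#' characters.
#'
#' @param a,b Character vectors (elementwise; not both empty in any pair).
#' @param normalize `"max"` (default) or `"mean"` string length.
#' @return Numeric vector in \[0, 1\].
#' @export
normalized_levenshtein <- function(a, b, normalize = c("max", "mean")) {
  normalize <- match.arg(normalize)
  d <- levenshtein(a, b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  denom <- switch(normalize,
                  max = pmax(nchar(a), nchar(b)),
                  mean = (nchar(a) + nchar(b)) / 2)
  if (any(denom == 0)) stop("normalized distance undefined for two empty strings")
  d / denom
}

#' Transmission fidelity between an input and an output language
#'
#' Transmission error is the mean of pairwise normalized Levenshtein
#' distances between the signals (full sentence strings, spaces included)
#' that correspond to the same meaning in the input and output language;
#' fidelity is 1 minus that error. A perfectly reproduced language has
#' fidelity 1.
#'
#' @param input,output `iterlang_language` objects over the same 16 meanings.
#' @param normalize Passed to [normalized_levenshtein()].
#' @return Fidelity in \[0, 1\].
#' @export
transmission_fidelity <- function(input, output, normalize = c("max", "mean")) {
  key <- function(d) paste(d$agent, d$number, d$event, sep = "/")
  if (!setequal(key(input), key(output)) || nrow(input) != nrow(output))
    stop("input and output languages cover different meaning sets")
  out_ord <- match(key(input), key(output))
  1 - mean(normalized_levenshtein(input$sentence, output$sentence[out_ord],
                                  normalize = normalize))
}

#' Type-token ratio of a language
#'
#' The number of distinct word forms (types) divided by the total number of
#' word tokens across all 16 sentences. No lemmatization is applied: `seg`
#' and `segl` are two types. A canonical generation-0 language scores
#' 10/28.
#'
#' @param lang An `iterlang_language`.
#' @return TTR in (0, 1].
#' @export
ttr <- function(lang) {
  tok <- language_tokens(lang)
  length(unique(tok)) / length(tok)
}

#' Part-of-speech type-token ratio
#'
#' TTR over the noun tokens (first word of each of the 16 sentences) or over
#' the verb tokens (second word of each sentence that has one; 12 in a
#' canonical language). Sentences lacking a verb contribute no verb token and
#' the denominator shrinks accordingly.
#'
#' @param lang An `iterlang_language`.
#' @param pos `"noun"` or `"verb"`.
#' @return TTR in (0, 1].
#' @export
ttr_pos <- function(lang, pos = c("noun", "verb")) {
  pos <- match.arg(pos)
  tok <- if (pos == "noun") noun_tokens(lang) else {
    v <- verb_table(lang)$verb
    v[!is.na(v)]
  }
  if (length(tok) == 0L) stop("language has no ", pos, " tokens")
  length(unique(tok)) / length(tok)
}

# Mean within-subcorpus TTR over the letters extracted by `extract` from the
# verbs grouped by `group`. Subcorpora with no verb tokens are skipped with a
# warning; an error is raised if none remain.
ttr_verb_letters <- function(lang, group, extract, what) {
  vt <- verb_table(lang)
  vt <- vt[vt$event != "none", , drop = FALSE]
  vals <- vapply(split(vt$verb, vt[[group]], drop = FALSE)[
    if (group == "event") EVENTS[-1] else AGENTS], function(v) {
      v <- v[!is.na(v)]
      if (length(v) == 0L) return(NA_real_)
      letters <- extract(v)
      length(unique(letters)) / length(letters)
    }, numeric(1))
  if (anyNA(vals)) {
    if (all(is.na(vals)))
      stop("no verb tokens at all: ", what, " TTR undefined")
    warning("subcorpus with no verb tokens skipped in ", what, " TTR")
    vals <- vals[!is.na(vals)]
  }
  mean(vals)
}

#' Verb-ending type-token ratio (agent-marking diversity)
#'
#' For each of the three events, the ending letters of its verb across the
#' four agent-by-number cells form a subcorpus; TTR (types/tokens) is taken
#' within each subcorpus and the three values are averaged. Grouping by event
#' removes lexical differences between verbs, so the measure isolates
#' agent/number marking: a language whose verbs are invariant across their
#' four cells (no marking) scores exactly 0.25, full double agent-marking
#' with two ending vowels scores 0.5.
#'
#' @param lang An `iterlang_language`.
#' @return Mean within-event ending TTR, in \[0.25, 1\] for canonical
#'   languages.
#' @export
ttr_ending <- function(lang) {
  ttr_verb_letters(lang, "event", verb_ending, "ending")
}

#' Verb-stem type-token ratio (lexical diversity of verbs)
#'
#' For each of the two agents, the stem letters (first letters) of the six
#' verbs occurring with that agent's noun form a subcorpus; TTR is taken
#' within each and the two values are averaged. Grouping by agent removes
#' agent-marking differences, so the measure isolates lexical distinctions
#' between verbs. Three fully distinct stems score 0.5; a single shared stem
#' scores 1/6.
#'
#' @param lang An `iterlang_language`.
#' @return Mean within-agent stem TTR.
#' @export
ttr_stem <- function(lang) {
  ttr_verb_letters(lang, "agent", verb_stem, "stem")
}

#' Unigram Shannon entropy of the word distribution
#'
#' Shannon entropy (bits) of the relative frequencies of word types among the
#' language's tokens: \eqn{-\sum_w p_w \log_2 p_w}. Zero for a language of 28
#' identical tokens; \eqn{\log_2 28} when all tokens are distinct.
#'
#' @param lang An `iterlang_language`.
#' @return Entropy in bits, nonnegative.
#' @export
entropy <- function(lang) {
  tok <- language_tokens(lang)
  p <- as.vector(table(tok)) / length(tok)
  -sum(p * log2(p))
}
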