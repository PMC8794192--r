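#' Construct a language over the 16-cell meaning space
#'
#' A language is a total mapping from the 16 meanings to sentences. Sentences
#' are strings of lowercase words separated by single spaces; by analysis
#' convention the first word is the noun and the second (when present) the
#' verb.
#'
#' @param sentences Character vector of length 16, in the canonical meaning
#'   order of [enumerate_meanings()]. Tokens are lowercased on ingestion.
#' @param label Optional label, conventionally `"<condition><chain>-<gen>"`
#'   (e.g. `"T25-0"`).
#' @return An object of class `iterlang_language`: a data frame with columns
#'   `agent`, `number`, `event`, `sentence` and a `label` attribute.
#' @examples
#' lang <- generate_initial_language(seed = 1)
#' ttr(lang)
#' @export
language <- function(sentences, label = NULL) {
  if (!is.character(sentences) || length(sentences) != 16L)
    stop("`sentences` must be a character vector of length 16")
  df <- enumerate_meanings()
  df$sentence <- tolower(trimws(sentences))
  structure(df, label = label, class = c("iterlang_language", "data.frame"))
}

#' @export
print.iterlang_language <- function(x, ...) {
  lab <- attr(x, "label")
  cat("Artificial language", if (!is.null(lab)) paste0("'", lab, "'"),
      "(16 meanings)\n")
  wide <- matrix(x$sentence, nrow = 8, ncol = 2,
                 dimnames = list(paste(x$number[1:8], x$event[1:8], sep = "."),
                                 AGENTS))
  print(as.data.frame(wide))
  invisible(x)
}

# Split sentences into word lists; canonical sentences have 1 or 2 words.
sentence_words <- function(lang) strsplit(lang$sentence, " ", fixed = TRUE)

# All word tokens of the language (28 for a canonical language).
language_tokens <- function(lang) unlist(sentence_words(lang), use.names = FALSE)

# First word of each sentence (the noun; 16 tokens).
noun_tokens <- function(lang) {
  vapply(sentence_words(lang), `[`, character(1), 1L)
}

# Second word where present (the verb), with its meaning coordinates.
verb_table <- function(lang) {
  w <- sentence_words(lang)
  verb <- vapply(w, function(x) if (length(x) >= 2L) x[[2L]] else NA_character_,
                 character(1))
  data.frame(agent = lang$agent, number = lang$number, event = lang$event,
             verb = verb, stringsAsFactors = FALSE)
}

#' Validate a language against the data-model invariants
#'
#' Checks that all 16 meanings are present exactly once, that tokens are
#' nonempty lowercase letter strings, that bare-noun meanings (`event ==
#' "none"`) have one-word sentences, and that no sentence exceeds two words.
#' Violations are reported, not raised: a flagged language remains measurable
#' (metrics treat word 1 as the noun and word 2 as the verb, ignoring extras).
#'
#' @param lang An `iterlang_language`.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_language <- function(lang) {
  v <- character(0)
  ref <- enumerate_meanings()
  key <- function(d) paste(d$agent, d$number, d$event, sep = "/")
  have <- key(lang); want <- key(ref)
  for (m in setdiff(want, have)) v <- c(v, paste0("missing meaning ", m))
  for (m in unique(have[duplicated(have)]))
    v <- c(v, paste0("duplicated meaning ", m))
  words <- sentence_words(lang)
  for (i in seq_len(nrow(lang))) {
    w <- words[[i]]
    m <- have[i]
    if (length(w) == 0L || any(!nzchar(w))) {
      v <- c(v, paste0("empty sentence or token for ", m)); next
    }
    if (any(grepl("[^a-z]", w)))
      v <- c(v, paste0("non-lowercase-letter characters in '",
                       lang$sentence[i], "' (", m, ")"))
    if (lang$event[i] == "none" && length(w) != 1L)
      v <- c(v, paste0("bare-noun meaning ", m, " has ", length(w), " words"))
    if (length(w) > 2L)
      v <- c(v, paste0("sentence '", lang$sentence[i], "' (", m,
                       ") has more than 2 words"))
  }
  v
}

#' Construct a transmission chain
#'
#' A chain is a condition label plus the sequence of languages produced at
#' generations 0..G. Partial chains (e.g. only generations 0 and 10, as when
#' reading printed fixtures) are allowed; the `languages` list is named by
#' generation.
#'
#' @param chain_id Integer chain identifier (1..45 in the full design).
#' @param condition `"N"` (normal), `"T"` (temporarily interrupted) or `"P"`
#'   (permanently interrupted).
#' @param languages Named list of `iterlang_language` objects; names are
#'   generation numbers as strings.
#' @param schedule Learner types (`"long"`/`"short"`) for generations 1..G;
#'   defaults to [make_schedule()] when the chain is contiguous from 0.
#' @return An object of class `iterlang_chain`.
#' @export
new_chain <- function(chain_id, condition, languages, schedule = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  if (is.null(names(languages)))
    names(languages) <- as.character(seq_along(languages) - 1L)
  gens <- as.integer(names(languages))
  if (anyNA(gens)) stop("language list names must be generation numbers")
  if (is.null(schedule) && identical(gens, seq(0L, length(languages) - 1L)) &&
      length(languages) > 1L)
    schedule <- make_schedule(condition, max(gens))
  structure(list(chain_id = as.integer(chain_id), condition = condition,
                 languages = languages, schedule = schedule),
            class = "iterlang_chain")
}

#' @export
print.iterlang_chain <- function(x, ...) {
  cat("Transmission chain ", x$condition, x$chain_id, ": ",
      length(x$languages), " generations (",
      paste(names(x$languages), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$schedule))
    cat("learner schedule:", paste(substr(toupper(x$schedule), 1, 1),
                                   collapse = " "), "\n")
  invisible(x)
}
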