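# Printed example languages: the first (generation 0) and final (generation
# 10) languages of chains N9, T18 and T25, transcribed with hyphens removed.
# Sentence order is the canonical meaning order of enumerate_meanings().
PRINTED_LANGUAGES <- list(
  "N9-0" = c(
    "rub",  "rub le",  "rub ze",  "rub ne",
    "rubp", "rubp le", "rubp ze", "rubp ne",
    "vad",  "vad lo",  "vad zo",  "vad no",
    "vadp", "vadp lo", "vadp zo", "vadp no"),
  "N9-10" = c(
    "rub",  "rub le",  "rub ze",  "rub ne",
    "rubs", "rubs le", "rubp ze", "rubp ne",
    "vad",  "vad lo",  "vad zo",  "vad no",
    "vadp", "vadp lo", "vadp zo", "vadp no"),
  "T18-0" = c(
    "dig",  "dig mo",  "dig po",  "dig ho",
    "dign", "dign mo", "dign po", "dign ho",
    "sez",  "sez mu",  "sez pu",  "sez hu",
    "sezn", "sezn mu", "sezn pu", "sezn hu"),
  "T18-10" = c(
    "senz", "senz po", "senz ho", "senz mo",
    "sezn", "sezn po", "sezn ho", "sezn mo",
    "sign", "sign po", "sign ho", "sign mo",
    "dign", "dign po", "digm ho", "dign mo"),
  "T25-0" = c(
    "jal",  "jal bu",  "jal fu",  "jal tu",
    "jald", "jald bu", "jald fu", "jald tu",
    "rok",  "rok be",  "rok fe",  "rok te",
    "rokd", "rokd be", "rokd fe", "rokd te"),
  "T25-10" = c(
    "jal",  "jal te",  "jal fu",  "jal fe",
    "jald", "jald te", "jald fu", "jald fe",
    "rok",  "rok te",  "rok fu",  "rok fe",
    "rokd", "rokd te", "rokd fu", "rokd fe")
)

#' Embedded example languages from three documented chains
#'
#' The first- and final-generation languages of chains N9 (normal), T18 and
#' T25 (temporarily interrupted), as printed in the study's worked examples.
#' N9 shows a minor complexification of the nominal system (`rubs` as a
#' second plural pattern); T18 lost all double agent-marking and reorganized
#' its nominal number marking; T25 lost double agent-marking by reanalyzing
#' the agent endings as parts of the verb stems (`fu`, `fe` both from the
#' original stem `f-`).
#'
#' @return Named list of six `iterlang_language` objects: `"N9-0"`,
#'   `"N9-10"`, `"T18-0"`, `"T18-10"`, `"T25-0"`, `"T25-10"`.
#' @examples
#' fx <- load_fixtures()
#' ttr_ending(fx[["T25-0"]])   # 0.5
#' ttr_ending(fx[["T25-10"]])  # 0.25
#' @export
load_fixtures <- function() {
  out <- lapply(names(PRINTED_LANGUAGES), function(nm)
    language(PRINTED_LANGUAGES[[nm]], label = nm))
  stats::setNames(out, names(PRINTED_LANGUAGES))
}

#' Assemble the embedded example languages into partial chains
#'
#' @return List of three `iterlang_chain` objects (chains 9, 18, 25) each
#'   holding generations 0 and 10.
#' @export
fixture_chains <- function() {
  fx <- load_fixtures()
  mk <- function(id, cond, a, b)
    new_chain(id, cond, stats::setNames(list(fx[[a]], fx[[b]]), c("0", "10")),
              schedule = NULL)
  list(mk(9L, "N", "N9-0", "N9-10"),
       mk(18L, "T", "T18-0", "T18-10"),
       mk(25L, "T", "T25-0", "T25-10"))
}
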