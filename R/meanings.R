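#' @keywords internal
"_PACKAGE"

# Canonical factor levels of the meaning space. Order matters: it fixes the
# serialization order of every language (agent-major, then number, then event).
AGENTS <- c("round", "square")
NUMBERS <- c("sg", "pl")
EVENTS <- c("none", "fall_apart", "grow_antlers", "fly_away")

CONDITIONS <- c("N", "T", "P")
LEARNER_TYPES <- c("long", "short")

#' Enumerate the 16-cell meaning space
#'
#' The meaning space is the Cartesian product of two agents (a round and a
#' square animal), two numbers (singular, plural) and four events (no event,
#' fall apart, grow antlers, fly away). Meanings with `event == "none"` are
#' expressed by a bare noun; all others by a noun--verb sentence.
#'
#' @return A data frame with 16 rows and factor columns `agent`, `number`,
#'   `event`, in the canonical order: agent varies slowest, then number, then
#'   event. This order is the serialization order used throughout the package.
#' @examples
#' m <- enumerate_meanings()
#' nrow(m)                       # 16
#' sum(m$event == "none")        # 4 one-word meanings
#' @export
enumerate_meanings <- function() {
  g <- expand.grid(
    event = factor(EVENTS, levels = EVENTS),
    number = factor(NUMBERS, levels = NUMBERS),
    agent = factor(AGENTS, levels = AGENTS),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g[, c("agent", "number", "event")]
}

#' Number of training blocks per learner type
#'
#' Long-exposure learners receive six training blocks, short-exposure learners
#' three; the contrast operationalizes imperfect learning.
#'
#' @param type `"long"` or `"short"` (vectorized).
#' @return Integer vector of block counts.
#' @export
learner_blocks <- function(type) {
  type <- match.arg(type, LEARNER_TYPES, several.ok = TRUE)
  unname(c(long = 6L, short = 3L)[type])
}
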