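#' Learner-type schedule for a transmission chain
#'
#' Condition N (normal) uses long-exposure learners throughout; condition T
#' (temporarily interrupted) uses short-exposure learners at generations 2-4;
#' condition P (permanently interrupted) uses short-exposure learners at every
#' generation but the first.
#'
#' @param condition `"N"`, `"T"` or `"P"`.
#' @param generations Number of learner generations (>= 1).
#' @return Character vector of `"long"`/`"short"` for generations
#'   1..`generations`.
#' @examples
#' make_schedule("T", 10)
#' @export
make_schedule <- function(condition, generations = 10L) {
  condition <- match.arg(condition, CONDITIONS)
  if (generations < 1L) stop("`generations` must be >= 1")
  g <- seq_len(generations)
  short <- switch(condition,
                  N = rep(FALSE, generations),
                  T = g >= 2L & g <= 4L,
                  P = g >= 2L)
  ifelse(short, "short", "long")
}

#' Parameters of the simulated imperfect learner
#'
#' The learner model is deliberately minimal, with the three levers the
#' analyses need: exposure-dependent recall, ending-biased regularization and
#' unbiased character noise. For each meaning independently the learner
#' recalls the input sentence verbatim with probability `p_recall_long`
#' (long-exposure) or `p_recall_short` (short-exposure); a non-recalled
#' sentence is reconstructed with per-character substitution noise, and its
#' verb ending is replaced by the input language's majority ending with
#' probability `simplification_bias` (the regularization pressure that erodes
#' agent-marking).
#'
#' @param p_recall_long,p_recall_short Per-meaning verbatim recall
#'   probabilities; `p_recall_short <= p_recall_long` mirrors the exposure
#'   manipulation (6 vs 3 training blocks).
#' @param simplification_bias Probability that a non-recalled verb takes the
#'   majority ending.
#' @param mutation_rate Per-character probability of a class-preserving
#'   random substitution in reconstructed words.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(p_recall_long = 0.95, p_recall_short = 0.65,
                         simplification_bias = 0.75, mutation_rate = 0.01) {
  p <- c(p_recall_long, p_recall_short, simplification_bias, mutation_rate)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all agent parameters must be probabilities in [0, 1]")
  if (p_recall_short > p_recall_long)
    stop("`p_recall_short` must not exceed `p_recall_long`")
  structure(list(p_recall_long = p_recall_long,
                 p_recall_short = p_recall_short,
                 simplification_bias = simplification_bias,
                 mutation_rate = mutation_rate),
            class = "agent_params")
}

# Most frequent verb-ending letter of a language; lexicographic tie-break so
# the result is deterministic.
majority_ending <- function(lang) {
  v <- verb_table(lang)
  v <- v$verb[v$event != "none" & !is.na(v$verb)]
  if (length(v) == 0L) return(NA_character_)
  tab <- table(verb_ending(v))
  names(tab)[which.max(tab)]  # ties: first in sorted table order
}

# Class-preserving per-character substitution: consonants stay consonants,
# vowels stay vowels; a mutated character always changes.
mutate_word <- function(word, rate) {
  if (rate == 0 || !nzchar(word)) return(word)
  chars <- strsplit(word, "")[[1L]]
  hit <- stats::runif(length(chars)) < rate
  for (i in which(hit)) {
    pool <- if (chars[i] %in% DEFAULT_VOWELS) DEFAULT_VOWELS else
      if (chars[i] %in% DEFAULT_CONSONANTS) DEFAULT_CONSONANTS else letters
    pool <- setdiff(pool, chars[i])
    chars[i] <- sample(pool, 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate one learner: learn an input language, produce an output language
#'
#' Applies the imperfect-learner model of [agent_params()] meaning by meaning.
#' With recall probability 1 the output equals the input (fidelity 1); with
#' recall 0, `simplification_bias` 1 and `mutation_rate` 0 every verb ending
#' collapses to the input's majority ending, driving the ending TTR to 0.25.
#' Uses the current RNG state; seed externally (see [run_chain()]).
#'
#' @param input An `iterlang_language`.
#' @param learner `"long"` or `"short"`.
#' @param params An [agent_params()] object.
#' @param label Label for the output language.
#' @return The produced `iterlang_language`.
#' @export
agent_learn_produce <- function(input, learner = c("long", "short"),
                                params = agent_params(), label = NULL) {
  learner <- match.arg(learner)
  stopifnot(inherits(params, "agent_params"))
  p_recall <- if (learner == "long") params$p_recall_long else
    params$p_recall_short
  maj <- majority_ending(input)
  words <- sentence_words(input)
  out <- vapply(words, function(w) {
    if (stats::runif(1) < p_recall) return(paste(w, collapse = " "))
    w[1L] <- mutate_word(w[1L], params$mutation_rate)
    if (length(w) >= 2L) {
      verb <- w[2L]
      body <- substr(verb, 1L, nchar(verb) - 1L)
      end <- verb_ending(verb)
      body <- mutate_word(body, params$mutation_rate)
      if (!is.na(maj) && stats::runif(1) < params$simplification_bias)
        end <- maj
      else
        end <- mutate_word(end, params$mutation_rate)
      w[2L] <- paste0(body, end)
    }
    paste(w, collapse = " ")
  }, character(1))
  language(out, label = label)
}

# Deterministic 32-bit seed stream: fold the components with a large prime
# modulo 2^31 - 1. Hierarchical (master -> chain -> generation) so adding
# chains or generations never perturbs existing ones.
derive_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 1000003 + as.numeric(x) + 1) %% 2147483647
  as.integer(s)
}

#' Experiment configuration
#'
#' Defaults reproduce the study scaffold: 45 transmission chains (15 per
#' condition), 10 one-learner generations each, seeded by 15 structurally
#' isomorphic generation-0 languages that are shared across conditions (chain
#' i in each condition starts from initial language i).
#'
#' @param n_chains_per_condition Chains per condition (default 15).
#' @param generations Learner generations per chain (default 10).
#' @param conditions Subset of `c("N", "T", "P")`.
#' @param agent_params An [agent_params()] object.
#' @param template A [morph_template()].
#' @param master_seed Integer master seed; every random draw in the
#'   experiment derives from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_chains_per_condition = 15L, generations = 10L,
                              conditions = CONDITIONS,
                              agent_params = iterlang::agent_params(),
                              template = morph_template(),
                              master_seed = 1L) {
  conditions <- match.arg(conditions, CONDITIONS, several.ok = TRUE)
  stopifnot(n_chains_per_condition >= 1L, generations >= 1L,
            inherits(agent_params, "agent_params"),
            inherits(template, "morph_template"))
  structure(list(n_chains_per_condition = as.integer(n_chains_per_condition),
                 generations = as.integer(generations),
                 conditions = conditions, agent_params = agent_params,
                 template = template,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Run one transmission chain
#'
#' Generation 0 is a freshly generated initial language; each later
#' generation's language is produced by [agent_learn_produce()] from the
#' previous one, with the learner type given by the condition's schedule.
#' RNG streams are derived deterministically from `(master_seed, chain_id,
#' generation)`, so the same configuration and chain id always reproduce the
#' identical chain.
#'
#' @param chain_id Integer chain id.
#' @param condition `"N"`, `"T"` or `"P"`.
#' @param config An [experiment_config()].
#' @param init_seed Seed for the generation-0 language; defaults to a stream
#'   derived from `(master_seed, chain_id)`. [run_experiment()] passes a
#'   shared per-index seed so conditions start from the same 15 languages.
#' @return An `iterlang_chain`.
#' @export
run_chain <- function(chain_id, condition, config = experiment_config(),
                      init_seed = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(inherits(config, "experiment_config"))
  G <- config$generations
  schedule <- make_schedule(condition, G)
  if (is.null(init_seed))
    init_seed <- derive_seed(config$master_seed, 900000L, chain_id)
  lab <- function(g) paste0(condition, chain_id, "-", g)
  langs <- vector("list", G + 1L)
  names(langs) <- as.character(0:G)
  langs[[1L]] <- generate_initial_language(config$template, seed = init_seed,
                                           label = lab(0))
  for (g in seq_len(G)) {
    withr::with_seed(derive_seed(config$master_seed, chain_id, g), {
      langs[[g + 1L]] <- agent_learn_produce(langs[[g]], schedule[g],
                                             config$agent_params,
                                             label = lab(g))
    })
  }
  new_chain(chain_id, condition, langs, schedule)
}

#' Run a full transmission-chain experiment
#'
#' Runs `n_chains_per_condition` chains for each requested condition, with
#' the standard chain numbering: ids 1..n are condition N, n+1..2n condition
#' T, 2n+1..3n condition P (1-15 / 16-30 / 31-45 in the default design).
#' Chains at the same within-condition index share their generation-0
#' language across conditions. Fully reproducible from `master_seed`.
#'
#' @param config An [experiment_config()].
#' @return List of `iterlang_chain` objects.
#' @examples
#' chains <- run_experiment(experiment_config(n_chains_per_condition = 2,
#'                                            generations = 3))
#' length(chains)
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_chains_per_condition
  chains <- list()
  for (cond in intersect(CONDITIONS, config$conditions)) {
    block <- match(cond, CONDITIONS) - 1L
    for (i in seq_len(n)) {
      id <- block * n + i
      chains[[length(chains) + 1L]] <-
        run_chain(id, cond, config,
                  init_seed = derive_seed(config$master_seed, 900000L, i))
    }
  }
  chains
}
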