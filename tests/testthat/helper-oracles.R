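# Independent oracles and small builders used across the tests.

# Brute-force recursive Levenshtein distance, straight from the definition:
# at each step drop a leading character of a (deletion), of b (insertion), or
# of both (match/substitution). Deliberately independent of utils::adist.
lev_oracle <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  rest <- function(s) substr(s, 2L, nchar(s))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(lev_oracle(rest(a), b) + 1L,
      lev_oracle(a, rest(b)) + 1L,
      lev_oracle(rest(a), rest(b)) + cost)
}

# Closed-form Welch statistics (textbook formulas).
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  p <- 2 * pt(-abs(t), df)
  tcrit <- qt(0.975, df)
  list(t = t, df = df, p = p,
       ci = (mean(x) - mean(y)) + c(-1, 1) * tcrit * sqrt(vx + vy),
       d = (mean(x) - mean(y)) /
         sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)))
}

# Collapse all verb-ending vowels of a language to a single letter, removing
# agent-marking; nouns untouched.
strip_agent_marking <- function(lang, ending = "e") {
  s <- vapply(strsplit(lang$sentence, " ", fixed = TRUE), function(w) {
    if (length(w) >= 2L) {
      v <- w[2L]
      w[2L] <- paste0(substr(v, 1L, nchar(v) - 1L), ending)
    }
    paste(w, collapse = " ")
  }, character(1))
  language(s, label = attr(lang, "label"))
}

# Apply a bijective letter renaming to every sentence of a language.
rename_letters <- function(lang, from, to) {
  language(chartr(from, to, lang$sentence), label = attr(lang, "label"))
}

# Simulated metric records with known log-linear structure: per-chain random
# intercepts/slopes around condition slopes, Gaussian noise, 0..G generations.
synthetic_records <- function(n_per_cond = 15, G = 10,
                              slopes = c(N = -0.007, T = -0.02, P = -0.02),
                              intercept = -1.024, sd_b0 = 0.05,
                              sd_b1 = 0.005, sd_eps = 0.05) {
  rows <- list()
  id <- 0
  for (cond in names(slopes)) {
    for (i in seq_len(n_per_cond)) {
      id <- id + 1
      b0 <- rnorm(1, 0, sd_b0); b1 <- rnorm(1, 0, sd_b1)
      g <- 0:G
      y <- intercept + b0 + (slopes[[cond]] + b1) * g + rnorm(G + 1, 0, sd_eps)
      rows[[id]] <- data.frame(chain_id = id, condition = cond,
                               generation = g, metric = "ttr_all",
                               value = exp(y), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
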