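test_that("levenshtein distance matches worked single-edit examples", {
  expect_equal(levenshtein("rub", "rub"), 0L)
  expect_equal(levenshtein("dign", "digm"), 1L)   # single substitution
  expect_equal(levenshtein("sez", "sezn"), 1L)    # single insertion
  expect_equal(levenshtein("", "abc"), 3L)
  # against the recursive oracle on assorted pairs, incl. spaces
  pairs <- list(c("jal bu", "jal te"), c("rub le", "rub"), c("senz", "sezn"),
                c("dig mo", "sezn hu"), c("", ""), c("a", "ba"))
  for (p in pairs) expect_equal(levenshtein(p[1], p[2]), lev_oracle(p[1], p[2]))
})

test_that("levenshtein is symmetric and satisfies the triangle inequality", {
  set.seed(42)
  rand_str <- function() paste(sample(letters[1:4], sample(0:5, 1),
                                      replace = TRUE), collapse = "")
  for (i in 1:50) {
    a <- rand_str(); b <- rand_str(); cc <- rand_str()
    expect_equal(levenshtein(a, b), levenshtein(b, a))
    expect_lte(levenshtein(a, cc), levenshtein(a, b) + levenshtein(b, cc))
  }
})

test_that("normalized levenshtein divides by the longer string", {
  expect_equal(normalized_levenshtein("rub le", "rub le"), 0)
  expect_equal(normalized_levenshtein("rub le", "rub"), 0.5)
  expect_equal(normalized_levenshtein("ab", "cd"), 1)
  expect_equal(normalized_levenshtein("abcd", "ab", normalize = "mean"), 2 / 3)
  expect_error(normalized_levenshtein("", ""), "empty")
})

test_that("transmission fidelity averages per-meaning normalized distances", {
  fx <- load_fixtures()
  for (lang in fx) expect_equal(transmission_fidelity(lang, lang), 1)
  # independently: sum the 16 per-meaning normalized distances of chain T25
  # by the recursive oracle
  a <- fx[["T25-0"]]; b <- fx[["T25-10"]]
  d <- mapply(function(x, y) lev_oracle(x, y) / max(nchar(x), nchar(y)),
              a$sentence, b$sentence)
  expect_equal(transmission_fidelity(a, b), 1 - mean(d))
  expect_equal(transmission_fidelity(a, b), 83 / 96)  # frozen regression value
  # all-different, equal-length signals give fidelity 0 (one-word sentences
  # so that no space character is shared)
  expect_equal(transmission_fidelity(language(rep("ab", 16)),
                                     language(rep("cd", 16))), 0)
  expect_error(transmission_fidelity(a, a[1:15, ]), "meaning")
})

test_that("overall TTR counts types over tokens with no lemmatization", {
  fx <- load_fixtures()
  expect_equal(ttr(fx[["N9-0"]]), 10 / 28)
  expect_equal(ttr(fx[["T25-10"]]), 7 / 28)  # {jal,rok,jald,rokd} + {te,fu,fe}
  m <- enumerate_meanings()
  all_distinct <- language(ifelse(m$event == "none",
                                  sprintf("n%s", letters[1:16]),
                                  paste(sprintf("n%s", letters[1:16]),
                                        sprintf("v%s", letters[1:16]))))
  expect_equal(ttr(all_distinct), 1)
})

test_that("POS TTR splits nouns (first words) from verbs (second words)", {
  fx <- load_fixtures()
  expect_equal(ttr_pos(fx[["N9-0"]], "noun"), 4 / 16)
  expect_equal(ttr_pos(fx[["N9-0"]], "verb"), 6 / 12)
  expect_equal(ttr_pos(fx[["T18-10"]], "verb"), 3 / 12)  # po, ho, mo x4 each
  expect_equal(ttr_pos(fx[["N9-10"]], "noun"), 5 / 16)   # rubs joins the system
})

test_that("ending TTR isolates agent/number marking within events", {
  fx <- load_fixtures()
  expect_equal(ttr_ending(fx[["T25-0"]]), 0.5)   # {u,u,e,e} x 3 events
  expect_equal(ttr_ending(fx[["T25-10"]]), 0.25) # invariant verbs
  expect_equal(ttr_ending(fx[["T18-0"]]), 0.5)
  expect_equal(ttr_ending(fx[["T18-10"]]), 0.25)
  expect_equal(ttr_ending(strip_agent_marking(generate_initial_language(seed = 5))),
               0.25)
})

test_that("stem TTR isolates lexical distinctions within agents", {
  fx <- load_fixtures()
  expect_equal(ttr_stem(fx[["T25-10"]]), 1 / 3)  # {t,t,f,f,f,f} per agent
  expect_equal(ttr_stem(fx[["T25-0"]]), 0.5)     # {b,f,t} x 2 numbers
  m <- enumerate_meanings()
  one_stem <- language(ifelse(m$event == "none", "rub", "rub ta"))
  expect_equal(ttr_stem(one_stem), 1 / 6)
})

test_that("missing verbs shrink denominators; empty subcorpora are skipped", {
  fx <- load_fixtures()
  lang <- fx[["T25-0"]]
  s <- lang$sentence
  # drop the verb from one fall_apart cell
  s[s == "jal bu"] <- "jal"
  partial <- language(s)
  expect_equal(ttr_pos(partial, "verb"), 6 / 11)
  # fall_apart subcorpus now {u,e,e}: 2/3; others still 1/2
  expect_equal(ttr_ending(partial), mean(c(2 / 3, 1 / 2, 1 / 2)))
  # drop an entire event's verbs -> skipped with a warning
  s2 <- lang$sentence
  s2[lang$event == "fall_apart"] <- sub(" .*", "", s2[lang$event == "fall_apart"])
  expect_warning(v <- ttr_ending(language(s2)), "skipped")
  expect_equal(v, 0.5)
  # no verbs at all -> error
  bare <- language(sub(" .*", "", lang$sentence))
  expect_error(suppressWarnings(ttr_ending(bare)), "no verb tokens")
  expect_error(ttr_pos(bare, "verb"), "verb")
})

test_that("entropy is 0 for uniform repetition and log2(n) for all-distinct", {
  m <- enumerate_meanings()
  same <- language(ifelse(m$event == "none", "aa", "aa aa"))
  expect_equal(entropy(same), 0)
  all_distinct <- language(ifelse(m$event == "none",
                                  sprintf("n%s", letters[1:16]),
                                  paste(sprintf("n%s", letters[1:16]),
                                        sprintf("v%s", letters[1:16]))))
  expect_equal(entropy(all_distinct), log2(28))
  # hand-tabulated frequency oracle for the printed N9 generation-0 language:
  # 4 noun forms x 4 tokens, 6 verb forms x 2 tokens
  p <- c(rep(4, 4), rep(2, 6)) / 28
  expect_equal(entropy(load_fixtures()[["N9-0"]]), -sum(p * log2(p)))
})

test_that("TTR metrics are invariant under bijective letter renaming", {
  rot <- function(x) chartr("abcdefghijklmnopqrstuvwxyz",
                            "bcdefghijklmnopqrstuvwxyza", x)
  for (seed in c(2, 13)) {
    lang <- generate_initial_language(seed = seed)
    ren <- language(rot(lang$sentence))
    for (f in list(ttr, ttr_ending, ttr_stem, entropy,
                   function(l) ttr_pos(l, "noun"),
                   function(l) ttr_pos(l, "verb"))) {
      expect_equal(f(ren), f(lang))
    }
  }
})

test_that("removing agent-marking strictly lowers TTR and floors ending TTR", {
  for (seed in c(3, 17, 31)) {
    lang <- generate_initial_language(seed = seed)
    stripped <- strip_agent_marking(lang)
    expect_lt(ttr(stripped), ttr(lang))
    expect_equal(ttr_ending(stripped), 0.25)
  }
})
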