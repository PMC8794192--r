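test_that("metric_table has one record per chain x generation x metric", {
  cfg <- experiment_config(n_chains_per_condition = 2, generations = 4,
                           master_seed = 2)
  chains <- run_experiment(cfg)
  rec <- metric_table(chains, "ttr_all")
  expect_equal(nrow(rec), 6 * 5)
  expect_equal(names(rec),
               c("chain_id", "condition", "generation", "metric", "value"))
  fid <- metric_table(chains, "fidelity")
  expect_equal(nrow(fid), 6 * 4)  # undefined at generation 0
  expect_false(any(fid$generation == 0))
})

test_that("metric_table on the printed fixtures recovers the worked values", {
  rec <- metric_table(fixture_chains(),
                      c("ttr_all", "ttr_ending", "ttr_stem"))
  get <- function(id, g, m)
    rec$value[rec$chain_id == id & rec$generation == g & rec$metric == m]
  expect_equal(get(25, 0, "ttr_ending"), 0.5)
  expect_equal(get(25, 10, "ttr_ending"), 0.25)
  expect_equal(get(25, 10, "ttr_stem"), 1 / 3)
  expect_equal(get(9, 0, "ttr_all"), 10 / 28)
  # partial chains (gens 0 and 10 only) yield no fidelity records
  expect_equal(nrow(metric_table(fixture_chains(), "fidelity")), 0L)
})

test_that("welch_t_test matches the closed-form Welch/Satterthwaite oracle", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- welch_t_test(x, y)
  want <- welch_oracle(x, y)
  expect_equal(got$t, want$t)
  expect_equal(got$df, want$df)
  expect_equal(got$p, want$p)
  expect_equal(c(got$ci_low, got$ci_high), want$ci)
  expect_equal(got$d, want$d)
  set.seed(7)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    got <- welch_t_test(x, y); want <- welch_oracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-6)
    expect_equal(got$df, want$df, tolerance = 1e-6)
    expect_equal(got$p, want$p, tolerance = 1e-6)
    expect_equal(got$d, want$d, tolerance = 1e-6)
  }
})

test_that("welch_t_test handles identical and degenerate samples", {
  x <- c(1, 2, 3, 4)
  got <- welch_t_test(x, x)
  expect_equal(got$t, 0)
  expect_equal(got$d, 0)
  expect_equal(got$p, 1)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("per-chain slopes are exact on noise-free log-linear trajectories", {
  g <- 0:10
  rec <- rbind(
    data.frame(chain_id = 1, condition = "T", generation = g,
               metric = "ttr_all", value = exp(-1 - 0.02 * g)),
    data.frame(chain_id = 2, condition = "N", generation = g,
               metric = "ttr_all", value = exp(-1)))
  sl <- per_chain_slopes(rec, "ttr_all")
  expect_equal(sl$slope[sl$chain_id == 1], -0.02)
  expect_equal(sl$slope[sl$chain_id == 2], 0)
  cs <- attr(sl, "condition_summary")
  expect_equal(cs$mean_slope[cs$condition == "T"], -0.02)
  short <- rec[rec$generation < 2, ]
  expect_error(per_chain_slopes(short, "ttr_all"), "fewer than 3")
})

test_that("fit_trend recovers exact slopes from noise-free data", {
  g <- 0:10
  mk <- function(id, cond, slope)
    data.frame(chain_id = id, condition = cond, generation = g,
               metric = "ttr_all", value = exp(-1.02 + slope * g))
  rec <- rbind(mk(1, "T", -0.02), mk(2, "T", -0.02),
               mk(3, "N", -0.007), mk(4, "N", -0.007),
               mk(5, "P", -0.02), mk(6, "P", -0.02))
  fit <- suppressMessages(fit_trend(rec))
  cf <- coef(fit)
  expect_equal(unname(cf["generation"]), -0.02, tolerance = 1e-6)
  expect_equal(unname(cf["conditionN:generation"]), 0.013, tolerance = 1e-5)
  expect_equal(unname(cf["conditionP:generation"]), 0, tolerance = 1e-6)
  expect_equal(unname(cf["(Intercept)"]), -1.02, tolerance = 1e-6)
})

test_that("fit_trend on constant records estimates zero slopes", {
  g <- 0:6
  rec <- do.call(rbind, lapply(1:6, function(i)
    data.frame(chain_id = i, condition = c("N", "T", "P")[(i - 1) %% 3 + 1],
               generation = g, metric = "ttr_all", value = 10 / 28)))
  fit <- suppressMessages(fit_trend(rec))
  cf <- coef(fit)
  expect_equal(unname(cf["generation"]), 0, tolerance = 1e-8)
  expect_equal(unname(cf["conditionN:generation"]), 0, tolerance = 1e-8)
  expect_equal(unname(cf["conditionP:generation"]), 0, tolerance = 1e-8)
})

test_that("changing the reference condition leaves fitted values unchanged", {
  set.seed(11)
  rec <- synthetic_records(n_per_cond = 5, G = 6)
  ft <- suppressMessages(fit_trend(rec, reference_condition = "T"))
  fn <- suppressMessages(fit_trend(rec, reference_condition = "N"))
  expect_false(isTRUE(all.equal(coef(ft), coef(fn), check.names = FALSE)))
  expect_equal(unname(fitted(ft)), unname(fitted(fn)), tolerance = 1e-6)
})

test_that("fit_trend validates its inputs", {
  rec <- data.frame(chain_id = 1, condition = "T", generation = 0:5,
                    metric = "ttr_all", value = c(0.5, 0.4, 0, 0.3, 0.2, 0.1))
  expect_error(fit_trend(rec), "at least 2 chains|log-transform")
  rec2 <- synthetic_records(n_per_cond = 2, G = 4)
  rec2$value[1] <- -1
  expect_error(suppressMessages(fit_trend(rec2)), "log-transform")
})

test_that("the POS model separates noun and verb generation slopes", {
  g <- 0:8
  mk <- function(id, cond, m, slope, base)
    data.frame(chain_id = id, condition = cond, generation = g,
               metric = m, value = exp(base + slope * g))
  rec <- do.call(rbind, c(
    lapply(1:2, function(i) mk(i, "T", "ttr_noun", 0.005, -1.4)),
    lapply(1:2, function(i) mk(i, "T", "ttr_verb", -0.05, -0.7)),
    lapply(3:4, function(i) mk(i, "N", "ttr_noun", 0.005, -1.4)),
    lapply(3:4, function(i) mk(i, "N", "ttr_verb", -0.02, -0.7))))
  fit <- suppressMessages(fit_trend(rec, model = "pos"))
  cf <- coef(fit)
  expect_equal(unname(cf["generation"]), 0.005, tolerance = 1e-5)
  expect_equal(unname(cf["generation:unitverb"]), -0.055, tolerance = 1e-5)
  expect_equal(unname(cf["conditionN:generation:unitverb"]), 0.03,
               tolerance = 1e-5)
})

test_that("the full pipeline is reproducible end to end from the master seed", {
  cfg <- experiment_config(n_chains_per_condition = 3, generations = 5,
                           master_seed = 77)
  run <- function() {
    rec <- metric_table(run_experiment(cfg), c("ttr_all", "fidelity"))
    suppressMessages(fit_trend(rec))$coefficients
  }
  expect_identical(run(), run())
})
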