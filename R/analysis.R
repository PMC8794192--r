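METRICS <- c("ttr_all", "ttr_noun", "ttr_verb", "ttr_ending", "ttr_stem",
             "entropy", "fidelity")

#' Compute a long table of per-generation metrics over chains
#'
#' One record per chain x generation x metric. `fidelity` is computed against
#' the previous generation's language and is therefore undefined (absent) at
#' generation 0 or after a gap in a partial chain. A metric that fails for a
#' cell (e.g. ending TTR of a language with no verbs) yields `NA` with a
#' warning rather than aborting the table.
#'
#' @param chains List of `iterlang_chain` objects (or a single chain).
#' @param metrics Subset of
#'   `c("ttr_all", "ttr_noun", "ttr_verb", "ttr_ending", "ttr_stem",
#'   "entropy", "fidelity")`.
#' @return Data frame with columns `chain_id`, `condition`, `generation`,
#'   `metric`, `value`, ordered by chain, generation, metric.
#' @export
metric_table <- function(chains, metrics = METRICS) {
  if (inherits(chains, "iterlang_chain")) chains <- list(chains)
  metrics <- match.arg(metrics, METRICS, several.ok = TRUE)
  eval_metric <- function(m, lang, prev) {
    switch(m,
           ttr_all = ttr(lang),
           ttr_noun = ttr_pos(lang, "noun"),
           ttr_verb = ttr_pos(lang, "verb"),
           ttr_ending = ttr_ending(lang),
           ttr_stem = ttr_stem(lang),
           entropy = entropy(lang),
           fidelity = if (is.null(prev)) NA_real_ else
             transmission_fidelity(prev, lang))
  }
  rows <- list()
  for (ch in chains) {
    gens <- as.integer(names(ch$languages))
    for (k in seq_along(gens)) {
      g <- gens[k]
      prev <- if (k > 1L && gens[k - 1L] == g - 1L)
        ch$languages[[k - 1L]] else NULL
      for (m in metrics) {
        if (m == "fidelity" && is.null(prev)) next
        val <- tryCatch(eval_metric(m, ch$languages[[k]], prev),
                        error = function(e) {
                          warning("metric ", m, " failed for chain ",
                                  ch$chain_id, " generation ", g, ": ",
                                  conditionMessage(e), call. = FALSE)
                          NA_real_
                        })
        rows[[length(rows) + 1L]] <-
          data.frame(chain_id = ch$chain_id, condition = ch$condition,
                     generation = g, metric = m, value = val,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chain_id = integer(0), condition = character(0),
                      generation = integer(0), metric = character(0),
                      value = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, two-tailed p-value, 95\% confidence interval for the difference
#' in means, and Cohen's d computed with the pooled standard deviation.
#'
#' @param x,y Numeric samples (each of size >= 2, nonzero variance in at
#'   least one).
#' @param conf_level Confidence level for the mean-difference interval.
#' @param alternative Test sidedness (default two-tailed).
#' @return Object of class `welch_test` with fields `t`, `df`, `p`,
#'   `ci_low`, `ci_high`, `d`, `mean_x`, `mean_y`.
#' @export
welch_t_test <- function(x, y, conf_level = 0.95,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample must have at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both samples have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level,
                      alternative = alternative)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 ci_low = ht$conf.int[1L], ci_high = ht$conf.int[2L],
                 d = (mean(x) - mean(y)) / sp,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, digits = 3, ...) {
  cat(sprintf("Welch two-sample t-test: t(%.1f) = %.2f, p = %.3g\n",
              x$df, x$t, x$p))
  cat(sprintf("mean difference %.4f, 95%% CI [%.4f, %.4f], Cohen's d = %.2f\n",
              x$mean_x - x$mean_y, x$ci_low, x$ci_high, x$d))
  invisible(x)
}

#' Per-chain OLS slopes of a log metric on generation
#'
#' For each chain, the ordinary-least-squares slope of `log(value)` (natural
#' log by default) on generation. This is the robustness companion (and
#' convergence fallback) of the mixed-effects trend model: the scientific
#' claims under test are slope signs and orderings.
#'
#' @param records A [metric_table()] data frame.
#' @param metric Which metric to use.
#' @param log_transform Log the values first (TTR-family metrics are fit on
#'   the log scale)?
#' @return Data frame of per-chain slopes (`chain_id`, `condition`,
#'   `n_generations`, `slope`) with a `condition_summary` attribute (mean,
#'   SD and n of slopes by condition).
#' @export
per_chain_slopes <- function(records, metric = "ttr_all",
                             log_transform = TRUE) {
  r <- records[records$metric == metric & !is.na(records$value), ]
  if (nrow(r) == 0L) stop("no records for metric ", metric)
  y <- if (log_transform) {
    if (any(r$value <= 0)) stop("non-positive values cannot be log-transformed")
    log(r$value)
  } else r$value
  r$y <- y
  out <- do.call(rbind, lapply(split(r, r$chain_id), function(d) {
    if (nrow(d) < 3L)
      stop("chain ", d$chain_id[1L], " has fewer than 3 usable generations")
    fit <- stats::lm(y ~ generation, data = d)
    data.frame(chain_id = d$chain_id[1L], condition = d$condition[1L],
               n_generations = nrow(d),
               slope = unname(stats::coef(fit)[2L]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  cs <- do.call(rbind, lapply(split(out, out$condition), function(d)
    data.frame(condition = d$condition[1L], mean_slope = mean(d$slope),
               sd_slope = stats::sd(d$slope), n = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(cs) <- NULL
  attr(out, "condition_summary") <- cs
  out
}

#' Fit the condition-by-generation trend model
#'
#' Fits a linear mixed-effects model of the log metric on condition,
#' generation and their interaction with by-chain random effects, via
#' [lmerTest::lmer()] (REML, Satterthwaite degrees of freedom):
#'
#' \itemize{
#'   \item `model = "overall"`:
#'     `log(value) ~ condition * generation + (1 + generation | chain)`.
#'   \item `model = "pos"`: adds part of speech (noun TTR vs verb TTR;
#'     reference noun) with all interactions; random structure
#'     `(0 + generation | chain) + (1 | chain)` (uncorrelated).
#'   \item `model = "morpheme"`: as `"pos"` but contrasting verb-stem vs
#'     verb-ending TTR (reference stem).
#' }
#'
#' Condition uses treatment coding with reference `"T"` by default, so the
#' `generation` coefficient is the T-condition slope and the interactions are
#' slope offsets for N and P. Generation is entered uncentered (0..G), so the
#' intercept is a generation-0 value. If the mixed fit fails or does not
#' converge, the model falls back to per-chain OLS slopes aggregated by
#' condition, flagged in the result.
#'
#' @param records A [metric_table()] data frame.
#' @param model `"overall"`, `"pos"` or `"morpheme"`.
#' @param metric Metric for `model = "overall"` (default `"ttr_all"`).
#' @param reference_condition Reference level for condition.
#' @param log_transform Log-transform the response (default TRUE; values
#'   must be strictly positive).
#' @return Object of class `trend_fit` with a `coefficients` data frame
#'   (`term`, `estimate`, `se`, `df`, `t`, `p`), flags `converged` and
#'   `fallback`, and (for mixed fits) the underlying `lmerMod` in `$model`.
#' @export
fit_trend <- function(records, model = c("overall", "pos", "morpheme"),
                      metric = "ttr_all", reference_condition = "T",
                      log_transform = TRUE) {
  model <- match.arg(model)
  reference_condition <- match.arg(reference_condition, CONDITIONS)
  if (model == "overall") {
    d <- records[records$metric == metric, ]
    form <- y ~ condition * generation + (1 + generation | chain)
  } else {
    lv <- if (model == "pos") c("ttr_noun", "ttr_verb") else
      c("ttr_stem", "ttr_ending")
    nm <- if (model == "pos") c("noun", "verb") else c("stem", "ending")
    d <- records[records$metric %in% lv, ]
    d$unit <- factor(nm[match(d$metric, lv)], levels = nm)
    form <- y ~ condition * generation * unit +
      (0 + generation | chain) + (1 | chain)
  }
  d <- d[!is.na(d$value), ]
  if (nrow(d) == 0L) stop("no usable records for the requested model")
  if (length(unique(d$condition)) > 1L &&
      min(table(unique(d[c("chain_id", "condition")])$condition)) < 2L)
    stop("need at least 2 chains per condition")
  if (log_transform && any(d$value <= 0))
    stop("non-positive values cannot be log-transformed")
  d$y <- if (log_transform) log(d$value) else d$value
  d$condition <- stats::relevel(factor(d$condition, levels = CONDITIONS),
                                ref = reference_condition)
  d$condition <- droplevels(d$condition)
  d$chain <- factor(d$chain_id)
  fit <- tryCatch(
    withCallingHandlers(
      lmerTest::lmer(form, data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   lme4::.makeCC(action = "ignore", tol = 1e-4))),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
          invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  ok <- !inherits(fit, "error") &&
    length(fit@optinfo$conv$lme4$messages) == 0L &&
    fit@optinfo$conv$opt == 0L
  if (ok) {
    cf <- as.data.frame(summary(fit)$coefficients)
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], df = cf[, "df"],
                        t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    res <- list(coefficients = coefs, model = fit, converged = TRUE,
                fallback = FALSE)
  } else {
    if (model != "overall")
      stop("mixed model failed and the per-chain-slope fallback only covers ",
           "the overall model")
    sl <- per_chain_slopes(records[records$metric == metric, ], metric,
                           log_transform = log_transform)
    cs <- attr(sl, "condition_summary")
    ref <- cs[cs$condition == reference_condition, ]
    rows <- list(data.frame(term = "generation", estimate = ref$mean_slope,
                            se = ref$sd_slope / sqrt(ref$n),
                            df = ref$n - 1,
                            t = ref$mean_slope / (ref$sd_slope / sqrt(ref$n)),
                            p = NA_real_, stringsAsFactors = FALSE))
    for (cond in setdiff(cs$condition, reference_condition)) {
      cc <- cs[cs$condition == cond, ]
      se <- sqrt(cc$sd_slope^2 / cc$n + ref$sd_slope^2 / ref$n)
      est <- cc$mean_slope - ref$mean_slope
      rows[[length(rows) + 1L]] <-
        data.frame(term = paste0("condition", cond, ":generation"),
                   estimate = est, se = se, df = cc$n + ref$n - 2,
                   t = est / se, p = NA_real_, stringsAsFactors = FALSE)
    }
    coefs <- do.call(rbind, rows)
    for (i in seq_len(nrow(coefs)))
      coefs$p[i] <- 2 * stats::pt(-abs(coefs$t[i]), coefs$df[i])
    res <- list(coefficients = coefs, model = NULL, converged = FALSE,
                fallback = TRUE, slopes = sl)
  }
  res$spec <- list(model = model, metric = metric,
                   reference_condition = reference_condition,
                   log_transform = log_transform)
  res$data <- d
  class(res) <- "trend_fit"
  res
}

#' @export
print.trend_fit <- function(x, digits = 3, ...) {
  cat("Condition-by-generation trend model (", x$spec$model,
      if (x$spec$model == "overall") paste0(", metric ", x$spec$metric),
      "; reference condition ", x$spec$reference_condition, ")\n", sep = "")
  if (x$fallback)
    cat("NOTE: mixed model did not converge; per-chain OLS slope fallback.\n")
  cf <- x$coefficients
  cf[-1L] <- lapply(cf[-1L], signif, digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.trend_fit <- function(object, ...) object$coefficients

#' @export
fitted.trend_fit <- function(object, ...) {
  if (is.null(object$model)) stop("no fitted mixed model (fallback fit)")
  stats::fitted(object$model)
}

#' Plot metric trajectories by condition
#'
#' Convenience base-graphics plot of condition-mean trajectories over
#' generations for one metric.
#'
#' @param records A [metric_table()] data frame.
#' @param metric Metric to plot.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the generation x condition matrix of means.
#' @export
plot_trajectories <- function(records, metric = "ttr_all", ...) {
  r <- records[records$metric == metric & !is.na(records$value), ]
  agg <- tapply(r$value, list(r$generation, r$condition), mean)
  graphics::matplot(as.integer(rownames(agg)), agg, type = "b", pch = 1:3,
                    lty = 1, xlab = "generation", ylab = metric, ...)
  graphics::legend("topright", legend = colnames(agg), pch = 1:3,
                   col = seq_len(ncol(agg)), lty = 1, bty = "n")
  invisible(agg)
}
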