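#' Write and read chain logs as TSV
#'
#' A chain log serializes one or more chains as a plain TSV with columns
#' `chain_id`, `condition`, `generation`, `agent`, `number`, `event`,
#' `sentence` (words space-separated), one row per meaning, preceded by
#' `#`-prefixed provenance comment lines. Row order is stable (chain,
#' generation, canonical meaning order), so identical chains always produce
#' byte-identical files.
#'
#' @param chains List of `iterlang_chain` objects (or a single chain).
#' @param path Output file path.
#' @param comments Optional extra provenance strings, one comment line each.
#' @return `path`, invisibly.
#' @export
write_chain_log <- function(chains, path, comments = character(0)) {
  if (inherits(chains, "iterlang_chain")) chains <- list(chains)
  tabs <- lapply(chains, function(ch) {
    do.call(rbind, lapply(names(ch$languages), function(g) {
      lang <- ch$languages[[g]]
      data.frame(chain_id = ch$chain_id, condition = ch$condition,
                 generation = as.integer(g),
                 agent = as.character(lang$agent),
                 number = as.character(lang$number),
                 event = as.character(lang$event),
                 sentence = lang$sentence, stringsAsFactors = FALSE)
    }))
  })
  tab <- do.call(rbind, tabs)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c("iterlang chain log",
           paste0("package version: ",
                  as.character(utils::packageVersion("iterlang"))),
           comments)
  writeLines(paste("#", hdr), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chain_log
#' @return For `read_chain_log`, the list of chains reconstructed from the
#'   file. Languages must be complete (16 rows each); malformed rows and
#'   unknown condition labels are reported with their line numbers. Partial
#'   chains (non-contiguous generations) are allowed.
#' @export
read_chain_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- startsWith(lines, "#")
  body_lines <- which(!is_comment)
  tab <- utils::read.delim(text = lines[body_lines], header = TRUE,
                           colClasses = "character")
  need <- c("chain_id", "condition", "generation", "agent", "number",
            "event", "sentence")
  if (!all(need %in% names(tab)))
    stop("chain log lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  # line number in the original file for each data row (header is first body line)
  tab$.line <- body_lines[-1L]
  bad <- !(tab$condition %in% CONDITIONS)
  if (any(bad))
    stop("unknown condition label(s) ",
         paste(unique(tab$condition[bad]), collapse = ", "),
         " at line(s) ", paste(utils::head(tab$.line[bad], 5L), collapse = ", "))
  ref <- enumerate_meanings()
  ref_key <- paste(ref$agent, ref$number, ref$event, sep = "/")
  chains <- list()
  for (id in unique(tab$chain_id)) {
    sub <- tab[tab$chain_id == id, ]
    cond <- unique(sub$condition)
    if (length(cond) != 1L)
      stop("chain ", id, " has inconsistent condition labels")
    gens <- sort(unique(as.integer(sub$generation)))
    langs <- stats::setNames(vector("list", length(gens)),
                             as.character(gens))
    for (g in gens) {
      rows <- sub[as.integer(sub$generation) == g, ]
      key <- paste(rows$agent, rows$number, rows$event, sep = "/")
      missing <- setdiff(ref_key, key)
      if (length(missing) > 0L)
        stop("chain ", id, " generation ", g, " (around line ",
             rows$.line[1L], "): missing meaning(s) ",
             paste(missing, collapse = "; "))
      dup <- key[duplicated(key)]
      if (length(dup) > 0L)
        stop("chain ", id, " generation ", g, ": duplicated meaning(s) ",
             paste(unique(dup), collapse = "; "))
      langs[[as.character(g)]] <-
        language(rows$sentence[match(ref_key, key)],
                 label = paste0(cond, id, "-", g))
    }
    chains[[length(chains) + 1L]] <-
      new_chain(as.integer(id), cond, langs)
  }
  chains
}

#' Write and read experiment configurations as JSON
#'
#' Serializes an [experiment_config()] (including agent parameters and
#' morphological template pools) so a simulation run can be reproduced from
#' its sidecar file.
#'
#' @param config An `experiment_config`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_run_config` returns the
#'   `experiment_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  x <- list(n_chains_per_condition = config$n_chains_per_condition,
            generations = config$generations,
            conditions = config$conditions,
            agent_params = unclass(config$agent_params),
            template = unclass(config$template),
            master_seed = config$master_seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_config(
    n_chains_per_condition = x$n_chains_per_condition,
    generations = x$generations,
    conditions = x$conditions,
    agent_params = do.call(agent_params, as.list(x$agent_params)),
    template = do.call(morph_template, as.list(x$template)),
    master_seed = x$master_seed)
}
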