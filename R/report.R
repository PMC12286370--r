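# Publication-style summary tables and the full analysis pipeline.

#' Degree summary table (per-mode in/out distributions)
#'
#' One row per (direction, mode) combination covering both pooled and
#' per-mode summaries of the degree distributions — the descriptive
#' table used to assess hierarchy on the market.
#'
#' @param net a \code{swipe_network}.
#' @param standardized summarise standardized degrees instead of raw
#'   counts.
#' @return data frame with one \code{\link{degree_summary}} row per
#'   (direction, mode).
#' @export
degree_table <- function(net, standardized = FALSE) {
  rows <- list()
  for (dir in c("in", "out")) {
    for (m in c("all", "men", "women")) {
      rows[[paste(dir, m)]] <-
        degree_summary(net, m, dir, standardized = standardized)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-network structure table
#'
#' Density, per-mode indegree centralization and reciprocity in one
#' data frame.
#'
#' @param net a \code{swipe_network}.
#' @return data frame with columns \code{measure} and \code{value}.
#' @export
structure_table <- function(net) {
  data.frame(
    measure = c("density", "centralization_men", "centralization_women",
                "reciprocity"),
    value = c(network_density(net),
              indegree_centralization(net, "men"),
              indegree_centralization(net, "women"),
              reciprocity(net)),
    stringsAsFactors = FALSE
  )
}

#' Tabulate CUG test results
#'
#' @param results list of \code{cug_result} objects.
#' @return data frame, one row per test: statistic, weighted flag,
#'   observed value, empirical p-values, simulated mean/SD, replicate
#'   accounting and seed.
#' @export
cug_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    stopifnot(inherits(x, "cug_result"))
    data.frame(statistic = x$statistic, weighted = x$weighted,
               observed = x$observed, p_le = x$p_le, p_ge = x$p_ge,
               sim_mean = x$sim_mean, sim_sd = x$sim_sd,
               n_sims = x$n_sims, n_missing = x$n_missing,
               seed = x$seed, stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline on a network
#'
#' Executes preprocessing (optional city split, bot filter, active-user
#' filter, in that order), descriptive tables, the cross-mode
#' desirability comparison, and the CUG test suite (all-ties gaps in
#' both directions, their outdegree-weighted variants, and the
#' reciprocated-only gap), and optionally writes the three summary
#' tables as CSV plus a JSON manifest recording the package version,
#' seed, parameters, filter reports and node/tie accounting.
#'
#' @param net a \code{swipe_network} (for multi-city inputs, pass the
#'   full network and set \code{by_city = TRUE}; each market is then
#'   analysed separately).
#' @param seed integer seed; required (the pipeline always includes
#'   stochastic tests).
#' @param n_sims CUG replicates (default 1,000).
#' @param n_permutations label permutations for the gender-gap
#'   randomization test.
#' @param min_received,accept_rate bot-filter parameters; set
#'   \code{min_received = Inf} to disable the filter.
#' @param by_city split into per-city markets before analysis.
#' @param weighted also run outdegree-weighted gap variants.
#' @param out_dir if non-\code{NULL}, write
#'   \code{<market>_degrees.csv}, \code{<market>_structure.csv},
#'   \code{<market>_cug.csv} and \code{manifest.json} there.
#' @return invisibly, a named list (one element per market) with
#'   components \code{network}, \code{filter_reports}, \code{degrees},
#'   \code{degrees_std}, \code{structure}, \code{gender_gap},
#'   \code{cug}, plus a \code{manifest} element at the top level.
#' @export
run_full_analysis <- function(net, seed, n_sims = 1000L,
                              n_permutations = 10000L,
                              min_received = 30, accept_rate = 1,
                              by_city = FALSE, weighted = TRUE,
                              out_dir = NULL) {
  stopifnot(inherits(net, "swipe_network"))
  if (missing(seed) || is.null(seed)) {
    stop("configuration error: `seed` is required because the pipeline ",
         "includes randomization and CUG tests", call. = FALSE)
  }
  markets <- if (by_city) split_markets(net, "city") else list(market = net)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  results <- list()
  for (label in names(markets)) {
    m <- markets[[label]]
    reports <- list()
    if (is.finite(min_received)) {
      fb <- stage("bot_filter",
                  filter_bots(m, min_received = min_received,
                              accept_rate = accept_rate))
      m <- fb$network
      reports$bots <- fb$report
    }
    fa <- stage("active_filter", filter_active(m))
    m <- fa$network
    reports$active <- fa$report

    degs <- stage("descriptives", degree_table(m))
    degs_std <- stage("descriptives", degree_table(m, standardized = TRUE))
    struct <- stage("descriptives", structure_table(m))
    gg <- stage("gender_gap",
                gender_gap(m, n_permutations = n_permutations,
                           seed = seed))
    specs <- list(
      list(stat = "gap_mw", weighted = FALSE),
      list(stat = "gap_wm", weighted = FALSE),
      list(stat = "reciprocal", weighted = FALSE)
    )
    if (weighted) {
      specs <- c(specs, list(list(stat = "gap_mw", weighted = TRUE),
                             list(stat = "gap_wm", weighted = TRUE)))
    }
    cugs <- lapply(specs, function(sp) {
      stage(paste0("cug_", sp$stat, if (sp$weighted) "_weighted"),
            cug_test(m, sp$stat, n_sims = n_sims, seed = seed,
                     weighted = sp$weighted))
    })
    results[[label]] <- list(network = m, filter_reports = reports,
                             degrees = degs, degrees_std = degs_std,
                             structure = struct, gender_gap = gg,
                             cug = cugs)
  }

  manifest <- list(
    package = "swipenet",
    version = as.character(utils::packageVersion("swipenet")),
    seed = as.integer(seed),
    parameters = list(n_sims = as.integer(n_sims),
                      n_permutations = as.integer(n_permutations),
                      min_received = min_received,
                      accept_rate = accept_rate,
                      by_city = by_city, weighted = weighted),
    markets = lapply(results, function(r) {
      list(n_women = length(r$network$women),
           n_men = length(r$network$men),
           n_ties = n_ties(r$network),
           filters = lapply(r$filter_reports, function(fr) {
             list(rule = fr$rule, n_removed = fr$n_removed,
                  removed_ids = fr$removed_ids,
                  ties_removed = fr$ties_removed, params = fr$params)
           }))
    })
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (label in names(results)) {
      r <- results[[label]]
      utils::write.csv(r$degrees,
                       file.path(out_dir, paste0(label, "_degrees.csv")),
                       row.names = FALSE)
      utils::write.csv(r$structure,
                       file.path(out_dir, paste0(label, "_structure.csv")),
                       row.names = FALSE)
      utils::write.csv(cug_table(r$cug),
                       file.path(out_dir, paste0(label, "_cug.csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(results, list(manifest = manifest)))
}
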