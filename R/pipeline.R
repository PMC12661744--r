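#' Run the full local-inconsistency pipeline on one network
#'
#' Chains every stage: event-risk filtering, eligibility checking,
#' split-node enumeration, Bayesian node-splitting per node, the
#' Kullback-Leibler interpretation index, node classification, and the
#' network verdict. An ineligible (or fully filtered) network returns a
#' report carrying the reason and no model fit.
#'
#' @param ds an [nma_data] object.
#' @param config optional list overriding defaults: `risk_lo`, `risk_hi`
#'   (event-risk bounds), `eligibility` (rules list for
#'   [check_eligibility()]), `prior` (a [prior_spec]), `mcmc` (an
#'   [mcmc_settings]), `threshold` (index cut-off).
#' @param id network identifier carried into the report.
#' @return An object of class `network_report`: list with `id`, `filter`,
#'   `eligibility`, `results` (`nodesplit_set` or `NULL`), `verdicts`
#'   (list of `node_verdict`), `network_verdict`, `threshold`, `converged`,
#'   `tau_band` (band of the median posterior `tau` medians across nodes),
#'   and `status` (`"analysed"`, `"excluded_by_filter"`, `"ineligible"`,
#'   `"no_split_nodes"`).
#' @export
analyze_network <- function(ds, config = list(), id = "network") {
  stopifnot(inherits(ds, "nma_data"))
  lo <- config$risk_lo %||% 0.15
  hi <- config$risk_hi %||% 0.85
  prior <- config$prior %||% prior_spec()
  mcmc <- config$mcmc %||% mcmc_settings()
  threshold <- config$threshold %||% low_inconsistency_threshold()

  filt <- filter_event_risk(ds, lo = lo, hi = hi)
  base <- list(id = id, filter = filt, eligibility = NULL, results = NULL,
               verdicts = NULL, network_verdict = NULL,
               threshold = threshold, converged = NA, tau_band = NA_character_)
  if (filt$all_removed) {
    base$status <- "excluded_by_filter"
    return(structure(base, class = "network_report"))
  }
  retained <- filt$retained
  elig <- check_eligibility(retained, rules = config$eligibility)
  base$eligibility <- elig
  if (!elig$overall_eligible) {
    base$status <- "ineligible"
    return(structure(base, class = "network_report"))
  }
  results <- run_all_nodes(retained, prior = prior, mcmc = mcmc)
  base$results <- results
  if (!length(results$results)) {
    base$status <- "no_split_nodes"
    return(structure(base, class = "network_report"))
  }
  verdicts <- lapply(results$results, classify_node, threshold = threshold)
  base$verdicts <- verdicts
  base$network_verdict <- classify_network(verdicts)
  base$converged <- results$converged
  tau_medians <- vapply(results$results, function(r) r$tau$median, numeric(1))
  base$tau_band <- heterogeneity_band(median(tau_medians))
  base$status <- "analysed"
  structure(base, class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat("Network report [", x$id, "]: status =", x$status, "\n")
  if (nrow(x$filter$removed_studies)) {
    cat("  studies removed by event-risk filter:",
        nrow(x$filter$removed_studies), "\n")
  }
  if (x$status == "ineligible") {
    failed <- names(x$eligibility$criteria)[!x$eligibility$criteria]
    cat("  failed criteria:", paste(failed, collapse = ", "), "\n")
  }
  if (x$status == "analysed") {
    cat(sprintf("  %d split node(s); threshold %.4f; converged: %s\n",
                length(x$verdicts), x$threshold, x$converged))
    print(x$network_verdict)
    cat("  heterogeneity band (median tau):", x$tau_band, "\n")
  }
  invisible(x)
}

#' Analyse a batch of networks
#'
#' Applies [analyze_network()] to a named list of datasets with one shared
#' configuration. Per-network seeds are derived by hashing the network id
#' together with the master seed, so the batch is reproducible and
#' insensitive to the order in which networks are supplied.
#'
#' @param datasets named list of [nma_data] objects (or paths readable by
#'   [read_nma_data()]).
#' @param config as in [analyze_network()].
#' @param seed master seed.
#' @return Named list of `network_report` objects.
#' @export
analyze_networks <- function(datasets, config = list(), seed = 1L) {
  stopifnot(length(datasets) >= 1L)
  ids <- names(datasets)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("network", seq_along(datasets))
  }
  out <- vector("list", length(datasets))
  names(out) <- ids
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    if (is.character(ds)) ds <- read_nma_data(ds)
    cfg <- config
    mcmc <- cfg$mcmc %||% mcmc_settings()
    mcmc$seed <- derive_seed(seed, ids[i])
    cfg$mcmc <- mcmc
    out[[i]] <- analyze_network(ds, config = cfg, id = ids[i])
  }
  out
}

# deterministic 31-bit seed from a master seed and a network id
derive_seed <- function(seed, id) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)) %% 7919)
  as.integer((as.double(seed) * 69991 + h) %% 2147483629)
}

#' Prevalence of inconsistency across analysed networks
#'
#' Tabulates split nodes and networks over the two decision rules: extent
#' (acceptably low / material, from the interpretation index) crossed with
#' conclusiveness (conclusive / inconclusive, from the 95% credible interval
#' of the inconsistency factor), plus the same node-level tabulation
#' restricted to single-study and multi-study split nodes. Percentages are
#' always recomputed from the stored counts.
#'
#' @param reports a list of `network_report` objects (only those with
#'   status `"analysed"` contribute).
#' @return An object of class `prevalence_summary` with `node_counts`,
#'   `node_counts_single`, `node_counts_multi` (2x2 integer matrices),
#'   `network_counts` (verdict table), `n_nodes`, `n_networks`.
#' @export
summarize_prevalence <- function(reports) {
  if (inherits(reports, "network_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1L)
  analysed <- Filter(function(r) identical(r$status, "analysed"), reports)
  dims <- list(extent = c("acceptably_low", "material"),
               conclusiveness = c("conclusive", "inconclusive"))
  empty <- matrix(0L, 2, 2, dimnames = dims)
  node_counts <- empty
  node_single <- empty
  node_multi <- empty
  network_counts <- matrix(
    0L, 2, 2, dimnames = list(
      index_based = c("consistent", "potentially_inconsistent"),
      cri_based = c("conclusive", "inconclusive")))
  for (r in analysed) {
    for (i in seq_along(r$verdicts)) {
      v <- r$verdicts[[i]]
      node_counts[v$extent, v$conclusiveness] <-
        node_counts[v$extent, v$conclusiveness] + 1L
      single <- r$results$results[[i]]$node$single_study
      if (single) {
        node_single[v$extent, v$conclusiveness] <-
          node_single[v$extent, v$conclusiveness] + 1L
      } else {
        node_multi[v$extent, v$conclusiveness] <-
          node_multi[v$extent, v$conclusiveness] + 1L
      }
    }
    nv <- r$network_verdict
    network_counts[nv$index_based, nv$cri_based] <-
      network_counts[nv$index_based, nv$cri_based] + 1L
  }
  structure(list(node_counts = node_counts,
                 node_counts_single = node_single,
                 node_counts_multi = node_multi,
                 network_counts = network_counts,
                 n_nodes = sum(node_counts),
                 n_networks = length(analysed),
                 n_reports = length(reports)),
            class = "prevalence_summary")
}

#' @export
print.prevalence_summary <- function(x, ...) {
  pct <- function(k, n) if (n > 0) sprintf("%d (%.0f%%)", k, 100 * k / n)
                        else "0"
  cat("Prevalence of inconsistency:", x$n_nodes, "split nodes in",
      x$n_networks, "analysed networks\n")
  cat("  split nodes:\n")
  cat("    material:        ",
      pct(sum(x$node_counts["material", ]), x$n_nodes), "\n")
  cat("    acceptably low:  ",
      pct(sum(x$node_counts["acceptably_low", ]), x$n_nodes), "\n")
  cat("    conclusive:      ",
      pct(sum(x$node_counts[, "conclusive"]), x$n_nodes), "\n")
  cat("    inconclusive:    ",
      pct(sum(x$node_counts[, "inconclusive"]), x$n_nodes), "\n")
  cat("  networks:\n")
  cat("    potentially inconsistent:",
      pct(sum(x$network_counts["potentially_inconsistent", ]),
          x$n_networks), "\n")
  cat("    consistent:              ",
      pct(sum(x$network_counts["consistent", ]), x$n_networks), "\n")
  invisible(x)
}

#' Export tidy tables behind the standard diagnostic plots
#'
#' Writes four delimited tables to `dir`, one per standard display:
#' `posterior_by_node_size.csv` (posterior mean and sd of the direct effect,
#' indirect effect and inconsistency factor, by split-node size group),
#' `index_vs_if.csv` (interpretation index against the posterior mean and sd
#' of the inconsistency factor), `kld_direction_diff.csv` (the difference
#' `d_di - d_id` against the index), and `index_vs_tau.csv` (index against
#' the posterior median of `tau`, with the heterogeneity band). Counts are
#' always exported alongside any derived quantity; rendering is left to the
#' caller.
#'
#' @param reports list of `network_report` objects.
#' @param dir output directory (created if missing).
#' @return Character vector of the four file paths, invisibly.
#' @export
export_plot_data <- function(reports, dir) {
  if (inherits(reports, "network_report")) reports <- list(reports)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  analysed <- Filter(function(r) identical(r$status, "analysed"), reports)

  rows <- list()
  for (r in analysed) {
    df <- as.data.frame(r$results)
    if (!nrow(df)) next
    df$network <- r$id
    df$extent <- vapply(r$verdicts, function(v) v$extent, character(1))
    df$conclusiveness <- vapply(r$verdicts, function(v) v$conclusiveness,
                                character(1))
    df$threshold <- r$threshold
    rows[[length(rows) + 1L]] <- df
  }
  all_df <- if (length(rows)) do.call(rbind, rows) else NULL
  grp <- function(df) ifelse(df$single_study, "single_study", "multi_study")

  schema <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  p1 <- file.path(dir, "posterior_by_node_size.csv")
  p2 <- file.path(dir, "index_vs_if.csv")
  p3 <- file.path(dir, "kld_direction_diff.csv")
  p4 <- file.path(dir, "index_vs_tau.csv")
  if (is.null(all_df)) {
    write.csv(schema(c("network", "treat1", "treat2", "node_size_group",
                       "parameter", "posterior_mean", "posterior_sd")),
              p1, row.names = FALSE)
    write.csv(schema(c("network", "treat1", "treat2", "node_size_group",
                       "index", "if_mean", "if_sd", "extent",
                       "conclusiveness")), p2, row.names = FALSE)
    write.csv(schema(c("network", "treat1", "treat2", "node_size_group",
                       "index", "d_di", "d_id", "kld_diff")),
              p3, row.names = FALSE)
    write.csv(schema(c("network", "treat1", "treat2", "node_size_group",
                       "index", "tau_median", "tau_band", "extent")),
              p4, row.names = FALSE)
    return(invisible(c(p1, p2, p3, p4)))
  }

  long1 <- do.call(rbind, lapply(
    c(direct = "direct", indirect = "indirect", IF = "if"),
    function(pre) {
      data.frame(network = all_df$network, treat1 = all_df$treat1,
                 treat2 = all_df$treat2, node_size_group = grp(all_df),
                 parameter = pre,
                 posterior_mean = all_df[[paste0(pre, "_mean")]],
                 posterior_sd = all_df[[paste0(pre, "_sd")]],
                 stringsAsFactors = FALSE)
    }))
  write.csv(long1, p1, row.names = FALSE)
  write.csv(data.frame(network = all_df$network, treat1 = all_df$treat1,
                       treat2 = all_df$treat2, node_size_group = grp(all_df),
                       index = all_df$index, if_mean = all_df$if_mean,
                       if_sd = all_df$if_sd, extent = all_df$extent,
                       conclusiveness = all_df$conclusiveness,
                       stringsAsFactors = FALSE),
            p2, row.names = FALSE)
  write.csv(data.frame(network = all_df$network, treat1 = all_df$treat1,
                       treat2 = all_df$treat2, node_size_group = grp(all_df),
                       index = all_df$index, d_di = all_df$d_di,
                       d_id = all_df$d_id,
                       kld_diff = all_df$d_di - all_df$d_id,
                       stringsAsFactors = FALSE),
            p3, row.names = FALSE)
  write.csv(data.frame(network = all_df$network, treat1 = all_df$treat1,
                       treat2 = all_df$treat2, node_size_group = grp(all_df),
                       index = all_df$index, tau_median = all_df$tau_median,
                       tau_band = heterogeneity_band(all_df$tau_median),
                       extent = all_df$extent, stringsAsFactors = FALSE),
            p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
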