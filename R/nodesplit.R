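#' Prior specification for the node-splitting model
#'
#' Vague normal priors are placed on every study baseline log odds and on
#' the basic and direct log odds-ratio parameters; the between-study
#' variance `tau^2` receives a log-normal prior. The default log-normal
#' location/scale (-2.56, 1.74) is an empirical predictive prior suitable
#' for subjective/semi-objective binary outcomes in pharmacological versus
#' placebo comparisons; both parameters should be reconsidered for the
#' outcome and treatment-comparison type at hand, which is why they are
#' configuration rather than constants.
#'
#' @param tau2_location,tau2_scale location and scale of the log-normal
#'   prior on `tau^2` (scale > 0).
#' @param effect_prior_sd standard deviation of the vague normal priors on
#'   baselines, basic parameters and the direct effect (> 0).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(tau2_location = -2.56, tau2_scale = 1.74,
                       effect_prior_sd = 100) {
  stopifnot(is.numeric(tau2_location), length(tau2_location) == 1L,
            is.numeric(tau2_scale), length(tau2_scale) == 1L,
            tau2_scale > 0,
            is.numeric(effect_prior_sd), length(effect_prior_sd) == 1L,
            effect_prior_sd > 0)
  structure(list(tau2_location = tau2_location, tau2_scale = tau2_scale,
                 effect_prior_sd = effect_prior_sd),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "Priors: tau2 ~ logNormal(%.3g, %.3g^2); effects ~ Normal(0, %.3g^2)\n",
    x$tau2_location, x$tau2_scale, x$effect_prior_sd))
  invisible(x)
}

#' MCMC settings for the node-splitting sampler
#'
#' Defaults mirror a standard production run: 3 chains, 20,000 iterations of
#' which the first 2,000 are discarded as burn-in, thinning at 10 (of the
#' post-burn-in iterations, those at positions divisible by the thinning
#' interval are retained). At least two chains are required so the
#' Gelman-Rubin diagnostic is defined.
#'
#' @param n_chains number of chains (>= 2).
#' @param n_iter total iterations per chain (burn-in included).
#' @param burn_in iterations discarded from the start of each chain
#'   (`burn_in < n_iter`).
#' @param thin thinning interval (>= 1).
#' @param seed master integer seed; all chain random-number generators and
#'   per-node seeds are derived from it deterministically.
#' @param n_adapt sampler adaptation iterations run before burn-in.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 20000, burn_in = 2000,
                          thin = 10, seed = 1, n_adapt = 500) {
  stopifnot(n_chains >= 2, thin >= 1, burn_in >= 0, burn_in < n_iter,
            n_adapt >= 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), n_adapt = as.integer(n_adapt)),
            class = "mcmc_settings")
}

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf(
    "MCMC: %d chains x %d iterations (burn-in %d, thin %d), seed %d\n",
    x$n_chains, x$n_iter, x$burn_in, x$thin, x$seed))
  invisible(x)
}

# JAGS code for the one-stage binomial-logit node-splitting model.
# Studies containing both split treatments are arranged with the anchor
# treatment first and the split treatment last; `split[i, k]` flags the
# split contrast, which gets its own mean (the direct parameter) and is
# excluded from the multi-arm conditional-normal adjustment. All remaining
# contrasts follow the standard consistency model with common tau.
nodesplit_model_code <- function() {
  "model {
  for (i in 1:ns) {
    mu[i] ~ dnorm(0, effect.prec)
    delta[i, 1] <- 0
    w[i, 1] <- 0
    for (k in 1:na[i]) {
      r[i, k] ~ dbin(p[i, k], n[i, k])
      logit(p[i, k]) <- mu[i] + delta[i, k]
    }
    for (k in 2:na[i]) {
      delta[i, k] ~ dnorm(md[i, k], precd[i, k])
      md[i, k] <- (1 - split[i, k]) * (d[t[i, k]] - d[t[i, 1]] + sw[i, k]) +
                  split[i, k] * direct
      w[i, k] <- (1 - split[i, k]) * (delta[i, k] - d[t[i, k]] + d[t[i, 1]])
      sw[i, k] <- sum(w[i, 1:(k - 1)]) / (k - 1)
      precd[i, k] <- prec * ((1 - split[i, k]) * 2 * (k - 1) / k +
                             split[i, k])
    }
  }
  d[1] <- 0
  for (j in 2:nt) {
    d[j] ~ dnorm(0, effect.prec)
  }
  direct ~ dnorm(0, effect.prec)
  tau2 ~ dlnorm(tau2.location, tau2.prec)
  tau <- sqrt(tau2)
  prec <- 1 / tau2
  indirect <- d[split2] - d[split1]
  IF <- direct - indirect
}"
}

#' Specify the node-splitting model for one comparison
#'
#' Builds the one-stage Bayesian random-effects node-splitting model on the
#' log odds-ratio scale: binomial likelihood per arm, logit link with a
#' study baseline plus a study-level random contrast, a common between-study
#' standard deviation `tau`, and the conditional-normal construction for the
#' correlated contrasts of multi-arm studies (variance inflation `k/(2(k-1))`
#' for the k-th contrast, inducing the `tau^2/2` covariance of the common-tau
#' assumption). The split comparison's contrast -- in every study containing
#' both of its treatments, re-anchored so the lower-coded treatment is the
#' study baseline and the higher-coded one the last arm -- gets a free
#' `direct` parameter informed only by that direct evidence and is excluded
#' from the multi-arm adjustment; the `indirect` effect is the consistency
#' functional of the basic parameters estimated from everything else, and
#' `IF = direct - indirect` per draw.
#'
#' @param ds an [nma_data] object.
#' @param node one row of [enumerate_split_nodes()] output, or a character
#'   vector of the two treatment labels.
#' @param prior a [prior_spec].
#' @return An object of class `nodesplit_model`: list with the JAGS model
#'   `code`, the prepared `data` list, `monitors`, the `node`, and an
#'   `inits` function of (chain, seed).
#' @export
specify_model <- function(ds, node, prior = prior_spec()) {
  stopifnot(inherits(ds, "nma_data"), inherits(prior, "prior_spec"))
  node <- as_split_pair(ds, node)
  net <- build_network(ds)
  sn <- enumerate_split_nodes(net)
  hit <- which(sn$treat1 == node[1] & sn$treat2 == node[2])
  if (!length(hit)) {
    stop("comparison ", node[2], " vs ", node[1],
         " is not splittable (no independent indirect evidence)",
         call. = FALSE)
  }
  anchor <- sn$anchor[hit[1]]
  free <- setdiff(node, anchor)
  # the sampler works on the free-vs-anchor contrast; when the anchor is the
  # higher-coded treatment the reported (treat2 vs treat1) draws are negated
  flip <- anchor == node[2]

  studies <- split(seq_len(nrow(ds$arms)), ds$arms$study)
  ns <- length(studies)
  na <- lengths(studies)
  t_mat <- matrix(NA_integer_, ns, max(na))
  r_mat <- matrix(NA_real_, ns, max(na))
  n_mat <- matrix(NA_real_, ns, max(na))
  s_mat <- matrix(0, ns, max(na))
  for (i in seq_len(ns)) {
    rows <- studies[[i]]
    tr <- ds$arms$treatment[rows]
    code <- match(tr, ds$treatments)
    ord <- order(code)
    direct_study <- all(node %in% tr)
    if (direct_study) {
      # anchor first, free (split) treatment last
      ord <- order(ifelse(tr == anchor, -1L,
                          ifelse(tr == free, .Machine$integer.max, code)))
    }
    rows <- rows[ord]
    t_mat[i, seq_len(na[i])] <- match(ds$arms$treatment[rows], ds$treatments)
    r_mat[i, seq_len(na[i])] <- ds$arms$events[rows]
    n_mat[i, seq_len(na[i])] <- ds$arms$sample_size[rows]
    if (direct_study) s_mat[i, na[i]] <- 1
  }

  data <- list(ns = ns, nt = length(ds$treatments), na = as.integer(na),
               t = t_mat, r = r_mat, n = n_mat, split = s_mat,
               split1 = match(anchor, ds$treatments),
               split2 = match(free, ds$treatments),
               effect.prec = 1 / prior$effect_prior_sd^2,
               tau2.location = prior$tau2_location,
               tau2.prec = 1 / prior$tau2_scale^2)
  inits <- function(chain, seed) {
    d0 <- rep(0, data$nt); d0[1] <- NA
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) + 17L * as.integer(chain)) %% 2147483629L,
         mu = rep(0, ns), d = d0, direct = 0, tau2 = 0.04)
  }
  structure(list(code = nodesplit_model_code(), data = data,
                 monitors = c("direct", "indirect", "IF", "tau"),
                 node = node, anchor = anchor, flip = flip,
                 treatments = ds$treatments, inits = inits),
            class = "nodesplit_model")
}

as_split_pair <- function(ds, node) {
  if (inherits(node, "split_nodes") || is.data.frame(node)) {
    stopifnot(nrow(node) == 1L)
    node <- c(node$treat1, node$treat2)
  }
  node <- as.character(node)
  stopifnot(length(node) == 2L)
  if (!all(node %in% ds$treatments)) {
    stop("unknown treatment(s): ",
         paste(setdiff(node, ds$treatments), collapse = ", "), call. = FALSE)
  }
  node[order(match(node, ds$treatments))]
}

posterior_summary <- function(draws) {
  # draws: iterations x chains
  pooled <- as.vector(draws)
  qs <- unname(quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE))
  structure(list(mean = mean(pooled), sd = stats::sd(pooled),
                 median = qs[2], q025 = qs[1], q975 = qs[3],
                 rhat = gelman_rubin(draws)),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "mean %.3f, sd %.3f, median %.3f, 95%% CrI [%.3f, %.3f], Rhat %.3f\n",
    x$mean, x$sd, x$median, x$q025, x$q975, x$rhat))
  invisible(x)
}

#' Fit the node-splitting model for one split node
#'
#' Runs the model of [specify_model()] with JAGS, pools the post-burn-in,
#' thinned draws across chains, and returns posterior summaries (mean, sd,
#' median, 2.5%/97.5% quantiles, Gelman-Rubin R-hat) for the direct effect,
#' the indirect effect, the per-draw inconsistency factor
#' `IF = direct - indirect`, and `tau`, together with the Kullback-Leibler
#' triple of the direct and indirect normal approximations. Results are
#' deterministic given the seed in `mcmc`. A maximum R-hat of 1.1 or more
#' across the monitored parameters flags the result as non-converged (with
#' a warning, never silently).
#'
#' @inheritParams specify_model
#' @param mcmc an [mcmc_settings].
#' @param keep_draws retain the thinned posterior draws (as an
#'   iterations x chains matrix per monitor) in the result.
#' @return An object of class `nodesplit_result` with elements `node`
#'   (treat1, treat2, n_direct_studies, single_study), `direct`, `indirect`,
#'   `inconsistency_factor`, `tau` (each a `posterior_summary`), `kld` (a
#'   `kld_triple`), `converged`, `max_rhat`, `n_draws`, and optionally
#'   `draws`.
#' @export
run_node_split <- function(ds, node, prior = prior_spec(),
                           mcmc = mcmc_settings(), keep_draws = FALSE) {
  stopifnot(inherits(mcmc, "mcmc_settings"))
  spec <- specify_model(ds, node, prior)
  inits <- lapply(seq_len(mcmc$n_chains), spec$inits, seed = mcmc$seed)
  jm <- rjags::jags.model(textConnection(spec$code), data = spec$data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  if (mcmc$burn_in > 0) update(jm, mcmc$burn_in, progress.bar = "none")
  samples <- rjags::coda.samples(jm, spec$monitors,
                                 n.iter = mcmc$n_iter - mcmc$burn_in,
                                 thin = mcmc$thin, progress.bar = "none")
  draw_mat <- function(par) {
    vapply(samples, function(ch) as.numeric(ch[, par]),
           numeric(nrow(samples[[1]])))
  }
  draws <- lapply(setNames(spec$monitors, spec$monitors), draw_mat)
  if (spec$flip) {
    for (par in c("direct", "indirect", "IF")) draws[[par]] <- -draws[[par]]
  }
  for (par in spec$monitors) {
    if (anyNA(draws[[par]]) || any(!is.finite(draws[[par]]))) {
      stop("sampler produced non-finite draws for '", par, "'",
           call. = FALSE)
    }
  }
  direct <- posterior_summary(draws$direct)
  indirect <- posterior_summary(draws$indirect)
  if_sum <- posterior_summary(draws$IF)
  tau_sum <- posterior_summary(draws$tau)
  max_rhat <- max(direct$rhat, indirect$rhat, if_sum$rhat, tau_sum$rhat)
  converged <- max_rhat < 1.1
  if (!converged) {
    warning(sprintf("node %s vs %s: max Rhat %.3f >= 1.1 (non-converged)",
                    spec$node[2], spec$node[1], max_rhat), call. = FALSE)
  }

  net <- build_network(ds)
  edge <- net$edges[net$edges$treat1 == spec$node[1] &
                      net$edges$treat2 == spec$node[2], ]
  res <- structure(list(
    node = list(treat1 = spec$node[1], treat2 = spec$node[2],
                n_direct_studies = edge$n_studies[1],
                single_study = edge$n_studies[1] == 1L,
                anchor = spec$anchor),
    direct = direct, indirect = indirect,
    inconsistency_factor = if_sum, tau = tau_sum,
    kld = interpretation_index(direct, indirect),
    converged = converged, max_rhat = max_rhat,
    n_draws = length(as.vector(draws$IF)),
    settings = mcmc),
    class = "nodesplit_result")
  if (keep_draws) res$draws <- draws
  res
}

#' @export
print.nodesplit_result <- function(x, ...) {
  cat(sprintf("Node split: %s vs %s (%d direct stud%s)\n",
              x$node$treat2, x$node$treat1, x$node$n_direct_studies,
              if (x$node$single_study) "y" else "ies"))
  cat("  direct:   "); print(x$direct)
  cat("  indirect: "); print(x$indirect)
  cat("  IF:       "); print(x$inconsistency_factor)
  cat("  tau:      "); print(x$tau)
  cat(sprintf("  KLD: D_DI %.4f, D_ID %.4f, index %.4f | converged: %s\n",
              x$kld$d_di, x$kld$d_id, x$kld$index, x$converged))
  invisible(x)
}

#' Fit the node-splitting model for every split node of a network
#'
#' Enumerates the split nodes and calls [run_node_split()] on each, with
#' per-node seeds derived deterministically from the master seed, so a rerun
#' with the same settings reproduces the results bitwise. The network-level
#' convergence flag is the maximum R-hat across all nodes and monitored
#' parameters being below 1.1.
#'
#' @inheritParams run_node_split
#' @param nodes optional subset of nodes (a `split_nodes` data frame); by
#'   default all splittable comparisons.
#' @return An object of class `nodesplit_set`: list with `results` (one
#'   `nodesplit_result` per node), `max_rhat`, `converged`. Empty (with a
#'   warning) when the network has nothing to split.
#' @export
run_all_nodes <- function(ds, prior = prior_spec(), mcmc = mcmc_settings(),
                          nodes = NULL, keep_draws = FALSE) {
  if (is.null(nodes)) nodes <- enumerate_split_nodes(build_network(ds))
  if (nrow(nodes) == 0L) {
    warning("network has no splittable comparisons", call. = FALSE)
    return(structure(list(results = list(), max_rhat = NA_real_,
                          converged = NA), class = "nodesplit_set"))
  }
  results <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    mcmc_i <- mcmc
    mcmc_i$seed <- as.integer((as.double(mcmc$seed) + 104729 * i) %% 2147483629)
    results[[i]] <- tryCatch(
      run_node_split(ds, nodes[i, , drop = FALSE], prior = prior,
                     mcmc = mcmc_i, keep_draws = keep_draws),
      error = function(e) {
        stop("node ", nodes$treat2[i], " vs ", nodes$treat1[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  max_rhat <- max(vapply(results, function(r) r$max_rhat, numeric(1)))
  structure(list(results = results, max_rhat = max_rhat,
                 converged = max_rhat < 1.1),
            class = "nodesplit_set")
}

#' @export
print.nodesplit_set <- function(x, ...) {
  cat("Node-splitting results:", length(x$results), "split node(s)\n")
  if (length(x$results)) {
    print(as.data.frame(x))
    cat(sprintf("max Rhat %.3f; network converged: %s\n", x$max_rhat,
                x$converged))
  }
  invisible(x)
}

#' @export
as.data.frame.nodesplit_set <- function(x, ...) {
  if (!length(x$results)) {
    return(data.frame(treat1 = character(), treat2 = character()))
  }
  do.call(rbind, lapply(x$results, as.data.frame))
}

#' @export
as.data.frame.nodesplit_result <- function(x, ...) {
  row <- data.frame(
    treat1 = x$node$treat1, treat2 = x$node$treat2,
    n_direct_studies = x$node$n_direct_studies,
    single_study = x$node$single_study,
    stringsAsFactors = FALSE)
  for (par in c("direct", "indirect", "inconsistency_factor", "tau")) {
    s <- x[[par]]
    nm <- if (par == "inconsistency_factor") "if" else par
    row[[paste0(nm, "_mean")]] <- s$mean
    row[[paste0(nm, "_sd")]] <- s$sd
    row[[paste0(nm, "_median")]] <- s$median
    row[[paste0(nm, "_q025")]] <- s$q025
    row[[paste0(nm, "_q975")]] <- s$q975
    row[[paste0(nm, "_rhat")]] <- s$rhat
  }
  row$d_di <- x$kld$d_di
  row$d_id <- x$kld$d_id
  row$index <- x$kld$index
  row$converged <- x$converged
  row
}

#' Export posterior draws for audit
#'
#' Writes the retained draws of a node-splitting result (run with
#' `keep_draws = TRUE`) as a delimited text file, one row per retained
#' iteration with chain and iteration identifiers.
#'
#' @param result a `nodesplit_result` carrying draws.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(result, path) {
  stopifnot(inherits(result, "nodesplit_result"))
  if (is.null(result$draws)) {
    stop("result carries no draws; rerun with keep_draws = TRUE",
         call. = FALSE)
  }
  n <- nrow(result$draws[[1]])
  m <- ncol(result$draws[[1]])
  df <- data.frame(chain = rep(seq_len(m), each = n),
                   iteration = rep(seq_len(n), times = m))
  for (par in names(result$draws)) df[[par]] <- as.vector(result$draws[[par]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
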