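# Fixtures are built in code; event counts are arbitrary moderate-risk values
# unless a test needs something specific.

triangle_ds <- function(per_edge = 2) {
  pairs <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  rows <- list()
  for (p in pairs) {
    for (s in seq_len(per_edge)) {
      rows[[length(rows) + 1L]] <- data.frame(
        study = paste0(p[1], p[2], s), treatment = p,
        events = c(20, 24), sample_size = c(80, 80),
        stringsAsFactors = FALSE)
    }
  }
  nma_data(do.call(rbind, rows))
}

star_ds <- function() {
  nma_data(data.frame(
    study = rep(c("s1", "s2", "s3"), each = 2),
    treatment = c("A", "B", "A", "C", "A", "D"),
    events = rep(c(20, 24), 3), sample_size = rep(80, 6),
    stringsAsFactors = FALSE))
}

# one three-arm A/B/C study plus one independent two-arm A-B study
abc_plus_ab_ds <- function() {
  nma_data(data.frame(
    study = c("t1", "t1", "t1", "t2", "t2"),
    treatment = c("A", "B", "C", "A", "B"),
    events = c(20, 24, 28, 22, 26), sample_size = rep(80, 5),
    stringsAsFactors = FALSE))
}

# line network A-B, B-C where the only A-B study has an extreme arm
line_extreme_ds <- function() {
  nma_data(data.frame(
    study = c("ab1", "ab1", "bc1", "bc1", "bc2", "bc2"),
    treatment = c("A", "B", "B", "C", "B", "C"),
    events = c(90, 40, 30, 35, 28, 33), sample_size = rep(100, 6),
    stringsAsFactors = FALSE))
}

fast_mcmc <- function(seed = 1) {
  mcmc_settings(n_chains = 3, n_iter = 2500, burn_in = 500, thin = 1,
                seed = seed, n_adapt = 300)
}

# Independent oracle: KL(p || q) for normals by numerical quadrature of
# the defining integral, never via the closed form under test.
kld_quadrature <- function(mu_p, var_p, mu_q, var_q) {
  f <- function(x) {
    dnorm(x, mu_p, sqrt(var_p)) *
      (dnorm(x, mu_p, sqrt(var_p), log = TRUE) -
         dnorm(x, mu_q, sqrt(var_q), log = TRUE))
  }
  integrate(f, mu_p - 12 * sqrt(var_p), mu_p + 12 * sqrt(var_p),
            rel.tol = 1e-10, subdivisions = 400L)$value
}

# minimal hand-built objects for classification tests (no MCMC)
fake_summary <- function(mean, sd, q025 = mean - 1.96 * sd,
                         q975 = mean + 1.96 * sd) {
  structure(list(mean = mean, sd = sd, median = mean, q025 = q025,
                 q975 = q975, rhat = 1), class = "posterior_summary")
}

fake_result <- function(index, if_q025, if_q975, single_study = FALSE,
                        tau_median = 0.2) {
  direct <- fake_summary(0, 1)
  indirect <- fake_summary(0, 1)
  kld <- structure(list(d_di = index, d_id = index, index = index),
                   class = "kld_triple")
  if_sum <- fake_summary((if_q025 + if_q975) / 2, 0.2, if_q025, if_q975)
  tau <- fake_summary(tau_median, 0.05)
  tau$median <- tau_median
  structure(list(
    node = list(treat1 = "A", treat2 = "B", n_direct_studies = 2L,
                single_study = single_study, anchor = "A"),
    direct = direct, indirect = indirect, inconsistency_factor = if_sum,
    tau = tau, kld = kld, converged = TRUE, max_rhat = 1, n_draws = 1000),
    class = "nodesplit_result")
}

fake_report <- function(verdict_specs, id = "net") {
  # verdict_specs: data frame with index, q025, q975, single_study
  results <- lapply(seq_len(nrow(verdict_specs)), function(i) {
    fake_result(verdict_specs$index[i], verdict_specs$q025[i],
                verdict_specs$q975[i], verdict_specs$single_study[i])
  })
  verdicts <- lapply(results, classify_node)
  structure(list(
    id = id,
    filter = structure(list(removed_studies = data.frame(study = character(),
                                                         reason = character()),
                            retained = NULL, all_removed = FALSE,
                            connectivity_intact = TRUE,
                            bounds = c(lo = 0.15, hi = 0.85)),
                       class = "filter_report"),
    eligibility = NULL,
    results = structure(list(results = results, max_rhat = 1,
                             converged = TRUE), class = "nodesplit_set"),
    verdicts = verdicts,
    network_verdict = classify_network(verdicts),
    threshold = low_inconsistency_threshold(), converged = TRUE,
    tau_band = "reasonable", status = "analysed"),
    class = "network_report")
}
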