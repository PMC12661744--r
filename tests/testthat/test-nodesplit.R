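test_that("model specification encodes the split structure and sign convention", {
  ds <- triangle_ds(per_edge = 2)
  spec <- specify_model(ds, c("A", "B"))
  expect_equal(spec$node, c("A", "B"))
  expect_equal(spec$data$split1, 1L)  # anchor A
  expect_equal(spec$data$split2, 2L)  # free arm B
  # exactly the two A-B studies carry a split contrast, in their last arm
  split_rows <- which(rowSums(spec$data$split) > 0)
  expect_equal(length(split_rows), 2L)
  for (i in split_rows) {
    expect_equal(spec$data$t[i, 1], 1L)
    expect_equal(spec$data$split[i, spec$data$na[i]], 1)
  }
  # two-arm-only dataset: no multi-arm rows
  expect_true(all(spec$data$na == 2L))

  expect_error(specify_model(star_ds(), c("A", "B")), "not splittable")
  expect_error(specify_model(ds, c("A", "Z")), "unknown")
})

test_that("multi-arm direct studies anchor the split pair and keep other contrasts", {
  ds <- generate_network(preset_scenarios()$multiarm_plus_independent_edge,
                         seed = 2)
  spec <- specify_model(ds, c("A", "B"))
  three_arm <- which(spec$data$na == 3L)
  expect_true(length(three_arm) > 0)
  for (i in three_arm) {
    # anchor A first, free B last, C in between; only the B contrast split
    expect_equal(spec$data$t[i, ], c(1L, 3L, 2L))
    expect_equal(spec$data$split[i, ], c(0, 0, 1))
  }
})

test_that("null data recover zero inconsistency with calibrated uncertainty", {
  ds <- generate_network(preset_scenarios()$consistent_triangle, seed = 42)
  res <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 7))
  expect_s3_class(res, "nodesplit_result")
  mcse <- res$inconsistency_factor$sd / sqrt(res$n_draws / 20)  # crude ESS
  expect_lt(abs(res$inconsistency_factor$mean), 4 * res$inconsistency_factor$sd)
  expect_true(res$inconsistency_factor$q025 <= 0 &&
                res$inconsistency_factor$q975 >= 0)
  expect_true(res$converged)
  # per-draw IF equals direct minus indirect up to Monte-Carlo error
  expect_equal(res$inconsistency_factor$mean,
               res$direct$mean - res$indirect$mean, tolerance = 1e-8)
  # posterior summary invariants
  for (par in c("direct", "indirect", "inconsistency_factor", "tau")) {
    s <- res[[par]]
    expect_true(s$q025 <= s$median && s$median <= s$q975)
    expect_gt(s$sd, 0)
  }
})

test_that("a large planted inconsistency is recovered and flagged", {
  ds <- generate_network(preset_scenarios()$inconsistent, seed = 11)
  res <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 5))
  expect_equal(res$inconsistency_factor$mean, 1.5, tolerance = 0.3)
  expect_gt(res$inconsistency_factor$q025, 0)   # conclusive
  expect_gte(res$kld$index, 0.64)               # material
  v <- classify_node(res)
  expect_equal(v$extent, "material")
  expect_equal(v$conclusiveness, "conclusive")
})

test_that("reruns are bitwise identical and seeds agree within Monte-Carlo error", {
  ds <- generate_network(preset_scenarios()$consistent_triangle, seed = 3)
  a <- run_node_split(ds, c("A", "C"), mcmc = fast_mcmc(seed = 9))
  b <- run_node_split(ds, c("A", "C"), mcmc = fast_mcmc(seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))

  c_ <- run_node_split(ds, c("A", "C"), mcmc = fast_mcmc(seed = 10))
  mcse <- function(r) r$inconsistency_factor$sd / sqrt(r$n_draws / 20)
  expect_lt(abs(a$inconsistency_factor$mean - c_$inconsistency_factor$mean),
            3 * (mcse(a) + mcse(c_)))
})

test_that("relabelling treatments preserves |IF| and the index", {
  ds <- generate_network(preset_scenarios()$consistent_triangle, seed = 21)
  res1 <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 4))

  relabel <- c(A = "Z", B = "B", C = "C")   # A becomes last in the coding
  arms2 <- ds$arms
  arms2$treatment <- unname(relabel[arms2$treatment])
  ds2 <- nma_data(arms2)
  res2 <- run_node_split(ds2, c("B", "Z"), mcmc = fast_mcmc(seed = 4))

  # comparison direction flips (B vs A becomes Z vs B), so IF flips sign
  tol <- 3 * (res1$inconsistency_factor$sd + res2$inconsistency_factor$sd) /
    sqrt(res1$n_draws / 20)
  expect_lt(abs(res1$inconsistency_factor$mean +
                  res2$inconsistency_factor$mean), tol)
  expect_lt(abs(res1$kld$index - res2$kld$index),
            0.1 + 0.2 * res1$kld$index)
})

test_that("posterior means agree with an independent frequentist reference", {
  skip_if_not_installed("metafor")
  ds <- generate_network(
    scenario_spec(geometry = data.frame(design = c("A+B", "A+C", "B+C"),
                                        n_studies = c(8, 8, 8)),
                  true_effects = c(B = 0.3, C = 0.5), tau = 0.1,
                  arm_size_range = c(400L, 600L)),
    seed = 8)
  res <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 2))

  pair_fit <- function(t_ref, t_alt) {
    arms <- ds$arms[grepl(paste0("^", t_ref, "\\+", t_alt), ds$arms$study), ]
    ref <- arms[arms$treatment == t_ref, ]
    alt <- arms[arms$treatment == t_alt, ]
    fit <- metafor::rma(
      measure = "OR", ai = alt$events, n1i = alt$sample_size,
      ci = ref$events, n2i = ref$sample_size, method = "REML")
    c(est = unname(fit$beta[1]), se = unname(fit$se))
  }
  dir_ref <- pair_fit("A", "B")
  ac <- pair_fit("A", "C")
  bc <- pair_fit("B", "C")
  ind_ref <- c(est = unname(ac["est"] - bc["est"]),
               se = unname(sqrt(ac["se"]^2 + bc["se"]^2)))

  expect_lt(abs(res$direct$mean - dir_ref["est"]),
            3 * sqrt(res$direct$sd^2 + dir_ref["se"]^2))
  expect_lt(abs(res$indirect$mean - ind_ref["est"]),
            3 * sqrt(res$indirect$sd^2 + ind_ref["se"]^2))
})

test_that("run_all_nodes derives per-node seeds and aggregates convergence", {
  ds <- generate_network(preset_scenarios()$consistent_triangle, seed = 13)
  set_ <- run_all_nodes(ds, mcmc = fast_mcmc(seed = 6))
  expect_equal(length(set_$results), 3L)
  expect_equal(set_$max_rhat,
               max(vapply(set_$results, function(r) r$max_rhat, numeric(1))))
  df <- as.data.frame(set_)
  expect_equal(nrow(df), 3L)
  expect_true(all(c("direct_mean", "if_q975", "index", "converged") %in%
                    names(df)))

  set2 <- run_all_nodes(ds, mcmc = fast_mcmc(seed = 6))
  expect_identical(as.data.frame(set2), df)

  expect_warning(empty <- run_all_nodes(star_ds(), mcmc = fast_mcmc()),
                 "no splittable")
  expect_equal(length(empty$results), 0L)
})

test_that("posterior draws export for audit and feed the draw-based KLD check", {
  ds <- generate_network(preset_scenarios()$consistent_triangle, seed = 17)
  res <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 3),
                        keep_draws = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(res, path)
  back <- read.csv(path)
  expect_equal(nrow(back), res$n_draws)
  expect_equal(mean(back$IF), res$inconsistency_factor$mean,
               tolerance = 1e-10)

  # normality convention audit: sample-based KLD close to the closed form
  est <- kld_from_draws(as.vector(res$draws$direct),
                        as.vector(res$draws$indirect))
  expect_equal(est, res$kld$d_di, tolerance = 0.15)

  res2 <- run_node_split(ds, c("A", "B"), mcmc = fast_mcmc(seed = 3))
  expect_error(write_draws(res2, path), "keep_draws")
})
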