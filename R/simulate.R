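#' Scenario specification for synthetic networks
#'
#' Describes a connected treatment network and the generating mechanism for
#' arm-level binary data: per-design study counts, true log odds ratios for
#' the basic parameters, a common between-study standard deviation `tau`,
#' optional loop-inconsistency offsets `omega` applied to the direct
#' evidence of chosen comparisons, baseline event risks drawn uniformly
#' within a range, and arm sizes drawn uniformly within an integer range.
#'
#' @param geometry data frame with columns `design` (treatment labels joined
#'   by `"+"`, e.g. `"A+B"` or `"A+B+C"`) and `n_studies`; the implied
#'   network must be connected.
#' @param true_effects named numeric: true log odds ratio of each
#'   non-reference treatment versus the reference (the lexicographically
#'   first treatment); treatments omitted default to 0.
#' @param tau common between-study standard deviation (log-OR scale).
#' @param inconsistency named numeric of omega offsets, names of the form
#'   `"A+B"`: omega is added to the log odds ratio of the later versus the
#'   earlier treatment in every study whose design contains both, shifting
#'   that comparison's direct evidence away from the consistency prediction.
#' @param baseline_risk_range range the baseline-arm event risk is drawn
#'   from; the default (0.3, 0.6) keeps moderate-effect arms inside the
#'   (0.15, 0.85) event-risk filter.
#' @param arm_size_range integer range of per-arm sample sizes.
#' @param seed default seed used by [generate_network()].
#' @param outcome_direction metadata carried into the generated dataset.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(geometry, true_effects = numeric(), tau = 0.1,
                          inconsistency = NULL,
                          baseline_risk_range = c(0.3, 0.6),
                          arm_size_range = c(100L, 300L), seed = 1L,
                          outcome_direction = "beneficial") {
  stopifnot(is.data.frame(geometry),
            all(c("design", "n_studies") %in% names(geometry)),
            all(geometry$n_studies >= 1),
            tau >= 0,
            length(baseline_risk_range) == 2L,
            baseline_risk_range[1] > 0, baseline_risk_range[2] < 1,
            baseline_risk_range[1] < baseline_risk_range[2],
            length(arm_size_range) == 2L, arm_size_range[1] >= 2,
            arm_size_range[1] <= arm_size_range[2])
  design_treats <- strsplit(geometry$design, "+", fixed = TRUE)
  if (any(lengths(design_treats) < 2L)) {
    stop("every design needs >= 2 treatments", call. = FALSE)
  }
  treatments <- sort(unique(unlist(design_treats)))
  em <- do.call(rbind, lapply(design_treats, function(tt) t(utils::combn(tt, 2))))
  g <- igraph::graph_from_data_frame(as.data.frame(em), directed = FALSE,
                                     vertices = data.frame(name = treatments))
  if (igraph::components(g)$no != 1L) {
    stop("geometry does not yield a connected network", call. = FALSE)
  }
  eff <- setNames(rep(0, length(treatments)), treatments)
  if (length(true_effects)) {
    unknown <- setdiff(names(true_effects), treatments)
    if (length(unknown)) stop("true_effects for unknown treatment(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    eff[names(true_effects)] <- true_effects
  }
  if (!is.null(inconsistency) && length(inconsistency)) {
    pairs <- strsplit(names(inconsistency), "+", fixed = TRUE)
    if (any(lengths(pairs) != 2L) ||
          !all(unlist(pairs) %in% treatments)) {
      stop("inconsistency names must be treatment pairs like 'A+B'",
           call. = FALSE)
    }
  }
  structure(list(geometry = geometry, treatments = treatments,
                 true_effects = eff, tau = tau,
                 inconsistency = inconsistency,
                 baseline_risk_range = baseline_risk_range,
                 arm_size_range = as.integer(arm_size_range),
                 seed = as.integer(seed),
                 outcome_direction = outcome_direction),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", sum(x$geometry$n_studies), "studies over",
      nrow(x$geometry), "design(s),", length(x$treatments), "treatments\n")
  cat("  tau =", x$tau,
      if (length(x$inconsistency)) {
        paste0("; omega: ", paste(names(x$inconsistency), "=",
                                  x$inconsistency, collapse = ", "))
      } else "; consistent (omega = 0)", "\n")
  invisible(x)
}

#' Generate an arm-level dataset from a scenario
#'
#' For each study: the baseline risk is drawn uniformly within the scenario
#' range; study-level true contrasts versus the design baseline (the
#' lowest-sorted treatment of the design) are drawn from the common-`tau`
#' random-effects distribution -- independent normals for two-arm studies
#' and the equicorrelated multivariate normal with covariance `tau^2 / 2`
#' (the conditional-normal construction the fitted model assumes) for
#' multi-arm studies -- around consistency means plus any omega offset; arm
#' probabilities follow by inverse logit and events are binomial draws.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param spec a [scenario_spec].
#' @param seed integer seed (defaults to the one in `spec`).
#' @return A validated [nma_data] object. Study labels encode the design and
#'   an index (`"A+B_s01"`).
#' @export
generate_network <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  # The design baseline is the sorted-first treatment, so the later member
  # of a sorted omega pair is never the baseline: adding omega to that
  # member's contrast shifts the pair's log OR by omega in every study whose
  # design contains both members.
  omega_for <- function(trt, design) {
    if (is.null(spec$inconsistency)) return(0)
    total <- 0
    for (nm in names(spec$inconsistency)) {
      pair <- sort(strsplit(nm, "+", fixed = TRUE)[[1]])
      if (all(pair %in% design) && trt == pair[2]) {
        total <- total + spec$inconsistency[[nm]]
      }
    }
    total
  }

  rows <- list()
  for (gi in seq_len(nrow(spec$geometry))) {
    design <- sort(strsplit(spec$geometry$design[gi], "+", fixed = TRUE)[[1]])
    base <- design[1]
    others <- design[-1]
    for (si in seq_len(spec$geometry$n_studies[gi])) {
      study_id <- sprintf("%s_s%02d", paste(design, collapse = "+"), si)
      p_base <- runif(1, spec$baseline_risk_range[1],
                      spec$baseline_risk_range[2])
      means <- vapply(others, function(trt) {
        spec$true_effects[[trt]] - spec$true_effects[[base]] +
          omega_for(trt, design)
      }, numeric(1))
      if (length(others) == 1L) {
        deltas <- rnorm(1, means, spec$tau)
      } else {
        # equicorrelated: delta_k = mean_k + tau (sqrt(.5) z0 + sqrt(.5) z_k)
        z0 <- rnorm(1)
        deltas <- means + spec$tau * (sqrt(0.5) * z0 +
                                        sqrt(0.5) * rnorm(length(others)))
      }
      sizes <- spec$arm_size_range[1] +
        sample.int(spec$arm_size_range[2] - spec$arm_size_range[1] + 1L,
                   length(design), replace = TRUE) - 1L
      probs <- c(p_base, plogis(qlogis(p_base) + deltas))
      events <- rbinom(length(design), sizes, probs)
      rows[[length(rows) + 1L]] <- data.frame(
        study = study_id, treatment = design, events = events,
        sample_size = sizes, stringsAsFactors = FALSE)
    }
  }
  nma_data(do.call(rbind, rows),
           outcome_direction = spec$outcome_direction)
}

#' Built-in simulation scenarios
#'
#' A catalogue of named [scenario_spec]s covering the structures the
#' analysis distinguishes:
#' \describe{
#'   \item{consistent_triangle}{three treatments, 5 two-arm studies per
#'     edge, `tau = 0.1`, no inconsistency -- the null scenario.}
#'   \item{single_study_edge}{as above but exactly one study on the A-B
#'     edge, making A-B a single-study split node.}
#'   \item{multiarm_plus_independent_edge}{a three-arm A/B/C design plus
#'     independent two-arm A-B and B-C evidence, exercising the multi-arm
#'     conditional-normal structure in the indirect part.}
#'   \item{inconsistent}{`omega = 1.5` added to the A-B direct evidence,
#'     10 large studies (800-1200 per arm) per edge, `tau = 0.1` -- a
#'     clear, well-powered inconsistency.}
#'   \item{high_tau_masking}{the same `omega = 1.5` but `tau = 0.7`: the
#'     inflated posterior variances shrink the interpretation index, the
#'     masking phenomenon.}
#' }
#' Every preset passes [check_eligibility()] at the default rules.
#'
#' @return Named list of `scenario_spec` objects.
#' @export
preset_scenarios <- function() {
  tri <- function(n_ab, n_ac, n_bc) {
    data.frame(design = c("A+B", "A+C", "B+C"),
               n_studies = c(n_ab, n_ac, n_bc), stringsAsFactors = FALSE)
  }
  eff <- c(B = 0.2, C = 0.4)
  list(
    consistent_triangle = scenario_spec(
      geometry = tri(5, 5, 5), true_effects = eff, tau = 0.1),
    single_study_edge = scenario_spec(
      geometry = tri(1, 5, 5), true_effects = eff, tau = 0.1),
    multiarm_plus_independent_edge = scenario_spec(
      geometry = data.frame(design = c("A+B+C", "A+B", "B+C"),
                            n_studies = c(2, 3, 3),
                            stringsAsFactors = FALSE),
      true_effects = eff, tau = 0.1),
    inconsistent = scenario_spec(
      geometry = tri(10, 10, 10), true_effects = eff, tau = 0.1,
      inconsistency = c("A+B" = 1.5),
      arm_size_range = c(800L, 1200L)),
    high_tau_masking = scenario_spec(
      geometry = tri(10, 10, 10), true_effects = eff, tau = 0.7,
      inconsistency = c("A+B" = 1.5),
      arm_size_range = c(800L, 1200L)))
}

#' Read or write a scenario specification
#'
#' Scenario files are YAML or JSON with entries mirroring the
#' [scenario_spec()] arguments (`geometry` as a list of
#' `{design, n_studies}` records).
#'
#' @param path scenario file path (`.yaml`/`.yml`/`.json`).
#' @return For `read_scenario()`, a `scenario_spec`; for `write_scenario()`,
#'   `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- read_config(path)
  geometry <- if (is.data.frame(cfg$geometry)) {
    cfg$geometry[, c("design", "n_studies")]
  } else {
    do.call(rbind, lapply(cfg$geometry, function(g) {
      data.frame(design = g$design, n_studies = g$n_studies,
                 stringsAsFactors = FALSE)
    }))
  }
  scenario_spec(
    geometry = geometry,
    true_effects = unlist(cfg$true_effects %||% list()),
    tau = cfg$tau %||% 0.1,
    inconsistency = if (length(cfg$inconsistency)) unlist(cfg$inconsistency),
    baseline_risk_range = unlist(cfg$baseline_risk_range %||% c(0.3, 0.6)),
    arm_size_range = unlist(cfg$arm_size_range %||% c(100L, 300L)),
    seed = cfg$seed %||% 1L,
    outcome_direction = cfg$outcome_direction %||% "beneficial")
}

#' @rdname read_scenario
#' @param spec a [scenario_spec] to serialise.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  out <- list(
    geometry = lapply(seq_len(nrow(spec$geometry)), function(i) {
      list(design = spec$geometry$design[i],
           n_studies = spec$geometry$n_studies[i])
    }),
    true_effects = as.list(spec$true_effects),
    tau = spec$tau,
    inconsistency = if (length(spec$inconsistency)) as.list(spec$inconsistency),
    baseline_risk_range = spec$baseline_risk_range,
    arm_size_range = spec$arm_size_range,
    seed = spec$seed,
    outcome_direction = spec$outcome_direction)
  if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
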