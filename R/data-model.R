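#' Arm-level network meta-analysis dataset
#'
#' Constructs and validates the canonical arm-level data object used by every
#' other function in the package. Each row of `arms` describes one arm of one
#' study: the study label, the treatment administered in that arm, the number
#' of events, and the arm sample size.
#'
#' Validation enforces the arm-level data model: counts within `[0, n]`,
#' positive sample sizes, at least two distinct treatments per study, no
#' duplicated (study, treatment) pair, and at least two distinct treatments
#' overall. Arms are canonicalised (sorted by study then treatment) so that
#' the input row order never affects downstream results.
#'
#' Treatment labels are opaque strings. Internally, treatments are coded as
#' integers `1..T` in lexicographic order with a configurable reference
#' treatment coded 1; all log odds ratios reported by the package are for the
#' higher-coded treatment relative to the lower-coded one, which fixes the
#' sign convention of direct, indirect and inconsistency estimates.
#'
#' @param arms data frame with columns `study`, `treatment`, `events`,
#'   `sample_size` (one row per arm).
#' @param outcome_direction `"beneficial"` or `"harmful"`; metadata only,
#'   carried through to reports.
#' @param reference reference treatment label (coded 1). Defaults to the
#'   lexicographically first treatment.
#' @return An object of class `nma_data`: a list with elements `arms`
#'   (canonicalised data frame), `treatments` (ordered labels, reference
#'   first), `outcome_direction`.
#' @seealso [read_nma_data()], [filter_event_risk()], [build_network()]
#' @export
#' @examples
#' ds <- nma_data(data.frame(
#'   study = c("s1", "s1", "s2", "s2"),
#'   treatment = c("A", "B", "A", "C"),
#'   events = c(12, 15, 10, 19),
#'   sample_size = c(50, 50, 40, 40)))
#' ds
nma_data <- function(arms, outcome_direction = c("beneficial", "harmful"),
                     reference = NULL) {
  outcome_direction <- match.arg(outcome_direction)
  required <- c("study", "treatment", "events", "sample_size")
  if (!is.data.frame(arms) || !all(required %in% names(arms))) {
    stop("`arms` must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  arms <- data.frame(study = as.character(arms$study),
                     treatment = as.character(arms$treatment),
                     events = as.numeric(arms$events),
                     sample_size = as.numeric(arms$sample_size),
                     stringsAsFactors = FALSE)
  validate_arms(arms)

  treatments <- sort(unique(arms$treatment))
  if (!is.null(reference)) {
    if (!reference %in% treatments) {
      stop("reference treatment '", reference, "' not present in the data",
           call. = FALSE)
    }
    treatments <- c(reference, setdiff(treatments, reference))
  }
  arms <- arms[order(arms$study, match(arms$treatment, treatments)), ,
               drop = FALSE]
  rownames(arms) <- NULL
  structure(list(arms = arms, treatments = treatments,
                 outcome_direction = outcome_direction),
            class = "nma_data")
}

validate_arms <- function(arms) {
  if (nrow(arms) == 0L) stop("dataset has no arms", call. = FALSE)
  if (anyNA(arms$events) || anyNA(arms$sample_size)) {
    bad <- unique(arms$study[is.na(arms$events) | is.na(arms$sample_size)])
    stop("non-numeric events/sample_size in study ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(arms$sample_size < 1 | arms$sample_size != round(arms$sample_size))) {
    bad <- unique(arms$study[arms$sample_size < 1 |
                               arms$sample_size != round(arms$sample_size)])
    stop("sample_size must be a positive integer; offending study: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(arms$events < 0 | arms$events > arms$sample_size |
            arms$events != round(arms$events))) {
    bad <- unique(arms$study[arms$events < 0 |
                               arms$events > arms$sample_size |
                               arms$events != round(arms$events)])
    stop("events must be an integer in [0, sample_size]; offending study: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(arms[c("study", "treatment")])
  if (any(dup)) {
    stop("duplicate (study, treatment) pair in study ",
         paste(unique(arms$study[dup]), collapse = ", "), call. = FALSE)
  }
  n_arms <- table(arms$study)
  if (any(n_arms < 2L)) {
    stop("every study must have >= 2 arms; offending study: ",
         paste(names(n_arms)[n_arms < 2L], collapse = ", "), call. = FALSE)
  }
  if (length(unique(arms$treatment)) < 2L) {
    stop("dataset must contain >= 2 distinct treatments", call. = FALSE)
  }
  invisible(arms)
}

#' @export
print.nma_data <- function(x, ...) {
  st <- unique(x$arms$study)
  na <- table(x$arms$study)
  cat("Arm-level NMA dataset:", length(st), "studies,",
      length(x$treatments), "treatments,", nrow(x$arms), "arms\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      "(reference:", paste0(x$treatments[1], ")"), "\n")
  cat("  multi-arm studies:", sum(na >= 3L), "\n")
  cat("  outcome direction:", x$outcome_direction, "\n")
  invisible(x)
}

n_studies <- function(ds) length(unique(ds$arms$study))

treatment_code <- function(ds, labels) match(labels, ds$treatments)

#' Read an arm-level dataset from a delimited long-format file
#'
#' The canonical input is long format: one header row, one data row per study
#' arm. Column names can be remapped through `mapping`, either a named
#' character vector/list (names `study`, `treatment`, `events`,
#' `sample_size`; values the file's column names) or a path to a YAML/JSON
#' configuration file with those entries.
#'
#' @param path path to a CSV (`.csv`) or TSV (`.tsv`/`.txt`) file.
#' @param mapping optional column mapping (see Details).
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @inheritParams nma_data
#' @return A validated [nma_data] object.
#' @export
read_nma_data <- function(path, mapping = NULL, sep = NULL,
                          outcome_direction = c("beneficial", "harmful"),
                          reference = NULL) {
  outcome_direction <- match.arg(outcome_direction)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- tryCatch(
    read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  mapping <- resolve_mapping(mapping)
  missing_cols <- setdiff(unname(unlist(mapping)), names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  arms <- data.frame(study = raw[[mapping$study]],
                     treatment = raw[[mapping$treatment]],
                     events = raw[[mapping$events]],
                     sample_size = raw[[mapping$sample_size]],
                     stringsAsFactors = FALSE)
  bad <- which(is.na(suppressWarnings(as.numeric(arms$events))) |
                 is.na(suppressWarnings(as.numeric(arms$sample_size))))
  if (length(bad)) {
    stop("malformed row(s) ", paste(bad + 1L, collapse = ", "),
         " in '", path, "' (line numbers include the header)", call. = FALSE)
  }
  nma_data(arms, outcome_direction = outcome_direction, reference = reference)
}

resolve_mapping <- function(mapping) {
  default <- list(study = "study", treatment = "treatment",
                  events = "events", sample_size = "sample_size")
  if (is.null(mapping)) return(default)
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- read_config(mapping)
  }
  mapping <- as.list(mapping)
  utils::modifyList(default, mapping[names(mapping) %in% names(default)])
}

#' Read a wide (one-row-per-study) file and normalise it to long format
#'
#' Convenience reader for the common wide layout with columns
#' `study, t1, r1, n1, t2, r2, n2, ...` (treatment label, events, sample size
#' per arm; trailing arms may be empty for two-arm studies). The data are
#' converted to the long arm-level representation immediately.
#'
#' @inheritParams read_nma_data
#' @return A validated [nma_data] object.
#' @export
read_nma_wide <- function(path, sep = NULL,
                          outcome_direction = c("beneficial", "harmful"),
                          reference = NULL) {
  outcome_direction <- match.arg(outcome_direction)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  t_cols <- grep("^t[0-9]+$", names(raw), value = TRUE)
  if (!"study" %in% names(raw) || !length(t_cols)) {
    stop("wide format requires columns study, t1, r1, n1, t2, r2, n2, ...",
         call. = FALSE)
  }
  long <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    rows <- lapply(t_cols, function(tc) {
      k <- sub("^t", "", tc)
      trt <- raw[[tc]][i]
      if (is.na(trt) || trt == "") return(NULL)
      data.frame(study = raw$study[i], treatment = trt,
                 events = raw[[paste0("r", k)]][i],
                 sample_size = raw[[paste0("n", k)]][i],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  nma_data(long, outcome_direction = outcome_direction, reference = reference)
}

#' Write an arm-level dataset to a delimited file
#'
#' @param ds an [nma_data] object.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_nma_data <- function(ds, path) {
  stopifnot(inherits(ds, "nma_data"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(ds$arms, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove studies with extreme event risks
#'
#' Removes every study that has, in at least one arm, an observed event risk
#' (events / sample size) strictly below `lo` or strictly above `hi`. The
#' default bounds 0.15 and 0.85 guard against quasi-separation in the
#' binomial-logit model: arms with very rare or near-universal events carry
#' little likelihood information about the log odds and can derail the
#' sampler. Comparisons are strict, so arms at exactly `lo` or `hi` are
#' retained.
#'
#' @param ds an [nma_data] object.
#' @param lo,hi lower/upper event-risk bounds, `0 <= lo < hi <= 1`.
#' @return An object of class `filter_report`: list with `removed_studies`
#'   (data frame of study label and reason), `retained` (filtered
#'   [nma_data], or `NULL` when nothing survives), `all_removed` flag, and
#'   `connectivity_intact` (is the retained treatment network connected?).
#' @export
filter_event_risk <- function(ds, lo = 0.15, hi = 0.85) {
  stopifnot(inherits(ds, "nma_data"))
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop("require 0 <= lo < hi <= 1", call. = FALSE)
  }
  risk <- ds$arms$events / ds$arms$sample_size
  flag <- risk < lo | risk > hi
  bad_studies <- sort(unique(ds$arms$study[flag]))
  removed <- data.frame(
    study = bad_studies,
    reason = vapply(bad_studies, function(s) {
      r <- risk[ds$arms$study == s]
      if (any(r < lo) && any(r > hi)) {
        sprintf("event risk below %g and above %g", lo, hi)
      } else if (any(r < lo)) {
        sprintf("event risk below %g in at least one arm", lo)
      } else sprintf("event risk above %g in at least one arm", hi)
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(removed) <- NULL

  keep <- !(ds$arms$study %in% bad_studies)
  all_removed <- !any(keep)
  retained <- NULL
  connectivity_intact <- FALSE
  if (!all_removed) {
    kept_arms <- ds$arms[keep, , drop = FALSE]
    if (length(unique(kept_arms$treatment)) >= 2L) {
      retained <- nma_data(kept_arms, outcome_direction = ds$outcome_direction,
                           reference = intersect(ds$treatments,
                                                 kept_arms$treatment)[1])
      # intact = the retained evidence still connects every ORIGINAL
      # treatment; a treatment lost entirely compromises connectivity too
      ret_net <- build_network(retained)
      g <- igraph::graph_from_data_frame(
        ret_net$edges[, c("treat1", "treat2")], directed = FALSE,
        vertices = data.frame(name = ds$treatments))
      connectivity_intact <- igraph::components(g)$no == 1L
    } else {
      all_removed <- TRUE   # a single surviving treatment is no network
      removed <- rbind(removed, data.frame(
        study = unique(kept_arms$study),
        reason = "fewer than 2 treatments remained after filtering",
        stringsAsFactors = FALSE))
    }
  }
  structure(list(removed_studies = removed, retained = retained,
                 all_removed = all_removed,
                 connectivity_intact = connectivity_intact,
                 bounds = c(lo = lo, hi = hi)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Event-risk filter (", x$bounds["lo"], ", ", x$bounds["hi"], "):\n",
      sep = "")
  cat("  removed studies:", nrow(x$removed_studies), "\n")
  if (nrow(x$removed_studies)) {
    for (i in seq_len(nrow(x$removed_studies))) {
      cat("    -", x$removed_studies$study[i], "--",
          x$removed_studies$reason[i], "\n")
    }
  }
  if (x$all_removed) {
    cat("  network excluded: no analysable studies remain\n")
  } else {
    cat("  retained studies:", n_studies(x$retained), "\n")
    cat("  connectivity intact:", x$connectivity_intact, "\n")
  }
  invisible(x)
}

#' Check network eligibility for node-splitting analysis
#'
#' Evaluates, criterion by criterion, whether a network supports a local
#' inconsistency analysis: a minimum number of treatments, at least as many
#' studies as treatments, a connected treatment graph, and at least one
#' closed loop not informed exclusively by the studies of a single multi-arm
#' design (see [has_valid_loop()]).
#'
#' The treatment-count and study-count thresholds are configurable because
#' eligibility conventions differ between applications; the defaults require
#' at least three treatments and at least as many studies as treatments.
#'
#' @param ds an [nma_data] object.
#' @param min_treatments minimum number of distinct treatments.
#' @param min_studies_per_treatment require
#'   `n_studies >= min_studies_per_treatment * n_treatments` (default 1).
#' @param rules optional list overriding the above (entries `min_treatments`,
#'   `min_studies_per_treatment`), e.g. loaded from a config file.
#' @return An object of class `eligibility_report` with one logical per
#'   criterion and `overall_eligible`, their conjunction.
#' @export
check_eligibility <- function(ds, min_treatments = 3,
                              min_studies_per_treatment = 1,
                              rules = NULL) {
  stopifnot(inherits(ds, "nma_data"))
  if (!is.null(rules)) {
    if (!is.null(rules$min_treatments)) min_treatments <- rules$min_treatments
    if (!is.null(rules$min_studies_per_treatment)) {
      min_studies_per_treatment <- rules$min_studies_per_treatment
    }
  }
  net <- build_network(ds)
  nt <- length(ds$treatments)
  ns <- n_studies(ds)
  criteria <- c(
    enough_treatments = nt >= min_treatments,
    enough_studies = ns >= min_studies_per_treatment * nt,
    connected = is_connected(net),
    valid_loop = has_valid_loop(net))
  structure(list(criteria = criteria,
                 overall_eligible = all(criteria),
                 n_treatments = nt, n_studies = ns,
                 thresholds = list(
                   min_treatments = min_treatments,
                   min_studies_per_treatment = min_studies_per_treatment)),
            class = "eligibility_report")
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("Network eligibility (", x$n_studies, " studies, ", x$n_treatments,
      " treatments):\n", sep = "")
  for (nm in names(x$criteria)) {
    cat(sprintf("  %-18s %s\n", nm, if (x$criteria[[nm]]) "pass" else "FAIL"))
  }
  cat("  overall:", if (x$overall_eligible) "eligible" else "NOT eligible",
      "\n")
  invisible(x)
}

#' Write node-splitting results to a delimited table
#'
#' One row per split node with the posterior summaries of the direct effect,
#' indirect effect, inconsistency factor and between-study standard
#' deviation, the Kullback-Leibler triple, and (when classified) the node
#' verdict. The table round-trips through [read_results_table()].
#'
#' @param results a `nodesplit_set` (see [run_all_nodes()]) or the data frame
#'   produced by `as.data.frame()` on one.
#' @param path output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  df <- if (is.data.frame(results)) results else as.data.frame(results)
  if (nrow(df) == 0L) stop("no results to write", call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE)
}

#' Read a YAML or JSON configuration file
#'
#' Dispatches on the file extension: `.yml`/`.yaml` via the yaml package,
#' `.json` via jsonlite.
#'
#' @param path configuration file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.(yml|yaml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format (use .yaml or .json): ", path,
         call. = FALSE)
  }
}

#' Serialise a filter or eligibility report to JSON
#'
#' @param report a `filter_report` or `eligibility_report`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (inherits(report, "filter_report")) {
    out <- list(type = "filter_report",
                bounds = as.list(report$bounds),
                removed_studies = report$removed_studies,
                all_removed = report$all_removed,
                connectivity_intact = report$connectivity_intact,
                n_retained_studies = if (is.null(report$retained)) 0L
                                     else n_studies(report$retained))
  } else if (inherits(report, "eligibility_report")) {
    out <- list(type = "eligibility_report",
                criteria = as.list(report$criteria),
                overall_eligible = report$overall_eligible,
                n_treatments = report$n_treatments,
                n_studies = report$n_studies)
  } else {
    stop("unsupported report type", call. = FALSE)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
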