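#' Build the treatment network of an arm-level dataset
#'
#' Derives the treatment graph: the observed comparisons (edges) with their
#' supporting studies, and the designs (the sorted treatment set of a study)
#' with the studies of each design. A study with `t` arms supports
#' `choose(t, 2)` comparisons and belongs to exactly one design.
#'
#' @param ds an [nma_data] object.
#' @return An object of class `treatment_network`: list with `treatments`
#'   (coding order: reference first), `edges` (data frame `treat1`, `treat2`,
#'   `n_studies`, plus a list column `studies`), `designs` (data frame
#'   `design` -- labels joined by `"+"` -- and list column `studies`), and
#'   `study_treatments` (named list: study -> treatment labels).
#' @export
build_network <- function(ds) {
  stopifnot(inherits(ds, "nma_data"))
  studies <- split(ds$arms$treatment, ds$arms$study)
  studies <- lapply(studies, function(tr) {
    tr[order(match(tr, ds$treatments))]
  })

  design_key <- vapply(studies, paste, character(1), collapse = "+")
  designs <- data.frame(design = sort(unique(design_key)),
                        stringsAsFactors = FALSE)
  designs$studies <- lapply(designs$design,
                            function(d) sort(names(design_key)[design_key == d]))
  designs$n_studies <- lengths(designs$studies)

  edge_rows <- list()
  for (s in names(studies)) {
    tr <- studies[[s]]
    idx <- match(tr, ds$treatments)
    cmb <- utils::combn(order(idx), 2)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(tr[cmb[1, j]], tr[cmb[2, j]], sep = "\r")
      edge_rows[[key]] <- c(edge_rows[[key]], s)
    }
  }
  keys <- names(edge_rows)
  t1 <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, character(1), 1)
  t2 <- vapply(strsplit(keys, "\r", fixed = TRUE), `[`, character(1), 2)
  ord <- order(match(t1, ds$treatments), match(t2, ds$treatments))
  edges <- data.frame(treat1 = t1[ord], treat2 = t2[ord],
                      stringsAsFactors = FALSE)
  edges$studies <- lapply(edge_rows[ord], sort)
  edges$n_studies <- lengths(edges$studies)

  structure(list(treatments = ds$treatments, edges = edges,
                 designs = designs, study_treatments = studies),
            class = "treatment_network")
}

#' @export
print.treatment_network <- function(x, ...) {
  cat("Treatment network:", length(x$treatments), "treatments,",
      nrow(x$edges), "observed comparisons,",
      nrow(x$designs), "designs\n")
  cat("  connected:", is_connected(x),
      "| valid closed loop:", has_valid_loop(x), "\n")
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s vs %s: %d stud%s\n", x$edges$treat2[i],
                x$edges$treat1[i], x$edges$n_studies[i],
                if (x$edges$n_studies[i] == 1L) "y" else "ies"))
  }
  invisible(x)
}

network_graph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("treat1", "treat2")], directed = FALSE,
    vertices = data.frame(name = net$treatments))
}

#' Is the treatment network connected?
#'
#' @param net a `treatment_network` (from [build_network()]).
#' @return `TRUE` iff the treatment graph has a single connected component.
#' @export
is_connected <- function(net) {
  stopifnot(inherits(net, "treatment_network"))
  if (nrow(net$edges) == 0L) return(length(net$treatments) <= 1L)
  igraph::components(network_graph(net))$no == 1L
}

#' Does the network contain a valid closed loop?
#'
#' A closed loop of comparisons is the structural prerequisite for comparing
#' direct against indirect evidence. A loop is *invalid* when every one of
#' its edges is supported only by the studies of one single multi-arm design
#' containing the whole loop: such a loop reproduces the internal consistency
#' of that design and carries no independent evidence about inconsistency.
#'
#' The test is an evidence degrees-of-freedom count per connected component:
#' each distinct design with `a` arms contributes `a - 1` independent
#' contrasts, and a component with `n` treatments needs `n - 1` contrasts to
#' be spanned. A valid loop exists iff some component has more design-level
#' contrasts than `n - 1`. Repeated studies of the same design estimate the
#' same contrasts and add no loop; a two-arm design alongside a multi-arm
#' design containing the same comparison does (parallel evidence on one
#' edge is a valid loop in the comparison multigraph).
#'
#' @param net a `treatment_network`.
#' @return `TRUE` iff at least one valid closed loop exists.
#' @export
has_valid_loop <- function(net) {
  stopifnot(inherits(net, "treatment_network"))
  if (nrow(net$edges) == 0L) return(FALSE)
  g <- network_graph(net)
  comp <- igraph::components(g)
  membership <- comp$membership
  design_treats <- strsplit(net$designs$design, "+", fixed = TRUE)
  for (cid in seq_len(comp$no)) {
    treats <- names(membership)[membership == cid]
    in_comp <- vapply(design_treats, function(tt) any(tt %in% treats),
                      logical(1))
    df_design <- sum(vapply(design_treats[in_comp], length, integer(1)) - 1L)
    if (df_design > length(treats) - 1L) return(TRUE)
  }
  FALSE
}

#' Enumerate the split nodes of a network
#'
#' A split node is an observed comparison with both direct evidence (at least
#' one study containing both treatments) and *independent* indirect evidence.
#' Independence is assessed with the arm-removal rule: from every study
#' containing both treatments of the comparison, remove the arm of the
#' higher-coded treatment (in direct studies that arm informs only the
#' direct-effect parameter of the split model, so its evidence must not be
#' counted as indirect); the comparison is splittable iff its two treatments
#' remain connected in the residual network. This guarantees that the
#' indirect estimate of the node-splitting model is identified by data rather
#' than by its prior.
#'
#' @param net a `treatment_network`.
#' @return A data frame of class `split_nodes` with columns `treat1`,
#'   `treat2` (comparison in coding order), `n_direct_studies` (studies
#'   containing both treatments), `single_study` (`n_direct_studies == 1`)
#'   and `anchor` (the treatment anchored as study baseline in direct
#'   studies; the other treatment's arm carries the free direct parameter),
#'   ordered deterministically by treatment coding. Zero rows when nothing
#'   can be split.
#' @export
enumerate_split_nodes <- function(net) {
  stopifnot(inherits(net, "treatment_network"))
  out <- net$edges[, c("treat1", "treat2"), drop = FALSE]
  out$n_direct_studies <- net$edges$n_studies
  anchor <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    anchor[i] <- split_anchor(net, out$treat1[i], out$treat2[i])
  }
  out$single_study <- out$n_direct_studies == 1L
  out$anchor <- anchor
  out <- out[!is.na(anchor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("split_nodes", "data.frame")
  out
}

# Identifiability of the indirect estimate: in direct studies the free
# treatment's arm informs only the direct parameter, so sever it and ask
# whether the pair stays connected through the residual evidence. Both
# anchorings are tried (lower-coded anchor first); NA when neither works.
split_anchor <- function(net, t1, t2) {
  if (indirect_identifiable(net, anchor = t1, free = t2)) return(t1)
  if (indirect_identifiable(net, anchor = t2, free = t1)) return(t2)
  NA_character_
}

indirect_identifiable <- function(net, anchor, free) {
  edge_rows <- list()
  for (s in names(net$study_treatments)) {
    tr <- net$study_treatments[[s]]
    if (anchor %in% tr && free %in% tr) tr <- setdiff(tr, free)
    if (length(tr) < 2L) next
    cmb <- utils::combn(tr, 2)
    for (j in seq_len(ncol(cmb))) {
      edge_rows[[length(edge_rows) + 1L]] <- cmb[, j]
    }
  }
  if (!length(edge_rows)) return(FALSE)
  em <- do.call(rbind, edge_rows)
  verts <- unique(c(net$treatments, em))
  g <- igraph::graph_from_data_frame(as.data.frame(em), directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  comp[[anchor]] == comp[[free]]
}

#' @export
print.split_nodes <- function(x, ...) {
  cat("Split nodes:", nrow(x), "\n")
  if (nrow(x)) {
    print.data.frame(x)
  }
  invisible(x)
}

#' Export a network summary as JSON
#'
#' Writes the treatments, observed comparisons (with study counts and
#' supporting studies), designs and split nodes of a network -- the payload
#' behind the command-line `describe` command.
#'
#' @param net a `treatment_network`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "treatment_network"))
  sn <- enumerate_split_nodes(net)
  out <- list(
    treatments = net$treatments,
    reference = net$treatments[1],
    connected = is_connected(net),
    valid_loop = has_valid_loop(net),
    edges = lapply(seq_len(nrow(net$edges)), function(i) {
      list(treat1 = net$edges$treat1[i], treat2 = net$edges$treat2[i],
           n_studies = net$edges$n_studies[i],
           studies = net$edges$studies[[i]])
    }),
    designs = lapply(seq_len(nrow(net$designs)), function(i) {
      list(design = net$designs$design[i],
           studies = net$designs$studies[[i]])
    }),
    split_nodes = lapply(seq_len(nrow(sn)), function(i) {
      list(treat1 = sn$treat1[i], treat2 = sn$treat2[i],
           n_direct_studies = sn$n_direct_studies[i],
           single_study = sn$single_study[i])
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
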