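#' Gelman-Rubin potential scale reduction factor
#'
#' Computes R-hat for one monitored scalar from two or more chains of equal
#' length. The `"classic"` variant is the textbook potential scale reduction
#' factor: with `m` chains of length `n`, between-chain variance
#' `B = n * var(chain means)`, within-chain variance `W = mean(chain
#' variances)`, pooled variance `V = (n-1)/n * W + B/n`, and
#' `Rhat = sqrt(V / W)`. The `"split"` variant first splits each chain in
#' half (detecting within-chain trends) and then applies the same formula to
#' the `2m` half-chains.
#'
#' Chains that are all constant and identical give `Rhat = 1` by convention
#' (the 0/0 limit of a converged degenerate posterior).
#'
#' @param chains a numeric matrix (iterations x chains) or a list of equal
#'   length numeric vectors; at least 2 chains of length >= 10 (>= 20 for
#'   the split variant).
#' @param variant `"classic"` (default) or `"split"`.
#' @return The potential scale reduction factor (positive scalar).
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(cbind(rnorm(100), rnorm(100)))          # ~1
#' gelman_rubin(cbind(rnorm(100), rnorm(100, 10)))      # >> 1.1
gelman_rubin <- function(chains, variant = c("classic", "split")) {
  variant <- match.arg(variant)
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L) stop("chains must have equal lengths",
                                call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains", call. = FALSE)
  if (variant == "split") {
    n <- nrow(chains)
    if (n < 20L) stop("split variant needs chain length >= 20", call. = FALSE)
    h <- floor(n / 2)
    chains <- cbind(chains[seq_len(h), , drop = FALSE],
                    chains[(n - h + 1):n, , drop = FALSE])
  }
  if (nrow(chains) < 10L) stop("need chain length >= 10", call. = FALSE)
  n <- nrow(chains)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(means)
  if (W <= .Machine$double.eps) {
    return(if (B <= .Machine$double.eps) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}
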