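# Evaluation metrics and diagnostics: composition error, dominant-type
# accuracy, spatial autocorrelation, type co-occurrence, Gelman-Rubin.

#' Average absolute composition error
#'
#' Mean over spots and types of |h_true - h_est|; for T types this lies in
#' \[0, 2/T\] (the maximum is attained by two different one-hot rows).
#'
#' @param h_true,h_est spot x type proportion matrices (rows sum to 1).
#' @return scalar error.
#' @export
proportion_error <- function(h_true, h_est) {
  if (!all(dim(h_true) == dim(h_est)))
    stop("proportion matrices must have the same shape")
  mean(abs(h_true - h_est))
}

#' Fraction of spots with the correct dominant type
#'
#' Compares the argmax of each estimated row with the argmax of the true
#' row; ties are broken towards the lowest type index with a warning.
#'
#' @param h_true,h_est spot x type proportion matrices.
#' @return fraction in \[0, 1\].
#' @export
dominant_type_accuracy <- function(h_true, h_est) {
  if (!all(dim(h_true) == dim(h_est)))
    stop("proportion matrices must have the same shape")
  argmax <- function(m) {
    ties <- apply(m, 1, function(r) sum(r == max(r)) > 1)
    if (any(ties))
      warning(sprintf("%d row(s) with tied maxima; lowest index used",
                      sum(ties)))
    apply(m, 1, which.max)
  }
  mean(argmax(h_true) == argmax(h_est))
}

#' Symmetric k-nearest-neighbour spot graph
#'
#' Binary adjacency built from spot coordinates: w_ij = 1 when j is among
#' i's k nearest neighbours or vice versa (k = 6 matches the hexagonal
#' packing of standard spot arrays); optionally restricted to distances
#' below `max_dist`.
#'
#' @param coords 2-column matrix (x, y), one row per spot.
#' @param k number of neighbours.
#' @param max_dist optional distance cutoff.
#' @return symmetric 0/1 weight matrix with zero diagonal.
#' @export
spot_graph <- function(coords, k = 6, max_dist = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of spots")
  d <- as.matrix(dist(coords))
  w <- matrix(0, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[2:(k + 1)]
    if (!is.null(max_dist)) nn <- nn[d[i, nn] <= max_dist]
    w[i, nn] <- 1
  }
  w <- pmax(w, t(w))
  diag(w) <- 0
  w
}

#' Moran's I spatial autocorrelation
#'
#' I = (n / sum w) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i
#' (x_i - xbar)^2, in \[-1, 1\]: positive values indicate spatial
#' clustering of similar values, ~0 randomness, negative dispersion.
#' `graph` may be a weight matrix from [spot_graph()] or a coordinate
#' matrix (a k-NN graph is then built). The raw weights enter the formula
#' as given (no row normalization).
#'
#' @param values per-spot numeric vector with nonzero variance.
#' @param graph weight matrix, or spot coordinates.
#' @param k neighbours used when `graph` is a coordinate matrix.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, graph, k = 6) {
  if (sd(values) == 0)
    stop("Moran's I is undefined for a constant vector")
  w <- as.matrix(graph)
  if (ncol(w) == 2 && nrow(w) == length(values) && nrow(w) != 2)
    w <- spot_graph(w, k = k)
  if (!all(dim(w) == length(values)))
    stop("weight matrix does not match the number of spots")
  if (sum(w) <= 0) stop("weight matrix has no positive weights")
  xc <- values - mean(values)
  (length(values) / sum(w)) * sum(w * outer(xc, xc)) / sum(xc^2)
}

#' Pairwise co-occurrence of inferred cell types
#'
#' Pearson correlations of type-proportion columns across spots, with
#' two-sided p-values from the product-moment t statistic. Positive entries
#' mark types that co-occur in the same spots, negative entries mutual
#' exclusion; entries with p > `level` are flagged insignificant.
#'
#' @param h spot x type proportion matrix (or a fitted `spotmix` object).
#' @param level significance level (default 0.05).
#' @return list with matrices `r`, `p_value` and logical `significant`.
#' @export
cooccurrence <- function(h, level = 0.05) {
  if (inherits(h, "spotmix")) h <- h$proportions
  n <- nrow(h)
  r <- cor(h)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  list(r = r, p_value = p, significant = p <= level)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes R-hat for a scalar quantity from two or more chains of equal
#' length: sqrt of (the pooled posterior variance estimate) / (the mean
#' within-chain variance). Values near 1 indicate the chains agree; > 1.1
#' is conventionally taken as non-convergence.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  m <- length(chains)
  if (m < 2) stop("need at least two chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 2) stop("chains too short")
  means <- vapply(chains, mean, 0)
  w <- mean(vapply(chains, var, 0))
  b <- n * var(means)
  v_hat <- (n - 1) / n * w + b / n
  sqrt(v_hat / w)
}

#' Convergence diagnostics for a fitted model
#'
#' R-hat for the base expression and for the proportion traces of a sample
#' of spot/type pairs, computed across the fit's chains.
#'
#' @param object a fitted `spotmix` object with at least two chains.
#' @param n_entries number of spot x type proportion traces to check.
#' @param seed seed for the entry sample.
#' @return data.frame with columns `quantity` and `rhat`.
#' @export
spotmix_diagnostics <- function(object, n_entries = 10, seed = 1) {
  if (object$control$n_chains < 2)
    stop("diagnostics require at least two chains")
  set.seed(seed)
  ch <- object$chains
  out <- data.frame(quantity = "lambda0",
                    rhat = gelman_rubin(lapply(ch, `[[`, "lambda0")))
  S <- dim(ch[[1]]$H)[2]; T <- dim(ch[[1]]$H)[3]
  idx <- cbind(sample(S, n_entries, replace = TRUE),
               sample(T, n_entries, replace = TRUE))
  for (i in seq_len(n_entries)) {
    traces <- lapply(ch, function(x) x$H[, idx[i, 1], idx[i, 2]])
    out <- rbind(out, data.frame(
      quantity = sprintf("h[%d,%d]", idx[i, 1], idx[i, 2]),
      rhat = gelman_rubin(traces)))
  }
  out
}
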