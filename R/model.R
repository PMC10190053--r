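# Core generative model: deterministic maps and the full-data log-likelihood.
#
# Conventions used throughout the package:
#   * counts C are stored gene x spot (readers transpose on request);
#   * the marker signature B is gene x type, binary, with a final all-zero
#     "dummy" column absorbing cells of unlisted types;
#   * the negative binomial NB(r, p) has mean r * p / (1 - p), i.e. `p` is the
#     over-dispersion ("success") parameter of the model, which corresponds to
#     `prob = 1 - p` in base R's dnbinom()/rnbinom().

#' Validate a spot-level count matrix
#'
#' Checks that `counts` is a non-negative integer-valued matrix in gene x spot
#' orientation with unique, non-missing dimnames, and returns it (with storage
#' mode coerced to double for downstream arithmetic).
#'
#' @param counts numeric matrix, genes in rows, spots in columns.
#' @return the validated matrix.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (genes x spots)")
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("`counts` contains negative entries")
  if (any(counts != floor(counts))) stop("`counts` must be integer-valued")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("spot", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicated spot identifiers")
  storage.mode(counts) <- "double"
  counts
}

#' Validate (and optionally complete) a binary marker signature
#'
#' `B` is a gene x type binary matrix; entry (g, t) is 1 when gene g is a
#' marker for type t. A trailing all-zero dummy column is required so the
#' model can park cells of unknown type; if no all-zero column is present and
#' `add_dummy = TRUE` one is appended (named `"dummy"`) with a message.
#'
#' @param B binary matrix, genes x types.
#' @param add_dummy append an all-zero dummy column when none exists.
#' @return the validated matrix with a `"dummy_index"` attribute.
#' @export
validate_markers <- function(B, add_dummy = TRUE) {
  if (!is.matrix(B) || !is.numeric(B))
    stop("`B` must be a numeric matrix (genes x types)")
  if (anyNA(B) || !all(B %in% c(0, 1)))
    stop("marker matrix entries must be 0 or 1")
  if (is.null(rownames(B)))
    rownames(B) <- paste0("gene", seq_len(nrow(B)))
  if (is.null(colnames(B)))
    colnames(B) <- paste0("type", seq_len(ncol(B)))
  zero_cols <- which(colSums(B) == 0)
  if (length(zero_cols) == 0L) {
    if (!add_dummy)
      stop("marker matrix must contain an all-zero dummy column")
    B <- cbind(B, dummy = 0)
    message("no all-zero type column found; appended a dummy type")
    zero_cols <- ncol(B)
  }
  dummy <- unname(zero_cols[length(zero_cols)])
  real <- setdiff(seq_len(ncol(B)), dummy)
  if (any(colSums(B[, real, drop = FALSE]) == 0))
    stop("every non-dummy type needs at least one marker gene")
  if (any(rowSums(B) == 0))
    stop("every gene must be a marker for at least one type")
  storage.mode(B) <- "double"
  attr(B, "dummy_index") <- dummy
  B
}

#' Normalize abundances into spot compositions
#'
#' Maps unnormalized type abundances theta to proportions h by dividing each
#' row by its sum. Accepts a vector (one spot) or a spot x type matrix.
#'
#' @param theta positive vector or matrix of abundances.
#' @return object of the same shape with rows summing to 1.
#' @export
proportions_from_abundance <- function(theta) {
  if (is.null(dim(theta))) {
    if (any(theta <= 0) || !all(is.finite(theta)))
      stop("abundances must be finite and strictly positive")
    return(theta / sum(theta))
  }
  if (any(theta <= 0) || !all(is.finite(theta)))
    stop("abundances must be finite and strictly positive")
  theta / rowSums(theta)
}

#' Mean expression surface of the model
#'
#' mu[g, s] = sum_t h[s, t] * (lambda0 + B[g, t] * Lambda[g, t]): the expected
#' per-cell expression of gene g in spot s given the spot composition, the
#' shared base level lambda0 and marker over-expressions Lambda.
#'
#' @param H spot x type proportion matrix (rows sum to 1).
#' @param B gene x type binary marker matrix.
#' @param lambda0 positive scalar base expression.
#' @param Lambda gene x type over-expression matrix (used where B is 1).
#' @return gene x spot matrix of means.
#' @export
mean_expression <- function(H, B, lambda0, Lambda) {
  if (!isTRUE(all.equal(rowSums(H), rep(1, nrow(H)), tolerance = 1e-6,
                        check.names = FALSE)))
    stop("rows of H must sum to 1")
  if (lambda0 <= 0) stop("lambda0 must be positive")
  if (!all(dim(B) == dim(Lambda))) stop("B and Lambda dimensions differ")
  if (ncol(H) != ncol(B)) stop("type dimension of H and B differ")
  # mu = lambda0 + (B * Lambda) %*% t(H) since rows of H sum to 1
  lambda0 + (B * Lambda) %*% t(H)
}

#' Negative binomial rate for a spot/gene pair
#'
#' The count of gene g in spot s is NB(r, p) with
#' r = N_s * (1 - p_g) / p_g * mu_gs, so that the mean is N_s * mu_gs: the
#' number of cells in a spot scales its expected expression.
#'
#' @param mu positive mean per-cell expression (scalar or array).
#' @param n_cells positive cell count (recycled against `mu`).
#' @param p over-dispersion parameter in (0, 1).
#' @return the NB rate parameter r.
#' @export
nb_rate <- function(mu, n_cells, p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (any(mu <= 0)) stop("mu must be positive")
  if (any(n_cells <= 0)) stop("cell counts must be positive")
  n_cells * (1 - p) / p * mu
}

#' Negative binomial log pmf in the model's parameterization
#'
#' log P(X = k) for X ~ NB(r, p) with mean r p/(1-p) and variance r p/(1-p)^2.
#' This wraps `dnbinom(k, size = r, prob = 1 - p)`: base R's success
#' probability is the complement of the over-dispersion parameter used here.
#'
#' @param k non-negative integer counts.
#' @param r positive rate parameter.
#' @param p over-dispersion parameter in (0, 1).
#' @return log-probabilities.
#' @export
nb_log_pmf <- function(k, r, p) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (any(k < 0) || any(k != floor(k))) stop("k must be non-negative integers")
  dnbinom(k, size = r, prob = 1 - p, log = TRUE)
}

#' Full-data log-likelihood
#'
#' Sums the NB log pmf over all genes and spots given a model state: spot
#' compositions H (or abundances theta), per-spot cell counts, the shared base
#' expression, marker over-expressions and per-gene dispersion.
#'
#' @param counts gene x spot count matrix.
#' @param B gene x type marker matrix.
#' @param H spot x type proportions (rows sum to 1).
#' @param n_cells per-spot positive cell counts.
#' @param lambda0 base expression level.
#' @param Lambda gene x type over-expression matrix.
#' @param p per-gene dispersion parameters in (0, 1).
#' @return scalar log-likelihood.
#' @export
total_log_likelihood <- function(counts, B, H, n_cells, lambda0, Lambda, p) {
  mu <- mean_expression(H, B, lambda0, Lambda)
  r <- sweep(sweep(mu, 2, n_cells, `*`), 1, (1 - p) / p, `*`)
  ll <- dnbinom(counts, size = r, prob = 1 - p, log = TRUE)
  if (!all(is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite log-likelihood at gene %d, spot %d",
                 bad[1], bad[2]))
  }
  sum(ll)
}

#' Expected number of distinct types per spot
#'
#' Under the Beta-Bernoulli feature-allocation prior with concentration alpha
#' over t_N types, the expected number of present types per spot is
#' D = t_N * alpha / (t_N + alpha). `alpha_for_types()` is the inverse: the
#' concentration giving a desired D (must satisfy D < t_N).
#'
#' @param alpha positive concentration parameter.
#' @param n_types number of types t_N.
#' @return expected number of distinct present types per spot.
#' @export
expected_types_per_spot <- function(alpha, n_types) {
  if (alpha <= 0) stop("alpha must be positive")
  n_types * alpha / (n_types + alpha)
}

#' @rdname expected_types_per_spot
#' @param d desired expected number of present types (0 < d < n_types).
#' @export
alpha_for_types <- function(d, n_types) {
  if (d <= 0 || d >= n_types)
    stop("d must lie strictly between 0 and the number of types")
  d * n_types / (n_types - d)
}
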