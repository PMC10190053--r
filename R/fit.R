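# Model fitting: user-facing spotmix() plus sampler configuration and
# initialization.

#' Sampler configuration
#'
#' Run-length, proposal and adaptation settings for the
#' Metropolis-within-Gibbs sampler. The defaults are the recommended
#' production settings (at least 40,000 burn-in iterations out of 50,000,
#' thinning 10, initial step sizes 0.1 for abundances, 2 for cell counts,
#' 0.05 for the base expression and 0.1 for dispersions, adaptation every
#' 10,000 burn-in iterations towards a 23% acceptance rate). Scale
#' `n_iter`/`burn_in`/`adapt_interval` down together for small problems.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in discarded initial iterations (must be < `n_iter`).
#' @param thinning keep every `thinning`-th post-burn-in draw.
#' @param n_chains number of independent chains (averaged at the end).
#' @param step_theta,step_n,step_lambda0,step_p initial proposal step sizes.
#' @param step_lambda optional per-gene step sizes for the over-expression
#'   updates; by default half of the data-driven initial values.
#' @param adapt_interval iterations between step-size adaptations during
#'   burn-in (0 disables adaptation).
#' @param adapt_eps multiplicative adaptation strength in (0, 1).
#' @param target_acceptance acceptance rate the adaptation aims for.
#' @param dummy_shrinkage hold the dummy type's presence indicator at 0.
#' @param fix_n treat per-spot cell counts as observed (fixed at their
#'   input values) rather than giving them a truncated-normal prior.
#' @param fix_lambda treat marker over-expression values as observed; requires
#'   a `Lambda` matrix passed to [spotmix()].
#' @param normalized_z use fully normalized Gamma densities in the presence
#'   indicator conditional (recommended); `FALSE` drops the normalizing
#'   constants (kernel-only weighting).
#' @return a list of class `"spotmix_control"`.
#' @export
spotmix_control <- function(n_iter = 50000, burn_in = 40000, thinning = 10,
                            n_chains = 1,
                            step_theta = 0.1, step_n = 2,
                            step_lambda0 = 0.05, step_p = 0.1,
                            step_lambda = NULL,
                            adapt_interval = 10000, adapt_eps = 0.1,
                            target_acceptance = 0.23,
                            dummy_shrinkage = TRUE,
                            fix_n = FALSE, fix_lambda = FALSE,
                            normalized_z = TRUE) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thinning < 1) stop("thinning must be >= 1")
  if (adapt_eps <= 0 || adapt_eps >= 1) stop("adapt_eps must be in (0, 1)")
  structure(as.list(environment()), class = "spotmix_control")
}

# Data-driven initial state; Lambda rows start at the mean of the gene's
# non-zero counts (fallback 1 for all-zero genes), abundances at draws from
# the "present" Gamma prior, indicators at 1 (dummy at 0 under shrinkage).
init_state <- function(counts, B, l, hyper, control, Lambda = NULL) {
  G <- nrow(counts); S <- ncol(counts); T <- ncol(B)
  lam_init <- apply(counts, 1, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) 1 else mean(nz)
  })
  if (is.null(Lambda))
    Lambda <- matrix(lam_init, G, T) * (B == 1)
  theta <- matrix(rgamma(S * T, shape = hyper$a, rate = hyper$b), S, T)
  pi <- matrix(rbeta(S * T, hyper$alpha / T, 1), S, T)
  Z <- matrix(1, S, T)
  if (control$dummy_shrinkage) Z[, attr(B, "dummy_index")] <- 0
  list(theta = theta, pi = pi, Z = Z,
       n_cells = pmax(1, round(l)),
       lambda0 = 0.2, p = rep(0.5, G), Lambda = Lambda,
       step_lambda = lam_init / 2)
}

#' Fit the marker-gene deconvolution model
#'
#' Estimates per-spot cell-type proportions from a gene x spot count matrix
#' over marker genes and a binary gene x type marker signature, using an
#' adaptive Metropolis-within-Gibbs sampler for the hierarchical
#' negative-binomial model. Per-spot cell-count estimates (e.g. nuclei counts
#' from an H&E image) enter as the means of truncated-normal priors on the
#' latent cell counts; without them an uninformative prior is used.
#'
#' @param counts gene x spot count matrix (marker genes only); see
#'   [read_counts()] for file input.
#' @param markers gene x type binary marker matrix; a zero dummy column is
#'   appended when absent. Row order need not match `counts`; genes are
#'   matched by name, and marker genes missing from `counts` are dropped
#'   with a warning.
#' @param cell_counts optional per-spot prior cell counts, a named or
#'   unnamed numeric vector of length `ncol(counts)`. `NULL` runs the
#'   unknown-counts mode: a flat prior (`sigma = 1000`) centered at
#'   `default_cells`.
#' @param alpha feature-allocation concentration; controls the expected
#'   number of distinct types per spot, D = t_N * alpha / (t_N + alpha)
#'   (see [alpha_for_types()]). Defaults to `t_N` (D = t_N / 2).
#' @param a,b,a0,b0 Gamma hyperparameters for abundances of present/absent
#'   types; the defaults (10, 1, 0.1, 1) keep present-type abundances well
#'   separated from absent ones.
#' @param sigma standard deviation of the truncated-normal prior on cell
#'   counts (smaller = stronger trust in `cell_counts`).
#' @param default_cells prior center used when `cell_counts` is `NULL`.
#' @param Lambda optional gene x type matrix of known marker over-expression
#'   values (used as initial values; fixed throughout when
#'   `control$fix_lambda` is `TRUE`).
#' @param control a [spotmix_control()] list.
#' @param seed integer master seed; all chains derive their seeds from it,
#'   so a rerun is bit-identical.
#' @return an object of class `"spotmix"`: a list with `proportions` (the
#'   spot x type posterior mean composition, averaged over retained draws
#'   and chains), `chains` (per-chain draws, acceptance rates and final
#'   step sizes), the matched `counts`/`markers`, and the call settings.
#' @seealso [sim_spot_data()] to generate ground-truthed inputs,
#'   [proportion_error()] and [dominant_type_accuracy()] for evaluation.
#' @export
spotmix <- function(counts, markers, cell_counts = NULL,
                    alpha = NULL, a = 10, b = 1, a0 = 0.1, b0 = 1,
                    sigma = 4, default_cells = 15, Lambda = NULL,
                    control = spotmix_control(), seed = 1) {
  counts <- validate_counts(counts)
  markers <- validate_markers(markers)

  # match marker genes against the count matrix by name
  missing <- setdiff(rownames(markers), rownames(counts))
  if (length(missing)) {
    warning(sprintf("%d marker gene(s) absent from counts and dropped: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")))
    markers <- validate_markers(
      markers[setdiff(rownames(markers), missing), , drop = FALSE])
  }
  counts <- counts[rownames(markers), , drop = FALSE]

  T <- ncol(markers); S <- ncol(counts)
  if (is.null(alpha)) alpha <- T
  if (alpha <= 0) stop("alpha must be positive")
  if (a / b <= a0 / b0)
    stop("Gamma(a, b) must dominate Gamma(a0, b0) in location (a/b > a0/b0)")

  if (is.null(cell_counts)) {
    l <- rep(default_cells, S)
    sigma <- 1000
  } else {
    if (!is.null(names(cell_counts))) {
      bad <- setdiff(colnames(counts), names(cell_counts))
      if (length(bad))
        stop("cell_counts missing for spot(s): ",
             paste(head(bad, 5), collapse = ", "))
      cell_counts <- cell_counts[colnames(counts)]
    }
    if (length(cell_counts) != S)
      stop("cell_counts must have one entry per spot")
    if (any(cell_counts <= 0)) stop("cell_counts must be positive")
    l <- as.numeric(cell_counts)
  }
  if (control$fix_lambda && is.null(Lambda))
    stop("fix_lambda requires a Lambda matrix")
  if (!is.null(Lambda) && !all(dim(Lambda) == dim(markers)))
    stop("Lambda must match the marker matrix dimensions")

  hyper <- list(alpha = alpha, a = a, b = b, a0 = a0, b0 = b0,
                sigma = sigma)
  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, control$n_chains)

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    st <- init_state(counts, markers, l, hyper, control, Lambda = Lambda)
    step_lam <- if (is.null(control$step_lambda)) st$step_lambda
                else rep_len(control$step_lambda, nrow(counts))
    res <- .run_chain_cpp(
      counts, markers, l, sigma,
      alpha, a, b, a0, b0,
      as.integer(control$n_iter), as.integer(control$burn_in),
      as.integer(control$thinning),
      control$step_theta, control$step_n, control$step_lambda0,
      control$step_p, step_lam,
      as.integer(control$adapt_interval), control$adapt_eps,
      control$target_acceptance,
      control$dummy_shrinkage, attr(markers, "dummy_index") - 1L,
      control$fix_n, control$fix_lambda, control$normalized_z,
      st$theta, st$pi, st$Z, as.numeric(st$n_cells),
      st$lambda0, st$p, st$Lambda)
    res$seed <- chain_seeds[ch]
    chains[[ch]] <- res
  }

  # posterior mean composition: average retained draws, then chains
  H_mean <- Reduce(`+`, lapply(chains, function(ch) {
    apply(ch$H, c(2, 3), mean)
  })) / control$n_chains
  H_mean <- H_mean / rowSums(H_mean)
  dimnames(H_mean) <- list(colnames(counts), colnames(markers))

  structure(list(
    proportions = H_mean,
    chains = chains,
    counts = counts,
    markers = markers,
    cell_counts = l,
    hyper = hyper,
    control = control,
    seed = seed,
    call = match.call()
  ), class = "spotmix")
}

# chain-and-draw-averaged posterior means of the scalar/vector parameters
posterior_means <- function(object) {
  ch <- object$chains
  list(
    lambda0 = mean(vapply(ch, function(x) mean(x$lambda0), 0)),
    n_cells = Reduce(`+`, lapply(ch, function(x) colMeans(x$n_cells))) /
      length(ch),
    p = Reduce(`+`, lapply(ch, function(x) colMeans(x$p))) / length(ch),
    Lambda = Reduce(`+`, lapply(ch, function(x) apply(x$Lambda, c(2, 3),
                                                      mean))) / length(ch)
  )
}
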