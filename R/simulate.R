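# Ground-truthed synthetic data: marker signatures with configurable
# overlap, latent truth from the generative prior, NB counts, and noisy /
# unknown cell-count regimes.

#' Simulate a block marker signature with optional overlap
#'
#' Builds a gene x type binary matrix over `sum(markers_per_type)` genes
#' (default 149 split 15/31/35/23/17/33/0, the last type being the zero
#' dummy). `overlap = "slight"` additionally marks 9 genes of type 2 as
#' markers of type 3 and 10 genes of type 3 as markers of type 4;
#' `"high"` further shares 17 genes of type 5 with type 4. The total gene
#' count is unchanged by overlap; which genes are shared is random.
#'
#' @param markers_per_type marker tally per type (last entry 0 = dummy).
#' @param overlap `"none"`, `"slight"` or `"high"`.
#' @return binary marker matrix with a `"dummy_index"` attribute.
#' @export
sim_markers <- function(markers_per_type = c(15, 31, 35, 23, 17, 33, 0),
                        overlap = c("none", "slight", "high")) {
  overlap <- match.arg(overlap)
  T <- length(markers_per_type)
  if (markers_per_type[T] != 0)
    stop("the last (dummy) type must have zero markers")
  G <- sum(markers_per_type)
  B <- matrix(0, G, T,
              dimnames = list(paste0("gene", seq_len(G)),
                              c(paste0("type", seq_len(T - 1)), "dummy")))
  blocks <- split(seq_len(G), rep(seq_len(T), markers_per_type))
  for (t in seq_len(T - 1)) B[blocks[[as.character(t)]], t] <- 1
  share <- function(from, to, n) {
    idx <- sample(blocks[[as.character(from)]], n)
    B[idx, to] <<- 1
  }
  if (overlap %in% c("slight", "high")) {
    share(2, 3, 9)
    share(3, 4, 10)
  }
  if (overlap == "high") share(5, 4, 17)
  attr(B, "dummy_index") <- T
  B
}

#' Simulate a ground-truthed spot dataset from the generative model
#'
#' Draws the latent truth from the model's prior (presence probabilities
#' Beta(alpha/t_N, 1), indicators Bernoulli, abundances Gamma(a, b) or
#' Gamma(a0, b0), dispersions Uniform(0, 1), integer cell counts with mean
#' `mean_cells`) and then samples NB counts for every gene and spot. The
#' `density` presets set alpha to 2 t_N (dense mixing, about five distinct
#' types per spot at t_N = 7) or 0.45 t_N (sparse, about two).
#'
#' @param n_spots number of spots (800 in the reference simulation).
#' @param density `"dense"` or `"sparse"` mixing preset (ignored when
#'   `alpha` is given).
#' @param overlap marker-sharing regime passed to [sim_markers()].
#' @param markers_per_type marker tally per type (last entry dummy = 0).
#' @param alpha optional explicit feature-allocation concentration.
#' @param lambda0 base expression level.
#' @param a,b,a0,b0 Gamma hyperparameters of present/absent abundances.
#' @param mean_cells mean of the (zero-truncated Poisson) cell counts.
#' @param lambda_sampler function(n) drawing positive marker
#'   over-expression values; default log-normal(meanlog 1, sdlog 1),
#'   emulating resampled cell-type average expressions.
#' @param count_noise observed cell-count regime: `"none"` (observed = true),
#'   `"moderate"` / `"high"` (Gaussian noise N(2, 3) / N(5, 5) randomly added
#'   or subtracted, floored at 1), or `"unknown"` (no observed counts).
#' @param seed optional seed.
#' @return a list of class `"spotmix_sim"`: `counts` (gene x spot),
#'   `markers`, `cell_counts` (observed, `NULL` for `"unknown"`), and
#'   `truth` (H, theta, Z, pi, n_cells, Lambda, p, lambda0, alpha).
#' @export
sim_spot_data <- function(n_spots = 800,
                          density = c("dense", "sparse"),
                          overlap = c("none", "slight", "high"),
                          markers_per_type = c(15, 31, 35, 23, 17, 33, 0),
                          alpha = NULL, lambda0 = 0.2,
                          a = 10, b = 1, a0 = 0.1, b0 = 1,
                          mean_cells = 15,
                          lambda_sampler = function(n) rlnorm(n, 1, 1),
                          count_noise = c("none", "moderate", "high",
                                          "unknown"),
                          seed = NULL) {
  density <- match.arg(density)
  overlap <- match.arg(overlap)
  count_noise <- match.arg(count_noise)
  if (!is.null(seed)) set.seed(seed)
  T <- length(markers_per_type)
  if (is.null(alpha))
    alpha <- if (density == "dense") 2 * T else 0.45 * T

  B <- sim_markers(markers_per_type, overlap)
  G <- nrow(B); S <- n_spots

  pi <- matrix(rbeta(S * T, alpha / T, 1), S, T)
  Z <- matrix(rbinom(S * T, 1, pi), S, T)
  # the dummy type stands for cell types absent from the signature; the
  # synthetic ground truth contains none, so its indicator is held at 0
  # (mirroring the shrinkage assumption used at inference time)
  Z[, attr(B, "dummy_index")] <- 0
  theta <- matrix(rgamma(S * T, shape = ifelse(Z == 1, a, a0), rate = 1),
                  S, T)
  theta <- theta / ifelse(Z == 1, b, b0)
  H <- theta / rowSums(theta)
  n_cells <- rpois(S, mean_cells)
  n_cells[n_cells == 0] <- 1
  p <- runif(G)
  Lambda <- matrix(0, G, T)
  Lambda[B == 1] <- lambda_sampler(sum(B == 1))

  mu <- lambda0 + (B * Lambda) %*% t(H)
  r <- sweep(sweep(mu, 2, n_cells, `*`), 1, (1 - p) / p, `*`)
  counts <- matrix(rnbinom(G * S, size = r, prob = 1 - p), G, S,
                   dimnames = list(rownames(B),
                                   paste0("spot", seq_len(S))))
  dimnames(H) <- list(colnames(counts), colnames(B))

  observed <- apply_count_noise(n_cells, count_noise)

  structure(list(
    counts = counts, markers = B, cell_counts = observed,
    truth = list(H = H, theta = theta, Z = Z, pi = pi,
                 n_cells = n_cells, Lambda = Lambda, p = p,
                 lambda0 = lambda0, alpha = alpha),
    scenario = list(n_spots = S, n_types = T, density = density,
                    overlap = overlap, count_noise = count_noise,
                    mean_cells = mean_cells, seed = seed)
  ), class = "spotmix_sim")
}

#' Corrupt true cell counts into observed prior means
#'
#' `"moderate"` and `"high"` add Gaussian noise (N(2, 3) and N(5, 5)
#' respectively) with a random sign to each true count, round, and floor at
#' 1; `"none"` returns the true counts; `"unknown"` returns `NULL` (no
#' observed counts available).
#'
#' @param n_cells true integer cell counts.
#' @param regime `"none"`, `"moderate"`, `"high"` or `"unknown"`.
#' @return integer vector of observed counts, or `NULL`.
#' @export
apply_count_noise <- function(n_cells,
                              regime = c("none", "moderate", "high",
                                         "unknown")) {
  regime <- match.arg(regime)
  if (regime == "unknown") return(NULL)
  if (regime == "none") return(n_cells)
  par <- switch(regime, moderate = c(2, 3), high = c(5, 5))
  e <- rnorm(length(n_cells), par[1], par[2])
  s <- sample(c(-1, 1), length(n_cells), replace = TRUE)
  pmax(1, round(n_cells + s * e))
}

#' Generate independent simulation replicates
#'
#' Repeats [sim_spot_data()] with per-replicate seeds derived from a master
#' seed; the seeds are recorded in each replicate's `scenario` block so any
#' replicate can be regenerated alone.
#'
#' @param n_replicates number of datasets.
#' @param seed master seed.
#' @param ... passed to [sim_spot_data()].
#' @return list of `spotmix_sim` objects.
#' @export
sim_replicates <- function(n_replicates, seed = 1, ...) {
  if (n_replicates == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  lapply(seq_len(n_replicates), function(i)
    sim_spot_data(..., seed = seeds[i]))
}
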