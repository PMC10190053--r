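# Metropolis-within-Gibbs building blocks, in plain R.
#
# These are the reference implementations of every conditional used by the
# sampler: exact Gibbs draws for the presence prior (pi) and the presence
# indicators (Z), truncated-normal proposal machinery, and the unnormalized
# log-targets of the Metropolis steps. The compiled chain (src/sampler.cpp)
# implements the same formulas; the R versions exist for interactive use and
# as the slow reference in the test suite.

#' Gibbs draw for the presence prior pi
#'
#' The conditional of pi given the presence indicator Z is
#' Beta(alpha / t_N + Z, 2 - Z). Vectorized over `z`.
#'
#' @param z binary presence indicators.
#' @param alpha feature-allocation concentration.
#' @param n_types number of types t_N.
#' @return draws from the conditional Beta.
#' @export
sample_pi <- function(z, alpha, n_types) {
  if (!all(z %in% c(0, 1))) stop("z must be binary")
  if (alpha <= 0 || n_types < 1) stop("invalid alpha or n_types")
  rbeta(length(z), alpha / n_types + z, 2 - z)
}

#' Gibbs draw (and conditional probability) of a presence indicator
#'
#' P(Z = 1 | theta, pi) = A / (A + B) with
#' A = pi * Gamma(theta | a, b), B = (1 - pi) * Gamma(theta | a0, b0).
#' By default the fully normalized Gamma densities are used (the normalizing
#' constants differ between the two branches and do not cancel);
#' `normalized = FALSE` drops them, matching a kernel-only weighting.
#'
#' @param theta positive abundances.
#' @param pi presence prior probabilities in \[0, 1\].
#' @param a,b Gamma shape/rate when the type is present.
#' @param a0,b0 Gamma shape/rate when the type is absent.
#' @param normalized use fully normalized Gamma densities (default).
#' @param prob return P(Z = 1) instead of a Bernoulli draw.
#' @return binary draws, or probabilities when `prob = TRUE`.
#' @export
sample_z <- function(theta, pi, a, b, a0, b0, normalized = TRUE,
                     prob = FALSE) {
  if (any(theta <= 0)) stop("theta must be positive")
  log_a <- log(pi) + dgamma(theta, shape = a, rate = b, log = TRUE)
  log_b <- log1p(-pi) + dgamma(theta, shape = a0, rate = b0, log = TRUE)
  if (!normalized) {
    log_a <- log_a - (a * log(b) - lgamma(a))
    log_b <- log_b - (a0 * log(b0) - lgamma(a0))
  }
  p1 <- 1 / (1 + exp(log_b - log_a))
  p1[pi == 1] <- 1
  p1[pi == 0] <- 0
  if (prob) return(p1)
  as.numeric(runif(length(p1)) < p1)
}

#' Hastings log-ratio for positive truncated-normal proposals
#'
#' The random-walk proposal is a normal centered at the current value and
#' truncated to (0, Inf); the proposal ratio reduces to
#' log Phi(x / sigma) - log Phi(y / sigma) for a move x -> y.
#'
#' @param x current positive value.
#' @param y proposed positive value.
#' @param sigma proposal step size.
#' @return log q(x | y) - log q(y | x).
#' @export
tn_hastings_log_ratio <- function(x, y, sigma) {
  pnorm(x / sigma, log.p = TRUE) - pnorm(y / sigma, log.p = TRUE)
}

# log(Phi(a) - Phi(b)) for a >= b, stable in both tails: below zero the
# lower-tail log-CDFs are subtracted in log space, above zero the
# survival functions are
log_pnorm_diff <- function(a, b) {
  lower <- pnorm(a, log.p = TRUE) +
    log1p(-exp(pnorm(b, log.p = TRUE) - pnorm(a, log.p = TRUE)))
  upper <- pnorm(b, lower.tail = FALSE, log.p = TRUE) +
    log1p(-exp(pnorm(a, lower.tail = FALSE, log.p = TRUE) -
                 pnorm(b, lower.tail = FALSE, log.p = TRUE)))
  ifelse(a <= 0, lower, ifelse(b >= 0, upper, log(pnorm(a) - pnorm(b))))
}

#' Log pmf of the ceiling of a positive truncated normal
#'
#' Y = ceiling(X) with X ~ N(mu, sigma) truncated to (0, Inf) gives the
#' integer proposal used for per-spot cell counts. P(Y = x) =
#' F(x) - F(x - 1) with F(x) = 1 - (1 - Phi((x - mu)/sigma)) / Phi(mu/sigma).
#'
#' @param x positive integers (x <= 0 has probability 0).
#' @param mu center of the underlying truncated normal.
#' @param sigma step size.
#' @return log-probabilities.
#' @export
ceiltn_log_pmf <- function(x, mu, sigma) {
  # P(Y = x) = [Phi((x-mu)/sigma) - Phi((x-1-mu)/sigma)] / Phi(mu/sigma),
  # computed in log space so far-tail probabilities stay finite
  out <- rep(-Inf, length(x))
  ok <- x >= 1 & x == floor(x)
  out[ok] <- log_pnorm_diff((x[ok] - mu) / sigma,
                            (x[ok] - 1 - mu) / sigma) -
    pnorm(mu / sigma, log.p = TRUE)
  out
}

#' Hastings log-ratio for the ceiling-truncated-normal proposal
#'
#' Closed form of log q(x | y) - log q(y | x) for integer moves x -> y:
#' log\{ Phi(x/s)/Phi(y/s) * \[Phi((x-y)/s) - Phi((x-1-y)/s)\] /
#' \[Phi((x-y)/s) - Phi((y-1-x)/s)\] \}. Equals
#' `ceiltn_log_pmf(x, y, s) - ceiltn_log_pmf(y, x, s)`.
#'
#' @param x,y positive integers (current, proposed).
#' @param sigma step size.
#' @return the log Hastings ratio.
#' @export
ceiltn_hastings_log_ratio <- function(x, y, sigma) {
  pnorm(x / sigma, log.p = TRUE) - pnorm(y / sigma, log.p = TRUE) +
    log_pnorm_diff((x - y) / sigma, (x - 1 - y) / sigma) -
    log_pnorm_diff((y - x) / sigma, (y - 1 - x) / sigma)
}

#' Draw from a positive truncated normal
#'
#' Rejection sampling of N(mu, sigma) restricted to (0, Inf); adequate for
#' random-walk steps where sigma is small relative to mu.
#'
#' @param mu center.
#' @param sigma standard deviation.
#' @return one positive draw.
#' @export
rtnorm_pos <- function(mu, sigma) {
  repeat {
    y <- rnorm(1, mu, sigma)
    if (y > 0) return(y)
  }
}

#' One Metropolis-Hastings accept/reject step
#'
#' Proposes from a positive truncated normal centered at `current`
#' (`proposal = "continuous"`) or its ceiling (`proposal = "ceiling"`, for
#' integer-valued variables), and accepts with probability
#' min(1, exp(delta log target + log Hastings ratio)). A proposal with
#' log-target -Inf is rejected, never an error.
#'
#' @param current current value (log_target must be finite there).
#' @param log_target function returning the unnormalized log-target.
#' @param step_size proposal standard deviation.
#' @param proposal "continuous" or "ceiling".
#' @return list with `value` and logical `accepted`.
#' @export
mh_step <- function(current, log_target, step_size,
                    proposal = c("continuous", "ceiling")) {
  proposal <- match.arg(proposal)
  y <- rtnorm_pos(current, step_size)
  if (proposal == "ceiling") {
    y <- ceiling(y)
    lhr <- ceiltn_hastings_log_ratio(current, y, step_size)
  } else {
    lhr <- tn_hastings_log_ratio(current, y, step_size)
  }
  lt_y <- log_target(y)
  if (!is.finite(lt_y)) return(list(value = current, accepted = FALSE))
  log_alpha <- lt_y - log_target(current) + lhr
  if (log(runif(1)) < log_alpha)
    list(value = y, accepted = TRUE)
  else
    list(value = current, accepted = FALSE)
}

#' Multiplicative step-size adaptation
#'
#' During burn-in the sampler nudges each step size towards the target
#' acceptance rate: shrink by (1 - eps) when the observed rate is below the
#' target, grow by (1 + eps) otherwise.
#'
#' @param step current step size(s).
#' @param acc_rate observed acceptance rate(s) since the last adaptation.
#' @param target target acceptance rate (0.23 by default).
#' @param eps adaptation strength in (0, 1).
#' @return updated step size(s).
#' @export
adapt_step_size <- function(step, acc_rate, target = 0.23, eps = 0.1) {
  ifelse(acc_rate < target, (1 - eps) * step, (1 + eps) * step)
}

# ---- unnormalized log-targets of the Metropolis updates --------------------
# Each takes the scalar being updated plus its Markov blanket and returns the
# log of a function proportional to the full conditional. `counts` is always
# gene x spot; single-spot contexts pass the spot's count column and the full
# theta row (changing one abundance changes every proportion in the row).

#' Log-target for one abundance entry theta\[s, t\]
#'
#' Spot-level NB likelihood (the whole count column of the spot, since h is a
#' normalization of the full theta row) plus the Gamma prior selected by the
#' presence indicator.
#'
#' @param theta_st candidate value for the abundance being updated.
#' @param t index of the type being updated within `theta_row`.
#' @param theta_row current abundance row of the spot.
#' @param counts_s count column of the spot (length = genes).
#' @param B,Lambda gene x type marker and over-expression matrices.
#' @param z_st presence indicator of (s, t).
#' @param lambda0 base expression.
#' @param n_s cell count of the spot.
#' @param p per-gene dispersions.
#' @param a,b,a0,b0 Gamma hyperparameters.
#' @return unnormalized log-density.
#' @export
log_target_theta <- function(theta_st, t, theta_row, counts_s, B, Lambda,
                             z_st, lambda0, n_s, p, a, b, a0, b0) {
  if (theta_st <= 0) return(-Inf)
  theta_row[t] <- theta_st
  h <- theta_row / sum(theta_row)
  mu <- drop(lambda0 + (B * Lambda) %*% h)
  ll <- sum(dnbinom(counts_s, size = n_s * (1 - p) / p * mu,
                    prob = 1 - p, log = TRUE))
  prior <- if (z_st == 1) dgamma(theta_st, a, rate = b, log = TRUE)
           else dgamma(theta_st, a0, rate = b0, log = TRUE)
  ll + prior
}

#' Log-target for the cell count of one spot
#'
#' NB likelihood of the spot's counts at cell count `n_s` plus the truncated
#' normal prior with mean `l_s` (the image-based estimate) and spread `sigma`.
#'
#' @param n_s candidate integer cell count (>= 1).
#' @param counts_s count column of the spot.
#' @param mu_s mean-expression column of the spot.
#' @param p per-gene dispersions.
#' @param l_s prior mean cell count.
#' @param sigma prior standard deviation.
#' @return unnormalized log-density.
#' @export
log_target_n <- function(n_s, counts_s, mu_s, p, l_s, sigma) {
  if (n_s < 1 || n_s != floor(n_s)) return(-Inf)
  ll <- sum(dnbinom(counts_s, size = n_s * (1 - p) / p * mu_s,
                    prob = 1 - p, log = TRUE))
  ll + dnorm(n_s, l_s, sigma, log = TRUE) -
    pnorm(l_s / sigma, log.p = TRUE)
}

#' Log-target for the shared base expression lambda0
#'
#' Pure likelihood over all genes and spots (flat improper prior on (0, Inf)).
#'
#' @param lambda0 candidate base expression.
#' @param counts gene x spot counts.
#' @param B,Lambda marker and over-expression matrices.
#' @param H spot x type proportions.
#' @param n_cells per-spot cell counts.
#' @param p per-gene dispersions.
#' @return unnormalized log-density.
#' @export
log_target_lambda0 <- function(lambda0, counts, B, H, n_cells, Lambda, p) {
  if (lambda0 <= 0) return(-Inf)
  total_log_likelihood(counts, B, H, n_cells, lambda0, Lambda, p)
}

#' Log-target for one over-expression entry Lambda\[g, t\]
#'
#' Likelihood of gene g across all spots (flat prior); entries with
#' B\[g, t\] = 0 never enter the likelihood and are not sampled.
#'
#' @param lambda_gt candidate over-expression value.
#' @param t type index being updated.
#' @param counts_g count row of the gene (length = spots).
#' @param B_g,Lambda_g marker/over-expression rows of the gene.
#' @param H spot x type proportions.
#' @param lambda0 base expression.
#' @param n_cells per-spot cell counts.
#' @param p_g dispersion of the gene.
#' @return unnormalized log-density.
#' @export
log_target_lambda_gt <- function(lambda_gt, t, counts_g, B_g, Lambda_g, H,
                                 lambda0, n_cells, p_g) {
  if (lambda_gt < 0) return(-Inf)
  Lambda_g[t] <- lambda_gt
  mu_g <- drop(H %*% (lambda0 + B_g * Lambda_g))
  sum(dnbinom(counts_g, size = n_cells * (1 - p_g) / p_g * mu_g,
              prob = 1 - p_g, log = TRUE))
}

#' Log-target for one dispersion parameter p\[g\]
#'
#' Likelihood of gene g across all spots; support (0, 1), proposals landing
#' at or above 1 have log-target -Inf and are rejected.
#'
#' @param p_g candidate dispersion.
#' @param counts_g count row of the gene.
#' @param mu_g mean-expression row of the gene.
#' @param n_cells per-spot cell counts.
#' @return unnormalized log-density.
#' @export
log_target_p <- function(p_g, counts_g, mu_g, n_cells) {
  if (p_g <= 0 || p_g >= 1) return(-Inf)
  sum(dnbinom(counts_g, size = n_cells * (1 - p_g) / p_g * mu_g,
              prob = 1 - p_g, log = TRUE))
}
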