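# Core model: proportion map, mean expression, NB parameterization,
# full-data log-likelihood, expected-types formula.

test_that("abundance normalization matches the elementwise oracle", {
  expect_equal(proportions_from_abundance(c(10, 10)), c(0.5, 0.5))
  expect_equal(proportions_from_abundance(c(0.1, 9.9)), c(0.01, 0.99))
  set.seed(1)
  for (i in 1:20) {
    th <- rgamma(7, 2, 1)
    expect_equal(proportions_from_abundance(th), th / sum(th),
                 tolerance = 1e-12)
  }
  m <- matrix(rgamma(21, 2), 3, 7)
  expect_equal(rowSums(proportions_from_abundance(m)), rep(1, 3),
               tolerance = 1e-9)
  expect_error(proportions_from_abundance(c(1, 0)), "positive")
  expect_error(proportions_from_abundance(c(-1, 2)), "positive")
})

test_that("mean expression combines base level and marker over-expression", {
  # single type, non-marker gene: mu is the base level
  expect_equal(
    mean_expression(matrix(1, 1, 1), matrix(0, 1, 1), 0.2,
                    matrix(5, 1, 1))[1, 1], 0.2)
  # equal mixture, marker for the first type only
  expect_equal(
    mean_expression(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), 0.2,
                    matrix(c(1.8, 0), 1))[1, 1], 1.1)
  # random 7-type case against a scalar loop
  set.seed(2)
  h <- proportions_from_abundance(rgamma(7, 2))
  Bg <- rbinom(7, 1, 0.4)
  Lg <- rgamma(7, 2)
  got <- mean_expression(matrix(h, 1), matrix(Bg, 1), 0.3,
                         matrix(Lg, 1))[1, 1]
  want <- sum(vapply(1:7, function(t) h[t] * (0.3 + Bg[t] * Lg[t]), 0))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(mean_expression(matrix(c(.7, .2), 1), matrix(0, 1, 2), 0.2,
                               matrix(0, 1, 2)), "sum to 1")
})

test_that("NB rate gives mean n_cells * mu and respects the p domain", {
  expect_equal(nb_rate(10, 1, 0.5), 10)
  r <- nb_rate(1, 15, 0.2)
  expect_equal(r, 60)
  expect_equal(r * 0.2 / 0.8, 15) # implied mean identity
  # p -> 1 shrinks the rate (heavier dispersion at fixed mean)
  expect_lt(nb_rate(10, 1, 0.999), nb_rate(10, 1, 0.5))
  expect_error(nb_rate(10, 1, 1), "p must")
  expect_error(nb_rate(10, 1, 0), "p must")
})

test_that("NB log pmf has the model's mean/variance convention", {
  expect_equal(nb_log_pmf(0, 2, 0.5), log(0.25), tolerance = 1e-12)
  expect_equal(sum(exp(nb_log_pmf(0:1000, 3, 0.3))), 1, tolerance = 1e-9)
  # hand-written log pmf oracle
  k <- c(0, 1, 4, 17); r <- 2.7; p <- 0.35
  want <- lgamma(k + r) - lgamma(r) - lfactorial(k) +
    r * log(1 - p) + k * log(p)
  expect_equal(nb_log_pmf(k, r, p), want, tolerance = 1e-12)
  # Monte-Carlo mean within 3 standard errors of r p / (1 - p)
  set.seed(3)
  r <- 4; p <- 0.6; n <- 1e5
  x <- rnbinom(n, size = r, prob = 1 - p)
  m <- r * p / (1 - p); v <- r * p / (1 - p)^2
  expect_lt(abs(mean(x) - m), 3 * sqrt(v / n))
  expect_lt(abs(var(x) - v) / v, 0.05)
  expect_error(nb_log_pmf(1, -1, 0.5), "positive")
})

test_that("NB additivity in r at shared p (sampling oracle)", {
  set.seed(4)
  n <- 2e5
  x <- rnbinom(n, size = 1.5, prob = 0.7) +
    rnbinom(n, size = 2.5, prob = 0.7)
  y <- rnbinom(n, size = 4, prob = 0.7)
  for (k in 0:8)
    expect_lt(abs(mean(x == k) - mean(y == k)), 0.006)
})

test_that("total log-likelihood: closed form, additivity, loop oracle", {
  # one gene, one spot, zero count: log P = r * log(1 - p)
  C <- matrix(0, 1, 1, dimnames = list("g1", "s1"))
  B <- matrix(0, 1, 1); Lam <- matrix(0, 1, 1)
  H <- matrix(1, 1, 1)
  expect_equal(
    total_log_likelihood(C, B, H, 1, 0.2, Lam, 0.5),
    0.2 * log(0.5), tolerance = 1e-9)

  set.seed(5)
  sim <- small_sim(n_spots = 5)
  tr <- sim$truth
  ll <- total_log_likelihood(sim$counts, sim$markers, tr$H, tr$n_cells,
                             tr$lambda0, tr$Lambda, tr$p)
  # slow double-loop oracle
  mu <- mean_expression(tr$H, sim$markers, tr$lambda0, tr$Lambda)
  acc <- 0
  for (g in seq_len(nrow(sim$counts)))
    for (s in seq_len(ncol(sim$counts))) {
      r <- tr$n_cells[s] * (1 - tr$p[g]) / tr$p[g] * mu[g, s]
      acc <- acc + dnbinom(sim$counts[g, s], size = r, prob = 1 - tr$p[g],
                           log = TRUE)
    }
  expect_equal(ll, acc, tolerance = 1e-10)

  # duplicating a spot doubles its contribution
  C2 <- cbind(sim$counts, dup = sim$counts[, 1])
  H2 <- rbind(tr$H, tr$H[1, ])
  ll2 <- total_log_likelihood(C2, sim$markers, H2,
                              c(tr$n_cells, tr$n_cells[1]),
                              tr$lambda0, tr$Lambda, tr$p)
  ll_s1 <- total_log_likelihood(sim$counts[, 1, drop = FALSE], sim$markers,
                                tr$H[1, , drop = FALSE], tr$n_cells[1],
                                tr$lambda0, tr$Lambda, tr$p)
  expect_equal(ll2, ll + ll_s1, tolerance = 1e-9)

  # invariant under a simultaneous gene permutation
  perm <- sample(nrow(sim$counts))
  ll3 <- total_log_likelihood(sim$counts[perm, ], sim$markers[perm, ],
                              tr$H, tr$n_cells, tr$lambda0,
                              tr$Lambda[perm, ], tr$p[perm])
  expect_equal(ll3, ll, tolerance = 1e-10)
})

test_that("expected types per spot and its inverse", {
  expect_equal(expected_types_per_spot(2 * 7, 7), 14 / 3,
               tolerance = 1e-12) # ~4.67, "circa five"
  expect_equal(round(expected_types_per_spot(0.45 * 7, 7), 2), 2.17)
  for (al in c(0.5, 3.15, 14, 100)) {
    d <- expected_types_per_spot(al, 7)
    expect_equal(alpha_for_types(d, 7), al, tolerance = 1e-12)
  }
  expect_error(alpha_for_types(7, 7), "between 0 and")
})

test_that("validators enforce the data invariants", {
  m <- tiny_counts()
  expect_silent(validate_counts(m))
  bad <- m; bad[1, 1] <- -1
  expect_error(validate_counts(bad), "negative")
  bad <- m; bad[1, 1] <- 1.5
  expect_error(validate_counts(bad), "integer")
  bad <- m; rownames(bad)[2] <- "g1"
  expect_error(validate_counts(bad), "duplicated gene")

  B <- tiny_markers()
  out <- validate_markers(B)
  expect_equal(attr(out, "dummy_index"), 4)
  expect_message(validate_markers(B[, 1:3]), "dummy")
  noB <- B; noB[, 2] <- 0
  expect_error(validate_markers(noB), "non-dummy")
  orphan <- B; orphan[1, ] <- 0
  expect_error(validate_markers(orphan), "at least one type")
})
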