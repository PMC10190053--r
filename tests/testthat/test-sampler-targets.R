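# The unnormalized MH log-targets against a full-joint oracle: differences
# of each conditional target must equal differences of the complete joint
# log-density when only that variable changes.

# full joint log-density of the model (oracle, written independently)
log_joint <- function(counts, B, theta, Z, pi, n_cells, lambda0, Lambda, p,
                      alpha, a, b, a0, b0, l, sigma) {
  H <- theta / rowSums(theta)
  ll <- total_log_likelihood(counts, B, H, n_cells, lambda0, Lambda, p)
  pr_theta <- sum(dgamma(theta, shape = ifelse(Z == 1, a, a0),
                         rate = ifelse(Z == 1, b, b0), log = TRUE))
  pr_pi <- sum(dbeta(pi, alpha / ncol(B), 1, log = TRUE))
  pr_z <- sum(Z * log(pi) + (1 - Z) * log1p(-pi))
  pr_n <- sum(dnorm(n_cells, l, sigma, log = TRUE) -
                pnorm(l / sigma, log.p = TRUE))
  ll + pr_theta + pr_pi + pr_z + pr_n
}

make_instance <- function(seed = 20, n_spots = 4) {
  set.seed(seed)
  sim <- small_sim(n_spots = n_spots, seed = seed)
  tr <- sim$truth
  list(counts = sim$counts, B = sim$markers, theta = tr$theta, Z = tr$Z,
       pi = pmin(pmax(tr$pi, 1e-6), 1 - 1e-6), n_cells = tr$n_cells,
       lambda0 = tr$lambda0, Lambda = tr$Lambda, p = tr$p,
       alpha = tr$alpha, a = 10, b = 1, a0 = 0.1, b0 = 1,
       l = tr$n_cells, sigma = 4)
}

joint_of <- function(st) {
  log_joint(st$counts, st$B, st$theta, st$Z, st$pi, st$n_cells, st$lambda0,
            st$Lambda, st$p, st$alpha, st$a, st$b, st$a0, st$b0, st$l,
            st$sigma)
}

test_that("theta target matches full-joint differences", {
  st <- make_instance()
  set.seed(21)
  for (i in 1:10) {
    s <- sample(nrow(st$theta), 1); t <- sample(ncol(st$theta), 1)
    new <- rgamma(1, 5)
    lt <- function(v)
      log_target_theta(v, t, st$theta[s, ], st$counts[, s], st$B,
                       st$Lambda, st$Z[s, t], st$lambda0, st$n_cells[s],
                       st$p, st$a, st$b, st$a0, st$b0)
    st2 <- st; st2$theta[s, t] <- new
    expect_equal(lt(new) - lt(st$theta[s, t]),
                 joint_of(st2) - joint_of(st), tolerance = 1e-8)
  }
  # zero genes: reduces to the Gamma log-prior
  empty_counts <- matrix(numeric(0), 0, 1)
  emptyB <- matrix(numeric(0), 0, 3)
  v <- log_target_theta(2, 1, c(2, 1, 1), numeric(0), emptyB,
                        emptyB, 1, 0.2, 5, numeric(0), 10, 1, 0.1, 1)
  expect_equal(v, dgamma(2, 10, rate = 1, log = TRUE))
  # scaling a theta row leaves proportions (hence likelihood) unchanged
  th <- c(2, 3, 5)
  expect_equal(proportions_from_abundance(7 * th),
               proportions_from_abundance(th))
})

test_that("cell-count target matches full-joint differences", {
  st <- make_instance(22)
  mu <- mean_expression(st$theta / rowSums(st$theta), st$B, st$lambda0,
                        st$Lambda)
  set.seed(23)
  for (i in 1:8) {
    s <- sample(length(st$n_cells), 1)
    new <- sample(1:30, 1)
    lt <- function(n)
      log_target_n(n, st$counts[, s], mu[, s], st$p, st$l[s], st$sigma)
    st2 <- st; st2$n_cells[s] <- new
    expect_equal(lt(new) - lt(st$n_cells[s]),
                 joint_of(st2) - joint_of(st), tolerance = 1e-8)
  }
  expect_identical(
    log_target_n(0, st$counts[, 1], mu[, 1], st$p, st$l[1], st$sigma),
    -Inf)
  # prior-only case peaks near the prior mean
  lt0 <- vapply(1:40, function(n)
    log_target_n(n, numeric(0), numeric(0), numeric(0), 15, 2), 0)
  expect_equal(which.max(lt0), 15)
})

test_that("lambda0, Lambda and p targets match full-joint differences", {
  st <- make_instance(24)
  H <- st$theta / rowSums(st$theta)
  # lambda0
  for (new in c(0.05, 0.4, 1.3)) {
    st2 <- st; st2$lambda0 <- new
    expect_equal(
      log_target_lambda0(new, st$counts, st$B, H, st$n_cells, st$Lambda,
                         st$p) -
        log_target_lambda0(st$lambda0, st$counts, st$B, H, st$n_cells,
                           st$Lambda, st$p),
      joint_of(st2) - joint_of(st), tolerance = 1e-8)
  }
  # Lambda entries (only where B = 1)
  set.seed(25)
  idx <- which(st$B == 1, arr.ind = TRUE)
  for (i in sample(nrow(idx), 6)) {
    g <- idx[i, 1]; t <- idx[i, 2]
    new <- rgamma(1, 3)
    lt <- function(v)
      log_target_lambda_gt(v, t, st$counts[g, ], st$B[g, ], st$Lambda[g, ],
                           H, st$lambda0, st$n_cells, st$p[g])
    st2 <- st; st2$Lambda[g, t] <- new
    expect_equal(lt(new) - lt(st$Lambda[g, t]),
                 joint_of(st2) - joint_of(st), tolerance = 1e-8)
  }
  # a Lambda entry with B = 0 never enters the likelihood
  g0 <- which(st$B[, 2] == 0)[1]
  st2 <- st; st2$Lambda[g0, 2] <- 99
  expect_equal(joint_of(st2), joint_of(st))
  # p
  set.seed(26)
  mu <- mean_expression(H, st$B, st$lambda0, st$Lambda)
  for (i in 1:5) {
    g <- sample(length(st$p), 1)
    new <- runif(1, 0.05, 0.95)
    lt <- function(v) log_target_p(v, st$counts[g, ], mu[g, ], st$n_cells)
    st2 <- st; st2$p[g] <- new
    expect_equal(lt(new) - lt(st$p[g]), joint_of(st2) - joint_of(st),
                 tolerance = 1e-8)
  }
  # support constraint: proposals at or above 1 are impossible
  expect_identical(log_target_p(1, st$counts[1, ], mu[1, ], st$n_cells),
                   -Inf)
})
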