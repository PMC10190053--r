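# Full-chain behavior: reproducibility, bookkeeping, state invariants,
# adaptation restriction, and parameter recovery on simulated data.

test_that("runs are bit-identical under the same master seed", {
  sim <- small_sim(n_spots = 10)
  f1 <- quick_fit(sim, n_iter = 400, burn_in = 200)
  f2 <- quick_fit(sim, n_iter = 400, burn_in = 200)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$chains[[1]]$lambda0, f2$chains[[1]]$lambda0)
  f3 <- quick_fit(sim, n_iter = 400, burn_in = 200, seed = 6)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("retained draw count and result shapes", {
  sim <- small_sim(n_spots = 8)
  fit <- quick_fit(sim, n_iter = 430, burn_in = 100)
  n_ret <- floor((430 - 100) / 5)
  ch <- fit$chains[[1]]
  expect_equal(dim(ch$H), c(n_ret, 8, 5))
  expect_equal(length(ch$lambda0), n_ret)
  expect_equal(dim(ch$n_cells), c(n_ret, 8))
  expect_equal(rowSums(coef(fit)), setNames(rep(1, 8), rownames(coef(fit))),
               tolerance = 1e-9)
})

test_that("model-state invariants hold after many sweeps", {
  sim <- small_sim(n_spots = 12)
  fit <- quick_fit(sim, n_iter = 100, burn_in = 0)
  st <- fit$chains[[1]]$final_state
  expect_true(all(st$theta > 0))
  expect_true(all(st$H > 0 & st$H < 1))
  expect_equal(rowSums(st$H), rep(1, 12), tolerance = 1e-9)
  expect_true(all(st$Z %in% c(0, 1)))
  expect_true(all(st$Z[, 5] == 0)) # dummy column under shrinkage
  expect_true(all(st$n_cells >= 1 & st$n_cells == floor(st$n_cells)))
  expect_true(all(st$p > 0 & st$p < 1))
  expect_true(st$lambda0 > 0)
  expect_true(all(st$Lambda[sim$markers == 0] == 0))
  acc <- fit$chains[[1]]$acceptance
  expect_true(all(unlist(acc) >= 0 & unlist(acc) <= 1))
})

test_that("frozen proposals leave only the Gibbs variables moving", {
  sim <- small_sim(n_spots = 6)
  frozen <- function(n_iter)
    spotmix(sim$counts, sim$markers, cell_counts = sim$truth$n_cells,
            alpha = sim$truth$alpha, sigma = 4,
            control = spotmix_control(
              n_iter = n_iter, burn_in = 0, thinning = 1,
              step_theta = 1e-14, step_n = 1e-14, step_lambda0 = 1e-14,
              step_p = 1e-14, step_lambda = 1e-14, adapt_interval = 0),
            seed = 3)
  f1 <- frozen(50); f2 <- frozen(120)
  s1 <- f1$chains[[1]]$final_state; s2 <- f2$chains[[1]]$final_state
  # theta, N, lambda0, Lambda, p never move away from their shared init
  expect_equal(s1$theta, s2$theta, tolerance = 1e-12)
  expect_equal(s1$n_cells, s2$n_cells)
  expect_equal(s1$lambda0, s2$lambda0)
  expect_equal(s1$Lambda, s2$Lambda, tolerance = 1e-12)
  expect_equal(s1$p, s2$p, tolerance = 1e-12)
  # while the Gibbs-sampled pi and Z do move
  expect_false(identical(s1$pi, s2$pi))
})

test_that("adaptation only acts during burn-in", {
  sim <- small_sim(n_spots = 10)
  # no burn-in: step sizes must come back untouched
  fit0 <- spotmix(sim$counts, sim$markers,
                  cell_counts = sim$truth$n_cells,
                  alpha = sim$truth$alpha,
                  control = spotmix_control(n_iter = 300, burn_in = 0,
                                            thinning = 1,
                                            adapt_interval = 50),
                  seed = 4)
  expect_equal(fit0$chains[[1]]$step_sizes$theta, 0.1)
  expect_equal(fit0$chains[[1]]$step_sizes$lambda0, 0.05)
  # with burn-in the theta step adapts away from its start value
  fit1 <- quick_fit(sim, n_iter = 900, burn_in = 800)
  expect_false(fit1$chains[[1]]$step_sizes$theta == 0.1)
})

test_that("posterior recovers simulated compositions on a 30-spot dataset", {
  sim <- small_sim(n_spots = 30, seed = 99)
  fit <- spotmix(sim$counts, sim$markers, cell_counts = sim$truth$n_cells,
                 alpha = sim$truth$alpha, sigma = 1,
                 control = spotmix_control(n_iter = 3000, burn_in = 1500,
                                           thinning = 5,
                                           adapt_interval = 200,
                                           adapt_eps = 0.3),
                 seed = 5)
  expect_lt(proportion_error(sim$truth$H, coef(fit)), 0.06)
})

test_that("base expression is recovered when cell counts are observed", {
  sim <- small_sim(n_spots = 60, seed = 100)
  fit <- spotmix(sim$counts, sim$markers, cell_counts = sim$truth$n_cells,
                 alpha = sim$truth$alpha,
                 control = spotmix_control(n_iter = 3000, burn_in = 1500,
                                           thinning = 5, fix_n = TRUE,
                                           adapt_interval = 200,
                                           adapt_eps = 0.3),
                 seed = 6)
  lam0 <- mean(fit$chains[[1]]$lambda0)
  # within +-50% of the simulated truth (0.2)
  expect_gt(lam0, 0.1)
  expect_lt(lam0, 0.3)
})

test_that("marker genes absent from the counts are dropped with a warning", {
  sim <- small_sim(n_spots = 6)
  B <- rbind(sim$markers, ghost = c(1, 0, 0, 0, 0))
  attr(B, "dummy_index") <- 5
  expect_warning(
    fit <- spotmix(sim$counts, B, cell_counts = sim$truth$n_cells,
                   alpha = sim$truth$alpha,
                   control = spotmix_control(n_iter = 60, burn_in = 0,
                                             thinning = 1,
                                             adapt_interval = 0),
                   seed = 2),
    "ghost")
  expect_equal(nrow(fit$markers), nrow(sim$markers))
})
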