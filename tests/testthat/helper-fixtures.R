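# Shared fixture builders. Everything is generated in code at test time.

# a tiny deterministic count matrix with named genes/spots
tiny_counts <- function(genes = 6, spots = 5, seed = 11) {
  set.seed(seed)
  m <- matrix(rpois(genes * spots, 5), genes, spots,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("s", seq_len(spots))))
  storage.mode(m) <- "double"
  m
}

# a small valid marker matrix: 2 genes for type A, 2 for B, rest for C
tiny_markers <- function(genes = 6) {
  B <- matrix(0, genes, 4,
              dimnames = list(paste0("g", seq_len(genes)),
                              c("A", "B", "C", "dummy")))
  B[1:2, 1] <- 1
  B[3:4, 2] <- 1
  B[5:genes, 3] <- 1
  B
}

# small simulated dataset for sampler tests
small_sim <- function(n_spots = 30, density = "dense", seed = 99, ...) {
  sim_spot_data(n_spots = n_spots, density = density,
                markers_per_type = c(6, 8, 6, 5, 0), seed = seed, ...)
}

# quick fit with scaled-down run lengths
quick_fit <- function(sim, n_iter = 1500, burn_in = 800, seed = 5, ...) {
  spotmix(sim$counts, sim$markers, cell_counts = sim$truth$n_cells,
          alpha = sim$truth$alpha, sigma = 4,
          control = spotmix_control(n_iter = n_iter, burn_in = burn_in,
                                    thinning = 5, adapt_interval = 200,
                                    adapt_eps = 0.3, ...),
          seed = seed)
}

# independent pair-count Kendall tau-b (O(n^2) oracle)
taub_oracle <- function(x, y) {
  n <- length(x)
  nc <- nd <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) nc <- nc + 1 else if (s < 0) nd <- nd + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (nc - nd) / sqrt((n0 - n1) * (n0 - n2))
}
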