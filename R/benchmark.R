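# Standard simulation benchmark: the six evaluation conditions (dense and
# sparse mixing; known-counts priors, noisy priors, unknown counts; known
# over-expression; high marker overlap), each run on freshly simulated
# ground-truthed replicates and scored by composition error and dominant-type
# accuracy.

benchmark_conditions <- c("dense_default", "sparse_default",
                          "sparse_known_lambda", "dense_noisy_high",
                          "dense_unknown", "sparse_high_overlap")

#' Run the standard simulation benchmark
#'
#' For each requested condition, simulates `n_replicates` ground-truthed
#' datasets from the generative model, fits the deconvolution model under
#' the condition's input regime, and records the average absolute
#' composition error and the fraction of correctly identified dominant
#' types per replicate. Conditions:
#'
#' * `dense_default` / `sparse_default`: true cell counts supplied as
#'   noise-free priors;
#' * `sparse_known_lambda`: over-expression values fixed to the simulated
#'   truth;
#' * `dense_noisy_high`: cell-count priors corrupted by N(5, 5) noise with
#'   random sign;
#' * `dense_unknown`: no cell-count input (uninformative prior);
#' * `sparse_high_overlap`: marker signature with the high-overlap sharing
#'   pattern.
#'
#' @param conditions subset of the condition names above.
#' @param n_spots spots per simulated dataset.
#' @param n_replicates replicates per condition.
#' @param control sampler settings used for every fit.
#' @param sigma_known cell-count prior standard deviation when the priors
#'   are noise-free (a small value: the counts are trusted).
#' @param sigma_noisy prior standard deviation for the noisy-count regime
#'   (matches the standard deviation of the injected noise).
#' @param seed master seed; per-replicate simulation and fitting seeds are
#'   derived from it.
#' @param verbose print one line per completed fit.
#' @return data.frame with columns `condition`, `replicate`, `error`,
#'   `dominant_accuracy`.
#' @export
deconv_benchmark <- function(conditions = benchmark_conditions,
                             n_spots = 160, n_replicates = 3,
                             control = spotmix_control(
                               n_iter = 4000, burn_in = 2500, thinning = 5,
                               adapt_interval = 250, adapt_eps = 0.3),
                             sigma_known = 1, sigma_noisy = 5,
                             seed = 1, verbose = FALSE) {
  conditions <- match.arg(conditions, benchmark_conditions,
                          several.ok = TRUE)
  set.seed(seed)
  # one simulation seed per replicate index, shared across conditions so
  # dense conditions see the same datasets (paired comparisons), plus
  # independent fit seeds
  sim_seeds <- sample.int(.Machine$integer.max, n_replicates)
  fit_seeds <- sample.int(.Machine$integer.max,
                          n_replicates * length(conditions))
  out <- NULL
  k <- 0
  for (cond in conditions) {
    density <- if (grepl("^dense", cond)) "dense" else "sparse"
    overlap <- if (cond == "sparse_high_overlap") "high" else "none"
    noise <- if (cond == "dense_noisy_high") "high" else "none"
    for (rep in seq_len(n_replicates)) {
      k <- k + 1
      sim <- sim_spot_data(n_spots = n_spots, density = density,
                           overlap = overlap, count_noise = noise,
                           seed = sim_seeds[rep])
      cell_counts <- switch(cond,
        dense_unknown = NULL,
        dense_noisy_high = sim$cell_counts,
        sim$truth$n_cells)
      sigma <- if (cond == "dense_noisy_high") sigma_noisy else sigma_known
      fit <- spotmix(
        sim$counts, sim$markers, cell_counts = cell_counts,
        alpha = sim$truth$alpha, sigma = sigma,
        Lambda = if (cond == "sparse_known_lambda") sim$truth$Lambda,
        control = utils::modifyList(control, list(
          fix_lambda = cond == "sparse_known_lambda")),
        seed = fit_seeds[k])
      res <- data.frame(
        condition = cond, replicate = rep,
        error = proportion_error(sim$truth$H, coef(fit)),
        dominant_accuracy = dominant_type_accuracy(sim$truth$H, coef(fit)))
      if (verbose)
        message(sprintf("%s rep %d: error %.4f, dominant %.3f",
                        cond, rep, res$error, res$dominant_accuracy))
      out <- rbind(out, res)
    }
  }
  out
}
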