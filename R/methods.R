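# S3 methods for fitted spotmix objects.

#' @export
#' @method print spotmix
print.spotmix <- function(x, ...) {
  cat("Marker-gene deconvolution fit (spotmix)\n")
  cat(sprintf("  %d spots, %d marker genes, %d cell types (incl. dummy)\n",
              ncol(x$counts), nrow(x$counts), ncol(x$markers)))
  cat(sprintf("  %d chain(s), %d iterations (burn-in %d, thinning %d)\n",
              x$control$n_chains, x$control$n_iter, x$control$burn_in,
              x$control$thinning))
  acc <- x$chains[[1]]$acceptance
  cat(sprintf(
    "  acceptance: theta %.2f, N %s, lambda0 %.2f, Lambda %s, p %.2f\n",
    acc$theta,
    if (is.na(acc$n_cells)) "fixed" else sprintf("%.2f", acc$n_cells),
    acc$lambda0,
    if (is.na(acc$Lambda)) "fixed" else sprintf("%.2f", acc$Lambda),
    acc$p))
  cat("  mean proportions by type:\n")
  print(round(colMeans(x$proportions), 3))
  invisible(x)
}

#' @export
#' @method summary spotmix
summary.spotmix <- function(object, ...) {
  H <- object$proportions
  pm <- posterior_means(object)
  dom <- apply(H, 1, which.max)
  out <- list(
    types = colnames(object$markers),
    mean_proportions = colMeans(H),
    dominant_counts = table(factor(colnames(object$markers)[dom],
                                   levels = colnames(object$markers))),
    lambda0 = pm$lambda0,
    mean_cells = mean(pm$n_cells),
    acceptance = object$chains[[1]]$acceptance
  )
  class(out) <- "summary.spotmix"
  out
}

#' @export
#' @method print summary.spotmix
print.summary.spotmix <- function(x, ...) {
  cat("Posterior mean composition by type:\n")
  print(round(x$mean_proportions, 3))
  cat("\nSpots dominated by each type:\n")
  print(x$dominant_counts)
  cat(sprintf("\nBase expression lambda0: %.3f;  mean cells per spot: %.1f\n",
              x$lambda0, x$mean_cells))
  invisible(x)
}

#' Extract the posterior mean spot compositions
#' @param object a fitted `spotmix` object.
#' @param ... unused.
#' @return spot x type matrix of proportions (rows sum to 1).
#' @export
coef.spotmix <- function(object, ...) object$proportions

#' Posterior-mean expected counts
#'
#' N_s * mu_gs evaluated at the posterior means of all parameters.
#'
#' @param object a fitted `spotmix` object.
#' @param ... unused.
#' @return gene x spot matrix of expected counts.
#' @export
fitted.spotmix <- function(object, ...) {
  pm <- posterior_means(object)
  mu <- mean_expression(object$proportions, object$markers, pm$lambda0,
                        pm$Lambda)
  sweep(mu, 2, pm$n_cells, `*`)
}

#' Pearson residuals under the fitted NB model
#'
#' (C - mean) / sd with mean N_s mu_gs and variance mean / (1 - p_g),
#' evaluated at posterior means.
#'
#' @param object a fitted `spotmix` object.
#' @param ... unused.
#' @return gene x spot matrix of residuals.
#' @export
residuals.spotmix <- function(object, ...) {
  pm <- posterior_means(object)
  m <- fitted(object)
  (object$counts - m) / sqrt(m / (1 - pm$p))
}

#' Predict spot compositions or dominant types
#'
#' @param object a fitted `spotmix` object.
#' @param type `"proportions"` for the full composition matrix,
#'   `"dominant"` for the highest-proportion type per spot.
#' @param ... unused.
#' @return a matrix of proportions or a named factor of dominant types.
#' @export
predict.spotmix <- function(object, type = c("proportions", "dominant"),
                            ...) {
  type <- match.arg(type)
  if (type == "proportions") return(object$proportions)
  idx <- apply(object$proportions, 1, which.max)
  factor(colnames(object$markers)[idx], levels = colnames(object$markers))
}

#' Simulate count matrices from the fitted model
#'
#' Draws gene x spot NB counts at the posterior means of all parameters
#' (a posterior-predictive check at the plug-in estimate).
#'
#' @param object a fitted `spotmix` object.
#' @param nsim number of replicate matrices.
#' @param seed optional seed.
#' @param ... unused.
#' @return a list of `nsim` gene x spot count matrices.
#' @export
simulate.spotmix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  pm <- posterior_means(object)
  mu <- mean_expression(object$proportions, object$markers, pm$lambda0,
                        pm$Lambda)
  r <- sweep(sweep(mu, 2, pm$n_cells, `*`), 1, (1 - pm$p) / pm$p, `*`)
  lapply(seq_len(nsim), function(i) {
    out <- matrix(rnbinom(length(r), size = r, prob = 1 - pm$p),
                  nrow(r), ncol(r), dimnames = dimnames(object$counts))
    out
  })
}

#' Plot the inferred compositions
#'
#' Stacked barplot of per-spot compositions (spots ordered by dominant
#' type), or a spot x type heatmap.
#'
#' @param x a fitted `spotmix` object.
#' @param which `"bars"` or `"heatmap"`.
#' @param max_spots downsample to at most this many spots in the barplot.
#' @param ... passed to the underlying graphics call.
#' @export
plot.spotmix <- function(x, which = c("bars", "heatmap"), max_spots = 100,
                         ...) {
  which <- match.arg(which)
  H <- x$proportions
  if (which == "heatmap") {
    image(t(H[order(apply(H, 1, which.max)), ]),
          col = hcl.colors(64, "viridis"), axes = FALSE,
          xlab = "cell type", ylab = "spot", ...)
    axis(1, at = seq(0, 1, length.out = ncol(H)), labels = colnames(H),
         las = 2, cex.axis = 0.7)
    return(invisible(x))
  }
  ord <- order(apply(H, 1, which.max), -apply(H, 1, max))
  H <- H[ord, , drop = FALSE]
  if (nrow(H) > max_spots)
    H <- H[round(seq(1, nrow(H), length.out = max_spots)), , drop = FALSE]
  cols <- hcl.colors(ncol(H), "Dark 3")
  barplot(t(H), col = cols, border = NA, space = 0, names.arg = NULL,
          xlab = "spots (ordered by dominant type)",
          ylab = "proportion", ...)
  legend("topright", legend = colnames(H), fill = cols, cex = 0.7,
         bg = "white")
  invisible(x)
}
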