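# Semi-automatic lead-gene-driven marker selection.
#
# The user supplies, per cell type, a (possibly large, noisy) candidate gene
# list and one trusted "lead" gene. The procedure (i) drops candidates with a
# weak expression signal, (ii) correlates each survivor with the lead gene
# across spots (Kendall tau-b and Pearson), (iii) normalizes each type's
# correlation vectors by their maxima, and (iv) keeps genes above both
# normalized thresholds. Genes claimed by too many types are removed, and a
# zero dummy column is appended.

#' Filter candidates on expression support
#'
#' A candidate is retained when it is expressed above level `r_k` in strictly
#' more than `r_n` spots. Candidates absent from the count matrix are dropped
#' with a warning.
#'
#' @param candidates character vector of candidate gene ids for one type.
#' @param counts gene x spot count matrix.
#' @param r_n spot-count threshold (default 5).
#' @param r_k expression-level threshold (default 0: any nonzero count).
#' @return character vector of retained gene ids.
#' @export
filter_low_expression <- function(candidates, counts, r_n = 5, r_k = 0) {
  unknown <- setdiff(candidates, rownames(counts))
  if (length(unknown))
    warning(sprintf("%d candidate(s) not in the count matrix: %s",
                    length(unknown),
                    paste(head(unknown, 5), collapse = ", ")))
  candidates <- intersect(candidates, rownames(counts))
  keep <- vapply(candidates, function(g)
    sum(counts[g, ] > r_k) > r_n, logical(1))
  candidates[keep]
}

#' Correlate retained candidates with a lead gene
#'
#' Kendall's tau (tau-b, tie-corrected, appropriate for tie-heavy counts)
#' and Pearson correlation of each retained gene with the type's lead gene
#' across spots. Genes with zero variance are excluded with a warning.
#'
#' @param genes retained candidate gene ids (should include the lead gene).
#' @param counts gene x spot count matrix.
#' @param lead_gene id of the lead gene.
#' @return data.frame with columns `gene`, `tau`, `rho`.
#' @export
lead_correlations <- function(genes, counts, lead_gene) {
  if (!lead_gene %in% rownames(counts))
    stop(sprintf("lead gene '%s' not in the count matrix", lead_gene))
  lead <- counts[lead_gene, ]
  if (sd(lead) == 0)
    stop(sprintf("lead gene '%s' has zero variance", lead_gene))
  keep <- vapply(genes, function(g) sd(counts[g, ]) > 0, logical(1))
  if (any(!keep))
    warning("excluded zero-variance gene(s): ",
            paste(genes[!keep], collapse = ", "))
  genes <- genes[keep]
  data.frame(
    gene = genes,
    tau = vapply(genes, function(g)
      cor(lead, counts[g, ], method = "kendall"), 0),
    rho = vapply(genes, function(g) cor(lead, counts[g, ]), 0),
    row.names = NULL)
}

#' Normalize correlations and apply thresholds
#'
#' Divides each correlation vector by its maximum over the retained set and
#' keeps genes whose normalized tau and rho both exceed their thresholds.
#' The gene attaining a normalized value of exactly 1 passes that threshold
#' even at a threshold of 1, so the lead gene can never exclude itself.
#'
#' @param report data.frame from [lead_correlations()].
#' @param tau_star,rho_star normalized thresholds in (0, 1].
#' @return the report restricted to selected genes, with normalized columns
#'   `tau_norm` and `rho_norm` added.
#' @export
normalize_and_select <- function(report, tau_star, rho_star) {
  if (nrow(report) == 0) return(cbind(report, tau_norm = numeric(0),
                                      rho_norm = numeric(0)))
  tmax <- max(report$tau); rmax <- max(report$rho)
  if (tmax <= 0 || rmax <= 0) {
    warning("nonpositive maximal correlation; no genes selected")
    return(report[0, ])
  }
  report$tau_norm <- report$tau / tmax
  report$rho_norm <- report$rho / rmax
  pass <- (report$tau_norm > tau_star | report$tau_norm == 1) &
          (report$rho_norm > rho_star | report$rho_norm == 1)
  report[pass, , drop = FALSE]
}

#' Assemble the binary marker matrix from per-type selections
#'
#' Genes selected for more than `max_types_per_gene` types are removed
#' entirely; a zero dummy column is appended.
#'
#' @param marker_sets named list (type -> selected gene ids).
#' @param max_types_per_gene maximal number of types a gene may mark
#'   (default 2).
#' @return binary gene x type matrix with a trailing dummy column.
#' @export
build_marker_matrix <- function(marker_sets, max_types_per_gene = 2) {
  genes <- sort(unique(unlist(marker_sets)))
  B <- vapply(marker_sets, function(set) as.numeric(genes %in% set),
              numeric(length(genes)))
  B <- matrix(B, nrow = length(genes),
              dimnames = list(genes, names(marker_sets)))
  promiscuous <- rowSums(B) > max_types_per_gene
  if (any(promiscuous))
    message(sprintf("removed %d gene(s) claimed by more than %d types",
                    sum(promiscuous), max_types_per_gene))
  B <- B[!promiscuous, , drop = FALSE]
  B <- cbind(B, dummy = 0)
  attr(B, "dummy_index") <- ncol(B)
  B
}

#' Lead-gene-driven marker selection
#'
#' Runs the full selection pipeline for every type: expression filtering,
#' lead-gene correlation, max-normalization, thresholding, and assembly of
#' the final binary marker matrix. Thresholds may be global scalars or
#' per-type named vectors.
#'
#' @param counts gene x spot count matrix.
#' @param candidates named list (type -> candidate gene ids).
#' @param lead_genes named character vector (type -> lead gene id); each
#'   lead gene must be among its type's candidates.
#' @param r_n,r_k expression-filter thresholds (see
#'   [filter_low_expression()]).
#' @param tau_star,rho_star normalized correlation thresholds, scalar or
#'   named per-type.
#' @param max_types_per_gene passed to [build_marker_matrix()].
#' @return list with `markers` (the binary matrix) and `report` (per-type
#'   correlation data.frames, including non-selected genes).
#' @export
select_markers <- function(counts, candidates, lead_genes,
                           r_n = 5, r_k = 0,
                           tau_star = 0.5, rho_star = 0.5,
                           max_types_per_gene = 2) {
  counts <- validate_counts(counts)
  types <- names(candidates)
  if (is.null(types) || !all(types %in% names(lead_genes)))
    stop("candidates and lead_genes must be named by the same types")
  thr <- function(x, t) if (length(x) == 1) x else unname(x[t])
  report <- list()
  sets <- list()
  for (t in types) {
    if (!lead_genes[[t]] %in% candidates[[t]])
      stop(sprintf("lead gene '%s' is not a candidate for type '%s'",
                   lead_genes[[t]], t))
    retained <- filter_low_expression(candidates[[t]], counts, r_n, r_k)
    if (length(retained) == 0) {
      warning(sprintf("type '%s': no candidates left after filtering", t))
      sets[[t]] <- character(0)
      report[[t]] <- data.frame(gene = character(0), tau = numeric(0),
                                rho = numeric(0))
      next
    }
    cors <- lead_correlations(retained, counts, lead_genes[[t]])
    sel <- normalize_and_select(cors, thr(tau_star, t), thr(rho_star, t))
    sets[[t]] <- sel$gene
    report[[t]] <- cors
  }
  list(markers = build_marker_matrix(sets, max_types_per_gene),
       report = report)
}
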