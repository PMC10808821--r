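## Core-microbiota filtering and community summaries for relative-abundance
## taxa tables (samples x taxa, percent scale).

check_taxa_matrix <- function(taxa) {
  if (is.data.frame(taxa)) taxa <- as.matrix(taxa)
  if (!is.matrix(taxa) || !is.numeric(taxa) || nrow(taxa) == 0L || ncol(taxa) == 0L)
    abort_validation("taxa table must be a non-empty numeric samples x taxa matrix")
  if (any(taxa < 0))
    abort_validation("taxa abundances must be nonnegative")
  if (any(rowSums(taxa) > 100 + 1e-6))
    abort_validation("taxa row sums exceed 100% — expected percent-scale relative abundances")
  taxa
}

#' Filter taxa to the core measurable microbiota
#'
#' Restricts a relative-abundance table to taxa measurable throughout the
#' cohort, limiting random error from low-abundance taxa before per-taxon
#' association screens. Under the default `"drop_low_prevalence"` rule a
#' taxon is dropped when its abundance falls below `threshold_abundance`
#' (percent) in at least `threshold_sample_fraction` of samples. The
#' `"keep_prevalent"` rule is the more common converse convention: keep a
#' taxon when its abundance is at or above the threshold in at least that
#' fraction of samples (the two differ only in how the boundary fractions are
#' treated).
#'
#' @param taxa Samples x taxa numeric matrix of percent-scale abundances.
#' @param threshold_abundance Abundance threshold in percent (default 0.01).
#' @param threshold_sample_fraction Sample-fraction threshold (default 0.10).
#' @param rule Filter direction, see Details.
#' @return List (class `core_filter`) with `kept_taxa`, `dropped_taxa`, the
#'   filtered `abundance` matrix, and the thresholds used.
#' @export
filter_core_microbiota <- function(taxa, threshold_abundance = 0.01,
                                   threshold_sample_fraction = 0.10,
                                   rule = c("drop_low_prevalence", "keep_prevalent")) {
  taxa <- check_taxa_matrix(taxa)
  rule <- match.arg(rule)
  frac_below <- colMeans(taxa < threshold_abundance)
  drop <- if (rule == "drop_low_prevalence") {
    frac_below >= threshold_sample_fraction
  } else {
    (1 - frac_below) < threshold_sample_fraction
  }
  nm <- colnames(taxa) %||% paste0("taxon", seq_len(ncol(taxa)))
  colnames(taxa) <- nm
  structure(list(kept_taxa = nm[!drop],
                 dropped_taxa = nm[drop],
                 abundance = taxa[, !drop, drop = FALSE],
                 threshold_abundance = threshold_abundance,
                 threshold_sample_fraction = threshold_sample_fraction,
                 rule = rule),
            class = "core_filter")
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} with \eqn{p_i} the taxon proportions of the
#' sample; natural log; zero-abundance taxa contribute nothing. Invariant to
#' rescaling, so percent-scale rows need no prior normalization.
#'
#' @param x Nonnegative abundance vector for one sample, or a samples x taxa
#'   matrix (one index per row).
#' @return Numeric Shannon index (vector for matrix input).
#' @export
shannon_index <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- check_taxa_matrix(x)
    if (any(rowSums(x) <= 0))
      abort_validation("every sample needs positive total abundance")
    return(as.numeric(vegan::diversity(x, index = "shannon")))
  }
  if (any(x < 0)) abort_validation("abundances must be nonnegative")
  if (sum(x) <= 0) abort_validation("all-zero abundance vector")
  as.numeric(vegan::diversity(matrix(x, nrow = 1), index = "shannon"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)}; symmetric, zero
#' diagonal, entries in \[0, 1\] for nonnegative data.
#'
#' @param taxa Samples x taxa numeric matrix.
#' @return Dense symmetric samples x samples matrix.
#' @export
bray_curtis_matrix <- function(taxa) {
  taxa <- check_taxa_matrix(taxa)
  if (nrow(taxa) < 2L) abort_validation("need at least 2 samples")
  zero <- rowSums(taxa) <= 0
  if (any(zero)) {
    nm <- rownames(taxa) %||% as.character(seq_len(nrow(taxa)))
    abort_validation(paste0("sample(s) with zero total abundance: ",
                            paste(nm[zero], collapse = ", ")))
  }
  as.matrix(vegan::vegdist(taxa, method = "bray"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers \eqn{-\tfrac{1}{2} D^2}, eigendecomposes, and returns
#' coordinates scaled by the square root of the positive eigenvalues. Axes
#' are ordered by descending eigenvalue; each axis sign is fixed so its
#' largest-magnitude coordinate is positive. Negative eigenvalues (the
#' dissimilarity not being Euclidean) are truncated with a warning reporting
#' the truncated eigenvalue mass.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @param axes_kept Number of axes to retain (default 3).
#' @return List (class `pcoa_ordination`) with `coordinates` (samples x axes,
#'   columns `PCoA-1..k`), `eigenvalues` (all, descending), and `axes_kept`.
#' @export
pcoa_ordination <- function(d, axes_kept = 3) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    abort_validation("dissimilarity matrix must be square and symmetric")
  if (any(abs(diag(d)) > 1e-8))
    abort_validation("dissimilarity matrix must have a zero diagonal")
  n <- nrow(d)
  ## cmdscale's own warning about non-positive eigenvalues is superseded by
  ## the negative-mass report below
  fit <- suppressWarnings(stats::cmdscale(d, k = min(axes_kept, n - 1), eig = TRUE))
  eig <- fit$eig
  neg_mass <- sum(abs(eig[eig < 0]))
  if (neg_mass > 1e-8)
    warning(sprintf("PCoA: truncated negative-eigenvalue mass %.4g (of total %.4g)",
                    neg_mass, sum(abs(eig))))
  coords <- fit$points
  k <- min(axes_kept, sum(eig > 1e-12), ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("PCoA-", seq_len(ncol(coords)))
  rownames(coords) <- rownames(d)
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 axes_kept = ncol(coords)),
            class = "pcoa_ordination")
}
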