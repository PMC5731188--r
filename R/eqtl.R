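#' Filter genes by mean expression
#'
#' Retains genes whose mean read count per animal is strictly greater than
#' `min_mean_reads` (default 8, the conventional "more than 8 exonic reads
#' per animal" expression floor).
#'
#' @param counts gene x sample count matrix.
#' @param min_mean_reads expression floor; strict inequality.
#' @return The filtered count matrix.
#' @export
filter_expressed_genes <- function(counts, min_mean_reads = 8) {
  if (!length(counts)) stop("empty count matrix")
  counts[rowMeans(counts) > min_mean_reads, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed as the median across genes of
#' the ratio of each count to the gene's geometric mean over samples.
#' Genes with any zero count are skipped when forming the reference
#' geometric means.
#'
#' @param counts gene x sample count matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  keep <- rowSums(counts == 0) == 0L
  if (!any(keep)) return(stats::setNames(rep(1, ncol(counts)), colnames(counts)))
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(exp(lg - ref), 2L, stats::median)
  sf / exp(mean(log(sf))) * exp(0)  # keep raw scale; no re-centering needed
}

#' Method-of-moments common negative-binomial dispersion
#'
#' For each gene, on size-factor-normalised counts, solves
#' `var = mean + alpha * mean^2` for `alpha`; the common dispersion is the
#' median of the positive per-gene estimates.
#'
#' @param counts gene x sample count matrix.
#' @param sf size factors (default [size_factors]).
#' @return Scalar dispersion estimate.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts)) {
  xn <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(xn)
  v <- apply(xn, 1L, stats::var)
  a <- (v - mu) / mu^2
  a <- a[is.finite(a) & a > 0]
  if (!length(a)) stop("cannot estimate dispersion: no overdispersed genes")
  stats::median(a)
}

#' Variance-stabilising transformation for negative-binomial counts
#'
#' Closed-form VST for NB counts with a common dispersion `alpha`:
#' `y = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x_norm))`, where `x_norm` is
#' the count divided by the sample's size factor.  For NB(mu, alpha) data
#' this makes the variance approximately independent of the mean; it is
#' strictly increasing in the count for a fixed size factor and maps 0 to 0.
#'
#' @param counts gene x sample count matrix.
#' @param dispersion positive common NB dispersion, or `"estimate"` to use
#'   [estimate_dispersion].
#' @param sf size factors; default [size_factors].
#' @return Real-valued matrix of transformed expression, same shape as
#'   `counts`, with the dispersion used stored in attribute `"dispersion"`.
#' @export
vst_transform <- function(counts, dispersion = "estimate",
                          sf = size_factors(counts)) {
  if (identical(dispersion, "estimate"))
    dispersion <- estimate_dispersion(counts, sf)
  if (!is.numeric(dispersion) || dispersion <= 0)
    stop("dispersion must be positive")
  xn <- sweep(counts, 2L, sf, "/")
  out <- (2 / sqrt(dispersion)) * asinh(sqrt(dispersion * xn))
  attr(out, "dispersion") <- dispersion
  out
}

#' Expression-sample outlier exclusion by PCA
#'
#' Principal components are computed with samples as observations (genes as
#' variables) on transformed expression; any sample whose score on any of
#' the first `n_components` available components lies more than `sd_limit`
#' standard deviations from that component's mean is excluded.  A single
#' pass only; no iteration.
#'
#' @param expr transformed gene x sample matrix (see [vst_transform]).
#' @param n_components number of leading components to screen (default 6;
#'   capped at the number available).
#' @param sd_limit exclusion limit in standard deviations (default 3).
#' @return The matrix restricted to retained samples; excluded sample ids
#'   and the offending components are in attribute `"excluded"`.
#' @export
pca_outlier_filter <- function(expr, n_components = 6L, sd_limit = 3) {
  if (ncol(expr) < 3L) stop("need at least 3 samples for PCA screening")
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  z <- sweep(sweep(sc, 2L, colMeans(sc)), 2L, apply(sc, 2L, stats::sd), "/")
  bad <- abs(z) > sd_limit
  drop_idx <- which(rowSums(bad) > 0L)
  excluded <- data.frame(
    sample_id = rownames(sc)[drop_idx],
    component = vapply(drop_idx, function(i) which(bad[i, ])[1L], integer(1)),
    stringsAsFactors = FALSE)
  out <- expr[, setdiff(seq_len(ncol(expr)), drop_idx), drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' cis-eQTL scan for one gene over a genomic window
#'
#' Runs the same GLS engine as the trait scan ([gls_scan]) with the gene's
#' transformed expression as the phenotype, over all variants inside the
#' window, on the intersection of genotyped and expression-profiled
#' animals.
#'
#' @param g a [genotype_matrix].
#' @param expr transformed gene x sample expression matrix.
#' @param gene gene id (row of `expr`).
#' @param window list or vector `(chrom, start, end)`; 1-based inclusive.
#' @param vm a [variance_model] covering the intersected animals (it may
#'   cover more; columns are subset).
#' @return An `association_result` restricted to window variants, with
#'   attributes `gene` and `window`.
#' @export
cis_eqtl_scan <- function(g, expr, gene, window, vm) {
  if (!gene %in% rownames(expr)) stop("gene '", gene, "' not in expression matrix")
  chrom <- as.character(window[[1L]])
  start <- as.numeric(window[[2L]]); end <- as.numeric(window[[3L]])
  keep <- which(g$variants$chrom == chrom &
                  g$variants$pos >= start & g$variants$pos <= end)
  if (!length(keep)) stop("no variants in window ", chrom, ":", start, "-", end)
  animals <- intersect(g$animal_ids, colnames(expr))
  animals <- intersect(animals, vm$animal_ids)
  if (!length(animals)) stop("no animals shared by genotypes, expression and pedigree")
  gw <- subset_genotypes(g, animals = animals, variants = keep)
  y <- stats::setNames(as.numeric(expr[gene, animals]), animals)
  if (stats::var(y) == 0) {
    out <- data.frame(variant_id = gw$variants$variant_id,
                      chrom = gw$variants$chrom, pos = gw$variants$pos,
                      beta = NA_real_, se = NA_real_, chi2 = NA_real_,
                      p = NA_real_, n_used = length(animals),
                      stringsAsFactors = FALSE)
    class(out) <- c("association_result", "data.frame")
  } else {
    out <- gls_scan(gw, y, subset_variance_model(vm, animals))
  }
  attr(out, "gene") <- gene
  attr(out, "window") <- list(chrom = chrom, start = start, end = end)
  out
}
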