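#' Composite LD between two variants
#'
#' Squared Pearson correlation between genotype dosage vectors over animals
#' called at both variants (genotypic/composite LD; no phasing).  Invariant
#' to allele relabelling.
#'
#' @param g a [genotype_matrix].
#' @param v1,v2 variant ids.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, v1, v2) {
  for (v in c(v1, v2))
    if (!v %in% g$variants$variant_id) stop("variant '", v, "' not in matrix")
  x <- g$dosages[, v1]; y <- g$dosages[, v2]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("monomorphic variant over shared called animals")
  stats::cor(x, y)^2
}

#' Top associated variant of a scan
#'
#' The variant with minimum p-value; exact ties broken by smallest
#' (chromosome, position).
#'
#' @param result an `association_result`.
#' @return variant id (character scalar).
#' @export
top_variant <- function(result) {
  ok <- which(!is.na(result$p))
  if (!length(ok)) stop("no non-missing p-values")
  o <- ok[order(result$p[ok], result$chrom[ok], result$pos[ok])][1L]
  result$variant_id[o]
}

#' Chi-square correlation between a QTL scan and an eQTL scan
#'
#' If a trait QTL and an eQTL respond to the same causal element, their
#' per-variant association statistics across a window should rise and fall
#' together.  This computes Pearson and Spearman correlations of the paired
#' chi-square vectors over variants present with finite statistics in both
#' scans (Spearman uses average ranks for ties).  Variants missing from
#' either scan are dropped pairwise.
#'
#' @param qtl,eqtl `association_result` objects over overlapping variants.
#' @return list with `pearson_r`, `spearman_rho`, `n_shared`.
#' @export
chi2_correlation <- function(qtl, eqtl) {
  shared <- intersect(qtl$variant_id[is.finite(qtl$chi2)],
                      eqtl$variant_id[is.finite(eqtl$chi2)])
  if (length(shared) < 3L)
    stop("need at least 3 shared variants with finite statistics (got ",
         length(shared), ")")
  a <- qtl$chi2[match(shared, qtl$variant_id)]
  b <- eqtl$chi2[match(shared, eqtl$variant_id)]
  list(pearson_r = stats::cor(a, b),
       spearman_rho = stats::cor(rank(a), rank(b)),
       n_shared = length(shared))
}

#' Score every (locus, gene) pair in a window
#'
#' @param qtl trait `association_result` restricted to the locus window.
#' @param eqtls named list of `association_result`s, one per gene (see
#'   [cis_eqtl_scan]).
#' @param g a [genotype_matrix] holding the window variants.
#' @return data.frame: `gene_id`, `pearson_r`, `spearman_rho`, `n_shared`,
#'   `top_ld_r2`, `eqtl_top_p`, `qtl_tag_p_in_eqtl`.
#' @export
coloc_scores <- function(qtl, eqtls, g) {
  tag <- top_variant(qtl)
  rows <- lapply(names(eqtls), function(gene) {
    e <- eqtls[[gene]]
    cc <- tryCatch(chi2_correlation(qtl, e), error = function(err) NULL)
    etop <- tryCatch(top_variant(e), error = function(err) NA_character_)
    ld <- if (is.na(etop)) NA_real_ else
      tryCatch(ld_r2(g, tag, etop), error = function(err) NA_real_)
    tag_in_e <- e$p[match(tag, e$variant_id)]
    data.frame(gene_id = gene,
               pearson_r = if (is.null(cc)) NA_real_ else cc$pearson_r,
               spearman_rho = if (is.null(cc)) NA_real_ else cc$spearman_rho,
               n_shared = if (is.null(cc)) 0L else cc$n_shared,
               top_variant = etop, top_ld_r2 = ld,
               eqtl_top_p = if (is.na(etop)) NA_real_ else
                 min(e$p, na.rm = TRUE),
               qtl_tag_p_in_eqtl = if (length(tag_in_e)) tag_in_e else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# consequence classes treated as protein-altering for the coding-LD rule
PROTEIN_ALTERING <- c("missense", "splice_region", "splice_donor")

#' Candidate-gene triage at a QTL locus
#'
#' A gene becomes a candidate when any rule fires:
#' \itemize{
#'   \item \code{coding_LD}: an annotated protein-altering variant in the
#'     gene has LD r-squared > `coding_ld` with the QTL top variant;
#'   \item \code{eqtl_correlation}: the gene's eQTL reaches `eqtl_alpha`
#'     and the Pearson or Spearman chi-square correlation exceeds `corr`;
#'   \item \code{shared_top_variant}: the gene's eQTL reaches `eqtl_alpha`
#'     and the LD r-squared between the QTL and eQTL top variants exceeds
#'     `top_ld`.
#' }
#' All firing reasons are recorded; the report is a deterministic function
#' of its inputs.
#'
#' @param qtl trait `association_result` restricted to the locus window.
#' @param eqtls named list of per-gene `association_result`s.
#' @param ann annotation table (see [read_annotations]).
#' @param g window [genotype_matrix].
#' @param thresholds list with elements `coding_ld` (default 0.9), `corr`
#'   (0.7), `top_ld` (0.9) and `eqtl_alpha` (the eQTL significance gate;
#'   no universal default -- commonly a Bonferroni level over the cumulative
#'   window variant count).
#' @return data.frame with one row per (gene, reason): `gene_id`, `reason`,
#'   `score` (the statistic that fired) plus the full coloc score columns.
#' @export
triage_candidates <- function(qtl, eqtls, ann, g,
                              thresholds = list(coding_ld = 0.9, corr = 0.7,
                                                top_ld = 0.9,
                                                eqtl_alpha = 2.53e-7)) {
  th <- utils::modifyList(
    list(coding_ld = 0.9, corr = 0.7, top_ld = 0.9, eqtl_alpha = 2.53e-7),
    thresholds)
  tag <- top_variant(qtl)
  scores <- if (length(eqtls)) coloc_scores(qtl, eqtls, g) else NULL
  rows <- list()
  add <- function(gene, reason, score) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene, reason = reason, score = score, stringsAsFactors = FALSE)
  }
  # rule (i): protein-altering variant in strong LD with the QTL tag
  ann_w <- ann[ann$consequence %in% PROTEIN_ALTERING &
                 ann$variant_id %in% g$variants$variant_id, , drop = FALSE]
  for (i in seq_len(nrow(ann_w))) {
    r2 <- tryCatch(ld_r2(g, tag, ann_w$variant_id[i]),
                   error = function(err) NA_real_)
    if (!is.na(r2) && r2 > th$coding_ld) add(ann_w$gene_id[i], "coding_LD", r2)
  }
  # rules (ii) and (iii): significant, co-segregating eQTL
  for (i in seq_len(NROW(scores))) {
    s <- scores[i, ]
    sig <- !is.na(s$eqtl_top_p) && s$eqtl_top_p <= th$eqtl_alpha
    if (!sig) next
    best_corr <- max(s$pearson_r, s$spearman_rho, na.rm = TRUE)
    if (is.finite(best_corr) && best_corr > th$corr)
      add(s$gene_id, "eqtl_correlation", best_corr)
    if (!is.na(s$top_ld_r2) && s$top_ld_r2 > th$top_ld)
      add(s$gene_id, "shared_top_variant", s$top_ld_r2)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), reason = character(),
               score = numeric(), stringsAsFactors = FALSE)
  if (!is.null(scores))
    out <- merge(out, scores, by = "gene_id", all.x = TRUE, sort = FALSE)
  out[order(out$gene_id, out$reason), , drop = FALSE]
}
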