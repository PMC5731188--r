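#' Per-variant allele frequencies
#'
#' Alternative-allele frequency is `mean(dosage) / 2` over called animals;
#' the minor allele frequency is `min(f, 1 - f)`.  `minor_is_ref` flags
#' variants whose minor allele is the reference allele (the asterisk
#' convention used in tag-variant frequency tables).
#'
#' @param g a [genotype_matrix].
#' @return data.frame with columns `variant_id`, `alt_freq`, `maf`,
#'   `minor_is_ref`, `call_rate`.  Variants with no called genotypes carry
#'   `NA` frequencies.
#' @export
maf <- function(g) {
  d <- g$dosages
  called <- colSums(!is.na(d))
  alt_freq <- colMeans(d, na.rm = TRUE) / 2
  alt_freq[called == 0L] <- NA_real_
  data.frame(
    variant_id   = g$variants$variant_id,
    alt_freq     = unname(alt_freq),
    maf          = unname(pmin(alt_freq, 1 - alt_freq)),
    minor_is_ref = unname(!is.na(alt_freq) & alt_freq > 0.5),
    call_rate    = unname(called / nrow(d)),
    stringsAsFactors = FALSE
  )
}

#' Variant quality-control filter
#'
#' Retains variants with minor allele frequency `>= min_maf` (computed over
#' called alleles only) and call rate `>= min_call_rate`.  The defaults
#' reproduce the standard sequence-variant QC of dropping call rate < 0.9
#' or MAF < 2.5%.  Idempotent: filtering twice equals filtering once.
#'
#' @param g a [genotype_matrix].
#' @param min_maf minimum minor allele frequency in `[0, 1]`.
#' @param min_call_rate minimum fraction of called genotypes in `[0, 1]`.
#' @return The filtered [genotype_matrix]; attribute `"qc_report"` records
#'   the number removed for each reason.
#' @export
qc_filter_variants <- function(g, min_maf = 0.025, min_call_rate = 0.9) {
  stopifnot(min_maf >= 0, min_maf <= 1, min_call_rate >= 0, min_call_rate <= 1)
  m <- maf(g)
  low_maf  <- is.na(m$maf) | m$maf < min_maf
  low_call <- m$call_rate < min_call_rate
  keep <- !(low_maf | low_call)
  out <- subset_genotypes(g, variants = which(keep))
  attr(out, "qc_report") <- list(
    n_input = ncol(g$dosages), n_kept = sum(keep),
    n_low_maf = sum(low_maf), n_low_call_rate = sum(low_call))
  out
}
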