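#' Read a phenotype table
#'
#' TSV/CSV with header; first column `animal_id`, remaining columns one per
#' trait (pre-adjusted real values in trait units).  Duplicate animal ids
#' are an error.
#'
#' @param path input file.
#' @return data.frame with `animal_id` plus one numeric column per trait.
#' @export
read_phenotypes <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  names(dt)[1L] <- "animal_id"
  dt$animal_id <- as.character(dt$animal_id)
  if (anyDuplicated(dt$animal_id)) stop("duplicate animal ids in phenotype table")
  dt
}

#' Extract one trait as a named phenotype vector
#'
#' @param phen a phenotype table (see [read_phenotypes]).
#' @param trait trait column name.
#' @return Named numeric vector.
#' @export
phenotype_vector <- function(phen, trait) {
  if (!trait %in% names(phen)) stop("trait '", trait, "' not in phenotype table")
  stats::setNames(as.numeric(phen[[trait]]), phen$animal_id)
}

#' Read a gene x sample expression count matrix
#'
#' TSV with header; first column `gene_id`, remaining columns one per
#' sample, entries non-negative integer read counts.
#'
#' @param path input file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  genes <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("expression counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write an expression count matrix
#' @param counts gene x sample integer matrix.
#' @param path output path.
#' @export
write_expression <- function(counts, path) {
  dt <- data.table::data.table(gene_id = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(counts))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a variant annotation table
#'
#' Stand-in for upstream consequence-prediction output: TSV with header
#' `variant_id`, `gene_id`, `consequence` (one of `missense`,
#' `splice_region`, `splice_donor`, `other`) and optional extra columns
#' (e.g. a deleteriousness label).
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- as.data.frame(data.table::fread(path, header = TRUE,
                                         colClasses = "character"))
  need <- c("variant_id", "gene_id", "consequence")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  known <- c("missense", "splice_region", "splice_donor", "other")
  bad <- setdiff(unique(ann$consequence), known)
  if (length(bad)) stop("unknown consequence class(es): ",
                        paste(bad, collapse = ", "))
  ann
}

#' Write an association result table
#'
#' One TSV row per variant with columns `variant_id`, `chrom`, `pos`,
#' `beta`, `se`, `chi2`, `p`.  Numeric values are serialised at full double
#' precision (p-values in scientific notation preserving at least 3
#' significant figures), so a round trip through [read_association_table]
#' reproduces them to within 1e-12.
#'
#' @param result an `association_result` (see [gls_scan]).
#' @param path output path.
#' @export
write_association_table <- function(result, path) {
  cols <- c("variant_id", "chrom", "pos", "beta", "se", "chi2", "p")
  out <- as.data.frame(result)[, cols]
  for (cc in c("beta", "se", "chi2", "p"))
    out[[cc]] <- formatC(out[[cc]], digits = 17, format = "g")
  out$p <- ifelse(out$p == "NA", "NA",
                  formatC(as.numeric(out$p), digits = 16, format = "e"))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an association result table written by [write_association_table]
#' @param path input file.
#' @return An `association_result` data.frame.
#' @export
read_association_table <- function(path) {
  out <- as.data.frame(data.table::fread(path, header = TRUE, na.strings = "NA"))
  for (cc in c("beta", "se", "chi2", "p")) out[[cc]] <- as.numeric(out[[cc]])
  out$pos <- as.integer(out$pos)
  out$variant_id <- as.character(out$variant_id)
  out$chrom <- as.character(out$chrom)
  class(out) <- c("association_result", "data.frame")
  out
}
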