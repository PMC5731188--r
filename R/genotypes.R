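#' Genotype matrix objects
#'
#' Dosages are counts of the alternative allele, coded 0/1/2 with `NA` for
#' missing, in an animals x variants matrix.  Variant coordinates are
#' 1-based, as in VCF; window arithmetic elsewhere in the package converts
#' to half-open `[start, end)` intervals internally.
#'
#' @param dosages numeric matrix, animals in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` (one row per column of `dosages`).
#' @param animal_ids character vector naming the rows of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants, animal_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(animal_ids)) stop("animal ids required")
  if (nrow(variants) != ncol(dosages))
    stop("variant table (", nrow(variants), ") does not match dosage columns (",
         ncol(dosages), ")")
  if (length(animal_ids) != nrow(dosages))
    stop("animal ids do not match dosage rows")
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or missing")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  variants$pos <- as.integer(variants$pos)
  # positions strictly increasing within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  dimnames(dosages) <- list(as.character(animal_ids), variants$variant_id)
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants,
                 animal_ids = as.character(animal_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d variants on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param g a [genotype_matrix].
#' @param animals,variants index vectors (logical, integer or character)
#'   selecting rows/columns; `NULL` keeps all.
#' @return A [genotype_matrix].
#' @export
subset_genotypes <- function(g, animals = NULL, variants = NULL) {
  d <- g$dosages
  v <- g$variants
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, v$variant_id)
    d <- d[, variants, drop = FALSE]
    v <- v[variants, , drop = FALSE]
  }
  if (!is.null(animals)) {
    if (is.character(animals)) animals <- match(animals, g$animal_ids)
    d <- d[animals, , drop = FALSE]
  }
  genotype_matrix(d, v, rownames(d))
}

gt_to_dosage <- function(gt, alt_index = 1L) {
  # GT strings like "0/1", "1|1", ".", "./."; dosage counts alleles equal to
  # alt_index; any missing allele makes the call missing
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == "." | a == "")) return(NA_real_)
    sum(as.integer(a) == alt_index)
  }, numeric(1))
}

read_genotypes_vcf <- function(path, multiallelic = c("reject", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required for the VCF dialect")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- lengths(altl)
  ids <- rownames(gt)
  bad <- grep("^[0-9.]+([/|][0-9.]+)*$", gt, invert = TRUE)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(gt))
    stop("malformed GT '", gt[bad[1L]], "' at record ", ids[i[1L]],
         ", sample ", colnames(gt)[i[2L]])
  }
  if (any(n_alt > 1L)) {
    if (multiallelic == "reject")
      stop("multi-allelic record(s): ",
           paste(utils::head(ids[n_alt > 1L], 3L), collapse = ", "))
  }
  rows <- list(); dos <- list()
  for (i in seq_along(ids)) {
    for (k in seq_len(n_alt[i])) {
      vid <- if (n_alt[i] > 1L) paste0(ids[i], "_alt", k) else ids[i]
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = vid, chrom = chrom[i], pos = pos[i],
        ref = ref[i], alt = as.character(altl[[i]][k]),
        stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- gt_to_dosage(gt[i, ], alt_index = k)
    }
  }
  variants <- do.call(rbind, rows)
  d <- do.call(cbind, dos)
  # split alleles inherit the record position; keep the matrix invariant
  # (strictly increasing positions) by nudging later co-located entries by
  # +1 bp, a documented convention for the rare split case
  while (any(dup <- duplicated(variants[c("chrom", "pos")])))
    variants$pos[dup] <- variants$pos[dup] + 1L
  genotype_matrix(d, variants, colnames(gt))
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  # layout: first column animal id, remaining columns one per variant named
  # variant_id; a companion ".variants.tsv" sidecar (or embedded header rows)
  # carries coordinates.  Sidecar path: <path>.variants.tsv or the file
  # written by write_genotypes_tsv().
  side <- paste0(path, ".variants.tsv")
  if (!file.exists(side))
    stop("TSV dosage matrix requires a variant sidecar at ", side)
  variants <- as.data.frame(data.table::fread(side, header = TRUE))
  animal_ids <- as.character(dt[[1L]])
  d <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(d) <- "double"
  if (!identical(colnames(d), variants$variant_id))
    variants <- variants[match(colnames(d), variants$variant_id), , drop = FALSE]
  genotype_matrix(d, variants, animal_ids)
}

#' Read genotypes from VCF or a TSV dosage matrix
#'
#' The VCF dialect parses the GT field (phased or unphased) into alternative
#' allele dosages; the TSV dialect reads an animals-as-rows dosage matrix
#' with a `<path>.variants.tsv` sidecar carrying the variant coordinates.
#' Both dialects produce identical [genotype_matrix] objects on equivalent
#' content.
#'
#' @param path input file.
#' @param dialect `"vcf"` or `"tsv"`; default guessed from the extension.
#' @param multiallelic policy for VCF records with more than one ALT allele:
#'   `"reject"` (error, the default) or `"split"` into per-allele dosage
#'   columns.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, dialect = c("auto", "vcf", "tsv"),
                           multiallelic = c("reject", "split")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  switch(dialect,
         vcf = read_genotypes_vcf(path, multiallelic),
         tsv = read_genotypes_tsv(path))
}

#' Write genotypes as a TSV dosage matrix (with variant sidecar)
#'
#' @param g a [genotype_matrix].
#' @param path output path; the variant table goes to `<path>.variants.tsv`.
#' @export
write_genotypes_tsv <- function(g, path) {
  dt <- data.table::data.table(animal_id = g$animal_ids)
  dt <- cbind(dt, data.table::as.data.table(g$dosages))
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  data.table::fwrite(g$variants, paste0(path, ".variants.tsv"), sep = "\t")
  invisible(path)
}

#' Write genotypes as a minimal VCFv4.2 file
#'
#' Emits GT-only records (`0/0`, `0/1`, `1/1`, `./.`) on one sample column
#' per animal.
#'
#' @param g a [genotype_matrix].
#' @param path output path (plain text `.vcf`).
#' @export
write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=pedgls",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$animal_ids), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    v <- g$variants[j, ]
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", code[d + 1L])
    writeLines(paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", ".",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
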