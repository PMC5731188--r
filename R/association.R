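#' Variance model for the GLS scan
#'
#' The phenotypic covariance used by the generalised least-squares engine is
#' `W = sigma2_P * (h2 * A + (1 - h2) * I)`: phenotypic variance partitioned
#' into an additive genetic component whose correlation structure is the
#' numerator relationship matrix `A`, and an i.i.d. environmental component,
#' weighted by the narrow-sense heritability `h2`.  `W` is never inverted
#' explicitly: one symmetric eigendecomposition of `h2*A + (1-h2)*I` is done
#' here and reused to whiten every per-variant regression.
#'
#' @param A numerator relationship matrix with animal ids as dimnames (see
#'   [build_numerator_relationship]); identity structure may be requested by
#'   passing `NULL` together with `animal_ids`.
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @param sigma2_P phenotypic variance (trait units squared); if `NULL` it
#'   is estimated as the sample variance of the phenotype at scan time.
#' @param animal_ids required when `A` is `NULL`.
#' @return An object of class `variance_model` caching the whitening
#'   rotation `Z` such that `Z' Z = (h2*A + (1-h2)*I)^{-1}`.
#' @export
variance_model <- function(A, h2, sigma2_P = NULL, animal_ids = NULL) {
  stopifnot(h2 >= 0, h2 <= 1)
  if (is.null(A)) {
    if (is.null(animal_ids)) stop("animal_ids required when A is NULL")
    n <- length(animal_ids)
    Z <- diag(n)
    dimnames(Z) <- list(NULL, animal_ids)
    return(structure(list(h2 = h2, sigma2_P = sigma2_P, Z = Z, A = NULL,
                          animal_ids = as.character(animal_ids)),
                     class = "variance_model"))
  }
  if (!is.null(sigma2_P) && sigma2_P <= 0) stop("sigma2_P must be positive")
  ids <- rownames(A)
  if (is.null(ids)) stop("A must carry animal ids as dimnames")
  K <- h2 * A + diag(1 - h2, nrow(A))
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8)
    stop("h2*A + (1-h2)*I is not positive semi-definite")
  vals <- pmax(eig$values, 1e-10)
  Z <- t(eig$vectors) / sqrt(vals)   # rows scaled: D^{-1/2} U'
  colnames(Z) <- ids
  structure(list(h2 = h2, sigma2_P = sigma2_P, Z = Z, A = A, animal_ids = ids),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("variance_model: n = %d, h2 = %.3f, sigma2_P = %s\n",
              length(x$animal_ids), x$h2,
              if (is.null(x$sigma2_P)) "<from data>" else format(x$sigma2_P)))
  invisible(x)
}

#' Restrict a variance model to a subset of animals
#'
#' The whitening rotation of a sub-cohort cannot be obtained by subsetting
#' the full rotation (the inverse of a submatrix is not the submatrix of
#' the inverse), so the model is rebuilt from the stored relationship
#' matrix restricted to the requested animals.
#'
#' @param vm a [variance_model].
#' @param animal_ids animals to keep (must be covered by `vm`).
#' @return A [variance_model] over `animal_ids`.
#' @export
subset_variance_model <- function(vm, animal_ids) {
  animal_ids <- as.character(animal_ids)
  if (!all(animal_ids %in% vm$animal_ids))
    stop("variance model does not cover all requested animals")
  if (setequal(animal_ids, vm$animal_ids)) return(vm)
  if (is.null(vm$A))
    return(variance_model(NULL, vm$h2, vm$sigma2_P, animal_ids = animal_ids))
  variance_model(vm$A[animal_ids, animal_ids, drop = FALSE], vm$h2, vm$sigma2_P)
}

#' Single-marker generalised least-squares association scan
#'
#' For each variant fits `y = b1 + b2 * x + e` by GLS, where `x` is the
#' dosage centred to mean zero and the error covariance is the
#' [variance_model] `W`.  The effect is `bhat = (X' W^-1 X)^-1 X' W^-1 y`,
#' its standard error `sqrt(diag((X' W^-1 X)^-1))`, and the association
#' statistic `chi2 = (b2 / se(b2))^2`, chi-square with 1 df under the null.
#' Missing dosages are mean-imputed per variant inside the engine only.
#' Monomorphic variants get missing statistics.
#'
#' @param g a [genotype_matrix].
#' @param y numeric phenotype vector, either named by animal id or aligned
#'   to `g$animal_ids`.
#' @param vm a [variance_model] covering all scanned animals.
#' @return data.frame of class `association_result`: `variant_id`, `chrom`,
#'   `pos`, `beta`, `se`, `chi2`, `p`, `n_used`.
#' @export
gls_scan <- function(g, y, vm) {
  ids <- g$animal_ids
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) stop("phenotype missing for some animals")
    y <- y[ids]
  } else if (length(y) != length(ids)) {
    stop("unnamed phenotype vector must match the genotype animal order")
  }
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  # the whitener is only valid on exactly the animal set it was built for
  # (a permutation is fine, a subset is not)
  if (!setequal(ids, vm$animal_ids))
    stop("variance model animal set does not match the scan; ",
         "rebuild it with subset_variance_model()")
  Z <- vm$Z[, ids, drop = FALSE]
  sigma2_P <- if (is.null(vm$sigma2_P)) stats::var(y) else vm$sigma2_P
  if (!is.finite(sigma2_P) || sigma2_P <= 0)
    stop("phenotypic variance must be positive")

  D <- g$dosages
  n <- nrow(D)
  # mean-impute missing dosages per variant, then centre
  mu <- colMeans(D, na.rm = TRUE)
  nas <- which(is.na(D))
  if (length(nas)) D[nas] <- mu[((nas - 1L) %/% n) + 1L]
  mono <- apply(D, 2L, function(x) length(unique(x)) < 2L) | !is.finite(mu)
  Dc <- sweep(D, 2L, colMeans(D), check.margin = FALSE)

  yt <- drop(Z %*% y)
  at <- drop(Z %*% rep(1, n))
  Gt <- Z %*% Dc
  Saa <- sum(at * at)
  Say <- sum(at * yt)
  Sax <- drop(crossprod(Gt, at))
  Sxy <- drop(crossprod(Gt, yt))
  Sxx <- colSums(Gt * Gt)
  det <- Saa * Sxx - Sax^2
  beta <- (Saa * Sxy - Sax * Say) / det
  var_beta <- sigma2_P * Saa / det
  se <- sqrt(pmax(var_beta, 0))
  chi2 <- (beta / se)^2
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  bad <- mono | det <= 0 | !is.finite(beta)
  beta[bad] <- se[bad] <- chi2[bad] <- p[bad] <- NA_real_

  out <- data.frame(
    variant_id = g$variants$variant_id,
    chrom = g$variants$chrom,
    pos = g$variants$pos,
    beta = unname(beta), se = unname(se), chi2 = unname(chi2),
    p = unname(p), n_used = n,
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  attr(out, "sigma2_P") <- sigma2_P
  attr(out, "h2") <- vm$h2
  out
}

# theoretical median of the chi-square distribution with 1 df, as used by
# the genomic-control convention
CHISQ1_MEDIAN <- 0.45494

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.45494`, the observed median association
#' statistic divided by the theoretical median of a 1-df chi-square.
#' Values above 1 indicate test-statistic inflation, e.g. from population
#' stratification or unmodelled relatedness.
#'
#' @param chi2 vector of association statistics; `NA`s are dropped.
#' @return The scalar inflation factor.
#' @export
inflation_factor <- function(chi2) {
  chi2 <- chi2[is.finite(chi2)]
  if (!length(chi2)) stop("no finite association statistics")
  stats::median(chi2) / CHISQ1_MEDIAN
}

#' Family-wise significance thresholds
#'
#' Computes the Bonferroni threshold `alpha / n_tests`; the
#' inflation-adjusted threshold, obtained by taking the 1-df chi-square
#' quantile with upper tail equal to the Bonferroni p-value, multiplying it
#' by `lambda`, and converting back to an upper-tail probability; and the
#' locus-prioritisation threshold corresponding to 1.5x the Bonferroni
#' threshold on the -log10 scale (`bonferroni_p ^ 1.5`).
#'
#' The inflation-adjusted threshold is reported for comparison; it is not
#' applied downstream unless explicitly requested, since genome-wide
#' inflation may be driven by true polygenic signal.
#'
#' @param n_tests number of tests.
#' @param alpha family-wise error level, default 0.05.
#' @param lambda inflation factor (values below 1 are passed through).
#' @return list with `n_tests`, `alpha`, `bonferroni_p`, `lambda`,
#'   `adjusted_p`, `priority_p`.
#' @export
significance_thresholds <- function(n_tests, alpha = 0.05, lambda = 1) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1, lambda > 0)
  bonferroni_p <- alpha / n_tests
  q <- stats::qchisq(bonferroni_p, df = 1, lower.tail = FALSE)
  adjusted_p <- stats::pchisq(lambda * q, df = 1, lower.tail = FALSE)
  priority_p <- 10^(-1.5 * (-log10(bonferroni_p)))
  list(n_tests = as.integer(n_tests), alpha = alpha,
       bonferroni_p = bonferroni_p, lambda = lambda,
       adjusted_p = adjusted_p, priority_p = priority_p)
}

#' Greedy locus definition around association peaks
#'
#' Repeatedly takes the most significant remaining variant at or below
#' `threshold_p` as a tag variant, assigns it a window of `window_bp`
#' centred on it (half-open internally), and removes all variants falling
#' inside.  Ties on p-value are broken by smallest (chromosome, position).
#' Loci are returned in genomic order.
#'
#' @param result an `association_result` (see [gls_scan]).
#' @param threshold_p significance threshold for tag variants.
#' @param window_bp window width in bp, default 1 Mbp.
#' @return data.frame with one row per locus: `chrom`, `tag_variant`,
#'   `tag_pos`, `tag_p`, `window_start`, `window_end` (1-based inclusive
#'   bounds), `n_members`, plus a list-column `members` of member variant
#'   ids.
#' @export
define_loci <- function(result, threshold_p, window_bp = 1e6) {
  half <- window_bp / 2
  avail <- which(!is.na(result$p) & result$p <= threshold_p)
  loci <- list()
  # order candidates once: by p, then chrom, then pos (documented tie-break)
  avail <- avail[order(result$p[avail], result$chrom[avail], result$pos[avail])]
  taken <- rep(FALSE, nrow(result))
  for (i in avail) {
    if (taken[i]) next
    ch <- result$chrom[i]; pos <- result$pos[i]
    inwin <- which(result$chrom == ch &
                     result$pos >= pos - half & result$pos < pos + half)
    taken[inwin] <- TRUE
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = ch, tag_variant = result$variant_id[i], tag_pos = pos,
      tag_p = result$p[i],
      window_start = as.integer(max(1, pos - half)),
      window_end = as.integer(pos + half - 1),
      n_members = length(inwin), stringsAsFactors = FALSE)
    loci[[length(loci)]]$members <- list(result$variant_id[inwin])
  }
  if (!length(loci))
    return(data.frame(chrom = character(), tag_variant = character(),
                      tag_pos = integer(), tag_p = numeric(),
                      window_start = integer(), window_end = integer(),
                      n_members = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, loci)
  out[order(out$chrom, out$tag_pos), , drop = FALSE]
}

#' Phenotypic variance explained by a variant
#'
#' Under Hardy-Weinberg, an additive allele-substitution effect `beta` at
#' allele frequency `p` contributes `2 p (1-p) beta^2` to the phenotypic
#' variance; the returned value is that contribution as a fraction of
#' `sigma2_P`.  Summing over independent tag variants gives a cumulative
#' variance-explained summary.
#'
#' @param beta allele substitution effect (trait units per alt allele).
#' @param alt_freq alternative allele frequency in `[0, 1]`.
#' @param sigma2_P phenotypic variance.
#' @return Fraction of phenotypic variance explained (vectorised).
#' @export
variance_explained <- function(beta, alt_freq, sigma2_P) {
  stopifnot(sigma2_P > 0, all(alt_freq >= 0), all(alt_freq <= 1))
  if (any(alt_freq == 0 | alt_freq == 1))
    warning("boundary allele frequency: variance explained is 0")
  2 * alt_freq * (1 - alt_freq) * beta^2 / sigma2_P
}
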