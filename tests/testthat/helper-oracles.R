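# Independent oracles used to freeze expected values.  These deliberately
# take the slow, literal route and share no code with the package internals.

# recursive kinship coefficient f(i, j); A = 2 * kinship
oracle_kinship <- function(ped) {
  idx <- seq_len(nrow(ped)); names(idx) <- ped$animal_id
  si <- unname(idx[ped$sire_id]); di <- unname(idx[ped$dam_id])
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      s <- si[i]; d <- di[i]
      0.5 * (1 + if (is.na(s) || is.na(d)) 0 else f(s, d))
    } else {
      # j is the later-born animal (topological order)
      s <- si[j]; d <- di[j]
      0.5 * ((if (is.na(s)) 0 else f(i, s)) + (if (is.na(d)) 0 else f(i, d)))
    }
    memo[[key]] <- val
    val
  }
  n <- nrow(ped)
  K <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  2 * K
}

# literal GLS by explicit matrix inversion: bhat = (X'W^-1X)^-1 X'W^-1 y,
# se = sqrt(diag((X'W^-1X)^-1)), chi2 = (b2/se2)^2
oracle_gls <- function(x, y, A, h2, sigma2_P) {
  W <- sigma2_P * (h2 * A + (1 - h2) * diag(nrow(A)))
  Wi <- solve(W)
  X <- cbind(1, x - mean(x))
  XtWiX_inv <- solve(t(X) %*% Wi %*% X)
  beta <- XtWiX_inv %*% t(X) %*% Wi %*% y
  se <- sqrt(diag(XtWiX_inv))
  chi2 <- (beta[2] / se[2])^2
  list(beta = beta[2], se = se[2], chi2 = chi2,
       p = pchisq(chi2, 1, lower.tail = FALSE))
}

# dosage matrix wrapped with sequential coordinates on one chromosome
toy_genotypes <- function(dosages, spacing = 1000L, chrom = "1") {
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("a%d", seq_len(nrow(dosages)))
  genotype_matrix(
    dosages,
    data.frame(variant_id = sprintf("v%d", seq_len(m)), chrom = chrom,
               pos = spacing * seq_len(m), ref = "A", alt = "B",
               stringsAsFactors = FALSE))
}

# founders F1/F2 (labelled), child C1 of both, grandchild via full sibs etc.
trio_pedigree <- function() pedigree(
  c("s", "d", "c"), c(NA, NA, "s"), c(NA, NA, "d"), c("HF", "J", NA))

# a bare association_result from vectors, for coloc fixtures
toy_result <- function(variant_id, chi2, pos = seq_along(variant_id) * 1000L,
                       chrom = "1", p = pchisq(chi2, 1, lower.tail = FALSE)) {
  out <- data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                    beta = sqrt(chi2), se = 1, chi2 = chi2, p = p,
                    n_used = 10L, stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

# small simulated population shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_founders = c(HF = 15, J = 15), n_generations = 3,
                        matings_per_generation = 50, n_variants = 300,
                        chrom_length_bp = 3e6,
                        expression = expression_spec(n_genes = 2,
                                                     n_samples = 80))
      cache <<- simulate_population(cfg, seed = 42)
    }
    cache
  }
})
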