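#' Simulation configuration
#'
#' Describes a two-breed pedigreed dairy population: founder pools for each
#' breed, discrete non-overlapping generations with a configurable
#' crossbreeding probability, a marker genome with LD, a quantitative trait
#' with planted QTL on a polygenic background, and negative-binomial
#' expression counts with planted cis-eQTL.
#'
#' Defaults describe a desk-scale stand-in for an outbred dairy cattle
#' population: two breeds diverged at F = 0.1 (of the order of the
#' Holstein-Friesian/Jersey differentiation), a lactose-concentration-like
#' trait (h2 = 0.557, sigma2_P = 0.0189 in squared percent units), and
#' moderately dispersed RNA-seq counts (NB dispersion 0.1).
#'
#' @param n_founders named integer vector, founders per breed.
#' @param n_generations number of discrete offspring generations.
#' @param matings_per_generation offspring produced per generation.
#' @param crossbreed_prob probability a mating deliberately crosses breed
#'   lineages.
#' @param n_chromosomes,chrom_length_bp,chrom_length_morgans,n_variants
#'   genome shape; `n_variants` is per chromosome.
#' @param base_freq_range ancestral allele frequencies are drawn uniformly
#'   from this interval.
#' @param breed_divergence_F Balding-Nichols divergence parameter; each
#'   breed's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral
#'   p.
#' @param ld_rho latent AR(1) correlation between adjacent markers on a
#'   haplotype (Gaussian-copula LD control; 0 = linkage equilibrium).
#' @param trait a [trait_spec].
#' @param expression an [expression_spec].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = c(HF = 40, J = 40),
                       n_generations = 4,
                       matings_per_generation = 120,
                       crossbreed_prob = 0.2,
                       n_chromosomes = 1,
                       chrom_length_bp = 5e6,
                       chrom_length_morgans = 1,
                       n_variants = 500,
                       base_freq_range = c(0.05, 0.95),
                       breed_divergence_F = 0.1,
                       ld_rho = 0.9,
                       trait = trait_spec(),
                       expression = expression_spec()) {
  n_founders <- unlist(n_founders)
  if (is.null(names(n_founders)))
    names(n_founders) <- paste0("B", seq_along(n_founders))
  stopifnot(all(n_founders >= 0), sum(n_founders) > 0,
            crossbreed_prob >= 0, crossbreed_prob <= 1,
            breed_divergence_F > 0, breed_divergence_F < 1,
            ld_rho >= 0, ld_rho < 1,
            base_freq_range[1] > 0, base_freq_range[2] < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Trait specification for the simulator
#'
#' @param h2 narrow-sense heritability (default 0.557, a high-heritability
#'   milk-composition trait).
#' @param sigma2_P phenotypic variance (default 0.0189 squared trait units).
#' @param n_qtl number of QTL to plant (ignored when `qtl` given).
#' @param qtl_var_frac fraction of phenotypic variance explained by each
#'   planted QTL (default 0.05).
#' @param qtl optional explicit data.frame `(variant_index, beta)`.
#' @param min_qtl_maf QTL are auto-placed on variants at or above this
#'   realized MAF.
#' @return list of class `trait_spec`.
#' @export
trait_spec <- function(h2 = 0.557, sigma2_P = 0.0189, n_qtl = 1,
                       qtl_var_frac = 0.05, qtl = NULL, min_qtl_maf = 0.15) {
  stopifnot(h2 >= 0, h2 <= 1, sigma2_P > 0)
  structure(as.list(environment()), class = "trait_spec")
}

#' Expression specification for the simulator
#'
#' Counts are drawn NB(mean = s_i * exp(mu + b * g_ij), dispersion alpha)
#' for sample size factors s_i; each gene's cis window is centred on its
#' causal variant.  The expression cohort is a subset of the phenotyped
#' animals, as is typical when only part of a genotyped population is
#' RNA-sequenced.
#'
#' @param n_genes number of genes.
#' @param n_samples animals with expression data (capped at cohort size).
#' @param mean_log baseline log mean expression.
#' @param log_fold allelic log-fold change `b` of planted cis-eQTL
#'   (0 = null gene).
#' @param dispersion common NB dispersion alpha.
#' @param size_factor_range sample size factors drawn uniformly from this
#'   interval.
#' @param window_bp cis window width.
#' @param min_eqtl_maf causal variants drawn at or above this realized MAF.
#' @return list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 4, n_samples = 400,
                            mean_log = log(200), log_fold = 0.5,
                            dispersion = 0.1,
                            size_factor_range = c(0.75, 1.33),
                            window_bp = 1e6, min_eqtl_maf = 0.15) {
  stopifnot(dispersion > 0, size_factor_range[1] > 0)
  structure(as.list(environment()), class = "expression_spec")
}

#' Simulate a two-breed pedigree with discrete generations
#'
#' Founders (generation 0) carry breed labels; each later generation holds
#' `matings_per_generation` offspring whose sire and dam are drawn from the
#' previous generation (sires from males, dams from females; sexes are
#' assigned alternately).  With probability `crossbreed_prob` a mating
#' deliberately crosses breed lineages; otherwise parents are drawn from
#' the same lineage where possible.  An animal's lineage label is its
#' parents' shared label, or `"X"` (crossbred) when they differ.
#'
#' @param cfg a [sim_config].
#' @return A [pedigree]; attribute `"generation"` maps id to generation and
#'   `"lineage"` to lineage label.
#' @export
simulate_pedigree <- function(cfg) {
  nf <- cfg$n_founders
  if (sum(nf) == 0) stop("at least one founder required")
  breeds <- names(nf)
  id <- unlist(lapply(seq_along(nf), function(b)
    sprintf("%s_%03d", breeds[b], seq_len(nf[b]))))
  ped <- data.frame(animal_id = id, sire_id = NA_character_,
                    dam_id = NA_character_,
                    breed = rep(breeds, nf), stringsAsFactors = FALSE)
  sex <- rep_len(c("M", "F"), nrow(ped))          # alternate within founders
  lineage <- ped$breed
  generation <- rep(0L, nrow(ped))
  prev <- seq_len(nrow(ped))
  for (g in seq_len(cfg$n_generations)) {
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1, " lacks one sex; increase founders/matings")
    new_rows <- vector("list", cfg$matings_per_generation)
    new_sex <- rep_len(c("F", "M"), cfg$matings_per_generation)
    for (k in seq_len(cfg$matings_per_generation)) {
      cross <- stats::runif(1) < cfg$crossbreed_prob
      dam <- sample1(females)
      lin_d <- lineage[dam]
      pool <- males
      if (!cross && lin_d %in% breeds) {
        same <- males[lineage[males] == lin_d]
        if (length(same)) pool <- same
      } else if (cross) {
        other <- males[lineage[males] != lin_d]
        if (length(other)) pool <- other
      }
      sire <- sample1(pool)
      child <- sprintf("G%d_%03d", g, k)
      new_rows[[k]] <- data.frame(animal_id = child,
                                  sire_id = ped$animal_id[sire],
                                  dam_id = ped$animal_id[dam],
                                  breed = NA_character_,
                                  stringsAsFactors = FALSE)
      lineage <- c(lineage,
                   if (lineage[sire] == lineage[dam]) lineage[sire] else "X")
    }
    ped <- rbind(ped, do.call(rbind, new_rows))
    sex <- c(sex, new_sex)
    prev <- seq.int(nrow(ped) - cfg$matings_per_generation + 1L, nrow(ped))
    generation <- c(generation, rep(g, cfg$matings_per_generation))
  }
  out <- pedigree(ped$animal_id, ped$sire_id, ped$dam_id, ped$breed)
  attr(out, "generation") <- stats::setNames(generation, ped$animal_id)
  attr(out, "lineage") <- stats::setNames(lineage, ped$animal_id)
  attr(out, "sex") <- stats::setNames(sex, ped$animal_id)
  out
}

#' Simulate breed-divergent founder haplotype pools
#'
#' Ancestral frequencies are uniform on `base_freq_range`; each breed's
#' frequency is a Balding-Nichols Beta draw around the ancestral value with
#' divergence `F`.  Haplotypes are generated from a latent Gaussian AR(1)
#' copula with parameter `ld_rho` (reset at chromosome boundaries), giving
#' exponentially decaying LD between nearby markers.
#'
#' @param cfg a [sim_config].
#' @return list with `variants` (coordinate table), `base_freq`,
#'   `breed_freq` (matrix breeds x variants) and `pools` (per-breed 0/1
#'   haplotype matrices, `2 * n_founders[b]` rows).
#' @export
simulate_founder_haplotypes <- function(cfg) {
  m <- cfg$n_variants * cfg$n_chromosomes
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), each = cfg$n_variants)
  pos <- as.vector(vapply(seq_len(cfg$n_chromosomes), function(cc)
    sort(sample.int(cfg$chrom_length_bp, cfg$n_variants)),
    integer(cfg$n_variants)))
  variants <- data.frame(
    variant_id = sprintf("chr%s_%d", chrom, pos), chrom = chrom, pos = pos,
    ref = "A", alt = "B", stringsAsFactors = FALSE)
  p0 <- stats::runif(m, cfg$base_freq_range[1], cfg$base_freq_range[2])
  F <- cfg$breed_divergence_F
  breeds <- names(cfg$n_founders)
  breed_freq <- t(vapply(breeds, function(b)
    stats::rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F), numeric(m)))
  rownames(breed_freq) <- breeds
  # guard against fixation so every variant can segregate somewhere
  breed_freq <- pmin(pmax(breed_freq, 1e-4), 1 - 1e-4)
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-m])
  pools <- lapply(breeds, function(b) {
    nh <- 2L * cfg$n_founders[[b]]
    thr <- stats::qnorm(breed_freq[b, ])
    z <- matrix(0, nh, m)
    z[, 1L] <- stats::rnorm(nh)
    r <- cfg$ld_rho; s <- sqrt(1 - r^2)
    for (j in 2L:m)
      z[, j] <- if (new_chrom[j]) stats::rnorm(nh) else
        r * z[, j - 1L] + s * stats::rnorm(nh)
    h <- matrix(0L, nh, m)
    h[sweep(z, 2L, thr, "<")] <- 1L
    h
  })
  names(pools) <- breeds
  list(variants = variants, base_freq = p0, breed_freq = breed_freq,
       pools = pools)
}

# one recombinant gamete from a parent's haplotype pair, per chromosome:
# crossover count ~ Poisson(length in Morgans), positions uniform in bp
meiosis <- function(h1, h2, pos, chrom_index, len_bp, len_morgans) {
  gam <- integer(length(pos))
  for (cc in unique(chrom_index)) {
    jj <- which(chrom_index == cc)
    k <- stats::rpois(1L, len_morgans)
    start <- sample.int(2L, 1L)
    if (k == 0L) {
      gam[jj] <- if (start == 1L) h1[jj] else h2[jj]
    } else {
      xo <- sort(stats::runif(k, 0, len_bp))
      seg <- (start - 1L + findInterval(pos[jj], xo)) %% 2L
      gam[jj] <- ifelse(seg == 0L, h1[jj], h2[jj])
    }
  }
  gam
}

#' Drop founder haplotypes through a pedigree
#'
#' Founders receive consecutive haplotype pairs from their breed's pool
#' (unlabelled founders draw from a pool mixing the breeds equally); every
#' non-founder inherits one recombinant gamete from each parent.  Dosage is
#' the haplotype sum, so parent-offspring pairs are Mendelian-consistent by
#' construction.
#'
#' @param ped a [pedigree].
#' @param fh founder haplotypes from [simulate_founder_haplotypes].
#' @param cfg a [sim_config].
#' @return A [genotype_matrix]; haplotypes are kept in attribute
#'   `"haplotypes"` (list of two animals x variants 0/1 matrices).
#' @export
gene_drop <- function(ped, fh, cfg) {
  m <- nrow(fh$variants)
  n <- nrow(ped)
  pos <- fh$variants$pos
  chrom_index <- match(fh$variants$chrom, unique(fh$variants$chrom))
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  rownames(H1) <- rownames(H2) <- ped$animal_id
  used <- stats::setNames(rep(0L, length(fh$pools)), names(fh$pools))
  idx <- stats::setNames(seq_len(n), ped$animal_id)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      b <- ped$breed[i]
      if (is.na(b)) b <- sample(names(fh$pools), 1L)
      pool <- fh$pools[[b]]
      if (used[b] + 2L > nrow(pool))
        stop("founder haplotype pool for breed ", b, " exhausted")
      H1[i, ] <- pool[used[b] + 1L, ]
      H2[i, ] <- pool[used[b] + 2L, ]
      used[b] <- used[b] + 2L
    } else {
      s <- idx[[ped$sire_id[i]]]; d <- idx[[ped$dam_id[i]]]
      H1[i, ] <- meiosis(H1[s, ], H2[s, ], pos, chrom_index,
                         cfg$chrom_length_bp, cfg$chrom_length_morgans)
      H2[i, ] <- meiosis(H1[d, ], H2[d, ], pos, chrom_index,
                         cfg$chrom_length_bp, cfg$chrom_length_morgans)
    }
  }
  g <- genotype_matrix(H1 + H2, fh$variants, ped$animal_id)
  attr(g, "haplotypes") <- list(H1, H2)
  g
}

# sample() protected against the length-1 integer gotcha
sample1 <- function(x) x[sample.int(length(x), 1L)]

# choose causal variant indices among sufficiently common variants
pick_causal <- function(g, n, min_maf) {
  f <- maf(g)
  ok <- which(!is.na(f$maf) & f$maf >= min_maf)
  if (length(ok) < n) stop("not enough variants at MAF >= ", min_maf)
  sort(ok[sample.int(length(ok), n)])
}

#' Simulate a quantitative trait over a genotyped pedigree
#'
#' `y = sum_j beta_j (g_j - mean) + u + e`, with polygenic values `u` drawn
#' with covariance `(h2 * sigma2_P - sum_j 2 p_j q_j beta_j^2) * A` through
#' a symmetric factor of `A`, and `e` i.i.d. with variance
#' `(1 - h2) * sigma2_P`.  Planted QTL count toward the additive budget; a
#' configuration whose planted variance exceeds `h2 * sigma2_P` is an
#' error.  When `qtl` is not given, `n_qtl` variants are drawn at random
#' among those with realized MAF at or above `min_qtl_maf`, each with
#' `beta = sqrt(qtl_var_frac * sigma2_P / (2 p q))`.
#'
#' @param g a [genotype_matrix].
#' @param A numerator relationship matrix over the same animals.
#' @param trait a [trait_spec].
#' @param A_factor optional upper-triangular Cholesky factor of
#'   `A + 1e-8 I` (as returned by `chol`), reusable across replicate draws
#'   on the same pedigree.
#' @return list with `phenotypes` (data.frame `animal_id`, `y`) and `truth`
#'   (causal table, per-animal breeding values, variance bookkeeping).
#' @export
simulate_phenotype <- function(g, A, trait = trait_spec(), A_factor = NULL) {
  n <- nrow(g$dosages)
  qtl <- trait$qtl
  if (is.null(qtl) && trait$n_qtl > 0) {
    idx <- pick_causal(g, trait$n_qtl, trait$min_qtl_maf)
    f <- maf(g)$alt_freq[idx]
    beta <- sqrt(trait$qtl_var_frac * trait$sigma2_P / (2 * f * (1 - f)))
    qtl <- data.frame(variant_index = idx, beta = beta)
  } else if (is.null(qtl)) {
    qtl <- data.frame(variant_index = integer(), beta = numeric())
  }
  v_qtl <- 0; g_eff <- numeric(n)
  if (nrow(qtl)) {
    X <- g$dosages[, qtl$variant_index, drop = FALSE]
    f <- colMeans(X) / 2
    v_qtl <- sum(2 * f * (1 - f) * qtl$beta^2)
    g_eff <- drop(scale(X, center = TRUE, scale = FALSE) %*% qtl$beta)
  }
  v_poly <- trait$h2 * trait$sigma2_P - v_qtl
  if (v_poly < -1e-12)
    stop("planted causal variance (", signif(v_qtl, 4),
         ") exceeds the additive budget h2 * sigma2_P = ",
         signif(trait$h2 * trait$sigma2_P, 4))
  v_poly <- max(v_poly, 0)
  u <- numeric(n)
  if (v_poly > 0) {
    L <- if (is.null(A_factor)) chol(A + diag(1e-8, n)) else A_factor
    u <- sqrt(v_poly) * drop(crossprod(L, stats::rnorm(n)))
  }
  e <- stats::rnorm(n, sd = sqrt((1 - trait$h2) * trait$sigma2_P))
  y <- g_eff + u + e
  qtl$variant_id <- g$variants$variant_id[qtl$variant_index]
  list(
    phenotypes = data.frame(animal_id = g$animal_ids, y = y,
                            stringsAsFactors = FALSE),
    truth = list(qtl = qtl, breeding_values = g_eff + u,
                 v_qtl = v_qtl, v_poly = v_poly,
                 h2 = trait$h2, sigma2_P = trait$sigma2_P))
}

#' Simulate negative-binomial expression counts with planted cis-eQTL
#'
#' For each gene, counts over the expression cohort follow
#' `NB(mean = s_i * exp(mean_log + b * g_ij), dispersion alpha)` where
#' `g_ij` is the causal-variant dosage and `s_i` a sample size factor.
#' Each gene's cis window is centred on its causal variant.  The cohort is
#' a random subset of the genotyped animals.
#'
#' @param g a [genotype_matrix].
#' @param espec an [expression_spec].
#' @param samples optional explicit character vector of cohort animal ids.
#' @param causal optional explicit causal variants (ids or column indices),
#'   one per gene; drawn at random among common variants when omitted.
#' @return list with `counts` (gene x sample matrix), `genes` (windows and
#'   causal variants), `size_factors`, `truth`.
#' @export
simulate_expression <- function(g, espec = expression_spec(), samples = NULL,
                                causal = NULL) {
  if (is.null(samples)) {
    ns <- min(espec$n_samples, length(g$animal_ids))
    samples <- sort(sample(g$animal_ids, ns))
  }
  idx <- if (is.null(causal)) {
    pick_causal(g, espec$n_genes, espec$min_eqtl_maf)
  } else {
    if (is.character(causal)) causal <- match(causal, g$variants$variant_id)
    if (anyNA(causal) || length(causal) != espec$n_genes)
      stop("causal must name one known variant per gene")
    as.integer(causal)
  }
  half <- espec$window_bp / 2
  genes <- data.frame(
    gene_id = sprintf("gene%02d", seq_len(espec$n_genes)),
    chrom = g$variants$chrom[idx],
    window_start = pmax(1, g$variants$pos[idx] - half),
    window_end = g$variants$pos[idx] + half - 1,
    causal_variant = g$variants$variant_id[idx],
    log_fold = espec$log_fold,
    stringsAsFactors = FALSE)
  sf <- stats::runif(length(samples), espec$size_factor_range[1],
                     espec$size_factor_range[2])
  names(sf) <- samples
  dose <- g$dosages[samples, idx, drop = FALSE]
  counts <- matrix(0L, espec$n_genes, length(samples),
                   dimnames = list(genes$gene_id, samples))
  for (k in seq_len(espec$n_genes)) {
    mu <- sf * exp(espec$mean_log + espec$log_fold * dose[, k])
    counts[k, ] <- stats::rnbinom(length(samples), size = 1 / espec$dispersion,
                                  mu = mu)
  }
  list(counts = counts, genes = genes, size_factors = sf,
       truth = list(genes = genes, dispersion = espec$dispersion))
}

#' Simulate a complete population
#'
#' Runs pedigree, founder-haplotype, gene-drop, phenotype and expression
#' simulation in a documented order from a single seed, and builds the
#' numerator relationship matrix.  Everything downstream is reproducible
#' bit-for-bit from `(cfg, seed)`.
#'
#' @param cfg a [sim_config].
#' @param seed integer seed.
#' @return list of class `sim_output`: `pedigree`, `genotypes`, `A`,
#'   `phenotypes`, `expression`, `truth`.
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  fh <- simulate_founder_haplotypes(cfg)
  g <- gene_drop(ped, fh, cfg)
  A <- build_numerator_relationship(ped)
  phe <- simulate_phenotype(g, A, cfg$trait)
  expr <- simulate_expression(g, cfg$expression)
  structure(list(pedigree = ped, genotypes = g, A = A,
                 phenotypes = phe$phenotypes, expression = expr,
                 truth = list(trait = phe$truth, expression = expr$truth,
                              founder_freq = fh$breed_freq),
                 config = cfg, seed = seed),
            class = "sim_output")
}
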