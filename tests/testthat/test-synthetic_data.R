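test_that("simulate_pedigree: generations, bookkeeping, determinism", {
  cfg <- sim_config(n_founders = c(HF = 8, J = 8), n_generations = 0,
                    n_variants = 10)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 16L)
  expect_true(all(ped$founder))
  expect_equal(build_numerator_relationship(ped), diag(16),
               ignore_attr = "dimnames")

  cfg <- sim_config(n_founders = c(HF = 8, J = 8), n_generations = 3,
                    matings_per_generation = 25, n_variants = 10)
  set.seed(1); p1 <- simulate_pedigree(cfg)
  set.seed(1); p2 <- simulate_pedigree(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # closed-form cohort size: founders + generations x matings
  expect_equal(nrow(p1), 16L + 3L * 25L)
  gen <- attr(p1, "generation")
  expect_equal(as.integer(table(gen)), c(16L, 25L, 25L, 25L))

  expect_error(simulate_pedigree(sim_config(n_founders = c(HF = 0, J = 0))),
               "founder")
})

test_that("founder haplotypes follow the divergence model", {
  m <- 10000
  cfg <- sim_config(n_founders = c(HF = 30, J = 30), n_variants = m,
                    chrom_length_bp = 1e8, breed_divergence_F = 0.1,
                    ld_rho = 0)
  set.seed(2)
  fh <- simulate_founder_haplotypes(cfg)
  expect_true(all(fh$breed_freq >= 0 & fh$breed_freq <= 1))
  expect_equal(dim(fh$pools$HF), c(60L, m))
  expect_true(all(fh$pools$HF %in% 0:1))
  # moment check: Var(p_b | p) = F p (1-p) under Balding-Nichols
  dev2 <- (fh$breed_freq["HF", ] - fh$base_freq)^2
  expected <- 0.1 * fh$base_freq * (1 - fh$base_freq)
  expect_lt(abs(mean(dev2) / mean(expected) - 1), 0.2)

  # near-zero divergence: breed frequencies hug the base frequencies
  cfg0 <- sim_config(n_founders = c(HF = 5, J = 5), n_variants = 2000,
                     chrom_length_bp = 1e7, breed_divergence_F = 1e-6)
  set.seed(3)
  fh0 <- simulate_founder_haplotypes(cfg0)
  expect_lt(max(abs(fh0$breed_freq["J", ] - fh0$base_freq)), 0.01)
})

test_that("LD control produces correlated adjacent markers", {
  cfg <- sim_config(n_founders = c(HF = 150, J = 0), n_variants = 300,
                    ld_rho = 0.95, breed_divergence_F = 0.01)
  set.seed(4)
  fh <- simulate_founder_haplotypes(cfg)
  h <- fh$pools$HF
  adj <- sapply(seq_len(ncol(h) - 1), function(j)
    suppressWarnings(cor(h[, j], h[, j + 1])))
  expect_gt(mean(adj, na.rm = TRUE), 0.5)

  cfg$ld_rho <- 0
  set.seed(4)
  fh0 <- simulate_founder_haplotypes(cfg)
  h0 <- fh0$pools$HF
  adj0 <- sapply(seq_len(ncol(h0) - 1), function(j)
    suppressWarnings(cor(h0[, j], h0[, j + 1])))
  expect_lt(abs(mean(adj0, na.rm = TRUE)), 0.05)
})

test_that("gene_drop transmits intact haplotypes at zero map length", {
  cfg <- sim_config(n_founders = c(HF = 6, J = 6), n_generations = 2,
                    matings_per_generation = 12, n_variants = 80,
                    chrom_length_morgans = 0)
  set.seed(5)
  ped <- simulate_pedigree(cfg)
  fh <- simulate_founder_haplotypes(cfg)
  g <- gene_drop(ped, fh, cfg)
  H <- attr(g, "haplotypes")
  idx <- setNames(seq_len(nrow(ped)), ped$animal_id)
  for (i in which(!ped$founder)) {
    s <- idx[[ped$sire_id[i]]]
    gam <- H[[1]][i, ]
    expect_true(identical(gam, H[[1]][s, ]) || identical(gam, H[[2]][s, ]))
  }
  # founder dosages equal assigned haplotype sums
  f1 <- which(ped$founder)[1]
  expect_equal(g$dosages[f1, ], H[[1]][f1, ] + H[[2]][f1, ],
               ignore_attr = "names")
  # Mendelian-consistent by construction
  expect_equal(sum(mendel_concordance(ped, g)$n_conflicts), 0L)
})

test_that("simulate_phenotype respects the variance budget and h2 partition", {
  # h2 = 0, no QTL: y is pure residual with variance sigma2_P
  d <- matrix(sample(0:2, 2000 * 2, TRUE), 2000)
  g <- toy_genotypes(d)
  set.seed(6)
  phe <- simulate_phenotype(g, A = diag(2000),
                            trait = trait_spec(h2 = 0, sigma2_P = 4, n_qtl = 0))
  expect_lt(abs(var(phe$phenotypes$y) / 4 - 1), 0.1)

  # budget violation is an error
  big <- trait_spec(h2 = 0.1, sigma2_P = 1,
                    qtl = data.frame(variant_index = 1L, beta = 10))
  expect_error(simulate_phenotype(g, diag(2000), big), "budget")

  # determinism given seed
  set.seed(7); y1 <- simulate_phenotype(g, diag(2000))$phenotypes$y
  set.seed(7); y2 <- simulate_phenotype(g, diag(2000))$phenotypes$y
  expect_identical(y1, y2)
})

test_that("at h2 = 1 with no residual, phenotype covariance tracks A", {
  sim <- small_sim()
  ped <- subset(as.data.frame(sim$pedigree), TRUE)
  n <- nrow(sim$A)
  A <- sim$A
  g <- sim$genotypes
  L <- chol(A + diag(1e-8, n))
  set.seed(8)
  reps <- 400
  Y <- matrix(0, reps, n)
  tr <- trait_spec(h2 = 1, sigma2_P = 1, n_qtl = 0)
  for (r in seq_len(reps))
    Y[r, ] <- simulate_phenotype(g, A, tr, A_factor = L)$phenotypes$y
  C <- crossprod(Y) / reps            # E[y] = 0, so raw second moment
  lt <- lower.tri(A)
  slope <- coef(lm(C[lt] ~ A[lt]))[2]
  expect_gt(slope, 0.85); expect_lt(slope, 1.15)
})

test_that("parent-offspring regression recovers about h2 / 2", {
  set.seed(9)
  cfg <- sim_config(n_founders = c(HF = 40, J = 40), n_generations = 3,
                    matings_per_generation = 300, n_variants = 200,
                    trait = trait_spec(h2 = 0.6, sigma2_P = 1, n_qtl = 0))
  ped <- simulate_pedigree(cfg)
  fh <- simulate_founder_haplotypes(cfg)
  g <- gene_drop(ped, fh, cfg)
  A <- build_numerator_relationship(ped)
  phe <- simulate_phenotype(g, A, cfg$trait)
  y <- setNames(phe$phenotypes$y, phe$phenotypes$animal_id)
  pairs <- as.data.frame(ped)[!ped$founder, c("animal_id", "sire_id", "dam_id")]
  child <- c(y[pairs$animal_id], y[pairs$animal_id])
  parent <- c(y[pairs$sire_id], y[pairs$dam_id])
  slope <- coef(lm(child ~ parent))[2]
  expect_lt(abs(slope - 0.3), 0.1)    # h2/2 = 0.3 within Monte-Carlo error
})

test_that("simulate_expression produces NB counts with the planted signal", {
  sim <- small_sim()
  e <- sim$expression
  expect_true(all(e$counts >= 0))
  expect_true(all(e$counts == round(e$counts)))
  expect_equal(ncol(e$counts), 80L)    # configured cohort size
  expect_true(all(colnames(e$counts) %in% sim$genotypes$animal_ids))

  # planted allelic fold change visible on raw means
  gene <- e$genes[1, ]
  dose <- sim$genotypes$dosages[colnames(e$counts), gene$causal_variant]
  m0 <- mean(e$counts[gene$gene_id, dose == 0])
  m2 <- mean(e$counts[gene$gene_id, dose == 2])
  if (is.finite(m0) && is.finite(m2) && m0 > 0)
    expect_gt(m2 / m0, exp(2 * gene$log_fold) * 0.5)
})

test_that("whole populations are reproducible bit-for-bit from (config, seed)", {
  cfg <- sim_config(n_founders = c(HF = 6, J = 6), n_generations = 2,
                    matings_per_generation = 15, n_variants = 50,
                    expression = expression_spec(n_genes = 1, n_samples = 20))
  s1 <- simulate_population(cfg, seed = 123)
  s2 <- simulate_population(cfg, seed = 123)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$expression$counts, s2$expression$counts)
  s3 <- simulate_population(cfg, seed = 124)
  expect_false(identical(s1$phenotypes, s3$phenotypes))
})
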