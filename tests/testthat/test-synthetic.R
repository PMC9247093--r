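test_that("cohort generator is deterministic and validates its spec", {
  spec <- cohort_sim_spec(n_individuals = 500, n_snps = 20, seed = 9)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(a$seed, 9)
  expect_s3_class(a$spec, "cohort_sim_spec")

  # depot positivity and required columns
  expect_true(all(a$cohort$vat > 0 & a$cohort$asat > 0 & a$cohort$gfat > 0))
  expect_true(all(c("sample_id", "sex", "age", "bmi", "height", "center",
                    "array", "PC1", "PC10") %in% names(a$cohort)))

  expect_error(cohort_sim_spec(effects = data.frame(
    snp = "rs1", trait = "nope", stratum = "combined", beta = 1)), "unknown")
  expect_error(simulate_cohort(cohort_sim_spec(
    n_individuals = 100, n_snps = 5, seed = 1,
    effects = data.frame(snp = "rs99", trait = "vat",
                         stratum = "combined", beta = 0.1))), "unknown SNP")
})

test_that("generated allele frequencies converge to the spec frequencies", {
  sim <- simulate_cohort(cohort_sim_spec(n_individuals = 4000, n_snps = 50,
                                         seed = 10))
  emp <- colMeans(sim$genotypes) / 2
  se <- sqrt(sim$maf * (1 - sim$maf) / (2 * nrow(sim$genotypes)))
  z <- (emp - sim$maf) / se
  # calibration of the standardized errors rather than a max bound, which is
  # not stable over 50 simultaneous binomial draws
  expect_lt(abs(mean(z)), 0.5)
  expect_gt(sqrt(mean(z^2)), 0.7)
  expect_lt(sqrt(mean(z^2)), 1.5)
})

test_that("planted SNP effects shift the right trait in the right stratum", {
  eff <- data.frame(snp = c("rs1", "rs2"), trait = c("vat", "gfat"),
                    stratum = c("combined", "female"), beta = c(0.5, 0.6))
  sim <- simulate_cohort(cohort_sim_spec(n_individuals = 6000, n_snps = 10,
                                         effects = eff, seed = 11))
  co <- sim$cohort
  # vat effect present in both sexes
  for (sx in c("male", "female")) {
    sel <- co$sex == sx
    fit <- coef(lm(co$vat[sel] ~ sim$genotypes[sel, "rs1"]))[2]
    expect_gt(fit, 0.2)
  }
  # gfat effect only in females
  fem <- co$sex == "female"
  fit_f <- coef(lm(co$gfat[fem] ~ sim$genotypes[fem, "rs2"]))[2]
  fit_m <- coef(lm(co$gfat[!fem] ~ sim$genotypes[!fem, "rs2"]))[2]
  expect_gt(fit_f, 0.5)
  expect_lt(abs(fit_m), 0.3)
})

test_that("summary-statistic generator has the stated moments and structure", {
  # zero loading matrices -> pure noise, z has mean ~0, variance ~1
  spec0 <- cluster_sim_spec(n_variants = 200, n_traits = 10, k = 2,
                            A_true = matrix(0, 200, 2),
                            B_true = matrix(0, 2, 10), seed = 15)
  ss0 <- simulate_summary_stats(spec0)
  expect_lt(abs(mean(ss0$z)), 0.05)
  expect_lt(abs(sd(ss0$z) - 1), 0.05)

  # rank-1 spec with vanishing noise gives numerical rank 1
  a <- matrix(runif(50, 1, 2), 50, 1)
  b <- matrix(runif(6, 1, 2), 1, 6)
  ss1 <- simulate_summary_stats(cluster_sim_spec(
    n_variants = 50, n_traits = 6, k = 1, A_true = a, B_true = b,
    noise_sd = 1e-8, seed = 16))
  sv <- svd(ss1$z)$d
  expect_gt(sv[1] / max(sv[2], 1e-300), 1e6)

  # beta/se reproduce z; se = 1/sqrt(N)
  ss <- simulate_summary_stats(cluster_sim_spec(seed = 17))
  t1 <- ss$stats$T01
  expect_equal(t1$BETA / t1$SE, unname(ss$z[, "T01"]))
  expect_equal(t1$SE, rep(1 / sqrt(ss$n_per_trait[["T01"]]), nrow(t1)))

  # determinism and invalid K
  ss2 <- simulate_summary_stats(cluster_sim_spec(seed = 17))
  expect_identical(ss$z, ss2$z)
  expect_error(cluster_sim_spec(n_variants = 5, n_traits = 3, k = 4), "k must")
})

test_that("burden generator plants carriers, masks and effects deterministically", {
  genes <- data.frame(gene = c("GL", "GM"), f_l = c(1e-3, 0),
                      f_m = c(1e-3, 1.5e-3), effect = c(1, 0))
  spec <- burden_sim_spec(genes, n_individuals = 3000, seed = 18)
  a <- simulate_gene_burden_data(spec)
  b <- simulate_gene_burden_data(spec)
  expect_identical(as.matrix(a$genotypes), as.matrix(b$genotypes))
  expect_identical(a$phenotype, b$phenotype)

  # gene with f_l = 0 has only missense variants (weight 1 downstream)
  gm_ann <- a$annotations[a$annotations$gene == "GM", ]
  expect_true(all(gm_ann$class == "missense_5of5"))
  bm <- gene_burden_matrix(a$genotypes, a$annotations)
  expect_equal(unname(bm$freqs$weight_missense[bm$freqs$gene == "GM"]), 1)

  # testable gene guaranteed >= 10 carriers
  expect_gte(a$gene_truth$n_carriers[a$gene_truth$gene == "GL"], 10)

  expect_error(burden_sim_spec(data.frame(gene = "x", f_l = 0.3, f_m = 0.3)),
               "0.5")
})

test_that("sex-stratified generator induces the requested estimate correlation", {
  sim <- simulate_sex_stratified_stats(n_snps = 4000, est_corr = 0.5,
                                       n_dimorphic = 100, dimorphic_delta = 0.1,
                                       seed = 19)
  noise_m <- sim$male$BETA - sim$truth$beta_male
  noise_f <- sim$female$BETA - sim$truth$beta_female
  expect_lt(abs(cor(noise_m, noise_f) - 0.5), 0.05)
  expect_equal(sim$truth$beta_male[1] - sim$truth$beta_female[1], 0.1)
  expect_equal(sim$truth$beta_male[101], sim$truth$beta_female[101])
})
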