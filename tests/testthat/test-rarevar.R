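test_that("genotype-call filter applies every depth and quality clause", {
  calls <- data.frame(
    genotype = c("het", "hom_ref", "het", "hom_ref", "hom_alt", "hom_alt",
                 "het", "missing", "hom_ref"),
    dp = c(9, 30, 50, 30, 30, 30, 300, 40, 30),
    gq = c(99, 40, 99, 15, 99, 99, 99, 99, 40),
    alt_ratio = c(0.5, 0.05, 0.15, 0.05, 0.95, 0.8, 0.5, 0.5, 0.05),
    pl_ref = c(60, 0, 60, 0, 60, 60, 60, 60, 0),
    stringsAsFactors = FALSE
  )
  out <- genotype_call_filter(calls)
  expect_equal(out, c(
    "set_missing",  # DP = 9 <= 10
    "keep",         # clean hom_ref
    "set_missing",  # het with alt ratio 0.15 < 0.2
    "set_missing",  # hom_ref with GQ 15 <= 20
    "keep",         # clean hom_alt
    "set_missing",  # hom_alt with alt ratio 0.8 < 0.9
    "set_missing",  # DP = 300 >= 200
    "set_missing",  # already missing
    "keep"))        # hom_ref boundary alt ratio exactly 0.1 kept

  # het with low PL_ref dropped
  expect_equal(genotype_call_filter(data.frame(
    genotype = "het", dp = 50, gq = 99, alt_ratio = 0.5, pl_ref = 10)),
    "set_missing")

  # missing quality field -> set_missing, with message
  expect_message(out2 <- genotype_call_filter(data.frame(
    genotype = "het", dp = 50, gq = 99, alt_ratio = NA, pl_ref = 60)),
    "missing quality")
  expect_equal(out2, "set_missing")

  # idempotent: applying the filter to its own output changes nothing
  calls2 <- calls
  calls2$genotype[out == "set_missing"] <- "missing"
  out3 <- genotype_call_filter(calls2)
  expect_equal(out3 == "set_missing", out == "set_missing")
})

test_that("variant-level QC drops excluded, HWE-violating, low-call, monomorphic sites", {
  variants <- data.frame(
    variant_id = c("ok", "lowcall", "hwe", "mono", "inbed"),
    chrom = c("1", "1", "2", "2", "3"),
    pos = c(100, 200, 300, 400, 5000),
    n_aa = c(900, 800, 500, 1000, 900),
    n_ab = c(95, 60, 0, 0, 95),
    n_bb = c(5, 4, 500, 0, 5),
    n_missing = c(0, 136, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  bed <- data.frame(chrom = "3", start = 4000, end = 6000)
  qc <- rare_variant_qc(variants, exclusion = bed)
  expect_equal(qc$keep, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_lt(qc$call_rate[2], 0.9)
  expect_lt(qc$hwe_p[3], 1e-15)
  expect_true(qc$monomorphic[4])
  expect_true(qc$excluded_region[5])
})

test_that("missense weight follows the frequency-ratio formula with cap", {
  expect_equal(missense_weight(0.001, 0.001), 1)    # equal frequencies
  expect_equal(missense_weight(0, 0.002), 1)        # no pLoF variants
  w <- missense_weight(4e-4, 1.6e-3)
  expect_equal(round(w, 4), 0.5003)
  expect_equal(w, sqrt((4e-4 * (1 - 4e-4)) / (1.6e-3 * (1 - 1.6e-3))))
  expect_equal(missense_weight(0.01, 0.001), 1)     # capped at 1

  # monotone: non-decreasing in f_l, non-increasing in f_m
  grid <- seq(1e-4, 4e-1, length.out = 25)
  w_l <- missense_weight(grid, 0.2)
  expect_true(all(diff(w_l) >= 0))
  w_m <- missense_weight(0.2, grid)
  expect_true(all(diff(w_m) <= 0))

  expect_error(missense_weight(0.001, 0), "inconsistent")
  expect_error(missense_weight(1, 0.5))
})

test_that("burden scores weight, cap and ignore missing calls", {
  geno <- rbind(
    s1 = c(1, 0, 0, 0),    # one pLoF allele
    s2 = c(0, 1, 0, 0),    # one missense allele
    s3 = c(0, 1, 1, 1),    # three missense alleles
    s4 = c(NA, 0, 0, 0),   # missing call contributes 0
    s5 = c(0, 0, 0, 0)
  )
  geno <- rbind(geno, matrix(0, 4000, 4))  # make the variants rare
  rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  colnames(geno) <- c("v_lof", "v_m1", "v_m2", "v_m3")
  ann <- data.frame(variant_id = colnames(geno), gene = "G1",
                    class = c("pLoF_HC", rep("missense_5of5", 3)))
  bm <- gene_burden_matrix(geno, ann, mask = "plof_missense")
  w <- bm$freqs$weight_missense
  expect_equal(unname(bm$scores["s1", "G1"]), 1)          # pLoF weight 1
  expect_equal(unname(bm$scores["s2", "G1"]), w)          # one missense
  expect_equal(unname(bm$scores["s3", "G1"]), min(1, 3 * w))
  expect_equal(unname(bm$scores["s4", "G1"]), 0)          # missing -> 0, retained
  expect_equal(unname(bm$n_carriers["G1"]), 3)

  # capped at one even when weights are forced high
  geno3 <- geno
  geno3["s3", c("v_m1", "v_m2", "v_m3")] <- 2
  bm3 <- gene_burden_matrix(geno3, ann, mask = "plof_missense")
  expect_lte(max(bm3$scores), 1)

  # pLoF-only mask ignores missense carriers
  bm_l <- gene_burden_matrix(geno, ann, mask = "plof")
  expect_equal(unname(bm_l$n_carriers["G1"]), 1)

  # invariant to variant order and duplicated zero-carrier variants
  geno_shuf <- geno[, c(3, 1, 4, 2)]
  bm_shuf <- gene_burden_matrix(geno_shuf, ann, mask = "plof_missense")
  expect_equal(bm_shuf$scores, bm$scores)
  geno_dup <- cbind(geno, v_zero = 0)
  ann_dup <- rbind(ann, data.frame(variant_id = "v_zero", gene = "G1",
                                   class = "missense_5of5"))
  bm_dup <- gene_burden_matrix(geno_dup, ann_dup, mask = "plof_missense")
  expect_equal(bm_dup$scores, bm$scores)

  # common variants (MAF >= 0.1%) never qualify
  geno_common <- geno
  geno_common[, "v_lof"] <- rbinom(nrow(geno), 2, 0.05)
  bm_c <- gene_burden_matrix(geno_common, ann, mask = "plof")
  expect_equal(unname(bm_c$n_carriers["G1"]), 0)

  expect_error(gene_burden_matrix(geno, transform(ann, variant_id = paste0(variant_id, "x"))),
               "absent")
})

test_that("burden association enforces the 10-carrier floor and recovers effects", {
  set.seed(41)
  genes <- data.frame(gene = c("BIG", "SMALL"),
                      f_l = c(2e-3, 2e-4), f_m = c(3e-3, 0),
                      effect = c(0.9, 0))
  genes$testable <- c(TRUE, FALSE)
  sim <- simulate_gene_burden_data(burden_sim_spec(genes, n_individuals = 4000,
                                                   seed = 42))
  bm <- gene_burden_matrix(sim$genotypes, sim$annotations)
  ba <- burden_association(bm, sim$phenotype, covariates = sim$covariates,
                           sex = sim$sex)
  comb <- ba[ba$stratum == "combined", ]
  expect_true("BIG" %in% comb$gene)
  big <- comb[comb$gene == "BIG", ]
  expect_lt(abs(big$beta - 0.9), 3 * big$se)
  # genes below the carrier floor are excluded from that stratum
  small_carriers <- bm$n_carriers["SMALL"]
  if (small_carriers < 10) expect_false("SMALL" %in% comb$gene)
  expect_true(all(c("male", "female") %in% ba$stratum))
  expect_true(is.numeric(attr(ba, "exome_wide_threshold")))
})
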