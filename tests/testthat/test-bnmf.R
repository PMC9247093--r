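make_two_trait_stats <- function(z1, z2, n1 = 100, n2 = 400) {
  snp <- paste0("rs", seq_along(z1))
  list(
    T1 = sumstat_frame(snp, beta = z1 / sqrt(n1), se = 1 / sqrt(n1),
                       n = n1, trait = "T1"),
    T2 = sumstat_frame(snp, beta = z2 / sqrt(n2), se = 1 / sqrt(n2),
                       n = n2, trait = "T2")
  )
}

test_that("signed z matrix splits, scales and aligns as specified", {
  # split rule: z row (2.5, -2.0) -> T1_pos 2.5, T2_neg 2.0
  st <- make_two_trait_stats(z1 = c(2.5, 3), z2 = c(-2.0, 4), n1 = 400, n2 = 400)
  sz <- build_signed_z_matrix(c("rs1", "rs2"), st, "T1",
                              n_snps_for_bonferroni = 2)
  expect_equal(unname(sz$X["rs1", c("T1_pos", "T1_neg", "T2_pos", "T2_neg")]),
               c(2.5, 0, 0, 2.0))
  expect_true(all(sz$X >= 0))
  # at most one of pos/neg nonzero per variant-trait
  expect_true(all(sz$X[, "T1_pos"] * sz$X[, "T1_neg"] == 0))

  # sample-size scaling: z 3 at N 100 scaled by sqrt(400/100) -> 6
  st2 <- make_two_trait_stats(z1 = c(3, 5), z2 = c(4, 6), n1 = 100, n2 = 400)
  sz2 <- build_signed_z_matrix(c("rs1", "rs2"), st2, "T2",
                               n_snps_for_bonferroni = 2)
  med <- median(c(100, 400))
  expect_equal(unname(sz2$Z["rs1", "T1"]), 3 * sqrt(med / 100))
  expect_equal(unname(sz2$Z["rs1", "T2"]), 4 * sqrt(med / 400))

  # doubling all sample sizes leaves the scaled matrix unchanged
  st2b <- make_two_trait_stats(z1 = c(3, 5), z2 = c(4, 6), n1 = 200, n2 = 800)
  sz2b <- build_signed_z_matrix(c("rs1", "rs2"), st2b, "T2",
                                n_snps_for_bonferroni = 2)
  expect_equal(sz2b$Z, sz2$Z)

  # negative primary z flips the whole row before splitting
  st3 <- make_two_trait_stats(z1 = c(-3, 3), z2 = c(4, 4), n1 = 400, n2 = 400)
  sz3 <- build_signed_z_matrix(c("rs1", "rs2"), st3, "T1",
                               n_snps_for_bonferroni = 2)
  expect_equal(unname(sz3$Z["rs1", ]), c(3, -4))
  expect_gt(sz3$Z["rs1", "T1"], 0)
})

test_that("signed z pipeline filters variants and traits", {
  # leads not nominally associated with the primary are dropped
  st <- make_two_trait_stats(z1 = c(5, 0.5, 4), z2 = c(3, 3, 3),
                             n1 = 400, n2 = 400)
  sz <- build_signed_z_matrix(c("rs1", "rs2", "rs3"), st, "T1",
                              n_snps_for_bonferroni = 3)
  expect_equal(sz$variants, c("rs1", "rs3"))
  expect_true("rs2" %in% sz$dropped$variants)

  # LD pruning keeps the lower primary p of a correlated pair
  ld <- ld_table(data.frame(snp_a = "rs1", snp_b = "rs3", r2 = 0.5))
  sz_ld <- build_signed_z_matrix(c("rs1", "rs2", "rs3"), st, "T1", ld = ld,
                                 n_snps_for_bonferroni = 3)
  expect_equal(sz_ld$variants, "rs1")

  # traits without any |z| above the Bonferroni quantile are dropped
  st_weak <- make_two_trait_stats(z1 = c(6, 7, 8), z2 = c(0.5, 0.3, -0.4),
                                  n1 = 400, n2 = 400)
  sz_w <- build_signed_z_matrix(c("rs1", "rs2", "rs3"), st_weak, "T1",
                                n_snps_for_bonferroni = 100)
  expect_equal(sz_w$traits, "T1")
  expect_true("T2" %in% sz_w$dropped$traits)

  # highly correlated trait pair collapses to the lower-min-p member
  z <- c(6, 7, 8, 5, 9)
  st_cor <- make_two_trait_stats(z1 = z, z2 = z * 1.02, n1 = 400, n2 = 400)
  st_cor$T2$P <- st_cor$T2$P * 0.5   # T2 has the lower minimum p: kept
  sz_c <- build_signed_z_matrix(paste0("rs", 1:5), st_cor, "T1",
                                n_snps_for_bonferroni = 5)
  expect_equal(sz_c$traits, "T2")

  # beta exactly zero on the primary trait drops the variant with a message
  st_z <- make_two_trait_stats(z1 = c(0, 6), z2 = c(3, 3), n1 = 400, n2 = 400)
  expect_message(sz_z <- build_signed_z_matrix(c("rs1", "rs2"), st_z, "T1",
                                               n_snps_for_bonferroni = 2),
                 "alignment undefined")
  expect_equal(sz_z$variants, "rs2")

  # missing summary statistics are an error, not silently zero-filled
  st_miss <- make_two_trait_stats(z1 = c(5, 6), z2 = c(3, 3),
                                  n1 = 400, n2 = 400)
  st_miss$T2 <- st_miss$T2[1, , drop = FALSE]
  expect_error(build_signed_z_matrix(c("rs1", "rs2"), st_miss, "T1"),
               "missing")
})

test_that("noiseless rank-1 matrix recovers K = 1 with tiny reconstruction error", {
  set.seed(21)
  a <- runif(30, 1, 2)
  b <- runif(8, 0.5, 2)
  X <- outer(a, b)
  rownames(X) <- paste0("v", 1:30)
  colnames(X) <- paste0("t", 1:8)
  fit <- fit_bnmf_ard(X, K0 = 8, n_restarts = 10, seed = 2)
  expect_equal(fit$modal_k, 1)
  recon <- t(fit$best$W %*% fit$best$H)
  expect_lt(max(abs(recon - X)), 1e-3)
  expect_lt(mean((recon - X)^2), 1e-6)
})

test_that("objective is non-increasing and restarts are reproducible", {
  set.seed(22)
  ss <- simulate_summary_stats(cluster_sim_spec(n_variants = 40, n_traits = 10,
                                                k = 2, seed = 8))
  sz <- build_signed_z_matrix(names(ss$labels), ss$stats, "T01")
  fit <- fit_bnmf_ard(sz, K0 = 10, n_restarts = 5, seed = 31)
  expect_true(all(diff(fit$best$trace) <= 1e-8 * abs(fit$best$trace[-1])))
  fit2 <- fit_bnmf_ard(sz, K0 = 10, n_restarts = 5, seed = 31)
  expect_identical(fit$restarts, fit2$restarts)
  expect_identical(fit$best$W, fit2$best$W)
  expect_true(all(fit$best$W >= 0), all(fit$best$H >= 0))
  expect_lte(fit$best$K, 10)
})

test_that("planted clusters are recovered and summaries rank structure", {
  ss <- simulate_summary_stats(cluster_sim_spec(seed = 13))
  sz <- build_signed_z_matrix(names(ss$labels), ss$stats, "T01")
  fit <- fit_bnmf_ard(sz, n_restarts = 25, seed = 14)
  expect_equal(fit$modal_k, 3)
  summ <- summarize_clusters(fit)
  truth <- ss$labels[names(summ$assignments)]
  expect_gte(mclust::adjustedRandIndex(summ$assignments, truth), 0.8)

  # top-weighted split-traits of each cluster match the generator's block
  for (k in seq_len(summ$k)) {
    vars_k <- names(summ$assignments)[summ$assignments == k]
    true_k <- as.integer(names(sort(table(truth[vars_k]), decreasing = TRUE))[1])
    block_traits <- colnames(ss$z)[ss$B_true[true_k, ] > 0]
    top <- names(summ$trait_rankings[[k]])[seq_len(4)]
    top_base <- sub("_(pos|neg)$", "", top)
    expect_gte(length(intersect(top_base, block_traits)), 3)
  }

  # rankings are non-increasing
  for (k in seq_len(summ$k)) {
    expect_true(all(diff(summ$trait_rankings[[k]]) <= 0))
    expect_true(all(diff(summ$variant_rankings[[k]]) <= 0))
  }

  # K = 1 solution puts everything in one cluster
  one <- summarize_clusters(list(W = matrix(1, 4, 1),
                                 H = matrix(runif(6), 1, 6,
                                            dimnames = list(NULL, paste0("v", 1:6)))))
  expect_true(all(one$assignments == 1))
})
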