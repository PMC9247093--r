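# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: naive loops, direct normal equations,
# explicit enumeration.

# Naive greedy clumping: literal restatement of the rule with a row-by-row
# scan, independent of ld_clump()'s vectorized path.
naive_clump <- function(stats, ld, cfg) {
  s <- stats
  s$assigned <- FALSE
  loci <- list()
  repeat {
    cand <- s[!s$assigned & s$P < cfg$p1, ]
    if (!nrow(cand)) break
    cand <- cand[order(cand$P, cand$CHR, cand$BP), ]
    lead <- cand[1, ]
    s$assigned[s$SNP == lead$SNP] <- TRUE
    members <- character(0)
    for (i in seq_len(nrow(s))) {
      if (s$assigned[i] || s$P[i] >= cfg$p2) next
      if (s$CHR[i] != lead$CHR) next
      if (abs(s$BP[i] - lead$BP) > cfg$window_kb * 1000) next
      if (ld_r2(ld, lead$SNP, s$SNP[i]) <= cfg$r2) next
      s$assigned[i] <- TRUE
      members <- c(members, s$SNP[i])
    }
    loci[[length(loci) + 1L]] <- list(lead = lead$SNP, members = sort(members))
  }
  loci
}

# Exhaustive HWE exact test: enumerate every genotype configuration with the
# observed allele counts, probability from first-principles multinomial
# counting (number of ways to arrange genotypes and alleles).
enumerate_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_alt <- 2 * n_bb + n_ab
  hets <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  weight <- vapply(hets, function(h) {
    bb <- (n_alt - h) / 2
    aa <- n - h - bb
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)) * 2^h
  }, numeric(1))
  prob <- weight / sum(weight)
  obs <- prob[match(n_ab, hets)]
  sum(prob[prob <= obs * (1 + 1e-10)])
}

# Small deterministic cohort for unit tests
toy_cohort <- function(n_per_sex = 20, seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_sex
  sex <- rep(c("male", "female"), each = n_per_sex)
  data.frame(
    sample_id = paste0("s", seq_len(n)),
    sex = sex,
    age = round(runif(n, 45, 80)),
    bmi = rnorm(n, 27, 3),
    height = rnorm(n, ifelse(sex == "male", 176, 163), 6),
    vat = exp(rnorm(n, log(ifelse(sex == "male", 4.5, 2.5)), 0.3)),
    asat = exp(rnorm(n, log(ifelse(sex == "male", 5.5, 7.5)), 0.3)),
    gfat = exp(rnorm(n, log(ifelse(sex == "male", 9, 11)), 0.2)),
    stringsAsFactors = FALSE
  )
}

sumstat_frame <- function(snp, beta, se = 0.01, ea = "A", oa = "G",
                          chr = 1, bp = seq_along(snp) * 1e6,
                          n = 10000, trait = "trait", stratum = "combined") {
  data.frame(CHR = chr, BP = bp, SNP = snp, EA = ea, OA = oa, EAF = 0.3,
             BETA = beta, SE = se,
             P = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
             N = n, TRAIT = trait, STRATUM = stratum, stringsAsFactors = FALSE)
}
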