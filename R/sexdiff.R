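#' Genome-wide Spearman correlation of sex-stratified effects
#'
#' Spearman rank correlation between male and female effect sizes across all
#' shared tested SNPs of a trait, the correlation term used by the
#' sex-heterogeneity test to account for the non-independence of
#' sex-stratified estimates. Alleles are aligned before comparison (a record
#' with swapped effect/other alleles has its beta sign-flipped); computed once
#' per trait over all shared SNPs, not per locus.
#'
#' @param male_stats,female_stats Summary statistics data frames with columns
#'   `SNP`, `EA`, `OA`, `BETA`.
#' @return Spearman correlation coefficient (average-rank ties).
#' @export
effect_rank_correlation <- function(male_stats, female_stats) {
  m <- merge(male_stats[, c("SNP", "EA", "OA", "BETA")],
             female_stats[, c("SNP", "EA", "OA", "BETA")],
             by = "SNP", suffixes = c("_m", "_f"))
  same <- m$EA_m == m$EA_f & m$OA_m == m$OA_f
  flipped <- m$EA_m == m$OA_f & m$OA_m == m$EA_f
  if (any(!same & !flipped)) {
    stop("allele mismatch between male and female records", call. = FALSE)
  }
  if (nrow(m) < 10) {
    stop("need at least 10 shared SNPs to estimate the effect correlation",
         call. = FALSE)
  }
  beta_f <- ifelse(flipped, -m$BETA_f, m$BETA_f)
  stats::cor(m$BETA_m, beta_f, method = "spearman")
}

#' Sex-heterogeneity test for a genetic effect
#'
#' Tests whether a variant's effect differs between males and females using
#' the correlation-adjusted statistic
#' \deqn{t = \frac{\beta_m - \beta_f}
#'   {\sqrt{se_m^2 + se_f^2 - 2 r \, se_m se_f}}}
#' where `r` is the genome-wide Spearman correlation between sex-stratified
#' effects (see [effect_rank_correlation()]). With biobank-scale sample sizes
#' the statistic is referred to the standard normal; `p_diff` is the two-sided
#' tail probability.
#'
#' @param beta_male,se_male,beta_female,se_female Sex-stratified effect sizes
#'   and standard errors (vectors are recycled together).
#' @param r Genome-wide effect correlation, shared across SNPs (-1 < r < 1).
#' @param snp_id Optional SNP identifiers carried through to the output.
#' @return Data frame with the inputs plus `t` and `p_diff`.
#' @export
sex_heterogeneity_test <- function(beta_male, se_male, beta_female, se_female,
                                   r, snp_id = NULL) {
  stopifnot(length(r) == 1, r >= -1, r <= 1,
            all(se_male > 0), all(se_female > 0))
  v <- se_male^2 + se_female^2 - 2 * r * se_male * se_female
  if (any(v <= 0)) {
    stop("degenerate denominator: se_m^2 + se_f^2 - 2*r*se_m*se_f <= 0",
         call. = FALSE)
  }
  t <- (beta_male - beta_female) / sqrt(v)
  out <- data.frame(
    snp_id = if (is.null(snp_id)) seq_along(t) else snp_id,
    beta_male = beta_male, se_male = se_male,
    beta_female = beta_female, se_female = se_female,
    r = r, t = t, p_diff = 2 * stats::pnorm(-abs(t)),
    stringsAsFactors = FALSE
  )
  out
}

#' Classify loci by the stratum driving significance
#'
#' Assigns each locus to `combined` (genome-wide significant in the
#' sex-combined analysis), `male_only` (significant in males but in neither
#' females nor sex-combined), `female_only` (the mirror image) or `none`.
#' Every locus must be present in all three strata. The Bonferroni threshold
#' for declaring sex dimorphism, 0.05 divided by the number of tested
#' locus-trait pairs, is attached as attribute `"dimorphism_threshold"`.
#'
#' @param combined,male,female Data frames with columns `SNP` and `P` covering
#'   the same loci.
#' @param threshold Genome-wide significance threshold (default 5e-8).
#' @return Data frame with `snp_id` and `class`.
#' @export
classify_sex_specific_loci <- function(combined, male, female,
                                       threshold = 5e-8) {
  snps <- combined$SNP
  miss_m <- setdiff(snps, male$SNP)
  miss_f <- setdiff(snps, female$SNP)
  extra <- unique(c(setdiff(male$SNP, snps), setdiff(female$SNP, snps)))
  if (length(miss_m) || length(miss_f) || length(extra)) {
    stop("locus missing a stratum: ",
         paste(utils::head(unique(c(miss_m, miss_f, extra)), 5), collapse = ", "),
         call. = FALSE)
  }
  p_c <- combined$P[match(snps, combined$SNP)]
  p_m <- male$P[match(snps, male$SNP)]
  p_f <- female$P[match(snps, female$SNP)]
  class <- ifelse(p_c < threshold, "combined",
           ifelse(p_m < threshold & p_f >= threshold, "male_only",
           ifelse(p_f < threshold & p_m >= threshold, "female_only", "none")))
  out <- data.frame(snp_id = snps, class = class, stringsAsFactors = FALSE)
  attr(out, "dimorphism_threshold") <- 0.05 / length(snps)
  out
}
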