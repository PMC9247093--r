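#' Hardy-Weinberg exact test
#'
#' Exact (Levene-Haldane) two-sided p-value for deviation from Hardy-Weinberg
#' equilibrium, computed by summing the probabilities of all heterozygote
#' counts compatible with the observed allele counts that are no more probable
#' than the observed configuration. The exact tail is essential here because
#' variant QC applies an extreme threshold (p < 1e-15) where the chi-square
#' approximation is unusable.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (hom-ref, het, hom-alt).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(length(n_aa) == 1, length(n_ab) == 1, length(n_bb) == 1,
            n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_bb + n_ab   # minor-side allele count (use alt; symmetric)
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  # heterozygote count shares parity with the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) - lfactorial(hom_common) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(het_obs, hets)] * (1 + 1e-10)])
}

#' Common-variant quality control
#'
#' Filters a dosage matrix using the array-variant or imputed-variant rules.
#' Array mode keeps variants with minor allele frequency >= `maf_min` (default
#' 1\%), Hardy-Weinberg exact p > `hwe_min` (default 1e-15, computed on
#' hard-called genotypes) and call rate >= `call_rate_min` (default 99\%).
#' Imputed mode drops variants with MAF < 0.005 or imputation INFO < 0.3.
#'
#' @param genotypes Numeric matrix (samples x variants) of dosages in [0, 2];
#'   `NA` denotes a missing call. Column names identify variants.
#' @param mode `"array"` or `"imputed"`.
#' @param info Numeric vector of INFO scores (imputed mode only).
#' @param maf_min,hwe_min,call_rate_min,info_min Filter thresholds.
#' @return Data frame with one row per variant: `variant`, `maf`, `call_rate`,
#'   `hwe_p` (array mode), `info` (imputed mode) and logical `keep`.
#' @export
variant_qc_common <- function(genotypes, mode = c("array", "imputed"),
                              info = NULL,
                              maf_min = if (match.arg(mode) == "array") 0.01 else 0.005,
                              hwe_min = 1e-15, call_rate_min = 0.99,
                              info_min = 0.3) {
  mode <- match.arg(mode)
  genotypes <- as.matrix(genotypes)
  rng <- range(genotypes, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(genotypes)))
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  call_rate <- colMeans(!is.na(genotypes))
  out <- data.frame(variant = ids, maf = maf, call_rate = call_rate,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (mode == "array") {
    hard <- round(genotypes)
    out$hwe_p <- vapply(seq_len(ncol(hard)), function(j) {
      g <- hard[, j]
      hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                     sum(g == 2, na.rm = TRUE))
    }, numeric(1))
    out$keep <- out$maf >= maf_min & out$hwe_p > hwe_min &
      out$call_rate >= call_rate_min
  } else {
    if (is.null(info)) stop("imputed mode requires an INFO vector", call. = FALSE)
    stopifnot(length(info) == ncol(genotypes))
    out$info <- info
    out$keep <- !(out$maf < maf_min | info < info_min)
  }
  out
}

#' Covariate-adjusted association scan
#'
#' Per-variant least-squares association of an inverse-normal-transformed trait
#' with genotype dosage, adjusting for covariates. The fit is computed by
#' residualizing trait and dosages on the covariates (with intercept) and
#' regressing residual on residual, which is numerically identical to the full
#' multiple regression; BETA, SE and the two-sided t-test p-value are reported
#' for the dosage coefficient. Missing dosages are mean-imputed per variant.
#' Variants with zero dosage variance after imputation are skipped (`NA` row);
#' near-perfect fits are flagged `degenerate`.
#'
#' @param genotypes Numeric matrix (samples x variants) of dosages in [0, 2].
#' @param trait Numeric vector, typically from [rank_inverse_normal()].
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (age, age squared, sex, PCs, ...). An intercept is always included.
#' @return Data frame with `SNP`, `EAF`, `BETA`, `SE`, `P`, `N` and logical
#'   `degenerate`; skipped variant ids are attached as attribute `"skipped"`.
#' @export
association_scan <- function(genotypes, trait, covariates = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  stopifnot(length(trait) == n)
  if (n < 30) stop("association_scan() needs at least 30 individuals", call. = FALSE)
  C <- if (is.null(covariates)) matrix(1, n, 1) else cbind(1, as.matrix(covariates))
  use <- is.finite(trait) & stats::complete.cases(C)
  if (!all(use)) {
    message("dropping ", sum(!use), " individuals with missing trait/covariates")
    genotypes <- genotypes[use, , drop = FALSE]
    trait <- trait[use]
    C <- C[use, , drop = FALSE]
    n <- sum(use)
  }
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("v", seq_len(ncol(genotypes)))

  eaf <- colMeans(genotypes, na.rm = TRUE) / 2
  # mean-impute missing dosages per variant
  if (anyNA(genotypes)) {
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- (2 * eaf)[idx[, 2]]
  }

  qr_c <- qr(C)
  p_cov <- qr_c$rank
  y_res <- qr.resid(qr_c, trait)
  g_res <- qr.resid(qr_c, genotypes)

  gg <- colSums(g_res^2)
  skip <- gg < 1e-12
  gy <- drop(crossprod(g_res, y_res))
  beta <- gy / gg
  df <- n - p_cov - 1
  rss <- sum(y_res^2) - beta^2 * gg
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / gg)
  tstat <- beta / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- rss <= 1e-10 * sum(y_res^2)

  out <- data.frame(SNP = ids, EAF = eaf, BETA = beta, SE = se, P = pval,
                    N = n, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[skip, c("BETA", "SE", "P")] <- NA_real_
  out$degenerate[skip] <- NA
  if (any(skip)) {
    message(sum(skip), " variant(s) skipped: zero dosage variance")
  }
  attr(out, "skipped") <- ids[skip]
  out
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}}: the median association chi-square statistic divided by
#' the null median of a 1-df chi-square (~0.4549).
#'
#' @param pvals Numeric vector of at least 100 p-values in (0, 1].
#' @return List with `lambda_gc` and `n_tested`.
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[is.finite(pvals)]
  if (length(pvals) < 100) {
    stop("genomic_inflation() needs at least 100 p-values", call. = FALSE)
  }
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  list(lambda_gc = stats::median(chisq) / stats::qchisq(0.5, df = 1),
       n_tested = length(pvals))
}

#' Bonferroni significance threshold
#'
#' Divides a familywise alpha sequentially by each supplied count (e.g. number
#' of tested genes, then number of analyses), returning the unrounded
#' threshold plus a two-significant-figure display form.
#'
#' @param alpha Familywise error rate in (0, 1).
#' @param counts Vector of positive integer test counts.
#' @return List with `threshold` (exact) and `display` (2 s.f.).
#' @export
bonferroni_threshold <- function(alpha, counts) {
  stopifnot(alpha > 0, alpha < 1, all(counts >= 1), all(counts == floor(counts)))
  threshold <- alpha / prod(counts)
  list(threshold = threshold, display = signif(threshold, 2))
}

#' Directional replication concordance
#'
#' Compares effect directions between this study and an external study on
#' allele-aligned lead SNPs and tests departure from 50\% concordance with a
#' two-sided exact binomial test,
#' \eqn{p = \min(1, 2 P(X \ge \max(k, n-k)))} for \eqn{X \sim Bin(n, 1/2)}.
#' Pairs with a zero effect in either source are excluded.
#'
#' @param beta_study,beta_external Signed effect sizes on the same effect
#'   allele, in the same SNP order.
#' @return List with `n_concordant`, `n_total`, `p_value`.
#' @export
replication_concordance <- function(beta_study, beta_external) {
  stopifnot(length(beta_study) == length(beta_external))
  zero <- beta_study == 0 | beta_external == 0
  if (any(zero)) {
    message("excluding ", sum(zero), " pair(s) with a zero effect size")
  }
  bs <- beta_study[!zero]
  be <- beta_external[!zero]
  n <- length(bs)
  if (!n) stop("no usable effect pairs", call. = FALSE)
  k <- sum(sign(bs) == sign(be))
  m <- max(k, n - k)
  p <- min(1, 2 * stats::pbinom(m - 1, n, 0.5, lower.tail = FALSE))
  list(n_concordant = k, n_total = n, p_value = p)
}
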