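#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector onto standard-normal quantiles of its (average) ranks,
#' the transform routinely applied to biobank phenotypes before association
#' testing. The quantile for rank \eqn{r} among \eqn{n} non-missing values is
#' \eqn{\Phi^{-1}((r - c) / (n - 2c + 1))} with offset \eqn{c = 0.5}, so the
#' output is symmetric about zero for symmetric rank configurations. Ties
#' receive the quantile of their average rank; missing values stay missing.
#'
#' @param x Numeric vector with at least two finite values.
#' @param offset Rank offset \eqn{c}; the default 0.5 is the common choice for
#'   biobank GWAS phenotypes.
#' @return Numeric vector of the same length as `x`, an order-preserving
#'   monotone transform of the ranks of `x`.
#' @examples
#' rank_inverse_normal(c(5, 1, 9))
#' @export
rank_inverse_normal <- function(x, offset = 0.5) {
  stopifnot(is.numeric(x))
  ok <- is.finite(x)
  n <- sum(ok)
  if (n < 2L) {
    stop("rank_inverse_normal() needs at least 2 finite values", call. = FALSE)
  }
  if (diff(range(x[ok])) == 0) {
    stop("all values identical: no rank variation to transform", call. = FALSE)
  }
  out <- rep(NA_real_, length(x))
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

validate_cohort <- function(cohort) {
  required <- c("sample_id", "sex", "age", "bmi", "height", "vat", "asat", "gfat")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cohort$sample_id)) {
    stop("duplicate sample_id in cohort table", call. = FALSE)
  }
  bad_sex <- !cohort$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("sex must be 'male' or 'female' for every row (",
         sum(bad_sex), " offending rows)", call. = FALSE)
  }
  depots <- as.matrix(cohort[, c("vat", "asat", "gfat")])
  if (any(depots <= 0, na.rm = TRUE)) {
    stop("depot volumes must be strictly positive", call. = FALSE)
  }
  invisible(cohort)
}

#' Derive local adiposity traits
#'
#' Computes the six derived local adiposity traits from raw depot volumes:
#' three "adj" traits (`vat_adj`, `asat_adj`, `gfat_adj`), the least-squares
#' residuals of each depot volume on age, age squared, BMI and height fitted
#' separately within each sex, and three dimensionless depot ratios
#' (`vat_asat`, `vat_gfat`, `asat_gfat`) taken on the raw volumes with no
#' residualization. Inverse-normal-transformed versions of all nine traits
#' (three raw depots, three adj, three ratios) are appended with an `_int`
#' suffix.
#'
#' Rows with a missing covariate (age, BMI or height) are dropped from the
#' corresponding within-sex fit and get `NA` adj values; within each sex the
#' adj traits have mean zero by construction.
#'
#' @param cohort Data frame with columns `sample_id`, `sex` ("male"/"female"),
#'   `age` (years), `bmi` (kg/m^2), `height` (cm) and depot volumes `vat`,
#'   `asat`, `gfat` in litres (strictly positive).
#' @return Data frame keyed by `sample_id` with the six derived traits plus
#'   `_int` columns for all nine adiposity traits.
#' @export
derive_local_adiposity <- function(cohort) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  out <- data.frame(sample_id = cohort$sample_id, stringsAsFactors = FALSE)
  depots <- c("vat", "asat", "gfat")
  for (d in depots) out[[paste0(d, "_adj")]] <- NA_real_

  for (sx in c("male", "female")) {
    in_sex <- cohort$sex == sx
    if (sum(in_sex) < 5L) {
      stop("need at least 5 individuals per sex for residualization (",
           sx, ": ", sum(in_sex), ")", call. = FALSE)
    }
    covs <- cohort[in_sex, c("age", "bmi", "height")]
    X <- cbind(1, covs$age, covs$age^2, covs$bmi, covs$height)
    for (d in depots) {
      y <- cohort[[d]][in_sex]
      use <- stats::complete.cases(X) & is.finite(y)
      qr_x <- qr(X[use, , drop = FALSE])
      if (qr_x$rank < ncol(X)) {
        stop("degenerate design for ", d, " in ", sx,
             ": covariates are collinear within sex", call. = FALSE)
      }
      res <- qr.resid(qr_x, y[use])
      col <- paste0(d, "_adj")
      idx <- which(in_sex)[use]
      out[[col]][idx] <- res
    }
  }

  out$vat_asat <- cohort$vat / cohort$asat
  out$vat_gfat <- cohort$vat / cohort$gfat
  out$asat_gfat <- cohort$asat / cohort$gfat

  nine <- list(
    vat = cohort$vat, asat = cohort$asat, gfat = cohort$gfat,
    vat_adj = out$vat_adj, asat_adj = out$asat_adj, gfat_adj = out$gfat_adj,
    vat_asat = out$vat_asat, vat_gfat = out$vat_gfat, asat_gfat = out$asat_gfat
  )
  for (nm in names(nine)) {
    out[[paste0(nm, "_int")]] <- rank_inverse_normal(nine[[nm]])
  }
  out
}

#' Collider-bias concordance diagnostic
#'
#' Adjusting a depot volume for BMI and height can induce spurious (collider)
#' associations at loci that act primarily on the adjustment covariates. As a
#' diagnostic, each genome-wide significant lead SNP of an adjusted trait is
#' checked for a strictly larger effect magnitude on the unadjusted depot
#' volume than on BMI: loci passing this check are unlikely to be
#' collider-driven.
#'
#' @param depot_stats Summary statistics (one row per lead SNP) for the raw
#'   depot volume, with columns `SNP`, `EA`, `OA`, `BETA`.
#' @param bmi_stats Summary statistics for BMI on the same SNPs, same columns.
#' @return Data frame with `snp_id`, `beta_depot_raw`, `beta_bmi` and logical
#'   `concordant` (TRUE iff `|beta_depot_raw| > |beta_bmi|`, ties discordant);
#'   the fraction concordant is attached as attribute `"fraction_concordant"`.
#' @export
collider_concordance <- function(depot_stats, bmi_stats) {
  m <- merge(depot_stats[, c("SNP", "EA", "OA", "BETA")],
             bmi_stats[, c("SNP", "EA", "OA", "BETA")],
             by = "SNP", suffixes = c("_depot", "_bmi"))
  if (!nrow(m)) stop("no shared SNPs between depot and BMI statistics", call. = FALSE)
  same <- m$EA_depot == m$EA_bmi & m$OA_depot == m$OA_bmi
  flipped <- m$EA_depot == m$OA_bmi & m$OA_depot == m$EA_bmi
  if (any(!same & !flipped)) {
    stop("allele mismatch between depot and BMI records for SNP(s): ",
         paste(utils::head(m$SNP[!same & !flipped], 5), collapse = ", "),
         call. = FALSE)
  }
  beta_bmi <- ifelse(flipped, -m$BETA_bmi, m$BETA_bmi)
  verdicts <- data.frame(
    snp_id = m$SNP,
    beta_depot_raw = m$BETA_depot,
    beta_bmi = beta_bmi,
    concordant = abs(m$BETA_depot) > abs(beta_bmi),
    stringsAsFactors = FALSE
  )
  attr(verdicts, "fraction_concordant") <- mean(verdicts$concordant)
  verdicts
}
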