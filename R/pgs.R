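#' Apply external polygenic-score weights
#'
#' Computes raw polygenic scores as the allele-aligned weighted sum of
#' dosages. When a weight row's effect allele matches the allele counted by
#' the dosage column the contribution is `weight * dosage`; when effect and
#' other alleles are swapped the dosage is flipped to `2 - dosage`;
#' unresolvable allele pairs are skipped and counted. Missing dosages are
#' replaced by the per-variant mean dosage.
#'
#' @param dosages Samples x variants dosage matrix with variant ids as column
#'   names.
#' @param weights Data frame with columns `SNP`, `EA`, `OA`, `WEIGHT`.
#' @param dosage_alleles Data frame with columns `SNP`, `EA`, `OA` describing
#'   the counted (`EA`) and other allele of each dosage column.
#' @return Numeric score vector (one per sample) with attributes
#'   `n_variants_used` and `n_variants_skipped`.
#' @export
apply_score <- function(dosages, weights, dosage_alleles) {
  stopifnot(all(c("SNP", "EA", "OA", "WEIGHT") %in% names(weights)),
            all(c("SNP", "EA", "OA") %in% names(dosage_alleles)))
  dosages <- as.matrix(dosages)
  m <- merge(weights, dosage_alleles, by = "SNP", suffixes = c("_w", "_d"))
  m <- m[m$SNP %in% colnames(dosages), , drop = FALSE]
  same <- m$EA_w == m$EA_d & m$OA_w == m$OA_d
  flipped <- m$EA_w == m$OA_d & m$OA_w == m$EA_d
  usable <- same | flipped
  n_skipped <- nrow(weights) - sum(usable)
  if (n_skipped > 0) {
    message(n_skipped, " weight variant(s) skipped (absent or unresolvable alleles)")
  }
  m <- m[usable, , drop = FALSE]
  score <- numeric(nrow(dosages))
  if (nrow(m)) {
    D <- dosages[, m$SNP, drop = FALSE]
    if (anyNA(D)) {
      mu <- colMeans(D, na.rm = TRUE)
      idx <- which(is.na(D), arr.ind = TRUE)
      D[idx] <- mu[idx[, 2]]
    }
    D[, flipped[usable]] <- 2 - D[, flipped[usable], drop = FALSE]
    score <- drop(D %*% m$WEIGHT)
  }
  attr(score, "n_variants_used") <- nrow(m)
  attr(score, "n_variants_skipped") <- n_skipped
  score
}

#' Residualize and percentile-rank a polygenic score
#'
#' Residualizes a raw score against genetic principal components by least
#' squares (so the residualized score is numerically uncorrelated with each
#' PC) and attaches percentile ranks. Ties in the score are broken by sample
#' order after a seeded shuffle, so ranks are uniform and reproducible.
#'
#' @param score Raw score vector, e.g. from [apply_score()].
#' @param pcs Matrix/data frame of principal components (may be `NULL`).
#' @param sample_id Optional identifiers.
#' @param seed Seed for the tie-breaking shuffle.
#' @return Data frame with `sample_id`, `score_raw`, `score_resid`,
#'   `percentile` (in (0, 1)).
#' @export
score_table <- function(score, pcs = NULL, sample_id = NULL, seed = 1) {
  n <- length(score)
  if (stats::var(score) == 0) {
    stop("constant score: percentiles are undefined", call. = FALSE)
  }
  resid <- if (is.null(pcs)) score - mean(score) else
    qr.resid(qr(cbind(1, as.matrix(pcs))), score)
  set.seed(seed)
  shuffle <- sample.int(n)
  r <- numeric(n)
  r[shuffle] <- rank(resid[shuffle], ties.method = "first")
  data.frame(sample_id = if (is.null(sample_id)) seq_len(n) else sample_id,
             score_raw = score, score_resid = resid,
             percentile = (r - 0.5) / n,
             stringsAsFactors = FALSE)
}

#' Phenotype-tail / score-tail enrichment
#'
#' Cross-tabulates membership in an empirical phenotype tail against
#' membership in a polygenic-score tail and reports the odds ratio with a
#' Woolf (log-scale normal) 95\% confidence interval. Tail membership is
#' strictly beyond the empirical (type-7) quantile. Zero cells get the
#' Haldane 0.5 continuity correction (logged via message).
#'
#' @param trait,score Numeric vectors on the same samples (complete).
#' @param trait_q,score_q Tail fractions (default 0.05).
#' @param trait_tail,score_tail `"top"` or `"bottom"`.
#' @return List with `counts` (2x2: tail membership trait x score),
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `corrected`.
#' @export
tail_enrichment <- function(trait, score, trait_q = 0.05, score_q = 0.05,
                            trait_tail = c("top", "bottom"),
                            score_tail = c("top", "bottom")) {
  trait_tail <- match.arg(trait_tail)
  score_tail <- match.arg(score_tail)
  stopifnot(length(trait) == length(score))
  n <- length(trait)
  if (n < 200) stop("tail_enrichment() needs n >= 200", call. = FALSE)
  if (anyNA(trait) || anyNA(score)) stop("trait and score must be complete", call. = FALSE)
  in_tail <- function(x, q, side) {
    if (side == "top") x > stats::quantile(x, 1 - q, type = 7)
    else x < stats::quantile(x, q, type = 7)
  }
  t_in <- in_tail(trait, trait_q, trait_tail)
  s_in <- in_tail(score, score_q, score_tail)
  if (sum(t_in) < 5 || sum(s_in) < 5) {
    stop("tail smaller than 5 individuals", call. = FALSE)
  }
  a <- sum(t_in & s_in); b <- sum(t_in & !s_in)
  c_ <- sum(!t_in & s_in); d <- sum(!t_in & !s_in)
  counts <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                   dimnames = list(trait = c("tail", "rest"),
                                   score = c("tail", "rest")))
  corrected <- any(counts == 0)
  if (corrected) {
    message("zero cell: applying Haldane 0.5 continuity correction")
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c_)
  se_log <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(counts = counts, odds_ratio = or,
       ci_lower = exp(log(or) - 1.96 * se_log),
       ci_upper = exp(log(or) + 1.96 * se_log),
       corrected = corrected)
}

#' Outcome associations of extreme polygenic-score indicators
#'
#' Regresses each outcome on indicator variables for the top and bottom tails
#' of a (residualized) polygenic score, adjusting for covariates: linear
#' regression for continuous outcomes, logistic for binary (0/1) outcomes.
#' A binary outcome with zero events among a tail is reported non-estimable
#' for that tail.
#'
#' @param score Residualized score vector (see [score_table()]).
#' @param outcomes Data frame of outcomes (continuous or 0/1 binary).
#' @param covariates Matrix/data frame of covariates (age, sex, PCs, ...).
#' @param top_q,bottom_q Tail fractions (default 0.05 each).
#' @return Data frame with one row per outcome x tail: `outcome`, `tail`,
#'   `type`, `estimate` (beta or log-OR), `or` (binary only), `ci_lower`,
#'   `ci_upper`, `p`, `estimable`.
#' @export
extreme_score_outcome_association <- function(score, outcomes, covariates = NULL,
                                              top_q = 0.05, bottom_q = 0.05) {
  n <- length(score)
  stopifnot(nrow(outcomes) == n)
  top <- score > stats::quantile(score, 1 - top_q, type = 7)
  bottom <- score < stats::quantile(score, bottom_q, type = 7)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  res <- list()
  for (nm in names(outcomes)) {
    y <- outcomes[[nm]]
    binary <- all(y %in% c(0, 1, NA))
    X <- data.frame(top5 = as.numeric(top), bottom5 = as.numeric(bottom))
    if (!is.null(C)) X <- cbind(X, C)
    dat <- cbind(y = y, X)
    for (tail_nm in c("top5", "bottom5")) {
      idx <- if (tail_nm == "top5") top else bottom
      estimable <- !binary || (sum(y[idx], na.rm = TRUE) > 0 &&
                                 sum(1 - y[idx], na.rm = TRUE) > 0)
      if (!estimable) {
        res[[length(res) + 1L]] <- data.frame(
          outcome = nm, tail = tail_nm, type = "binary", estimate = NA_real_,
          or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
          p = NA_real_, estimable = FALSE, stringsAsFactors = FALSE)
        next
      }
      fit <- if (binary) stats::glm(y ~ ., data = dat, family = stats::binomial())
             else stats::lm(y ~ ., data = dat)
      sm <- summary(fit)$coefficients
      est <- sm[tail_nm, 1]; se <- sm[tail_nm, 2]; p <- sm[tail_nm, 4]
      res[[length(res) + 1L]] <- data.frame(
        outcome = nm, tail = tail_nm,
        type = if (binary) "binary" else "continuous",
        estimate = est,
        or = if (binary) exp(est) else NA_real_,
        ci_lower = if (binary) exp(est - 1.96 * se) else est - 1.96 * se,
        ci_upper = if (binary) exp(est + 1.96 * se) else est + 1.96 * se,
        p = p, estimable = TRUE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
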