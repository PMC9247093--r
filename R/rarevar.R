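#' Exome genotype-call quality filter
#'
#' Classifies each genotype call as `keep` or `set_missing` using the
#' depth/quality rules applied before rare-variant burden testing: a call is
#' set missing if read depth DP <= 10 or DP >= 200; if homozygous-reference
#' with genotype quality GQ <= 20 or alt-read ratio > 0.1; if heterozygous
#' with alt-read ratio < 0.2 or Phred likelihood of the reference allele
#' PL_ref < 20; if homozygous-alternate with alt-read ratio < 0.9 or
#' PL_ref < 20. Calls with a missing required quality field are set missing
#' (with a message), so the filter is total and idempotent.
#'
#' @param calls Data frame with columns `genotype` (one of `hom_ref`, `het`,
#'   `hom_alt`, `missing`), `dp`, `gq`, `alt_ratio`, `pl_ref`.
#' @return Character vector (`"keep"` / `"set_missing"`), one per call.
#' @export
genotype_call_filter <- function(calls) {
  stopifnot(all(c("genotype", "dp") %in% names(calls)))
  g <- calls$genotype
  stopifnot(all(g %in% c("hom_ref", "het", "hom_alt", "missing")))
  n <- nrow(calls)
  get_col <- function(nm) if (nm %in% names(calls)) calls[[nm]] else rep(NA_real_, n)
  dp <- calls$dp
  gq <- get_col("gq")
  ab <- get_col("alt_ratio")
  pl <- get_col("pl_ref")

  drop <- g == "missing"
  drop <- drop | is.na(dp) | dp <= 10 | dp >= 200
  need <- rep(FALSE, n)
  hr <- g == "hom_ref"
  need[hr] <- is.na(gq[hr]) | is.na(ab[hr])
  drop[hr] <- drop[hr] | (!need[hr] & (gq[hr] <= 20 | ab[hr] > 0.1))
  he <- g == "het"
  need[he] <- is.na(ab[he]) | is.na(pl[he])
  drop[he] <- drop[he] | (!need[he] & (ab[he] < 0.2 | pl[he] < 20))
  ha <- g == "hom_alt"
  need[ha] <- is.na(ab[ha]) | is.na(pl[ha])
  drop[ha] <- drop[ha] | (!need[ha] & (ab[ha] < 0.9 | pl[ha] < 20))
  if (any(need & !drop)) {
    message(sum(need & !drop), " call(s) with missing quality fields set missing")
  }
  drop <- drop | need
  ifelse(drop, "set_missing", "keep")
}

#' Rare-variant site-level quality control
#'
#' Drops a variant if it falls in a supplied exclusion region (e.g.
#' low-complexity or segmental-duplication intervals), deviates from
#' Hardy-Weinberg equilibrium with exact p < 1e-15, has post-filter call rate
#' below 90\%, or is monomorphic after genotype-call filtering.
#'
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), and post-filter genotype counts `n_aa`, `n_ab`, `n_bb`,
#'   `n_missing`.
#' @param exclusion Optional exclusion regions: a `GRanges`, or a data frame
#'   with `chrom`, `start`, `end` (1-based closed intervals, e.g. from
#'   [read_bed_regions()]).
#' @param hwe_min,call_rate_min Thresholds (defaults 1e-15 and 0.90).
#' @return Data frame with per-variant `call_rate`, `hwe_p`, `excluded_region`,
#'   `monomorphic` and logical `keep`.
#' @export
rare_variant_qc <- function(variants, exclusion = NULL,
                            hwe_min = 1e-15, call_rate_min = 0.90) {
  stopifnot(all(c("variant_id", "chrom", "pos", "n_aa", "n_ab", "n_bb",
                  "n_missing") %in% names(variants)))
  n_called <- variants$n_aa + variants$n_ab + variants$n_bb
  call_rate <- n_called / (n_called + variants$n_missing)
  hwe_p <- mapply(hwe_exact_test, variants$n_aa, variants$n_ab, variants$n_bb)
  monomorphic <- (variants$n_ab + variants$n_bb == 0) |
    (variants$n_aa + variants$n_ab == 0)

  in_region <- rep(FALSE, nrow(variants))
  if (!is.null(exclusion)) {
    excl_gr <- if (methods::is(exclusion, "GRanges")) exclusion else {
      stopifnot(all(c("chrom", "start", "end") %in% names(exclusion)))
      GenomicRanges::GRanges(exclusion$chrom,
                             IRanges::IRanges(exclusion$start, exclusion$end))
    }
    var_gr <- GenomicRanges::GRanges(variants$chrom,
                                     IRanges::IRanges(variants$pos, variants$pos))
    hits <- GenomicRanges::findOverlaps(var_gr, excl_gr)
    in_region[unique(S4Vectors::queryHits(hits))] <- TRUE
  }

  data.frame(variant_id = variants$variant_id,
             call_rate = call_rate, hwe_p = hwe_p,
             excluded_region = in_region, monomorphic = monomorphic,
             keep = !in_region & hwe_p >= hwe_min & call_rate >= call_rate_min &
               !monomorphic,
             stringsAsFactors = FALSE)
}

#' Missense mask weight from cumulative allele frequencies
#'
#' Gene-specific weight for damaging-missense variants relative to
#' high-confidence predicted loss-of-function (pLoF) variants:
#' \deqn{w = \min\!\left(1, \sqrt{\frac{f_L (1 - f_L)}{f_M (1 - f_M)}}\right)}
#' where \eqn{f_L} and \eqn{f_M} are the cumulative allele frequencies of the
#' gene's qualifying rare pLoF and missense variants. Genes with no
#' high-confidence pLoF variant (\eqn{f_L = 0}) get weight 1; pLoF variants
#' themselves always carry weight 1.
#'
#' @param f_l,f_m Cumulative allele frequencies in [0, 1), recycled together.
#' @return Numeric weight vector in (0, 1].
#' @export
missense_weight <- function(f_l, f_m) {
  stopifnot(all(f_l >= 0 & f_l < 1), all(f_m >= 0 & f_m < 1))
  if (any(f_m == 0 & f_l > 0)) {
    stop("inconsistent input: f_m = 0 but missense variants claimed for gene ",
         "with f_l > 0", call. = FALSE)
  }
  k <- max(length(f_l), length(f_m))
  f_l <- rep_len(f_l, k)
  f_m <- rep_len(f_m, k)
  w <- rep(1, k)
  nz <- f_l > 0
  w[nz] <- pmin(1, sqrt((f_l[nz] * (1 - f_l[nz])) / (f_m[nz] * (1 - f_m[nz]))))
  w
}

#' Per-gene weighted rare-variant burden scores
#'
#' Aggregates qualifying rare variants (cohort MAF < `max_af`, default 0.1\%)
#' into a per-sample, per-gene burden score: the allele-dosage-weighted sum of
#' qualifying variants, capped at 1. Under the `plof` mask only
#' high-confidence pLoF variants qualify (weight 1); under `plof_missense`,
#' 5/5-damaging missense variants additionally qualify with the gene-specific
#' weight of [missense_weight()] computed from cohort cumulative allele
#' frequencies. Samples with a missing call at a mask variant are retained
#' with that variant contributing 0.
#'
#' @param genotypes Samples x variants dosage matrix (0/1/2, `NA` missing);
#'   dense or `Matrix` sparse; column names are variant ids.
#' @param annotations Data frame with `variant_id`, `gene` and
#'   `class` in `pLoF_HC` / `missense_5of5`.
#' @param mask `"plof"` or `"plof_missense"`.
#' @param max_af Cohort allele-frequency ceiling for a qualifying variant.
#' @return List with `scores` (samples x genes matrix of capped scores),
#'   `n_carriers` (per gene), and `freqs` (per-gene `f_l`, `f_m`,
#'   `weight_missense`).
#' @export
gene_burden_matrix <- function(genotypes, annotations,
                               mask = c("plof_missense", "plof"),
                               max_af = 0.001) {
  mask <- match.arg(mask)
  stopifnot(all(c("variant_id", "gene", "class") %in% names(annotations)),
            all(annotations$class %in% c("pLoF_HC", "missense_5of5")))
  ids <- colnames(genotypes)
  missing_ids <- setdiff(annotations$variant_id, ids)
  if (length(missing_ids)) {
    stop("annotation variants absent from genotype matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(genotypes)
  n_called <- n - Matrix::colSums(is.na(genotypes))
  ac <- Matrix::colSums(genotypes, na.rm = TRUE)
  af <- ifelse(n_called > 0, ac / (2 * n_called), 0)
  names(af) <- ids

  ann <- annotations[af[annotations$variant_id] < max_af &
                       af[annotations$variant_id] > 0, , drop = FALSE]
  genes <- sort(unique(annotations$gene))
  freqs <- data.frame(gene = genes,
                      f_l = vapply(genes, function(g)
                        sum(af[ann$variant_id[ann$gene == g & ann$class == "pLoF_HC"]]),
                        numeric(1)),
                      f_m = vapply(genes, function(g)
                        sum(af[ann$variant_id[ann$gene == g & ann$class == "missense_5of5"]]),
                        numeric(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
  freqs$weight_missense <- ifelse(freqs$f_m > 0,
                                  missense_weight(freqs$f_l, pmax(freqs$f_m, 1e-300)),
                                  NA_real_)

  if (mask == "plof") ann <- ann[ann$class == "pLoF_HC", , drop = FALSE]
  scores <- matrix(0, n, length(genes), dimnames = list(rownames(genotypes), genes))
  for (g in genes) {
    va <- ann[ann$gene == g, , drop = FALSE]
    if (!nrow(va)) next
    w <- ifelse(va$class == "pLoF_HC", 1,
                freqs$weight_missense[match(g, freqs$gene)])
    G <- as.matrix(genotypes[, va$variant_id, drop = FALSE])
    G[is.na(G)] <- 0
    scores[, g] <- pmin(1, drop(G %*% w))
  }
  list(scores = scores,
       n_carriers = colSums(scores > 0),
       freqs = freqs)
}

#' Covariate-adjusted gene burden association
#'
#' Regresses an inverse-normal-transformed trait on each gene's burden score
#' plus covariates by least squares, sex-combined and (when `sex` is given)
#' sex-stratified. Genes with fewer than `min_carriers` carriers in a stratum
#' are excluded from that stratum before multiplicity accounting; exome-wide
#' (0.05 / genes tested) and study-wide (further divided by `n_analyses`)
#' thresholds are attached as attributes.
#'
#' @param burden Output of [gene_burden_matrix()], or a samples x genes score
#'   matrix.
#' @param trait Numeric vector (inverse-normal transformed).
#' @param covariates Numeric matrix/data frame of covariates (excluding sex).
#' @param sex Optional character vector ("male"/"female") enabling stratified
#'   runs; in the combined run sex is added as a covariate.
#' @param min_carriers Carrier floor for testing a gene (default 10).
#' @param n_analyses Divisor for the study-wide threshold (default 1).
#' @return Data frame with `gene`, `stratum`, `n_carriers`, `beta`, `se`,
#'   `p`, `unstable`; thresholds in attributes `exome_wide_threshold` and
#'   `study_wide_threshold`.
#' @export
burden_association <- function(burden, trait, covariates = NULL, sex = NULL,
                               min_carriers = 10, n_analyses = 1) {
  scores <- if (is.list(burden) && !is.null(burden$scores)) burden$scores else
    as.matrix(burden)
  n <- nrow(scores)
  stopifnot(length(trait) == n)
  strata <- list(combined = rep(TRUE, n))
  C_combined <- covariates
  if (!is.null(sex)) {
    stopifnot(length(sex) == n, all(sex %in% c("male", "female")))
    strata$male <- sex == "male"
    strata$female <- sex == "female"
    C_combined <- cbind(if (is.null(covariates)) NULL else as.matrix(covariates),
                        sex_male = as.numeric(sex == "male"))
  }

  res <- list()
  for (st in names(strata)) {
    idx <- strata[[st]]
    y <- trait[idx]
    S <- scores[idx, , drop = FALSE]
    C <- if (st == "combined") C_combined else covariates
    Cm <- if (is.null(C)) matrix(1, sum(idx), 1) else
      cbind(1, as.matrix(C)[idx, , drop = FALSE])
    carriers <- colSums(S > 0)
    testable <- carriers >= min_carriers
    if (!any(testable)) next
    qr_c <- qr(Cm)
    y_res <- qr.resid(qr_c, y)
    s_res <- qr.resid(qr_c, S[, testable, drop = FALSE])
    ss <- colSums(s_res^2)
    sy <- drop(crossprod(s_res, y_res))
    beta <- sy / ss
    df <- length(y) - qr_c$rank - 1
    rss <- pmax(sum(y_res^2) - beta^2 * ss, 0)
    se <- sqrt(rss / df / ss)
    p <- 2 * stats::pt(abs(beta / se), df, lower.tail = FALSE)
    unstable <- !is.finite(se) | se == 0 | ss < 1e-12
    if (any(unstable)) {
      warning(sum(unstable), " gene(s) flagged unstable in stratum ", st,
              call. = FALSE)
    }
    res[[st]] <- data.frame(gene = colnames(S)[testable], stratum = st,
                            n_carriers = carriers[testable],
                            beta = beta, se = se, p = p, unstable = unstable,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  n_genes <- length(unique(out$gene[out$stratum == "combined"]))
  if (!n_genes) n_genes <- length(unique(out$gene))
  ew <- bonferroni_threshold(0.05, n_genes)
  sw <- bonferroni_threshold(0.05, c(n_genes, n_analyses))
  attr(out, "exome_wide_threshold") <- ew$threshold
  attr(out, "study_wide_threshold") <- sw$threshold
  out
}
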