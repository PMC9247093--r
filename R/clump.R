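#' LD lookup table
#'
#' Wraps pairwise r-squared values for fast symmetric lookup during clumping,
#' pruning and novelty flagging. Accepts either a square matrix with SNP ids
#' as dimnames or a long-format data frame with columns `snp_a`, `snp_b`,
#' `r2`. Self-pairs always return 1; a pair of known SNPs with no recorded
#' entry returns 0 (independent); SNPs absent from the table altogether are
#' reported by [ld_has()].
#'
#' @param x Square numeric matrix with dimnames, or a data frame
#'   (`snp_a`, `snp_b`, `r2`).
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(x) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || !identical(rownames(x), colnames(x))) {
      stop("LD matrix needs identical row and column SNP names", call. = FALSE)
    }
    if (max(abs(x - t(x))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
    snps <- rownames(x)
    ut <- which(upper.tri(x) & x != 0, arr.ind = TRUE)
    a <- snps[ut[, 1]]; b <- snps[ut[, 2]]; r2 <- x[ut]
  } else {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(x)))
    a <- as.character(x$snp_a); b <- as.character(x$snp_b); r2 <- x$r2
    snps <- unique(c(a, b))
  }
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]", call. = FALSE)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  for (i in seq_along(key)) assign(key[i], r2[i], envir = env)
  structure(list(env = env, snps = snps), class = "ld_table")
}

#' @rdname ld_table
#' @param ld An `ld_table`.
#' @param snps Character vector of SNP ids.
#' @return `ld_has()`: logical vector, TRUE where the SNP appears in the table.
#' @export
ld_has <- function(ld, snps) {
  stopifnot(inherits(ld, "ld_table"))
  snps %in% ld$snps
}

#' @rdname ld_table
#' @param a Single SNP id.
#' @param b Character vector of SNP ids to pair with `a`.
#' @return `ld_r2()`: numeric vector of r-squared values (0 where unrecorded).
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"), length(a) == 1)
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  out <- vapply(key, function(k) {
    v <- get0(k, envir = ld$env, ifnotfound = 0)
    as.numeric(v)
  }, numeric(1), USE.NAMES = FALSE)
  out[b == a] <- 1
  out
}

#' Clumping configuration
#'
#' Parameter bundle for greedy LD clumping, defaulting to the standard PLINK
#' settings used for lead-SNP prioritization: index threshold `p1 = 5e-8`,
#' member threshold `p2 = 5e-6`, `r2 = 0.1`, window 1000 kb.
#'
#' @param p1,p2 Index and member p-value thresholds (`p1 <= p2`).
#' @param r2 Minimum r-squared with the index SNP for assignment (exclusive).
#' @param window_kb Physical window around the index SNP in kb.
#' @return List of class `clump_config`.
#' @export
clump_config <- function(p1 = 5e-8, p2 = 5e-6, r2 = 0.1, window_kb = 1000) {
  stopifnot(p1 > 0, p2 > 0, p1 <= p2, r2 > 0, r2 < 1, window_kb > 0)
  structure(list(p1 = p1, p2 = p2, r2 = r2, window_kb = window_kb),
            class = "clump_config")
}

#' Greedy LD clumping
#'
#' Partitions significant variants into loci by the greedy rule: repeatedly
#' take the lowest-p unassigned variant with `P < p1` as a lead, then assign
#' to it every unassigned variant with `P < p2`, within `window_kb` of the
#' lead on the same chromosome and with r-squared strictly greater than `r2`
#' with the lead; iterate until no candidate leads remain. Ties in p-value
#' are broken by ascending (CHR, BP) so output is deterministic. Missing LD
#' entries between known SNPs are treated as r-squared 0 (a warning reports
#' SNPs absent from the LD table entirely).
#'
#' @param stats Summary statistics with columns `CHR`, `BP`, `SNP`, `P`.
#' @param ld An [ld_table()].
#' @param cfg A [clump_config()].
#' @return List of loci; each locus is a list with `lead` (one-row data frame)
#'   and `members` (character vector of assigned SNP ids).
#' @export
ld_clump <- function(stats, ld, cfg = clump_config()) {
  stopifnot(inherits(cfg, "clump_config"),
            all(c("CHR", "BP", "SNP", "P") %in% names(stats)))
  if (anyDuplicated(stats$SNP)) stop("duplicate SNP ids in stats", call. = FALSE)
  absent <- !ld_has(ld, stats$SNP)
  if (any(absent)) {
    warning(sum(absent), " SNP(s) absent from the LD table; treating their ",
            "pairwise r2 as 0", call. = FALSE)
  }
  ord <- order(stats$P, stats$CHR, stats$BP)
  stats <- stats[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(stats))
  loci <- list()
  repeat {
    cand <- which(!assigned & stats$P < cfg$p1)
    if (!length(cand)) break
    i <- cand[1]
    assigned[i] <- TRUE
    lead <- stats[i, , drop = FALSE]
    pool <- which(!assigned & stats$P < cfg$p2 & stats$CHR == lead$CHR &
                    abs(stats$BP - lead$BP) <= cfg$window_kb * 1000)
    members <- character(0)
    if (length(pool)) {
      r2 <- ld_r2(ld, lead$SNP, stats$SNP[pool])
      hit <- pool[r2 > cfg$r2]
      assigned[hit] <- TRUE
      members <- stats$SNP[hit]
    }
    loci[[length(loci) + 1L]] <- list(lead = lead, members = members)
  }
  loci
}

#' Flag newly-identified loci
#'
#' A lead SNP is flagged novel when its maximum r-squared with every SNP in a
#' user-supplied catalog of previously reported associations is strictly below
#' `r2_threshold` (default 0.1; a value of exactly 0.1 counts as known). Leads
#' absent from the LD lookup are flagged `indeterminate`, never novel. An
#' empty catalog makes every resolvable lead novel.
#'
#' @param loci List of loci from [ld_clump()], or a character vector of lead
#'   SNP ids.
#' @param catalog_snps Character vector of catalog SNP ids.
#' @param ld An [ld_table()].
#' @param r2_threshold Novelty boundary (strict).
#' @return Data frame with `lead_snp`, `max_catalog_r2` and
#'   `status` in `novel` / `known` / `indeterminate`.
#' @export
flag_novel_loci <- function(loci, catalog_snps, ld, r2_threshold = 0.1) {
  leads <- if (is.character(loci)) loci else
    vapply(loci, function(l) l$lead$SNP, character(1))
  status <- character(length(leads))
  max_r2 <- rep(NA_real_, length(leads))
  for (i in seq_along(leads)) {
    if (!ld_has(ld, leads[i])) {
      status[i] <- "indeterminate"
      next
    }
    max_r2[i] <- if (length(catalog_snps)) max(ld_r2(ld, leads[i], catalog_snps)) else 0
    status[i] <- if (max_r2[i] < r2_threshold) "novel" else "known"
  }
  data.frame(lead_snp = leads, max_catalog_r2 = max_r2, status = status,
             stringsAsFactors = FALSE)
}
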