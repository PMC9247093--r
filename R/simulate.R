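#' Cohort simulation specification
#'
#' Parameters for [simulate_cohort()]. The defaults emulate the statistical
#' structure of a biobank MRI substudy: sex-specific depot volume means of
#' 5.0 (male) / 2.6 (female) litres for VAT, 5.9 / 7.9 for ASAT and
#' 9.3 / 11.3 for GFAT, with a latent shared-adiposity factor whose loadings
#' place the sex-combined depot-BMI Pearson correlation in the 0.77-0.88
#' band. Within-sex depot standard deviations and factor loadings are
#' documented package defaults (litres): VAT 2.5/1.4, ASAT 2.2/2.8,
#' GFAT 2.2/2.6 with loadings 0.97, 0.90, 0.90.
#'
#' @param n_individuals Cohort size (default 20000).
#' @param sex_fraction_female Fraction female (default 0.51).
#' @param depot_means,depot_sds 3 x 2 matrices (rows vat/asat/gfat, columns
#'   male/female), litres.
#' @param adiposity_loading Named vector of per-depot loadings on the shared
#'   adiposity factor, each in (0, 1).
#' @param bmi_mean,bmi_sd BMI distribution (kg/m^2), shared across sexes; BMI
#'   is taken as the observable proxy of the shared-adiposity factor.
#' @param height_mean,height_sd Named male/female height parameters (cm).
#' @param age_mean,age_sd,age_range Age distribution (years, truncated).
#' @param n_snps,maf_range Genotype panel size and allele-frequency range.
#' @param effects Optional planted-effect table with columns `snp`, `trait`
#'   (`vat`/`asat`/`gfat`/`bmi`), `stratum` (`combined`/`male`/`female`) and
#'   `beta` (per standardized-dosage, in within-sex depot-SD units).
#' @param n_pcs Number of synthetic genetic PCs (default 10).
#' @param floor_l Positivity floor for depot volumes in litres; generating
#'   means are analytically shifted so cell means equal `depot_means` in
#'   expectation despite flooring.
#' @param seed Seed recorded in the output metadata.
#' @return List of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_individuals = 20000,
                            sex_fraction_female = 0.51,
                            depot_means = matrix(c(5.0, 2.6, 5.9, 7.9, 9.3, 11.3),
                                                 nrow = 3, byrow = TRUE,
                                                 dimnames = list(c("vat", "asat", "gfat"),
                                                                 c("male", "female"))),
                            depot_sds = matrix(c(2.5, 1.4, 2.2, 2.8, 2.2, 2.6),
                                               nrow = 3, byrow = TRUE,
                                               dimnames = list(c("vat", "asat", "gfat"),
                                                               c("male", "female"))),
                            adiposity_loading = c(vat = 0.97, asat = 0.90, gfat = 0.90),
                            bmi_mean = 27.4, bmi_sd = 4.0,
                            height_mean = c(male = 175.6, female = 162.4),
                            height_sd = c(male = 6.8, female = 6.2),
                            age_mean = 64.5, age_sd = 7.5, age_range = c(44, 82),
                            n_snps = 100, maf_range = c(0.05, 0.5),
                            effects = NULL, n_pcs = 10, floor_l = 0.05,
                            seed = 1) {
  stopifnot(n_individuals >= 10, sex_fraction_female >= 0, sex_fraction_female <= 1,
            all(depot_sds > 0), bmi_sd > 0,
            all(adiposity_loading > 0 & adiposity_loading < 1),
            n_snps >= 1, maf_range[1] > 0, maf_range[2] < 1)
  if (!is.null(effects)) {
    stopifnot(all(c("snp", "trait", "stratum", "beta") %in% names(effects)))
    bad_trait <- !effects$trait %in% c("vat", "asat", "gfat", "bmi")
    bad_stratum <- !effects$stratum %in% c("combined", "male", "female")
    if (any(bad_trait) || any(bad_stratum)) {
      stop("effect table references unknown trait or stratum", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "cohort_sim_spec")
}

# mean of max(N(mu, s), floor)
floored_mean <- function(mu, s, floor) {
  z <- (floor - mu) / s
  mu + (floor - mu) * stats::pnorm(z) + s * stats::dnorm(z)
}

# generating mean such that the floored variable has expectation `target`
compensated_mean <- function(target, s, floor) {
  if (stats::pnorm((floor - target) / s) < 1e-12) return(target)
  stats::uniroot(function(mu) floored_mean(mu, s, floor) - target,
                 lower = target - 2 * s, upper = target + s)$root
}

#' Simulate a cohort with genotypes and planted effects
#'
#' Generates a cohort table (phenotypes, covariates) plus a genotype dosage
#' matrix from a [cohort_sim_spec()]. Genotypes are Binomial(2, MAF) per SNP;
#' each depot volume is its sex-specific mean plus within-sex SD times a
#' standardized component combining the shared-adiposity factor (which also
#' generates BMI), planted standardized genetic effects, and Gaussian noise.
#' Volumes are floored at `floor_l` litres with a mean-compensating shift so
#' cell means match the specification in expectation. The same spec and seed
#' always reproduce identical output.
#'
#' @param spec A [cohort_sim_spec()].
#' @return List of class `sim_cohort` with `cohort` (data frame: `sample_id`,
#'   `sex`, `age`, `bmi`, `height`, `vat`, `asat`, `gfat`, `center`, `array`,
#'   `PC1`..), `genotypes` (n x n_snps dosage matrix), `maf`, and the `spec`
#'   (seed included) as metadata.
#' @export
simulate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  sex <- ifelse(stats::runif(n) < spec$sex_fraction_female, "female", "male")
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                   spec$age_range[1]), spec$age_range[2])
  height <- stats::rnorm(n, spec$height_mean[sex], spec$height_sd[sex])

  maf <- stats::runif(spec$n_snps, spec$maf_range[1], spec$maf_range[2])
  G <- matrix(stats::rbinom(n * spec$n_snps, 2, rep(maf, each = n)),
              nrow = n, ncol = spec$n_snps)
  colnames(G) <- paste0("rs", seq_len(spec$n_snps))

  adipo <- stats::rnorm(n)
  bmi <- spec$bmi_mean + spec$bmi_sd * adipo

  eff <- spec$effects
  if (!is.null(eff)) {
    unknown <- setdiff(eff$snp, colnames(G))
    if (length(unknown)) {
      stop("effect table references unknown SNP(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  genetic_component <- function(trait) {
    g <- numeric(n)
    if (is.null(eff)) return(g)
    rows <- which(eff$trait == trait)
    for (i in rows) {
      p <- maf[match(eff$snp[i], colnames(G))]
      gs <- (G[, eff$snp[i]] - 2 * p) / sqrt(2 * p * (1 - p))
      sel <- if (eff$stratum[i] == "combined") rep(TRUE, n) else sex == eff$stratum[i]
      g[sel] <- g[sel] + eff$beta[i] * gs[sel]
    }
    g
  }
  bmi <- bmi + spec$bmi_sd * genetic_component("bmi")

  depots <- list()
  for (d in c("vat", "asat", "gfat")) {
    lam <- spec$adiposity_loading[[d]]
    core <- lam * adipo + sqrt(1 - lam^2) * stats::rnorm(n) + genetic_component(d)
    val <- numeric(n)
    for (sx in c("male", "female")) {
      sel <- sex == sx
      s_cell <- spec$depot_sds[d, sx] * stats::sd(core[sel])
      mu_star <- compensated_mean(spec$depot_means[d, sx], s_cell, spec$floor_l)
      val[sel] <- pmax(mu_star + spec$depot_sds[d, sx] * core[sel], spec$floor_l)
    }
    depots[[d]] <- val
  }

  pcs <- matrix(stats::rnorm(n * spec$n_pcs), n, spec$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(spec$n_pcs))))
  cohort <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    sex = sex, age = age, bmi = bmi, height = height,
    vat = depots$vat, asat = depots$asat, gfat = depots$gfat,
    center = stats::rbinom(n, 1, 0.5), array = stats::rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, pcs)
  rownames(G) <- cohort$sample_id
  structure(list(cohort = cohort, genotypes = G, maf = maf, spec = spec,
                 seed = spec$seed),
            class = "sim_cohort")
}

#' Multi-trait summary-statistic simulation specification
#'
#' Parameters for [simulate_summary_stats()], which emulates the z-score
#' model used for locus clustering: each variant belongs to one of `k` latent
#' clusters; its loading times the cluster's non-negative trait-weight vector
#' gives the mean z-score, observed with unit-variance estimation noise. All
#' clusters load `primary_weight` on the first (primary) trait so every
#' variant is detectably associated with the primary trait, mirroring a
#' primary-trait-selected lead-SNP panel.
#'
#' @param n_variants,n_traits,k Matrix dimensions and true cluster count.
#' @param a_range Variant loading range (uniform).
#' @param b_range Cluster trait-weight range on each cluster's characteristic
#'   trait block (uniform).
#' @param primary_weight Weight of every cluster on the primary trait.
#' @param noise_sd Estimation noise SD on the z scale (default 1).
#' @param n_range Per-trait GWAS sample-size range.
#' @param A_true,B_true Optional explicit non-negative loading
#'   (variants x k) and weight (k x traits) matrices overriding the random
#'   construction.
#' @param seed Seed recorded in the output metadata.
#' @return List of class `cluster_sim_spec`.
#' @export
cluster_sim_spec <- function(n_variants = 100, n_traits = 20, k = 3,
                             a_range = c(1.5, 2.5), b_range = c(1, 2),
                             primary_weight = 3, noise_sd = 1,
                             n_range = c(150000, 450000),
                             A_true = NULL, B_true = NULL, seed = 1) {
  if (k > min(n_variants, n_traits)) {
    stop("k must not exceed min(n_variants, n_traits)", call. = FALSE)
  }
  stopifnot(noise_sd > 0)
  if (!is.null(A_true)) stopifnot(all(A_true >= 0),
                                  nrow(A_true) == n_variants, ncol(A_true) == k)
  if (!is.null(B_true)) stopifnot(all(B_true >= 0),
                                  nrow(B_true) == k, ncol(B_true) == n_traits)
  structure(as.list(environment()), class = "cluster_sim_spec")
}

#' Simulate clustered multi-trait summary statistics
#'
#' Draws `z = A_true B_true + noise`, converts to (BETA, SE, P, N) records per
#' trait with `SE = 1/sqrt(N_trait)` and `BETA = z * SE`, and returns the true
#' variant-to-cluster labels for recovery scoring.
#'
#' @param spec A [cluster_sim_spec()].
#' @return List of class `sim_sumstats` with `stats` (named list of per-trait
#'   summary-statistic data frames; trait `T01` is the primary), `labels`
#'   (named integer vector of true clusters), `z` (noisy z matrix), `A_true`,
#'   `B_true`, `n_per_trait`, `spec`.
#' @export
simulate_summary_stats <- function(spec = cluster_sim_spec()) {
  stopifnot(inherits(spec, "cluster_sim_spec"))
  set.seed(spec$seed)
  nv <- spec$n_variants; nt <- spec$n_traits; k <- spec$k
  labels <- sample(rep_len(seq_len(k), nv))
  A <- spec$A_true
  if (is.null(A)) {
    A <- matrix(0, nv, k)
    A[cbind(seq_len(nv), labels)] <- stats::runif(nv, spec$a_range[1], spec$a_range[2])
  } else {
    labels <- apply(A, 1, which.max)
  }
  B <- spec$B_true
  if (is.null(B)) {
    B <- matrix(0, k, nt)
    B[, 1] <- spec$primary_weight
    blocks <- split(seq.int(2, nt), rep_len(seq_len(k), nt - 1))
    for (kk in seq_len(k)) {
      B[kk, blocks[[kk]]] <- stats::runif(length(blocks[[kk]]),
                                          spec$b_range[1], spec$b_range[2])
    }
  }
  z <- A %*% B + matrix(stats::rnorm(nv * nt, sd = spec$noise_sd), nv, nt)

  snp <- sprintf("rs%04d", seq_len(nv))
  chr <- ((seq_len(nv) - 1) %% 22) + 1
  bp <- 1e6 + ((seq_len(nv) - 1) %/% 22) * 2e6
  eaf <- stats::runif(nv, 0.05, 0.95)
  n_per_trait <- round(stats::runif(nt, spec$n_range[1], spec$n_range[2]))
  traits <- sprintf("T%02d", seq_len(nt))
  names(n_per_trait) <- traits

  stats_list <- lapply(seq_len(nt), function(j) {
    se <- 1 / sqrt(unname(n_per_trait[j]))
    data.frame(CHR = chr, BP = bp, SNP = snp, EA = "A", OA = "G", EAF = eaf,
               BETA = z[, j] * se, SE = se,
               P = pmax(2 * stats::pnorm(-abs(z[, j])), 1e-300),
               N = unname(n_per_trait[j]), TRAIT = traits[j], STRATUM = "combined",
               stringsAsFactors = FALSE)
  })
  names(stats_list) <- traits
  names(labels) <- snp
  rownames(z) <- snp; colnames(z) <- traits
  structure(list(stats = stats_list, labels = labels, z = z,
                 A_true = A, B_true = B, n_per_trait = n_per_trait,
                 spec = spec, seed = spec$seed),
            class = "sim_sumstats")
}

#' Simulate sex-stratified effect estimates under correlated noise
#'
#' Generates paired male/female summary statistics for a panel of SNPs with
#' true effects `beta_male` / `beta_female` and bivariate-normal estimation
#' noise with correlation `est_corr` (the correlation induced in real data by
#' sample overlap and shared architecture). The default is the sharp null
#' (equal effects), used to calibrate the sex-heterogeneity test; the first
#' `n_dimorphic` SNPs can instead receive effects split by
#' `dimorphic_delta`.
#'
#' @param n_snps Panel size.
#' @param beta Shared true effect (scalar or vector).
#' @param se_male,se_female Estimation SEs.
#' @param est_corr Noise correlation between the two estimates.
#' @param n_dimorphic,dimorphic_delta Optional planted sex-dimorphic subset:
#'   male effect `beta + delta/2`, female `beta - delta/2`.
#' @param seed Seed.
#' @return List with `male` and `female` summary-statistic data frames and a
#'   `truth` data frame of generating effects.
#' @export
simulate_sex_stratified_stats <- function(n_snps = 20000, beta = 0,
                                          se_male = 0.02, se_female = 0.02,
                                          est_corr = 0.3,
                                          n_dimorphic = 0, dimorphic_delta = 0,
                                          seed = 1) {
  stopifnot(abs(est_corr) < 1, n_dimorphic <= n_snps)
  set.seed(seed)
  beta <- rep_len(beta, n_snps)
  beta_m <- beta; beta_f <- beta
  if (n_dimorphic > 0) {
    idx <- seq_len(n_dimorphic)
    beta_m[idx] <- beta[idx] + dimorphic_delta / 2
    beta_f[idx] <- beta[idx] - dimorphic_delta / 2
  }
  e1 <- stats::rnorm(n_snps)
  e2 <- est_corr * e1 + sqrt(1 - est_corr^2) * stats::rnorm(n_snps)
  bm <- beta_m + se_male * e1
  bf <- beta_f + se_female * e2
  snp <- sprintf("rs%06d", seq_len(n_snps))
  chr <- ((seq_len(n_snps) - 1) %% 22) + 1
  bp <- 1e6 + ((seq_len(n_snps) - 1) %/% 22) * 1e4
  mk <- function(b, se, stratum) {
    data.frame(CHR = chr, BP = bp, SNP = snp, EA = "A", OA = "G", EAF = 0.3,
               BETA = b, SE = se, P = pmax(2 * stats::pnorm(-abs(b / se)), 1e-300),
               N = 10000, TRAIT = "trait", STRATUM = stratum,
               stringsAsFactors = FALSE)
  }
  list(male = mk(bm, se_male, "male"), female = mk(bf, se_female, "female"),
       truth = data.frame(SNP = snp, beta_male = beta_m, beta_female = beta_f))
}

#' Simulate a block-LD panel for clumping
#'
#' Generates per-SNP association p-values and a block-structured LD table:
#' SNPs fall into blocks with exchangeable within-block r-squared (drawn per
#' block from `r2_range`) and zero r-squared across blocks, the structure
#' used to exercise the greedy clumping algorithm against a reference
#' implementation.
#'
#' @param n_snps,n_blocks Panel size and block count.
#' @param r2_range Within-block exchangeable r-squared range.
#' @param spacing_range Within-block inter-SNP spacing range in bp (wide
#'   blocks exercise the physical clumping window).
#' @param seed Seed.
#' @return List with `stats` (data frame `CHR`, `BP`, `SNP`, `P`, `block`)
#'   and `ld` (an [ld_table()]).
#' @export
simulate_clump_panel <- function(n_snps = 200, n_blocks = 20,
                                 r2_range = c(0.02, 0.8),
                                 spacing_range = c(1e3, 3e5), seed = 1) {
  set.seed(seed)
  block <- sort(sample(rep_len(seq_len(n_blocks), n_snps)))
  r2_block <- stats::runif(n_blocks, r2_range[1], r2_range[2])
  chr <- ((seq_len(n_blocks) - 1) %% 6) + 1
  bp <- numeric(n_snps); chrs <- integer(n_snps)
  offset <- 1e6
  pairs <- list()
  for (b in seq_len(n_blocks)) {
    idx <- which(block == b)
    steps <- stats::runif(length(idx), spacing_range[1], spacing_range[2])
    bp[idx] <- offset + cumsum(steps)
    chrs[idx] <- chr[b]
    offset <- max(bp[idx]) + 5e6
    if (length(idx) > 1) {
      cmb <- utils::combn(idx, 2)
      pairs[[b]] <- data.frame(snp_a = sprintf("snp%04d", cmb[1, ]),
                               snp_b = sprintf("snp%04d", cmb[2, ]),
                               r2 = r2_block[b])
    }
  }
  stats <- data.frame(CHR = chrs, BP = round(bp),
                      SNP = sprintf("snp%04d", seq_len(n_snps)),
                      P = 10^(-stats::runif(n_snps, 0, 12)),
                      block = block, stringsAsFactors = FALSE)
  ld <- ld_table(do.call(rbind, pairs))
  list(stats = stats, ld = ld)
}

#' Rare-variant burden simulation specification
#'
#' Parameters for [simulate_gene_burden_data()]. Each gene has target
#' cumulative allele frequencies `f_l` (high-confidence pLoF) and `f_m`
#' (5/5-damaging missense) split across a few variants, and an `effect` on an
#' inverse-normal-scale phenotype acting through the capped weighted burden
#' score. Genes flagged `testable` are guaranteed at least 10 carriers by
#' redrawing their genotypes (bounded retries).
#'
#' @param genes Data frame with `gene`, `f_l`, `f_m`, `effect` and optional
#'   logical `testable` (default: `effect != 0`).
#' @param n_individuals Cohort size (default 10000).
#' @param n_plof,n_missense Variants per gene per mask class.
#' @param noise_sd Phenotype residual SD (default 1).
#' @param seed Seed.
#' @return List of class `burden_sim_spec`.
#' @export
burden_sim_spec <- function(genes, n_individuals = 10000,
                            n_plof = 3, n_missense = 5,
                            noise_sd = 1, seed = 1) {
  stopifnot(all(c("gene", "f_l", "f_m") %in% names(genes)))
  if (is.null(genes$effect)) genes$effect <- 0
  if (is.null(genes$testable)) genes$testable <- genes$effect != 0
  stopifnot(all(genes$f_l >= 0), all(genes$f_m >= 0))
  if (any(genes$f_l + genes$f_m >= 0.5)) {
    stop("f_l + f_m must be below 0.5 for every gene", call. = FALSE)
  }
  structure(list(genes = genes, n_individuals = n_individuals,
                 n_plof = n_plof, n_missense = n_missense,
                 noise_sd = noise_sd, seed = seed),
            class = "burden_sim_spec")
}

#' Simulate rare-variant carrier data with planted gene effects
#'
#' Draws rare-variant carrier genotypes per gene (alleles placed on random
#' chromosomes at the spec's allele frequencies), annotates variants with
#' pLoF / damaging-missense mask classes, and builds a phenotype equal to
#' each gene's planted effect times its capped weighted burden score plus
#' Gaussian noise. Same seed, same carrier sets.
#'
#' @param spec A [burden_sim_spec()].
#' @return List of class `sim_burden` with `genotypes` (sparse samples x
#'   variants dosage matrix), `annotations` (`variant_id`, `gene`, `class`),
#'   `phenotype`, `covariates` (age, PCs), `sex`, `gene_truth` (per-gene
#'   realized carriers, weight, effect), `spec`.
#' @export
simulate_gene_burden_data <- function(spec) {
  stopifnot(inherits(spec, "burden_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  genes <- spec$genes
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  ann <- list()
  truth <- list()
  col_offset <- 0L

  draw_gene <- function(afs) {
    dose <- vector("list", length(afs))
    for (v in seq_along(afs)) {
      m <- stats::rbinom(1, 2 * n, afs[v])
      if (m > 0) {
        chrom_idx <- sample.int(2 * n, m)
        person <- ceiling(chrom_idx / 2)
        tab <- table(person)
        dose[[v]] <- list(i = as.integer(names(tab)), x = as.integer(tab))
      } else {
        dose[[v]] <- list(i = integer(0), x = integer(0))
      }
    }
    dose
  }

  for (g in seq_len(nrow(genes))) {
    n_l <- if (genes$f_l[g] > 0) spec$n_plof else 0L
    n_m <- if (genes$f_m[g] > 0) spec$n_missense else 0L
    if (n_l + n_m == 0L) next
    split_f <- function(f, k) {
      if (k == 0) return(numeric(0))
      w <- stats::runif(k, 0.5, 1.5)
      f * w / sum(w)
    }
    afs <- c(split_f(genes$f_l[g], n_l), split_f(genes$f_m[g], n_m))
    classes <- c(rep("pLoF_HC", n_l), rep("missense_5of5", n_m))
    for (try in seq_len(100)) {
      dose <- draw_gene(afs)
      carriers <- length(unique(unlist(lapply(dose, `[[`, "i"))))
      if (!isTRUE(genes$testable[g]) || carriers >= 10) break
    }
    vid <- sprintf("%s_v%d", genes$gene[g], seq_along(afs))
    for (v in seq_along(afs)) {
      trip_i[[length(trip_i) + 1L]] <- dose[[v]]$i
      trip_j[[length(trip_j) + 1L]] <- rep(col_offset + v, length(dose[[v]]$i))
      trip_x[[length(trip_x) + 1L]] <- dose[[v]]$x
    }
    ann[[length(ann) + 1L]] <- data.frame(variant_id = vid, gene = genes$gene[g],
                                          class = classes, stringsAsFactors = FALSE)
    w_m <- if (genes$f_m[g] > 0) missense_weight(genes$f_l[g], genes$f_m[g]) else NA_real_
    truth[[length(truth) + 1L]] <- data.frame(
      gene = genes$gene[g], effect = genes$effect[g],
      f_l = genes$f_l[g], f_m = genes$f_m[g], weight_missense = w_m,
      n_carriers = carriers, stringsAsFactors = FALSE)
    col_offset <- col_offset + length(afs)
  }
  annotations <- do.call(rbind, ann)
  G <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(n, col_offset),
                            dimnames = list(sprintf("S%06d", seq_len(n)),
                                            annotations$variant_id))
  gene_truth <- do.call(rbind, truth)

  # phenotype: planted effect times the capped weighted burden score
  pheno <- stats::rnorm(n, sd = spec$noise_sd)
  for (g in which(gene_truth$effect != 0)) {
    va <- annotations[annotations$gene == gene_truth$gene[g], , drop = FALSE]
    w <- ifelse(va$class == "pLoF_HC", 1, gene_truth$weight_missense[g])
    sc <- pmin(1, drop(as.matrix(G[, va$variant_id, drop = FALSE]) %*% w))
    pheno <- pheno + gene_truth$effect[g] * sc
  }
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  covariates <- data.frame(age = stats::rnorm(n, 64.5, 7.5),
                           pc1 = stats::rnorm(n), pc2 = stats::rnorm(n))
  structure(list(genotypes = G, annotations = annotations, phenotype = pheno,
                 covariates = covariates, sex = sex, gene_truth = gene_truth,
                 spec = spec, seed = spec$seed),
            class = "sim_burden")
}
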