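#' Build the signed, scaled, split z-score matrix for clustering
#'
#' Prepares the non-negative variant-by-trait association matrix consumed by
#' [fit_bnmf_ard()]. Starting from a set of lead SNPs and complete per-trait
#' summary statistics, the pipeline is:
#' \enumerate{
#'   \item keep leads nominally associated (p < 0.05) with the primary trait;
#'   \item LD-prune the survivors at r-squared 0.1, retaining the SNP with the
#'     lower primary-trait p-value from each correlated pair;
#'   \item form z = beta / se for every trait;
#'   \item scale each trait's column by \eqn{\sqrt{N_{med} / N_{trait}}}
#'     where \eqn{N_{med}} is the median sample size across traits;
#'   \item flip each variant's whole z row so its primary-trait z is positive
#'     (alignment to the primary-trait-increasing allele);
#'   \item drop traits with no |z| above the two-sided Bonferroni quantile for
#'     0.05 / n_variants;
#'   \item among trait pairs with |Pearson correlation| > 0.85 on the signed
#'     z columns, drop the trait with the larger minimum p-value;
#'   \item split each signed column into non-negative `_pos` / `_neg` pairs.
#' }
#'
#' @param leads Character vector of candidate lead SNP ids (the union of loci
#'   across traits).
#' @param stats Named list of summary-statistic data frames (one per trait,
#'   columns `SNP`, `EA`, `OA`, `BETA`, `SE`, `P`, `N`); every trait must
#'   cover every lead (missing entries are an error).
#' @param primary_trait Name of the primary trait (must be in `names(stats)`).
#' @param ld Optional [ld_table()] for the pruning step; `NULL` skips pruning.
#' @param n_snps_for_bonferroni Denominator for the trait-retention threshold;
#'   defaults to the number of variants remaining after pruning.
#' @param cor_limit Trait-pair correlation ceiling (default 0.85).
#' @return Object of class `signed_z`: list with `X` (variants x 2M
#'   non-negative matrix with `_pos`/`_neg` columns), `Z` (signed pre-split
#'   matrix), `variants`, `traits`, `n_per_trait`, `median_n`,
#'   `primary_trait`, and `dropped` bookkeeping.
#' @export
build_signed_z_matrix <- function(leads, stats, primary_trait, ld = NULL,
                                  n_snps_for_bonferroni = NULL,
                                  cor_limit = 0.85) {
  stopifnot(is.list(stats), !is.null(names(stats)),
            primary_trait %in% names(stats))
  traits <- names(stats)
  dropped <- list(variants = character(0), traits = character(0))

  prim <- stats[[primary_trait]]
  prim <- prim[match(leads, prim$SNP), , drop = FALSE]
  if (anyNA(prim$SNP)) {
    stop("primary-trait statistics missing for lead(s): ",
         paste(utils::head(leads[is.na(prim$SNP)], 5), collapse = ", "),
         call. = FALSE)
  }
  zero_beta <- prim$BETA == 0
  if (any(zero_beta)) {
    message("dropping ", sum(zero_beta),
            " variant(s) with primary-trait beta exactly 0 (alignment undefined)")
    dropped$variants <- c(dropped$variants, leads[zero_beta])
    leads <- leads[!zero_beta]
    prim <- prim[!zero_beta, , drop = FALSE]
  }

  keep <- prim$P < 0.05
  dropped$variants <- c(dropped$variants, leads[!keep])
  leads <- leads[keep]
  prim <- prim[keep, , drop = FALSE]
  if (!length(leads)) stop("no leads nominally associated with the primary trait",
                           call. = FALSE)

  if (!is.null(ld)) {
    ord <- order(prim$P)
    kept <- character(0)
    for (s in leads[ord]) {
      if (!length(kept) || all(ld_r2(ld, s, kept) <= 0.1)) kept <- c(kept, s)
    }
    pruned <- setdiff(leads, kept)
    dropped$variants <- c(dropped$variants, pruned)
    keep <- leads %in% kept
    leads <- leads[keep]
    prim <- prim[keep, , drop = FALSE]
  }

  n_var <- length(leads)
  Z <- matrix(NA_real_, n_var, length(traits),
              dimnames = list(leads, traits))
  P <- Z
  n_per_trait <- numeric(length(traits))
  names(n_per_trait) <- traits
  prim_ea <- prim$EA
  prim_oa <- prim$OA
  for (tr in traits) {
    st <- stats[[tr]]
    st <- st[match(leads, st$SNP), , drop = FALSE]
    if (anyNA(st$SNP)) {
      stop("summary statistics for trait '", tr, "' missing for lead(s): ",
           paste(utils::head(leads[is.na(st$SNP)], 5), collapse = ", "),
           call. = FALSE)
    }
    same <- st$EA == prim_ea & st$OA == prim_oa
    flipped <- st$EA == prim_oa & st$OA == prim_ea
    if (any(!same & !flipped)) {
      stop("allele mismatch between trait '", tr, "' and the primary trait",
           call. = FALSE)
    }
    beta <- ifelse(flipped, -st$BETA, st$BETA)
    Z[, tr] <- beta / st$SE
    P[, tr] <- st$P
    n_per_trait[tr] <- stats::median(st$N)
  }
  median_n <- stats::median(n_per_trait)
  Z <- sweep(Z, 2, sqrt(median_n / n_per_trait), `*`)

  flip <- Z[, primary_trait] < 0
  Z[flip, ] <- -Z[flip, , drop = FALSE]

  if (is.null(n_snps_for_bonferroni)) n_snps_for_bonferroni <- n_var
  z_crit <- stats::qnorm(1 - (0.05 / n_snps_for_bonferroni) / 2)
  weak <- apply(abs(Z), 2, max) < z_crit
  weak[traits == primary_trait] <- FALSE
  dropped$traits <- traits[weak]
  Z <- Z[, !weak, drop = FALSE]
  P <- P[, !weak, drop = FALSE]
  traits <- colnames(Z)

  # collapse highly correlated trait pairs, keeping the lower-minimum-p trait
  # (needs at least 3 variants for the correlation to be meaningful)
  repeat {
    if (ncol(Z) < 2 || nrow(Z) < 3) break
    cz <- abs(stats::cor(Z))
    cz[is.na(cz)] <- 0
    diag(cz) <- 0
    if (max(cz) <= cor_limit) break
    idx <- which(cz == max(cz), arr.ind = TRUE)[1, ]
    minp <- apply(P[, idx, drop = FALSE], 2, min)
    drop_i <- idx[which.max(minp)]
    dropped$traits <- c(dropped$traits, colnames(Z)[drop_i])
    Z <- Z[, -drop_i, drop = FALSE]
    P <- P[, -drop_i, drop = FALSE]
  }
  traits <- colnames(Z)

  X <- cbind(pmax(Z, 0), pmax(-Z, 0))
  colnames(X) <- c(paste0(traits, "_pos"), paste0(traits, "_neg"))
  # interleave so each trait's pos/neg columns sit together
  ord <- as.vector(rbind(seq_along(traits), seq_along(traits) + length(traits)))
  X <- X[, ord, drop = FALSE]

  structure(list(X = X, Z = Z, variants = leads, traits = traits,
                 n_per_trait = n_per_trait, median_n = median_n,
                 primary_trait = primary_trait, dropped = dropped),
            class = "signed_z")
}

bnmf_objective <- function(V, W, H, lambda, b0, C) {
  0.5 * sum((V - W %*% H)^2) +
    sum((0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b0) / lambda) +
    C * sum(log(lambda))
}

bnmf_single <- function(V, K0, a0, b0, tol, max_iter, eps = 1e-16,
                        decay_iter = 200L) {
  Fdim <- nrow(V); N <- ncol(V)
  C <- (Fdim + N) / 2 + a0 + 1
  mV <- mean(V)
  W <- matrix(stats::runif(Fdim * K0), Fdim, K0) * sqrt(mV)
  H <- matrix(stats::runif(K0 * N), K0, N) * sqrt(mV)
  lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b0) / C
  obj <- bnmf_objective(V, W, H, lambda, b0, C)
  trace <- numeric(max_iter + decay_iter)
  converged <- FALSE
  it <- 0L
  extra <- 0L
  while (it < max_iter + decay_iter) {
    it <- it + 1L
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + H / lambda + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + sweep(W, 2, lambda, `/`) + eps)
    lambda <- (0.5 * colSums(W^2) + 0.5 * rowSums(H^2) + b0) / C
    new_obj <- bnmf_objective(V, W, H, lambda, b0, C)
    trace[it] <- new_obj
    if (!converged && abs(obj - new_obj) <= tol * abs(obj)) converged <- TRUE
    obj <- new_obj
    if (converged) {
      # extra updates after objective convergence let pruned components'
      # residual weight decay to numerical zero before K is counted
      extra <- extra + 1L
      if (extra >= decay_iter) break
    }
  }
  list(W = W, H = H, lambda = lambda, objective = obj,
       trace = trace[seq_len(it)], iterations = it, converged = converged)
}

bnmf_active <- function(W, H, prune_tol) {
  w <- colSums(W^2) + rowSums(H^2)
  w > prune_tol * max(w)
}

# Unpenalized multiplicative refinement of the retained components: the ARD
# prior selects K but leaves a small shrinkage bias in W and H; polishing at
# fixed K removes it (exact reconstruction in the noiseless low-rank limit).
bnmf_polish <- function(V, W, H, tol = 1e-12, max_iter = 5000, eps = 1e-16) {
  err <- sum((V - W %*% H)^2)
  for (it in seq_len(max_iter)) {
    H <- H * crossprod(W, V) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- sum((V - W %*% H)^2)
    if (abs(err - new_err) <= tol * max(err, eps)) break
    err <- new_err
  }
  list(W = W, H = H, rss = err)
}

#' Bayesian NMF with automatic relevance determination
#'
#' Factorizes the non-negative split association matrix X (variants x 2M
#' split traits) as \eqn{X^T \approx W H}, where W (2M x K) carries trait
#' weights and H (K x variants) carries variant loadings. Each restart
#' minimizes the negative log-posterior
#' \deqn{\tfrac12 \lVert X^T - WH \rVert_F^2 +
#'   \sum_k \frac{\tfrac12\lVert W_{\cdot k}\rVert^2 +
#'   \tfrac12\lVert H_{k \cdot}\rVert^2 + b_0}{\lambda_k} +
#'   C \sum_k \log \lambda_k}
#' by alternating multiplicative updates with the closed-form relevance-weight
#' update \eqn{\lambda_k = (\tfrac12\lVert W_{\cdot k}\rVert^2 +
#' \tfrac12\lVert H_{k\cdot}\rVert^2 + b_0) / C}, the half-normal ARD scheme:
#' irrelevant components see their \eqn{\lambda_k} collapse and their columns
#' shrink to zero, so the retained component count K is inferred rather than
#' fixed. The modal K across restarts is reported and the lowest-objective
#' restart among modal-K solutions is returned as the representative solution.
#'
#' @param X A `signed_z` object from [build_signed_z_matrix()], or a
#'   non-negative matrix (variants x split traits) with dimnames.
#' @param K0 Maximum component count (default 20).
#' @param n_restarts Number of random restarts (default 100).
#' @param seed Master seed; restart r uses seed + r - 1.
#' @param tol Relative objective-change convergence tolerance (default 1e-7).
#' @param max_iter Iteration cap per restart (default 10000).
#' @param a0 ARD prior shape hyperparameter (default 10); the prior scale
#'   \eqn{b_0} is set to `sqrt((a0-1)*(a0-2)*mean(X)/K0)` following standard
#'   ARD-NMF practice.
#' @param prune_tol Relative component-weight threshold below which a
#'   component counts as pruned (default 1e-8).
#' @return Object of class `bnmf_fit`: list with `restarts` (data frame of
#'   seed, K, objective, iterations, converged), `modal_k`,
#'   `modal_k_fraction`, and `best` (the representative solution: `W`, `H`,
#'   `lambda`, `K`, `objective`, `trace`, `seed`, restricted to active
#'   components ordered by weight). The reported `W`/`H` are refined at the
#'   selected K by unpenalized multiplicative updates, removing the small
#'   shrinkage bias of the ARD prior; `objective` and `trace` refer to the
#'   regularized fit that selected the components.
#' @export
fit_bnmf_ard <- function(X, K0 = 20, n_restarts = 100, seed = 1,
                         tol = 1e-7, max_iter = 10000, a0 = 10,
                         prune_tol = 1e-8) {
  if (inherits(X, "signed_z")) X <- X$X
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative", call. = FALSE)
  if (any(rowSums(X) == 0)) stop("X has all-zero rows", call. = FALSE)
  V <- t(X)  # 2M x N
  b0 <- sqrt((a0 - 1) * (a0 - 2) * mean(V) / K0)

  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    runs[[r]] <- bnmf_single(V, K0, a0, b0, tol, max_iter)
  }
  converged <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(converged)) {
    stop("no restart converged within ", max_iter, " iterations at tol ", tol,
         call. = FALSE)
  }
  K <- vapply(runs, function(s) sum(bnmf_active(s$W, s$H, prune_tol)), integer(1))
  objective <- vapply(runs, `[[`, numeric(1), "objective")
  restarts <- data.frame(seed = seed + seq_len(n_restarts) - 1L,
                         K = K, objective = objective,
                         iterations = vapply(runs, `[[`, integer(1), "iterations"),
                         converged = converged)
  k_tab <- table(K[converged])
  modal_k <- as.integer(names(k_tab)[which.max(k_tab)])
  modal_frac <- max(k_tab) / sum(converged)

  cand <- which(converged & K == modal_k)
  best_i <- cand[which.min(objective[cand])]
  s <- runs[[best_i]]
  act <- which(bnmf_active(s$W, s$H, prune_tol))
  wgt <- (colSums(s$W^2) + rowSums(s$H^2))[act]
  act <- act[order(wgt, decreasing = TRUE)]
  pol <- bnmf_polish(V, s$W[, act, drop = FALSE], s$H[act, , drop = FALSE])
  W <- pol$W
  H <- pol$H
  rownames(W) <- colnames(X)
  colnames(H) <- rownames(X)
  colnames(W) <- rownames(H) <- paste0("k", seq_along(act))

  structure(list(restarts = restarts, modal_k = modal_k,
                 modal_k_fraction = modal_frac,
                 best = list(W = W, H = H, lambda = s$lambda[act],
                             K = length(act), objective = s$objective,
                             trace = s$trace, seed = seed + best_i - 1L,
                             iterations = s$iterations)),
            class = "bnmf_fit")
}

#' Summarize a bNMF clustering solution
#'
#' Orders each cluster's traits by weight and variants by loading, and
#' hard-assigns every variant to its maximum-loading cluster for reporting
#' (ties go to the lowest-index cluster, with a message).
#'
#' @param fit A `bnmf_fit` from [fit_bnmf_ard()], or a list with `W` and `H`.
#' @return List with `assignments` (named integer vector, variant -> cluster),
#'   `trait_rankings` and `variant_rankings` (per-cluster named numeric
#'   vectors, non-increasing), `k` and `modal_k_fraction` (NA if unknown).
#' @export
summarize_clusters <- function(fit) {
  sol <- if (inherits(fit, "bnmf_fit")) fit$best else fit
  W <- sol$W; H <- sol$H
  stopifnot(!is.null(W), !is.null(H), ncol(W) == nrow(H))
  k <- ncol(W)
  ties <- apply(H, 2, function(h) sum(h == max(h)) > 1)
  if (any(ties)) {
    message(sum(ties), " variant(s) tied in max loading; assigned to the ",
            "lowest-index cluster")
  }
  assignments <- apply(H, 2, which.max)
  names(assignments) <- colnames(H)
  trait_rankings <- lapply(seq_len(k), function(j) sort(W[, j], decreasing = TRUE))
  variant_rankings <- lapply(seq_len(k), function(j) sort(H[j, ], decreasing = TRUE))
  names(trait_rankings) <- names(variant_rankings) <- colnames(W)
  list(assignments = assignments, trait_rankings = trait_rankings,
       variant_rankings = variant_rankings, k = k,
       modal_k_fraction = if (inherits(fit, "bnmf_fit")) fit$modal_k_fraction else NA_real_)
}
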