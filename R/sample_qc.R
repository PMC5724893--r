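# Sample-level pruning: relatedness (robust pairwise kinship over a common
# SNP panel) and population outliers (iterative PCA with a per-PC sigma
# threshold).

#' Robust pairwise kinship coefficients
#'
#' Within-pair robust estimator over a common biallelic SNP panel coded
#' 0/1/2 (minor allele dosage), missing allowed:
#' \deqn{\phi_{ij} = \frac{N_{het,het} - 2 N_{AA,aa}}{N_{het}(i) + N_{het}(j)}}
#' where counts run over sites non-missing in both samples. Duplicates give
#' 0.5, parent-offspring pairs about 0.25, unrelated pairs about 0.
#' Estimates are clipped to \[-0.5, 0.5\]; a pair with no jointly typed
#' heterozygous site is reported as `NA` with a warning (treated as
#' unrelated downstream).
#'
#' @param geno samples-by-SNPs integer matrix (0/1/2, NA = missing) with
#'   sample IDs as rownames.
#' @return Symmetric matrix of class `kinship_matrix`; diagonal set to 0.5.
#' @export
kinship_estimate <- function(geno) {
  assert_that(!is.null(rownames(geno)), "genotype matrix needs sample rownames")
  H <- (geno == 1) * 1
  A0 <- (geno == 0) * 1
  A2 <- (geno == 2) * 1
  if (anyNA(geno)) {
    M <- !is.na(geno) * 1
    H[is.na(H)] <- 0; A0[is.na(A0)] <- 0; A2[is.na(A2)] <- 0
    n_hh <- tcrossprod(H)
    n_opp <- tcrossprod(A0, A2); n_opp <- n_opp + t(n_opp)
    het_i <- tcrossprod(H, M)        # het in i, typed in j
    denom <- het_i + t(het_i)
  } else {
    n_hh <- tcrossprod(H)
    n_opp <- tcrossprod(A0, A2); n_opp <- n_opp + t(n_opp)
    nh <- rowSums(H)
    denom <- outer(nh, nh, `+`)
  }
  phi <- (n_hh - 2 * n_opp) / denom
  phi[denom == 0] <- NA
  if (anyNA(phi[upper.tri(phi)]))
    warning("kinship undefined for some pairs (no jointly typed het sites); treated as unrelated")
  phi <- pmin(pmax(phi, -0.5), 0.5)
  diag(phi) <- 0.5
  dimnames(phi) <- list(rownames(geno), rownames(geno))
  class(phi) <- c("kinship_matrix", class(phi))
  phi
}

#' Prune related samples
#'
#' Greedy removal until no retained pair exceeds the kinship cutoff:
#' repeatedly delete the sample with the most remaining relatedness edges,
#' preferring to delete controls over cases, then lower mean CCDS coverage,
#' then the lexicographically later sample ID.
#'
#' @param kinship a `kinship_matrix`.
#' @param manifest sample manifest (needs `sample_id`, `phenotype`, and
#'   optionally `mean_ccds_coverage` for tie-breaking).
#' @param cutoff kinship threshold above which a pair counts as related
#'   (default 0.1).
#' @return Character vector of retained sample IDs, with the removal log
#'   (data.frame) attached as attribute `"removals"`.
#' @export
prune_related <- function(kinship, manifest, cutoff = 0.1) {
  ids <- rownames(kinship)
  stopifnot(all(ids %in% manifest$sample_id))
  phi <- unclass(kinship)
  diag(phi) <- 0
  phi[is.na(phi)] <- 0
  adj <- phi > cutoff
  is_case <- manifest$phenotype[match(ids, manifest$sample_id)] == "case"
  covg <- manifest$mean_ccds_coverage[match(ids, manifest$sample_id)]
  covg[is.na(covg)] <- -Inf
  alive <- rep(TRUE, length(ids))
  log <- list()
  repeat {
    deg <- rowSums(adj[alive, alive, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    cand <- names(deg)[deg == max(deg)]
    ci <- match(cand, ids)
    # prefer deleting controls, then lower coverage, then later sample_id
    ord <- order(is_case[ci], covg[ci], -rank(cand, ties.method = "first"))
    victim <- cand[ord[1]]
    vi <- match(victim, ids)
    log[[length(log) + 1L]] <- data.frame(
      removed = victim, degree = max(deg),
      phenotype = ifelse(is_case[vi], "case", "control"),
      stringsAsFactors = FALSE)
    alive[vi] <- FALSE
  }
  retained <- ids[alive]
  attr(retained, "removals") <- if (length(log)) do.call(rbind, log) else
    data.frame(removed = character(0), degree = integer(0),
               phenotype = character(0))
  retained
}

#' LD pruning of a SNP panel
#'
#' Sliding-window greedy pruning: within each window no retained pair of
#' SNPs has squared genotype correlation above the threshold; on conflict
#' the earlier-position SNP is retained. Monomorphic SNPs (undefined r^2)
#' are dropped first.
#'
#' @param geno samples-by-SNPs dosage matrix (columns in genomic order).
#' @param r2_threshold maximum allowed r^2 (default 0.1).
#' @param window window size in SNPs (default 50).
#' @param step window slide in SNPs (default 5).
#' @return Integer indices (into the original columns) of retained SNPs.
#' @export
ld_prune <- function(geno, r2_threshold = 0.1, window = 50, step = 5) {
  m <- ncol(geno)
  sds <- apply(geno, 2, sd, na.rm = TRUE)
  keep <- sds > 0 & !is.na(sds)
  alive <- keep
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    win <- s:min(s + window - 1, m)
    win <- win[alive[win]]
    if (length(win) < 2) next
    r2 <- suppressWarnings(cor(geno[, win, drop = FALSE],
                               use = "pairwise.complete.obs"))^2
    r2[!is.finite(r2)] <- 0
    for (a in seq_along(win)) {
      if (!alive[win[a]]) next
      for (b in seq_along(win)) {
        if (b <= a || !alive[win[b]]) next
        if (r2[a, b] > r2_threshold) alive[win[b]] <- FALSE
      }
    }
    if (win[length(win)] >= m) break
  }
  which(alive)
}

#' Iterative PCA outlier removal
#'
#' Each iteration standardizes genotypes per SNP (subtract twice the
#' current allele frequency, divide by \eqn{\sqrt{2\hat p(1-\hat p)}}),
#' eigendecomposes the sample covariance, and removes every sample whose
#' coordinate on any of the top `n_pcs` principal components lies more than
#' `sigma` standard deviations from that component's mean. Stops after
#' `iterations` rounds or when an iteration removes nobody. SNPs that
#' become monomorphic are dropped from the standardization for that
#' iteration. PC signs are fixed by making the largest-magnitude SNP
#' loading positive.
#'
#' @param geno samples-by-SNPs dosage matrix with sample rownames
#'   (typically LD-pruned).
#' @param n_pcs number of leading components examined (default 10).
#' @param sigma per-PC z-score threshold (default 6).
#' @param iterations maximum outlier-removal rounds (default 5).
#' @return List of class `pca_result`: `scores` (final coordinates),
#'   `eigenvalues`, `retained` (sample IDs), `removed` (list of IDs removed
#'   per iteration).
#' @export
pca_outlier_removal <- function(geno, n_pcs = 10, sigma = 6.0, iterations = 5) {
  assert_that(!is.null(rownames(geno)), "genotype matrix needs sample rownames")
  alive <- rownames(geno)
  removed <- list()
  scores <- NULL; evals <- NULL
  decompose <- function(ids) {
    X <- geno[ids, , drop = FALSE]
    p <- colMeans(X, na.rm = TRUE) / 2
    ok <- p > 0 & p < 1 & !is.na(p)
    X <- X[, ok, drop = FALSE]
    p <- p[ok]
    Xs <- sweep(X, 2, 2 * p)
    Xs <- sweep(Xs, 2, sqrt(2 * p * (1 - p)), "/")
    Xs[is.na(Xs)] <- 0
    K <- min(n_pcs, length(ids) - 1)
    e <- eigen(tcrossprod(Xs) / ncol(Xs), symmetric = TRUE)
    U <- e$vectors[, seq_len(K), drop = FALSE]
    # deterministic sign: largest |loading| positive
    L <- crossprod(Xs, U)
    for (k in seq_len(K)) {
      j <- which.max(abs(L[, k]))
      if (L[j, k] < 0) U[, k] <- -U[, k]
    }
    rownames(U) <- ids
    list(scores = U, values = pmax(e$values[seq_len(K)], 0))
  }
  iter_done <- 0
  if (iterations > 0) for (it in seq_len(iterations)) {
    assert_that(length(alive) > n_pcs, "fewer samples than requested PCs")
    d <- decompose(alive)
    z <- scale(d$scores)
    out <- rowSums(abs(z) > sigma, na.rm = TRUE) > 0
    iter_done <- it
    scores <- d$scores; evals <- d$values
    if (!any(out)) break
    removed[[it]] <- alive[out]
    alive <- alive[!out]
  }
  # final coordinates on the retained set
  if (is.null(scores) || nrow(scores) != length(alive)) {
    d <- decompose(alive)
    scores <- d$scores; evals <- d$values
  }
  structure(list(scores = scores, eigenvalues = evals, retained = alive,
                 removed = removed, iterations_run = iter_done),
            class = "pca_result")
}

#' @exportS3Method base::print
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples retained, %d removed over %d iteration(s)\n",
              length(x$retained), length(unlist(x$removed)), x$iterations_run))
  invisible(x)
}
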