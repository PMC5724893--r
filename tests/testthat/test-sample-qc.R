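# Kinship estimation, relatedness pruning, LD pruning and iterative PCA.

# Mendelian-transmission simulator: the independent oracle for the kinship
# estimator's expected values on known pedigrees.
sim_pedigree_panel <- function(n_pairs, m = 10000, kind = "parent_offspring",
                               maf = NULL) {
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  g <- matrix(0L, 2 * n_pairs, m)
  for (i in seq_len(n_pairs)) {
    a <- rbinom(m, 2, maf)
    b <- if (kind == "parent_offspring")
      rbinom(m, 1, a / 2) + rbinom(m, 1, maf)   # transmitted + population allele
    else rbinom(m, 2, maf)                      # unrelated
    g[2 * i - 1, ] <- a; g[2 * i, ] <- as.integer(b)
  }
  rownames(g) <- sprintf("S%03d", seq_len(2 * n_pairs))
  g
}

test_that("kinship: duplicates hit 0.5 and pedigree simulation matches theory", {
  set.seed(501)
  # exact duplicate with het sites present
  g <- rbind(A = c(0, 1, 2, 1, 0, 1), B = c(0, 1, 2, 1, 0, 1),
             C = c(2, 0, 0, 1, 2, 1))
  kin <- kinship_estimate(g)
  expect_equal(kin["A", "B"], 0.5)

  panel <- sim_pedigree_panel(15, kind = "parent_offspring")
  kin <- kinship_estimate(panel)
  po <- vapply(seq_len(15), function(i) kin[2 * i - 1, 2 * i], 0)
  expect_lt(abs(mean(po) - 0.25), 0.02)

  panel_u <- sim_pedigree_panel(15, kind = "unrelated")
  kin_u <- kinship_estimate(panel_u)
  un <- vapply(seq_len(15), function(i) kin_u[2 * i - 1, 2 * i], 0)
  expect_lt(abs(mean(un)), 0.02)
})

test_that("kinship handles missing genotypes and undefined pairs", {
  g <- rbind(A = c(1, 1, NA, 0), B = c(1, NA, 1, 0), C = c(0, 0, 2, 2))
  kin <- suppressWarnings(kinship_estimate(g))
  # A-B over jointly typed sites {1, 4}: both het at site 1
  expect_equal(kin["A", "B"], 0.5)
  g2 <- rbind(A = c(0, 2, 0), B = c(0, 2, 0))   # no het sites at all
  expect_warning(kin2 <- kinship_estimate(g2), "undefined")
  expect_true(is.na(kin2["A", "B"]))
})

test_that("relatedness pruning prefers cases, then coverage, and clears all edges", {
  man <- data.frame(
    sample_id = c("CASEA", "CTRLA", "CTRLB", "CTRLC", "CTRLD"),
    phenotype = c("case", "control", "control", "control", "control"),
    mean_ccds_coverage = c(0.90, 0.99, 0.95, 0.90, 0.97))
  phi <- matrix(0, 5, 5, dimnames = list(man$sample_id, man$sample_id))
  phi["CASEA", "CTRLA"] <- phi["CTRLA", "CASEA"] <- 0.3   # case-control pair
  phi["CTRLB", "CTRLC"] <- phi["CTRLC", "CTRLB"] <- 0.2   # coverage tie-break
  diag(phi) <- 0.5
  class(phi) <- c("kinship_matrix", class(phi))
  kept <- prune_related(phi, man, cutoff = 0.1)
  expect_true("CASEA" %in% kept)
  expect_false("CTRLA" %in% kept)                 # control removed, case kept
  expect_true("CTRLB" %in% kept)                  # 0.95 coverage beats 0.90
  expect_false("CTRLC" %in% kept)
  expect_true("CTRLD" %in% kept)
  # no retained pair above the cutoff (exhaustive)
  sub <- unclass(phi)[kept, kept]; diag(sub) <- 0
  expect_true(all(sub <= 0.1))
  # nothing related -> identity
  phi0 <- phi; phi0[upper.tri(phi0)] <- 0; phi0[lower.tri(phi0)] <- 0
  expect_equal(sort(prune_related(phi0, man, 0.1)), sort(man$sample_id),
               ignore_attr = TRUE)
})

test_that("pruned output never contains an edge above cutoff on noisy kinship", {
  set.seed(77)
  n <- 40
  ids <- sprintf("S%02d", 1:n)
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in 1:25) {
    ij <- sample(n, 2)
    phi[ij[1], ij[2]] <- phi[ij[2], ij[1]] <- runif(1, 0.05, 0.5)
  }
  diag(phi) <- 0.5
  class(phi) <- c("kinship_matrix", class(phi))
  man <- data.frame(sample_id = ids,
                    phenotype = sample(c("case", "control"), n, TRUE),
                    mean_ccds_coverage = runif(n, 0.8, 1))
  kept <- prune_related(phi, man, cutoff = 0.1)
  sub <- unclass(phi)[kept, kept]; diag(sub) <- 0
  expect_true(all(sub <= 0.1))
})

test_that("LD pruning keeps one of a perfectly correlated pair, deterministically", {
  set.seed(88)
  n <- 200
  base <- matrix(rbinom(n * 30, 2, 0.3), n, 30)
  g <- cbind(base[, 1], base[, 1], base[, -1])   # duplicated first SNP
  kept <- ld_prune(g, r2_threshold = 0.1, window = 10, step = 3)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  expect_identical(kept, ld_prune(g, r2_threshold = 0.1, window = 10, step = 3))
  # independent SNPs are essentially all retained
  g_ind <- matrix(rbinom(n * 120, 2, runif(120, 0.1, 0.5)[rep(1:120, each = n)]),
                  n, 120)
  kept_ind <- ld_prune(g_ind, r2_threshold = 0.1, window = 20, step = 5)
  expect_gt(length(kept_ind) / 120, 0.95)
  # monomorphic SNPs are dropped
  g_mono <- cbind(g_ind, 0L)
  expect_false(121 %in% ld_prune(g_mono, 0.1, 20, 5))
})

test_that("iterative PCA removes a planted diverged sample and nothing else", {
  # a single diverged sample only rises above the eigenvector noise floor
  # when SNPs comfortably outnumber samples (here ~33x)
  set.seed(99)
  n <- 300; m <- 10000
  maf <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  # homogeneous population: no removals in any iteration
  res0 <- pca_outlier_removal(g, n_pcs = 10, sigma = 6, iterations = 5)
  expect_equal(length(res0$retained), n)
  expect_equal(length(unlist(res0$removed)), 0)

  # one sample from a strongly diverged population is caught in iteration 1
  maf_out <- rbeta(m, maf * 4, (1 - maf) * 4)    # Fst-like divergence 0.2
  g_out <- g
  g_out["S001", ] <- rbinom(m, 2, maf_out)
  res1 <- pca_outlier_removal(g_out, n_pcs = 10, sigma = 6, iterations = 5)
  expect_equal(unlist(res1$removed), "S001", ignore_attr = TRUE)
  expect_equal(res1$removed[[1]], "S001")          # caught in iteration 1
  expect_false("S001" %in% res1$retained)

  # iterations = 0 is the identity
  res_id <- pca_outlier_removal(g_out, iterations = 0)
  expect_equal(length(res_id$retained), n)
})

test_that("PCA coordinates are deterministic with the documented sign convention", {
  set.seed(111)
  g <- matrix(rbinom(80 * 300, 2, 0.3), 80, 300,
              dimnames = list(sprintf("S%02d", 1:80), NULL))
  a <- pca_outlier_removal(g, n_pcs = 5, iterations = 1)
  b <- pca_outlier_removal(g, n_pcs = 5, iterations = 1)
  expect_identical(a$scores, b$scores)
  expect_true(all(is.finite(a$scores)))
  # components orthogonal
  cp <- crossprod(a$scores)
  expect_equal(max(abs(cp[upper.tri(cp)])), 0, tolerance = 1e-8)
})

test_that("full sample QC recovers exactly the planted duplicates and outlier", {
  sim <- small_sim(seed = 202, n_panel_snps = 10000, n_cases = 40,
                   n_controls = 160, subpop_fst = 0)
  kin <- kinship_estimate(sim$snp_panel)
  rel <- sim$truth$related_pairs
  dup <- rel[rel$kind == "duplicate", ]
  expect_lt(abs(kin[dup$sample1, dup$sample2] - 0.5), 0.02)
  kept <- prune_related(kin, sim$manifest, cutoff = 0.1)
  removed <- setdiff(sim$manifest$sample_id, kept)
  # exactly one sample per planted pair goes; the duplicate's control half
  # is removed (case preferred), the parent-offspring pair loses one member
  po <- rel[rel$kind == "parent_offspring", ]
  expect_equal(length(removed), 2)
  expect_true(dup$sample2 %in% removed)
  expect_equal(sum(c(po$sample1, po$sample2) %in% removed), 1)
  pca <- pca_outlier_removal(sim$snp_panel[kept, ])
  expect_equal(unlist(pca$removed), sim$truth$outlier_samples,
               ignore_attr = TRUE)
})
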