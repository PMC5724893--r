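# Label permutation schemes, the weighted urn, expected order statistics
# and the genomic inflation factor.

test_that("simple permutation conserves the case count and the seed", {
  lab <- permute_simple(100, 17, seed = 5)
  expect_equal(sum(lab), 17)
  expect_identical(lab, permute_simple(100, 17, seed = 5))
  set.seed(10)
  freq <- rowMeans(vapply(1:4000, function(i) permute_simple(25, 5),
                          logical(25)))
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 4000)))
  expect_error(permute_simple(10, 0), "0 < n_cases")
})

test_that("urn weights come from the confounder fit and satisfy the odds identity", {
  set.seed(21)
  z <- rpois(500, 5)
  y <- rbinom(500, 1, plogis(-2 + 0.15 * z))
  w <- urn_weights(y, z)
  gam <- attr(w, "gamma")
  expect_gt(gam, 0)
  expect_true(all(diff(w[order(z)]) >= -1e-12))       # monotone in z
  # pairwise odds ratios reproduce the fitted coefficient exactly
  i <- 1; j <- which(z != z[1])[1]
  expect_equal(w[i] / w[j], exp(gam * (z[i] - z[j])), tolerance = 1e-10)
  expect_equal(prod(w)^(1 / length(w)), 1, tolerance = 1e-8)
  # constant covariate: all weights equal
  expect_equal(unique(urn_weights(y, rep(2, 500))), 1)
})

test_that("urn weights fall back to the Firth fit under separation", {
  z <- c(rep(0, 20), rep(10, 20))
  y <- c(rep(0, 20), rep(1, 20))        # complete separation in the confounder
  expect_message(w <- urn_weights(y, z), "Firth")
  expect_true(all(is.finite(w) & w > 0))
})

test_that("weighted urn preserves the case count and reduces to uniform", {
  w <- rep(1, 30)
  draws <- permute_weighted(w, 6, n_draws = 4000, seed = 31)
  expect_true(all(colSums(draws) == 6))
  # equal weights: per-sample inclusion indistinguishable from uniform
  incl <- rowSums(draws)
  chi <- sum((incl - mean(incl))^2 / mean(incl))
  expect_lt(chi, qchisq(0.999, 29))
  # reproducibility
  expect_identical(permute_weighted(w, 6, n_draws = 3, seed = 7),
                   permute_weighted(w, 6, n_draws = 3, seed = 7))
})

test_that("weighted permutation maintains the confounder profile of the cases", {
  set.seed(41)
  n <- 800
  z <- rpois(n, 6) + rbinom(n, 1, 0.3) * rpois(n, 4)
  y <- rbinom(n, 1, plogis(-2.2 + 0.12 * (z - mean(z))))
  n_cases <- sum(y)
  w <- urn_weights(y, z)
  draws_w <- permute_weighted(w, n_cases, n_draws = 400, seed = 42)
  mean_z_w <- mean(colSums(draws_w * z) / n_cases)
  draws_s <- vapply(1:400, function(i) permute_simple(n, n_cases), logical(n))
  mean_z_s <- mean(colSums(draws_s * z) / n_cases)
  true_case_mean <- mean(z[y == 1])
  se <- sd(colSums(draws_w * z) / n_cases) / sqrt(400)
  expect_lt(abs(mean_z_w - true_case_mean), 3 * se + 0.05)
  # simple permutation recovers the population mean instead
  expect_lt(abs(mean_z_s - mean(z)), 0.1)
  expect_gt(abs(true_case_mean - mean(z)), 0.3)   # the contrast is real
})

test_that("expected order statistics approach the uniform limit on a null cohort", {
  sim <- small_sim(seed = 51, risk_genes = c(GENE00001 = 0.05),
                   background_carrier_prob = 0.05, n_genes = 100,
                   n_cases = 100, n_controls = 400)
  cm <- build_collapsing_matrix(suppressMessages(apply_variant_qc(sim$cohort)),
                                sim$manifest, genes = sim$config$gene_names)
  ens <- expected_order_statistics(cm, test = "fisher", permuter = "simple",
                                   n_perm = 300, seed = 8)
  G <- length(ens$mean_sorted_p)
  uniform <- seq_len(G) / (G + 1)
  # Fisher p-values are discrete, so the continuous-uniform limit is only
  # approached loosely at these carrier counts: check location and slope
  expect_lt(mean(abs(ens$mean_sorted_p - uniform)), 0.1)
  fitl <- coef(lm(ens$mean_sorted_p ~ uniform))
  expect_lt(abs(fitl[2] - 1), 0.15)
  # band ordering
  expect_true(all(ens$lower_p <= ens$upper_p + 1e-12))
  expect_identical(ens$mean_sorted_p,
                   expected_order_statistics(cm, "fisher", "simple",
                                             n_perm = 300, seed = 8)$mean_sorted_p)
  expect_error(expected_order_statistics(cm, n_perm = 1), "at least 2")
})

test_that("observed null statistics fall inside the permutation band", {
  sim <- small_sim(seed = 52, risk_genes = setNames(numeric(0), character(0)),
                   background_carrier_prob = 0.05, n_genes = 120,
                   n_cases = 100, n_controls = 400,
                   syn_case_mean = 5, syn_control_mean = 5)
  cm <- build_collapsing_matrix(suppressMessages(apply_variant_qc(sim$cohort)),
                                sim$manifest, genes = sim$config$gene_names)
  fit <- collapsing_fit(cm, tests = "fisher")
  ens <- expected_order_statistics(cm, "fisher", "simple", n_perm = 300,
                                   seed = 9)
  obs <- sort(fit$results$fisher_p)
  inside <- obs >= ens$lower_p & obs <= ens$upper_p
  expect_gte(mean(inside), 0.93)
})

test_that("genomic lambda: identity at p = 0.5, calibrated on uniform p", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1.0)
  set.seed(61)
  expect_lt(abs(genomic_lambda(runif(10000)) - 1), 0.03)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("qq_table aligns observed and expected ranks", {
  sim <- small_sim(seed = 53, n_genes = 40)
  cm <- build_collapsing_matrix(suppressMessages(apply_variant_qc(sim$cohort)),
                                sim$manifest, genes = sim$config$gene_names)
  fit <- collapsing_fit(cm, tests = "fisher")
  ens <- expected_order_statistics(cm, "fisher", "simple", n_perm = 50,
                                   seed = 3)
  qq <- qq_table(fit, ens, "fisher")
  expect_equal(nrow(qq), 40)
  expect_equal(qq$observed_log10, -log10(sort(fit$results$fisher_p)),
               tolerance = 1e-12)
  expect_true(all(qq$lower_log10 <= qq$upper_log10 + 1e-12))
})
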