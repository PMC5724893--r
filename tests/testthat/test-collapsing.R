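# Qualifying-variant logic, the dominant-model matrix and the synonymous
# covariate.

test_that("cohort allele copies count het as 1 and hom-alt as 2", {
  v <- rbind(tiny_variant("v1"), tiny_variant("v2", pos = 200),
             tiny_variant("v3", pos = 300))
  g <- rbind(tiny_genotype("v1", "CASE1"),
             tiny_genotype("v2", "CASE1", call = "hom_alt", alt_reads = 30),
             tiny_genotype("v2", "CTRL1", call = "hom_alt", alt_reads = 30))
  co <- new_cohort(v, g, tiny_manifest()$sample_id)
  copies <- cohort_alt_copies(co)
  expect_equal(unname(copies[c("v1", "v2", "v3")]), c(1L, 4L, 0L))
  # restricting the sample set restricts the count
  expect_equal(unname(cohort_alt_copies(co, c("CASE1", "CASE2"))[["v2"]]), 2L)
})

test_that("qualifying decisions follow rarity, databases and impact", {
  rule <- qualifying_rule()
  mk <- function(...) tiny_variant(...)
  expect_true(is_qualifying(mk(effect = "stop_gained", polyphen = "unknown"),
                            rule, copies = 1))
  expect_false(is_qualifying(mk(in_exac = TRUE), rule, copies = 1))
  expect_false(is_qualifying(mk(in_evs = TRUE), rule, copies = 1))
  expect_false(is_qualifying(mk(polyphen = "possibly_damaging"), rule, 1))
  expect_false(is_qualifying(mk(), rule, copies = 5))
  expect_true(is_qualifying(mk(), rule, copies = 4))
  expect_false(is_qualifying(mk(effect = "synonymous", polyphen = "unknown"),
                             rule, 1))
})

test_that("dominant collapse: multiple qualifying variants still give indicator 1", {
  v <- rbind(tiny_variant("v1", gene = "G1"),
             tiny_variant("v2", pos = 200, gene = "G1"),
             tiny_variant("v3", pos = 300, gene = "G2"))
  g <- rbind(tiny_genotype("v1", "CASE1"), tiny_genotype("v2", "CASE1"),
             tiny_genotype("v3", "CTRL1"))
  co <- new_cohort(v, g, tiny_manifest()$sample_id)
  cm <- build_collapsing_matrix(co, tiny_manifest(), genes = c("G1", "G2", "G3"))
  expect_equal(as.vector(cm$indicator["G1", ]), c(1, 0, 0, 0) > 0)
  expect_equal(as.vector(cm$indicator["G2", ]), c(0, 0, 1, 0) > 0)
  expect_equal(sum(cm$indicator["G3", ]), 0)    # zero-qualifying gene: all-zero row
})

test_that("matrix row sums match a brute-force recount on a simulated cohort", {
  sim <- small_sim(seed = 71)
  co <- suppressMessages(apply_variant_qc(sim$cohort))
  cm <- build_collapsing_matrix(co, sim$manifest, genes = sim$config$gene_names)
  # brute force: recount qualifying carriers per gene from raw tables
  v <- co$variants
  copies <- cohort_alt_copies(co)
  qual <- is_qualifying(v, qualifying_rule(), copies[v$variant_id])
  g <- co$genotypes[co$genotypes$call %in% c("het", "hom_alt"), ]
  g <- g[g$variant_id %in% v$variant_id[qual], ]
  g$gene <- v$gene[match(g$variant_id, v$variant_id)]
  brute <- tapply(g$sample_id, g$gene, function(s) length(unique(s)))
  got <- rowSums(cm$indicator)
  expect_equal(unname(got[names(brute)]), unname(as.integer(brute)))
  # conservation: case + control carriers equals the row sum
  y <- cm$phenotype == "case"
  expect_equal(as.vector(cm$indicator %*% y + cm$indicator %*% !y),
               unname(as.vector(got)))
  # planted truth: post-QC carriers equal the generator's counts exactly
  expect_equal(unname(got[names(sim$truth$planted_carriers)]),
               unname(as.integer(sim$truth$planted_carriers)))
})

test_that("stricter rules never increase carrier counts", {
  sim <- small_sim(seed = 72)
  co <- suppressMessages(apply_variant_qc(sim$cohort))
  base <- rowSums(build_collapsing_matrix(
    co, sim$manifest, qualifying_rule(), genes = sim$config$gene_names)$indicator)
  for (strict in list(qualifying_rule(max_cohort_alt_copies = 1),
                      qualifying_rule(lof_effects = LOF_EFFECTS,
                                      missense_polyphen = "no_such_label"))) {
    tightened <- rowSums(build_collapsing_matrix(
      co, sim$manifest, strict, genes = sim$config$gene_names)$indicator)
    expect_true(all(tightened <= base))
  }
})

test_that("synonymous covariate counts distinct ultra-rare synonymous variants", {
  v <- rbind(tiny_variant("s1", effect = "synonymous", polyphen = "unknown"),
             tiny_variant("s2", pos = 200, effect = "synonymous",
                          polyphen = "unknown"),
             tiny_variant("s3", pos = 300, effect = "synonymous",
                          polyphen = "unknown"),
             tiny_variant("s4", pos = 400, effect = "synonymous",
                          polyphen = "unknown", in_exac = TRUE),
             tiny_variant("m1", pos = 500))
  g <- rbind(tiny_genotype("s1", "CASE1"),
             tiny_genotype("s2", "CASE1", call = "hom_alt", alt_reads = 30),
             tiny_genotype("s3", "CASE1"),
             tiny_genotype("s4", "CASE1"),      # in ExAC: contributes 0
             tiny_genotype("m1", "CASE1"),      # missense: not synonymous
             tiny_genotype("s1", "CTRL1"))
  co <- new_cohort(v, g, tiny_manifest()$sample_id)
  z <- synonymous_covariate(co)
  expect_equal(unname(z[c("CASE1", "CASE2", "CTRL1", "CTRL2")]),
               c(3L, 0L, 1L, 0L))
  # and the generator's planted counts are recovered exactly
  sim <- small_sim(seed = 73)
  z_sim <- synonymous_covariate(sim$cohort)
  expect_equal(z_sim, sim$truth$syn_counts[names(z_sim)])
})

test_that("coverage-pruned sites drop out of both qualifying and covariate counts", {
  v <- rbind(tiny_variant("v1", pos = 100, gene = "G1"),
             tiny_variant("s1", pos = 200, effect = "synonymous",
                          polyphen = "unknown", gene = "G1"))
  g <- rbind(tiny_genotype("v1", "CASE1"), tiny_genotype("s1", "CASE1"))
  co <- new_cohort(v, g, tiny_manifest()$sample_id)
  cm <- suppressMessages(build_collapsing_matrix(
    co, tiny_manifest(), retained_sites = "1:200", genes = "G1"))
  expect_equal(sum(cm$indicator), 0)            # v1's site was pruned
  expect_equal(unname(cm$syn_covariate["CASE1"]), 1L)
  cm2 <- suppressMessages(build_collapsing_matrix(
    co, tiny_manifest(), retained_sites = "1:100", genes = "G1"))
  expect_equal(sum(cm2$indicator), 1)
  expect_equal(unname(cm2$syn_covariate["CASE1"]), 0L)
})
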