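# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A hand-built cohort with fully known content for unit-level checks.
# 4 samples (2 cases, 2 controls), 1 gene territory per chromosome.
tiny_manifest <- function() {
  data.frame(
    sample_id = c("CASE1", "CASE2", "CTRL1", "CTRL2"),
    phenotype = c("case", "case", "control", "control"),
    mean_ccds_coverage = c(0.95, 0.93, 0.96, 0.90),
    stringsAsFactors = FALSE)
}

tiny_variant <- function(variant_id = "1:100:A:T", chrom = "1", pos = 100,
                         ref = "A", alt = "T", qual = 200, qd = 10, mq = 60,
                         rprs = 0, mqrs = 0, fs = 1, vqsr_pass = TRUE,
                         is_indel = FALSE, gene = "G1", effect = "missense",
                         polyphen = "probably_damaging", in_evs = FALSE,
                         in_exac = FALSE, on_artifact_list = FALSE) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, qual = qual, qd = qd, mq = mq, rprs = rprs,
             mqrs = mqrs, fs = fs, vqsr_pass = vqsr_pass,
             is_indel = is_indel, gene = gene, effect = effect,
             polyphen = polyphen, in_evs = in_evs, in_exac = in_exac,
             on_artifact_list = on_artifact_list, stringsAsFactors = FALSE)
}

tiny_genotype <- function(variant_id, sample_id, call = "het", depth = 30,
                          gq = 99, alt_reads = 15) {
  data.frame(variant_id = variant_id, sample_id = sample_id, call = call,
             depth = depth, gq = gq, alt_reads = alt_reads,
             stringsAsFactors = FALSE)
}

# Small simulated cohort used by several integration tests.
small_sim <- function(seed = 11, ...) {
  args <- modifyList(list(
    n_cases = 50, n_controls = 200, n_genes = 60,
    background_carrier_prob = 0.01,
    risk_genes = c(GENE00001 = 0.3),
    syn_control_mean = 4, syn_case_mean = 5,
    n_panel_snps = 500, n_artifact_variants = 2, n_qcfail_variants = 2,
    seed = seed), list(...))
  simulate_cohort(do.call(sim_config, args))
}
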