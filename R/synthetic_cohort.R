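# Synthetic case-control exome cohorts with the statistical structure the
# collapsing analysis assumes: ultra-rare qualifying-variant carriers with
# designated risk genes enriched in cases, a per-sample ultra-rare
# synonymous count that is shifted in cases (batch confounder) and can
# drive the background qualifying-variant rate, capture-kit-style coverage
# imbalance at a minority of sites, planted related pairs and a
# two-subpopulation common-SNP panel for the sample-QC stages.
#
# The simulation is carrier-level: the collapsing statistic only sees
# carrier status, so each (gene, sample) carriage event is a Bernoulli
# draw and carriers are grouped into variants with 1-4 cohort allele
# copies, emulating the ultra-rare copy ceiling without simulating a full
# site frequency spectrum.

#' Simulation configuration
#'
#' Defaults emulate a large epileptic-encephalopathy-style exome study:
#' 488 cases vs 12,151 controls, a genome-wide gene set, per-gene
#' background ultra-rare qualifying carrier probability of 0.001, three
#' risk genes with case carrier probabilities matching the strongest
#' reported signals (0.0205, 0.0123, 0.0164), a negative-binomial
#' ultra-rare synonymous count shifted in cases, coverage imbalance at 5%
#' of sites, one duplicate and one parent-offspring pair, and mild
#' two-subpopulation structure on a common-SNP panel. Tests and examples
#' pass smaller explicit sizes.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_genes number of genes (named `GENE00001` ...).
#' @param background_carrier_prob per-gene qualifying-carrier probability
#'   in controls (and in cases for non-risk genes).
#' @param risk_genes named numeric vector: gene -> case carrier
#'   probability. Names must be valid gene names (hard error otherwise).
#' @param syn_control_mean,syn_case_mean,syn_dispersion negative-binomial
#'   model (mu, size) for the per-sample ultra-rare synonymous count.
#' @param covariate_effect log-odds change in the per-sample qualifying
#'   carrier probability per unit of (synonymous count - cohort mean); a
#'   nonzero value makes the synonymous count a genuine confounder.
#' @param coverage_gap_fraction fraction of variant sites with a
#'   capture-kit coverage gap between cases and controls.
#' @param coverage_gap_case_rate,coverage_gap_control_rate per-sample
#'   >= 10x probability at gap sites.
#' @param coverage_background_uncovered background per-genotype
#'   probability of < 10x coverage at ordinary sites.
#' @param n_duplicate_pairs,n_parent_offspring_pairs planted related pairs
#'   (each pairs a case with a control or two controls, on the SNP panel).
#' @param genotype_error per-SNP flip probability for planted duplicates.
#' @param n_panel_snps common SNPs in the sample-QC panel.
#' @param subpop_fraction,subpop_fst two-subpopulation mixture on the
#'   panel (Balding-Nichols divergence `subpop_fst`).
#' @param n_outlier_samples,outlier_fst control samples drawn from a
#'   strongly diverged population (PCA outliers).
#' @param nonqualifying_rate expected non-qualifying background variants
#'   per gene (database-present or benign; exercise the filters).
#' @param n_artifact_variants,n_qcfail_variants planted case-enriched
#'   decoy variants that must be removed by artifact screening / site QC.
#' @param seed integer seed recorded in the output metadata.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 488, n_controls = 12151, n_genes = 18503,
                       background_carrier_prob = 0.001,
                       risk_genes = c(GENE00001 = 0.0205,
                                      GENE00002 = 0.0123,
                                      GENE00003 = 0.0164),
                       syn_control_mean = 6, syn_case_mean = 7.5,
                       syn_dispersion = 8,
                       covariate_effect = 0,
                       coverage_gap_fraction = 0.05,
                       coverage_gap_case_rate = 0.75,
                       coverage_gap_control_rate = 0.97,
                       coverage_background_uncovered = 0.002,
                       n_duplicate_pairs = 1,
                       n_parent_offspring_pairs = 1,
                       genotype_error = 0.005,
                       n_panel_snps = 5000,
                       subpop_fraction = 0.5, subpop_fst = 0.005,
                       n_outlier_samples = 1, outlier_fst = 0.2,
                       nonqualifying_rate = 0.5,
                       n_artifact_variants = 5, n_qcfail_variants = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  assert_that(n_cases >= 1 && n_controls >= 1, "need at least one case and control")
  probs <- c(background_carrier_prob, risk_genes, coverage_gap_fraction,
             coverage_gap_case_rate, coverage_gap_control_rate,
             coverage_background_uncovered, subpop_fraction, genotype_error)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  gene_names <- sprintf("GENE%05d", seq_len(n_genes))
  if (length(risk_genes)) {
    bad <- setdiff(names(risk_genes), gene_names)
    assert_that(length(bad) == 0, "risk gene(s) not among the %d genes: %s",
                n_genes, paste(bad, collapse = ", "))
  }
  cfg$gene_names <- gene_names
  structure(cfg, class = "sim_config")
}

# gene g -> genomic interval (22 chromosomes, 10 kb stride, 2 kb "exon")
.gene_coords <- function(g_idx) {
  chrom <- as.character(((g_idx - 1) %% 22) + 1)
  block <- (g_idx - 1) %/% 22
  start0 <- block * 10000 + 1000          # 0-based region start
  list(chrom = chrom, start0 = start0, end0 = start0 + 2000)
}

.rand_base <- function(n, not = NULL) {
  b <- c("A", "C", "G", "T")
  out <- sample(b, n, replace = TRUE)
  if (!is.null(not)) {
    clash <- out == not
    while (any(clash)) {
      out[clash] <- sample(b, sum(clash), replace = TRUE)
      clash <- out == not
    }
  }
  out
}

#' Simulate a case-control collapsing cohort
#'
#' @param config a [sim_config()].
#' @return Object of class `rv_sim`: `cohort` (an `rv_cohort`),
#'   `coverage` (`rv_coverage`), `manifest`, `regions`, `snp_panel`
#'   (samples x SNPs dosage matrix), and `truth` (planted risk genes,
#'   decoy variants, coverage-gap sites, related pairs, subpopulation and
#'   outlier labels, seed). Fully reproducible given `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  n_ca <- cfg$n_cases; n_co <- cfg$n_controls; n <- n_ca + n_co
  samples <- c(sprintf("CASE%05d", seq_len(n_ca)),
               sprintf("CTRL%05d", seq_len(n_co)))
  is_case <- c(rep(TRUE, n_ca), rep(FALSE, n_co))
  manifest <- data.frame(
    sample_id = samples,
    phenotype = ifelse(is_case, "case", "control"),
    mean_ccds_coverage = round(runif(n, 0.88, 0.97), 4),
    stringsAsFactors = FALSE)

  genes <- cfg$gene_names
  G <- length(genes)

  # per-sample ultra-rare synonymous counts (batch-confounded covariate)
  z <- rnbinom(n, size = cfg$syn_dispersion,
               mu = ifelse(is_case, cfg$syn_case_mean, cfg$syn_control_mean))

  # --- qualifying-candidate carriers per gene -----------------------------
  p_case <- rep(cfg$background_carrier_prob, G)
  names(p_case) <- genes
  if (length(cfg$risk_genes)) p_case[names(cfg$risk_genes)] <- cfg$risk_genes
  p_ctrl <- rep(cfg$background_carrier_prob, G)

  b <- cfg$covariate_effect
  zc <- z - mean(z)
  carrier_list <- vector("list", G)
  if (b == 0) {
    cnt_ca <- rbinom(G, n_ca, p_case)
    cnt_co <- rbinom(G, n_co, p_ctrl)
    for (g in seq_len(G)) {
      ca <- if (cnt_ca[g] > 0) sample.int(n_ca, cnt_ca[g]) else integer(0)
      co <- if (cnt_co[g] > 0) n_ca + sample.int(n_co, cnt_co[g]) else integer(0)
      carrier_list[[g]] <- c(ca, co)
    }
  } else {
    base_ca <- qlogis(p_case); base_co <- qlogis(p_ctrl)
    for (g in seq_len(G)) {
      eta <- ifelse(is_case, base_ca[g], base_co[g]) + b * zc
      carrier_list[[g]] <- which(runif(n) < plogis(eta))
    }
  }

  # --- group carriers into variants (<= 4 cohort allele copies) -----------
  v_gene <- list(); v_carriers <- list(); v_hom <- list()
  for (g in seq_len(G)) {
    cs <- carrier_list[[g]]
    if (!length(cs)) next
    cs <- cs[sample.int(length(cs))]
    while (length(cs)) {
      s <- sample(1:4, 1, prob = c(0.65, 0.2, 0.1, 0.05))
      take <- cs[seq_len(min(s, length(cs)))]
      cs <- cs[-seq_len(min(s, length(cs)))]
      hom <- length(take) == 1 && runif(1) < 0.02   # 2 copies, still <= 4
      k <- length(v_gene) + 1L
      v_gene[[k]] <- g; v_carriers[[k]] <- take; v_hom[[k]] <- hom
    }
  }
  n_qv <- length(v_gene)
  qual_class <- rep("qualifying", n_qv)

  # --- planted decoys: artifacts and site-QC failures, case-enriched ------
  add_decoy <- function(n_var, class) {
    non_risk <- setdiff(seq_len(G), match(names(cfg$risk_genes), genes))
    for (i in seq_len(n_var)) {
      g <- sample(non_risk, 1)
      k <- length(v_gene) + 1L
      v_gene[[k]] <<- g
      v_carriers[[k]] <<- sample.int(n_ca, min(n_ca, 6))   # case-skewed
      v_hom[[k]] <<- FALSE
      qual_class[k] <<- class
    }
  }
  add_decoy(cfg$n_artifact_variants, "artifact")
  add_decoy(cfg$n_qcfail_variants, "qcfail")

  # --- background non-qualifying variants ---------------------------------
  n_bg <- rpois(1, cfg$nonqualifying_rate * G)
  if (n_bg > 0) for (i in seq_len(n_bg)) {
    g <- sample.int(G, 1)
    k <- length(v_gene) + 1L
    v_gene[[k]] <- g
    v_carriers[[k]] <- sample.int(n, sample(1:3, 1))
    v_hom[[k]] <- FALSE
    qual_class[k] <- sample(c("benign_missense", "in_exac_missense", "in_exac_lof"),
                            1, prob = c(0.5, 0.3, 0.2))
  }

  # --- synonymous singletons realizing the covariate ----------------------
  syn_sample <- rep(seq_len(n), z)
  syn_gene <- sample.int(G, length(syn_sample), replace = TRUE)

  # --- assemble the variant table -----------------------------------------
  n_v <- length(v_gene)
  gene_idx <- unlist(v_gene)
  # functional-variant offsets: distinct positions in 1..999 per gene
  off <- integer(n_v)
  for (g in unique(gene_idx)) {
    sel <- which(gene_idx == g)
    off[sel] <- sample.int(999, length(sel))
  }
  co <- .gene_coords(gene_idx)
  pos <- co$start0 + off                    # 1-based: start0 + off in (start0, end0]
  chrom <- co$chrom
  # synonymous offsets: reserved band 1000..1999, sequential per gene
  syn_off <- integer(length(syn_gene))
  if (length(syn_gene)) {
    ord <- order(syn_gene)
    rle_g <- rle(syn_gene[ord])
    assert_that(max(rle_g$lengths) <= 999,
                "too many synonymous variants per gene; increase n_genes")
    syn_off[ord] <- 1000L + sequence(rle_g$lengths)
  }
  co_s <- .gene_coords(syn_gene)
  syn_pos <- co_s$start0 + syn_off
  syn_chrom <- co_s$chrom

  eff_lof <- function(k) sample(LOF_EFFECTS, k, replace = TRUE)
  effect <- character(n_v); polyphen <- character(n_v)
  in_exac <- logical(n_v); artifact <- logical(n_v); qcfail <- logical(n_v)
  for (cls in unique(qual_class)) {
    sel <- which(qual_class == cls)
    kk <- length(sel)
    if (cls %in% c("qualifying", "artifact", "qcfail")) {
      lof <- runif(kk) < 0.3
      effect[sel] <- ifelse(lof, eff_lof(kk), "missense")
      polyphen[sel] <- ifelse(lof, "unknown", "probably_damaging")
      artifact[sel] <- cls == "artifact"
      qcfail[sel] <- cls == "qcfail"
    } else if (cls == "benign_missense") {
      effect[sel] <- "missense"
      polyphen[sel] <- sample(c("possibly_damaging", "benign"), kk, replace = TRUE)
    } else if (cls == "in_exac_missense") {
      effect[sel] <- "missense"; polyphen[sel] <- "probably_damaging"
      in_exac[sel] <- TRUE
    } else {
      effect[sel] <- eff_lof(kk); polyphen[sel] <- "unknown"
      in_exac[sel] <- TRUE
    }
  }
  is_indel <- effect %in% c("frame_shift", "exon_deleted")
  ref <- .rand_base(n_v)
  alt <- ifelse(is_indel, paste0(ref, .rand_base(n_v)), .rand_base(n_v, not = ref))

  all_chrom <- c(chrom, syn_chrom)
  all_pos <- c(pos, syn_pos)
  all_ref <- c(ref, .rand_base(length(syn_pos)))
  syn_alt <- .rand_base(length(syn_pos), not = all_ref[n_v + seq_along(syn_pos)])
  all_alt <- c(alt, syn_alt)
  n_all <- length(all_pos)
  variants <- data.frame(
    variant_id = variant_key(all_chrom, all_pos, all_ref, all_alt),
    chrom = all_chrom, pos = all_pos, ref = all_ref, alt = all_alt,
    qual = pmax(35, round(rnorm(n_all, 300, 40), 1)),
    qd = pmax(3, round(rnorm(n_all, 12, 3), 2)),
    mq = pmin(70, pmax(45, round(rnorm(n_all, 60, 2), 2))),
    rprs = round(rnorm(n_all, 0, 0.8), 3),
    mqrs = round(rnorm(n_all, 0, 0.8), 3),
    fs = round(abs(rnorm(n_all, 2, 2)), 3),
    vqsr_pass = TRUE,
    is_indel = c(is_indel, rep(FALSE, length(syn_pos))),
    gene = genes[c(gene_idx, syn_gene)],
    effect = c(effect, rep("synonymous", length(syn_pos))),
    polyphen = c(polyphen, rep("unknown", length(syn_pos))),
    in_evs = FALSE,
    in_exac = c(in_exac, rep(FALSE, length(syn_pos))),
    on_artifact_list = c(artifact, rep(FALSE, length(syn_pos))),
    stringsAsFactors = FALSE)
  # planted site-QC failures: drop QUAL below threshold
  variants$qual[which(c(qcfail, rep(FALSE, length(syn_pos))))] <- 25

  # --- genotype rows ------------------------------------------------------
  gt_var <- c(rep(variants$variant_id[seq_len(n_v)],
                  vapply(v_carriers, length, 1L)),
              variants$variant_id[n_v + seq_along(syn_sample)])
  gt_sample_idx <- c(unlist(v_carriers), syn_sample)
  hom_flag <- c(rep(unlist(v_hom), vapply(v_carriers, length, 1L)),
                rep(FALSE, length(syn_sample)))
  n_gt <- length(gt_var)
  depth <- pmax(10L, rpois(n_gt, 40))
  gq <- sample(60:99, n_gt, replace = TRUE)
  alt_reads <- ifelse(hom_flag, depth,
                      pmax(ceiling(0.25 * depth), rbinom(n_gt, depth, 0.5)))
  genotypes <- data.frame(
    variant_id = gt_var, sample_id = samples[gt_sample_idx],
    call = ifelse(hom_flag, "hom_alt", "het"),
    depth = depth, gq = gq, alt_reads = as.integer(alt_reads),
    stringsAsFactors = FALSE)
  cohort <- new_cohort(variants, genotypes, samples)

  # --- regions ------------------------------------------------------------
  gco <- .gene_coords(seq_len(G))
  regions <- normalize_regions(data.frame(
    chrom = gco$chrom, start = gco$start0, end = gco$end0,
    stringsAsFactors = FALSE))

  # --- coverage -----------------------------------------------------------
  site_keys <- unique(site_key(variants$chrom, variants$pos))
  n_sites <- length(site_keys)
  n_gap <- round(cfg$coverage_gap_fraction * n_sites)
  gap_sites <- sample.int(n_sites, n_gap)
  ui <- integer(0); uj <- integer(0)
  n_unc <- rbinom(1, n_sites * n, cfg$coverage_background_uncovered)
  if (n_unc > 0) {
    ui <- sample.int(n_sites, n_unc, replace = TRUE)
    uj <- sample.int(n, n_unc, replace = TRUE)
  }
  if (n_gap > 0) {
    miss_ca <- matrix(runif(n_gap * n_ca), n_gap) > cfg$coverage_gap_case_rate
    miss_co <- matrix(runif(n_gap * n_co), n_gap) > cfg$coverage_gap_control_rate
    wca <- which(miss_ca, arr.ind = TRUE)
    wco <- which(miss_co, arr.ind = TRUE)
    ui <- c(ui, gap_sites[wca[, 1]], gap_sites[wco[, 1]])
    uj <- c(uj, wca[, 2], n_ca + wco[, 2])
  }
  keep <- !duplicated(cbind(ui, uj))
  uncov <- sparseMatrix(i = ui[keep], j = uj[keep],
                        dims = c(n_sites, n),
                        dimnames = list(site_keys, samples))
  coverage <- structure(list(backend = "sites", site_keys = site_keys,
                             samples = samples,
                             uncov = as(uncov, "CsparseMatrix")),
                        class = "rv_coverage")

  # --- common-SNP panel: subpopulations, outliers, related pairs ----------
  m <- cfg$n_panel_snps
  p_anc <- runif(m, 0.05, 0.5)
  bn <- function(p, fst) if (fst <= 0) p else
    rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  p1 <- bn(p_anc, cfg$subpop_fst); p2 <- bn(p_anc, cfg$subpop_fst)
  pop <- rbinom(n, 1, cfg$subpop_fraction)
  panel <- matrix(0L, n, m, dimnames = list(samples, NULL))
  for (k in 0:1) {
    rows <- which(pop == k)
    pk <- if (k == 0) p1 else p2
    if (length(rows))
      panel[rows, ] <- matrix(rbinom(length(rows) * m, 2, rep(pk, each = length(rows))),
                              length(rows), m)
  }
  out_ids <- character(0)
  if (cfg$n_outlier_samples > 0) {
    p_out <- bn(p_anc, cfg$outlier_fst)
    out_rows <- n_ca + sample.int(n_co, cfg$n_outlier_samples)
    panel[out_rows, ] <- matrix(rbinom(cfg$n_outlier_samples * m, 2,
                                       rep(p_out, each = cfg$n_outlier_samples)),
                                cfg$n_outlier_samples, m)
    out_ids <- samples[out_rows]
  }
  rel <- data.frame(kind = character(0), sample1 = character(0),
                    sample2 = character(0), stringsAsFactors = FALSE)
  avail_ctrl <- setdiff(seq_len(n_co), match(out_ids, samples) - n_ca)
  take_ctrl <- function(k) {
    got <- avail_ctrl[seq_len(k)]
    avail_ctrl <<- avail_ctrl[-seq_len(k)]
    n_ca + got
  }
  if (cfg$n_duplicate_pairs > 0) for (i in seq_len(cfg$n_duplicate_pairs)) {
    a <- min(i, n_ca)                       # duplicate a case into a control
    bz <- take_ctrl(1)
    gdup <- panel[a, ]
    flip <- runif(m) < cfg$genotype_error
    gdup[flip] <- sample(0:2, sum(flip), replace = TRUE)
    panel[bz, ] <- gdup
    rel[nrow(rel) + 1, ] <- c("duplicate", samples[a], samples[bz])
  }
  if (cfg$n_parent_offspring_pairs > 0)
    for (i in seq_len(cfg$n_parent_offspring_pairs)) {
      pr <- take_ctrl(2)
      parent <- panel[pr[1], ]
      transmitted <- rbinom(m, 1, parent / 2)
      other <- rbinom(m, 1, p1)             # mate from subpopulation 1
      panel[pr[2], ] <- as.integer(transmitted + other)
      rel[nrow(rel) + 1, ] <- c("parent_offspring", samples[pr[1]], samples[pr[2]])
    }

  truth <- list(
    risk_genes = cfg$risk_genes,
    background_carrier_prob = cfg$background_carrier_prob,
    planted_carriers = setNames(vapply(carrier_list, length, 1L), genes),
    decoy_artifact = variants$variant_id[which(c(qual_class == "artifact",
                                                 rep(FALSE, length(syn_pos))))],
    decoy_qcfail = variants$variant_id[which(c(qual_class == "qcfail",
                                               rep(FALSE, length(syn_pos))))],
    coverage_gap_sites = site_keys[gap_sites],
    related_pairs = rel,
    outlier_samples = out_ids,
    subpopulation = setNames(pop, samples),
    syn_counts = setNames(z, samples),
    seed = cfg$seed)

  structure(list(cohort = cohort, coverage = coverage, manifest = manifest,
                 regions = regions, snp_panel = panel, truth = truth,
                 config = cfg),
            class = "rv_sim")
}

#' @exportS3Method base::print
print.rv_sim <- function(x, ...) {
  cat(sprintf("rv_sim: %d cases / %d controls, %d genes, %d variants (seed %d)\n",
              x$config$n_cases, x$config$n_controls, x$config$n_genes,
              nrow(x$cohort$variants), x$config$seed))
  invisible(x)
}

#' Simulate a null cohort with a confounded covariate
#'
#' As [simulate_cohort()] with the risk set emptied: no gene carries a
#' true effect, but the synonymous covariate keeps its configured
#' case-control shift and (when `covariate_effect > 0`) its influence on
#' the background qualifying-carrier rate, so unadjusted tests inflate
#' while covariate-adjusted ones stay calibrated.
#'
#' @param config a [sim_config()].
#' @export
simulate_null_pvalue_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$risk_genes <- setNames(numeric(0), character(0))
  simulate_cohort(config)
}

#' Serialize a simulated cohort to the pipeline's file formats
#'
#' Writes the VCF, annotation and flags tables, manifest, region BED,
#' coverage (dense-table dialect), SNP panel, known-gene list (the planted
#' risk genes) and a truth JSON into `dir`.
#'
#' @param sim an `rv_sim`.
#' @param dir output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  paths <- list(vcf = pth("cohort.vcf"), annotation = pth("annotation.tsv"),
                flags = pth("flags.tsv"), manifest = pth("manifest.tsv"),
                regions = pth("regions.bed"), coverage = pth("coverage.tsv"),
                snp_panel = pth("snp_panel.tsv"),
                known_genes = pth("known_genes.txt"),
                truth = pth("truth.json"))
  write_cohort(sim$cohort, paths$vcf, paths$annotation, paths$flags)
  write_manifest(sim$manifest, paths$manifest)
  write_region_set(sim$regions, paths$regions)
  cov_dense <- coverage_matrix(sim$coverage,
                               sub(":.*", "", sim$coverage$site_keys),
                               as.integer(sub(".*:", "", sim$coverage$site_keys)),
                               sim$coverage$samples)
  rownames(cov_dense) <- sim$coverage$site_keys
  write_coverage(cov_dense, paths$coverage, "table")
  panel <- data.frame(sample_id = rownames(sim$snp_panel), sim$snp_panel,
                      check.names = FALSE)
  write.table(panel, paths$snp_panel, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(names(sim$truth$risk_genes), paths$known_genes)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
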