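# End-to-end orchestration: variant QC -> sample QC -> coverage
# harmonization -> collapsing -> association -> permutation QQ ->
# enrichment, from a single config, with per-stage logging and a run
# report. Stages are ordinary exported functions, so each is invocable
# and testable in isolation; `run_pipeline()` wires files to the
# in-memory core `run_collapsing_pipeline()`.

# Tiny dependency-free rolling hash for config provenance.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), checks it against the schema,
#' fills defaults (QC thresholds, kinship cutoff 0.1, PCA sigma 6.0 / top
#' 10 PCs / 5 iterations, LD r^2 0.1, coverage max difference 0.1197,
#' copy ceiling 4, 1000 permutations) and reports every violation at
#' once rather than stopping at the first.
#'
#' @param config path to a YAML file or a named list.
#' @return Validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML path")
  defaults <- list(
    qc_thresholds = list(), qualifying_rule = list(),
    kinship_cutoff = 0.1, ld_r2 = 0.1,
    pca_sigma = 6.0, pca_n_pcs = 10, pca_iterations = 5,
    max_coverage_diff = 0.1197,
    tests = c("fisher", "firth"), use_covariate = TRUE,
    n_permutations = 1000, n_permutations_firth = 0,
    n_genes_targeted = NULL, seed = 1, output_dir = NULL)
  cfg <- modifyList(defaults, config)
  errors <- character(0)
  for (f in c("vcf", "annotation", "flags", "manifest")) {
    if (is.null(cfg[[f]])) errors <- c(errors, sprintf("missing required path '%s'", f))
    else if (!file.exists(cfg[[f]]))
      errors <- c(errors, sprintf("'%s' file does not exist: %s", f, cfg[[f]]))
  }
  for (f in c("coverage", "regions", "snp_panel", "known_genes"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      errors <- c(errors, sprintf("'%s' file does not exist: %s", f, cfg[[f]]))
  if (cfg$max_coverage_diff < 0) errors <- c(errors, "max_coverage_diff must be >= 0")
  if (cfg$kinship_cutoff < 0) errors <- c(errors, "kinship_cutoff must be >= 0")
  if (cfg$n_permutations < 0) errors <- c(errors, "n_permutations must be >= 0")
  if (!all(cfg$tests %in% c("fisher", "firth")))
    errors <- c(errors, "tests must be a subset of fisher, firth")
  th <- tryCatch(do.call(qc_thresholds, cfg$qc_thresholds),
                 error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  qr <- tryCatch(do.call(qualifying_rule, cfg$qualifying_rule),
                 error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  if (length(errors))
    stop_rv("invalid config:\n  - %s", paste(errors, collapse = "\n  - "))
  cfg$qc_thresholds <- th
  cfg$qualifying_rule <- qr
  class(cfg) <- "run_config"
  cfg
}

#' Run the collapsing pipeline on in-memory objects
#'
#' Executes the analysis stages in order on already-loaded inputs. Any of
#' `coverage`, `regions`, `snp_panel`, `known_genes` may be `NULL`, in
#' which case the corresponding stage is skipped (logged).
#'
#' @param cohort an `rv_cohort`.
#' @param manifest sample manifest data.frame.
#' @param coverage optional `rv_coverage`.
#' @param regions optional region set.
#' @param snp_panel optional samples-by-SNPs dosage matrix for the
#'   relatedness and PCA stages.
#' @param known_genes optional character vector for the enrichment stage.
#' @param thresholds,rule QC thresholds and qualifying rule.
#' @param kinship_cutoff,ld_r2,pca_sigma,pca_n_pcs,pca_iterations
#'   sample-QC parameters.
#' @param max_coverage_diff coverage-harmonization threshold.
#' @param tests,use_covariate,n_genes_targeted association options.
#' @param n_permutations simple-permutation count for the Fisher QQ
#'   ensemble (0 skips); `n_permutations_firth` likewise for the
#'   weighted-urn Firth ensemble (defaults to 0: the Firth refits make it
#'   by far the most expensive stage, so it is opt-in).
#' @param n_permutations_firth see above.
#' @param genes optional gene universe for the matrix rows.
#' @param seed integer seed driving every stochastic stage.
#' @return Object of class `rv_pipeline_result`.
#' @export
run_collapsing_pipeline <- function(cohort, manifest, coverage = NULL,
                                    regions = NULL, snp_panel = NULL,
                                    known_genes = NULL,
                                    thresholds = qc_thresholds(),
                                    rule = qualifying_rule(),
                                    kinship_cutoff = 0.1, ld_r2 = 0.1,
                                    pca_sigma = 6.0, pca_n_pcs = 10,
                                    pca_iterations = 5,
                                    max_coverage_diff = 0.1197,
                                    tests = c("fisher", "firth"),
                                    use_covariate = TRUE,
                                    n_permutations = 1000,
                                    n_permutations_firth = 0,
                                    n_genes_targeted = NULL, genes = NULL,
                                    seed = 1) {
  counts <- list(samples_in = nrow(manifest), variants_in = nrow(cohort$variants))

  if (!is.null(regions)) cohort <- restrict_to_regions(cohort, regions)
  counts$variants_in_regions <- nrow(cohort$variants)

  cohort <- apply_variant_qc(cohort, thresholds)
  counts$variants_post_qc <- nrow(cohort$variants)

  retained <- manifest$sample_id
  removal_log <- NULL; pca <- NULL
  if (!is.null(snp_panel)) {
    kin <- kinship_estimate(snp_panel[retained, , drop = FALSE])
    retained <- prune_related(kin, manifest, cutoff = kinship_cutoff)
    removal_log <- attr(retained, "removals")
    keep_snps <- ld_prune(snp_panel[retained, , drop = FALSE],
                          r2_threshold = ld_r2)
    pca <- pca_outlier_removal(snp_panel[retained, keep_snps, drop = FALSE],
                               n_pcs = pca_n_pcs, sigma = pca_sigma,
                               iterations = pca_iterations)
    retained <- pca$retained
  } else pipe_log("no SNP panel supplied; relatedness and PCA stages skipped")
  counts$samples_retained <- length(retained)
  manifest_r <- manifest[manifest$sample_id %in% retained, , drop = FALSE]

  retained_sites <- NULL
  if (!is.null(coverage)) {
    retained_sites <- harmonize_coverage(cohort, coverage, manifest_r,
                                         max_diff = max_coverage_diff)
    counts$sites_pruned_fraction <- attr(retained_sites, "pruned_fraction")
  } else pipe_log("no coverage data supplied; harmonization skipped")

  cm <- build_collapsing_matrix(cohort, manifest_r, rule,
                                samples = manifest_r$sample_id,
                                retained_sites = retained_sites, genes = genes)
  fit <- collapsing_fit(cm, tests = tests, use_covariate = use_covariate,
                        n_genes_targeted = n_genes_targeted)

  ensembles <- list()
  if ("fisher" %in% tests && n_permutations >= 2)
    ensembles$fisher <- expected_order_statistics(
      cm, test = "fisher", permuter = "simple",
      n_perm = n_permutations, seed = seed)
  if ("firth" %in% tests && n_permutations_firth >= 2)
    ensembles$firth <- expected_order_statistics(
      cm, test = "firth", permuter = "weighted",
      n_perm = n_permutations_firth, seed = seed + 1,
      use_covariate = use_covariate)

  enr <- NULL
  if (!is.null(known_genes)) {
    scan <- rank_scan(fit, known_genes)
    p_col <- if ("firth" %in% tests) fit$results$firth_p else fit$results$fisher_p
    known_p <- p_col[match(known_genes, fit$results$gene)]
    enr <- list(
      scan = scan,
      burden = aggregate_burden(cm, intersect(known_genes, cm$genes)),
      nominal_p = nominal_enrichment(sum(known_p < 0.05, na.rm = TRUE),
                                     length(known_genes),
                                     sum(p_col < 0.05),
                                     nrow(fit$results)))
  }

  lambda <- lapply(setNames(tests, tests), function(t)
    genomic_lambda(fit$results[[paste0(t, "_p")]]))
  sig <- lapply(setNames(tests, tests), function(t)
    fit$results$gene[fit$results[[paste0(t, "_p")]] < fit$bonferroni])
  report <- list(counts = counts, lambda = lambda,
                 bonferroni = fit$bonferroni,
                 significant = c(sig, list(
                   joint = Reduce(intersect, sig))),
                 seed = seed,
                 r_version = as.character(getRversion()),
                 package_version = as.character(utils::packageVersion("rvburden")))
  structure(list(fit = fit, matrix = cm, ensembles = ensembles,
                 enrichment = enr, pca = pca, removal_log = removal_log,
                 retained_samples = retained,
                 retained_sites = retained_sites, report = report),
            class = "rv_pipeline_result")
}

#' @exportS3Method base::print
print.rv_pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Collapsing pipeline run\n")
  cat(sprintf("  samples: %d in, %d retained\n", r$counts$samples_in,
              r$counts$samples_retained))
  cat(sprintf("  variants: %d in, %d post QC\n", r$counts$variants_in,
              r$counts$variants_post_qc))
  for (t in names(r$lambda))
    cat(sprintf("  lambda (%s): %.3f\n", t, r$lambda[[t]]))
  cat(sprintf("  genome-wide significant (joint): %s\n",
              if (length(r$significant$joint))
                paste(r$significant$joint, collapse = ", ") else "none"))
  invisible(x)
}

#' Run the pipeline from a config of file paths
#'
#' Reads every input named in the validated config, executes
#' [run_collapsing_pipeline()], and (when `output_dir` is set) serializes
#' gene results, QQ data, enrichment, pruning logs and a JSON run report
#' (config hash, seed, versions) for provenance. Reruns with identical
#' config and seed produce identical result files.
#'
#' @param config a YAML path, a list, or a validated `run_config`.
#' @return An `rv_pipeline_result`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_rv("[stage:%s] %s", name, conditionMessage(e)))
  }
  manifest <- stage("read_manifest", read_manifest(config$manifest))
  cohort <- stage("read_variants",
                  read_variants(config$vcf, config$annotation, config$flags))
  regions <- if (!is.null(config$regions))
    stage("read_regions", read_region_set(config$regions)) else NULL
  coverage <- if (!is.null(config$coverage))
    stage("read_coverage", read_coverage(config$coverage, manifest$sample_id))
    else NULL
  snp_panel <- if (!is.null(config$snp_panel)) stage("read_snp_panel", {
    p <- read.delim(config$snp_panel, check.names = FALSE)
    m <- as.matrix(p[, -1, drop = FALSE])
    rownames(m) <- p[[1]]
    storage.mode(m) <- "integer"
    m
  }) else NULL
  known <- if (!is.null(config$known_genes))
    stage("read_known_genes", readLines(config$known_genes)) else NULL

  res <- stage("analysis", run_collapsing_pipeline(
    cohort, manifest, coverage = coverage, regions = regions,
    snp_panel = snp_panel, known_genes = known,
    thresholds = config$qc_thresholds, rule = config$qualifying_rule,
    kinship_cutoff = config$kinship_cutoff, ld_r2 = config$ld_r2,
    pca_sigma = config$pca_sigma, pca_n_pcs = config$pca_n_pcs,
    pca_iterations = config$pca_iterations,
    max_coverage_diff = config$max_coverage_diff,
    tests = config$tests, use_covariate = config$use_covariate,
    n_permutations = config$n_permutations,
    n_permutations_firth = config$n_permutations_firth,
    n_genes_targeted = config$n_genes_targeted, seed = config$seed))

  if (!is.null(config$output_dir)) {
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.table(res$fit$results, file.path(out, "gene_results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (t in names(res$ensembles))
      write.table(qq_table(res$fit, res$ensembles[[t]], t),
                  file.path(out, sprintf("qq_%s.tsv", t)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$enrichment))
      write.table(res$enrichment$scan, file.path(out, "enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$removal_log))
      write.table(res$removal_log, file.path(out, "relatedness_removals.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    report <- res$report
    report$config_hash <- .config_hash(unclass(config))
    jsonlite::write_json(report, file.path(out, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
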