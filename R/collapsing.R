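# Qualifying-variant determination and the gene-by-sample dominant-model
# indicator matrix, plus the per-sample ultra-rare synonymous covariate.

#' Qualifying-variant rule
#'
#' A variant is qualifying iff it is absent from EVS and ExAC, has at most
#' `max_cohort_alt_copies` alternate-allele copies among the retained
#' cohort samples (QC-passing genotypes only; het = 1 copy, hom-alt = 2),
#' and is predicted loss-of-function or missense "probably damaging"
#' (PolyPhen-2 HumDiv).
#'
#' @param require_absent_evs,require_absent_exac database-absence
#'   requirements (defaults `TRUE`).
#' @param max_cohort_alt_copies cohort allele-count ceiling (default 4).
#' @param lof_effects effect classes treated as loss-of-function.
#' @param missense_polyphen PolyPhen-2 HumDiv label a missense variant
#'   must carry (default `"probably_damaging"`).
#' @return A `qualifying_rule` list.
#' @export
qualifying_rule <- function(require_absent_evs = TRUE,
                            require_absent_exac = TRUE,
                            max_cohort_alt_copies = 4,
                            lof_effects = LOF_EFFECTS,
                            missense_polyphen = "probably_damaging") {
  assert_that(max_cohort_alt_copies >= 1, "max_cohort_alt_copies must be >= 1")
  structure(list(require_absent_evs = require_absent_evs,
                 require_absent_exac = require_absent_exac,
                 max_cohort_alt_copies = max_cohort_alt_copies,
                 lof_effects = lof_effects,
                 missense_polyphen = missense_polyphen),
            class = "qualifying_rule")
}

#' Cohort alternate-allele copy counts
#'
#' Copies per variant summed over the given samples: het genotypes
#' contribute 1, hom-alt 2, anything else 0. Apply genotype QC before
#' counting (only passing genotypes count toward the ceiling).
#'
#' @param cohort an `rv_cohort` (genotypes already QC-filtered).
#' @param samples samples to count over (default: all cohort samples).
#' @return Named integer vector, one entry per variant.
#' @export
cohort_alt_copies <- function(cohort, samples = cohort$samples) {
  g <- cohort$genotypes
  g <- g[g$sample_id %in% samples & g$call %in% c("het", "hom_alt"), ,
         drop = FALSE]
  copies <- setNames(integer(nrow(cohort$variants)), cohort$variants$variant_id)
  if (nrow(g)) {
    add <- rowsum(ifelse(g$call == "hom_alt", 2L, 1L), g$variant_id)
    copies[rownames(add)] <- as.integer(add)
  }
  copies
}

#' Decide which variants are qualifying
#'
#' @param variants variant table of an `rv_cohort`.
#' @param rule a [qualifying_rule()].
#' @param copies cohort alternate-allele copies per variant (aligned with
#'   `variants`), from [cohort_alt_copies()].
#' @return Logical vector.
#' @export
is_qualifying <- function(variants, rule, copies) {
  impact <- variants$effect %in% rule$lof_effects |
    (variants$effect == "missense" &
       variants$polyphen == rule$missense_polyphen)
  (!rule$require_absent_evs | !variants$in_evs) &
    (!rule$require_absent_exac | !variants$in_exac) &
    copies <= rule$max_cohort_alt_copies &
    impact
}

# Rarity part of the rule alone (shared by the synonymous covariate).
.is_ultra_rare <- function(variants, rule, copies) {
  (!rule$require_absent_evs | !variants$in_evs) &
    (!rule$require_absent_exac | !variants$in_exac) &
    copies <= rule$max_cohort_alt_copies
}

#' Build the gene-by-sample collapsing matrix
#'
#' Dominant model: `indicator[g, s] = 1` iff sample `s` carries at least
#' one qualifying variant annotated to gene `g` (two qualifying variants
#' in one gene still give 1). Also computes the per-sample ultra-rare
#' synonymous covariate: the number of distinct synonymous variants
#' carried that satisfy the same rarity rule (database absence and the
#' cohort copy ceiling) -- no impact filter.
#'
#' Variants at sites failing coverage harmonization are excluded from both
#' the qualifying and the covariate counts. Variants with an empty gene
#' are skipped (logged).
#'
#' @param cohort QC-filtered `rv_cohort`.
#' @param manifest sample manifest.
#' @param rule a [qualifying_rule()].
#' @param samples retained (post sample-QC) sample IDs; default all.
#' @param retained_sites optional character vector of `chrom:pos` site
#'   keys that survived coverage harmonization; `NULL` keeps all sites.
#' @param genes gene universe for the matrix rows; defaults to all genes
#'   seen in the variant table.
#' @return Object of class `collapsing_matrix`: sparse logical
#'   `indicator` (genes x samples), `syn_covariate` (named per-sample
#'   counts), `genes`, `samples`, `phenotype`.
#' @export
build_collapsing_matrix <- function(cohort, manifest, rule = qualifying_rule(),
                                    samples = cohort$samples,
                                    retained_sites = NULL, genes = NULL) {
  v <- cohort$variants
  if (!is.null(retained_sites)) {
    keep <- site_key(v$chrom, v$pos) %in% retained_sites
    pipe_log("collapsing: %d of %d variants at coverage-harmonized sites",
             sum(keep), length(keep))
    v <- v[keep, , drop = FALSE]
  }
  no_gene <- is.na(v$gene) | v$gene == ""
  if (any(no_gene))
    pipe_log("collapsing: skipped %d variants with no gene annotation",
             sum(no_gene))
  copies_all <- cohort_alt_copies(cohort, samples)
  copies <- copies_all[v$variant_id]
  qual <- is_qualifying(v, rule, copies) & !no_gene
  rare <- .is_ultra_rare(v, rule, copies)
  syn <- rare & v$effect == "synonymous"

  if (is.null(genes)) genes <- sort(unique(v$gene[!no_gene]))
  samples <- as.character(samples)
  g <- cohort$genotypes
  g <- g[g$sample_id %in% samples & g$call %in% c("het", "hom_alt"), ,
         drop = FALSE]

  qv <- v$variant_id[qual]
  gq <- g[g$variant_id %in% qv, , drop = FALSE]
  gi <- match(v$gene[match(gq$variant_id, v$variant_id)], genes)
  si <- match(gq$sample_id, samples)
  ok <- !is.na(gi)
  indicator <- sparseMatrix(i = gi[ok], j = si[ok], x = TRUE,
                            dims = c(length(genes), length(samples)),
                            dimnames = list(genes, samples), use.last.ij = TRUE)
  indicator <- as(indicator, "CsparseMatrix")

  sv <- v$variant_id[syn]
  gs <- g[g$variant_id %in% sv, , drop = FALSE]
  syn_cov <- setNames(integer(length(samples)), samples)
  if (nrow(gs)) {
    cnt <- table(gs$sample_id)
    syn_cov[names(cnt)] <- as.integer(cnt)
  }
  phen <- manifest$phenotype[match(samples, manifest$sample_id)]
  assert_that(!anyNA(phen), "samples missing from manifest")
  structure(list(indicator = indicator, syn_covariate = syn_cov,
                 genes = genes, samples = samples, phenotype = phen,
                 qualifying_variants = qv),
            class = "collapsing_matrix")
}

#' @exportS3Method base::print
print.collapsing_matrix <- function(x, ...) {
  cat(sprintf("collapsing_matrix: %d genes x %d samples; %d qualifying variants; mean syn covariate %.2f\n",
              length(x$genes), length(x$samples),
              length(x$qualifying_variants), mean(x$syn_covariate)))
  invisible(x)
}

#' Per-sample ultra-rare synonymous counts
#'
#' Standalone accessor for the covariate computed by
#' [build_collapsing_matrix()]: the number of distinct ultra-rare
#' (database-absent, cohort copies within the ceiling) synonymous variants
#' each sample carries; a het or hom-alt genotype counts the variant once.
#'
#' @inheritParams build_collapsing_matrix
#' @return Named integer vector over `samples`.
#' @export
synonymous_covariate <- function(cohort, rule = qualifying_rule(),
                                 samples = cohort$samples,
                                 retained_sites = NULL) {
  v <- cohort$variants
  if (!is.null(retained_sites))
    v <- v[site_key(v$chrom, v$pos) %in% retained_sites, , drop = FALSE]
  copies <- cohort_alt_copies(cohort, samples)[v$variant_id]
  syn <- .is_ultra_rare(v, qualifying_rule(
    require_absent_evs = rule$require_absent_evs,
    require_absent_exac = rule$require_absent_exac,
    max_cohort_alt_copies = rule$max_cohort_alt_copies), copies) &
    v$effect == "synonymous"
  g <- cohort$genotypes
  g <- g[g$sample_id %in% samples & g$call %in% c("het", "hom_alt") &
           g$variant_id %in% v$variant_id[syn], , drop = FALSE]
  out <- setNames(integer(length(samples)), samples)
  if (nrow(g)) {
    cnt <- table(g$sample_id)
    out[names(cnt)] <- as.integer(cnt)
  }
  out
}
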