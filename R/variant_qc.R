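# Hard site- and genotype-level quality filters, plus artifact / external
# database screening.
#
# Inequality directions follow the usual wording of such filters exactly:
# "at least" thresholds are >=, "greater than" thresholds are strict.
# Rank-sum annotations (RPRS, MQRS) and QD may be absent at sites where the
# caller does not emit them; an absent statistic passes its criterion --
# it is undefined, not bad.

#' Site and genotype QC thresholds
#'
#' Defaults: QUAL >= 30, QD >= 2, MQ >= 40, RPRS > -3, MQRS > -6, FS <= 200
#' (indels only), VQSR pass required; genotype DP >= 10, GQ >= 20, and
#' heterozygous alternate allele ratio >= 0.25.
#'
#' @param ... overrides for any threshold field.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(...) {
  t <- list(min_depth = 10, min_qual = 30, min_gq = 20, min_qd = 2,
            min_mq = 40, min_rprs = -3, min_mqrs = -6, max_fs_indel = 200,
            het_alt_ratio_min = 0.25, require_vqsr_pass = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(t))
  assert_that(length(bad) == 0, "unknown QC threshold(s): %s",
              paste(bad, collapse = ", "))
  t[names(over)] <- over
  num <- unlist(t[names(t) != "require_vqsr_pass"])
  assert_that(all(is.finite(num)), "QC thresholds must be finite")
  structure(t, class = "qc_thresholds")
}

#' Site-level QC
#'
#' Vectorized over the variant table. A site passes iff QUAL >= min_qual,
#' QD >= min_qd, MQ >= min_mq, RPRS > min_rprs, MQRS > min_mqrs, FS <=
#' max_fs_indel for indels, and the VQSR filter is PASS. Missing statistics
#' pass their criterion.
#'
#' @param variants variant table of an `rv_cohort` (or a compatible
#'   data.frame).
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame with `variant_id`, logical `pass`, and a `reasons`
#'   string listing every failed criterion (comma-separated, `""` if none).
#' @export
site_passes <- function(variants, thresholds = qc_thresholds()) {
  t <- thresholds
  chk <- function(x, ok) ifelse(is.na(x), TRUE, ok)
  fail <- cbind(
    qual = !chk(variants$qual, variants$qual >= t$min_qual),
    qd   = !chk(variants$qd,   variants$qd >= t$min_qd),
    mq   = !chk(variants$mq,   variants$mq >= t$min_mq),
    rprs = !chk(variants$rprs, variants$rprs > t$min_rprs),
    mqrs = !chk(variants$mqrs, variants$mqrs > t$min_mqrs),
    fs   = variants$is_indel & !chk(variants$fs, variants$fs <= t$max_fs_indel),
    vqsr = if (isTRUE(t$require_vqsr_pass)) !variants$vqsr_pass
           else rep(FALSE, nrow(variants)))
  reasons <- apply(fail, 1, function(r) paste(colnames(fail)[r], collapse = ","))
  data.frame(variant_id = variants$variant_id,
             pass = rowSums(fail) == 0, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Genotype-level QC
#'
#' A genotype passes iff depth >= min_depth, GQ >= min_gq and, for
#' heterozygous calls only, alt_reads / depth >= het_alt_ratio_min.
#' Missing calls never pass; a zero depth with a non-missing call fails.
#'
#' @param genotypes genotype table of an `rv_cohort`.
#' @param thresholds a [qc_thresholds()] object.
#' @return Logical vector, one element per genotype row.
#' @export
genotype_passes <- function(genotypes, thresholds = qc_thresholds()) {
  t <- thresholds
  dp <- genotypes$depth; gq <- genotypes$gq
  ratio_ok <- genotypes$call != "het" |
    (!is.na(genotypes$alt_reads) & !is.na(dp) & dp > 0 &
       genotypes$alt_reads / dp >= t$het_alt_ratio_min)
  pass <- genotypes$call != "missing" &
    !is.na(dp) & dp >= t$min_depth &
    !is.na(gq) & gq >= t$min_gq & ratio_ok
  zero_dp <- genotypes$call != "missing" & !is.na(dp) & dp == 0
  if (any(zero_dp))
    pipe_log("%d non-missing genotypes with zero depth failed QC", sum(zero_dp))
  pass
}

#' Artifact and external-database screening
#'
#' A variant is excluded (returns `FALSE`) when it sits on the sequencing
#' artifact blacklist; the flags file's `artifact` column is expected to
#' carry both the blacklist and any "marked problematic by EVS/ExAC"
#' designations (the `in_evs`/`in_exac` presence flags are a separate
#' concept, used by the rarity rule). The decision never looks at genotype
#' content.
#'
#' @param variants variant table of an `rv_cohort`.
#' @return Logical vector: `TRUE` = retained.
#' @export
screen_external <- function(variants) {
  !variants$on_artifact_list
}

#' Apply all variant-level QC to a cohort
#'
#' Drops variants failing [site_passes()] or [screen_external()] and
#' genotypes failing [genotype_passes()]; returns the filtered cohort with
#' a QC report attached as attribute `"qc_report"`.
#'
#' @param cohort an `rv_cohort`.
#' @param thresholds a [qc_thresholds()] object.
#' @export
apply_variant_qc <- function(cohort, thresholds = qc_thresholds()) {
  sp <- site_passes(cohort$variants, thresholds)
  ext <- screen_external(cohort$variants)
  keep <- sp$pass & ext
  report <- sp
  report$artifact <- !ext
  pipe_log("variant QC: %d of %d sites retained", sum(keep), length(keep))
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  gp <- genotype_passes(cohort$genotypes, thresholds)
  cohort$genotypes <- cohort$genotypes[
    gp & cohort$genotypes$variant_id %in% cohort$variants$variant_id, ,
    drop = FALSE]
  attr(cohort, "qc_report") <- report
  cohort
}
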