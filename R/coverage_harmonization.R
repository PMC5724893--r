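# Site pruning by case/control imbalance of the >= 10x coverage fraction.
# Sites where the fraction of covered cases and covered controls differ by
# more than the threshold would otherwise feed coverage-driven spurious
# association into both the qualifying-variant counts and the synonymous
# covariate, so a pruned site is excluded from both.

#' Per-site coverage fractions by phenotype group
#'
#' For each site, the fraction of cases and controls with >= 10x coverage.
#' Comparisons downstream use exact integer arithmetic (counts and group
#' sizes), not rounded fractions.
#'
#' @param cov an `rv_coverage` accessor.
#' @param manifest sample manifest restricted to post-sample-QC samples.
#' @param sites data.frame with `chrom` and `pos` (1-based) columns.
#' @return data.frame of class `site_coverage`: `site`, `n_cases_10x`,
#'   `n_controls_10x`, `frac_cases_10x`, `frac_controls_10x`.
#' @export
coverage_fractions <- function(cov, manifest, sites) {
  cases <- manifest$sample_id[manifest$phenotype == "case"]
  controls <- manifest$sample_id[manifest$phenotype == "control"]
  assert_that(length(cases) > 0 && length(controls) > 0,
              "coverage_fractions needs both cases and controls")
  mc <- coverage_matrix(cov, sites$chrom, sites$pos, cases)
  mk <- coverage_matrix(cov, sites$chrom, sites$pos, controls)
  out <- data.frame(
    site = site_key(sites$chrom, sites$pos),
    n_cases_10x = rowSums(mc), n_controls_10x = rowSums(mk),
    stringsAsFactors = FALSE)
  out$frac_cases_10x <- out$n_cases_10x / length(cases)
  out$frac_controls_10x <- out$n_controls_10x / length(controls)
  attr(out, "n_cases") <- length(cases)
  attr(out, "n_controls") <- length(controls)
  class(out) <- c("site_coverage", class(out))
  out
}

#' Prune sites with imbalanced case/control coverage
#'
#' A site is retained iff the absolute difference between the case and
#' control >= 10x fractions is at most `max_diff`; the comparison is
#' strict (`> max_diff` prunes), evaluated on exact integer counts:
#' a site is pruned iff
#' `|n_cases_10x * n_controls - n_controls_10x * n_cases| > max_diff * n_cases * n_controls`.
#'
#' @param summaries a `site_coverage` data.frame from
#'   [coverage_fractions()].
#' @param max_diff maximum tolerated fraction difference (default 0.1197).
#' @return Character vector of retained site keys; pruned keys and the
#'   pruned fraction are attached as attributes `"pruned"` and
#'   `"pruned_fraction"`.
#' @export
prune_imbalanced_sites <- function(summaries, max_diff = 0.1197) {
  assert_that(max_diff >= 0, "max_diff must be non-negative")
  nca <- attr(summaries, "n_cases"); nco <- attr(summaries, "n_controls")
  lhs <- abs(summaries$n_cases_10x * nco - summaries$n_controls_10x * nca)
  # rationalize the threshold (6 decimal places) so the boundary case
  # "difference exactly equal to max_diff" is retained exactly
  keep <- lhs * 1e6 <= round(max_diff * 1e6) * nca * nco
  retained <- summaries$site[keep]
  pruned <- summaries$site[!keep]
  pipe_log("coverage harmonization pruned %d of %d sites (%.2f%%)",
           length(pruned), nrow(summaries),
           100 * length(pruned) / max(1, nrow(summaries)))
  attr(retained, "pruned") <- pruned
  attr(retained, "pruned_fraction") <- length(pruned) / max(1, nrow(summaries))
  retained
}

#' Run coverage harmonization for a cohort
#'
#' Convenience wrapper: computes per-site fractions at the cohort's variant
#' sites and prunes the imbalanced ones.
#'
#' @inheritParams coverage_fractions
#' @inheritParams prune_imbalanced_sites
#' @param cohort an `rv_cohort`.
#' @return As [prune_imbalanced_sites()].
#' @export
harmonize_coverage <- function(cohort, cov, manifest, max_diff = 0.1197) {
  sites <- unique(cohort$variants[, c("chrom", "pos")])
  prune_imbalanced_sites(coverage_fractions(cov, manifest, sites), max_diff)
}
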