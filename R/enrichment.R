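# Known-gene recovery: upper-tail hypergeometric test at each observed
# ranking of the known genes, and Fisher enrichment among nominally
# significant genes.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, r)`: the probability of
#' observing `x` or more known genes at ranking `r` if `r` genes were
#' drawn at random, without replacement, from a collection of `N` genes of
#' which `K` are known. Evaluated through the stable upper-tail routine of
#' the hypergeometric distribution (log-space internals).
#'
#' @param x observed number of known genes at rank <= r.
#' @param r ranking (number of genes drawn).
#' @param K number of known genes.
#' @param N total genes tested.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(x, r, K, N) {
  assert_that(all(x >= 0) && all(x <= pmin(r, K)) && all(r <= N) && all(K <= N),
              "need 0 <= x <= min(r, K) <= N")
  ifelse(x == 0, 1, phyper(x - 1, K, N - K, r, lower.tail = FALSE))
}

#' Hypergeometric rank-enrichment scan
#'
#' For the j-th known gene in the genome-wide ranking (rank `r_j`), the
#' upper-tail hypergeometric probability of seeing `j` or more known genes
#' at rank `r_j` or better. Known genes absent from the results are listed
#' with a missing rank and excluded from the scan (logged).
#'
#' @param fit a `collapsing_fit` (genes ranked by Firth p, ties by Fisher
#'   p then gene name).
#' @param known_genes character vector of known disease genes.
#' @param N total genes in the ranking (default: genes tested in `fit`).
#' @param K size of the known set used in the draw (default:
#'   `length(known_genes)`, including any genes missing from the results).
#' @return data.frame: `gene`, `rank`, `n_known_at_rank`, `hypergeom_p`,
#'   plus the per-gene association columns of `fit` for the known genes.
#' @export
rank_scan <- function(fit, known_genes, N = NULL, K = NULL) {
  stopifnot(inherits(fit, "collapsing_fit"))
  res <- fit$results
  N <- N %||% nrow(res)
  K <- K %||% length(known_genes)
  missing <- setdiff(known_genes, res$gene)
  if (length(missing))
    pipe_log("rank_scan: %d known genes absent from results: %s",
             length(missing), paste(head(missing, 5), collapse = ", "))
  present <- intersect(known_genes, res$gene)
  sub <- res[match(present, res$gene), ]
  sub <- sub[order(sub$rank), ]
  sub$n_known_at_rank <- seq_len(nrow(sub))
  sub$hypergeom_p <- hypergeom_upper_tail(sub$n_known_at_rank, sub$rank, K, N)
  rownames(sub) <- NULL
  sub
}

#' Enrichment of known genes among nominally significant genes
#'
#' Two-tailed Fisher's exact test of the 2x2 table splitting genes by
#' known-set membership and nominal significance.
#'
#' @param known_nominal known genes reaching nominal significance.
#' @param known_total size of the known set.
#' @param all_nominal nominally significant genes overall (including the
#'   known ones).
#' @param all_total total genes tested.
#' @return Two-sided Fisher p-value.
#' @export
nominal_enrichment <- function(known_nominal, known_total, all_nominal,
                               all_total) {
  a <- known_nominal
  b <- known_total - known_nominal
  c_ <- all_nominal - known_nominal
  d <- (all_total - known_total) - c_
  assert_that(all(c(a, b, c_, d) >= 0), "inconsistent counts (negative cell)")
  fisher_two_tailed(a, b, c_, d)
}
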