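# Per-gene association: two-tailed Fisher's exact test on carrier counts,
# Firth penalized logistic regression with the ultra-rare synonymous
# covariate, Bonferroni thresholding and the aggregate known-gene burden.

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Table layout: `[[a, b], [c, d]]` = `[[qualifying cases, non-qualifying
#' cases], [qualifying controls, non-qualifying controls]]`. The two-sided
#' p-value is the sum over all tables with the observed margins whose
#' point hypergeometric probability does not exceed the observed one
#' (within a relative tolerance of 1e-7), the convention used by standard
#' statistical software. An all-zero margin gives p = 1.
#'
#' Vectorized over `a, b, c, d`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return Two-sided p-value(s) in (0, 1].
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  mapply(function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
    lo <- max(0L, k - n); hi <- min(k, m)
    dens <- dhyper(lo:hi, m, n, k)
    min(1, sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)]))
  }, a, b, c, d)
}

# Cached per-(carriers, case-carriers) Fisher p lookup for a fixed cohort
# size split; used by the permutation machinery where the same margins
# recur thousands of times.
.fisher_lookup <- function(n_cases, n_controls) {
  cache <- new.env(parent = emptyenv())
  function(k, a) {
    out <- numeric(length(k))
    for (kk in unique(k)) {
      key <- as.character(kk)
      tab <- cache[[key]]
      if (is.null(tab)) {
        lo <- max(0L, kk - n_controls); hi <- min(kk, n_cases)
        dens <- dhyper(lo:hi, n_cases, n_controls, kk)
        tab <- vapply(lo:hi, function(aa)
          min(1, sum(dens[dens <= dens[aa - lo + 1] * (1 + 1e-7)])), 0)
        tab <- c(rep(NA_real_, lo), tab)   # index by a+1
        cache[[key]] <- tab
      }
      sel <- k == kk
      out[sel] <- if (kk == 0) 1 else tab[a[sel] + 1]
    }
    out
  }
}

#' Bonferroni significance threshold
#'
#' @param n_genes_targeted number of genes aimed to be tested.
#' @return `0.05 / n`, reported to 3 significant digits.
#' @export
bonferroni_threshold <- function(n_genes_targeted) {
  assert_that(n_genes_targeted >= 1, "need at least one gene")
  signif(0.05 / n_genes_targeted, 3)
}

#' Gene-based collapsing association analysis
#'
#' The central model fit: for every gene in the collapsing matrix, compares
#' the carrier proportion between cases and controls with a two-tailed
#' Fisher's exact test and (by default) a Firth penalized logistic
#' regression of phenotype on the carrier indicator adjusting for the
#' per-sample ultra-rare synonymous count, tested by penalized profile
#' likelihood ratio. Genes with zero carriers (or with every sample a
#' carrier) are reported with p = 1. Genes are ranked by the Firth p-value
#' with ties broken by the Fisher p-value and then gene name.
#'
#' @param cm a `collapsing_matrix` (see [build_collapsing_matrix()]).
#' @param tests character subset of `c("fisher", "firth")`.
#' @param use_covariate include the synonymous covariate in the Firth
#'   model (default `TRUE`).
#' @param n_genes_targeted denominator for the Bonferroni threshold;
#'   defaults to the number of genes in the matrix.
#' @return Object of class `collapsing_fit`: `results` (one row per gene:
#'   carrier counts, frequencies, p-values, rank), `n_cases`,
#'   `n_controls`, `bonferroni`, `tests`.
#' @seealso [aggregate_burden()], [expected_order_statistics()],
#'   [rank_scan()]
#' @export
collapsing_fit <- function(cm, tests = c("fisher", "firth"),
                           use_covariate = TRUE, n_genes_targeted = NULL) {
  stopifnot(inherits(cm, "collapsing_matrix"))
  tests <- match.arg(tests, several.ok = TRUE)
  y <- as.numeric(cm$phenotype == "case")
  n_cases <- sum(y); n_controls <- sum(1 - y)
  assert_that(n_cases > 0 && n_controls > 0,
              "cohort needs both cases and controls")
  ind <- cm$indicator
  k <- as.vector(rowSums(ind))
  a <- as.vector(ind %*% y)
  res <- data.frame(
    gene = cm$genes,
    qualifying_cases = as.integer(a),
    qualifying_controls = as.integer(k - a),
    case_freq = a / n_cases,
    control_freq = (k - a) / n_controls,
    stringsAsFactors = FALSE)
  if ("fisher" %in% tests) {
    lk <- .fisher_lookup(n_cases, n_controls)
    res$fisher_p <- lk(k, as.integer(a))
  }
  if ("firth" %in% tests) {
    z <- if (use_covariate) cm$syn_covariate else NULL
    fp <- .firth_scan(ind, y, z)
    res$firth_p <- fp$p
    res$firth_beta <- fp$beta
  }
  ord <- if ("firth" %in% tests)
    order(res$firth_p, res$fisher_p %||% res$firth_p, res$gene)
  else order(res$fisher_p, res$gene)
  rank_col <- integer(nrow(res)); rank_col[ord] <- seq_len(nrow(res))
  res$rank <- rank_col
  n_target <- n_genes_targeted %||% nrow(res)
  structure(list(results = res[order(res$rank), ],
                 n_cases = n_cases, n_controls = n_controls,
                 n_genes_tested = nrow(res),
                 bonferroni = bonferroni_threshold(n_target),
                 tests = tests, use_covariate = use_covariate,
                 call = match.call()),
            class = "collapsing_fit")
}

# Genome scan of Firth penalized profile likelihood ratio tests.
# Aggregates samples by covariate value once, then per gene moves the few
# carriers into the x = 1 stratum; each gene costs two small Newton fits.
.firth_scan <- function(ind, y, z = NULL, maxit = 100, tol = 1e-6) {
  n <- length(y)
  G <- nrow(ind)
  if (is.null(z)) z <- numeric(n)
  uz <- sort(unique(z))
  zf <- match(z, uz)
  nz <- length(uz)
  tot_n <- tabulate(zf, nz)
  tot_s <- as.vector(rowsum(y, zf))
  has_cov <- nz > 1
  # CSC over genes for fast carrier extraction
  tm <- as(as(Matrix::t(ind), "generalMatrix"), "CsparseMatrix")
  p_out <- rep(1, G); beta_out <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    ptr <- (tm@p[g] + 1):(tm@p[g + 1])
    if (tm@p[g + 1] == tm@p[g]) next           # zero carriers -> p = 1
    carriers <- tm@i[ptr] + 1L
    if (length(carriers) == n) next            # everyone a carrier -> p = 1
    c_n <- tabulate(zf[carriers], nz)
    c_s <- tabulate(zf[carriers][y[carriers] == 1], nz)
    r0 <- which(tot_n - c_n > 0); r1 <- which(c_n > 0)
    Xa <- cbind(`(Intercept)` = 1,
                carrier = c(rep(0, length(r0)), rep(1, length(r1))))
    if (has_cov) Xa <- cbind(Xa, covariate = c(uz[r0], uz[r1]))
    nn <- c(tot_n[r0] - c_n[r0], c_n[r1])
    ss <- c(tot_s[r0] - c_s[r0], c_s[r1])
    fit_pair <- tryCatch(list(
      full = .firth_core(Xa, nn, ss, maxit = maxit, tol = tol),
      con = .firth_core(Xa, nn, ss, free = setdiff(seq_len(ncol(Xa)), 2),
                        beta0 = numeric(ncol(Xa)), maxit = maxit, tol = tol)),
      error = function(e) NULL)
    if (is.null(fit_pair)) {
      # covariate collinear with the carrier indicator in this gene's
      # strata; fall back to the covariate-free design
      Xa <- Xa[, 1:2, drop = FALSE]
      fit_pair <- list(
        full = .firth_core(Xa, nn, ss, maxit = maxit, tol = tol),
        con = .firth_core(Xa, nn, ss, free = 1L,
                          beta0 = numeric(2), maxit = maxit, tol = tol))
    }
    full <- fit_pair$full; con <- fit_pair$con
    chisq <- max(0, 2 * (full$plog - con$plog))
    p_out[g] <- pchisq(chisq, 1, lower.tail = FALSE)
    beta_out[g] <- full$coefficients[2]
  }
  list(p = p_out, beta = beta_out)
}

#' @exportS3Method base::print
print.collapsing_fit <- function(x, ...) {
  cat(sprintf("Gene-based collapsing analysis: %d genes, %d cases vs %d controls\n",
              x$n_genes_tested, x$n_cases, x$n_controls))
  cat(sprintf("tests: %s; Bonferroni threshold %.3g\n",
              paste(x$tests, collapse = " + "), x$bonferroni))
  cat("top genes:\n")
  print(head(x$results, 5), row.names = FALSE, digits = 3)
  invisible(x)
}

#' @exportS3Method base::summary
summary.collapsing_fit <- function(object, alpha_nominal = 0.05, ...) {
  r <- object$results
  sig <- list()
  for (t in object$tests) {
    p <- r[[paste0(t, "_p")]]
    sig[[t]] <- list(
      genomewide = r$gene[p < object$bonferroni],
      n_nominal = sum(p < alpha_nominal),
      lambda = genomic_lambda(p))
  }
  out <- list(fit = object, significance = sig)
  class(out) <- "summary.collapsing_fit"
  out
}

#' @exportS3Method base::print
print.summary.collapsing_fit <- function(x, ...) {
  print(x$fit)
  for (t in names(x$significance)) {
    s <- x$significance[[t]]
    cat(sprintf("%s: lambda = %.3f; %d nominally significant; genome-wide: %s\n",
                t, s$lambda, s$n_nominal,
                if (length(s$genomewide)) paste(s$genomewide, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

#' QQ plot of the observed p-value distribution
#'
#' Observed sorted -log10 p-values against expected ones; the expected
#' line and the 95% band come from a permutation ensemble when supplied
#' (see [expected_order_statistics()]), otherwise from the uniform
#' order-statistic expectation i/(G+1).
#'
#' @param x a `collapsing_fit`.
#' @param test which test's p-values to plot.
#' @param ensemble optional `permutation_ensemble`.
#' @param ... passed to `plot()`.
#' @export
plot.collapsing_fit <- function(x, test = x$tests[1], ensemble = NULL, ...) {
  p <- sort(x$results[[paste0(test, "_p")]])
  G <- length(p)
  if (!is.null(ensemble)) {
    stopifnot(length(ensemble$mean_sorted_p) == G)
    exp_l <- -log10(ensemble$mean_sorted_p)
    lo <- -log10(ensemble$upper_p); hi <- -log10(ensemble$lower_p)
  } else {
    exp_l <- -log10(seq_len(G) / (G + 1))
    lo <- hi <- NULL
  }
  obs <- -log10(p)
  plot(exp_l, obs, xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), pch = 20, col = "red3", ...)
  abline(0, 1, col = "grey40")
  if (!is.null(lo)) {
    lines(exp_l, lo, lty = 2, col = "grey60")
    lines(exp_l, hi, lty = 2, col = "grey60")
  }
  invisible(x)
}

#' Aggregate carrier burden over a gene set
#'
#' A sample counts once if it carries at least one qualifying variant in
#' any gene of the set (union semantics); carriers versus non-carriers are
#' compared by the two-tailed Fisher's exact test.
#'
#' @param cm a `collapsing_matrix`.
#' @param gene_set non-empty character vector of genes in the matrix.
#' @return List: `table` (2x2 carrier matrix), `fisher_p`,
#'   `case_fraction`, `control_fraction`.
#' @export
aggregate_burden <- function(cm, gene_set) {
  assert_that(length(gene_set) > 0, "empty gene set")
  missing <- setdiff(gene_set, cm$genes)
  assert_that(length(missing) == 0, "genes not in matrix: %s",
              paste(head(missing, 5), collapse = ", "))
  sub <- cm$indicator[match(gene_set, cm$genes), , drop = FALSE]
  carrier <- as.vector(colSums(sub)) > 0
  y <- cm$phenotype == "case"
  a <- sum(carrier & y); b <- sum(!carrier & y)
  c_ <- sum(carrier & !y); d <- sum(!carrier & !y)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("carrier", "non_carrier")))
  list(table = tab, fisher_p = fisher_two_tailed(a, b, c_, d),
       case_fraction = a / (a + b), control_fraction = c_ / (c_ + d))
}
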