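# Permutation-based expected p-value distributions and the genomic
# inflation factor.
#
# Two permutation schemes: a simple uniform relabelling (for the
# unadjusted Fisher test) and a covariate-preserving weighted-urn
# relabelling that samples the case set from the multivariate Fisher
# noncentral hypergeometric distribution with per-sample odds taken from a
# phenotype ~ covariate logistic fit. The weighted scheme keeps the
# confounding role of the covariate in each permuted data set while
# breaking the genotype-phenotype association.

#' Simple case/control label permutation
#'
#' A uniformly random subset of `n_cases` samples is labelled case; the
#' case count is preserved exactly.
#'
#' @param n_samples,n_cases cohort size and case count (0 < cases <
#'   samples).
#' @param seed optional integer for a self-contained reproducible draw;
#'   `NULL` uses (and advances) the caller's RNG stream.
#' @return Logical vector of length `n_samples` (`TRUE` = case).
#' @export
permute_simple <- function(n_samples, n_cases, seed = NULL) {
  assert_that(n_cases > 0 && n_cases < n_samples,
              "need 0 < n_cases < n_samples")
  with_seed(seed, {
    lab <- logical(n_samples)
    lab[sample.int(n_samples, n_cases)] <- TRUE
    lab
  })
}

#' Per-sample urn weights from the confounder fit
#'
#' Fits `phenotype ~ covariate` by ordinary logistic regression and takes
#' each sample's fitted odds `exp(alpha + gamma z_i)` as its urn weight,
#' rescaled to geometric mean 1. If the confounder fit separates (infinite
#' estimates), the Firth fit is used instead (logged).
#'
#' @param y binary phenotype (0/1 or logical).
#' @param z per-sample covariate (ultra-rare synonymous count).
#' @return Numeric weight vector with attribute `"gamma"` (the fitted
#'   covariate coefficient); constant when `z` is constant.
#' @export
urn_weights <- function(y, z) {
  y <- as.numeric(y)
  if (var(z) == 0) {
    w <- rep(1, length(y))
    attr(w, "gamma") <- 0
    return(w)
  }
  fit <- suppressWarnings(glm(y ~ z, family = binomial()))
  cf <- coef(fit)
  if (!fit$converged || any(!is.finite(cf)) || any(abs(cf) > 15)) {
    pipe_log("confounder fit separated; using Firth fit for urn weights")
    ff <- firth_fit(y, cbind(z = z))
    cf <- coef(ff)
  }
  eta <- cf[1] + cf[2] * z
  w <- exp(eta - mean(eta))          # geometric mean 1
  attr(w, "gamma") <- unname(cf[2])
  w
}

#' Weighted-urn label permutation
#'
#' Draws a case set of exactly `n_cases` samples from the multivariate
#' Fisher noncentral hypergeometric distribution with odds proportional to
#' `weights`: \eqn{P(S) \propto \prod_{i \in S} w_i} over all subsets of
#' size `n_cases`. Sampling is by acceptance-rejection against the
#' conditional Bernoulli law: independent Bernoulli draws with inclusion
#' probabilities calibrated so the expected case count equals `n_cases`,
#' accepted when the realized count matches exactly. With equal weights
#' this reduces to [permute_simple()].
#'
#' @param weights positive per-sample weights (see [urn_weights()]).
#' @param n_cases number of case labels to assign.
#' @param n_draws number of independent permutations to draw.
#' @param seed optional integer seed (see [permute_simple()]).
#' @return Logical vector (`n_draws = 1`) or a samples-by-draws logical
#'   matrix.
#' @export
permute_weighted <- function(weights, n_cases, n_draws = 1, seed = NULL) {
  n <- length(weights)
  assert_that(all(is.finite(weights) & weights > 0),
              "weights must be finite and positive")
  assert_that(n_cases > 0 && n_cases < n, "need 0 < n_cases < n_samples")
  # calibrate c so that sum of pi_i = n_cases with odds(pi_i) = c * w_i
  f <- function(lc) sum(plogis(lc + log(weights))) - n_cases
  lc <- uniroot(f, lower = -50, upper = 50, tol = 1e-12)$root
  pi <- plogis(lc + log(weights))
  with_seed(seed, {
    out <- matrix(FALSE, n, n_draws)
    got <- 0
    batch <- max(16L, min(4096L, ceiling(4 * n_draws * sqrt(sum(pi * (1 - pi)) + 1))))
    guard <- 0
    while (got < n_draws) {
      guard <- guard + 1
      assert_that(guard < 1e5, "weighted permutation: acceptance rate too low")
      m <- matrix(runif(n * batch), n, batch) < pi
      hits <- which(colSums(m) == n_cases)
      if (length(hits)) {
        take <- hits[seq_len(min(length(hits), n_draws - got))]
        out[, got + seq_along(take)] <- m[, take]
        got <- got + length(take)
      }
    }
    if (n_draws == 1) out[, 1] else out
  })
}

#' Permutation-based expected p-value order statistics
#'
#' Recomputes the gene-wise association test under `n_perm` label
#' permutations, sorts each permutation's p-values, and returns the
#' per-rank mean across permutations (the average 1st, 2nd, ... order
#' statistic) together with per-rank 2.5% / 97.5% percentile bands. These
#' are the empirical expected ordered p-values for the QQ plot; they do
#' not assume the null p-values are uniform.
#'
#' @param cm a `collapsing_matrix`.
#' @param test `"fisher"` (fast path, cached hypergeometric lookups) or
#'   `"firth"` (refits every gene per permutation; use smaller `n_perm`).
#' @param permuter `"simple"` or `"weighted"` (covariate-preserving urn,
#'   weights from [urn_weights()] on the matrix's synonymous covariate).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param use_covariate include the synonymous covariate in the Firth
#'   refits (default `TRUE`).
#' @return Object of class `permutation_ensemble`: `mean_sorted_p`,
#'   `lower_p`, `upper_p` (per-rank 2.5%/97.5% percentiles), `n_perm`,
#'   `seed`.
#' @export
expected_order_statistics <- function(cm, test = c("fisher", "firth"),
                                      permuter = c("simple", "weighted"),
                                      n_perm = 1000, seed = NULL,
                                      use_covariate = TRUE) {
  test <- match.arg(test)
  permuter <- match.arg(permuter)
  assert_that(n_perm >= 2, "need at least 2 permutations")
  y <- as.numeric(cm$phenotype == "case")
  n <- length(y); n_cases <- sum(y)
  G <- length(cm$genes)
  ind <- cm$indicator
  k <- as.vector(rowSums(ind))
  lk <- .fisher_lookup(n_cases, n - n_cases)
  w <- if (permuter == "weighted") urn_weights(y, cm$syn_covariate) else NULL
  sorted <- matrix(NA_real_, G, n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- if (permuter == "simple") permute_simple(n, n_cases)
            else permute_weighted(w, n_cases)
      yp <- as.numeric(yp)
      pvals <- if (test == "fisher") {
        a <- as.vector(ind %*% yp)
        lk(k, as.integer(a))
      } else {
        .firth_scan(ind, yp, if (use_covariate) cm$syn_covariate else NULL)$p
      }
      sorted[, b] <- sort(pvals)
    }
  })
  structure(list(mean_sorted_p = rowMeans(sorted),
                 lower_p = apply(sorted, 1, quantile, 0.025),
                 upper_p = apply(sorted, 1, quantile, 0.975),
                 n_perm = n_perm, test = test, permuter = permuter,
                 seed = seed),
            class = "permutation_ensemble")
}

#' @exportS3Method base::print
print.permutation_ensemble <- function(x, ...) {
  cat(sprintf("permutation_ensemble: %d permutations (%s test, %s permuter), %d ranks\n",
              x$n_perm, x$test, x$permuter, length(x$mean_sorted_p)))
  invisible(x)
}

#' Genomic inflation factor
#'
#' Median-based 1-df definition: the observed p-values are converted to
#' chi-squared quantiles and the median is divided by the null median
#' (about 0.4549).
#'
#' @param observed_p p-values in (0, 1].
#' @return lambda (1 indicates calibration).
#' @export
genomic_lambda <- function(observed_p) {
  assert_that(length(observed_p) > 0, "no p-values supplied")
  assert_that(all(observed_p > 0 & observed_p <= 1), "p-values must be in (0, 1]")
  median(qchisq(observed_p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}

#' QQ data table
#'
#' Rank-aligned observed and permutation-expected -log10 p-values with the
#' 95% band, ready for serialization or plotting.
#'
#' @param fit a `collapsing_fit`.
#' @param ensemble a `permutation_ensemble` over the same genes.
#' @param test which test's observed p-values to use.
#' @export
qq_table <- function(fit, ensemble, test = ensemble$test) {
  obs <- sort(fit$results[[paste0(test, "_p")]])
  stopifnot(length(obs) == length(ensemble$mean_sorted_p))
  data.frame(rank = seq_along(obs),
             observed_log10 = -log10(obs),
             expected_log10 = -log10(ensemble$mean_sorted_p),
             lower_log10 = -log10(ensemble$upper_p),
             upper_log10 = -log10(ensemble$lower_p))
}
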