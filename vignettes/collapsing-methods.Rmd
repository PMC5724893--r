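---
title: "Rare-variant collapsing analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The model

A collapsing analysis tests, gene by gene, whether cases carry
"qualifying" variants more often than controls. The per-gene sufficient
statistic is the 2×2 carrier table under a dominant model: a sample is a
carrier if it holds at least one qualifying variant in the gene,
regardless of how many. Qualifying means simultaneously ultra-rare
(absent from the EVS and ExAC reference databases **and** at most
`max_cohort_alt_copies = 4` alternate-allele copies across the whole
cohort, counting het = 1 and hom-alt = 2 over QC-passing genotypes only)
and predicted damaging (one of six loss-of-function classes, or missense
with a PolyPhen-2 HumDiv "probably damaging" rating). The rarity ceiling
is deliberately evaluated *within* the analyzed cohort: it adapts the
definition of "ultra-rare" to the sample size at hand.

Two tests are computed per gene:

* **Two-tailed Fisher's exact test** on the carrier table, two-sided by
  the sum-of-small-probabilities rule (all tables with fixed margins
  whose point probability is at most the observed one, within a relative
  tolerance of 1e-7). This is the convention of the major statistical
  packages; `stats::fisher.test` is used as an independent oracle in the
  test suite, while the implementation itself evaluates the
  hypergeometric mass directly so that permutation replicates can reuse
  cached tail sums.
* **Firth penalized logistic regression** of phenotype on the carrier
  indicator plus the per-sample count of ultra-rare *synonymous*
  variants. Synonymous variants pass the same rarity rules but carry no
  impact filter, so their per-sample count tracks how much ultra-rare
  variation a sample presents for purely technical and demographic
  reasons (capture kit, sequencing center, ancestry) — exactly the
  confounder a rare-variant burden test must absorb. The penalized
  likelihood is $\ell(\beta) + \tfrac12 \log |I(\beta)|$; estimates stay
  finite under complete separation, and the reported p-value is a
  penalized profile likelihood ratio referred to $\chi^2_1$.

Genes are ranked by the Firth p-value (ties: Fisher p, then gene name);
the genome-wide threshold is Bonferroni, `0.05 / n_genes_targeted`.

## Numerical behavior of the Firth fitter

The fitter aggregates samples into unique (carrier, covariate) patterns —
a binomial reformulation that is algebraically identical to the
per-sample form but turns a 12,000-row fit into a ~50-row fit, which is
what makes genome-wide scans and permutation ensembles affordable in pure
R. Newton steps use the Fisher information as Hessian with step-halving
on the penalized likelihood; convergence is declared when the adjusted
score drops below `1e-6`, or when the objective sits on a numerical
plateau for two consecutive iterations. The plateau branch matters for
genes with a single carrier: there the Jeffreys penalty nearly cancels
the likelihood curvature along the carrier coordinate, the penalized
likelihood is flat to machine precision over a small ridge, and the
score-only criterion would never trigger even though every quantity the
profile test consumes is already exact. Degenerate designs resolve by
convention: zero carriers (or all carriers) give p = 1, a constant
covariate is dropped, and a covariate collinear with the carrier
indicator falls back to the covariate-free design for that gene.

## Permutation diagnostics

Expected p-value distributions are empirical: labels are permuted, the
gene-wise test recomputed, each permutation's p-values sorted, and the
per-rank mean across permutations (the average k-th order statistics,
averaged on the p scale) forms the expected line, with 2.5%/97.5%
per-rank percentiles as the 95% band. No uniformity assumption enters —
important because the exact test's null is discrete and visibly
non-uniform at rare carrier counts.

For the covariate-adjusted model a uniform permutation would destroy the
covariate-phenotype association along with the genotype-phenotype one.
The weighted-urn permuter therefore draws case sets from the multivariate
Fisher noncentral hypergeometric distribution with per-sample odds taken
from a logistic fit of phenotype on the covariate (Firth fallback under
separation), rescaled to geometric mean one. Sampling is
acceptance-rejection against the conditional Bernoulli law: inclusion
probabilities are calibrated by a one-dimensional root solve so the
expected case count equals the real one, and draws are accepted when the
realized count matches exactly. This is exact (verified against the
enumerable three-sample law in the tests) and vectorizes across draws;
with equal weights it provably reduces to the uniform permutation.

The genomic inflation factor uses the median-based 1-df definition,
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$. The field uses
several variants of this quantity; the median version is the least
sensitive to true signal in the tail, and the choice is recorded in the
run report.

## Sample QC

Kinship uses the within-pair robust estimator
$\phi_{ij} = (N_{het,het} - 2N_{AA,aa}) / (N_{het}(i) + N_{het}(j))$
over jointly typed sites of a common-SNP panel: 0.5 for duplicates,
~0.25 for first-degree pairs, ~0 for unrelated pairs, with no reliance on
population allele frequencies. Acceptance is by pedigree simulation
(Mendelian transmission), not by matching any particular tool's output
bit for bit. Pruning at cutoff 0.1 is greedy max-degree-first — the
standard, testable choice for breaking relatedness graphs — deleting
controls before cases, then lower mean coding coverage, then the
lexicographically later ID, so reruns are deterministic.

PCA standardizes each SNP by its current allele frequency, removes any
sample more than 6 SD from the mean on any of the top 10 components, and
iterates up to 5 times, recomputing frequencies, components and SDs on
the surviving samples each round (that recomputation is what "iterations"
means here). The sigma rule is applied per component rather than as a
Mahalanobis distance, matching the convention of the standard PCA
outlier-removal tools; PC signs are fixed by making the largest-magnitude
SNP loading positive.

One practical limit worth knowing: a *single* outlier from a population
diverged at $F_{st} \approx 0.2$ only rises above the eigenvector noise
floor when the panel has roughly 40× more SNPs than there are samples
(Marchenko-Pastur edge); with smaller panels the outlier is
statistically invisible to any PCA, not just this one. The tests
therefore use ~10,000-SNP panels for a few hundred samples when they
assert exact outlier recovery.

## Coverage harmonization

For every analyzed site the fraction of cases and of controls with ≥10×
coverage is computed from integer counts, and the site is dropped when
the fractions differ by more than 11.97% (strict inequality, evaluated on
exact integer cross-products so the boundary case is kept). The
threshold is taken as a given constant of the procedure and is
configurable. Pruned sites are excluded from qualifying-variant *and*
synonymous-covariate counting: both feed the same association model, and
letting a coverage-biased site into either would reintroduce the
confounding the step exists to remove.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
at carrier level: each (gene, sample) carriage event is a Bernoulli draw
— background probability 0.001 per gene in controls, matching the
reported control carrier frequencies of known-gene studies (1e-4 to
3e-3) — and carriers are grouped into variants of 1–4 cohort copies, so
the ultra-rare copy ceiling is respected without simulating a site
frequency spectrum. Defaults mirror the emulated study: 488 cases vs
12,151 controls, 18,503 genes, three risk genes with case carrier
probabilities 0.0205 / 0.0123 / 0.0164 (the strongest reported signals);
tests pass smaller explicit sizes. The synonymous covariate is negative
binomial (control mean 6, case mean 7.5, dispersion 8) — the
distribution is not prescribed anywhere, and an overdispersed count is
the realistic stressor for the covariate adjustment; when
`covariate_effect > 0` the covariate also multiplies the background
carrier odds, producing the confounded null on which the unadjusted test
must inflate and the adjusted one must not. Capture-kit structure is a
coverage gap at 5% of sites (case coverage rate 0.75 vs control 0.97);
relatedness is planted as one case-control duplicate (0.5% genotype
error) and one parent-offspring pair built by explicit Mendelian
transmission; population structure is a two-subpopulation
Balding-Nichols mixture on the SNP panel only — rare qualifying variants
get no haplotype structure, which is the main respect in which the
generator is *less* adversarial than real exomes (no linkage between
qualifying variants, no recurrent artifacts correlated across genes).
Decoy variants (case-enriched artifacts and QC failures) are planted so
that an end-to-end run demonstrates the filters actually matter.

Passing tests on these cohorts shows the pipeline is correct under its
own model — carrier-level sampling, independent genes, honest
annotations. It does not certify behavior under misannotation, caller
batch effects correlated with phenotype, or fine-scale structure within
the rare variants themselves.

## Calibration checks and problem sizes

The suite's statistical acceptance checks run at sizes chosen to keep
the whole suite in the minutes range while leaving Monte-Carlo error
well inside the asserted bands: type-I error over 10,000 null genes at
500 cases / 2,000 controls; inflation-factor contrast over 20,000
confounded-null genes (the median-based λ has standard error
≈ 3.3/√G, so 20,000 genes give ±0.023); the weighted-urn law over
50,000 draws; and a full end-to-end run at 500 / 2,000 samples and 2,000
genes with 200 permutations. Carrier prevalence for the calibration
cohorts is 0.10: the exact test's null distribution is discrete, and at
realistic ultra-rare counts its size is *structurally* below nominal
(0.033 at 10 carriers) — a property of exact tests, not of this
implementation — so nominal-level calibration is only a meaningful
assertion where the null support is dense.

## Known limitations

* Hemizygous calls are not modelled; hom-alt counts 2 copies everywhere.
* The Firth permutation ensemble refits every gene in every permutation;
  it is opt-in (`n_permutations_firth`) and meant for focused follow-up,
  not routine genome-wide use at full permutation counts.
* `fisher_two_tailed` / `firth_fit` assume biallelic decomposition has
  already happened (the VCF reader does it); genotypes not involving the
  decomposed allele are treated as homozygous reference, a convention
  the underlying study does not specify.
* The generator writes dense VCFs; at the full default cohort size the
  file-based round trip is impractical and the in-memory interface is
  the intended path.
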