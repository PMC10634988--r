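---
title: "Models and design choices in tfcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in tfcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcascade)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-data generators
do and do not emulate, and the numerical choices that matter in corner
cases. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The negative-binomial lineage smoother

Counts for gene $g$ in cell $i$ are modelled as
$Y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi_g)$ with

$$\log \mu_{gi} = \sum_{l=1}^{L} s_{gl}(T_{li})\, Z_{li}
  + U_i \alpha_g + \log N_i ,$$

where $s_{gl}(t) = \sum_{k=1}^{K} b_k(t)\, \beta_{glk}$ is a cubic
B-spline smoother of pseudotime, one per lineage; $Z$ is a hard one-hot
lineage assignment; $U$ holds optional cell-level covariates; and $N_i$ is
a per-cell depth offset entering as $\log N_i$. Assumptions worth making
explicit:

* **Hard assignment.** Every cell contributes to exactly one lineage's
  smoother. Soft lineage weights are a deliberate non-goal; downstream
  cascade logic reasons about cells as members of one branch.
* **Shared basis.** The basis functions $b_k$ are identical for all genes
  and lineages: boundary knots sit at the minimum and maximum of the
  assigned cells' pooled pseudotimes (full multiplicity, clamped basis)
  and interior knots at pseudotime quantiles. This makes coefficients
  comparable across genes and lineages.
* **Unpenalized regression spline.** With $K = 6$ coefficients per lineage
  the basis is already heavily restricted, so no smoothness penalty is
  applied. The payoff is an exact coefficient covariance (no
  effective-degrees-of-freedom machinery), which the derivative test
  consumes directly. This is a documented deviation from penalized-GAM
  practice; penalized fits would shrink derivative estimates and their
  covariance in ways that are hard to propagate exactly.
* **"Knots" vocabulary.** $K$ counts basis functions (equivalently,
  regression coefficients per lineage), not knot locations. For a clamped
  cubic basis, $K = 6$ means two interior knots.

Fitting alternates IRLS for $(\beta, \alpha)$ at fixed $\phi_g$ with a
univariate maximum-likelihood update of $\phi_g$ (bounded to
$[10^{-8}, 10^{8}]$), stopping when the relative log-likelihood change
falls below $10^{-8}$ or after 200 alternations. Step-halving guards the
occasional IRLS overshoot at low counts. The reported covariance $V$ is
the inverse *observed* information at the optimum with $\phi_g$ held
fixed; for the NB log link the observed-information weights are
$(y_i + \phi)\,\phi\,\mu_i/(\mu_i + \phi)^2$. All-zero genes yield a
flagged degenerate fit rather than an error, and downstream operations
return null records for them.

$K$ can be chosen by mean AIC over a gene subset
(`select_knots_aic()`), with AIC $= -2\,\ell + 2\,(\text{number of mean-model
coefficients})$; the dispersion is not counted, so comparisons across $K$
reflect mean-structure complexity only.

Predictions for cross-lineage comparison (`predict_smoother()`, the
cascade matrix, the 1.5-fold specificity rule) exclude offsets and set
covariates to their zero reference row: curves are per-unit-depth
expression functions, comparable across lineages and genes.

## The derivative cascade test

Derivatives are central finite differences of the basis,
$\hat\delta_{glj} = \sum_k \frac{b_k(t^*_{lj}+\epsilon) -
b_k(t^*_{lj}-\epsilon)}{2\epsilon}\, \hat\beta_{glk}$, on a grid of
$J = 100$ equally spaced points per lineage with $\epsilon = 10^{-7}$.
Because the derivative is linear in the coefficients, its standard error
is $\sqrt{d^\top V_{ll}\, d}$ for the same difference weights $d$. At the
two grid endpoints $t \pm \epsilon$ can leave the knot span; there a
one-sided difference is used and flagged.

Per grid point the thresholded statistic is
$T_{glj} = \max(0, \hat\delta_{glj} - c)/\hat\sigma_{glj}$ with $c = 0.1$:
increases shallower than 0.1 log-units per pseudotime unit are treated as
biologically negligible, which also makes the test conservative under the
null (the one-sided p-value $1 - \Phi(T)$ is 0.5 wherever the derivative
stays below $c$). Benjamini–Hochberg adjustment is applied **across the
$J$ grid points within one (gene, lineage)** — not across genes — matching
the grid-wise testing construction; the scope is configurable. A gene is
involved in a lineage when $\min_j p^{\mathrm{adj}}_{glj} < 0.05$. The
p-values are numerical summaries for ranking and thresholding; no strong
frequentist calibration is claimed, and the acceptance checks treat the
null involvement rate as a bound, not an exact level.

Numerical corner cases, with their resolutions:

* $\hat\sigma = 0$ at a grid point: $p = 1$ there (conservative), so a
  degenerate covariance can never manufacture involvement.
* Ties in $\arg\min_j p^{\mathrm{adj}}$: the earliest grid index wins —
  deterministic, and biased toward earlier activation, consistent with
  reading cascades left to right.
* Peak localization: the first sign change of $\hat\delta$ after the
  minimizing grid point, refined by linear interpolation between the
  bracketing grid points (sub-grid accuracy without re-evaluating the
  model). If the derivative never crosses zero the gene is still rising at
  the end of the lineage; the peak is set to the lineage end and flagged
  `lineage_end`.

The cascade matrix evaluates each involved gene's response-scale smoother
at the midpoints of 100 equal-width pseudotime bins, z-scales each row,
and orders rows by peak time (ties: minimum adjusted p-value, then gene
identifier). Hierarchical clustering of rows uses Euclidean distance with
Ward linkage — the distance is part of the method's definition, the
linkage is a design choice (Ward gives compact, balanced clusters) and is
configurable. Cluster enrichment uses the exact hypergeometric upper tail
against a supplied universe, BH-adjusted, reporting the top 10 sets.

A TF is **lineage-specific** when involved in a lineage and its
response-scale smoother maximum is $\ge 1.5\times$ the corresponding
maximum in every other lineage; it is **shared** when it has a localized
peak in every lineage and the largest pairwise peak-time difference is
below 1 pseudotime unit, on the raw pseudotime scale (all lineages share
the trajectory origin, so no rescaling is applied). Sharedness counts
genes with a *peak* in every lineage (the stricter reading of
"peaks in all lineages"), not merely involvement.

## TF-activity deconvolution

Target-gene counts decompose over GRN parents:
$X_{tgi} \sim \mathrm{Poisson}(N_i\, \beta_{tg}\, a_{ti})$ with
$Y_{gi} = \sum_t X_{tgi}$, so
$Y_{gi} \sim \mathrm{Poisson}(N_i \sum_{t \in pa(g)} \beta_{tg} a_{ti})$.
EM alternates responsibilities
$\xi_{tgi} = \beta_{tg} a_{ti} / \sum_{t'} \beta_{t'g} a_{t'i}$ with
blockwise closed-form updates — $\beta$ first, then $a$ with refreshed
responsibilities — which keeps the log-likelihood nondecreasing (each
block is an exact M-step; simultaneous updates would forfeit the
guarantee). Default tolerance $10^{-8}$ relative log-likelihood change,
500 iterations maximum. Design choices:

* GRN edge weights define the support and the initialization of $\beta$
  (uniform if all weights are zero); they do not enter the likelihood as
  priors, since no principled weighting scheme is implied by an
  importance-scored network.
* The factorization is scale-unidentifiable per TF
  ($\beta \to s\beta,\ a \to a/s$); after convergence each TF's rates are
  normalized to sum to one and the scale absorbed into the activities, so
  activities are expected molecule counts per cell and comparable across
  runs.
* Denominators are floored at $10^{-12}$; cells with zero total count over
  the retained targets get zero activity and drop out of the M-step
  denominators; genes without a GRN parent are excluded before fitting
  (counted in a message), mirroring the restriction of the analysis to the
  network's genes.
* No hierarchical prior is imposed on $\beta$ or $a$: the likelihood above
  is the minimal model consistent with molecule assignment by EM, and the
  implementation is self-contained.

Reported activity is $A_{ti} = \sum_g Y_{gi}\, \xi_{tgi}$ — expected
molecules attributed to TF $t$ in cell $i$ — which conserves each cell's
total target count to machine precision by construction.
`activity_over_pseudotime()` averages activity in equal-width pseudotime
bins (empty bins interpolated linearly, with a message), z-scales per TF,
clusters the binned profiles (Ward/Euclidean) and labels clusters by their
peak bin: early/mid/late for $k = 3$. Activity *curves* (binned profiles)
are the object of interest; per-cell activities are noisy for weakly
connected TFs, and recovery guarantees are stated for curves.

## Chromatin priming

Early-response genes satisfy `expr_pre <= 1` (RPKM-like), `lfc >= 1`
(log2) and `fdr <= 0.05` by default. These defaults operationalize
"no or very low expression before, upregulated after"; they are
configuration, not claims, and all three are arguments.

Accessibility is quantified in symmetric TSS windows (default flank
2,000 bp each side; the window size is a convention choice) with
any-overlap (≥ 1 bp) fragment counting — fragment-midpoint counting was
rejected for simplicity — and CPM normalization by the total library.
Accessibility change is $\log_2((\mathrm{CPM}_{post} + 1) /
(\mathrm{CPM}_{pre} + 1))$ with a 1-CPM pseudocount. Classification, in
order: *primed* (induced, $|\mathrm{lfc}_{acc}| \le 0.5$, pre-injury CPM
at or above the floor), *induced_accessible* (induced,
$\mathrm{lfc}_{acc} > 0.5$), *constitutive* (not induced, accessible),
*silent_closed* (otherwise). The accessibility floor defaults to the
median + 2 MAD of pre-injury CPM over a silent negative-control gene set
(e.g. olfactory receptors), anchoring "accessible" to an empirical
closed-chromatin distribution rather than a fixed constant. TSS-window
quantification is the default; gene-body quantification can be emulated
by supplying custom windows to `count_fragments()`.

All genomic intervals are 0-based half-open internally and on disk (BED
convention); 1-based TSS annotations are converted exactly once at the
boundary, and the conversion round-trips losslessly.

## The synthetic-data generators

`simulate_trajectory_counts()` draws NB counts around log-scale Gaussian
bump means,
$\log \mu(t) = \mathrm{baseline} + \mathrm{amplitude} \cdot
e^{-(t - \mathrm{peak})^2 / 2\,\mathrm{width}^2}$, with pseudotimes
uniform per lineage on a shared $[0, 10]$ range (lineages share the
trajectory origin, which is what makes the 1-unit shared-peak window
meaningful), offsets log-normal with sdlog 0.3 (realistic depth variation
without extreme outliers), and a hard one-hot lineage assignment. The
Gaussian bump guarantees a unique interior peak and a one-signed
derivative before it, so the true peak is well defined for recovery
checks. The truth table marks a (gene, lineage) involved when its
amplitude is at least 0.5 log-units — below that the expected derivative
never clears the test threshold $c = 0.1$.

Two generator-design rules matter for interpretation of passing tests:

* **Resolution.** The $K = 6$ clamped basis over a 10-unit range has
  ~2.5-unit knot spacing and attenuates features much narrower than half
  that spacing. Recovery settings therefore use bump widths of at least
  1.3 pseudotime units; narrower bumps are outside the smoother family
  and would be recovered with systematic peak-height bias.
* **Detectability.** The expected peak slope of a bump is
  $\mathrm{amplitude} \cdot e^{-1/2}/\mathrm{width}$. Recovery settings
  keep amplitude/width $\gtrsim 0.85$ so this slope clears $c = 0.1$ by
  several interior-grid standard errors (≈ 0.1 each at 300 cells per
  lineage) — i.e. amplitudes of 1.7–2.5 natural-log units (5–12 fold
  induction, typical of strongly induced lineage TFs). Shallower or
  narrower programs are legitimately hard at this depth and are not what
  the recovery checks claim to cover.

`simulate_grn_dataset()` draws TF out-degrees log-normally around a
median of 27 targets, gives orphan targets a random parent, gamma edge
rates, and smooth activity curves (Gaussian bumps with distinct peaks
along the cell ordering, positive baseline) — distinct peaks keep the
factorization identifiable. `simulate_priming_dataset()` places genes on
one synthetic chromosome and writes fragments whose window counts are the
*rounded rates* rather than Poisson draws: sampling noise on counts would
occasionally push a gene across the ±0.5 window or the adaptive floor,
and the generator's contract is that truth lies strictly outside the
classification margins. Closed windows carry a fixed 1/2/3-count pattern
(spread keeps the MAD-based floor strictly above every closed gene), and
a constant 200,000-fragment background pool far from genes keeps pre/post
library sizes comparable, as in real ATAC libraries where TSS-proximal
fragments are a small minority.

What the generators do **not** emulate: UMI chemistry, doublets, ambient
RNA, batch effects, zero inflation, trajectory-inference uncertainty
(pseudotime and lineage assignments are taken as given), GRN estimation
error (the network is taken as given), replicate structure in the bulk
data, or read-level sequence content. Passing recovery tests therefore
demonstrates correctness of the statistics under the stated model, not
robustness to upstream misspecification.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 100 random
fits for the derivative oracle; 5 replicates × 200 flat genes × 3
lineages × 300 cells for null calibration; 50 bump genes × 3 lineages ×
300 cells for peak recovery; 20 random EM instances for monotonicity and
conservation plus 10 small instances against an independent dense
KL-factorization oracle; one 10-TF × 100-target × 500-cell network for
activity recovery; 25 genes per class for priming. These sizes were
chosen so each property is measured with comfortable Monte-Carlo margin
while the whole suite completes in about a minute. Every stochastic step
is seeded; generators are bit-reproducible for a fixed seed.

## Known limitations

* Unpenalized $K = 6$ smoothers trade flexibility for exact covariance;
  genes with genuinely sharper dynamics than the basis resolution are
  attenuated rather than flagged.
* The derivative test's null calibration is conservative by construction
  (threshold $c$); its p-values are ranking devices, not calibrated error
  rates.
* The EM deconvolution ignores TF–target sign (repression) and provides
  no uncertainty on activities; non-identifiability can persist for TFs
  with heavily overlapping target sets even with the per-TF scale
  convention.
* Priming classification inherits every thresholding choice (baseline,
  fold change, FDR, window, floor); the class counts are threshold- and
  data-dependent and not comparable across datasets without matching
  configurations.
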