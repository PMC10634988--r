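# tfcascade

Trajectory-based regulatory analysis for single-cell and bulk regeneration
studies. `tfcascade` is aimed at analysts who already have a pseudotime
trajectory (lineage assignments and pseudotimes per cell) and want to ask
*when* genes — typically transcription factors (TFs) — switch on along each
lineage, *which* TFs drive which lineage, *how much* each TF contributes to
downstream expression, and *whether* injury-response genes were already
accessible at the chromatin level before activation.

## What it computes

**Lineage smoothers.** For gene *g* in cell *i*, counts follow a negative
binomial model with a log link,

    Y_gi ~ NB(mu_gi, phi_g)
    log mu_gi = sum_l s_gl(T_li) Z_li + U_i alpha_g + log N_i

where `s_gl(t) = sum_k b_k(t) beta_glk` is a cubic B-spline smoother of
pseudotime with K = 6 coefficients per lineage, `Z` assigns each cell to one
lineage, `U` holds optional covariates and `N_i` is a per-cell depth offset.
Fitting alternates iteratively reweighted least squares for the coefficients
with maximum-likelihood updates of the dispersion `phi_g`
([`fit_gene()`]).

**Derivative cascade test.** First derivatives of each smoother are
approximated by central finite differences of the basis functions on a grid
of J = 100 equally spaced pseudotimes (step 1e-7), with standard errors
propagated from the coefficient covariance. At each grid point the
thresholded statistic `T = max(0, delta - c)/se` (c = 0.1) gets a one-sided
normal p-value; Benjamini–Hochberg adjustment runs across the grid, and a
gene is *involved* in a lineage when the minimum adjusted p-value is below
0.05. The expression peak is the first zero crossing of the derivative
after the most significant grid point. Ordering involved TFs by peak time
yields the activation cascade ([`cascade_test()`], [`build_cascade()`]).
A TF is *lineage-specific* when its smoother maximum is at least 1.5-fold
that of every other lineage, and *shared* when it peaks in all lineages
within one pseudotime unit.

**TF-activity deconvolution.** Given a gene regulatory network (GRN),
target-gene counts decompose into latent TF-attributed molecules,
`X_tgi ~ Poisson(N_i beta_tg a_ti)` with `Y_gi = sum_t X_tgi`, fitted by EM
with rates supported on the GRN edges. The expected molecules assigned to a
TF in a cell are its activity proxy ([`em_fit()`], [`assign_molecules()`]);
binned over pseudotime, activities cluster into early/mid/late waves.

**Chromatin priming.** From paired pre/post-injury bulk RNA and ATAC data,
early-response genes (silent before, upregulated after) are split into
*primed* (TSS already accessible, |log2 accessibility change| ≤ 0.5) versus
*de-novo accessible* (accessibility gained, change > 0.5)
([`classify_priming()`]).

A synthetic-data module generates NB trajectory counts with known bump
programs, Poisson counts from a known GRN, and paired expression/fragment
data with known priming classes, so every stage is verifiable without
external data.

## Worked example

```r
library(tfcascade)

programs <- rbind(
  gene_program("Tf_early", baseline = log(2), amplitude = 2,
               peak_time = c(2.0, 2.2, 2.1), width = 1.5),
  gene_program("Tf_mid",   baseline = log(2), amplitude = 2,
               peak_time = c(5.0, 6.5, 5.2), width = 1.5),
  gene_program("Tf_flat",  baseline = log(3), amplitude = 0))
sim   <- simulate_trajectory_counts(programs, cells_per_lineage = 300,
                                    seed = 1)
fits  <- fit_genes(sim$data)
peaks <- cascade_test(fits)
print(peaks, digits = 3)
#>       gene lineage involved min_p_adj peak_time     peak_rule
#> 1 Tf_early      L1     TRUE  4.13e-03      1.95 zero_crossing
#> 2 Tf_early      L2     TRUE  6.13e-03      1.80 zero_crossing
#> 3 Tf_early      L3     TRUE  2.63e-04      1.77 zero_crossing
#> 4   Tf_mid      L1     TRUE  2.35e-18      4.77 zero_crossing
#> 5   Tf_mid      L2     TRUE  8.38e-17      6.74 zero_crossing
#> 6   Tf_mid      L3     TRUE  4.41e-12      5.39 zero_crossing
#> 7  Tf_flat      L1    FALSE  5.00e-01        NA          <NA>
#> 8  Tf_flat      L2    FALSE  5.00e-01        NA          <NA>
#> 9  Tf_flat      L3    FALSE  5.00e-01        NA          <NA>

shared_tfs(peaks)
#> [1] "Tf_early"
rownames(build_cascade(fits, peaks, "L1"))
#> [1] "Tf_early" "Tf_mid"
```

The two bump genes are detected in every lineage with peaks close to their
generating times (2.0/2.2/2.1 and 5.0/6.5/5.2); the flat gene is never
involved (its derivative never clears the threshold, so every grid p-value
is 0.5). `Tf_early` peaks within one pseudotime unit in all three lineages
and is called shared; `Tf_mid` is not (6.74 − 4.77 > 1). The cascade matrix
orders rows by peak time.

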