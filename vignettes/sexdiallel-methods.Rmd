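---
title: "Sex-specific diallel analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific diallel analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the choices
made where the methodology left room, and what the simulation-backed tests
do and do not establish.

## The mixed model

Fitness is an offspring count; the response is `log(fitness + 1)`. The
offset of 1 is required because zero counts occur (a focal individual can
fail to produce any offspring); it is the main arbitrary constant in the
package and anyone comparing absolute variance-component magnitudes against
other software should check which offset (if any) that software used. On
data without zeros the choice is numerically immaterial.

The full sexed model partitions phenotypic variance into fixed effects —
intercept, replicate block `x`, the self-vs-outcross contrast `b1`
(inbreeding), sex `S`, and `S×b1` — and ten random inheritance classes:
additive `a`, parental `c`, parent-specific dominance `b2`, symmetric
epistasis `b3`, asymmetric epistasis `d`, and their sex interactions. The
incidence coding is:

* `a`: one column per strain; entry = number of times the strain appears as
  a parent (2 on its self).
* `c`: dam minus sire indicator (0 on selfs) — reciprocal/parental effects.
* `b2`: strain presence on outcross rows only, 0 on selfs. `b2` is therefore
  identified by the contrast between a strain's outcrosses and what its self
  predicts — strain-specific dominance. This is one defensible reading of
  the classical parent-specific dominance item; other implementations use
  internally orthogonalized contrasts, and component magnitudes (not the
  model space) can shift with that choice.
* `b3`: one column per unordered outcross pair (both orientations), n(n−1)/2
  levels — 120 for 16 strains.
* `d`: the same pair columns signed by orientation (+1 when dam < sire).
* `S×q`: each incidence multiplied row-wise by the sex contrast, +1 female /
  −1 male. With this sign convention a positive `S×q` prediction is
  female-beneficial, matching the rotation `q_SA = (q_F − q_M)/√2`.

Sex-subset models drop all `S` terms and filter to one sex.

## Unconstrained REML

Variance components are estimated by maximizing the restricted
log-likelihood with **no positivity constraint**: the only requirement is
that the marginal covariance `V = Σ σ²_q Z_q Z_qᵀ + σ²_ε I` stays positive
definite. Negative estimates are reported as such (and read as "zero");
constrained solvers would silently redistribute that variance into other
components, which is exactly what this analysis must avoid. This is why the
solver is authored in the package rather than delegated to a bounded
mixed-model library.

Numerical design:

* The likelihood is profiled over `σ²_ε` and optimized in the variance
  ratios `γ_q = σ²_q/σ²_ε`, reduced to m×m crossproduct algebra (m = total
  random levels, 576 for the full sexed 16-strain model) via the Woodbury
  and Sylvester identities, so a fit on thousands of records only
  factorizes m×m matrices.
* Positive definiteness is checked through a Cholesky factorization of
  `I + S Γ S` (S the symmetric square root of `ZᵀZ`), which shares its
  spectrum with `I + Z Γ Zᵀ`; a failed factorization returns a large
  objective value, which acts as step control.
* Optimization runs in `φ = asinh(γ)`: smooth, sign-preserving (negative
  ratios stay reachable) and well-conditioned when near-noise-free data push
  ratios into the thousands. The analytic score vector is supplied;
  `nlminb` results are accepted when its convergence code is clean or the
  final score norm is below 1e-2, with a short Nelder–Mead polish otherwise.
  Starting values are `γ = 0.05` for every component.
* Standard errors come from the observed information — a numerical Hessian
  of the restricted log-likelihood in `(σ²_1, …, σ²_ε)` at the optimum with
  relative step sizes — inverted; non-invertible information yields `NA`
  with a warning rather than a fabricated number.
* Fixed effects are GLS at the optimum, with per-term Wald F statistics on
  denominator df = n − rank(X). Exact small-sample df corrections
  (Kenward–Roger and kin) are out of scope, so printed F/p values are
  approximate and are not used as primary evidence anywhere in the package.
* BLUPs are `û_q = γ_q Zᵀ_q H⁻¹(y − Xβ̂)`. Classes estimated negative refuse
  BLUP extraction (`extract_blups`): predictions under a negative prior
  variance are not meaningful, and downstream geometry excludes such
  classes with an explicit reason.

The test suite pins the solver to two independent oracles: a dense-matrix
implementation of the restricted likelihood (brute-force grid comparison on
a 4-strain two-component model) and a dense Henderson mixed-model-equation
solve for the BLUPs and GLS fixed effects (agreement to 1e-8).

## SC/SA geometry

BLUP vectors are variance-standardized by dividing by their sample standard
deviation (n − 1 denominator) **without centering** — BLUPs are already
centered near zero by construction, and centering would discard the small
mean displacement that is part of the prediction. Pair-level classes
(`b3`, `d`) are collapsed to strain means of the raw pair predictions before
standardization; for the antisymmetric class `d` this collapse is
convention-dependent (the pair sign flips with orientation) and its
strain-level geometry should be read with that caveat. Angles use
unit-norm vectors, `θ = arccos(u·v)` with the inner product clamped to
[−1, 1] against round-off, reported in degrees.

## The SSDR array-covariance test

The pipeline: fit `y = mu + x + b1 + b3 + ε` (adding random `a` for the
conservative variant), subtract the fixed part and the `b3` (and optionally
`a`) BLUPs, tabulate family means per sex from the residuals (pooling
replicates across blocks, un-weighted — block is already removed), compute
each strain's `σ_P,r` (dam-side and sire-side covariances against the
partners' self means, averaged; sample covariance, n − 1 denominator;
missing families drop the affected partner pairwise; at least 3 usable
partners per side required), and correlate male against female `σ_P,r`
across strains. Pearson confidence intervals use the Fisher z transform
with the conventional 1.96 critical value; p-values use the t statistic on
n − 2 df for both Pearson and (as an approximation) Spearman.

One deliberate deviation from the minimal residualization model: the
inbreeding contrast `b1` sits in the fixed part. The array covariance is
provably invariant to the constant self-vs-outcross shift that `b1`
absorbs (covariances ignore location), but leaving that large shift in the
data lets it alias into the uncentered `b3` incidence — whose column span
contains the all-pairs-equal direction — inflating `σ²_b3` and letting the
BLUP removal strip essentially all pair-level structure. Classical
implementations of the Hayman partition use orthogonal contrasts for the
dominance items, which has the same protective effect.

`wr_vr_diagnostic` regresses `σ_P,r` on the array variance `V_r`. Hayman's
slope-1 law presumes dominance *variation among arrays*, no epistasis and
raw (unresidualized) family means; under a purely additive architecture all
arrays share one theoretical (V_r, W_r) point and the regression is
degenerate. The tests therefore check the slope against 1 on raw family
means under a dominance-varying noise-free architecture, not under
additivity.

## What the generator emulates — and what it does not

`sim_config()` defaults describe a study-scale experiment: a 16×16 diallel
(240 outcross families + 16 selfs), two replicate blocks with a small block
effect (0, −0.1 log units), about 2,900 assays (3 planned replicates per
family × sex × block thinned by 6% i.i.d. missingness — the unbalanced
replication of real assays), baseline log fitness `log(30)`, and residual
log-scale noise σ_e = 0.3 (residual log-variance ≈ 0.09, the magnitude this
kind of assay shows). The genetic architecture follows the inference that
fitness variance in such populations reflects relatively few larger-effect
polymorphisms under balancing selection: 8 SA + 6 SC loci of effect 0.2
log units at allele frequency 0.4, dominance of the beneficial allele
concentrated near 0.8 (Beta(10, 1)), and one private recessive load locus
per strain (0.3 log units in females, doubled in males) producing
inbreeding depression that is stronger in males. Allele frequency sits off
0.5 deliberately: at exactly 0.5 the per-strain mean dominance deviation is
constant across strains and the parent-specific dominance class is
structurally empty.

Two pinned presets support the Monte-Carlo sign checks:

* `high_signal_config()` — full reversal, 4 SA + 10 SC loci, effect 0.4,
  near-complete dominance (Beta(20, 0.5)), p = 0.45, σ_e = 0.1, 5
  replicates, no missingness. Under these conditions the cross-sex
  `σ_P,r` correlation is reliably negative.
* `concordant_control_config()` — the matching positive control with
  sex-shared dominance. It is *not* simply the high-signal preset with the
  mode switched: under concordant dominance the sex-pooled pair deviations
  removed by the `b3` residualization contain the signal itself, so the
  control uses strong-but-not-extreme dominance and moderate per-pair
  replication, keeping the `b3` shrinkage mild enough for the shared signal
  to survive.

Pilot analysis of the generator exposed two structural facts worth keeping
in mind when reading test results. First, the test's signal-to-noise
*decreases* with the number of loci: both the per-strain signal and the
partner-sampling noise of a covariance over 15 partners scale with total
genetic variance, but the signal concentrates as per-locus effects grow.
Many-small-loci architectures are undetectable at n = 16 regardless of
replication. Second, a detectable reversal signature requires sexually
concordant variance among the self means: if the selfs' values are purely
sexually antagonistic (P_M ≈ −P_F), a sex-shared finite-sample variance
term dominates the arrays and the cross-sex correlation is not negative.
Both properties belong to the method, not the implementation, and they
bound what a passing simulation says about real data: the tests demonstrate
correct machinery and correct sign behaviour under architectures the test
can see, not that every reversal architecture would be detected.

Not emulated: linkage and sex-linked loci (inheritance classes are
autosomal), generative parental effects or reciprocal asymmetries (`c` and
`d` carry no simulated variance), heteroscedastic residuals by sex, and
epistatic generative terms beyond what the exponential link induces.

## Problem sizes and determinism

The suite runs its heavier checks at deliberately chosen desk scales: the
REML grid oracle on a 4-strain, 96-record, two-component model; parametric
bootstrap consistency at 150 replicates of that model; additive-recovery at
8 strains × 4 replicates over a handful of seeds; the reversal sign
property over 50 seeded 16-strain runs (and 24 in the acceptance script);
geometry alignment on a 16-strain near-noise-free additive simulation.
Every stochastic quantity flows from an explicit seed; `generate_diallel`
re-seeds from its config, so identical configurations reproduce identical
datasets, tables and test statistics byte for byte.

## Known limitations

* Variance-component magnitudes depend on the `b2`/`d` incidence
  convention and the log offset; cross-software comparisons should expect
  small systematic shifts even when the model space is identical.
* Standard errors are curvature-based (observed information); no profile
  or resampling intervals.
* The Spearman p-value uses the t approximation, which is anticonservative
  at very small n compared with exact permutation.
* `σ_P,r` needs the full self diagonal; partial diallels without selfs are
  rejected for the SSDR stage rather than approximated.
* Negative-variance classes are excluded from geometry rather than
  propagated with pseudo-BLUPs; on small designs this can exclude most
  classes.
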