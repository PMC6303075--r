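# sexdiallel

Quantitative-genetic analysis of **full diallel crosses with sex-specific
fitness data**: variance partitioning into the Hayman inheritance classes
and their sex interactions by unconstrained REML, a geometric reading of the
sexed components as sexually antagonistic (SA) axes, and the array-covariance
test for **sex-specific dominance reversal (SSDR)** — the situation in which
the allele favoured in one sex is also dominant in that sex and recessive in
the other, generating net heterozygote advantage and balancing selection on
fitness.

The package is aimed at evolutionary quantitative geneticists running diallel
crosses among inbred (isogenic) strains and assaying fitness in both sexes,
and at anyone who wants a tested, simulation-backed implementation of the
Hayman array-covariance machinery.

## The model

For individual fitness assays `y` (log-transformed offspring counts) over all
`n × n` ordered crosses among `n` isogenic strains, the full sexed model is

```
y = mu + x + b1 + S + S×b1                     (fixed)
    + a + c + b2 + b3 + d                      (random)
    + S×a + S×c + S×b2 + S×b3 + S×d + eps      (random)
```

with block `x`, inbreeding (self vs outcross) `b1`, sex `S` (+1 female,
−1 male), additive/GCA `a` (one level per strain, incidence 2 on selfs),
parental `c` (dam − sire, signed), parent-specific dominance `b2`
(outcross-only per-strain), symmetric epistasis `b3` (one level per unordered
strain pair), asymmetric epistasis `d` (signed by orientation), and each
random class crossed with the sex contrast. Variance components are estimated
by **unconstrained** REML — negative estimates are permitted, interpreted as
zero, and must not disrupt the remaining components — which is why the solver
is written in-package rather than delegated to a positivity-constrained mixed
model library.

Three analyses build on the fit:

* **Variance partitioning** — the per-class `sigma^2` table with
  standard errors from the observed information matrix.
* **SC/SA geometry** — strain BLUPs from separate male and female fits are
  variance-standardized and rotated 45°,
  `q_SC = (q_F + q_M)/sqrt(2)`, `q_SA = (q_F − q_M)/sqrt(2)`; the full
  model's unsexed BLUPs align with `q_SC` and its sexed BLUPs with `q_SA`,
  with the angle `theta = arccos(q · S×q)` between them near 90° when the
  sexed component is genuinely sexually antagonistic.
* **SSDR test** — after residualizing block, inbreeding and symmetric
  epistasis, each strain's array covariance
  `sigma_P,r = ½[cov(r_dam, P) + cov(r_sire, P)]` between its outcross
  family means and its partners' self means estimates that strain's relative
  load of recessive (vs dominant) alleles; correlating male against female
  `sigma_P,r` across strains is the test: negative ⇒ dominance reversed
  between the sexes.

A synthetic diallel generator (`sim_config()`, `generate_diallel()`) with an
explicit biallelic-locus architecture — SA and SC loci, per-sex dominance
coefficients up to full reversal, strain-private recessive load, block
effects, count-like noise — makes every stage testable end to end.

## Worked example

Simulate a 16-strain diallel under full sex-specific dominance reversal and
run the SSDR test:

```r
library(sexdiallel)

cfg <- high_signal_config(seed = 1)   # full reversal, few large-effect loci
sim <- generate_diallel(cfg)
validate_diallel(sim$dataset)
#> Diallel validation report
#>   records:       5120
#>   strains:      16 (256 possible families)
#>   by sex:        F=2560  M=2560
#>   blocks:        1=2560  2=2560
#>   missing:       0 outcross families, 0 selfs

ssdr_statistics(sim$dataset)
#> SSDR array-covariance test (baseline, 16 strains)
#>   Pearson r  = -0.673  (95% CI -0.88 to -0.27), P = 0.004277
#>   Spearman rho = -0.635, P = 0.008182
```

The strongly negative cross-sex correlation says that strains whose fixed
alleles act dominantly in sons act recessively in daughters and vice versa —
the SSDR signature the generator planted. A concordant-dominance control
(`concordant_control_config()`) drives the same statistic positive.

The full pipeline (validation, full sexed + sex-specific REML fits, SC/SA
geometry, both SSDR variants) is one call:

```r
report <- run_pipeline(cfg, out_dir = "out")   # or a CSV path, or a dataset
report$varcomp      # variance components with s.e.
report$geometry     # r(q, q_SC), r(S×q, q_SA), theta per class
report$ssdr         # baseline and SC-additive-removed test results
```

Real data enter through `read_diallel_table()` — a long-format CSV (or xlsx
sheet) with columns `fitness, sex, sire, dam, block` and sex coded
1 = female / 2 = male.

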