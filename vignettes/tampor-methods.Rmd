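---
title: "Methods: the tunable median polish of ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the tunable median polish of ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and what the polish corrects

Quantitative omics abundance matrices (features in rows, samples in
columns) carry multiplicative technical structure on top of the biology:
per-feature-by-batch effects (multiplex labeling, digestion day, LC
column, site, platform), per-sample loading factors (imperfect equal-mass
loading), and per-value technical noise.  On the log2 scale these act
additively:

$$\log_2 x_{ij} = \mu_i + \beta_{i,k(j)} + \lambda_j + b_{ij} + \varepsilon_{ij},$$

where $\mu_i$ is the latent feature level, $\beta_{i,k}$ the batch effect
of feature $i$ in batch $k$, $\lambda_j$ the sample loading, $b_{ij}$
biology and $\varepsilon_{ij}$ noise.  The polish removes $\beta$ and
$\lambda$ by alternating two robust centering steps until the matrix stops
changing:

1. **Row-wise ratio.**  Every value is divided by a per-row, per-batch
   denominator median $D_{ik}$ and re-referenced through a batch factor:
   $r_{ij} = x_{ij} / D_{ik} \cdot \mathrm{grand}_i / M_{ik}$, where
   $\mathrm{grand}_i$ is the median of $M_{i\cdot}$ over batches.  This
   drives the denominator set's median ratio in every batch toward 1,
   equalizing the batches' central tendencies per row.
2. **Column centering.**  The log2 ratios have each column's median
   subtracted, centering every sample at a log2 ratio of 0.  This is the
   loading correction; it leans on the orders-of-magnitude dynamic range
   *between* features within a sample, which dominates the within-feature
   variance across samples.  Data whose inter-feature dynamic range has
   been ablated (e.g. per-row percent-of-maximum scaling) has no
   meaningful sample-wise central tendency and must not be fed to the
   polish.

The centered ratios are antilogged and multiplied by the per-row medians
of the input, saved once before the first iteration, so output stays in
input units; the loop repeats, recomputing all medians from the current
working matrix, until the absolute difference of successive Frobenius
norms of the working log2 matrix (present entries only) falls below the
tolerance (default `1e-8`, cap 250 iterations).  A run that hits the cap
is flagged with a warning and should be treated as preliminary: inspect
the convergence trace for where the precipitous decline ends.

### The three denominator modes

* **`noGIS`** — $D_{ik}$ is the median of *all* samples of batch $k$;
  $M \equiv 1$.  Requires batches whose biological traits are balanced,
  because aligning whole-batch medians redistributes any signal that is
  confounded with batch.
* **`gis_only`** (flag `GIS`) — both ratio terms use the intra-batch
  medians of the global internal standard (GIS) channels, a pooled
  equal mixture of all samples replicated in every batch.  The least
  aggressive variant: non-GIS samples never enter a denominator.
* **`gis_plus_nonGIS`** (flag `useAllNonGIS`) — $D_{ik}$ uses GIS
  medians while $M_{ik} = \mathrm{median(non\mbox{-}GIS)} /
  \mathrm{median(GIS)}$ re-references each batch to its own samples.
  This tolerates *defective* GIS channels (e.g. bridging standards
  digested separately from the batch mixtures): the defective GIS median
  cancels out of the product $D_{ik} M_{ik}$.

Mode choice is a statement about the data: use `gis_only` when the
bridging channels are trustworthy, `gis_plus_nonGIS` when they exist but
may be compromised, and `noGIS` when there are none and batches were
randomized with trait balancing.  Sequential passes with different batch
columns (first multiplex batch, then cohort/site) compose by calling
`run_tampor()` twice; no special machinery is needed.

### Assumptions and degenerate cases

* All present values must be positive (`sanitize_nonpositive()` converts
  zeros and negatives to missing, with a count).
* Missingness per feature must stay below 50% (`filter_rows_by_missingness()`,
  removal at exactly 50%), so that every median is a true non-noise value.
  Count-type (RNA-seq-like) input is first left-tail censored
  (`censor_low_signal()`): values at or below a noise threshold become
  missing, and features whose noise-plus-missing fraction exceeds the cap
  are dropped.
* Medians are computed over present values only; the even-count median is
  the arithmetic mean of the central pair (in linear space).  A feature
  constant within a denominator set is valid (its ratio is exactly
  $\mathrm{grand}/M$).  A (feature, batch) whose denominator set is
  entirely missing makes those entries missing rather than aborting.
* Any systematic whole-sample concentration difference (e.g. by
  diagnosis) is removed by design; if loading differences are themselves
  the signal, this is the wrong normalization.
* The core loop uses no randomness; results are reproducible to
  floating-point associativity.

### Algebraic properties, stated precisely

Properties the implementation guarantees (and the test suite asserts):

* **Row-scale equivariance** — scaling input row $i$ by $c$ scales output
  row $i$ by exactly $c$.
* **Column-scale invariance of the normalized profile** — in `gis_only`
  mode, scaling any columns by arbitrary positive factors leaves
  `corrected / saved row medians` bitwise-stable (the trajectory of
  centered ratios is identical; loadings are absorbed by column
  centering).  The *raw* output additionally carries the saved input row
  medians, which can shift when a rescaled value crosses the order
  statistics that define a median, so raw-output invariance is only
  approximate.  The same order-statistic effect makes the non-GIS modes
  approximately, not exactly, invariant.
* **Fixed point** — one further iteration of the map on a converged
  matrix (with the original saved medians) is a no-op.  Re-running
  `run_tampor()` from scratch is idempotent in `noGIS` mode with odd
  batch sizes (there the recomputed row medians coincide exactly with the
  saved ones); in the GIS modes a re-run rescales rows by the ratio of
  new to old saved medians.
* **Missing-pattern preservation** — output missingness is the input
  missingness plus entries whose denominators were undefined; no value is
  invented.
* **Equivalence to Tukey's median polish** — for a single batch in
  `noGIS` mode the working log2 matrix follows exactly the residual
  sequence of the classical two-way median polish (row sweep then column
  sweep), offset by the saved log2 row medians.  This holds for odd
  sample counts; for even counts the conventions legitimately differ
  (arithmetic mean of the central pair in linear versus log space).

### Convergence statistic

The default statistic is the absolute difference of successive Frobenius
norms.  Because a norm difference can be small while the matrix still
moves, `tampor_config(convergence = "matrix_diff")` exposes the stricter
$\|A_t - A_{t-1}\|_F$ variant (off by default, matching the published
wording).  Tests of fixed-point properties use tightened tolerances
(`1e-11`-`1e-12`) to approach the mathematical fixed point; user-facing
defaults stay at `1e-8`/250.

## QC metrics

* **Mean-SD series** — per-feature mean and sample SD ($n-1$) of log2
  abundance, ranked by mean descending.  Correction should lower the SD
  band at all ranks.
* **Classical MDS** — Torgerson scaling (`stats::cmdscale`) of Euclidean
  inter-sample distances over pairwise-complete features, each squared
  distance rescaled by (total features / shared features) so distances
  stay comparable under missingness.  Before correction samples cluster
  by batch; after, one focus.  The distance flavor is a package choice;
  the rescaling is unverifiable against any published convention.
* **Variance partition** — per feature, each factor scored *marginally*:
  categorical factors by a one-way method-of-moments variance-component
  fraction $\hat\sigma_b^2 / (\hat\sigma_b^2 + \hat\sigma_w^2)$ (between
  component truncated at zero; unbalanced-design $n_0$), continuous
  traits by squared Pearson correlation.  This deliberately approximates
  mixed-model variance partitioning: fractions of correlated factors are
  not orthogonalized, and the residual is reported as
  $\max(0, 1 - \sum)$.
* **Correlations** — Pearson over pairwise-complete values, and the
  biweight midcorrelation with the conventional tuning constant 9 and
  *raw* MAD (no 1.4826 consistency factor): deviations beyond 9 MADs get
  zero weight, so sparse gross outliers cannot attenuate it.
* **Correlation-shift analyses** — replicate pairs and all non-replicate
  pairs are correlated on log2, per-feature median-centered data (the row
  profile would otherwise push every correlation to ~1), GIS channels
  excluded.  The one-tailed Welch t-test compares the absolute
  correlation change of improved versus worsened pairs.
* **Differential abundance** — per-feature Welch t-test on log2 values
  (the pooled-variance and moderated alternatives are not used; the
  choice is a package decision), log2 fold change as difference of group
  means, Benjamini-Hochberg adjustment across tested features; features
  with under two present values per group, or zero variance in both
  groups, are skipped and counted.

## The synthetic-data generator

`simulate_dataset()` draws from exactly the model above, with ground
truth stored so recovery is checkable: log-normal latent medians spanning
`dynamic_range_orders` (default 4) decades, per-feature-by-batch log2
effects (`batch_effect_sd`), per-sample loadings (`loading_sd`),
per-value noise (`technical_noise_sd`), group fold changes
(`spike_log2fc`) on a `spike_frac` subset, GIS channels equal to the
linear-scale mean of all case columns, random and batch-wise masking
(applied last), and cross-batch technical replicate pairs.  The RNG
(Mersenne-Twister/Inversion) is pinned in the design so seeds are
portable.

Choices worth stating:

* **Trait balance** (`balance_groups = TRUE` by default): donor groups are
  interleaved systematically so every batch is (near-)balanced.  This is
  the cohort design the correction assumes; with confounded batches the
  median alignment provably redistributes group signal into batch
  corrections (we keep random assignment available as a stress option and
  demonstrate the bias it causes).
* **GIS defect** (`gis_defect_sd`): contaminated-normal per
  feature-by-GIS-channel — a fraction `gis_defect_frac` (default 1%) of
  cells shifted by $N(0, (\sigma/\sqrt{f})^2)$ so the marginal SD equals
  `gis_defect_sd`.  Digestion defects are physically per digestion
  (channel) and plausibly ablate a minority of proteins strongly rather
  than nudging all of them; sparse large shifts are also what separates
  Pearson (attenuated) from bicor (robust).  The magnitude 0.5 log2 used
  in the benchmarks is a package choice, not a published value.
* **Episodic bursts** (`burst_prob`, `burst_log2_scale`): one-sided log2
  elevations of feature-specific gamma magnitudes, per donor (technical
  replicates share them).  Without some skewed shared structure,
  simulated samples are mutually independent and all-pair correlations
  average to zero, leaving nothing for a correction to "boost";
  right-skewed episodic expression (inflammation proteins, blood
  contamination of CSF) is the realistic source of the positive all-pair
  correlation baseline real proteomes show.  Off by default.
* **Left-tail-biased masking** (`mnar = TRUE`) exists for stress tests but
  is off by default: the polish assumes missingness without extreme bias.

Two designs are pinned in the package.  The **standard benchmark**
(`tampor_standard_benchmark()`): 1,000 features, 10 batches of 8 cases +
2 GIS (100 samples), batch SD 1.0, loading SD 0.5, noise SD 0.3, 10%
spikes at log2FC 1, seed 20230412.  The **replicate-pair benchmark**
(`tampor_replicate_benchmark()`): 500 features, 40 small batches of 3
cases + 3 GIS channels, 60 donors all measured twice across batch halves,
case fraction 1/3 with exact per-batch balance, channel-level GIS defect
SD 0.5, bursts at probability 0.25 — corrected with `gis_only` and
compared against the naive intra-batch GIS-mean ratio.

What the generator does **not** emulate: peptide-to-protein rollup,
isotopic interference, instrument drift, co-expression module structure,
or missing-not-at-random patterns beyond the simple left-tail option.
Passing recovery tests therefore show the algorithm does what it claims
under its own model assumptions; they do not certify behavior on data
that violates them (confounded batches, ablated dynamic range, extreme
MNAR).

## Problem sizes and known limitations

The test suite and acceptance script run the standard benchmark
(1,000 x 100), a 5-batch variant with 20 samples per group for
fold-change recovery, five seeds of the defect and replicate benchmarks,
and oracle batteries of 1,000+ random small instances; together they
complete in a few minutes on one CPU, sizes chosen to make every claimed
behavior measurable at desk scale.

Limitations to keep in mind:

* Differential tests on corrected data are anti-conservative: aligning
  per-batch medians estimated from the same few samples shrinks
  within-batch variance (at 8 samples per batch we measure ~15% of null
  features below p = 0.05).  Corrected data is well suited to estimation
  and network analysis; for strict error control include batch in the
  model or calibrate by permutation.
* Median alignment with $n$ denominator samples adds residual alignment
  noise of order $\pi\sigma^2/2n$ per (feature, batch); tiny batches pay
  for robustness in precision.
* Convergence is not guaranteed for every matrix; non-converged runs are
  reported as such, never silently accepted.
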