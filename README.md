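# tampor

Batch-effect correction and multi-cohort / multi-platform harmonization of
omics abundance matrices by a **tunable, iterative median polish of
ratios** — for proteomics (TMT or label-free), metabolomics, and left-tail
censored transcriptomics, aimed at anyone who needs one clean
feature-by-sample matrix out of many batches, sites, or measurement
platforms before downstream (systems-level) analysis.

## The method

For feature *i*, sample *j* in batch *k*, each iteration computes

```
ratio_ijk = x_ij / D_ik  *  grand_i / M_ik
```

where `D_ik` is the per-row denominator median of batch *k* and `M_ik` a
per-row batch factor with `grand_i = median_k(M_ik)`.  Log2 ratios are then
column-median-centered (loading correction), antilogged, and rescaled by
the per-row input medians saved before iteration 1; the loop repeats until
the difference of successive Frobenius norms of the working log2 matrix
drops below `1e-8` (cap 250 iterations).

Three denominator tunings cover the practical regimes:

| mode | `D_ik` | `M_ik` | when |
|---|---|---|---|
| `noGIS` | median of all samples in batch | 1 | no bridging standards; trait-balanced batches |
| `gis_only` (`GIS`) | median of GIS channels | 1 | trustworthy pooled bridging standards in every batch |
| `gis_plus_nonGIS` (`useAllNonGIS`) | median of GIS channels | median(non-GIS)/median(GIS) | GIS present but possibly defective |

GIS = global internal standard, a pooled all-sample mixture replicated in
every batch.  The same machinery harmonizes multiple measurement
platforms by transposing the problem: samples become rows, assays become
columns, platforms become batches, and the features shared by all
platforms act as the GIS (`transpose_for_multiplatform()`).

The package also ships the field's standard QC battery (mean-SD series,
classical MDS, per-feature variance partition, Pearson and biweight
midcorrelation, replicate-pair and all-pair correlation-shift analyses,
Welch/BH differential abundance), a seeded synthetic-data generator with
full ground truth, and a small CLI.

## Worked example

```r
library(tampor)

design <- simulation_design(n_batches = 5)   # 1,000 features, 5 batches of 8 cases + 2 GIS
ds  <- simulate_dataset(design)
fit <- run_tampor(ds$abundance, ds$annotation, tampor_config("useAllNonGIS"))
print(fit)
#> median polish of ratios: 1000 features x 50 samples
#>   mode: gis_plus_nonGIS
#>   iterations: 50 (converged)
#>   final delta: 9.456016e-09

before <- evaluate_recovery(ds$abundance,  ds$truth)
after  <- evaluate_recovery(fit$abundance, ds$truth)
sprintf("median batch variance fraction: %.2f -> %.2f",
        before$batch_fraction_median, after$batch_fraction_median)
#> "median batch variance fraction: 0.64 -> 0.00"
sprintf("spiked log2FC median abs error after correction: %.3f",
        after$spike_log2fc_mae)
#> "spiked log2FC median abs error after correction: 0.086"
```

Reading: the generator plants per-feature batch effects explaining ~64%
of the median feature's variance; after the polish the method-of-moments
batch fraction of the median feature is 0, while the spiked group fold
changes (truth: 1.0 log2) are still recovered to within 0.09 — batch
structure is removed without flattening the biology.  On files instead of
objects:

```sh
Rscript inst/cli/tampor.R run --input abundance.tsv --annotation samples.tsv \
    --out run1 --mode useAllNonGIS --qc
```

writes `corrected.tsv`, `trace.csv`, `manifest.json` and `qc/*.tsv`.

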