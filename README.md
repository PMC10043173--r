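# epimem

Does a stimulus leave a durable epigenetic mark on dividing cells, or is the
mark simply washed out two-fold at every round of DNA replication?
Stimulus-induced histone modifications (H3K4me1, H3K4me3, H3K27Ac) have been
proposed as the substrate of trained immunity, yet no mechanism is known
that copies these marks from parental to daughter DNA strands. Under purely
passive segregation, a modification present on a fraction *p₀* of alleles is
expected to fall to

> *p(d) = p₀ · r^d*, with *r = 0.5* (50% loss per division),

after *d* divisions. `epimem` implements the full statistical workflow for
testing this dilution model on division-indexed ChIP-seq / RNA-seq time
courses, together with a synthetic-data generator that reproduces the
experimental design: two conditions (control vs stimulus-experienced),
timepoints T0 and D2–D14 in steps of two divisions, three replicates nested
in experimental batches, negative-binomial counts, and latent coupling
between peaks and genes.

The pipeline stages are:

1. **Simulation** — nucleosome-level Monte-Carlo dilution
   (`simulate_nucleosome_dilution()`) and NB count matrices with known
   per-feature effect trajectories (`simulate_counts()`,
   `simulate_priming_counts()`): non-persistent (*δ_d = δ₀ r^d*), retained
   (*δ_d = δ₀*), induced (*δ_d = δ₀·[d ≥ d_on]*), or null.
2. **Differential testing** — TMM normalization (`tmm_factors()`, via
   edgeR), log₂-CPM (`log_cpm()`), and per-feature OLS on per-timepoint
   designs such as `~ 1 + experiment + time + condition:time`
   (`fit_model()`), with moment-matched empirical-Bayes variance moderation
   and BH FDR per contrast.
3. **Decay analysis** — retention curves of T0-significant features
   (`retention_fractions()`), the 0.5^d null (`dilution_null()`), a
   Kolmogorov–Smirnov comparison (`ks_compare()`), and a log-linear
   retention-rate fit (`fit_retention_rate()`).
4. **Trajectories and coupling** — classification into non-persistent /
   induced / retained by significance at the first and last divisions
   (`classify_trajectories()`), mean |log₂FC| group curves, midpoint-to-TSS
   nearest-gene assignment (`nearest_gene()`), Fisher-exact peak–gene
   trajectory concordance (`fisher_concordance()`), and PC1×PC2
   epigenome–transcriptome coupling (`pc_product_coupling()`).
5. **Priming** — per-timepoint secondary-stimulation contrasts
   (`priming_contrast()`, design `~ 1 + experiment + primary +
   Pam:primary`), adaptive shrinkage with local false sign rates
   (`shrink_effects()`, primed genes at lfsr < 0.01), overlap patterns and
   primed-gene/peak enrichment.

`run_pipeline()` chains everything and writes TSV/BED/JSON artifacts plus a
run log; `inst/cli/epimem.R` is a small command-line wrapper.

## Worked example

```r
library(epimem)

cfg <- sim_config(n_peaks = 5000, n_genes = 50,
                  fraction_responsive = 0.4, fraction_maintained = 0,
                  fraction_induced = 0, coupling_fraction = 0,
                  retention_rate = 0.5,   # passive dilution
                  seed = 1)
sim  <- simulate_counts(cfg)
fit  <- fit_model(log_cpm(sim$peaks, tmm_factors(sim$peaks)), sim$meta,
                  "washout")
sig  <- significant_features(fit, alpha = 0.1)
names(sig) <- sub("^d", "", names(sig))
curve <- retention_fractions(sig[["0"]], sig)
print(curve)
#> Retention curve (2204 features significant at T0)
#>  division observed      null
#>         0  1.00000 1.000e+00
#>         2  0.40336 2.500e-01
#>         4  0.03221 6.250e-02
#>         6  0.00000 1.562e-02
#>         8  0.00000 3.906e-03
#>        10  0.00000 9.766e-04
#>        12  0.00000 2.441e-04
#>        14  0.00000 6.104e-05

fit_retention_rate(curve)
#> Retention-rate fit over 3 points: r = 0.424 per division
#> (half-life 0.81 divisions), R^2 = 0.931

ks_compare(curve$observed, curve$null)
#> $D = 0.625, $p = 0.0879
```

2204 of 5000 peaks respond at T0; by two divisions only ~40% of them are
still significant and by six divisions none are. The fitted per-division
retention rate (~0.42) is close to the passive value 0.5, and the K-S test
does not reject the 0.5^d null (p = 0.088) — the simulated marks behave
like passively diluted ones.
Re-running with `retention_rate = 1` (maintained marks) gives a flat curve,
a fitted rate of ~1.0 and a strongly rejecting K-S test.

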