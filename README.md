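# pseudospec

Correlation-based deconvolution of multi-sample GC/MS and LC/MS(n)
metabolomics peak tables into per-metabolite pseudo-spectra and spectral
library entries.

## The problem

Non-targeted metabolomics profiles every small molecule in a sample by
chromatography coupled to mass spectrometry. Each metabolite produces many
redundant ion peaks — EI fragments, adducts (m+H, m+Na, ...), multimers,
isotopes, in-source fragments — and incompletely separated metabolites
co-elute, so a single sample's spectrum is an undecomposable mixture.
Ion-centric statistics over such data inflate false discovery rates and
skew multivariate analyses toward compounds that happen to ionize into
more peaks.

`pseudospec` is for analysts who already have integrated peak tables (one
row per detected ion per sample) from a multi-sample study and want them
organized by *chemical*, not by ion. It exploits the fact that every ion
of a metabolite inherits that metabolite's biological abundance in each
sample: across a diverse study, ions of one compound are highly correlated
while ions of different compounds are largely non-covariant.

## The method

1. **Retention-index calibration** — piecewise-linear interpolation of
   each peak's RT through per-sample internal-standard (rt, ri) pairs.
2. **Ion binning** — greedy, area-descending partition of all MS1 ions
   into cross-sample bins within a mass window (±0.4 Th) and RI window
   (±25), iterated to a stable partition with bin centers reset to
   singlet means; near-miss ions are recovered from under-filled bins
   within extended windows when their area lies within 4 SD of the bin's
   singlet areas.
3. **Grouping** — bins sorted by mean area; the largest unassigned bin
   normalizes a new group, and a smaller bin joins when the Pearson
   correlation *r* of common-singlet areas with the normalizer satisfies
   *r* ≥ 0.8 (tunable 0.70–0.90), with gates on RI difference, number of
   common singlets, and the RSD of the per-sample area ratio. Each group
   is one metabolite's pseudo-spectrum.
4. **Chemical intelligence** (LC data) — for an ion form with adduct mass
   *a* and multimer count *n*, measured = *n*·M + *a*; candidate monomer
   masses M from all (bin, form) pairs are merged within ±0.3 Th and
   scored by Σ area × probability. The winning M labels each bin's form,
   and mass-consistent adduct/isotope bins stranded in smaller groups are
   rescued at a relaxed correlation threshold of 0.4 (isotopes only below
   half the parent's area).
5. **Spectral library** — groups become entries (ion averages, relative
   areas, monomer, MS2 sub-spectra) persisted as JSON and MSP; queries
   are matched by RI-gated cosine on √(relative area), and non-matching
   groups are registered as `UNKNOWN-<n>` for tracking across studies.

A synthetic-study generator (`simulate_study()` and presets) reproduces
the statistical structure the method assumes — shared per-compound
log-normal abundance, multiplicative ion noise, co-elution, shared ions —
with ground truth, so every stage is testable without instrument data.

## Worked example

Three compounds co-eluting at one retention index, with the masses 73.0
and 147.1 shared by all three — inseparable in any single scan:

```r
library(pseudospec)

sim <- simulate_study(preset_coelution(), sim_config(n_samples = 33, seed = 1))
res <- ps_deconvolute(sim$sample_set)
res$groups
#>   group_id normalizer_bin_id group_ri normalizer_area n_members
#> 1        1                 4 1899.196        145483.3         6
#> 2        2                 1 1899.492        135675.8         5
#> 3        3                 2 1900.373        132381.4         5

evaluate_grouping(res, sim$truth, ri_window = c(1875, 1925))$per_group
#>   group_id n_bins majority_compound purity
#> 1        1      6    phosphate_like      1
#> 2        2      5      leucine_like      1
#> 3        3      5     glycerol_like      1
```

The 16 recurring ions are pulled apart into exactly three pseudo-spectra,
each containing only one compound's ions (purity 1): the mixture scan is
resolved by correlation across the 33 samples. Per-group detail — member
masses, areas relative to the normalizer (= 100), and each member's
correlation with it:

```r
head(write_group_table(res)[, c("group_id", "bin_id", "mean_mz",
                                "relative_area_pct", "correlation")])
#>   group_id bin_id mean_mz relative_area_pct correlation
#> 1        1      4    73.0            100.00      1.0000
#> 2        1      5    99.0             88.94      0.9577
#> 3        1      8   299.2             54.93      0.9629
#> 4        1     11   314.2             39.91      0.9617
#> 5        1     12   133.1             31.85      0.9585
#> 6        1     14   211.1             22.66      0.9650
```

The shared 73.0 ion (whose area is the sum of all three compounds'
contributions) lands in the group of its dominant parent. Ion-form labels
and monomer masses are chemically meaningful for LC-mode data — see
`preset_lc_adducts()` and the vignette
(`vignettes/correlation-deconvolution.Rmd`) for the model, parameter
defaults and their rationale, and known limitations.

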