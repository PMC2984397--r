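---
title: "Correlation-based deconvolution of multi-sample metabolomics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based deconvolution of multi-sample metabolomics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudospec)
```

## The problem

A non-targeted GC/MS or LC/MS(n) metabolomics study produces, for every
sample, hundreds to thousands of integrated ion peaks, each characterized by
mass (m/z), retention time and index (RT, RI), and area. A single metabolite
rarely produces a single peak: electron ionization fragments it into many
ions, and electrospray produces adducts (m+H, m+Na, m+K, formate, ...),
multimers (2m+H, 2m+Na, ...), water losses, isotopes and in-source
fragments. Worse, chromatographic separation is incomplete: two or more
metabolites can co-elute, so the spectrum observed in any one scan is a
mixture that cannot be decomposed from a single sample alone.

`pseudospec` resolves this by working across the whole sample set at once.
Every ion a metabolite produces carries the metabolite's biological
abundance in that sample as a common factor; across a biologically diverse
study the areas of ions from one compound are therefore highly correlated,
while ions of different compounds are largely non-covariant. Binning
recurring ions across samples and grouping correlated bins yields one
*pseudo-spectrum* per metabolite — including metabolites nobody has named
yet, which can be registered in a spectral library as numbered unknowns and
tracked across future studies.

## The procedure

### Retention-index calibration

Retention times drift between runs; retention indices, calibrated per
sample against co-injected internal standards, are comparable across the
study. `assign_retention_index()` interpolates each peak's RT through the
sample's standard (rt, ri) pairs piecewise-linearly. The calibration
reference we follow does not prescribe an interpolation order; linear
interpolation between adjacent standards is the minimal assumption and is
exact whenever the RI of the standards is itself affine in RT between
calibration points. Peaks eluting outside the standards' span are
extrapolated with the nearest segment's slope rather than dropped —
dropping them would silently deflate the fill fraction of early- and
late-eluting bins.

### Ion binning

`iterate_binning()` partitions all MS1 ions into cross-sample bins:

1. Sort ions by area, descending.
2. Greedily bin smaller ions around larger ones: an ion joins the first
   bin whose center lies within the mass window (±0.4 Th) and RI window
   (±25) — choosing, among eligible bins, the one minimizing the
   scale-free distance |Δmz|/mass_window + |Δri|/ri_window — or opens a
   new bin centered on itself.
3. Compute per-bin means and SDs of mass, RI, RT and area over *singlet*
   ions only (samples contributing exactly one ion to the bin; a sample
   contributing more than one is a multiplet, i.e. a collision indicating
   co-elution).
4. Recenter every bin on its singlet means; drop bins with no singlets.
5. Re-bin all ions against the recentered bins.
6. Repeat 3-5 until the peak-to-bin partition stabilizes.

The iteration has no prescribed stop rule beyond "repeat"; we cap it at 10
rounds, and detect convergence on the partition itself (bin identities may
churn while the partition is already stable). In practice well-separated
data converges in one round.

A bin missing some samples may have near-miss ions sitting just outside its
windows. `recover_outlier_ions()` searches, for each missing sample, the
less-filled bins within the extended windows (±0.5 Th, ±38 RI) and migrates
the best-matching candidate whose area lies within 4 SD of the bin's
singlet areas. Bins with fewer than 3 singlets are not recovery targets:
with one or two observations the area SD is not a meaningful gate.

### Grouping by correlation

`group_bins()` sorts bins by mean area descending and uses the largest
unassigned bin as the *normalizer* of a new group; every remaining smaller
bin joins if all of the following hold over their common singlet samples:

* mean-RI difference at most `max_ri_difference` (default = the RI window);
* at least `min_correlated_ions` common singlets (default 3 — Pearson on
  fewer points is uninformative; the printed legal range is 1-999 with no
  stated default);
* relative standard deviation of the per-sample area ratio at most
  `max_rsd_pct` (default 100, the permissive end of the printed 0-100
  range; no default is stated);
* Pearson correlation at least `min_correlation` (default 0.8, tunable —
  practice is trial and error between 0.70 and 0.90 depending on matrix
  and study size; `sweep_correlation()` reports group counts over a grid
  so the user can judge).

Samples where either area exceeds `max_linear_area` are excluded from the
pairs (detector saturation breaks linearity); the default is infinite.
Undefined correlations — fewer than 2 pairs, or zero variance as happens
for compounds with limited biological variability — are treated as "not
correlated", a known limitation of the approach rather than an error.

Greedy first-fit assignment means a bin eligible for several normalizers
joins the largest one; each bin lands in exactly one group, so an ion
shared between co-eluting compounds (its area being the *sum* of both
parents' contributions) ends up with the parent it correlates with best,
if any.

### Chemical intelligence

For LC data the measured mass of an ion in form (adduct a, multimer count
n) relates to the neutral monomer mass M as measured = n·M + a, so
M = (measured − a)/n. The shipped form table (`default_adduct_table()`)
lists 30 forms with prior probabilities; it is used exactly as printed in
its source configuration, including three internally inconsistent rows
("3 m-H" with a positive adduct mass, "m + H-H20" with −17.01, and a bare
"m-" at adduct 0) — the numeric columns are authoritative and the labels
are treated as annotations.

`score_monomer_candidates()` enumerates (bin, form) pairs from large areas
and high probabilities downward; each proposal either merges into an
existing candidate within ±0.3 Th (adding area × probability to its score;
the candidate's mass stays at its first contributor's value) or opens a
new candidate. The top-scoring candidate is the group's monomer mass, and
`annotate_ion_forms()` labels each bin with the most probable form whose
predicted mass matches it; unexplained bins (e.g. in-source fragments) are
"unassigned".

Adduct ions can be more variant than the main ion and miss the strict
correlation threshold, stranding their bin in a wrong, smaller group.
`recover_missing_adducts()` computes each form's expected mass from the
group's monomer, searches smaller groups within ±0.4 Th and the
normalizer's RI window, and migrates the best-correlating bin when its
correlation with the normalizer exceeds 0.4. `recover_isotopes()` applies
the same logic at +1.00335 and +2.00670 Th from each grouped bin — the
¹³C spacings, chosen because ¹³C dominates biological isotope patterns;
the source procedure does not print offsets — with the extra requirement
that the candidate's mean area be at most half the parent ion's.

### MS2 spectra and the spectral library

For MS/MS studies, `bin_secondary_ions()` collects MS2 peaks whose
precursor lies within the mass window of a primary bin, from that bin's
singlet samples only, bins them along the mass axis, keeps fragments with
at least `min_correlated_ions` singlets, normalizes to the
maximal-mean-intensity fragment and drops fragments below 1% relative
intensity (no default is printed for this floor; 1% keeps everything a
practitioner would call signal).

`build_library_entry()` turns a group into a persistent spectral
definition: per-ion averages of mass, RI, RT, area relative to the
normalizer (= 100), form labels, the monomer mass, MS2 sub-spectra and
provenance. Libraries persist as versioned JSON (full fidelity) and export
to MSP text (masses to 4 decimals, relative areas to 2) for use in other
spectral tools.

`match_library()` gates candidates by |ΔRI| ≤ 50 and scores
100 × cosine similarity between √(relative area) vectors with ions paired
within the mass window — the standard spectral dot-product; the original
procedure does not specify its matching algorithm or confidence scale, so
the choice is isolated behind this one function. Queries scoring below 70
are registered by `register_unknown()` as `UNKNOWN-<n>` entries (ids never
reused), which is what lets unknowns be identified retroactively when an
authentic standard is measured later.

## The synthetic-study generator

Real acquisitions from the original studies are not available, so
`simulate_study()` generates peak tables with exactly the statistical
structure the method exploits: per compound c and sample s an abundance
A<sub>cs</sub> = exp(N(mean<sub>c</sub>, sd<sub>c</sub>)); each ion's area
is base × A<sub>cs</sub> × relative intensity × exp(N(0, noise_sd)). Both
choices are log-normal because MS intensity data are strictly positive
with multiplicative error; the source states no noise model. Shared ions
sum their parents' contributions; RIs jitter around the compound's elution
point; a small dropout rate removes ions from individual samples; and the
ground truth (peak → compound) is emitted for scoring.

Defaults mirror the study conditions described for the reference data:
33 samples, abundance log-SD 0.7 (a spread typical of liver metabolite
panels and enough to order samples distinctly per compound),
ion noise SD 0.05, RI jitter SD 3, dropout 2%.
`preset_coelution()` reproduces the canonical hard case: three GC/EI
compounds (phosphate-like, leucine-like, glycerol-like) co-eluting at one
RI with the masses 73.0 and 147.1 shared by all three.
`preset_lc_adducts()` generates compounds observed as m+H, m+Na, 2m+H and
m−H2O for exercising monomer inference and rescue.

What the generator does *not* emulate: chromatographic peak shapes (only
integrated areas are modeled, matching the tool's input contract), mass
error (ion m/z values are exact, so binning is stressed by co-elution and
shared masses rather than by mass drift), correlated noise between ions,
and instrument batch effects. Passing tests therefore demonstrate the
statistical logic of the method, not robustness to every artifact of real
instruments.

## Numerical choices and degenerate inputs

* All windows are half-widths (center ± value).
* Ties in greedy binning go to the bin minimizing the combined normalized
  distance, then to the earliest-created bin; input row order never
  matters because ions are processed in descending area order with
  deterministic tie-breaks.
* SD of a single observation is defined as 0 (it gates nothing).
* Monomer-candidate score ties break toward the larger total contributing
  area.
* An empty peak table deconvolutes to empty outputs without error; a bin
  that loses its last singlet during outlier recovery keeps its members
  but is skipped by statistics-dependent stages.
* Test and example problem sizes (33 samples, 3-10 compounds, 5-8 ions
  each) match the scale at which the method's claims are stated while
  keeping any single check under a few seconds.

## Known limitations

* Compounds with little biological variability produce near-constant ion
  areas and undefined or low correlations; their ions remain singleton
  bins. This is inherent to the approach.
* A shared ion is assigned to exactly one parent compound (or none); its
  area is not split.
* Charge states above 1 and isotope-pattern fits to elemental formulas are
  out of scope, as is identification against external databases — matching
  is only against the local library.
* The greedy normalizer scheme is order-dependent by design; no graph or
  hierarchical clustering alternative is provided.
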