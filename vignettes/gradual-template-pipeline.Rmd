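---
title: "Gradual-template transcriptome selection and preclinical endpoints: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradual-template transcriptome selection and preclinical endpoints: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradRT)
```

# The scientific setting

gradRT analyses preclinical experiments that combine external beam
radiotherapy (EBRT; photon or carbon-ion irradiation) with tumor-targeting
endoradiotherapy (EndoRT; a radionuclide-conjugated agent such as a
radiolabelled anti-EGFR antibody or a melanin-binding benzamide). The
typical design has six treatment arms — untreated control, EndoRT only,
photon-EBRT only, carbon-EBRT only, and the two dual combinations
(photon + EndoRT, carbon + EndoRT) — with a handful of animals per arm.
Two families of questions arise:

1. **Transcriptome**: which genes respond to *treatment intensification*,
   i.e. change monotonically from EndoRT only, over EBRT only, to combined
   treatment? What pathways and interaction networks do they form?
2. **Efficacy**: how do the arms compare on tumor growth, tracer
   biodistribution, time to progression, vascularity and proliferation?

## The gradual template and PTM selection

After filtering and control normalization, each gene is scored by Pavlidis
Template Matching (PTM): the Pearson correlation $r$ between the gene's
per-sample fold changes and a user-defined template over the non-control
samples. The template here is the 3-step *gradual* profile that assigns
every sample the level of its arm category,

$$\text{endoRT} = 1 \;<\; \text{EBRT} = 2 \;<\; \text{combined} = 3,$$

with photon- and carbon-EBRT pooled on the middle level. Correlation is
invariant to affine maps of the levels, so only the ordering and relative
spacing matter; equal spacing is the natural uninformative choice.
Significance uses the standard $t$ transform of a Pearson correlation,

$$t = r\sqrt{\frac{n-2}{1-r^2}}, \qquad t \sim t_{n-2}
\text{ under } H_0: \rho = 0,$$

two-sided. With the default design ($n = 15$ non-control samples),
$r = 0.8$ gives $t = 4.81$ and $p \approx 3.4\times10^{-4}$, which is why
the cutoffs $r \ge 0.8$ and $r \ge 0.7$ pair with $p < 0.001$ and
$p < 0.01$ respectively. Genes with $r \ge r_{\min}$ form the **UpCor**
selection, genes with $r \le -r_{\min}$ the **DownCor** selection; the
selections are nested across cutoffs by construction.

Three design choices were genuinely open and are resolved as follows:

* **PTM operates on all filtered transcripts**, not only on an ANOVA-ranked
  subset. The ANOVA screen (`anova_screen()`, one-way fixed-effects F
  across arms, $p < 0.01$, top 500) and the hierarchical clustering /
  centroid path (`cluster_genes()`, `centroid_profiles()`; Euclidean
  distance, average linkage) exist to *derive and justify* the template:
  the centroids of the dominant clusters visibly mirror the gradual
  profile. Selection itself is supervised and genome-wide.
* **PTM correlates per-sample values** (the template value replicated
  within each arm), not arm means — this respects replicate-level noise
  and gives the documented $n$ for the $t$ transform. An arm-mean mode is
  available via `ptm(..., arm_means = TRUE)`.
* **Fold changes are log2 by default.** The scale of the original analysis
  is not documented; log2 makes up- and down-regulation symmetric around
  zero, which is the natural scale for a correlation against a symmetric
  template. Raw ratios are available with `normalize_to_control(...,
  log2 = FALSE)`.

## Filters and normalization

Two transcript filters emulate BeadChip-style quality control:

* **Detection**: genes with 30% *or more* non-assessable entries are
  excluded — implemented as strict-`<` retention at the boundary, so a
  gene missing in exactly 3 of 10 samples is dropped.
* **Intensity**: genes whose mean over non-missing entries is below 100
  (the background-noise level of the array) are excluded — boundary
  *inclusive*, a gene sitting exactly at 100 is kept.

Normalization divides each gene by its arithmetic mean over the
(non-missing) control-arm samples, so control rows average to 1 (0 in
log2). Missing values are never imputed; they are excluded pairwise from
means, F statistics and correlations.

## Enrichment and the population map

Gene-set enrichment of a selection is the upper-tail hypergeometric test:
with universe size $N$, set size $K$, selection size $n$ and overlap $k$,

$$p = P[X \ge k] = \sum_{i=k}^{\min(K,n)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

The universe is the set of transcripts that survived preprocessing *and*
appear in the collection's namespace — the most conservative choice given
that the original universe definition is not documented. Significance is
declared at raw $p < 0.05$, matching how such enrichment tables are
conventionally reported; Benjamini–Hochberg adjusted values are emitted
alongside as a clearly non-default column. The *population map*
(`population_map()`) is the binary gene × pathway membership matrix over
significant sets, with rows and columns ordered by hierarchical clustering
of membership vectors so genes shared between pathways form blocks.

## Direct-interaction networks

`induce_subgraph()` restricts a protein–protein interaction graph to a
selection without adding intermediate nodes ("no interpolation");
`subnetwork_components()` reports components of two or more nodes, the
largest-component size, and hub genes ranked by within-component degree
(ties broken lexicographically). `network_fraction()` is the percentage of
the selection captured by the largest component — e.g. 57 of 219 UpCor
transcripts is 26%.

The significance of a largest component is assessed by permutation,
because the null model behind the originally reported network p-values is
not documented: draw `n_perm` uniform random node sets of the selection's
size from the full graph, record each largest induced-component size, and
report the add-one permutation p-value

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_{\text{perm}} + 1}
\in \Big[\tfrac{1}{n_{\text{perm}}+1},\, 1\Big].$$

Uniform node resampling ignores the degree bias of selections toward
well-studied hub proteins; a degree-stratified variant
(`component_size_pvalue(..., degree_bins = k, selection = ...)`) draws
within degree-quantile bins instead and is the more conservative option
for real interaction databases.

## Preclinical endpoints

* Tumor volume from calipers: $V = \tfrac{1}{2} w^2 \ell$ (mm³), width the
  smaller dimension by convention (swapped with a warning otherwise).
* Growth inhibition: $100\,(1 - \bar V_{\text{treated}}/\bar
  V_{\text{control}})$, reported rounded to integer percent (full
  precision retained internally, as for all percent endpoints).
* Relative biological effectiveness from iso-effective schedules:
  photon dose / carbon dose (e.g. $5\times2$ Gy photon vs $5\times1$ Gy
  carbon $\Rightarrow$ RBE $= 2$).
* Biodistribution: $\%\mathrm{ID/g} = 100\,(A_{\text{organ}}/
  A_{\text{injected}})/m_{\text{organ}}$; tumor-to-muscle ratio (TMR) and
  its percent change quantify targeting selectivity.
* Time to progression: the first measurement day on which the volume
  reaches the threshold (500 mm³ or 1000 mm³ depending on the model, a
  5-fold increase over treatment start), with **no interpolation** between
  discrete caliper days; animals never crossing are censored at their last
  observation. The Kaplan–Meier estimator and the log-rank test (standard
  aggregated-risk-set tie handling) come from the survival package; the
  reported median is the *first time the curve drops to 0.5 or below* —
  deliberately not survfit's interval-midpoint convention, so the median
  of four uncensored events at days 1–4 is day 2.
* Microvessel density is the mean CD31⁺ vessel count per high-power
  field; the Ki-67 index is Ki-67⁺/DAPI⁺ pooled within section, averaged
  over sections. Student's pooled-variance t-test is the default
  (`group_ttest()`, Welch by flag), with the study's significance wording
  ($p<0.05$ significant, $p<0.01$ highly significant).

# What the synthetic generator emulates — and what it does not

`generate_expression_study()` produces a gene × sample intensity matrix
with known ground truth:

* log2-normal baseline intensities (default mean 9, SD 1, i.e. median
  ~512 — comfortably above the intensity filter);
* planted *gradual* genes (default 5% up, 5% down) whose expected arm
  means move by a factor `effect_step` (default 2) per template level, so
  a noise-free up-regulated gene has arm means in ratio 1 : 2 : 4 along
  endoRT : EBRT : combined;
* planted low-intensity genes (default 10%, log2 mean 3) far below the
  background threshold, giving the intensity filter known targets;
* per-observation log2-normal noise (default SD 0.25) and
  missing-completely-at-random non-assessable entries (default 2%).

`generate_ppi()` plants a connected module (a random spanning tree over
up-regulated genes) in a sparse Erdős–Rényi background;
`generate_gene_sets()` plants one set drawn from up-regulated genes among
uniform decoys; `generate_efficacy_tables()` produces exponential-growth
caliper series with arm-specific post-treatment doubling times and organ
uptake tables whose default means (tumor 9.0 %ID/g, TMR 107.6, spleen
2.4, liver 0.6, kidney 0.5, lung 0.5) match the melanoma biodistribution
setting they emulate.

All generators are pure functions of (configuration, seed).

**Not emulated**: probe chemistry and array batch effects, structured
(intensity-dependent) missingness, correlated gene–gene noise,
degree-biased interaction coverage, tumor-growth plateaus or regression
below the starting volume. Passing tests on this synthetic data therefore
demonstrate that the *pipeline arithmetic and selection logic* are
correct and well calibrated under idealized noise — they do not
demonstrate robustness to array artefacts, nor that any particular
biological pathway would be recovered from real arrays.

Replicate-level array variance is not documented for the original data,
so the noise SD is a free parameter, not an estimate; 0.25 on the log2
scale (≈ 19% CV) is a realistic magnitude for within-group variation of
BeadChip log intensities and, against a planted effect of 1 log2 unit per
level, yields the operating point the tests pin down: ≥ 90% recovery of
planted gradual genes at $r \ge 0.7$ with ≤ 2% false positives among null
genes.

# Numerical choices

* **Boundaries**: detection filter strict (`< 0.30` retained), intensity
  filter inclusive (`>= 100` retained) — both follow the documented
  wording of the respective rules.
* **Dendrogram determinism**: `stats::hclust` (average linkage) resolves
  equal-distance merges by its own deterministic rule; given a fixed gene
  order the clustering is reproducible. Flat clusters are invariant to
  input order up to labeling.
* **Degenerate inputs** are excluded with a logged message rather than
  propagated: all-missing genes (undefined mean), non-positive control
  means, zero within-group variance (undefined F), constant template
  profiles or fewer than 3 paired observations (undefined r), zero-DAPI
  fields (undefined index). Zero variance in *both* t-test samples is an
  error.
* **Permutation p** uses the add-one correction, so p can never be 0 and
  is bounded below by $1/(n_{\text{perm}}+1)$; all permutation draws flow
  from an explicit seed.
* **Rounding** only at the reporting boundary: percent endpoints are
  rounded to integers for display, never inside computations.

# Problem sizes

The test-suite and acceptance runs use desk-scale data chosen to finish
comfortably on a laptop while leaving every statistical property
measurable: 2,000 transcripts (not the ~48,000 of a real chip) × 18
samples, 999 permutations for network significance, 200 replicates × 199
permutations for the uniformity check of the permutation p (on a
600-node near-critical random graph, where the null largest-component
size has wide support), and 20 generator seeds for the planted-module
detection rate. The full synthetic pipeline runs in about a second.

# Known limitations

* The permutation null is degree-unadjusted by default (see above); for
  real PPI snapshots the degree-stratified variant should be preferred.
* The headline transcript counts of the motivating study (e.g. 219/129
  UpCor/DownCor at $r \ge 0.8$) require the deposited arrays
  (ArrayExpress E-MTAB-6514/6515) and a contemporary interaction-database
  snapshot; they are not reproducible from synthetic data and are not
  targets of this package's tests.
* The tie-break inside `hclust` differs from the original in-house
  software's (undocumented) rule; merge *heights* are unaffected.
* `time_to_progression()` reports the first measurement day at or beyond
  the threshold, which overestimates the true crossing time by up to one
  measurement interval; this mirrors how discrete caliper data are
  conventionally read.
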