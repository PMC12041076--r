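---
title: "Methods: marker-rule cell typing, percent-expression DEG, and spatial statistics for targeted in situ sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-rule cell typing, percent-expression DEG, and spatial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippotx)
```

## The problem this package addresses

Targeted in situ sequencing reads out a fixed panel of genes — here 158
neural genes — as decoded spots with image coordinates in tissue
sections of the mouse hippocampal formation. After upstream cell
segmentation assigns spots to cells, the scientific questions are
tabular and spatial: which cells are which type, how does the fraction
of cells expressing each gene differ between experimental groups, which
differences induced by familial Alzheimer's disease (FAD) pathology are
*restored* when adult neurogenesis is enhanced, and does the spatial
clustering of cell types change. `hippotx` implements that pipeline
end to end, together with a synthetic-cohort generator carrying ground
truth, so that every stage is testable without the original animal
dataset.

The experimental design the defaults emulate: four groups crossing
genotype (NB = Nestin-CreERT2;Bax^fl/fl^; NBF = NB × 5XFAD) with
treatment (C = corn-oil vehicle; T = tamoxifen, which deletes *Bax* in
neural stem cells and so enhances newborn-neuron survival), three
tissue sections per group from two subjects, and per-section region
masks for CA1, CA2, CA3, the dentate gyrus (DG), its subgranular layer
(SGL), and the entorhinal cortex (EC).

## Geometry: regions and cell assignment

Region masks are simple polygons in micrometre image coordinates
(y increasing downward; all geometry only assumes masks and spots share
a frame). A cell belongs to the region whose polygon contains its
centroid, using exact even–odd containment with boundary points counted
inside. We deliberately use exact polygon containment rather than
convex-hull containment: hippocampal regions (DG blades, curved CA
bands) are non-convex, and hull assignment would mislabel cells in the
concavities. A `convex_hull` switch reproduces hull behaviour for
comparison. Two further conventions make assignment deterministic: the
SGL polygon is nested inside the DG and recorded as a flag
(`in_sgl`) on top of `region = "DG"`, and if a centroid falls in
several other polygons the smallest-area polygon wins. Areas come from
the shoelace formula and are reported in mm².

## Cell typing: a divisive hierarchy of marker rules

Classification uses a priori marker rules applied to positivity calls,
where a cell is positive for a gene when it has at least
`min_spots_positive` spots (default 1 — on a targeted panel with a
median of ~5 detected genes per cell, any stricter threshold would
contradict the ordinary meaning of "expressed"; the threshold is still
a parameter). The cascade splits cells into seven mutually exclusive
labels:

1. **Neurons** are cells negative for all 12 glial/vascular exclusion
   genes (*Acta2, Aldoc, Aqp4, Dcn, Gfap, Gja1, Itgam, Kcnj8, Laptm5,
   Mbp, Plp1, S1pr1*); the rest are nonneurons.
2. **Immature neurons** are neurons in the SGL positive for any of
   *Dcx, Ncam1, Neurod1*, or neurons positive for *Prox1* and negative
   for *Rbfox3*. The second clause is location-free by default; the
   source rule text is ambiguous about whether SGL residence also
   gates it, so `immature_requires_sgl_always = TRUE` implements the
   stricter reading. (The generator only places immature profiles in
   the SGL, so the two readings agree on conforming data.)
3. **Inhibitory neurons** are mature neurons positive for at least one
   pan-neuronal gene (*Map2, Prox1, Rbfox3, Syn1, Tubb3*) and at least
   one of 37 interneuron markers (*Adarb2 … Vipr2*); remaining mature
   neurons are **excitatory**.
4. Nonneurons gate to **astrocyte** (*Aldoc⁺*, *Laptm5/Acta2/Kcnj8⁻*),
   **microglia** (*Laptm5⁺*, *Aldoc/Acta2/Kcnj8⁻*), then
   **oligodendrocyte** (*Mbp⁺*, *Acta2/Aldoc/Kcnj8/Laptm5⁻*). The three
   predicates are pairwise unsatisfiable (proved by truth table in the
   test suite), so the gating order is immaterial; the remainder is
   **other**.

Positivity is monotone in counts, so adding spots can only move cells
toward (never away from) positivity for a gene; the suite asserts the
partition property on random count vectors against an independent
restatement of the rules.

## Percent-expression differential expression

All differential expression operates on *percent expression*: 100 × the
fraction of cells in a stratum (cell type × region × group, cells
pooled within group) positive for the gene. For each gene and pairwise
group comparison we form the 2×2 table of expressing / non-expressing
cells and apply the two-sided Fisher exact test (summation of table
probabilities no larger than the observed one — implementations differ,
so the convention matters; ours matches full hypergeometric enumeration
to 1e-12 in the tests). Benjamini–Hochberg FDR is applied across the
158 panel genes within each (cell type, region, comparison) stratum by
default — matching how results are reported per region and cell type —
with `fdr_scope = "global"` available.

Fold changes are computed on percent expression with a pseudovalue:
`log2((pct1 + s)/(pct2 + s))`. The pseudovalue `s` exists to avoid
infinite values, so it is taken as the minimum *nonzero* percent
expression over all genes of the stratum pair (a zero minimum would
defeat its purpose); a fixed constant can be supplied instead. Genes
are called up- or downregulated when the fold change exceeds 1.5 in
either direction; significance is always a separate, explicit `alpha`.

### Restored genes

A gene is **restored** in T-NBF when it is significant
(q < `alpha`) in the T-NBF/C-NBF comparison and its fold change has the
same strictly nonzero sign as in the C-NB/C-NBF comparison — enhanced
neurogenesis moved expression in the FAD background the same way the
healthy baseline differs from FAD. It is **fully restored** when the
C-NB/C-NBF change is also significant. A zero fold change in either
comparison is never restored (a "same direction" requirement presumes a
direction). `alpha` defaults to 0.05 and is a parameter because some
analyses (e.g. oligodendrocytes) use 0.2. Fold-change consistency
between the two comparisons is summarized by OLS of the C-NB/C-NBF
log2FC on the T-NBF/C-NBF log2FC per region, plus a pooled fit over
genes with q < 0.2 in at least one comparison; the regression
orientation is a convention, so the orientation-free Pearson r is
reported alongside.

## Spatial statistics

Ripley's K is computed exactly as
K(t) = (1/λ) Σᵢ Σⱼ≠ᵢ I(dᵢⱼ < t)/n with λ = n/A and A the annotated
polygon area (not the convex hull of the points), and the
variance-stabilized L(t) = √(K/π). **No edge correction is applied by
default** — the estimator is used as defined, and all comparisons
(between groups, or against a null) use the same estimator so the edge
bias cancels; an isotropic-corrected variant is available via
`edge_correction` for sensitivity analysis. Under complete spatial
randomness (CSR) L(t) ≈ t; per-sample curves are averaged within group
with SEM ribbons.

The CSR reference envelope (`csr_envelope()`) simulates fixed-n uniform
patterns in the same polygon with the same estimator. Its default is a
*simultaneous* (global) envelope built from the Monte-Carlo
distribution of the maximum absolute deviation around the simulated
mean curve: an entire CSR curve lies inside it with the nominal
probability, which is the property "the observed curve stays within the
envelope" actually requires. Pointwise quantile bands are available but
a full curve escapes a 95% pointwise band far more often than 5% of the
time.

Cell densities are counts divided by polygon area (cells/mm²), compared
across groups per sample with one-way ANOVA and the Kruskal–Wallis test
(df = groups − 1); both match textbook-formula implementations to
1e-10 in the suite. With all-identical values the Kruskal–Wallis
statistic is defined as 0 (p = 1) and the ANOVA F is flagged NA.

### Entorhinal-cortex layers

Upper (1–3) vs lower (4–6) EC layers are estimated per sample from
*Calb1* expression as an upper-layer proxy. The construction is
deliberately deterministic: project EC cell centroids on the two
principal axes of their coordinates and take as the depth axis the one
with the larger standardized separation between the median of
Calb1-positive cells and the overall median. We do *not* simply take
the first principal axis: the EC strip is typically wider than it is
deep, so the major axis runs along the layers rather than across them,
and layer labels from PC1 degrade to near-chance on banded test data.
The axis is oriented so the Calb1 median lies on the negative (upper)
side, the boundary sits one standard deviation of the Calb1 projections
beyond their median, and cells at depth ≤ boundary are "upper". The
whole construction is invariant to translation and rotation of the
image frame. At least 10 marker-positive cells are required; below
that the function stops and advises manual layer masks. Calb1-positive
*cell centroids* are the default coordinate source (spot coordinates
can be supplied by building a cell matrix from spots directly).

## Binned expression and embedding

For panel-wide QC the bounding rectangle of the tissue is divided into
50 μm × 50 μm bins (we read "50 μm² bins" in the source material as
50 μm squares, matching the stated bin area of tissue figures; the bin
size is a parameter), spots outside the contour are excluded, and bin ×
gene counts are formed; included totals are conserved exactly, and
refined 25 μm bins re-aggregate to the 50 μm grid exactly. Bins are
median-normalized (every nonempty bin scaled to the median bin total —
preserving the zero pattern), ln(1 + x)-transformed, and embedded in
2-D with UMAP (uwot, seeded) or PCA. Embedding coordinates are
implementation-dependent, so tests assert only label separability
(silhouette of region labels), never coordinates.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes —
not tissue realism:

* **Design**: 4 groups × 3 samples (two subjects per group), six
  polygon masks per sample using simple band/block templates; labeled
  geometry is what matters downstream, not anatomy.
* **Placement**: homogeneous Poisson with region-specific intensity
  (cells/mm²; DG highest, as in tissue), or a Thomas cluster process
  (Poisson parents, Gaussian offspring with ~50 μm spread) when
  clustered patterns are needed.
* **Expression**: per cell, gene detection is Bernoulli(π) with π
  depending on (cell type, gene), and detected genes get 1 +
  Poisson(μ − 1) spots scattered within 5 μm of the centroid. Only
  positivity enters any downstream statistic, so the count law is free;
  the shifted Poisson keeps detected counts ≥ 1.
* **Profiles** are rule-conforming: genes a type's classification path
  requires absent get π = 1e-4, defining positives get high π
  (0.9–0.995), and all other genes share a background π. The negative
  level 1e-4 is deliberate: with the 37-gene inhibitory marker list, a
  negative π of 1e-3 already leaks ≈3.6% of excitatory cells into the
  inhibitory class, while 1e-4 bounds total misclassification under 1%.
  Defaults give ≈99.3% recovery of the designed types.
* **Group effects** multiply π for chosen (gene, cell type, region,
  group) cells, clamped at 1 with a logged count. The default design
  shifts twelve non-rule genes ×2.5 in the C-NBF group in EC excitatory
  neurons from a baseline π of 0.10 — so C-NB and T-NBF sit at a common
  baseline and the genes are fully restored by construction. These are
  the designed truths the restoration caller is validated against.
* **Calibration**: `tune_unique_genes()` bisects a common scale on all
  π until the simulated median unique-genes-per-cell equals a target
  (default 5, the detection depth of the assay); the calibration
  simulation is internally seeded from the config seed, so tuning is
  deterministic and the tuned configuration reproduces the target on
  fresh seeds.

Everything is a deterministic function of the configuration seed.

What passing tests on this generator do and do not show: they validate
the *statistical machinery* — rule logic, exact-test calibration,
restoration scoring, spatial statistics — under the assumed model
(independent Bernoulli detection given type, homogeneous placement,
clean segmentation). They do not validate robustness to segmentation
errors, optical crowding, spatial expression gradients within regions,
or doublets, none of which the generator simulates.

## Numerical and design choices

* Fisher p-values are clamped at 1 (floating summation of the full
  hypergeometric support can exceed 1 by ~2e-16).
* BH adjustment excludes NA p-values from the number of tests and
  propagates them as NA.
* Null-calibration analyses (false-positive rate of the DEG engine at
  p < 0.05 under label permutation) use genes with detection
  probabilities in [0.1, 0.6] at 500 cells per group, so expected
  positives per group are ≥ 25: Fisher's exact test is conservative on
  sparse tables, and a calibration check is only informative where the
  attainable test levels are close to nominal.
* Recovery of the designed restored set is scored on the
  *fully restored* call category — the category the designed pattern
  (C-NBF shifted, both baselines equal) lands in by construction; this
  makes misses strict (a designed gene called merely "restored" counts
  as a miss) and keeps chance hits from sparse background genes, whose
  merely-restored calls are an expected ~0.2–0.3 per cohort for any
  correctly calibrated test, out of the false-call count.
* Problem sizes in the test suite and the reproduction script are
  chosen as the smallest that leave the statistical assertions
  comfortably powered: cohorts of ~800 EC excitatory cells per group
  for restoration recovery, 400–550 points for spatial envelopes with
  199 simulations, 50–200 label permutations for calibration.

## Known limitations

* Hard (non-probabilistic) cell typing: a cell co-expressing markers of
  two glial classes falls to "other" rather than receiving a soft
  assignment.
* Cells are pooled within group for DEG; per-sample stratified or
  mixed-effect alternatives are out of scope.
* The uncorrected Ripley estimator is biased near region boundaries;
  comparisons are valid because every curve (including the null
  envelope) shares the bias, but absolute L values should not be read
  as unbiased clustering scales.
* The upstream assay documentation mentions both 158 and 159 probed
  genes in different places; the bundled panel is the 158-symbol list
  and the discrepancy is flagged in `?gene_panel`, not resolved.
* One marker symbol appears as "Ncam" in the rule text and "Ncam1" on
  the panel; the rules use *Ncam1*.
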