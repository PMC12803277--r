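---
title: "Integrating dual-chemistry spatial transcriptomics runs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating dual-chemistry spatial transcriptomics runs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imaging-based spatial platforms decode probe-bound transcripts over
fluorescence cycles. A small custom panel decoded with the high-sensitivity
chemistry ("V1", up to 480 genes) and a large pan-tissue panel decoded with
the broad chemistry ("Prime", 5001 genes) can be co-hybridized on one section
and decoded in two sequential instrument runs. The payoff is both depth and
breadth *in the same cells*; the price is an integration problem:

1. re-seating the slide cassette between runs shifts the stage coordinate
   frame by a small, roughly rigid offset;
2. only one segmentation should define cells, so the second run's transcripts
   must be re-assigned to the first run's (transformed) masks;
3. the two panels share target genes (239 of 480 in the motivating design),
   so features must be disambiguated by panel before the matrices can be
   concatenated;
4. co-hybridization may cost the broad chemistry some sensitivity on shared
   targets (competitive binding), which needs a calibrated statistical check.

`duplexium` implements these four steps and the surrounding quality control.

## Registration model

The inter-run map is linear: `p' = L p + t` in micrometers. The default model
is a **similarity** (`L = s R`, uniform scale times rotation, reflections
excluded), because a cassette re-seating is a rigid-like perturbation; a full
affine (shear, anisotropic scale) is available behind `model = "affine"` for
optics-induced distortion. `estimate_transform()` uses the closed-form
least-squares (Procrustes/Umeyama) solution for the similarity model and QR
least squares for the affine model, and reports the residual RMS over
anchors. Anchors are consumed from a file contract (`landmarks.csv`) rather
than placed interactively.

Two numerical points deserve note:

* **Degeneracy.** Similarity needs ≥ 2 distinct anchor pairs, affine ≥ 3
  non-collinear ones; rank deficiency is a classed error, not a silent fit.
* **Origin dependence of the translation.** With a rotation error δθ, the
  fitted translation parameter absorbs a lever-arm term proportional to the
  distance between the coordinate origin and the anchor centroid. Translation
  recovery is therefore assessed as the displacement error at the anchor
  centroid, where it is decoupled from rotation/scale error; at a corner
  origin the same fit can look worse than 1 µm even when the registration
  over the tissue is sub-micron.

**Refinement.** Landmark fits leave a residual of the order of the anchor
placement error. `refine_by_centroids()` removes it by iterative closest
point over cell centroids: greedy one-to-one nearest-neighbour matching
within a cutoff (default 15 µm, about one cell diameter; ties broken by
ascending distance), then a rigid (rotation + translation) correction from
the matched pairs, iterated until the mean matched distance improves by less
than 1e-4 µm or 50 iterations. The returned transform is the best seen, so
refinement never worsens the alignment; zero matches within the cutoff raise
a classed error carrying the initial transform.

## Assignment and quality control

`assign_to_masks()` re-implements transcript-to-cell assignment:
boundary-inclusive even-odd (ray-casting) containment, with a uniform-grid
spatial index over polygon bounding boxes for sub-quadratic behaviour. The
index is a performance device only — results are contractually identical to
an exhaustive scan, and the test suite enforces equality with an independent
brute-force oracle. Where overlapping masks both contain a point, the tie
goes to the smaller cell area, then the lexicographically smaller cell id:
deterministic, and conservative in the sense that a transcript inside a small
cell nested in a larger one is credited to the small cell. Whether the vendor
implementation includes boundaries is not documented anywhere we know of;
the inclusive rule is a stated choice, and points exactly on a boundary have
measure zero in practice.

Upstream transcript QC keeps transcripts with `QV ≥ 20` (the threshold
removes `QV < 20`, so 20.0 itself is kept), nuclear overlap, and a cell
assignment (`cell_id != "UNASSIGNED"`). The nuclear-overlap requirement is a
flag because slide-level transcript tallies meaningfully include non-nuclear
transcripts even though matrix building uses the nucleus-partitioned subset.
Each removed transcript is tallied under exactly one reason (priority: qv,
nucleus, unassigned) so the tally sums to the removed count.

Cell-level QC retains a cell when all four hold on the view being filtered:
`n_counts ≥ 50`, `n_genes ≥ 5`, `cell_area ∈ [5, 140]` µm²,
`nucleus_area ≥ 3` µm² — all boundaries inclusive, exactly as the thresholds
are written. Because the combined view's `n_counts`/`n_genes` are sums over
both panels while the area filters are shared, every cell retained in a
single-panel view is retained in the combined view; combined retention
dominating both single panels is an exact invariant, not a tendency.

## Panel merging

Features are tagged `"<gene>-<panel>"` (`SFTPC-V1`, `SFTPC-Prime`), an
injective map inverted by `parse_feature()` (the split is at the last hyphen,
so hyphenated gene symbols survive). All three views — V1-only, Prime-only,
combined — share one cell roster; cells with zero transcripts in a run stay
in the matrix as zero rows, which is what makes pre/post-filtering
comparisons across views well defined. Matrices are written as MatrixMarket
coordinate-real-general triplets (1-based indices) with `features.tsv` and
`cells.tsv` sidecars, in the conventional features × cells orientation.

## Cross-panel statistics

* **Aggregate correlations.** Expression is aggregated across all cells per
  gene and correlated between runs. The default is Pearson on `log1p` totals:
  raw-scale Pearson is dominated by a handful of highly expressed genes, so
  both transforms (and Spearman) are exposed and reported side by side.
* **Z-score sensitivity comparison.** Within each run, per-gene totals
  (default `log1p`) are standardized over that run's full panel using the
  sample standard deviation (n − 1; the convention matters — two genes with
  totals (0, 10) get z = ±0.707). Shifts `dz = z_solo − z_dual` are compared
  for the overlap genes versus a seeded random subset of equal size drawn
  without replacement from the non-overlapping genes. Each group gets a
  median shift and a Wilcoxon signed-rank test implemented internally (ranks
  with average ties, tie-corrected variance, continuity-corrected normal
  approximation) — the statistic is part of the package's contract, and the
  implementation is cross-checked against the reference in the tests. A group
  is called *null-consistent* when its signed-rank p ≥ 0.01, a band chosen a
  priori so a truly null control subset is called consistent ~99% of the
  time.
* **Per-gene cross-chemistry rho.** Spearman rank correlation across cells
  between a shared gene's V1-tagged and Prime-tagged counts, with
  zero-variance genes flagged undefined. Even with a strong shared biological
  signal, count noise and the Prime chemistry's many zeros attenuate this
  correlation well below the latent correlation; the tests verify it rises
  monotonically with Prime sensitivity.
* **Secretome diversity.** Per cell, the number of distinct secreted genes
  detected at ≥ 1 count in a view — a simple illustration of what the broad
  panel buys (538 of 5001 Prime genes versus 59 of 480 V1 genes are secreted
  in the motivating design, fractions the generator reproduces by default).
* **Cluster-label concordance.** Clustering itself is out of scope (labels
  are consumed from external tools); the package cross-tabulates two
  labelings (cells filtered out under one view tracked in a `"(filtered)"`
  margin) and computes the adjusted Rand index from the contingency table on
  the shared cells.

## The synthetic generator

`generate_dual_experiment()` emulates the features of a dual-run experiment
that the pipeline must survive, with fully known ground truth:

* **Geometry.** Jittered hexagonal cells (circumradius 5 µm, spacing 13 µm —
  non-overlap is guaranteed by construction, areas ~50–80 µm² inside the QC
  window) with nucleus rings scaled 0.6 linearly (≈ 36% of the cell area,
  so nuclear partitioning visibly bites, and `nucleus_area` ≈ 20 µm² passes
  its filter); 17 rectangular sample regions by default, emulating TMA cores.
* **Counts.** Per-gene abundance weights are lognormal(0, 1.2) shared across
  panels; cells get gamma(3, 3) size factors; counts are Poisson given the
  rates, i.e. negative-binomial marginally (the generative model is a package
  choice — nothing in the motivating experiment constrains it — picked for
  realistic overdispersion). Overlapping genes carry a per-cell lognormal
  activity (sd 0.5) shared between the two panels' measurements, so
  cross-chemistry correlation is real but attenuated, as observed in tissue.
* **Study conditions.** Defaults are the motivating design's: 480/5001 gene
  panels with 239 shared genes; 125 and 115 expected transcripts per cell for
  V1 and Prime (the solo runs' median transcripts per cell); and a 0.8
  multiplicative attenuation of the Prime rates of shared genes in the dual
  run — the competitive-binding effect under study. 400 cells by default:
  large enough for stable retention and correlation behaviour, small enough
  that the full default pipeline runs in seconds.
* **Noise.** A two-component QV mixture (pass ≈ N(40, 3) clipped to ≥ 20,
  fail ≈ N(10, 3) clipped to < 20; 10% failures by default) exercises the
  QV filter with an exactly known failure indicator. Background transcripts
  fall uniformly on cell-free area at 0.05/µm². Anchor pairs are cell
  centroids with 0.5 µm Gaussian placement error (a manual-click scale);
  the second run's observed centroids carry 0.2 µm jitter, emulating
  independent re-segmentation.
* **Frames.** Run-2 coordinates are exactly `true_transform` applied to
  run-1 frame positions. The magnitude of a real inter-run offset is not
  documented, so it is a parameter; the default (rotation 0.3°, scale 1.002,
  translation (12, −7) µm) is a "very small offset" on a multi-millimetre
  slide. Solo slides of the same tissue are emulated by sharing
  `expression_seed` (per-gene abundances, secreted identity) while varying
  `seed` (cells, counts, placement) — two configs with the same
  `expression_seed` are serial sections in the statistical sense.

What the generator does **not** emulate: pixel-level images, z-stacks,
segmentation errors (masks are truth), spatial expression patterns within a
sample region, probe-sequence effects, and cell-type structure. Passing tests
therefore demonstrate the correctness of the integration machinery and the
calibration of the statistics under a known model — not platform performance
on tissue.

## Calibration and problem sizes

The statistical suites run at reduced sizes chosen once: sensitivity
detection and type-I calibration use the generator's count layer
(`simulate_panel_counts()` — exactly the model inside the spatial generator)
at 120 cells with 150/750-gene panels and 80 overlap genes, 100 seeds for
detection at attenuation 0.8 and 500 seeds for type-I at attenuation 1. At
these sizes the overlap-group median z-shift under 0.8 attenuation is ≈ 0.14
and is detected (positive median, null-consistent control) in ~99% of seeds,
while the type-I rejection rate of the signed-rank test at α = 0.05 stays
within 2 percentage points of nominal. End-to-end checks (assignment truth,
retention ordering, pipeline determinism) use the full spatial generator, at
the 400-cell default for retention ordering.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → register → assign → merge → stats, each
stage reading only its persisted inputs under `out_dir`, so any stage can be
re-run in isolation with identical downstream artifacts. The configuration is
one YAML document (flags can override it in the CLI wrapper). A manifest with
an MD5 content hash per artifact is written last; with fixed seeds, reruns
are byte-identical — this is asserted in the tests, not just intended. All
tabular artifacts are plain CSV/TSV (UTF-8, "." decimal, micrometers); the
sentinel for unassigned transcripts is the literal string `UNASSIGNED`.

## Known limitations

* The registration model is linear; nonlinear (deformable) warps and
  image-intensity (DAPI) registration are out of scope.
* Containment is 2-D; transcripts are not resolved in z.
* The generator's solo/dual pairing shares gene abundances but not cells, so
  it emulates serial sections, not repeated measures of one section.
* Normalization, doublet detection, imputation, clustering and differential
  expression are deliberately not provided; the package ends at validated,
  panel-tagged matrices and the cross-panel quality statistics.
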