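---
title: "Benchmarking layered vision models against face-patch tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking layered vision models against face-patch tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## What this package measures

Electrophysiology in the macaque face-patch system (the middle-lateral patch
ML, the anterior-lateral patch AL, and the anterior-medial patch AM) has
characterized face-selective populations by a small set of quantitative
tuning properties: how population similarity structure is organized over
facial views and identities, how tolerant responses are to changes in
stimulus size, whether units prefer shape or appearance variation in a
parametric face space, how broadly they are tuned over elementary facial
geometry parameters, and which contrast polarities between face parts they
prefer. `fpbench` implements the full measurement protocol for any layered
vision model that can report unit activations to images, so that each model
layer can be compared, property by property, against those populations.

A "layered model" is anything satisfying a one-function contract:
`activate(stimuli, unit_filter)` returns a units x stimuli matrix per layer,
deterministically. The package ships an untrained convolutional network
fixture (`untrained_cnn_fixture()`) so the entire pipeline runs end to end
without any external weights; users plug in their own models through
`layered_model()`.

## Synthetic stimuli instead of photo databases

Every experiment in the protocol originally used images that cannot be
redistributed (photographic face databases, hand-built stimulus sets). The
package instead generates all stimuli procedurally:

* **Annotated faces** (`make_annotated_face_dataset()`): faces are rendered
  from anti-aliased geometric primitives, so the 95 facial landmarks are the
  exact control points of the renderer rather than hand annotations. Views
  (frontal, half-profiles, profiles, up, down, back) come from a
  parameterized compression/shear of the same geometry; left views are exact
  pixel mirrors of right views.
* **Face-view sets** (`make_face_view_set()`): 25 identities x 8 views by
  default, one image per combination.
* **Selectivity probes** (`make_selectivity_probes()`): 50 rendered faces,
  50 structured non-face images (smooth random texture fields with random
  polygons), and one all-zero blank that defines the baseline response.
* **Cartoon faces** (`sample_cartoon_set()`): a 19-parameter cartoon design
  (face aspect ratio, inter-eye distance, mouth size, ...), every parameter
  on the 11-value grid -5..+5 with 0 the average face. The default set has
  5000 images sampled uniformly over the grid.
* **Mosaic faces** (`build_covering_set()`): a mean face area fragmented
  into 11 named parts, each filled with one of 11 intensity levels. The
  covering constructor emits 432 images such that every one of the 55
  part-pairs is observed at every intensity level in both directions
  (`verify_coverage()` checks this exhaustively).

Because the downstream statistics depend only on the parameterization
structure (landmark count, grid cardinalities, part identities), procedural
stimuli exercise every computation that photographic stimuli would, while
keeping the package fully self-contained and deterministic.

`make_designed_population()` additionally builds populations of *designed
units* with closed-form tuning (view templates, identity templates, linear
kernels in the face space, part-pair contrast units, seeded noise units).
These carry retrievable ground truth and serve as test oracles for every
analysis; they are not models of vision.

## The face space

`fit_face_space()` constructs the 50-dimensional shape-appearance space in
the active-appearance-model style:

1. the landmark coordinates of the training faces (default 200) are PCA-ed;
   the first 25 components are the **shape dimensions**;
2. each training image is warped to the mean landmark configuration by a
   piecewise-affine warp on a Delaunay triangulation (`warp_image()`), and
   the shape-normalized pixels are PCA-ed; the first 25 components are the
   **appearance dimensions**;
3. each dimension is scaled by its training standard deviation, so feature
   vectors live in SD units and an isotropic standard Gaussian
   (`sample_feature_vectors()`) spans natural variation.

`reconstruct_image()` synthesizes a face from a feature vector (shape half
-> landmarks, appearance half -> texture, warped to the landmarks) and
`project_image()` inverts it. The round trip `project(reconstruct(f))`
correlates with `f` above 0.99 for moderate vectors, which is what the
spike-triggered-average analysis relies on. `fit_cross_view_map()` learns
the affine map between the feature spaces of two views from identity-matched
pairs (it needs at least 51 pairs for the 50-dimensional default and recovers
a noiseless affine map to machine precision).

## Tuning metrics

* **Face selectivity** (`compute_fsi()`): FSI = (Rf - Ro) / (Rf + Ro) on
  baseline-subtracted mean responses to faces and objects. FSI clamps to +1
  when only faces drive the unit above baseline, to -1 in the reverse case,
  and is undefined (NA) for units at or below baseline for both categories.
  Units with FSI strictly above 1/3 form the face-selective population.
* **View-identity structure** (`compute_rsm()`): the stimulus x stimulus
  Pearson correlation matrix of population response vectors, ordered by view
  group then identity. View-tuned populations produce block-diagonal
  structure; view-invariant identity-tuned populations produce para-diagonal
  bands. `rsm_correlation()` compares two RSMs over the off-diagonal upper
  triangle, intersecting on `view:identity` labels when the reference omits
  stimuli.
* **Size invariance** (`make_size_ladder()`, `compute_sii()`): faces and
  objects are rescaled to 7 sizes (224 down to 56 px) on a mid-gray canvas.
  The SII is the smallest canvas fraction at which the mean face response
  still exceeds 1.4x the mean object response at that and every larger size;
  1 if the preference never holds. Lower SII means stronger invariance.
* **Shape-appearance preference** (`compute_sta()`): the STA is the average
  of the stimulus feature vectors weighted by the unit's mean-subtracted,
  rectified responses. Rectification is used because units of arbitrary
  layered models have no spike threshold; subtracting the mean response and
  clipping at zero treats above-average activation as the analogue of firing,
  and for a rectified-linear unit this estimator aligns with the unit's
  kernel. SPI = (S - A)/(S + A) with S and A the norms of the shape and
  appearance halves; +1 is purely shape-tuned, -1 purely appearance-tuned,
  and the index is antisymmetric under exchanging the halves.
* **View tolerance** (`sta_view_correlation()`): STAs are estimated
  separately from two views (profile feature vectors mapped to the frontal
  space through the cross-view map), then correlated per dimension across
  units; the mean per-dimension correlation is the summary statistic.
* **Facial geometry tuning** (`estimate_tuning_curves()`): for each unit and
  each of the 19 cartoon parameters, the marginal mean response at each of
  the 11 grid values, smoothed with a discrete Gaussian (SD one grid step).
  Significance of each (unit, parameter) tuning is a one-way permutation
  ANOVA on the unsmoothed means (default 1000 permutations, alpha = 0.01).
  FPU counts parameters per unit, UPF units per parameter;
  `fpu_histogram()` tabulates FPU over 0..19.
* **Contrast polarity** (`polarity_preferences()`): for every part-pair
  (A, B), responses where A is lighter than B are compared with responses
  where A is darker by a two-sample permutation test; significant units
  contribute to one of 110 signed bins (55 pairs x 2 directions).

## Comparison statistics and null models

Reference data from physiology (digitized RSMs, FPU/UPF histograms, polarity
histograms, SPI samples) are supplied by the user as CSV/JSON; the package
itself ships only scalar summary constants (`reference_constants()`), each
tagged `packaged_constant`. Per-layer similarity scores are assembled by
`build_report()` into a table with the reference value, its provenance, and
a randomized null band:

* `random_rsm_null()` draws Gaussian off-diagonals matched in mean and
  variance to the reference RSM and collects its correlation with the
  reference.
* `random_histogram_null()` draws uniform tuned-feature counts (FPU) or
  uniform per-bin counts (UPF, polarity) and collects cosine similarities.
* `random_sta_null()` draws independent Gaussian STA matrices and collects
  mean per-dimension correlations.

All bands are center +/- 2 SD over 1000 replicates by default; about 95% of
fresh null samples fall inside them. `bootstrap_mean_ci()` provides
percentile bootstrap CIs for reference means supplied as samples.

## The pipeline and its defaults

`run_pipeline(run_config(seed = 1))` executes every stage on the untrained
CNN fixture. The defaults are the protocol's design cardinalities:

| field | default | meaning |
|---|---|---|
| `n_identities`, `views` | 25, all 8 | face-view set (200 images) |
| `n_face_probes`, `n_object_probes` | 50, 50 | probes + 1 blank |
| `size_ladder` | 224..56 (7 steps) | size-invariance ladder |
| `face_space_train` | 200 | training faces per view |
| `face_space_samples` | 2000 | sampled faces for the STA |
| `cartoon_n` | 5000 | cartoon stimulus count |
| `mosaic_n` | 432 | covering mosaic count |
| `units_cap` | 100 | cap per layer for unit-level analyses |
| `n_perm`, `alpha` | 1000, 0.01 | permutation significance |
| `n_null`, `n_boot` | 1000, 200 | null-band / bootstrap replicates |

`units_cap` bounds the cost of the unit-level analyses (STA, tuning curves,
polarity) on very wide convolutional layers by randomly subsampling the
selected population with the run's seed; population-level analyses (RSM,
SII) always use the full selected population. Every stage derives its own
seed stream from the root seed, so two runs with the same configuration
produce identical outputs. With `output_dir` set, the run writes
`report.json`/`report.csv`, per-layer RSM tables, `summary.json`, and a
`manifest.json` with the configuration, seeds, and MD5 content hashes of
every output file.

A thin command-line wrapper is installed with the package
(`system.file("exec", "fpbench", package = "fpbench")`) with subcommands
`run`, `validate`, `stimuli` and `analyze`; it exits non-zero on any
failure. Stimulus sets and models are serialized as PNG + CSV/JSON only, so
every artifact is plain text or a standard image format.

## Limitations

* The untrained CNN fixture demonstrates the harness; scientific conclusions
  about a model family require the user to supply trained weights through
  the `layered_model()` contract.
* Procedural faces are not photorealistic, and non-frontal views come from a
  2-D compression/shear rather than a 3-D head model; cross-view analyses
  exercise the machinery, not primate-grade view statistics.
* The cartoon artwork and the mosaic fragmentation follow documented
  in-package geometry; analyses depend only on the parameterization and the
  region identities, not the exact contours.
* Permutation ANOVA and two-sample permutation tests are used where the
  original significance procedures were inherited from earlier experimental
  work; the substitution is declared in the function documentation and its
  false-positive rate is verified in the test suite.
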