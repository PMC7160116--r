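---
title: "Quantifying cell-division phenotypes in high-content screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-division phenotypes in high-content screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

RNAi screens for cell-division genes image thousands of wells of fixed,
stained cells and reduce each well to a handful of phenotype rates: the
fraction of viable cells in mitosis (mitotic index), the fraction with two
or more nuclei (multinucleation, a signature of failed cytokinesis), the
fraction of anaphases showing residual chromatin between the separating
DNA masses (chromatin bridges and lagging chromatids, collectively
chromosome segregation errors), and the number of persisting
alpha-tubulin-positive intercellular bridges with a gamma-tubulin midbody
(cytokinetic bridges) per viable cell. Wells whose rates stand out against
the library background, after plate normalization, become candidate hits.

`mitoscan` implements that whole quantitative path as reusable,
rule-based components: a synthetic image generator with exact per-cell
ground truth, segmentation and feature measurement, the phenotype rule
cascade, plate normalization and Z-score hit calling, confocal z-stack
quantification, and the p-value combination statistics used downstream of
loss-of-function genomics experiments. Because commercial screen-analysis
workflows (and wet-lab images) are not portable, every component is
validated against the simulator's ground truth rather than against any
proprietary reference.

# The synthetic well generator

`render_well()` draws cell *events* — an anaphase/telophase pair, a
multinucleated group or a bridged daughter pair is one event — onto
channel planes, convolves with a Gaussian point-spread function, and adds
Poisson shot noise plus Gaussian read noise. Two channel sets mirror the
two staining configurations of a two-arm screen: `screenB` carries DNA,
alpha-tubulin, the mitotic marker PHH3 (phospho-histone H3), and
gamma-tubulin; `screenA` carries DNA, alpha-tubulin, CEP215 and actin.

Key conventions:

* **Units.** All geometry is specified in micrometres and converted by the
  configured pixel size (default 0.65 um/px, the scale of a x20 air
  objective on a screening confocal). Intensities are arbitrary units;
  classifier intensity thresholds are therefore documented as calibrated
  to the generator's default amplitude scale.
* **Phenotype encodings.** Mitotic figures are small bright DNA discs with
  high PHH3 (or, in `screenA`, a bright spindle with low CEP215).
  Anaphase/telophase events are two small DNA masses elongated
  perpendicular to the division axis; the inter-nucleus corridor carries
  low tubulin in anaphase and high tubulin in telophase, which is the
  stage discriminator the classifier uses. Segregation errors are rendered
  as a detached lagging-chromatid blob plus a faint chromatin strand in
  the corridor, deliberately dimmer than the nucleus segmentation
  threshold so that the error neither merges the daughter nuclei into one
  object nor distorts their measured shape — mirroring the fact that
  lagging chromatin is far less substantial than the main DNA masses.
  Cytokinetic bridges are two short, bright tubulin half-segments
  (the dark midbody gap between them) joining two daughter cells, with a
  gamma-tubulin midbody spot. Dead cells are small bright DNA fragments
  with no cytoskeleton.
* **Calibration.** The generator's free geometry (sizes, gaps,
  amplitudes; see `sim_geometry()`) was chosen once so that the default
  classifier thresholds separate the classes, and the defaults are
  documented as the study conditions of all simulation results. They are
  not photorealistic; the generator's job is the statistical structure of
  a screen, not microscopy physics.
* **Reproducibility.** One master seed; per-well substreams derive from it
  by a fixed affine counter scheme, so any single well re-renders
  bit-identically in isolation. Rendering mutates planes patch-wise inside
  an environment, keeping cost linear in cell number.

What the generator does *not* emulate: uneven illumination, focus drift,
cell clumping beyond light crowding, debris other than dead-cell
fragments, staining variation between channels beyond a per-event
log-normal amplitude jitter, mitotic sub-stages, and 3D structure.
Consequently, passing the simulation-based checks demonstrates the
internal consistency and statistical behaviour of the pipeline under
controlled conditions, not its accuracy on real micrographs, which would
need threshold re-calibration per assay.

# Segmentation

Nuclei: global Otsu threshold on a Gaussian-smoothed DNA plane, then a
watershed whose surface combines the distance transform with the smoothed
DNA intensity. The intensity term is what splits adjacent condensed
figures (e.g. anaphase nuclei) whose thresholded masks touch; the distance
term splits touching round nuclei. Objects below `min_area_um2` are
dropped. The default of 1.5 um^2 is deliberately small: dead-cell
fragments and anaphase nuclei are legitimate downstream objects and must
survive segmentation (a coarser screen could raise it).

Cytoplasm: seeded propagation of the nucleus labels across the tubulin
channel restricted to a foreground mask (median + 3 robust SDs of the
tubulin plane); the permissive robust threshold keeps the dim cytoplasm of
multinucleated cells that a global Otsu would discard. Spot detection is
scale-normalized Laplacian-of-Gaussian filtering with local-maximum
selection, used for bridge half-parts and midbody spots.

Feature measurement reports centroids, moment-based ellipse axes, aspect
ratio, roundness `4*pi*area/perimeter^2` with a crack-length perimeter
(exposed pixel edges scaled by pi/4, unbiased for smooth convex shapes so
a disc measures roundness ~1), and per-channel integrated/mean/perinuclear
intensities, the last on a morphological ring (default 2 um) outside the
object.

# The phenotype rule cascade

The cascade runs per well (`phenotype_well()`):

1. **Dead-cell filter.** Nucleus area outside a viable range or mean
   tubulin below a floor (debris has no cytoskeleton).
2. **Mitotic classification.** Condensed DNA (small area) plus a high
   mitotic marker (`screenB`) or high tubulin with low CEP215 (`screenA`).
   Thresholds given as `"auto"` resolve per well by Otsu's method on the
   per-object distribution, with two numerical safeguards: the
   between-class criterion is flat across an empty valley, so the plateau
   midpoint is taken; and in wells with no positive class the two halves
   of the Otsu split differ by only a few within-class spreads (the means
   are compared against 5x the larger within-half MAD), in which case no
   object is called positive. Genuinely bimodal wells separate by far
   more, however unbalanced the classes.
3. **Anaphase/telophase pairing.** Among mitotic objects, candidates are
   small, elongated, low-integrated-DNA nuclei; greedy mutual
   nearest-neighbour pairing in increasing distance (deterministic given
   label order); a pair passes the distance gate and is staged by
   inter-nucleus tubulin (anaphase lower). See "The distance caps" below.
4. **Segregation-error scoring.** For anaphase pairs only, the mean DNA in
   the inter-nucleus corridor — the band joining the two centroids, as
   wide as the mean minor axis — is compared against a background
   reference plus `cse_dna_threshold_sd` (default 3) robust SDs. Two
   details matter. First, the pair's own nuclei are excluded from the
   corridor by their *fitted moment ellipses* plus a margin rather than by
   their segmented masks, so chromatin that the segmenter happened to
   attach to a nucleus stays measurable; the ellipse's along-axis semi-axis
   is capped at 0.35 x major axis because the very chromatin being scored
   inflates the fitted minor axis. Second, the default reference is a
   matched local background: the same band shifted sideways past the
   nuclei (`cse_reference = "flank"`), which absorbs the point-spread
   bleed of the bright daughter nuclei; a whole-image background reference
   is available (`"image"`).
5. **Multinucleation.** Step 1: binucleated cells as close, round,
   normal-sized nucleus pairs (centroid distance, area, aspect, roundness
   gates). Step 2: remaining nuclei with low perinuclear tubulin that
   share one connected cytoplasm component. Overlapping step-1/step-2
   groups merge by union-find, so e.g. a trinucleate cell with one tight
   sub-pair is still one cell.
6. **Cytokinetic bridges.** Bright tubulin spots are paired into doublets
   by separation; the daughters' cytoplasm labels are sampled just
   *beyond* each half part (away from the midbody, where the propagated
   cell boundary cannot fall); the union component must be elongated and
   of plausible length, and (by default) a gamma-tubulin spot must sit
   near the doublet midpoint. An elongated tubulin structure inside a
   single cell — a stress-fibre mimic — fails the two-cell requirement.
7. **Counting.** Pairs and multinucleated groups count once; dead cells
   are excluded from the viable denominator; the segregation-error rate is
   relative to anaphase events; a well with no viable cells reports zero
   ratios with an `empty_flag` instead of NaN so screen tables stay
   rectangular.

## The distance caps

The screen's published rule gives maxima of 0.65 um (anaphase) and 2.6 um
(telophase) for "the distance between both nuclei", used "to discard two
daughter non-mitotic cells". Taken literally as the stage gate, the
anaphase cap contradicts the same pipeline's segregation-error
measurement: within 0.65 um of both DNA masses there is no measurable
inter-nucleus corridor at screen resolution (the point-spread function
alone spans about that distance). The pipeline's own stated stage
discriminator is inter-nucleus alpha-tubulin. `mitoscan` therefore
defaults to: pair admission requires the boundary gap at most the
telophase cap (2.6 um), which is the daughter-discard role of the distance
criterion, and the anaphase/telophase split is decided by corridor
tubulin (`stage_rule = "tubulin"`). The literal reading is available as
`stage_rule = "distance"`, and both boundary-gap and centroid
interpretations of the distance are supported (`pair_dist_mode`,
default `"gap"` since centroid separations in anaphase far exceed the
printed values). None of these options is silently inverted: anaphase is
always the *lower*-tubulin corridor, as printed.

# Screen statistics

Per-well counts are divided by the number of viable cells (density
normalization), then plates are equalized: the average ratio per plate and
the grand average across plates define a reference mean, and each plate is
scaled so its average equals the reference. Z-scores are
`z = (x - mu) / sigma` with `mu` the reference mean and `sigma` the
standard deviation of normalized ratios across wells. Whether control
wells enter `mu`/`sigma` is configurable; the default excludes them,
since hits are defined relative to the library distribution. Two exact
consequences are tested: per-plate means equal the reference to 1e-9
relative tolerance for arbitrary plate factors, and any plate-wide
multiplicative batch effect leaves every Z-score unchanged. Hits are
targets with aggregated `z` past a threshold in the chosen direction
(default: increase), ties broken lexicographically; replicate concordance
is Spearman's rank correlation with average-rank ties.

# The simulated validation screen

`validation_screen_config()` reproduces the design of a candidate
validation screen: 2 biological replicates x 4 technical-replicate plates
sharing one 96-well layout, plate batch factors {0.7, 1, 1.3, 2} (one per
technical plate), ~100 cells per well, 92 library targets plus 4 negative
controls. Library targets carry heterogeneous true effects — multipliers
of the mitotic-class fractions drawn once per target from a truncated
normal (mean 1, SD 0.5, floor 0.15) — because a validation screen ranks
candidates spanning a range of phenotype strengths; 5% of targets are
designated hits at exactly 3x. The base mitotic index is 0.10
(`screen_base_well()`). Against this screen the package's acceptance
checks measure hit recall at `z >= 2`, the false-positive rate among
non-hit targets, and the inter-replicate Spearman correlation of the
mitotic index (per-target technical-replicate means). With only strong
binary hits and no effect heterogeneity the inter-replicate correlation
of a 96-well screen is bounded near 0.15 regardless of assay quality —
rank concordance requires true between-target variation — which is why
heterogeneous effects are part of the scenario definition rather than a
tuning choice.

# Z-stack quantification

`intensity_ratio()` follows the spindle-ratio recipe: per optical slice,
integrated intensity in a circular selection divided by its area, minus
background; slice values averaged per channel over the stack; ratio of
the two channel means (e.g. acetylated tubulin over alpha-tubulin — a
readout of microtubule stability). `total_intensity()` is the numerator
path alone (e.g. total EB1). Background defaults to the median of an
annulus at 1-1.5 radii outside the selection, estimated once per stack;
per-slice estimation was considered and rejected as the default because a
manual circle is usually placed once per cell and published descriptions
subtract a single background. Inter-kinetochore distances are Euclidean
distances in one focal plane scaled by pixel size, with per-cell medians
and means (at least seven pairs per cell is the usual reporting
convention); the measurements are exactly invariant under rigid motion.

# Combination statistics

For consistency across loss-of-function methods (e.g. RNAi and LNA
gapmers), one-sided p-values are combined per direction by an
intersection-union test: the combined p is the maximum across methods, so
significance requires every method to be significant. How the two
directional combined p-values become one per-gene significance before FDR
correction is genuinely under-determined; the default assembles a
two-sided p as `min(1, 2 * min(p_up, p_down))`, and
`assembly = "per_direction"` leaves the directions separate for
direction-wise FDR. Both are exposed rather than guessed silently.

For windowed genomic analyses (CUT&RUN-style differential binding),
windows of all sizes are filtered to at least fivefold the background
abundance, combined across methods per window by the maximum p, clustered
by single-linkage overlap of their half-open intervals (abutting windows
do not merge; clustering is order-invariant), and each cluster receives a
Simes combined p-value `min_i (m * p_(i) / i)` with Benjamini-Hochberg
correction at FDR 5% defining differentially bound regions. For
pulldown-versus-sense-control comparisons (CHART-style), the empirical
FDR is the ratio of sense-enriched to antisense-enriched clusters below a
p cutoff; binding sites are usually called at eFDR 30%
(`efdr_threshold()` finds the largest qualifying cutoff). An empty
denominator reports eFDR 1 with a flag — maximally conservative.

# Numerical choices and degenerate inputs

* Greedy mutual-nearest-neighbour pairing is deterministic: candidates are
  processed sorted by label, and the globally closest remaining pair is
  always mutual.
* A degenerate corridor (touching nuclei) scores no segregation error and
  warns; an empty nucleus mask yields an empty cytoplasm mask, not an
  error; a plate whose mean ratio is zero is left unscaled with a warning;
  `sigma = 0` in Z-scoring is an error, not an NaN.
* P-values are validated into `(0, 1]`; BH adjustment delegates to
  `stats::p.adjust`, window overlap to `IRanges::reduce` — both are
  cross-checked in the test suite against hand-written brute-force
  oracles, which are kept independent of the implementation path.
* Problem sizes in the test suite and acceptance script (a 768-well
  screen at ~100 cells/well; 32- and 16-well recovery sweeps; 1,000-trial
  oracle comparisons; a 10,000-gene null) were chosen as the smallest
  designs at which the measured quantities are stable; they are the
  package's declared study conditions.

# Known limitations

* Intensity-threshold defaults are in the simulator's arbitrary units;
  applying the cascade to real images requires re-calibration (the
  `"auto"` thresholds help, the fixed ones must be set per assay).
* The binucleation geometry gates assume nucleus pairs closer than
  unrelated neighbours; in extremely dense fields step 1 could pair
  neighbouring cells. The simulator's placement respects this; real
  images may not.
* Stage discrimination by corridor tubulin assumes midbody tubulin
  accumulation in telophase; drugs that abolish the midbody would make
  telophases read as anaphases.
* No spatial (edge-well) correction, loess surface or SSMD is provided;
  plate normalization is mean scaling only.
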