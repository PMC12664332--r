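---
title: "Methods: jaw biomechanics, outline shape and disparity through time"
author: "jawspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jaw biomechanics, outline shape and disparity through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawspace)
```

# The problem

Late Palaeozoic (Carboniferous--Permian) tetrapods diversified into the
first terrestrial vertebrate ecosystems, and the lower jaw is the organ where
feeding ecology leaves its clearest osteological signature.  Two broad
questions motivate this package: did amniotes explore a larger region of jaw
form--function space than non-amniote tetrapods, and how did jaw disparity
wax and wane across the roughly 95 Myr from the Visean to the Changhsingian,
through events such as the Carboniferous Rainforest Collapse and the
Capitanian extinctions?

The package implements three coupled workflows on a common morphospace
machinery:

1. **Functional (biomechanical) traits** -- nine dimensionless measurements
   taken from landmarks on the medial side of the jaw.
2. **Outline shape** -- elliptical Fourier analysis (EFA) of binary jaw
   silhouettes in lateral and occlusal view.
3. **Disparity through time** -- morphospace occupation metrics resolved
   over geological stage or series bins, partitioned across clades.

A synthetic-data generator provides specimen tables, trait matrices and
parametric jaw outlines with known structure so that every stage of the
pipeline can be validated end to end without external data.

# Functional traits

The nine traits, in the package's canonical order (`trait_names()`):

| trait | definition |
|---|---|
| anterior MA | in-lever / out-lever to the anterior jaw tip |
| posterior MA | in-lever / out-lever to the posterior tooth-row end |
| opening MA | opening in-lever (retroarticular) / out-lever to the tip |
| maximum AR | deepest dorsoventral station / jaw length |
| average AR | mean depth over the jaw axis / jaw length |
| articular offset | joint height above the tooth-row line / jaw length |
| relative tooth-row length | tooth-row chord / jaw length |
| relative fossa length | adductor-fossa chord / jaw length |
| relative symphysial length | tip-to-symphysis chord / jaw length |

Mechanical advantage (MA) is the standard lever model of the jaw: the
articulation is the fulcrum, the adductor musculature inserts at the
in-lever point, and the bite point is the out-lever end.  High MA transmits
force (durophagy, herbivory); low MA transmits speed (snapping predators).

Conventions that the code fixes, because the underlying measurement
tradition leaves them open:

* **Jaw length** is the joint to anterior-tip chord and is the common
  normaliser for every relative measure.  A single consistent denominator
  keeps the nine traits commensurable; it can differ by a fraction of a
  percent from the horizontal extent when the joint is elevated.
* **Closing in-lever point.**  When an explicit `insertion` landmark is
  available it is used (`insertion_rule = "explicit"`, the default);
  otherwise the midpoint of the adductor fossa serves as the conventional
  proxy (`"fossa-midpoint"`).
* **Average aspect ratio** uses the trapezoidal mean of the depth profile
  over its stations, so unevenly spaced profiles are handled correctly.
* Edentulous taxa are accommodated by reading the tooth-row landmarks as the
  functional "dental" margin; no tooth-level traits exist by design.

All nine traits are ratios, hence invariant under rigid motion and uniform
scaling of the landmark configuration -- a property the test suite checks to
machine precision.  Before ordination the trait matrix is Z-standardised
(`z_standardize()`, mean 0, sample sd 1 per column, n - 1 denominator) so
that each trait carries equal weight; PCA of the standardised matrix is then
correlation-equivalent.

# Outline shape

## Silhouette to outline

`read_silhouette()` reads PNG/TIFF rasters; pixels darker than 50%
luminance are foreground (black silhouette on white), with an `invert`
option.  `extract_outline()` labels connected components (4-connectivity),
keeps the largest, and traces its boundary along pixel edges, so the traced
loop's shoelace area equals the component's pixel count exactly.  Image rows
are converted to mathematical y-up coordinates (row r maps to y = height -
r), keeping "dorsal = +y" semantics.  Outlines are oriented
counter-clockwise on ingest.

Occlusal jaw arches are cut at a per-specimen symphysis position with
`split_ramus()` (the split is supplied by the analyst; no automatic
symphysis detection is attempted), and right hemimandibles are converted to
the left-side standard with `mirror_outline()`, which preserves orientation
by reversing vertex order.

## Normalisation

`resample_closed()` places k equally spaced points along the closed polygon
(660 for lateral jaws, 500 for occlusal rami -- the package's standard point
counts).  `normalize_geometry()` then removes position (vertex centroid to
the origin), size (unit centroid size, the root-mean-square vertex distance)
and orientation (major principal axis of the vertex covariance onto the
x-axis, by proper rotation only).  The 180-degree ambiguity is resolved by a
stored anterior-tip hint when one exists, otherwise by placing the longer
extent on +x; for exactly symmetric shapes a final tie-break on the first
vertex keeps the operation idempotent.  Before decomposition the starting
vertex is rotated to the maximal-x (anterior) vertex (`rotate_start()`),
which fixes the EFA starting-point ambiguity without first-harmonic phase
normalisation.

As a sensitivity alternative, the classical first-ellipse normalisation
(`normalize_first_ellipse()`, or `normalization = "first-ellipse"` in
`run_shape()`) rescales and rotates the Fourier coefficients by the first
harmonic instead of pre-aligning the outline; the two routes generally give
similar but not identical morphospaces, which is precisely why both are
exposed.

## Elliptical Fourier analysis

`efa_decompose()` computes the classical four-coefficient-per-harmonic
descriptors of the arc-length parameterised closed polygon: with perimeter T
and harmonic index n,

$$x(t) = A_0 + \sum_n a_n \cos\frac{2\pi n t}{T} + b_n \sin\frac{2\pi n t}{T},
\qquad
y(t) = C_0 + \sum_n c_n \cos\frac{2\pi n t}{T} + d_n \sin\frac{2\pi n t}{T}.$$

The coefficients follow from closed-form integration of the piecewise-linear
segments; the test suite verifies them against an independent per-segment
Gauss--Legendre quadrature of the defining integrals to 1e-9.  A unit circle
traversed counter-clockwise from (1, 0) gives exactly a1 = d1 = 1.  Two
numerical caveats worth knowing:

* An *eccentric ellipse is not a single exact harmonic* under arc-length
  parameterisation: parameter speed varies along the ellipse, shifting a few
  percent of power into odd harmonics (for a 3:1 ellipse, a1 is about 2.62
  rather than 3).  The first harmonic still carries >97% of the power.
* The synthetic "featureless" jaw (no coronoid, no offset, symmetric depth
  profile) keeps its flat tooth-row margin, so it is a half-oval rather than
  a true oval; its first-harmonic power fraction is about 0.98.

Harmonic power is $P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2$.
`calibrate_harmonics()` chooses the smallest H whose cumulative power
fraction reaches a threshold (default 99%), computed against a high-order
reference decomposition ($H_{ref} = \lfloor k/2 \rfloor - 1$).  Because the
aggregation across specimens is not fixed by convention, the package
defaults to the conservative **worst-case rule** (every specimen must reach
the threshold) with a mean-case alternative behind a flag; worst-case never
selects fewer harmonics than mean-case.

PCA of the coefficient table is centred but **not rescaled per
coefficient**, the standard convention in outline morphometrics: rescaling
would inflate the weight of high-order harmonics that mostly carry
digitisation noise.

# Ordination and disparity

`jaw_pca()` is a covariance PCA (n - 1 denominator) with two deterministic
conventions: axes with numerically zero variance are dropped, and each
loading column is signed so its largest-magnitude entry is positive, making
score tables reproducible across platforms.

Disparity metrics:

* **Sum of variances** (`sum_of_variances()`): the sum over PC axes of the
  subset's sample score variances; insensitive to modest sample-size
  variation, which matters when time bins hold unequal numbers of taxa.
  Single-specimen subsets return 0 with a `degenerate` flag rather than
  being dropped, keeping time series aligned.
* **Bootstrap intervals** (`bootstrap_disparity()`): specimens are resampled
  with replacement (default 1000 replicates), and the distribution is
  summarised by its median and an equal-tailed 95% interval.  Percentile
  intervals for a variance-type statistic undercover somewhat at small n;
  the test suite checks roughly nominal coverage at n = 100.
* **Foote partial disparity** (`partial_disparity()`):
  $PD_g = \sum_{i \in g} \lVert x_i - \bar{x} \rVert^2 / (N - 1)$ with
  $\bar{x}$ the grand centroid.  The squared-distance form is the default
  because it alone partitions the total sum of variances additively across
  groups -- the property that makes stacked partial-disparity plots
  meaningful.  An unsquared variant (sometimes described verbally in the
  literature) is available via `squared = FALSE` for sensitivity checks; it
  is not additive.
* Within time bins, partial disparity uses the **bin centroid** (the
  disparity being partitioned is the bin's own), not the global centroid.

## Time binning

`build_time_bins()` carries the fifteen stage bins Visean--Changhsingian and
the five series bins (Mississippian--Lopingian) with boundary ages from the
ICS International Chronostratigraphic Chart (2023).  Bins are half-open
`[older, younger)` with the older bound inclusive, so an age on a shared
boundary belongs to the younger bin.  `assign_bins()` places a taxon in
every bin its first-to-last appearance (FAD--LAD) interval overlaps with
*positive duration* -- merely touching a boundary does not count -- while
point ranges (FAD = LAD) go to the single bin containing the point.  The
series level exists because per-stage occlusal samples are too sparse
(single-specimen stages) for meaningful variances.

# Group-comparison statistics

* `pairwise_t_tests()` -- two-sided t-tests per group pair; the default
  pools a common error variance across *all* groups (the behaviour of the
  classical pairwise-comparison routine), with per-pair pooling behind a
  flag; Bonferroni correction multiplies p by the number of pairs, capped
  at 1.
* `levene_test()` -- one-way ANOVA on absolute deviations from the group
  centre; default centre is the **median** (Brown--Forsythe), robust for
  the skewed trait distributions typical of ratio data; mean-centring gives
  the classical Levene test.
* `permanova()` -- centroid separation on all PC axes with Euclidean
  pseudo-F, $F = (SS_B/(g-1)) / (SS_W/(N-g))$, and permutation p-value
  $(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$, default 999
  permutations (so the smallest attainable p is 0.001).  For tiny instances
  an exhaustive mode enumerates every distinct label arrangement.
* `rank_sum()` -- the Mann--Whitney pair count W (ties half); exact null
  enumeration when both samples have at most 10 untied values, otherwise a
  tie-corrected normal approximation with continuity correction.  Its role
  here is comparing two *bootstrap disparity distributions* ("does group A
  occupy more morphospace than group B?"), which is why W is of order
  n_boot squared (about 10^6 at the default 1000 replicates).
* `linear_r2()` -- ordinary least squares R-squared and slope-test p for
  trait-pair association.

# The synthetic data generator

`sim_config()` defaults encode the study conditions the package emulates:
202 taxa; clade weights 85 : 83 : 34 (non-amniote : synapsid : sauropsid);
56/202 herbivores; figure availability 198/202 lateral, 111/202 medial,
73/202 occlusal; ages spanning 346.7--251.9 Ma; and subclade-flag rates
(diadectomorph 7/85 of non-amniotes, recumbirostran 10/85,
captorhinid-group 15/34 of sauropsids) chosen so the four amniote-definition
hypotheses H1--H4 move realistic numbers of taxa between clades.

Traits are drawn from independent normals per group (`trait_group =
"amniote"` by default): amniote means are shifted upward on opening MA, both
aspect ratios, articular offset and symphysial length, and amniote
*variance* is inflated (factor 1.8) on five of the nine traits -- the
qualitative contrast the empirical data show.  Baseline means (e.g. anterior
MA 0.20, maximum AR 0.22) sit centrally within the empirically reported
trait ranges.  The `variance_multipliers` act on the variance (the standard
deviation is scaled by their square root).  Independence across traits is a
deliberate simplification: the generator's job is mean/variance recovery and
pipeline validation, not emulating trait covariance, and the configuration
matrices make richer structures easy to add.

Stratigraphic ranges draw the first appearance uniformly in the age window
and a duration uniform on [0, span/3], truncating at the younger window
edge -- a stated, simple null; real FAD/LAD distributions are neither
uniform nor independent of clade.

## Parametric jaws

`shape_params()` defines a family of lateral jaw silhouettes with
closed-form trait values: the jaw axis runs from the articulation to the
anterior tip; the ventral margin is a smooth unimodal depth profile peaking
at `depth_peak_position`; the dorsal margin carries the tooth row (y = 0), a
Gaussian coronoid bump (rescaled so it vanishes exactly at both ends and
reaches exactly `coronoid_height` at its centre) and a cubic taper up to the
articular offset.  `make_landmarks()` places the nine-trait landmark set
consistently (in-lever points on the joint-tip axis, so anterior and opening
MA equal their defining fractions exactly), and `ground_truth_traits()`
evaluates the traits directly from the parameters;
`compute_traits(make_landmarks(p), depth_profile_from_params(p))` matches it
to 1e-9 across random parameter draws.  Two boundary notes: a negative
articular offset cannot be rendered as a simple outline (the margins would
cross) and is rejected by `make_jaw_outline()` with a self-intersection
error; and the aspect-ratio profile is sampled on a fixed station grid
shared between generator and ground truth, so the maximum is exact on that
grid.

`make_shape_set()` adds group structure on top (deeper jaws and taller
coronoids in amniotes, longer symphyses and larger offsets in herbivores,
multiplicative lognormal jitter sd 0.08), which gives the EFA-PCA
morphospace recoverable group separation at realistic effect sizes.

## What passing tests do and do not show

The generator emulates group means, group variances, class imbalance, view
availability and stratigraphic ranges -- so green tests demonstrate that the
pipeline *recovers known structure of those kinds*.  It does **not** emulate
phylogenetic covariance, temporal trends in disparity (no built-in
Capitanian peak), digitisation noise in real silhouettes, or missing-data
patterns correlated with geology.  Conclusions about the empirical system
require the empirical data; the published raw-measurement and specimen
tables can be dropped into `inst/extdata/peerj/` to activate the
reproduction checks in the acceptance test file.

# Problem sizes and runtime choices

The test suite runs the stochastic recovery checks at the design points that
make them meaningful: Levene power at n = 200 per group over 100 seeds
(fourfold variance inflation, alpha 0.01), and shape-effect recovery by
PERMANOVA at n = 30 outlines per group over 100 seeds with 199 permutations.
The acceptance script runs the full pipeline at the emulated study scale
(202 taxa, 660-point lateral outlines, 1000 bootstrap replicates, 999
permutations), which completes in well under a minute on one CPU.  Outline
vertex counts in unit tests are reduced (120--300 points) where the property
under test does not depend on resolution.

# Known limitations

* Trait noise is independent per trait; no phylogenetic or developmental
  covariance.
* The occlusal synthetic family is a stand-in arch, not a parametric jaw
  ramus in occlusal view.
* `split_ramus()` requires exactly two crossings of the split line; strongly
  recurved arches need a pre-rotation.
* Exhaustive PERMANOVA enumerates label arrangements and is only feasible
  for roughly N <= 12 with two groups.
* Boundary ages follow one chart edition (ICS 2023); analyses tied to a
  different edition should supply their own `TimeBin` table, which
  `assign_bins()` accepts unchanged.
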