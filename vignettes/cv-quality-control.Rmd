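---
title: "Coefficient-of-variation quality control and gray-matter group ICA for resting-state fMRI"
author: "boldqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coefficient-of-variation quality control and gray-matter group ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resting-state fMRI group studies in neurodegenerative disease face two
coupled nuisances. First, subtle technical artifacts — stripe-like intensity
offsets along the slice axis from within-TR motion or gradient glitches, and
widespread transient signal defects — evade both visual inspection of the 4D
series and motion-parameter screening, yet they perturb exactly the signal
statistics that spatial ICA relies on. Second, gray-matter atrophy replaces
cortical tissue with CSF, so patient voxels carry partial-volume CSF
pulsation that inflates apparent connectivity differences (or masks real
ones) in whole-brain analyses.

`boldqc` implements a two-part answer. A *coefficient-of-variation (CV)
map* condenses each subject's 4D run into one 3D image of temporal signal
dispersion, scored against a normative reference so that artifactual runs
can be flagged reproducibly. A *gray-matter-restricted group ICA* followed
by dual regression and permutation inference then estimates group
connectivity differences on the voxels where the signal of interest
actually lives. A seeded synthetic phantom cohort generator provides ground
truth for end-to-end validation of the whole chain.

## Quality-control model

For a voxel time series $X$ with temporal mean $\bar X$ and sample standard
deviation $\sigma(X)$ (divisor $t-1$ throughout the package),

$$\mathrm{CV} = \frac{\sigma(X)}{\bar X}, \qquad
  \mathrm{tSNR} = \frac{\bar X}{\sigma(X)},$$

so CV and tSNR are reciprocal on jointly valid voxels. Voxels whose mean
(for CV) or SD (for tSNR) falls below a floor — by default $10^{-6}$ times
the run's median absolute intensity — are marked invalid rather than
producing division blow-ups in background air.

CV maps are computed on data that have been volume-dropped and temporally
high-pass filtered but *not* smoothed or masked: filtering removes slow
drift that would inflate CV everywhere, while smoothing would blur exactly
the slice-localized deviations the CV map must expose.

A normative reference is the voxelwise mean and sample SD of CV maps from a
healthy cohort (181 subjects in a full-scale application; 20 phantom
subjects in this package's validation runs). Each study subject's CV map
becomes a deviation z-map, $z = (\mathrm{CV} - \mu_{\mathrm{ref}}) /
\max(\sigma_{\mathrm{ref}}, \epsilon)$, from which two scores are taken:

* **stripe score** — the maximum over slices of the mean $|z|$ within a
  slice, minus the median over slices. Slice-localized deviation scores
  high; a global offset scores zero.
* **defect score** — the fraction of valid voxels with $|z| > 3$; high for
  widespread deviation.

A run is flagged when either score exceeds its threshold. Thresholds
default to median + 5 MAD over the normative cohort's own scores, floored
at stripe $\ge 1.0$ and defect $\ge 0.15$. The floors state what "clear
aberration" means on each scale: pure noise puts about 0.3% of voxels
beyond $|z| = 3$, and genuine disease effects (reduced network fluctuation
amplitude, atrophy-driven partial-volume change) measure at most a few
percent on the defect scale and a few tenths on the stripe scale, whereas
injected technical artifacts at realistic amplitudes exceed the floors
severalfold (stripe scores of 20–40, defect scores of 0.4–0.9 in the
bundled validation cohorts). Flagging therefore targets technical
aberration, not biology — replacing expert visual discarding with an
explicit, reproducible convention.

Included and excluded runs are compared on mean tSNR within a brain mask
using a Mann–Whitney U test: exact by exhaustive enumeration of group
assignments for combined $n \le 12$ (ties handled exactly), and the
tie-corrected normal approximation otherwise.

## Preprocessing

The chain mirrors a minimal FSL-style pipeline on pre-aligned data, in this
order: drop initial volumes (default 3, for T1 saturation), high-pass
filter, *(CV maps here)*, Gaussian smoothing, gray-matter masking.

The high-pass filter is a local Gaussian-weighted running-line detrend with
kernel SD `cutoff_seconds / (2 * TR)` volumes, the voxel mean re-added
afterwards. It preserves constants and linear trends exactly and is
characterized by its measured gain rather than by bit-compatibility with
any external tool: at the 199-volume, TR 1.8 s record the pipeline
produces, the amplitude gain is about 0.98 at a 50 s period and 0.16 at a
400 s period. Because a running-line fit tracks any fluctuation slow
relative to the record, the stopband gain depends on record length (it
rises toward ~0.27 at 400 s for very long records); the filter is always
characterized at the acquisition length in use.

Smoothing uses a separable Gaussian with $\sigma = \mathrm{FWHM} /
(2\sqrt{2\ln 2})$ per axis (5 mm FWHM $\to$ 2.12 mm), discrete kernels
normalized to unit mass, zero padding at the grid boundary. Gray-matter
partial-volume maps are block-averaged onto the BOLD grid when their grid
is an integer multiple of it, and binarized at partial volume > 0.5. Both
the padding rule and the 0.5 threshold are stated conventions.

## Group ICA

Subjects are temporally concatenated after per-voxel demeaning and variance
normalization within subject (voxels with vanishing variance stay zero, so
a patient's atrophied voxels contribute nothing). The concatenated matrix
is conditioned by removing each volume's grand mean over voxels; this makes
the principal subspace orthogonal to the constant map, so the subsequent
z-scoring of source maps is a pure rescaling and the fitted
`mixing %*% spatial_maps` reproduces the rank-$k$ principal reconstruction
exactly.

Dimensionality is reduced to $k$ principal components via the smaller Gram
matrix, and the whitened spatial components are rotated to maximal
non-Gaussianity of the voxelwise source distributions using the log-cosh
contrast with symmetric decorrelation (tolerance $10^{-6}$, at most 1000
iterations; non-convergence is an error, which the study pipeline retries
from a short ladder of deterministic restart seeds, as the fixed point can
stall on noise-dominated subspaces). Each map is z-scored over voxels and
its sign fixed so the skewness is non-negative, which makes fits
reproducible: same seed, identical maps; different seeds, maps pairable at
$|r| \ge 0.95$ on well-separated sources. Full-scale studies typically use
$k = 50$; phantom validation uses $k$ equal to or slightly above the number
of embedded networks (3–4), since 50 components are meaningless on a small
grid.

Maps are thresholded by an EM fit of a Gaussian (background) plus a
positive-tail gamma (activation; a negative gamma is optional), keeping
voxels whose posterior probability of activation exceeds 0.5 — false
positives and false negatives weighted equally. Gamma parameters are
updated by weighted moment matching; if the EM degenerates the map falls
back to $|z| > 2.3$ with a warning. Components are identified against
named templates by maximal spatial Pearson correlation (ties to the lower
index); matches under $r = 0.2$ are reported unmatched, and all components
at or above the floor are retained as the Bonferroni set for duplicate
networks.

`gmICA` runs on the union of the subjects' binary gray-matter masks (a
shared voxel set is required for concatenation while masks are
subject-specific under atrophy); `wbICA` runs on all brain voxels.

## Dual regression and inference

Stage A regresses each volume on the group maps (maps demeaned over voxels,
data demeaned per voxel over time) to obtain per-subject component time
courses, which are then variance-normalized to unit sample SD. Stage B
regresses each voxel's series on those time courses; the coefficients form
subject-specific maps. Both demeaning conventions are declared choices. On
noise-free constructions the two stages invert the construction exactly, up
to scale.

Group differences use a pooled-variance two-sample t per voxel with
max-statistic permutation FWE control: group labels are permuted (10,000
draws at full scale; exhaustive enumeration is auto-selected whenever the
number of assignments fits the budget), the maximum $|t|$ over voxels is
recorded per permutation, and $p_{\mathrm{FWE}}(v) = (1 + \#\{\max \ge
|t_v|\}) / (n_{\mathrm{perm}} + 1)$ for random draws (the plain tail
proportion under exhaustive enumeration). Ties count against significance.
Voxelwise FWE is used rather than cluster or TFCE inference. When a
network is represented by $m$ duplicate components, each component's p map
is Bonferroni-scaled by $m$. Difference-map summaries report significant
voxel count, volume (count × voxel volume), peak location in voxel
indices, and t-score statistics.

## The phantom

Each subject is a grid (default 24×24×12 voxels of 4 mm, 100 volumes at
TR 1.8 s) of concentric compartments on a normalized-radius ellipsoid: CSF
core (r ≤ 0.3), white-matter ring (0.3–0.6), gray-matter shell (0.6–0.95),
air outside (exactly zero). The signal model is

$$X_{s}(v, t) = \mathrm{baseline} + \textstyle\sum_k \beta_{sk}\,
  \mathrm{map}_k(v)\, \mathrm{tc}_{sk}(t) + \mathrm{noise},$$

with white noise of SD 2% of baseline in all tissue (typical tSNR ≈ 50), a
spatially coherent band-limited pulsation regressor added in CSF at 0.6–0.9
of the Nyquist frequency (cardiac-aliased range), and network time courses
drawn as band-limited noise in the standard resting-state band
0.01–0.1 Hz, one draw per subject and network. Three default networks sit
in the GM shell: a posterior default-mode-like network carrying the group
deficit (control amplitude 2.5% of baseline, patient 1%), a bilateral
salience-like pair, and a visual-like blob. Per-subject amplitudes are the
group amplitude times a factor $\sim N(1, 0.15)$ truncated at 0.3 — enough
spread that subject-level estimates can be validated against ground truth,
while keeping a two-group deficit detectable at $n = 10$ per group under
familywise-corrected voxel inference.

Patient atrophy removes a seeded random fraction (default 15%) of
network-adjacent GM voxels: their partial volume is zeroed, their network
contribution vanishes, and they acquire a half-amplitude copy of the CSF
pulsation — the partial-volume mechanism that motivates gray-matter-masked
analysis in the first place.

Two artifact classes are injected last, as pure additive offsets, so a
seed-matched artifact-free cohort differs exactly on the ledgered
footprint: *stripes* (offset on a slice subset for a volume subset) and
*signal defects* (whole-brain offset on a volume subset). The paper-style
artifact appearance is qualitative, so amplitudes were calibrated once to
produce unmistakable CV-map aberration — stripe offsets of 8–12× the noise
SD over 20–30% of volumes, defects of 5× over ~15% — and then frozen; at
these levels artifact scores exceed the flagging floors severalfold while
clean and merely-diseased runs stay well below them.

The phantom deliberately omits head motion, scanner drift, susceptibility
distortion, physiological noise structure beyond the CSF regressor, k-space
simulation, and registration error (all subjects share one grid). Passing
tests therefore demonstrate that the algorithms do what they claim on data
satisfying their assumptions — they do not certify performance on real
clinical data, where registration residuals and richer noise would loosen
every margin.

## Validation design and problem sizes

The package's end-to-end checks run at sizes chosen to exercise every code
path while keeping a full validation cycle to a few minutes: QC detection
on 20 clean + 5 stripe-artifacted runs against a 20-subject normative
phantom; ICA/dual-regression recovery on a 3-network, 20-subject cohort at
$k = 3$; permutation validity over 200 seeded null cohorts (5 vs 5
subjects, 16×16×8 grid, 500 permutations each, expecting any-significant
rates near the nominal 5%); and the exclusion mechanism on a 10 vs 10
cohort carrying the deficit plus five distinct-footprint artifacts.

For the mechanism demonstration, $k$ is set to 3 — the number of embedded
networks — so that the high-variance artifact sources must compete with the
networks for components. This reproduces the blind spot the QC method
exists for: with artifacted subjects included, the deficit network's group
map is degraded or displaced and the deficit goes undetected; after
CV-based exclusion it is recovered; excluding the same number of randomly
chosen subjects instead does not restore it. With generous extra
components an ICA can sometimes isolate a single-footprint artifact as its
own component and partially clean it through the dual-regression design —
which is why the validation artifacts carry distinct per-subject
footprints, as real per-subject glitches do.

## Numerical conventions

* Sample SD (divisor $n-1$) everywhere: CV, tSNR, normative SD, stage-A
  normalization, t statistics.
* PCA via eigendecomposition of the smaller Gram matrix; rank deficits
  beyond $10^{-8}$ of the leading eigenvalue are rejected.
* Permutation p-values never reach zero (the +1 convention for random
  draws; the observed assignment is part of the exhaustive set).
* Constant series yield invalid (not infinite) tSNR voxels; constant maps
  refuse mixture thresholding; duplicate group maps are rejected as
  collinear with the offending pair reported.
* All randomness flows through explicit seeds; the study pipeline derives
  a named sub-seed per stage (QC normative draw, per-arm ICA restarts,
  per-test permutations, random exclusion) from the single study seed, so
  stages are independently reproducible.

## Limitations

The mixture-model threshold approximates the probabilistic-ICA treatment
(no noise-floor model-order estimation; $k$ is user-set). The Mann–Whitney
normal approximation omits the continuity correction. The CLI's `dualreg`
subcommand is a thin alias of the study runner restricted to its
dual-regression stages rather than a separately optimized tool. Peak
coordinates are reported as voxel indices, not physical coordinates, since
phantom grids carry no meaningful anatomical space.
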