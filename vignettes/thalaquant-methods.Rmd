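---
title: "Quantification methods for a thalamic neurodegeneration study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for a thalamic neurodegeneration study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalaquant)
```

`thalaquant` reimplements, as tested reusable code, the quantitative
analysis chain of a mouse study in which loss of ClC-3-mediated
2Cl^-^/H^+^ exchange causes thalamic neurodegeneration: tracer-uptake
quantification from phosphor-plate autoradiograms, intrinsic-property
extraction from current-clamp recordings, dendritic morphometry,
immunofluorescence quantification, open-field trajectory metrics, and
the group statistics connecting them. The study's raw images and
recordings are not public, so every input class has a synthetic
generator with exact ground truth; all claims the test suite makes are
claims about recovery of that ground truth, plus reconstructions of
derived quantities from the published summary tables.

## Autoradiographic SUV/SUVR quantification

The uptake measure is the standardized uptake value,
$\mathrm{SUV} = \frac{r}{N(t)} \cdot w$, where $r$ is the
background-subtracted activity concentration (MBq/g) in a circular ROI
of 0.4 mm diameter, $w$ the body weight (g), and
$N(t) = N_0 e^{-\lambda t}$ the injected activity decay-corrected over
the uptake interval ($\lambda = \ln 2 / t_{1/2}$; the ^18^F half-life is
fixed at the physical constant 109.77 min and is configurable for other
isotopes). Regional uptake is reported as the ratio to the brainstem,
$\mathrm{SUVR} = \mathrm{SUV}_{region}/\mathrm{SUV}_{brainstem}$, which
cancels the global tracer background. Per-animal values aggregate
slices as mean ± SEM with the sectioning policy of the study: six
slices per animal for hippocampus, striatum and brainstem, three for
the thalamus; nonstandard counts warn rather than fail.

Calibration maps plate intensity to MBq/g by ordinary least squares over
the co-exposed standards ladder (1.5, 0.8, 0.4, 0.2 and 0.04 MBq). The
fit uses a free intercept by default because residual plate background
can survive subtraction; a through-origin option exists. A pixel belongs
to a circular ROI when its centre lies within the radius — the simplest
unambiguous discretisation at 25 µm resolution. Negative
post-subtraction concentrations are flagged and clamped to zero only at
the SUV step, since a negative SUV is physically meaningless.

Two choices were genuinely open. First, the placement of the background
ROI is not documented in the source study; it is exposed as a parameter
with a default over tissue-free plate. Second, the standards can be read
as activities per section (divided by a section mass of area × 20 µm ×
unit density; `standard_section_mass()` supports this) or as incubation
concentrations of the homogenate. The phantom generator uses the
concentration reading: it keeps tissue and standard intensities within
one 16-bit dynamic range, so the ladder brackets the tissue
concentrations and the TIFF interface stays quantitative. The mass-based
API remains available for data where per-section activities apply.

### The phantom generator

`generate_phantom_autoradiogram()` renders brain-region polygons at
intensities consistent with their programmed SUVRs (given an embedded
injection record: 15 MBq injected, 120 min uptake, 25 g animal), paints
the standards ladder, and adds optional Gaussian noise. The reference
region is programmed at exactly SUVR 1. Noise is additive Gaussian on
intensities; phosphor-plate noise statistics were not characterised in
the source study, so this is a stand-in, not inferred intent. At zero
noise the full chain — standards, calibration, ROI activity, decay
correction, SUV, SUVR — recovers the programmed SUVR to better than
10^-6^ relative; this round trip is the module's oracle. The phantoms
use realistic slide geometry (25 µm pixels, 0.4 mm ROIs) but make no
attempt at anatomical realism.

## Current-clamp feature extraction

Cells enter analysis only with resting potential below −55 mV and
series resistance below 40 MΩ (strict inequalities, missing values are
errors). Potentials are reported uncorrected for the −15.8 mV junction
potential, matching the source convention; the correction is carried as
an annotation column and never applied silently.

Protocols mirror the study: 1 s steps from −50 to +50 pA in 10 pA
increments (passive), −20 pA upward in 25 pA increments (F–I), and a
single −50 pA step (rebound). The rebound step is implemented as
hyperpolarizing: the written protocol mentions a "50 pA" pulse, but
rebound bursting by definition follows release from hyperpolarization,
so the negative sign is taken as intended. Sampling is 10 kHz; sample
intervals above 0.2 ms cannot resolve spike waveforms and are refused.

Definitions: input resistance is the least-squares slope of
steady-state deflection versus current over subthreshold sweeps
(mV/pA → MΩ); the membrane time constant is a single-exponential fit
over the 5–95% band of the onset transient of the smallest
hyperpolarizing step, chosen to avoid sag contamination; sag is
$100 (V_{peak} - V_{ss}) / (V_{peak} - V_{baseline})$ on the −50 pA
sweep; rheobase is the smallest amplitude evoking at least one spike
(flagged undefined when nothing spikes). AP features are measured on
the first spike of the rheobase sweep: threshold at the
derivative-criterion crossing, amplitude as peak − threshold,
half-width at half amplitude with sub-sample interpolation, latency
from step onset, AHP as threshold minus the post-spike minimum. The
F–I slope is fit from rheobase up to the first step reaching 90% of the
maximal rate, excluding the saturation plateau. Rebound spikes are
counted in a 300 ms post-offset window.

The source study does not state its spike-threshold criterion; the
package uses the common dV/dt ≥ 20 mV/ms convention, configurable to
10 or 50. Spike detection anchors each event on the run of samples
whose derivative exceeds the criterion, confirmed by a 0 mV crossing
within 2 ms and a 1 ms refractory period. On noisy traces the run
criterion is raised to six robust SDs of the sample-to-sample
derivative noise (MAD-estimated); for clean traces the MAD is zero and
the stated criterion applies unchanged. This keeps the detected
threshold within a fraction of a millivolt of truth at 0.5 mV recording
noise while remaining exactly the stated convention in the noiseless
limit. Similarly, the sag peak is read from a ~5 ms smoothed trace;
a raw minimum over 10^4^ noisy samples carries an extreme-value bias
of one to two millivolts.

### The neuron simulator

Ground-truth recordings come from an adaptive exponential
integrate-and-fire cell (capacitance $C$, leak $g_L$ with reversal
$E_L$, exponential spike initiation with slope factor $\Delta_T$,
adaptation conductance $a$, spike-triggered increment $b$, time
constant $\tau_w$) extended with a low-threshold Ca^2+^-like current
$I_T = g_T\, m_\infty(V)\, h\, (E_{Ca} - V)$ whose inactivation gate
$h$ recovers during hyperpolarization — the classical mechanism behind
post-inhibitory rebound bursts of thalamocortical relay neurons. The
model was chosen because the study reports rebound bursts driven by
low-threshold Ca^2+^ currents but prescribes no biophysical model;
multi-compartment realism is out of scope. Integration is forward Euler
at 0.1 ms in compiled code; measurement noise is added to the recorded
trace only, so spike timing is deterministic given parameters.

When the deterministic upstroke first satisfies the 20 mV/ms criterion
inside the exponential blow-up region, a stylized waveform is painted:
linear rise to the spike peak over 0.3 ms, exponential decay to the
reset with a 1.2 ms time constant. The initiation voltage is recorded
as ground-truth threshold, and amplitude, half-width (analytic, from
the rendered shape) and AHP follow from the rendering parameters — so
waveform-feature recovery can be tested to sub-sample accuracy.

Two presets, `wt_neuron_params()` and `td_neuron_params()`, encode the
study's qualitative conditions and were calibrated once, before the
recovery tests were frozen: both pass QC, reach rheobase within the
±50 pA protocol and fire ≥2-spike rebound bursts at $g_T$ = 5 nS; the
wild-type-like cell has a more negative threshold (−42 vs −39 mV),
smaller spike amplitude (94 vs 108 mV) and larger sag (≈22% vs ≈15%,
close to the published 21.1% vs 14.5%) than the transport-deficient
cell. Ground-truth conventions for parameter recovery: steady-state
input resistance is $1/(g_L + a)$, the membrane time constant $C/g_L$,
and the slow-adaptation sag limit $a/(g_L + a)$; the latter two are
exact only when $a = 0$ or $\tau_w \gg \tau_m$, so recovery tests that
need exactness use $a = 0$, $g_T = 0$ configurations. With the full
presets the passive measurements include the genuine contamination by
$I_T$ and adaptation — as they would in a real cell.

## Dendritic morphometry

SWC reconstructions (7-column, types 1 soma / 2 axon / 3–4 dendrite)
are validated as single-rooted trees with parents preceding children.
Shrinkage from histological processing is corrected by 1.1× in-plane
and 2.1× axially; the correction affects lengths only, never counts.
Total dendritic length sums Euclidean parent–child distances over
dendrite nodes; primary dendrites are dendrite children of the soma;
branch points with three or more dendrite children count once as
bifurcation nodes (the exact reconstruction-software convention being
unknown); terminal endings are dendrite leaves. For strictly binary
trees the Euler identity endings = bifurcations + primaries holds and
is enforced as a property test. The toy generator grows strictly
binary trees (balanced, or with seeded random attachment for varied
topologies) whose metrics are known in closed form.

## Immunofluorescence quantification

Cell counting follows a standard pipeline: global Otsu threshold on
the image's own intensity range (making counts invariant to intensity
rescaling), hole filling, distance-transform watershed to split
touching objects, and a size filter defaulting to nuclei of roughly
4–8 µm radius at 1 µm/pixel. The immunoreactive area fraction is the
percentage of pixels above the automatic threshold; a constant field
carries no contrast and is treated as fully immunoreactive when bright
and empty when zero. Per-animal values average 3–5 slices; averaging
across channels is refused. The published pipeline's threshold and
size parameters are unpublished, so published table values
parameterise synthetic fixtures rather than serving as recovery
targets: the disk-cell generator places non-overlapping cells by
seeded rejection sampling and reports the exact rendered mask
fraction, and recovery is tested against that exact truth (exact
counts for separated cells, ≥95% with moderate overlap, IR area
within one percentage point).

## Open-field metrics

The 44 × 44 cm arena splits into an 11 cm border strip and a 22 × 22 cm
centre. Distance is the sum of segment lengths, each segment assigned
to the zone of its midpoint (boundary points belong to the centre only
when strictly inside); time per zone sums inter-sample intervals the
same way, so centre + border time equals the session duration exactly,
and velocity is distance over duration. Session binning is not
specified in the source; metrics are computed over the whole session
by default. Trajectory generators provide stationary and centre-bound
controls plus a reflected random walk with an optional pull toward the
nearest wall; with that thigmotaxis bias the walks spend >80% of time
in the border, matching the reported behaviour, though they are more
wall-bound than real mice and model no grooming, rearing or pauses.

## Group statistics

The package's statistical contribution is the summary-statistics
one-way ANOVA: from published means, SEMs and group sizes,
$SS_{between}$ is taken about the $n$-weighted grand mean and
$SS_{within} = \sum_i (n_i - 1)\, n_i\, \mathrm{SEM}_i^2$ (since
$SD_i = \mathrm{SEM}_i \sqrt{n_i}$), giving an $F$ that equals the
raw-data ANOVA exactly for error-free summaries (tested to 10^-10^
against a brute-force oracle). Reconstructed from printed (rounded)
summaries, agreement within about ±3% of the published $F$ is the
realistic expectation, and the published microglia-marker row
reconstructs to within 0.5%. One published $F$ (the neuronal-count
row) is not recoverable from its heavily rounded summaries —
reconstruction gives ≈119 against a printed 106 — and is therefore
reported but not used as a check. Fisher's LSD and Tukey's HSD run off
the reconstructed within-group mean square, so post hoc comparisons
work when only summaries exist.

Rank comparisons use the two-sided Mann–Whitney test with the exact
null for untied samples of combined size ≤12 and the tie-corrected
normal approximation otherwise; the exact branch is verified against
full enumeration of labelings. The two-way repeated-measures ANOVA is
the classical univariate mixed model (genotype tested against
between-subject variation, time and interaction against the
within-subject residual), delegated to `aov` with an `Error(subject)`
stratum; a single timepoint collapses to the one-way result. Percent
and fold changes report magnitudes with the direction separate,
matching how the source quotes, e.g., a 7.8% increase against a
negative baseline.

## Problem sizes and limitations

Test and acceptance runs use phantoms of 320 × 400 pixels, 100 noise
seeds for the phantom bias check, 50 simulator seeds for parameter
recovery, 256 × 256 pixel cell fields, 100 random toy trees and
20-minute trajectories at 25 Hz — sizes chosen so the whole suite
exercises every pipeline at full fidelity while remaining quick to run
end to end.

Passing tests demonstrate recovery of synthetic ground truth and
agreement with published derived quantities; they cannot demonstrate
agreement with the study's raw data, which are not deposited. Known
gaps between generators and reality: Gaussian plate noise without a
point-spread function; stylized spike shapes rather than conductance
waveforms; disk-shaped cells of uniform brightness; random-walk
locomotion without behavioural microstructure. The analysis scripts
under `analysis/` present the same pipelines at study-like scale, and
the exported functions are the programmatic interface for real data in
the supported formats (TIFF + JSON sidecar, wide sweep CSV, SWC,
trajectory CSV).
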