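---
title: "Quantification methods for cochlear hair-cell imaging, audiology, and auditory behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods for cochlear hair-cell imaging, audiology, and auditory behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

otoquant quantifies the read-outs of inner-ear gene-therapy experiments in
the mouse: hair-cell survival and nuclear position in confocal whole-mount
stacks, auditory brainstem responses (ABR) and distortion-product
otoacoustic emissions (DPOAE), and auditory behavior (cued fear
conditioning, open field). This vignette documents the models and
procedures, the parameters that matter, and the design choices made where
the method definition left room.

## The synthetic-data generator

Every analysis stage is validated against data with known ground truth.
`sim_cochlea_stack()` renders a whole-mount specimen: one row of inner
hair cells (IHC) and three rows of outer hair cells (OHC) along a planar,
gently bowed cochlear axis, imaged in four channels (DAPI, myosin-VIIa,
GFP, FLAG) on an anisotropic voxel grid (default 0.5 x 0.5 x 1 um).

The key construction is the **cell arc**. Each cell is laid out along a
circular arc of radius 40 um in the plane spanned by the stack depth axis
and the local lateral direction, starting at the cuticular plate (the
apical landmark) and ending at the basal end 15 um of arc length later.
The nucleus centre is placed *on that arc* at a programmed arc distance
from the apical landmark. Because the three landmarks lie on a known
circle, the true arc distance is available by construction without
running any fitting code — the morphometry stage can therefore be
validated end to end: its circumcircle must reproduce the generator's
circle, and on noiseless renders the re-measured arc distances agree with
truth to well under one voxel diagonal.

Genotype enters in two ways:

* **Nuclear mispositioning.** Under `KO`, OHC nuclei shift apically
  (toward the cuticular plate) by `nucleus_offset_effect` um plus
  per-cell Gaussian jitter (`nucleus_jitter_sd`, default 0.4 um).
  Whole-mount descriptions of the mispositioning are qualitative; no
  effect size in micrometres is established, so the default of 3 um —
  about one nuclear radius — is a package choice, not a literature
  value. `KO_treated`
  reverses a `treated_rescue` fraction (default 0.9) of the shift.
* **OHC loss.** Under `KO`, each OHC survives with probability
  `survival_base + survival_slope * (position/L - 0.5)`. The default
  slope is negative (stronger loss toward the base), consistent with the
  high-frequency-dominant hearing loss of this disease model; the slope
  is signed and configurable because whole-mount descriptions of
  apex-to-base gradients are easy to read in either direction. IHCs
  always survive, matching the disease phenotype.

Nuclei are soft-edged ellipsoids (sigmoidal falloff) with a brighter
Gaussian rim at the boundary emulating perinuclear heterochromatin; the
rim is what makes "the periphery of the nucleus, defined by maximal DAPI
fluorescence" a well-defined landmark for envelope profiles. The
myosin-VIIa cell body is a chain of soft spheres stamped along the cell
arc with centres inset by one body radius, so the half-maximum edge of
the myosin signal falls exactly at the apical and basal landmarks — the
property the landmark extractor relies on. GFP fills the nucleus with a
per-cell intensity drawn from the transduced ("on", mean 150 a.u.) or
untransduced ("off", mean 30 a.u.) distribution; FLAG is rendered as a
Gaussian shell at the nuclear boundary of transduced cells. Additive
Gaussian noise (default SD 5 a.u. against a nuclear amplitude of 100,
i.e. SNR 20) is applied to all channels.

What the generator does **not** emulate: optical point-spread functions,
depth-dependent attenuation, photobleaching, touching nuclei in dense
epithelium, non-hair-cell DAPI signal (supporting cells), or the true 3D
spiral of the cochlea (the axis is a planar curve). Passing tests
therefore demonstrate correctness of the measurement pipeline, not
robustness to every artefact of real confocal data.

ABR series are simulated as averaged traces: below the true threshold,
pure Gaussian noise with SD `noise_sd / sqrt(n_sweeps)` (single-sweep SD
2 uV, 512 sweeps, the standard averaging count); at and above threshold,
a P1/N1 complex whose P1 amplitude grows linearly (0.04 uV/dB above
threshold, 0.5 uV at threshold) and whose latency shortens (8 us/dB).
Two interleaved half averages are emitted alongside the full average so
reproducibility-based detection criteria can be exercised. DPOAE spectra
carry the two primaries at `f2/1.2` and `f2`, a flat noise floor with
2 dB per-bin jitter, and a 2f1-f2 component that rises 10 dB above the
floor at threshold and grows 1 dB/dB beyond it. Behavior traces render
programmed freeze bouts (activity exactly 0) into an activity channel
that is otherwise ~0.2, with bout edges snapped to the frame grid so the
truth bout table matches the rendered channel exactly; "hearing" animals
freeze after the day-2 tone onset, "deaf" animals freeze the same total
time at uniformly random times.

## Nucleus segmentation and cell classification

Segmentation follows the classical automatic-thresholding-plus-watershed
recipe in 3D: Otsu's threshold on the DAPI histogram (256 bins) defines
the foreground; the exact Euclidean distance transform (separable
parabola algorithm, anisotropic voxel spacing) is computed on the mask;
its regional maxima (26-connectivity, plateaus merged, maxima below
`min_seed_radius` = 1 um suppressed) seed a marker-based watershed that
floods the mask in order of decreasing distance, splitting touching
nuclei at distance ridges. Regions below `min_volume` (20 um^3, about a
tenth of a hair-cell nucleus) are discarded. Labels are renumbered in
raster-scan order of first occurrence, so segmentation is deterministic.
These 3D primitives are implemented in compiled code under `src/`.

Row classification fits a principal axis through the nucleus centroids,
a smoothing spline for the mid-curve of the cell band, and clusters the
signed lateral offsets from that curve by splitting at gaps wider than
`min_gap` (4 um, half the row spacing). Up to four row groups are
accepted. The IHC row is the extreme group with the larger mean nuclear
volume — IHC somata and nuclei are larger than OHC ones — and a lone row
is typed IHC. OHC rows are numbered 1-3 by distance from the IHC row.
Segments equidistant from two row centres are assigned to the lower row
index and flagged `ambiguous` rather than dropped. This automated row
model replaces the manual cell identification used in practice and is
validated only against synthetic geometry; on real data a curator should
review flagged cells.

Apical and basal landmarks are read from the myosin channel: within a
4.5 um cylinder around each nucleus, the z-extent of the above-half-max
myosin profile gives the apical (top) and basal (bottom) planes, and the
landmark xy is the myosin intensity centroid of that plane.

## Transduction quantification

Per-cell intensity is the mean GFP over the nucleus mask. Against an
un-injected control specimen imaged with the same settings,
`control_stats()` gives the per-cell-type mean `mu_c` and SD `sigma_c`;
a cell is **positive** when `I > mu_c + 2 sigma_c`, and its
**normalized intensity** is `(I - mu_c) / mu_c` — background subtraction
and expression in units of the control mean in one step, which keeps
plots interpretable ("2.5" means 2.5 control means above background).
The cutoff is computed per cell type by default because IHC and OHC
baseline fluorescence differs; a pooled cutoff is available
(`pooled = TRUE`). Positivity is invariant under a global acquisition
gain applied to both specimens, which the test suite asserts.

Envelope profiles cast a radial line outward from the nucleus centroid,
centre it at the maximal DAPI position along the line (the nuclear
periphery), sample both channels on +/- `half_width` um around that
centre, and normalize each channel by its own maximum on the line.

## Arc morphometry

`fit_arc()` scales the three landmarks to micrometres, then computes the
circumcircle of the triangle in its own plane. Arc lengths are measured
along the arc from apical to basal *that passes through the nucleus* —
the three-point construction forces that choice of arc. Nuclear position
is reported as the arc length from the apical landmark ("distance from
the cuticular plate") and as the fraction of the total apical-to-basal
arc. Collinear triples — triangle area below `1e-9 |AB|^2`, a scale-free
tolerance that prevents the circumradius from blowing up — fall back to
straight segments. Rigid-motion invariance and agreement with numerical
quadrature of the fitted circle (to 1e-9 relative) are asserted by the
test suite on random landmark triples.

## Cochleogram and the place-frequency map

Detections are projected to the nearest point of the axis polyline
(perpendicular foot or vertex; exact ties toward the smaller arc length)
and counted in contiguous 100 um bins from the apex. The final partial
bin is kept and its density rescaled by `bin_width / actual width`, so
apical and basal extremes are not silently lost; detections projecting
beyond the polyline ends land in the terminal bins and are counted in
`n_flagged`.

The place-frequency transform is the published mouse map,
`percent from base = 156.5 - 82.5 log10(f/kHz)`, with percent converted
to mm from the apex using the organ-of-Corti length `L`. `L` defaults to
5.13 mm — the organ length underlying the published map — because that
value reproduces the conventional 12 kHz scoring window at
1.63-1.69 mm from the apex; it is configurable for specimens measured at
other lengths. `region_density()` exposes the scoring-window width as a
parameter (default 0.06 mm) since counting bins (100 um) and scoring
windows (60 um) legitimately differ: the window is a place-map band, the
bins are a survival map.

## ABR and DPOAE feature extraction

**Response detection.** A trace is a response when the peak-to-peak
amplitude in the response window exceeds `k` times the residual noise
SD. The noise SD comes from the difference of the two interleaved half
averages when available — the "plus-minus" estimate standard in evoked
potentials, which cancels stimulus-locked signal over the whole record —
and otherwise from the pre-stimulus baseline. `k` defaults to 6, not the
4 often quoted for SD-based criteria: the expected peak-to-peak of pure
noise across an ~80-sample response window is already about 5 SD, so
k = 4 fires on noise alone regardless of recording quality, while k = 6
holds the per-trace false-positive rate at a few percent and costs no
sensitivity at realistic averaged-trace SNR. A split-half
cross-correlation criterion (`method = "xcorr"`) is available as an
alternative operationalisation of "reproducible waveform".

**Thresholds.** The ABR threshold is the lowest intensity detected at
itself and at every higher intensity; the monotone rule makes a single
false positive below threshold harmless. When nothing is detected the
threshold is censored and encoded as grid maximum plus one step (95 dB
SPL for the 10-90/5 grid) with an explicit `censored` flag — the
encoding keeps group means computable, the flag keeps the censoring
honest. DPOAE thresholds follow the same rule over stimulus levels.

**P1/N1 features.** P1 is the first local maximum after stimulus onset
in the search window, N1 the first local minimum after P1. On noisy
averages "first local maximum" would otherwise be won by the first noise
ripple, so candidate peaks are located on a lightly Gaussian-smoothed
copy (SD 0.25 ms, about the P1 width; only maxima reaching 40% of the
window maximum qualify) and the reported latency and amplitudes are then
read from the raw trace at the local extremum nearest the candidate —
clean traces are therefore measured exactly.

**DPOAE.** The distortion product is read at the bin nearest
`2 f1 - f2`; the noise floor is the mean of 5 bins per side, skipping 2
guard bins adjacent to the DP bin and any primary-tone bins; detection
requires the DP to exceed the floor by 6 dB. The 6 dB criterion is a field
convention rather than a universal constant, and is exposed in the
interface.

## Behavior

Activity is the fraction of pixels changing by more than a threshold
between consecutive frames (first frame 0 by convention). Freezing is a
maximal run of activity below `theta` lasting at least `min_duration`;
the defaults (`theta` = 0.01, `min_duration` = 1 s) are explicit
stand-ins — freezing thresholds are conventionally calibrated by manual
video inspection per rig, and no portable number exists — and both are
exposed
everywhere they are used. Bouts crossing an analysis-bin boundary
contribute their overlap to each bin. The day-2 fear-conditioning
summary reports mean activity and cumulative freezing in the pre-tone
(90-150 s) and post-tone (150-210 s) bins, the edge being the tone
onset.

Open-field analysis runs on the 300-900 s window (the first five minutes
are adaptation). Rotations accumulate the signed angle of the
centre-to-nose vector, counting one rotation per full 360 degrees,
clockwise and counterclockwise separately; the accumulator resets after
each counted rotation and on direction reversal, so partial rotations do
not carry across reversals — which also makes the count invariant to
temporal resampling. Distance is the summed centre displacement in cm;
centre time is the time spent inside the central square (0.4 m^2 of the
2.5 m^2 arena by default). Without a nose track, rotations are `NA` and
the other metrics are still computed.

## Statistics

The study-level tests are Pearson correlation with two-tailed p (via
`cor.test`), balanced two-way fixed-effects ANOVA with interaction (via
`aov`; unbalanced designs are rejected since the classical decomposition
is not unique there, and the per-frequency group designs this package
targets are balanced), paired before/after contrasts (paired t via `t.test`), and
Holm-Sidak step-down adjusted p-values, implemented directly —
`adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1)` down the sorted list with
monotone enforcement and a cap at 1 — because base R's `p.adjust` offers
Holm (step-down Bonferroni) but not the Sidak variant. All p-values are
two-tailed. Degenerate inputs are flagged, not silently numeric:
all-equal ANOVA responses report F = 0 with a `degenerate` flag,
zero-variance paired differences return `NA` p with a flag (identical
before/after returns t = 0, p = 1).

## Pipeline and reproducibility

`run_pipeline()` executes
simulate → segment → classify → morphometry → cochleogram
(→ transduction) → stats from one YAML or list config, echoes every
stage's parameters (no silent defaults), and writes CSVs with fixed
column order and 6-significant-digit floats so identical runs are
byte-identical; the JSON manifest records the seed, package version,
stage parameters, and an MD5 per output. Every generator draws from one
seeded RNG per call and restores the caller's RNG state.

## Problem sizes used by the test suite

The suite validates at deliberately modest scale, chosen as the smallest
sizes at which each property is meaningfully exercised: specimens of
8-17 cells per row (up to ~200 um of cochlea, ~1-2 million voxels);
parameter recovery of the 3 um OHC shift over 5 seed pairs of KO/WT
specimens with ~50 OHC per group at SNR 20; ABR threshold recovery over
100 simulated series; DPOAE false positives over 200 pure-noise spectra;
ANOVA type-I behaviour over 1000 null simulations; a 100,000-permutation
null for the Pearson p. Full-cochlea stacks (5+ mm) are out of testing
scope but differ only in extent, not in any algorithmic parameter.

## Known limitations

* The row model and landmark extractor assume a roughly planar,
  well-separated 4-row geometry; severely degenerated or dissection-
  damaged specimens will need manual landmarks (which `measure_nuclei()`
  accepts directly as a table).
* The segmentation has no shape prior: debris above threshold larger
  than `min_volume` becomes a segment and must be filtered by the row
  classifier's flags or by volume.
* Censored thresholds are placed one step above the grid; group means
  including censored animals are therefore lower bounds, and downstream
  statistics should check the `censored` flag.
* The behavioral freezing threshold is rig-specific; the defaults here
  are calibrated to the synthetic activity scale, not to any particular
  tracking system.
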