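---
title: "Localizing auditory and visual thalamus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing auditory and visual thalamus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalamloc)
```

# The problem

The medial geniculate nucleus (MGN, auditory relay) and lateral geniculate
nucleus (LGN, visual relay) are small subcortical structures — a few dozen
2 mm voxels each — whose position varies across individuals enough that
atlas- or segmentation-based masks are unreliable for individual-level
connectivity analyses. `thalamloc` implements a functional-localizer
pipeline that finds each participant's MGN and LGN from a short
clustered-sparse fMRI task, and validates the resulting functional ROIs
(fROIs) with resting-state functional connectivity (RSFC).

The pipeline's logic is: alternating auditory and visual stimulation drives
both the sensory cortices and their thalamic relays; a voxel that coactivates
with auditory cortex (AC) but not visual cortex (VC) over the task — assessed
by partial correlation against cortical reference time series, not merely by
a task contrast — is auditory thalamus, and conversely for visual thalamus.

# The task and its schedule

Scanner noise masks auditory stimuli, so the task uses clustered-sparse
temporal acquisition: each 12 s trial is silence (`gap`), 9 s of stimulation,
silence (`gap`), then a cluster of 3 BOLD volumes acquired back-to-back.
The gap is calibrated so the trial lasts exactly 12 s:

$$\mathrm{gap} = \tfrac{1}{2}\left(T_{trial} - T_{stim} - n_{cluster}\,TR\right)$$

giving 225 ms at TR = 850 ms and 300 ms at TR = 800 ms, the two site
configurations shipped as presets (`site_config("nyspi")`,
`site_config("sbu")`). A run is one fixation trial followed by 8 auditory
and 8 visual trials in seeded pseudorandom order. The published design says
only "pseudorandom"; we additionally cap same-condition runs at 3
(`max_consecutive`, configurable) so a run cannot degenerate into a block
design. Auditory trials are nine 900 ms music segments each followed by
100 ms silence, sampled without replacement within a trial and
amplitude-normalized to the pool's grand mean absolute amplitude.

The fixation trial is followed by an acquisition cluster exactly like
stimulus trials (the acquisition grid is uniform); its volumes simply carry
zero in both task indicator columns.

# Task GLM on sparse samples

Because acquisition is not continuous there is no meaningful hemodynamic
convolution; task regressors are unconvolved indicators covering the whole
cluster after each trial. The per-run design is: intercept, auditory,
visual, 6 motion parameters and their squares, WM and CSF compartment
signals, and indicators for the 2nd and 3rd volume of each cluster — the
latter absorb T1-relaxation offsets, since clustered sampling never reaches
steady state. Volume 1 of each cluster is the reference level, so T1
offsets load on the intercept and on the volume-2/3 betas and leave the
Auditory − Visual contrast untouched (verified to 1e−8 in the tests).

Design choices here:

* Runs are fit independently and contrasts averaged. The block-diagonal
  joint system decomposes exactly into per-run fits (property-tested), so
  nothing is lost.
* Nuisance columns are mean-centered and unit-scaled per run. Centering
  keeps the intercept interpretable as baseline; scaling is purely
  numerical — motion traces and their squares can differ by six orders of
  magnitude and make the cross-product matrix ill-conditioned without
  affecting the task betas.
* Constant nuisance columns (e.g. all-zero motion) are dropped with a
  warning rather than tolerated into rank deficiency.

WM/CSF compartment signals come from unsmoothed data as the mean over the
compartment mask after iterative erosion: up to three 6-connected erosions,
stopping before an erosion that would leave fewer than two voxels.

# Cortical references and thalamic search regions

AC/VC reference series: per hemisphere, the Auditory − Visual contrast is
rank-thresholded inside a search mask (BA 41/42 union for AC, BA 17/18 for
VC, each dilated once) to its top (AC) or bottom (VC) 10 %; components
smaller than 10 voxels are discarded; the surviving component containing
the greatest-magnitude peak is the reference cluster. The reference series
is the spatial mean per hemisphere, averaged across hemispheres, from
smoothed data. Rank thresholding keeps exactly `ceil(0.10 N)` voxels with
boundary ties included — unambiguous under ties, and never below the
nominal count.

Thalamic search regions (TSRs) start from segmentation-style seed labels:
the MGN seed dilated 3 times, the LGN seed once (LGN segmentation priors
are larger). An exclusion union is removed — cortical gray matter,
parahippocampal WM and hippocampus as-is; mediodorsal nucleus, insular WM,
choroid plexus, pulvinar, putamen and pallidum each dilated once. Then the
two posterior-most slices *of the TSR itself* are deleted, and MGN-TSR
voxels strictly superior to the inferior-most bilateral pulvinar slice are
deleted. We interpret "posterior-most two slices" per-TSR rather than as
global image slices (a global reading would usually delete nothing), and
"superior to" strictly (the boundary slice is kept). All morphology is
26-connected by default and configurable; compartment erosion uses the
6-connected cross.

# Coactivation mapping and fROI extraction

Within each TSR, every voxel's smoothed task series (runs concatenated) is
partially correlated with the AC and the VC reference series, controlling:
WM, CSF, global gray matter (cortical GM eroded once) and TSR-local WM
signals from unsmoothed data, cluster-volume-2/3 indicators, and per-run
intercepts (needed because concatenated runs have different baselines — the
published per-run formulation makes this implicit). Local WM is the mean
over WM voxels between one and five 26-neighbor dilation steps from the TSR.

Each coactivation map is thresholded to its top `ceil(f N)` voxels, with
`f = 32 / mean MGN-TSR size` or `20 / mean LGN-TSR size` (averaged across
hemispheres; the constants are exposed, not hard-coded, since they were
chosen in the source analysis only to yield reasonably sized fROIs).
Voxels surviving in both the AC and VC maps of a TSR are removed from both;
the largest remaining 26-connected component of the AC map (MGN) or VC map
(LGN) is the fROI. Ties are resolved by peak coactivation, then smallest
linear index — determinism over elegance.

QC flags replace the published manual review with explicit heuristics: an
LGN centroid inferior to, or more medial than, the same hemisphere's MGN
centroid, and a size asymmetry `|ln(size_L/size_R)| > ln 3`. Flags are
advisory; exclusion is the caller's decision.

# Volume censoring

Resting-state runs are censored by three criteria combined as a union:

* **LPF-FD**: each motion parameter is low-pass filtered (zero-phase
  order-2 Butterworth, 0.2 Hz), rotations converted to arc length on a
  50 mm sphere, and framewise displacement computed as the sum of absolute
  backward differences; volumes with FD > Φ_F = 0.07587 mm are censored.
* **GEV-DV**: DV is the RMS over brain voxels of the backward difference of
  low-pass-filtered voxel series; a generalized extreme value distribution
  is fit to the run's DV values by maximum likelihood, and the run-wise
  threshold is `location + d_G · scale` with d_G = 3.105. The exact
  low-pass cutoff and threshold functional form are defined in the
  censoring-optimization literature rather than in the source analysis;
  both are explicit parameters here so they can be aligned exactly. On fit
  failure the threshold falls back to `median + d_G · IQR` with a warning.
  For large brains the RMS is computed over a deterministic stride
  subsample of up to 10 000 voxels; the RMS of several thousand i.i.d.-noise
  voxels estimates the brain-wide value to well under a percent.
* **Eye closure**: closures strictly longer than 3 s censor their volumes;
  volumes between two such closures less than 30 s apart are censored too.
  The 30 s rule applies only between closures that themselves exceed 3 s —
  ordinary blinks do not chain.

Contiguous kept segments shorter than 8 s are discarded (a segment of
exactly 8 s survives); runs need ≥ 90 s retained, participants ≥ 2 valid
runs and ≥ 300 s total. First-volume FD and DV are defined as 0 (backward
differences, length-preserving).

Worth knowing: with d_G = 3.105 the GEV threshold censors roughly the top
4–5 % of DV values even in artifact-free synthetic data — the exceedance
probability of a Gumbel-like fit at `loc + 3.105·scale` is about e^(−3.105).
That is a property of the published study-wide parameter, not a bug, and
the phantom tests account for it.

# Resting-state post-processing and connectivity

Rest runs are mode-1000 normalized (modal in-brain intensity after integer
rounding, first value on count ties), linearly detrended, censored points
linearly interpolated, band-pass filtered (0.009–0.08 Hz, order-2
zero-phase Butterworth), interpolated points re-censored, and
`ceil(22 s / TR)` volumes trimmed from each end (26 volumes at TR 0.85 s,
28 at 0.80 s). All of these operations are linear and voxelwise-identical,
so the processed mean series of an ROI equals the processed ROI-mean
series; ROI analyses therefore extract spatial means first, which is why
the package can afford a phantom with full-length runs on a laptop.

Connectivity per pair (MGN–AC, MGN–VC, LGN–AC, LGN–VC) is the mean of the
four hemispheric partial correlations (L–L, L–R, R–L, R–R), controlling
band-passed motion parameters, their squares, their backward derivatives,
the squares of the derivatives, and WM and CSF signals with their
derivatives. Run values are averaged as plain r (a Fisher-z switch exists
but is off by default, since the source procedure states an unweighted
average), and runs failing retention are excluded. Selectivity contrasts
(MGN-AC > MGN-VC, MGN-AC > LGN-AC, LGN-VC > LGN-AC, LGN-VC > MGN-VC) are
one-tailed one-sample t-tests with Benjamini–Hochberg correction across
the four tests. Benchmarking against alternative ROI sets takes
within-participant differences of MGN-AC and LGN-VC and applies two-tailed
t-tests; zero-variance differences (identical ROI sets) report the mean
difference with no test statistic. Seed maps residualize every brain voxel
against the same nuisance set, average run maps, then average the L/R seed
maps.

The hand-rolled Butterworth design and forward–backward filtering (no DSP
package is available in the target environment) reproduce the standard
design to 10 significant digits against an independent reference
implementation, which the tests freeze as coefficients.

# The phantom: a stated world

Every stage is testable without scanner data through a synthetic phantom:
a 40×48×36 voxel grid at 2 mm with an ellipsoidal brain (~27 000 voxels)
containing all labels the pipeline needs. Its stated conditions:

* **Geometry.** Truth MGN (20 voxels/hemisphere) and LGN (30) implanted in
  posterior thalamus with the LGN superior and lateral to the MGN, so
  correct extraction raises no QC flag. Segmentation-style seeds are the
  truth masks shifted one voxel posterior (`seed_jitter_vox`, 0 disables).
  The direction is fixed rather than random for a structural reason: the
  LGN search region is the seed dilated once, and the posterior-slice trim
  always removes the TSR's own two posterior slices — only a posterior seed
  offset leaves the full truth mask inside the final search region. A
  zero-jitter phantom loses the truth LGN's posterior slice from its TSR;
  the tests document this.
* **Task signal.** `voxel = 1000·(1 + a·c(t) + t1(pos)) + drift + ε` with
  a = 2 % for condition-matched structures (truth MGN and auditory cortex
  on auditory trials; truth LGN and visual cortex on visual trials),
  T1-relaxation offsets (5 %, 2 %, 0) on cluster volumes 1–3, a shared
  0.3 % slow sinusoidal drift, and white noise σ = 10 (temporal SNR 100 at
  baseline 1000 — ordinary 3 T EPI territory). No hemodynamic convolution,
  matching the unconvolved design. The published work reports no
  geniculate effect sizes, so the 2 % amplitude is this package's
  documented placeholder, exposed in `phantom_config()`.
* **Rest signal.** Band-limited (0.009–0.08 Hz, the same filter as the
  analysis, so recovery tests are not confounded by pass-band mismatch)
  unit-variance latent sources per structure, amplitude 10. Truth MGN mixes
  the AC source at `r = 0.4` (`r·s_AC + √(1−r²)·s_MGN`), truth LGN the VC
  source likewise; crossed couplings are zero. A global source (amplitude
  3) enters all brain voxels, WM- and CSF-specific sources (amplitude 4)
  their compartments, white noise σ = 5 on top. Baseline 1000 makes
  mode-1000 normalization a near-identity perturbation, i.e. testable.
* **Motion and eyes.** Slow sinusoidal drift (0.01 mm / 0.0002 rad) plus
  realignment-like jitter at one fifth of that amplitude — the jitter is
  what keeps the six traces and their squares linearly independent in the
  GLM, as real realignment output is — and Poisson-placed 0.5 mm
  single-volume spikes (2/min) whose filtered FD exceeds Φ_F only near the
  spikes. Eye closures (0.4/min) draw durations from {1.5, 2, 4, 6} s,
  spanning the 3 s boundary.

Rest runs can be generated in `"flat"` storage (brain-voxels × time matrix
with the mask attached) instead of a full 4D array; the two are verified
identical through every mask-based analysis, and flat storage is several
times cheaper. Phantoms are byte-reproducible from `(config, seed)` and the
generators restore the session RNG state.

What the phantom does **not** emulate: hemodynamic shape and latency,
spatial autocorrelation of physiological noise, spin-history or distortion
artifacts, heavy-tailed motion, site differences beyond TR, or any
anatomical variability. A green recovery test therefore establishes that
the analysis chain is correct under its own assumptions — not that it is
robust to everything real data does.

# Numerical conventions

* Coordinates are voxel indices, x/y/z with x left→right, y
  posterior→anterior, z inferior→superior; "posterior-most" = smallest y.
  The NIfTI reader/writer (hand-rolled, as no NIfTI package is available in
  the target environment) treats orientation as a data contract and does
  not resample; mixed grids are refused outright.
* Rank thresholds use `ceil` and include boundary ties.
* The Gaussian smoothing kernel is discretely normalized (interior mass
  conserved exactly), truncated at 4σ, and applied separably per volume,
  never across time.
* GEV fitting maximizes the likelihood over (location, log scale, shape)
  by Nelder–Mead from a Gumbel moment start.
* Degenerate voxels or references in partial correlation (residual norm
  below 1e−8 of the centered-signal norm) are excluded (voxels, with a
  warning) or rejected (references, as an error).

# Scaling choices in the test suite

The acceptance-style tests run the full stated world: 20 phantom
participants for fROI recovery (median Dice ≥ 0.7 against truth for both
nuclei) and 20 participants × 4 rest runs at r = 0.4 for connectivity
recovery. The monotonicity sweep across r ∈ {0, 0.2, 0.6} uses 2 rest runs
per participant instead of 4 purely for runtime; this halves per-level
information but does not bias the estimator, and the spacing of the levels
(0.2 in r against standard errors near 0.02) leaves the ordering
unambiguous.

# Known limitations

* Multi-site harmonization, permutation inference and covariate imputation
  are out of scope; the connectivity table carries a `site` column as the
  adapter point.
* The censoring low-pass cutoff (0.2 Hz) and GEV threshold form are
  best-effort reconstructions of parameters defined in external tooling;
  both are configurable where an exact alignment is needed.
* Whether the original analyses entered WM/CSF regressors raw or centered,
  and whether audio segments were sampled without replacement across (not
  just within) trials, is unstated in the source; this package centers
  nuisance columns and samples without replacement within trials only.
* The published run length (3 min 46 s) exceeds 17 × 12 s by 22 s of
  unexplained acquisition (likely lead-in); the schedule reports 204 s of
  trial time and leaves run padding to the caller rather than guessing.
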