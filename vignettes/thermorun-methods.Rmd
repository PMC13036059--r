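---
title: "Models and methods behind thermorun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermorun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermorun)
```

## The measurement problem

Infrared thermography of the posterior lower legs during treadmill running
captures, at video rate, the skin-temperature signature of exercise
thermoregulation: sympathetic vasoconstriction cools the skin within minutes
of exercise onset, stored metabolic heat slowly warms it back, and the
release of vasoconstriction after exercise produces a rapid rebound.
Superficial veins and cutaneous perforator vessels appear as warm
curvilinear and punctate patterns against the surrounding tissue, and their
temperatures track external load more tightly than the bulk skin mean.

`thermorun` implements the analysis side of such an experiment: from
calibrated radiometric frames and a four-class segmentation to synchronized,
stage-aggregated series of four skin-temperature metrics (`T_MEAN`, `T_NV`,
`T_V`, `T_P`) with Shannon entropies, and on to the reliability statistics
(intraclass correlations, repeated-measures correlations) that quantify
whether those series are reproducible across repeated sessions.

Because raw recordings from such studies are generally not redistributable,
the package also contains a first-class synthetic-session generator. It is
not a rendering toy: every downstream stage is tested against the
generator's pixel-level and series-level ground truth.

## Session protocols

`build_protocol()` encodes three 49-min sessions sharing a 10-min warm-up at
60% of the velocity at the individual anaerobic threshold (vIAT), a 36-min
main block, and a 3-min walking recovery at 4 km/h, on a 1.5% incline:

* **T1** — main block fully continuous at 85% vIAT;
* **T2** — 18 min continuous (85%) then 18 min intermittent: three cycles of
  3 min at 105% alternating with 3 min at 65%;
* **T3** — the same blocks in reverse order.

The intermittent block averages (105 + 65)/2 = 85%, so all three sessions
impose the same mean external load — the property that makes their
comparison a pure test of load *sequencing*. Analysis phases are the
warm-up (WU), the two 18-min halves of the main block (FH, SH), and the
recovery (REC). Around every commanded velocity change, samples inside a
treadmill ramp (1 (km/h)/s plus a 2 s margin) are excluded from stage
aggregates; the sample at exactly the change time belongs to the ramp.

## The physiological forward model

`simulate_physiology()` drives everything with a small set of first-order
states responding to the commanded load \(u(t)\) in % vIAT:

* heart rate and VO2 relax toward load-proportional targets
  (\(\tau_{HR} = 30\) s, \(\tau_{VO_2} = 40\) s);
* core temperature relaxes (\(\tau_{core} = 1200\) s) toward a target set by
  a *low-pass-filtered* load (\(\tau_{load} = 600\) s, the thermal inertia
  of heat production). The double filter is what keeps the core rise
  continuous through 3-min intermittent bouts — with a direct load drive the
  core would visibly dip in each 65% bout, which is not what gastrointestinal
  pill measurements show at these timescales;
* a fast vasoconstriction state (\(\tau_{fast} = 45\) s) cools the skin in
  proportion to relative load;
* a rebound state (\(\tau_{rebound} = 90\) s) activates once the load falls
  below 40% vIAT after running and adds the post-exercise warm-up;
* non-vessel skin temperature combines them:
  \(T_{NV}(t) = T_{NV,0} - a\,x_{fast}(t) + g\,(T_{core}(t) - T_{core,0})
  + r\,x_{reb}(t)\),
  with \(a = 2.1\) °C, \(g = 2.8\) (an effective, lumped gain — it absorbs
  perfusion as well as storage pathways), \(r = 0.35\) °C.

Vessel metrics are constant offsets above the non-vessel tissue
(veins +1.2 °C, perforators +0.8 °C), which enforces the observed ordering
`T_V > T_P > T_MEAN > T_NV` at every time point by construction.

**Integration.** The load is piecewise constant, so each state has a
closed-form update per step (`x ← target + (x − target)·e^{−dt/τ}`). We use
that exact exponential stepping rather than an Euler scheme: it is equally
simple and makes noise-free simulated step responses match the analytic
solution to machine precision, which the test suite exploits as an oracle.

**Calibration.** Defaults were chosen once so that the standard protocols
reproduce the magnitudes reported for this kind of experiment: an early
warm-up `T_NV` drop inside [−1.3, −1.1] °C, a residual deficit at warm-up
end, and a mean post-continuous-exercise 3-min rebound of about +1.4 °C
(within [1.1, 1.8] °C across the four metrics). The test suite asserts those
windows; the acceptance script recomputes the values.

**Inter-individual structure.** `participant_params()` adds a deterministic
fitness link (vasoconstriction amplitude increasing with vIAT, +4% per km/h
around the cohort mean of 12.2) plus seeded log-normal jitter (6% SD) on
amplitudes and Gaussian jitter on baselines, so cohort analyses have
realistic between-subject variance.

## The thermogram renderer

Frames are composed per gait-phase bin (8 bins per cycle): two elliptical
calves on the ambient background at the instantaneous `T_NV`, veins painted
along smooth curvilinear centerlines, perforators as compact discs. During
the swing arc (phase in (π/2, 3π/2)) the calf area shrinks by up to 35% and
the frame is blurred with a σ = 3 px Gaussian — the motion-blur/occlusion
surrogate that stance-phase selection must reject. Pixel noise is i.i.d.
Gaussian, default σ = 0.05 °C.

Two rendering choices deserve justification:

* **Top-hat vessel cross-sections.** Vessels are painted with a *uniform*
  offset over a footprint of half-width `vessel_profile_sigma` rather than a
  Gaussian profile. With a Gaussian shoulder, the mean over labelled vein
  pixels would sit well below `T_NV + vein_delta` and the shoulder would
  leak into the non-vessel region, making exact ground truth impossible;
  with the top-hat, labelled-region means equal the configured offsets
  exactly, and the oracle tests can assert sub-0.01 °C agreement.
* **Linear composition.** A frame is affine in `T_NV`
  (`ambient + (T_NV − ambient)·body + offsets`), so the blurred swing-frame
  basis fields are precomputed once per phase bin and each of the thousands
  of session frames costs two AXPYs plus noise.

**Scale.** Defaults are desk-scale: 72×96 px at 2 fps with a 0.4 Hz gait so
that a gait cycle spans five frames at the reduced rate; the full camera
geometry (768×1024 at 30 fps, 2.8 Hz cadence) is available through
`scene_config()` and is exercised by short-burst tests. Session-scale tests
and the acceptance script run the complete 49-min timeline (5 880 frames) at
the desk scale.

## Segmentation

The trained networks used for vessel detection in real studies are not
reproducible from public material, so the package fixes the *contract* of
that stage — frame in, 4-label mask out — and ships three interchangeable
implementations: a ground-truth oracle, an external-mask adapter, and a
classical segmenter:

1. **Body**: Otsu threshold on the temperature histogram (or a fixed
   threshold), disc opening, hole filling, keep the up-to-two largest
   components above `min_body_area`.
2. **Vessel enhancement**: multiscale Hessian ridge/blob response (scales
   {1, 2, 3} px, matched to the synthetic vessel width). The background is
   replaced by the within-body median before smoothing and the response is
   zeroed outside an eroded interior, so the 10 °C calf/ambient step cannot
   masquerade as a vessel. The raw scale-normalized response `r` (°C) maps
   onto [0, 1) by the strictly monotone squash `r/(r + 1 °C)`; a per-frame
   max normalization would force structure-free frames to full scale.
3. **Classification**: threshold at the `vessel_quantile` (default 0.75) of
   within-body response; per candidate component, an elongation
   (major/minor moment ratio) of at least 3 makes a vein, otherwise an area
   in [10, 200] px makes a perforator, and anything else merges back into
   non-vessel tissue.

Quality floors asserted by the tests: body Dice ≥ 0.95 noise-free and
≥ 0.85 at default noise; mean vein∪perforator Dice ≥ 0.6 over a 20-scene
battery.

## Frame selection, metrics, fusion

**Stance selection** partitions the timeline into windows of one gait cycle
(`round(fps/step_frequency)` frames) and takes the per-window area maximum,
ties to the earlier frame; selections below half the running median of
selected areas are rejected as occluded.

**Metrics** are region means plus Shannon entropies over a fixed histogram:
0.1 °C bins spanning the 25–35 °C calibration range with two open-ended
overflow bins, log base 2. Entropies are computed on calibrated °C (the
alternative — raw digital numbers — differs only by the fixed linear
calibration, which with matching bins gives identical histograms). Regions
smaller than `min_pixels` (25) yield missing values, which the fusion layer
fills by linear interpolation with nearest-value extension at the edges —
the same rule applied to gappy vein series before filtering. `T_MEAN` is
defined over the whole calf *including* vessel pixels, so it is exactly the
pixel-count-weighted mean of the three regional metrics (asserted to 1e-9)
and sits between `T_NV` and the vessel metrics.

**Filters.** Savitzky–Golay smoothing uses polynomial order 3 (unstated in
most protocols; order 3 is the common default and is exact on cubics). The
canonical window of 151 samples corresponds to ≈ 54 s at a ~2.8 Hz
stance-selection rate, so the pipeline parameterises smoothing in *seconds*
(default 54) and converts to an odd sample count at the actual
selected-frame rate; `savgol_smooth()` itself defaults to 151 samples. The
low-pass Butterworth filter is 3rd order with normalized cutoff 0.04 — the
phrase "0.04 Hz normalized by the Nyquist frequency" is self-contradictory
(Hz versus normalized), and we adopt the conventional signal-API reading,
cutoff = 0.04 × Nyquist. It is applied forward–backward for zero phase,
with odd-extension padding and steady-state initial conditions (without
which the filter shows multi-unit edge transients); a single causal pass is
available by flag. The rolling median (default 350 samples) uses a centered
window truncated at the edges.

## Reliability statistics

`icc()` computes both two-way single-measures forms from the ANOVA mean
squares: consistency ICC(3,1) and absolute agreement ICC(2,1), with the
F-based interval for consistency and the Satterthwaite-df construction for
agreement. Rows with any missing cell are dropped listwise (whole
participant/session exclusions are the practice in this field; no cell-level
imputation). Interpretation bands: < 0.5 poor, 0.5–0.75 moderate, 0.75–0.9
good, > 0.9 excellent (boundaries 0.5 and 0.75 fall into the closed
"between" bands, values strictly above 0.9 are excellent).

`rmcorr()` removes between-subject intercepts by within-subject centering
and correlates the residuals — algebraically the common-slope ANCOVA — with
`df = N − n_subjects − 1` and p from the F statistic. Confidence intervals
come from a *cluster* bootstrap resampling subjects with replacement
(duplicated subjects count as distinct clusters), percentile interval,
2000 replicates by default, fully seeded. Subjects with fewer than two
observations contribute nothing; when none remain, the call errors.

`section_icc_report()` compares the six standard sections (warm-up across
all sessions, the three matched continuous pairs, the intermittent pair,
recovery) with rows = resampled time points and columns = sessions, aligned
on relative time within a block because the continuous and intermittent
blocks sit at different clock times in T2 and T3. The pooled estimate is
the ICC of the per-participant matrices stacked row-wise, reported alongside
the per-participant coefficients.

`median_split()` assigns the median participant to the lower group for odd
cohort sizes and breaks value ties by participant id, so grouping is
deterministic.

## Orchestration and problem sizes

`run_session_analysis()` chains simulate → segment → select → metrics →
fuse → physio → report with stage-attributed errors and a JSON manifest
(stage list, seeds, parameter hash, output checksums); reruns with the same
configuration are bit-identical. `run_reproducibility()` generates the
three-session cohort; by default it uses the generator's truth series plus
frame-level measurement noise (0.02 °C) for the 33 session series — under
oracle masks, rendering adds nothing to the reliability statistics but two
orders of magnitude of compute — while `use_frames = TRUE` runs the full
frame pipeline per session. The single-session parameter-recovery checks do
run the full frame pipeline (5 880 frames) in both noise-free and
default-noise conditions.

## What passing tests do and do not show

The generator reproduces the *statistical* structure of such experiments:
magnitudes and time constants of the skin/core/cardiopulmonary responses,
the metric ordering, gait-driven area oscillation with blurred swing frames,
vessel-like warm patterns, sensor noise, and between-subject variance. It
does not model biomechanics (the gait is a sinusoid), perspective or
occlusion geometry, radiometric atmosphere, perfusion physiology beyond
lumped first-order states, or entropy dynamics of real perforator patterns
(synthetic vessel regions are homogeneous, so their entropies are
noise-dominated and carry no physiological signal). Passing the suite
therefore demonstrates correctness of the *computations* — segmentation
contracts, selection, metric arithmetic, filtering, reliability statistics,
end-to-end recovery of known truth — not validity of any physiological
claim about real athletes.

Known limitations: the classical segmenter is a stand-in with its own
failure modes on low-contrast vessels (its Dice floor is 0.6, far below a
trained network's); vein/perforator discrimination by elongation and area is
a heuristic the field has not standardized; and absolute-agreement ICC
intervals use an approximate df. The `Pre` baseline anchor is the end of the
standing acclimatisation (the 5 s before warm-up onset) and is configurable,
since protocols differ on whether acclimatisation frames enter the baseline.
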