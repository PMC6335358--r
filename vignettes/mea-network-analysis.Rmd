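---
title: "Methods: network activity analysis for MEA and calcium recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network activity analysis for MEA and calcium recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meanet)
```

This vignette is the package's account of its methods: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where the
underlying procedures leave room.

## Recording model and geometry

The electrophysiology side assumes a planar MEA sampling extracellular
voltage at 20 kHz per channel. `mea_geometry()` reproduces the standard
59-channel layout: an 8 × 8 grid at 200 µm pitch with no corner
electrodes and one electrode reserved as internal reference. Channels are
treated as independent point sources; no spike sorting is attempted — in
dense cultures each electrode reports a local cell group, and all
downstream statistics (bursts, connectivity, hubs) are defined at the
electrode level.

The imaging side assumes ROI-averaged fluorescence traces on an 8-bit
scale (0–255) sampled at 4 Hz. ROI selection itself is out of scope: the
pipeline starts at traces.

## Spike detection

Detection runs per channel on the band-pass filtered signal
(`bandpass_filter()`, 300 Hz – 8 kHz). The filter is a 2nd-order
Butterworth applied forward and backward (`signal::filtfilt`), so it is
zero-phase: spike timestamps are not shifted by the filter. The upper
cutoff must stay below Nyquist; with 20-kHz sampling the default band
leaves a comfortable margin.

The noise scale is estimated as `sigma = median(|x|) / 0.6745`. For
Gaussian noise, `median(|x|) = Phi^-1(0.75) * sd(x)`, and
`Phi^-1(0.75) = 0.6745` to four decimals, so `sigma` is a consistent
estimator of the noise SD. Its virtue over the raw SD is robustness:
spikes occupy a small fraction of samples, and the median of the absolute
signal barely moves when they are added (the test suite checks < 5%
deviation at 1% contamination). The threshold is `T = N_s * sigma` with
`N_s = 4` by default; detection uses the magnitude `|x| > T`, so both
polarities are caught. Within each suprathreshold excursion the
extremal-magnitude sample provides the spike time (0-based sample
indexing, seconds), and crossings within the 1-ms refractory interval of
an accepted spike are suppressed.

Two practical notes. First, `sigma` is estimated per channel; electrode
noise differs across the array, and a global estimate would over- or
under-threshold individual channels. Second, a 4-SD threshold on
band-limited Gaussian noise has an irreducible crossing rate of roughly
one event per channel-second (Rice's formula with ~8 kHz effective
bandwidth). Precision figures for the detector are therefore meaningful
at burst-like firing rates, where true spikes dominate the count; at
sparse basal rates the residual noise crossings dominate any detector
operating at this threshold. The chosen coefficient guarantees reliable
detection of spikes above ~20 µV on ~5 µV noise, not a zero false-positive
rate.

## Network bursts

`compute_tsr()` counts spikes from all electrodes in half-open 50-ms bins
aligned to t = 0; the bin sum always equals the raster spike count. Burst
detection thresholds the raw TSR at `T_burst = 0.1 * sd(TSR)`; the SD is
taken over the whole series, bursts included and without mean
subtraction. The coefficient 0.1 is empirical — at realistic activity
levels the TSR SD is dominated by the bursts themselves, so one tenth of
it sits comfortably above the basal bin counts while still catching burst
flanks.

Suprathreshold runs separated by at most `gap_bins = 1` subthreshold bin
are merged, so a single quiet bin inside one population event does not
split it. Candidates must then show at least 4 spikes on at least 4
distinct electrodes in their peak 50-ms bin — the classical definition of
a network burst, applied where the event is strongest. Size classes
follow the peak-bin count: 4–100 spikes *small*, ≥ 101 *large*.

Burst bounds are refined, by default, to the first and last spike inside
the suprathreshold run (`refine = TRUE`). The alternative — outer bin
edges — quantizes every duration to the 50-ms grid and can misstate a
sub-second burst's duration by up to one bin per side, i.e. by more than
10% for bursts shorter than a second, which would defeat duration
validation. Bin-edge bounds remain available via `refine = FALSE`.

## Delayed-synchrony connectivity and hubs

The coefficient `C_ij = n_synchr,ij / n_j` counts the spikes of the
putative postsynaptic channel j that fall within ±δ/2 of some spike of i
shifted by the conduction delay `tau_ij = d_ij / v`; each j-spike counts
at most once, so `C_ij` is a fraction in [0, 1]. The implementation uses
a sorted-search per pair and is checked in the tests against an
exhaustive O(n_i × n_j) pair-scan oracle.

Two constants are not dictated by the method and are exposed as
parameters: the tolerance δ (default 2 ms — twice the refractory
interval, tight enough that background coincidences at basal rates stay
rare) and the conduction velocity v (default 300 µm/ms, a typical
unmyelinated-axon scale in culture; delays across the array are then
0.7–6.6 ms). Channels with no spikes get `C_ij = 0` and are flagged
rather than erroring.

The functional graph retains the largest 5% of coefficients over all
n(n−1) ordered pairs — exactly `floor(0.05 * n * (n-1))` edges (171 for
59 electrodes), with ties at the cut broken lexicographically so the
selection is deterministic; zero coefficients are never promoted to
edges. Hubs are electrodes whose total (in + out) degree reaches
`min_degree` (default 10, the connections-per-hub scale of maturing
cultures); the hub coefficient divides an electrode's degree by the total
edge count. Session overlap divides the shared directed edges by the
earlier session's edge count.

One subtlety the generator exposed: when a hub broadcasts copies of one
source spike to several targets, quasi-collinear target pairs acquire
genuine delayed synchrony with each other (the geometry delay matches the
difference of their propagation delays). Planted-hub recovery is
therefore evaluated with hubs planted well above the criterion
(out-degree 20 against a criterion of 15): hub detection separates
degrees, and secondary shared-source edges are real edges, not detector
errors.

## Calcium transients

Traces are smoothed by two-point averaging (`y[k] = (F[k] + F[k+1])/2`),
differentiated (`d[k] = y[k+1] - y[k]`), and thresholded at
`accuracy_coeff * sd(d)` (default coefficient 2.0). A transient opens at
the first sample of a positive suprathreshold run and closes at the last
sample of the next negative suprathreshold run; unmatched openings close
at the trace end. Because the threshold scales with the trace's own
derivative SD, detection is exactly invariant to baseline shifts and to
multiplicative rescaling.

The bare algorithm needs two guards, both exposed as parameters. A
suprathreshold run must span at least `min_run = 2` consecutive samples:
isolated single-sample noise excursions then never open or close events,
while a genuine single-frame intensity step still produces a two-sample
run because the two-point smoothing spreads it. And events shorter than
`min_duration = 1` s are discarded; at 4 Hz anything shorter is below
the timescale of a somatic calcium transient. Event timestamps use the
convention that derivative sample k is centred on original frame k + 1,
which keeps detected square-pulse bounds within one frame of truth.

Population statistics define an active cell as one with at least one
transient; the oscillation rate is averaged over active cells (the mean
over all cells is also reported), and durations are averaged over all
transients.

## The synthetic-data generator

The generator's role is to plant exactly the features the detectors look
for, with ground truth, at the activity levels of the reference study
conditions. It is first-class, tested code.

**Rasters** (`simulate_raster()`): homogeneous Poisson background spiking
per electrode; network bursts as spike clouds over a chosen electrode
span; optional hub-structured propagation in which each source spike is
copied along each planted edge with a configurable probability, delayed
by distance/velocity plus Gaussian jitter. A 1-ms minimal inter-spike
interval is enforced per channel, matching the detector's refractory
convention, and ground truth records the *realized* burst bounds
(first/last surviving planted spike) and counts — the quantities a
detector can actually be asked to recover.

Burst onsets come from a hard-core renewal process: interval = burst
duration + guard gap + exponential slack whose mean is chosen so the
stationary rate equals the configured rate exactly. A thinned Poisson
process would bias the realized rate low and could not guarantee the
non-overlap that planted-versus-detected matching requires. The guard gap
defaults to 0.15 s — three TSR bins, the smallest separation that can
never be bridged by the detector's 1-bin merge tolerance regardless of
bin alignment.

Two intra-burst envelopes are available. The truncated-Gaussian envelope
(±2 SD, SD = duration/4) gives the sharp-onset bell of a real population
burst and concentrates ~26–27% of the burst's spikes in the peak 50-ms
bin — this is what the mature-culture preset uses, and it is what makes a
~507-spike burst a *large* one (peak ≈ 130 ≥ 101). The uniform envelope
holds constant spike density up to the bounds; it exists because a
Gaussian envelope has vanishing edge density and therefore no crisp
realized boundary, so duration-accuracy validation
(`preset_burst_validation()`) plants uniform bursts whose "actual
duration" is well defined. At the 5-Hz validation rate the planted
duration drops to 40 ms so that bursts plus guard gaps still fit the
renewal interval.

The basal background rate defaults to 0.1 spikes/s/electrode. Basal
trains in culture appear as roughly one spike per 10–100 ms on a small,
shifting subset of electrodes; read as a network-wide average over 59
electrodes this is on the order of 5–10 spikes/s total, i.e. ~0.1 per
electrode-second. This choice also keeps the basal TSR well below the
burst threshold, which is the regime the 0.1 coefficient presupposes.

**Voltage** (`simulate_voltage()`): Gaussian noise per channel with a
biphasic (negative-then-positive) 1-ms template of configurable peak
amplitude injected at each raster spike time, extremal lobe aligned to
the spike time. The biphasic shape is the standard extracellular
signature; since detection thresholds the magnitude, polarity is
non-critical.

**Calcium traces** (`simulate_calcium()`): per cell, non-overlapping
transients from the same hard-core renewal scheme, added to a baseline
with Gaussian noise and clipped to [0, 255]. Each transient occupies a
finite support [onset, onset + duration]: an exponential rise
(`rise_tau = 0.8` s, ~2.4-s rise phase), a slow exponential decay
(`decay_tau = 10` s), and a terminal 1-s linear clearance ramp that
returns the trace to baseline exactly at the planted end. The ramp is a
deliberate modelling choice: a pure exponential tail has derivative
magnitude decaying below any threshold long before the event "ends", so
no derivative-threshold detector could recover a planted duration from a
tail-shaped event — the planted quantity would be ill-defined. With the
terminal ramp, events end the way network-wide calcium events do, with a
fast coordinated return to baseline, and the planted duration is a
recoverable quantity. The sham preset (1.55 events/min of mean duration
9.67 s across 50 cells × 300 s) puts about 25% of each trace inside
events; amplitude 100 on noise SD 2 keeps detection limited by shape, not
noise.

**What the generator does not emulate**: developmental dynamics (each
preset is one age in vitro), electrode-specific noise spectra and spike
waveform diversity, burst-internal propagation structure apart from the
explicit hub edges, glial slow signals, photobleaching, or movement
artifacts in the imaging branch. Passing recovery tests on this generator
therefore demonstrates that the chain measures what it claims on data
with the stated statistical structure — not that real recordings contain
no further nuisance structure.

## Numerical and reproducibility choices

All generator randomness flows from one explicit seed per call; the
global RNG state is saved and restored, so package calls never perturb a
caller's stream, and fixed seeds reproduce outputs bit for bit. Spike
times are serialized with 17 significant digits so CSV round trips are
exact. Degenerate inputs are handled explicitly: empty rasters give
all-zero TSR series and no bursts; a constant TSR (SD 0) gives no bursts;
flat calcium traces detect nothing and warn; empty target channels flag
`C_ij` as undefined rather than erroring; an empty graph refuses hub
coefficients and overlap (undefined denominators). Edge selection breaks
ties deterministically.

Validation problem sizes are chosen to exercise the statistics at the
reference conditions while remaining quick: 10 seeds per condition,
5-minute rasters for burst statistics, 60-s rasters per rate for
duration validation, 50 cells × 300 s for calcium. The brute-force
synchrony oracle runs on rasters of a few hundred spikes, where
exhaustive pair scanning is exact and fast.

## Known limitations

* Electrode-level analysis only; multi-unit activity under one electrode
  is never separated, so "hub" means a hub *site*.
* The 5% edge rule fixes graph density by construction; comparisons of
  edge counts across recordings are meaningful only through overlap and
  degree structure, not through the count itself.
* The delayed-synchrony coefficient is asymmetric and unnormalized for
  rate differences: a silent-but-for-copies channel can show `C = 1`
  while a busy one saturates lower. This matches its definition as a
  transmitted-spike fraction.
* At the default 4-SD spike threshold, noise crossings of ~1/s/channel
  are expected; spike-count statistics at very sparse activity levels
  should be interpreted accordingly.
* The calcium detector reports derivative-crossing bounds; for waveforms
  with long sub-threshold tails it will systematically report the steep
  part of the event, shorter than any nominal "full" duration.
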