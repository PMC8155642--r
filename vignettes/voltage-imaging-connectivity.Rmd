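---
title: "Methods: spike detection and functional connectivity from voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike detection and functional connectivity from voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltconn)
```

## The measurement model

`voltconn` analyzes high-speed voltage-imaging recordings of small, complete
neuronal networks ("microislands") grown on lithographically patterned
adhesion regions of roughly 650 × 120 µm, each holding 10–25 hippocampal
neurons. Because a microisland fits inside a single camera field of view
(2048 × 400 px at 0.325 µm/px, about 0.087 mm²), *every* neuron of the
network is recorded simultaneously — unlike a bulk coverslip culture, where
one field samples well under 0.1% of the ~113 mm² culture area:

```{r geometry}
fov <- fov_area_mm2(2048, 400, 0.325)
fov
percent_outside_fov(fov, coverslip_area_mm2(12))
```

A recording session is six 10 s epochs ("movies") at 500 Hz (2 ms frames).
Each movie is a T × H × W TIFF stack; somata and one background region are
outlined as ROIs. The fluorescence trace of an ROI is its per-frame pixel
mean minus the background ROI's per-frame mean (`extract_traces()`), and the
optical voltage signal is the fractional change
ΔF/F = (F − F₀)/F₀ with F₀ the mean of the leading 25 frames of each epoch
(`compute_dff()`). Epochs are always analyzed independently: no interval —
ISI, STTC tile, or connectivity lag — may bridge an epoch boundary, because
the epochs are separate acquisitions.

Assumptions inherited from the acquisition:

* the voltage dye brightens with depolarization (set
  `detection_config(invert = TRUE)` for dimming indicators);
* timing metadata comes from the caller, never from TIFF tags;
* spike times are quantized at the frame period (2 ms at 500 Hz), which
  bounds every downstream timing claim.

## Spike detection

`detect_spikes()` classifies the pooled ΔF/F samples of one ROI into three
classes — putative spike, subthreshold event, baseline — by 1-D k-means with
k = 3 fixed by the method, then turns contiguous runs of spike-class frames
into events timed at their peak frame. An event is kept when its SNR

> (peak ΔF/F − noise mean) / noise σ ≥ `snr_threshold` (default 4)

and events closer than `min_separation_frames` (default 3 frames = 6 ms, the
shortest inter-spike interval seen in these cultures) merge into the higher
peak.

Two numerical choices matter here:

**Noise floor.** The noise mean and σ are the median and the 1.4826-scaled
MAD of the *full* pooled trace, not moments of the baseline-labeled samples.
Spike transients occupy a tiny fraction of frames, so the robust statistics
track the baseline noise; cluster-membership-based estimates are unstable
because with sparse firing k-means may spend its centroids partitioning the
baseline noise itself, and the labels then censor the noise distribution.

**k-means initialization.** Purely random restarts almost never seed a
center inside a sparse spike cluster (tens of frames out of 30 000), and
Lloyd's algorithm then converges to a split of the baseline noise. The
internal 1-D k-means therefore adds a deterministic grid of quantile-triplet
starts (median plus upper-tail quantiles) to the random restarts and keeps
the start with the lowest within-cluster sum of squares. The test suite
checks the result against an exhaustive optimal contiguous partition, which
is the global k-means optimum in one dimension.

Detection fidelity is measured against the simulator's ground truth: at the
study's operating point (amplitude/σ = 10, 500 Hz), mean sensitivity and
precision exceed 0.95 with timing errors within one frame.

## Spike-train metrics

`average_frequency()` is total spikes over total recorded time;
`isi_and_instfreq()` returns within-epoch ISIs and their reciprocals (20 ms
↔ 50 Hz); `quiescent_fraction()` is the fraction of neurons with zero
detected spikes, optionally per cell type; `normalize_by_reference()`
rescales a metric by the mean of a reference condition within each
replicate, the normalization used for culture-to-culture comparisons.

## Spike-time tiling coefficient (STTC)

`compute_sttc()` implements

> STTC = ½ [(P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A)]

where T_X is the fraction of recording time within ±Δt of X's spikes
(interval union, clipped at epoch boundaries) and P_X the proportion of X's
spikes within ±Δt of a spike of the other train. Δt defaults to 10 ms. The
index is symmetric, firing-rate-insensitive, 1 for identical trains, near 0
for independent ones, and deliberately *undefined* (NA, with a reason) for
empty trains or vanishing denominators — never silently 0, because 0 is a
meaningful value. The implementation is verified against a 0.1 ms grid
discretization oracle to better than 10⁻³.

## Directed connectivity: the cross-correlation index (XCI)

`xci(a, b)` is the fraction of source spikes followed by at least one target
spike at a lag in the monosynaptic window (default 8–14 ms, bounds
inclusive, same epoch, each source spike credited once). It estimates the
probability that a source action potential triggers a target action
potential, and is directional by construction. The window is where
`lag_histogram()`'s transmission peak sits: lags are t_B − t_A in 2 ms bins
(the frame period) out to ±50 ms.

One subtlety: pooled over *ordered* pairs, the signed histogram is exactly
symmetric about 0 (every unordered pair enters once per direction), so
`lag_histogram()` also returns a `folded` |lag| histogram, which is the
object whose mode is interpretable. In recordings with common drive the
folded mode sits at 0–2 ms (coincidence); the 8–14 ms transmission peak
isolates only in networks driven through directed edges, which is how the
acceptance suite checks it (feed-forward chains without common input).

`xci_matrix()` evaluates all ordered pairs of an island and
`celltype_xci_summary()` pools pairs by (source type, target type), the
profile used to ask whether the native DGC → CA3 → CA1 hippocampal wiring
re-forms in culture. Type pairs with no defined value are reported as NA
with `n_pairs = 0`, never as 0.

## Cell typing

`assign_cell_type()` encodes the immunomarker decision table with explicit
precedence: GAD67 → inhibitory (unconditionally); else CaMKII ∧ Prox1 →
DGC; else CaMKII ∧ CTIP2 → CA1; else CaMKII → CA3; else unknown. Prox1 is
checked before CTIP2, so triple-positive profiles read as DGC. All 16
marker combinations are pinned in the tests.

## The ground-truth simulator

`sample_network()` + `simulate_spike_trains()` generate synthetic
microislands for end-to-end validation:

* cell types drawn from the observed composition (DGC 0.34, CA3 0.30,
  CA1 0.20, inhibitory 0.16);
* background firing as per-type homogeneous Poisson processes (inhibitory
  1.4, CA3 1.1, CA1 0.9, DGC 0.4 Hz), multiplied 2.5× for excitatory cells
  when the island has no interneuron (disinhibition);
* transmission as a branching process: each spike of neuron *i* triggers a
  spike in neuron *j* with probability w[i, j], at a lag uniform on 8–14 ms;
  triggered spikes trigger further spikes (disynaptic chains);
* a 6 ms refractory guard discards too-close spikes;
* the hippocampal weight preset elevates DGC→CA3, CA3→CA1 and CA1→CA1
  (0.25 vs 0.08 background).

Stability requires a subcritical weight matrix (spectral radius < 1), and
constant per-pair weights grow the radius linearly with island size, so
`sample_network()` uniformly rescales any draw above
`max_spectral_radius = 0.6` — strongly recurrent yet safely subcritical —
preserving the preset's relative structure. Under this model the expected
rates obey the first-moment branching law r = (I − wᵀ)⁻¹λ, which the tests
verify to within 3 standard errors over 200 seeds (the law is exact only
with the refractory guard disabled).

The simulator emulates: Poisson background firing, probabilistic
monosynaptic transmission with realistic delays, polysynaptic cascades,
disinhibition, refractoriness, frame-quantized optical readout with
exponential-decay transients and additive Gaussian noise
(`render_traces()`), and painted-soma movies whose ROI extraction closes
the loop (`render_movie()`). It does **not** emulate: subthreshold
dynamics, bursting or adaptation, inhibitory rate *suppression* (interneuron
presence only gates the disinhibition factor), photobleaching, motion, or
correlated noise. Conclusions about those phenomena cannot be validated
against it.

## Problem sizes and budgets

The shipped tests run islands of 1–12 neurons, sessions of up to 6 × 10 s
epochs at 500 Hz (30 000 frames per ROI), 100-island connectivity-recovery
sweeps, and 200-seed rate-law replications; everything completes on one CPU
in well under the suite's time budget. `scripts/acceptance.R --seed <s>
--out <path>` recomputes the headline quantities on synthetic data and
writes them as JSON.

## Worked example

```{r example}
net <- sample_network(10, seed = 1)
sim <- simulate_spike_trains(net, sim_config(), seed = 2)
dff <- render_traces(sim, seed = 3)
trains <- lapply(seq_along(dff), function(i) {
  detect_spikes(dff[[i]], detection_config(), frame_period_ms = 2,
                roi_id = paste0("n", i), cell_type = net$cell_type[i])
})
vapply(trains, average_frequency, 1)
pairwise_sttc(trains)$matrix[1:3, 1:3]
head(xci_matrix(trains)$table[, c("source_roi", "target_roi", "xci")])
celltype_xci_summary(xci_matrix(trains)$table)
```

## Limitations

* Detected spike times are frame-quantized; sub-frame latencies are not
  recoverable, and the 2 ms bin width of the lag histogram is a hard floor
  on delay resolution.
* The SNR threshold is a calibration parameter: it was established against
  ground-truth electrophysiology for this preparation, and a different
  dye/camera/noise regime needs re-calibration.
* XCI is correlational. An 8–14 ms lag consistent with monosynaptic
  transmission can also arise from shared drive with offset delays; the
  simulator's ground-truth parentage is the only place "causality" is known.
* The cell-type decision table is specific to the CaMKII/GAD67/CTIP2/Prox1
  panel and its published precedence rules.
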