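# voltconn

Spike detection and functional connectivity from high-speed voltage imaging
of neuronal microislands.

## The scientific problem

Patterned "microisland" cultures confine a complete hippocampal network of
10–25 neurons to a ~650 × 120 µm adhesion region — small enough that a
single camera field of view (2048 × 400 px at 0.325 µm/px, ≈ 0.087 mm²)
records *every* neuron simultaneously with a voltage-sensitive dye at
500 Hz. That turns functional-connectivity inference from a sampling
problem into a complete-network measurement. `voltconn` implements the full
analysis chain:

1. **Dataset I/O** — multi-frame TIFF movies, coverslip/area directory
   scanning, polygon/mask ROIs with JSON round-trip.
2. **Trace extraction** — per-frame ROI means with background subtraction;
   ΔF/F = (F − F₀)/F₀ against a leading-frames (or percentile) baseline.
3. **Spike detection** — 1-D k-means (k = 3: spike / subthreshold /
   baseline) on the pooled ΔF/F samples, an SNR ≥ 4 threshold against a
   robust median/MAD noise floor, and a 6 ms merge guard.
4. **Spike metrics** — firing rates, within-epoch ISIs and instantaneous
   frequencies, quiescent fractions, reference-condition normalization.
5. **STTC** — the spike-time tiling coefficient

   STTC = ½ [(P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A)],

   a firing-rate-insensitive pairwise correlation (±10 ms default window).
6. **Directed connectivity (XCI)** — the fraction of source spikes followed
   by a target spike at a monosynaptic 8–14 ms lag, evaluated over all
   ordered pairs and summarized by hippocampal cell type
   (DGC → CA3 → CA1), plus pooled lag-time histograms.
7. **Cell typing** — the CaMKII/GAD67/CTIP2/Prox1 marker decision table
   with explicit precedence.
8. **Ground-truth simulator** — a branching-process network model that
   generates spike trains, rendered ΔF/F traces, and synthetic movies so
   every stage is validated end to end.
9. **Pipeline CLI** — `run_pipeline()` / `inst/scripts/voltconn` runs the
   whole chain over a dataset tree and writes CSV tables plus a checksummed
   manifest.

## Worked example

Simulate a 10-neuron island, detect spikes from rendered ΔF/F traces, and
recover its connectivity:

```r
library(voltconn)

net <- sample_network(10, seed = 1)   # types + transmission weights
table(net$cell_type)
#>        CA1        CA3        DGC inhibitory
#>          1          3          3          3

sim <- simulate_spike_trains(net, sim_config(), seed = 2)  # 6 x 10 s epochs
dff <- render_traces(sim, seed = 3)   # amplitude 0.10, sigma 0.01, 500 Hz
trains <- lapply(seq_along(dff), function(i) {
  detect_spikes(dff[[i]], detection_config(), frame_period_ms = 2,
                roi_id = paste0("n", i), cell_type = net$cell_type[i])
})

round(vapply(trains, average_frequency, 1), 3)
#>  [1] 1.200 2.183 2.467 2.150 1.417 2.450 2.350 2.700 2.450 1.600
```

Detection is faithful to the simulator's ground truth:

```r
spike_train_agreement(sim$trains[[1]], trains[[1]], tol_ms = 2)
#> $tp                  70
#> $n_true              70
#> $n_detected          72
#> $sensitivity         1
#> $precision           0.972
#> $max_timing_error_ms 0.999
```

Pairwise STTC and directed XCI:

```r
round(pairwise_sttc(trains)$matrix[1:4, 1:4], 3)
#>       n1    n2    n3    n4
#> n1 1.000 0.170 0.194 0.087
#> n2 0.170 1.000 0.158 0.136
#> n3 0.194 0.158 1.000 0.097
#> n4 0.087 0.136 0.097 1.000

celltype_xci_summary(xci_matrix(trains)$table)
#>   source_type target_type   mean_xci         sem n_pairs
#> 1         DGC         DGC 0.08278186 0.003000450       6
#> 2         CA3         DGC 0.08158462 0.008074520       9
#> 3         CA1         DGC 0.09259259 0.007127781       3
#> 4         DGC         CA3 0.18300654 0.015752396       9
#> 5         CA3         CA3 0.09026442 0.006178753       6
#> 6         CA1         CA3 0.09465021 0.002057613       3
#> 7         DGC         CA1 0.10383987 0.020998639       3
#> 8         CA3         CA1 0.20710323 0.008996911       3
#> 9         CA1         CA1         NA          NA       0
```

The elevated DGC → CA3 (0.183) and CA3 → CA1 (0.207) entries against the
~0.09 background recover the native hippocampal pathway that was built into
the simulated network — the same analysis the package applies to real
recordings. (The CA1 → CA1 cell is NA because this island has a single CA1
neuron, hence no CA1 → CA1 pair; absent pairs are never reported as 0.)

The textbook STTC pair works out to its published value:

```r
compute_sttc(spike_train("a", c(100, 500), 1000),
             spike_train("b", c(105, 900), 1000), delta_t_ms = 10)$value
#> [1] 0.4693878
```

See the vignette (`vignettes/voltage-imaging-connectivity.Rmd`) for the
model assumptions, parameter defaults, and the simulator's scope.

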