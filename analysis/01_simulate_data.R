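#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic inputs.
#
# Produces (a) the prototype spike layout, (b) a micro-CT-like trabecular
# volume of the periarticular specimen with ground truth, and (c) ten
# replicate embedding force-distance curves with the three-region shape.
# Everything is seeded, so downstream stages are reproducible.

suppressPackageStartupMessages(library(scaffembed))
dir.create("results", showWarnings = FALSE)
seed <- 42L

layout <- build_spike_layout(scaffold_params(n_rings = 1L))
write_spike_layout(layout, "results/spike_layout.json")
message(sprintf("layout: %d spikes at %.2f mm pitch", nrow(layout$spikes),
                layout$radial_pitch))

vol <- generate_trabecular_volume(
  volume_spec(shape = c(160L, 160L, 208L), target_marrow_fraction = 0.67,
              n_canals = 3L, n_lacunae = 20L, n_speckles = 50L,
              seed = seed + 2L))
write_ct_volume(vol$volume, "results/specimen_baseline.nii.gz")
message(sprintf("baseline volume: %.1f%% marrow fraction (ground truth)",
                100 * mean(!vol$bone_mask)))

curves <- generate_force_curves(curve_spec(seed = seed + 1L))
write_force_curves(curves, "results/force_curves.csv")
message(sprintf("curves: %d replicates, %d samples each",
                max(curves$replicate), sum(curves$replicate == 1L)))
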