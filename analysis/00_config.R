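# Shared configuration for the demo analysis: a synthetic two-group cohort
# with a planted short-range coupling deficit (patients) and a planted
# long-range pair decoupling, analysed with the reference parameter set
# (R > 0.6, 20% GM mask, 0.01-0.08 Hz, 6 mm FWHM, voxel p = 0.01, r = 5 mm).

library(fcdmapr)

GRID <- c(20L, 20L, 20L)
VOXEL_MM <- c(3, 3, 3)

# planted structure: a contiguous block whose coupling patients lose, and a
# remote pair whose long-range coupling patients lose
local_block <- block_cuboid("motor_like", 17:19, 9:11, 9:11, coupling = 0.8)
remote_pair <- block_spec("temporal_pair",
                          rbind(as.matrix(expand.grid(3:5, 7:9, 7:9)),
                                as.matrix(expand.grid(5:7, 15:17, 8:10))),
                          "remote_pair", coupling = 0.8)

COHORT <- cohort_spec(
  n_per_group = 12L, grid_shape = GRID, voxel_size_mm = VOXEL_MM,
  n_volumes = 160L, tr_s = 2, noise_fwhm_mm = 6,
  blocks = list(local_block, remote_pair),
  group_effects = list(
    list(block = "motor_like", group = "patient", multiplier = 0.3),
    list(block = "temporal_pair", group = "patient", multiplier = 0.2)),
  seed = 20260925L)

CONFIG <- default_run_config(n_iterations = 1000L, seed = 7L)

GM_PROB <- synthetic_gm_prob(GRID)
MASK <- make_gm_mask(GM_PROB, CONFIG$mask_prob)

SCRATCH <- "scratch/analysis"
RESULTS <- "results"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
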