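#!/usr/bin/env Rscript
# Simulate the demo cohort and write it to disk in the exchange formats a
# real study would use (4D NIfTI + SPM-style motion text + manifest CSV).

source("analysis/00_config.R")

stopifnot(all(MASK[COHORT$blocks[[1]]$member_voxels]),
          all(MASK[COHORT$blocks[[2]]$member_voxels]))

cat(sprintf("Simulating %d patients + %d controls, %s grid, %d volumes, TR %g s\n",
            COHORT$n_per_group, COHORT$n_per_group,
            paste(GRID, collapse = "x"), COHORT$n_volumes, COHORT$tr_s))

cohort_dir <- file.path(SCRATCH, "cohort")
records <- generate_cohort(COHORT)
manifest <- write_cohort(records, cohort_dir)
write_map_nifti(GM_PROB, file.path(cohort_dir, "gm_prob.nii.gz"), VOXEL_MM)

clin <- generate_clinical_table(records)
write.csv(clin, file.path(RESULTS, "clinical_table.csv"), row.names = FALSE)

cat(sprintf("Wrote %d subjects to %s\n", nrow(manifest), cohort_dir))
cat(sprintf("Gray-matter mask at >%g probability: %d voxels (%.0f%% of grid)\n",
            CONFIG$mask_prob, sum(MASK), 100 * mean(MASK)))
cat(sprintf("Patient ALSFRS-R %.1f +/- %.1f, progression rate %.2f +/- %.2f\n",
            mean(clin$alsfrs_r), sd(clin$alsfrs_r),
            mean(clin$progression_rate), sd(clin$progression_rate)))
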