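#!/usr/bin/env Rscript
# Stage 1: simulate the default synthetic cohort — 24 benign and 22
# malignant ellipsoidal thyroid-nodule phantoms whose whole-lesion mean
# IVIM parameters follow the published benign/malignant group
# distributions, with cystic subregions, spatially correlated texture and
# Rician noise. Writes the cohort manifest and one example nodule's files
# (NIfTI + bval + JSON sidecar) under results/.

suppressPackageStartupMessages(library(ivimroi))

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(n_benign = 24, n_malignant = 22, seed = seed)
write.csv(cohort$manifest, file.path(out, "cohort_manifest.csv"),
          row.names = FALSE)

by_group <- split(cohort$manifest, cohort$manifest$group)
for (g in names(by_group)) {
  m <- by_group[[g]]
  cat(sprintf("%-9s n = %2d | true D %.2f +/- %.2f | f %.1f +/- %.1f | D* %.1f +/- %.1f\n",
              g, nrow(m), mean(m$true_D), sd(m$true_D),
              mean(m$true_f), sd(m$true_f),
              mean(m$true_D_star), sd(m$true_D_star)))
}

# one example nodule on disk, usable with fit_only()
ex <- cohort$nodules[[1]]
write_dwi_volume(ex$volume, file.path(out, "example_nodule"))
write_mask_nifti(ex$true_mask, file.path(out, "example_nodule_mask.nii.gz"),
                 voxel_size = ex$spec$voxel_size)
cat("manifest and example nodule written under", out, "\n")
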