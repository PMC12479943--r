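#!/usr/bin/env Rscript
# Phantom autoradiography study: programs the published group-mean
# thalamic/hippocampal/striatal SUVRs into synthetic slides, runs the
# full measurement chain (standards calibration, background-subtracted
# circular ROIs, decay-corrected SUV, brainstem-referenced SUVR) on
# every slice, and aggregates slices per animal exactly as the slice
# policy prescribes (6 per animal; 3 for the thalamus).

library(thalaquant)
dir.create("results", showWarnings = FALSE)

# group-mean SUVRs used as programmed phantom truth (inputs to the
# phantoms, not claims about recovery)
conditions <- list(
  wt_P30 = c(hippocampus = 2.33, thalamus = 1.99, striatum = 2.19),
  wt_P70 = c(hippocampus = 2.09, thalamus = 1.68, striatum = 1.79),
  td_P30 = c(hippocampus = 2.26, thalamus = 4.65, striatum = 2.07),
  td_P70 = c(hippocampus = 1.99, thalamus = 5.45, striatum = 1.76),
  ko_P30 = c(hippocampus = 3.93, thalamus = 4.61, striatum = 2.26),
  ko_P70 = c(hippocampus = 3.13, thalamus = 10.09, striatum = 1.56))

rows <- list()
for (cond in names(conditions)) {
  prog <- c(conditions[[cond]], brainstem = 1.0)
  # slight per-slice plate noise; slice policy: 6 slices (3 for thalamus)
  sp <- phantom_spec(programmed_suvr = prog, noise_sd = 1.0)
  per_slice <- lapply(1:6, function(s) {
    quantify_phantom(generate_phantom_autoradiogram(
      sp, seed = 1000 * match(cond, names(conditions)) + s))
  })
  for (region in names(conditions[[cond]])) {
    n_slices <- if (region == "thalamus") 3 else 6
    suvrs <- vapply(per_slice[seq_len(n_slices)], function(q) {
      q$suvr[q$region == region]
    }, numeric(1))
    g <- aggregate_region(suvrs, region)
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, region = region, n_slices = n_slices,
      suvr_programmed = prog[[region]],
      suvr_mean = g$mean, suvr_sem = g$sem)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/autoradiography_suvr.csv", row.names = FALSE)
cat("Per-animal SUVR recovery (programmed vs measured):\n")
print(tab, digits = 4)
cat("max |recovery error| =",
    signif(max(abs(tab$suvr_mean - tab$suvr_programmed)), 3), "SUVR\n")
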