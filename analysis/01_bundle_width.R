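#!/usr/bin/env Rscript
# Cortical actin bundle width: two synthetic populations ("control" with
# narrow bundles, "silenced" with 1.5x broader bundles), measured with the
# full width pipeline (orientation fit, density map, centerline, perpendicular
# distance histogram, Gaussian fit, precision deconvolution).

suppressPackageStartupMessages(library(nanometrics))
dir.create("results", showWarnings = FALSE)

measure_population <- function(label, sigma_true_nm, n_bundles, seed0) {
  do.call(rbind, lapply(seq_len(n_bundles), function(i) {
    sc <- simulate_bundle_localizations(
      bundle_spec(sigma_true_nm = sigma_true_nm, seed = seed0 + i))
    w <- measure_bundle_width(sc$table)
    data.frame(population = label, bundle = i,
               sigma_true_nm = sigma_true_nm,
               fwhm_true_nm = sc$truth$fwhm_true_nm,
               sigma_meas_nm = w$sigma_meas_nm,
               sigma_corr_nm = w$sigma_corr_nm,
               fwhm_meas_nm = w$fwhm_meas_nm,
               fwhm_corr_nm = w$fwhm_corr_nm,
               n_events = w$n_events)
  }))
}

tab <- rbind(
  measure_population("control", 30, 12, 100),
  measure_population("silenced", 45, 12, 200)
)
write.csv(tab, "results/bundle_width_per_bundle.csv", row.names = FALSE)

agg <- aggregate(fwhm_corr_nm ~ population, tab, mean)
ratio <- agg$fwhm_corr_nm[agg$population == "silenced"] /
  agg$fwhm_corr_nm[agg$population == "control"]
summary <- data.frame(
  population = agg$population,
  mean_fwhm_corr_nm = agg$fwhm_corr_nm,
  sd_fwhm_corr_nm = aggregate(fwhm_corr_nm ~ population, tab, sd)$fwhm_corr_nm
)
write.csv(summary, "results/bundle_width_summary.csv", row.names = FALSE)
cat(sprintf("mean corrected FWHM: control %.1f nm, silenced %.1f nm (ratio %.3f, true 1.500)\n",
            agg$fwhm_corr_nm[agg$population == "control"],
            agg$fwhm_corr_nm[agg$population == "silenced"], ratio))
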