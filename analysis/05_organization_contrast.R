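#!/usr/bin/env Rscript
# Self-organization contrast of microtubule fields.
#
# Renders phenomenological organization time-lapses (uniform field,
# bundle-forming, aster-forming) and computes the contrast statistic: the
# standard deviation of all pixels of each tubulin-channel frame. Aster
# formation concentrates fluorescence into radial foci and drives the
# contrast to a plateau within ~10 min; bundling does so more slowly
# (~20 min); an unorganized field stays flat.

suppressPackageStartupMessages(library(kinetracer))
out_dir <- "results/organization"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

series <- list()
for (sc in c("uniform", "bundling", "aster")) {
  cfg <- fixture_config(if (sc == "bundling") "org_bundle" else "org_aster")
  stk <- simulate_organization_field(cfg, scenario = sc)
  ctr <- compute_contrast(stk)
  series[[sc]] <- ctr$contrast
  t_half <- if (max(ctr$contrast) > 0)
    ctr$time_s[min(which(ctr$contrast >= 0.5 * max(ctr$contrast)))] / 60
  else NA
  cat(sprintf("%-9s final contrast %7.2f | half-rise at %s min\n",
              sc, ctr$contrast[nrow(ctr)],
              ifelse(is.na(t_half), "-", sprintf("%.1f", t_half))))
}

write.csv(data.frame(time_s = seq(0, by = 15,
                                  length.out = length(series$uniform)),
                     uniform = series$uniform,
                     bundling = series$bundling,
                     aster = series$aster),
          file.path(out_dir, "contrast_series.csv"), row.names = FALSE)
cat("wrote", file.path(out_dir, "contrast_series.csv"), "\n")
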