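#!/usr/bin/env Rscript
# Fluorescence-intensity stoichiometry of moving clusters.
#
# Renders surface-adhered single-dye spots and first-frame moving-cluster
# spots, measures every spot with the background-corrected 2D-Gaussian
# routine, and reports the cluster-to-single fold difference in mean
# integrated intensity. Also counts photobleaching steps on simulated
# dimer and aggregate traces: dimers bleach in 1-2 steps, aggregates in
# more, which is how single dimers are distinguished from multimotor
# clusters.

suppressPackageStartupMessages(library(kinetracer))
out_dir <- "results/intensity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

m <- run_scenario("cluster_intensity", out_dir = out_dir)
int <- m$results$intensity
cat(sprintf("singles : n = %d, mean = %.0f a.u.\n",
            int$singles$n, int$singles$mean))
cat(sprintf("clusters: n = %d, mean = %.0f a.u.\n",
            int$clusters$n, int$clusters$mean))
cat(sprintf("fold difference (moving clusters / singles): %.2f\n", int$fold))

# stepwise photobleaching: dimer vs 5-mer aggregate
cfg <- fixture_config("cluster_intensity")
cfg$n_frames <- 300L
cfg$noise_sd <- 100
counts <- sapply(c(dimer = 2L, aggregate = 5L), function(k) {
  vapply(1:100, function(s)
    count_photobleach_steps(
      simulate_photobleach_trace(cfg, k, trace_seed = 100 * k + s)$trace,
      single_intensity = cfg$intensity_mean)$n_steps, numeric(1))
})
cat(sprintf("\ndimer traces scored 1-2 steps: %d%%\n",
            round(100 * mean(counts[, "dimer"] %in% 1:2))))
cat(sprintf("aggregate traces scored >2 steps: %d%%\n",
            round(100 * mean(counts[, "aggregate"] > 2))))
write.csv(data.frame(trace = seq_len(nrow(counts)),
                     dimer_steps = counts[, "dimer"],
                     aggregate_steps = counts[, "aggregate"]),
          file.path(out_dir, "photobleach_steps.csv"), row.names = FALSE)
cat("wrote", out_dir, "\n")
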