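#!/usr/bin/env Rscript
# Maximum-entropy (BioEn) refinement of conformer ensembles against the
# two measured transfer-efficiency moments: a synthetic conformer
# ensemble stands in for a chain-growth ensemble, and discretized
# polymer-model priors are reweighted the way low-efficiency ssDNA
# constructs are handled.

suppressPackageStartupMessages(library(ssnadyn))
dir.create("results", showWarnings = FALSE)

R0 <- 5.4
d_prior <- calibrate_to_efficiency("GC", 0.55, R0)

## conformer ensemble with a deliberate prior-data mismatch
ens <- synthetic_ensemble(2000, d_prior, R0, seed = 501)
targets <- reweight_targets(target_mean = 0.50, target_var = 0.10)
sel <- select_theta(ens, targets)
write.csv(sel$trace, "results/05_theta_trace.csv", row.names = FALSE)
write_bioen_json(sel$result, "results/05_bioen_ensemble.json",
                 weights_csv = "results/05_bioen_weights.csv")
cat(sprintf("Conformer ensemble (N = %d): theta* = %.3g\n",
            length(ens$eff), sel$theta_star))
cat(sprintf("  reweighted <eps> = %.3f (target 0.50 +/- 0.03), var = %.4f\n",
            sel$result$mean_eff, sel$result$var_eff))
cat(sprintf("  phi_eff = %.2f: %.0f%% of the prior ensemble is retained\n",
            sel$result$phi_eff, 100 * sel$result$phi_eff))

## discretized polymer priors: all three models against one target
models <- list(
  GC    = calibrate_to_efficiency("GC", 0.55, R0),
  WLC   = calibrate_to_efficiency("WLC", 0.55, R0, lc = 19 * 0.63),
  SAWNU = calibrate_to_efficiency("SAWNU", 0.55, R0, b = 0.63, n = 19))
grid_res <- do.call(rbind, lapply(names(models), function(nm) {
  prior <- polymer_prior_on_grid(models[[nm]], R0)
  s <- select_theta(prior, targets)
  data.frame(model = nm, theta_star = s$theta_star,
             mean_eff = s$result$mean_eff, var_eff = s$result$var_eff,
             phi_eff = s$result$phi_eff)
}))
write.csv(grid_res, "results/05_polymer_prior_reweight.csv",
          row.names = FALSE)
cat("\nDiscretized polymer priors (33 bins, d_eps = 0.03):\n")
print(grid_res, digits = 3)
cat("All three priors reweight to nearly the same moments, mirroring the\n",
    "insensitivity of the refined distribution to the prior choice.\n")
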