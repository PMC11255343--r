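#!/usr/bin/env Rscript
# Hierarchical chain growth exercised on a synthetic freely-jointed
# fragment library: grow an ensemble under the RMSD and clash gates,
# verify the polymer limit against the Gaussian chain, and push the
# grown distance distribution through the FRET observables.

suppressPackageStartupMessages(library(ssnadyn))
dir.create("results", showWarnings = FALSE)

lib <- synthetic_fragment_library(n_members = 128, step_A = 15,
                                  seed = 601)
ens <- grow_chain(lib, n_fragments = 32, n_chains = 400, seed = 602)
write_ensemble_distances(ens, "results/06_grown_distances.csv")
r <- ens$distances_nm

msd_fjc <- 32 * 1.5^2
gd <- dist_gc(msd_fjc)
cdf <- function(q) vapply(q, function(z)
  integrate(function(x) ddist_pdf(gd, x), 0, z, rel.tol = 1e-8)$value, 0)
ks <- suppressWarnings(ks.test(r, cdf))
cat(sprintf("Grew %d chains of 32 segments (junction acceptance %.3f)\n",
            length(r), ens$acceptance_rate))
cat(sprintf("  <r^2> = %.1f nm^2 (ideal freely-jointed: %.1f)\n",
            mean(r^2), msd_fjc))
cat(sprintf("  KS vs Gaussian chain: D = %.3f, p = %.3f\n",
            ks$statistic, ks$p.value))

# grown ensemble -> empirical distance distribution -> FRET observables
den <- density(r, from = 0.01)
de <- dist_empirical(den$x, den$y)
m <- efficiency_moments(de, 5.4)
cat(sprintf("\nEmpirical distribution of the grown ensemble: <eps> = %.3f,
            var = %.4f at R0 = 5.4 nm\n", m$mean_eff, m$var_eff))
jsonlite::write_json(list(acceptance = ens$acceptance_rate,
                          msd = mean(r^2), ks_p = ks$p.value,
                          mean_eff = m$mean_eff, var_eff = m$var_eff),
                     "results/06_chain_growth_summary.json",
                     auto_unbox = TRUE, digits = NA)
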