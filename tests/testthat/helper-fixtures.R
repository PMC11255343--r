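# shared fixtures: small, fast objects reused across test files

R0_REF <- 5.4          # Foerster radius of the Alexa 488/594 pair, nm
LC_19MER <- 19 * 0.63  # contour length of a 19-nucleotide ssDNA, nm

gc_ref    <- function() dist_gc(36)
wlc_ref   <- function() dist_wlc(11, 1.5)
sawnu_ref <- function() dist_sawnu(R = 6, b = 0.63, n = 19)

all_families <- function() {
  list(GC = gc_ref(), WLC = wlc_ref(), SAWNU = sawnu_ref())
}

# numeric integral of a density over its support
integral_of <- function(dist) {
  s <- ddist_support(dist)
  stats::integrate(function(r) ddist_pdf(dist, r), s[1], s[2],
                   rel.tol = 1e-10, subdivisions = 500L)$value
}

# narrow Gaussian spike as a near-delta empirical distribution
spike_dist <- function(r0, sd = 0.005) {
  r <- seq(max(0, r0 - 8 * sd), r0 + 8 * sd, length.out = 2001)
  dist_empirical(r, stats::dnorm(r, r0, sd))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
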