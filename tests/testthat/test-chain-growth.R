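triad <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0, 0, 1.5))

test_that("superposition: identity geometry, rotation handedness, and
           strict RMSD gate", {
  # identical overlap after an arbitrary rigid motion: rmsd 0, pass
  set.seed(201)
  R <- ssnadyn:::random_rotation()
  moved <- sweep(triad %*% R, 2, c(3, -2, 7), "+")
  tr <- superpose_and_gate(triad, moved)
  expect_lt(tr$rmsd, 1e-10)
  expect_true(tr$pass)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-10)
  expect_equal(ssnadyn:::apply_transform(moved, tr), triad,
               tolerance = 1e-10)
  # mirrored target: proper rotation enforced, chirality never flipped
  mirr <- triad %*% diag(c(-1, 1, 1))
  tr2 <- superpose_and_gate(mirr, triad)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-10)
  expect_gt(tr2$rmsd, 0.1)
  expect_error(superpose_and_gate(triad[1:2, ], triad[1:2, ]),
               "underdetermined")
})

test_that("RMSD agrees with an independent least-squares fitting oracle
           and lower-bounds a random rotation search", {
  set.seed(202)
  for (i in 1:3) {
    a <- triad + matrix(stats::rnorm(12, 0, 0.3), 4)
    b <- triad + matrix(stats::rnorm(12, 0, 0.3), 4)
    tr <- superpose_and_gate(a, b, assembly_gates(rmsd_max = 100))
    # any random proper rotation (centroid-matched) does no better
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    rand <- vapply(1:2000, function(k) {
      Q <- ssnadyn:::random_rotation()
      sqrt(mean(rowSums((bc %*% Q - ac)^2)))
    }, 0)
    expect_true(all(tr$rmsd <= rand + 1e-9))
    # independent implementation: bio3d least-squares fit
    if (requireNamespace("bio3d", quietly = TRUE)) {
      fitted <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(a)),
                                                as.numeric(t(b))))
      rb <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                 a)^2)))
      expect_equal(tr$rmsd, rb, tolerance = 1e-6)
    }
  }
})

test_that("RMSD gate is strict at the threshold", {
  # two overlap sets with a known rmsd: scale one triad radially
  scale_for <- function(target) {
    rms0 <- sqrt(mean(rowSums(sweep(triad, 2, colMeans(triad))^2)))
    1 + target / rms0
  }
  mk <- function(rmsd_target) triad * scale_for(rmsd_target)
  g <- assembly_gates(rmsd_max = 0.8)
  r_lo <- superpose_and_gate(triad, mk(0.7), g)
  r_hi <- superpose_and_gate(triad, mk(0.9), g)
  expect_equal(r_lo$rmsd, 0.7, tolerance = 0.02)
  expect_equal(r_hi$rmsd, 0.9, tolerance = 0.02)
  expect_true(r_lo$pass)
  expect_false(r_hi$pass)
})

test_that("clash test: threshold behavior and exclusions", {
  a <- matrix(c(0, 0, 0), 1)
  expect_false(clash_test(a, matrix(c(1.9, 0, 0), 1), 2.0))
  expect_true(clash_test(a, matrix(c(2.1, 0, 0), 1), 2.0))
  expect_true(clash_test(a, matrix(c(1.9, 0, 0), 1), 2.0, excl2 = 1L))
})

test_that("cell-list clash search equals the all-pairs oracle on random
           assemblies", {
  set.seed(203)
  for (i in 1:6) {
    n1 <- 260; n2 <- 250  # above the vectorized fast-path cutoff
    x1 <- matrix(stats::runif(3 * n1, 0, 25), ncol = 3)
    x2 <- matrix(stats::runif(3 * n2, 0, 25), ncol = 3)
    got <- clash_test(x1, x2, 2.0)
    dmin <- min(as.matrix(stats::dist(rbind(x1, x2)))[1:n1, n1 + 1:n2])
    expect_equal(got, dmin >= 2.0)
  }
})

test_that("library of identical straight fragments grows a deterministic
           straight chain with additive span", {
  step <- 8
  tail_tr <- sweep(triad[1:3, ], 2, c(step, 0, 0), "+")
  frag <- cg_fragment(rbind(triad[1:3, ], tail_tr), head_idx = 1:3,
                      tail_idx = 4:6)
  ens <- grow_chain(list(frag), n_fragments = 8, n_chains = 3, seed = 204)
  expect_equal(ens$distances_nm, rep(8 * step / 10, 3), tolerance = 1e-9)
  expect_equal(ens$acceptance_rate, 1)
})

test_that("freely-jointed library converges to Gaussian-chain statistics", {
  lib <- synthetic_fragment_library(128, step_A = 15, seed = 205)
  ens <- grow_chain(lib, n_fragments = 32, n_chains = 300, seed = 206)
  r <- ens$distances_nm
  msd_fjc <- 32 * 1.5^2
  expect_rel_equal(mean(r^2), msd_fjc, 0.12)
  gd <- dist_gc(msd_fjc)
  cdf <- function(q) vapply(q, function(z)
    stats::integrate(function(x) ddist_pdf(gd, x), 0, z,
                     rel.tol = 1e-8)$value, 0)
  expect_gt(suppressWarnings(stats::ks.test(r, cdf))$p.value, 0.01)
  # grown distances feed the empirical distribution type directly
  de <- dist_empirical(stats::density(r, from = 0)$x[-1],
                       stats::density(r, from = 0)$y[-1])
  expect_s3_class(de, "distance_distribution")
})

test_that("chain growth is seed-deterministic and seeds differ", {
  lib <- synthetic_fragment_library(32, step_A = 12, seed = 207)
  a <- grow_chain(lib, n_fragments = 8, n_chains = 10, seed = 208)
  b <- grow_chain(lib, n_fragments = 8, n_chains = 10, seed = 208)
  c_ <- grow_chain(lib, n_fragments = 8, n_chains = 10, seed = 209)
  expect_identical(a$distances_nm, b$distances_nm)
  expect_false(identical(a$distances_nm, c_$distances_nm))
  expect_error(grow_chain(lib, n_fragments = 6, n_chains = 2, seed = 1),
               "power-of-two")
  seqm <- grow_chain(lib, n_fragments = 6, n_chains = 2, seed = 1,
                     mode = "sequential")
  expect_length(seqm$distances_nm, 2L)
})

test_that("loosening either gate never reduces acceptance on a fixed seed
           sequence", {
  lib <- synthetic_fragment_library(24, step_A = 5, seed = 210)
  # jitter the overlap triads so some superpositions genuinely fail
  lib <- lapply(lib, function(fr) {
    fr$xyz[fr$head_idx, ] <- fr$xyz[fr$head_idx, ] +
      matrix(stats::rnorm(9, 0, 0.25), 3)
    fr
  })
  acc_at <- function(rmsd_max, clash_dist) {
    e <- grow_chain(lib, n_fragments = 4, n_chains = 15, seed = 211,
                    gates = assembly_gates(rmsd_max, clash_dist))
    e$acceptance_rate
  }
  expect_lte(acc_at(0.6, 2.0), acc_at(1.2, 2.0))
  expect_lte(acc_at(1.2, 3.5), acc_at(1.2, 2.0))
})

test_that("dye fragments attach at the ends and set the reported distance", {
  step <- 10
  tail_tr <- sweep(triad[1:3, ], 2, c(step, 0, 0), "+")
  frag <- cg_fragment(rbind(triad[1:3, ], tail_tr), head_idx = 1:3,
                      tail_idx = 4:6)
  # dyes: head triad plus a displaced reference atom for the fluorophore
  dye_h <- cg_fragment(rbind(triad[1:3, ], c(0, 6, 0)), head_idx = 1:3,
                       tail_idx = 1:3, is_dye = TRUE, ref_idx = 4L)
  dye_t <- cg_fragment(rbind(triad[1:3, ], c(0, 0, 7)), head_idx = 1:3,
                       tail_idx = 1:3, is_dye = TRUE, ref_idx = 4L)
  ens <- grow_chain(list(frag), n_fragments = 4, n_chains = 2,
                    seed = 212, dye_head = list(dye_h),
                    dye_tail = list(dye_t))
  expect_length(ens$distances_nm, 2L)
  expect_true(all(is.finite(ens$distances_nm)))
  # dye-to-dye differs from the bare-chain end-to-end distance
  bare <- grow_chain(list(frag), n_fragments = 4, n_chains = 1,
                     seed = 212)
  expect_false(isTRUE(all.equal(ens$distances_nm[1],
                                bare$distances_nm[1])))
})

test_that("fragment PDB + JSON round trip preserves geometry and overlap
           lists", {
  skip_if_not_installed("bio3d")
  frag <- cg_fragment(triad, head_idx = 1:3, tail_idx = c(2L, 3L, 4L))
  pf <- tempfile(fileext = ".pdb"); jf <- tempfile(fileext = ".json")
  suppressWarnings(write_fragment_pdb(frag, pf, jf))
  back <- suppressWarnings(read_fragment_pdb(pf, jf))
  expect_equal(back$xyz, frag$xyz, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$head_idx, frag$head_idx)
  expect_equal(back$tail_idx, frag$tail_idx)
  unlink(c(pf, jf))
})
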