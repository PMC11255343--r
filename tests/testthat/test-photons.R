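# build a stream with a prescribed number of photons in chosen bins
stream_with_bins <- function(counts, bin_ns = 1000, channel = "D") {
  recs <- do.call(rbind, lapply(seq_along(counts), function(i) {
    n <- counts[i]
    if (n == 0) return(NULL)
    data.frame(time_ns = sort(stats::runif(n, (i - 1) * bin_ns,
                                           i * bin_ns - 1e-9)),
               microtime_ns = stats::rexp(n, 1 / 3),
               channel = channel, polarization = "par",
               excitation = "Dex")
  }))
  recs <- recs[order(recs$time_ns), ]
  class(recs) <- c("photon_stream", "data.frame")
  recs
}

test_that("burst threshold is strict: 50 photons is not a burst, 51 is", {
  set.seed(161)
  s50 <- stream_with_bins(c(50, 10))
  expect_equal(nrow(find_bursts(s50, bin_ns = 1000, threshold = 50)), 0L)
  s51 <- stream_with_bins(c(51, 10))
  b <- find_bursts(s51, bin_ns = 1000, threshold = 50)
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_total, 51)
  expect_equal(find_bursts(s51[0, ], 1000), find_bursts(s51[0, ], 1000))
})

test_that("consecutive hot bins merge; a cold bin splits bursts", {
  set.seed(162)
  s <- stream_with_bins(c(60, 70, 5, 80))
  b <- find_bursts(s, bin_ns = 1000, threshold = 50)
  expect_equal(nrow(b), 2L)
  expect_equal(b$n_total, c(130, 80))
  expect_equal(b$duration_ns, c(2000, 1000))
})

test_that("uniform background produces bursts at the Poisson tail rate", {
  set.seed(163)
  lambda <- 30; n_bins <- 20000; bin_ns <- 1000
  n <- stats::rpois(1, lambda * n_bins)
  s <- data.frame(time_ns = sort(stats::runif(n, 0, n_bins * bin_ns)),
                  microtime_ns = 0, channel = "D", polarization = "par",
                  excitation = "Dex")
  b <- find_bursts(s, bin_ns = bin_ns, threshold = 50)
  p_tail <- stats::ppois(50, lambda, lower.tail = FALSE)
  expected <- n_bins * p_tail
  # observed false positives inside a generous Poisson band
  expect_lte(nrow(b), stats::qpois(0.999, expected) + 1)
})

test_that("count corrections follow the fixed order and identity case", {
  b <- data.frame(burst_id = 1L, start_ns = 0, stop_ns = 1e6,
                  duration_ns = 1e6, n_D_raw = 100, n_A_raw = 60,
                  n_Aex_raw = 40, n_total = 200)
  id <- correct_counts(b, correction_factors())
  expect_equal(id$n_D, 100); expect_equal(id$n_A, 60)
  # background 1 kHz over 1 ms removes one count per channel
  bg <- correct_counts(b, correction_factors(bg_rate_D = 1e-6,
                                             bg_rate_A = 1e-6))
  expect_equal(bg$n_D, 99); expect_equal(bg$n_A, 59)
  # full chain: bg -> leakage -> direct excitation -> gamma
  cf <- correction_factors(bg_rate_D = 1e-6, bg_rate_A = 1e-6,
                           crosstalk = 0.05, direct_exc = 0.1,
                           gamma = 1.2)
  full <- correct_counts(b, cf)
  expect_equal(full$n_D, 1.2 * 99)
  expect_equal(full$n_A, 59 - 0.05 * 99 - 0.1 * 40)
  # overshooting corrections clamp at zero with a flag
  tiny <- b; tiny$n_A_raw <- 1
  cl <- correct_counts(tiny, correction_factors(crosstalk = 0.2))
  expect_equal(cl$n_A, 0)
  expect_true(cl$clamped)
})

test_that("crosstalk correction removes the leaked acceptor signal of a
           donor-only species", {
  set.seed(164)
  n_bursts <- 1000
  nD <- stats::rpois(n_bursts, 120)
  # correction factor is leaked-to-detected-donor ratio lk = 0.05, i.e.
  # a per-photon rerouting probability lk/(1 + lk)
  leak <- stats::rbinom(n_bursts, nD, 0.05 / 1.05)
  b <- data.frame(burst_id = seq_len(n_bursts), start_ns = 0, stop_ns = 0,
                  duration_ns = 1e5, n_D_raw = nD - leak, n_A_raw = leak,
                  n_Aex_raw = 0, n_total = nD)
  cc <- correct_counts(b, correction_factors(crosstalk = 0.05))
  # the leaked signal (~5.7 counts/burst) is removed to the sub-photon
  # level; zero-clamping keeps the burst-mean slightly above zero
  expect_gt(mean(b$n_A_raw), 5)
  expect_lt(mean(cc$n_A), 1)
  expect_equal(stats::median(cc$n_A), 0)
})

test_that("efficiency and stoichiometry filtering: values, strictness, and
           donor-only removal", {
  b <- data.frame(burst_id = 1:4, start_ns = 0, stop_ns = 0,
                  duration_ns = 1e5,
                  n_D = c(30, 40, 100, 35), n_A = c(30, 10, 2, 32),
                  n_Aex_raw = c(15, 15, 15, 268),
                  n_D_raw = 0, n_A_raw = 0, n_total = 0)
  f_all <- efficiency_stoichiometry_filter(b, e_peak = 0.5,
                                           apply_s = FALSE)
  expect_equal(f_all$E[f_all$burst_id == 1], 0.5)
  # S = 67/(67+268) = 0.2 exactly: rejected by the strict inequality
  f_s <- efficiency_stoichiometry_filter(b, e_peak = 0.5)
  expect_false(4 %in% f_s$burst_id)
  # donor-only burst (E ~ 0.02) removed by the efficiency window
  expect_false(3 %in% f_all$burst_id)
  expect_true(all(abs(f_all$E - 0.5) <= 0.2))
  # S = 0.8 exactly is rejected too
  b8 <- b[1, ]; b8$n_Aex_raw <- 15  # S = 60/75 = 0.8
  expect_equal(nrow(efficiency_stoichiometry_filter(b8, e_peak = 0.5)), 0L)
})

test_that("filter criteria commute (S then E equals E then S)", {
  set.seed(165)
  n <- 300
  b <- data.frame(burst_id = 1:n, start_ns = 0, stop_ns = 0,
                  duration_ns = 1e5,
                  n_D = stats::rpois(n, 60), n_A = stats::rpois(n, 55),
                  n_Aex_raw = stats::rpois(n, sample(c(30, 500), n, TRUE)),
                  n_D_raw = 0, n_A_raw = 0, n_total = 0)
  se <- efficiency_stoichiometry_filter(b, e_peak = 0.5)
  es <- efficiency_stoichiometry_filter(
    efficiency_stoichiometry_filter(b, e_peak = 0.5, apply_s = FALSE),
    e_peak = 0.5)
  expect_equal(sort(se$burst_id), sort(es$burst_id))
})

test_that("burst mean lifetime: formula limits and worked arithmetic", {
  # tau' = 3.0, <t>_bg = 12.5, alpha = 0.2, <t>_IRF = 0.5 -> 0.125 ns
  expect_equal((3.0 - 0.2 * 12.5) / (1 - 0.2) - 0.5, 0.125)
  set.seed(166)
  # photons drawn from exp(4 ns): recovered mean lifetime near 4
  n <- 200
  st <- data.frame(time_ns = sort(stats::runif(n, 0, 1e5)),
                   microtime_ns = stats::rexp(n, 1 / 4),
                   channel = "D", polarization = "par",
                   excitation = "Dex")
  class(st) <- c("photon_stream", "data.frame")
  b <- data.frame(burst_id = 1L, start_ns = 0, stop_ns = 1e5,
                  duration_ns = 1e5, n_D_raw = n, n_A_raw = 0,
                  n_Aex_raw = 0, n_total = n)
  out <- burst_mean_lifetime(st, b, correction_factors(), bin_ns = 1e5)
  expect_lt(abs(out$tau_D_ns - 4), 3 * 4 / sqrt(n))
  # alpha = 0 limit: just the IRF shift
  out2 <- burst_mean_lifetime(st, b,
                              correction_factors(mean_irf_ns = 0.5),
                              bin_ns = 1e5)
  expect_equal(out2$tau_D_ns, out$tau_D_ns - 0.5)
  # background exceeding the signal flags the burst
  out3 <- burst_mean_lifetime(st, b,
                              correction_factors(bg_rate_D = 1,
                                                 bg_mean_time_D = 2),
                              bin_ns = 1e5)
  expect_true(out3$alpha_exceeded)
  expect_true(is.na(out3$tau_D_ns))
})

test_that("perpendicular photons are weighted 2G in the mean microtime", {
  st <- data.frame(time_ns = c(10, 20), microtime_ns = c(2, 5),
                   channel = "D", polarization = c("par", "perp"),
                   excitation = "Dex")
  class(st) <- c("photon_stream", "data.frame")
  b <- data.frame(burst_id = 1L, start_ns = 0, stop_ns = 100,
                  duration_ns = 100, n_D_raw = 2, n_A_raw = 0,
                  n_Aex_raw = 0, n_total = 2)
  out <- burst_mean_lifetime(st, b, correction_factors(G_pol = 1.5),
                             bin_ns = 100)
  expect_equal(out$tau_D_ns, (2 + 2 * 1.5 * 5) / (1 + 2 * 1.5))
})

test_that("sampling-oracle lifetime recovery over many bursts", {
  set.seed(167)
  n_bursts <- 300; per <- 80
  mt <- stats::rexp(n_bursts * per, 1 / 4)
  st <- data.frame(time_ns = sort(stats::runif(n_bursts * per, 0, 3e7)),
                   microtime_ns = mt, channel = "D",
                   polarization = "par", excitation = "Dex")
  class(st) <- c("photon_stream", "data.frame")
  b <- find_bursts(st, bin_ns = 1e5, threshold = 50)
  out <- burst_mean_lifetime(st, b, correction_factors(), bin_ns = 1e5)
  est <- mean(out$tau_D_ns, na.rm = TRUE)
  expect_lt(abs(est - 4), 2 * 4 / sqrt(sum(b$n_total)) * 3)
})

test_that("shot-noise PDA: binomial mean/variance identities and chi2
           contrast between shot-noise-limited and broadened data", {
  set.seed(168)
  n_bursts <- 2000; E <- 0.55
  sizes <- stats::rpois(n_bursts, 150) + 30
  nA <- stats::rbinom(n_bursts, sizes, E)
  b <- data.frame(burst_id = seq_len(n_bursts), n_D = sizes - nA,
                  n_A = nA, E = nA / sizes)
  pda <- fit_efficiency_histogram(b, "shotnoise_pda", mean_E = E)
  # predicted histogram mean equals <E> for any burst-size distribution
  mids <- (pda$breaks[-1] + pda$breaks[-length(pda$breaks)]) / 2
  expect_equal(sum(mids * pda$expected) / sum(pda$expected), E,
               tolerance = 0.002)
  expect_lt(pda$chi2 / pda$dof, 2.2)  # consistent with shot noise
  # extra distance variance inflates chi2
  E_i <- pmin(pmax(stats::rnorm(n_bursts, E, 0.08), 0.01), 0.99)
  nA2 <- stats::rbinom(n_bursts, sizes, E_i)
  b2 <- data.frame(burst_id = seq_len(n_bursts), n_D = sizes - nA2,
                   n_A = nA2, E = nA2 / sizes)
  pda2 <- fit_efficiency_histogram(b2, "shotnoise_pda", mean_E = E)
  expect_gt(pda2$chi2 / pda2$dof, 3 * pda$chi2 / pda$dof)
  # single burst size: predicted variance is E(1-E)/n
  b3 <- data.frame(burst_id = 1:500, n_D = 100 - stats::rbinom(500, 100, E),
                   n_A = stats::rbinom(500, 100, E))
  b3$E <- b3$n_A / 100
  pda3 <- fit_efficiency_histogram(b3, "shotnoise_pda", mean_E = E,
                                   breaks = seq(-0.005, 1.005, 0.01))
  m3 <- (pda3$breaks[-1] + pda3$breaks[-length(pda3$breaks)]) / 2
  pv <- sum(m3^2 * pda3$expected) / sum(pda3$expected) -
        (sum(m3 * pda3$expected) / sum(pda3$expected))^2
  expect_equal(pv, E * (1 - E) / 100, tolerance = 0.05)
})

test_that("gaussian peak fit recovers the mean and the shot-noise width
           scaling", {
  set.seed(169)
  mk <- function(nbar) {
    sizes <- stats::rpois(3000, nbar) + 20
    nA <- stats::rbinom(3000, sizes, 0.5)
    data.frame(burst_id = seq_along(sizes), n_D = sizes - nA, n_A = nA,
               E = nA / sizes)
  }
  f_small <- fit_efficiency_histogram(mk(60), "gaussian")
  f_big   <- fit_efficiency_histogram(mk(240), "gaussian")
  expect_equal(f_small$mean, 0.5, tolerance = 0.01)
  expect_equal(f_big$mean, 0.5, tolerance = 0.01)
  # width tracks sqrt(<1/n>): quadrupling burst size halves the sd
  expect_equal(f_small$sd / f_big$sd, 2, tolerance = 0.25)
  expect_error(fit_efficiency_histogram(mk(60)[1:10, ], "gaussian"),
               ">= 50")
})
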