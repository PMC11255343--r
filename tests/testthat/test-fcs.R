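test_that("independent Poisson streams decorrelate to G = 0", {
  set.seed(171)
  t1 <- sort(stats::runif(4e4, 0, 1e6))
  t2 <- sort(stats::runif(4e4, 0, 1e6))
  cv <- correlate_pair(t1, t2, linear_lag_grid(200, 4),
                       duration_ns = 1e6)
  se <- 1 / sqrt(cv$pairs)
  expect_true(all(abs(cv$G) < 4 * se))
  expect_lt(mean(abs(cv$G) > 2 * se), 0.15)
  expect_error(correlate_pair(numeric(0), t2, c(0, 1)), "empty")
})

test_that("telegraph-modulated emission matches the analytic correlation", {
  set.seed(172)
  k <- 1e-3            # switch rate each way (1/ns): tau_c = 1/(2k)
  rate_on <- 0.05
  dur <- 4e6
  sw <- cumsum(stats::rexp(ceiling(4 * dur * k), k))
  sw <- sw[sw < dur]
  n <- stats::rpois(1, rate_on * dur)
  tt <- sort(stats::runif(n, 0, dur))
  on <- findInterval(tt, sw) %% 2 == 0
  tt <- tt[on]
  half <- split_detectors(tt)
  cv <- correlate_pair(half$det1, half$det2,
                       linear_lag_grid(3000, 50), duration_ns = dur)
  # analytic: amplitude (1-p)/p = 1 at p = 0.5, decay rate 2k
  fit <- minpack.lm::nlsLM(G ~ A * exp(-lag_ns * rr),
                           data = data.frame(G = cv$G, lag_ns = cv$lag_ns),
                           start = list(A = 0.8, rr = 1e-3))
  co <- stats::coef(fit)
  expect_rel_equal(unname(co["A"]), 1, 0.05)
  expect_rel_equal(unname(co["rr"]), 2 * k, 0.05)
})

test_that("FRET photon streams give positive auto- and negative
           cross-correlation amplitudes with a shared timescale", {
  d <- gc_ref()
  traj <- simulate_end_to_end_bd(d, 0.5, dt = 0.05, n_steps = 2e7,
                                 seed = 173)
  cfg <- photon_sim_config(mode = "CW", ex_rate = 0.05,
                           duration_ns = 9.9e5, R0 = R0_REF,
                           tau_D0 = 1, tau_A0 = 1)
  st <- simulate_photon_stream(traj, cfg, seed = 174)
  set.seed(175)
  sA <- split_detectors(st$time_ns[st$channel == "A"])
  sD <- split_detectors(st$time_ns[st$channel == "D"])
  edges <- linear_lag_grid(150, 2)
  cAA <- correlate_pair(sA$det1, sA$det2, edges)
  cDD <- correlate_pair(sD$det1, sD$det2, edges)
  cAD <- correlate_pair(sA$det1, sD$det2, edges)
  fit <- fit_nsfcs(list(AA = cAA, DD = cDD, AD = cAD), tau_max_ns = 140)
  expect_gt(fit$per_curve$c_cd[fit$per_curve$pair == "AA"], 0)
  expect_gt(fit$per_curve$c_cd[fit$per_curve$pair == "DD"], 0)
  expect_lt(fit$per_curve$c_cd[fit$per_curve$pair == "AD"], 0)
  # shared timescale of the right magnitude (the quantitative recovery
  # check runs on a longer stream in the headline suite)
  tau_true <- trajectory_correlation_time(
    traj, function(r) efficiency_of_distance(r, R0_REF))
  expect_gt(fit$tau_cd, tau_true / 2)
  expect_lt(fit$tau_cd, tau_true * 2)
})

test_that("nsFCS generative recovery: curves synthesized from the model
           return tau_cd within 2%", {
  set.seed(176)
  edges <- linear_lag_grid(150, 1)
  lag <- (edges[-1] + edges[-length(edges)]) / 2
  true <- list(AA = list(b = 1, c_ab = 0.6, tau_ab = 2, c_cd = 0.3),
               DD = list(b = 1, c_ab = 0.5, tau_ab = 2.2, c_cd = 0.25),
               AD = list(b = 1, c_ab = 0.4, tau_ab = 1.8, c_cd = -0.35))
  curves <- lapply(true, function(p) {
    g <- ssnadyn:::nsfcs_model(lag, p$b, p$c_ab, p$tau_ab, p$c_cd, 10)
    gn <- g - 1 + stats::rnorm(length(g), 0, 0.003)  # back to G scale
    structure(data.frame(lag_ns = lag, G = gn, weight = 1 / 0.003^2,
                         pairs = 1),
              class = c("correlation_curve", "data.frame"))
  })
  fit <- fit_nsfcs(curves, tau_max_ns = 150)
  expect_rel_equal(fit$tau_cd, 10, 0.02)
  expect_equal(fit$per_curve$c_cd, c(0.3, 0.25, -0.35), tolerance = 0.05)
  expect_warning(fit_nsfcs(curves, tau_max_ns = 30, tau_cd_init = 10),
                 "tau_max")
})

test_that("full FCS global fit recovers generating parameters and the
           shared-timescale constraint", {
  set.seed(177)
  edges <- log_lag_grid(1, 1e8, 16)
  lag <- (edges[-1] + edges[-length(edges)]) / 2
  pars <- list(
    AA = list(a = 0.8, c_ab = 0.8, tau_ab = 2, c_cd = 0.25, c_T = 0.3,
              tau_T = 3e3, tau_diff = 1e6),
    DD = list(a = 0.6, c_ab = 0.7, tau_ab = 2.5, c_cd = 0.2, c_T = 0.25,
              tau_T = 3e3, tau_diff = 1e6),
    AD = list(a = 0.7, c_ab = 0.5, tau_ab = 2.2, c_cd = -0.3, c_T = 0.2,
              tau_T = 3e3, tau_diff = 1e6))
  tau_cd <- 12
  curves <- lapply(pars, function(p) {
    g <- ssnadyn:::full_fcs_model(lag, p$a, p$c_ab, p$tau_ab, p$c_cd,
                                  tau_cd, p$c_T, p$tau_T, p$tau_diff, 5.3)
    s <- 0.01 * pmax(abs(g), 0.02)
    structure(data.frame(lag_ns = lag, G = g + stats::rnorm(length(g), 0, s),
                         weight = 1 / s^2, pairs = 1),
              class = c("correlation_curve", "data.frame"))
  })
  fit <- fit_full_fcs(curves, s_fixed = 5.3)
  # tau_cd within 3 sd of the generating value (sd from the covariance)
  cv <- solve(fit$fit$hessian)
  s2 <- fit$fit$deviance / (length(fit$fit$fvec) - length(fit$fit$par))
  sd_l <- sqrt(cv["ltau_cd", "ltau_cd"] * s2)
  expect_lt(abs(log(fit$tau_cd) - log(tau_cd)), 3 * sd_l)
  expect_equal(fit$per_curve$a, c(0.8, 0.6, 0.7), tolerance = 0.05)
  expect_equal(fit$per_curve$c_cd, c(0.25, 0.2, -0.3), tolerance = 0.15)
  expect_length(fit$tau_cd, 1L)  # one shared dynamics time for all curves

  # null chain-dynamics component: with tau_cd pinned by a dynamic
  # curve, a curve generated with c_cd = 0 fits a c_cd consistent with 0
  mk0 <- function(p, ccd) {
    g <- ssnadyn:::full_fcs_model(lag, p$a, p$c_ab, p$tau_ab, ccd, tau_cd,
                                  p$c_T, p$tau_T, p$tau_diff, 5.3)
    s <- 0.01 * pmax(abs(g), 0.02)
    structure(data.frame(lag_ns = lag, G = g + stats::rnorm(length(g), 0, s),
                         weight = 1 / s^2, pairs = 1),
              class = c("correlation_curve", "data.frame"))
  }
  fit0 <- fit_full_fcs(list(AA = mk0(pars$AA, 0.25),
                            DD = mk0(pars$DD, 0)), s_fixed = 5.3)
  expect_lt(abs(fit0$per_curve$c_cd[2]), 0.05)
})

test_that("the short-lag reduction of the full model recovers tau_cd when
           timescales are separated", {
  set.seed(178)
  edges <- linear_lag_grid(150, 1)
  lag <- (edges[-1] + edges[-length(edges)]) / 2
  # timescale separation >= 30x above the fit window: tau_cd 10,
  # tau_T 3e3, tau_diff 1e6
  curves <- lapply(list(AA = 0.25, DD = 0.2, AD = -0.3), function(ccd) {
    g <- ssnadyn:::full_fcs_model(lag, 0.7, 0.6, 2, ccd, 10, 0.25, 3e3,
                                  1e6, 5.3)
    structure(data.frame(lag_ns = lag,
                         G = g + stats::rnorm(length(g), 0, 0.002),
                         weight = 1 / 0.002^2, pairs = 1),
              class = c("correlation_curve", "data.frame"))
  })
  fit <- fit_nsfcs(curves, tau_max_ns = 100)
  expect_rel_equal(fit$tau_cd, 10, 0.05)
})

test_that("normalization constants track the correlation at tau_max", {
  set.seed(179)
  edges <- linear_lag_grid(150, 1)
  lag <- (edges[-1] + edges[-length(edges)]) / 2
  g <- ssnadyn:::nsfcs_model(lag, 1, 0.5, 2, 0.3, 10)
  cv <- structure(data.frame(lag_ns = lag, G = 0.4 * g - 1 + 0.4,
                             weight = 1e4, pairs = 1),
                  class = c("correlation_curve", "data.frame"))
  fit <- fit_nsfcs(list(AA = cv, AA2 = cv), tau_max_ns = 150)
  tail_G <- mean(cv$G[cv$lag_ns >= 0.7 * 150])
  expect_equal(unname(fit$b_norm[1]), 1 / (1 + tail_G), tolerance = 1e-10)
})

test_that("within-burst correlation restricts pairs to single bursts", {
  set.seed(180)
  # two bursts far apart; pairs across the gap must not contribute
  t_b1 <- sort(stats::runif(400, 0, 5e4))
  t_b2 <- sort(stats::runif(400, 2e6, 2e6 + 5e4))
  tt <- c(t_b1, t_b2)
  ids <- rep(c(1L, 2L), each = 400)
  cv <- correlate_pair(tt, tt, linear_lag_grid(1e4, 500),
                       within_bursts = TRUE, id_i = ids, id_j = ids,
                       burst_durations_ns = c(5e4, 5e4))
  # flat (Poisson within burst): G ~ 0, and it must not error
  expect_true(all(is.finite(cv$G)))
  expect_lt(mean(abs(cv$G[cv$lag_ns < 2e4])), 0.2)
})

test_that("viscosity calibration: exact interpolation, identity point,
           monotonicity guard, and noisy coverage", {
  cal <- data.frame(eta_rel = c(1, 1.5, 2, 2.5, 3),
                    tau_diff = 0.4 * c(1, 1.5, 2, 2.5, 3))
  expect_equal(suppressWarnings(viscosity_from_diffusion(0.4, cal))$eta_est,
               1, tolerance = 1e-9)
  expect_equal(suppressWarnings(
    viscosity_from_diffusion(0.4 * 1.75, cal))$eta_est, 1.75,
    tolerance = 1e-9)
  bad <- cal; bad$tau_diff[3] <- 0.2
  expect_error(viscosity_from_diffusion(0.5, bad), "monotone")
  set.seed(181)
  tq <- stats::qt(0.975, df = 3)  # 5 points, 2 fitted coefficients
  hits <- vapply(1:500, function(i) {
    noisy <- cal
    noisy$tau_diff <- cal$tau_diff * (1 + stats::rnorm(5, 0, 0.05))
    noisy <- noisy[order(noisy$eta_rel), ]
    if (any(diff(noisy$tau_diff) <= 0)) return(NA)
    v <- viscosity_from_diffusion(0.4 * 2.2, noisy)
    abs(v$eta_est - 2.2) < tq * v$sd
  }, NA)
  expect_gt(mean(hits, na.rm = TRUE), 0.85)
})

test_that("correlation curve CSV round trip", {
  set.seed(182)
  t1 <- sort(stats::runif(5e3, 0, 1e6)); t2 <- sort(stats::runif(5e3, 0, 1e6))
  cv <- correlate_pair(t1, t2, linear_lag_grid(100, 5), duration_ns = 1e6)
  f <- tempfile(fileext = ".csv")
  write_correlation_csv(cv, f, pair = "AD")
  back <- read_correlation_csv(f)
  expect_equal(back$G, cv$G)
  unlink(f)
})
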