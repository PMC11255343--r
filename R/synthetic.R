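#' Brownian end-to-end distance trajectory in a potential of mean force
#'
#' Overdamped Langevin (Euler-Maruyama) integration of the end-to-end
#' distance r(t) with drift D dlnP/dr (the PMF force in k_B T units) and
#' noise sqrt(2 D dt), with reflecting boundaries at the edges of the
#' region where the density exceeds 1e-10 of its maximum. This is the
#' generative counterpart of the diffusion-in-a-PMF model used to convert
#' correlation times, and serves as its simulation oracle.
#'
#' @param dist a [distance_distribution] defining the PMF.
#' @param D diffusion coefficient (nm^2/ns).
#' @param dt time step (ns); should be well below the reconfiguration
#'   time (dt <= tau_r / 500 recommended).
#' @param n_steps number of steps.
#' @param seed RNG seed (integer); NULL uses the current RNG state.
#' @param thin keep every `thin`-th point.
#' @param burn_in steps discarded before recording (defaults to
#'   min(n_steps/10, 2e5) to reach stationarity from the mode start).
#' @param r_start starting distance; defaults to the distribution mode.
#' @return object of class `bd_trajectory`: list with `r` (nm), `dt`
#'   (effective output spacing, ns), `D`, and the source `dist`.
#' @export
simulate_end_to_end_bd <- function(dist, D, dt, n_steps, seed = NULL,
                                   thin = 1L, burn_in = NULL,
                                   r_start = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(burn_in)) burn_in <- as.integer(min(n_steps / 10, 2e5))
  tab <- bd_drift_table(dist)
  # stability: the drift step must stay well below the well width over
  # the dynamically relevant region (deep-tail forces are clamped to the
  # noise scale by the integrator)
  core <- tab$p >= 1e-4 * max(tab$p)
  if (max(abs(D * tab$dlnp[core])) * dt > 0.2 * (tab$rmax - tab$rmin))
    stop("dt too large for this PMF: drift step exceeds well width; ",
         "reduce dt", call. = FALSE)
  if (is.null(r_start)) r_start <- tab$r[which.max(tab$p)]
  total <- as.integer(burn_in) + as.integer(n_steps)
  r <- bd_simulate_cpp(r_start, D, dt, total, tab$dlnp, tab$r[1],
                       tab$r[2] - tab$r[1], tab$rmin, tab$rmax,
                       as.integer(thin))
  drop <- as.integer(burn_in / thin)
  r <- r[(drop + 1):length(r)]
  structure(list(r = r, dt = dt * thin, D = D, dist = dist),
            class = "bd_trajectory")
}

bd_drift_table <- function(dist, n = 4001L, floor_rel = 1e-10) {
  rg <- ddist_grid(dist, n)
  p <- ddist_pdf(dist, rg)
  keep <- which(p >= floor_rel * max(p))
  idx <- min(keep):max(keep)
  rg <- rg[idx]; p <- p[idx]
  lp <- log(p)
  dlnp <- c(diff(lp[1:2]), (lp[-(1:2)] - lp[1:(length(lp) - 2)]) / 2,
            diff(lp[(length(lp) - 1):length(lp)])) / diff(rg[1:2])
  list(r = rg, p = p, dlnp = dlnp, rmin = rg[1], rmax = rg[length(rg)])
}

#' First-passage times to end-to-end contact by Brownian dynamics
#'
#' Simulates first-passage times from stationary starting distances
#' (drawn from the distribution, restricted above the contact distance)
#' to an absorbing boundary at r = a -- the simulation oracle for the
#' diffusion-limited part of the end-to-end contact rate.
#'
#' @param dist a [distance_distribution].
#' @param D diffusion coefficient (nm^2/ns).
#' @param a contact (absorbing) distance, nm.
#' @param n_starts number of independent starts.
#' @param dt time step (ns).
#' @param t_max_ns per-start time cap (unreached passages return NA).
#' @param seed RNG seed.
#' @return numeric vector of passage times (ns), NA where the cap was hit.
#' @export
simulate_first_passage <- function(dist, D, a = 0.4, n_starts = 200,
                                   dt = 0.002, t_max_ns = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- bd_drift_table(dist)
  starts <- ddist_sample(dist, 3 * n_starts)
  starts <- starts[starts > a][seq_len(n_starts)]
  if (is.null(t_max_ns))
    t_max_ns <- 100 * contact_rate(dist, D, a = a)$tau_diff_ns
  bd_first_passage_cpp(starts, a, D, dt, as.integer(t_max_ns / dt),
                       tab$dlnp, tab$r[1], tab$r[2] - tab$r[1],
                       tab$rmin, tab$rmax)
}

#' Decorrelation time of a trajectory observable
#'
#' Integral of the normalized autocorrelation function of f(r(t)),
#' integrated up to its first decay below `cut` (with exponential-tail
#' completion), the simulation-side definition of a correlation time.
#'
#' @param traj a `bd_trajectory` (or list with `r`, `dt`).
#' @param f observable function of r (default identity).
#' @param max_lag_ns maximum lag considered.
#' @param cut normalized-ACF level at which integration stops and the
#'   remaining tail is completed assuming exponential decay.
#' @return correlation time in ns.
#' @export
trajectory_correlation_time <- function(traj, f = identity,
                                        max_lag_ns = NULL, cut = 0.05) {
  x <- f(traj$r)
  x <- x - mean(x)
  n <- length(x)
  if (is.null(max_lag_ns)) max_lag_ns <- n * traj$dt / 50
  lag_max <- min(n - 2L, ceiling(max_lag_ns / traj$dt))
  # FFT autocorrelation (zero-padded, biased normalization cancels in
  # the ratio to lag 0 over the short lags used here)
  m <- stats::nextn(2L * n)
  ft <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(Mod(ft)^2, inverse = TRUE))[1:(lag_max + 1)]
  ac <- ac / ac[1]
  below <- which(ac < cut)
  k <- if (length(below)) below[1] else length(ac)
  tau_sum <- (sum(ac[1:k]) - 0.5 * (ac[1] + ac[k])) * traj$dt
  # exponential completion of the truncated tail
  if (ac[k] > 0 && k > 2) {
    rate <- -log(ac[k] / ac[max(1, k - 5)]) / (5 * traj$dt)
    if (is.finite(rate) && rate > 0) tau_sum <- tau_sum + ac[k] / rate
  }
  tau_sum
}

#' Configuration for the FRET photon-stream simulator
#'
#' @param mode "CW" (continuous donor excitation, Poisson excitation
#'   events) or "PIE" (pulsed interleaved excitation with alternating
#'   donor/acceptor pulses).
#' @param ex_rate donor excitation rate (1/ns) in CW mode.
#' @param pulse_period_ns full alternation period in PIE mode (default 50
#'   ns, i.e. 20 MHz per excitation color with donor and acceptor pulses
#'   interleaved at half-period).
#' @param p_ex_pulse excitation probability per pulse (PIE).
#' @param R0,tau_D0,tau_A0 Foerster radius (nm) and unquenched donor /
#'   acceptor lifetimes (ns).
#' @param bg_rate_D,bg_rate_A background count rates (1/ns).
#' @param crosstalk donor-photon leakage fraction into the acceptor
#'   channel.
#' @param direct_exc probability of direct acceptor excitation per donor
#'   excitation event.
#' @param det_eff_donor relative donor detection efficiency (the gamma
#'   nuisance; 1 = balanced).
#' @param triplet_rate_on,triplet_rate_off dark-state entry rate and
#'   recovery rate (1/ns); both 0 disables blinking.
#' @param diff_time_ns mean in-focus dwell of the optional two-state
#'   in-focus/out-of-focus intensity envelope emulating translational
#'   diffusion; NULL disables it.
#' @param diff_duty fraction of time in focus (sets the mean
#'   out-of-focus dwell to diff_time_ns (1 - duty)/duty).
#' @param irf_mean_ns,irf_sd_ns IRF time shift and Gaussian jitter applied
#'   to microtimes.
#' @param p_perp probability that a detected photon is perpendicular
#'   polarized.
#' @param duration_ns total simulated time.
#' @return list of class `photon_sim_config`.
#' @export
photon_sim_config <- function(mode = c("CW", "PIE"), ex_rate = 0.05,
                              pulse_period_ns = 50, p_ex_pulse = 0.5,
                              R0 = 5.4, tau_D0 = 4.0, tau_A0 = 3.9,
                              bg_rate_D = 0, bg_rate_A = 0,
                              crosstalk = 0, direct_exc = 0,
                              det_eff_donor = 1,
                              triplet_rate_on = 0, triplet_rate_off = 0,
                              diff_time_ns = NULL, diff_duty = 0.5,
                              irf_mean_ns = 0, irf_sd_ns = 0,
                              p_perp = 0.5, duration_ns = 1e6) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, ex_rate = ex_rate,
              pulse_period_ns = pulse_period_ns, p_ex_pulse = p_ex_pulse,
              R0 = R0, tau_D0 = tau_D0, tau_A0 = tau_A0,
              bg_rate_D = bg_rate_D, bg_rate_A = bg_rate_A,
              crosstalk = crosstalk, direct_exc = direct_exc,
              det_eff_donor = det_eff_donor,
              triplet_rate_on = triplet_rate_on,
              triplet_rate_off = triplet_rate_off,
              diff_time_ns = diff_time_ns, diff_duty = diff_duty,
              irf_mean_ns = irf_mean_ns, irf_sd_ns = irf_sd_ns,
              p_perp = p_perp, duration_ns = duration_ns)
  stopifnot(all(vapply(cfg[c("ex_rate", "bg_rate_D", "bg_rate_A")],
                       function(x) x >= 0, TRUE)), duration_ns > 0)
  structure(cfg, class = "photon_sim_config")
}

# alternating on/off state of a telegraph process at query times;
# returns TRUE where the process is "on". Starts "on".
telegraph_switches <- function(duration, rate_to_off, rate_to_on) {
  if (rate_to_off <= 0 || rate_to_on <= 0) return(numeric(0))
  sw <- numeric(0); t <- 0
  while (t < duration) {
    k <- 200L  # even block size keeps the on/off parity
    dwell <- stats::rexp(k, rate = rep(c(rate_to_off, rate_to_on),
                                       length.out = k))
    sw <- c(sw, t + cumsum(dwell))
    t <- sw[length(sw)]
  }
  sw
}

telegraph_state <- function(times, switches) {
  if (!length(switches)) return(rep(TRUE, length(times)))
  findInterval(times, switches) %% 2 == 0  # even count => initial (on)
}

#' Simulate a FRET photon stream from a distance trajectory
#'
#' Generates donor/acceptor photon records for a single molecule whose
#' interdye distance follows the supplied trajectory (or stays at a fixed
#' distance). Each excitation event transfers to the acceptor with
#' probability eps(r(t)); donor photons carry exponential microtimes with
#' the FRET-quenched lifetime tau_D0 (1 - eps), acceptor photons the
#' transfer delay plus an exponential tau_A0 stage. Nuisance processes --
#' crosstalk, direct acceptor excitation, background, triplet blinking,
#' detection-efficiency imbalance, a diffusion intensity envelope, and
#' IRF broadening of microtimes -- are each independently switchable via
#' the configuration.
#'
#' @param traj a `bd_trajectory`, or a single number for a static
#'   distance (nm).
#' @param cfg a [photon_sim_config].
#' @param seed RNG seed; NULL uses the current state.
#' @return data.frame of class `photon_stream`, sorted by arrival time,
#'   with columns `time_ns`, `microtime_ns`, `channel` ("D"/"A"),
#'   `polarization` ("par"/"perp"), `excitation` ("Dex"/"Aex").
#' @export
simulate_photon_stream <- function(traj, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "photon_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  dur <- cfg$duration_ns
  static_r <- NULL
  if (is.numeric(traj) && length(traj) == 1L) {
    static_r <- traj
  } else {
    stopifnot(inherits(traj, "bd_trajectory"))
    if (length(traj$r) * traj$dt < dur)
      stop("trajectory shorter than requested stream duration",
           call. = FALSE)
  }
  # donor-excitation event times
  if (cfg$mode == "CW") {
    n_ex <- stats::rpois(1, cfg$ex_rate * dur)
    t_ex <- sort(stats::runif(n_ex, 0, dur))
    t_aex <- numeric(0)
  } else {
    pulses_d <- seq(0, dur, by = cfg$pulse_period_ns)
    pulses_a <- pulses_d + cfg$pulse_period_ns / 2
    pulses_a <- pulses_a[pulses_a < dur]
    t_ex  <- pulses_d[stats::runif(length(pulses_d)) < cfg$p_ex_pulse]
    t_aex <- pulses_a[stats::runif(length(pulses_a)) < cfg$p_ex_pulse]
    if (cfg$p_ex_pulse > 1)
      warning("excitation probability per pulse cannot exceed 1",
              call. = FALSE)
  }
  # nuisance gates: one shared realization for all excitation slots
  trip_sw <- telegraph_switches(dur, cfg$triplet_rate_on,
                                cfg$triplet_rate_off)
  diff_sw <- if (!is.null(cfg$diff_time_ns)) {
    t_on <- cfg$diff_time_ns
    telegraph_switches(dur, 1 / t_on,
                       cfg$diff_duty / (t_on * (1 - cfg$diff_duty)))
  } else numeric(0)
  gate <- function(tt) {
    telegraph_state(tt, trip_sw) & telegraph_state(tt, diff_sw)
  }
  t_ex <- t_ex[gate(t_ex)]
  # antibunching: a molecule already in the excited state cannot be
  # re-excited; drop excitation events landing inside the previous
  # event's excited-state dwell
  if (length(t_ex) > 1L && cfg$mode == "CW") {
    dwell <- stats::rexp(length(t_ex)) * cfg$tau_D0  # upper-bound dwell
    keep <- logical(length(t_ex))
    last_free <- -Inf
    for (i in seq_along(t_ex)) {
      if (t_ex[i] >= last_free) {
        keep[i] <- TRUE
        last_free <- t_ex[i] + dwell[i]
      }
    }
    t_ex <- t_ex[keep]
  }
  r_at <- function(tt) {
    if (!is.null(static_r)) rep(static_r, length(tt))
    else traj$r[pmin(floor(tt / traj$dt) + 1L, length(traj$r))]
  }
  eps <- efficiency_of_distance(r_at(t_ex), cfg$R0)
  transfer <- stats::runif(length(t_ex)) < eps
  tauD <- cfg$tau_D0 * (1 - eps)

  # donor emissions (no transfer), thinned by donor detection efficiency
  dn <- which(!transfer & stats::runif(length(t_ex)) < cfg$det_eff_donor)
  d_delay <- stats::rexp(length(dn)) * tauD[dn]
  # acceptor emissions from transfer
  an <- which(transfer)
  a_delay <- stats::rexp(length(an)) * tauD[an] +
    stats::rexp(length(an)) * cfg$tau_A0
  # direct acceptor excitation during donor period
  de <- which(stats::runif(length(t_ex)) < cfg$direct_exc)
  de_delay <- stats::rexp(length(de)) * cfg$tau_A0

  mk <- function(t0, delay, channel, excitation) {
    if (!length(t0)) return(NULL)
    data.frame(time_ns = t0 + delay, microtime_ns = delay,
               channel = channel, excitation = excitation)
  }
  recs <- list(mk(t_ex[dn], d_delay, "D", "Dex"),
               mk(t_ex[an], a_delay, "A", "Dex"),
               mk(t_ex[de], de_delay, "A", "Dex"))
  # acceptor-excitation (PIE) photons
  if (length(t_aex)) {
    t_aex <- t_aex[gate(t_aex)]
    recs <- c(recs, list(mk(t_aex, stats::rexp(length(t_aex)) * cfg$tau_A0,
                            "A", "Aex")))
  }
  # crosstalk: donor photons re-routed to the acceptor channel
  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (cfg$crosstalk > 0) {
    is_d <- out$channel == "D"
    flip <- is_d & stats::runif(nrow(out)) < cfg$crosstalk
    out$channel[flip] <- "A"
  }
  # background, uniform in time and microtime window
  for (ch in c("D", "A")) {
    rate <- if (ch == "D") cfg$bg_rate_D else cfg$bg_rate_A
    if (rate > 0) {
      nb <- stats::rpois(1, rate * dur)
      win <- if (cfg$mode == "PIE") cfg$pulse_period_ns / 2 else 25
      out <- rbind(out, data.frame(
        time_ns = stats::runif(nb, 0, dur),
        microtime_ns = stats::runif(nb, 0, win),
        channel = ch,
        excitation = sample(c("Dex", "Aex"), nb, replace = TRUE,
                            prob = c(if (cfg$mode == "PIE") c(.5, .5)
                                     else c(1, 0)))))
    }
  }
  # IRF shift + jitter on microtimes
  if (cfg$irf_mean_ns > 0 || cfg$irf_sd_ns > 0)
    out$microtime_ns <- pmax(0, out$microtime_ns + cfg$irf_mean_ns +
                                stats::rnorm(nrow(out), 0, cfg$irf_sd_ns))
  out$polarization <- ifelse(stats::runif(nrow(out)) < cfg$p_perp,
                             "perp", "par")
  out <- out[order(out$time_ns),
             c("time_ns", "microtime_ns", "channel", "polarization",
               "excitation")]
  rownames(out) <- NULL
  class(out) <- c("photon_stream", "data.frame")
  out
}

#' Synthetic conformer ensemble drawn from a distance distribution
#'
#' Draws member distances from the target distribution, converts them to
#' transfer efficiencies, and assigns uniform prior weights -- a stand-in
#' for a chain-growth conformer ensemble in reweighting tests.
#'
#' @param n_members ensemble size, >= 10.
#' @param dist target [distance_distribution].
#' @param R0 Foerster radius (nm).
#' @param seed RNG seed.
#' @return a [weighted_ensemble].
#' @export
synthetic_ensemble <- function(n_members, dist, R0, seed = NULL) {
  if (n_members < 10L) stop("n_members must be >= 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- ddist_sample(dist, n_members)
  weighted_ensemble(efficiency_of_distance(r, R0))
}

#' Synthetic viscosity series for internal-friction fitting
#'
#' tau_r = tau_i + eta_rel * tau_s plus Gaussian noise of standard
#' deviation noise_sd at each relative viscosity.
#'
#' @param tau_i,tau_s internal-friction and solvent terms (ns).
#' @param eta_rel vector of relative viscosities (>= 2 values).
#' @param noise_sd Gaussian noise sd (ns).
#' @param seed RNG seed.
#' @return data.frame with eta_rel, tau_r_ns, sd_ns.
#' @export
synthetic_viscosity_series <- function(tau_i, tau_s, eta_rel,
                                       noise_sd = 0, seed = NULL) {
  if (length(eta_rel) < 2L) stop("need >= 2 viscosities", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tau <- tau_i + eta_rel * tau_s +
    if (noise_sd > 0) stats::rnorm(length(eta_rel), 0, noise_sd) else 0
  data.frame(eta_rel = eta_rel, tau_r_ns = tau,
             sd_ns = rep(max(noise_sd, 1e-12), length(eta_rel)))
}

#' Photon-stream CSV I/O
#'
#' Tabular photon format: time_ns, microtime_ns, channel, polarization,
#' excitation.
#' @param stream a `photon_stream` data.frame; `path` a file path.
#' @name photon_io
#' @export
write_photon_csv <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname photon_io
#' @export
read_photon_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_ns", "microtime_ns", "channel", "polarization",
            "excitation")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$time_ns), need]
  rownames(df) <- NULL
  class(df) <- c("photon_stream", "data.frame")
  df
}
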