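#' Photon-pair correlation between two detection channels
#'
#' Unbiased pair estimator of the intensity correlation
#' \deqn{G_{ij}(\tau) = \langle I_i(t) I_j(t+\tau)\rangle /
#'   (\langle I_i\rangle \langle I_j\rangle) - 1}
#' from two photon arrival-time streams: ordered pair lags are histogrammed
#' on the supplied grid and divided by the count expected for independent
#' stationary streams. Correlating distinct detector pairs (never a
#' detector with itself) keeps the estimate free of deadtime and
#' afterpulsing artifacts by construction. With `within_bursts`, only
#' photon pairs inside the same burst are counted and the normalization
#' uses burst-local rates, restricting the correlation to the selected
#' subpopulation.
#'
#' @param t_i,t_j sorted photon arrival times (ns) of the two channels.
#' @param lag_edges increasing lag-bin edges (ns), >= 0.
#' @param within_bursts count pairs only within the same burst.
#' @param id_i,id_j per-photon burst ids (from [assign_bursts()]);
#'   required when `within_bursts`.
#' @param duration_ns total observation time (defaults to the joint time
#'   span).
#' @param burst_durations_ns per-burst durations, indexed by burst id
#'   (required for burst-local normalization).
#' @return data.frame of class `correlation_curve` with `lag_ns` (bin
#'   midpoints), `G`, `weight` (inverse variance, Poisson approximation),
#'   and `pairs` (raw pair counts).
#' @export
correlate_pair <- function(t_i, t_j, lag_edges, within_bursts = FALSE,
                           id_i = NULL, id_j = NULL, duration_ns = NULL,
                           burst_durations_ns = NULL) {
  stopifnot(!is.unsorted(t_i), !is.unsorted(t_j),
            all(diff(lag_edges) > 0), lag_edges[1] >= 0)
  if (!length(t_i) || !length(t_j))
    stop("empty photon stream: correlation undefined", call. = FALSE)
  widths <- diff(lag_edges)
  if (within_bursts) {
    if (is.null(id_i) || is.null(id_j) || is.null(burst_durations_ns))
      stop("within-burst correlation needs burst ids and durations",
           call. = FALSE)
    keep_i <- !is.na(id_i); keep_j <- !is.na(id_j)
    ti <- t_i[keep_i]; tj <- t_j[keep_j]
    ii <- id_i[keep_i]; jj <- id_j[keep_j]
    counts <- pair_counts_cpp(ti, tj, lag_edges, as.integer(ii),
                              as.integer(jj))
    # burst-local expected rate: sum_b n_i^b n_j^b / T_b per unit lag
    nb_i <- tapply(ii, ii, length)
    nb_j <- tapply(jj, jj, length)
    common <- intersect(names(nb_i), names(nb_j))
    dens <- sum(as.numeric(nb_i[common]) * as.numeric(nb_j[common]) /
                burst_durations_ns[as.integer(common)])
    expected <- dens * widths
  } else {
    counts <- pair_counts_cpp(t_i, t_j, lag_edges, integer(0), integer(0))
    if (is.null(duration_ns))
      duration_ns <- max(t_i[length(t_i)], t_j[length(t_j)]) -
                     min(t_i[1], t_j[1])
    expected <- as.numeric(length(t_i)) * as.numeric(length(t_j)) *
      widths / duration_ns
  }
  if (all(expected <= 0))
    stop("no expected pair counts: streams do not overlap", call. = FALSE)
  G <- counts / expected - 1
  w <- ifelse(counts > 0, expected^2 / counts, 0)
  out <- data.frame(lag_ns = (lag_edges[-1] + lag_edges[-length(lag_edges)]) / 2,
                    G = G, weight = w, pairs = counts)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Split one detection channel over two virtual detectors
#'
#' Emulates the 50/50 beam splitter in front of paired detectors:
#' each photon is routed to one of two detectors at random. Correlating
#' the two halves against each other (never a detector with itself)
#' keeps zero-lag artifacts -- self-pairs, deadtime, afterpulsing -- out
#' of the correlation.
#'
#' @param times sorted photon times (ns).
#' @param p routing probability to detector 1.
#' @return list with `det1` and `det2` time vectors.
#' @export
split_detectors <- function(times, p = 0.5) {
  to1 <- stats::runif(length(times)) < p
  list(det1 = times[to1], det2 = times[!to1])
}

#' Logarithmic (multi-tau style) and linear lag grids
#' @param lag_min_ns,lag_max_ns lag range (ns).
#' @param points_per_decade log-grid density.
#' @param bin_ns linear bin width (ns).
#' @return numeric vector of lag-bin edges.
#' @export
log_lag_grid <- function(lag_min_ns = 1, lag_max_ns = 1e9,
                         points_per_decade = 8) {
  n <- ceiling(log10(lag_max_ns / lag_min_ns) * points_per_decade)
  unique(lag_min_ns * 10^(seq(0, log10(lag_max_ns / lag_min_ns),
                              length.out = n + 1)))
}

#' @rdname log_lag_grid
#' @export
linear_lag_grid <- function(lag_max_ns, bin_ns = 1) {
  seq(0, lag_max_ns, by = bin_ns)
}

full_fcs_model <- function(tau, a, c_ab, tau_ab, c_cd, tau_cd, c_T,
                           tau_T, tau_diff, s) {
  a * (1 - c_ab * exp(-abs(tau) / tau_ab)) *
      (1 + c_cd * exp(-abs(tau) / tau_cd)) *
      (1 + c_T  * exp(-abs(tau) / tau_T)) /
      ((1 + abs(tau) / tau_diff) * sqrt(1 + abs(tau) / (s^2 * tau_diff)))
}

nsfcs_model <- function(tau, b, c_ab, tau_ab, c_cd, tau_cd) {
  b * (1 - c_ab * exp(-abs(tau) / tau_ab)) *
      (1 + c_cd * exp(-abs(tau) / tau_cd))
}

#' Global fit of full FCS curves
#'
#' Fits the product model with photon antibunching, chain dynamics,
#' triplet blinking, and translational diffusion through a 3D-Gaussian
#' confocal volume,
#' \deqn{G_{ij}(\tau) = a_{ij} \frac{(1 - c_{ab} e^{-|\tau|/\tau_{ab}})
#'   (1 + c_{cd} e^{-|\tau|/\tau_{cd}})(1 + c_T e^{-|\tau|/\tau_T})}
#'   {(1 + |\tau|/\tau_{D})(1 + |\tau|/(s^2 \tau_{D}))^{1/2}},}
#' jointly over several detector-pair curves with the chain-dynamics time
#' tau_cd shared; all other parameters are per curve. The aspect ratio s
#' of the detection volume is fixed (5.3 confocal, 1.0 in zero-mode
#' waveguides).
#'
#' @param curves named list of `correlation_curve` data.frames.
#' @param s_fixed fixed PSF aspect ratio.
#' @param start optional start values: list with shared `tau_cd` and
#'   per-curve lists (a, c_ab, tau_ab, c_cd, c_T, tau_T, tau_diff).
#' @return list with `tau_cd`, per-curve parameter data.frame, the
#'   `nls.lm` object, and fitted values per curve.
#' @export
fit_full_fcs <- function(curves, s_fixed = 5.3, start = NULL) {
  stopifnot(length(curves) >= 2L)
  nm <- names(curves)
  if (is.null(start)) {
    start <- list(tau_cd = 10, per_curve = lapply(curves, function(cv) {
      list(a = max(abs(cv$G[1:3])), c_ab = 0.5, tau_ab = 2,
           c_cd = 0.2 * sign(cv$G[1] + 1e-12), c_T = 0.2, tau_T = 2e3,
           tau_diff = 1e6)
    }))
  }
  # parameter packing: log for timescales/amplitude-positives, free for c's
  pack <- function(st) {
    p <- c(ltau_cd = log(st$tau_cd))
    for (k in seq_along(nm)) {
      pc <- st$per_curve[[k]]
      p <- c(p, stats::setNames(
        c(pc$a, pc$c_ab, log(pc$tau_ab), pc$c_cd, pc$c_T, log(pc$tau_T),
          log(pc$tau_diff)),
        paste0(c("a", "c_ab", "ltau_ab", "c_cd", "c_T", "ltau_T",
                 "ltau_diff"), "_", k)))
    }
    p
  }
  resid_fn <- function(p) {
    unlist(lapply(seq_along(nm), function(k) {
      cv <- curves[[k]]
      g <- full_fcs_model(cv$lag_ns,
                          a = p[paste0("a_", k)],
                          c_ab = p[paste0("c_ab_", k)],
                          tau_ab = exp(p[paste0("ltau_ab_", k)]),
                          c_cd = p[paste0("c_cd_", k)],
                          tau_cd = exp(p["ltau_cd"]),
                          c_T = p[paste0("c_T_", k)],
                          tau_T = exp(p[paste0("ltau_T_", k)]),
                          tau_diff = exp(p[paste0("ltau_diff_", k)]),
                          s = s_fixed)
      sqrt(pmax(cv$weight, 0)) * (cv$G - g)
    }))
  }
  fit <- minpack.lm::nls.lm(pack(start), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop("full FCS fit did not converge; residual norm ",
         signif(fit$deviance, 4), call. = FALSE)
  p <- fit$par
  per <- do.call(rbind, lapply(seq_along(nm), function(k) {
    data.frame(pair = nm[k], a = p[[paste0("a_", k)]],
               c_ab = p[[paste0("c_ab_", k)]],
               tau_ab = exp(p[[paste0("ltau_ab_", k)]]),
               c_cd = p[[paste0("c_cd_", k)]],
               c_T = p[[paste0("c_T_", k)]],
               tau_T = exp(p[[paste0("ltau_T_", k)]]),
               tau_diff = exp(p[[paste0("ltau_diff_", k)]]))
  }))
  list(tau_cd = exp(p[["ltau_cd"]]), per_curve = per, s = s_fixed,
       fit = fit)
}

#' Global nsFCS fit at nanosecond lags
#'
#' Fits the reduced short-lag model (the full FCS model in the limit of
#' lags far below the triplet and diffusion times, after normalization to
#' unity at tau_max)
#' \deqn{g_{ij}(\tau) = b_{ij}(1 - c_{ab} e^{-|\tau|/\tau_{ab}})
#'   (1 + c_{cd} e^{-|\tau|/\tau_{cd}})}
#' jointly over the donor/acceptor autocorrelations and the
#' donor-acceptor crosscorrelation, sharing tau_cd; the sign of the
#' per-curve chain-dynamics amplitude c_cd is free (negative for the
#' crosscorrelation).
#'
#' @param curves named list of `correlation_curve` data.frames on a
#'   linear lag grid (typically AA, DD, and the averaged AD/DA curve).
#' @param tau_max_ns normalization lag; curves are divided by their mean
#'   G over the last bins up to tau_max. Should exceed tau_cd by an order
#'   of magnitude.
#' @param tau_cd_init initial chain-dynamics time (ns).
#' @param start optional start list (shared `tau_cd`, per-curve b, c_ab,
#'   tau_ab, c_cd).
#' @return list with shared `tau_cd`, per-curve parameters, `fit`, and
#'   the normalization constants `b_norm` (1/(1 + G(tau_max)), the
#'   correlation measured on the coincidence-rate scale).
#' @export
fit_nsfcs <- function(curves, tau_max_ns, tau_cd_init = 10,
                      start = NULL) {
  nm <- names(curves)
  stopifnot(length(curves) >= 2L)
  if (tau_max_ns < 5 * tau_cd_init)
    warning("tau_max below 5x the initial tau_cd guess; ",
            "the plateau may be poorly defined", call. = FALSE)
  # work on the 1 + G scale so the tau_max plateau is finite even for
  # fully stationary streams (G -> 0); the Eq.-12 shape and the shared
  # tau_cd are unaffected by this affine normalization choice
  b_norm <- vapply(curves, function(cv) {
    tail_sel <- cv$lag_ns >= 0.7 * tau_max_ns & cv$lag_ns <= tau_max_ns
    1 / mean(1 + cv$G[tail_sel])
  }, 0)
  curves <- lapply(seq_along(curves), function(k) {
    cv <- curves[[k]]
    cv <- cv[cv$lag_ns <= tau_max_ns, , drop = FALSE]
    cv$weight <- cv$weight / b_norm[k]^2
    cv$G <- (1 + cv$G) * b_norm[k]
    cv
  })
  names(curves) <- nm
  make_start <- function(tcd, tab) {
    list(tau_cd = tcd, per_curve = lapply(curves, function(cv) {
      mid <- cv$lag_ns >= tcd & cv$lag_ns <= 3 * tcd
      c_cd0 <- if (any(mid)) mean(cv$G[mid]) - 1 else 0.1
      c_ab0 <- min(max(1 - mean(cv$G[1:3]) / (1 + c_cd0), 0.05), 0.9)
      list(b = 1, c_ab = c_ab0, tau_ab = tab, c_cd = c_cd0)
    }))
  }
  starts <- if (is.null(start)) {
    # multi-start over the dynamics and antibunching timescales guards
    # against the local minimum where one component absorbs the other
    c(lapply(tau_cd_init * c(0.3, 1, 3), make_start, tab = 2),
      lapply(tau_cd_init * c(0.5, 1), make_start, tab = 0.5))
  } else list(start)
  # b and timescales positive (log), antibunching contrast in (0, 1)
  # (logit): a single emitter cannot be more than fully antibunched
  pack <- function(st) {
    p <- c(ltau_cd = log(st$tau_cd))
    for (k in seq_along(nm)) {
      pc <- st$per_curve[[k]]
      p <- c(p, stats::setNames(
        c(log(pc$b), stats::qlogis(min(max(pc$c_ab, 1e-3), 1 - 1e-3)),
          log(pc$tau_ab), pc$c_cd),
        paste0(c("lb", "qc_ab", "ltau_ab", "c_cd"), "_", k)))
    }
    p
  }
  resid_fn <- function(p) {
    unlist(lapply(seq_along(nm), function(k) {
      cv <- curves[[k]]
      g <- nsfcs_model(cv$lag_ns, b = exp(p[paste0("lb_", k)]),
                       c_ab = stats::plogis(p[paste0("qc_ab_", k)]),
                       tau_ab = exp(p[paste0("ltau_ab_", k)]),
                       c_cd = p[paste0("c_cd_", k)],
                       tau_cd = exp(p["ltau_cd"]))
      sqrt(pmax(cv$weight, 0)) * (cv$G - g)
    }))
  }
  fits <- lapply(starts, function(st)
    minpack.lm::nls.lm(pack(st), fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12)))
  fit <- fits[[which.min(vapply(fits, function(f) f$deviance, 0))]]
  p <- fit$par
  per <- do.call(rbind, lapply(seq_along(nm), function(k) {
    data.frame(pair = nm[k], b = exp(p[[paste0("lb_", k)]]),
               c_ab = stats::plogis(p[[paste0("qc_ab_", k)]]),
               tau_ab = exp(p[[paste0("ltau_ab_", k)]]),
               c_cd = p[[paste0("c_cd_", k)]])
  }))
  list(tau_cd = exp(p[["ltau_cd"]]), per_curve = per, fit = fit,
       b_norm = b_norm)
}

#' FCS-based viscosity calibration and inverse prediction
#'
#' The translational diffusion time through the confocal volume is
#' proportional to solvent viscosity; a linear fit of
#' buffer-normalized diffusion times against known relative viscosities
#' turns a measured diffusion time into a viscosity estimate with
#' propagated uncertainty (delta method on the fit covariance).
#'
#' @param tau_diff_sample measured diffusion time of the sample (same
#'   units as the calibration).
#' @param calibration data.frame with `eta_rel` and `tau_diff` columns
#'   (>= 2 points; tau_diff must increase with eta_rel).
#' @return list with `eta_est`, `sd`, and the calibration `fit`.
#' @export
viscosity_from_diffusion <- function(tau_diff_sample, calibration) {
  stopifnot(all(c("eta_rel", "tau_diff") %in% names(calibration)))
  if (nrow(calibration) < 2L)
    stop("need >= 2 calibration points", call. = FALSE)
  o <- order(calibration$eta_rel)
  if (any(diff(calibration$tau_diff[o]) <= 0))
    stop("calibration is not monotone in viscosity", call. = FALSE)
  # fit on the raw times: normalizing by the fitted (not the measured)
  # buffer point keeps the buffer measurement's noise out of every
  # other point
  fit <- stats::lm(tau_diff ~ eta_rel, data = calibration)
  co <- stats::coef(fit)
  eta <- (tau_diff_sample - co[1]) / co[2]
  V <- stats::vcov(fit)
  grad <- c(-1 / co[2], -(tau_diff_sample - co[1]) / co[2]^2)
  sd <- sqrt(drop(t(grad) %*% V %*% grad))
  t0_fit <- co[1] + co[2]  # fitted diffusion time at eta/eta0 = 1
  list(eta_est = unname(eta), sd = unname(sd), fit = fit,
       tau_diff_buffer = unname(t0_fit))
}

#' Correlation-curve CSV I/O
#' @param curve a `correlation_curve`; `path` file path; `pair` label
#'   stored in the file.
#' @name fcs_io
#' @export
write_correlation_csv <- function(curve, path, pair = "") {
  utils::write.csv(cbind(curve, pair = pair), path, row.names = FALSE)
  invisible(path)
}

#' @rdname fcs_io
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- df[c("lag_ns", "G", "weight", "pairs")]
  class(out) <- c("correlation_curve", "data.frame")
  out
}
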