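#' Correction factors for burst analysis
#'
#' Background rates, spectral crosstalk (donor leakage into the acceptor
#' channel), detection-efficiency/quantum-yield ratio gamma, direct
#' acceptor excitation, the polarization G factor, and the timing
#' references needed for burst-averaged lifetimes (mean background
#' microtimes and mean IRF time).
#'
#' @param bg_rate_D,bg_rate_A background count rates (1/ns).
#' @param crosstalk donor leakage fraction into the acceptor channel,
#'   in [0, 1).
#' @param gamma detection-efficiency x quantum-yield ratio applied to
#'   donor counts.
#' @param direct_exc fraction of acceptor-excitation-derived counts
#'   subtracted from the acceptor signal (direct excitation correction).
#' @param G_pol polarization correction factor (perpendicular photons
#'   weighted 2 G in lifetime averages).
#' @param mean_irf_ns mean time of the instrument response function (ns).
#' @param bg_mean_time_D,bg_mean_time_A mean microtime of background
#'   photons per channel (ns).
#' @return list of class `correction_factors`.
#' @export
correction_factors <- function(bg_rate_D = 0, bg_rate_A = 0,
                               crosstalk = 0, gamma = 1, direct_exc = 0,
                               G_pol = 1, mean_irf_ns = 0,
                               bg_mean_time_D = 0, bg_mean_time_A = 0) {
  stopifnot(bg_rate_D >= 0, bg_rate_A >= 0,
            crosstalk >= 0, crosstalk < 1,
            direct_exc >= 0, direct_exc < 1, gamma > 0, G_pol > 0)
  structure(list(bg_rate_D = bg_rate_D, bg_rate_A = bg_rate_A,
                 crosstalk = crosstalk, gamma = gamma,
                 direct_exc = direct_exc, G_pol = G_pol,
                 mean_irf_ns = mean_irf_ns,
                 bg_mean_time_D = bg_mean_time_D,
                 bg_mean_time_A = bg_mean_time_A),
            class = "correction_factors")
}

#' Identify photon bursts by fixed-bin thresholding
#'
#' Photon arrivals are counted in fixed time bins; bins with more than
#' `threshold` photons are burst bins, and runs of consecutive
#' above-threshold bins are merged into single bursts (no gap tolerance).
#' Counts are tallied per channel and excitation slot.
#'
#' @param stream a `photon_stream` data.frame (time-sorted).
#' @param bin_ns bin width in ns (1 ms = 1e6 ns without ZMWs, 0.2 ms with).
#' @param threshold burst bins must contain strictly more than this many
#'   photons (default 50).
#' @return data.frame of bursts: burst_id, start_ns, stop_ns, duration_ns,
#'   n_D_raw, n_A_raw (donor-excitation donor/acceptor counts),
#'   n_Aex_raw (acceptor-excitation acceptor counts), n_total.
#' @export
find_bursts <- function(stream, bin_ns = 1e6, threshold = 50) {
  if (bin_ns <= 0) stop("bin_ns must be positive", call. = FALSE)
  empty <- data.frame(burst_id = integer(), start_ns = numeric(),
                      stop_ns = numeric(), duration_ns = numeric(),
                      n_D_raw = numeric(), n_A_raw = numeric(),
                      n_Aex_raw = numeric(), n_total = numeric())
  if (nrow(stream) == 0L) return(empty)
  bin <- floor(stream$time_ns / bin_ns)
  cnt <- table(bin)
  hot <- as.numeric(names(cnt))[cnt > threshold]
  if (!length(hot)) return(empty)
  hot <- sort(hot)
  grp <- cumsum(c(1, diff(hot) > 1))  # consecutive bins merge
  ids <- integer(nrow(stream))
  for (g in unique(grp)) {
    bins_g <- hot[grp == g]
    ids[bin %in% bins_g] <- g
  }
  in_burst <- ids > 0
  agg <- function(cond) {
    v <- tapply(cond[in_burst], ids[in_burst], sum)
    as.numeric(v)
  }
  uid <- sort(unique(ids[in_burst]))
  start <- as.numeric(tapply(stream$time_ns[in_burst], ids[in_burst], min))
  stop_ <- as.numeric(tapply(stream$time_ns[in_burst], ids[in_burst], max))
  # duration: span of the merged bins (background rate x duration needs
  # the observation window, not the photon span)
  bstart <- vapply(uid, function(g) min(hot[grp == g]) * bin_ns, 0)
  bstop  <- vapply(uid, function(g) (max(hot[grp == g]) + 1) * bin_ns, 0)
  data.frame(
    burst_id = seq_along(uid),
    start_ns = start, stop_ns = stop_,
    duration_ns = bstop - bstart,
    n_D_raw = agg(stream$channel == "D" & stream$excitation == "Dex"),
    n_A_raw = agg(stream$channel == "A" & stream$excitation == "Dex"),
    n_Aex_raw = agg(stream$channel == "A" & stream$excitation == "Aex"),
    n_total = as.numeric(table(ids[in_burst])))
}

#' Assign each photon to a burst
#'
#' @param stream a `photon_stream`.
#' @param bursts output of [find_bursts()].
#' @param bin_ns the bin width used for the burst search.
#' @return integer vector, one per photon: the burst id, or NA outside
#'   bursts.
#' @export
assign_bursts <- function(stream, bursts, bin_ns = 1e6) {
  out <- rep(NA_integer_, nrow(stream))
  if (!nrow(bursts)) return(out)
  # burst windows are whole bins; photon span is within [start, stop]
  for (i in seq_len(nrow(bursts))) {
    sel <- stream$time_ns >= bursts$start_ns[i] &
           stream$time_ns <= bursts$stop_ns[i]
    out[sel] <- bursts$burst_id[i]
  }
  out
}

#' Apply count corrections to bursts
#'
#' Fixed correction order: subtract background (rate x duration per
#' channel), subtract donor leakage (crosstalk x corrected donor counts
#' from the acceptor channel), subtract direct acceptor excitation
#' (fraction of the acceptor-excitation counts), then scale donor counts
#' by gamma. Counts driven negative are clamped at zero and flagged.
#'
#' @param bursts data.frame from [find_bursts()].
#' @param corr a [correction_factors] list.
#' @return `bursts` with corrected columns `n_D`, `n_A` and a logical
#'   `clamped` flag.
#' @export
correct_counts <- function(bursts, corr) {
  stopifnot(inherits(corr, "correction_factors"))
  nD <- bursts$n_D_raw - corr$bg_rate_D * bursts$duration_ns
  nA <- bursts$n_A_raw - corr$bg_rate_A * bursts$duration_ns
  nA <- nA - corr$crosstalk * nD
  nA <- nA - corr$direct_exc * bursts$n_Aex_raw
  nD <- corr$gamma * nD
  clamped <- nD < 0 | nA < 0
  bursts$n_D <- pmax(nD, 0)
  bursts$n_A <- pmax(nA, 0)
  bursts$clamped <- clamped
  bursts
}

#' Transfer efficiency, stoichiometry, and burst filtering
#'
#' Computes per-burst E = n_A / (n_A + n_D) from corrected counts and the
#' PIE stoichiometry S = (n_D + n_A) / (n_D + n_A + n_Aex), then keeps
#' bursts with 0.2 < S < 0.8 (strict inequalities) and, within the
#' FRET-active subpopulation, |E - E_peak| <= `e_window`. E is stored
#' unclipped: corrections can push it outside [0, 1] on small bursts.
#'
#' @param bursts corrected bursts (after [correct_counts()]).
#' @param s_lo,s_hi stoichiometry window (strict).
#' @param e_window half-width of the efficiency subpopulation window
#'   around the FRET-active peak.
#' @param e_peak FRET-active peak efficiency; estimated as the density
#'   mode of E over bursts with E > 0.25 (excluding the donor-only
#'   cluster at E ~ 0) when NULL.
#' @param apply_s whether to apply the stoichiometry filter (requires
#'   acceptor-excitation counts, i.e. PIE data).
#' @return filtered bursts with columns `E`, `S` added; bursts with zero
#'   total corrected counts are dropped. The estimated peak is attached
#'   as attribute `e_peak`.
#' @export
efficiency_stoichiometry_filter <- function(bursts, s_lo = 0.2,
                                            s_hi = 0.8, e_window = 0.2,
                                            e_peak = NULL,
                                            apply_s = TRUE) {
  tot <- bursts$n_D + bursts$n_A
  bursts <- bursts[tot > 0, , drop = FALSE]
  tot <- tot[tot > 0]
  bursts$E <- bursts$n_A / tot
  bursts$S <- tot / (tot + bursts$n_Aex_raw)
  if (apply_s && any(bursts$n_Aex_raw > 0))
    bursts <- bursts[bursts$S > s_lo & bursts$S < s_hi, , drop = FALSE]
  if (is.null(e_peak)) {
    cand <- bursts$E[bursts$E > 0.25]
    if (length(cand) >= 10) {
      den <- stats::density(cand, bw = "nrd0")
      e_peak <- den$x[which.max(den$y)]
    } else e_peak <- mean(bursts$E)
  }
  out <- bursts[abs(bursts$E - e_peak) <= e_window, , drop = FALSE]
  attr(out, "e_peak") <- e_peak
  out
}

#' Burst-averaged fluorescence lifetimes with background and IRF
#' correction
#'
#' The mean photon detection time per burst and channel (perpendicular
#' photons weighted 2 G to correct for anisotropy) is converted to a mean
#' fluorescence lifetime by
#' \deqn{\tau_x = (\tau'_x - \alpha \langle t\rangle_{bg,x}) / (1 -
#'   \alpha) - \langle t\rangle_{IRF}, \quad \alpha = n_{bg,x} \Delta /
#'   N_x,}
#' where \eqn{\tau'_x} is the raw mean microtime, \eqn{\Delta} the burst
#' duration and \eqn{N_x} the uncorrected photon count in channel x.
#'
#' @param stream the `photon_stream` the bursts came from.
#' @param bursts burst table ([find_bursts()] output or later stage).
#' @param corr a [correction_factors] list.
#' @param bin_ns the burst-search bin width.
#' @return `bursts` with `tau_D_ns`, `tau_A_ns` columns; NA (flagged in
#'   `alpha_exceeded`) where background exceeds the burst signal
#'   (alpha >= 1).
#' @export
burst_mean_lifetime <- function(stream, bursts, corr, bin_ns = 1e6) {
  ids <- assign_bursts(stream, bursts, bin_ns)
  w <- ifelse(stream$polarization == "perp", 2 * corr$G_pol, 1)
  tau <- matrix(NA_real_, nrow(bursts), 2)
  alpha_bad <- logical(nrow(bursts))
  for (i in seq_len(nrow(bursts))) {
    for (k in 1:2) {
      ch <- c("D", "A")[k]
      sel <- which(ids == bursts$burst_id[i] & stream$channel == ch &
                   stream$excitation == "Dex")
      if (!length(sel)) next
      tp <- sum(w[sel] * stream$microtime_ns[sel]) / sum(w[sel])
      n_bg <- if (ch == "D") corr$bg_rate_D else corr$bg_rate_A
      t_bg <- if (ch == "D") corr$bg_mean_time_D else corr$bg_mean_time_A
      alpha <- n_bg * bursts$duration_ns[i] / length(sel)
      if (alpha >= 1) { alpha_bad[i] <- TRUE; next }
      tau[i, k] <- (tp - alpha * t_bg) / (1 - alpha) - corr$mean_irf_ns
    }
  }
  bursts$tau_D_ns <- tau[, 1]
  bursts$tau_A_ns <- tau[, 2]
  bursts$alpha_exceeded <- alpha_bad
  bursts
}

#' Fit the burst transfer-efficiency histogram
#'
#' Gaussian mode: least-squares fit of a Gaussian peak to the binned E
#' histogram. Shot-noise PDA mode: the predicted histogram for a fixed
#' mean efficiency is the mixture, over the observed burst-size
#' distribution, of binomially partitioned counts (E_hat = k/n with
#' k ~ Binomial(n, E)); the deviation of the data from this shot-noise
#' limit is summarized by a chi-squared statistic.
#'
#' @param bursts filtered bursts with `E`, `n_D`, `n_A` columns (>= 50
#'   bursts).
#' @param mode "gaussian" or "shotnoise_pda".
#' @param breaks histogram breaks (efficiency axis).
#' @param mean_E fixed mean efficiency for the PDA prediction (default:
#'   the burst-averaged E).
#' @return gaussian mode: list(mean, sd, amplitude, fit). PDA mode:
#'   list(mean_E, breaks, observed, expected, chi2, dof, p_value).
#' @export
fit_efficiency_histogram <- function(bursts,
                                     mode = c("gaussian", "shotnoise_pda"),
                                     breaks = seq(-0.1, 1.1, by = 0.025),
                                     mean_E = NULL) {
  mode <- match.arg(mode)
  if (nrow(bursts) < 50L)
    stop("need >= 50 bursts for a histogram fit", call. = FALSE)
  h <- graphics::hist(bursts$E, breaks = breaks, plot = FALSE)
  if (mode == "gaussian") {
    x <- h$mids; y <- h$counts
    if (sum(y > 0) < 4L) stop("degenerate histogram", call. = FALSE)
    m0 <- stats::weighted.mean(x, y)
    s0 <- sqrt(stats::weighted.mean((x - m0)^2, y))
    fit <- minpack.lm::nlsLM(
      y ~ a * exp(-(x - m)^2 / (2 * s^2)),
      start = list(a = max(y), m = m0, s = max(s0, 0.01)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(fit)
    return(list(mean = unname(co["m"]), sd = abs(unname(co["s"])),
                amplitude = unname(co["a"]), fit = fit))
  }
  # shot-noise PDA: mixture over the observed burst-size distribution
  sizes <- pmax(1L, round(bursts$n_D + bursts$n_A))
  mean_estimated <- is.null(mean_E)
  if (mean_estimated) mean_E <- mean(bursts$E)
  size_tab <- table(sizes)
  probs <- numeric(length(h$mids))
  for (j in seq_along(size_tab)) {
    n <- as.integer(names(size_tab))[j]
    wn <- size_tab[[j]] / length(sizes)
    k <- 0:n
    pk <- stats::dbinom(k, n, mean_E)
    bin <- findInterval(k / n, breaks, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= length(probs)
    probs[sort(unique(bin[ok]))] <- probs[sort(unique(bin[ok]))] +
      wn * as.numeric(tapply(pk[ok], bin[ok], sum))
  }
  expected <- probs * length(sizes)
  use <- expected >= 5
  chi2 <- sum((h$counts[use] - expected[use])^2 / expected[use])
  dof <- sum(use) - 1L - mean_estimated
  list(mean_E = mean_E, breaks = breaks, observed = h$counts,
       expected = expected, chi2 = chi2, dof = dof,
       p_value = stats::pchisq(chi2, dof, lower.tail = FALSE))
}

#' Burst-table CSV I/O
#' @param bursts a burst data.frame; `path` file path.
#' @name burst_io
#' @export
write_bursts_csv <- function(bursts, path) {
  utils::write.csv(bursts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname burst_io
#' @export
read_bursts_csv <- function(path) utils::read.csv(path)
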