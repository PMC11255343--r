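#' FRET efficiency of a fixed interdye distance
#'
#' \deqn{\varepsilon(r) = R_0^6 / (R_0^6 + r^6)} with Foerster radius R0
#' (5.4 nm for the Alexa 488/594 pair at kappa^2 = 2/3).
#'
#' @param r interdye distance(s), nm, >= 0.
#' @param R0 Foerster radius, nm.
#' @return efficiencies in (0, 1]; strictly decreasing in r.
#' @export
efficiency_of_distance <- function(r, R0) {
  if (any(r < 0)) stop("distance r must be non-negative", call. = FALSE)
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive", call. = FALSE)
  1 / (1 + (r / R0)^6)
}

#' Transfer-efficiency moments over a distance distribution
#'
#' Mean \eqn{\langle\varepsilon\rangle = \int \varepsilon(r) P(r) dr} and
#' variance \eqn{\sigma_\varepsilon^2 = \int (\varepsilon(r) -
#' \langle\varepsilon\rangle)^2 P(r) dr} of the transfer efficiency for a
#' chain sampling P(r) slowly compared to the donor lifetime but fast
#' compared to the interphoton time.
#'
#' @param dist a [distance_distribution].
#' @param R0 Foerster radius (nm).
#' @return list with `mean_eff` and `var_eff`. The variance always obeys
#'   the binomial-type bound var <= mean (1 - mean).
#' @export
efficiency_moments <- function(dist, R0) {
  if (dist$family == "EMPIRICAL") {
    eps <- efficiency_of_distance(dist$r, R0)
    z  <- trapz(dist$r, dist$density)
    if (abs(z - 1) > 1e-5)
      stop("distribution is not normalized", call. = FALSE)
    m1 <- trapz(dist$r, eps * dist$density) / z
    v  <- trapz(dist$r, (eps - m1)^2 * dist$density) / z
    return(list(mean_eff = m1, var_eff = v))
  }
  s <- ddist_support(dist)
  qq <- function(f) stats::integrate(f, s[1], s[2], rel.tol = 1e-10,
                                     subdivisions = 500L)$value
  z <- qq(function(r) ddist_pdf(dist, r))
  if (abs(z - 1) > 1e-5) stop("distribution is not normalized", call. = FALSE)
  m1 <- qq(function(r) efficiency_of_distance(r, R0) * ddist_pdf(dist, r)) / z
  v  <- qq(function(r) (efficiency_of_distance(r, R0) - m1)^2 *
             ddist_pdf(dist, r)) / z
  list(mean_eff = m1, var_eff = v)
}

#' @rdname efficiency_moments
#' @export
mean_efficiency <- function(dist, R0) efficiency_moments(dist, R0)$mean_eff

#' Donor and acceptor FRET lines for dynamic chains
#'
#' For a chain whose end-to-end distance distribution is sampled fast
#' relative to the burst duration but slow relative to the donor lifetime,
#' the burst-averaged relative lifetimes deviate from the static line
#' 1 - E by the efficiency variance:
#' \deqn{\tau_D/\tau_{D0} = 1 - \langle\varepsilon\rangle +
#'       \sigma_\varepsilon^2 / (1 - \langle\varepsilon\rangle)}
#' \deqn{(\tau_A - \tau_{A0})/\tau_{D0} = 1 - \langle\varepsilon\rangle -
#'       \sigma_\varepsilon^2 / \langle\varepsilon\rangle}
#' The dynamic lines are generated by sweeping the model's free parameter
#' (GC: mean-square distance; WLC: persistence length at fixed contour
#' length; SAW-nu: scaling exponent).
#'
#' @param family polymer family, "GC", "WLC" or "SAWNU".
#' @param fret list with `R0` (nm), `tau_D0`, `tau_A0` (ns); lifetimes are
#'   carried through for reference, the line itself is dimensionless.
#' @param sweep numeric vector of the swept parameter (GC: msd nm^2; WLC:
#'   lp nm; SAWNU: nu).
#' @param lc fixed WLC contour length (nm).
#' @param b,n fixed SAW-nu segment length and count.
#' @param tau_rot,tau_r optional rotational correlation and chain
#'   reconfiguration times (ns); if supplied with the lifetimes, a warning
#'   is emitted unless tau_rot < tau_D0 < tau_r (the regime in which the
#'   moment relations hold).
#' @return data.frame with columns E, rel_donor, rel_acceptor, var_eff,
#'   model, param; points whose efficiency leaves (0, 1) are dropped with a
#'   warning. The static line is the identity `rel = 1 - E`.
#' @export
fret_lines <- function(family = c("GC", "WLC", "SAWNU"), fret, sweep,
                       lc = NULL, b = NULL, n = NULL,
                       tau_rot = NULL, tau_r = NULL) {
  family <- match.arg(family)
  check_fret_system(fret)
  if (!is.null(tau_rot) && !is.null(tau_r) &&
      !(tau_rot < fret$tau_D0 && fret$tau_D0 < tau_r))
    warning("timescales violate tau_rot < tau_D < tau_r; ",
            "lifetime moment relations may not apply", call. = FALSE)
  rows <- lapply(sweep, function(p) {
    d <- switch(family,
      GC    = dist_gc(p),
      WLC   = dist_wlc(lc, p),
      SAWNU = dist_sawnu(nu = p, b = b, n = n))
    m <- efficiency_moments(d, fret$R0)
    data.frame(E = m$mean_eff,
               rel_donor = 1 - m$mean_eff + m$var_eff / (1 - m$mean_eff),
               rel_acceptor = 1 - m$mean_eff - m$var_eff / m$mean_eff,
               var_eff = m$var_eff, model = family, param = p)
  })
  out <- do.call(rbind, rows)
  bad <- out$E <= 0 | out$E >= 1
  if (any(bad)) {
    warning(sum(bad), " sweep point(s) outside efficiency range (0,1) ",
            "dropped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

check_fret_system <- function(fret) {
  need <- c("R0", "tau_D0", "tau_A0")
  if (!all(need %in% names(fret)) ||
      !all(vapply(fret[need], function(x) is.finite(x) && x > 0, TRUE)))
    stop("fret system needs positive R0, tau_D0, tau_A0", call. = FALSE)
  invisible(fret)
}

#' Static FRET line
#'
#' Relative lifetime of fluorophores at a fixed interdye distance:
#' identical 1 - E for donor and acceptor.
#' @param E transfer efficiency.
#' @export
static_fret_line <- function(E) 1 - E

# refractive indices of glycerol-water mixtures (w/w %, 20 C, sodium D
# line), from standard physico-chemical tables; linear interpolation
.glycerol_n_table <- data.frame(
  pct = c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50),
  n   = c(1.3330, 1.3388, 1.3448, 1.3510, 1.3572, 1.3637,
          1.3703, 1.3772, 1.3841, 1.3910, 1.3981))

#' Refractive index of a glycerol-water mixture
#' @param pct_glycerol glycerol mass fraction in percent (0-50).
#' @export
glycerol_refractive_index <- function(pct_glycerol) {
  if (any(pct_glycerol < 0 | pct_glycerol > 50))
    stop("tabulated range is 0-50% w/w glycerol", call. = FALSE)
  stats::approx(.glycerol_n_table$pct, .glycerol_n_table$n,
                xout = pct_glycerol)$y
}

#' Foerster radius corrected for solvent refractive index
#'
#' R0 scales with the medium refractive index as n^{-2/3} (through the
#' n^{-4} factor in the Foerster rate and the sixth-root in R0).
#' @param R0 Foerster radius in water (nm).
#' @param n_medium refractive index of the new medium.
#' @param n_ref reference refractive index (water, 1.3330).
#' @export
correct_R0_refractive_index <- function(R0, n_medium, n_ref = 1.3330) {
  R0 * (n_medium / n_ref)^(-2 / 3)
}

#' Conformational free-energy change from two mean-square distances
#'
#' For two Gaussian-chain states a and b with mean-square end-to-end
#' distances msd_a and msd_b, the difference of the distribution entropies
#' reduces to the closed form
#' \deqn{\Delta F / k_B T = \ln\sqrt{msd_b / msd_a},}
#' used to estimate the effect of a viscogen on chain conformation from
#' the measured transfer-efficiency shift.
#'
#' @param msd_a,msd_b mean-square end-to-end distances (nm^2) of the two
#'   states (a: reference, e.g. 0% glycerol; b: perturbed).
#' @return list with `dF_kT` (signed, k_B T) and `dR_nm`
#'   (= sqrt(msd_b) - sqrt(msd_a), nm).
#' @export
glycerol_free_energy <- function(msd_a, msd_b) {
  if (!is.finite(msd_a) || !is.finite(msd_b) || msd_a <= 0 || msd_b <= 0)
    stop("mean-square distances must be positive", call. = FALSE)
  list(dF_kT = log(sqrt(msd_b / msd_a)),
       dR_nm = sqrt(msd_b) - sqrt(msd_a))
}

#' Glycerol worked example: free-energy change from an efficiency shift
#'
#' Full workup for a chain whose mean transfer efficiency changes by
#' `delta_E` on addition of glycerol: calibrate a Gaussian chain to the
#' base efficiency at R0 in water and to the shifted efficiency at R0
#' corrected for the mixture's refractive index, then convert the two
#' mean-square distances to a free-energy change.
#'
#' @param E_base mean transfer efficiency without glycerol.
#' @param delta_E magnitude of the efficiency shift on glycerol addition.
#' @param R0 Foerster radius in water (nm).
#' @param pct_glycerol glycerol mass percent of the perturbed state.
#' @param direction whether glycerol compacts the chain (efficiency
#'   increases by `delta_E`; the default) or expands it. The free-energy
#'   magnitude depends only weakly on this choice through the calibration
#'   asymmetry; the sign of `dF_kT` and `dR_nm` flips with it.
#' @return list with the two calibrated distributions, `dF_kT` and `dR_nm`
#'   (both signed: negative when the glycerol state is the more compact
#'   one).
#' @export
glycerol_workup <- function(E_base = 0.5, delta_E = 0.07, R0 = 5.4,
                            pct_glycerol = 35,
                            direction = c("compaction", "expansion")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "expansion") -1 else 1
  R0_gly <- correct_R0_refractive_index(
    R0, glycerol_refractive_index(pct_glycerol))
  d0 <- calibrate_to_efficiency("GC", E_base, R0)
  d1 <- calibrate_to_efficiency("GC", E_base + sgn * delta_E, R0_gly)
  fe <- glycerol_free_energy(d0$msd, d1$msd)
  c(list(dist_0 = d0, dist_gly = d1, R0_gly = R0_gly), fe)
}
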