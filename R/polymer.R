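#' Parametric end-to-end distance distributions for disordered chains
#'
#' Constructors for the radial end-to-end distance densities P(r) used to
#' interpret single-molecule FRET data of unstructured single-stranded
#' nucleic acids: the Gaussian chain (GC), the worm-like chain (WLC), the
#' modified self-avoiding walk (SAW-nu), and empirical (gridded) densities,
#' e.g. from chain-growth ensembles. All lengths are in nm; densities in
#' 1/nm.
#'
#' The GC density is
#' \deqn{P(r) = 4\pi r^2 [3/(2\pi \langle r^2\rangle)]^{3/2}
#'       \exp(-3 r^2 / (2\langle r^2\rangle)).}
#' The WLC density (valid for r <= l_c, zero beyond the contour length) is
#' \deqn{P(r) = C (r/l_c)^2 (1-(r/l_c)^2)^{-9/2}
#'       \exp\{-3 l_c / [4 l_p (1-(r/l_c)^2)]\},}
#' with C fixed by normalization. The SAW-nu density is
#' \deqn{P(r) = A (4\pi/R) (r/R)^{2+g} \exp(-\alpha (r/R)^\delta),}
#' with \eqn{g = (\gamma-1)/\nu}, \eqn{\delta = 1/(1-\nu)},
#' \eqn{\gamma \approx 1.1615}, and A, \eqn{\alpha} fixed jointly by
#' normalization and the second-moment condition
#' \eqn{\langle r^2\rangle = R^2} (closed form in Gamma functions).
#'
#' @param msd mean-square end-to-end distance \eqn{\langle r^2\rangle}
#'   (nm^2) of the Gaussian chain.
#' @param lc,lp contour and persistence length (nm) of the worm-like chain.
#' @param R root-mean-square end-to-end distance (nm) of the SAW-nu model.
#' @param nu Flory scaling exponent, 0 < nu < 1. If omitted, derived from
#'   (R, b, n) as \eqn{\nu = \ln(R/b)/\ln(n)}.
#' @param b,n segment length (nm) and number of segments; optional unless
#'   `nu` is to be derived, or `R` is to be derived from (b, n, nu).
#' @param r,density grid (strictly increasing, nm) and density values
#'   (1/nm) for an empirical distribution.
#' @param normalize for [dist_empirical()]: renormalize the density to unit
#'   integral (default TRUE).
#'
#' @return An object of class `distance_distribution` (family-specific
#'   subclass), with fields depending on the family.
#' @examples
#' d <- dist_gc(36)           # <r^2> = 36 nm^2, R = 6 nm
#' ddist_pdf(d, 5)
#' ddist_moments(d)$R
#' @name distance_distribution
NULL

SAW_GAMMA <- 1.1615

new_ddist <- function(family, fields) {
  structure(c(list(family = family), fields),
            class = c(paste0("ddist_", tolower(family)),
                      "distance_distribution"))
}

#' @rdname distance_distribution
#' @export
dist_gc <- function(msd) {
  stopifnot(is.numeric(msd), length(msd) == 1L)
  if (!is.finite(msd) || msd <= 0)
    stop("GC mean-square distance must be positive", call. = FALSE)
  new_ddist("GC", list(msd = msd))
}

#' @rdname distance_distribution
#' @export
dist_wlc <- function(lc, lp) {
  if (!is.finite(lc) || lc <= 0 || !is.finite(lp) || lp <= 0)
    stop("WLC requires positive contour and persistence lengths",
         call. = FALSE)
  d <- new_ddist("WLC", list(lc = lc, lp = lp, C = 1))
  # normalization constant: no closed form, computed once per parameter set
  z <- stats::integrate(function(r) ddist_pdf(d, r), 0, lc,
                        rel.tol = 1e-10, subdivisions = 500L)$value
  d$C <- 1 / z
  d
}

#' @rdname distance_distribution
#' @export
dist_sawnu <- function(R = NULL, nu = NULL, b = NULL, n = NULL) {
  if (is.null(nu)) {
    if (is.null(R) || is.null(b) || is.null(n))
      stop("supply nu, or R with b and n to derive it", call. = FALSE)
    nu <- log(R / b) / log(n)
  }
  if (is.null(R)) {
    if (is.null(b) || is.null(n))
      stop("supply R, or b and n with nu to derive it", call. = FALSE)
    R <- b * n^nu
  }
  if (!is.finite(nu) || nu <= 0 || nu >= 1)
    stop("SAW-nu exponent must satisfy 0 < nu < 1 (got ", signif(nu, 4),
         ")", call. = FALSE)
  if (R <= 0) stop("SAW-nu R must be positive", call. = FALSE)
  g     <- (SAW_GAMMA - 1) / nu
  delta <- 1 / (1 - nu)
  # alpha and A from the normalization + second-moment (<r^2> = R^2)
  # conditions; both integrals are Gamma functions of (r/R)
  lg3 <- lgamma((3 + g) / delta)
  lg5 <- lgamma((5 + g) / delta)
  alpha <- exp((lg5 - lg3) * delta / 2)
  A <- delta * alpha^((3 + g) / delta) / (4 * pi * exp(lg3))
  new_ddist("SAWNU", list(R = R, nu = nu, b = b, n = n,
                          g = g, delta = delta, alpha = alpha, A = A))
}

#' @rdname distance_distribution
#' @export
dist_empirical <- function(r, density, normalize = TRUE) {
  stopifnot(length(r) == length(density), length(r) >= 2L)
  if (any(diff(r) <= 0))
    stop("empirical r-grid must be strictly increasing", call. = FALSE)
  if (any(density < 0) || any(!is.finite(density)))
    stop("empirical density must be finite and non-negative", call. = FALSE)
  z <- trapz(r, density)
  if (z <= 0) stop("empirical density integrates to zero", call. = FALSE)
  if (normalize) density <- density / z
  else if (abs(z - 1) > 1e-6)
    stop("empirical density is not normalized (integral = ", signif(z, 6),
         ")", call. = FALSE)
  new_ddist("EMPIRICAL", list(r = r, density = density))
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Evaluate a distance density
#'
#' @param dist a [distance_distribution].
#' @param r distances (nm), all >= 0.
#' @return density values (1/nm); exactly 0 beyond the support (e.g. r >
#'   l_c for the WLC).
#' @export
ddist_pdf <- function(dist, r) {
  if (any(r < 0)) stop("distance r must be non-negative", call. = FALSE)
  UseMethod("ddist_pdf")
}

#' @export
ddist_pdf.ddist_gc <- function(dist, r) {
  msd <- dist$msd
  4 * pi * r^2 * (3 / (2 * pi * msd))^1.5 * exp(-1.5 * r^2 / msd)
}

#' @export
ddist_pdf.ddist_wlc <- function(dist, r) {
  x <- r / dist$lc
  out <- numeric(length(r))
  in_sup <- x < 1
  u <- 1 - x[in_sup]^2
  out[in_sup] <- dist$C * x[in_sup]^2 * u^(-4.5) *
    exp(-3 * dist$lc / (4 * dist$lp * u))
  out
}

#' @export
ddist_pdf.ddist_sawnu <- function(dist, r) {
  x <- r / dist$R
  dist$A * (4 * pi / dist$R) * x^(2 + dist$g) * exp(-dist$alpha * x^dist$delta)
}

#' @export
ddist_pdf.ddist_empirical <- function(dist, r) {
  out <- numeric(length(r))
  inside <- r >= dist$r[1] & r <= dist$r[length(dist$r)]
  out[inside] <- stats::approx(dist$r, dist$density, xout = r[inside])$y
  out
}

#' Support and quadrature grid of a distance distribution
#'
#' The upper cap is max(6 R, l_c) for parametric families (all densities
#' decay at least Gaussian-fast) and the stored grid range for empirical
#' ones.
#'
#' @param dist a [distance_distribution].
#' @param n number of grid points.
#' @return for `ddist_support`, c(r_min, r_max) in nm; for `ddist_grid`, an
#'   equispaced grid of length `n` on the support.
#' @export
ddist_support <- function(dist) {
  switch(dist$family,
    GC        = c(0, 6 * sqrt(dist$msd)),
    WLC       = c(0, dist$lc),
    SAWNU     = c(0, max(6 * dist$R,
                         dist$R * (60 / dist$alpha)^(1 / dist$delta))),
    EMPIRICAL = range(dist$r))
}

#' @rdname ddist_support
#' @export
ddist_grid <- function(dist, n = 4001L) {
  s <- ddist_support(dist)
  seq(s[1], s[2], length.out = n)
}

#' Moments of a distance distribution
#'
#' Mean, mean-square, and root-mean-square end-to-end distance by adaptive
#' quadrature (parametric families) or trapezoidal integration (empirical).
#'
#' @param dist a [distance_distribution].
#' @return list with `mean_r` (nm), `msd` (nm^2), and `R = sqrt(msd)` (nm).
#' @export
ddist_moments <- function(dist) {
  if (dist$family == "GC") {
    # closed form; quadrature adds nothing for the GC
    return(list(mean_r = sqrt(8 * dist$msd / (3 * pi)),
                msd = dist$msd, R = sqrt(dist$msd)))
  }
  if (dist$family == "EMPIRICAL") {
    z <- trapz(dist$r, dist$density)
    if (!is.finite(z) || z <= 0) stop("non-normalizable input", call. = FALSE)
    m1 <- trapz(dist$r, dist$r * dist$density) / z
    m2 <- trapz(dist$r, dist$r^2 * dist$density) / z
    return(list(mean_r = m1, msd = m2, R = sqrt(m2)))
  }
  s <- ddist_support(dist)
  mom <- function(k) stats::integrate(function(r) r^k * ddist_pdf(dist, r),
                                      s[1], s[2], rel.tol = 1e-9,
                                      subdivisions = 500L)$value
  z <- mom(0)
  if (abs(z - 1) > 1e-5) stop("non-normalizable input", call. = FALSE)
  m1 <- mom(1) / z; m2 <- mom(2) / z
  list(mean_r = m1, msd = m2, R = sqrt(m2))
}

#' Draw samples from a distance distribution by inverse-CDF lookup
#'
#' @param dist a [distance_distribution].
#' @param n number of samples.
#' @param grid_n grid resolution for the tabulated CDF.
#' @return numeric vector of distances (nm). Uses the R RNG (seed with
#'   [set.seed()] for reproducibility).
#' @export
ddist_sample <- function(dist, n, grid_n = 20001L) {
  r <- ddist_grid(dist, grid_n)
  p <- ddist_pdf(dist, r)
  cdf <- c(0, cumsum(diff(r) * (p[-1] + p[-length(p)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  # strip flat CDF stretches so approx() inverts a monotone function
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], r[keep], xout = u, rule = 2)$y
}

#' Calibrate a polymer model to a target mean transfer efficiency
#'
#' Solves the free model parameter so that the distribution's mean transfer
#' efficiency \eqn{\langle\varepsilon\rangle = \int \varepsilon(r) P(r) dr}
#' equals `target_E`: the GC mean-square distance, the WLC persistence
#' length at fixed contour length, or the SAW-nu exponent at fixed segment
#' length and count. Root bracketing plus Brent's method (uniroot) on the
#' free parameter.
#'
#' @param family one of "GC", "WLC", "SAWNU".
#' @param target_E target mean transfer efficiency, in (0, 1).
#' @param R0 Foerster radius (nm).
#' @param lc fixed contour length (nm, WLC).
#' @param b,n fixed segment length (nm) and segment count (SAW-nu).
#' @param tol efficiency tolerance of the solve.
#' @return the calibrated [distance_distribution].
#' @export
calibrate_to_efficiency <- function(family = c("GC", "WLC", "SAWNU"),
                                    target_E, R0, lc = NULL, b = NULL,
                                    n = NULL, tol = 1e-9) {
  family <- match.arg(family)
  if (!is.finite(target_E) || target_E <= 0 || target_E >= 1)
    stop("target efficiency must lie strictly in (0, 1)", call. = FALSE)
  make <- switch(family,
    GC    = function(x) dist_gc(exp(x)),
    WLC   = function(x) {
      if (is.null(lc)) stop("WLC calibration needs fixed lc", call. = FALSE)
      dist_wlc(lc, exp(x))
    },
    SAWNU = function(x) {
      if (is.null(b) || is.null(n))
        stop("SAW-nu calibration needs fixed b and n", call. = FALSE)
      dist_sawnu(nu = stats::plogis(x), b = b, n = n)
    })
  fn <- function(x) mean_efficiency(make(x), R0) - target_E
  # expanding bracket on the log/logit-transformed free parameter
  lo <- -2; hi <- 2
  flo <- fn(lo); fhi <- fn(hi)
  for (i in 1:40) {
    if (flo * fhi <= 0) break
    if (abs(flo) < abs(fhi)) { lo <- lo - 1.5; flo <- fn(lo) }
    else                     { hi <- hi + 1.5; fhi <- fn(hi) }
  }
  if (flo * fhi > 0)
    stop("target efficiency unreachable within parameter bounds",
         call. = FALSE)
  root <- stats::uniroot(fn, c(lo, hi), tol = 1e-12, maxiter = 200L)
  out <- make(root$root)
  if (abs(mean_efficiency(out, R0) - target_E) > max(tol, 1e-6))
    stop("calibration did not reach the efficiency tolerance", call. = FALSE)
  out
}

#' Boltzmann inversion of a distance distribution
#'
#' Converts P(r) to a potential of mean force F(r)/k_B T = -ln P(r),
#' clamped below at `floor` to keep the log finite at support edges, and
#' anchored so that min F = 0.
#'
#' @param dist a [distance_distribution].
#' @param floor density clamp (1/nm), > 0.
#' @param n grid size.
#' @return object of class `pmf_curve`: list with `r` (nm) and `F` (k_B T).
#' @export
boltzmann_invert <- function(dist, floor = 1e-12, n = 4001L) {
  if (!is.finite(floor) || floor <= 0)
    stop("density floor must be positive", call. = FALSE)
  r <- ddist_grid(dist, n)
  p <- ddist_pdf(dist, r)
  if (all(p <= 0)) stop("all-zero density", call. = FALSE)
  f <- -log(pmax(p, floor))
  f <- f - min(f)
  structure(list(r = r, F = f, floor = floor), class = "pmf_curve")
}

#' Read/write empirical distance distributions and PMFs as CSV
#'
#' Two-column CSV with header: (r_nm, density_per_nm) for distributions,
#' (r_nm, F_kT) for potentials of mean force.
#'
#' @param dist a [distance_distribution] (EMPIRICAL on write; any family is
#'   tabulated onto its grid first).
#' @param pmf a `pmf_curve`.
#' @param path file path.
#' @param n grid size used when tabulating a parametric family.
#' @name ddist_io
#' @export
write_ddist_csv <- function(dist, path, n = 1001L) {
  if (dist$family == "EMPIRICAL") {
    df <- data.frame(r_nm = dist$r, density_per_nm = dist$density)
  } else {
    r <- ddist_grid(dist, n)
    df <- data.frame(r_nm = r, density_per_nm = ddist_pdf(dist, r))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ddist_io
#' @export
read_ddist_csv <- function(path) {
  df <- utils::read.csv(path)
  dist_empirical(df[[1]], df[[2]])
}

#' @rdname ddist_io
#' @export
write_pmf_csv <- function(pmf, path) {
  utils::write.csv(data.frame(r_nm = pmf$r, F_kT = pmf$F), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname ddist_io
#' @export
read_pmf_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(r = df[[1]], F = df[[2]], floor = NA_real_),
            class = "pmf_curve")
}

#' @export
print.distance_distribution <- function(x, ...) {
  pars <- switch(x$family,
    GC    = sprintf("<r^2> = %.4g nm^2", x$msd),
    WLC   = sprintf("l_c = %.4g nm, l_p = %.4g nm", x$lc, x$lp),
    SAWNU = sprintf("R = %.4g nm, nu = %.4g", x$R, x$nu),
    EMPIRICAL = sprintf("%d grid points on [%.3g, %.3g] nm",
                        length(x$r), x$r[1], x$r[length(x$r)]))
  cat(sprintf("End-to-end distance distribution [%s]: %s\n", x$family, pars))
  invisible(x)
}
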