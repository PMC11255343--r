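#' Correlation time of a distance-dependent observable for diffusion in a
#' potential of mean force
#'
#' For a chain whose end-to-end distance r(t) undergoes diffusive motion
#' (diffusion coefficient D) in the potential of mean force
#' F(r) = -k_B T ln P(r), the correlation time of any observable f(r)
#' (defined as the integral of its normalized autocorrelation function) is
#' \deqn{\tau_f = \frac{\int_0^\infty P(r)^{-1}
#'   \left[\int_0^r \delta f(\rho) P(\rho) d\rho\right]^2 dr}
#'   {D \int_0^\infty \delta f(r)^2 P(r) dr},}
#' with \eqn{\delta f = f - \langle f\rangle_P}. Evaluated by nested
#' trapezoidal quadrature on a shared grid; the outer integrand's
#' integrable 1/P singularity at the support edges is regularized by
#' flooring P at 1e-12 of its maximum and truncating where P falls below
#' that floor.
#'
#' @param dist a [distance_distribution].
#' @param D effective end-to-end diffusion coefficient (nm^2/ns).
#' @param f observable, a vectorized function of r (nm).
#' @param n grid size.
#' @return correlation time in ns (proportional to 1/D).
#' @export
observable_correlation_time <- function(dist, D, f, n = 6001L) {
  if (!is.finite(D) || D <= 0) stop("D must be positive", call. = FALSE)
  r <- ddist_grid(dist, n)
  p <- ddist_pdf(dist, r)
  pmax_v <- max(p)
  keep <- p >= 1e-12 * pmax_v
  # restrict to the contiguous high-density region
  idx <- range(which(keep))
  r <- r[idx[1]:idx[2]]; p <- p[idx[1]:idx[2]]
  z <- trapz(r, p)
  fv <- f(r)
  fbar <- trapz(r, fv * p) / z
  df <- fv - fbar
  varf <- trapz(r, df^2 * p) / z
  if (varf <= .Machine$double.eps * max(abs(fv))^2 || varf == 0)
    stop("observable is constant over the distribution (zero variance)",
         call. = FALSE)
  inner <- cumtrapz(r, df * p)
  outer <- trapz(r, inner^2 / pmax(p, 1e-12 * pmax_v))
  outer / (D * varf * z)
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))
}

#' Conversion ratio between fluorescence and chain reconfiguration times
#'
#' theta = tau_cd / tau_r, the ratio of the correlation time of the
#' transfer efficiency (f = eps(r), what nsFCS measures) to that of the
#' end-to-end distance itself (f = r). The diffusion coefficient cancels,
#' so theta depends only on the distance distribution and R0.
#'
#' @param dist a [distance_distribution].
#' @param R0 Foerster radius (nm).
#' @param n quadrature grid size.
#' @return dimensionless ratio theta.
#' @export
conversion_ratio <- function(dist, R0, n = 6001L) {
  tau_eps <- observable_correlation_time(
    dist, 1, function(r) efficiency_of_distance(r, R0), n = n)
  tau_r <- observable_correlation_time(dist, 1, identity, n = n)
  tau_eps / tau_r
}

#' Chain reconfiguration time and diffusion coefficient from a measured
#' fluorescence correlation time
#'
#' Converts the nsFCS chain-dynamics time tau_cd (the transfer-efficiency
#' correlation time) to the reconfiguration time tau_r = tau_cd / theta
#' and recovers the effective diffusion coefficient D from the 1/D scaling
#' of the correlation time.
#'
#' @param dist a [distance_distribution].
#' @param R0 Foerster radius (nm).
#' @param tau_cd measured fluorescence correlation time (ns), > 0.
#' @param n quadrature grid size.
#' @return list of class `dynamics_result` with `tau_cd`, `tau_r`,
#'   `theta_conv`, and `D` (nm^2/ns).
#' @export
reconfiguration_time <- function(dist, R0, tau_cd, n = 6001L) {
  if (!is.finite(tau_cd) || tau_cd <= 0)
    stop("tau_cd must be positive", call. = FALSE)
  k_eps <- observable_correlation_time(
    dist, 1, function(r) efficiency_of_distance(r, R0), n = n)
  k_r <- observable_correlation_time(dist, 1, identity, n = n)
  theta <- k_eps / k_r
  structure(list(tau_cd = tau_cd, tau_r = tau_cd / theta,
                 theta_conv = theta, D = k_eps / tau_cd),
            class = "dynamics_result")
}

#' Internal friction from the viscosity dependence of reconfiguration
#' times
#'
#' Decomposes the chain reconfiguration time into an additive
#' solvent-independent (internal friction) term and a term linear in
#' relative solvent viscosity,
#' \deqn{\tau_r \approx \tau_i + (\eta/\eta_0) \tau_s,}
#' by weighted linear least squares; tau_i is the extrapolation to zero
#' viscosity. 95% confidence intervals from the t distribution on the
#' weighted-least-squares covariance.
#'
#' @param series data.frame with columns `eta_rel` (relative viscosity
#'   eta/eta_0), `tau_r_ns`, and optionally `sd_ns` (per-point standard
#'   deviations; weights 1/sd^2).
#' @return list with `tau_i`, `tau_s` (ns), `ci_tau_i`, `ci_tau_s` (95%
#'   intervals; NA with < 3 points), and the `fit` (lm object).
#' @export
internal_friction_fit <- function(series) {
  stopifnot(all(c("eta_rel", "tau_r_ns") %in% names(series)))
  if (nrow(series) < 2L) stop("need >= 2 points", call. = FALSE)
  if (length(unique(series$eta_rel)) < 2L)
    stop("singular design: all viscosities equal", call. = FALSE)
  w <- if ("sd_ns" %in% names(series) && all(series$sd_ns > 0))
    1 / series$sd_ns^2 else rep(1, nrow(series))
  fit <- stats::lm(tau_r_ns ~ eta_rel, data = series, weights = w)
  co <- stats::coef(fit)
  ci <- if (nrow(series) >= 3L) suppressWarnings(stats::confint(fit, level = 0.95))
        else matrix(NA_real_, 2, 2)
  list(tau_i = unname(co[1]), tau_s = unname(co[2]),
       ci_tau_i = unname(ci[1, ]), ci_tau_s = unname(ci[2, ]),
       fit = fit)
}

#' End-to-end contact rate for diffusion in a potential of mean force
#'
#' Mean rate of end-to-end contact formation for a chain with distance
#' distribution P(r) diffusing with coefficient D, with quenching at rate
#' q upon reaching the contact distance a:
#' \deqn{1/k_{ee} = 1/(q P(a)) + D^{-1} \int_a^\infty P(r)^{-1}
#'   \left[\int_r^\infty P(\rho) d\rho\right]^2 dr.}
#' The first term is the reaction-limited time 1/k_R with k_R = q P(a);
#' the second is the diffusion-limited mean first-passage time to contact
#' from the equilibrium distribution.
#'
#' @param dist a [distance_distribution].
#' @param D diffusion coefficient (nm^2/ns).
#' @param q quenching rate at contact, in 1/s (default 1e12).
#' @param a contact distance (nm, default 0.4).
#' @param n grid size.
#' @return list with `k_ee` (1/s), `k_R` (1/s), `tau_diff_ns` (the
#'   diffusion-limited time in ns) and `diffusion_limited_only` (TRUE when
#'   P(a) = 0 so the reaction-limited rate is undefined; `k_ee` then
#'   reports the diffusion-limited rate alone).
#' @export
contact_rate <- function(dist, D, q = 1e12, a = 0.4, n = 12001L) {
  if (!is.finite(q) || q <= 0 || !is.finite(a) || a <= 0)
    stop("q and a must be positive", call. = FALSE)
  if (!is.finite(D) || D <= 0) stop("D must be positive", call. = FALSE)
  sup <- ddist_support(dist)
  if (a >= sup[2])
    stop("contact distance a lies beyond the distribution support",
         call. = FALSE)
  r <- seq(max(a, sup[1]), sup[2], length.out = n)
  p <- ddist_pdf(dist, r)
  pa <- ddist_pdf(dist, a)  # 0 when a falls below the support
  # survival integral Q(r) = int_r^inf P, from the top down
  Q <- rev(cumtrapz(rev(r), rev(p)))
  pmax_v <- max(ddist_pdf(dist, ddist_grid(dist, 2001L)))
  keep <- p >= 1e-12 * pmax_v
  integ <- Q^2 / pmax(p, 1e-12 * pmax_v)
  tau_diff_ns <- trapz(r[keep], integ[keep]) / D
  q_ns <- q * 1e-9                      # rate in 1/ns for internal units
  if (pa <= 0) {
    k_ns <- 1 / tau_diff_ns
    return(list(k_ee = k_ns * 1e9, k_R = 0, tau_diff_ns = tau_diff_ns,
                diffusion_limited_only = TRUE))
  }
  kR_ns <- q_ns * pa
  k_ns <- 1 / (1 / kR_ns + tau_diff_ns)
  list(k_ee = k_ns * 1e9, k_R = kR_ns * 1e9, tau_diff_ns = tau_diff_ns,
       diffusion_limited_only = FALSE)
}

#' Viscosity series I/O and dynamics-result JSON export
#'
#' Viscosity series as CSV (eta_rel, tau_r_ns, sd_ns); dynamics results
#' and friction fits as JSON.
#' @param series data.frame; `path` file path; `x` a `dynamics_result` or
#'   the list returned by [internal_friction_fit()].
#' @name dynamics_io
#' @export
read_viscosity_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("eta_rel", "tau_r_ns") %in% names(df)))
  df
}

#' @rdname dynamics_io
#' @export
write_viscosity_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @rdname dynamics_io
#' @export
write_dynamics_json <- function(x, path) {
  out <- x[setdiff(names(x), "fit")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat(sprintf(paste0("Chain dynamics: tau_cd = %.3g ns, tau_r = %.3g ns ",
                     "(theta = %.3f), D = %.3g nm^2/ns\n"),
              x$tau_cd, x$tau_r, x$theta_conv, x$D))
  invisible(x)
}
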