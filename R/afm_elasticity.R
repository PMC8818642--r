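# Young's modulus from AFM force-indentation curves via the Hertz model.
#
# For a sharp indenter the Hertz contact force is
#   F = C(geometry) * E / (1 - nu^2) * (delta - delta0)^2
# with C = (2/pi) tan(alpha) for a cone (Sneddon) and C = 0.7453 tan(alpha)
# for a four-sided pyramid (Bilodeau). Fits are restricted to loading
# forces at or below 0.5 nN by default, matching gentle live-cell
# indentation.

#' Hertz geometry coefficient
#'
#' @param geometry `"cone"` or `"pyramid"`.
#' @param alpha_deg tip half-angle (cone) or face angle (pyramid), degrees.
#' @return the dimensionless coefficient C.
#' @export
hertz_coefficient <- function(geometry = c("cone", "pyramid"), alpha_deg = 35) {
  geometry <- match.arg(geometry)
  a <- alpha_deg * pi / 180
  switch(geometry, cone = (2 / pi) * tan(a), pyramid = 0.7453 * tan(a))
}

#' Hertz forward model
#'
#' @param delta_nm indentation depth(s) past contact, nm (negative values
#'   give zero force).
#' @param E_pa Young's modulus, Pa.
#' @param geometry,alpha_deg indenter geometry (see [hertz_coefficient()]).
#' @param nu Poisson ratio (default 0.5, incompressible cell).
#' @return force in nN.
#' @export
hertz_force <- function(delta_nm, E_pa, geometry = "cone", alpha_deg = 35,
                        nu = 0.5) {
  hertz_coefficient(geometry, alpha_deg) * E_pa / (1 - nu^2) *
    pmax(delta_nm, 0)^2 * 1e-9
}

#' Construct a force curve
#'
#' @param position_nm indentation-axis positions (monotone non-decreasing on
#'   the approach segment), nm. Pass piezo z and `deflection_nm` +
#'   `k_spring_n_per_m` to convert instrument output.
#' @param force_nN measured force, nN (computed from deflection when a
#'   spring constant is given: F = k * deflection).
#' @param geometry,alpha_deg,nu tip model (defaults: cone, 35 deg, 0.5).
#' @param deflection_nm optional cantilever deflection (nm).
#' @param k_spring_n_per_m optional spring constant (N/m).
#' @return a `force_curve`.
#' @export
force_curve <- function(position_nm, force_nN = NULL, geometry = "cone",
                        alpha_deg = 35, nu = 0.5, deflection_nm = NULL,
                        k_spring_n_per_m = NULL) {
  if (is.null(force_nN)) {
    if (is.null(deflection_nm) || is.null(k_spring_n_per_m))
      stop("supply force_nN, or deflection_nm plus k_spring_n_per_m")
    force_nN <- k_spring_n_per_m * deflection_nm # N/m * nm = nN
  }
  stopifnot(length(position_nm) == length(force_nN), all(is.finite(force_nN)))
  structure(list(position_nm = position_nm, force_nN = force_nN,
                 geometry = geometry, alpha_deg = alpha_deg, nu = nu),
            class = "force_curve")
}

#' Detect the contact point of a force curve
#'
#' Grid search over candidate contact points: for each candidate the curve
#' is modeled as a flat baseline before contact and a Hertz parabola after,
#' and the candidate minimizing the total squared residual wins. Errors when
#' the curve has no pre-contact baseline region or no detectable contact.
#'
#' @param curve a `force_curve`.
#' @param max_force_nN fit window cap (default 0.5 nN).
#' @param min_pre,min_post minimum samples before/after contact.
#' @return list with `contact_nm`, `baseline_nN`, `E_pa` (coarse), `ssr`.
#' @export
detect_contact_point <- function(curve, max_force_nN = 0.5, min_pre = 5,
                                 min_post = 10) {
  d <- curve$position_nm
  f <- curve$force_nN
  n <- length(d)
  if (n < min_pre + min_post)
    stop("curve too short for contact-point detection")
  cc <- hertz_coefficient(curve$geometry, curve$alpha_deg) /
    (1 - curve$nu^2) * 1e-9
  best <- list(ssr = Inf)
  for (i in min_pre:(n - min_post)) {
    base <- mean(f[1:i])
    post <- (i + 1):n
    g <- cc * (d[post] - d[i])^2
    y <- f[post] - base
    win <- y <= max_force_nN
    if (sum(win) < min_post) next
    E <- sum(y[win] * g[win]) / sum(g[win]^2)
    if (!is.finite(E) || E < 0) E <- 0
    ssr <- sum((f[1:i] - base)^2) + sum((y[win] - E * g[win])^2) +
      if (any(!win)) sum((y[!win] - E * g[!win])^2) else 0
    if (ssr < best$ssr)
      best <- list(contact_nm = d[i], baseline_nN = base, E_pa = E, ssr = ssr)
  }
  if (!is.finite(best$ssr)) stop("contact-point search failed")
  # no-contact guard: the Hertz part must explain signal above the noise
  resid_rms <- sqrt(best$ssr / n)
  max_model <- best$E_pa * cc * (max(d) - best$contact_nm)^2
  if (best$E_pa <= 0 || max_model < 3 * resid_rms)
    stop("no contact detected: curve is consistent with a flat baseline")
  # continuous refinement: the true contact generally falls between samples,
  # so polish (baseline, contact, E) jointly from the grid optimum.
  # The force window is applied through the model (indentation depth at
  # which the fitted force reaches the cap) rather than the noisy measured
  # force, which would preferentially drop high-noise samples near the cap
  # and bias the modulus low.
  for (pass in 1:2) {
    delta_cap <- sqrt(max_force_nN / (cc * best$E_pa))
    use <- d <= best$contact_nm + delta_cap
    ref <- tryCatch({
      fit <- minpack.lm::nlsLM(
        ff ~ b0 + E * cc * pmax(dd - d0, 0)^2,
        start = list(b0 = best$baseline_nN, d0 = best$contact_nm,
                     E = best$E_pa),
        data = list(ff = f[use], dd = d[use], cc = cc),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      as.list(stats::coef(fit))
    }, error = function(e) NULL)
    if (is.null(ref) || !is.finite(ref$E) || ref$E <= 0 ||
        ref$d0 <= min(d) || ref$d0 >= max(d)) break
    moved <- abs(ref$d0 - best$contact_nm)
    best$contact_nm <- ref$d0
    best$baseline_nN <- ref$b0
    best$E_pa <- ref$E
    if (moved < 0.1) break
  }
  best
}

#' Fit Young's modulus with the Hertz model
#'
#' Least-squares fit of F = C E / (1 - nu^2) (delta - delta0)^2 to the
#' post-contact samples with force at most `max_force_nN`. The contact point
#' and baseline are detected automatically unless supplied.
#'
#' @param curve a `force_curve`.
#' @param max_force_nN fit window cap (default 0.5 nN).
#' @param contact optional result of [detect_contact_point()].
#' @param min_post minimum post-contact samples inside the window.
#' @return a `hertz_fit`: `E_pa`, `contact_nm`, `baseline_nN`,
#'   `residual_rms_nN`, `geometry`, `n_fit`.
#' @export
fit_hertz <- function(curve, max_force_nN = 0.5, contact = NULL,
                      min_post = 10) {
  if (is.null(contact)) contact <- detect_contact_point(curve, max_force_nN,
                                                        min_post = min_post)
  d <- curve$position_nm
  f <- curve$force_nN - contact$baseline_nN
  cc <- hertz_coefficient(curve$geometry, curve$alpha_deg) /
    (1 - curve$nu^2) * 1e-9
  # model-based force window (see detect_contact_point): depth at which the
  # detected-fit force reaches the cap
  delta_cap <- if (is.finite(contact$E_pa) && contact$E_pa > 0)
    sqrt(max_force_nN / (cc * contact$E_pa)) else Inf
  post <- d > contact$contact_nm & d <= contact$contact_nm + delta_cap
  if (sum(post) < min_post)
    stop("fewer than ", min_post, " post-contact samples within the force window")
  g <- cc * (d[post] - contact$contact_nm)^2
  E <- sum(f[post] * g) / sum(g^2)
  if (!is.finite(E) || E <= 0) stop("Hertz fit returned a non-positive modulus")
  res <- f[post] - E * g
  structure(list(E_pa = E, contact_nm = contact$contact_nm,
                 baseline_nN = contact$baseline_nN,
                 residual_rms_nN = sqrt(mean(res^2)),
                 geometry = curve$geometry, n_fit = sum(post)),
            class = "hertz_fit")
}

#' Assemble an elasticity map from a grid of force curves
#'
#' Fits every curve; failed fits are recorded as missing cells and excluded
#' from the modulus probability histogram (which sums to 1).
#'
#' @param curves list of `force_curve`s in column-major cell order.
#' @param dim `c(nrow, ncol)` of the map grid.
#' @param grid_pitch_nm spatial spacing of adjacent curves (< 100 nm in the
#'   underlying acquisitions; recorded only).
#' @param max_force_nN fit window cap.
#' @param breaks histogram breaks for the modulus distribution (default:
#'   Sturges over the fitted values).
#' @return an `elasticity_map`: `E_pa` (matrix), `histogram` (`breaks`,
#'   `mids`, `prob`), `n_failed`, `grid_pitch_nm`.
#' @export
map_elasticity <- function(curves, dim, grid_pitch_nm = 100,
                           max_force_nN = 0.5, breaks = NULL) {
  stopifnot(length(curves) == prod(dim))
  E <- vapply(curves, function(cv) {
    tryCatch(fit_hertz(cv, max_force_nN)$E_pa, error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(E))) stop("all Hertz fits failed")
  Em <- matrix(E, dim[1], dim[2])
  ok <- E[!is.na(E)]
  if (is.null(breaks)) breaks <- pretty(range(ok), n = grDevices::nclass.Sturges(ok))
  h <- graphics::hist(ok, breaks = breaks, plot = FALSE)
  structure(list(E_pa = Em,
                 histogram = list(breaks = h$breaks, mids = h$mids,
                                  prob = h$counts / sum(h$counts)),
                 n_failed = sum(is.na(E)),
                 grid_pitch_nm = grid_pitch_nm),
            class = "elasticity_map")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("hertz_fit (%s): E = %.4g Pa, contact %.1f nm, baseline %.3g nN, RMS %.3g nN (%d pts)\n",
              x$geometry, x$E_pa, x$contact_nm, x$baseline_nN,
              x$residual_rms_nN, x$n_fit))
  invisible(x)
}
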