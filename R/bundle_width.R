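# Cortical actin bundle width (FWHM) from raw localizations.
#
# Pipeline: (i) rough orientation of the selected bundle by a total
# least-squares line; (ii) Gaussian kernel density map of the localizations
# (kernel SD 40-80 nm depending on density); (iii) polynomial fit along the
# column maxima of the density map, following the bundle's curvature;
# (iv) numeric signed perpendicular distance of every localization from the
# fitted curve, histogrammed and fitted with a single Gaussian; (v) the
# per-event localization precision deconvolved from the measured profile by
# Gaussian quadrature subtraction (linker length 0 nm, appropriate for a
# small phalloidin label). The FWHM of the corrected profile is the bundle
# width.

#' Fit the rough orientation of a bundle
#'
#' Total-least-squares line through the point cloud: the first principal
#' direction of the centered coordinates. The angle is reported in
#' (-pi/2, pi/2].
#'
#' @param x_nm,y_nm localization coordinates (or pass a `loc_table` as
#'   `x_nm`).
#' @param min_anisotropy warn (flag in the result) when the SD ratio along
#'   the two principal axes is below this (near-isotropic cloud).
#' @return list with `theta` (radians), `anisotropy` (sqrt of eigenvalue
#'   ratio), `isotropic_warning`.
#' @export
fit_orientation <- function(x_nm, y_nm = NULL, min_anisotropy = 2) {
  if (is.null(y_nm)) {
    y_nm <- x_nm$y_nm
    x_nm <- x_nm$x_nm
  }
  if (length(x_nm) < 3) stop("need at least 3 localizations to fit an orientation")
  cc <- cbind(x_nm - mean(x_nm), y_nm - mean(y_nm))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  v <- ev$vectors[, 1]
  theta <- atan2(v[2], v[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  aniso <- sqrt(max(ev$values[1], 0) / max(ev$values[2], .Machine$double.eps))
  list(theta = theta, anisotropy = aniso,
       isotropic_warning = aniso < min_anisotropy)
}

#' Smoothed localization density map
#'
#' Gaussian kernel density of the localizations on a regular grid,
#' implemented as count binning followed by separable Gaussian convolution.
#' The map integrates (sum times cell area) to the localization count up to
#' edge truncation.
#'
#' @param x_nm,y_nm localization coordinates.
#' @param kernel_sigma_nm Gaussian kernel SD; 40-80 nm unless
#'   `allow_any_kernel` is set (sparser data calls for larger kernels).
#' @param grid_pitch_nm grid cell size (default 10 nm).
#' @param bounds optional `c(xmin, xmax, ymin, ymax)`; default tight box
#'   padded by 3 kernel SDs.
#' @param allow_any_kernel set TRUE to bypass the 40-80 nm guard.
#' @return a `density_map`: list with `density` (matrix, rows = y, in
#'   events/nm^2), `x_nm`/`y_nm` (cell-center axes), `grid_pitch_nm`,
#'   `kernel_sigma_nm`, `n_events`.
#' @export
compute_density_map <- function(x_nm, y_nm, kernel_sigma_nm = 60,
                                grid_pitch_nm = 10, bounds = NULL,
                                allow_any_kernel = FALSE) {
  stopifnot(kernel_sigma_nm > 0, grid_pitch_nm > 0)
  if (!allow_any_kernel &&
      (kernel_sigma_nm < 40 || kernel_sigma_nm > 80))
    stop("kernel_sigma_nm outside the 40-80 nm working range; ",
         "set allow_any_kernel = TRUE to override")
  p <- grid_pitch_nm
  if (is.null(bounds)) {
    pad <- 3 * kernel_sigma_nm
    bounds <- c(min(x_nm) - pad, max(x_nm) + pad,
                min(y_nm) - pad, max(y_nm) + pad)
  }
  nc <- max(1L, ceiling((bounds[2] - bounds[1]) / p))
  nr <- max(1L, ceiling((bounds[4] - bounds[3]) / p))
  col <- floor((x_nm - bounds[1]) / p) + 1
  row <- floor((y_nm - bounds[3]) / p) + 1
  inb <- col >= 1 & col <= nc & row >= 1 & row <= nr
  counts <- matrix(tabulate((col[inb] - 1) * nr + row[inb], nbins = nr * nc),
                   nr, nc)
  dens <- gaussian_blur(counts, kernel_sigma_nm / p) / p^2
  structure(list(density = dens,
                 x_nm = bounds[1] + (seq_len(nc) - 0.5) * p,
                 y_nm = bounds[3] + (seq_len(nr) - 0.5) * p,
                 grid_pitch_nm = p, kernel_sigma_nm = kernel_sigma_nm,
                 n_events = sum(inb)),
            class = "density_map")
}

#' Fit a polynomial centerline along density-map ridge maxima
#'
#' Operates in the bundle frame (the caller rotates coordinates by -theta
#' before computing the map). For every grid column whose peak density
#' exceeds a noise floor, the density-weighted peak position is extracted
#' (centroid over a window around the column argmax) and a polynomial is
#' least-squares fitted through the peaks.
#'
#' @param density a [compute_density_map()] result in the rotated frame.
#' @param theta rotation angle that was applied (recorded in the fit).
#' @param degree polynomial degree (default 3; reduced with a warning when
#'   too few usable columns exist).
#' @param floor_frac columns whose peak is below `floor_frac` of the global
#'   maximum are ignored (default 0.1).
#' @param trim_sigmas columns within this many kernel SDs of the ends of the
#'   usable range are excluded (default 3): near the ends the kernel sees
#'   data on one side only, which biases the ridge along sloped bundles.
#' @return a `centerline_fit`: `theta`, `coef` (increasing powers), `domain`
#'   (x range of used columns, rotated frame), `ridge` (x, y of column
#'   peaks), `residual_rms_nm`, `degree`.
#' @export
fit_centerline <- function(density, theta = 0, degree = 3, floor_frac = 0.1,
                           trim_sigmas = 3) {
  d <- density$density
  gmax <- max(d)
  col_max <- apply(d, 2, max)
  col_min <- apply(d, 2, min)
  usable <- which(col_max > floor_frac * gmax & col_max > col_min + 1e-12)
  if (length(usable) == 0)
    stop("no ridge: density map has no usable columns (flat in y)")
  trim <- ceiling(trim_sigmas * density$kernel_sigma_nm / density$grid_pitch_nm)
  if (length(usable) > 2 * trim + degree + 1)
    usable <- usable[(trim + 1):(length(usable) - trim)]
  ys <- density$y_nm
  ridge_y <- vapply(usable, function(c) {
    col <- d[, c]
    i <- which.max(col)
    w <- max(1, i - 3):min(length(col), i + 3)
    sum(ys[w] * col[w]) / sum(col[w])
  }, numeric(1))
  ridge_x <- density$x_nm[usable]
  deg <- degree
  if (length(usable) < deg + 1) {
    deg <- length(usable) - 1
    if (deg < 1) stop("too few usable density columns to fit a centerline")
    warning("reducing centerline polynomial degree to ", deg)
  }
  X <- outer(ridge_x, 0:deg, `^`)
  fit <- stats::lm.fit(X, ridge_y)
  structure(list(theta = theta, coef = fit$coefficients,
                 domain = range(ridge_x),
                 ridge = cbind(x = ridge_x, y = ridge_y),
                 residual_rms_nm = sqrt(mean(fit$residuals^2)),
                 degree = deg),
            class = "centerline_fit")
}

#' Evaluate a centerline fit
#' @param fit a `centerline_fit`.
#' @param x_nm positions (rotated frame).
#' @return y (rotated frame).
#' @export
evaluate_centerline <- function(fit, x_nm) polyval(unname(fit$coef), x_nm)

#' Signed perpendicular distances of localizations from a centerline
#'
#' The nearest point on the curve is found numerically: the curve is sampled
#' densely, the nearest sample is located per event, and the distance is
#' refined by exact projection onto the two adjacent chord segments. The
#' sign is positive on the left of the increasing-x direction (rotated
#' frame). Events outside the centerline domain are dropped and counted.
#'
#' @param x_nm,y_nm localization coordinates in the ROI frame (unrotated).
#' @param fit a `centerline_fit` (with its `theta`).
#' @param sample_pitch_nm curve sampling pitch (default 2 nm).
#' @return list with `distance_nm` (signed, per kept event), `kept`
#'   (logical index into the input), `n_dropped`.
#' @export
perpendicular_distances <- function(x_nm, y_nm, fit, sample_pitch_nm = 2) {
  r <- rotate_xy(x_nm, y_nm, -fit$theta)
  keep <- r[, 1] >= fit$domain[1] & r[, 1] <= fit$domain[2]
  px <- r[keep, 1]; py <- r[keep, 2]
  xs <- seq(fit$domain[1], fit$domain[2], by = sample_pitch_nm)
  if (xs[length(xs)] < fit$domain[2]) xs <- c(xs, fit$domain[2])
  ysv <- evaluate_centerline(fit, xs)
  ns <- length(xs)
  n <- length(px)
  # coarse-to-fine nearest-sample search: locate the nearest coarse sample
  # (every K-th), then scan the fine samples within +-2K of it
  K <- 16L
  coarse <- unique(c(seq(1L, ns, by = K), ns))
  j <- integer(n)
  chunk <- 4000L
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    D2 <- outer(px[idx], xs[coarse], `-`)^2 + outer(py[idx], ysv[coarse], `-`)^2
    j[idx] <- coarse[max.col(-D2, ties.method = "first")]
  }
  best_d2 <- rep(Inf, n)
  best_j <- j
  for (off in (-2L * K):(2L * K)) {
    cand <- pmax(1L, pmin(ns, j + off))
    d2 <- (px - xs[cand])^2 + (py - ysv[cand])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_j[upd] <- cand[upd]
  }
  # exact projection onto the chords adjacent to the nearest sample
  best_d2 <- rep(Inf, n)
  best_cross <- numeric(n)
  for (side in c(-1L, 0L)) {
    a <- pmax(1L, pmin(ns - 1L, best_j + side))
    ax <- xs[a]; ay <- ysv[a]
    bx <- xs[a + 1L]; cy <- ysv[a + 1L]
    vx <- bx - ax; vy <- cy - ay
    tt <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / (vx^2 + vy^2)))
    qx <- ax + tt * vx; qy <- ay + tt * vy
    d2 <- (px - qx)^2 + (py - qy)^2
    cross <- vx * (py - qy) - vy * (px - qx)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_cross[upd] <- cross[upd]
  }
  dist_signed <- sign(best_cross) * sqrt(best_d2)
  list(distance_nm = dist_signed, kept = keep, n_dropped = sum(!keep))
}

#' Fit a single Gaussian to the perpendicular-distance histogram
#'
#' Least-squares fit of A exp(-(d - mu)^2 / (2 sigma^2)) (plus an optional
#' constant baseline for high-background data) to the binned distances.
#'
#' @param distances_nm signed perpendicular distances.
#' @param bin_width_nm histogram bin width (default 5 nm).
#' @param baseline add a constant baseline term (default FALSE: the profile
#'   is a single Gaussian).
#' @param min_events minimum number of distances (default 50).
#' @return a `width_profile`: histogram (`breaks`, `mids`, `counts`), fit
#'   parameters (`amplitude`, `mu_nm`, `sigma_nm`, `baseline`), `r_squared`,
#'   `sigma_sd_nm` (binless SD diagnostic), `n`.
#' @export
fit_width_profile <- function(distances_nm, bin_width_nm = 5, baseline = FALSE,
                              min_events = 50) {
  n <- length(distances_nm)
  if (n < min_events)
    stop("need at least ", min_events, " distances to fit a width profile")
  if (stats::sd(distances_nm) < 1e-9)
    stop("degenerate distance distribution (all values identical)")
  lo <- floor(min(distances_nm) / bin_width_nm) * bin_width_nm
  hi <- ceiling(max(distances_nm) / bin_width_nm) * bin_width_nm
  if (hi <= lo) hi <- lo + bin_width_nm
  breaks <- seq(lo, hi, by = bin_width_nm)
  h <- graphics::hist(distances_nm, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  start <- list(A = max(y), mu = stats::median(distances_nm),
                s = max(bin_width_nm / 2, stats::mad(distances_nm)))
  fml <- if (baseline) y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + c0
         else y ~ A * exp(-(x - mu)^2 / (2 * s^2))
  if (baseline) start$c0 <- min(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(x = x, y = y), start = start,
                      lower = if (baseline) c(0, -Inf, 1e-6, 0)
                              else c(0, -Inf, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit did not converge (start: A=",
                             signif(start$A, 3), ", mu=", signif(start$mu, 3),
                             ", sigma=", signif(start$s, 3), "): ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(breaks = breaks, mids = x, counts = y,
                 amplitude = unname(cf["A"]), mu_nm = unname(cf["mu"]),
                 sigma_nm = abs(unname(cf["s"])),
                 baseline = if (baseline) unname(cf["c0"]) else 0,
                 r_squared = r2, sigma_sd_nm = stats::sd(distances_nm), n = n),
            class = "width_profile")
}

#' Deconvolve the localization precision from a measured width
#'
#' The measured profile is the true Gaussian cross-section convolved with
#' the (Gaussian) localization error, so SDs add in quadrature:
#' sigma_corr = sqrt(sigma_meas^2 - sigma_prec^2), with sigma_prec the RMS
#' of the contributing events' precisions. The linker contribution is fixed
#' at 0 nm (small phalloidin label). FWHM = 2 sqrt(2 ln 2) sigma.
#'
#' @param sigma_meas_nm fitted SD of the distance profile.
#' @param precisions_nm per-event precisions of the contributing events, or
#'   a single pre-aggregated RMS value.
#' @param method aggregate as `"rms"` (default) or `"mean"` of the per-event
#'   precisions.
#' @return list with `sigma_prec_nm`, `sigma_corr_nm`, `fwhm_meas_nm`,
#'   `fwhm_corr_nm`, `linker_nm` (always 0).
#' @export
correct_for_precision <- function(sigma_meas_nm, precisions_nm,
                                  method = c("rms", "mean")) {
  method <- match.arg(method)
  sigma_prec <- if (length(precisions_nm) == 1) precisions_nm
    else if (method == "rms") sqrt(mean(precisions_nm^2))
    else mean(precisions_nm)
  if (sigma_prec >= sigma_meas_nm)
    stop("unresolvable width: aggregate precision (", signif(sigma_prec, 4),
         " nm) is not smaller than the measured sigma (",
         signif(sigma_meas_nm, 4), " nm)")
  sigma_corr <- sqrt(sigma_meas_nm^2 - sigma_prec^2)
  list(sigma_prec_nm = sigma_prec, sigma_corr_nm = sigma_corr,
       fwhm_meas_nm = sigma_to_fwhm(sigma_meas_nm),
       fwhm_corr_nm = sigma_to_fwhm(sigma_corr), linker_nm = 0)
}

#' Measure the width of one cortical actin bundle
#'
#' Composition of the full pipeline: orientation fit, density map in the
#' rotated bundle frame, polynomial centerline along the ridge, signed
#' perpendicular distances, single-Gaussian histogram fit, and
#' localization-precision deconvolution. All intermediates are retained.
#'
#' @param table a [loc_table()].
#' @param roi optional `c(xmin, xmax, ymin, ymax)` nm rectangle selecting
#'   the bundle.
#' @param kernel_sigma_nm density-map kernel SD (40-80 nm, default 60).
#' @param grid_pitch_nm density grid pitch (default 10 nm).
#' @param degree centerline polynomial degree (default 3).
#' @param bin_width_nm histogram bin width (default 5 nm).
#' @param baseline include a constant baseline in the Gaussian fit.
#' @param min_events minimum localizations in the ROI (default 300).
#' @param precision_method `"rms"` or `"mean"` aggregation of precisions.
#' @return a `width_measurement` with `fwhm_corr_nm` as the headline width
#'   plus every intermediate stage result.
#' @export
measure_bundle_width <- function(table, roi = NULL, kernel_sigma_nm = 60,
                                 grid_pitch_nm = 10, degree = 3,
                                 bin_width_nm = 5, baseline = FALSE,
                                 min_events = 300,
                                 precision_method = "rms") {
  if (!is.null(roi)) {
    sel <- table$x_nm >= roi[1] & table$x_nm <= roi[2] &
           table$y_nm >= roi[3] & table$y_nm <= roi[4]
    table <- table[sel, , drop = FALSE]
  }
  if (nrow(table) < min_events)
    stage_stop("roi", "only ", nrow(table), " localizations in the ROI (minimum ",
               min_events, ")")
  orient <- tryCatch(fit_orientation(table$x_nm, table$y_nm),
                     error = function(e) stage_stop("orientation", conditionMessage(e)))
  r <- rotate_xy(table$x_nm, table$y_nm, -orient$theta)
  dens <- tryCatch(
    compute_density_map(r[, 1], r[, 2], kernel_sigma_nm, grid_pitch_nm),
    error = function(e) stage_stop("density_map", conditionMessage(e)))
  cl <- tryCatch(fit_centerline(dens, theta = orient$theta, degree = degree),
                 error = function(e) stage_stop("centerline", conditionMessage(e)))
  pd <- tryCatch(perpendicular_distances(table$x_nm, table$y_nm, cl),
                 error = function(e) stage_stop("distances", conditionMessage(e)))
  prof <- tryCatch(fit_width_profile(pd$distance_nm, bin_width_nm, baseline),
                   error = function(e) stage_stop("profile_fit", conditionMessage(e)))
  corr <- tryCatch(
    correct_for_precision(prof$sigma_nm, table$precision_nm[pd$kept],
                          method = precision_method),
    error = function(e) stage_stop("precision_correction", conditionMessage(e)))
  structure(c(list(orientation = orient, density = dens, centerline = cl,
                   distances = pd, profile = prof, n_events = nrow(table)),
              corr, list(sigma_meas_nm = prof$sigma_nm)),
            class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat(sprintf(paste0("width_measurement: FWHM_meas %.1f nm, FWHM_corr %.1f nm\n",
                     "  sigma_meas %.2f nm, sigma_prec %.2f nm, sigma_corr %.2f nm\n",
                     "  %d events, Gaussian fit R^2 %.3f, centerline degree %d\n"),
              x$fwhm_meas_nm, x$fwhm_corr_nm, x$sigma_meas_nm,
              x$sigma_prec_nm, x$sigma_corr_nm, x$n_events,
              x$profile$r_squared, x$centerline$degree))
  invisible(x)
}
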