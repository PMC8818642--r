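# Bundle width pipeline: orientation, density map, centerline,
# perpendicular distances, Gaussian profile, precision deconvolution.

test_that("orientation is the total-least-squares direction and is equivariant", {
  # points on y = x -> 45 degrees
  o <- fit_orientation(1:50, 1:50)
  expect_equal(o$theta, pi / 4)

  # horizontal line plus symmetric noise -> 0 +- 1 degree
  tab <- straight_bundle_table(5000, sigma = 20, seed = 3)
  o <- fit_orientation(tab)
  expect_lt(abs(o$theta), pi / 180)
  expect_false(o$isotropic_warning)

  # rotating all points by +20 degrees rotates theta by +20 degrees (mod pi)
  r <- rotate_xy(tab$x_nm, tab$y_nm, 20 * pi / 180)
  o2 <- fit_orientation(r[, 1], r[, 2])
  d <- (o2$theta - o$theta - 20 * pi / 180) %% pi
  expect_lt(min(d, pi - d), 1e-6)

  # isotropic cloud is flagged; too few points is an error
  set.seed(1)
  oi <- fit_orientation(rnorm(500), rnorm(500))
  expect_true(oi$isotropic_warning)
  expect_error(fit_orientation(1:2, 1:2), "at least 3")
})

test_that("density map conserves mass and superposes", {
  # single localization -> a single Gaussian bump centered on it
  dm <- compute_density_map(500, 300, kernel_sigma_nm = 60)
  pk <- which(dm$density == max(dm$density), arr.ind = TRUE)
  expect_lt(abs(dm$x_nm[pk[1, 2]] - 500), dm$grid_pitch_nm)
  expect_lt(abs(dm$y_nm[pk[1, 1]] - 300), dm$grid_pitch_nm)
  expect_equal(sum(dm$density) * dm$grid_pitch_nm^2, 1, tolerance = 0.01)

  # two distant localizations -> two equal bumps, total mass 2
  # (explicit mirror-symmetric bounds so edge truncation is identical)
  dm2 <- compute_density_map(c(300, 1300), c(300, 300), kernel_sigma_nm = 60,
                             bounds = c(0, 1600, 0, 600))
  expect_equal(sum(dm2$density) * dm2$grid_pitch_nm^2, 2, tolerance = 0.01)
  left <- dm2$density[, dm2$x_nm < 800]
  right <- dm2$density[, dm2$x_nm >= 800]
  expect_equal(sum(left), sum(right), tolerance = 1e-6)
  expect_equal(max(left), max(right), tolerance = 1e-6)

  expect_error(compute_density_map(1, 1, kernel_sigma_nm = 20), "40-80")
  expect_error(compute_density_map(1, 1, kernel_sigma_nm = -5,
                                   allow_any_kernel = TRUE), "kernel_sigma_nm > 0")
})

test_that("density-map column ridges agree with a direct-sum KDE oracle", {
  tab <- straight_bundle_table(1e4, sigma = 40, seed = 7)
  dm <- compute_density_map(tab$x_nm, tab$y_nm, kernel_sigma_nm = 60)
  # exhaustive direct-sum Gaussian KDE on the same grid (separable product)
  s <- dm$kernel_sigma_nm
  gx <- exp(-outer(dm$x_nm, tab$x_nm, `-`)^2 / (2 * s^2))
  gy <- exp(-outer(dm$y_nm, tab$y_nm, `-`)^2 / (2 * s^2))
  oracle <- gy %*% t(gx)
  # per-column argmax within 1 grid cell of the oracle's
  core <- dm$x_nm > min(tab$x_nm) & dm$x_nm < max(tab$x_nm)
  am <- apply(dm$density[, core], 2, which.max)
  am_or <- apply(oracle[, core], 2, which.max)
  expect_lte(max(abs(am - am_or)), 1)
})

test_that("centerline follows a straight bundle and a known parabola", {
  # straight bundle: higher-order coefficients ~ 0, line matched < 2 nm RMS
  tab <- straight_bundle_table(2e4, sigma = 20, seed = 11)
  dm <- compute_density_map(tab$x_nm, tab$y_nm)
  cl <- fit_centerline(dm, theta = 0, degree = 3)
  xs <- seq(cl$domain[1], cl$domain[2], by = 10)
  expect_lt(sqrt(mean(evaluate_centerline(cl, xs)^2)), 2)
  expect_lt(max(abs(cl$coef[3] * xs^2)), 2)
  expect_lt(max(abs(cl$coef[4] * xs^3)), 2)

  # noiseless points on y = 1e-4 x^2: fitted curve within 1 grid cell
  x <- seq(0, 2000, by = 2)
  dmp <- compute_density_map(x, 1e-4 * x^2)
  clp <- fit_centerline(dmp, theta = 0, degree = 3)
  # evaluate where the generating points live (the fitted domain extends
  # into the kernel padding, where the ridge is one-sided by construction)
  xs <- seq(max(clp$domain[1], 0), min(clp$domain[2], 2000), by = 10)
  expect_lt(max(abs(evaluate_centerline(clp, xs) - 1e-4 * xs^2)),
            dmp$grid_pitch_nm)

  # density map constant in y has no ridge
  flat <- dmp
  flat$density[] <- 1
  expect_error(fit_centerline(flat), "no ridge")
})

test_that("perpendicular distances are signed and match a brute-force search", {
  line <- structure(list(theta = 0, coef = 0, domain = c(-1000, 1000)),
                    class = "centerline_fit")
  d <- perpendicular_distances(c(0, 100, -50), c(5, 0, -7), line)
  expect_equal(d$distance_nm, c(5, 0, -7), tolerance = 1e-9)
  expect_equal(d$n_dropped, 0)

  # events outside the domain are dropped and counted
  d2 <- perpendicular_distances(c(0, 2000), c(5, 5), line)
  expect_equal(d2$n_dropped, 1)
  expect_equal(d2$distance_nm, 5, tolerance = 1e-9)

  # 1e3 random points vs a cubic: 1e5-sample brute-force oracle within 0.1 nm
  cubic <- structure(list(theta = 0, coef = c(50, 0.1, -2e-4, 8e-8),
                          domain = c(0, 2000)),
                     class = "centerline_fit")
  set.seed(13)
  px <- runif(1000, 100, 1900)
  py <- evaluate_centerline(cubic, px) + rnorm(1000, 0, 80)
  impl <- perpendicular_distances(px, py, cubic)
  xs <- seq(0, 2000, length.out = 1e5)
  ys <- evaluate_centerline(cubic, xs)
  brute <- vapply(seq_along(px), function(i)
    sqrt(min((px[i] - xs)^2 + (py[i] - ys)^2)), numeric(1))
  expect_lt(max(abs(abs(impl$distance_nm) - brute)), 0.1)
  # sign: above the curve (left of increasing x) is positive
  expect_true(all(sign(impl$distance_nm) ==
                    sign(py - evaluate_centerline(cubic, px))))
})

test_that("the Gaussian profile fit recovers a known sigma", {
  set.seed(17)
  prof <- fit_width_profile(rnorm(1e5, 0, 30))
  expect_lt(abs(prof$sigma_nm - 30), 1)
  expect_lt(abs(prof$mu_nm), 1)
  expect_gt(prof$r_squared, 0.99)

  # all distances identical is degenerate
  expect_error(fit_width_profile(rep(5, 100)), "degenerate")
  expect_error(fit_width_profile(rnorm(10)), "at least 50")

  # 95% N(0,30) + 5% uniform background with a baseline term: within 5%
  set.seed(19)
  mix <- c(rnorm(19000, 0, 30), runif(1000, -300, 300))
  profb <- fit_width_profile(mix, baseline = TRUE)
  expect_lt(abs(profb$sigma_nm - 30) / 30, 0.05)
})

test_that("precision deconvolution follows the quadrature closed forms", {
  co <- correct_for_precision(31.62, 10)
  expect_equal(co$sigma_corr_nm, sqrt(31.62^2 - 100))
  expect_equal(round(co$sigma_corr_nm, 2), 30.00)
  expect_equal(co$linker_nm, 0)

  # sigma_prec = 0 is the identity
  expect_equal(correct_for_precision(25, 0)$sigma_corr_nm, 25)

  # FWHM closed form: sigma 10 -> 23.548
  expect_equal(round(sigma_to_fwhm(10), 3), 23.548)
  expect_equal(co$fwhm_corr_nm, 2 * sqrt(2 * log(2)) * co$sigma_corr_nm)

  # RMS aggregation of per-event precisions
  pr <- c(5, 10, 20)
  expect_equal(correct_for_precision(40, pr)$sigma_prec_nm,
               sqrt(mean(pr^2)))
  expect_equal(correct_for_precision(40, pr, method = "mean")$sigma_prec_nm,
               mean(pr))
  expect_error(correct_for_precision(10, c(12, 12)), "unresolvable")
})

test_that("the full pipeline inverts the simulator's quadrature law", {
  # sigma_true 30 (FWHM 70.6), precision fixed at 15, ~2e4 events
  spec <- bundle_spec(sigma_true_nm = 30, precision_mean_nm = 15,
                      precision_sd_nm = 0, density_per_um = 1e4, seed = 23)
  sc <- simulate_bundle_localizations(spec)
  w <- measure_bundle_width(sc$table)
  fwhm_true <- sigma_to_fwhm(30)
  fwhm_meas_pred <- sigma_to_fwhm(sqrt(30^2 + 15^2))
  expect_lt(abs(w$fwhm_meas_nm - fwhm_meas_pred) / fwhm_meas_pred, 0.05)
  expect_lt(abs(w$fwhm_corr_nm - fwhm_true) / fwhm_true, 0.05)
  expect_lte(w$sigma_corr_nm, w$sigma_meas_nm)
  expect_lt(abs(w$profile$mu_nm), w$sigma_meas_nm / 2)

  # rotation invariance: rotating the ROI contents changes fwhm_corr < 2%
  r <- rotate_xy(sc$table$x_nm, sc$table$y_nm, 30 * pi / 180)
  rot <- loc_table(frame = sc$table$frame, x_nm = r[, 1], y_nm = r[, 2],
                   precision_nm = sc$table$precision_nm)
  wr <- measure_bundle_width(rot)
  expect_lt(abs(wr$fwhm_corr_nm - w$fwhm_corr_nm) / w$fwhm_corr_nm, 0.02)
})

test_that("small precisions leave the measured profile nearly unchanged", {
  # all precisions < 40 nm and sigma_meas >= 60 nm: correction < 15%
  spec <- bundle_spec(sigma_true_nm = 60, precision_mean_nm = 20,
                      precision_sd_nm = 4, density_per_um = 5e3, seed = 29)
  sc <- simulate_bundle_localizations(spec)
  w <- measure_bundle_width(sc$table)
  expect_gte(w$sigma_meas_nm, 60)
  expect_lt(abs(w$fwhm_corr_nm - w$fwhm_meas_nm) / w$fwhm_meas_nm, 0.15)
})

test_that("pipeline failures are tagged with their stage", {
  tab <- straight_bundle_table(500, sigma = 20, seed = 31)
  expect_error(measure_bundle_width(tab, roi = c(0, 50, -50, 50)),
               "\\[roi\\]")
  # near-line events narrower than their stated precision: unresolvable width
  on_line <- straight_bundle_table(5000, sigma = 5, seed = 37)
  on_line$precision_nm[] <- 15
  expect_error(measure_bundle_width(on_line),
               "\\[precision_correction\\].*unresolvable")
})
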