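# Blind lateral drift correction for localization tables.
#
# The acquisition is split into temporal bins with equal event counts, each
# bin is rendered into a superresolution image, and the shift of every bin
# relative to the first (reference) bin is estimated at the image
# cross-correlation peak with sub-pixel parabolic refinement. Per-frame
# shifts are obtained by piecewise-linear interpolation between bin centers
# with constant extrapolation at the ends.

# FFT cross-correlation shift between two equally sized images.
# Returns c(dx, dy) in pixels such that img ~= ref translated by +(dx, dy)
# (in the x-right / y-up convention of rendered images: dx along columns,
# dy along rows). Zero-padded to twice the size to avoid wrap-around;
# the peak is refined by a 1D parabolic fit in each axis.
xcorr_shift_px <- function(ref, img, max_shift_px = NULL) {
  stopifnot(all(dim(ref) == dim(img)))
  nr <- nrow(ref); nc <- ncol(ref)
  pr <- 2L * nr; pc <- 2L * nc
  A <- matrix(0, pr, pc); B <- matrix(0, pr, pc)
  A[1:nr, 1:nc] <- ref - mean(ref)
  B[1:nr, 1:nc] <- img - mean(img)
  cc <- Re(stats::fft(stats::fft(B) * Conj(stats::fft(A)), inverse = TRUE))
  # lag along rows: values 0..nr-1 at indices 1..nr, -nr..-1 at pr-nr+1..pr
  lag_r <- c(0:(nr - 1), rep(NA, pr - 2 * nr + 1), -(nr - 1):-1)
  lag_c <- c(0:(nc - 1), rep(NA, pc - 2 * nc + 1), -(nc - 1):-1)
  valid_r <- !is.na(lag_r); valid_c <- !is.na(lag_c)
  if (!is.null(max_shift_px)) {
    valid_r <- valid_r & !is.na(lag_r) & abs(lag_r) <= max_shift_px
    valid_c <- valid_c & !is.na(lag_c) & abs(lag_c) <= max_shift_px
  }
  sub <- cc[valid_r, valid_c, drop = FALSE]
  sub_lag_r <- lag_r[valid_r]; sub_lag_c <- lag_c[valid_c]
  pk <- which(sub == max(sub), arr.ind = TRUE)
  # tie-break toward the smallest |shift|
  if (nrow(pk) > 1) {
    mag <- sub_lag_r[pk[, 1]]^2 + sub_lag_c[pk[, 2]]^2
    pk <- pk[which.min(mag), , drop = FALSE]
  }
  ri <- pk[1, 1]; ci <- pk[1, 2]
  # parabolic sub-pixel refinement using wrapped neighbors in the full map
  full_ri <- which(valid_r)[ri]; full_ci <- which(valid_c)[ci]
  parab <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (den >= 0) 0 else 0.5 * (m1 - p1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dr <- parab(cc[wrap(full_ri - 1, pr), full_ci], cc[full_ri, full_ci],
              cc[wrap(full_ri + 1, pr), full_ci])
  dc <- parab(cc[full_ri, wrap(full_ci - 1, pc)], cc[full_ri, full_ci],
              cc[full_ri, wrap(full_ci + 1, pc)])
  c(dx = sub_lag_c[ci] + dc, dy = sub_lag_r[ri] + dr)
}

#' Estimate lateral drift blindly from a localization table
#'
#' @param table a [loc_table()].
#' @param n_bins number of temporal bins (default 10); bins hold
#'   approximately equal event counts over contiguous frame ranges.
#' @param pixel_size_nm render pixel used for the correlation images.
#' @param min_events_per_bin estimation refuses to run on thinner bins.
#' @param max_shift_px optional search radius for the correlation peak
#'   (default: a quarter of the smaller image dimension).
#' @return a `drift_trace`: bin center frames, per-bin shifts (nm, reference
#'   bin = first = zero), the covered frame range, and a residual metric
#'   (mean correlation-peak curvature is not retained; the per-bin shifts
#'   are the estimate).
#' @export
estimate_drift <- function(table, n_bins = 10, pixel_size_nm = 20,
                           min_events_per_bin = 100, max_shift_px = NULL) {
  stopifnot(n_bins >= 2)
  ord <- order(table$frame)
  frames <- table$frame[ord]
  n <- length(frames)
  # contiguous equal-count frame ranges
  breaks <- unique(stats::quantile(frames, probs = seq(0, 1, length.out = n_bins + 1),
                                   type = 1))
  bin <- findInterval(frames, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  if (length(counts) < 2 || any(counts < min_events_per_bin))
    stop("under-populated temporal bins (", min(counts),
         " events); use fewer bins or more localizations")
  nb <- length(counts)
  pad <- 2 * pixel_size_nm
  bounds <- c(min(table$x_nm) - pad, max(table$x_nm) + pad,
              min(table$y_nm) - pad, max(table$y_nm) + pad)
  imgs <- lapply(seq_len(nb), function(i) {
    idx <- ord[bin == i]
    render_image(table[idx, , drop = FALSE], pixel_size_nm, bounds)$pixels
  })
  if (is.null(max_shift_px))
    max_shift_px <- max(4, floor(min(dim(imgs[[1]])) / 4))
  shifts <- matrix(0, nb, 2)
  for (i in 2:nb) {
    s <- xcorr_shift_px(imgs[[1]], imgs[[i]], max_shift_px)
    shifts[i, ] <- s * pixel_size_nm
  }
  centers <- vapply(seq_len(nb), function(i) mean(frames[bin == i]), numeric(1))
  structure(list(bin_center_frame = centers,
                 dx_nm = shifts[, 1], dy_nm = shifts[, 2],
                 frame_range = range(table$frame),
                 n_bins = nb, pixel_size_nm = pixel_size_nm,
                 bin_counts = counts),
            class = "drift_trace")
}

#' Evaluate a drift trace at given frames
#'
#' Piecewise-linear interpolation between bin centers, constant
#' extrapolation beyond the first/last bin center.
#'
#' @param trace a `drift_trace`.
#' @param frames frame indices.
#' @return matrix with columns `dx_nm`, `dy_nm`.
#' @export
drift_at <- function(trace, frames) {
  dx <- stats::approx(trace$bin_center_frame, trace$dx_nm, xout = frames,
                      rule = 2)$y
  dy <- stats::approx(trace$bin_center_frame, trace$dy_nm, xout = frames,
                      rule = 2)$y
  cbind(dx_nm = dx, dy_nm = dy)
}

#' Remove estimated drift from a localization table
#'
#' Each event is translated by minus its frame's interpolated shift. The
#' record count is unchanged.
#'
#' @param table a [loc_table()].
#' @param trace a `drift_trace` covering the table's frame range.
#' @return the corrected `loc_table`.
#' @export
correct_drift <- function(table, trace) {
  if (min(table$frame) < trace$frame_range[1] ||
      max(table$frame) > trace$frame_range[2])
    stop("drift trace does not cover the table's frame range")
  d <- drift_at(trace, table$frame)
  table$x_nm <- table$x_nm - d[, 1]
  table$y_nm <- table$y_nm - d[, 2]
  table
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("drift_trace: %d bins over frames %d-%d; max |shift| %.1f nm\n",
              x$n_bins, x$frame_range[1], x$frame_range[2],
              max(abs(c(x$dx_nm, x$dy_nm)))))
  invisible(x)
}
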