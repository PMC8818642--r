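# Localization-table I/O and rendering.
#
# A localization table holds one row per accepted single-molecule blink
# event: frame index, x/y position in nm, and the per-event localization
# precision in nm (the SD of the position estimate). Tables are plain
# data.frames with class "loc_table" so they print and subset naturally.

LOC_COLUMNS <- c("frame", "x_nm", "y_nm", "precision_nm")

# Column-name maps per dialect. generic_csv expects the canonical names
# unless an explicit map is supplied; rainstorm_like maps the typical
# exported headers.
dialect_columns <- function(dialect) {
  switch(dialect,
    generic_csv = c(frame = "frame", x_nm = "x_nm", y_nm = "y_nm",
                    precision_nm = "precision_nm"),
    rainstorm_like = c(frame = "Frame", x_nm = "X_nm", y_nm = "Y_nm",
                       precision_nm = "Precision_nm"),
    stop("unknown dialect: ", dialect)
  )
}

#' Construct a localization table
#'
#' @param frame non-negative integer frame indices.
#' @param x_nm,y_nm event coordinates in nm (finite).
#' @param precision_nm per-event localization precision in nm (> 0).
#' @param photons optional photon counts.
#' @param extra optional data.frame of extra columns carried through I/O.
#' @return a `loc_table` (data.frame).
#' @export
loc_table <- function(frame, x_nm, y_nm, precision_nm, photons = NULL,
                      extra = NULL) {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n, length(frame) == n, length(precision_nm) == n)
  if (any(frame < 0)) stop("frame indices must be non-negative")
  if (any(!is.finite(x_nm)) || any(!is.finite(y_nm)))
    stop("x_nm and y_nm must be finite")
  if (any(precision_nm < 0) || any(!is.finite(precision_nm)))
    stop("precision_nm must be finite and non-negative")
  tab <- data.frame(frame = as.integer(frame), x_nm = x_nm, y_nm = y_nm,
                    precision_nm = precision_nm)
  if (!is.null(photons)) tab$photons <- photons
  if (!is.null(extra)) tab <- cbind(tab, extra)
  class(tab) <- c("loc_table", "data.frame")
  tab
}

#' Read a localization table from CSV
#'
#' Rows with non-finite coordinates are dropped; the number dropped is stored
#' in the `"dropped"` attribute of the result.
#'
#' @param path CSV file with a header row.
#' @param dialect `"generic_csv"` (canonical column names, overridable via
#'   `columns`) or `"rainstorm_like"` (typical reconstruction-software export
#'   names).
#' @param columns optional named character map from canonical names
#'   (`frame`, `x_nm`, `y_nm`, `precision_nm`) to the file's header names.
#' @param unit coordinate unit in the file: `"nm"` or `"px"` (camera/render
#'   pixels; requires `pixel_size_nm`).
#' @param pixel_size_nm nm per pixel when `unit = "px"`.
#' @return a [loc_table()] in nm; unknown extra columns are carried through.
#' @export
read_localizations <- function(path, dialect = c("generic_csv", "rainstorm_like"),
                               columns = NULL, unit = c("nm", "px"),
                               pixel_size_nm = NULL) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  map <- if (is.null(columns)) dialect_columns(dialect) else columns
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  scale <- if (unit == "px") {
    if (is.null(pixel_size_nm)) stop("unit 'px' requires pixel_size_nm")
    pixel_size_nm
  } else 1
  x <- as.numeric(raw[[map[["x_nm"]]]]) * scale
  y <- as.numeric(raw[[map[["y_nm"]]]]) * scale
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  # a header-only file is a legal empty table; a file whose rows all fail to
  # parse is an input error
  if (nrow(raw) > 0 && !any(keep))
    stop("no parseable localization rows in ", path)
  extra_names <- setdiff(names(raw), unname(map))
  tab <- loc_table(
    frame = raw[[map[["frame"]]]][keep],
    x_nm = x[keep], y_nm = y[keep],
    precision_nm = as.numeric(raw[[map[["precision_nm"]]]][keep]) * scale,
    extra = if (length(extra_names)) raw[keep, extra_names, drop = FALSE]
  )
  attr(tab, "dropped") <- dropped
  tab
}

#' Write a localization table to CSV
#'
#' The file is re-readable by [read_localizations()] with the same dialect.
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @param dialect column-name dialect (see [read_localizations()]).
#' @export
write_localizations <- function(table, path,
                                dialect = c("generic_csv", "rainstorm_like")) {
  dialect <- match.arg(dialect)
  map <- dialect_columns(dialect)
  out <- as.data.frame(table)
  idx <- match(names(map), names(out))
  names(out)[idx[!is.na(idx)]] <- map[!is.na(idx)]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Keep only high-precision localizations
#'
#' Retains records with `precision_nm` strictly below the threshold,
#' mirroring the acceptance rule for localizations with precision < 40 nm.
#' Order is preserved; an empty result is legal.
#'
#' @param table a [loc_table()].
#' @param max_precision_nm strict upper bound on precision (default 40 nm).
#' @return the filtered `loc_table`.
#' @export
filter_by_precision <- function(table, max_precision_nm = 40) {
  stopifnot(max_precision_nm > 0)
  out <- table[table$precision_nm < max_precision_nm, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render localizations into a count-mode superresolution image
#'
#' Pixels are half-open squares: pixel (r, c) covers
#' `[x0 + (c-1) p, x0 + c p) x [y0 + (r-1) p, y0 + r p)` with the origin at
#' the lower-left corner and row index increasing with y. Events exactly on a
#' bin edge fall into the higher-index pixel. The pixel sum equals the number
#' of in-bounds events.
#'
#' @param table a [loc_table()] (non-empty).
#' @param pixel_size_nm render pixel size (default 20 nm).
#' @param bounds optional `c(xmin, xmax, ymin, ymax)` in nm; default is the
#'   tight bounding box padded by one pixel.
#' @return a `rendered_image`: list with `pixels` (matrix, rows = y),
#'   `pixel_size_nm`, and `origin_nm`.
#' @export
render_image <- function(table, pixel_size_nm = 20, bounds = NULL) {
  stopifnot(pixel_size_nm > 0)
  if (nrow(table) == 0) stop("cannot render an empty localization table")
  p <- pixel_size_nm
  if (is.null(bounds)) {
    bounds <- c(min(table$x_nm) - p, max(table$x_nm) + p,
                min(table$y_nm) - p, max(table$y_nm) + p)
  }
  x0 <- bounds[1]; y0 <- bounds[3]
  nc <- max(1L, ceiling((bounds[2] - x0) / p))
  nr <- max(1L, ceiling((bounds[4] - y0) / p))
  col <- floor((table$x_nm - x0) / p) + 1
  row <- floor((table$y_nm - y0) / p) + 1
  inb <- col >= 1 & col <= nc & row >= 1 & row <= nr
  pix <- matrix(0, nr, nc)
  if (any(inb)) {
    counts <- tabulate((col[inb] - 1) * nr + row[inb], nbins = nr * nc)
    pix <- matrix(counts, nr, nc)
  }
  structure(list(pixels = pix, pixel_size_nm = p, origin_nm = c(x0, y0)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d px, %.3g nm/px, origin (%.4g, %.4g) nm, sum %g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm,
              x$origin_nm[1], x$origin_nm[2], sum(x$pixels)))
  invisible(x)
}
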