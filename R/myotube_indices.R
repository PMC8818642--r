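# Myotube differentiation and fusion indices from labeled masks.
#
# Inputs are two label images of equal shape: nuclei (integer labels, 0 =
# background) and desmin-positive cells/myotubes. The differentiation index
# is the number of desmin-positive cells over the total number of nuclei;
# the fusion index is the fraction of all nuclei residing in desmin-positive
# myotubes with at least 2 nuclei. Nuclei-per-myotube counts are reported in
# the categories 2, 3-5, and >5, and each myotube's area and length are
# quantified.

# centroid (row, col) of every label in an integer label image
label_centroids <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  idx <- which(lab > 0)
  r <- ((idx - 1) %% nrow(lab)) + 1
  c <- ((idx - 1) %/% nrow(lab)) + 1
  v <- lab[idx]
  data.frame(label = ids,
             row = as.numeric(tapply(r, v, mean)[as.character(ids)]),
             col = as.numeric(tapply(c, v, mean)[as.character(ids)]))
}

#' Assign nuclei to desmin-positive objects
#'
#' A nucleus is assigned to the desmin object containing its centroid
#' (default), or to the object with the majority pixel overlap.
#'
#' @param nuclei integer nuclei label matrix (0 = background).
#' @param desmin integer desmin label matrix, same shape.
#' @param method `"centroid"` or `"majority"`.
#' @return named integer vector: nucleus label -> desmin label (0 = none).
#' @export
assign_nuclei <- function(nuclei, desmin, method = c("centroid", "majority")) {
  method <- match.arg(method)
  stopifnot(all(dim(nuclei) == dim(desmin)))
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (length(ids) == 0) stop("no nuclei in the mask")
  if (method == "centroid") {
    cen <- label_centroids(nuclei)
    out <- desmin[cbind(round(cen$row), round(cen$col))]
    names(out) <- cen$label
  } else {
    out <- vapply(ids, function(id) {
      over <- desmin[nuclei == id]
      over <- over[over > 0]
      if (!length(over)) return(0L)
      as.integer(names(which.max(table(over))))
    }, integer(1))
    names(out) <- ids
  }
  out
}

#' Differentiation/fusion indices and myotube morphometrics
#'
#' @param nuclei,desmin integer label matrices (0 = background).
#' @param pixel_size_um pixel size in micrometres.
#' @param assignment optional precomputed [assign_nuclei()] result.
#' @param min_nuclei myotube definition: desmin-positive object with at
#'   least this many assigned nuclei (default 2).
#' @return a `fusion_metrics`: `differentiation_index`, `fusion_index`,
#'   `category_histogram` (2 / 3-5 / >5 nuclei), `n_nuclei`,
#'   `n_desmin_objects`, `n_myotubes`, and a per-myotube data.frame with
#'   nuclei count, area (um^2), skeleton length and major-axis length (um).
#' @export
compute_indices <- function(nuclei, desmin, pixel_size_um = 1,
                            assignment = NULL, min_nuclei = 2) {
  if (is.null(assignment)) assignment <- assign_nuclei(nuclei, desmin)
  n_nuclei <- length(assignment)
  des_ids <- sort(unique(desmin[desmin > 0]))
  n_desmin <- length(des_ids)
  counts <- table(factor(assignment[assignment > 0], levels = des_ids))
  myo_ids <- des_ids[counts >= min_nuclei]
  nuclei_in_myotubes <- sum(counts[counts >= min_nuclei])
  per_myo <- lapply(myo_ids, function(id) {
    obj <- desmin == id
    npx <- sum(obj)
    idx <- which(obj)
    r <- ((idx - 1) %% nrow(desmin)) + 1
    c <- ((idx - 1) %/% nrow(desmin)) + 1
    # major-axis length from the second moments (ellipse-equivalent)
    cv <- stats::cov(cbind(r, c))
    major_um <- 4 * sqrt(max(eigen(cv, symmetric = TRUE,
                                   only.values = TRUE)$values, 0)) *
      pixel_size_um
    data.frame(label = id,
               n_nuclei = as.integer(counts[as.character(id)]),
               area_um2 = npx * pixel_size_um^2,
               length_um = skeleton_longest_path_nm(obj, pixel_size_um * 1000) / 1000,
               major_axis_um = major_um)
  })
  per_myo <- if (length(per_myo)) do.call(rbind, per_myo)
             else data.frame(label = integer(0), n_nuclei = integer(0),
                             area_um2 = numeric(0), length_um = numeric(0),
                             major_axis_um = numeric(0))
  structure(list(
    differentiation_index = n_desmin / n_nuclei,
    fusion_index = nuclei_in_myotubes / n_nuclei,
    category_histogram = nuclei_category_histogram(
      as.integer(counts[counts >= min_nuclei])),
    n_nuclei = n_nuclei,
    n_desmin_objects = n_desmin,
    n_myotubes = length(myo_ids),
    myotubes = per_myo,
    assignment = assignment
  ), class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  cat(sprintf(paste0("fusion_metrics: DI = %.3f, FI = %.3f\n",
                     "  %d nuclei, %d desmin-positive objects, %d myotubes ",
                     "(categories 2/3-5/>5: %d/%d/%d)\n"),
              x$differentiation_index, x$fusion_index, x$n_nuclei,
              x$n_desmin_objects, x$n_myotubes,
              x$category_histogram["2"], x$category_histogram["3-5"],
              x$category_histogram[">5"]))
  invisible(x)
}
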