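# Seeded synthetic-scene generators with recorded ground truth.
#
# Each generator emulates one class of input the analysis stages consume:
# localizations scattered around a curved bundle centerline (dSTORM), raster
# images of branched filament networks, Hertzian AFM force curves, and
# labeled nuclei/myotube masks. Every generator returns the artifact plus a
# ground-truth record, so parameter recovery can be tested without
# instrument data.

# Evaluate a polynomial with coefficients in increasing power order.
polyval <- function(coef, x) {
  out <- numeric(length(x))
  for (i in rev(seq_along(coef))) out <- out * x + coef[i]
  out
}

# Derivative coefficients of a polynomial (increasing power order).
polyder <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

# Positive-truncated normal draws (precision values are strictly positive).
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Specify a synthetic cortical actin bundle
#'
#' The bundle is a curved centerline `y(x) = sum(coef[i] x^(i-1))` over
#' `x_domain` with a Gaussian cross-section of SD `sigma_true_nm`
#' (FWHM = 2 sqrt(2 ln 2) sigma). Event density, per-event localization
#' precision, uniform background, and the number of camera frames emulate a
#' typical 20,000-50,000-frame dSTORM acquisition.
#'
#' @param coef centerline polynomial coefficients (nm, increasing powers).
#' @param x_domain `c(xmin, xmax)` nm.
#' @param sigma_true_nm true cross-section SD (> 0 except for degenerate
#'   test scenes).
#' @param density_per_um signal localizations per micrometre of centerline.
#' @param precision_mean_nm,precision_sd_nm per-event precision model
#'   (normal truncated > 0).
#' @param background_per_um2 nonspecific background localization density.
#' @param n_frames number of camera frames (default 30000).
#' @param seed RNG seed; identical specs give bitwise-identical scenes.
#' @return a `bundle_spec` list.
#' @export
bundle_spec <- function(coef = c(0, 0, 1e-4), x_domain = c(0, 2000),
                        sigma_true_nm = 30, density_per_um = 2500,
                        precision_mean_nm = 15, precision_sd_nm = 4,
                        background_per_um2 = 10, n_frames = 30000, seed = 1) {
  stopifnot(sigma_true_nm >= 0, density_per_um > 0,
            diff(x_domain) > 0, n_frames >= 1)
  structure(list(coef = coef, x_domain = x_domain,
                 sigma_true_nm = sigma_true_nm, density_per_um = density_per_um,
                 precision_mean_nm = precision_mean_nm,
                 precision_sd_nm = precision_sd_nm,
                 background_per_um2 = background_per_um2,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Simulate dSTORM localizations of a cortical actin bundle
#'
#' Signal events are placed arc-length-uniformly along the centerline,
#' offset perpendicular by N(0, sigma_true), then blurred by an isotropic
#' N(0, precision_i) localization error where precision_i is that event's
#' recorded precision. Background events are uniform over the padded
#' bounding box and carry precisions from the same model. Frames are
#' assigned uniformly.
#'
#' @param spec a [bundle_spec()].
#' @return list with `table` (a [loc_table()]) and `truth` (sigma/FWHM,
#'   centerline, counts, and the realized perpendicular offsets of the
#'   signal events).
#' @export
simulate_bundle_localizations <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  if (spec$density_per_um <= 0) stop("density_per_um must be positive")
  set.seed(spec$seed)
  xs <- seq(spec$x_domain[1], spec$x_domain[2], by = 1)
  ys <- polyval(spec$coef, xs)
  cum <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  arc_len <- cum[length(cum)]
  n_sig <- max(1L, round(spec$density_per_um * arc_len / 1000))
  u <- stats::runif(n_sig, 0, arc_len)
  xc <- stats::approx(cum, xs, xout = u)$y
  yc <- polyval(spec$coef, xc)
  slope <- polyval(polyder(spec$coef), xc)
  inv_norm <- 1 / sqrt(1 + slope^2)
  nx <- -slope * inv_norm
  ny <- inv_norm
  off <- stats::rnorm(n_sig, 0, spec$sigma_true_nm)
  prec_sig <- rtnorm_pos(n_sig, spec$precision_mean_nm, spec$precision_sd_nm)
  ex <- stats::rnorm(n_sig, 0, prec_sig)
  ey <- stats::rnorm(n_sig, 0, prec_sig)
  x_sig <- xc + nx * off + ex
  y_sig <- yc + ny * off + ey

  pad <- 4 * spec$sigma_true_nm + 3 * spec$precision_mean_nm + 20
  box <- c(spec$x_domain[1] - pad, spec$x_domain[2] + pad,
           min(ys) - pad, max(ys) + pad)
  area_um2 <- (box[2] - box[1]) * (box[4] - box[3]) / 1e6
  n_bg <- stats::rpois(1, spec$background_per_um2 * area_um2)
  x_bg <- stats::runif(n_bg, box[1], box[2])
  y_bg <- stats::runif(n_bg, box[3], box[4])
  prec_bg <- rtnorm_pos(n_bg, spec$precision_mean_nm, spec$precision_sd_nm)

  n_tot <- n_sig + n_bg
  tab <- loc_table(
    frame = sample.int(spec$n_frames, n_tot, replace = TRUE),
    x_nm = c(x_sig, x_bg), y_nm = c(y_sig, y_bg),
    precision_nm = c(prec_sig, prec_bg)
  )
  # realized perpendicular displacement of each signal event: structural
  # offset plus the perpendicular component of the isotropic precision error
  perp <- off + ex * nx + ey * ny
  truth <- list(
    sigma_true_nm = spec$sigma_true_nm,
    fwhm_true_nm = sigma_to_fwhm(spec$sigma_true_nm),
    coef = spec$coef, x_domain = spec$x_domain,
    n_signal = n_sig, n_background = n_bg,
    is_signal = c(rep(TRUE, n_sig), rep(FALSE, n_bg)),
    perp_offsets_nm = perp,
    precision_rms_nm = sqrt(mean(prec_sig^2))
  )
  list(table = tab, truth = truth)
}

#' Specify a synthetic filament network
#'
#' @param nodes n x 2 matrix of node coordinates (nm).
#' @param edges data.frame with `from`, `to` (node indices) and `width_nm`.
#' @param bounds `c(xmin, xmax, ymin, ymax)` nm; the graph must lie inside.
#' @param pixel_size_nm raster pixel size (default 20 nm).
#' @param seed RNG seed (recorded; rasterization itself is deterministic).
#' @return a `network_spec` list.
#' @export
network_spec <- function(nodes, edges, bounds, pixel_size_nm = 20, seed = 1) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 2, all(c("from", "to", "width_nm") %in% names(edges)))
  if (any(edges$from < 1 | edges$from > nrow(nodes)) ||
      any(edges$to < 1 | edges$to > nrow(nodes)))
    stop("edges reference non-existent nodes")
  if (any(nodes[, 1] < bounds[1] | nodes[, 1] > bounds[2] |
          nodes[, 2] < bounds[3] | nodes[, 2] > bounds[4]))
    stop("graph must lie fully inside bounds")
  if (nrow(nodes) > 1) {
    d <- as.matrix(stats::dist(nodes))
    diag(d) <- Inf
    if (min(d) < pixel_size_nm)
      stop("overlapping-node degeneracy: two nodes closer than one pixel")
  }
  structure(list(nodes = nodes, edges = edges, bounds = bounds,
                 pixel_size_nm = pixel_size_nm, seed = as.integer(seed)),
            class = "network_spec")
}

# Merge degree-2 pass-through nodes of the spec graph into maximal branches.
# Returns list of branches, each a polyline (matrix of node coords) with its
# arc length. Assumes no isolated cycles (generators never produce them).
merge_network_branches <- function(nodes, edges) {
  n <- nrow(nodes)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  used <- matrix(FALSE, n, n)
  branches <- list()
  terminals <- which(deg != 2 & deg > 0)
  for (t in terminals) {
    for (nb in adj[[t]]) {
      if (used[t, nb]) next
      path <- c(t, nb)
      used[t, nb] <- used[nb, t] <- TRUE
      while (deg[path[length(path)]] == 2) {
        cur <- path[length(path)]
        nxt <- setdiff(adj[[cur]], path[length(path) - 1])[1]
        used[cur, nxt] <- used[nxt, cur] <- TRUE
        path <- c(path, nxt)
      }
      poly <- nodes[path, , drop = FALSE]
      len <- sum(sqrt(rowSums(diff(poly)^2)))
      branches[[length(branches) + 1]] <- list(path = path, polyline = poly,
                                               length_nm = len)
    }
  }
  branches
}

#' Rasterize a synthetic filament network into a binary-ready image
#'
#' Edges are drawn as foreground ribbons of their stated width (a pixel is
#' foreground when its center lies within width/2 of an edge segment). The
#' ground truth records the branch decomposition after merging degree-2
#' pass-through nodes.
#'
#' @param spec a [network_spec()].
#' @return list with `image` (a `rendered_image` of 0/1 pixels) and `truth`
#'   (branch count, per-branch polyline lengths in nm).
#' @export
simulate_network_image <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  p <- spec$pixel_size_nm
  b <- spec$bounds
  nc <- ceiling((b[2] - b[1]) / p)
  nr <- ceiling((b[4] - b[3]) / p)
  cx <- b[1] + (seq_len(nc) - 0.5) * p
  cy <- b[3] + (seq_len(nr) - 0.5) * p
  img <- matrix(0, nr, nc)
  for (e in seq_len(nrow(spec$edges))) {
    a <- spec$nodes[spec$edges$from[e], ]
    bb <- spec$nodes[spec$edges$to[e], ]
    half <- spec$edges$width_nm[e] / 2
    ci <- which(cx >= min(a[1], bb[1]) - half - p & cx <= max(a[1], bb[1]) + half + p)
    ri <- which(cy >= min(a[2], bb[2]) - half - p & cy <= max(a[2], bb[2]) + half + p)
    if (!length(ci) || !length(ri)) next
    px <- rep(cx[ci], each = length(ri))
    py <- rep(cy[ri], times = length(ci))
    vx <- bb[1] - a[1]; vy <- bb[2] - a[2]
    len2 <- vx^2 + vy^2
    tr <- ((px - a[1]) * vx + (py - a[2]) * vy) / len2
    t <- pmin(1, pmax(0, tr))
    d2 <- (px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2
    # butt caps: the ribbon ends flush at the nodes so the drawn ink has
    # exactly the arc length recorded in the ground truth
    hit <- matrix(d2 <= half^2 & tr >= 0 & tr <= 1, nrow = length(ri))
    img[ri, ci] <- pmax(img[ri, ci], hit * 1)
  }
  branches <- merge_network_branches(spec$nodes, spec$edges)
  truth <- list(branch_count = length(branches),
                branch_lengths_nm = vapply(branches, `[[`, numeric(1), "length_nm"),
                branches = branches)
  image <- structure(list(pixels = img, pixel_size_nm = p,
                          origin_nm = c(b[1], b[3])),
                     class = "rendered_image")
  list(image = image, truth = truth)
}

#' Grow a random branched network specification
#'
#' Grows a tree edge by edge from a central root, enforcing geometric
#' sanity (minimum edge length, node separation, incident-edge angle, and
#' clearance between non-adjacent segments) so that rasterization followed
#' by skeletonization can recover the topology.
#'
#' @param n_edges number of edges (default 12).
#' @param bounds image bounds in nm.
#' @param len_range edge length range in nm (default 200-400).
#' @param width_nm ribbon width (default 60 nm).
#' @param pixel_size_nm raster pixel (default 20 nm).
#' @param seed RNG seed.
#' @return a [network_spec()].
#' @export
random_network_spec <- function(n_edges = 12, bounds = c(0, 4000, 0, 4000),
                                len_range = c(200, 400), width_nm = 60,
                                pixel_size_nm = 20, seed = 1) {
  set.seed(seed)
  min_sep <- 160
  clearance <- 110
  min_angle <- 70 * pi / 180
  margin <- 120
  nodes <- matrix(c(mean(bounds[1:2]), mean(bounds[3:4])), 1, 2)
  edges <- data.frame(from = integer(0), to = integer(0), width_nm = numeric(0))
  inc_angle <- list(numeric(0)) # outgoing edge angles per node

  seg_clear <- function(a, b) {
    # sampled clearance of candidate segment (a,b) against existing edges
    # that do not share node a
    ts <- seq(0, 1, length.out = max(3, ceiling(sqrt(sum((b - a)^2)) / 15)))
    sx <- a[1] + ts * (b[1] - a[1])
    sy <- a[2] + ts * (b[2] - a[2])
    for (e in seq_len(nrow(edges))) {
      pa <- nodes[edges$from[e], ]; pb <- nodes[edges$to[e], ]
      vx <- pb[1] - pa[1]; vy <- pb[2] - pa[2]
      tt <- pmin(1, pmax(0, ((sx - pa[1]) * vx + (sy - pa[2]) * vy) / (vx^2 + vy^2)))
      d2 <- (sx - (pa[1] + tt * vx))^2 + (sy - (pa[2] + tt * vy))^2
      shares <- isTRUE(all.equal(pa, a)) || isTRUE(all.equal(pb, a))
      if (shares) {
        # ignore the region near the shared node
        keep <- ((sx - a[1])^2 + (sy - a[2])^2) > min_sep^2
        if (any(d2[keep] < clearance^2)) return(FALSE)
      } else if (any(d2 < clearance^2)) return(FALSE)
    }
    TRUE
  }

  # add one edge from node i at a feasible angle; returns TRUE on success
  try_add_edge <- function(i, max_tries = 60) {
    for (k in seq_len(max_tries)) {
      ang <- stats::runif(1, 0, 2 * pi)
      prev <- inc_angle[[i]]
      if (length(prev) > 0) {
        dd <- abs(((ang - prev + pi) %% (2 * pi)) - pi)
        if (min(dd) < min_angle) next
      }
      len <- stats::runif(1, len_range[1], len_range[2])
      p_new <- nodes[i, ] + len * c(cos(ang), sin(ang))
      if (p_new[1] < bounds[1] + margin || p_new[1] > bounds[2] - margin ||
          p_new[2] < bounds[3] + margin || p_new[2] > bounds[4] - margin) next
      if (min(sqrt(rowSums((nodes - matrix(p_new, nrow(nodes), 2,
                                           byrow = TRUE))^2))) < min_sep) next
      if (!seg_clear(nodes[i, ], p_new)) next
      nodes <<- rbind(nodes, p_new)
      edges <<- rbind(edges, data.frame(from = i, to = nrow(nodes),
                                        width_nm = width_nm))
      inc_angle[[i]] <<- c(inc_angle[[i]], ang)
      inc_angle[[nrow(nodes)]] <<- (ang + pi) %% (2 * pi)
      return(TRUE)
    }
    FALSE
  }

  # grow without ever leaving a node at degree 2 (degree-2 nodes would be
  # merged away in the branch decomposition): single edges attach to nodes
  # of degree 0, 2 or 3; leaves (degree 1) receive two edges atomically.
  attempts <- 0
  restarts <- 0
  while (nrow(edges) < n_edges) {
    attempts <- attempts + 1
    if (attempts > 400) {
      # geometrically blocked growth front: restart within the same RNG
      # stream (still deterministic given the seed)
      restarts <- restarts + 1
      if (restarts > 25)
        stop("could not grow a feasible network; relax the constraints")
      nodes <- nodes[1, , drop = FALSE]
      edges <- edges[0, , drop = FALSE]
      inc_angle <- list(numeric(0))
      attempts <- 0
      next
    }
    deg <- if (nrow(edges)) tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
           else rep(0L, nrow(nodes))
    rem <- n_edges - nrow(edges)
    singles <- which(deg == 0 | deg == 2 | deg == 3)
    # crowded growth fronts: fall back to enlarging existing junctions
    if (!length(singles) && (rem == 1 || attempts > 200))
      singles <- which(deg >= 3)
    leaves <- which(deg == 1)
    use_pair <- rem >= 2 && length(leaves) &&
      (!length(singles) || stats::runif(1) < 0.5)
    if (use_pair) {
      i <- leaves[sample.int(length(leaves), 1)]
      n_nodes0 <- nrow(nodes)
      if (try_add_edge(i)) {
        if (!try_add_edge(i)) { # rollback to avoid a degree-2 node
          nodes <- nodes[seq_len(n_nodes0), , drop = FALSE]
          edges <- edges[-nrow(edges), , drop = FALSE]
          inc_angle[[i]] <- inc_angle[[i]][-length(inc_angle[[i]])]
          inc_angle[n_nodes0 + 1] <- NULL
        }
      }
    } else if (length(singles)) {
      try_add_edge(singles[sample.int(length(singles), 1)])
    }
  }
  rownames(nodes) <- NULL
  network_spec(nodes, edges, bounds, pixel_size_nm, seed)
}

#' Shift localizations by a per-frame drift trajectory
#'
#' Test harness for blind drift correction: each event is translated by its
#' frame's (dx, dy).
#'
#' @param table a [loc_table()].
#' @param drift n_frames x 2 matrix of (dx, dy) in nm; row f applies to
#'   frame f.
#' @return the drifted `loc_table`.
#' @export
inject_drift <- function(table, drift) {
  drift <- as.matrix(drift)
  stopifnot(ncol(drift) == 2)
  if (any(table$frame < 1) || any(table$frame > nrow(drift)))
    stop("drift trajectory does not cover all frames present in the table")
  table$x_nm <- table$x_nm + drift[table$frame, 1]
  table$y_nm <- table$y_nm + drift[table$frame, 2]
  table
}

#' Linear drift trajectory
#'
#' @param n_frames number of frames.
#' @param total_dx_nm,total_dy_nm total drift accumulated from frame 1 to
#'   frame `n_frames`.
#' @return n_frames x 2 matrix of per-frame shifts (nm).
#' @export
linear_drift <- function(n_frames, total_dx_nm, total_dy_nm = 0) {
  cbind(seq(0, total_dx_nm, length.out = n_frames),
        seq(0, total_dy_nm, length.out = n_frames))
}

#' Simulate an AFM force-indentation curve with Hertzian contact
#'
#' Forward model of sharp-indenter Hertz contact: F = 0 before the contact
#' point, F = C(geometry) E / (1 - nu^2) (delta - delta0)^2 after, plus
#' optional additive and/or proportional Gaussian force noise; the curve is
#' truncated at `max_force_nN` (mirroring acquisition with a loading force
#' < 0.5 nN).
#'
#' @param E_true_pa true Young's modulus (Pa, > 0).
#' @param geometry `"cone"` or `"pyramid"` (see [hertz_force()]).
#' @param alpha_deg tip (half-)angle in degrees.
#' @param nu Poisson ratio (0.5 = incompressible cell).
#' @param noise_sd_nN additive force noise SD.
#' @param noise_frac proportional force noise: each sample is scaled by
#'   `1 + N(0, noise_frac)` (0 = off).
#' @param max_force_nN truncation force (default 0.5 nN).
#' @param contact_nm contact point position on the indentation axis.
#' @param pre_contact_nm extent of the pre-contact baseline region.
#' @param step_nm sample spacing.
#' @param seed optional RNG seed.
#' @return list with `curve` (a `force_curve`) and `truth`.
#' @export
simulate_force_curve <- function(E_true_pa, geometry = c("cone", "pyramid"),
                                 alpha_deg = 35, nu = 0.5, noise_sd_nN = 0,
                                 noise_frac = 0,
                                 max_force_nN = 0.5, contact_nm = 0,
                                 pre_contact_nm = 200, step_nm = 2,
                                 seed = NULL) {
  geometry <- match.arg(geometry)
  if (E_true_pa <= 0) stop("E_true_pa must be positive")
  if (!is.null(seed)) set.seed(seed)
  cc <- hertz_coefficient(geometry, alpha_deg) * E_true_pa / (1 - nu^2) * 1e-9
  delta_max <- sqrt(max_force_nN / cc)
  d <- seq(contact_nm - pre_contact_nm, contact_nm + delta_max, by = step_nm)
  f <- cc * pmax(d - contact_nm, 0)^2
  if (noise_sd_nN > 0) f <- f + stats::rnorm(length(d), 0, noise_sd_nN)
  if (noise_frac > 0) f <- f * (1 + stats::rnorm(length(d), 0, noise_frac))
  curve <- force_curve(d, f, geometry = geometry, alpha_deg = alpha_deg, nu = nu)
  list(curve = curve, truth = list(E_pa = E_true_pa, contact_nm = contact_nm))
}

#' Simulate a grid of force curves over a known modulus map
#'
#' @param E_grid matrix of true Young's moduli (Pa), one per map cell.
#' @param noise_frac noise SD as a fraction of `max_force_nN`.
#' @param seed RNG seed.
#' @param ... forwarded to [simulate_force_curve()].
#' @return list with `curves` (list in column-major cell order), `dim`, and
#'   `truth` (the E grid).
#' @export
simulate_elasticity_scene <- function(E_grid, noise_frac = 0.05, seed = 1, ...) {
  E_grid <- as.matrix(E_grid)
  args <- list(...)
  max_f <- if (!is.null(args$max_force_nN)) args$max_force_nN else 0.5
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(E_grid))
  curves <- lapply(seq_along(E_grid), function(i) {
    do.call(simulate_force_curve,
            c(list(E_true_pa = E_grid[i], noise_sd_nN = noise_frac * max_f,
                   seed = seeds[i]), args))$curve
  })
  list(curves = curves, dim = dim(E_grid), truth = list(E_grid_pa = E_grid))
}

#' Generate labeled nuclei and desmin/myotube mask fixtures
#'
#' Places non-overlapping labeled objects on a canvas: multinucleated
#' desmin-positive myotubes (each with its assigned nuclei inside),
#' mononucleated desmin-positive cells (one nucleus each), and free
#' background nuclei. Truth indices are computed arithmetically from the
#' assignment.
#'
#' @param n_nuclei total number of nuclei.
#' @param myotube_assignment integer vector, nuclei per myotube (each >= 2).
#' @param n_desmin_pos_cells number of mononucleated desmin-positive cells.
#' @param pixel_size_um pixel size of the masks (default 1 um).
#' @param seed RNG seed (placement jitter).
#' @return list with `nuclei` and `desmin` integer label matrices,
#'   `pixel_size_um`, and `truth` (differentiation index, fusion index,
#'   per-myotube nuclei counts, category histogram, nucleus-to-myotube
#'   assignment).
#' @export
generate_myotube_masks <- function(n_nuclei, myotube_assignment = integer(0),
                                   n_desmin_pos_cells = 0, pixel_size_um = 1,
                                   seed = 1) {
  myotube_assignment <- as.integer(myotube_assignment)
  if (length(myotube_assignment) && any(myotube_assignment < 2))
    stop("each myotube must contain at least 2 nuclei")
  n_in_tubes <- sum(myotube_assignment)
  if (n_in_tubes + n_desmin_pos_cells > n_nuclei)
    stop("assigned nuclei exceed the total nucleus count")
  set.seed(seed)

  # item list: type, width, height
  items <- list()
  for (k in myotube_assignment)
    items[[length(items) + 1]] <- list(type = "myotube", k = k,
                                       w = 8 * k + 8, h = 9)
  for (i in seq_len(n_desmin_pos_cells))
    items[[length(items) + 1]] <- list(type = "mono", w = 9, h = 9)
  n_free <- n_nuclei - n_in_tubes - n_desmin_pos_cells
  for (i in seq_len(n_free))
    items[[length(items) + 1]] <- list(type = "free", w = 3, h = 3)

  # simple shelf packing with jitter
  max_row_w <- 420L
  gap <- 7L
  x <- gap; y <- gap; row_h <- 0L
  canvas_w <- max_row_w + 2L * gap
  placements <- list()
  for (it in items) {
    if (x + it$w > canvas_w - gap) {
      x <- gap
      y <- y + row_h + gap
      row_h <- 0L
    }
    jx <- sample.int(3, 1) - 1L
    jy <- sample.int(3, 1) - 1L
    placements[[length(placements) + 1]] <- c(it, list(x = x + jx, y = y + jy))
    x <- x + it$w + gap + 3L
    row_h <- max(row_h, it$h + 3L)
  }
  canvas_h <- y + row_h + gap
  nuc <- matrix(0L, canvas_h, canvas_w)
  des <- matrix(0L, canvas_h, canvas_w)

  nuc_label <- 0L
  des_label <- 0L
  assignment <- integer(0) # nucleus label -> desmin label (0 = none)
  myotube_labels <- integer(0)
  put <- function(m, r0, c0, h, w, val) {
    m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- val
    m
  }
  for (pl in placements) {
    r0 <- pl$y; c0 <- pl$x
    if (pl$type == "myotube") {
      des_label <- des_label + 1L
      myotube_labels <- c(myotube_labels, des_label)
      des <- put(des, r0, c0, pl$h, pl$w, des_label)
      for (j in seq_len(pl$k)) {
        nuc_label <- nuc_label + 1L
        nuc <- put(nuc, r0 + 3L, c0 + 4L + 8L * (j - 1L), 3L, 3L, nuc_label)
        assignment[nuc_label] <- des_label
      }
    } else if (pl$type == "mono") {
      des_label <- des_label + 1L
      des <- put(des, r0, c0, 9L, 9L, des_label)
      nuc_label <- nuc_label + 1L
      nuc <- put(nuc, r0 + 3L, c0 + 3L, 3L, 3L, nuc_label)
      assignment[nuc_label] <- des_label
    } else {
      nuc_label <- nuc_label + 1L
      nuc <- put(nuc, r0, c0, 3L, 3L, nuc_label)
      assignment[nuc_label] <- 0L
    }
  }
  n_myo <- length(myotube_assignment)
  truth <- list(
    n_nuclei = n_nuclei,
    n_desmin_objects = n_myo + n_desmin_pos_cells,
    n_myotubes = n_myo,
    nuclei_per_myotube = myotube_assignment,
    differentiation_index = (n_myo + n_desmin_pos_cells) / n_nuclei,
    fusion_index = n_in_tubes / n_nuclei,
    category_histogram = nuclei_category_histogram(myotube_assignment),
    assignment = assignment,
    myotube_labels = myotube_labels
  )
  list(nuclei = nuc, desmin = des, pixel_size_um = pixel_size_um, truth = truth)
}

#' Nuclei-per-myotube category histogram
#'
#' Standard reporting categories for myotube maturity: 2 nuclei, 3-5
#' nuclei, more than 5 nuclei.
#'
#' @param counts integer vector of nuclei per myotube.
#' @return named integer vector over categories `"2"`, `"3-5"`, `">5"`.
#' @export
nuclei_category_histogram <- function(counts) {
  c("2" = sum(counts == 2),
    "3-5" = sum(counts >= 3 & counts <= 5),
    ">5" = sum(counts > 5))
}
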