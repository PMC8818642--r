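# Actin-network skeleton morphometry from rendered superresolution images.
#
# Rendered images are binarized (Otsu or manual threshold), homogenized with
# a 2D Gaussian kernel (SD 3-4 px, i.e. 60-80 nm at 20 nm/px) and
# re-binarized, thinned to a 1-pixel 8-connected skeleton, and decomposed
# into node-terminated branches. Branches shorter than 120 nm are omitted
# from the metric accounting. The normalized branch number is the branch
# pixels divided by all skeleton pixels.

# ---- thresholding -----------------------------------------------------------

#' Otsu threshold of an image
#'
#' Maximizes the between-class variance over candidate thresholds; the
#' foreground is `pixels > threshold`. For integer-valued images every
#' present level is a candidate (equivalent to an exhaustive level search);
#' continuous images are quantized to 256 bins. Ties are broken toward the
#' smallest threshold.
#'
#' @param values numeric vector or matrix of pixel values.
#' @return the threshold (same scale as the input).
#' @export
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  if (max(v) == min(v)) stop("cannot apply Otsu thresholding to a constant image")
  integerish <- all(v == round(v)) && length(unique(v)) <= 4096
  if (integerish) {
    levels <- sort(unique(v))
    counts <- tabulate(match(v, levels))
  } else {
    nb <- 256
    edges <- seq(min(v), max(v), length.out = nb + 1)
    idx <- pmin(nb, findInterval(v, edges, rightmost.closed = TRUE))
    counts <- tabulate(idx, nbins = nb)
    levels <- edges[-1] # threshold candidates are upper bin edges
  }
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * levels) / n
  mu_t <- mu[length(mu)]
  # between-class variance for threshold = levels[k] (class 0: <= levels[k])
  k <- seq_len(length(levels) - 1)
  bcv <- (mu_t * w0[k] - mu[k])^2 / (w0[k] * (1 - w0[k]))
  bcv[!is.finite(bcv)] <- -Inf
  levels[k[which.max(bcv)]]
}

#' Binarize a rendered image
#'
#' @param image a `rendered_image` or a numeric matrix.
#' @param method `"otsu"` (between-class variance maximization) or
#'   `"manual"`.
#' @param manual_threshold threshold value when `method = "manual"`.
#' @param gain scalar multiplier applied to the Otsu threshold before
#'   binarization (default 1).
#' @param pixel_size_nm required when `image` is a bare matrix.
#' @return a `binary_mask`: list with `mask` (logical matrix),
#'   `pixel_size_nm`, `threshold`, `method`.
#' @export
binarize <- function(image, method = c("otsu", "manual"),
                     manual_threshold = NULL, gain = 1,
                     pixel_size_nm = NULL) {
  method <- match.arg(method)
  if (inherits(image, "rendered_image")) {
    pix <- image$pixels
    pixel_size_nm <- image$pixel_size_nm
  } else {
    pix <- image
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required for bare matrices")
  }
  thr <- if (method == "otsu") otsu_threshold(pix) * gain
  else {
    if (is.null(manual_threshold)) stop("manual binarization requires manual_threshold")
    manual_threshold
  }
  structure(list(mask = pix > thr, pixel_size_nm = pixel_size_nm,
                 threshold = thr, method = method),
            class = "binary_mask")
}

#' Gaussian smoothing followed by Otsu re-binarization
#'
#' Homogenizes pixelated binary renders: the mask is filtered with a 2D
#' Gaussian (SD 3-4 px by default, i.e. 60-80 nm at a 20 nm render pixel)
#' and thresholded again with Otsu's method.
#'
#' @param mask a `binary_mask`.
#' @param sigma_px Gaussian SD in pixels (3-4 unless `allow_any_sigma`).
#' @param allow_any_sigma bypass the 3-4 px guard.
#' @return the re-binarized `binary_mask`.
#' @export
smooth_and_rebinarize <- function(mask, sigma_px = 3, allow_any_sigma = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!allow_any_sigma && (sigma_px < 3 || sigma_px > 4))
    stop("sigma_px outside the 3-4 px working range; set allow_any_sigma = TRUE")
  sm <- gaussian_blur(mask$mask * 1, sigma_px)
  thr <- otsu_threshold(sm)
  structure(list(mask = sm > thr, pixel_size_nm = mask$pixel_size_nm,
                 threshold = thr, method = "otsu_after_smoothing"),
            class = "binary_mask")
}

# ---- thinning ---------------------------------------------------------------

# out[r, c] = m[r + dr, c + dc] with zero padding (neighbor lookup).
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Guo-Hall two-subiteration thinning to a 1-px-wide 8-connected skeleton.
thin_mask <- function(m) {
  m <- m & TRUE
  repeat {
    changed <- FALSE
    for (iter in 1:2) {
      p2 <- shift_mat(m, 1, 0)   # N (row index increases with y)
      p3 <- shift_mat(m, 1, 1)   # NE
      p4 <- shift_mat(m, 0, 1)   # E
      p5 <- shift_mat(m, -1, 1)  # SE
      p6 <- shift_mat(m, -1, 0)  # S
      p7 <- shift_mat(m, -1, -1) # SW
      p8 <- shift_mat(m, 0, -1)  # W
      p9 <- shift_mat(m, 1, -1)  # NW
      C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
           (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nmin <- pmin(n1, n2)
      g3 <- if (iter == 1) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- m & C == 1 & nmin >= 2 & nmin <= 3 & !g3
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# ---- skeleton graph ---------------------------------------------------------

NEIGH_OFFSETS <- cbind(dr = c(1, 1, 0, -1, -1, -1, 0, 1),
                       dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# degree (number of 8-connected skeleton neighbors) of every pixel
neighbor_degree <- function(m) {
  deg <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(8)) deg <- deg + shift_mat(m, NEIGH_OFFSETS[i, 1],
                                               NEIGH_OFFSETS[i, 2])
  deg
}

# crossing number: 0->1 transitions around the cyclic 8-neighborhood ring.
# This counts distinct branch directions; raw degree over-counts at
# crossings, where a path pixel also touches the transverse arm diagonally.
ring_transitions <- function(m) {
  nb <- lapply(seq_len(8), function(i)
    shift_mat(m, NEIGH_OFFSETS[i, 1], NEIGH_OFFSETS[i, 2]))
  trans <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(8)) trans <- trans + (!nb[[i]] & nb[[i %% 8 + 1]])
  trans
}

# connected-component labels of TRUE pixels, BFS
# (8-connectivity for foreground; 4 is the dual connectivity for background)
label_components <- function(m, connectivity = 8) {
  offs <- if (connectivity == 8) NEIGH_OFFSETS
          else NEIGH_OFFSETS[c(1, 3, 5, 7), , drop = FALSE]
  lab <- matrix(0L, nrow(m), ncol(m))
  cur <- 0L
  todo <- which(m)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    nr <- nrow(m)
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- ((p - 1) %% nr) + 1
      c <- ((p - 1) %/% nr) + 1
      for (i in seq_len(nrow(offs))) {
        rr <- r + offs[i, 1]; cc <- c + offs[i, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > ncol(m)) next
        q <- (cc - 1) * nr + rr
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Fill small enclosed background holes in a binary mask
#'
#' Background components (4-connected, the dual of the 8-connected
#' foreground) that do not touch the image border and are at most
#' `max_px` pixels are set to foreground. Rasterized filament unions trap
#' single-pixel background holes where two branches diverge from a node;
#' topology-preserving thinning would otherwise keep a spurious ring around
#' each of them.
#'
#' @param mask logical matrix.
#' @param max_px largest hole area (pixels) to fill (default 10).
#' @return the filled logical matrix.
#' @export
fill_small_holes <- function(mask, max_px = 10) {
  bg <- label_components(!mask, connectivity = 4)
  if (max(bg) == 0L) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  sizes <- tabulate(bg, nbins = max(bg))
  fill <- setdiff(which(sizes <= max_px), border)
  mask[bg %in% fill] <- TRUE
  mask
}

step_length_px <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- abs(diff(path))
  sum(ifelse(d[, 1] > 0 & d[, 2] > 0, sqrt(2), 1))
}

# Decompose a 1-px skeleton mask into a node/branch graph.
build_skeleton_graph <- function(skel, pixel_size_nm, source_mask = NULL) {
  nr <- nrow(skel)
  deg <- neighbor_degree(skel)
  deg[!skel] <- -1L
  junction <- skel & ring_transitions(skel) >= 3
  endpoint <- skel & deg == 1
  jlab <- label_components(junction)
  n_jclusters <- max(jlab)
  # node id per pixel: junction clusters 1..J, endpoints J+1..J+E
  node_id <- matrix(0L, nr, ncol(skel))
  node_id[junction] <- jlab[junction]
  ep_idx <- which(endpoint)
  node_id[ep_idx] <- n_jclusters + seq_along(ep_idx)
  is_node <- node_id > 0L

  # junction-cluster centroids: branch lengths are measured node-center to
  # node-center, so junction-terminated paths are extended from the cluster
  # pixel where they stop to the cluster's centroid
  jcent <- if (n_jclusters > 0) {
    jx <- which(junction)
    jr <- ((jx - 1) %% nr) + 1
    jc <- ((jx - 1) %/% nr) + 1
    cbind(tapply(jr, jlab[jx], mean), tapply(jc, jlab[jx], mean))
  } else matrix(numeric(0), 0, 2)

  neighbors_of <- function(r, c) {
    rr <- r + NEIGH_OFFSETS[, 1]; cc <- c + NEIGH_OFFSETS[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(skel)
    cbind(rr[ok], cc[ok])[skel[cbind(rr[ok], cc[ok])], , drop = FALSE]
  }

  visited <- matrix(FALSE, nr, ncol(skel)) # interior (degree-2) pixels
  seen_pair <- character(0)                # direct node-node adjacencies
  segments <- list()
  add_segment <- function(path, nodes, kinds) {
    segments[[length(segments) + 1]] <<- list(path = path, nodes = nodes,
                                              kinds = kinds)
  }

  node_px <- which(is_node)
  for (p in node_px) {
    r <- ((p - 1) %% nr) + 1
    c <- ((p - 1) %/% nr) + 1
    for (nb in seq_len(nrow(nbs <- neighbors_of(r, c)))) {
      rr <- nbs[nb, 1]; cc <- nbs[nb, 2]
      q <- (cc - 1) * nr + rr
      if (is_node[q]) {
        if (node_id[q] == node_id[p]) next # same junction cluster
        key <- paste(sort(c(p, q)), collapse = "-")
        if (key %in% seen_pair) next
        seen_pair <- c(seen_pair, key)
        add_segment(rbind(c(r, c), c(rr, cc)),
                    nodes = c(node_id[p], node_id[q]),
                    kinds = c(if (junction[p]) "junction" else "endpoint",
                              if (junction[q]) "junction" else "endpoint"))
      } else if (!visited[q]) {
        path <- rbind(c(r, c), c(rr, cc))
        visited[q] <- TRUE
        prev <- c(r, c)
        cur <- c(rr, cc)
        repeat {
          nxt <- neighbors_of(cur[1], cur[2])
          nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), , drop = FALSE]
          if (nrow(nxt) == 0) break # dead end (shouldn't happen on clean skeletons)
          qi <- (nxt[, 2] - 1) * nr + nxt[, 1]
          node_nb <- is_node[qi]
          # terminate at a node of another cluster if one is adjacent
          other <- which(node_nb & node_id[qi] != node_id[p])
          if (length(other)) {
            path <- rbind(path, nxt[other[1], ])
            break
          }
          # the first interior pixel of a branch can touch several pixels of
          # the start cluster; keep walking rather than folding back onto it
          cont <- which(!node_nb & !visited[qi])
          if (length(cont) > 1) {
            # at a fork next to a junction mouth, follow the continuation
            # most aligned with the current travel direction
            dirv <- cur - prev
            score <- vapply(cont, function(k) {
              d <- nxt[k, ] - cur
              sum(d * dirv) / sqrt(sum(d^2))
            }, numeric(1))
            cont <- cont[order(-score)]
          }
          if (length(cont)) {
            step <- nxt[cont[1], ]
            visited[(step[2] - 1) * nr + step[1]] <- TRUE
            path <- rbind(path, step)
            prev <- cur
            cur <- step
            next
          }
          # no interior continuation: a genuine loop back to the start cluster
          same <- which(node_nb)
          if (length(same)) path <- rbind(path, nxt[same[1], ])
          break
        }
        last <- path[nrow(path), ]
        ql <- (last[2] - 1) * nr + last[1]
        if (is_node[ql]) {
          add_segment(path, nodes = c(node_id[p], node_id[ql]),
                      kinds = c(if (junction[p]) "junction" else "endpoint",
                                if (junction[ql]) "junction" else "endpoint"))
        } else {
          add_segment(path, nodes = c(node_id[p], NA),
                      kinds = c(if (junction[p]) "junction" else "endpoint",
                                "open"))
        }
      }
    }
  }
  # isolated cycles: unvisited non-node pixels not adjacent to any node
  leftover <- which(skel & !is_node & !visited)
  for (s in leftover) {
    if (visited[s]) next
    r <- ((s - 1) %% nr) + 1
    c <- ((s - 1) %/% nr) + 1
    visited[s] <- TRUE
    path <- rbind(c(r, c))
    prev <- c(NA_integer_, NA_integer_)
    cur <- c(r, c)
    repeat {
      nxt <- neighbors_of(cur[1], cur[2])
      if (!is.na(prev[1]))
        nxt <- nxt[!(nxt[, 1] == prev[1] & nxt[, 2] == prev[2]), , drop = FALSE]
      if (nrow(nxt) == 0) break
      step <- nxt[1, ]
      if (step[1] == r && step[2] == c) { # closed the loop
        path <- rbind(path, step)
        break
      }
      q <- (step[2] - 1) * nr + step[1]
      if (visited[q]) {
        path <- rbind(path, step)
        break
      }
      visited[q] <- TRUE
      path <- rbind(path, step)
      prev <- cur
      cur <- step
    }
    add_segment(path, nodes = c(NA, NA), kinds = c("cycle", "cycle"))
  }

  # Thinning pulls a junction's pixel cluster into the narrowest wedge between
  # the incident arms, so the cluster centroid is a biased node estimate.
  # Refine each node position as the least-squares intersection of the
  # incident branch directions (fit on interior pixels near the node).
  end_line <- function(path, end) {
    n <- nrow(path)
    idx <- if (end == 1) seq(2, min(n - 1, 13)) else seq(n - 1, max(2, n - 12))
    if (length(idx) < 4) return(NULL)
    pts <- path[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    u <- svd(sweep(pts, 2, ctr))$v[, 1]
    list(a = ctr, u = u)
  }
  node_pt <- jcent
  if (n_jclusters > 0) {
    lines_by <- vector("list", n_jclusters)
    for (sg in segments) {
      if (!anyNA(sg$nodes) && sg$nodes[1] == sg$nodes[2]) next
      for (end in 1:2) {
        id <- sg$nodes[end]
        if (is.na(id) || sg$kinds[end] != "junction") next
        ln <- end_line(sg$path, end)
        if (!is.null(ln)) lines_by[[id]] <- c(lines_by[[id]], list(ln))
      }
    }
    for (id in seq_len(n_jclusters)) {
      lns <- lines_by[[id]]
      if (length(lns) < 2) next
      A <- matrix(0, 2, 2)
      b <- c(0, 0)
      for (ln in lns) {
        P <- diag(2) - tcrossprod(ln$u)
        A <- A + P
        b <- b + P %*% ln$a
      }
      if (abs(det(A)) > 1e-8) {
        x <- drop(solve(A, b))
        # accept only if the refined point stays near the pixel cluster
        if (sqrt(sum((x - jcent[id, ])^2)) <= 4) node_pt[id, ] <- x
      }
    }
  }
  # Thinning leaves staircase parity artifacts (one-pixel lateral detours)
  # that inflate the digital path length. Report each segment as the shortest
  # 8-connected geodesic between its endpoints through the source mask,
  # restricted to a one-pixel corridor around the traced path so genuine
  # bends are preserved while parity wobble relaxes to straight runs.
  corridor_geodesic_px <- function(path) {
    n <- nrow(path)
    if (is.null(source_mask) || n < 3 ||
        all(path[1, ] == path[n, ])) return(step_length_px(path))
    sel <- matrix(FALSE, nr, ncol(skel))
    for (i in seq_len(n)) {
      r0 <- max(1, path[i, 1] - 1); r1 <- min(nr, path[i, 1] + 1)
      c0 <- max(1, path[i, 2] - 1); c1 <- min(ncol(skel), path[i, 2] + 1)
      sel[r0:r1, c0:c1] <- TRUE
    }
    sel <- sel & source_mask
    sel[cbind(path[, 1], path[, 2])] <- TRUE
    idx <- which(sel)
    id <- integer(nr * ncol(skel))
    id[idx] <- seq_along(idx)
    dd <- rep(Inf, length(idx))
    done <- logical(length(idx))
    src <- id[(path[1, 2] - 1) * nr + path[1, 1]]
    dst <- id[(path[n, 2] - 1) * nr + path[n, 1]]
    dd[src] <- 0
    repeat {
      u <- which.min(dd + ifelse(done, Inf, 0))
      if (is.infinite(dd[u]) || u == dst) break
      done[u] <- TRUE
      lu <- idx[u]
      r <- ((lu - 1) %% nr) + 1
      c <- ((lu - 1) %/% nr) + 1
      for (k in seq_len(8)) {
        rr <- r + NEIGH_OFFSETS[k, 1]; cc <- c + NEIGH_OFFSETS[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > ncol(skel)) next
        v <- id[(cc - 1) * nr + rr]
        if (v == 0L || done[v]) next
        w <- if (abs(NEIGH_OFFSETS[k, 1]) + abs(NEIGH_OFFSETS[k, 2]) == 2)
          sqrt(2) else 1
        if (dd[u] + w < dd[v]) dd[v] <- dd[u] + w
      }
    }
    if (is.finite(dd[dst])) dd[dst] else step_length_px(path)
  }
  # Thinning also retracts free branch tips inside the foreground ribbon.
  # Compensate by extending each endpoint-terminated tip along its local
  # direction until it exits the source mask (less the half-pixel the mask
  # itself extends past the last foreground pixel center).
  tip_extension <- function(path, end) {
    if (is.null(source_mask)) return(0)
    n <- nrow(path)
    tip <- path[if (end == 1) 1 else n, ]
    ln <- end_line(path, end)
    if (is.null(ln)) {
      if (n < 2) return(0)
      u <- tip - path[if (end == 1) 2 else n - 1, ]
    } else {
      u <- ln$u
      if (sum(u * (tip - ln$a)) < 0) u <- -u
    }
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) return(0)
    u <- u / nu
    marched <- 0
    while (marched < 5) {
      pos <- tip + (marched + 0.25) * u
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 1 || r > nrow(source_mask) || c < 1 || c > ncol(source_mask) ||
          !source_mask[r, c]) break
      marched <- marched + 0.25
    }
    max(0, marched - 0.5)
  }
  # branch length: interior path length, with each junction-terminated end
  # replaced by the straight run from the last interior pixel to the node point
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    n <- nrow(sg$path)
    ext <- 0
    same_node <- !anyNA(sg$nodes) && sg$nodes[1] == sg$nodes[2]
    to_node <- function(inner, terminal, id)
      sqrt(sum((inner - node_pt[id, ])^2)) - sqrt(sum((inner - terminal)^2))
    if (!same_node && n >= 2) {
      if (!is.na(sg$nodes[1]) && sg$kinds[1] == "junction")
        ext <- ext + to_node(sg$path[2, ], sg$path[1, ], sg$nodes[1])
      if (!is.na(sg$nodes[2]) && sg$kinds[2] == "junction")
        ext <- ext + to_node(sg$path[n - 1, ], sg$path[n, ], sg$nodes[2])
      if (sg$kinds[1] == "endpoint") ext <- ext + tip_extension(sg$path, 1)
      if (sg$kinds[2] == "endpoint") ext <- ext + tip_extension(sg$path, 2)
    }
    base <- if (same_node) step_length_px(sg$path)
            else corridor_geodesic_px(sg$path)
    segments[[i]]$length_nm <- (base + ext) * pixel_size_nm
  }

  structure(list(mask = skel, pixel_size_nm = pixel_size_nm,
                 source_mask = source_mask,
                 segments = segments,
                 skeleton_pixel_count = sum(skel),
                 junction_pixel_count = sum(junction),
                 endpoint_count = length(ep_idx),
                 junction_cluster_count = n_jclusters,
                 excluded = rep(FALSE, length(segments))),
            class = "skeleton_graph")
}

#' Skeletonize a binary mask
#'
#' Topology-preserving thinning to a 1-pixel-wide 8-connected skeleton,
#' decomposed into node-terminated branch segments (nodes: endpoint pixels
#' with one skeleton neighbor, junction clusters with three or more).
#' An empty mask gives an empty graph with zero branches.
#'
#' @param mask a `binary_mask` (or logical matrix plus `pixel_size_nm`).
#' @param pixel_size_nm required for bare matrices.
#' @return a `skeleton_graph`.
#' @export
skeletonize <- function(mask, pixel_size_nm = NULL) {
  if (inherits(mask, "binary_mask")) {
    m <- mask$mask
    pixel_size_nm <- mask$pixel_size_nm
  } else {
    m <- mask
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required for bare matrices")
  }
  skel <- thin_mask(m)
  build_skeleton_graph(skel, pixel_size_nm, source_mask = m)
}

#' Prune short branches from a skeleton graph
#'
#' Endpoint-terminated spurs shorter than `min_length_nm` are removed from
#' the skeleton and the node classification is recomputed (iterated until
#' stable); remaining junction-junction segments below the minimum are kept
#' in the skeleton but excluded from the metric accounting.
#'
#' @param graph a `skeleton_graph`.
#' @param min_length_nm minimum branch size (default 120 nm).
#' @return the pruned `skeleton_graph`.
#' @export
prune_branches <- function(graph, min_length_nm = 120) {
  skel <- graph$mask
  px <- graph$pixel_size_nm
  g <- graph
  repeat {
    short_spur <- vapply(g$segments, function(s) {
      s$length_nm < min_length_nm && any(s$kinds == "endpoint")
    }, logical(1))
    if (!any(short_spur)) break
    trans <- ring_transitions(skel)
    for (s in g$segments[short_spur]) {
      for (i in seq_len(nrow(s$path))) {
        r <- s$path[i, 1]; c <- s$path[i, 2]
        # keep junction pixels shared with surviving branches
        if (skel[r, c] && trans[r, c] >= 3) next
        skel[r, c] <- FALSE
      }
    }
    # removal can leave redundant corner pixels; re-thin before rebuilding
    skel <- thin_mask(skel)
    g <- build_skeleton_graph(skel, px, source_mask = graph$source_mask)
  }
  g$excluded <- vapply(g$segments, function(s) s$length_nm < min_length_nm,
                       logical(1))
  g
}

#' Branch metrics of a skeleton graph
#'
#' Branch count, per-branch geodesic lengths (axial step = pixel, diagonal
#' step = sqrt(2) pixel), mean branch length, and the normalized branch
#' number (branch pixels / all skeleton pixels, junction pixels counting as
#' skeleton but not branch).
#'
#' @param graph a (typically pruned) `skeleton_graph`.
#' @param image_area_um2 optional field area for branches-per-area.
#' @return a `network_metrics` list.
#' @export
network_metrics <- function(graph, image_area_um2 = NULL) {
  keep <- !graph$excluded
  lengths <- vapply(graph$segments[keep], `[[`, numeric(1), "length_nm")
  skel_px <- graph$skeleton_pixel_count
  branch_px <- skel_px - graph$junction_pixel_count
  out <- list(
    branch_count = length(lengths),
    branch_lengths_nm = lengths,
    mean_branch_length_nm = if (length(lengths)) mean(lengths) else NA_real_,
    skeleton_pixel_count = skel_px,
    branch_pixel_count = branch_px,
    normalized_branch_number = if (skel_px > 0) branch_px / skel_px else NA_real_
  )
  if (!is.null(image_area_um2))
    out$branches_per_um2 <- out$branch_count / image_area_um2
  structure(out, class = "network_metrics")
}

#' Full actin-network analysis of a rendered image
#'
#' Binarize, smooth and re-binarize, skeletonize, prune short branches, and
#' compute branch metrics.
#'
#' @param image a `rendered_image`.
#' @param method,manual_threshold,gain see [binarize()].
#' @param sigma_px smoothing SD in pixels (default 3).
#' @param min_branch_nm pruning threshold (default 120 nm).
#' @param smooth set FALSE to skip the homogenization step (e.g. for images
#'   that are already clean binary ribbons).
#' @param fill_holes_px largest enclosed background hole (pixels) filled
#'   before thinning (see [fill_small_holes()]); 0 disables.
#' @return list with `mask`, `graph`, `metrics`.
#' @export
analyze_network <- function(image, method = "otsu", manual_threshold = NULL,
                            gain = 1, sigma_px = 3, min_branch_nm = 120,
                            smooth = TRUE, fill_holes_px = 10) {
  mask <- binarize(image, method, manual_threshold, gain)
  if (smooth) mask <- smooth_and_rebinarize(mask, sigma_px)
  if (fill_holes_px > 0) mask$mask <- fill_small_holes(mask$mask, fill_holes_px)
  graph <- skeletonize(mask)
  graph <- prune_branches(graph, min_branch_nm)
  dims <- dim(mask$mask)
  area_um2 <- prod(dims) * (mask$pixel_size_nm / 1000)^2
  list(mask = mask, graph = graph,
       metrics = network_metrics(graph, image_area_um2 = area_um2))
}

#' Longest geodesic path length of a skeletonized object (nm)
#'
#' Thin the object mask, then take the largest pairwise geodesic distance
#' along the skeleton (axial step = pixel, diagonal = sqrt(2) pixel).
#' Used as the length measure for elongated objects such as myotubes.
#'
#' @param mask logical matrix of one object.
#' @param pixel_size_nm pixel size.
#' @return length in nm (0 for empty or single-pixel skeletons).
#' @export
skeleton_longest_path_nm <- function(mask, pixel_size_nm) {
  skel <- thin_mask(mask)
  pxs <- which(skel)
  if (length(pxs) < 2) return(0)
  nr <- nrow(skel)
  r <- ((pxs - 1) %% nr) + 1
  c <- ((pxs - 1) %/% nr) + 1
  id <- seq_along(pxs)
  names(id) <- pxs
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(8)) {
    rr <- r + NEIGH_OFFSETS[i, 1]; cc <- c + NEIGH_OFFSETS[i, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(skel)
    q <- (cc[ok] - 1) * nr + rr[ok]
    hit <- skel[cbind(rr[ok], cc[ok])]
    src <- id[ok][hit]
    dst <- id[as.character(q[hit])]
    diag_step <- NEIGH_OFFSETS[i, 1] != 0 & NEIGH_OFFSETS[i, 2] != 0
    from <- c(from, src); to <- c(to, dst)
    w <- c(w, rep(if (diag_step) sqrt(2) else 1, sum(hit)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = id))
  # double sweep: farthest node from an arbitrary node, then farthest from it
  d1 <- igraph::distances(g, v = 1)
  far <- which.max(ifelse(is.finite(d1), d1, -1))
  d2 <- igraph::distances(g, v = far)
  max(d2[is.finite(d2)]) * pixel_size_nm
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network_metrics: %d branches, mean length %.1f nm,\n",
                     "  normalized branch number %.4f (%d/%d skeleton px)\n"),
              x$branch_count, x$mean_branch_length_nm,
              x$normalized_branch_number, x$branch_pixel_count,
              x$skeleton_pixel_count))
  invisible(x)
}
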