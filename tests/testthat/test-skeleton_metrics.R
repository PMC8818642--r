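# Thresholding, thinning, and branch morphometry.
# (otsu_oracle lives in helper-fixtures.R)

test_that("Otsu separates a two-level image and matches the exhaustive oracle", {
  img <- matrix(c(0, 0, 0, 10, 10), 1)
  thr <- otsu_threshold(img)
  expect_equal(sum(img > thr), 2)
  expect_lt(thr, 10)

  # random 8-bit images against the brute-force oracle
  set.seed(41)
  for (k in 1:20) {
    v <- sample(0:255, 400, replace = TRUE,
                prob = dnorm(0:255, sample(60:200, 1), sample(10:80, 1)) + 1e-4)
    expect_equal(otsu_threshold(v), otsu_oracle(v))
  }

  expect_error(otsu_threshold(matrix(7, 3, 3)), "constant")
})

test_that("binarize handles manual thresholds and boundary cases", {
  img <- matrix(runif(100, 0, 255), 10)
  bm <- binarize(img, "manual", manual_threshold = max(img),
                 pixel_size_nm = 20)
  expect_false(any(bm$mask)) # foreground is strictly > threshold
  expect_error(binarize(img, "manual", pixel_size_nm = 20),
               "manual_threshold")
  expect_error(binarize(img, "otsu"), "pixel_size_nm")
  # gain scales the otsu threshold
  b1 <- binarize(img, "otsu", pixel_size_nm = 20)
  b2 <- binarize(img, "otsu", gain = 1e6, pixel_size_nm = 20)
  expect_false(any(b2$mask))
  expect_true(sum(b1$mask) > 0)
})

test_that("smoothing homogenizes: blobs persist, gaps merge, specks vanish", {
  px <- 20
  # solid 40x40 rectangle on a 60x60 canvas: preserved up to 2 px at edges
  m <- matrix(FALSE, 60, 60)
  m[11:50, 11:50] <- TRUE
  bm <- structure(list(mask = m, pixel_size_nm = px, threshold = 0,
                       method = "manual"), class = "binary_mask")
  sm <- smooth_and_rebinarize(bm, sigma_px = 3)
  expect_true(all(sm$mask[13:48, 13:48]))         # eroded core kept
  expect_false(any(sm$mask[c(1:8, 53:60), ]))     # dilation bounded by 2 px
  expect_false(any(sm$mask[, c(1:8, 53:60)]))

  # two parallel 1-px lines 2 px apart merge into one ribbon
  m2 <- matrix(FALSE, 40, 80)
  m2[20, 10:70] <- TRUE
  m2[23, 10:70] <- TRUE
  bm2 <- structure(list(mask = m2, pixel_size_nm = px, threshold = 0,
                        method = "manual"), class = "binary_mask")
  sm2 <- smooth_and_rebinarize(bm2, sigma_px = 3)
  expect_true(all(sm2$mask[21:22, 20:60])) # the gap is filled

  # isolated pixel far from a large blob falls below the new threshold
  m3 <- matrix(FALSE, 80, 80)
  m3[10:40, 10:40] <- TRUE
  m3[70, 70] <- TRUE
  bm3 <- structure(list(mask = m3, pixel_size_nm = px, threshold = 0,
                        method = "manual"), class = "binary_mask")
  sm3 <- smooth_and_rebinarize(bm3, sigma_px = 3)
  expect_false(any(sm3$mask[60:80, 60:80]))
  expect_true(any(sm3$mask[10:40, 10:40]))

  expect_error(smooth_and_rebinarize(bm, sigma_px = 10), "3-4")
})

test_that("skeletonization of canonical shapes and idempotence", {
  # filled 5x101 bar: one path, 2 endpoints, no junctions
  bar <- matrix(FALSE, 11, 107)
  bar[4:8, 4:104] <- TRUE
  g <- skeletonize(bar, pixel_size_nm = 20)
  expect_equal(length(g$segments), 1)
  expect_equal(g$endpoint_count, 2)
  expect_equal(g$junction_cluster_count, 0)

  # "+" cross of two 1-px lines: 1 junction, 4 endpoints, 4 segments
  gc <- skeletonize(cross_mask(arm = 20), pixel_size_nm = 20)
  expect_equal(gc$junction_cluster_count, 1)
  expect_equal(gc$endpoint_count, 4)
  expect_equal(length(gc$segments), 4)

  # empty mask: empty graph, not an error
  ge <- skeletonize(matrix(FALSE, 10, 10), pixel_size_nm = 20)
  expect_equal(length(ge$segments), 0)
  expect_equal(network_metrics(ge)$branch_count, 0)

  # idempotence: re-skeletonizing the skeleton leaves the pixel set unchanged
  g2 <- skeletonize(g$mask, pixel_size_nm = 20)
  expect_identical(g2$mask, g$mask)
  gc2 <- skeletonize(gc$mask, pixel_size_nm = 20)
  expect_identical(gc2$mask, gc$mask)
})

test_that("short spurs are pruned and pruning is monotone", {
  px <- 20
  # 81-px line with a 5-px (100 nm) spur: spur pruned, halves re-merged
  m <- matrix(FALSE, 20, 90)
  m[10, 5:85] <- TRUE
  m[11:15, 45] <- TRUE
  g <- skeletonize(m, pixel_size_nm = px)
  expect_equal(length(g$segments), 3)
  pg <- prune_branches(g, 120)
  met <- network_metrics(pg)
  expect_equal(met$branch_count, 1)
  expect_equal(met$branch_lengths_nm, 80 * px)

  # all segments >= 120 nm: identity
  gc <- skeletonize(cross_mask(arm = 20), pixel_size_nm = px)
  pc <- prune_branches(gc, 120)
  expect_equal(network_metrics(pc)$branch_count, 4)
  expect_identical(pc$mask, gc$mask)

  # monotonicity: branch_count non-increasing in min_length
  sp <- random_network_spec(n_edges = 12, seed = 5)
  net <- simulate_network_image(sp)
  gr <- skeletonize(binarize(net$image))
  counts <- vapply(c(0, 120, 300, 600, 1200), function(L)
    network_metrics(prune_branches(gr, L))$branch_count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("branch metrics match fixture arithmetic", {
  px <- 20
  # cross with 20-px arms: 4 x 400 nm, normalized branch number 80/81
  gc <- prune_branches(skeletonize(cross_mask(arm = 20), pixel_size_nm = px))
  met <- network_metrics(gc)
  expect_equal(met$branch_count, 4)
  expect_equal(unname(met$branch_lengths_nm), rep(400, 4))
  expect_equal(met$normalized_branch_number, 80 / 81)
  expect_equal(met$skeleton_pixel_count, 81)

  # diagonal 11-px line: single segment of 10 * sqrt(2) * 20 nm
  d <- matrix(FALSE, 15, 15)
  d[cbind(3:13, 3:13)] <- TRUE
  md <- network_metrics(skeletonize(d, pixel_size_nm = px))
  expect_equal(md$branch_count, 1)
  expect_equal(md$branch_lengths_nm, 10 * sqrt(2) * px)
  expect_equal(md$normalized_branch_number, 1) # no junctions

  # normalized branch number always in [0, 1]
  for (seed in c(3, 8)) {
    sp <- random_network_spec(n_edges = 12, seed = seed)
    net <- simulate_network_image(sp)
    met <- analyze_network(net$image)$metrics
    expect_gte(met$normalized_branch_number, 0)
    expect_lte(met$normalized_branch_number, 1)
  }
})

test_that("random-network branch topology and lengths are recovered", {
  px <- 20
  for (seed in c(5, 44)) {
    sp <- random_network_spec(n_edges = 12, seed = seed)
    net <- simulate_network_image(sp)
    # clean binary ribbons need no pixelation homogenization
    res <- analyze_network(net$image, min_branch_nm = 120, smooth = FALSE)
    met <- res$metrics
    expect_equal(met$branch_count, net$truth$branch_count)
    got <- sort(met$branch_lengths_nm)
    want <- sort(net$truth$branch_lengths_nm)
    expect_lt(max(abs(got - want)), (1 + sqrt(2)) * px)
  }
})
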