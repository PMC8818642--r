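# Seeded generators and their ground truth.

test_that("bundle simulation is deterministic and honors the degenerate limit", {
  spec <- bundle_spec(seed = 99)
  a <- simulate_bundle_localizations(spec)
  b <- simulate_bundle_localizations(spec)
  expect_identical(a$table, b$table)

  # sigma_true = 0, precision 0, no background: events exactly on the line
  spec0 <- bundle_spec(coef = c(10, 0.2), sigma_true_nm = 0,
                       precision_mean_nm = 0, precision_sd_nm = 0,
                       background_per_um2 = 0, seed = 5)
  sc <- simulate_bundle_localizations(spec0)
  resid <- sc$table$y_nm - (10 + 0.2 * sc$table$x_nm)
  # perpendicular distance = residual / sqrt(1 + slope^2)
  expect_lt(max(abs(resid)) / sqrt(1.04), 1e-9)
})

test_that("perpendicular offsets follow the quadrature law", {
  # sigma_true = 30, precision 0: SD of y-offsets within 1% at 1e5 events
  spec <- bundle_spec(coef = c(0, 0), sigma_true_nm = 30,
                      precision_mean_nm = 0, precision_sd_nm = 0,
                      background_per_um2 = 0, density_per_um = 5e4, seed = 2)
  sc <- simulate_bundle_localizations(spec)
  expect_gt(sc$truth$n_signal, 9e4)
  expect_lt(abs(sd(sc$table$y_nm) - 30) / 30, 0.01)

  # sigma 30 + precision 15: quadrature oracle on the simulator's own draws
  spec <- bundle_spec(coef = c(0, 0), sigma_true_nm = 30,
                      precision_mean_nm = 15, precision_sd_nm = 0,
                      background_per_um2 = 0, density_per_um = 5e4, seed = 3)
  sc <- simulate_bundle_localizations(spec)
  expect_lt(abs(sd(sc$truth$perp_offsets_nm) - sqrt(30^2 + 15^2)) /
              sqrt(30^2 + 15^2), 0.01)
})

test_that("network rasterization records the merged branch topology", {
  # single straight edge
  sp <- network_spec(nodes = rbind(c(200, 500), c(600, 500)),
                     edges = data.frame(from = 1, to = 2, width_nm = 60),
                     bounds = c(0, 1000, 0, 1000))
  net <- simulate_network_image(sp)
  expect_equal(net$truth$branch_count, 1)
  expect_equal(net$truth$branch_lengths_nm, 400)
  expect_true(any(net$image$pixels > 0))

  # "+" cross: two orthogonal 800-nm edges crossing at their midpoints,
  # modeled as 4 edges from the central node
  ctr <- c(1000, 1000)
  nodes <- rbind(ctr, ctr + c(400, 0), ctr - c(400, 0),
                 ctr + c(0, 400), ctr - c(0, 400))
  sp <- network_spec(nodes, data.frame(from = 1, to = 2:5, width_nm = 60),
                     bounds = c(0, 2000, 0, 2000))
  net <- simulate_network_image(sp)
  expect_equal(net$truth$branch_count, 4)
  expect_equal(unname(net$truth$branch_lengths_nm), rep(400, 4))

  # degree-2 pass-through nodes merge into one branch
  nodes <- rbind(c(200, 500), c(500, 500), c(800, 600))
  sp <- network_spec(nodes, data.frame(from = c(1, 2), to = c(2, 3),
                                       width_nm = 60),
                     bounds = c(0, 1000, 0, 1000))
  net <- simulate_network_image(sp)
  expect_equal(net$truth$branch_count, 1)
  expect_equal(net$truth$branch_lengths_nm, 300 + sqrt(300^2 + 100^2))

  # nodes closer than one pixel are a degeneracy
  expect_error(
    network_spec(rbind(c(100, 100), c(100, 110)),
                 data.frame(from = 1, to = 2, width_nm = 60),
                 bounds = c(0, 1000, 0, 1000), pixel_size_nm = 20),
    "degeneracy")
})

test_that("random networks have the requested edge count and arithmetic lengths", {
  for (seed in c(1, 17, 303)) {
    sp <- random_network_spec(n_edges = 12, seed = seed)
    expect_equal(nrow(sp$edges), 12)
    net <- simulate_network_image(sp)
    expect_equal(net$truth$branch_count, 12) # tree growth leaves no degree-2 nodes
    # graph-side arithmetic oracle: per-branch polyline length
    for (br in net$truth$branches) {
      seg <- sp$nodes[br$path, , drop = FALSE]
      expect_equal(br$length_nm, sum(sqrt(rowSums(diff(seg)^2))))
    }
    expect_true(all(net$truth$branch_lengths_nm >= 200))
  }
})

test_that("drift injection shifts events by their frame's trajectory", {
  tab <- straight_bundle_table(500, sigma = 20, seed = 8)
  zero <- inject_drift(tab, matrix(0, 1000, 2))
  expect_equal(zero, tab)

  const <- inject_drift(tab, cbind(rep(50, 1000), rep(0, 1000)))
  expect_equal(const$x_nm, tab$x_nm + 50)
  expect_equal(const$y_nm, tab$y_nm)

  # linear drift: mean injected shift of the last-decile frames ~ 95% of total
  drift <- linear_drift(1000, 100)
  lin <- inject_drift(tab, drift)
  late <- tab$frame > 900
  expected <- mean(drift[tab$frame[late], 1])
  expect_equal(mean(lin$x_nm[late] - tab$x_nm[late]), expected)
  expect_gt(expected, 90)

  expect_error(inject_drift(tab, matrix(0, 10, 2)), "cover")
})

test_that("force-curve forward model matches the closed form and inverts", {
  # cone, alpha 35 deg, nu 0.5, E 5 kPa, delta 500 nm -> ~0.743 nN
  f <- hertz_force(500, 5000, "cone", 35, 0.5)
  expect_equal(f, (2 / pi) * tan(35 * pi / 180) * 5000 / 0.75 * (500e-9)^2 * 1e9)
  expect_equal(round(f, 3), 0.743)

  for (E in c(500, 2000, 20000)) {
    sim <- simulate_force_curve(E, "cone", noise_sd_nN = 0, contact_nm = 50)
    fit <- fit_hertz(sim$curve)
    expect_lt(abs(fit$E_pa - E) / E, 1e-6)
  }
  expect_error(simulate_force_curve(-5), "positive")
})

test_that("myotube mask fixtures carry exact arithmetic truth", {
  fx <- generate_myotube_masks(100, myotube_assignment = 30,
                               n_desmin_pos_cells = 0, seed = 1)
  expect_equal(fx$truth$fusion_index, 0.30)
  expect_equal(fx$truth$differentiation_index, 0.01)
  expect_equal(max(fx$nuclei), 100)

  fx0 <- generate_myotube_masks(40, seed = 2)
  expect_equal(fx0$truth$fusion_index, 0)
  expect_equal(fx0$truth$n_myotubes, 0)

  fx3 <- generate_myotube_masks(50, myotube_assignment = c(2, 4, 7),
                                n_desmin_pos_cells = 5, seed = 3)
  expect_equal(fx3$truth$category_histogram,
               c("2" = 1L, "3-5" = 1L, ">5" = 1L))
  expect_equal(fx3$truth$fusion_index, 13 / 50)
  expect_equal(fx3$truth$differentiation_index, 8 / 50)

  expect_error(generate_myotube_masks(10, myotube_assignment = c(1, 3)),
               "at least 2")
  expect_error(generate_myotube_masks(5, myotube_assignment = c(3, 4)),
               "exceed")
  # masks are non-overlapping labeled objects
  expect_equal(sort(unique(as.vector(fx3$nuclei[fx3$nuclei > 0]))), 1:50)
  expect_equal(sort(unique(as.vector(fx3$desmin[fx3$desmin > 0]))), 1:8)
})
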