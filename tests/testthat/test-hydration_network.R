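test_that("channel segments all have the configured length and builds are deterministic", {
  net <- build_pore_network(0.5, segment_length_um = 100,
                            n_hetero_regions = 3, seed = 42)
  expect_true(all(net$channels$length_um == 100))
  net2 <- build_pore_network(0.5, segment_length_um = 100,
                             n_hetero_regions = 3, seed = 42)
  expect_identical(net$channels, net2$channels)
  expect_identical(net$nodes, net2$nodes)
  net3 <- build_pore_network(0.5, segment_length_um = 100,
                             n_hetero_regions = 3, seed = 43)
  expect_false(identical(net$channels$r_ins_um, net3$channels$r_ins_um))
})

test_that("geometry is sane: nodes inside the disk, connected, quadratic channel scaling", {
  counts <- sapply(c(1, 2, 4), function(r) {
    net <- build_pore_network(r, n_hetero_regions = 0, seed = 1)
    R <- net$disk_radius_um
    expect_true(all(net$nodes$x_um^2 + net$nodes$y_um^2 <= R^2 + 1e-9))
    expect_true(length(net$boundary_nodes) > 0)
    deg <- tabulate(c(net$channels$node_a, net$channels$node_b),
                    nbins = nrow(net$nodes))
    expect_true(all(deg >= 1))
    nrow(net$channels)
  })
  # channel count should grow ~ quadratically with radius
  expect_lt(abs(counts[2] / counts[1] - 4), 0.15 * 4)
  expect_lt(abs(counts[3] / counts[1] - 16), 0.15 * 16)
})

test_that("sampled inscribed radii match the requested arithmetic moments", {
  net <- build_pore_network(3.5, n_hetero_regions = 0, seed = 7)
  r <- net$channels$r_ins_um
  expect_gt(length(r), 10000)
  expect_lt(abs(mean(r) - 30) / 30, 0.02)
  expect_lt(abs(stats::var(r) - 10) / 10, 0.10)
  th <- net$channels$theta_deg
  expect_true(all(th >= 30 & th <= 150))
})

test_that("degenerate geometry is rejected", {
  expect_error(build_pore_network(0.05, segment_length_um = 100),
               "degenerate")
})

test_that("saturation limit: psi = 0 fills every channel", {
  net <- small_net()
  g <- corner_water_geometry(net$channels, hydration_params(0))
  expect_true(all(g$water_area_fraction == 1))
  expect_true(all(g$saturated))
})

test_that("meniscus curvature follows Young-Laplace", {
  # gamma = 0.072 N/m at -3 kPa: r_c = 0.072/3000 m = 24 um
  expect_equal(soilage:::.curvature_radius_um(0.072, -3), 24)
  expect_equal(soilage:::.curvature_radius_um(0.072, -7), 72 / 7)
})

test_that("film thickness and water fraction shrink monotonically as soil dries", {
  net <- small_net()
  sweep <- lapply(c(0, -1, -2, -3, -4, -5, -6, -7), function(psi)
    corner_water_geometry(net$channels, hydration_params(psi)))
  for (i in seq_len(length(sweep) - 1)) {
    expect_true(all(sweep[[i + 1]]$water_area_fraction <=
                      sweep[[i]]$water_area_fraction + 1e-12))
    expect_true(all(sweep[[i + 1]]$film_thickness_um <=
                      sweep[[i]]$film_thickness_um + 1e-12))
  }
  last <- sweep[[length(sweep)]]
  expect_true(all(last$water_area_fraction >= 0 &
                    last$water_area_fraction <= 1))
})

test_that("effective diffusivities partition exactly between phases", {
  net <- small_net()
  for (psi in c(0, -3, -7)) {
    d <- channel_diffusivities(net$channels, hydration_params(psi),
                               D_aq0 = 1000, D_gas0 = 2e7)
    expect_equal(d$D_aq_eff / 1000 + d$D_gas_eff / 2e7,
                 rep(1, nrow(net$channels)), tolerance = 1e-12)
  }
  # saturated channel: no gas path; fraction 1 recovers the free diffusivity
  sat <- channel_diffusivities(net$channels, hydration_params(0),
                               D_aq0 = 1000, D_gas0 = 2e7)
  expect_true(all(sat$D_gas_eff == 0))
  expect_true(all(sat$D_aq_eff == 1000))
  # linear scaling in the water fraction
  g3 <- corner_water_geometry(net$channels[1, ], hydration_params(-3))
  d3 <- channel_diffusivities(net$channels[1, ], hydration_params(-3),
                              D_aq0 = 1000, D_gas0 = 2e7)
  expect_equal(d3$D_aq_eff, 1000 * g3$water_area_fraction)
})

test_that("network round-trips through the CSV/JSON writer", {
  net <- build_pore_network(0.4, n_hetero_regions = 2, seed = 9)
  dir <- withr::local_tempdir()
  write_pore_network(net, dir)
  back <- read_pore_network(dir)
  expect_equal(back$channels$r_ins_um, net$channels$r_ins_um)
  expect_equal(back$center_node, net$center_node)
  expect_equal(back$boundary_nodes, net$boundary_nodes)
})

test_that("toy networks satisfy the module invariants at several hydration levels", {
  net <- toy_pore_network(1, seed = 3)
  expect_equal(nrow(net$nodes), 7) # center + 6-node hex ring
  expect_equal(length(net$boundary_nodes), 6)
  net2 <- toy_pore_network(3, seed = 8)
  for (psi in c(0, -3, -7)) {
    g <- corner_water_geometry(net2$channels, hydration_params(psi))
    expect_true(all(g$water_area_fraction > 0 & g$water_area_fraction <= 1))
    expect_true(all(g$film_thickness_um > 0))
  }
  expect_identical(toy_pore_network(3, seed = 8)$channels, net2$channels)
})
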