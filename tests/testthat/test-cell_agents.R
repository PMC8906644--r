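test_that("Monod kinetics saturate and factor multiplicatively", {
  p <- growth_params()
  expect_equal(monod_rate(p$K_C, 1e6, p), p$mu_max / 2, tolerance = 1e-6)
  expect_equal(monod_rate(p$K_C, p$K_O, p), p$mu_max / 4)
  expect_equal(monod_rate(0, 1, p), 0)
  expect_true(all(monod_rate(10^(-3:3), 10^(-3:3), p) <= p$mu_max))
  # oxygen-independent growth drops the oxygen factor
  pf <- growth_params(oxygen_dependent = FALSE)
  expect_equal(monod_rate(pf$K_C, 0, pf), pf$mu_max / 2)
})

test_that("a saturated cell divides at exactly the optimal generation time", {
  p <- growth_params(maintenance_m = 0)
  cell <- list(cell_id = 1L, lineage_id = 1L, generation = 0L,
               biomass = p$m_birth, birth_time = 0)
  t <- 0
  repeat {
    r <- grow_and_maybe_divide(cell, p$mu_max, 10, t, p)
    t <- t + 10
    if (!is.null(r$event)) break
    cell <- r$cells[[1]]
    if (t > 3600) stop("no division within an hour")
  }
  expect_equal(r$event$time / 60, 28) # minutes
  expect_equal(r$event$generation_time / 60, 28)
  # biomass conservation at the split
  expect_equal(r$cells[[1]]$biomass + r$cells[[2]]$biomass,
               p$m_birth * exp(p$mu_max * (r$event$time / 3600)),
               tolerance = 1e-9)
  expect_equal(r$cells[[1]]$generation, 1L)
  expect_equal(r$cells[[1]]$birth_time, r$event$time)
})

test_that("growth at the maintenance balance point leaves biomass unchanged", {
  p <- growth_params()
  cell <- list(cell_id = 1L, lineage_id = 1L, generation = 0L,
               biomass = 200, birth_time = 0)
  r <- grow_and_maybe_divide(cell, p$maintenance_m, 3600, 0, p)
  expect_null(r$event)
  expect_equal(r$cells[[1]]$biomass, 200)
  # starving cells shrink but never below the dormancy floor
  r2 <- grow_and_maybe_divide(cell, 0, 1e9, 0, p)
  expect_equal(r2$cells[[1]]$biomass, 0.5 * p$m_birth)
})

test_that("pinned cells do not move and displacement never exceeds the run length", {
  net <- small_net()
  mp <- motility_params(run_speed = 20, pinning_film_um = 1)
  cell <- list(channel = 5L, offset = 0.5, heading = 1L)
  out <- motility_step(cell, local_gradient = 1, film_thickness = 0.5,
                       mp = mp, dt_s = 10, network = net)
  expect_identical(out$offset, 0.5)
  expect_identical(out$channel, 5L)
  # property: across many random steps, |displacement| <= run_speed * dt
  set.seed(99)
  n <- 2000
  st <- list(channel = sample.int(nrow(net$channels), n, replace = TRUE),
             offset = runif(n), heading = sample(c(-1L, 1L), n, TRUE))
  adj <- soilage:::.node_channels(net)
  grad <- rnorm(nrow(net$channels))
  film <- runif(nrow(net$channels), 0, 10)
  out <- soilage:::.motility_core(st, grad, film, mp, 10, net, adj)
  # path length cap: 20 um/s * 10 s = 200 um = 2 channel lengths
  expect_true(all(out$offset >= 0 & out$offset <= 1))
  d_eucl <- sqrt((net$nodes$x_um[net$channels$node_a[out$channel]] -
                    net$nodes$x_um[net$channels$node_a[st$channel]])^2 +
                   (net$nodes$y_um[net$channels$node_a[out$channel]] -
                      net$nodes$y_um[net$channels$node_a[st$channel]])^2)
  expect_true(all(d_eucl <= 200 + 2 * net$segment_length_um))
})

test_that("zero chemotactic bias tumbles equally in both directions", {
  mp <- motility_params(chemo_bias = 0)
  # with bias 0 the effective tumble rate is identical up- and down-gradient
  lam_up <- mp$tumble_rate * (1 - mp$chemo_bias)
  lam_down <- mp$tumble_rate * (1 + mp$chemo_bias)
  expect_equal(lam_up, lam_down)
})

test_that("fixed seeds reproduce event logs exactly and populations never shrink", {
  net <- small_net()
  cfg <- sim_config(psi = -3, n_inoculum = 15, t_end_s = 2 * 3600, seed = 31)
  sim1 <- simulate_hotspot(cfg, net)
  sim2 <- simulate_hotspot(cfg, net)
  expect_identical(sim1$events, sim2$events)
  expect_false(is.unsorted(sim1$ledger$n_cells))
  expect_gt(nrow(sim1$events), 0)
})

test_that("the biomass ledger closes: dB = yield-weighted uptake minus maintenance", {
  net <- small_net()
  cfg <- sim_config(psi = -2, n_inoculum = 10, t_end_s = 3600, seed = 4)
  sim <- simulate_hotspot(cfg, net)
  led <- sim$ledger
  b0 <- 10 * cfg$growth$m_birth
  db <- diff(c(b0, led$total_biomass_fg))
  expect_lt(max(abs(db - (led$uptake_fg - led$maintenance_fg)) /
                  pmax(abs(db), 1e-9)), 1e-6)
})

test_that("division bookkeeping is exact in full simulations", {
  net <- small_net()
  cfg <- sim_config(psi = -1, n_inoculum = 8, t_end_s = 2 * 3600, seed = 12)
  sim <- simulate_hotspot(cfg, net)
  ev <- sim$events
  fin <- sim$snapshots[[length(sim$snapshots)]]
  # generation time equals event time minus the parent's birth time by
  # construction; children generations increment: verify via the snapshot
  expect_true(all(ev$generation_time_s > 0))
  expect_true(all(ev$generation >= 1))
  # every cell's age is time since its recorded birth
  expect_true(all(fin$age_s >= 0 & fin$age_s <= cfg$t_end_s))
  # lineages in the snapshot are all founders
  expect_true(all(fin$lineage_id %in% sim$inoculum_lineages))
})

test_that("the motility switch freezes every cell in place", {
  net <- small_net()
  cfg <- sim_config(psi = -1, n_inoculum = 12, t_end_s = 1800, seed = 8,
                    growth = growth_params(motile = FALSE),
                    snapshot_times_s = c(600, 1800))
  sim <- simulate_hotspot(cfg, net)
  s1 <- sim$snapshots[[1]]; s2 <- sim$snapshots[[2]]
  founders <- s1$cell_id %in% 1:12
  m <- match(s1$cell_id[founders], s2$cell_id)
  live <- !is.na(m) # founders that did not divide between snapshots
  expect_true(all(s1$channel_id[founders][live] == s2$channel_id[m[live]]))
  expect_true(all(s1$offset[founders][live] == s2$offset[m[live]]))
})

test_that("oxygen-independent growth ignores the oxygen field entirely", {
  net <- small_net()
  cfg <- sim_config(psi = -2, n_inoculum = 10, t_end_s = 1800, seed = 21,
                    growth = growth_params(oxygen_dependent = FALSE))
  sim1 <- simulate_hotspot(cfg, net)
  # same run with a radically different oxygen boundary: identical growth
  cfg2 <- sim_config(psi = -2, n_inoculum = 10, t_end_s = 1800, seed = 21,
                     growth = growth_params(oxygen_dependent = FALSE),
                     oxygen_boundary_mM = 1e-6)
  sim2 <- simulate_hotspot(cfg2, net)
  expect_identical(sim1$events, sim2$events)
  expect_identical(sim1$ledger$total_biomass_fg, sim2$ledger$total_biomass_fg)
})

test_that("a piecewise hydration schedule rewets and redries the domain", {
  net <- small_net()
  sched <- list(time_s = c(0, 1200), psi = c(-7, -1))
  cfg <- sim_config(psi_schedule = sched, n_inoculum = 10, t_end_s = 2400,
                    seed = 5)
  sim <- simulate_hotspot(cfg, net)
  expect_s3_class(sim, "hotspot_sim")
  expect_false(is.unsorted(sim$ledger$n_cells))
})
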