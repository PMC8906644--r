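test_that("generation-time extrapolation matches the closed form", {
  p <- growth_params(maintenance_m = 0)
  # newborn at net rate 1/h doubles in ln 2 hours
  ex <- extrapolate_generation_time(0, p$m_birth, 1, p)
  expect_equal(ex$tau_hat_h, log(2), tolerance = 1e-12)
  expect_false(ex$censored)
  # aged cell partway to division
  ex2 <- extrapolate_generation_time(2, 1.5 * p$m_birth, 1, p)
  expect_equal(ex2$tau_hat_h, 2 + log(4 / 3), tolerance = 1e-12)
  # at the maintenance balance the value is censored at the cap
  pm <- growth_params()
  ex3 <- extrapolate_generation_time(1, 200, pm$maintenance_m, pm, cap = 720)
  expect_true(ex3$censored)
  expect_equal(ex3$tau_hat_h, 720)
  expect_error(extrapolate_generation_time(0, 10 * p$m_birth, 1, p),
               "invariant")
})

test_that("extrapolation predicts the realized generation time for constant-rate cells", {
  # simulate a cell to division at constant mu and compare against the
  # prediction made at every earlier age
  p <- growth_params(maintenance_m = 0.1)
  mu <- 0.8
  dt <- 10
  cell <- list(cell_id = 1L, lineage_id = 1L, generation = 0L,
               biomass = p$m_birth, birth_time = 0)
  t <- 0
  preds <- c()
  repeat {
    preds <- c(preds, t / 3600 +
                 log(p$m_division / cell$biomass) / (mu - p$maintenance_m))
    r <- grow_and_maybe_divide(cell, mu, dt, t, p)
    t <- t + dt
    if (!is.null(r$event)) break
    cell <- r$cells[[1]]
  }
  realized <- r$event$generation_time / 3600
  expect_true(all(abs(preds - realized) <= dt / 3600 + 1e-9))
})

test_that("the ECDF is right-continuous with standard tie handling", {
  F1 <- generation_time_ecdf(c(1, 2, 3))
  expect_equal(F1(2), 2 / 3)
  F2 <- generation_time_ecdf(c(1, 1, 2))
  expect_equal(F2(1), 2 / 3)
  expect_equal(F2(2), 1)
  expect_error(generation_time_ecdf(numeric(0)), "empty")
})

test_that("the ECDF of exponential draws stays inside the DKW band", {
  set.seed(7)
  n <- 1e4
  x <- rexp(n)
  Fh <- generation_time_ecdf(x)
  grid <- seq(0.01, 8, length.out = 500)
  eps <- sqrt(log(2 / 0.01) / (2 * n)) # 99% DKW band
  expect_lt(max(abs(Fh(grid) - pexp(grid))), eps)
})

test_that("the lineage table reproduces a synthetic fixture's truth ledger exactly", {
  fx <- synthetic_event_log(fixture_spec(n_lineages = 40, horizon_h = 12,
                                         seed = 14))
  lt <- lineage_table(fx$events, fx$snapshot,
                      inoculum_lineages = seq_len(40))
  expect_equal(nrow(lt), 40)
  truth_gen <- vapply(fx$truth, function(x) x$max_generation, numeric(1))
  truth_n <- vapply(fx$truth, function(x) x$n_cells_final, numeric(1))
  expect_equal(lt$reproductive_success, as.integer(truth_gen))
  expect_equal(lt$n_cells_final, as.integer(truth_n))
  expect_equal(sum(lt$biomass_fraction_final), 1, tolerance = 1e-9)
  expect_equal(sum(lt$n_cells_final), nrow(fx$snapshot))
  # never-divided lineages: success 0 and no generation-time average
  none <- lt$reproductive_success == 0
  expect_true(all(is.na(lt$mean_generation_time_h[none])))
})

test_that("the lineage table rejects orphan barcodes", {
  fx <- synthetic_event_log(fixture_spec(n_lineages = 5, horizon_h = 5,
                                         seed = 2))
  expect_error(lineage_table(fx$events, fx$snapshot,
                             inoculum_lineages = 1:4),
               "orphan")
})

test_that("cross-entropy threshold separates distinct clusters and matches a brute-force oracle", {
  thr <- min_cross_entropy_threshold(c(1, 1, 1, 100, 100))
  expect_gt(thr, 1)
  expect_lt(thr, 100)
  expect_error(min_cross_entropy_threshold(rep(3, 5)), "no partition")

  # independent oracle: evaluate the cross-entropy objective at every cut
  # between consecutive order statistics and take the argmin
  brute <- function(x) {
    xs <- sort(x)
    cuts <- unique((xs[-1] + xs[-length(xs)]) / 2)
    # a valid cut must leave both classes nonempty
    cuts <- cuts[vapply(cuts, function(tc) any(x < tc) && any(x >= tc),
                        logical(1))]
    eta <- sapply(cuts, function(tc) {
      lo <- x[x < tc]; hi <- x[x >= tc]
      v <- 0
      if (sum(lo) > 0) v <- v - sum(lo) * log(mean(lo))
      if (sum(hi) > 0) v <- v - sum(hi) * log(mean(hi))
      v
    })
    cuts[which.min(eta)]
  }
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:500, 1)
    x <- switch(1 + rep %% 3,
                rexp(n, 0.2),
                rlnorm(n, 1, 1),
                c(rpois(n, 3), rpois(n, 40))) # zero-inflated-ish mixture
    x <- x[is.finite(x)]
    if (length(unique(x)) < 2) next
    expect_equal(min_cross_entropy_threshold(x), brute(x))
  }
})

test_that("thresholding a well-separated lognormal mixture recovers the labels", {
  set.seed(5)
  n <- 400
  comp <- rbinom(n, 1, 0.4)
  x <- ifelse(comp == 1, rlnorm(n, log(50), 0.35), rlnorm(n, log(5), 0.35))
  thr <- min_cross_entropy_threshold(x)
  agreement <- mean((x >= thr) == (comp == 1))
  expect_gte(agreement, 0.95)
})

test_that("dominant/rare classification summarizes counts and biomass shares", {
  # 10 prolific lineages, 90 failures
  lt <- data.frame(lineage_id = 1:100,
                   reproductive_success = c(rep(12L, 10), rep(0L, 90)),
                   n_cells_final = c(rep(4096L, 10), rep(1L, 90)),
                   biomass_fraction_final = c(rep(0.0995, 10), rep(5e-5, 90)),
                   mean_age_h = 1, mean_generation_time_h = 1)
  class(lt) <- c("lineage_table", "data.frame")
  cl <- classify_dominant_rare(lt)
  expect_equal(cl$fraction_dominant, 0.1)
  expect_equal(cl$rare_biomass_fraction, 90 * 5e-5, tolerance = 1e-12)
  expect_true(all(cl$table$label[1:10] == "dominant"))
  # degenerate case: identical values fall back to all-dominant
  lt$reproductive_success <- rep(3L, 100)
  cl2 <- classify_dominant_rare(lt)
  expect_equal(cl2$fraction_dominant, 1)
  expect_equal(cl2$rare_biomass_fraction, 0)
})

test_that("age histograms are normalized and flag clearly bimodal samples", {
  ages <- rep(5, 100)
  ad <- age_distribution(ages, bins = 10)
  expect_false(ad$bimodal)
  set.seed(3)
  mix <- c(rnorm(500, 1, 0.1), rnorm(500, 100, 0.1))
  ad2 <- age_distribution(mix, bins = 50)
  expect_true(ad2$bimodal)
  expect_gt(ad2$bimodality_coefficient, 5 / 9)
  # histogram integrates to 1
  h <- ad2$histogram
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-9)
  expect_error(age_distribution(numeric(0)), "empty")
})
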