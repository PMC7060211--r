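make_single_dataset <- function(mean_R = 45.7, width = 17.6, counts = 3e6,
                                seed = 11) {
  truth <- distance_model(
    tibble::tibble(fraction = 1, mean_R = mean_R, width = width),
    donor_lifetimes = tibble::tibble(amplitude = 1, tau_ns = 4), R0 = 52)
  irf <- gaussian_irf(512L)
  da <- simulate_decay_histogram(truth, irf, counts, scatter_fraction = 0.002,
                                 background_fraction = 0.005, seed = seed)
  d0 <- simulate_decay_histogram(
    distance_model(tibble::tibble(fraction = 1, mean_R = 500, width = 1),
                   donor_lifetimes = truth$donor_lifetimes, R0 = 52),
    irf, counts / 2, scatter_fraction = 0.002, background_fraction = 0.005,
    seed = seed + 1L)
  decay_dataset(da, d0, irf)
}

test_that("single-component fit recovers a broad linker distribution", {
  ds <- cached("ds_1comp", function() make_single_dataset())
  fit <- cached("fit_1comp", function() fit_decays_global(ds, 1, R0 = 52))
  est <- tidy(fit)
  expect_equal(est$mean_R, 45.7, tolerance = 0.02)
  expect_equal(est$width, 17.6, tolerance = 0.05)
  expect_lt(fit$chi2r_global, 1.1)
  expect_true(fit$converged)
  # donor lifetime shared with the DOnly curve is recovered
  expect_equal(fit$donor[[1]]$tau_ns, 4, tolerance = 0.01)
})

test_that("support-plane scan is self-consistent around the optimum", {
  ds <- cached("ds_1comp", function() make_single_dataset())
  fit <- cached("fit_1comp", function() fit_decays_global(ds, 1, R0 = 52))
  ctr <- tidy(fit)$mean_R
  sp <- support_plane_scan(fit, "mean_R", grid = seq(ctr - 1, ctr + 1,
                                                     length.out = 9))
  # profile minimum within one grid step of the fitted optimum
  expect_lt(abs(sp$value[which.min(sp$chi2r_global)] - ctr), 0.3)
  ci <- attr(sp, "ci")
  expect_true(ci[1] < ctr && ctr < ci[2])
  expect_gt(attr(sp, "threshold"), min(sp$chi2r_global))
  # asymmetric statistical distance errors are reported
  expect_gte(attr(sp, "dR_minus"), 0)
  expect_gte(attr(sp, "dR_plus"), 0)
  # a grid missing the optimum is flagged
  expect_warning(support_plane_scan(fit, "mean_R",
                                    grid = seq(ctr + 3, ctr + 5,
                                               length.out = 5), maxiter = 5),
                 "does not cover")
})

test_that("MCMC sampler reproduces a Gaussian posterior and is seeded", {
  lp <- function(p) -0.5 * sum((p - c(2, -1))^2 / c(0.5, 2)^2)
  s <- fretdyn:::adaptive_metropolis(lp, c(a = 0, b = 0), 4000, seed = 1)
  expect_equal(unname(colMeans(s$samples)), c(2, -1), tolerance = 0.1)
  expect_equal(unname(apply(s$samples, 2, sd)), c(0.5, 2), tolerance = 0.05 * 2.5)
  s2 <- fretdyn:::adaptive_metropolis(lp, c(a = 0, b = 0), 4000, seed = 1)
  expect_identical(s$samples, s2$samples)
})

test_that("decay MCMC samples concentrate near the fitted parameters", {
  ds <- cached("ds_1comp", function() make_single_dataset())
  fit <- cached("fit_1comp", function() fit_decays_global(ds, 1, R0 = 52))
  mc <- mcmc_uncertainty(fit, n_samples = 600, seed = 3)
  expect_false(mc$flagged)
  td <- tidy(mc)
  est_R <- td$estimate[td$parameter == "mean_R_1"]
  sd_R <- td$sd[td$parameter == "mean_R_1"]
  expect_lt(abs(est_R - tidy(fit)$mean_R), 5 * max(sd_R, 0.02))
  mc2 <- mcmc_uncertainty(fit, n_samples = 600, seed = 3)
  expect_identical(mc$samples, mc2$samples)
})

test_that("global fits share fractions across datasets", {
  set.seed(31)
  mk <- function(seed, means) {
    truth <- distance_model(
      tibble::tibble(fraction = c(0.6, 0.4), mean_R = means, width = c(6, 6)),
      donor_lifetimes = tibble::tibble(amplitude = 1, tau_ns = 4), R0 = 52)
    irf <- gaussian_irf(512L)
    da <- simulate_decay_histogram(truth, irf, 3e6, scatter_fraction = 0.002,
                                   background_fraction = 0.005, seed = seed)
    d0 <- simulate_decay_histogram(
      distance_model(tibble::tibble(fraction = 1, mean_R = 500, width = 1),
                     donor_lifetimes = truth$donor_lifetimes, R0 = 52),
      irf, 1e6, scatter_fraction = 0.002, background_fraction = 0.005,
      seed = seed + 1L)
    decay_dataset(da, d0, irf, name = paste0("v", seed))
  }
  fit <- fit_decays_global(list(mk(41, c(40, 55)), mk(43, c(42, 58))),
                           n_components = 2, R0 = 52, seed = 1)
  est <- tidy(fit)
  # identical shared fractions in both datasets
  f1 <- est$fraction[est$dataset_id == 1]
  f2 <- est$fraction[est$dataset_id == 2]
  expect_identical(f1, f2)
  expect_equal(sort(f1), c(0.4, 0.6), tolerance = 0.12)
  # distances remain dataset-specific
  expect_equal(est$mean_R[est$dataset_id == 1], c(40, 55), tolerance = 0.1)
  expect_equal(est$mean_R[est$dataset_id == 2], c(42, 58), tolerance = 0.1)
})

test_that("fixing a shared fraction reproduces the paper-style x3 profiling", {
  ds <- cached("ds_3comp", function() {
    fx <- make_fixtures("decays", seed = 21)
    decay_dataset(fx$da, fx$donly, fx$irf)
  })
  fit <- cached("fit_3comp", function() fit_decays_global(ds, 3, R0 = 52,
                                                          seed = 21))
  sp <- support_plane_scan(fit, "fraction", grid = seq(0.05, 0.4, by = 0.05),
                           component = 3, maxiter = 12)
  # the profile has a minimum and rises towards the edges
  i_min <- which.min(sp$chi2r_global)
  expect_gt(sp$chi2r_global[length(sp$chi2r_global)], min(sp$chi2r_global))
  expect_true(i_min > 1 || sp$chi2r_global[1] <= sp$chi2r_global[2])
})

test_that("fit rejects invalid inputs", {
  ds <- cached("ds_1comp", function() make_single_dataset())
  expect_error(fit_decays_global(ds, 0, R0 = 52), "n_components")
})
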