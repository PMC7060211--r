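test_that("filters on disjoint patterns are scaled indicators", {
  p1 <- c(1, 1, 0, 0) / 2
  p2 <- c(0, 0, 1, 1) / 2
  total <- c(10, 20, 30, 40)
  fs <- build_filters(cbind(a = p1, b = p2), total)
  W <- fs$weights
  # unbiasedness: w_i . (N_j p_j) = delta_ij N_j
  for (i in 1:2) for (j in 1:2) {
    expect_equal(sum(W[, i] * 100 * cbind(p1, p2)[, j]),
                 if (i == j) 100 else 0, tolerance = 1e-10)
  }
  expect_equal(W[3:4, 1], c(0, 0))
  expect_equal(W[1:2, 2], c(0, 0))
})

test_that("overlapping exponential patterns recover mixture amplitudes", {
  ch <- seq(0.5, 63.5, by = 1)
  p1 <- exp(-ch / 10); p1 <- p1 / sum(p1)   # tau = 10 channels
  p2 <- exp(-ch / 30); p2 <- p2 / sum(p2)   # tau = 30 channels
  N <- c(5e4, 2e4)
  total <- N[1] * p1 + N[2] * p2
  fs <- build_filters(cbind(p1, p2), total)
  got <- drop(crossprod(fs$weights, total))
  expect_equal(unname(got), N, tolerance = 1e-6)
  # hand oracle: 2x2 weighted normal equations give the same filters
  M <- cbind(p1, p2); D <- diag(1 / total)
  W_hand <- t(solve(t(M) %*% D %*% M, t(M) %*% D))
  expect_equal(unname(fs$weights), unname(W_hand), tolerance = 1e-8)
})

test_that("linearly dependent patterns raise a singular error", {
  p1 <- c(0.5, 0.3, 0.2)
  p2 <- c(0.2, 0.5, 0.3)
  p3 <- 0.5 * p1 + 0.5 * p2
  expect_error(build_filters(cbind(A = p1, B = p2, C = p3), c(10, 10, 10)),
               "dependent|singular")
})

test_that("a homogeneous Poisson stream is uncorrelated", {
  set.seed(5)
  n <- 2e5
  t <- sort(stats::runif(n, 0, 1e4))    # 20/ms over 10 s
  st <- tibble::tibble(macrotime = floor(t * 1e6 / 32),
                       microtime_channel = sample(0:4095, n, TRUE),
                       detector = 0L)
  class(st) <- c("photon_stream", class(st))
  attr(st, "sync_period_ns") <- 32
  attr(st, "micro_channel_width_ns") <- 32 / 4096
  attr(st, "duration_s") <- 10
  cur <- correlate_filtered(st, NULL, max_lag_ms = 10)
  expect_true(all(abs(cur$G) < 5 * pmax(cur$sd, 1e-4)))
})

test_that("pure diffusion round trip recovers the diffusion time", {
  one <- cached("stream_diffusion", function() {
    cfg <- sim_config(states = tibble::tibble(efficiency = 0.5,
                                              brightness_kHz = 200),
                      duration_s = 20, n_molecules = 30, dt_ms = 0.0015)
    list(cfg = cfg, stream = simulate_photon_stream(cfg, seed = 6))
  })
  cur <- correlate_filtered(one$stream, NULL, max_lag_ms = 30)
  fit <- fit_correlations(cur, n_relax = 0,
                          axial_ratio = one$cfg$w_z_um / one$cfg$w_xy_um)
  t_diff_true <- one$cfg$w_xy_um^2 / (4 * one$cfg$diff_um2_ms)
  expect_lt(abs(fit$t_diff_ms - t_diff_true) / t_diff_true, 0.10)
  # adding a kinetic term with A ~ 0 leaves the diffusion time in place
  fit1 <- fit_correlations(cur, n_relax = 1,
                           axial_ratio = one$cfg$w_z_um / one$cfg$w_xy_um)
  expect_lt(abs(fit1$t_diff_ms - fit$t_diff_ms) / fit$t_diff_ms, 0.15)
})

test_that("two-state exchange appears as an anti-correlated sCCF term", {
  ts <- cached("stream_two_state", function() two_state_stream())
  filt <- two_state_filters(ts$cfg, ts$stream)
  cur <- cached("curves_two_state", function() {
    correlate_filtered(ts$stream, filt, max_lag_ms = 20)
  })
  ccf <- dplyr::filter(cur, .data$kind == "sCCF")
  fit <- fit_correlations(cur, n_relax = 1)
  # relaxation time 1/(k12+k21) = 10 us within the fit tolerance
  expect_lt(abs(fit$t_R_ms * 1e3 - 10) / 10, 0.2)
  # anti-correlation: the sCCF kinetic amplitudes are negative
  A_ccf <- fit$per_curve$A1[grepl("sCCF", fit$per_curve$curve)]
  expect_true(all(A_ccf < 0))
  # detailed-balance symmetry of the two cross-correlations
  c12 <- dplyr::filter(ccf, .data$species_i == "low")
  c21 <- dplyr::filter(ccf, .data$species_i == "high")
  mid <- c12$lag_ms > 0.001 & c12$lag_ms < 1
  pool_sd <- sqrt(c12$sd[mid]^2 + c21$sd[mid]^2)
  expect_lt(mean(abs(c12$G[mid] - c21$G[mid]) / pmax(pool_sd, 1e-4)), 3)
})

test_that("filters summing to one reproduce the plain correlation", {
  set.seed(9)
  n <- 5e4
  t <- sort(stats::runif(n, 0, 5e3))
  st <- tibble::tibble(macrotime = floor(t * 1e6 / 32),
                       microtime_channel = sample(0:4095, n, TRUE),
                       detector = sample(0:1, n, TRUE))
  class(st) <- c("photon_stream", class(st))
  attr(st, "sync_period_ns") <- 32
  attr(st, "micro_channel_width_ns") <- 32 / 4096
  attr(st, "duration_s") <- 5
  # two filters that add to 1 in every channel
  W <- cbind(a = rep(0.3, 128), b = rep(0.7, 128))
  fs <- structure(list(weights = W, patterns = NULL, total = NULL,
                       keep = rep(TRUE, 128)), class = "filter_set")
  cur <- correlate_filtered(st, fs, n_micro_bins = 64L, max_lag_ms = 5)
  plain <- correlate_filtered(st, NULL, max_lag_ms = 5)
  # sum_ij G_ij weighted by intensity fractions equals the plain ACF
  agg <- cur |>
    dplyr::group_by(.data$lag_ms) |>
    dplyr::summarise(G = sum(c(0.09, 0.21, 0.21, 0.49) *
                               .data$G[order(.data$species_i,
                                             .data$species_j)]),
                     .groups = "drop")
  expect_equal(agg$G, plain$G, tolerance = 1e-8)
})

test_that("non-global fits return independent per-curve estimates", {
  ts <- cached("stream_two_state", function() two_state_stream())
  filt <- two_state_filters(ts$cfg, ts$stream)
  cur <- cached("curves_two_state", function() {
    correlate_filtered(ts$stream, filt, max_lag_ms = 20)
  })
  fits <- fit_correlations(cur, n_relax = 1, global = FALSE)
  expect_length(fits, 4)
  t_Rs <- vapply(fits, function(f) f$t_R_ms * 1e3, numeric(1))
  # every individual curve still carries the 10 us relaxation
  expect_true(all(abs(t_Rs - 10) / 10 < 0.5))
})
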