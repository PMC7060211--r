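test_that("pure background yields no bursts", {
  cfg <- sim_config(states = tibble::tibble(efficiency = 0,
                                            brightness_kHz = 0),
                    duration_s = 5, n_molecules = 1,
                    background_kHz = c(1, 1))
  st <- simulate_photon_stream(cfg, seed = 1)
  b <- select_bursts(st)
  expect_equal(nrow(b), 0)
  expect_equal(nrow(select_bursts(st[0, ])), 0)
})

test_that("a constructed bright transit is found as exactly one burst", {
  # hand-built stream: sparse background plus one dense 1-ms transit
  sync <- 32e-9
  bg_t <- seq(0.05, 4.95, by = 0.01)       # 100 Hz background
  transit_t <- seq(2.0, 2.001, length.out = 300)  # dense 1-ms transit
  t_all <- sort(c(bg_t, transit_t))
  st <- tibble::tibble(macrotime = floor(t_all / sync),
                       microtime_channel = 100L, detector = 0L)
  class(st) <- c("photon_stream", class(st))
  attr(st, "sync_period_ns") <- 32
  attr(st, "micro_channel_width_ns") <- 32 / 4096
  attr(st, "duration_s") <- 5
  b <- select_bursts(st, T_us = 120, L = 10, min_photons = 60)
  expect_equal(nrow(b), 1)
  expect_gt(b$n_photons, 250)
  expect_lt(abs(b$t_start_ms - 2000), 1)
})

test_that("raising the neighbour threshold never adds bursts", {
  bt <- cached("stream_E075", function() {
    cfg <- sim_config(states = tibble::tibble(efficiency = 0.75,
                                              brightness_kHz = 150),
                      duration_s = 6, n_molecules = 20)
    list(cfg = cfg, stream = simulate_photon_stream(cfg, seed = 4))
  })
  n_prev <- Inf
  for (L in c(5, 10, 20, 40)) {
    n_now <- nrow(select_bursts(bt$stream, L = L))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("burst indicators reproduce closed-form corrections", {
  # E = F_A / (F_A + gamma F_D) on ideal counts
  st <- tibble::tibble(
    macrotime = as.numeric(seq_len(100)) * 10,
    microtime_channel = rep(400L, 100),
    detector = c(rep(1L, 75), rep(0L, 25)))
  class(st) <- c("photon_stream", class(st))
  attr(st, "sync_period_ns") <- 32
  attr(st, "micro_channel_width_ns") <- 32 / 4096
  attr(st, "duration_s") <- 1
  b <- tibble::tibble(burst_id = 1L, first = 1L, last = 100L,
                      t_start_ms = 0, duration_ms = 0.1, n_photons = 100L)
  bi <- burst_indicators(st, b)
  expect_equal(bi$E, 0.75)
  expect_true(bi$valid)
  # gamma rebalances the efficiency
  bi2 <- burst_indicators(st, b, gamma = 3)
  expect_equal(bi2$E, 75 / (75 + 3 * 25))
})

test_that("burst lifetime MLE reaches the exponential CRLB scale", {
  set.seed(8)
  n_ph <- 500
  tau_true <- 2
  reps <- 40
  errs <- replicate(reps, {
    mic <- 2 + stats::rexp(n_ph, 1 / tau_true)   # delta IRF at 2 ns
    mic <- mic[mic < 32]
    fretdyn:::exp_mle_truncated(mean(mic) - 2, 32 - 2) - tau_true
  })
  # CRLB: sd(tau_hat) ~ tau/sqrt(n); allow 3 SE on the mean of reps
  expect_lt(abs(mean(errs)), 3 * tau_true / sqrt(n_ph) / sqrt(reps) + 0.02)
  expect_lt(stats::sd(errs), 2 * tau_true / sqrt(n_ph))
})

test_that("FRET-lines pass through their defining points", {
  # sigma_link = 0: static line is exactly E = 1 - tau/tau_D0
  ln0 <- fret_lines(4, "static", R0 = 52, sigma_link = 0)
  expect_equal(ln0$E, 1 - ln0$tau_F_ns / 4, tolerance = 1e-10)
  # static line passes through (tau_D0, 0)
  lnl <- fret_lines(4, "static", R0 = 52, sigma_link = 6)
  expect_lt(abs(lnl$E[which.max(lnl$tau_F_ns)]), 0.05)
  # linker broadening shifts the line right: at fixed E the lifetime grows
  E_mid <- 0.5
  t0 <- stats::approx(ln0$E, ln0$tau_F_ns, xout = E_mid)$y
  t1 <- stats::approx(lnl$E, lnl$tau_F_ns, xout = E_mid)$y
  expect_gt(t1, t0)

  # dynamic line: endpoints and the equal-fraction mixture point
  dyn <- fret_lines(4, "dynamic", endpoints = c(1, 3))
  expect_equal(fretdyn:::fret_line_E_at(dyn, 1), 1 - 1 / 4, tolerance = 1e-9)
  expect_equal(fretdyn:::fret_line_E_at(dyn, 3), 1 - 3 / 4, tolerance = 1e-9)
  # equal fractions: tau_F = (1 + 9)/(1 + 3) = 2.5, tau_x = 2, E = 0.5
  expect_equal(fretdyn:::fret_line_E_at(dyn, 2.5), 0.5, tolerance = 1e-9)
  expect_error(fret_lines(4, "static", sigma_link = -1), "sigma_link")
})

test_that("histogram comparison is calibrated", {
  set.seed(12)
  mk_bursts <- function(n) {
    tibble::tibble(E = stats::rnorm(n, 0.5, 0.1),
                   tau_ns = stats::rnorm(n, 2, 0.3),
                   valid = TRUE)
  }
  b1 <- mk_bursts(400)
  # identical sets: p = 1 on every axis
  same <- compare_histograms(b1, b1, tau_D0 = 4, n_boot = 200, seed = 1)
  expect_true(all(same$p == 1))
  # clearly different sets: small p
  b2 <- dplyr::mutate(b1, E = .data$E + 0.3)
  diffp <- compare_histograms(b2, b1, tau_D0 = 4, n_boot = 200, seed = 1)
  expect_lt(diffp$p[diffp$axis == "E"], 0.05)
  # too few bursts is flagged
  expect_warning(small <- compare_histograms(mk_bursts(10), b1, n_boot = 10),
                 "50")
  expect_true(all(is.na(small$p)))
})

test_that("null p-values are uniform when both sets share a generator", {
  set.seed(77)
  pool <- tibble::tibble(E = stats::rnorm(3000, 0.5, 0.12),
                         tau_ns = stats::rnorm(3000, 2, 0.4), valid = TRUE)
  pvals <- vapply(1:60, function(r) {
    i <- sample.int(3000, 250)
    j <- sample.int(3000, 250)
    compare_histograms(pool[i, ], pool[j, ], tau_D0 = 4, n_boot = 200,
                       seed = r)$p[1]
  }, numeric(1))
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
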