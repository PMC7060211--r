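test_that("state trajectories follow the exponential dwell law", {
  # single state: one segment spanning the duration
  net1 <- rate_network("C1", tibble::tibble(from = character(),
                                            to = character(),
                                            rate = numeric()))
  tr1 <- simulate_state_trajectory(net1, 3, seed = 1)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$dwell_ms, 3000)

  # symmetric two-state at 1/ms: mean dwell 1 ms within 3 SE
  net2 <- rate_network(c("C1", "C2"),
                       tibble::tibble(from = c("C1", "C2"), to = c("C2", "C1"),
                                      rate = c(1, 1)))
  tr2 <- simulate_state_trajectory(net2, 10, seed = 2)
  dw <- tr2$dwell_ms[-nrow(tr2)]     # last dwell is censored
  se <- 1 / sqrt(length(dw))         # exponential: sd = mean
  expect_lt(abs(mean(dw) - 1), 3 * se)
  # dwell-time distribution passes a KS test against Exponential(1)
  ks <- stats::ks.test(dw, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
  # entry times strictly increasing
  expect_true(all(diff(tr2$entry_ms) > 0))
})

test_that("long-run occupancies match the stationary vector", {
  net <- rate_network(c("C1", "C2", "C3"), linear_chain_rates(1, 1, 1, 1))
  tr <- simulate_state_trajectory(net, 40, seed = 3)
  occ <- tapply(tr$dwell_ms, tr$state, sum) / sum(tr$dwell_ms)
  # 3 SE with an effective sample size of the number of visits
  n_vis <- nrow(tr)
  for (s in c("C1", "C2", "C3")) {
    expect_lt(abs(occ[[s]] - 1 / 3), 3 * sqrt(1 / 3 * 2 / 3 / n_vis) * 3)
  }
  # absorbing networks terminate in the absorbing state
  net_abs <- rate_network(c("C1", "C2"),
                          tibble::tibble(from = "C1", to = "C2", rate = 5))
  tr_abs <- simulate_state_trajectory(net_abs, 5, seed = 4)
  expect_equal(tr_abs$state[nrow(tr_abs)], "C2")
})

test_that("an immobile molecule at the focus emits Poisson counts", {
  cfg <- sim_config(states = tibble::tibble(efficiency = 0,
                                            brightness_kHz = 50),
                    duration_s = 2, n_molecules = 1, diff_um2_ms = 0)
  st <- simulate_photon_stream(cfg, seed = 3,
                               init_positions = matrix(0, 1, 3))
  lambda <- 50 * 2000
  expect_lt(abs(nrow(st) - lambda), 3 * sqrt(lambda))
  expect_true(all(diff(st$macrotime) >= 0))
  expect_true(all(st$microtime_channel < 4096))
})

test_that("static high-FRET molecules give the right proximity ratio", {
  bt <- cached("stream_E075", function() {
    cfg <- sim_config(states = tibble::tibble(efficiency = 0.75,
                                              brightness_kHz = 150),
                      duration_s = 6, n_molecules = 20)
    list(cfg = cfg, stream = simulate_photon_stream(cfg, seed = 4))
  })
  st <- bt$stream
  n_red <- sum(st$detector == 1)
  p_hat <- n_red / nrow(st)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / nrow(st)))
})

test_that("donor-only molecules put photons only in the green channel", {
  cfg <- sim_config(states = tibble::tibble(efficiency = 0,
                                            brightness_kHz = 100),
                    duration_s = 3, n_molecules = 10)
  st <- simulate_photon_stream(cfg, seed = 5)
  expect_gt(nrow(st), 100)
  expect_equal(sum(st$detector == 1), 0)
  # with background, the red channel carries only background
  cfg_bg <- sim_config(states = tibble::tibble(efficiency = 0,
                                               brightness_kHz = 100),
                       duration_s = 3, n_molecules = 10,
                       background_kHz = c(0, 1))
  st_bg <- simulate_photon_stream(cfg_bg, seed = 5)
  n_red <- sum(st_bg$detector == 1)
  expect_lt(abs(n_red - 3000), 3 * sqrt(3000))
})

test_that("micro-times follow the lifetime law through the IRF", {
  bt <- cached("stream_E075", function() {
    cfg <- sim_config(states = tibble::tibble(efficiency = 0.75,
                                              brightness_kHz = 150),
                      duration_s = 6, n_molecules = 20)
    list(cfg = cfg, stream = simulate_photon_stream(cfg, seed = 4))
  })
  st <- bt$stream
  chan_w <- attr(st, "micro_channel_width_ns")
  mic <- (st$microtime_channel[st$detector == 0] + 0.5) * chan_w
  # tail beyond the IRF: exponential with the quenched donor lifetime 1 ns
  sel <- mic > 3.5 & mic < 10
  h <- hist(mic[sel], breaks = seq(3.5, 10, by = 0.25), plot = FALSE)
  fitc <- stats::lm(log(h$counts + 0.5) ~ h$mids)
  tau_hat <- -1 / stats::coef(fitc)[2]
  expect_equal(unname(tau_hat), 1, tolerance = 0.08)
})

test_that("identical seeds give identical streams, different seeds differ", {
  cfg <- sim_config(states = tibble::tibble(efficiency = 0.5,
                                            brightness_kHz = 100),
                    duration_s = 1, n_molecules = 5)
  s1 <- simulate_photon_stream(cfg, seed = 9)
  s2 <- simulate_photon_stream(cfg, seed = 9)
  s3 <- simulate_photon_stream(cfg, seed = 10)
  expect_identical(s1$macrotime, s2$macrotime)
  expect_identical(s1$microtime_channel, s2$microtime_channel)
  expect_false(identical(s1$macrotime, s3$macrotime))
})

test_that("photon stream CSV round trip preserves records and metadata", {
  withr::with_tempdir({
    cfg <- sim_config(states = tibble::tibble(efficiency = 0.5,
                                              brightness_kHz = 100),
                      duration_s = 0.5, n_molecules = 5)
    st <- simulate_photon_stream(cfg, seed = 1)
    write_photon_csv(st, "stream.csv")
    back <- read_photon_csv("stream.csv")
    expect_equal(back$macrotime, st$macrotime)
    expect_equal(back$microtime_channel, st$microtime_channel)
    expect_equal(back$detector, st$detector)
    expect_equal(attr(back, "sync_period_ns"), attr(st, "sync_period_ns"))
  })
})

test_that("config validation catches unphysical settings", {
  expect_error(sim_config(states = tibble::tibble(efficiency = 1.5,
                                                  brightness_kHz = 10)),
               "efficiencies")
  expect_error(sim_config(states = tibble::tibble(efficiency = 0.5,
                                                  brightness_kHz = 10),
                          sync_period_ns = -1), "period")
  expect_warning(sim_config(states = tibble::tibble(efficiency = 0.5,
                                                    brightness_kHz = 10),
                            sync_period_ns = 10), "span|wrap")
})
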