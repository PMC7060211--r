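# shared fixture cache: expensive synthetic datasets are built once per test
# run and reused across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# random linear three-state networks with rates spread over two decades
random_chain <- function() {
  k <- stats::runif(4, 0.05, 20)
  rate_network(c("C1", "C2", "C3"),
               linear_chain_rates(k[1], k[2], k[3], k[4]))
}

# a short bright static-molecule stream for burst tests
burst_test_stream <- function(efficiency, duration_s = 20, seed = 101) {
  cfg <- sim_config(
    states = tibble::tibble(efficiency = efficiency,
                            brightness_kHz = rep(150, length(efficiency))),
    duration_s = duration_s, n_molecules = 25L)
  list(cfg = cfg, stream = simulate_photon_stream(cfg, seed = seed))
}

# two-state exchange stream (shared by ffcs and acceptance tests)
two_state_stream <- function(k_each = 50, duration_s = 30, seed = 7,
                             E = c(0.3, 0.8)) {
  net <- rate_network(c("C1", "C2"),
                      tibble::tibble(from = c("C1", "C2"), to = c("C2", "C1"),
                                     rate = c(k_each, k_each)))
  cfg <- sim_config(
    states = tibble::tibble(efficiency = E, brightness_kHz = c(150, 150)),
    duration_s = duration_s, n_molecules = 30L, dt_ms = 0.001)
  list(net = net, cfg = cfg,
       stream = simulate_photon_stream(cfg, net, seed = seed))
}

two_state_filters <- function(cfg, stream, E = c(0.3, 0.8)) {
  pats <- cbind(low = fretdyn:::state_pattern(cfg, E[1]),
                high = fretdyn:::state_pattern(cfg, E[2]))
  ch <- fretdyn:::photon_filter_channel(stream, 64L)
  build_filters(pats, tabulate(ch, 128L))
}

toy_screen_fixture <- function() {
  cached("toy_screen", function() {
    fx <- make_fixtures("structures", seed = 1)
    dx <- make_fixtures("distance_set", seed = 1)
    scr <- screen_structures(fx$structures, dx$distance_set, spacing_A = 1.2)
    list(structures = fx$structures, distance_set = dx$distance_set,
         screen = scr)
  })
}
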