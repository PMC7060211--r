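test_that("relaxation spectrum matches closed forms", {
  # two-state: t_R = 1/(k_f + k_b)
  net2 <- rate_network(c("C1", "C2"),
                       tibble::tibble(from = c("C1", "C2"), to = c("C2", "C1"),
                                      rate = c(125, 125)))  # 0.125/us each
  sp2 <- relaxation_spectrum(net2)
  expect_equal(sp2$t_R, 1 / 250, tolerance = 1e-12)  # 4 us in ms

  # equal-rate chain: eigenvalues {0, -1, -3}/ms
  net3 <- rate_network(c("C1", "C2", "C3"), linear_chain_rates(1, 1, 1, 1))
  sp3 <- relaxation_spectrum(net3)
  expect_equal(sp3$t_R, c(1 / 3, 1), tolerance = 1e-10)
  expect_equal(unname(sp3$fractions), rep(1 / 3, 3), tolerance = 1e-10)

  # homogeneity: scaling all rates by c scales t_R by 1/c, fractions fixed
  net3c <- rate_network(c("C1", "C2", "C3"), linear_chain_rates(5, 5, 5, 5))
  sp3c <- relaxation_spectrum(net3c)
  expect_equal(sp3c$t_R, sp3$t_R / 5, tolerance = 1e-10)
  expect_equal(sp3c$fractions, sp3$fractions, tolerance = 1e-10)
})

test_that("stationary fractions obey detailed balance over random chains", {
  set.seed(42)
  for (i in 1:200) {
    net <- random_chain()
    sp <- relaxation_spectrum(net)
    x <- sp$fractions
    k <- net$rates$rate
    expect_equal(x[["C1"]] * k[1], x[["C2"]] * k[2], tolerance = 1e-8)
    expect_equal(x[["C2"]] * k[3], x[["C3"]] * k[4], tolerance = 1e-8)
    expect_equal(sum(x), 1, tolerance = 1e-12)
  }
})

test_that("three-state inversion round trip recovers generating rates", {
  set.seed(7)
  for (i in 1:200) {
    net <- random_chain()
    k <- net$rates$rate
    sp <- relaxation_spectrum(net)
    sols <- invert_three_state(sp$t_R[1], sp$t_R[2],
                               sp$fractions[[1]], sp$fractions[[2]],
                               sp$fractions[[3]])
    errs <- vapply(sols, function(s) max(abs(s$rates$rate - k) / k),
                   numeric(1))
    expect_lt(min(errs), 1e-9)
    # every returned solution reproduces the inputs
    for (s in sols) {
      sps <- relaxation_spectrum(s)
      expect_equal(sps$t_R, sp$t_R, tolerance = 1e-9)
      expect_equal(sps$fractions, sp$fractions, tolerance = 1e-9)
    }
  }
})

test_that("the two inversion solutions swap the fast exchange pair", {
  # wt**-like inputs: 4 us and 230 us relaxation, fractions 0.44/0.38/0.18
  sols <- invert_three_state(4e-3, 0.23, 0.44, 0.38, 0.18)
  expect_length(sols, 2)
  ex <- vapply(sols, function(s) {
    r <- s$rates
    c(ex12 = sum(r$rate[r$from %in% c("C1", "C2") & r$to %in% c("C1", "C2")]),
      ex23 = sum(r$rate[r$from %in% c("C2", "C3") & r$to %in% c("C2", "C3")]))
  }, numeric(2))
  # first solution: C1-C2 fast; second: C2-C3 fast
  expect_gt(ex["ex12", 1], ex["ex12", 2])
  expect_lt(ex["ex23", 1], ex["ex23", 2])
})

test_that("degenerate double root is merged to one solution", {
  net <- rate_network(c("C1", "C2", "C3"), linear_chain_rates(1, 1, 1, 1))
  sp <- relaxation_spectrum(net)
  sols <- invert_three_state(sp$t_R[1], sp$t_R[2], 1 / 3, 1 / 3, 1 / 3)
  expect_length(sols, 1)
  expect_equal(sols[[1]]$rates$rate, rep(1, 4), tolerance = 1e-7)
})

test_that("energy landscape follows the Boltzmann relations", {
  net <- rate_network(c("C1", "C2"),
                      tibble::tibble(from = c("C1", "C2"), to = c("C2", "C1"),
                                     rate = c(1, exp(1))))
  el <- energy_landscape(net, k_0 = exp(1))
  # symmetric rates give zero free-energy difference
  el_sym <- energy_landscape(
    rate_network(c("C1", "C2"),
                 tibble::tibble(from = c("C1", "C2"), to = c("C2", "C1"),
                                rate = c(3, 3))), k_0 = 10)
  expect_equal(el_sym$dG0, c(0, 0))
  # reverse/forward ratio e gives -1 kT for the forward row
  expect_equal(el$dG0[el$from == "C1"], -1, tolerance = 1e-12)
  expect_equal(el$dG0[el$from == "C2"], 1, tolerance = 1e-12)
  # activation energies against the reference pre-factor
  expect_equal(sort(el$dG_act), c(0, 1), tolerance = 1e-12)
  expect_error(energy_landscape(net, k_0 = -1), "k_0")
})

test_that("invalid networks are rejected", {
  expect_error(rate_network(c("A", "B"),
                            tibble::tibble(from = "A", to = "B", rate = -1)),
               ">= 0")
  disconnected <- rate_network(c("A", "B", "C"),
                               tibble::tibble(from = "A", to = "B", rate = 1))
  # C is absorbing and disconnected from the A/B pair once B feeds nothing
  expect_error(relaxation_spectrum(disconnected), "disconnected|unique")
  expect_error(invert_three_state(0.2, 0.1, 0.3, 0.3, 0.4), "t_R1 < t_R2")
  expect_error(invert_three_state(0.1, 0.2, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("cyclic topologies are representable but excluded from inversion", {
  cyc <- rate_network(c("C1", "C2", "C3"), tibble::tibble(
    from = c("C1", "C2", "C2", "C3", "C3", "C1"),
    to   = c("C2", "C1", "C3", "C2", "C1", "C3"),
    rate = c(1, 2, 3, 4, 5, 6)))
  expect_s3_class(cyc, "rate_network")
  expect_error(invert_network(cyc), "unsupported topology")
  # linear chains invert through the same entry point
  net <- rate_network(c("C1", "C2", "C3"), linear_chain_rates(2, 1, 4, 3))
  sols <- invert_network(net)
  errs <- vapply(sols, function(s) max(abs(s$rates$rate - c(2, 1, 4, 3))),
                 numeric(1))
  expect_lt(min(errs), 1e-9)
})
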