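test_that("decoupled species grow exactly exponentially", {
  cfg <- community_config(
    list(species_spec("S1", 0.5), species_spec("S2", -0.2)),
    init = c(S1 = 1e3, S2 = 1e4))
  tr <- simulate_community(cfg, 10)
  expect_equal(unname(tr$species[nrow(tr$species), "S1"]),
               1e3 * exp(0.5 * 10),
               tolerance = 1e-6)
  expect_equal(unname(tr$species[nrow(tr$species), "S2"]),
               1e4 * exp(-0.2 * 10),
               tolerance = 1e-6)
})

test_that("a reusable mediator follows its closed-form accumulation", {
  # with zero initial concentration, C1(t) = (beta/r10) S10 (e^{r10 t}-1)
  cfg <- pair_config(kind = "reusable", init = c(S1 = 1e4, S2 = 1e4))
  tr <- simulate_community(cfg, 10)
  closed <- (1e-6 / 0.5) * 1e4 * (exp(0.5 * tr$times) - 1)
  expect_equal(tr$mediators[, "C1"], closed, tolerance = 1e-6)
})

test_that("reusable mediator production balances pointwise", {
  cfg <- pair_config(kind = "reusable")
  rhs <- build_rhs(cfg)
  tr <- simulate_community(cfg, 20)
  for (i in seq(1, nrow(tr$species), by = 40)) {
    y <- c(tr$species[i, ], tr$mediators[i, ])
    dy <- eval_rhs(rhs, y)
    expect_equal(unname(dy[3]), 1e-6 * y[["S1"]], tolerance = 1e-12)
  }
})

test_that("the coexistence fixed point is stationary in the rhs", {
  cfg <- pair_config()  # Case II parameters
  p <- as_single_mediator(cfg)
  ss <- steady_state(p)
  rhs <- build_rhs(cfg)
  S1 <- 1e6
  y <- c(S1, ss[["RS_star"]] * S1, ss[["C1_star"]])
  dy <- eval_rhs(rhs, y)
  # dC1/dt = 0 and d(S2/S1)/dt = 0 at (C1*, RS*)
  expect_equal(unname(dy[3]), 0, tolerance = 1e-8 * 1e-6 * S1)
  dRS <- (dy[2] * y[1] - y[2] * dy[1]) / y[1]^2
  expect_equal(dRS, 0, tolerance = 1e-10 * ss[["RS_star"]])
})

test_that("species-ratio dynamics satisfy the growth-rate identity", {
  # d(RS)/dt = (r20 + rS2C1 C1/(C1+K) - r10) RS along the trajectory
  cfg <- pair_config()
  tr <- simulate_community(cfg, 25, n_out = 2000)
  RS <- tr$species[, "S2"] / tr$species[, "S1"]
  C1 <- tr$mediators[, "C1"]
  mid <- seq(100, 1900, by = 200)
  num <- (RS[mid + 1] - RS[mid - 1]) /
    (tr$times[mid + 1] - tr$times[mid - 1])
  pred <- (0.3 + 0.4 * C1[mid] / (C1[mid] + 1) - 0.5) * RS[mid]
  expect_equal(num, pred, tolerance = 1e-3)
})

test_that("turbidostat dilutions settle at ln(ratio)/r and record events", {
  cfg <- community_config(
    list(species_spec("S1", 0.5)), init = c(S1 = 1e7),
    dilution = turbidostat10())
  tr <- simulate_community(cfg, 60)
  gaps <- diff(tr$dilution_times)
  expect_equal(unname(tail(gaps, 1)), log(10) / 0.5,
               tolerance = 1e-6)
  # total density never exceeds the threshold
  expect_lte(max(rowSums(tr$species)), 1e8 * (1 + 1e-6))
})

test_that("species below the extinction floor are zeroed at dilutions", {
  cfg <- pair_config(r10 = 0.7, r20 = 0.1, rS2C1 = 0.1,
                     dilution = turbidostat10(),
                     init = c(S1 = 9999999, S2 = 1e-1))
  tr <- simulate_community(cfg, 40)
  expect_equal(unname(tr$species[nrow(tr$species), "S2"]), 0)
})

test_that("states stay non-negative", {
  cfg <- generate_regime_config("modification_consume3", 5)
  tr <- simulate_community(cfg, 100)
  expect_gte(min(tr$species), 0)
  expect_gte(min(tr$mediators), -1e-10)
})

test_that("halving solver tolerances leaves terminal fractions stable", {
  cfg <- pair_config(dilution = turbidostat10())
  tr1 <- simulate_community(cfg, 80, rtol = 1e-8, atol = 1e-10)
  tr2 <- simulate_community(cfg, 80, rtol = 5e-9, atol = 5e-11)
  f1 <- species_fractions(tr1)[nrow(tr1$species), ]
  f2 <- species_fractions(tr2)[nrow(tr2$species), ]
  expect_lt(max(abs(f1 - f2) / f2), 1e-3)
})

test_that("phase traces expose the mediator-ratio coordinates", {
  cfg <- pair_config(init = c(S1 = 1e7, S2 = 1e7))
  ph <- phase_trace(cfg, t_end = 60)
  # Case II: scaled coordinates approach the steady state (1, 1)
  expect_equal(tail(ph$C1_hat, 1), 1, tolerance = 0.02)
  expect_equal(tail(ph$RS_hat, 1), 1, tolerance = 0.02)
  expect_equal(tail(ph$f, 1), 0, tolerance = 0.01)
  # zero production: mediator stays identically zero
  cfg0 <- pair_config(beta = 1e-30)
  ph0 <- phase_trace(cfg0, t_end = 10)
  expect_lt(max(ph0$C1), 1e-15)
})

test_that("competitive-commensal resource bookkeeping is yield-coupled", {
  cfg <- generate_regime_config("competitive_commensal", 1)
  rhs <- build_rhs(cfg)
  y <- c(1e6, 1e6, 0.5, 10)
  dy <- eval_rhs(rhs, y)
  # resource consumption equals yield times realised growth per species
  p <- Filter(function(l) l$role == "effect" && l$species == "S1",
              cfg$links)[[1]]
  g1 <- p$r * y[3] / (y[3] + p$K)
  sup <- cfg$mediators[[1]]$supply
  co <- Filter(function(l) l$role == "effect" && l$species == "S2",
               cfg$links)
  cc <- c(y[3] / co[[1]]$K, y[4] / co[[2]]$K)
  g2 <- co[[1]]$r * (cc[1] * cc[2] / sum(cc)) *
    (1 / (cc[1] + 1) + 1 / (cc[2] + 1))
  expect_equal(unname(dy[3]),
               sup - 1e-6 * g1 * y[1] - 1e-6 * g2 * y[2],
               tolerance = 1e-10)
})
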