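mk_traj <- function(times, S, ids = colnames(S)) {
  medlv:::new_trajectory(times, `colnames<-`(S, ids))
}

test_that("the fold-difference metric behaves as a pseudometric", {
  t <- seq(0, 10, length.out = 50)
  A <- cbind(S1 = 1e5 * exp(0.5 * t), S2 = 1e4 * exp(0.3 * t))
  ta <- mk_traj(t, A)
  expect_equal(dbar(ta, ta), 0)
  # a uniform 10-fold offset scores exactly 1
  tb <- mk_traj(t, A * 10)
  expect_equal(dbar(ta, tb), 1, tolerance = 1e-12)
  expect_equal(dbar(tb, ta), dbar(ta, tb))
  # offsetting one species by 100x scores (2 + 0)/2 = 1
  tc <- mk_traj(t, cbind(S1 = A[, 1] * 100, S2 = A[, 2]))
  expect_equal(dbar(ta, tc), 1, tolerance = 1e-12)
  # densities below the extinction floor are floored before the log
  td <- mk_traj(t, cbind(S1 = A[, 1], S2 = rep(1e-9, 50)))
  te <- mk_traj(t, cbind(S1 = A[, 1], S2 = rep(1e-6, 50)))
  expect_equal(dbar(td, te, S_ext = 1e-2), 0)
  expect_error(dbar(ta, mk_traj(t, A, ids = c("X", "Y"))), "mismatch")
})

test_that("quadrature refinement leaves the metric stable", {
  # smooth (batch) trajectories: refinement changes the score by < 0.1%
  cfg <- pair_config()
  tr <- simulate_community(cfg, 40, n_out = 1200)
  spec <- derive_alternative(cfg)
  pt <- simulate_pairwise(spec, cfg$init, 40, n_out = 1200)
  d1 <- dbar(pt, tr, c(5, 35), n_grid = 201)
  d2 <- dbar(pt, tr, c(5, 35), n_grid = 2001)
  expect_lt(abs(d1 - d2) / max(d2, 1e-12), 1e-3)
  # with dilution discontinuities in the window the integrand has kinks;
  # refinement still only moves the score at the percent level
  cfgd <- pair_config(dilution = turbidostat10())
  trd <- simulate_community(cfgd, 60, n_out = 3000)
  ptd <- simulate_pairwise(spec, cfgd$init, 60, dilution = cfgd$dilution,
                           n_out = 3000)
  e1 <- dbar(ptd, trd, c(5, 55), n_grid = 201)
  e2 <- dbar(ptd, trd, c(5, 55), n_grid = 2001)
  expect_lt(abs(e1 - e2) / max(e2, 1e-12), 0.03)
})

test_that("outcome classification keys on sustained terminal fractions", {
  t <- seq(0, 100, length.out = 200)
  co <- mk_traj(t, cbind(S1 = rep(6e6, 200), S2 = rep(4e6, 200)))
  out <- classify_outcome(co)
  expect_identical(out$verdict, "coexistence")
  expect_identical(out$dominant, "S1")
  ex <- mk_traj(t, cbind(S1 = rep(1e7, 200),
                         S2 = 1e5 * exp(-0.5 * t)))
  expect_identical(classify_outcome(ex)$verdict, "S1_excludes")
  single <- mk_traj(t, cbind(S1 = 1e5 * exp(0.2 * t)))
  expect_identical(classify_outcome(single)$verdict, "coexistence")
})

test_that("monoculture fits recover exponential and logistic parameters", {
  t <- seq(0, 12, length.out = 120)
  ref <- mk_traj(t, cbind(S1 = 2e4 * exp(0.4321 * t)))
  fit <- fit_monoculture(ref, "exponential")
  expect_equal(fit$monoculture$r0, 0.4321, tolerance = 1e-4)
  expect_lt(fit$dbar_train, 1e-4)
  lg <- logistic_lv_spec("S1", 0.5, matrix(2e7))
  ref2 <- simulate_pairwise(lg, c(S1 = 1e4), 50, n_out = 200)
  fit2 <- fit_monoculture(ref2, "logistic")
  expect_equal(fit2$monoculture$r0, 0.5, tolerance = 1e-3)
  expect_equal(fit2$monoculture$Lambda, 2e7, tolerance = 1e-3)
})

test_that("interaction fits recover parameters within the model class", {
  sp <- c("S1", "S2")
  r <- matrix(c(NA, NA, 0.31, NA), 2, 2, byrow = TRUE)
  K <- matrix(c(NA, NA, 2.4e6, NA), 2, 2, byrow = TRUE)
  truth <- saturable_lv_spec(sp, c(0.5, 0.3), r, K)
  ref <- simulate_pairwise(truth, c(S1 = 1e5, S2 = 1e5), 12,
                           n_out = 300)
  fit <- fit_interaction(ref, "saturable_lv", c(S1 = 0.5, S2 = 0.3),
                         window = c(0, 12), pairs = list(c("S2", "S1")),
                         seed = 3)
  expect_equal(fit$spec$r[2, 1], 0.31, tolerance = 1e-3)
  expect_equal(fit$spec$K[2, 1], 2.4e6, tolerance = 1e-2)
  expect_true(fit$converged)
  # prediction of a within-class fit scores like its training window
  ps <- predict_and_score(fit, ref, c(6, 12))
  expect_lt(ps$dbar_test, 1e-3)
  expect_true(ps$match)
})

test_that("staged fitting freezes monoculture parameters", {
  # the interaction fit leaves basal fitness exactly as supplied
  sp <- c("S1", "S2")
  truth <- divided_spec(sp, c(0.5, 0.3), rho = 0.17)
  ref <- simulate_pairwise(truth, c(S1 = 1e5, S2 = 2e5), 15,
                           n_out = 200)
  fit <- fit_interaction(ref, "divided_simplified",
                         c(S1 = 0.5, S2 = 0.3), window = c(0, 15),
                         seed = 2, n_starts = 2)
  expect_equal(unname(fit$spec$r0), c(0.5, 0.3))
  expect_equal(fit$spec$rho, 0.17, tolerance = 1e-3)
})
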