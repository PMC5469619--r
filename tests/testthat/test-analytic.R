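test_that("regime classification partitions the parameter space", {
  expect_identical(classify_case(pair_params(r10 = 0.5, r20 = 0.1,
                                             rS2C1 = 0.3)), "I")
  expect_identical(classify_case(pair_params(r10 = 0.5, r20 = 0.3,
                                             rS2C1 = 0.5)), "II")
  expect_identical(classify_case(pair_params(r10 = 0.1, r20 = 0.5,
                                             rS2C1 = 0.3)), "III")
  expect_identical(classify_case(pair_params(r10 = 0.5, r20 = 0.5,
                                             rS2C1 = 0.3)), "boundary")
  expect_identical(classify_case(pair_params(r10 = 0.5, r20 = 0.2,
                                             rS2C1 = 0.3)), "boundary")
  expect_error(classify_case(single_mediator_params(
    -0.1, 0.3, 0.3, 1, 1e-6, 1e-6, 1)), "basal")
  # every generated config maps to exactly one case
  for (seed in 1:10)
    expect_true(classify_case(generate_regime_config("caseII", seed))
                %in% "II")
})

test_that("the closed-form steady state equalises the growth rates", {
  p <- pair_params(r10 = 0.47, r20 = 0.29, rS2C1 = 0.33,
                   K_S2C1 = 2.2, beta = 3e-7, alpha = 8e-7,
                   K_C1S2 = 0.7)
  ss <- steady_state(p)
  g2 <- p$r20 + p$rS2C1 * ss[["C1_star"]] /
    (ss[["C1_star"]] + p$K_S2C1)
  expect_equal(g2, p$r10, tolerance = 1e-12)
  # r10 -> r20+ limit: C1* -> 0 and RS* -> infinity
  p2 <- pair_params(r10 = 0.3 + 1e-6, r20 = 0.3, rS2C1 = 0.4)
  ss2 <- steady_state(p2)
  expect_lt(ss2[["C1_star"]], 1e-5)
  expect_gt(ss2[["RS_star"]], 1e4)
  expect_error(steady_state(pair_params(r10 = 0.5, r20 = 0.1,
                                        rS2C1 = 0.2)), "Case II")
})

test_that("derived saturable potency scales inversely with production", {
  p1 <- pair_params(kind = "reusable", beta = 1e-6)
  p2 <- pair_params(kind = "reusable", beta = 2e-6)
  s1 <- derive_reusable_lv(p1)
  s2 <- derive_reusable_lv(p2)
  expect_equal(s2$K[2, 1], s1$K[2, 1] / 2)
  expect_equal(s1$r[2, 1], p1$rS2C1)
})

test_that("alternative-model constants follow from the kinetic constants", {
  p <- pair_params(K_S2C1 = 1, K_C1S2 = 1)
  alt <- derive_alternative(p)
  expect_equal(alt$omega, 0)
  expect_equal(attr(alt, "rho"), p$rS2C1 * p$beta / p$alpha)
  p2 <- pair_params(K_S2C1 = 0.5, K_C1S2 = 2, alpha = 2e-6,
                    beta = 1e-6)
  alt2 <- derive_alternative(p2)
  expect_equal(alt2$omega, 1 - 0.5 / 2)
  expect_equal(alt2$psi, 0.5 * 2e-6 / (2 * 1e-6))
  # the full mediator-elimination expression and the compact form agree
  S1 <- 3e5; S2 <- 7e5
  full <- p2$rS2C1 * p2$beta * p2$K_C1S2 * S1 /
    (p2$beta * (p2$K_C1S2 - p2$K_S2C1) * S1 +
       p2$alpha * p2$K_S2C1 * S2)
  compact <- p2$rS2C1 * S1 / (alt2$omega * S1 + alt2$psi * S2)
  expect_equal(full, compact, tolerance = 1e-12)
})

test_that("the f-zero-isocline passes through the fixed point", {
  p <- pair_params()
  expect_equal(f_zero_isocline(p, 1), 1)
  Khat <- p$K_C1S2 / steady_state(p)[["C1_star"]]
  expect_equal(f_zero_isocline(p, 1e9), 1 / (1 + Khat),
               tolerance = 1e-6)
  # consumer-takeover regime: unscaled asymptote beta/alpha
  p3 <- pair_params(r10 = 0.2, r20 = 0.5, beta = 1e-6, alpha = 2e-6)
  expect_equal(f_zero_isocline(p3, 1e9), 1e-6 / 2e-6, tolerance = 1e-6)
  # along a converged mechanistic trajectory, f is near zero
  cfg <- pair_config(init = c(S1 = 1e7, S2 = 1e7))
  ph <- phase_trace(cfg, t_end = 80)
  expect_lt(abs(tail(ph$f, 1)), 0.01)
})

test_that("convergence-time estimates scale as derived", {
  p <- pair_params()
  a <- estimate_tf(p, 1e4, 4e7)
  b <- estimate_tf(p, 1e4, 8e7)
  expect_identical(a$subcase, "II-1")
  expect_equal(a$t_f / 2, b$t_f)   # t_f proportional to 1/S2(0)
  # consumer-takeover dilute-consumer estimate grows logarithmically
  p3 <- pair_params(r10 = 0.2, r20 = 0.5)
  t1 <- estimate_tf(p3, 1e7, 1e7 * 1e-3)$t_f
  t2 <- estimate_tf(p3, 1e7, 1e7 * 1e-4)$t_f
  expect_equal(t2 - t1, log(10) / (0.5 - 0.2), tolerance = 1e-9)
  # monotone: smaller initial ratio, longer approach
  expect_gt(t2, t1)
  # the mediator-accumulation regime has no isocline to approach
  pI <- pair_params(r10 = 0.6, r20 = 0.1, rS2C1 = 0.2)
  tfI <- estimate_tf(pI, 1e6, 1e6)
  expect_identical(tfI$subcase, "I")
  expect_true(is.na(tfI$t_f) && tfI$acclimation > 0)
})

test_that("alternative-model convergence verdicts follow the singularity", {
  expect_true(check_alt_convergence(0.5, 0.25, 10, "II")$converges)
  v <- check_alt_convergence(-1, 1, 0.5, "II")
  expect_false(v$converges)
  expect_identical(v$verdict, "false_extinction")
  v2 <- check_alt_convergence(-9, 5, 1, "III")
  expect_identical(v2$verdict, "false_coexistence")
  expect_identical(check_alt_convergence(0.8, 0.1, 1, "III")$verdict,
                   "S1_exclusion")
  # direct integration agrees for a convergent and a divergent set
  ok <- integrate_ratio_ode(0.5, 0.3, 0.4, 0.5, 0.25, RS_0 = 0.1)
  expect_identical(ok$behaviour, "converged")
  bad <- integrate_ratio_ode(0.5, 0.3, 0.4, -1, 1, RS_0 = 0.5)
  expect_identical(bad$behaviour, "extinction")
})

test_that("two-mediator influences reduce only under similarity or dominance", {
  # equal potencies: exact single-term representation with summed effect
  r <- two_mediator_reducibility(0.5, 0.2, 0.3, 1, 1, 5e-7, 5e-7)
  expect_true(r$reducible)
  expect_identical(r$reason, "similar_potency")
  expect_equal(r$single$r21, 0.5)
  KC <- 1 * 0.5 / 5e-7
  expect_equal(r$combined_effect(KC), 0.5 * KC / (KC + KC) * 2 / 2)
  # one vanishing term: dominance
  r2 <- two_mediator_reducibility(0.5, 0.3, 0, 1, 1, 1e-6, 1e-8)
  expect_true(r2$reducible)
  expect_identical(r2$reason, "dominance")
  # dissimilar potencies with comparable strengths: irreducible
  r3 <- two_mediator_reducibility(0.5, 0.3, -0.31, 1e3 * 1e-6 / 0.5,
                                  1e5 * 1e-6 / 0.5, 1e-6, 1e-6)
  expect_false(r3$reducible)
  expect_equal(r3$K_C1, 1e3)
  expect_equal(r3$K_C2, 1e5)
})

test_that("regime reports assemble the analytic summary", {
  cfg <- pair_config(init = c(S1 = 1e7, S2 = 1e7))
  rep <- regime_report(cfg, 1e7, 1e7)
  expect_identical(rep$case, "II")
  expect_identical(rep$recommended_form, "alternative")
  expect_true(rep$converges)
  expect_gt(rep$C1_star, 0)
  repI <- regime_report(pair_params(r10 = 0.6, r20 = 0.1, rS2C1 = 0.2))
  expect_identical(repI$recommended_form, "saturable_lv")
})
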