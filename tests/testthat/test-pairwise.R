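sp2 <- c("S1", "S2")

test_that("linear form reduces to exponential growth without terms", {
  spec <- linear_lv_spec(sp2, c(0.4, 0.2), matrix(0, 2, 2))
  tr <- simulate_pairwise(spec, c(S1 = 100, S2 = 10), 8)
  expect_equal(tr$species[nrow(tr$species), ],
               c(S1 = 100 * exp(0.4 * 8), S2 = 10 * exp(0.2 * 8)),
               tolerance = 1e-6)
})

test_that("logistic parameters map onto the linear form", {
  # logistic r0 (1 - sum Sj/Lij) equals linear with r_ij = -r0/Lij
  r0 <- c(0.5, 0.3)
  L <- matrix(c(1e7, 3e7, 2e7, 5e6), 2, 2)
  lg <- logistic_lv_spec(sp2, r0, L)
  ln <- linear_lv_spec(sp2, r0, -r0 / L)
  init <- c(S1 = 1e5, S2 = 3e5)
  t1 <- simulate_pairwise(lg, init, 30)
  t2 <- simulate_pairwise(ln, init, 30)
  expect_equal(t1$species, t2$species, tolerance = 1e-8)
})

test_that("single-species logistic settles at its carrying capacity", {
  lg <- logistic_lv_spec("S1", 0.5, matrix(2e7))
  tr <- simulate_pairwise(lg, c(S1 = 1e4), 60)
  expect_equal(unname(tr$species[nrow(tr$species), 1]), 2e7,
               tolerance = 1e-6)
  # at S = Lambda the derivative vanishes
  rhs <- pairwise_rhs(lg)
  expect_equal(eval_rhs(rhs, 2e7), 0)
})

test_that("two-species logistic equilibrium matches the isocline solution", {
  L <- matrix(c(1e7, 4e7, 3e7, 2e7), 2, 2, byrow = TRUE)  # [i,j]
  lg <- logistic_lv_spec(sp2, c(0.5, 0.4), L)
  tr <- simulate_pairwise(lg, c(S1 = 1e5, S2 = 1e5), 400)
  # solve 1 - S1/L11 - S2/L12 = 0, 1 - S1/L21 - S2/L22 = 0
  A <- rbind(c(1 / L[1, 1], 1 / L[1, 2]), c(1 / L[2, 1], 1 / L[2, 2]))
  eq <- solve(A, c(1, 1))
  expect_equal(unname(tr$species[nrow(tr$species), ]), eq,
               tolerance = 1e-4)
})

test_that("the saturable term halves at its half-saturation density", {
  r <- matrix(c(NA, NA, 0.3, NA), 2, 2, byrow = TRUE)
  K <- matrix(c(NA, NA, 1e6, NA), 2, 2, byrow = TRUE)
  spec <- saturable_lv_spec(sp2, c(0.5, 0.2), r, K)
  rhs <- pairwise_rhs(spec)
  dy <- eval_rhs(rhs, c(1e6, 1e3))
  expect_equal(dy[2] / 1e3, 0.2 + 0.3 / 2, tolerance = 1e-12)
})

test_that("the saturable form approaches the linear form at low density", {
  r <- matrix(c(NA, NA, 0.3, NA), 2, 2, byrow = TRUE)
  K <- matrix(c(NA, NA, 1e8, NA), 2, 2, byrow = TRUE)
  sat <- saturable_lv_spec(sp2, c(0.3, 0.2), r, K)
  lin <- linear_lv_spec(sp2, c(0.3, 0.2),
                        matrix(c(NA, NA, 0.3 / 1e8, NA), 2, 2,
                               byrow = TRUE))
  init <- c(S1 = 1e4, S2 = 1e4)
  t1 <- simulate_pairwise(sat, init, 15)
  t2 <- simulate_pairwise(lin, init, 15)
  # influencer stays below K/100, so the two differ by < 1%
  expect_lt(max(abs(log(t1$species / t2$species))), 0.01)
})

test_that("alternative form with omega = 0 equals the divided form", {
  alt <- alternative_spec(sp2, c(0.5, 0.3), r21 = 0.4, omega = 0,
                          psi = 2)
  div <- divided_spec(sp2, c(0.5, 0.3), rho = 0.4 / 2)
  init <- c(S1 = 1e5, S2 = 2e5)
  t1 <- simulate_pairwise(alt, init, 40)
  t2 <- simulate_pairwise(div, init, 40)
  expect_lt(max(abs(log(t1$species / t2$species))), 1e-6)
})

test_that("divided-form steady state sits at rho/(r10 - r20)", {
  div <- divided_spec(sp2, c(0.5, 0.3), rho = 0.1)
  tr <- simulate_pairwise(div, c(S1 = 1e5, S2 = 1e5), 80,
                          dilution = turbidostat10())
  RS <- tr$species[, "S2"] / tr$species[, "S1"]
  expect_equal(tail(RS, 1), 0.1 / (0.5 - 0.3), tolerance = 1e-3)
})

test_that("psi must be positive and the form set is closed", {
  expect_error(alternative_spec(sp2, c(0.5, 0.3), 0.4, 0.5, psi = 0),
               "psi")
  expect_error(saturable_lv_spec(sp2, c(0.5, 0.3),
                                 matrix(0.3, 2, 2),
                                 matrix(c(1, 1, NA, 1), 2, 2)), "K")
})

test_that("competitive-commensal form reduces to logistic when decoupled", {
  # with r21 = 0 and d = 0, dSi/dt = bi0 (1 - sum Sj/Lij) Si
  L <- matrix(c(1e7, 4e7, 3e7, 2e7), 2, 2, byrow = TRUE)
  cc <- competitive_commensal_spec(sp2, b0 = c(0.5, 0.4), d = c(0, 0),
                                   L = L, r21 = 0)
  lg <- logistic_lv_spec(sp2, c(0.5, 0.4), L)
  init <- c(S1 = 1e5, S2 = 1e5)
  expect_equal(simulate_pairwise(cc, init, 60)$species,
               simulate_pairwise(lg, init, 60)$species,
               tolerance = 1e-8)
  # shared-resource exhaustion zeroes the birth term regardless of S1
  cc2 <- competitive_commensal_spec(sp2, b0 = c(0.5, 0.4),
                                    d = c(0.05, 0.02), L = L, r21 = 1e-8)
  rhs <- pairwise_rhs(cc2)
  S2 <- 1e6
  S1 <- L[2, 1] * (1 - S2 / L[2, 2])  # 1 - S1/L21 - S2/L22 = 0
  dy <- eval_rhs(rhs, c(S1, S2))
  expect_equal(dy[2], -0.02 * S2, tolerance = 1e-9)
})

test_that("fitness terms ignore uninvolved species", {
  # perturbing S3 must not change the S1<-S2 terms of a pair component
  r <- matrix(c(NA, 0.2, NA, NA), 2, 2, byrow = TRUE)
  K <- matrix(c(NA, 1e6, NA, NA), 2, 2, byrow = TRUE)
  s12 <- saturable_lv_spec(sp2, c(0.5, 0.3), r, K)
  s3 <- saturable_lv_spec(c("S3"), 0.1, matrix(NA_real_),
                          matrix(NA_real_))
  asm <- assemble_multispecies(list(s12, s3))
  rhs <- medlv:::assembly_rhs(asm)
  d1 <- eval_rhs(rhs, c(1e5, 2e5, 1e3))
  d2 <- eval_rhs(rhs, c(1e5, 2e5, 1e7))
  expect_equal(d1[1:2], d2[1:2])
})

test_that("assembly rejects conflicting basal fitness", {
  a <- saturable_lv_spec(sp2, c(0.5, 0.3), matrix(NA_real_, 2, 2),
                         matrix(NA_real_, 2, 2))
  b <- saturable_lv_spec(c("S2", "S3"), c(0.35, 0.2),
                         matrix(NA_real_, 2, 2),
                         matrix(NA_real_, 2, 2))
  expect_error(assemble_multispecies(list(a, b)), "basal fitness")
})

test_that("assemblies with no interaction terms are independent exponentials", {
  a <- saturable_lv_spec(sp2, c(0.5, 0.3), matrix(NA_real_, 2, 2),
                         matrix(NA_real_, 2, 2))
  b <- saturable_lv_spec(c("S2", "S3"), c(0.3, 0.2),
                         matrix(NA_real_, 2, 2),
                         matrix(NA_real_, 2, 2))
  asm <- assemble_multispecies(list(a, b))
  tr <- simulate_pairwise(asm, c(S1 = 10, S2 = 20, S3 = 30), 5)
  expect_equal(unname(tr$species[nrow(tr$species), ]),
               c(10 * exp(0.5 * 5), 20 * exp(0.3 * 5), 30 * exp(0.2 * 5)),
               tolerance = 1e-7)
})

test_that("positive initial densities stay positive in every form", {
  init <- c(S1 = 1e4, S2 = 1e4)
  specs <- list(
    linear_lv_spec(sp2, c(0.5, -0.4),
                   matrix(c(NA, -1e-8, 1e-9, NA), 2, 2, byrow = TRUE)),
    logistic_lv_spec(sp2, c(0.5, 0.4),
                     matrix(c(1e6, 2e6, 4e6, 1e6), 2, 2)),
    alternative_spec(sp2, c(0.5, 0.3), 0.4, omega = 0.5, psi = 0.5),
    divided_spec(sp2, c(0.5, 0.3), rho = 0.2))
  for (spec in specs) {
    tr <- simulate_pairwise(spec, init, 30)
    expect_gt(min(tr$species), 0)
  }
})

test_that("predator-prey signs in the linear form give cycles", {
  r <- matrix(c(NA, -1e-6, 5e-7, NA), 2, 2, byrow = TRUE)
  spec <- linear_lv_spec(c("prey", "pred"), c(0.5, -0.3), r)
  tr <- simulate_pairwise(spec, c(prey = 1e5, pred = 1e5), 120,
                          n_out = 2000)
  prey <- tr$species[, "prey"]
  # oscillations: multiple local maxima returning near the start level
  pk <- which(diff(sign(diff(prey))) == -2) + 1
  expect_gte(length(pk), 3)
  expect_equal(log(prey[pk[3]]), log(prey[pk[1]]), tolerance = 0.05)
})
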