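test_that("trajectories round-trip through the tidy text format", {
  cfg <- pair_config(dilution = turbidostat10())
  tr <- simulate_community(cfg, 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  expect_true(file.exists(paste0(f, ".meta.json")))
  back <- read_trajectory(f)
  expect_equal(back$times, tr$times)
  expect_equal(back$species, tr$species)
  expect_equal(back$mediators, tr$mediators)
  expect_equal(back$dilution_times, tr$dilution_times)
})

test_that("interpolation and state extraction are consistent", {
  t <- seq(0, 10, length.out = 100)
  tr <- medlv:::new_trajectory(t, cbind(S1 = exp(t), S2 = 2 * exp(t)))
  at <- trajectory_at(tr, c(2.5, 7.5))
  expect_equal(dim(at), c(2L, 2L))
  expect_equal(unname(at[1, "S2"] / at[1, "S1"]), 2, tolerance = 1e-9)
  st <- trajectory_state(tr, 5)
  expect_named(st, c("S1", "S2"))
  expect_error(trajectory_at(tr, 11), "outside")
  fr <- species_fractions(tr)
  expect_equal(unname(fr[1, ]), c(1, 2) / 3)
})
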