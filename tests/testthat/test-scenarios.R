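test_that("every shipped scenario fixture loads and validates", {
  nms <- scenario_names()
  expect_gte(length(nms), 15L)
  for (nm in nms) {
    sc <- load_scenario(nm)
    expect_identical(sc$name, nm)
    expect_true(is.list(sc$expect) && length(sc$expect) > 0)
    for (fld in intersect(c("config", "config_low", "config_high"),
                          names(sc)))
      expect_s3_class(sc[[fld]], "community_config")
  }
})

test_that("the derived assembly mirrors the mechanistic topology", {
  cfg <- load_scenario("chain3")$config
  asm <- derive_pairwise_assembly(cfg)
  expect_identical(asm$species, c("S1", "S2", "S3"))
  expect_length(asm$terms, 2L)
  cfg2 <- load_scenario("mod_consume")$config
  asm2 <- derive_pairwise_assembly(cfg2)
  expect_length(asm2$terms, 2L)  # S1->S2 and S1->S3, nothing for S2-S3
  forms <- vapply(asm2$components, `[[`, "", "form")
  expect_true(all(forms == "alternative"))
})

test_that("cheap scenario presets run end to end and pass", {
  r <- run_scenario("alt_convergence")
  expect_true(r$pass)
  r2 <- run_scenario("caseIII_takeover")
  expect_true(r2$pass)
  expect_identical(r2$observed$verdict, "S2_excludes")
})

test_that("the scenario harness reports are well-formed", {
  out <- run_all_scenarios(c("alt_convergence", "caseIII_takeover"),
                           report_path = withr::local_tempfile(
                             fileext = ".json"))
  expect_identical(nrow(out), 2L)
  expect_true(all(out$pass))
  # empty scenario list gives an empty report
  empty <- run_all_scenarios(character(0))
  expect_identical(nrow(empty), 0L)
})
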