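# Scenario presets: each fixture file declares a mechanistic community
# (or two density variants), the training/test protocol, and the expected
# qualitative outcome.  run_scenario() executes the
# generate -> simulate -> fit/derive -> predict -> score pipeline and
# compares the observed outcome against the declared expectation.

#' Names of the shipped scenario fixtures
#'
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() {
  dir <- system.file("extdata", "scenarios", package = "medlv")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

scenario_file <- function(name) {
  f <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                   package = "medlv")
  if (!nzchar(f)) stop("scenario fixture '", name, "' not found")
  f
}

#' Load a scenario fixture
#'
#' @param name Scenario name (see [scenario_names()]).
#' @return List with `name`, `type`, `expect` (the declared expectation),
#'   `params`, and the parsed `config` (or `config_low` / `config_high`).
#' @export
load_scenario <- function(name) {
  raw <- yaml::read_yaml(scenario_file(name))
  for (fld in intersect(c("config", "config_low", "config_high"),
                        names(raw)))
    raw[[fld]] <- config_from_list(raw[[fld]])
  raw
}

#' Run a scenario preset
#'
#' Executes the scenario's full pipeline and scores the observed outcome
#' against the expectation declared in the fixture.
#'
#' @param name Scenario name.
#' @param seed Seed for the fitting multi-starts.
#' @return A `scenario_result`: list with `name`, `type`, `expect`,
#'   `observed` (named values), and `pass`.
#' @export
run_scenario <- function(name, seed = 1) {
  sc <- load_scenario(name)
  runner <- switch(sc$type,
    reusable_exact = run_reusable_exact,
    case1 = run_case1,
    case2_windows = run_case2_windows,
    case3 = run_case3,
    alt_convergence = run_alt_convergence,
    density_flip = run_density_flip,
    two_mediator = run_two_mediator,
    competitive_commensal = run_competitive_commensal,
    assembly = run_assembly,
    stop("unknown scenario type '", sc$type, "'"))
  res <- runner(sc, seed)
  structure(c(list(name = sc$name, type = sc$type, expect = sc$expect),
              res),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result '", x$name, "'> pass: ", x$pass, "\n", sep = "")
  for (nm in names(x$observed))
    cat("  ", nm, ": ", format(x$observed[[nm]], digits = 4), "\n",
        sep = "")
  invisible(x)
}

#' Run every shipped scenario
#'
#' @param names Scenarios to run (default: all).
#' @param seed Fitting seed.
#' @param report_path Optional path; when given, a machine-readable JSON
#'   report and a tab-separated summary (`<path>.tsv`) are written.
#' @return Data frame with one row per scenario (name, type, pass, and a
#'   compact observed-value summary).
#' @export
run_all_scenarios <- function(names = scenario_names(), seed = 1,
                              report_path = NULL) {
  results <- lapply(names, run_scenario, seed = seed)
  df <- data.frame(
    scenario = names,
    type = vapply(results, `[[`, "", "type"),
    pass = vapply(results, function(r) isTRUE(r$pass), TRUE),
    observed = vapply(results, function(r)
      paste(names(r$observed), vapply(r$observed, function(v)
        format(v, digits = 3), ""), sep = "=", collapse = "; "), ""),
    stringsAsFactors = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      lapply(results, function(r)
        list(name = r$name, type = r$type, pass = isTRUE(r$pass),
             observed = r$observed)),
      report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(df, paste0(report_path, ".tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  df
}

# ---- runners ------------------------------------------------------------

run_reusable_exact <- function(sc, seed) {
  cfg <- sc$config
  p <- as_single_mediator(cfg)
  pr <- sc$params
  tr <- simulate_community(cfg, pr$t_end, n_out = 800)
  spec <- derive_reusable_lv(cfg)
  test_win <- c(pr$acclimation,
                pr$acclimation + pr$test_generations * log(2) / p$r10)
  ps <- predict_and_score(spec, tr, test_win, dilution = cfg$dilution,
                          S_ext = cfg$S_ext)
  fit_win <- c(pr$acclimation,
               pr$acclimation + 10 * log(10) / p$r10)
  fit <- fit_interaction(tr, "saturable_lv",
                         r0 = setNames(c(p$r10, p$r20),
                                       c(p$producer, p$consumer)),
                         window = fit_win,
                         pairs = list(c(p$consumer, p$producer)),
                         dilution = cfg$dilution, S_ext = cfg$S_ext,
                         seed = seed)
  r21_err <- abs(fit$spec$r[2, 1] - spec$r[2, 1]) / abs(spec$r[2, 1])
  K21_err <- abs(fit$spec$K[2, 1] - spec$K[2, 1]) / spec$K[2, 1]
  obs <- list(dbar_derived = ps$dbar_test, r21_rel_err = r21_err,
              K21_rel_err = K21_err)
  list(observed = obs,
       pass = ps$dbar_test < sc$expect$dbar_max &&
         r21_err < sc$expect$param_rel_err_max &&
         K21_err < sc$expect$param_rel_err_max,
       fit = fit, derived = spec)
}

run_case1 <- function(sc, seed) {
  cfg <- sc$config
  p <- as_single_mediator(cfg)
  pr <- sc$params
  tr <- simulate_community(cfg, pr$t_end, n_out = 700)
  acc <- 10 * estimate_tf(p, cfg$init[[p$producer]],
                          cfg$init[[p$consumer]])$acclimation
  C1 <- approx(tr$times, tr$mediators[, p$mediator], xout = acc)$y
  S1 <- approx(tr$times, tr$species[, p$producer], xout = acc)$y
  target <- p$beta / p$r10
  ratio_err <- abs(C1 / S1 - target) / target
  horizon <- c(pr$horizon_start, pr$t_end)
  sat <- predict_and_score(derive_reusable_lv(p), tr, horizon,
                           dilution = cfg$dilution, S_ext = cfg$S_ext)
  alt <- predict_and_score(derive_alternative(p), tr, horizon,
                           dilution = cfg$dilution, S_ext = cfg$S_ext)
  obs <- list(c1_s1_rel_err = ratio_err, sat_dbar = sat$dbar_test,
              alt_dbar = alt$dbar_test,
              sat_match = sat$match)
  list(observed = obs,
       pass = ratio_err < sc$expect$ratio_err_max &&
         sat$dbar_test < sc$expect$sat_dbar_max &&
         alt$dbar_test > sc$expect$alt_dbar_min && sat$match)
}

run_case2_windows <- function(sc, seed) {
  cfg <- sc$config
  p <- as_single_mediator(cfg)
  pr <- sc$params
  r0 <- setNames(c(p$r10, p$r20), c(p$producer, p$consumer))
  tr <- simulate_community(cfg, pr$t_end, n_out = 900)
  wins <- lapply(pr$train_windows, unlist)
  fits <- lapply(wins, function(w) list(
    sat = fit_interaction(tr, "saturable_lv", r0, w,
                          pairs = list(c(p$consumer, p$producer)),
                          dilution = cfg$dilution, S_ext = cfg$S_ext,
                          seed = seed),
    alt = fit_interaction(tr, "alternative", r0, w,
                          dilution = cfg$dilution, S_ext = cfg$S_ext,
                          seed = seed)))
  total0 <- sum(cfg$init)
  alt_dbars <- c(); alt_ok <- TRUE; sat_wrong_altered <- FALSE
  for (RS0 in unlist(pr$test_ratios)) {
    init <- c(total0 / (1 + RS0), total0 * RS0 / (1 + RS0))
    names(init) <- c(p$producer, p$consumer)
    cfg2 <- cfg
    cfg2$init <- init
    tr2 <- simulate_community(cfg2, pr$test_t_end, n_out = 500)
    for (k in seq_along(fits)) {
      pa <- predict_and_score(fits[[k]]$alt, tr2,
                              c(0, pr$test_t_end), init = init,
                              dilution = cfg$dilution, S_ext = cfg$S_ext)
      alt_dbars <- c(alt_dbars, pa$dbar_test)
      alt_ok <- alt_ok && pa$match &&
        pa$outcome_pair$verdict == "coexistence"
    }
    psat <- predict_and_score(fits[[pr$steady_window]]$sat, tr2,
                              c(0, pr$test_t_end), init = init,
                              dilution = cfg$dilution, S_ext = cfg$S_ext)
    if (!psat$match) sat_wrong_altered <- TRUE
  }
  obs <- list(alt_dbar_max = max(alt_dbars), alt_ok = alt_ok,
              sat_wrong_at_altered_ratio = sat_wrong_altered)
  list(observed = obs,
       pass = max(alt_dbars) < sc$expect$alt_dbar_max && alt_ok &&
         sat_wrong_altered,
       fits = fits)
}

run_case3 <- function(sc, seed) {
  cfg <- sc$config
  pr <- sc$params
  tr <- simulate_community(cfg, pr$t_end, n_out = 500)
  ph <- phase_trace(cfg, traj = tr)
  alt <- predict_and_score(derive_alternative(cfg), tr, c(0, pr$t_end),
                           init = cfg$init, dilution = cfg$dilution,
                           S_ext = cfg$S_ext)
  obs <- list(RS_final = ph$RS[nrow(ph)], C1_final = ph$C1[nrow(ph)],
              alt_dbar = alt$dbar_test,
              verdict = classify_outcome(tr)$verdict)
  list(observed = obs,
       pass = obs$RS_final > sc$expect$RS_min &&
         obs$C1_final < sc$expect$C1_max &&
         alt$dbar_test < sc$expect$alt_dbar_max &&
         obs$verdict == sc$expect$verdict)
}

run_alt_convergence <- function(sc, seed) {
  ok <- TRUE
  obs <- list()
  for (set in sc$params$sets) {
    v <- check_alt_convergence(set$omega, set$psi, set$RS0, set$case)
    ode <- integrate_ratio_ode(set$r10, set$r20, set$rS2C1,
                               set$omega, set$psi, set$RS0,
                               t_end = set$t_end %||% 500)
    agreed <- switch(v$verdict,
      coexistence = ode$behaviour == "converged" && ode$final > 0.01,
      S1_exclusion = ode$behaviour == "unbounded",
      false_extinction = ode$behaviour == "extinction",
      false_coexistence = ode$behaviour == "converged")
    obs[[set$label]] <- v$verdict
    ok <- ok && agreed && identical(v$verdict, set$expected_verdict)
  }
  list(observed = obs, pass = ok)
}

run_density_flip <- function(sc, seed) {
  pr <- sc$params
  p <- as_single_mediator(sc$config_low)
  sat <- derive_reusable_lv(p)
  alt <- derive_alternative(p)
  score <- function(cfg) {
    tr <- simulate_community(cfg, pr$t_end, n_out = 600)
    h <- c(pr$horizon_start, pr$t_end)
    c(sat = predict_and_score(sat, tr, h, dilution = cfg$dilution,
                              S_ext = cfg$S_ext)$dbar_test,
      alt = predict_and_score(alt, tr, h, dilution = cfg$dilution,
                              S_ext = cfg$S_ext)$dbar_test)
  }
  lo <- score(sc$config_low)
  hi <- score(sc$config_high)
  obs <- list(low_sat_dbar = lo[["sat"]], low_alt_dbar = lo[["alt"]],
              high_sat_dbar = hi[["sat"]], high_alt_dbar = hi[["alt"]])
  list(observed = obs,
       pass = lo[["sat"]] < lo[["alt"]] && hi[["alt"]] < hi[["sat"]])
}

run_two_mediator <- function(sc, seed) {
  pr <- sc$params
  lo <- sc$config_low
  hi <- sc$config_high
  r0 <- setNames(vapply(lo$species, `[[`, 0, "r0"),
                 config_species_ids(lo))
  tlo <- simulate_community(lo, pr$t_end_low, n_out = 800)
  thi <- simulate_community(hi, pr$t_end_high, n_out = 600)
  w <- unlist(pr$train_window)
  flo <- fit_interaction(tlo, "saturable_lv", r0, w,
                         pairs = list(c("S2", "S1")),
                         dilution = lo$dilution, S_ext = lo$S_ext,
                         seed = seed, n_starts = 4)
  fhi <- fit_interaction(thi, "saturable_lv", r0, w,
                         pairs = list(c("S2", "S1")),
                         dilution = hi$dilution, S_ext = hi$S_ext,
                         seed = seed, n_starts = 4)
  h <- c(w[2], pr$t_end_low)
  plo <- predict_and_score(flo, tlo, h, dilution = lo$dilution,
                           S_ext = lo$S_ext)
  phi <- predict_and_score(fhi, tlo, h, dilution = lo$dilution,
                           S_ext = lo$S_ext)
  tm <- two_mediator_params(lo)
  red <- two_mediator_reducibility(tm$r10, tm$rS2C1, tm$rS2C2,
                                   tm$K_S2C1, tm$K_S2C2,
                                   tm$beta1, tm$beta2)
  obs <- list(r21_low = flo$spec$r[2, 1], r21_high = fhi$spec$r[2, 1],
              low_fit_on_low_dbar = plo$dbar_test,
              low_fit_match = plo$match,
              high_fit_on_low_dbar = phi$dbar_test,
              high_fit_verdict = phi$outcome_pair$verdict,
              reducible = red$reducible)
  list(observed = obs,
       pass = obs$r21_low > 0 && obs$r21_high < 0 &&
         plo$dbar_test < sc$expect$low_fit_dbar_max && plo$match &&
         !phi$match && !red$reducible,
       fits = list(low = flo, high = fhi))
}

run_competitive_commensal <- function(sc, seed) {
  cfg <- sc$config
  pr <- sc$params
  r0 <- setNames(vapply(cfg$species, `[[`, 0, "r0"),
                 config_species_ids(cfg))
  tr <- simulate_community(cfg, pr$t_end, n_out = 700)
  # Step 1: monoculture fit of the producer (logistic rise to its
  # resource-limited capacity); the death rates are taken from the
  # mechanistic basal fitnesses, and the obligate commensal consumer has
  # zero birth without its partner
  mono_cfg <- cfg
  mono_cfg$species <- cfg$species[1]
  mono_cfg$links <- Filter(function(l) l$species == "S1", cfg$links)
  mono_cfg$mediators <- Filter(function(m) {
    cons <- vapply(mono_cfg$links, function(l)
      l$mediator == m$id && l$role == "consumption", TRUE)
    any(cons) || m$supply > 0
  }, cfg$mediators)
  keep <- vapply(mono_cfg$links, function(l)
    l$mediator %in% vapply(mono_cfg$mediators, `[[`, "", "id"), TRUE)
  mono_cfg$links <- mono_cfg$links[keep]
  mono_cfg$init <- cfg$init["S1"]
  mono_tr <- simulate_community(mono_cfg, pr$t_end, n_out = 500)
  mono_tr$mediators <- NULL
  d <- abs(r0)
  mono <- fit_monoculture(mono_tr, "logistic",
                          window = c(0, pr$train_end), seed = seed)
  r10_eff <- mono$monoculture$r0
  L_eff <- mono$monoculture$Lambda
  b10 <- r10_eff + d[["S1"]]
  L11 <- L_eff / (1 - d[["S1"]] / b10)
  # Step 2: interaction fit with monoculture parameters frozen
  fit <- fit_interaction(tr, "competitive_commensal_lv",
                         r0 = c(S1 = b10 - d[["S1"]], S2 = -d[["S2"]]),
                         window = c(0, pr$train_end),
                         b0 = c(b10, 0), d = unname(d[c("S1", "S2")]),
                         L11 = L11, S_ext = cfg$S_ext, seed = seed,
                         n_starts = 6)
  ps <- predict_and_score(fit, tr, c(pr$train_end, pr$t_end),
                          S_ext = cfg$S_ext)
  obs <- list(dbar_train = fit$dbar_train, dbar_test = ps$dbar_test,
              verdict_pair = ps$outcome_pair$verdict,
              verdict_mech = ps$outcome_ref$verdict,
              match = ps$match)
  pass <- if (identical(sc$expect$outcome, "predicts")) {
    ps$match && ps$dbar_test < sc$expect$dbar_test_max
  } else {
    !ps$match || ps$dbar_test > sc$expect$dbar_test_min
  }
  list(observed = obs, pass = pass, fit = fit)
}

run_assembly <- function(sc, seed) {
  cfg <- sc$config
  pr <- sc$params
  tr <- simulate_community(cfg, pr$t_end, n_out = 700)
  asm <- derive_pairwise_assembly(cfg)
  h <- c(pr$horizon_start %||% 0, pr$t_end)
  ps <- predict_and_score(asm, tr, h,
                          init = if (h[1] == 0) cfg$init,
                          dilution = cfg$dilution, S_ext = cfg$S_ext)
  obs <- list(dbar = ps$dbar_test,
              verdict_pair = ps$outcome_pair$verdict,
              verdict_mech = ps$outcome_ref$verdict,
              match = ps$match)
  pass <- if (identical(sc$expect$outcome, "predicts")) {
    ps$match && ps$dbar_test < sc$expect$dbar_max
  } else {
    !ps$match && ps$dbar_test > sc$expect$dbar_min
  }
  list(observed = obs, pass = pass, assembly = asm,
       prediction = ps)
}
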