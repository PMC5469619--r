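# Seeded generation of community parameter sets falling into each analytic
# regime.  Sampling ranges follow the orders of magnitude of the study
# conditions: basal fitnesses of a few tenths per hour, half-saturation
# constants of order one concentration unit, per-cell production and
# consumption rates of order 1e-6, turbidostat cycles spanning a 10-fold
# density range.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)
rlog10 <- function(lo, hi) 10^stats::runif(1, lo, hi)

default_dilution <- function() {
  dilution_policy("turbidostat", threshold = 1e8, reset_total = 1e7)
}

# one consumable-mediator commensal pair with given fitness parameters
single_mediator_config <- function(r10, r20, rS2C1, K_S2C1, beta, alpha,
                                   K_C1S2, init,
                                   dilution = default_dilution(),
                                   S_ext = 1e-2, name = NULL,
                                   kind = "consumable") {
  links <- list(production_link("C1", "S1", beta),
                effect_link("C1", "S2", rS2C1, K_S2C1))
  if (kind == "consumable")
    links <- c(links, list(consumption_link("C1", "S2", alpha, K_C1S2)))
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20)),
    mediators = list(mediator_spec("C1", kind)),
    links = links, init = init, dilution = dilution, S_ext = S_ext,
    name = name)
}

#' Generate a community configuration in a given analytic regime
#'
#' Samples mechanistic parameters from documented ranges and verifies that
#' the regime's defining inequality holds (rejection sampling with a
#' bounded number of attempts).  Deterministic for a fixed
#' `(regime, seed)` pair; the caller's random-number state is left
#' untouched.
#'
#' Regimes:
#' * `"caseI"`, `"caseII"`, `"caseIII"`: the consumable-mediator commensal
#'   pair in the corresponding fitness regime (`r10 - r20 > rS2C1`,
#'   `rS2C1 > r10 - r20 > 0`, `r10 < r20`).
#' * `"two_reusable"`: one species influencing another via two reusable
#'   mediators of dissimilar potency (irreducible to one saturable term).
#' * `"competitive_commensal"`: two species competing for an abiotically
#'   supplied resource while the first feeds the second a consumable
#'   metabolite (batch environment, basal net death).
#' * `"chain3"`: three-species interaction chain S1 -> S2 -> S3 via two
#'   independent reusable mediators.
#' * `"modification_consume3"`: a third species consumes the mediator by
#'   which S1 stimulates S2 (interaction modification by mediator
#'   removal).
#' * `"modification_share3"`: S1 and S3 both release the strongly
#'   saturating mediator that stimulates S2 (interaction modification by
#'   shared production).
#'
#' @param regime One of the regimes above.
#' @param seed Integer seed.
#' @return A validated [community_config()].
#' @export
generate_regime_config <- function(regime = c("caseI", "caseII", "caseIII",
                                              "two_reusable",
                                              "competitive_commensal",
                                              "chain3",
                                              "modification_consume3",
                                              "modification_share3"),
                                   seed = 1) {
  regime <- match.arg(regime)
  with_seed(seed, {
    for (attempt in 1:100) {
      cfg <- switch(regime,
        caseI = sample_case(1, seed),
        caseII = sample_case(2, seed),
        caseIII = sample_case(3, seed),
        two_reusable = sample_two_reusable(seed),
        competitive_commensal = sample_competitive_commensal(seed),
        chain3 = sample_chain3(seed),
        modification_consume3 = sample_mod_consume3(seed),
        modification_share3 = sample_mod_share3(seed))
      if (regime_holds(regime, cfg)) return(validate_config(cfg))
    }
    stop("internal error: could not satisfy regime '", regime,
         "' in 100 attempts")
  })
}

sample_case <- function(case, seed) {
  r10 <- runif1(0.25, 0.7)
  if (case == 1) {
    r20 <- r10 * runif1(0.15, 0.45)
    rS2C1 <- (r10 - r20) * runif1(0.3, 0.8)
  } else if (case == 2) {
    r20 <- r10 * runif1(0.55, 0.85)
    rS2C1 <- (r10 - r20) * runif1(1.5, 3)
  } else {
    r20 <- min(r10 * runif1(1.3, 2.2), 0.85)
    r10 <- r20 * runif1(0.45, 0.75)
    rS2C1 <- runif1(0.1, 0.4)
  }
  single_mediator_config(
    r10 = r10, r20 = r20, rS2C1 = rS2C1,
    K_S2C1 = rlog10(-0.5, 0.5), beta = rlog10(-6.5, -6),
    alpha = rlog10(-6.5, -6), K_C1S2 = rlog10(-0.5, 0.5),
    init = c(S1 = 5e6, S2 = 5e6),
    name = sprintf("case%s_seed%d", c("I", "II", "III")[case], seed))
}

sample_two_reusable <- function(seed) {
  r10 <- runif1(0.4, 0.6)
  r20 <- r10 - runif1(0.08, 0.12)
  rS2C1 <- runif1(0.25, 0.4)
  rS2C2 <- -(rS2C1 + runif1(0.005, 0.02))
  beta1 <- rlog10(-6.2, -5.8)
  beta2 <- rlog10(-6.2, -5.8)
  KC1 <- rlog10(2.8, 3.2)   # potency of the stimulatory mediator
  KC2 <- rlog10(4.8, 5.2)   # potency of the inhibitory mediator
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20)),
    mediators = list(mediator_spec("C1", "reusable"),
                     mediator_spec("C2", "reusable")),
    links = list(production_link("C1", "S1", beta1),
                 production_link("C2", "S1", beta2),
                 effect_link("C1", "S2", rS2C1, KC1 * beta1 / r10),
                 effect_link("C2", "S2", rS2C2, KC2 * beta2 / r10)),
    init = c(S1 = 1e3, S2 = 1e3),
    dilution = dilution_policy("turbidostat", threshold = 2e4,
                               reset_total = 2e3),
    name = sprintf("two_reusable_seed%d", seed))
}

sample_competitive_commensal <- function(seed) {
  competitive_commensal_config(
    r10 = -runif1(0.05, 0.12), r20 = -runif1(0.05, 0.12),
    rS1C1 = runif1(0.5, 0.8), K_S1C1 = 1,
    rS2C12 = runif1(0.5, 0.9), K_S2C1 = 1, K_S2C2 = rlog10(3.5, 4.5),
    beta0 = runif1(30, 80), betaC2S1 = rlog10(-9.5, -8.5),
    alphaC1S1 = 1e-6, alphaC1S2 = 1e-6, alphaC2S2 = 1e-6,
    init = c(S1 = 1e5, S2 = 1e5),
    name = sprintf("competitive_commensal_seed%d", seed))
}

#' Competitive-commensal mechanistic configuration
#'
#' Builds the batch-environment community where S1 and S2 compete for an
#' abiotically supplied resource C1 while S1 releases a metabolite C2 that
#' S2 additionally requires: C1 is supplied at constant rate `beta0`, both
#' species have negative basal fitness (net death without the resource),
#' S1 grows on C1 with Monod kinetics, S2 grows on C1 and C2 through a
#' dual-resource co-limitation term, and all consumption is yield-coupled
#' (resource consumed in proportion to realised growth).
#'
#' @param r10,r20 Basal net growth rates (negative: death rates).
#' @param rS1C1,K_S1C1 Monod parameters of S1 growth on C1.
#' @param rS2C12,K_S2C1,K_S2C2 Shared maximal rate and per-resource
#'   half-saturations of S2's co-limited growth.
#' @param beta0 Abiotic supply rate of C1 (concentration/hour).
#' @param betaC2S1 Production rate of C2 per S1 cell.
#' @param alphaC1S1,alphaC1S2,alphaC2S2 Yields: resource consumed per unit
#'   realised growth.
#' @param init Initial densities.
#' @param S_ext Extinction floor.
#' @param name Config name.
#' @return A [community_config()] (batch: no dilution).
#' @export
competitive_commensal_config <- function(r10, r20, rS1C1, K_S1C1,
                                         rS2C12, K_S2C1, K_S2C2,
                                         beta0, betaC2S1,
                                         alphaC1S1, alphaC1S2, alphaC2S2,
                                         init = c(S1 = 1e5, S2 = 1e5),
                                         S_ext = 1e-2, name = NULL) {
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20)),
    mediators = list(mediator_spec("C1", "consumable", supply = beta0),
                     mediator_spec("C2", "consumable")),
    links = list(
      effect_link("C1", "S1", rS1C1, K_S1C1),
      consumption_link("C1", "S1", alphaC1S1, mode = "yield"),
      effect_link("C1", "S2", rS2C12, K_S2C1, colimit = "res"),
      effect_link("C2", "S2", rS2C12, K_S2C2, colimit = "res"),
      consumption_link("C1", "S2", alphaC1S2, mode = "yield"),
      consumption_link("C2", "S2", alphaC2S2, mode = "yield"),
      production_link("C2", "S1", betaC2S1)),
    init = init, dilution = no_dilution(), S_ext = S_ext, name = name)
}

sample_chain3 <- function(seed) {
  r <- sort(runif(3, 0.2, 0.5), decreasing = TRUE)
  b1 <- rlog10(-6.2, -5.8); b2 <- rlog10(-6.2, -5.8)
  community_config(
    species = list(species_spec("S1", r[1]), species_spec("S2", r[2]),
                   species_spec("S3", r[3])),
    mediators = list(mediator_spec("C1", "reusable"),
                     mediator_spec("C2", "reusable")),
    links = list(production_link("C1", "S1", b1),
                 effect_link("C1", "S2", runif1(0.15, 0.3),
                             rlog10(5.8, 6.2) * b1 / r[1]),
                 production_link("C2", "S2", b2),
                 effect_link("C2", "S3", runif1(0.15, 0.3),
                             rlog10(5.8, 6.2) * b2 / r[2])),
    init = c(S1 = 3e6, S2 = 3e6, S3 = 3e6),
    dilution = default_dilution(),
    name = sprintf("chain3_seed%d", seed))
}

sample_mod_consume3 <- function(seed) {
  r10 <- runif1(0.4, 0.55)
  r20 <- r10 * runif1(0.6, 0.8)
  rS2C1 <- (r10 - r20) * runif1(1.6, 2.5)
  r30 <- runif1(0.45, 0.6)
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20),
                   species_spec("S3", r30)),
    mediators = list(mediator_spec("C1", "consumable")),
    links = list(production_link("C1", "S1", rlog10(-6.2, -5.8)),
                 effect_link("C1", "S2", rS2C1, rlog10(-0.2, 0.2)),
                 consumption_link("C1", "S2", rlog10(-6.2, -5.8),
                                  rlog10(-0.2, 0.2)),
                 consumption_link("C1", "S3", rlog10(-4.8, -4.2),
                                  rlog10(-0.2, 0.2))),
    init = c(S1 = 3e6, S2 = 3e6, S3 = 3e6),
    dilution = default_dilution(),
    name = sprintf("modification_consume3_seed%d", seed))
}

sample_mod_share3 <- function(seed) {
  r10 <- runif1(0.4, 0.55)
  r20 <- r10 * runif1(0.55, 0.75)
  r30 <- r10 * runif1(0.9, 1.05)
  b1 <- rlog10(-6.2, -5.8); b3 <- rlog10(-6.2, -5.8)
  # strongly saturating effect: half-saturation far below accumulated C1
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20),
                   species_spec("S3", r30)),
    mediators = list(mediator_spec("C1", "reusable")),
    links = list(production_link("C1", "S1", b1),
                 production_link("C1", "S3", b3),
                 effect_link("C1", "S2", (r10 - r20) * runif1(1.3, 1.8),
                             rlog10(-2.2, -1.8))),
    init = c(S1 = 3e6, S2 = 3e6, S3 = 3e6),
    dilution = default_dilution(),
    name = sprintf("modification_share3_seed%d", seed))
}

regime_holds <- function(regime, cfg) {
  ok <- switch(regime,
    caseI = classify_case(cfg) == "I",
    caseII = classify_case(cfg) == "II",
    caseIII = classify_case(cfg) == "III",
    two_reusable = {
      p <- two_mediator_params(cfg)
      red <- two_mediator_reducibility(p$r10, p$rS2C1, p$rS2C2,
                                       p$K_S2C1, p$K_S2C2,
                                       p$beta1, p$beta2)
      !red$reducible
    },
    competitive_commensal = all(vapply(cfg$species, `[[`, 0, "r0") < 0),
    TRUE)
  isTRUE(ok) && !inherits(try(validate_config(cfg), silent = TRUE),
                          "try-error")
}

# parameters of the two-reusable-mediator topology (S1 influencing S2)
two_mediator_params <- function(cfg) {
  stopifnot(length(cfg$mediators) == 2L)
  prod <- Filter(function(l) l$role == "production", cfg$links)
  eff <- Filter(function(l) l$role == "effect", cfg$links)
  betas <- setNames(vapply(prod, `[[`, 0, "beta"),
                    vapply(prod, `[[`, "", "mediator"))
  effs <- setNames(eff, vapply(eff, `[[`, "", "mediator"))
  md <- config_mediator_ids(cfg)
  r0 <- setNames(vapply(cfg$species, `[[`, 0, "r0"),
                 config_species_ids(cfg))
  list(r10 = r0[[1]], r20 = r0[[2]],
       rS2C1 = effs[[md[1]]]$r, rS2C2 = effs[[md[2]]]$r,
       K_S2C1 = effs[[md[1]]]$K, K_S2C2 = effs[[md[2]]]$K,
       beta1 = betas[[md[1]]], beta2 = betas[[md[2]]])
}

#' Generate a configuration in a specific convergence-time subcase
#'
#' Like [generate_regime_config()] but additionally places the initial
#' densities so that the requested `t_f` subcase applies and its
#' initial-density sufficiency inequality holds with a comfortable margin.
#' These configurations carry no dilution (the convergence-time analysis
#' is for uninterrupted growth).
#'
#' @param subcase One of `"II-1"`, `"II-2"`, `"II-3"`, `"III-1"`,
#'   `"III-2"`.
#' @param seed Integer seed.
#' @return A [community_config()] whose [estimate_tf()] report matches the
#'   requested subcase with `sufficient = TRUE`.
#' @export
generate_subcase_config <- function(subcase = c("II-1", "II-2", "II-3",
                                                "III-1", "III-2"),
                                    seed = 1) {
  subcase <- match.arg(subcase)
  if (subcase == "II-1") {
    # Dedicated sampling with a small fitness gap: the consumer keeps
    # growing appreciably while the trajectory traverses to the
    # isocline, so the sharp traverse-time estimate K_C1S2/(alpha S2(0))
    # stays conservative, and the initial consumer density is set so the
    # traverse takes about one consumer e-folding.
    return(with_seed(seed + 1000L, {
      r10 <- runif1(0.35, 0.5)
      gap <- runif1(0.015, 0.022)
      p <- single_mediator_params(r10, r10 - gap, gap * runif1(1.8, 2.5),
                                  K_S2C1 = rlog10(-0.5, 0.5),
                                  beta = rlog10(-6.5, -6),
                                  alpha = rlog10(-6.5, -6),
                                  K_C1S2 = rlog10(-0.5, 0.5))
      ss <- steady_state(p)
      RS0 <- ss[["RS_star"]] * 10 *
        max(1, p$K_S2C1 / ss[["C1_star"]] - 1) * runif1(1, 1.5)
      S2_0 <- p$K_C1S2 * p$r20 / (1.2 * p$alpha)
      cfg <- single_mediator_config(
        p$r10, p$r20, p$rS2C1, p$K_S2C1, p$beta, p$alpha, p$K_C1S2,
        init = c(S1 = S2_0 / RS0, S2 = S2_0), dilution = no_dilution(),
        name = sprintf("subcase_II-1_seed%d", seed))
      tf <- estimate_tf(cfg, S2_0 / RS0, S2_0)
      if (!identical(tf$subcase, "II-1") || !isTRUE(tf$sufficient))
        stop("internal error: generated config does not satisfy",
             " subcase II-1")
      cfg
    }))
  }
  base <- generate_regime_config(
    if (grepl("^III", subcase)) "caseIII" else "caseII", seed)
  p <- as_single_mediator(base)
  with_seed(seed + 1000L, {
    if (subcase %in% c("II-2", "II-3")) {
      ss <- steady_state(p)
      C1s <- ss[["C1_star"]]; RSs <- ss[["RS_star"]]
      if (subcase == "II-2") {
        RS0 <- RSs * runif1(0.8, 1.25)
        S1_0 <- 30 * (p$r10 - p$r20) * C1s / p$beta * runif1(1, 3)
        S1_0 <- max(S1_0, 1e6)
        S2_0 <- RS0 * S1_0
      } else {
        RS0 <- (p$beta / p$alpha) / 10 * runif1(0.1, 1)
        S1_0 <- 30 * p$r10 * C1s / p$beta * runif1(1, 3)
        S1_0 <- max(S1_0, 1e6)
        S2_0 <- RS0 * S1_0
      }
    } else {
      asym <- p$beta / p$alpha
      if (subcase == "III-1") {
        RS0 <- 10 * asym * runif1(1.5, 5)
        S1_0 <- 30 * (p$r20 - p$r10) * p$K_C1S2 / (p$alpha * RS0) *
          runif1(1, 3)
        S1_0 <- max(S1_0, 1e5)
        S2_0 <- RS0 * S1_0
      } else {
        RS0 <- asym / 10 * runif1(0.05, 1)
        S1_0 <- 1e7 * runif1(0.5, 2)
        S2_0 <- RS0 * S1_0
      }
    }
    cfg <- single_mediator_config(
      p$r10, p$r20, p$rS2C1, p$K_S2C1, p$beta, p$alpha, p$K_C1S2,
      init = c(S1 = S1_0, S2 = S2_0), dilution = no_dilution(),
      name = sprintf("subcase_%s_seed%d", subcase, seed))
    tf <- estimate_tf(cfg, S1_0, S2_0)
    if (!identical(tf$subcase, subcase) || !isTRUE(tf$sufficient))
      stop("internal error: generated config does not satisfy subcase ",
           subcase)
    cfg
  })
}
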