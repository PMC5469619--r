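# Closed-form machinery for the commensal pair coupled by a single
# mediator: S1 releases C1 (rate beta per cell), C1 stimulates S2 with a
# saturable fitness effect (maximum rS2C1, half-saturation K_S2C1) and,
# when consumable, is depleted by S2 with Monod kinetics (maximum alpha,
# half-saturation K_C1S2).
#
# Regimes (strict inequalities; r10, r20 > 0):
#   Case I:   r10 - r20 > rS2C1  -> consumer falls behind, C1 accumulates
#             in proportion to S1, saturable L-V applies.
#   Case II:  rS2C1 > r10 - r20 > 0 -> coexistence; (C1, RS = S2/S1) has a
#             steady state and the alternative (divided-influence) model
#             applies near the f-zero-isocline.
#   Case III: r10 < r20 -> consumer takes over, C1 -> 0, alternative model
#             applies along the isocline.

#' Single-mediator parameter set
#'
#' Bundle of the mechanistic parameters of the producer-consumer pair used
#' by all regime analysis functions.
#'
#' @param r10,r20 Basal fitnesses (per hour, > 0) of producer and consumer.
#' @param rS2C1 Maximal fitness effect of the mediator on the consumer
#'   (per hour).
#' @param K_S2C1 Half-saturation concentration of the fitness effect.
#' @param beta Production rate of the mediator per producer cell.
#' @param alpha Maximal consumption rate (NA for a reusable mediator).
#' @param K_C1S2 Half-saturation concentration of consumption (NA for a
#'   reusable mediator).
#' @param kind `"consumable"` or `"reusable"`.
#' @return A list of class `single_mediator_params`.
#' @export
single_mediator_params <- function(r10, r20, rS2C1, K_S2C1, beta,
                                   alpha = NA_real_, K_C1S2 = NA_real_,
                                   kind = c("consumable", "reusable")) {
  kind <- match.arg(kind)
  if (r10 <= 0 || r20 <= 0)
    stop("basal fitnesses r10 and r20 must be > 0 for the regime analysis")
  if (K_S2C1 <= 0) stop("K_S2C1 must be > 0")
  if (beta <= 0) stop("beta must be > 0")
  if (kind == "consumable" && (is.na(alpha) || alpha <= 0 ||
                               is.na(K_C1S2) || K_C1S2 <= 0))
    stop("consumable mediator needs alpha > 0 and K_C1S2 > 0")
  structure(list(r10 = r10, r20 = r20, rS2C1 = rS2C1, K_S2C1 = K_S2C1,
                 beta = beta, alpha = alpha, K_C1S2 = K_C1S2, kind = kind,
                 producer = "S1", consumer = "S2", mediator = "C1"),
            class = "single_mediator_params")
}

#' Extract single-mediator parameters from a community configuration
#'
#' @param x A [community_config()] with exactly two species and one
#'   mediator produced by one species and influencing the other, or an
#'   existing `single_mediator_params` object (returned unchanged).
#' @return A `single_mediator_params` object carrying the producer,
#'   consumer and mediator ids of the config.
#' @export
as_single_mediator <- function(x) {
  if (inherits(x, "single_mediator_params")) return(x)
  if (!inherits(x, "community_config"))
    stop("expected a community_config or single_mediator_params")
  if (length(x$species) != 2L || length(x$mediators) != 1L)
    stop("topology mismatch: need exactly two species and one mediator")
  med <- x$mediators[[1]]
  prod <- Filter(function(l) l$role == "production", x$links)
  eff <- Filter(function(l) l$role == "effect", x$links)
  cons <- Filter(function(l) l$role == "consumption", x$links)
  if (length(prod) != 1L || length(eff) != 1L)
    stop("topology mismatch: need one production and one effect link")
  if (eff[[1]]$form != "saturable")
    stop("topology mismatch: regime analysis assumes a saturable effect")
  producer <- prod[[1]]$species
  consumer <- eff[[1]]$species
  if (producer == consumer)
    stop("topology mismatch: producer must differ from the influenced",
         " species")
  r0 <- setNames(vapply(x$species, `[[`, 0, "r0"), config_species_ids(x))
  if (med$kind == "consumable") {
    if (length(cons) != 1L || cons[[1]]$species != consumer ||
        cons[[1]]$mode != "monod")
      stop("topology mismatch: consumable mediator must be consumed by",
           " the influenced species with Monod kinetics")
    p <- single_mediator_params(r0[[producer]], r0[[consumer]],
                                eff[[1]]$r, eff[[1]]$K, prod[[1]]$beta,
                                cons[[1]]$alpha, cons[[1]]$K,
                                kind = "consumable")
  } else {
    p <- single_mediator_params(r0[[producer]], r0[[consumer]],
                                eff[[1]]$r, eff[[1]]$K, prod[[1]]$beta,
                                kind = "reusable")
  }
  p$producer <- producer
  p$consumer <- consumer
  p$mediator <- med$id
  p
}

#' Classify the fitness regime of a single-consumable-mediator pair
#'
#' @param p A `single_mediator_params` (or a config accepted by
#'   [as_single_mediator()]).
#' @param tol Relative tolerance below which an inequality is treated as an
#'   equality and the parameter set reported as `"boundary"`.
#' @return `"I"`, `"II"`, `"III"`, or `"boundary"`.
#' @export
classify_case <- function(p, tol = 1e-12) {
  p <- as_single_mediator(p)
  d <- p$r10 - p$r20
  scale <- max(abs(p$r10), abs(p$r20), abs(p$rS2C1))
  if (abs(d) <= tol * scale || abs(d - p$rS2C1) <= tol * scale)
    return("boundary")
  if (d < 0) return("III")
  if (d > p$rS2C1) return("I")
  "II"
}

#' Coexistence steady state of mediator concentration and species ratio
#'
#' In the coexistence regime (Case II) the mediator concentration and the
#' consumer-to-producer ratio `RS = S2/S1` reach
#' `C1* = K_S2C1 (r10 - r20) / (r20 + rS2C1 - r10)` (where the two species'
#' growth rates are equal) and
#' `RS* = (beta/alpha) (1 + K_C1S2/C1*)` (where mediator production and
#' consumption balance).
#'
#' @inheritParams classify_case
#' @return Named vector `c(C1_star, RS_star)`.
#' @export
steady_state <- function(p) {
  p <- as_single_mediator(p)
  if (classify_case(p) != "II")
    stop("steady state only exists in the coexistence regime (Case II)")
  C1s <- p$K_S2C1 * (p$r10 - p$r20) / (p$r20 + p$rS2C1 - p$r10)
  RSs <- (p$beta / p$alpha) * (1 + p$K_C1S2 / C1s)
  c(C1_star = C1s, RS_star = RSs)
}

#' Analytically derived saturable pairwise model for a reusable mediator
#'
#' Once the mediator has acclimated to be proportional to its producer
#' (`C1 = (beta/r10) S1`), substituting into the saturable effect gives an
#' exact saturable L-V pairwise model with `r21 = rS2C1` and potency
#' `K21 = K_S2C1 r10 / beta` (the producer density at which the effect
#' half-saturates).
#'
#' @inheritParams classify_case
#' @return A saturable [pairwise-specs] over `(producer, consumer)`.
#' @export
derive_reusable_lv <- function(p) {
  p <- as_single_mediator(p)
  sp <- c(p$producer, p$consumer)
  r <- matrix(NA_real_, 2, 2)
  K <- matrix(NA_real_, 2, 2)
  r[2, 1] <- p$rS2C1
  K[2, 1] <- p$K_S2C1 * p$r10 / p$beta
  saturable_lv_spec(sp, c(p$r10, p$r20), r, K)
}

#' Analytically derived alternative (divided-influence) pairwise model
#'
#' Eliminating a consumable mediator along the f-zero-isocline yields
#' `dS2/dt = (r20 + rS2C1 S1/(omega S1 + psi S2)) S2` with
#' `omega = 1 - K_S2C1/K_C1S2` and
#' `psi = K_S2C1 alpha / (K_C1S2 beta)`.  When the two half-saturation
#' constants coincide (`omega = 0`) the model simplifies further to the
#' divided form `dS2/dt = (r20 + rho S1/S2) S2` with
#' `rho = rS2C1 beta / alpha`.
#'
#' @inheritParams classify_case
#' @return An alternative-form [pairwise-specs]; the simplified `rho` is
#'   attached as attribute `"rho"` when `omega` is (numerically) zero.
#' @export
derive_alternative <- function(p) {
  p <- as_single_mediator(p)
  if (p$kind != "consumable")
    stop("the alternative model applies to a consumable mediator")
  omega <- 1 - p$K_S2C1 / p$K_C1S2
  psi <- p$K_S2C1 * p$alpha / (p$K_C1S2 * p$beta)
  spec <- alternative_spec(c(p$producer, p$consumer), c(p$r10, p$r20),
                           r21 = p$rS2C1, omega = omega, psi = psi)
  if (abs(omega) < 1e-12)
    attr(spec, "rho") <- p$rS2C1 * p$beta / p$alpha
  spec
}

#' @rdname derive_alternative
#' @export
derive_divided <- function(p) {
  p <- as_single_mediator(p)
  divided_spec(c(p$producer, p$consumer), c(p$r10, p$r20),
               rho = p$rS2C1 * p$beta / p$alpha)
}

#' The f-zero-isocline in mediator-ratio phase space
#'
#' The curve along which the mediator's scaled net production rate
#' `f = 1 - (alpha/beta) C1/(C1+K_C1S2) RS` vanishes, i.e. where the
#' mediator can be eliminated to give a pairwise model.  In the
#' coexistence regime the isocline is returned in steady-state-scaled
#' coordinates `RS_hat(C1_hat) = (1 + K_hat/C1_hat)/(1 + K_hat)` with
#' `K_hat = K_C1S2/C1*`; otherwise unscaled,
#' `RS(C1) = (beta/alpha)(1 + K_C1S2/C1)`.
#'
#' @inheritParams classify_case
#' @param C1 Grid of (scaled or unscaled) mediator concentrations.
#' @param scaled `"auto"` scales when the pair is in Case II;
#'   `"steady_state"` forces scaling; `"none"` forces unscaled.
#' @return Vector of (scaled) species-ratio values on the isocline.
#' @export
f_zero_isocline <- function(p, C1,
                            scaled = c("auto", "steady_state", "none")) {
  p <- as_single_mediator(p)
  scaled <- match.arg(scaled)
  if (scaled == "auto")
    scaled <- if (classify_case(p) == "II") "steady_state" else "none"
  if (scaled == "steady_state") {
    Khat <- p$K_C1S2 / steady_state(p)[["C1_star"]]
    (1 + Khat / C1) / (1 + Khat)
  } else {
    (p$beta / p$alpha) * (1 + p$K_C1S2 / C1)
  }
}

#' Time scale for a community to approach the f-zero-isocline
#'
#' Estimates `t_f`, the acclimation time after which the mediator can be
#' eliminated and a pairwise model derived, for the analytically tractable
#' initial-condition subcases (mediator initially absent).  "Much greater
#' than" conditions are operationalised as a factor-of-`factor`
#' separation; initial ratios within a factor `band` of the steady-state
#' ratio count as "comparable".  Estimates are conservative time scales,
#' not sharp values.
#'
#' Subcases and estimates (`RS_hat(0)` is `RS(0)/RS*`):
#' * II-1 (`RS_hat(0) >> max(1, K_S2C1/C1* - 1)`):
#'   `t_f ~ K_C1S2/(alpha S2(0))`, sufficient when
#'   `S2(0) >> K_C1S2 (r10 - r20)/alpha`.
#' * II-2 (`RS_hat(0) ~ 1`): `t_f ~ factor/r10` (the near-steady-state
#'   relaxation rate exceeds `r10`), sufficient when
#'   `S1(0) >> (r10 - r20) C1*/beta`.
#' * II-3 (`RS(0) << beta/alpha`):
#'   `t_f ~ 1/r10 + ln(beta/(alpha RS(0)))/(r20 + rS2C1 - r10)`,
#'   sufficient when `S1(0) >> r10 C1*/beta`.
#' * III-1 (`RS(0) >> beta/alpha`): `t_f ~ K_C1S2/(alpha S2(0))`,
#'   sufficient when `S1(0) >> (r20 - r10) K_C1S2/(alpha RS(0))`.
#' * III-2 (`RS(0) << beta/alpha`):
#'   `t_f ~ ln(beta/(alpha RS(0)))/(r20 - r10)`.
#'
#' For a Case I pair `t_f` does not apply (there is no isocline to reach);
#' the mediator-accumulation acclimation time
#' `max(ln(alpha RS(0)/beta)/|r20 + rS2C1 - r10|, 1/r10)` is returned with
#' subcase `"I"`.
#'
#' @inheritParams classify_case
#' @param S1_0,S2_0 Initial densities (cells/ml, > 0).
#' @param factor Operationalisation of ">>" (default 10).
#' @param band "Comparable to 1" band for subcase II-2 (default 3).
#' @return List with `case`, `subcase` (`"II-1"`, ..., `"III-2"`,
#'   `"indeterminate"`, or `"I"`), `t_f` (hours; `NA` when indeterminate),
#'   and `sufficient` (does the initial producer density satisfy the
#'   subcase's sufficiency inequality?).
#' @export
estimate_tf <- function(p, S1_0, S2_0, factor = 10, band = 3) {
  p <- as_single_mediator(p)
  if (p$kind != "consumable")
    stop("t_f applies to a consumable mediator")
  stopifnot(S1_0 > 0, S2_0 > 0)
  RS0 <- S2_0 / S1_0
  case <- classify_case(p)
  if (case == "boundary")
    stop("boundary parameter set: regime analysis not applicable")
  if (case == "I") {
    acc <- max(log(p$alpha * RS0 / p$beta) /
                 abs(p$r20 + p$rS2C1 - p$r10), 1 / p$r10)
    return(list(case = "I", subcase = "I", t_f = NA_real_,
                acclimation = acc, sufficient = NA))
  }
  if (case == "II") {
    ss <- steady_state(p)
    C1s <- ss[["C1_star"]]
    RShat0 <- RS0 / ss[["RS_star"]]
    Khat_S2C1 <- p$K_S2C1 / C1s
    if (RShat0 >= factor * max(1, Khat_S2C1 - 1)) {
      return(list(case = "II", subcase = "II-1",
                  t_f = p$K_C1S2 / (p$alpha * S2_0),
                  sufficient = S2_0 >= factor * p$K_C1S2 *
                    (p$r10 - p$r20) / p$alpha))
    }
    if (RShat0 >= 1 / band && RShat0 <= band) {
      return(list(case = "II", subcase = "II-2", t_f = factor / p$r10,
                  sufficient = S1_0 >= factor * (p$r10 - p$r20) * C1s /
                    p$beta))
    }
    if (RS0 <= (p$beta / p$alpha) / factor) {
      return(list(case = "II", subcase = "II-3",
                  t_f = 1 / p$r10 + log(p$beta / (p$alpha * RS0)) /
                    (p$r20 + p$rS2C1 - p$r10),
                  sufficient = S1_0 >= factor * p$r10 * C1s / p$beta))
    }
    return(list(case = "II", subcase = "indeterminate", t_f = NA_real_,
                sufficient = NA))
  }
  # Case III
  asym <- p$beta / p$alpha
  if (RS0 >= factor * asym) {
    return(list(case = "III", subcase = "III-1",
                t_f = p$K_C1S2 / (p$alpha * S2_0),
                sufficient = S1_0 >= factor * (p$r20 - p$r10) *
                  p$K_C1S2 / (p$alpha * RS0)))
  }
  if (RS0 <= asym / factor) {
    return(list(case = "III", subcase = "III-2",
                t_f = log(asym / RS0) / (p$r20 - p$r10),
                sufficient = TRUE))
  }
  list(case = "III", subcase = "indeterminate", t_f = NA_real_,
       sufficient = NA)
}

#' Convergence of the alternative pairwise model to mechanistic dynamics
#'
#' The species-ratio dynamics of the alternative model,
#' `dRS/dt = (r20 + rS2C1/(omega + psi RS) - r10) RS`, has a singularity at
#' `RS = -omega/psi` when `omega < 0`.  The model converges to the
#' mechanistic behaviour (coexistence steady state in Case II; unbounded
#' consumer takeover at rate `r20 - r10` in Case III) for every initial
#' ratio when `omega >= 0`, and only for `RS(0) > -omega/psi` when
#' `omega < 0`; otherwise it falsely predicts consumer extinction
#' (Case II) or a spurious coexistence plateau (Case III).
#'
#' @param omega,psi Alternative-model constants (`psi > 0`).
#' @param RS_0 Initial consumer-to-producer ratio.
#' @param case `"II"` or `"III"`.
#' @return List with `converges`, `verdict` (one of
#'   `"coexistence"`, `"S1_exclusion"`, `"false_extinction"`,
#'   `"false_coexistence"`), and the `singularity` location (`NA` when
#'   `omega >= 0`).
#' @export
check_alt_convergence <- function(omega, psi, RS_0,
                                  case = c("II", "III")) {
  case <- match.arg(case)
  if (psi <= 0) stop("psi must be > 0")
  if (omega >= 0) {
    return(list(converges = TRUE,
                verdict = if (case == "II") "coexistence" else
                  "S1_exclusion",
                singularity = NA_real_))
  }
  sing <- -omega / psi
  if (RS_0 > sing) {
    list(converges = TRUE,
         verdict = if (case == "II") "coexistence" else "S1_exclusion",
         singularity = sing)
  } else {
    list(converges = FALSE,
         verdict = if (case == "II") "false_extinction" else
           "false_coexistence",
         singularity = sing)
  }
}

#' Direct integration of the alternative model's ratio dynamics
#'
#' Integrates the one-dimensional ratio equation
#' `dRS/dt = (r20 + rS2C1/(omega + psi RS) - r10) RS` and classifies the
#' long-run behaviour, as an independent check of
#' [check_alt_convergence()].
#'
#' @param r10,r20,rS2C1 Fitness parameters.
#' @param omega,psi Alternative-model constants.
#' @param RS_0 Initial ratio.
#' @param t_end Integration time (hours).
#' @param extinct_ratio Ratio below which the consumer counts as extinct.
#' @param growth_tol Late-time relative growth rate below which the ratio
#'   counts as converged.
#' @return List with the `RS` series, final value, and `behaviour` one of
#'   `"converged"`, `"extinction"`, `"unbounded"`.
#' @export
integrate_ratio_ode <- function(r10, r20, rS2C1, omega, psi, RS_0,
                                t_end = 500, extinct_ratio = 1e-6,
                                growth_tol = 1e-4) {
  rhs <- function(t, y, parms) {
    den <- omega + psi * y[1]
    list((r20 + rS2C1 / den - r10) * y[1])
  }
  times <- seq(0, t_end, length.out = 500)
  out <- deSolve::ode(c(RS = RS_0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-14)
  RS <- out[, 2]
  final <- RS[length(RS)]
  rate <- (log(pmax(RS[length(RS)], 1e-300)) -
             log(pmax(RS[length(RS) - 10], 1e-300))) /
    (times[length(times)] - times[length(times) - 10])
  behaviour <- if (final < extinct_ratio * RS_0) "extinction"
  else if (abs(rate) < growth_tol) "converged"
  else if (rate > 0) "unbounded"
  else "transient"
  list(times = times, RS = RS, final = final, behaviour = behaviour)
}

#' Reducibility of a two-mediator influence to one saturable term
#'
#' When one species releases two reusable mediators that additively affect
#' another, the combined fitness effect as a function of producer density
#' is `r_S2C1 S1/(S1 + K_C1) + r_S2C2 S1/(S1 + K_C2)` with potencies
#' `K_Ci = K_S2Ci r10 / beta_i`.  A single saturable pairwise term can
#' represent the combination only when the potencies are similar or one
#' term dominates.
#'
#' @param r10 Producer basal fitness (per hour).
#' @param rS2C1,rS2C2 Maximal fitness effects of the two mediators.
#' @param K_S2C1,K_S2C2 Half-saturation concentrations of the effects.
#' @param beta1,beta2 Production rates of the two mediators.
#' @param S1_range Producer density range (cells/ml) over which dominance
#'   is assessed.
#' @param similarity_band Potency ratio within `[1/band, band]` counts as
#'   similar.
#' @param dominance_frac One term whose magnitude never exceeds this
#'   fraction of the other (over `S1_range`) counts as negligible.
#' @return List with `reducible`, `reason` (`"similar_potency"`,
#'   `"dominance"`, or `"irreducible"`), the two potencies, the equivalent
#'   single-term parameters when exactly reducible, and the
#'   `combined_effect(S1)` function.
#' @export
two_mediator_reducibility <- function(r10, rS2C1, rS2C2, K_S2C1, K_S2C2,
                                      beta1, beta2,
                                      S1_range = c(1e2, 1e8),
                                      similarity_band = 3,
                                      dominance_frac = 0.05) {
  KC1 <- K_S2C1 * r10 / beta1
  KC2 <- K_S2C2 * r10 / beta2
  combined <- function(S1)
    rS2C1 * S1 / (S1 + KC1) + rS2C2 * S1 / (S1 + KC2)
  grid <- 10^seq(log10(S1_range[1]), log10(S1_range[2]), length.out = 200)
  t1 <- abs(rS2C1 * grid / (grid + KC1))
  t2 <- abs(rS2C2 * grid / (grid + KC2))
  ratio <- KC1 / KC2
  similar <- ratio >= 1 / similarity_band && ratio <= similarity_band
  dom <- all(t2 <= dominance_frac * pmax(t1, .Machine$double.eps)) ||
    all(t1 <= dominance_frac * pmax(t2, .Machine$double.eps))
  reason <- if (similar) "similar_potency" else if (dom) "dominance" else
    "irreducible"
  single <- NULL
  if (similar || dom) {
    # representative single-term parameters (exact when potencies equal
    # or one term vanishes)
    if (dom && all(t1 <= dominance_frac * pmax(t2, .Machine$double.eps)))
      single <- list(r21 = rS2C2, K21 = KC2)
    else if (dom) single <- list(r21 = rS2C1, K21 = KC1)
    else single <- list(r21 = rS2C1 + rS2C2, K21 = sqrt(KC1 * KC2))
  }
  list(reducible = similar || dom, reason = reason,
       K_C1 = KC1, K_C2 = KC2, single = single,
       combined_effect = combined)
}

#' Compare a simulated coexistence community against its closed form
#'
#' Simulates a Case II community under its turbidostat policy with the
#' mediator left undiluted (so the end-of-cycle state can be compared
#' against the dilution-free fixed point; the species-ratio dynamics are
#' unaffected by whether the mediator is diluted) and returns the
#' relative deviation of the late-time mediator concentration and species
#' ratio from `C1*` and `RS*`.
#'
#' @param config A Case II [community_config()] with a turbidostat
#'   dilution policy.
#' @param t_end Simulation time (hours).
#' @return List with `C1_rel_err`, `RS_rel_err`, the simulated values and
#'   the closed-form targets.
#' @export
steady_state_error <- function(config, t_end = 300) {
  p <- as_single_mediator(config)
  ss <- steady_state(p)
  cfg <- config
  if (cfg$dilution$mode != "turbidostat")
    stop("steady_state_error expects a turbidostat policy")
  cfg$dilution$dilute_mediators <- FALSE
  tr <- simulate_community(cfg, t_end)
  if (length(tr$dilution_times) < 3L)
    stop("too few dilution cycles for a late-time sample")
  i <- which.min(abs(tr$times - tr$dilution_times[
    length(tr$dilution_times)]))
  C1 <- tr$mediators[i, p$mediator]
  RS <- tr$species[i, p$consumer] / tr$species[i, p$producer]
  list(C1 = C1, RS = RS,
       C1_star = ss[["C1_star"]], RS_star = ss[["RS_star"]],
       C1_rel_err = abs(C1 - ss[["C1_star"]]) / ss[["C1_star"]],
       RS_rel_err = abs(RS - ss[["RS_star"]]) / ss[["RS_star"]])
}

#' Does a community reach the f-zero-isocline within a time budget?
#'
#' Simulates the mechanistic model in chunks and stops as soon as the
#' scaled mediator net-production rate satisfies `|f| < tol`, so that the
#' convergence-time estimates of [estimate_tf()] can be verified without
#' integrating the unbounded growth further than necessary.
#'
#' @param config A single-consumable-mediator [community_config()].
#' @param t_budget Time budget (hours), typically a small multiple of the
#'   `t_f` estimate.
#' @param tol Isocline tolerance on `|f|`.
#' @param n_chunks Number of integration chunks.
#' @return List with `reached` and `t_reached` (`NA` if not reached).
#' @export
reaches_isocline <- function(config, t_budget, tol = 0.05,
                             n_chunks = 10) {
  stopifnot(t_budget > 0)
  bounds <- seq(0, t_budget, length.out = n_chunks + 1)
  state <- c(unname(config$init[config_species_ids(config)]),
             vapply(config$mediators, `[[`, 0, "C0"))
  rhs <- build_rhs(config)
  p <- as_single_mediator(config)
  sp_ids <- config_species_ids(config)
  i1 <- match(p$producer, sp_ids); i2 <- match(p$consumer, sp_ids)
  for (k in seq_len(n_chunks)) {
    times <- seq(bounds[k], bounds[k + 1], length.out = 40)
    out <- try(suppressWarnings(
      deSolve::ode(state, times, rhs, NULL, method = "lsoda",
                   rtol = 1e-8, atol = 1e-10, maxsteps = 20000)),
      silent = TRUE)
    if (inherits(out, "try-error")) return(list(reached = FALSE,
                                                t_reached = NA_real_))
    C1 <- out[, 1 + length(sp_ids) + 1]
    RS <- out[, 1 + i2] / pmax(out[, 1 + i1], .Machine$double.xmin)
    f <- 1 - (p$alpha / p$beta) * C1 / (C1 + p$K_C1S2) * RS
    hit <- which(abs(f) < tol)
    if (length(hit))
      return(list(reached = TRUE, t_reached = out[hit[1], 1]))
    state <- out[nrow(out), -1]
    if (out[nrow(out), 1] < bounds[k + 1] * (1 - 1e-9))
      return(list(reached = FALSE, t_reached = NA_real_))
  }
  list(reached = FALSE, t_reached = NA_real_)
}

#' Full analytic report for a single-consumable-mediator community
#'
#' Convenience wrapper assembling the regime classification, steady state,
#' derived pairwise parameters, convergence-time estimate and
#' alternative-model convergence verdict into one report.
#'
#' @inheritParams classify_case
#' @param S1_0,S2_0 Initial densities; when omitted, subcase and
#'   convergence verdicts that depend on them are left out.
#' @param ... Passed to [estimate_tf()].
#' @return An object of class `regime_report`.
#' @export
regime_report <- function(p, S1_0 = NULL, S2_0 = NULL, ...) {
  p <- as_single_mediator(p)
  case <- classify_case(p)
  rep <- list(params = p, case = case, subcase = NULL,
              C1_star = NA_real_, RS_star = NA_real_,
              omega = NA_real_, psi = NA_real_, rho = NA_real_,
              t_f = NA_real_, sufficient = NA, converges = NA,
              recommended_form = "none")
  if (p$kind == "consumable" && case != "boundary") {
    alt <- derive_alternative(p)
    rep$omega <- alt$omega
    rep$psi <- alt$psi
    if (abs(rep$omega) < 1e-12) rep$rho <- attr(alt, "rho")
    rep$recommended_form <- if (case == "I") "saturable_lv" else
      "alternative"
    if (case == "II") {
      ss <- steady_state(p)
      rep$C1_star <- ss[["C1_star"]]
      rep$RS_star <- ss[["RS_star"]]
    }
    if (!is.null(S1_0) && !is.null(S2_0)) {
      tf <- estimate_tf(p, S1_0, S2_0, ...)
      rep$subcase <- tf$subcase
      rep$t_f <- tf$t_f
      rep$sufficient <- tf$sufficient
      if (case %in% c("II", "III"))
        rep$converges <- check_alt_convergence(rep$omega, rep$psi,
                                               S2_0 / S1_0,
                                               case)$converges
    }
  } else if (p$kind == "reusable") {
    rep$recommended_form <- "saturable_lv"
  }
  class(rep) <- "regime_report"
  rep
}

#' @export
print.regime_report <- function(x, ...) {
  cat("<regime_report> Case", x$case,
      if (!is.null(x$subcase)) paste0("(subcase ", x$subcase, ")"), "\n")
  if (!is.na(x$C1_star))
    cat("  steady state: C1* =", signif(x$C1_star, 4),
        " RS* =", signif(x$RS_star, 4), "\n")
  if (!is.na(x$omega))
    cat("  alternative-model constants: omega =", signif(x$omega, 4),
        " psi =", signif(x$psi, 4),
        if (!is.na(x$rho)) paste(" rho =", signif(x$rho, 4)), "\n")
  if (!is.na(x$t_f))
    cat("  t_f =", signif(x$t_f, 4), "h; initial densities sufficient:",
        x$sufficient, "\n")
  if (!is.na(x$converges))
    cat("  alternative model converges:", x$converges, "\n")
  cat("  recommended pairwise form:", x$recommended_form, "\n")
  invisible(x)
}
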