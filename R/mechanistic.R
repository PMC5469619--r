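# Mechanistic reference dynamics: species densities plus explicit mediator
# concentrations.
#
# Per mediator: dC/dt = supply + sum_j beta_Cj * Sj  (production)
#                      - sum_j consumption_Cj(C) * Sj (consumable only)
# Per species: dS/dt = [r0 + intra-species term + sum of mediator fitness
#                       effects] * S
# Fitness effects combine additively across mediators; a pair of effect
# links tagged as co-limiting contributes a single dual-resource term.
# Consumption is either Monod (alpha * C/(C+K)) or yield-coupled
# (alpha * realised growth term), the latter used when the mediator is a
# biomass-limiting resource.

#' Build the mechanistic derivative function for a community
#'
#' @param config A [community_config()].
#' @return A function `f(t, y, parms)` in `deSolve` form, where
#'   `y = c(species densities, mediator concentrations)` in config order.
#' @export
build_rhs <- function(config) {
  validate_config(config)
  sp_ids <- config_species_ids(config)
  md_ids <- config_mediator_ids(config)
  nS <- length(sp_ids)
  nM <- length(md_ids)
  r0 <- vapply(config$species, `[[`, 0, "r0")
  r_self <- vapply(config$species, function(s) s$r_self %||% NA_real_, 0)
  K_self <- vapply(config$species, function(s) s$K_self %||% NA_real_, 0)
  supply <- if (nM) vapply(config$mediators, `[[`, 0, "supply") else
    numeric(0)

  link_idx <- function(l) c(sp = match(l$species, sp_ids),
                            md = match(l$mediator, md_ids))
  prod_l <- Filter(function(l) l$role == "production", config$links)
  cons_l <- Filter(function(l) l$role == "consumption", config$links)
  eff_l <- Filter(function(l) l$role == "effect", config$links)

  p_sp <- vapply(prod_l, function(l) link_idx(l)[["sp"]], 0L)
  p_md <- vapply(prod_l, function(l) link_idx(l)[["md"]], 0L)
  p_beta <- vapply(prod_l, `[[`, 0, "beta")

  # split plain effect links from co-limitation groups
  is_co <- vapply(eff_l, function(l) !is.null(l$colimit), TRUE)
  single <- eff_l[!is_co]
  e_sp <- vapply(single, function(l) link_idx(l)[["sp"]], 0L)
  e_md <- vapply(single, function(l) link_idx(l)[["md"]], 0L)
  e_r <- vapply(single, `[[`, 0, "r")
  e_K <- vapply(single, `[[`, 0, "K")
  e_lin <- vapply(single, function(l) l$form == "linear", TRUE)

  co_groups <- list()
  if (any(is_co)) {
    co <- eff_l[is_co]
    key <- vapply(co, function(l) paste(l$species, l$colimit), "")
    for (k in unique(key)) {
      g <- co[key == k]
      co_groups[[k]] <- list(sp = match(g[[1]]$species, sp_ids),
                             md = vapply(g, function(l)
                               match(l$mediator, md_ids), 0L),
                             K = vapply(g, `[[`, 0, "K"),
                             r = g[[1]]$r)
    }
  }

  c_sp <- vapply(cons_l, function(l) link_idx(l)[["sp"]], 0L)
  c_md <- vapply(cons_l, function(l) link_idx(l)[["md"]], 0L)
  c_alpha <- vapply(cons_l, `[[`, 0, "alpha")
  c_K <- vapply(cons_l, function(l) l$K %||% NA_real_, 0)
  c_yield <- vapply(cons_l, function(l) l$mode == "yield", TRUE)

  # for yield-coupled consumption, locate the growth term of the consumer
  # on that mediator: either a single effect link or a co-limitation group
  yield_src <- lapply(seq_along(cons_l), function(i) {
    if (!c_yield[i]) return(NULL)
    j <- which(e_sp == c_sp[i] & e_md == c_md[i])
    if (length(j) == 1L) return(list(type = "single", idx = j))
    for (k in seq_along(co_groups)) {
      g <- co_groups[[k]]
      if (g$sp == c_sp[i] && c_md[i] %in% g$md)
        return(list(type = "colimit", idx = k))
    }
    stop("configuration error: yield-coupled consumption of '",
         cons_l[[i]]$mediator, "' by '", cons_l[[i]]$species,
         "' has no matching effect link")
  })

  function(t, y, parms) {
    S <- y[seq_len(nS)]
    C <- if (nM) pmax(y[nS + seq_len(nM)], 0) else numeric(0)
    g <- r0
    sel <- !is.na(r_self)
    if (any(sel))
      g[sel] <- g[sel] + r_self[sel] * S[sel] / (S[sel] + K_self[sel])

    e_term <- numeric(length(e_sp))
    if (length(e_sp)) {
      Cm <- C[e_md]
      e_term <- ifelse(e_lin, e_r * Cm / e_K, e_r * Cm / (Cm + e_K))
      for (k in seq_along(e_sp)) g[e_sp[k]] <- g[e_sp[k]] + e_term[k]
    }
    co_term <- numeric(length(co_groups))
    if (length(co_groups)) for (k in seq_along(co_groups)) {
      gr <- co_groups[[k]]
      cc <- C[gr$md] / gr$K
      tot <- cc[1] + cc[2]
      co_term[k] <- if (tot > 0)
        gr$r * (cc[1] * cc[2] / tot) *
          (1 / (cc[1] + 1) + 1 / (cc[2] + 1)) else 0
      g[gr$sp] <- g[gr$sp] + co_term[k]
    }

    dC <- supply
    if (length(p_sp))
      for (k in seq_along(p_sp))
        dC[p_md[k]] <- dC[p_md[k]] + p_beta[k] * S[p_sp[k]]
    if (length(c_sp)) for (k in seq_along(c_sp)) {
      rate <- if (!c_yield[k]) {
        c_alpha[k] * C[c_md[k]] / (C[c_md[k]] + c_K[k]) * S[c_sp[k]]
      } else {
        src <- yield_src[[k]]
        gk <- if (src$type == "single") e_term[src$idx] else
          co_term[src$idx]
        c_alpha[k] * gk * S[c_sp[k]]
      }
      dC[c_md[k]] <- dC[c_md[k]] - rate
    }
    list(c(g * S, dC))
  }
}

#' Simulate the mechanistic model of a community
#'
#' Integrates species and mediator dynamics with a stiff-capable solver.
#' Under a turbidostat dilution policy each threshold crossing is located
#' by root finding; all species (and mediators, when
#' `dilute_mediators = TRUE`) are then rescaled so that the total species
#' density returns to the inoculation total, species below the extinction
#' floor `S_ext` are set to zero, and integration resumes.
#'
#' @param config A [community_config()].
#' @param t_end End time (hours, > 0).
#' @param n_out Approximate number of recorded time points.
#' @param rtol,atol Solver tolerances.
#' @return A `trajectory` with species densities, mediator concentrations,
#'   and dilution-event times.
#' @export
simulate_community <- function(config, t_end, n_out = 400,
                               rtol = 1e-8, atol = 1e-10) {
  rhs <- build_rhs(config)
  sp_ids <- config_species_ids(config)
  md_ids <- config_mediator_ids(config)
  y0 <- c(unname(config$init[sp_ids]),
          vapply(config$mediators, `[[`, 0, "C0"))
  res <- integrate_dilution(rhs, y0, t_end, length(sp_ids),
                            config$dilution, config$S_ext,
                            n_out = n_out, rtol = rtol, atol = atol)
  sp <- res$states[, seq_along(sp_ids), drop = FALSE]
  colnames(sp) <- sp_ids
  md <- NULL
  if (length(md_ids)) {
    md <- res$states[, length(sp_ids) + seq_along(md_ids), drop = FALSE]
    colnames(md) <- md_ids
  }
  new_trajectory(res$times, sp, md, dilution_times = res$dilution_times,
                 meta = list(config = config$name,
                             config_hash = config_hash(config),
                             solver = list(rtol = rtol, atol = atol),
                             t_end = t_end))
}

#' Phase-plane trace of a single-consumable-mediator community
#'
#' Projects a mechanistic trajectory into the (mediator concentration,
#' species ratio) phase plane used by the regime analysis: `C1` versus
#' `R_S = S2/S1`, together with the scaled mediator net-production rate
#' `f = 1 - (alpha/beta) * C1/(C1 + K_C1S2) * R_S` whose zero isocline is
#' where the mediator can be eliminated to give a pairwise model.  In a
#' coexistence-regime community the coordinates scaled by their steady
#' state values are included.
#'
#' @param config A [community_config()] with the producer-consumer,
#'   single-consumable-mediator topology.
#' @param t_end Simulation end time (hours).
#' @param traj Optional pre-computed trajectory of `config`.
#' @param ... Passed to [simulate_community()].
#' @return A data frame with columns `time`, `C1`, `RS`, `f` (and `C1_hat`,
#'   `RS_hat` when the community is in the coexistence regime).
#' @export
phase_trace <- function(config, t_end = NULL, traj = NULL, ...) {
  p <- as_single_mediator(config)
  if (is.null(traj)) {
    if (is.null(t_end)) stop("either t_end or traj must be given")
    traj <- simulate_community(config, t_end, ...)
  }
  C1 <- traj$mediators[, p$mediator]
  S1 <- traj$species[, p$producer]
  S2 <- traj$species[, p$consumer]
  RS <- S2 / pmax(S1, .Machine$double.xmin)
  f <- 1 - (p$alpha / p$beta) * C1 / (C1 + p$K_C1S2) * RS
  out <- data.frame(time = traj$times, C1 = C1, RS = RS, f = f)
  if (classify_case(p) == "II") {
    ss <- steady_state(p)
    out$C1_hat <- C1 / ss[["C1_star"]]
    out$RS_hat <- RS / ss[["RS_star"]]
  }
  out
}
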