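# Automatic construction of a multispecies pairwise model from a
# mechanistic configuration, the way an experimentalist would build it:
# each (producer, influenced species) pair is reduced in isolation to a
# two-species pairwise model, and the components are combined additively.

#' Derive a multispecies pairwise assembly from a mechanistic config
#'
#' For every mediator path from a producer to an influenced species, the
#' corresponding two-species pairwise model is derived analytically as if
#' the pair were alone: a reusable mediator gives a saturable L-V term
#' with potency `K = K_effect * r0_producer / beta`; a consumable mediator
#' consumed by the influenced species gives an alternative
#' (divided-influence) term with
#' `omega = 1 - K_effect/K_consume` and
#' `psi = K_effect * alpha / (K_consume * beta)`.  The terms are then
#' assembled additively into an N-species pairwise model — precisely the
#' construction whose validity the interaction-modification scenarios
#' probe.
#'
#' @param config A [community_config()] whose links are production,
#'   Monod consumption and saturable effect links.
#' @return A `pairwise_assembly` (see [assemble_multispecies()]).
#' @export
derive_pairwise_assembly <- function(config) {
  validate_config(config)
  r0 <- setNames(vapply(config$species, `[[`, 0, "r0"),
                 config_species_ids(config))
  specs <- list()
  for (m in config$mediators) {
    prods <- Filter(function(l) l$role == "production" &&
                      l$mediator == m$id, config$links)
    effs <- Filter(function(l) l$role == "effect" &&
                     l$mediator == m$id, config$links)
    cons <- Filter(function(l) l$role == "consumption" &&
                     l$mediator == m$id, config$links)
    if (any(vapply(effs, function(l) !is.null(l$colimit) ||
                   l$form != "saturable", TRUE)))
      stop("cannot derive a pairwise assembly for co-limited or linear",
           " effect links")
    for (e in effs) for (p in prods) {
      if (p$species == e$species) next
      sp <- c(p$species, e$species)
      if (m$kind == "reusable") {
        r <- K <- matrix(NA_real_, 2, 2, dimnames = list(sp, sp))
        r[2, 1] <- e$r
        K[2, 1] <- e$K * r0[[p$species]] / p$beta
        specs[[length(specs) + 1L]] <-
          saturable_lv_spec(sp, r0[sp], r, K)
      } else {
        cn <- Filter(function(l) l$species == e$species, cons)
        if (length(cn) != 1L || cn[[1]]$mode != "monod")
          stop("consumable mediator '", m$id, "': the influenced species",
               " must consume it with Monod kinetics")
        cn <- cn[[1]]
        specs[[length(specs) + 1L]] <- alternative_spec(
          sp, r0[sp], r21 = e$r,
          omega = 1 - e$K / cn$K,
          psi = e$K * cn$alpha / (cn$K * p$beta))
      }
    }
  }
  all_sp <- config_species_ids(config)
  asm <- if (length(specs)) assemble_multispecies(specs) else
    structure(list(species = all_sp, r0 = r0, terms = list(),
                   components = list()),
              class = "pairwise_assembly")
  # keep the config's species order (including non-interacting species)
  asm$species <- all_sp
  asm$r0 <- r0[all_sp]
  asm
}
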