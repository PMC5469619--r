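# Domain types for mechanistic community configurations.
#
# Units package-wide: time in hours, species densities in cells/ml,
# mediator concentrations in arbitrary concentration units (only ratios to
# the half-saturation constants matter).

#' Species specification
#'
#' @param id Character label for the species (e.g. `"S1"`).
#' @param r0 Basal fitness: net growth rate (per hour) of an individual in
#'   isolation.  May be negative (net death, e.g. when an essential shared
#'   resource is modelled explicitly).
#' @param r_self,K_self Optional intra-species density-dependent fitness
#'   term `r_self * S / (S + K_self)` added to the growth rate (`K_self` in
#'   cells/ml, must be positive when given).
#' @param b0,d Optional maximal birth rate and death rate (per hour) used by
#'   the competitive-commensal pairwise form; `d` must be non-negative.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(id, r0, r_self = NULL, K_self = NULL,
                         b0 = NULL, d = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.numeric(r0))
  if (!is.null(r_self) && (is.null(K_self) || K_self <= 0))
    stop("species ", id, ": K_self must be > 0 when r_self is given")
  if (!is.null(d) && d < 0)
    stop("species ", id, ": death rate d must be >= 0")
  structure(list(id = id, r0 = r0, r_self = r_self, K_self = K_self,
                 b0 = b0, d = d),
            class = "species_spec")
}

#' Mediator specification
#'
#' @param id Character label (e.g. `"C1"`).
#' @param kind `"reusable"` (influences recipients without being depleted,
#'   e.g. a signalling molecule) or `"consumable"` (depleted as it acts,
#'   e.g. a metabolite).
#' @param C0 Initial concentration (>= 0).  Defaults to 0, the pre-washed
#'   state that can be imposed experimentally.
#' @param supply Constant abiotic supply rate (concentration/hour, >= 0).
#' @return An object of class `mediator_spec`.
#' @export
mediator_spec <- function(id, kind = c("reusable", "consumable"),
                          C0 = 0, supply = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L)
  if (C0 < 0) stop("mediator ", id, ": C0 must be >= 0")
  if (supply < 0) stop("mediator ", id, ": supply must be >= 0")
  structure(list(id = id, kind = kind, C0 = C0, supply = supply),
            class = "mediator_spec")
}

#' Influence links between species and mediators
#'
#' Three link roles connect species to mediators: production (a species
#' releases the mediator), consumption (a species depletes it), and effect
#' (the mediator changes a species' growth rate).  First subscript of each
#' rate parameter names the focal entity, the second the influencer, so
#' `beta` in `production_link("C1", "S1", beta)` is the release rate of C1
#' per S1 cell.
#'
#' @param mediator,species Character ids referencing the community's
#'   mediators and species.
#' @param beta Production rate (concentration * ml / cell / hour, >= 0).
#' @param alpha Maximal consumption rate in `"monod"` mode, or the amount of
#'   mediator consumed per unit of realised growth in `"yield"` mode
#'   (>= 0).
#' @param K Half-saturation concentration (> 0): of consumption for
#'   `consumption_link`, of the fitness effect for `effect_link`.
#' @param mode Consumption kinetics: `"monod"` gives
#'   `alpha * C/(C + K) * S`; `"yield"` couples consumption to the
#'   consumer's realised growth on this mediator,
#'   `alpha * g(C, ...) * S` where `g` is the fitness-effect term of the
#'   matching effect link (used by the competitive-commensal model, where
#'   `alpha` is the amount of resource consumed to produce a new cell).
#' @param r Maximal fitness effect of the mediator on the species
#'   (per hour; sign gives stimulation/inhibition).
#' @param form `"saturable"` gives `r * C/(C + K)`; `"linear"` gives
#'   `r * C/K` (the low-concentration limit of the saturable form, kept on
#'   the same parameter scale).
#' @param colimit Optional character tag.  Effect links on the same target
#'   species sharing a `colimit` tag are combined into a single
#'   dual-resource co-limitation term
#'   `r * (c1*c2/(c1+c2)) * (1/(c1+1) + 1/(c2+1))` with `ci = Ci/Ki`,
#'   which reduces to the Monod form in either `ci` when that resource is
#'   limiting.  The links must share the same `r`.
#' @return A link object (class `production_link`, `consumption_link` or
#'   `effect_link`).
#' @name influence-links
NULL

#' @rdname influence-links
#' @export
production_link <- function(mediator, species, beta) {
  if (beta < 0) stop("production link: beta must be >= 0")
  structure(list(role = "production", mediator = mediator,
                 species = species, beta = beta),
            class = c("production_link", "influence_link"))
}

#' @rdname influence-links
#' @export
consumption_link <- function(mediator, species, alpha, K = NULL,
                             mode = c("monod", "yield")) {
  mode <- match.arg(mode)
  if (alpha < 0) stop("consumption link: alpha must be >= 0")
  if (mode == "monod" && (is.null(K) || K <= 0))
    stop("consumption link: K must be > 0 in monod mode")
  structure(list(role = "consumption", mediator = mediator,
                 species = species, alpha = alpha, K = K, mode = mode),
            class = c("consumption_link", "influence_link"))
}

#' @rdname influence-links
#' @export
effect_link <- function(mediator, species, r, K,
                        form = c("saturable", "linear"), colimit = NULL) {
  form <- match.arg(form)
  if (K <= 0) stop("effect link: K must be > 0")
  structure(list(role = "effect", mediator = mediator, species = species,
                 r = r, K = K, form = form, colimit = colimit),
            class = c("effect_link", "influence_link"))
}

#' Dilution policy
#'
#' In `"turbidostat"` mode the community is diluted back to its inoculation
#' density whenever the total population reaches a high-density threshold,
#' keeping resources that are not part of the interaction non-limiting.
#'
#' @param mode `"none"` or `"turbidostat"`.
#' @param threshold Total density (cells/ml) that triggers a dilution.
#' @param reset_total Total density after dilution; must be below
#'   `threshold`.
#' @param dilute_mediators Should mediator concentrations be rescaled by the
#'   same factor as the cells?  Defaults to `TRUE` (mediators share the
#'   culture volume).
#' @return An object of class `dilution_policy`.
#' @export
dilution_policy <- function(mode = c("none", "turbidostat"),
                            threshold = NULL, reset_total = NULL,
                            dilute_mediators = TRUE) {
  mode <- match.arg(mode)
  if (mode == "turbidostat") {
    if (is.null(threshold) || is.null(reset_total))
      stop("turbidostat mode needs threshold and reset_total")
    if (!(threshold > reset_total))
      stop("dilution threshold must exceed reset_total")
  }
  structure(list(mode = mode, threshold = threshold,
                 reset_total = reset_total,
                 dilute_mediators = isTRUE(dilute_mediators)),
            class = "dilution_policy")
}

#' @rdname dilution_policy
#' @export
no_dilution <- function() dilution_policy("none")

#' Community configuration
#'
#' The full parameterisation of a mechanistic community: species, chemical
#' mediators, the influence links between them, initial state, dilution
#' policy and the extinction floor.
#'
#' @param species List of [species_spec()] objects.
#' @param mediators List of [mediator_spec()] objects (may be empty).
#' @param links List of link objects (see [influence-links]).
#' @param init Named numeric vector of initial densities (cells/ml), one
#'   entry per species.
#' @param dilution A [dilution_policy()].
#' @param S_ext Extinction floor (cells/ml, > 0): species below `S_ext` at a
#'   dilution event are set to zero, and densities are floored at `S_ext`
#'   when computing the log10 fold-difference metric.
#' @param name Optional configuration name.
#' @return A validated object of class `community_config`.
#' @export
community_config <- function(species, mediators = list(), links = list(),
                             init, dilution = no_dilution(), S_ext = 1e-2,
                             name = NULL) {
  cfg <- structure(list(species = species, mediators = mediators,
                        links = links, init = init, dilution = dilution,
                        S_ext = S_ext, name = name),
                   class = "community_config")
  validate_config(cfg)
}

#' Validate a community configuration
#'
#' Checks every structural invariant: link references resolve, consumable
#' mediators have at least one consumer, reusable mediators have none,
#' initial densities are non-negative and complete, and the extinction
#' floor is positive.
#'
#' @param cfg A `community_config`.
#' @return `cfg`, invisibly unchanged, or an error naming the violated
#'   field.
#' @export
validate_config <- function(cfg) {
  sp_ids <- vapply(cfg$species, `[[`, "", "id")
  md_ids <- vapply(cfg$mediators, `[[`, "", "id")
  if (anyDuplicated(sp_ids)) stop("config: duplicated species ids")
  if (anyDuplicated(md_ids)) stop("config: duplicated mediator ids")
  if (!is.numeric(cfg$S_ext) || cfg$S_ext <= 0)
    stop("config: S_ext must be > 0")
  if (is.null(names(cfg$init)) || !setequal(names(cfg$init), sp_ids))
    stop("config: init must be a named vector covering every species")
  if (any(cfg$init < 0)) stop("config: initial densities must be >= 0")
  if (!inherits(cfg$dilution, "dilution_policy"))
    stop("config: dilution must be a dilution_policy")
  for (ln in cfg$links) {
    if (!ln$mediator %in% md_ids)
      stop("config: link references unknown mediator '", ln$mediator, "'")
    if (!ln$species %in% sp_ids)
      stop("config: link references unknown species '", ln$species, "'")
  }
  for (m in cfg$mediators) {
    consumers <- Filter(function(l) l$role == "consumption" &&
                          l$mediator == m$id, cfg$links)
    if (m$kind == "consumable" && length(consumers) == 0L)
      stop("config: consumable mediator '", m$id,
           "' has no consumption link")
    if (m$kind == "reusable" && length(consumers) > 0L)
      stop("config: reusable mediator '", m$id,
           "' must not have consumption links")
  }
  # co-limitation groups: exactly two effect links per (species, tag),
  # sharing the same maximal fitness effect
  eff <- Filter(function(l) l$role == "effect" && !is.null(l$colimit),
                cfg$links)
  if (length(eff)) {
    key <- vapply(eff, function(l) paste(l$species, l$colimit), "")
    for (k in unique(key)) {
      grp <- eff[key == k]
      if (length(grp) != 2L)
        stop("config: co-limitation group '", k,
             "' must contain exactly two effect links")
      if (abs(grp[[1]]$r - grp[[2]]$r) > 1e-12 * max(1, abs(grp[[1]]$r)))
        stop("config: co-limitation group '", k,
             "' links must share the same r")
    }
  }
  invisible(cfg)
}

#' @export
print.community_config <- function(x, ...) {
  cat("<community_config", if (!is.null(x$name)) paste0("'", x$name, "'"),
      ">\n")
  cat("  species:  ", paste(vapply(x$species, `[[`, "", "id"),
                            collapse = ", "), "\n")
  cat("  mediators:", if (length(x$mediators))
    paste(vapply(x$mediators, function(m) paste0(m$id, " (", m$kind, ")"),
                 ""), collapse = ", ") else "none", "\n")
  cat("  links:    ", length(x$links), "\n")
  cat("  dilution: ", x$dilution$mode, "\n")
  invisible(x)
}

# internal accessors
config_species_ids <- function(cfg) vapply(cfg$species, `[[`, "", "id")
config_mediator_ids <- function(cfg) vapply(cfg$mediators, `[[`, "", "id")
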