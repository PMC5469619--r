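# Reading and writing community configurations as YAML.
#
# Schema (one document per file):
#   name: optional string
#   S_ext: number
#   dilution: {mode, threshold, reset_total, dilute_mediators}
#   species: [{id, r0, r_self, K_self, b0, d}]
#   mediators: [{id, kind, C0, supply}]
#   links:
#     - {role: production, mediator, species, beta}
#     - {role: consumption, mediator, species, alpha, K, mode}
#     - {role: effect, mediator, species, r, K, form, colimit}
#   init: {S1: 1e5, ...}
# Unset optional fields are simply omitted.

#' Load a community configuration from a YAML file
#'
#' @param path Path to a YAML file following the documented schema.
#' @return A validated [community_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config_from_list(yaml::read_yaml(path))
}

config_from_list <- function(raw) {
  for (fld in c("species", "init"))
    if (is.null(raw[[fld]])) stop("config file: missing field '", fld, "'")
  species <- lapply(raw$species, function(s) {
    if (is.null(s$id) || is.null(s$r0))
      stop("config file: species entries need 'id' and 'r0'")
    species_spec(s$id, as.numeric(s$r0),
                 r_self = null_num(s$r_self), K_self = null_num(s$K_self),
                 b0 = null_num(s$b0), d = null_num(s$d))
  })
  mediators <- lapply(raw$mediators %||% list(), function(m) {
    if (is.null(m$id) || is.null(m$kind))
      stop("config file: mediator entries need 'id' and 'kind'")
    mediator_spec(m$id, m$kind, C0 = m$C0 %||% 0, supply = m$supply %||% 0)
  })
  links <- lapply(raw$links %||% list(), function(l) {
    if (is.null(l$role)) stop("config file: link entries need 'role'")
    switch(l$role,
      production = production_link(l$mediator, l$species,
                                   as.numeric(l$beta)),
      consumption = consumption_link(l$mediator, l$species,
                                     as.numeric(l$alpha),
                                     K = null_num(l$K),
                                     mode = l$mode %||% "monod"),
      effect = effect_link(l$mediator, l$species, as.numeric(l$r),
                           as.numeric(l$K), form = l$form %||% "saturable",
                           colimit = l$colimit),
      stop("config file: unknown link role '", l$role, "'"))
  })
  dl <- raw$dilution %||% list(mode = "none")
  dilution <- dilution_policy(dl$mode %||% "none",
                              threshold = null_num(dl$threshold),
                              reset_total = null_num(dl$reset_total),
                              dilute_mediators =
                                dl$dilute_mediators %||% TRUE)
  init <- unlist(raw$init)
  community_config(species, mediators, links, init,
                   dilution = dilution,
                   S_ext = raw$S_ext %||% 1e-2,
                   name = raw$name)
}

#' Save a community configuration to a YAML file
#'
#' `load_config(save_config(cfg, path))` round-trips exactly.
#'
#' @param cfg A [community_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path, precision = 15L)
  invisible(path)
}

config_to_list <- function(cfg) {
  validate_config(cfg)
  out <- list(
    name = cfg$name,
    S_ext = cfg$S_ext,
    dilution = drop_null(list(
      mode = cfg$dilution$mode,
      threshold = cfg$dilution$threshold,
      reset_total = cfg$dilution$reset_total,
      dilute_mediators = cfg$dilution$dilute_mediators)),
    species = lapply(cfg$species, function(s)
      drop_null(list(id = s$id, r0 = s$r0, r_self = s$r_self,
                     K_self = s$K_self, b0 = s$b0, d = s$d))),
    mediators = lapply(cfg$mediators, function(m)
      drop_null(list(id = m$id, kind = m$kind, C0 = m$C0,
                     supply = m$supply))),
    links = lapply(cfg$links, function(l)
      drop_null(switch(l$role,
        production = list(role = "production", mediator = l$mediator,
                          species = l$species, beta = l$beta),
        consumption = list(role = "consumption", mediator = l$mediator,
                           species = l$species, alpha = l$alpha, K = l$K,
                           mode = l$mode),
        effect = list(role = "effect", mediator = l$mediator,
                      species = l$species, r = l$r, K = l$K,
                      form = l$form, colimit = l$colimit)))),
    init = as.list(cfg$init))
  drop_null(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
null_num <- function(x) if (is.null(x)) NULL else as.numeric(x)
drop_null <- function(x) x[!vapply(x, is.null, TRUE)]
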