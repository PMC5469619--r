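# Small community builders shared across tests.

pair_config <- function(r10 = 0.5, r20 = 0.3, rS2C1 = 0.4,
                        K_S2C1 = 1, beta = 1e-6, alpha = 1e-6,
                        K_C1S2 = 1, kind = "consumable",
                        init = c(S1 = 5e6, S2 = 5e6),
                        dilution = no_dilution(), S_ext = 1e-2) {
  links <- list(production_link("C1", "S1", beta),
                effect_link("C1", "S2", rS2C1, K_S2C1))
  if (kind == "consumable")
    links <- c(links, list(consumption_link("C1", "S2", alpha, K_C1S2)))
  community_config(
    species = list(species_spec("S1", r10), species_spec("S2", r20)),
    mediators = list(mediator_spec("C1", kind)),
    links = links, init = init, dilution = dilution, S_ext = S_ext)
}

turbidostat10 <- function(threshold = 1e8)
  dilution_policy("turbidostat", threshold, threshold / 10)

pair_params <- function(...) as_single_mediator(pair_config(...))

# evaluate a deSolve-style rhs at a state, returning the derivative vector
eval_rhs <- function(rhs, y, t = 0) rhs(t, y, NULL)[[1]]
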