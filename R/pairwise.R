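# The pairwise (Lotka-Volterra-type) model family.  All forms share the
# multiplicative structure dSi/dt = [ri0 + sum_j f_ij] * Si except the
# competitive-commensal hybrid, whose birth term is multiplicative so that
# growth stops when the shared resource is exhausted.

#' Pairwise model specifications
#'
#' Constructors for each pairwise model form.  Interaction matrices are
#' indexed `[focal, influencer]`; `NA` entries mean "no term".
#'
#' * `linear_lv_spec`: `dSi/dt = (ri0 + sum_j r[i,j] Sj) Si`.
#' * `logistic_lv_spec`: `dSi/dt = ri0 (1 - sum_j Sj/Lambda[i,j]) Si`,
#'   the classical competition form (`Lambda[i,j] > 0`).
#' * `saturable_lv_spec`:
#'   `dSi/dt = (ri0 + sum_j r[i,j] Sj/(K[i,j] + Sj)) Si`, where `K[i,j]` is
#'   the influencer density at which half the maximal fitness effect is
#'   reached; self terms (`j = i`) are permitted.
#' * `alternative_spec` (divided-influence model, for one species feeding a
#'   consumable mediator to another):
#'   `dS2/dt = (r20 + r21 S1/(omega S1 + psi S2)) S2` with the influencer
#'   growing exponentially at `r10`; `psi > 0`.  Species order is
#'   `c(influencer, focal)`.
#' * `divided_spec`: the `omega = 0` simplification
#'   `dS2/dt = (r20 + rho S1/S2) S2`, with `S2` floored at `S_ext` during
#'   integration to avoid division blow-up.
#' * `competitive_commensal_spec`:
#'   `dS1/dt = b10 (1 - S1/L[1,1] - S2/L[1,2]) S1 - d1 S1`,
#'   `dS2/dt = (b20 + r21 S1)(1 - S1/L[2,1] - S2/L[2,2]) S2 - d2 S2`:
#'   logistic competition for a shared resource plus a commensal boost of
#'   the birth rate, structured so the boost cannot sustain growth once
#'   the shared resource is exhausted.
#'
#' @param species Character vector of species ids.
#' @param r0 Named (or ordered) numeric vector of basal fitnesses.
#' @param r,K,Lambda Interaction matrices as described above.
#' @param r21,omega,psi,rho Scalars of the divided-influence forms.
#' @param b0,d,L Birth rates, death rates and carrying-capacity matrix of
#'   the competitive-commensal form.
#' @return An object of class `pairwise_spec`.
#' @name pairwise-specs
NULL

new_pairwise_spec <- function(form, species, r0, params) {
  r0 <- as.numeric(r0)
  stopifnot(length(r0) == length(species))
  names(r0) <- species
  structure(c(list(form = form, species = species, r0 = r0), params),
            class = "pairwise_spec")
}

check_mat <- function(m, species, what, positive = FALSE) {
  if (is.null(m)) stop("pairwise spec: missing parameter '", what, "'")
  m <- as.matrix(m)
  if (!all(dim(m) == length(species)))
    stop("pairwise spec: '", what, "' must be ",
         length(species), "x", length(species))
  if (positive && any(!is.na(m) & m <= 0))
    stop("pairwise spec: '", what, "' entries must be > 0")
  dimnames(m) <- list(species, species)
  m
}

#' @rdname pairwise-specs
#' @export
linear_lv_spec <- function(species, r0, r) {
  new_pairwise_spec("linear_lv", species, r0,
                    list(r = check_mat(r, species, "r")))
}

#' @rdname pairwise-specs
#' @export
logistic_lv_spec <- function(species, r0, Lambda) {
  new_pairwise_spec("logistic_lv", species, r0,
                    list(Lambda = check_mat(Lambda, species, "Lambda",
                                            positive = TRUE)))
}

#' @rdname pairwise-specs
#' @export
saturable_lv_spec <- function(species, r0, r, K) {
  r <- check_mat(r, species, "r")
  K <- check_mat(K, species, "K", positive = TRUE)
  if (any(!is.na(r) & r != 0 & is.na(K)))
    stop("pairwise spec: K missing for a non-zero saturable term")
  new_pairwise_spec("saturable_lv", species, r0, list(r = r, K = K))
}

#' @rdname pairwise-specs
#' @export
alternative_spec <- function(species, r0, r21, omega, psi) {
  stopifnot(length(species) == 2L)
  if (!is.numeric(psi) || psi <= 0)
    stop("pairwise spec: psi must be > 0")
  new_pairwise_spec("alternative", species, r0,
                    list(r21 = r21, omega = omega, psi = psi))
}

#' @rdname pairwise-specs
#' @export
divided_spec <- function(species, r0, rho) {
  stopifnot(length(species) == 2L)
  new_pairwise_spec("divided_simplified", species, r0, list(rho = rho))
}

#' @rdname pairwise-specs
#' @export
competitive_commensal_spec <- function(species, b0, d, L, r21) {
  stopifnot(length(species) == 2L, length(b0) == 2L, length(d) == 2L)
  if (any(b0 < 0) || any(d < 0))
    stop("pairwise spec: b0 and d must be >= 0")
  new_pairwise_spec("competitive_commensal_lv", species, b0 - d,
                    list(b0 = b0, d = d,
                         Lambda = check_mat(L, species, "L",
                                            positive = TRUE),
                         r21 = r21))
}

#' @export
print.pairwise_spec <- function(x, ...) {
  cat("<pairwise_spec form=", x$form, "> species: ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# ---- term decomposition -------------------------------------------------

# Each pairwise form (except the competitive-commensal hybrid) is compiled
# to additive fitness terms: list(focal, fn(Sj, Si)).  `influencer` and
# `focal` are species ids; fn receives the influencer and focal densities.
pairwise_terms <- function(spec, S_ext = 1e-2) {
  sp <- spec$species
  terms <- list()
  add <- function(focal, influencer, fn)
    terms[[length(terms) + 1L]] <<- list(focal = focal,
                                         influencer = influencer, fn = fn)
  switch(spec$form,
    linear_lv = {
      for (i in sp) for (j in sp) {
        rij <- spec$r[i, j]
        if (!is.na(rij) && rij != 0)
          add(i, j, local({ rij <- rij; function(Sj, Si) rij * Sj }))
      }
    },
    logistic_lv = {
      for (i in sp) for (j in sp) {
        Lij <- spec$Lambda[i, j]
        if (!is.na(Lij)) {
          ri0 <- spec$r0[[i]]
          add(i, j, local({ ri0 <- ri0; Lij <- Lij
            function(Sj, Si) -ri0 * Sj / Lij }))
        }
      }
    },
    saturable_lv = {
      for (i in sp) for (j in sp) {
        rij <- spec$r[i, j]
        if (!is.na(rij) && rij != 0) {
          Kij <- spec$K[i, j]
          add(i, j, local({ rij <- rij; Kij <- Kij
            function(Sj, Si) rij * Sj / (Kij + Sj) }))
        }
      }
    },
    alternative = {
      add(sp[2], sp[1],
          local({ r21 <- spec$r21; om <- spec$omega; ps <- spec$psi
            function(Sj, Si) {
              den <- om * Sj + ps * Si
              if (abs(den) < .Machine$double.xmin)
                den <- sign(den + .Machine$double.xmin) *
                  .Machine$double.xmin
              r21 * Sj / den
            } }))
    },
    divided_simplified = {
      add(sp[2], sp[1],
          local({ rho <- spec$rho; fl <- S_ext
            function(Sj, Si) rho * Sj / max(Si, fl) }))
    },
    stop("pairwise form '", spec$form,
         "' cannot be decomposed into additive terms"))
  terms
}

#' Derivative function of a pairwise model
#'
#' @param spec A [pairwise-specs] object.
#' @param S_ext Floor used by the divided-influence form.
#' @return A function `f(t, y, parms)` in `deSolve` form over the spec's
#'   species densities.
#' @export
pairwise_rhs <- function(spec, S_ext = 1e-2) {
  sp <- spec$species
  n <- length(sp)
  if (spec$form == "competitive_commensal_lv") {
    b0 <- spec$b0; d <- spec$d; L <- spec$Lambda; r21 <- spec$r21
    return(function(t, y, parms) {
      S <- pmax(y, 0)
      free1 <- 1 - S[1] / L[1, 1] - S[2] / L[1, 2]
      free2 <- 1 - S[1] / L[2, 1] - S[2] / L[2, 2]
      g <- c(b0[1] * free1 - d[1],
             (b0[2] + r21 * S[1]) * free2 - d[2])
      list(pmin(pmax(g, -50), 50) * S)
    })
  }
  terms <- pairwise_terms(spec, S_ext)
  r0 <- unname(spec$r0[sp])
  t_focal <- match(vapply(terms, `[[`, "", "focal"), sp)
  t_infl <- match(vapply(terms, `[[`, "", "influencer"), sp)
  t_fn <- lapply(terms, `[[`, "fn")
  function(t, y, parms) {
    S <- pmax(y, 0)
    g <- r0
    for (k in seq_along(t_fn))
      g[t_focal[k]] <- g[t_focal[k]] + t_fn[[k]](S[t_infl[k]], S[t_focal[k]])
    # per-capita rates beyond +-50/h are unphysical; capping them keeps
    # the solver away from the divided-form singularity during fitting
    list(pmin(pmax(g, -50), 50) * S)
  }
}

#' Simulate a pairwise model
#'
#' Integrates a pairwise spec under the same dilution protocol and
#' extinction rules as the mechanistic simulator, so that fold-difference
#' comparisons between the two are like for like.
#'
#' @param spec A [pairwise-specs] object or a multispecies assembly from
#'   [assemble_multispecies()].
#' @param init Named initial densities (cells/ml).
#' @param t_end End time (hours).
#' @param dilution A [dilution_policy()].
#' @param S_ext Extinction floor (cells/ml).
#' @param n_out,rtol,atol Solver settings.
#' @return A `trajectory` (species only).
#' @export
simulate_pairwise <- function(spec, init, t_end, dilution = no_dilution(),
                              S_ext = 1e-2, n_out = 400,
                              rtol = 1e-8, atol = 1e-10,
                              maxsteps = 50000, max_events = 20000) {
  sp <- spec$species
  stopifnot(all(sp %in% names(init)))
  rhs <- if (inherits(spec, "pairwise_assembly"))
    assembly_rhs(spec, S_ext) else pairwise_rhs(spec, S_ext)
  res <- integrate_dilution(rhs, unname(init[sp]), t_end, length(sp),
                            dilution, S_ext, n_out = n_out,
                            rtol = rtol, atol = atol,
                            maxsteps = maxsteps, max_events = max_events)
  spm <- res$states
  colnames(spm) <- sp
  new_trajectory(res$times, spm, NULL,
                 dilution_times = res$dilution_times,
                 meta = list(form = spec$form %||% "assembly",
                             t_end = t_end))
}

# ---- multispecies assembly ----------------------------------------------

#' Assemble a multispecies pairwise model from two-species components
#'
#' Builds an N-species pairwise model
#' `dSi/dt = (ri0 + sum_j f_ij(Sj)) Si` from fitted or derived two-species
#' specs, combining fitness effects additively.  Mixed forms are allowed
#' per pair (the central observation being that different pairs may need
#' different forms).  Basal fitnesses for the same species must agree
#' across components.
#'
#' @param specs List of two-species [pairwise-specs] objects (any additive
#'   form: linear, logistic, saturable, alternative, divided).
#' @param r0_tol Relative tolerance for basal-fitness agreement.
#' @return An object of class `pairwise_assembly` usable with
#'   [simulate_pairwise()].
#' @export
assemble_multispecies <- function(specs, r0_tol = 1e-8) {
  species <- unique(unlist(lapply(specs, `[[`, "species")))
  r0 <- setNames(rep(NA_real_, length(species)), species)
  for (s in specs) {
    for (id in s$species) {
      v <- s$r0[[id]]
      if (is.na(r0[[id]])) r0[[id]] <- v
      else if (abs(r0[[id]] - v) > r0_tol * max(1, abs(v)))
        stop("assembly error: conflicting basal fitness for species '",
             id, "' (", r0[[id]], " vs ", v, ")")
    }
  }
  terms <- unlist(lapply(specs, pairwise_terms), recursive = FALSE)
  structure(list(species = species, r0 = r0, terms = terms,
                 components = specs),
            class = "pairwise_assembly")
}

assembly_rhs <- function(asm, S_ext = 1e-2) {
  sp <- asm$species
  r0 <- unname(asm$r0[sp])
  t_focal <- match(vapply(asm$terms, `[[`, "", "focal"), sp)
  t_infl <- match(vapply(asm$terms, `[[`, "", "influencer"), sp)
  t_fn <- lapply(asm$terms, `[[`, "fn")
  function(t, y, parms) {
    S <- pmax(y, 0)
    g <- r0
    for (k in seq_along(t_fn))
      g[t_focal[k]] <- g[t_focal[k]] + t_fn[[k]](S[t_infl[k]], S[t_focal[k]])
    list(pmin(pmax(g, -50), 50) * S)
  }
}

#' @export
print.pairwise_assembly <- function(x, ...) {
  cat("<pairwise_assembly> species: ", paste(x$species, collapse = ", "),
      "; ", length(x$terms), " interaction terms\n", sep = "")
  invisible(x)
}
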