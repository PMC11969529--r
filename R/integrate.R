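#' Merge cell-type models into one multi-compartment brain model
#'
#' Reaction ids, subsystems and compartment tokens of each input model are
#' suffixed with that model's cell token (metabolite `glc[c]` of the
#' neuron becomes `glc[c_N]`), so the merged stoichiometric matrix is
#' block-diagonal over the inputs until intercellular reactions are added.
#' Gene identifiers live in the shared global namespace and are not
#' suffixed. An empty suffix `""` leaves a model untouched, which is how
#' an already-merged model is extended: sequential pairwise merging and a
#' one-shot merge of all models give the same canonical model.
#'
#' @param models List of >= 2 `metabolic_model`s.
#' @param suffixes Character vector, one token per model (`""` = already
#'   suffixed); non-empty tokens must be unique.
#' @return The merged `metabolic_model`.
#' @export
merge_models <- function(models, suffixes) {
  stopifnot(is.list(models), length(models) >= 2L,
            length(suffixes) == length(models))
  nonempty <- suffixes[nzchar(suffixes)]
  if (anyDuplicated(nonempty)) stop("suffix collision: suffixes must be unique")
  suffixed <- mapply(.suffix_model, models, suffixes, SIMPLIFY = FALSE)
  all_rxns <- unlist(lapply(suffixed, `[[`, "reactions"), recursive = FALSE)
  rxn_ids <- vapply(all_rxns, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) {
    stop(sprintf("suffix collision: duplicated reaction id(s) after merge: %s",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  mets <- do.call(rbind, lapply(suffixed, `[[`, "metabolites"))
  mets <- mets[!duplicated(mets$id), , drop = FALSE]
  genes <- sort(unique(unlist(lapply(suffixed, `[[`, "genes"))))
  ann <- list(merged_from = unlist(lapply(seq_along(models), function(i) {
    stats::setNames(models[[i]]$id, suffixes[i])
  })))
  canonicalize_model(metabolic_model(
    id = paste0("brain_", paste(nonempty, collapse = "")),
    reactions = all_rxns, metabolites = mets, genes = genes,
    annotations = ann))
}

.suffix_model <- function(model, suffix) {
  if (!nzchar(suffix)) return(model)
  ids <- model$metabolites$id
  new_met <- function(id) {
    base <- sub("\\[[^]]*\\]$", "", id)
    comp <- met_compartment(id)
    sprintf("%s[%s_%s]", base, comp, suffix)
  }
  met_map <- stats::setNames(vapply(ids, new_met, character(1)), ids)
  model$metabolites$id <- unname(met_map[model$metabolites$id])
  model$metabolites$compartment <- paste(model$metabolites$compartment,
                                         suffix, sep = "_")
  model$reactions <- lapply(model$reactions, function(r) {
    r$id <- paste(r$id, suffix, sep = "_")
    names(r$stoichiometry) <- unname(met_map[names(r$stoichiometry)])
    r$subsystem <- paste(r$subsystem, suffix, sep = "_")
    r
  })
  model
}

#' Intercellular transport specification
#'
#' Each row moves one metabolite between two cells' interstitial
#' interfaces (or to the shared brain interstitial pool with the `to`
#' token `"shared"`, used for lactate exchange among all cells).
#'
#' @param rows data.frame with columns metabolite (base name, no
#'   compartment), from, to (cell suffix tokens or `"shared"`),
#'   reversible (logical), and optionally ub (capacity, default 1000).
#' @return A list of class `intercellular_spec`.
#' @export
intercellular_spec <- function(rows) {
  need <- c("metabolite", "from", "to", "reversible")
  if (!all(need %in% names(rows))) {
    stop(sprintf("intercellular spec needs columns %s", paste(need, collapse = ", ")))
  }
  if (is.null(rows$ub)) rows$ub <- rep(1000, nrow(rows))
  if (any(rows$from == rows$to)) {
    stop("intercellular spec: from and to must differ")
  }
  key <- paste(rows$metabolite, rows$from, rows$to)
  if (anyDuplicated(key)) {
    stop(sprintf("intercellular spec: duplicated row(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  structure(list(rows = rows), class = "intercellular_spec")
}

#' Default intercellular reaction set of the toy brain
#'
#' Encodes the neurotransmitter and metabolite crosstalk the integrated
#' brain model is built around: glutamate and GABA transfer from neuron
#' to astrocyte with glutamine returned from astrocyte to neuron (the
#' glutamate/glutamine/GABA cycle), reversible glycine/aspartate/alanine
#' exchange between neuron and astrocyte, glutamine transfer from
#' astrocyte to microglia and glutamate from neuron to microglia, NAA
#' transfer from neuron to oligodendrocyte, and lactate exchange among
#' all four cells through a shared interstitial lactate pool (one
#' reversible reaction per cell rather than pairwise transfers).
#' Capacities are the toy network's neurotransmitter-scale fluxes; the
#' glutamine cycle capacity (0.040) is what the cycle objective saturates
#' at rest.
#'
#' @return An [intercellular_spec()].
#' @export
default_intercellular_spec <- function() {
  rows <- rbind(
    data.frame(metabolite = "glu", from = "N", to = "A", reversible = FALSE, ub = 0.05),
    data.frame(metabolite = "gln", from = "A", to = "N", reversible = FALSE, ub = 0.04),
    data.frame(metabolite = "gaba", from = "N", to = "A", reversible = FALSE, ub = 0.05),
    data.frame(metabolite = "gly", from = "N", to = "A", reversible = TRUE, ub = 0.01),
    data.frame(metabolite = "asp", from = "N", to = "A", reversible = TRUE, ub = 0.01),
    data.frame(metabolite = "ala", from = "N", to = "A", reversible = TRUE, ub = 0.01),
    data.frame(metabolite = "gln", from = "A", to = "M", reversible = FALSE, ub = 0.01),
    data.frame(metabolite = "glu", from = "N", to = "M", reversible = FALSE, ub = 0.01),
    data.frame(metabolite = "naa", from = "N", to = "O", reversible = FALSE, ub = 0.01),
    data.frame(metabolite = "lac", from = "N", to = "shared", reversible = TRUE, ub = 0.05),
    data.frame(metabolite = "lac", from = "A", to = "shared", reversible = TRUE, ub = 0.05),
    data.frame(metabolite = "lac", from = "M", to = "shared", reversible = TRUE, ub = 0.05),
    data.frame(metabolite = "lac", from = "O", to = "shared", reversible = TRUE, ub = 0.05)
  )
  intercellular_spec(rows)
}

#' Add intercellular transport reactions to a merged brain model
#'
#' Each spec row becomes one transport reaction `ICT_<met>_<from>_to_<to>`
#' moving the metabolite from `met[e_<from>]` to `met[e_<to>]` (subsystem
#' `"Intercellular"`). The `"shared"` destination denotes the unsuffixed
#' brain interstitial compartment `e`, whose pool metabolites are created
#' on first use. Mass is conserved: coefficients are -1/+1 on the two
#' pools.
#'
#' @param brain Merged `metabolic_model`.
#' @param spec An [intercellular_spec()].
#' @return The extended model.
#' @export
add_intercellular_reactions <- function(brain, spec = default_intercellular_spec()) {
  stopifnot(inherits(spec, "intercellular_spec"))
  rows <- spec$rows
  for (i in seq_len(nrow(rows))) {
    met <- rows$metabolite[i]
    ends <- c(rows$from[i], rows$to[i])
    ids <- vapply(ends, function(tok) {
      if (tok == "shared") sprintf("%s[e]", met) else sprintf("%s[e_%s]", met, tok)
    }, character(1))
    for (k in seq_along(ids)) {
      if (ends[k] != "shared" && !(ids[k] %in% brain$metabolites$id)) {
        stop(sprintf("intercellular: metabolite '%s' missing at cell '%s'",
                     met, ends[k]))
      }
    }
    rid <- sprintf("ICT_%s_%s_to_%s", met, rows$from[i], rows$to[i])
    if (rid %in% reaction_ids(brain)) {
      stop(sprintf("intercellular: duplicated reaction '%s'", rid))
    }
    lb <- if (isTRUE(rows$reversible[i])) -rows$ub[i] else 0
    brain <- add_reaction(brain, reaction(
      rid, stats::setNames(c(-1, 1), ids),
      lower_bound = lb, upper_bound = rows$ub[i],
      subsystem = "Intercellular"))
  }
  validate_model(brain)
  brain
}

#' Transfer single-cell exchange behaviour into the merged model
#'
#' The merged model's per-cell uptake capacities are taken from the
#' single-cell solutions: each exchange's uptake bound becomes the flux
#' that cell actually used on its own (floored at the default -0.01),
#' with release left unconstrained (`pin = "capacity"`, the default). The
#' alternative `pin = "exact"` clamps each exchange to the single-cell
#' flux within a tolerance, reproducing the single-cell boundary exactly
#' but leaving no headroom for intercellular objectives.
#'
#' @param brain Merged `metabolic_model`.
#' @param states Named list (suffix token -> single-cell `flux_state`).
#' @param pin `"capacity"` or `"exact"`.
#' @param default_lb Fallback uptake bound (default -0.01).
#' @param tol Clamp half-width for `pin = "exact"`.
#' @param exclude Base exchange ids left untouched. Fuel exchanges are
#'   excluded by default: their capacities model vascular delivery, not
#'   the isolated cell's consumption, and the perturbation protocols act
#'   on exactly these bounds.
#' @return The constrained merged model.
#' @export
transfer_exchange_constraints <- function(brain, states, pin = c("capacity", "exact"),
                                          default_lb = -0.01, tol = 1e-6,
                                          exclude = c("EX_o2", "EX_glc",
                                                      "EX_acac", "EX_bhb",
                                                      "EX_ffa")) {
  pin <- match.arg(pin)
  ids <- reaction_ids(brain)
  for (sfx in names(states)) {
    st <- states[[sfx]]
    ex <- grep(sprintf("^EX_.*_%s$", sfx), ids, value = TRUE)
    ex <- ex[!(sub(sprintf("_%s$", sfx), "", ex) %in% exclude)]
    for (rid in ex) {
      base <- sub(sprintf("_%s$", sfx), "", rid)
      v <- st$fluxes[[base]]
      if (is.null(v) || is.na(v)) next
      if (pin == "exact") {
        brain <- set_bounds(brain, rid, lb = v - tol, ub = v + tol)
      } else {
        brain <- set_bounds(brain, rid, lb = min(v, default_lb), ub = 1000)
      }
    }
  }
  brain
}
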