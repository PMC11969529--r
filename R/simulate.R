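#' Flux balance analysis
#'
#' Solves `max (or min) c'v` subject to steady state `S v = 0` and the
#' model's flux bounds. Fluxes are in umol/g tissue/min throughout.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id(s) (coefficient 1 each) or a named numeric
#'   coefficient vector.
#' @param sense `"max"` (default) or `"min"`.
#' @return A `flux_state` with per-reaction fluxes, objective value,
#'   solver status (`optimal`, `infeasible` or `error`) and the steady-state
#'   residual `max|S v|`.
#' @export
fba <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- .model_lp_parts(model)
  cc <- .objective_vector(model, objective)
  r <- .lp_solve(cc, p$S, rep(0, nrow(p$S)), p$lb, p$ub, sense = sense)
  if (r$status != "optimal") {
    return(.flux_state(model, NULL, NA_real_, r$status))
  }
  .flux_state(model, r$x, r$objective, "optimal")
}

#' Two-stage flux balance analysis (parsimonious solution)
#'
#' Stage 1 optimizes the linear objective; stage 2 fixes the objective at
#' its optimum and minimizes the squared sum of fluxes over all reactions,
#' removing the degeneracy of alternate optima. The returned state is the
#' unique quadratic-stage solution.
#'
#' @inheritParams fba
#' @return A `flux_state`; `objective_value` is the stage-1 optimum.
#' @export
fba_two_stage <- function(model, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- .model_lp_parts(model)
  cc <- .objective_vector(model, objective)
  s1 <- .lp_solve(cc, p$S, rep(0, nrow(p$S)), p$lb, p$ub, sense = sense)
  if (s1$status != "optimal") return(.flux_state(model, NULL, NA_real_, s1$status))
  E <- rbind(p$S, cc)
  b <- c(rep(0, nrow(p$S)), s1$objective)
  s2 <- .qp_nearest(rep(0, length(cc)), E, b, p$lb, p$ub)
  if (s2$status != "optimal") {
    stop(sprintf("second-stage QP failed: %s", s2$message))
  }
  .flux_state(model, s2$x, s1$objective, "optimal")
}

#' Flux variability analysis
#'
#' Minimizes and maximizes the flux through each reaction under the
#' model's constraints, giving the attainable flux range per reaction.
#'
#' @param model A `metabolic_model`.
#' @param reactions Reaction ids to analyse (default: all).
#' @param fix_objective Optional list `list(objective =, value =)` fixing a
#'   linear combination of fluxes (e.g. the FBA optimum) during the scan.
#' @return data.frame with columns reaction_id, min, max, status; a
#'   per-reaction solver failure is recorded in `status`, not raised.
#' @export
fva <- function(model, reactions = NULL, fix_objective = NULL) {
  p <- .model_lp_parts(model)
  if (is.null(reactions)) reactions <- p$ids
  idx <- match(reactions, p$ids)
  if (anyNA(idx)) stop("fva: unknown reaction id(s)")
  E <- p$S
  b <- rep(0, nrow(p$S))
  if (!is.null(fix_objective)) {
    E <- rbind(E, .objective_vector(model, fix_objective$objective))
    b <- c(b, fix_objective$value)
  }
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    cc <- rep(0, length(p$ids)); cc[idx[k]] <- 1
    lo <- .lp_solve(cc, E, b, p$lb, p$ub, sense = "min")
    hi <- .lp_solve(cc, E, b, p$lb, p$ub, sense = "max")
    if (lo$status == "optimal") out$min[k] <- lo$objective
    if (hi$status == "optimal") out$max[k] <- hi$objective
    if (lo$status != "optimal" || hi$status != "optimal") {
      out$status[k] <- paste(unique(c(lo$status, hi$status)), collapse = "/")
    }
  }
  out
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux distribution of the (perturbed) model nearest in
#' Euclidean distance to a reference distribution: `min ||v - v_ref||^2`
#' subject to `S v = 0` and the current bounds. Used to predict the
#' metabolic response to a perturbation as a minimal rerouting of the
#' reference state rather than a re-optimization.
#'
#' @param model The perturbed `metabolic_model` (same reaction set as the
#'   reference, possibly with changed bounds).
#' @param reference A `flux_state` or named flux vector on the same
#'   reaction set.
#' @return A `flux_state`; `distance` is the Euclidean distance to the
#'   reference, `objective_value` the squared distance.
#' @export
moma <- function(model, reference) {
  ref <- if (inherits(reference, "flux_state")) reference$fluxes else reference
  ids <- reaction_ids(model)
  if (!all(ids %in% names(ref))) {
    stop("reference does not cover all model reactions")
  }
  refv <- unname(ref[ids])
  p <- .model_lp_parts(model)
  r <- .qp_nearest(refv, p$S, rep(0, nrow(p$S)), p$lb, p$ub)
  if (r$status != "optimal") return(.flux_state(model, NULL, NA_real_, r$status))
  .flux_state(model, r$x, r$distance2, "optimal", distance = sqrt(max(0, r$distance2)))
}

#' Build a constraint table
#'
#' @param bounds data.frame with columns reaction_id, lb, ub (`NA` keeps
#'   the model bound).
#' @param couplings data.frame with columns reaction_a, reaction_b, alpha,
#'   each row enforcing `v_a = alpha * v_b` exactly.
#' @param exchange_lb,exchange_ub Default bounds applied to every exchange
#'   reaction not listed in `bounds`: uptake capped at 0.01 (lb = -0.01)
#'   and release effectively unlimited (ub = 1000).
#' @return A list of class `constraint_table`.
#' @export
constraint_table <- function(bounds = NULL, couplings = NULL,
                             exchange_lb = -0.01, exchange_ub = 1000) {
  if (is.null(bounds)) {
    bounds <- data.frame(reaction_id = character(0), lb = numeric(0),
                         ub = numeric(0), stringsAsFactors = FALSE)
  }
  if (is.null(couplings)) {
    couplings <- data.frame(reaction_a = character(0), reaction_b = character(0),
                            alpha = numeric(0), stringsAsFactors = FALSE)
  }
  bad <- !is.na(bounds$lb) & !is.na(bounds$ub) & bounds$lb > bounds$ub
  if (any(bad)) {
    stop(sprintf("constraint_table: lb > ub for %s",
                 paste(bounds$reaction_id[bad], collapse = ", ")))
  }
  if (any(couplings$alpha < 0)) stop("constraint_table: coupling alpha must be >= 0")
  structure(list(bounds = bounds, couplings = couplings,
                 exchange_lb = exchange_lb, exchange_ub = exchange_ub),
            class = "constraint_table")
}

#' Apply a constraint table to a model
#'
#' Applies the default exchange policy (every exchange reaction not listed
#' explicitly gets lb = `exchange_lb`, ub = `exchange_ub`), the explicit
#' bound rows, and the coupling rows. For the glial roles `"microglia"`
#' and `"oligodendrocyte"` the explicit bound rows are reused with lower
#' bounds of internal (non-exchange) reactions set to zero, mirroring the
#' use of astrocyte-derived upper bounds for the other glial cells.
#'
#' Couplings `v_a = alpha * v_b` are materialized as extra stoichiometric
#' rows: a balance pseudo-metabolite `cpl_<a>__<b>[x]` is produced by
#' reaction a (+1) and consumed by reaction b (-alpha), so the steady-state
#' condition enforces the ratio exactly in every solution.
#'
#' @param model A `metabolic_model`.
#' @param table A [constraint_table()].
#' @param cell_role Optional role of the cell the table is applied to
#'   (`"neuron"`, `"astrocyte"`, `"microglia"`, `"oligodendrocyte"`).
#' @return The constrained model.
#' @export
apply_constraints <- function(model, table, cell_role = NULL) {
  stopifnot(inherits(table, "constraint_table"))
  ids <- reaction_ids(model)
  unknown <- setdiff(table$bounds$reaction_id, ids)
  if (length(unknown)) {
    stop(sprintf("apply_constraints: unknown reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  # the default uptake policy concerns the system boundary only:
  # single-metabolite reactions on extracellular species. Internal demand
  # drains (DM_*) keep their own bounds - a negative lower bound there
  # would be a free source of matter.
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  exch <- vapply(model$reactions, function(r) {
    length(r$stoichiometry) == 1L &&
      startsWith(comp[[names(r$stoichiometry)]], "e")
  }, logical(1))
  default_exch <- ids[exch & !(ids %in% table$bounds$reaction_id)]
  if (length(default_exch)) {
    model <- set_bounds(model, default_exch, lb = table$exchange_lb,
                        ub = table$exchange_ub)
  }
  bounds <- table$bounds
  if (!is.null(cell_role) && cell_role %in% c("microglia", "oligodendrocyte")) {
    internal <- bounds$reaction_id %in% ids[!exch]
    bounds$lb[internal] <- 0
  }
  if (nrow(bounds)) {
    model <- set_bounds(model, bounds$reaction_id, lb = bounds$lb, ub = bounds$ub)
  }
  if (nrow(table$couplings)) {
    for (i in seq_len(nrow(table$couplings))) {
      model <- .add_coupling(model, table$couplings$reaction_a[i],
                             table$couplings$reaction_b[i],
                             table$couplings$alpha[i])
    }
  }
  model
}

# Enforce v_a = alpha * v_b via a balance pseudo-metabolite.
.add_coupling <- function(model, rxn_a, rxn_b, alpha) {
  ids <- reaction_ids(model)
  for (r in c(rxn_a, rxn_b)) {
    if (!(r %in% ids)) stop(sprintf("coupling: unknown reaction '%s'", r))
  }
  met <- sprintf("cpl_%s__%s[x]", rxn_a, rxn_b)
  if (met %in% model$metabolites$id) {
    stop(sprintf("coupling between '%s' and '%s' already present", rxn_a, rxn_b))
  }
  model$metabolites <- rbind(model$metabolites,
                             metabolite_table(met, name = met, compartment = "x"))
  ia <- match(rxn_a, ids); ib <- match(rxn_b, ids)
  model$reactions[[ia]]$stoichiometry[met] <- 1
  model$reactions[[ib]]$stoichiometry[met] <-
    if (is.na(model$reactions[[ib]]$stoichiometry[met])) -alpha else
      model$reactions[[ib]]$stoichiometry[met] - alpha
  model
}

#' Glutamate/glutamine/GABA cycle objective for the integrated brain
#'
#' The neuron-astrocyte neurotransmitter cycle is operationalized as the
#' glutamine transfer flux from astrocyte to neuron; intercellular GABA
#' flux from neuron to astrocyte is coupled to 25% of that cycle flux
#' (both configurable). Returns the coupled model plus the objective
#' reaction so callers can run [fba_two_stage()].
#'
#' @param brain The merged brain `metabolic_model` with intercellular
#'   reactions.
#' @param cycle_reaction Id of the glutamine astrocyte-to-neuron transfer.
#' @param gaba_reaction Id of the GABA neuron-to-astrocyte transfer.
#' @param gaba_ratio GABA/cycle coupling ratio (default 0.25).
#' @return list(model = coupled model, objective = cycle reaction id).
#' @export
brain_objective_ggg <- function(brain, cycle_reaction = "ICT_gln_A_to_N",
                                gaba_reaction = "ICT_gaba_N_to_A",
                                gaba_ratio = 0.25) {
  ids <- reaction_ids(brain)
  for (r in c(cycle_reaction, gaba_reaction)) {
    if (!(r %in% ids)) {
      stop(sprintf("brain_objective_ggg: missing intercellular reaction '%s'", r))
    }
  }
  if (!is.null(gaba_ratio)) {
    brain <- .add_coupling(brain, gaba_reaction, cycle_reaction, gaba_ratio)
  }
  list(model = brain, objective = cycle_reaction)
}

#' Subsystem activity summary of a flux state
#'
#' Activity of a subsystem is the sum of absolute fluxes of its reactions;
#' a reaction counts as active when `|v|` exceeds the zero threshold
#' (default 1e-6 umol/g tissue/min). Transport, exchange/demand and
#' intercellular subsystems are flagged `boundary` and are excluded from
#' mean-subsystem-flux style summaries by downstream consumers.
#'
#' @param state A `flux_state`.
#' @param model The model it was solved on.
#' @param zero_tol Active-flux threshold.
#' @return data.frame: subsystem, flux_sum, active, total, boundary.
#' @export
subsystem_activity <- function(state, model, zero_tol = 1e-6) {
  stopifnot(inherits(state, "flux_state"))
  subs <- reaction_subsystems(model)
  v <- abs(state$fluxes[names(subs)])
  df <- data.frame(subsystem = unname(subs), absflux = unname(v),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$subsystem), function(d) {
    data.frame(subsystem = d$subsystem[1],
               flux_sum = sum(d$absflux),
               active = sum(d$absflux > zero_tol),
               total = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$boundary <- grepl("^(Transport|Exchange/demand|Intercellular)", agg$subsystem)
  agg[order(agg$subsystem), , drop = FALSE]
}

# Set a per-cell exchange bound in a merged model: base id + suffix.
.set_cell_exchange <- function(brain, base_id, suffixes, lb = NA, ub = NA) {
  ids <- paste(base_id, suffixes, sep = "_")
  present <- ids %in% reaction_ids(brain)
  if (!any(present)) stop(sprintf("no reaction matching '%s_<suffix>'", base_id))
  set_bounds(brain, ids[present], lb = lb, ub = ub)
}

#' Run a perturbation protocol on the integrated brain model
#'
#' Protocols mirror in-silico dietary and pathological conditions:
#' \describe{
#'   \item{resting}{the baseline two-stage optimization of the
#'     glutamate/glutamine/GABA cycle objective.}
#'   \item{glucose}{glucose uptake capacity of each cell raised to
#'     0.210 umol/g tissue/min (glucose supplementation).}
#'   \item{ketogenic}{acetoacetate and (R)-3-hydroxybutanoate uptake
#'     capacities raised to 0.050 and glucose to 0.210 in all cells.}
#'   \item{hypoxia}{each cell's oxygen uptake capacity reduced by 0.100
#'     (floored at zero).}
#'   \item{demyelination}{the oligodendrocyte myelin-formation flux is
#'     stepped from 0.010 to 0 at 10% intervals (11 levels) and each level
#'     is solved by [moma()] against the resting reference.}
#' }
#'
#' @param brain Constrained merged brain model (before the cycle objective
#'   coupling; it is added here).
#' @param protocol One of `"resting"`, `"glucose"`, `"ketogenic"`,
#'   `"hypoxia"`, `"demyelination"`.
#' @param config Protocol parameters; see [default_run_config()].
#' @param reference Optional resting `flux_state` (computed if missing;
#'   required shape for demyelination deltas).
#' @return list with elements `protocol`, `states` (named list of
#'   `flux_state`), `activity` (per-state subsystem activity tables),
#'   `activity_delta` (activity minus resting activity),
#'   `intercellular` (per-state fluxes of intercellular reactions), and
#'   for demyelination `levels` and `infeasible_levels`.
#' @export
run_protocol <- function(brain, protocol = c("resting", "glucose", "ketogenic",
                                             "hypoxia", "demyelination"),
                         config = default_run_config(), reference = NULL) {
  protocol <- match.arg(protocol)
  cfg <- config$protocol
  obj <- brain_objective_ggg(brain,
                             cycle_reaction = cfg$cycle_reaction,
                             gaba_reaction = cfg$gaba_reaction,
                             gaba_ratio = cfg$gaba_ratio)
  base <- obj$model
  suffixes <- cfg$cell_suffixes
  if (is.null(reference)) {
    reference <- fba_two_stage(base, obj$objective)
    if (reference$status != "optimal") {
      stop("run_protocol: resting state is not solvable")
    }
  }
  ict_ids <- grep("^ICT_", reaction_ids(base), value = TRUE)
  states <- list(resting = reference)
  levels <- NULL; infeasible <- integer(0)
  if (protocol == "glucose") {
    m <- .set_cell_exchange(base, cfg$glucose_exchange, suffixes,
                            lb = -cfg$supplemented_glucose)
    states$glucose <- fba_two_stage(m, obj$objective)
  } else if (protocol == "ketogenic") {
    m <- .set_cell_exchange(base, cfg$glucose_exchange, suffixes,
                            lb = -cfg$supplemented_glucose)
    for (ex in cfg$ketone_exchanges) {
      # ketone uptake is a pinned rate (see default_cell_constraints)
      m <- .set_cell_exchange(m, ex, suffixes, lb = -cfg$ketone_uptake,
                              ub = -cfg$ketone_uptake)
    }
    states$ketogenic <- fba_two_stage(m, obj$objective)
  } else if (protocol == "hypoxia") {
    m <- base
    for (sfx in suffixes) {
      id <- paste(cfg$oxygen_exchange, sfx, sep = "_")
      if (!(id %in% reaction_ids(m))) next
      lb0 <- reaction_bounds(m)$lower_bound[match(id, reaction_ids(m))]
      m <- set_bounds(m, id, lb = min(lb0 + cfg$hypoxia_o2_decrement, 0))
    }
    states$hypoxia <- fba_two_stage(m, obj$objective)
  } else if (protocol == "demyelination") {
    levels <- cfg$myelin_levels
    myelin_id <- cfg$myelin_reaction
    if (!(myelin_id %in% reaction_ids(base))) {
      stop(sprintf("run_protocol: myelin reaction '%s' not in model", myelin_id))
    }
    for (k in seq_along(levels)) {
      m <- set_bounds(base, myelin_id, lb = levels[k], ub = levels[k])
      st <- moma(m, reference)
      nm <- sprintf("myelin_%.3f", levels[k])
      states[[nm]] <- st
      if (st$status != "optimal") infeasible <- c(infeasible, k)
    }
  }
  activity <- lapply(states, function(s) {
    if (s$status == "optimal") subsystem_activity(s, base, config$zero_flux_tol) else NULL
  })
  rest_act <- activity$resting
  activity_delta <- lapply(activity, function(a) {
    if (is.null(a)) return(NULL)
    d <- a
    d$flux_sum <- a$flux_sum - rest_act$flux_sum[match(a$subsystem, rest_act$subsystem)]
    d$active <- a$active - rest_act$active[match(a$subsystem, rest_act$subsystem)]
    d[c("subsystem", "flux_sum", "active", "boundary")]
  })
  intercellular <- do.call(rbind, lapply(names(states), function(nm) {
    s <- states[[nm]]
    if (s$status != "optimal") return(NULL)
    data.frame(state = nm, reaction_id = ict_ids,
               flux = unname(s$fluxes[ict_ids]),
               stringsAsFactors = FALSE)
  }))
  list(protocol = protocol, objective = obj$objective, states = states,
       activity = activity, activity_delta = activity_delta,
       intercellular = intercellular, levels = levels,
       infeasible_levels = infeasible)
}
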