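#' TPM normalization
#'
#' Transcripts per million: reads are first divided by gene length (reads
#' per kilobase would differ only by a constant) and then scaled so the
#' normalized values sum to one million, accounting for both gene length
#' and sequencing depth.
#'
#' @param counts Named non-negative numeric vector of raw read counts.
#' @param lengths Named positive numeric vector of gene lengths (bp),
#'   covering all genes in `counts`.
#' @return Named numeric vector of TPM values summing to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  if (is.null(names(counts)) || is.null(names(lengths))) {
    stop("counts and lengths must be named by gene")
  }
  missing <- setdiff(names(counts), names(lengths))
  if (length(missing)) {
    stop(sprintf("missing gene length(s): %s", paste(missing, collapse = ", ")))
  }
  lengths <- lengths[names(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) stop("all counts are zero; cannot normalize")
  rate / total * 1e6
}

#' Mean expression across samples of one cell type
#'
#' @param profiles A genes x samples matrix of per-sample TPM values, or a
#'   list of identically-named per-sample TPM vectors.
#' @return Named numeric vector of per-gene arithmetic means.
#' @export
mean_expression <- function(profiles) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    gene_sets <- lapply(profiles, names)
    ref <- gene_sets[[1]]
    same <- vapply(gene_sets, function(g) identical(sort(g), sort(ref)), logical(1))
    if (!all(same)) stop("samples do not share a common gene set")
    profiles <- do.call(cbind, lapply(profiles, function(p) p[ref]))
  }
  if (is.null(rownames(profiles))) stop("profiles must be named by gene")
  rowMeans(profiles)
}

#' Score reactions by expression evidence
#'
#' Maps gene-level evidence (mean TPM) to reaction-level evidence through
#' the GPR rules (complex = min, isozymes = max) and flags reactions as
#' expressed at the cutoff. Reactions without a GPR (exchanges,
#' spontaneous transport) get `NA` evidence: they are evidence-neutral
#' and never removed for lack of expression.
#'
#' @param model A `metabolic_model`.
#' @param gene_scores Named numeric vector (e.g. from [mean_expression()]);
#'   genes missing from it score 0.
#' @param cutoff Expression threshold (default 1 TPM).
#' @return data.frame: reaction_id, evidence, expressed (NA for
#'   evidence-neutral reactions).
#' @export
reaction_evidence <- function(model, gene_scores, cutoff = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ev <- vapply(model$reactions, function(r) evaluate_gpr(r$gpr, gene_scores),
               numeric(1))
  data.frame(reaction_id = reaction_ids(model), evidence = ev,
             expressed = ifelse(is.na(ev), NA, ev >= cutoff),
             stringsAsFactors = FALSE)
}

#' Define a metabolic task
#'
#' A task is a feasibility query: with all model exchanges closed, can the
#' network produce the required outputs from the allowed inputs alone?
#' Inputs and outputs are implemented as temporary boundary reactions on
#' the named metabolites, so tasks can demand internal metabolites
#' directly. Optional fixed bounds force specific reactions (e.g. a
#' minimum ATP-maintenance flux turning an output task into an energy
#' task).
#'
#' @param id,description Identifiers.
#' @param inputs data.frame(metabolite, max_uptake) of allowed inputs.
#' @param outputs data.frame(metabolite, min_production); `min_production`
#'   0 marks a permitted by-product, > 0 a requirement. At least one row
#'   must have `min_production > 0` unless `bounds` forces a flux.
#' @param bounds Optional data.frame(reaction_id, lb, ub).
#' @return A list of class `metabolic_task`.
#' @export
metabolic_task <- function(id, description = id,
                           inputs = NULL, outputs = NULL, bounds = NULL) {
  inputs <- inputs %||% data.frame(metabolite = character(0), max_uptake = numeric(0))
  outputs <- outputs %||% data.frame(metabolite = character(0), min_production = numeric(0))
  if (any(inputs$max_uptake < 0) || any(outputs$min_production < 0)) {
    stop(sprintf("task '%s': task fluxes must be >= 0", id))
  }
  forced <- !is.null(bounds) && nrow(bounds) > 0 && any(bounds$lb > 0, na.rm = TRUE)
  if (!any(outputs$min_production > 0) && !forced) {
    stop(sprintf("task '%s': at least one required output (or forced bound) needed", id))
  }
  structure(list(id = id, description = description, inputs = inputs,
                 outputs = outputs, bounds = bounds),
            class = "metabolic_task")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.task_df <- function(metabolite, flux) {
  data.frame(metabolite = metabolite, flux = flux, stringsAsFactors = FALSE)
}

#' Check whether a model can perform a metabolic task
#'
#' All exchange/demand reactions are closed (both bounds 0), temporary
#' sources are added for the allowed inputs (flux in `[0, max_uptake]`),
#' temporary sinks for the outputs (flux in `[min_production, 1000]`),
#' any fixed task bounds applied, and feasibility decided by LP. When
#' feasible, the reported achieved flux is the maximized sum of
#' required-output sink fluxes.
#'
#' @param model A `metabolic_model`.
#' @param task A [metabolic_task()].
#' @return list(feasible, achieved_flux, reason). Referencing a
#'   metabolite the model lacks yields `feasible = FALSE` with a reason,
#'   not an error; genuine solver failure raises an error.
#' @export
check_task <- function(model, task) {
  stopifnot(inherits(task, "metabolic_task"))
  .check_task_lp(.task_parts(model), task)
}

# Precompute the LP skeleton task checks share: stoichiometric matrix,
# bounds, and which columns are boundary exchanges (single-metabolite
# reactions on an extracellular species; internal demand drains stay
# open as obligatory turnover).
.task_parts <- function(model) {
  p <- .model_lp_parts(model)
  comp <- stats::setNames(model$metabolites$compartment, model$metabolites$id)
  exch <- vapply(model$reactions, function(r) {
    length(r$stoichiometry) == 1L &&
      startsWith(comp[[names(r$stoichiometry)]], "e")
  }, logical(1))
  list(S = p$S, lb = p$lb, ub = p$ub, ids = p$ids, exch = exch,
       mets = rownames(p$S))
}

# Solve one task LP on a precomputed skeleton. `zero` names reactions
# treated as absent (bounds clamped to zero before task bounds apply).
.check_task_lp <- function(parts, task, zero = character(0)) {
  referenced <- c(task$inputs$metabolite, task$outputs$metabolite)
  absent <- setdiff(referenced, parts$mets)
  if (length(absent)) {
    return(list(feasible = FALSE, achieved_flux = NA_real_,
                reason = sprintf("metabolite(s) not in model: %s",
                                 paste(absent, collapse = ", "))))
  }
  lb <- parts$lb; ub <- parts$ub
  lb[parts$exch] <- 0; ub[parts$exch] <- 0
  if (length(zero)) {
    zi <- match(zero, parts$ids)
    lb[zi] <- 0; ub[zi] <- 0
  }
  if (!is.null(task$bounds) && nrow(task$bounds)) {
    bi <- match(task$bounds$reaction_id, parts$ids)
    if (anyNA(bi)) {
      return(list(feasible = FALSE, achieved_flux = NA_real_,
                  reason = sprintf("reaction(s) not in model: %s",
                                   paste(task$bounds$reaction_id[is.na(bi)],
                                         collapse = ", "))))
    }
    ok <- !is.na(task$bounds$lb); lb[bi[ok]] <- task$bounds$lb[ok]
    ok <- !is.na(task$bounds$ub); ub[bi[ok]] <- task$bounds$ub[ok]
  }
  n_in <- nrow(task$inputs); n_out <- nrow(task$outputs)
  m <- nrow(parts$S)
  extra <- matrix(0, m, n_in + n_out)
  if (n_in) extra[cbind(match(task$inputs$metabolite, parts$mets), seq_len(n_in))] <- 1
  if (n_out) {
    extra[cbind(match(task$outputs$metabolite, parts$mets),
                n_in + seq_len(n_out))] <- -1
  }
  S <- cbind(parts$S, extra)
  lb <- c(lb, rep(0, n_in), task$outputs$min_production)
  ub <- c(ub, task$inputs$max_uptake, rep(1000, n_out))
  cc <- numeric(ncol(S))
  required <- which(task$outputs$min_production > 0)
  if (length(required)) cc[ncol(parts$S) + n_in + required] <- 1 else cc[ncol(parts$S) + 1L] <- 1
  r <- .lp_solve(cc, S, rep(0, m), lb, ub, sense = "max")
  if (r$status == "error") stop("check_task: solver failure")
  if (r$status != "optimal") {
    return(list(feasible = FALSE, achieved_flux = NA_real_, reason = r$status))
  }
  list(feasible = TRUE, achieved_flux = r$objective, reason = NULL)
}

#' Cell-type task lists for the toy brain
#'
#' Essential tasks (ATP regeneration from glucose and oxygen, biomass
#' precursor synthesis) apply to every cell type; on top of these, each
#' cell carries the literature-derived neurotransmitter and lipid tasks of
#' its type: glutamine-to-glutamate conversion (neuron, microglia),
#' glutamate-to-GABA (neuron), GABA-to-glutamate (neuron, astrocyte),
#' glutamine synthesis from glutamate (astrocyte), serine/glycine
#' interconversion (neuron forward, astrocyte reverse), branched-chain
#' amino acid transamination (neuron, astrocyte), dopamine synthesis from
#' levodopa (neuron), norepinephrine from dopamine (neuron, astrocyte),
#' adrenaline and acetylcholine production (neuron), NAA synthesis
#' (neuron) and degradation (oligodendrocyte), and myelin formation
#' (oligodendrocyte). OPCs get the essential tasks only.
#'
#' @param cell_type Toy cell type (or `"master"` = union of all).
#' @return Named list of [metabolic_task()] objects.
#' @export
default_brain_tasks <- function(cell_type) {
  t_in <- function(...) {
    v <- c(...)
    data.frame(metabolite = names(v), max_uptake = unname(v),
               stringsAsFactors = FALSE)
  }
  t_out <- function(...) {
    v <- c(...)
    data.frame(metabolite = names(v), min_production = unname(v),
               stringsAsFactors = FALSE)
  }
  fuel <- c("glc[e]" = 1, "o2[e]" = 10, "nh4[e]" = 1)
  essentials <- list(
    atp_from_glc_o2 = metabolic_task(
      "atp_from_glc_o2", "regenerate ATP from glucose and oxygen",
      inputs = t_in("glc[e]" = 1, "o2[e]" = 10),
      outputs = t_out("co2[c]" = 0, "lac[c]" = 0),
      bounds = data.frame(reaction_id = "ATPM", lb = 2, ub = 1000)),
    biomass_precursors = metabolic_task(
      "biomass_precursors", "grow on glucose, oxygen and ammonia",
      inputs = t_in(fuel),
      outputs = t_out("biomass[c]" = 0.05, "co2[c]" = 0, "lac[c]" = 0))
  )
  neuron <- list(
    gln_to_glu = metabolic_task(
      "gln_to_glu", "produce glutamate from glutamine",
      inputs = t_in("gln[e]" = 1),
      outputs = t_out("glu[c]" = 0.5, "nh4[c]" = 0)),
    glu_to_gaba = metabolic_task(
      "glu_to_gaba", "convert glutamate into GABA",
      inputs = t_in("glu[e]" = 1),
      outputs = t_out("gaba[c]" = 0.5, "co2[c]" = 0)),
    gaba_to_glu = metabolic_task(
      "gaba_to_glu", "convert GABA into glutamate",
      inputs = t_in("gaba[e]" = 1, "glc[e]" = 1, "o2[e]" = 10),
      outputs = t_out("glu[c]" = 0.5, "co2[c]" = 0, "lac[c]" = 0)),
    ser_to_gly = metabolic_task(
      "ser_to_gly", "convert serine into glycine",
      inputs = t_in("ser[e]" = 1),
      outputs = t_out("gly[c]" = 0.5)),
    bcaa_transamination = metabolic_task(
      "bcaa_transamination",
      "transaminate leucine, isoleucine and valine to their keto-acids",
      inputs = t_in("leu[e]" = 1, "ile[e]" = 1, "val[e]" = 1, "glc[e]" = 2,
                    "o2[e]" = 10, "nh4[e]" = 1),
      outputs = t_out("kic[c]" = 0.2, "kmv[c]" = 0.2, "kiv[c]" = 0.2,
                      "glu[c]" = 0, "co2[c]" = 0, "lac[c]" = 0)),
    ldopa_to_dopamine = metabolic_task(
      "ldopa_to_dopamine", "produce dopamine from levodopa",
      inputs = t_in("ldopa[e]" = 1),
      outputs = t_out("dopa[c]" = 0.5, "co2[c]" = 0)),
    dopamine_to_ne = metabolic_task(
      "dopamine_to_ne", "convert dopamine into norepinephrine",
      inputs = t_in("dopa[e]" = 1, "o2[e]" = 10),
      outputs = t_out("ne[c]" = 0.5)),
    adrenaline_production = metabolic_task(
      "adrenaline_production", "produce adrenaline from levodopa",
      inputs = t_in("ldopa[e]" = 1, "o2[e]" = 10),
      outputs = t_out("adr[c]" = 0.5, "co2[c]" = 0)),
    acetylcholine_production = metabolic_task(
      "acetylcholine_production", "produce acetylcholine",
      inputs = t_in("glc[e]" = 1, "o2[e]" = 10, "chln[e]" = 1),
      outputs = t_out("ach[c]" = 0.1, "co2[c]" = 0, "lac[c]" = 0)),
    naa_synthesis = metabolic_task(
      "naa_synthesis", "synthesize NAA from glucose-derived precursors",
      inputs = t_in(fuel),
      outputs = t_out("naa[c]" = 0.1, "co2[c]" = 0, "lac[c]" = 0))
  )
  astrocyte <- list(
    glu_to_gln = metabolic_task(
      "glu_to_gln", "produce glutamine from glutamate",
      inputs = t_in("glu[e]" = 1, "nh4[e]" = 1, "glc[e]" = 1, "o2[e]" = 10),
      outputs = t_out("gln[c]" = 0.5, "co2[c]" = 0, "lac[c]" = 0)),
    gaba_to_glu = neuron$gaba_to_glu,
    gly_to_ser = metabolic_task(
      "gly_to_ser", "convert glycine into serine",
      inputs = t_in("gly[e]" = 1),
      outputs = t_out("ser[c]" = 0.5)),
    bcaa_transamination = neuron$bcaa_transamination,
    dopamine_to_ne = neuron$dopamine_to_ne
  )
  microglia <- list(gln_to_glu = neuron$gln_to_glu)
  oligodendrocyte <- list(
    naa_degradation = metabolic_task(
      "naa_degradation", "degrade NAA to aspartate and acetate",
      inputs = t_in("naa[e]" = 1, "glc[e]" = 1, "o2[e]" = 10),
      outputs = t_out("asp[c]" = 0.5, "ac[c]" = 0, "co2[c]" = 0,
                      "lac[c]" = 0)),
    myelin_formation = metabolic_task(
      "myelin_formation", "assemble myelin sheath lipids",
      inputs = t_in("glc[e]" = 5, "o2[e]" = 10, "nh4[e]" = 1, "chln[e]" = 1,
                    "etn[e]" = 1),
      outputs = t_out("myelin[c]" = 0.05, "co2[c]" = 0, "lac[c]" = 0))
  )
  extra <- switch(cell_type,
    neuron = neuron,
    astrocyte = astrocyte,
    microglia = microglia,
    oligodendrocyte = oligodendrocyte,
    OPC = list(),
    master = c(neuron, astrocyte[setdiff(names(astrocyte), names(neuron))],
               oligodendrocyte),
    stop(sprintf("unknown cell type '%s'", cell_type))
  )
  c(essentials, extra)
}

#' Read or write metabolic task lists as YAML
#'
#' Each task is a YAML map with `id`, `description`, `inputs`
#' (metabolite -> max uptake), `outputs` (metabolite -> min production)
#' and optional `bounds` (reaction -> [lb, ub]).
#'
#' @param path YAML file path.
#' @return For `read_tasks_yaml`, a named list of [metabolic_task()]s.
#' @export
read_tasks_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(tk) {
    inputs <- if (length(tk$inputs)) {
      data.frame(metabolite = names(tk$inputs),
                 max_uptake = as.numeric(unlist(tk$inputs)),
                 stringsAsFactors = FALSE)
    } else NULL
    outputs <- if (length(tk$outputs)) {
      data.frame(metabolite = names(tk$outputs),
                 min_production = as.numeric(unlist(tk$outputs)),
                 stringsAsFactors = FALSE)
    } else NULL
    bounds <- if (length(tk$bounds)) {
      data.frame(reaction_id = names(tk$bounds),
                 lb = vapply(tk$bounds, function(b) as.numeric(b[[1]]), numeric(1)),
                 ub = vapply(tk$bounds, function(b) as.numeric(b[[2]]), numeric(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    metabolic_task(tk$id, tk$description %||% tk$id,
                   inputs = inputs, outputs = outputs, bounds = bounds)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' @rdname read_tasks_yaml
#' @param tasks Named list of [metabolic_task()]s.
#' @export
write_tasks_yaml <- function(tasks, path) {
  ser <- lapply(tasks, function(tk) {
    out <- list(id = tk$id, description = tk$description)
    if (nrow(tk$inputs)) {
      out$inputs <- stats::setNames(as.list(tk$inputs$max_uptake),
                                    tk$inputs$metabolite)
    }
    if (nrow(tk$outputs)) {
      out$outputs <- stats::setNames(as.list(tk$outputs$min_production),
                                     tk$outputs$metabolite)
    }
    if (!is.null(tk$bounds) && nrow(tk$bounds)) {
      out$bounds <- stats::setNames(
        lapply(seq_len(nrow(tk$bounds)),
               function(i) list(tk$bounds$lb[i], tk$bounds$ub[i])),
        tk$bounds$reaction_id)
    }
    out
  })
  yaml::write_yaml(unname(ser), path)
  invisible(path)
}

#' Extract a context-specific model (task-checked greedy tINIT variant)
#'
#' Starting from the parent network, reactions are first verified to
#' support every task. Non-expressed reactions (evidence below the
#' cutoff) are then visited in ascending evidence order (ties broken
#' lexicographically by reaction id) and greedily removed; a removal is
#' kept only if every task remains feasible without the reaction.
#' Expressed, evidence-neutral (no GPR) and protected reactions are never
#' removed, so the result always satisfies 100% of its task list while
#' discarding unsupported reactions.
#'
#' @param model Parent `metabolic_model`.
#' @param evidence data.frame from [reaction_evidence()].
#' @param tasks List of [metabolic_task()] objects.
#' @param protected Reaction ids never removed (biomass, myelin and
#'   demand reactions by default, matched by prefix).
#' @return The extracted sub-model (subset of reactions with induced
#'   metabolites and genes); annotation `extraction` records counts.
#' @export
extract_context_model <- function(model, evidence, tasks,
                                  protected = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- reaction_ids(model)
  if (is.null(protected)) {
    protected <- grep("^(BIOMASS|MYELIN|DM_)", ids, value = TRUE)
  }
  # reactions a task forces flux through (positive lower bound) are
  # structurally required and never removal candidates
  forced <- unique(unlist(lapply(tasks, function(tk) {
    if (is.null(tk$bounds)) return(character(0))
    tk$bounds$reaction_id[!is.na(tk$bounds$lb) & tk$bounds$lb > 0]
  })))
  protected <- union(protected, forced)
  parts <- .task_parts(model)
  failing <- Filter(function(nm) !.check_task_lp(parts, tasks[[nm]])$feasible,
                    names(tasks))
  if (length(failing)) {
    stop(sprintf("parent model fails task(s): %s", paste(failing, collapse = ", ")))
  }
  if (nrow(evidence) == 0 || all(is.na(evidence$expressed))) {
    warning("empty evidence: returning the parent model unchanged")
    return(model)
  }
  ev <- evidence[match(ids, evidence$reaction_id), ]
  candidates <- ids[!is.na(ev$expressed) & !ev$expressed & !(ids %in% protected)]
  cand_ev <- ev$evidence[match(candidates, ev$reaction_id)]
  ord <- order(cand_ev, candidates)
  candidates <- candidates[ord]
  removed <- character(0)
  for (rid in candidates) {
    trial <- c(removed, rid)
    ok <- all(vapply(tasks, function(tk) {
      .check_task_lp(parts, tk, zero = trial)$feasible
    }, logical(1)))
    if (ok) removed <- trial
  }
  out <- remove_reactions(model, removed)
  out$annotations$extraction <- list(
    parent = model$id, removed = removed,
    n_candidates = length(candidates), n_removed = length(removed))
  validate_model(out)
  out
}
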