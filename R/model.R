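#' Construct a reaction record
#'
#' @param id Reaction identifier, unique within a model.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed). Exchange/demand reactions carry
#'   exactly one metabolite; all other reactions at least two entries.
#' @param name Human-readable name (defaults to `id`).
#' @param lower_bound,upper_bound Flux bounds in umol/g tissue/min.
#' @param gpr GPR rule string (see [parse_gpr()]); `""` for none.
#' @param subsystem Pathway label; defaults to `"Exchange/demand"` for
#'   single-metabolite reactions and `"Transport"` otherwise when missing.
#' @return A list of class `brainflux_reaction`.
#' @export
reaction <- function(id, stoichiometry, name = id, lower_bound = -1000,
                     upper_bound = 1000, gpr = "", subsystem = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry)))) {
    stop(sprintf("reaction '%s': stoichiometry must be a named numeric vector", id))
  }
  if (anyDuplicated(names(stoichiometry))) {
    stop(sprintf("reaction '%s': duplicated metabolite in stoichiometry", id))
  }
  if (lower_bound > upper_bound) {
    stop(sprintf("reaction '%s': lower_bound %g exceeds upper_bound %g",
                 id, lower_bound, upper_bound))
  }
  if (is.null(subsystem)) {
    subsystem <- if (length(stoichiometry) == 1L) "Exchange/demand" else "Transport"
  }
  if (is.na(gpr)) gpr <- ""
  if (nzchar(gpr)) parse_gpr(gpr)  # fail early on malformed rules
  structure(list(id = id, name = name,
                 stoichiometry = stoichiometry,
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 gpr = gpr, subsystem = subsystem),
            class = "brainflux_reaction")
}

#' Construct a metabolite table
#'
#' @param id Metabolite identifiers of the form `"name[compartment]"`
#'   (e.g. `"glc[c]"`); the compartment token is parsed from the id when
#'   `compartment` is missing.
#' @param name,compartment,formula,charge Optional per-metabolite fields.
#' @return A data.frame with columns id, name, compartment, formula, charge.
#' @export
metabolite_table <- function(id, name = NULL, compartment = NULL,
                             formula = NA_character_, charge = NA_integer_) {
  stopifnot(is.character(id))
  if (anyDuplicated(id)) stop("duplicated metabolite ids")
  if (is.null(compartment)) compartment <- met_compartment(id)
  if (any(is.na(compartment) | !nzchar(compartment))) {
    bad <- id[is.na(compartment) | !nzchar(compartment)]
    stop(sprintf("metabolite(s) without compartment token: %s",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(name)) name <- sub("\\[[^]]*\\]$", "", id)
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Extract the compartment token from metabolite ids
#'
#' @param id Character vector of ids like `"glc[c]"`.
#' @return Character vector of compartment tokens (`NA` where absent).
#' @export
met_compartment <- function(id) {
  m <- regmatches(id, regexpr("\\[[^]]+\\]$", id))
  out <- rep(NA_character_, length(id))
  has <- grepl("\\[[^]]+\\]$", id)
  out[has] <- substr(m, 2L, nchar(m) - 1L)
  out
}

#' Construct a compartmentalized metabolic model
#'
#' A model is the unit all other stages operate on: a stoichiometric
#' reaction network with flux bounds, GPR rules and subsystem labels.
#' Metabolites referenced by reactions but absent from `metabolites` are
#' created automatically (compartment parsed from the id).
#'
#' @param id Model identifier.
#' @param reactions List of [reaction()] records.
#' @param metabolites Optional metabolite table ([metabolite_table()]).
#' @param genes Optional character vector; defaults to the union of genes
#'   in all GPRs.
#' @param annotations Free-form named list (cell type, provenance, ...).
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, reactions, metabolites = NULL,
                            genes = NULL, annotations = list()) {
  stopifnot(is.list(reactions))
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) {
    stop(sprintf("duplicated reaction id(s): %s",
                 paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  used_mets <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  if (is.null(metabolites)) {
    metabolites <- metabolite_table(sort(used_mets))
  } else {
    missing <- setdiff(used_mets, metabolites$id)
    if (length(missing)) {
      metabolites <- rbind(metabolites, metabolite_table(sort(missing)))
    }
  }
  gpr_all <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- sort(gpr_all)
  model <- structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    genes = genes,
    annotations = annotations
  ), class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, that every metabolite referenced
#' by a reaction exists, that every GPR gene is declared, and that
#' non-exchange reactions have at least two stoichiometry entries.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly; errors describe the offending record.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) stop("duplicated metabolite ids")
  if (any(is.na(mets$compartment) | !nzchar(mets$compartment))) {
    stop("empty compartment token in metabolite table")
  }
  rxn_ids <- reaction_ids(model)
  if (anyDuplicated(rxn_ids)) stop("duplicated reaction ids")
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), mets$id)
    if (length(unknown)) {
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   r$id, paste(unknown, collapse = ", ")))
    }
    if (r$lower_bound > r$upper_bound) {
      stop(sprintf("reaction '%s': lower_bound exceeds upper_bound", r$id))
    }
    if (length(r$stoichiometry) == 0L) {
      stop(sprintf("reaction '%s': empty stoichiometry", r$id))
    }
    g <- gpr_genes(r$gpr)
    miss <- setdiff(g, model$genes)
    if (length(miss)) {
      stop(sprintf("reaction '%s': GPR gene(s) not in model gene list: %s",
                   r$id, paste(miss, collapse = ", ")))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model '%s': %d metabolites, %d reactions, %d genes\n",
              x$id, nrow(x$metabolites), length(x$reactions), length(x$genes)))
  subs <- table(vapply(x$reactions, `[[`, character(1), "subsystem"))
  cat(sprintf("  subsystems: %d (%s, ...)\n", length(subs),
              paste(utils::head(names(sort(subs, decreasing = TRUE)), 3), collapse = ", ")))
  invisible(x)
}

#' Reaction ids of a model, in model order
#' @param model A `metabolic_model`.
#' @return Character vector.
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, character(1), "id")

#' Per-reaction field accessors
#'
#' @param model A `metabolic_model`.
#' @return Named vector (by reaction id) of bounds or subsystem labels.
#' @export
reaction_bounds <- function(model) {
  ids <- reaction_ids(model)
  data.frame(id = ids,
             lower_bound = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
             upper_bound = vapply(model$reactions, `[[`, numeric(1), "upper_bound"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname reaction_bounds
#' @export
reaction_subsystems <- function(model) {
  stats::setNames(vapply(model$reactions, `[[`, character(1), "subsystem"),
                  reaction_ids(model))
}

#' Identify exchange/demand reactions
#'
#' Exchange and demand reactions carry exactly one metabolite and move it
#' across the system boundary; by convention negative flux is uptake.
#'
#' @param model A `metabolic_model`.
#' @return Logical vector along `model$reactions`.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions, function(r) length(r$stoichiometry) == 1L, logical(1))
}

#' Assemble the stoichiometric matrix S
#'
#' @param model A `metabolic_model`.
#' @return A sparse `dgCMatrix` (metabolites x reactions) with dimnames;
#'   entry (i, j) is the coefficient of metabolite i in reaction j, in
#'   model reaction order.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  m <- nrow(model$metabolites)
  n <- length(model$reactions)
  if (n == 0L || m == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(m, n),
                                dimnames = list(model$metabolites$id,
                                                reaction_ids(model))))
  }
  met_index <- stats::setNames(seq_len(m), model$metabolites$id)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (j in seq_len(n)) {
    st <- model$reactions[[j]]$stoichiometry
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n),
                       dimnames = list(model$metabolites$id, reaction_ids(model)))
}

#' Add a reaction to a model
#'
#' @param model A `metabolic_model`.
#' @param rxn A [reaction()] record.
#' @param metabolites Optional metabolite table supplying new metabolites
#'   referenced by `rxn`; unknown metabolites without an entry here are
#'   created automatically from their id.
#' @return The extended, re-validated model.
#' @export
add_reaction <- function(model, rxn, metabolites = NULL) {
  stopifnot(inherits(model, "metabolic_model"), inherits(rxn, "brainflux_reaction"))
  if (rxn$id %in% reaction_ids(model)) {
    stop(sprintf("reaction id '%s' already present", rxn$id))
  }
  if (!is.null(metabolites)) {
    new_mets <- metabolites[!metabolites$id %in% model$metabolites$id, , drop = FALSE]
    if (nrow(new_mets)) model$metabolites <- rbind(model$metabolites, new_mets)
  }
  dangling <- setdiff(names(rxn$stoichiometry), model$metabolites$id)
  if (length(dangling)) {
    model$metabolites <- rbind(model$metabolites, metabolite_table(sort(dangling)))
  }
  model$reactions <- c(model$reactions, list(rxn))
  model$genes <- union(model$genes, gpr_genes(rxn$gpr))
  validate_model(model)
  model
}

#' Remove reactions and prune the induced model
#'
#' Drops the named reactions, then removes metabolites no longer
#' referenced and genes no longer appearing in any GPR.
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids to remove.
#' @return The pruned model.
#' @export
remove_reactions <- function(model, ids) {
  keep <- !(reaction_ids(model) %in% ids)
  model$reactions <- model$reactions[keep]
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoichiometry))))
  model$metabolites <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  used_genes <- unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr))))
  model$genes <- intersect(model$genes, used_genes)
  model
}

#' Set flux bounds on named reactions
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction ids.
#' @param lb,ub Replacement bounds, recycled along `ids`; `NA` leaves the
#'   existing bound unchanged.
#' @return The updated model.
#' @export
set_bounds <- function(model, ids, lb = NA, ub = NA) {
  idx <- match(ids, reaction_ids(model))
  if (anyNA(idx)) {
    stop(sprintf("unknown reaction(s): %s", paste(ids[is.na(idx)], collapse = ", ")))
  }
  lb <- rep_len(as.numeric(lb), length(ids))
  ub <- rep_len(as.numeric(ub), length(ids))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (!is.na(lb[k])) model$reactions[[i]]$lower_bound <- lb[k]
    if (!is.na(ub[k])) model$reactions[[i]]$upper_bound <- ub[k]
    if (model$reactions[[i]]$lower_bound > model$reactions[[i]]$upper_bound) {
      stop(sprintf("reaction '%s': lower_bound exceeds upper_bound after update",
                   ids[k]))
    }
  }
  model
}

#' Canonicalize a model
#'
#' Produces the normal form used for structural comparison and round-trip
#' I/O: metabolites, reactions, genes and stoichiometry entries sorted by
#' id, zero coefficients dropped, bounds stored as plain doubles.
#'
#' @param model A `metabolic_model`.
#' @return The canonical model.
#' @export
canonicalize_model <- function(model) {
  model$reactions <- lapply(model$reactions, function(r) {
    st <- r$stoichiometry[r$stoichiometry != 0]
    r$stoichiometry <- st[order(names(st))]
    r
  })
  ord <- order(reaction_ids(model))
  model$reactions <- model$reactions[ord]
  model$metabolites <- model$metabolites[order(model$metabolites$id), , drop = FALSE]
  rownames(model$metabolites) <- NULL
  model$genes <- sort(model$genes)
  if (length(model$annotations)) {
    model$annotations <- model$annotations[order(names(model$annotations))]
  }
  model
}
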