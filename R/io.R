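#' Write a metabolic model to the package's JSON dialect
#'
#' The dialect is a plain JSON object with fields `id`, `annotations`,
#' `genes`, `metabolites` (array of objects with `id`, `name`,
#' `compartment`, optional `formula`/`charge`) and `reactions` (array of
#' objects with `id`, `name`, `stoichiometry` map, `lower_bound`,
#' `upper_bound`, `gpr`, `subsystem`). Models are canonicalized before
#' writing so write-then-read is the identity on canonical form.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  model <- canonicalize_model(validate_model(model))
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    row <- model$metabolites[i, ]
    out <- list(id = row$id, name = row$name, compartment = row$compartment)
    if (!is.na(row$formula)) out$formula <- row$formula
    if (!is.na(row$charge)) out$charge <- row$charge
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gpr = r$gpr, subsystem = r$subsystem)
  })
  obj <- list(id = model$id, annotations = model$annotations,
              genes = model$genes, metabolites = mets, reactions = rxns)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a metabolic model from the JSON dialect
#'
#' @param path File written by [write_model()] (or hand-authored in the
#'   same schema).
#' @return A canonical `metabolic_model`; schema violations raise an error
#'   naming the offending JSON path.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("id", "metabolites", "reactions")) {
    if (is.null(obj[[field]])) stop(sprintf("model JSON: missing $%s", field))
  }
  mets <- do.call(rbind, lapply(seq_along(obj$metabolites), function(i) {
    m <- obj$metabolites[[i]]
    if (is.null(m$id)) stop(sprintf("model JSON: $metabolites[%d] missing id", i))
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) {
                 met_compartment(m$id)
               } else m$compartment,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else as.integer(m$charge),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(seq_along(obj$reactions), function(i) {
    r <- obj$reactions[[i]]
    loc <- sprintf("$reactions[%d]", i)
    if (is.null(r$id)) stop(sprintf("model JSON: %s missing id", loc))
    if (is.null(r$stoichiometry) || !length(r$stoichiometry)) {
      stop(sprintf("model JSON: %s ('%s') missing stoichiometry", loc, r$id))
    }
    st <- unlist(r$stoichiometry)
    lb <- if (is.null(r$lower_bound)) -1000 else r$lower_bound
    ub <- if (is.null(r$upper_bound)) 1000 else r$upper_bound
    if (lb > ub) {
      stop(sprintf("model JSON: %s ('%s') lower_bound > upper_bound", loc, r$id))
    }
    reaction(id = r$id, stoichiometry = st,
             name = if (is.null(r$name)) r$id else r$name,
             lower_bound = lb, upper_bound = ub,
             gpr = if (is.null(r$gpr)) "" else r$gpr,
             subsystem = if (is.null(r$subsystem)) NULL else r$subsystem)
  })
  genes <- if (is.null(obj$genes)) NULL else unlist(obj$genes)
  ann <- if (is.null(obj$annotations)) list() else obj$annotations
  canonicalize_model(metabolic_model(obj$id, rxns, metabolites = mets,
                                     genes = genes, annotations = ann))
}

#' Write a flux table as TSV
#'
#' Columns: reaction_id, flux, lower, upper (bounds of the model the state
#' was solved on). Numbers are printed with `%.10g` so identical states
#' produce byte-identical files.
#'
#' @param state A `flux_state` from [fba()] and friends.
#' @param model The model the state was solved on.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(state, model, path) {
  b <- reaction_bounds(model)
  v <- state$fluxes[b$id]
  lines <- c("reaction_id\tflux\tlower\tupper",
             sprintf("%s\t%.10g\t%.10g\t%.10g", b$id, v, b$lower_bound, b$upper_bound))
  writeLines(lines, path)
  invisible(path)
}

#' Read a constraint table from TSV
#'
#' Expected columns: `reaction_id`, `lb`, `ub` (either may be `NA` to keep
#' the model bound).
#'
#' @param path TSV path.
#' @return A data.frame usable as the `bounds` element of a
#'   [constraint_table()].
#' @export
read_constraints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "lb", "ub")
  if (!all(need %in% names(df))) {
    stop(sprintf("constraint TSV must have columns %s", paste(need, collapse = ", ")))
  }
  df[need]
}

#' Write expression profiles as TSV
#'
#' Layout: one row per gene with its length followed by one count column
#' per sample, named `<cell_type>.<k>`.
#'
#' @param profiles Result of [generate_expression_profiles()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(profiles, path) {
  counts <- do.call(cbind, lapply(names(profiles$counts), function(ct) {
    m <- profiles$counts[[ct]]
    colnames(m) <- paste(ct, seq_len(ncol(m)), sep = ".")
    m
  }))
  df <- data.frame(gene = names(profiles$lengths),
                   length = unname(profiles$lengths), counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write GMT-style pathway sets
#'
#' GMT: one pathway per line, tab-separated: name, description, members.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (pathway -> metabolite ids).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
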