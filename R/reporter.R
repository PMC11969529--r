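#' Transform gene p-values to Z-scores
#'
#' `Z_g = qnorm(1 - p_g)`: small p-values map to large positive Z.
#' Values outside (0, 1) are clamped to `[1e-15, 1 - 1e-15]` so extreme
#' p-values stay finite.
#'
#' @param p Named numeric vector of gene p-values.
#' @return Named numeric vector of Z-scores.
#' @export
gene_p_to_z <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  stats::qnorm(1 - p)
}

#' Default currency-metabolite blocklist
#'
#' Cofactors and ubiquitous small molecules whose gene neighborhoods span
#' the whole network and carry no localized signal; excluded from
#' reporter scoring by default (matched on the metabolite base name, any
#' compartment).
#'
#' @return Character vector of base names.
#' @export
currency_metabolites <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa", "co2",
    "o2", "h2o", "h", "pi", "nh4")
}

#' Reporter-metabolite analysis
#'
#' Scores every metabolite by aggregating the differential-expression
#' evidence of its gene neighborhood: the distinct genes appearing in the
#' GPRs of reactions that produce or consume the metabolite. For a
#' neighborhood of k scored genes, `z_raw = sum(Z_g) / sqrt(k)`; the
#' score is background-corrected against the null of random gene sets by
#' sampling `n_background` size-k sets from all scored genes
#' (`z_corrected = (z_raw - mu_k) / sigma_k`) and converted to an
#' upper-tail p-value. Metabolites with no scored neighbors are listed
#' separately, not scored.
#'
#' @param model A `metabolic_model` supplying the topology and GPRs.
#' @param gene_z Named numeric vector of gene Z-scores (see
#'   [gene_p_to_z()]); only genes present in the model's GPRs are used.
#' @param n_background Background sample count per neighborhood size.
#' @param seed Integer seed for the background sampling.
#' @param exclude Base names of currency metabolites to skip.
#' @param pool_compartments If `TRUE`, neighborhoods are pooled across
#'   compartments and scores reported per base name, regardless of
#'   subcellular localization.
#' @return list with `scores` (data.frame metabolite, k, z_raw,
#'   z_corrected, p, sorted by p) and `unscored` (metabolites with empty
#'   neighborhoods).
#' @export
reporter_metabolites <- function(model, gene_z, n_background = 10000L,
                                 seed = 1L, exclude = currency_metabolites(),
                                 pool_compartments = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  model_genes <- unique(unlist(lapply(model$reactions,
                                      function(r) gpr_genes(r$gpr))))
  scored_genes <- intersect(model_genes, names(gene_z))
  if (!length(scored_genes)) {
    stop("no genes shared between gene_z and the model's GPRs")
  }
  zpool <- unname(gene_z[scored_genes])
  base <- sub("\\[[^]]*\\]$", "", model$metabolites$id)
  keep <- !(base %in% exclude)
  met_ids <- model$metabolites$id[keep]
  met_key <- if (pool_compartments) base[keep] else met_ids
  # neighborhood: distinct scored genes over adjacent reactions
  nbhd <- new.env(parent = emptyenv())
  for (r in model$reactions) {
    g <- intersect(gpr_genes(r$gpr), scored_genes)
    if (!length(g)) next
    for (mid in intersect(names(r$stoichiometry), met_ids)) {
      key <- met_key[match(mid, met_ids)]
      nbhd[[key]] <- union(nbhd[[key]], g)
    }
  }
  keys <- unique(met_key)
  genes_by_key <- lapply(keys, function(k) nbhd[[k]])
  names(genes_by_key) <- keys
  ks <- lengths(genes_by_key)
  unscored <- keys[ks == 0]
  keys <- keys[ks > 0]
  ks <- ks[ks > 0]
  bg <- .with_seed(seed, {
    lapply(sort(unique(ks)), function(k) {
      if (k >= length(zpool)) {
        # degenerate: every sample is the full pool
        s <- sum(zpool) / sqrt(k)
        return(list(k = k, mu = s, sd = 0))
      }
      samples <- matrix(sample.int(length(zpool), n_background * k, replace = TRUE),
                        nrow = n_background)
      vals <- rowSums(matrix(zpool[samples], nrow = n_background)) / sqrt(k)
      list(k = k, mu = mean(vals), sd = stats::sd(vals))
    })
  })
  bg_mu <- stats::setNames(vapply(bg, `[[`, numeric(1), "mu"),
                           vapply(bg, `[[`, numeric(1), "k"))
  bg_sd <- stats::setNames(vapply(bg, `[[`, numeric(1), "sd"),
                           vapply(bg, `[[`, numeric(1), "k"))
  z_raw <- vapply(keys, function(key) {
    g <- genes_by_key[[key]]
    sum(gene_z[g]) / sqrt(length(g))
  }, numeric(1))
  mu <- bg_mu[as.character(ks)]
  sd <- bg_sd[as.character(ks)]
  z_corr <- ifelse(sd > 0, (z_raw - mu) / sd, 0)
  p <- stats::pnorm(z_corr, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  scores <- data.frame(metabolite = keys, k = unname(ks),
                       z_raw = unname(z_raw), z_corrected = unname(z_corr),
                       p = unname(p), stringsAsFactors = FALSE)
  scores <- scores[order(scores$p, scores$metabolite), , drop = FALSE]
  rownames(scores) <- NULL
  list(scores = scores, unscored = unscored)
}

#' Hypergeometric over-representation analysis of metabolite sets
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least the observed number of reporter metabolites when sampling
#' `|reporters|` metabolites from the universe without replacement.
#'
#' @param reporters Character vector of significant metabolites (subset
#'   of the universe).
#' @param pathways Named list of metabolite sets (see [pathway_sets()]).
#' @param universe All scoreable metabolites.
#' @param alpha Significance filter used for the `significant` column.
#' @return data.frame: pathway, overlap, size, p, significant; sorted by p.
#' @export
ora_hypergeometric <- function(reporters, pathways, universe, alpha = 0.05) {
  if (!length(universe)) stop("empty universe")
  bad <- setdiff(reporters, universe)
  if (length(bad)) {
    stop(sprintf("reporter(s) outside the universe: %s", paste(bad, collapse = ", ")))
  }
  N <- length(universe)
  n <- length(reporters)
  out <- do.call(rbind, lapply(names(pathways), function(nm) {
    set <- intersect(pathways[[nm]], universe)
    K <- length(set)
    x <- length(intersect(set, reporters))
    p <- if (x == 0) 1 else stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = x, size = K, p = p,
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build pathway sets from model subsystems
#'
#' Convenience constructor for toy analyses: each subsystem becomes a
#' metabolite set (the metabolites its reactions touch, currency
#' metabolites excluded), usable directly with [ora_hypergeometric()].
#'
#' @param model A `metabolic_model`.
#' @param exclude Currency base names to drop.
#' @return list(sets = named list of metabolite ids, universe = character).
#' @export
pathway_sets <- function(model, exclude = currency_metabolites()) {
  base <- sub("\\[[^]]*\\]$", "", model$metabolites$id)
  universe <- model$metabolites$id[!(base %in% exclude)]
  subs <- reaction_subsystems(model)
  sets <- list()
  for (r in model$reactions) {
    mets <- intersect(names(r$stoichiometry), universe)
    if (!length(mets)) next
    sets[[r$subsystem]] <- union(sets[[r$subsystem]], mets)
  }
  list(sets = sets, universe = universe)
}
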