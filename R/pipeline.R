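#' Run the full toy-brain pipeline
#'
#' Chains every stage on the synthetic toy brain: generate the master
#' network and per-cell expression, extract context-specific cell models
#' (task-checked), apply resting constraints and solve each cell alone,
#' merge the four brain cell types with intercellular reactions, run the
#' perturbation protocols, and finish with reporter-metabolite and
#' enrichment analysis on the oligodendrocyte model with planted
#' differential expression. All randomness derives from `config$seed`;
#' rerunning with the same seed reproduces every output file byte for
#' byte.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory (created if missing); receives model
#'   JSON files, flux/activity/reporter TSV tables, the echoed config and
#'   a plain-text log.
#' @param hot_metabolite Metabolite id to plant as the differential-
#'   expression hot spot for the reporter stage.
#' @param protocols Protocols to run.
#' @return Invisibly, a list with the intermediate objects (models,
#'   states, protocol results, reporter tables).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         hot_metabolite = "naa[c]",
                         protocols = c("glucose", "ketogenic", "hypoxia",
                                       "demyelination")) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, logf)
    invisible(line)
  }
  say("brainflux pipeline, seed %d", config$seed)

  spec <- toy_brain_spec(seed = config$seed)
  cells <- c("neuron", "astrocyte", "microglia", "oligodendrocyte")
  master <- generate_toy_cell_model("master", spec)
  say("stage synth: master network %d reactions / %d metabolites / %d genes",
      length(master$reactions), nrow(master$metabolites), length(master$genes))
  reference_models <- stats::setNames(
    lapply(cells, generate_toy_cell_model, spec = spec), cells)
  profiles <- generate_expression_profiles(reference_models, seed = config$seed)
  write_expression_tsv(profiles, file.path(out_dir, "expression.tsv"))

  extracted <- list()
  for (ct in cells) {
    tpm <- apply(profiles$counts[[ct]], 2, tpm_normalize,
                 lengths = profiles$lengths)
    mean_tpm <- mean_expression(tpm)
    ev <- reaction_evidence(master, mean_tpm, cutoff = config$cutoff)
    protected <- c("BIOMASS", "DM_biomass", "DM_r5p")
    if (ct == "oligodendrocyte") protected <- c(protected, "MYELIN", "DM_myelin")
    extracted[[ct]] <- extract_context_model(
      master, ev, default_brain_tasks(ct), protected = protected)
    extracted[[ct]]$id <- sprintf("toy_%s_extracted", ct)
    extracted[[ct]]$annotations$cell_type <- ct
    write_model(extracted[[ct]], file.path(out_dir, sprintf("model_%s.json", ct)))
    say("stage extract (%s): %d reactions kept, %d removed", ct,
        length(extracted[[ct]]$reactions),
        extracted[[ct]]$annotations$extraction$n_removed)
  }

  constrained <- stats::setNames(lapply(cells, function(ct) {
    apply_constraints(extracted[[ct]], default_cell_constraints(ct, config),
                      cell_role = ct)
  }), cells)
  single_states <- stats::setNames(lapply(cells, function(ct) {
    st <- fba_two_stage(constrained[[ct]], "BIOMASS")
    write_flux_tsv(st, constrained[[ct]],
                   file.path(out_dir, sprintf("flux_single_%s.tsv", ct)))
    say("stage simulate (%s alone): biomass flux %.4f", ct, st$objective_value)
    st
  }), cells)

  suffixes <- config$protocol$cell_suffixes
  brain <- merge_models(unname(constrained[cells]), suffixes)
  brain <- add_intercellular_reactions(brain, default_intercellular_spec())
  brain <- transfer_exchange_constraints(
    brain, stats::setNames(single_states, suffixes),
    pin = "capacity", default_lb = config$exchange_lb)
  brain <- set_bounds(brain, config$protocol$myelin_reaction,
                      lb = config$protocol$myelin_resting_flux,
                      ub = config$protocol$myelin_resting_flux)
  for (i in seq_along(cells)) {
    bm <- paste0("BIOMASS_", suffixes[i])
    target <- config$biomass_fraction * single_states[[cells[i]]]$objective_value
    brain <- set_bounds(brain, bm, lb = target)
  }
  write_model(brain, file.path(out_dir, "model_brain.json"))
  say("stage merge: brain model %d reactions (%d intercellular)",
      length(brain$reactions), sum(grepl("^ICT_", reaction_ids(brain))))

  protocol_results <- list()
  reference <- NULL
  for (pr in protocols) {
    res <- run_protocol(brain, pr, config = config, reference = reference)
    reference <- res$states$resting
    protocol_results[[pr]] <- res
    for (nm in names(res$states)) {
      st <- res$states[[nm]]
      if (st$status != "optimal") {
        say("stage protocol %s: state %s %s", pr, nm, st$status)
        next
      }
      act <- res$activity[[nm]]
      utils::write.table(
        format(act, digits = 10, scientific = FALSE, trim = TRUE),
        file.path(out_dir, sprintf("activity_%s_%s.tsv", pr, nm)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$intercellular)) {
      utils::write.table(
        format(res$intercellular, digits = 10, scientific = FALSE, trim = TRUE),
        file.path(out_dir, sprintf("intercellular_%s.tsv", pr)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    say("stage protocol %s: %d state(s), cycle flux %.4f", pr,
        length(res$states), res$states$resting$objective_value)
  }

  oligo <- extracted$oligodendrocyte
  planted <- planted_de_spec(hot_metabolite, effect = 3, seed = config$seed)
  pvals <- generate_de_pvalues(oligo, planted)
  utils::write.table(
    data.frame(gene = names(pvals), pvalue = sprintf("%.10g", pvals)),
    file.path(out_dir, "de_pvalues.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  rep_res <- reporter_metabolites(oligo, gene_p_to_z(pvals),
                                  n_background = config$reporter$n_background,
                                  seed = config$seed)
  utils::write.table(
    format(rep_res$scores, digits = 10, scientific = FALSE, trim = TRUE),
    file.path(out_dir, "reporter_metabolites.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  reporters <- rep_res$scores$metabolite[rep_res$scores$p < config$reporter$p_threshold]
  ps <- pathway_sets(oligo)
  ora <- ora_hypergeometric(reporters, ps$sets, ps$universe,
                            alpha = config$reporter$p_threshold)
  utils::write.table(
    format(ora, digits = 10, scientific = FALSE, trim = TRUE),
    file.path(out_dir, "ora.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  say("stage reporter: top metabolite %s (p = %.3g), %d reporter(s) at p < %.3g",
      rep_res$scores$metabolite[1], rep_res$scores$p[1], length(reporters),
      config$reporter$p_threshold)

  write_run_config(config, file.path(out_dir, "config_echo.yaml"))
  say("pipeline complete")
  invisible(list(master = master, extracted = extracted,
                 constrained = constrained, single_states = single_states,
                 brain = brain, protocols = protocol_results,
                 reporter = rep_res, ora = ora, config = config))
}
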