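# Shared expensive fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Constrained single-cell models, their two-stage solutions, and the
# merged resting brain with intercellular reactions and the resting
# myelin/biomass constraints applied.
brain_fixture <- function() {
  if (!is.null(.fixture_cache$brain)) return(.fixture_cache$brain)
  spec <- toy_brain_spec()
  cfg <- default_run_config()
  cells <- c("neuron", "astrocyte", "microglia", "oligodendrocyte")
  suffixes <- cfg$protocol$cell_suffixes
  cons <- stats::setNames(lapply(cells, function(ct) {
    apply_constraints(generate_toy_cell_model(ct, spec),
                      default_cell_constraints(ct, cfg), cell_role = ct)
  }), cells)
  singles <- stats::setNames(lapply(cells, function(ct) {
    fba_two_stage(cons[[ct]], "BIOMASS")
  }), cells)
  brain <- merge_models(unname(cons), suffixes)
  brain <- add_intercellular_reactions(brain, default_intercellular_spec())
  brain <- transfer_exchange_constraints(brain, stats::setNames(singles, suffixes))
  brain <- set_bounds(brain, cfg$protocol$myelin_reaction,
                      lb = cfg$protocol$myelin_resting_flux,
                      ub = cfg$protocol$myelin_resting_flux)
  for (i in seq_along(cells)) {
    brain <- set_bounds(brain, paste0("BIOMASS_", suffixes[i]),
                        lb = cfg$biomass_fraction * singles[[cells[i]]]$objective_value)
  }
  fx <- list(spec = spec, cfg = cfg, cells = cells, suffixes = suffixes,
             cons = cons, singles = singles, brain = brain)
  .fixture_cache$brain <- fx
  fx
}

# Resting state of the fixture brain (cycle objective, two-stage).
brain_resting <- function() {
  if (!is.null(.fixture_cache$resting)) return(.fixture_cache$resting)
  fx <- brain_fixture()
  res <- run_protocol(fx$brain, "resting", fx$cfg)
  .fixture_cache$resting <- res
  res
}

# Brain-level activity of a subsystem across the four cells.
brain_activity <- function(state, subsystem, model) {
  a <- subsystem_activity(state, model)
  sum(a$flux_sum[match(paste0(subsystem, "_", c("N", "A", "M", "O")),
                       a$subsystem)])
}
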