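# Model merging and intercellular reactions.

test_that("merging suffixes ids, compartments and subsystems", {
  spec <- toy_brain_spec()
  neu <- generate_toy_cell_model("neuron", spec)
  ast <- generate_toy_cell_model("astrocyte", spec)
  merged <- merge_models(list(neu, ast), c("N", "A"))
  n_ids <- grep("_N$", reaction_ids(merged), value = TRUE)
  expect_equal(length(n_ids), length(neu$reactions))
  expect_true(all(grepl("_(N|A)$", reaction_ids(merged))))
  expect_true(all(grepl("_(N|A)$", merged$metabolites$compartment)))
  expect_true(all(grepl("_(N|A)$", unname(reaction_subsystems(merged)))))
  # genes stay in the global namespace
  expect_true(all(merged$genes %in% union(neu$genes, ast$genes)))
  expect_equal(length(merged$reactions), length(neu$reactions) + length(ast$reactions))
  expect_error(merge_models(list(neu, ast), c("N", "N")), "collision")
})

test_that("sequential and one-shot merges give the same canonical model", {
  spec <- toy_brain_spec()
  ms <- lapply(c("neuron", "astrocyte", "microglia", "oligodendrocyte"),
               generate_toy_cell_model, spec = spec)
  oneshot <- merge_models(ms, c("N", "A", "M", "O"))
  seq2 <- merge_models(list(ms[[1]], ms[[2]]), c("N", "A"))
  seq3 <- merge_models(list(seq2, ms[[3]]), c("", "M"))
  seq4 <- merge_models(list(seq3, ms[[4]]), c("", "O"))
  seq4$id <- oneshot$id
  seq4$annotations <- oneshot$annotations
  expect_equal(canonicalize_model(seq4)$metabolites,
               canonicalize_model(oneshot)$metabolites)
  expect_equal(reaction_ids(canonicalize_model(seq4)),
               reaction_ids(canonicalize_model(oneshot)))
  expect_equal(lapply(canonicalize_model(seq4)$reactions, `[[`, "stoichiometry"),
               lapply(canonicalize_model(oneshot)$reactions, `[[`, "stoichiometry"))
})

test_that("intercellular reactions conserve mass and validate their spec", {
  spec <- toy_brain_spec()
  ms <- lapply(c("neuron", "astrocyte", "microglia", "oligodendrocyte"),
               generate_toy_cell_model, spec = spec)
  brain <- merge_models(ms, c("N", "A", "M", "O"))
  wired <- add_intercellular_reactions(brain, default_intercellular_spec())
  ict <- grep("^ICT_", reaction_ids(wired), value = TRUE)
  expect_equal(length(ict), 13L)
  for (rid in ict) {
    st <- wired$reactions[[match(rid, reaction_ids(wired))]]$stoichiometry
    expect_equal(sort(unname(st)), c(-1, 1), info = rid)
  }
  # empty spec leaves the model unchanged
  empty <- intercellular_spec(data.frame(metabolite = character(0),
                                         from = character(0), to = character(0),
                                         reversible = logical(0)))
  expect_equal(length(add_intercellular_reactions(brain, empty)$reactions),
               length(brain$reactions))
  # duplicated rows and self-transfers are rejected
  expect_error(intercellular_spec(data.frame(
    metabolite = c("glu", "glu"), from = c("N", "N"), to = c("A", "A"),
    reversible = FALSE)), "duplicated")
  expect_error(intercellular_spec(data.frame(
    metabolite = "glu", from = "N", to = "N", reversible = FALSE)),
    "must differ")
  # a metabolite absent from a cell's interface is an error naming both
  ghost <- intercellular_spec(data.frame(metabolite = "myelin", from = "N",
                                         to = "A", reversible = FALSE))
  expect_error(add_intercellular_reactions(brain, ghost), "myelin.*'N'")
})

test_that("zero intercellular flux preserves each cell's standalone optimum", {
  spec <- toy_brain_spec()
  cfg <- default_run_config()
  cells <- c("neuron", "astrocyte")
  cons <- lapply(cells, function(ct) {
    apply_constraints(generate_toy_cell_model(ct, spec),
                      default_cell_constraints(ct, cfg), cell_role = ct)
  })
  singles <- lapply(cons, function(m) fba(m, "BIOMASS")$objective_value)
  brain <- merge_models(cons, c("N", "A"))
  spec_na <- intercellular_spec(data.frame(
    metabolite = c("glu", "gln"), from = c("N", "A"), to = c("A", "N"),
    reversible = FALSE, ub = 0.05))
  brain <- add_intercellular_reactions(brain, spec_na)
  brain <- set_bounds(brain, grep("^ICT_", reaction_ids(brain), value = TRUE),
                      lb = 0, ub = 0)
  for (i in seq_along(cells)) {
    sfx <- c("N", "A")[i]
    st <- fba(brain, paste0("BIOMASS_", sfx))
    expect_equal(st$objective_value, singles[[i]], tolerance = 1e-6,
                 info = cells[i])
  }
})

test_that("capacity transfer tightens non-fuel uptake to single-cell usage", {
  spec <- toy_brain_spec()
  cfg <- default_run_config()
  cons <- lapply(c("neuron", "astrocyte"), function(ct) {
    apply_constraints(generate_toy_cell_model(ct, spec),
                      default_cell_constraints(ct, cfg), cell_role = ct)
  })
  singles <- lapply(cons, fba_two_stage, objective = "BIOMASS")
  brain <- merge_models(cons, c("N", "A"))
  out <- transfer_exchange_constraints(brain, list(N = singles[[1]], A = singles[[2]]))
  b <- reaction_bounds(out)
  # fuel exchanges keep their vascular capacities
  expect_equal(b$lower_bound[b$id == "EX_glc_N"], -cfg$resting$glucose_uptake)
  expect_equal(b$lower_bound[b$id == "EX_o2_N"], -cfg$resting$oxygen_uptake)
  # non-fuel exchanges are capped at the single-cell uptake (or the default)
  nh4_used <- singles[[1]]$fluxes[["EX_nh4"]]
  expect_equal(b$lower_bound[b$id == "EX_nh4_N"], min(nh4_used, -0.01))
  # exact pinning clamps fluxes to the reference within tolerance
  pinned <- transfer_exchange_constraints(brain, list(N = singles[[1]]),
                                          pin = "exact", exclude = character(0))
  bp <- reaction_bounds(pinned)
  glc <- singles[[1]]$fluxes[["EX_glc"]]
  expect_equal(bp$lower_bound[bp$id == "EX_glc_N"], glc - 1e-6)
  expect_equal(bp$upper_bound[bp$id == "EX_glc_N"], glc + 1e-6)
})
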