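# Normalization, evidence, task checking, context-specific extraction.

test_that("TPM normalization has the closed form and sums to one million", {
  expect_equal(unname(tpm_normalize(c(g = 7), c(g = 1500))), 1e6)
  tpm <- tpm_normalize(c(a = 10, b = 10), c(a = 1000, b = 2000))
  expect_equal(unname(tpm), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  set.seed(5)
  counts <- stats::setNames(rpois(50, 100), paste0("g", 1:50))
  lens <- stats::setNames(sample(200:5000, 50), paste0("g", 1:50))
  expect_equal(sum(tpm_normalize(counts, lens)), 1e6, tolerance = 1e-6 * 1e6)
  expect_error(tpm_normalize(c(a = 0, b = 0), c(a = 100, b = 100)), "all counts are zero")
  expect_error(tpm_normalize(c(a = 1), c(b = 100)), "missing gene length")
})

test_that("mean expression averages samples and rejects mismatched gene sets", {
  expect_equal(mean_expression(list(c(a = 3, b = 1))), c(a = 3, b = 1))
  expect_equal(mean_expression(list(c(a = 0), c(a = 2))), c(a = 1))
  set.seed(9)
  samples <- lapply(1:5, function(i) stats::setNames(runif(10), paste0("g", 1:10)))
  got <- mean_expression(samples)
  manual <- sapply(paste0("g", 1:10), function(g) {
    acc <- 0
    for (s in samples) acc <- acc + s[[g]]
    acc / 5
  })
  expect_equal(got, manual)
  expect_error(mean_expression(list(c(a = 1), c(b = 1))), "common gene set")
})

test_that("reaction evidence maps genes through GPRs and flags neutrality", {
  m <- metabolic_model("ev", list(
    reaction("R1", c("A[c]" = -1, "B[c]" = 1), gpr = "g1 and g2"),
    reaction("R2", c("B[c]" = -1, "C[c]" = 1), gpr = "g1 or g3"),
    reaction("EX_A", c("A[c]" = -1), lower_bound = -1)))
  ev <- reaction_evidence(m, c(g1 = 5, g2 = 0.4, g3 = 2), cutoff = 1)
  expect_equal(ev$evidence[ev$reaction_id == "R1"], 0.4)
  expect_false(ev$expressed[ev$reaction_id == "R1"])
  expect_equal(ev$evidence[ev$reaction_id == "R2"], 5)
  expect_true(ev$expressed[ev$reaction_id == "R2"])
  expect_true(is.na(ev$expressed[ev$reaction_id == "EX_A"]))
  expect_error(reaction_evidence(m, c(g1 = 1), cutoff = 0), "cutoff")
})

test_that("task checking distinguishes capable from incapable networks", {
  spec <- toy_brain_spec()
  neu <- generate_toy_cell_model("neuron", spec)
  atp_task <- default_brain_tasks("neuron")$atp_from_glc_o2
  expect_true(check_task(neu, atp_task)$feasible)
  # deleting glycolysis and oxphos removes every route to ATP
  crippled <- remove_reactions(neu, c("GLYC1", "GLYC2", "OXPHOS"))
  expect_false(check_task(crippled, atp_task)$feasible)
  # a task naming an absent metabolite is infeasible-with-reason, not an error
  ghost <- metabolic_task("ghost", inputs = data.frame(metabolite = "glc[e]",
                                                       max_uptake = 1),
                          outputs = data.frame(metabolite = "unobtainium[c]",
                                               min_production = 1))
  res <- check_task(neu, ghost)
  expect_false(res$feasible)
  expect_match(res$reason, "unobtainium")

  # NAA synthesis separates neurons from microglia
  mic <- generate_toy_cell_model("microglia", spec)
  naa <- default_brain_tasks("neuron")$naa_synthesis
  expect_true(check_task(neu, naa)$feasible)
  expect_false(check_task(mic, naa)$feasible)
})

test_that("extraction keeps expressed reactions and stays task-sound", {
  spec <- toy_brain_spec()
  master <- generate_toy_cell_model("master", spec)
  tasks <- default_brain_tasks("neuron")

  # all reactions expressed: nothing to remove
  all_on <- stats::setNames(rep(10, length(master$genes)), master$genes)
  ev_all <- reaction_evidence(master, all_on)
  out_all <- extract_context_model(master, ev_all, tasks)
  expect_equal(length(out_all$reactions), length(master$reactions))

  # empty evidence: parent returned with a warning
  ev_empty <- ev_all[0, ]
  expect_warning(out_e <- extract_context_model(master, ev_empty, tasks),
                 "empty evidence")
  expect_equal(length(out_e$reactions), length(master$reactions))

  # a single silent, task-irrelevant reaction is removed exactly
  ev_one <- ev_all
  ev_one$evidence[ev_one$reaction_id == "PNMT"] <- 0
  ev_one$expressed[ev_one$reaction_id == "PNMT"] <- FALSE
  neuron_tasks_no_adr <- tasks[setdiff(names(tasks), "adrenaline_production")]
  out_one <- extract_context_model(master, ev_one, neuron_tasks_no_adr)
  expect_setequal(setdiff(reaction_ids(master), reaction_ids(out_one)), "PNMT")
})

test_that("extraction on silenced profiles passes all tasks with no removable slack", {
  spec <- toy_brain_spec()
  master <- generate_toy_cell_model("master", spec)
  tasks <- default_brain_tasks("neuron")
  neuron <- generate_toy_cell_model("neuron", spec)
  protected <- c("BIOMASS", "DM_biomass", "DM_r5p")
  for (seed in 1:2) {
    set.seed(seed)
    # neuron genes on; 20% of them silenced; foreign genes off
    scores <- stats::setNames(rep(0, length(master$genes)), master$genes)
    scores[neuron$genes] <- 10
    silenced <- sample(neuron$genes, round(0.2 * length(neuron$genes)))
    scores[silenced] <- 0
    ev <- reaction_evidence(master, scores)
    out <- extract_context_model(master, ev, tasks, protected = protected)
    # soundness: every task passes in the extracted model
    for (nm in names(tasks)) {
      expect_true(check_task(out, tasks[[nm]])$feasible,
                  info = sprintf("seed %d task %s", seed, nm))
    }
    # minimality audit: no remaining non-expressed reaction can be removed
    # (reactions a task forces flux through are required by definition)
    forced <- unique(unlist(lapply(tasks, function(tk) {
      if (is.null(tk$bounds)) character(0) else
        tk$bounds$reaction_id[tk$bounds$lb > 0]
    })))
    ev_out <- reaction_evidence(out, scores)
    removable <- ev_out$reaction_id[!is.na(ev_out$expressed) & !ev_out$expressed &
                                      !(ev_out$reaction_id %in% c(protected, forced))]
    for (rid in removable) {
      trial <- remove_reactions(out, rid)
      still_ok <- all(vapply(tasks, function(tk) check_task(trial, tk)$feasible,
                             logical(1)))
      expect_false(still_ok, info = sprintf("seed %d: %s removable", seed, rid))
    }
  }
})

test_that("adding evidence never shrinks the retained reaction set", {
  spec <- toy_brain_spec()
  master <- generate_toy_cell_model("master", spec)
  tasks <- default_brain_tasks("microglia")
  mic <- generate_toy_cell_model("microglia", spec)
  scores_lo <- stats::setNames(rep(0, length(master$genes)), master$genes)
  scores_lo[mic$genes] <- 10
  out_lo <- extract_context_model(master, reaction_evidence(master, scores_lo), tasks)
  scores_hi <- scores_lo
  extra <- setdiff(master$genes, mic$genes)[1:10]
  scores_hi[extra] <- 10
  out_hi <- extract_context_model(master, reaction_evidence(master, scores_hi), tasks)
  expect_true(all(reaction_ids(out_lo) %in% reaction_ids(out_hi)))
})

test_that("task lists round-trip through YAML and drive shipped fixtures", {
  tasks <- default_brain_tasks("neuron")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tasks_yaml(tasks, path)
  back <- read_tasks_yaml(path)
  expect_identical(names(back), names(tasks))
  expect_equal(back$atp_from_glc_o2$bounds$lb, tasks$atp_from_glc_o2$bounds$lb)
  expect_equal(back$bcaa_transamination$outputs, tasks$bcaa_transamination$outputs)
  opc <- read_model(system.file("extdata", "toy_opc.json", package = "brainflux"))
  expect_true(check_task(opc, back$atp_from_glc_o2)$feasible)
})
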