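# Model data structures, GPR evaluation, stoichiometric matrix, JSON I/O.

test_that("GPR parsing and evaluation follow complex/isozyme semantics", {
  expect_equal(evaluate_gpr("G1 and G2", c(G1 = 5, G2 = 2)), 2)
  expect_equal(evaluate_gpr("G1 or G2", c(G1 = 5, G2 = 2)), 5)
  expect_equal(evaluate_gpr("(G1 and G2) or G3", c(G1 = 1, G2 = 0, G3 = 4)), 4)
  # missing genes score zero; empty rule is the "no evidence" sentinel
  expect_equal(evaluate_gpr("G1 and GX", c(G1 = 5)), 0)
  expect_true(is.na(evaluate_gpr("", c(G1 = 1))))
  expect_false(identical(evaluate_gpr("", c(G1 = 1)), 0))
  expect_setequal(gpr_genes("(G1 and G2) or (G2 and G3)"), c("G1", "G2", "G3"))
  expect_error(parse_gpr("G1 and (G2"), "parenthesis")
  expect_error(parse_gpr("and G1"), "malformed")
})

test_that("GPR evaluation is monotone in every gene score", {
  set.seed(42)
  rules <- c("(G1 and G2) or G3", "G1 or (G2 and (G3 or G4))",
             "G1 and G2 and G3", "(G1 or G2) and (G3 or G4)")
  for (rule in rules) {
    genes <- gpr_genes(rule)
    for (rep in 1:20) {
      s <- stats::setNames(stats::runif(length(genes), 0, 10), genes)
      base <- evaluate_gpr(rule, s)
      g <- sample(genes, 1)
      s2 <- s
      s2[g] <- s[g] + stats::runif(1, 0, 5)
      expect_gte(evaluate_gpr(rule, s2), base)
    }
  }
})

test_that("stoichiometric matrix transcribes coefficients in model order", {
  empty <- metabolic_model("empty", list(
    reaction("dummy", c("a[c]" = -1, "b[c]" = 1))))
  empty <- remove_reactions(empty, "dummy")
  S0 <- build_stoichiometric_matrix(empty)
  expect_equal(dim(S0), c(0L, 0L))

  m <- metabolic_model("two", list(
    reaction("R1", c("A[c]" = -1, "B[c]" = 1)),
    reaction("EX_A", c("A[c]" = -1), lower_bound = -10)))
  S <- build_stoichiometric_matrix(m)
  expect_equal(unname(as.matrix(S)[, "R1"]), c(-1, 1))
  expect_equal(colnames(S), c("R1", "EX_A"))

  # column sums over a generated model match a per-reaction loop
  toy <- generate_toy_cell_model("neuron", toy_brain_spec())
  St <- build_stoichiometric_matrix(toy)
  manual <- vapply(toy$reactions, function(r) sum(r$stoichiometry), numeric(1))
  expect_equal(unname(Matrix::colSums(St)), unname(manual))
})

test_that("add_reaction validates ids and metabolites", {
  m <- metabolic_model("m", list(reaction("R1", c("A[c]" = -1, "B[c]" = 1))))
  m2 <- add_reaction(m, reaction("EX_B", c("B[c]" = -1), lower_bound = -0.01))
  expect_equal(length(m2$reactions), 2L)
  expect_equal(length(m2$genes), 0L)
  expect_error(add_reaction(m2, reaction("EX_B", c("B[c]" = -1))), "already present")
  # dangling metabolites are created from their id (compartment parsed)
  m3 <- add_reaction(m2, reaction("R2", c("B[c]" = -1, "C[m]" = 1)))
  expect_true("C[m]" %in% m3$metabolites$id)
  expect_equal(m3$metabolites$compartment[m3$metabolites$id == "C[m]"], "m")
})

test_that("adding the myelin reaction makes the myelin task feasible", {
  spec <- toy_brain_spec()
  oli <- generate_toy_cell_model("oligodendrocyte", spec)
  task <- default_brain_tasks("oligodendrocyte")$myelin_formation
  stripped <- remove_reactions(oli, c("MYELIN", "DM_myelin"))
  expect_false(check_task(stripped, task)$feasible)
  my <- c("chol[c]" = -1, "galcer[c]" = -1, "pc[c]" = -1, "pe[c]" = -1,
          "sm[c]" = -1, "myelin[c]" = 1)
  restored <- add_reaction(stripped, reaction("MYELIN", my,
                                              subsystem = "Myelin metabolism"))
  expect_true(check_task(restored, task)$feasible)
})

test_that("model JSON round-trips on canonical form and rejects bad bounds", {
  spec <- toy_brain_spec()
  ast <- generate_toy_cell_model("astrocyte", spec)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(ast, path)
  back <- read_model(path)
  canon <- canonicalize_model(ast)
  expect_equal(reaction_ids(back), reaction_ids(canon))
  expect_equal(back$metabolites$id, canon$metabolites$id)
  expect_equal(back$genes, canon$genes)
  for (i in seq_along(canon$reactions)) {
    expect_equal(back$reactions[[i]]$stoichiometry,
                 canon$reactions[[i]]$stoichiometry,
                 info = canon$reactions[[i]]$id)
    expect_equal(back$reactions[[i]]$lower_bound, canon$reactions[[i]]$lower_bound)
  }

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id":"x","metabolites":[{"id":"a[c]"}],
    "reactions":[{"id":"r","stoichiometry":{"a[c]":-1},
                  "lower_bound":5,"upper_bound":1}]}', bad)
  expect_error(read_model(bad), "lower_bound > upper_bound")
})

test_that("canonicalization drops zero-coefficient stoichiometry entries", {
  m <- metabolic_model("z", list(
    reaction("R1", c("A[c]" = -1, "B[c]" = 1, "C[c]" = 0))))
  canon <- canonicalize_model(m)
  expect_equal(names(canon$reactions[[1]]$stoichiometry), c("A[c]", "B[c]"))
})

test_that("merged stoichiometric matrix is block-diagonal plus intercellular columns", {
  spec <- toy_brain_spec()
  neu <- generate_toy_cell_model("neuron", spec)
  ast <- generate_toy_cell_model("astrocyte", spec)
  merged <- merge_models(list(neu, ast), c("N", "A"))
  S <- as.matrix(build_stoichiometric_matrix(merged))
  Sn <- as.matrix(build_stoichiometric_matrix(neu))
  Sa <- as.matrix(build_stoichiometric_matrix(ast))
  # neuron rows x astrocyte columns must be all zero and vice versa
  n_rows <- grepl("_N\\]$", rownames(S))
  a_cols <- grepl("_A$", colnames(S))
  expect_true(all(S[n_rows, a_cols] == 0))
  expect_true(all(S[!n_rows, !a_cols] == 0))
  expect_equal(sum(S != 0), sum(Sn != 0) + sum(Sa != 0))
})
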