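#' Specification of the synthetic toy brain
#'
#' The toy brain is a deliberately small, lumped metabolic network that
#' reproduces the qualitative physiology the pipeline is built around:
#' glucose and ketone bodies as competing fuels, aerobic (TCA cycle +
#' oxidative phosphorylation) versus anaerobic (lactate) ATP generation,
#' the neuron-astrocyte glutamate/glutamine/GABA cycle, NAA transfer from
#' neuron to oligodendrocyte, and myelin lipid synthesis competing with
#' growth. Each pathway can be toggled; disabling a pathway a cell's
#' biomass depends on is a specification error, not a silent degradation.
#'
#' @param cell_types Subset of `"neuron"`, `"astrocyte"`, `"microglia"`,
#'   `"oligodendrocyte"`, `"OPC"`.
#' @param pathways Named logical vector over the pathway vocabulary (see
#'   [toy_pathways()]); missing entries default to `TRUE`.
#' @param seed Integer seed used by the stochastic generators
#'   (expression, DE p-values); the network itself is deterministic.
#' @return A list of class `toy_brain_spec`.
#' @export
toy_brain_spec <- function(cell_types = c("neuron", "astrocyte", "microglia",
                                          "oligodendrocyte", "OPC"),
                           pathways = NULL, seed = 1L) {
  known_cells <- c("neuron", "astrocyte", "microglia", "oligodendrocyte", "OPC")
  bad <- setdiff(cell_types, known_cells)
  if (length(bad)) stop(sprintf("unknown cell type(s): %s", paste(bad, collapse = ", ")))
  pw <- stats::setNames(rep(TRUE, length(toy_pathways())), toy_pathways())
  if (!is.null(pathways)) {
    unknown <- setdiff(names(pathways), toy_pathways())
    if (length(unknown)) {
      stop(sprintf("unknown pathway toggle(s): %s", paste(unknown, collapse = ", ")))
    }
    pw[names(pathways)] <- pathways
  }
  if (pw[["glu_gln_gaba"]] && !all(c("neuron", "astrocyte") %in% cell_types)) {
    stop("glu_gln_gaba pathway requires both neuron and astrocyte cell types")
  }
  if (pw[["myelin"]] && !("oligodendrocyte" %in% cell_types)) {
    stop("myelin pathway requires the oligodendrocyte cell type")
  }
  # biomass viability: every cell's biomass reaction draws on these routes
  for (need in c("glycolysis", "TCA", "oxphos", "PPP", "fatty_acid_synthesis")) {
    if (!pw[[need]]) {
      stop(sprintf("spec error: biomass requires the disabled pathway '%s'", need))
    }
  }
  if (pw[["myelin"]] && !pw[["cholesterol_synthesis"]]) {
    stop("spec error: myelin formation requires cholesterol_synthesis")
  }
  structure(list(cell_types = cell_types, pathways = pw, seed = as.integer(seed)),
            class = "toy_brain_spec")
}

#' Pathway vocabulary of the toy brain
#' @return Character vector of toggle names.
#' @export
toy_pathways <- function() {
  c("glycolysis", "TCA", "oxphos", "PPP", "beta_oxidation", "carnitine_shuttle",
    "ketone_utilization", "cholesterol_synthesis", "fatty_acid_synthesis",
    "glu_gln_gaba", "lactate_shuttle", "NAA", "myelin")
}

# ---- master reaction catalog -------------------------------------------
# One fixed, hand-curated catalog; cell models are filtered views of it.
# Lumped stoichiometries are not mass balanced (mass balance is advisory
# for user-defined reactions); cofactor pairs (ATP/ADP, NAD(P)H/NAD(P))
# are balanced so energy accounting is meaningful.
.toy_catalog <- function(myelin_stoichiometry = NULL) {
  rx <- function(id, stoich, gpr = "", subsystem, cells = "all",
                 pathway = NA_character_, lb = 0, ub = 1000) {
    list(id = id, stoich = stoich, gpr = gpr, subsystem = subsystem,
         cells = cells, pathway = pathway, lb = lb, ub = ub)
  }
  NEU <- "neuron"; AST <- "astrocyte"; MIC <- "microglia"
  OLI <- "oligodendrocyte"
  my <- myelin_stoichiometry
  if (is.null(my)) {
    my <- c("chol[c]" = -1, "galcer[c]" = -1, "pc[c]" = -1, "pe[c]" = -1,
            "sm[c]" = -1)
  }
  list(
    # -- uptake and housekeeping
    rx("GLCt", c("glc[e]" = -1, "glc[c]" = 1), "G0001", "Transport",
       pathway = "glycolysis"),
    rx("O2t", c("o2[e]" = -1, "o2[c]" = 1), "", "Transport"),
    rx("CO2t", c("co2[c]" = -1, "co2[e]" = 1), "", "Transport", lb = -1000),
    rx("NH4t", c("nh4[e]" = -1, "nh4[c]" = 1), "G0002", "Transport", lb = -1000),
    rx("ATPM", c("atp[c]" = -1, "adp[c]" = 1), "G0003", "Energy maintenance"),
    rx("BIOMASS", c("atp[c]" = -5, "glu[c]" = -0.5, "r5p[c]" = -0.2,
                    "palm[c]" = -0.1, "adp[c]" = 5, "biomass[c]" = 1),
       "G0004", "Biomass"),
    rx("DM_biomass", c("biomass[c]" = -1), "", "Exchange/demand"),
    rx("DM_r5p", c("r5p[c]" = -1), "", "Exchange/demand", pathway = "PPP"),
    rx("NADPHOX", c("nadph[c]" = -1, "nadp[c]" = 1), "G0005",
       "Antioxidant metabolism", pathway = "PPP"),
    # -- mitochondrial carriers
    rx("ATPtm", c("atp[m]" = -1, "adp[c]" = -1, "atp[c]" = 1, "adp[m]" = 1),
       "G0006", "Transport", pathway = "TCA"),
    rx("MAS", c("nadh[c]" = -1, "nad[m]" = -1, "nad[c]" = 1, "nadh[m]" = 1),
       "G0007 and G0008", "Transport", pathway = "TCA"),
    rx("PYRtm", c("pyr[c]" = -1, "pyr[m]" = 1), "G0009", "Transport",
       pathway = "TCA"),
    # -- glycolysis
    rx("GLYC1", c("glc[c]" = -1, "atp[c]" = -2, "g3p[c]" = 2, "adp[c]" = 2),
       "G0010 and G0011", "Glycolysis", pathway = "glycolysis"),
    rx("GLYC2", c("g3p[c]" = -1, "nad[c]" = -1, "adp[c]" = -2, "pyr[c]" = 1,
                  "nadh[c]" = 1, "atp[c]" = 2),
       "G0012", "Glycolysis", pathway = "glycolysis"),
    # -- pyruvate / lactate
    rx("LDH", c("pyr[c]" = -1, "nadh[c]" = -1, "lac[c]" = 1, "nad[c]" = 1),
       "G0013 or G0014", "Pyruvate metabolism", pathway = "lactate_shuttle",
       lb = -1000),
    rx("LACt", c("lac[c]" = -1, "lac[e]" = 1), "G0015", "Transport",
       pathway = "lactate_shuttle", lb = -1000),
    rx("PDH", c("pyr[m]" = -1, "nad[m]" = -1, "accoa[m]" = 1, "nadh[m]" = 1,
                "co2[c]" = 1),
       "G0016 and G0017", "Pyruvate metabolism", pathway = "TCA"),
    rx("PC", c("pyr[m]" = -1, "atp[m]" = -1, "co2[c]" = -1, "oaa[m]" = 1,
               "adp[m]" = 1),
       "G0018", "Pyruvate metabolism", pathway = "TCA"),
    # -- TCA cycle
    rx("CS", c("accoa[m]" = -1, "oaa[m]" = -1, "cit[m]" = 1), "G0019",
       "TCA cycle", pathway = "TCA"),
    rx("ICDH", c("cit[m]" = -1, "nad[m]" = -1, "akg[m]" = 1, "nadh[m]" = 1,
                 "co2[c]" = 1),
       "G0020 or G0021", "TCA cycle", pathway = "TCA"),
    rx("AKGDH", c("akg[m]" = -1, "nad[m]" = -3, "oaa[m]" = 1,
                  "nadh[m]" = 3, "co2[c]" = 1),
       "G0022 and G0023", "TCA cycle", pathway = "TCA"),
    # -- oxidative phosphorylation
    rx("OXPHOS", c("nadh[m]" = -1, "o2[c]" = -0.5, "adp[m]" = -2.5,
                   "nad[m]" = 1, "atp[m]" = 2.5),
       "G0024 and G0025 and G0026", "Oxidative phosphorylation",
       pathway = "oxphos"),
    # -- pentose phosphate pathway
    rx("PPP", c("glc[c]" = -1, "atp[c]" = -1, "nadp[c]" = -2, "r5p[c]" = 1,
                "nadph[c]" = 2, "co2[c]" = 1, "adp[c]" = 1),
       "G0027", "Pentose phosphate pathway", pathway = "PPP"),
    # -- ketone body utilization (acetyl-CoA entry bypassing glycolysis)
    rx("ACACt", c("acac[e]" = -1, "acac[c]" = 1), "G0028", "Transport",
       pathway = "ketone_utilization"),
    rx("BHBt", c("bhb[e]" = -1, "bhb[c]" = 1), "G0029", "Transport",
       pathway = "ketone_utilization"),
    rx("BDH", c("bhb[c]" = -1, "nad[m]" = -1, "acac[c]" = 1, "nadh[m]" = 1),
       "G0030", "Ketone body metabolism", pathway = "ketone_utilization"),
    rx("KU", c("acac[c]" = -1, "accoa[m]" = 1), "G0031 and G0032",
       "Ketone body metabolism", pathway = "ketone_utilization"),
    # -- fatty acid oxidation
    rx("FFAt", c("ffa[e]" = -1, "ffa[c]" = 1), "G0033", "Transport",
       pathway = "beta_oxidation"),
    rx("CPT", c("ffa[c]" = -1, "ffa[m]" = 1), "G0034 and G0035",
       "Carnitine shuttle", pathway = "carnitine_shuttle"),
    rx("BOX", c("ffa[m]" = -1, "nad[m]" = -4, "accoa[m]" = 4, "nadh[m]" = 4),
       "G0036", "Fatty acid oxidation", pathway = "beta_oxidation"),
    # -- lipogenesis
    rx("CITtm", c("cit[m]" = -1, "cit[c]" = 1), "G0037", "Transport",
       pathway = "fatty_acid_synthesis"),
    rx("ACLY", c("cit[c]" = -1, "atp[c]" = -1, "accoa[c]" = 1, "oaa[m]" = 1,
                 "adp[c]" = 1),
       "G0038", "Fatty acid biosynthesis", pathway = "fatty_acid_synthesis"),
    rx("FAS", c("accoa[c]" = -1, "nadph[c]" = -0.5, "atp[c]" = -1, "palm[c]" = 1,
                "nadp[c]" = 0.5, "adp[c]" = 1),
       "G0039 and G0040", "Fatty acid biosynthesis",
       pathway = "fatty_acid_synthesis"),
    rx("CHOLS", c("accoa[c]" = -1, "nadph[c]" = -0.5, "atp[c]" = -1,
                  "chol[c]" = 1, "nadp[c]" = 0.5, "adp[c]" = 1),
       "G0041", "Cholesterol biosynthesis", cells = c(AST, OLI),
       pathway = "cholesterol_synthesis"),
    # -- glutamate / glutamine / GABA
    rx("GDH", c("akg[m]" = -1, "nh4[c]" = -1, "nadh[c]" = -1, "glu[c]" = 1,
                "nad[c]" = 1),
       "G0042", "Glutamate metabolism", pathway = "TCA"),
    rx("GLS", c("gln[c]" = -1, "glu[c]" = 1, "nh4[c]" = 1), "G0043",
       "Glutamate metabolism", cells = c(NEU, MIC), pathway = "glu_gln_gaba"),
    rx("GS", c("glu[c]" = -1, "nh4[c]" = -1, "atp[c]" = -1, "gln[c]" = 1,
               "adp[c]" = 1),
       "G0044", "Glutamate metabolism", cells = AST, pathway = "glu_gln_gaba"),
    rx("GAD", c("glu[c]" = -1, "gaba[c]" = 1, "co2[c]" = 1), "G0045",
       "Glutamate metabolism", cells = NEU, pathway = "glu_gln_gaba"),
    rx("GABA2GLU", c("gaba[c]" = -1, "akg[m]" = -1, "nad[m]" = -1,
                     "glu[c]" = 1, "oaa[m]" = 1, "nadh[m]" = 1),
       "G0046 and G0047", "Glutamate metabolism", cells = c(NEU, AST),
       pathway = "glu_gln_gaba"),
    rx("GLUt", c("glu[c]" = -1, "glu[e]" = 1), "G0048", "Transport",
       cells = c(NEU, AST, MIC), pathway = "glu_gln_gaba", lb = -1000),
    rx("GLNt", c("gln[c]" = -1, "gln[e]" = 1), "G0049", "Transport",
       cells = c(NEU, AST, MIC), pathway = "glu_gln_gaba", lb = -1000),
    rx("GABAt", c("gaba[c]" = -1, "gaba[e]" = 1), "G0050", "Transport",
       cells = c(NEU, AST), pathway = "glu_gln_gaba", lb = -1000),
    # -- serine / glycine, aspartate, alanine
    rx("SERSYN", c("g3p[c]" = -1, "glu[c]" = -1, "ser[c]" = 1, "akg[m]" = 1),
       "G0051", "Glycine, serine and threonine metabolism",
       pathway = "glycolysis"),
    rx("SHMT", c("ser[c]" = -1, "gly[c]" = 1), "G0052 or G0053",
       "Glycine, serine and threonine metabolism", cells = c(NEU, AST),
       lb = -1000),
    rx("AST", c("oaa[m]" = -1, "glu[c]" = -1, "asp[c]" = 1, "akg[m]" = 1),
       "G0054", "Alanine, aspartate and glutamate metabolism",
       pathway = "TCA", lb = -1000),
    rx("ALT", c("pyr[c]" = -1, "glu[c]" = -1, "ala[c]" = 1, "akg[m]" = 1),
       "G0055", "Alanine, aspartate and glutamate metabolism",
       cells = c(NEU, AST), lb = -1000),
    rx("SERt", c("ser[c]" = -1, "ser[e]" = 1), "G0056", "Transport",
       lb = -1000),
    rx("GLYt", c("gly[c]" = -1, "gly[e]" = 1), "G0057", "Transport",
       cells = c(NEU, AST), lb = -1000),
    rx("ALAt", c("ala[c]" = -1, "ala[e]" = 1), "G0058", "Transport",
       cells = c(NEU, AST), lb = -1000),
    rx("ASPt", c("asp[c]" = -1, "asp[e]" = 1), "G0059", "Transport",
       cells = c(NEU, AST, OLI), lb = -1000),
    # -- branched-chain amino acids (shared LAT transporter, shared BCAT)
    rx("LEUt", c("leu[e]" = -1, "leu[c]" = 1), "G0060", "Transport",
       cells = c(NEU, AST)),
    rx("ILEt", c("ile[e]" = -1, "ile[c]" = 1), "G0060", "Transport",
       cells = c(NEU, AST)),
    rx("VALt", c("val[e]" = -1, "val[c]" = 1), "G0060", "Transport",
       cells = c(NEU, AST)),
    rx("BCAT_leu", c("leu[c]" = -1, "akg[m]" = -1, "kic[c]" = 1, "glu[c]" = 1),
       "G0061", "Valine, leucine and isoleucine metabolism",
       cells = c(NEU, AST)),
    rx("BCAT_ile", c("ile[c]" = -1, "akg[m]" = -1, "kmv[c]" = 1, "glu[c]" = 1),
       "G0061", "Valine, leucine and isoleucine metabolism",
       cells = c(NEU, AST)),
    rx("BCAT_val", c("val[c]" = -1, "akg[m]" = -1, "kiv[c]" = 1, "glu[c]" = 1),
       "G0061", "Valine, leucine and isoleucine metabolism",
       cells = c(NEU, AST)),
    # -- catecholamines and acetylcholine
    rx("LDOPAt", c("ldopa[e]" = -1, "ldopa[c]" = 1), "G0062", "Transport",
       cells = NEU),
    rx("DDC", c("ldopa[c]" = -1, "dopa[c]" = 1, "co2[c]" = 1), "G0063",
       "Neurotransmitter metabolism", cells = NEU),
    rx("DOPAt", c("dopa[c]" = -1, "dopa[e]" = 1), "G0064", "Transport",
       cells = c(NEU, AST), lb = -1000),
    rx("DBH", c("dopa[c]" = -1, "o2[c]" = -0.5, "ne[c]" = 1), "G0065",
       "Neurotransmitter metabolism", cells = c(NEU, AST)),
    rx("PNMT", c("ne[c]" = -1, "adr[c]" = 1), "G0066",
       "Neurotransmitter metabolism", cells = NEU),
    rx("CHLNt", c("chln[e]" = -1, "chln[c]" = 1), "G0068", "Transport",
       cells = c(NEU, OLI)),
    rx("CHAT", c("accoa[c]" = -1, "chln[c]" = -1, "ach[c]" = 1), "G0069",
       "Neurotransmitter metabolism", cells = NEU),
    # -- N-acetyl-L-aspartate
    rx("NAASYN", c("asp[c]" = -1, "accoa[m]" = -1, "naa[c]" = 1), "G0070",
       "NAA metabolism", cells = NEU, pathway = "NAA"),
    rx("NAAt", c("naa[c]" = -1, "naa[e]" = 1), "G0071", "Transport",
       cells = c(NEU, OLI), pathway = "NAA", lb = -1000),
    rx("ASPA", c("naa[c]" = -1, "asp[c]" = 1, "ac[c]" = 1), "G0072",
       "NAA metabolism", cells = OLI, pathway = "NAA"),
    rx("ACS", c("ac[c]" = -1, "atp[c]" = -1, "accoa[c]" = 1, "adp[c]" = 1),
       "G0073", "NAA metabolism", cells = OLI, pathway = "NAA"),
    # -- myelin lipid synthesis (oligodendrocyte only)
    rx("ETNt", c("etn[e]" = -1, "etn[c]" = 1), "G0074", "Transport",
       cells = OLI, pathway = "myelin"),
    rx("CERS", c("palm[c]" = -0.5, "ser[c]" = -0.5, "cer[c]" = 1), "G0075",
       "Sphingolipid metabolism", cells = OLI, pathway = "myelin"),
    rx("GALCERS", c("cer[c]" = -1, "glc[c]" = -0.5, "galcer[c]" = 1), "G0076",
       "Sphingolipid metabolism", cells = OLI, pathway = "myelin"),
    rx("SMS", c("cer[c]" = -1, "pc[c]" = -1, "sm[c]" = 1), "G0077",
       "Sphingolipid metabolism", cells = OLI, pathway = "myelin"),
    rx("PCSYN", c("palm[c]" = -0.5, "chln[c]" = -0.5, "atp[c]" = -1,
                  "pc[c]" = 1, "adp[c]" = 1),
       "G0078", "Glycerophospholipid metabolism", cells = OLI,
       pathway = "myelin"),
    rx("PESYN", c("palm[c]" = -0.5, "etn[c]" = -0.5, "atp[c]" = -1,
                  "pe[c]" = 1, "adp[c]" = 1),
       "G0079", "Glycerophospholipid metabolism", cells = OLI,
       pathway = "myelin"),
    rx("MYELIN", c(my, "myelin[c]" = 1), "G0080", "Myelin metabolism",
       cells = OLI, pathway = "myelin"),
    rx("DM_myelin", c("myelin[c]" = -1), "", "Exchange/demand", cells = OLI,
       pathway = "myelin")
  )
}

#' Generate a toy cell-type metabolic model
#'
#' Filters the fixed master catalog by cell type and enabled pathways,
#' adds an exchange reaction (bounded uptake -0.01, free release) for
#' every extracellular metabolite in use, and validates the result. The
#' network structure is fully deterministic; the spec seed only matters
#' for the stochastic generators built on top.
#'
#' @param cell_type One of the toy cell types, or `"master"` for the union
#'   of all cell types (the parent network extraction starts from).
#' @param spec A [toy_brain_spec()].
#' @param myelin_stoichiometry Optional named coefficient override for the
#'   myelin formation reaction (default: 1 each of cholesterol,
#'   galactosylceramide, phosphatidylcholine, phosphatidylethanolamine,
#'   sphingomyelin).
#' @return A `metabolic_model`.
#' @export
generate_toy_cell_model <- function(cell_type, spec = toy_brain_spec(),
                                    myelin_stoichiometry = NULL) {
  stopifnot(inherits(spec, "toy_brain_spec"))
  known <- c("neuron", "astrocyte", "microglia", "oligodendrocyte", "OPC",
             "master")
  if (!cell_type %in% known) stop(sprintf("unknown cell type '%s'", cell_type))
  pw <- spec$pathways
  catalog <- .toy_catalog(myelin_stoichiometry)
  keep <- vapply(catalog, function(r) {
    in_cell <- cell_type == "master" || identical(r$cells, "all") ||
      cell_type %in% r$cells
    pw_on <- is.na(r$pathway) || isTRUE(pw[[r$pathway]])
    # the carnitine shuttle only exists as the entry step of beta oxidation
    if (identical(r$pathway, "carnitine_shuttle") && !pw[["beta_oxidation"]]) {
      pw_on <- FALSE
    }
    in_cell && pw_on
  }, logical(1))
  catalog <- catalog[keep]
  rxns <- lapply(catalog, function(r) {
    reaction(r$id, r$stoich, lower_bound = r$lb, upper_bound = r$ub,
             gpr = r$gpr, subsystem = r$subsystem)
  })
  emets <- unique(unlist(lapply(catalog, function(r) {
    ids <- names(r$stoich)
    ids[met_compartment(ids) == "e"]
  })))
  for (m in sort(emets)) {
    base <- sub("\\[e\\]$", "", m)
    rxns <- c(rxns, list(reaction(paste0("EX_", base),
                                  stats::setNames(-1, m),
                                  lower_bound = -0.01, upper_bound = 1000,
                                  subsystem = "Exchange/demand")))
  }
  metabolic_model(
    id = sprintf("toy_%s", cell_type),
    reactions = rxns,
    annotations = list(cell_type = cell_type, generator = "brainflux_toy",
                       seed = spec$seed)
  )
}

#' Shipped resting-state constraint table for a toy cell
#'
#' Encodes the resting condition of the toy brain: per-cell uptake
#' capacities for glucose, oxygen, ketone bodies and fatty acids, lipid
#' head-group precursors for the myelinating oligodendrocyte, a forced
#' ATP-maintenance flux for neuron and astrocyte, and the pentose
#' phosphate pathway couplings (5% of glucose uptake in neurons, 6% in
#' astrocytes). Microglia and oligodendrocytes reuse the astrocyte table
#' with internal lower bounds zeroed via the `cell_role` mechanism of
#' [apply_constraints()].
#'
#' @param cell_type Toy cell type.
#' @param config A `run_config`.
#' @return A [constraint_table()].
#' @export
default_cell_constraints <- function(cell_type, config = default_run_config()) {
  r <- config$resting
  glial_like <- cell_type %in% c("microglia", "oligodendrocyte", "OPC")
  atpm <- if (cell_type %in% names(r$atp_maintenance)) {
    r$atp_maintenance[[cell_type]]
  } else {
    r$atp_maintenance[["astrocyte"]]  # reused, then zeroed by the role rule
  }
  # ketone-body uptake is a measured rate, not a capacity: the exchange is
  # pinned (lb = ub) the way arteriovenous-difference constraints are
  # applied, and the ketogenic protocol raises this pinned rate
  bounds <- data.frame(
    reaction_id = c("EX_glc", "EX_o2", "EX_acac", "EX_bhb", "EX_ffa", "ATPM"),
    lb = c(-r$glucose_uptake, -r$oxygen_uptake, -r$ketone_uptake,
           -r$ketone_uptake, -r$fatty_acid_uptake, atpm),
    ub = c(1000, 0, -r$ketone_uptake, -r$ketone_uptake, 1000, 1000),
    stringsAsFactors = FALSE
  )
  if (cell_type %in% c("oligodendrocyte", "neuron")) {
    bounds <- rbind(bounds, data.frame(
      reaction_id = "EX_chln", lb = -r$choline_uptake, ub = 1000))
  }
  if (cell_type == "oligodendrocyte") {
    bounds <- rbind(bounds, data.frame(
      reaction_id = c("EX_etn", "EX_nh4"),
      lb = c(-r$ethanolamine_uptake, -r$ammonia_uptake_oligodendrocyte),
      ub = 1000))
  }
  couplings <- NULL
  if (cell_type %in% names(config$ppp_ratio)) {
    couplings <- data.frame(reaction_a = "PPP", reaction_b = "GLCt",
                            alpha = unname(config$ppp_ratio[[cell_type]]),
                            stringsAsFactors = FALSE)
  }
  constraint_table(bounds = bounds, couplings = couplings,
                   exchange_lb = config$exchange_lb,
                   exchange_ub = config$exchange_ub)
}

#' Generate synthetic single-cell expression profiles
#'
#' Emulates a per-cell-type RNA-seq count table over the shared toy gene
#' namespace. For each cell type the genes appearing in that cell's GPRs
#' form the expressed set and receive negative-binomial counts scaled by
#' gene length (floored so each expressed gene clears the TPM cutoff);
#' all other genes are silent (zero counts, hence TPM below any positive
#' cutoff). The expressed/silent partition is a property of the models,
#' not of the seed: different seeds give different counts but the same
#' partition.
#'
#' @param models Named list of `metabolic_model`s (name = cell type)
#'   sharing the global gene namespace.
#' @param seed Integer seed.
#' @param n_samples Samples (cells) per cell type.
#' @param mean_rate Mean sequencing rate (expected reads per kilobase) for
#'   expressed genes.
#' @return list with `lengths` (named integer vector, bp), `counts`
#'   (per cell type: genes x samples integer matrix) and `expressed`
#'   (per cell type: character vector of expressed genes).
#' @export
generate_expression_profiles <- function(models, seed = 1L, n_samples = 4L,
                                         mean_rate = 300) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  genes <- sort(unique(unlist(lapply(models, `[[`, "genes"))))
  if (!length(genes)) stop("models carry no genes")
  rng <- .with_seed(seed, {
    lengths <- stats::setNames(sample(500:3000, length(genes), replace = TRUE),
                               genes)
    counts <- lapply(models, function(m) {
      expressed <- m$genes
      mat <- matrix(0L, nrow = length(genes), ncol = n_samples,
                    dimnames = list(genes, NULL))
      mu <- mean_rate * lengths[expressed] / 1000
      for (s in seq_len(n_samples)) {
        draw <- stats::rnbinom(length(expressed), mu = mu, size = 20)
        mat[expressed, s] <- pmax(draw, 5L)
      }
      mat
    })
    list(lengths = lengths, counts = counts)
  })
  list(lengths = rng$lengths, counts = rng$counts,
       expressed = lapply(models, `[[`, "genes"))
}

#' Planted differential-expression specification
#'
#' Describes how synthetic gene-level p-values are generated: background
#' genes draw p ~ Uniform(0,1); genes in the GPRs of reactions adjacent
#' to a "hot" metabolite draw -log10(p) from a Gamma distribution with
#' the requested mean, planting a transcriptional hot spot around that
#' metabolite for the reporter analysis to recover.
#'
#' @param hot_metabolites Character vector of metabolite ids (may be
#'   empty for a pure null dataset).
#' @param effect Mean of -log10(p) for the planted genes; `0` disables
#'   planting.
#' @param seed Integer seed.
#' @return A list of class `planted_de_spec`.
#' @export
planted_de_spec <- function(hot_metabolites = character(0), effect = 3,
                            seed = 1L) {
  if (effect < 0) stop("effect must be >= 0")
  structure(list(hot_metabolites = hot_metabolites, effect = effect,
                 seed = as.integer(seed)),
            class = "planted_de_spec")
}

#' Generate synthetic gene-level differential-expression p-values
#'
#' @param model The `metabolic_model` whose gene namespace and topology
#'   define adjacency (a gene is adjacent to a metabolite if it appears in
#'   the GPR of a reaction producing or consuming it).
#' @param planted A [planted_de_spec()].
#' @return Named numeric vector of p-values over `model$genes`.
#' @export
generate_de_pvalues <- function(model, planted) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(planted, "planted_de_spec"))
  genes <- model$genes
  hot_genes <- character(0)
  for (met in planted$hot_metabolites) {
    if (!met %in% model$metabolites$id) {
      stop(sprintf("hot metabolite '%s' not in model", met))
    }
    adj <- Filter(function(r) met %in% names(r$stoichiometry), model$reactions)
    g <- unique(unlist(lapply(adj, function(r) gpr_genes(r$gpr))))
    if (!length(g)) {
      stop(sprintf("hot metabolite '%s' has no gene-associated adjacent reactions",
                   met))
    }
    hot_genes <- union(hot_genes, g)
  }
  .with_seed(planted$seed, {
    p <- stats::setNames(stats::runif(length(genes)), genes)
    if (planted$effect > 0 && length(hot_genes)) {
      neglog <- stats::rgamma(length(hot_genes), shape = 8,
                              scale = planted$effect / 8)
      p[hot_genes] <- 10^(-pmin(neglog, 15))
    }
    p
  })
}

# Run expr with a local RNG state seeded by `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
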