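---
title: "Multi-compartment brain metabolic modeling with brainflux: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment brain metabolic modeling with brainflux: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the constraint-based models, the algorithms, the tunable
parameters, and the design decisions taken where more than one
reasonable choice existed. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The modeling framework

A metabolic model is a set of reactions over compartmentalized
metabolites (`glc[c]`, `pyr[m]`, `lac[e]`, ...), each with a signed
stoichiometry, flux bounds in umol of metabolite per gram of tissue per
minute, a boolean gene-protein-reaction (GPR) rule, and a subsystem
label. All analyses rest on the steady-state assumption: the
stoichiometric matrix $S$ (metabolites x reactions) and flux vector $v$
satisfy $S v = 0$ with $lb \le v \le ub$. Exchange reactions carry a
single metabolite across the system boundary; by convention negative
flux is uptake. Unlisted exchanges default to $lb = -0.01$ (a small
permitted uptake, preventing free metabolite influx while keeping
networks exploratory) and $ub = 1000$ (effectively unbounded release).

Flux balance analysis (FBA) maximizes a linear objective over this
polytope. Because FBA optima are usually degenerate, the package's
standard solve is two-stage: fix the stage-1 optimum as an equality and
minimize $\sum_j v_j^2$ over all reactions. The quadratic stage has a
unique solution, distributes flux across parallel routes, and is what
all reported flux states are. (The squared-flux minimization is taken
over all reactions rather than only internal ones; boundary fluxes are
either pinned by constraints or already determined by the internal
solution, so the distinction is immaterial here and the simpler
formulation was kept.) Flux variability analysis (FVA) minimizes and
maximizes each reaction's flux separately. MOMA (minimization of
metabolic adjustment) finds the feasible flux vector of a perturbed
model nearest in Euclidean distance to a reference state — the
hypothesis that an acutely perturbed network reroutes minimally rather
than re-optimizing.

### Numerical layer

No dedicated LP package is assumed; the LP core is a dense two-phase
bounded-variable primal simplex written for this package, with Dantzig
pricing, a Bland's-rule fallback against cycling, and index-based
tie-breaks so results are reproducible bit for bit. Flux LPs are
heavily degenerate (most reactions sit at a zero bound in any vertex),
which is also why the quadratic problems are not delegated to an
active-set QP method alone: `quadprog` is tried first and is exact and
fast when its Goldfarb–Idnani pivoting succeeds, and the fallback is
Dykstra's alternating-projection algorithm, which computes the same
projection (all our QPs are Euclidean projections onto
$\{S v = b\} \cap [lb, ub]$) without pivoting and therefore without
degeneracy failures. Tolerances: simplex pivot and feasibility
$10^{-9}$; steady-state residual of any reported optimal state must be
below $10^{-6}$; a reaction counts as active when $|v| > 10^{-6}$
umol/g tissue/min; coupling ratios are enforced as exact stoichiometric
rows (see below) and hold to solver precision ($10^{-8}$ in the tests).
Linearly dependent equality rows (conserved moieties) are QR-reduced
before projection solves; infinite bounds are clamped to a large box
and unboundedness is detected from solutions on the box.

### Coupling constraints

Ratio constraints of the form $v_A = \alpha\, v_B$ (GABA transfer =
25% of the glutamine cycle; pentose phosphate flux = 5% of neuronal and
6% of astrocytic glucose uptake) are materialized as balance
pseudo-metabolites: a row in which reaction A produces one unit and
reaction B consumes $\alpha$ units. Steady state then enforces the
ratio exactly in every solution of every solver, rather than
approximately through objective terms.

## Context-specific extraction ("tINIT-lite")

Expression evidence enters as mean TPM per gene
($TPM_g = (c_g/l_g)/\sum_h (c_h/l_h) \times 10^6$, averaged over the
samples of one cell type), mapped to reactions through the GPR rules
with the standard semantics: AND-nodes (enzyme complexes) take the
minimum of their subunits, OR-nodes (isozymes) the maximum. A reaction
is *expressed* when its evidence reaches the cutoff (default 1 TPM).
Reactions without a GPR — exchanges, spontaneous diffusion — are
evidence-neutral and never removed for lack of expression. Missing
genes score 0, which an empty rule deliberately does not: "no rule" is
`NA`, not zero evidence.

Extraction starts from a parent network verified to pass every
metabolic task of the target cell type. A task is a feasibility query:
with all extracellular exchanges closed, can the network produce the
required outputs from the allowed inputs alone? Inputs and outputs are
temporary boundary reactions on the named metabolites, so tasks can
demand internal species (ATP regeneration is expressed as a forced
maintenance flux plus permitted by-products). Internal demand drains
are left open during task checks — they model obligatory turnover, and
the task boundary is the extracellular space.

The full task-driven extraction algorithm published for human tissue
models solves a MILP; at the scale of this package a greedy variant
implements the same contract: visit non-expressed reactions in
ascending evidence order (ties broken lexicographically by reaction
id), tentatively remove each, and keep the removal only if every task
remains feasible. Expressed, evidence-neutral, protected (biomass,
myelin, demand) and task-forced reactions are never candidates. The
result provably satisfies 100% of its task list, and adding evidence
can only grow the retained set. The tests audit minimality post hoc by
exhaustive single-removal.

Cell-specific task lists encode the classical literature assignments:
glutamine-to-glutamate (neuron, microglia), glutamate-to-GABA (neuron),
GABA-to-glutamate (neuron, astrocyte), glutamine synthesis (astrocyte),
serine/glycine interconversion (neuron forward, astrocyte reverse),
branched-chain amino-acid transamination (both), dopamine from
levodopa (neuron), norepinephrine from dopamine (both), adrenaline and
acetylcholine production (neuron), NAA synthesis (neuron) and
degradation (oligodendrocyte), and myelin formation (oligodendrocyte);
oligodendrocyte-precursor cells carry only the essential tasks.

## Integration and the intercellular reaction set

Cell models merge under cell-token suffixes on reaction ids,
compartments and subsystems (`glc[c]` of the neuron becomes
`glc[c_N]`), leaving gene identifiers global. The merged matrix is
block-diagonal until intercellular transport reactions are added, so
with all intercellular fluxes at zero each cell's standalone optimum
remains attainable — a property the tests assert. Sequential pairwise
merging equals a one-shot merge on canonical form.

The default intercellular set covers every transfer the integrated
model's analyses need: glutamate and GABA from neuron to astrocyte with
glutamine returned (the glutamate/glutamine/GABA cycle), reversible
glycine/aspartate/alanine exchange between neuron and astrocyte,
glutamine from astrocyte to microglia, glutamate from neuron to
microglia, NAA from neuron to oligodendrocyte, and lactate among all
four cells. Lactate is implemented as one reversible reaction per cell
against a shared, unsuffixed interstitial pool rather than twelve
pairwise transfers — fewer reactions, identical flux semantics. Users
override the set via `intercellular_spec()`.

The brain-level objective maximizes the glutamine astrocyte-to-neuron
transfer as the operational scalar for the glutamate/glutamine/GABA
cycle (the cycle has no unique scalar definition; this choice is
configurable), couples the intercellular GABA flux to 25% of it, and
then applies the usual two-stage solve.

Exchange behaviour transfers from the single-cell solutions to the
merged model in capacity form: each cell's non-fuel uptake bound
becomes the flux it actually used alone (floored at the default
-0.01), with release unconstrained. Fuel exchanges — glucose, oxygen,
ketone bodies, fatty acids — keep their vascular capacity bounds: those
capacities are properties of blood delivery rather than of the
isolated-cell solution, and the perturbation protocols act on exactly
these bounds. An exact pinning mode (`pin = "exact"`) clamps every
exchange to the single-cell flux within $10^{-6}$; it reproduces the
isolated boundary faithfully but leaves no headroom for intercellular
objectives, which is why capacity transfer is the default.

## Perturbation protocols

All protocol numbers live in `default_run_config()` and mirror the
resting/perturbed conditions the package is built to analyse:

| parameter | value | meaning |
|---|---|---|
| glucose uptake, resting | 0.180 | per-cell vascular capacity |
| glucose uptake, supplemented | 0.210 | glucose / ketogenic protocols |
| oxygen uptake, resting | 0.205 | per-cell capacity |
| hypoxia decrement | 0.100 | subtracted from each O2 uptake capacity, floored at 0 |
| ketone-body uptake, resting | 0.001 each | pinned rate (acetoacetate, 3-hydroxybutyrate) |
| ketone-body uptake, ketogenic | 0.050 each | pinned rate |
| myelin flux, resting | 0.010 | fixed in the merged model |
| demyelination grid | 0.010 to 0 in 11 steps | each solved by MOMA vs. rest |
| GABA coupling | 0.25 | fraction of glutamine cycle flux |
| PPP coupling | 0.05 / 0.06 | fraction of glucose uptake (neuron / astrocyte) |
| ATP maintenance | 0.62 / 0.58 | forced flux, neuron / astrocyte |

(Fluxes in umol/g tissue/min.) Ketone-body uptake is treated as a
*pinned rate* (lb = ub), the way arteriovenous-difference measurements
enter constraint-based models, not as a capacity: a parsimonious
quadratic stage never volunteers to use a fuel whose oxidative load
exceeds glycolysis' short route, so a pure capacity reading would make
the ketogenic condition a no-op. Oxygen reduction is implemented as a
decrement of uptake capacity (floored at zero) rather than an absolute
new bound; the alternative reading is a one-line config change.
Microglia and oligodendrocytes reuse the astrocyte constraint rows with
the lower bounds of internal reactions set to zero — glial cells share
upper-bound physiology, but forced neuron/astrocyte rates are not
imposed on them.

Subsystem activity is the sum of absolute fluxes over a subsystem's
reactions, with the count of active reactions ($|v| > 10^{-6}$)
alongside; transport, exchange/demand and intercellular groups are
flagged and excluded from mean-subsystem summaries.

## The synthetic toy brain

The generator emulates the *inputs* of a full-scale brain GEM study:
a compartmentalized master network, per-cell-type expression, and
differential-expression p-values with planted structure. It is a fixed,
hand-curated catalog of ~100 lumped reactions — glycolysis (two lumps),
TCA cycle (three), oxidative phosphorylation, pentose phosphate
pathway, ketolysis, beta-oxidation behind a carnitine shuttle,
lipogenesis (fatty acids, cholesterol, myelin lipids), the
glutamate/glutamine/GABA enzymes, amino-acid and neurotransmitter
pathways, NAA synthesis/degradation, and a biomass reaction drawing
ATP, glutamate, ribose-5-phosphate and palmitate. Each cell type is a
filtered view of the catalog; `"master"` is the union that extraction
starts from. Cofactor pairs (ATP/ADP, NAD(P)H/NAD(P)) are balanced so
energy accounting is meaningful; carbon/nitrogen mass balance of lumped
reactions is advisory, as it must be for user-defined reactions whose
formulas are unspecified (the myelin reaction in particular: its five
lipid components enter equimolar by default and are overridable).

The toy network is *constructed* so that the qualitative physiology of
interest emerges from its stoichiometry, and the tests assert exactly
those constructed properties:

* ketone bodies enter as acetyl-CoA past glycolysis, so raising their
  pinned uptake raises TCA and oxidative-phosphorylation activity and
  lowers glycolysis' share;
* oxygen restriction forces the pyruvate-to-lactate valve open, so
  hypoxia raises glycolysis and lowers oxidative phosphorylation and
  the TCA cycle (glutamate dehydrogenase reoxidizes *cytosolic* NADH
  and the lumped TCA carries no substrate-level phosphorylation, so
  mitochondrial NADH turnover — and with it TCA flux — is strictly
  tied to respiration);
* myelin lipids compete with growth for acetyl-CoA, NADPH and ATP, so
  forced myelin production monotonically lowers oligodendrocyte
  biomass flux, and the resting myelin rate of 0.010 is attainable
  within the fuel capacities with biomass headroom.

Calibration of the free quantities was done once, when the network was
designed, to place the resting state in the physiologically sensible
interior: resting oxygen use per neuron/astrocyte (~0.11) lies between
the hypoxic cap (0.105) and the resting cap (0.205), and resting
glucose use leaves anaerobic headroom, so the hypoxia protocol is
feasible and direction-revealing rather than degenerate. Maintenance
ATP (0.62/0.58) dominates the energy budget, as it does in real brain
tissue; glial biomass in the merged model is held at 80% of each
cell's standalone optimum so the cells stay metabolically busy while
the cycle objective has fuel headroom.

Expression profiles: each cell type's expressed set is exactly the
genes of its reactions; expressed genes draw length-scaled
negative-binomial counts (floored so every expressed gene clears the
TPM cutoff of 1), silent genes draw zero counts. The partition is a
property of the models; the seed changes counts only. Planted
differential expression: genes adjacent to a chosen hot metabolite draw
$-\log_{10} p$ from a Gamma distribution with the requested mean
(shape 8 — dispersion moderate enough that a planted effect of 3 is a
stable, realistic signal rather than an intermittent one); all other
genes draw $p \sim U(0,1)$.

What passing tests on this fixture do **not** show: recovery of
genome-scale model sizes or absolute fluxes, transcript-level
quantification realism, cell-to-cell heterogeneity within a type, or
thermodynamic feasibility. The toy brain validates the *machinery* —
extraction soundness, coupling exactness, protocol directions, reporter
recovery and calibration — not the biology of any particular
reconstruction.

## Reporter metabolites and enrichment

Gene p-values map to $Z_g = \Phi^{-1}(1 - p_g)$ (clamped to
$[10^{-15}, 1-10^{-15}]$). A metabolite's neighborhood is the set of
*distinct* genes in the GPRs of reactions that produce or consume it —
a gene catalysing two adjacent reactions counts once, and how to weight
such genes is otherwise unspecified in the field, so the distinct-gene
union is the documented choice. For neighborhood size $k$:
$z_{raw} = \sum_g Z_g / \sqrt{k}$, background-corrected by sampling
`n_background` (default 10000, seeded) random size-$k$ sets from all
scored genes: $z_{corr} = (z_{raw} - \mu_k)/\sigma_k$, with
$z_{corr} = 0$ defined for the degenerate $\sigma_k = 0$ case, and
$p = 1 - \Phi(z_{corr})$. Currency metabolites (ATP, NAD(P)H, CO2, ...)
are excluded by a configurable blocklist; metabolites with no scored
neighbors are listed separately, not scored. Scores are computed per
compartmentalized metabolite with an option to pool across
compartments. Raw p-values are reported against the conventional 0.05
and 0.025 filters without multiple-testing correction; directional
(up/down) variants are not computed. Note the null calibration is
approximate by construction: metabolites sharing genes are correlated,
so the false-positive rate over many seeds sits near, not exactly at,
the nominal level — the tests use a correspondingly conservative band.

Enrichment of a reporter set against metabolite pathway sets is the
upper-tail hypergeometric probability of at least the observed overlap;
`pathway_sets()` derives toy sets from subsystems, and GMT files are
supported for external sets.

## Known limitations

* The greedy extraction is order-dependent by design (deterministic
  given its documented ordering) and does not guarantee the global
  minimum-reaction subnetwork the MILP formulation would.
* The simplex is dense; it is sized for networks of a few hundred
  reactions, not for genome-scale matrices.
* Lumped toy stoichiometry is not mass-balanced; mass-balance checking
  is advisory only.
* Protocol feasibility depends on the shipped constraint set; user
  constraint tables that force demands beyond fuel capacities will
  surface as `infeasible` solver statuses, which the protocols record
  per level rather than masking.
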