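---
title: "Methods: validating and comparing genome-scale metabolic models with gemqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating and comparing genome-scale metabolic models with gemqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemqc)
```

## The problem gemqc addresses

Genome-scale metabolic reconstructions — such as the community-curated
consensus network of *Saccharomyces cerevisiae* — are released as SBML files
and evaluated with a standard battery of constraint-based analyses: does the
model grow on defined media? Which single-gene deletion mutants does it
predict to be inviable, and how do those predictions score against curated
essential-gene lists? Which auxotrophies does it capture? How many of its
reactions can carry flux at all? And what, concretely, changed between two
versions of the network? `gemqc` packages exactly this evaluation
methodology: flux balance analysis (FBA), single-gene-deletion screening
through gene–protein–reaction (GPR) boolean logic, flux variability analysis
(FVA) and blocked-reaction detection, contingency-table benchmarking with
the Matthews correlation coefficient (MCC), annotation-coverage auditing,
and identifier-based model diffing.

## Model representation and conventions

A model is a plain container: compartments, metabolites, reactions with flux
bounds (mmol·gDW⁻¹·h⁻¹) and GPR trees, genes, and one linear objective
(normally the biomass pseudo-reaction). Conventions that matter:

* **Sign convention for exchanges.** An exchange reaction is written
  `metabolite → ∅` with coefficient −1, so *positive* flux is secretion into
  the medium and *negative* flux is uptake. A nutrient is made available by
  a strictly negative lower bound; "supplement X" therefore means "give X's
  exchange a negative lower bound" (default −1 when a magnitude is not
  specified, keeping the LP bounded).
* **Biomass as a species.** The biomass pseudo-reaction produces an explicit
  biomass species which a biomass exchange drains, mirroring the encoding
  used by the consensus yeast distributions. The biomass flux is the growth
  proxy.
* **Bounds.** Unbounded directions are `±Inf` internally and are written as
  `±1000` (the de-facto interchange cap) on serialisation; the reader keeps
  whatever number the file holds. Everywhere two bound sets are compared
  (round-trip equality, model diffing) values at or beyond the cap are
  normalised to infinity first, so `±1000` and `±Inf` encodings never
  produce spurious differences; `diff_models(..., normalize_caps = FALSE)`
  disables this.
* **GPR logic.** `AND` = enzyme complex (all subunits needed), `OR` =
  isozymes (any one suffices). The *empty* association evaluates `TRUE`
  under every deletion: a reaction with no gene annotation (spontaneous,
  unannotated transport, exchange) must survive all knockouts. This is the
  standard convention in constraint-based modelling.
* **Unknown genes** in a deletion request or benchmark list are reported and
  skipped, never fatal: curated lists routinely contain ORFs outside the
  model's gene complement, and a model-absent gene cannot change any GPR.

## SBML dialects

Two dialects are read and written: SBML Level 3 with the Flux Balance
Constraints package (bounds as parameters referenced per reaction, GPRs as
`geneProductAssociation` trees, an explicit objective), and the older
Level 2 COBRA-compatible encoding (bounds and objective coefficient as
`kineticLaw` parameters, GPRs as a `GENE_ASSOCIATION:` notes line). A third
`reconstruction_only` mode writes the evidence-only network and refuses to
carry an objective, preserving the distinction between a reconstruction
(GENRE) and a simulable model (GEM). Annotations are MIRIAM-style
controlled-vocabulary RDF terms (`identifiers.org` / `urn:miriam:`
resources: ChEBI for metabolites, UniProt for gene products, PubMed for
evidence); scavenging PMIDs from legacy Notes fields is available behind an
explicit `notes_fallback` flag only, because the convention followed here
encodes annotations per the SBML specification rather than in COBRA Notes.
Species flagged `boundaryCondition="true"` are treated as outside the
system boundary and removed, which collapses `A → A_b` encodings into
ordinary single-metabolite exchange reactions. Only the constraint-based
subset of SBML is supported — no kinetics, events or rules.

## The LP core and its tolerances

No LP solver library is available in the target environment, so the FBA
engine carries its own solver: a dense two-phase full-tableau simplex with
Bland's anti-cycling rule, with variables shifted to `x = v − lb ≥ 0`,
finite upper bounds as explicit slack rows, and zero-level artificials
pivoted out (or their redundant rows dropped) between phases. This is
adequate and exact-in-exact-arithmetic for the fixture and small-model sizes
the package targets; it is O((m+n)²) memory per tableau and is not meant for
repeated whole-genome FVA sweeps where a barrier/revised-simplex library
would be preferred. Numerical choices, embedded in every report:

* pivot/feasibility tolerance `1e-9`;
* classification tolerances `1e-6`: growth below this is "lethal"/"no
  growth", FVA extrema within it of zero are "blocked";
* infinite bounds capped at `exchange_cap = 1000` when the LP is built;
* degenerate optima: the *optimum* is deterministic and reproducible; the
  flux vector is one of possibly many optimal vertices and is advisory;
* FVA iterates reactions in column order, for reproducible logs.

The growth threshold separating viable from lethal is not something the
evaluation literature states explicitly; `1e-6` in flux units is standard
practice, is configurable everywhere, and is recorded in report headers.

Blocked reactions are detected with every exchange opened to
`(−cap, +cap)` and no objective constraint, so a reaction is blocked only
for structural reasons (dead ends, disconnected subnetworks, irreversibility
conflicts) and never merely because of the chosen medium. The exact
condition behind published whole-model blocked counts is not documented by
the model distributions; this default is therefore exposed as flags
(`--exchange-cap`, medium override) rather than hard-coded.

## Benchmarks and metrics

**Essentiality.** The evaluation universe is the intersection of the model's
genes with a verified-ORF list; each gene is deleted, the LP re-solved, and
the mutant classified viable/lethal. The contingency table orientation takes
*predicted growth* as the positive class: TP = predicted viable and truly
inessential, TN = predicted lethal and truly essential. MCC is invariant to
this orientation but sensitivity/specificity are not, so the orientation is
attached to the table object. Ratio metrics (`TP/(TP+FN)` etc.) return `NA`
on a zero denominator — never a silent 0 — while MCC uses the documented
convention that any zero marginal gives 0, the limiting value of the
Pearson correlation of the expanded binary vectors (tables stay numeric).
Geometric-mean accuracy `sqrt(sensitivity × specificity)` is provided
because it has historical use in model evaluation, with the caveat that it
ignores precision.

**Auxotrophy.** A prediction is *correct* iff the deletion mutant fails to
grow on minimal medium *and* grows on its supplemented medium — the
two-condition definition, which the "incorrectly inviable in supplemented
medium" failure class presupposes. When no gene-specific supplement is
known, the default supplement opens uptake (−1) through every exchange the
minimal medium leaves closed: a generic rich rescue.

**Diffing.** Consensus releases guarantee stable `r_####`/`s_####`
identifiers across versions, so the diff is identifier-based by design: two
reactions with identical stoichiometry but different ids are different
entities. Constraint diffs compare `(lb, ub)` pairs only (tolerance `1e-9`,
caps normalised as above); objective coefficients are not "constraints" in
this sense.

## The synthetic fixture generator

`make_toy_model()` builds small networks whose ground truth is known by
construction: a glucose-analogue uptake feeding a linear chain (each step
carrying a single essential gene), optional isozyme steps (`OR` GPRs —
inessential singly, lethal jointly), dead-end metabolites (each contributing
exactly one structurally blocked reaction), an auxotrophy branch (a biomass
precursor synthesisable by one gene product or importable through a
supplement exchange the minimal medium keeps closed), and an energy branch
(high-yield respiration consuming oxygen — the "ATP synthase analogue"
restrictable to force fermentation and ethanol secretion — versus low-yield
fermentation). Wild-type growth has the closed form
`uptake / (1 + aux + atp/2)`. Topology and ground truth are deterministic
functions of the spec; the seed only drives cosmetic annotation sampling.
Defaults (uptake cap 10 mmol·gDW⁻¹·h⁻¹, yields 2:1 for respiration vs
fermentation, supplement uptake −1) were chosen once as round, LP-friendly
values; the fixtures are LP test articles, not biology.

What a green fixture test does and does not establish: it verifies the
*machinery* — GPR propagation, LP correctness against an independent dense
solver, metric formulas, round-trip fidelity — on networks orders of
magnitude smaller and cleaner than a real reconstruction. It does not
establish parser robustness against the full variety of SBML in the wild,
numerical behaviour on 2000-reaction LPs, or any biological claim about a
real model. The whole-model published counts (entity totals, 40.4% PMID
coverage, 738 blocked reactions, the 1868/97 shared-reaction constraint
diff, anaerobic sterol rescue) are checked by a dedicated acceptance test
that requires the externally distributed model files and fails with an
explanatory message when they are absent.

## Independent oracles

Every nontrivial computation has a second, independent route used by the
test suite: GPR trees are re-serialised and evaluated through R's own
parser; deletion screens, FVA and blocked-reaction sets are recomputed with
a dense formulation solved by an external scipy/HiGHS subprocess (a
different solver, formulation and codebase from the in-package simplex);
contingency metrics are recomputed from expanded binary vectors, and MCC is
checked against the Pearson correlation of those vectors. Oracles are never
used as the implementation.

## Known limitations

* The simplex is dense; whole-genome FVA (thousands of LPs on a
  1888-reaction model) is possible but slow — minutes, not seconds.
* Media presets ship with consensus-network exchange ids that could not be
  verified against the distributed files offline; they are explicitly
  best-effort and user-overridable, and the sterol exchange ids in the
  supplemented preset are labelled as guesses to be matched by metabolite
  name against the user's file.
* Compartment-level membrane topology (e.g. flippases) and regulatory
  constraints are out of scope, as is any parsimonious-FBA/MOMA-style
  extension.
* Biomass species detection on foreign files is name-based
  (case-insensitive "biomass"), matching the consensus naming.
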