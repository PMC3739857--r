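#' Specification for a synthetic toy reconstruction
#'
#' The fixture generator builds small metabolic models with ground truth
#' known by construction, so the FBA engine, the deletion screen, the
#' blocked-reaction detector and the benchmarking code are all testable
#' without downloading a real reconstruction. The topology is deterministic
#' from the spec; the seed only drives cosmetic randomness (which internal
#' reactions receive synthetic PubMed annotations), never the ground truth.
#'
#' The generated network is a glucose-analogue chain: an uptake exchange
#' feeds a linear pathway whose end product is consumed by a biomass
#' pseudo-reaction producing an explicit biomass species, itself drained by
#' a biomass exchange. Options add isozyme-catalysed steps (OR-GPRs),
#' dead-end metabolites (blocked reactions), an auxotrophy branch (a biomass
#' precursor that can be synthesised internally by a gene product or
#' imported through a supplement exchange that the minimal medium keeps
#' closed), and an energy branch with a high-yield respiratory route
#' consuming oxygen and a low-yield fermentative route secreting an
#' ethanol analogue.
#'
#' @param chain_length Number of single-gene chain steps (each essential).
#' @param n_isozyme_pairs Extra chain steps catalysed by either of two genes.
#' @param n_dead_ends Dead-end metabolites, each fed by one blocked reaction.
#' @param include_auxotroph_branch Add the auxotrophy scenario.
#' @param include_energy_branch Add respiration vs fermentation.
#' @param seed Integer seed for the cosmetic annotation sampling.
#' @param uptake_cap Glucose-analogue uptake cap, mmol/gDW/h.
#' @return A `toy_model_spec` list.
#' @export
toy_model_spec <- function(chain_length = 3, n_isozyme_pairs = 0,
                           n_dead_ends = 0, include_auxotroph_branch = FALSE,
                           include_energy_branch = FALSE, seed = 1L,
                           uptake_cap = 10) {
  stopifnot(chain_length >= 1, n_isozyme_pairs >= 0, n_dead_ends >= 0,
            uptake_cap > 0)
  structure(list(chain_length = as.integer(chain_length),
                 n_isozyme_pairs = as.integer(n_isozyme_pairs),
                 n_dead_ends = as.integer(n_dead_ends),
                 include_auxotroph_branch = isTRUE(include_auxotroph_branch),
                 include_energy_branch = isTRUE(include_energy_branch),
                 seed = as.integer(seed), uptake_cap = uptake_cap),
            class = "toy_model_spec")
}

#' Generate a toy model with known ground truth
#'
#' @param spec A [toy_model_spec()].
#' @return List with elements `model` (a `gem_model`) and `truth`, a record
#'   holding `essential_genes` (lethal on the minimal medium),
#'   `inessential_genes`, `blocked` (reaction ids), `auxotroph_genes`,
#'   `supplements` (named list gene -> supplement medium),
#'   `minimal_medium`, `exchanges`, `wild_type_growth` (closed form),
#'   `n_annotated_reactions` and `atp_synthase_analogue` (reaction id or NA).
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  U <- spec$uptake_cap
  mets <- list(); rxns <- list(); genes <- list()
  s_i <- 0L; r_i <- 0L; g_i <- 0L
  sid <- function() { s_i <<- s_i + 1L; sprintf("s_%04d", s_i) }
  rid <- function() { r_i <<- r_i + 1L; sprintf("r_%04d", r_i) }
  gid <- function() { g_i <<- g_i + 1L; sprintf("Y%03dW", g_i) }
  add_met <- function(name, comp, biomass = FALSE, chebi = NULL) {
    id <- sid()
    refs <- if (is.null(chebi)) no_refs() else
      data.frame(database = "chebi", accession = chebi,
                 stringsAsFactors = FALSE)
    mets[[length(mets) + 1L]] <<-
      metabolite_row(id, name, comp, biomass, refs)
    id
  }
  add_rxn <- function(name, stoich, lb, ub, gpr = gpr_empty(),
                      exch = NA) {
    id <- rid()
    rxns[[length(rxns) + 1L]] <<-
      reaction_row(id, name, stoich, lb, ub, gpr, character(0), exch)
    id
  }
  add_gene <- function(std = NA_character_) {
    id <- gid()
    genes[[length(genes) + 1L]] <<- gene_row(id, std,
      data.frame(database = "uniprot",
                 accession = paste0("P", 10000 + g_i),
                 stringsAsFactors = FALSE))
    id
  }

  glc_e <- add_met("glucose [extracellular]", "e", chebi = "CHEBI:17234")
  glc_c <- add_met("glucose [cytoplasm]", "c", chebi = "CHEBI:17234")
  ex_glc <- add_rxn("glucose exchange", stats::setNames(-1, glc_e), -U, Inf)
  add_rxn("glucose transport", stats::setNames(c(-1, 1), c(glc_e, glc_c)),
          0, Inf)

  essential <- character(0); inessential <- character(0)
  prev <- glc_c
  for (k in seq_len(spec$chain_length)) {
    nxt <- add_met(sprintf("intermediate %d [cytoplasm]", k), "c")
    g <- add_gene(sprintf("CHN%d", k))
    add_rxn(sprintf("chain step %d", k),
            stats::setNames(c(-1, 1), c(prev, nxt)), 0, Inf, gpr_leaf(g))
    essential <- c(essential, g)
    prev <- nxt
  }
  for (k in seq_len(spec$n_isozyme_pairs)) {
    nxt <- add_met(sprintf("iso intermediate %d [cytoplasm]", k), "c")
    ga <- add_gene(sprintf("ISA%d", k)); gb <- add_gene(sprintf("ISB%d", k))
    add_rxn(sprintf("isozyme step %d", k),
            stats::setNames(c(-1, 1), c(prev, nxt)), 0, Inf,
            gpr_or(gpr_leaf(ga), gpr_leaf(gb)))
    inessential <- c(inessential, ga, gb)
    prev <- nxt
  }
  precursor_final <- prev

  blocked <- character(0)
  for (k in seq_len(spec$n_dead_ends)) {
    dm <- add_met(sprintf("dead end %d [cytoplasm]", k), "c")
    blocked <- c(blocked,
                 add_rxn(sprintf("dead-end reaction %d", k),
                         stats::setNames(c(-1, 1), c(glc_c, dm)), 0, Inf))
  }

  biomass_needs <- stats::setNames(-1, precursor_final)
  auxotroph_genes <- character(0); supplements <- list()
  ex_prec <- NA_character_
  if (spec$include_auxotroph_branch) {
    prec_c <- add_met("precursor [cytoplasm]", "c")
    prec_e <- add_met("precursor [extracellular]", "e")
    g_aux <- add_gene("AUX1")
    add_rxn("precursor synthase",
            stats::setNames(c(-1, 1), c(glc_c, prec_c)), 0, Inf,
            gpr_leaf(g_aux))
    add_rxn("precursor transport",
            stats::setNames(c(-1, 1), c(prec_e, prec_c)), -Inf, Inf)
    ex_prec <- add_rxn("precursor exchange", stats::setNames(-1, prec_e),
                       0, Inf)
    biomass_needs <- c(biomass_needs, stats::setNames(-1, prec_c))
    essential <- c(essential, g_aux)    # minimal medium keeps ex_prec closed
    auxotroph_genes <- g_aux
  }

  ex_o2 <- ex_eth <- atp_synthase <- NA_character_
  if (spec$include_energy_branch) {
    o2_e <- add_met("oxygen [extracellular]", "e", chebi = "CHEBI:15379")
    o2_c <- add_met("oxygen [cytoplasm]", "c", chebi = "CHEBI:15379")
    atp <- add_met("atp analogue [cytoplasm]", "c")
    eth_c <- add_met("ethanol analogue [cytoplasm]", "c")
    eth_e <- add_met("ethanol analogue [extracellular]", "e")
    ex_o2 <- add_rxn("oxygen exchange", stats::setNames(-1, o2_e), -Inf, Inf)
    add_rxn("oxygen transport", stats::setNames(c(-1, 1), c(o2_e, o2_c)),
            0, Inf)
    g_resp <- add_gene("RSP1"); g_ferm <- add_gene("FRM1")
    atp_synthase <- add_rxn("respiration (ATP synthase analogue)",
                            stats::setNames(c(-1, -1, 2), c(glc_c, o2_c, atp)),
                            0, Inf, gpr_leaf(g_resp))
    add_rxn("fermentation",
            stats::setNames(c(-1, 1, 1), c(glc_c, atp, eth_c)),
            0, Inf, gpr_leaf(g_ferm))
    add_rxn("ethanol export", stats::setNames(c(-1, 1), c(eth_c, eth_e)),
            0, Inf)
    ex_eth <- add_rxn("ethanol exchange", stats::setNames(-1, eth_e), 0, Inf)
    inessential <- c(inessential, g_resp, g_ferm)
    biomass_needs <- c(biomass_needs, stats::setNames(-1, atp))
  }

  bm <- add_met("biomass [cytoplasm]", "c", biomass = TRUE)
  r_biomass <- add_rxn("biomass pseudo-reaction",
                       c(biomass_needs, stats::setNames(1, bm)), 0, Inf)
  add_rxn("biomass exchange", stats::setNames(-1, bm), 0, Inf)

  model <- gem_model(
    id = sprintf("toy_L%d_I%d_D%d%s%s", spec$chain_length,
                 spec$n_isozyme_pairs, spec$n_dead_ends,
                 if (spec$include_auxotroph_branch) "_aux" else "",
                 if (spec$include_energy_branch) "_nrg" else ""),
    name = "synthetic toy reconstruction",
    compartments = c(c = "cytoplasm", e = "extracellular"),
    metabolites = do.call(rbind, mets),
    reactions = do.call(rbind, rxns),
    genes = if (length(genes)) do.call(rbind, genes) else empty_gene_table(),
    objective_reaction_id = r_biomass,
    objective_sense = "maximize", dialect = "fbc3")

  # cosmetic, seeded: sprinkle synthetic PubMed ids over internal reactions
  internal <- which(!model$reactions$is_exchange)
  n_annot <- 0L
  if (length(internal)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    pick <- internal[stats::runif(length(internal)) < 0.5]
    for (j in pick)
      model$reactions$pubmed_refs[[j]] <-
        as.character(sample.int(999999L, sample.int(2L, 1L)))
    n_annot <- length(pick)
  }

  exchanges <- find_exchange_reactions(model)
  minimal <- data.frame(reaction_id = ex_glc, lower_bound = -U,
                        upper_bound = Inf, stringsAsFactors = FALSE)
  if (!is.na(ex_o2))
    minimal <- rbind(minimal, data.frame(reaction_id = ex_o2,
                                         lower_bound = -Inf,
                                         upper_bound = Inf))
  minimal_medium <- medium(minimal, name = "toy_minimal")
  if (spec$include_auxotroph_branch) {
    supp <- rbind(minimal, data.frame(reaction_id = ex_prec,
                                      lower_bound = -1, upper_bound = Inf))
    supplements[[auxotroph_genes]] <- medium(supp, name = "toy_supplemented")
  }

  # closed-form wild-type growth on the minimal medium: each unit of biomass
  # draws 1 glucose through the chain, +1 for the precursor branch, +1/2 for
  # ATP via respiration (yield 2 per glucose)
  demand <- 1 + spec$include_auxotroph_branch +
    0.5 * spec$include_energy_branch
  truth <- list(
    essential_genes = essential,
    inessential_genes = inessential,
    blocked = blocked,
    auxotroph_genes = auxotroph_genes,
    supplements = supplements,
    minimal_medium = minimal_medium,
    exchanges = exchanges,
    wild_type_growth = U / demand,
    n_annotated_reactions = n_annot,
    atp_synthase_analogue = atp_synthase,
    ethanol_exchange = ex_eth,
    oxygen_exchange = ex_o2,
    glucose_exchange = ex_glc,
    precursor_exchange = ex_prec)
  list(model = model, truth = truth)
}

# ---------------------------------------------------------------------------
# Independent oracle path: dense problems are shipped as JSON to a small
# scipy/HiGHS script (inst/python/lp_oracle.py) run through the system
# `python`. This is deliberately a different solver, formulation and code
# path from the package's own simplex, so results can be cross-checked.

oracle_script <- function() {
  p <- system.file("python", "lp_oracle.py", package = "gemqc")
  if (!nzchar(p)) p <- file.path("inst", "python", "lp_oracle.py")
  if (!file.exists(p)) stop("lp_oracle.py not found; is gemqc installed?")
  p
}

#' Solve a batch of LPs with the independent scipy/HiGHS oracle
#'
#' @param S Dense stoichiometric matrix (may have zero rows).
#' @param problems List of problems, each a list with `obj`, `lb`, `ub`
#'   (capped, finite), `maximize`, and optionally `Ageq`/`bgeq`.
#' @return List of results with `status`, `objective`, `solution`.
#' @keywords internal
oracle_lp_batch <- function(S, problems) {
  n <- if (length(problems)) length(problems[[1L]]$obj) else ncol(S)
  job <- list(n = n, S = as.matrix(S), problems = problems)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(job, fin, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  status <- system2("python", c(oracle_script(), fin, fout),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(fout))
    stop("LP oracle subprocess failed (exit ", status, ")")
  res <- jsonlite::read_json(fout, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(res, function(r) list(
    status = r$status,
    objective = if (r$status == "optimal") as.numeric(r$objective) else NA_real_,
    solution = if (r$status == "optimal") as.numeric(r$solution)
               else rep(NA_real_, n)))
}

oracle_lp <- function(S, lb, ub, obj, maximize = TRUE, cap = 1000) {
  b <- cap_bounds(lb, ub, cap = cap)
  oracle_lp_batch(S, list(list(obj = obj, lb = b$lb, ub = b$ub,
                               maximize = maximize)))[[1L]]
}

oracle_fba <- function(model, exchange_cap = 1000) {
  S <- as.matrix(build_stoich_matrix(model))
  obj <- as.numeric(reaction_ids(model) == model$objective_reaction_id)
  oracle_lp(S, model$reactions$lower_bound, model$reactions$upper_bound,
            obj, maximize = model$objective_sense == "maximize",
            cap = exchange_cap)
}

#' Brute-force flux-variability oracle
#'
#' Independent dense min/max per reaction via the scipy/HiGHS oracle, for
#' cross-checking [flux_variability()].
#'
#' @inheritParams brute_force_essential
#' @return Data frame with `reaction_id`, `v_min`, `v_max`.
#' @export
brute_force_fva <- function(model, exchange_cap = 1000) {
  S <- as.matrix(build_stoich_matrix(model))
  b <- cap_bounds(model$reactions$lower_bound, model$reactions$upper_bound,
                  cap = exchange_cap)
  n <- n_reactions(model)
  probs <- vector("list", 2L * n)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    probs[[2L * j - 1L]] <- list(obj = obj, lb = b$lb, ub = b$ub,
                                 maximize = FALSE)
    probs[[2L * j]] <- list(obj = obj, lb = b$lb, ub = b$ub, maximize = TRUE)
  }
  res <- oracle_lp_batch(S, probs)
  bad <- vapply(res, function(r) r$status != "optimal", logical(1))
  if (any(bad)) stop("FVA oracle subproblem not optimal")
  data.frame(
    reaction_id = reaction_ids(model),
    v_min = vapply(seq_len(n), function(j) res[[2L * j - 1L]]$objective,
                   numeric(1)),
    v_max = vapply(seq_len(n), function(j) res[[2L * j]]$objective,
                   numeric(1)),
    stringsAsFactors = FALSE)
}

#' Brute-force essential-gene oracle
#'
#' Independent route for validating [single_gene_deletions()]: for each gene
#' the GPR trees are re-evaluated through a second code path (the textual
#' serialisation is parsed and evaluated as an R boolean expression) and the
#' deletion LPs are solved densely by the scipy/HiGHS oracle subprocess, a
#' different solver and formulation from the package's own simplex.
#'
#' @param model A `gem_model`.
#' @param threshold Lethality cutoff.
#' @param exchange_cap Cap for infinite bounds.
#' @return Character vector of essential gene ids.
#' @export
brute_force_essential <- function(model, threshold = 1e-6,
                                  exchange_cap = 1000) {
  wt <- oracle_fba(model, exchange_cap)
  if (wt$status != "optimal" || wt$objective < threshold)
    stop("oracle: wild type does not grow")
  S <- as.matrix(build_stoich_matrix(model))
  obj <- as.numeric(reaction_ids(model) == model$objective_reaction_id)
  maximize <- model$objective_sense == "maximize"
  b0 <- cap_bounds(model$reactions$lower_bound, model$reactions$upper_bound,
                   cap = exchange_cap)
  genes <- gene_ids(model)
  affected <- logical(length(genes))
  probs <- list()
  for (k in seq_along(genes)) {
    closed <- vapply(model$reactions$gpr, function(tree) {
      !gpr_eval_via_expression(tree, genes[k])
    }, logical(1))
    if (!any(closed)) next
    affected[k] <- TRUE
    lb <- b0$lb; ub <- b0$ub
    lb[closed] <- 0; ub[closed] <- 0
    probs[[length(probs) + 1L]] <- list(obj = obj, lb = lb, ub = ub,
                                        maximize = maximize)
  }
  if (!length(probs)) return(character(0))
  res <- oracle_lp_batch(S, probs)
  lethal <- vapply(res, function(r)
    r$status != "optimal" || r$objective < threshold, logical(1))
  genes[affected][lethal]
}

# Second GPR evaluation path: serialise to text, substitute gene truth
# values, and let R's parser/evaluator do the boolean work.
gpr_eval_via_expression <- function(tree, deleted) {
  s <- gpr_to_string(tree)
  if (!nzchar(s)) return(TRUE)
  gs <- gpr_genes(tree)
  gs <- gs[order(-nchar(gs))]   # longest first so ids are not substrings
  env <- new.env(parent = baseenv())
  safe <- paste0("gene_", seq_along(gs))
  for (k in seq_along(gs)) {
    assign(safe[k], !(gs[k] %in% deleted), envir = env)
    s <- gsub(gs[k], safe[k], s, fixed = TRUE)
  }
  s <- gsub("\\band\\b", "&&", s)
  s <- gsub("\\bor\\b", "||", s)
  isTRUE(eval(parse(text = s)[[1]], envir = env))
}

#' Brute-force blocked-reaction oracle
#'
#' Independent route for validating [blocked_reactions()]: every exchange is
#' opened to `(-cap, cap)` and each reaction's flux is minimised and
#' maximised densely by the scipy/HiGHS oracle subprocess. Blocked iff both
#' optima are zero within `zero_tol`.
#'
#' @inheritParams brute_force_essential
#' @param zero_tol Classification tolerance.
#' @return Character vector of blocked reaction ids.
#' @export
brute_force_blocked <- function(model, exchange_cap = 1000, zero_tol = 1e-6) {
  exch <- find_exchange_reactions(model)
  i <- match(exch, model$reactions$id)
  model$reactions$lower_bound[i] <- -exchange_cap
  model$reactions$upper_bound[i] <- exchange_cap
  fva <- brute_force_fva(model, exchange_cap = exchange_cap)
  fva$reaction_id[abs(fva$v_min) <= zero_tol & abs(fva$v_max) <= zero_tol]
}
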