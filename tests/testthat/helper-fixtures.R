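# Shared fixture builders. Everything is generated in code at test time;
# no binary or downloaded fixtures.

# hand-built linear chain: EX_A (uptake cap 10) -> A -> B -> C -> biomass
# drain; every internal conversion carries a single-gene GPR. The expected
# stoichiometric matrix and FBA optimum are writable by hand.
tiny_chain_model <- function(uptake = 10) {
  mets <- rbind(
    gemqc:::metabolite_row("s_0001", "A", "c"),
    gemqc:::metabolite_row("s_0002", "B", "c"),
    gemqc:::metabolite_row("s_0003", "C (biomass)", "c", is_biomass = TRUE))
  rxns <- rbind(
    gemqc:::reaction_row("r_0001", "A exchange", c(s_0001 = -1), -uptake, Inf),
    gemqc:::reaction_row("r_0002", "A->B", c(s_0001 = -1, s_0002 = 1), 0, Inf,
                         gpr = gpr_leaf("gA")),
    gemqc:::reaction_row("r_0003", "B->C", c(s_0002 = -1, s_0003 = 1), 0, Inf,
                         gpr = gpr_leaf("gB")),
    gemqc:::reaction_row("r_0004", "C drain", c(s_0003 = -1), 0, Inf))
  gem_model("chain", compartments = c(c = "cytoplasm"),
            metabolites = mets, reactions = rxns,
            genes = rbind(gemqc:::gene_row("gA"), gemqc:::gene_row("gB")),
            objective_reaction_id = "r_0004")
}

# random GPR tree over a fixed gene alphabet
random_gpr <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4)
    return(gpr_leaf(sample(genes, 1)))
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_gpr(genes, depth - 1))
  if (stats::runif(1) < 0.5) gpr_and(kids) else gpr_or(kids)
}

# random contingency table (counts 0..40)
random_table <- function() {
  n <- sample(0:40, 4, replace = TRUE)
  contingency_table(n[1], n[2], n[3], n[4])
}

# expand a contingency table into paired binary prediction/observation
# vectors (1 = viable); the independent second path for every metric
expand_table <- function(t) {
  pred <- c(rep(1, t$TP), rep(1, t$FP), rep(0, t$TN), rep(0, t$FN))
  obs  <- c(rep(1, t$TP), rep(0, t$FP), rep(0, t$TN), rep(1, t$FN))
  list(pred = pred, obs = obs)
}

# vector-path metric formulas (independent of the package's count-based path)
vec_metrics <- function(t) {
  v <- expand_table(t)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(
    sensitivity = div(sum(v$pred == 1 & v$obs == 1), sum(v$obs == 1)),
    specificity = div(sum(v$pred == 0 & v$obs == 0), sum(v$obs == 0)),
    ppv = div(sum(v$pred == 1 & v$obs == 1), sum(v$pred == 1)),
    npv = div(sum(v$pred == 0 & v$obs == 0), sum(v$pred == 0)))
}

# the four fixture corners exercised by benchmark/oracle identity tests
fixture_corners <- function(seed = 42) {
  list(
    make_toy_model(toy_model_spec(chain_length = 3, seed = seed)),
    make_toy_model(toy_model_spec(chain_length = 2, n_isozyme_pairs = 2,
                                  n_dead_ends = 1, seed = seed)),
    make_toy_model(toy_model_spec(chain_length = 2,
                                  include_auxotroph_branch = TRUE,
                                  n_dead_ends = 2, seed = seed)),
    make_toy_model(toy_model_spec(chain_length = 2, n_isozyme_pairs = 1,
                                  include_auxotroph_branch = TRUE,
                                  include_energy_branch = TRUE,
                                  seed = seed)))
}
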