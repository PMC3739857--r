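test_that("FBA solves the hand-solvable chain exactly", {
  m <- tiny_chain_model(uptake = 10)
  r <- fba(m)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 10)
  # every flux in the chain runs at the uptake cap
  expect_equal(unname(abs(r$fluxes)), c(10, 10, 10, 10))
  # steady state and bounds hold
  S <- as.matrix(build_stoich_matrix(m))
  expect_lt(max(abs(S %*% r$fluxes)), 1e-6)
  # closed medium: zero growth
  m0 <- constrain_reaction(m, "r_0001", c(0, 0))
  expect_equal(fba(m0)$objective_value, 0)
  # no objective set is a configuration error
  m$objective_reaction_id <- NA_character_
  expect_error(fba(m), "no objective")
})

test_that("FBA optimum is deterministic and matches generator closed forms", {
  for (corner in fixture_corners()) {
    r1 <- fba(corner$model)
    r2 <- fba(corner$model)
    expect_equal(r1$objective_value, r2$objective_value, tolerance = 1e-9)
    expect_equal(r1$objective_value, corner$truth$wild_type_growth,
                 tolerance = 1e-7, label = corner$model$id)
  }
})

test_that("shrinking a bound interval never increases the optimum", {
  set.seed(21)
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       n_isozyme_pairs = 1,
                                       include_energy_branch = TRUE))
  m <- toy$model
  base <- fba(m)$objective_value
  for (i in 1:15) {
    j <- sample(n_reactions(m), 1)
    lb <- max(m$reactions$lower_bound[j], -1000)
    ub <- min(m$reactions$upper_bound[j], 1000)
    mid <- stats::runif(1, lb, ub)
    m2 <- constrain_reaction(m, reaction_ids(m)[j],
                             sort(c(stats::runif(1, lb, mid), mid)))
    r2 <- fba(m2)
    val <- if (r2$status == "optimal") r2$objective_value else 0
    expect_lte(val, base + 1e-7)
  }
})

test_that("single-gene deletion screen matches truth and handles edge genes", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       n_isozyme_pairs = 1,
                                       include_auxotroph_branch = TRUE))
  m <- toy$model
  res <- single_gene_deletions(m)
  lethal <- res$gene[res$classification == "lethal"]
  expect_setequal(lethal, toy$truth$essential_genes)
  # isozyme singles keep wild-type growth
  wt <- attr(res, "wild_type_growth")
  iso <- toy$truth$inessential_genes
  expect_equal(res$growth[match(iso, res$gene)], rep(wt, length(iso)))
  # gene outside the model: viable at wild-type growth, flagged
  res2 <- single_gene_deletions(m, genes = c("YZZ9W", gene_ids(m)[1]))
  expect_false(res2$in_model[1])
  expect_equal(res2$growth[1], wt)
  expect_equal(res2$classification[1], "viable")
  # non-growing wild type aborts the screen
  closed <- constrain_reaction(m, toy$truth$glucose_exchange, c(0, 0))
  expect_error(single_gene_deletions(closed), "does not grow")
})

test_that("deleting a gene in no GPR leaves the optimum unchanged exactly", {
  m <- tiny_chain_model()
  m$genes <- rbind(m$genes, gemqc:::gene_row("gOrphan"))
  r <- single_gene_deletions(m, genes = "gOrphan")
  expect_identical(r$growth, attr(r, "wild_type_growth"))
})

test_that("FVA brackets the chain and matches the independent dense oracle", {
  m <- tiny_chain_model(uptake = 10)
  # hand LP: all chain fluxes range [-10..0] for the uptake, [0,10] forward
  fva <- flux_variability(m)
  expect_equal(fva$v_max, c(0, 10, 10, 10))   # exchange is uptake-only
  expect_equal(fva$v_min, c(-10, 0, 0, 0))
  expect_true(all(fva$v_min <= fva$v_max + 1e-9))
  # a (0,0) reaction reports (0,0)
  m00 <- constrain_reaction(m, "r_0002", c(0, 0))
  f00 <- flux_variability(m00)
  expect_equal(unname(unlist(f00[f00$reaction_id == "r_0002",
                                 c("v_min", "v_max")])), c(0, 0))
  # oracle equivalence on a composite fixture
  toy <- make_toy_model(toy_model_spec(chain_length = 2, n_isozyme_pairs = 1,
                                       n_dead_ends = 1,
                                       include_energy_branch = TRUE))
  fva2 <- flux_variability(toy$model)
  orc <- brute_force_fva(toy$model)
  expect_equal(fva2$v_min, orc$v_min, tolerance = 1e-6)
  expect_equal(fva2$v_max, orc$v_max, tolerance = 1e-6)
})

test_that("FVA with an objective fraction keeps growth near the optimum", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       include_energy_branch = TRUE))
  m <- toy$model
  opt <- fba(m)$objective_value
  fva <- flux_variability(m, objective_fraction = 0.9)
  j <- match(m$objective_reaction_id, fva$reaction_id)
  expect_gte(fva$v_min[j], 0.9 * opt - 1e-6)
})

test_that("blocked reactions equal ground truth and the dense oracle", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2, n_dead_ends = 2,
                                       include_auxotroph_branch = TRUE))
  bl <- blocked_reactions(toy$model)
  expect_setequal(bl, toy$truth$blocked)
  expect_setequal(bl, brute_force_blocked(toy$model))
  # fully coupled chain with open exchanges: nothing blocked
  expect_length(blocked_reactions(tiny_chain_model()), 0)
  # closing a reaction makes it blocked
  m <- constrain_reaction(tiny_chain_model(), "r_0003", c(0, 0))
  expect_true("r_0003" %in% blocked_reactions(m))
})

test_that("relaxing reversibility can unblock dead-end fluxes", {
  # B is produced by two irreversible reactions and consumed by nothing, so
  # both producers are blocked even with every exchange open; making C->B
  # reversible creates the through-path A -> B -> C -> (out)
  mets <- rbind(
    gemqc:::metabolite_row("s_0001", "A", "c"),
    gemqc:::metabolite_row("s_0002", "B", "c"),
    gemqc:::metabolite_row("s_0003", "C", "c"))
  rxns <- rbind(
    gemqc:::reaction_row("r_0001", "A exchange", c(s_0001 = -1), -10, Inf),
    gemqc:::reaction_row("r_0002", "A->B", c(s_0001 = -1, s_0002 = 1),
                         0, 10),
    gemqc:::reaction_row("r_0003", "C->B", c(s_0003 = -1, s_0002 = 1),
                         0, 10),
    gemqc:::reaction_row("r_0004", "C exchange", c(s_0003 = -1), 0, Inf))
  m <- gem_model("relaxfix", compartments = c(c = "cytoplasm"),
                 metabolites = mets, reactions = rxns)
  # with B unconsumable nothing can carry steady-state flux at all
  before <- blocked_reactions(m)
  expect_true(all(c("r_0002", "r_0003") %in% before))
  after <- blocked_reactions(relax_reversibility(m, "r_0003"))
  expect_lt(length(after), length(before))
  expect_setequal(after, brute_force_blocked(relax_reversibility(m, "r_0003")))
})

test_that("growth checks distinguish media, including the supplement rescue", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       include_auxotroph_branch = TRUE))
  m <- toy$model
  minimal <- toy$truth$minimal_medium
  expect_true(check_growth(m, minimal)$grows)
  # closed carbon source: no growth
  closed <- medium(data.frame(reaction_id = toy$truth$glucose_exchange,
                              lower_bound = 0, upper_bound = 0), "closed")
  expect_false(check_growth(m, closed)$grows)
  # the auxotroph mutant: dead on minimal, rescued by the supplement
  mut <- apply_deletion(m, toy$truth$auxotroph_genes)
  expect_false(check_growth(mut, minimal)$grows)
  supp <- toy$truth$supplements[[toy$truth$auxotroph_genes]]
  expect_true(check_growth(mut, supp)$grows)
})

test_that("restricting the ATP-synthase analogue reroutes flux to fermentation", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       include_energy_branch = TRUE))
  m <- toy$model
  r_aerobic <- fba(m)
  expect_equal(abs(unname(r_aerobic$fluxes[toy$truth$ethanol_exchange])), 0,
               tolerance = 1e-7)   # respiration preferred at optimum
  restricted <- constrain_reaction(m, toy$truth$atp_synthase_analogue,
                                   c(0, 0))
  r2 <- fba(restricted)
  expect_equal(r2$status, "optimal")
  expect_gt(unname(r2$fluxes[toy$truth$ethanol_exchange]), 1e-6)
  expect_lt(r2$objective_value, r_aerobic$objective_value)
})
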