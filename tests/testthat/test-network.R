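test_that("build_stoich_matrix reproduces the hand-written chain matrix", {
  m <- tiny_chain_model()
  S <- as.matrix(build_stoich_matrix(m))
  expected <- matrix(0, 3, 4,
    dimnames = list(c("s_0001", "s_0002", "s_0003"),
                    c("r_0001", "r_0002", "r_0003", "r_0004")))
  expected["s_0001", "r_0001"] <- -1
  expected["s_0001", "r_0002"] <- -1; expected["s_0002", "r_0002"] <- 1
  expected["s_0002", "r_0003"] <- -1; expected["s_0003", "r_0003"] <- 1
  expected["s_0003", "r_0004"] <- -1
  expect_identical(S, expected)
  # nonzero count equals total stoichiometry entries
  expect_equal(Matrix::nnzero(build_stoich_matrix(m)),
               sum(lengths(m$reactions$stoichiometry)))
})

test_that("empty model gives a 0x0 matrix and zero summary counts", {
  m0 <- gem_model("empty")
  expect_equal(dim(build_stoich_matrix(m0)), c(0L, 0L))
  s <- summarize_model(m0)
  expect_equal(unlist(s[c("genes", "metabolites", "reactions")]),
               c(genes = 0L, metabolites = 0L, reactions = 0L))
  expect_length(find_exchange_reactions(m0), 0)
})

test_that("exchange detection uses the flag, falling back to structure", {
  m <- tiny_chain_model()
  expect_setequal(find_exchange_reactions(m), c("r_0001", "r_0004"))
  # drop the flag entirely: structural single-metabolite rule kicks in
  m$reactions$is_exchange <- FALSE
  expect_setequal(find_exchange_reactions(m), c("r_0001", "r_0004"))
  # generator bookkeeping: k exchanges in, k ids out
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       include_energy_branch = TRUE))
  expect_setequal(find_exchange_reactions(toy$model), toy$truth$exchanges)
})

test_that("apply_deletion closes exactly the GPR-disabled reactions", {
  m <- tiny_chain_model()
  # no-op deletion: identical model
  expect_identical(apply_deletion(m, character(0)), m)
  # gene absent from every GPR: bounds untouched, warning raised
  expect_warning(m2 <- apply_deletion(m, "ghost"), "not in model")
  expect_identical(m2$reactions$lower_bound, m$reactions$lower_bound)
  # closing a chain gene zeroes that reaction only
  m3 <- apply_deletion(m, "gA")
  expect_equal(unname(m3$reactions$lower_bound[2]), 0)
  expect_equal(unname(m3$reactions$upper_bound[2]), 0)
  expect_identical(m3$reactions$upper_bound[-2], m$reactions$upper_bound[-2])
  # idempotence
  expect_identical(apply_deletion(m3, "gA", warn_unknown = FALSE), m3)
  # the original model object is untouched
  expect_equal(unname(m$reactions$upper_bound[2]), Inf)
})

test_that("isozyme OR logic needs both genes deleted to close the reaction", {
  toy <- make_toy_model(toy_model_spec(chain_length = 1,
                                       n_isozyme_pairs = 1))
  m <- toy$model
  iso <- which(vapply(m$reactions$gpr, function(g) g$type == "or",
                      logical(1)))
  pair <- gpr_genes(m$reactions$gpr[[iso]])
  one <- apply_deletion(m, pair[1])
  expect_gt(one$reactions$upper_bound[iso], 0)
  both <- apply_deletion(m, pair)
  expect_equal(unname(both$reactions$upper_bound[iso]), 0)
})

test_that("apply_medium sets listed bounds and closes unlisted uptake", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       include_auxotroph_branch = TRUE))
  m <- toy$model
  med <- toy$truth$minimal_medium
  m2 <- apply_medium(m, med)
  i_glc <- match(toy$truth$glucose_exchange, m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i_glc], -10)
  # unlisted exchange: secretion allowed, uptake forbidden
  i_prec <- match(toy$truth$precursor_exchange, m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i_prec], 0)
  expect_equal(m2$reactions$upper_bound[i_prec], Inf)
  # internal reactions never touched
  internal <- !m$reactions$is_exchange
  expect_identical(m2$reactions$lower_bound[internal],
                   m$reactions$lower_bound[internal])
  expect_identical(m2$reactions$upper_bound[internal],
                   m$reactions$upper_bound[internal])
  # empty medium: every exchange becomes (0, Inf)
  m3 <- apply_medium(m, medium(data.frame(reaction_id = character(0),
                                          lower_bound = numeric(0),
                                          upper_bound = numeric(0)),
                               "closed"))
  i_ex <- m3$reactions$is_exchange
  expect_true(all(m3$reactions$lower_bound[i_ex] == 0))
  expect_true(all(m3$reactions$upper_bound[i_ex] == Inf))
  # referencing an internal reaction is an error naming it
  bad <- medium(data.frame(reaction_id = "r_0002", lower_bound = -1,
                           upper_bound = 1), "bad")
  expect_error(apply_medium(m, bad), "non-exchange.*r_0002")
  # unknown reaction id is also an error
  worse <- medium(data.frame(reaction_id = "r_9999", lower_bound = -1,
                             upper_bound = 1), "worse")
  expect_error(apply_medium(m, worse), "unknown reaction")
})

test_that("medium TSV round trip and invariant checks", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_medium(toy$truth$minimal_medium, f)
  med <- read_medium(f)
  expect_equal(med$bounds$reaction_id,
               toy$truth$minimal_medium$bounds$reaction_id)
  expect_equal(med$bounds$lower_bound,
               toy$truth$minimal_medium$bounds$lower_bound)
  expect_error(medium(data.frame(reaction_id = "x", lower_bound = 2,
                                 upper_bound = 1), "inverted"),
               "lower_bound > upper_bound")
})

test_that("shipped media presets load and follow the sign convention", {
  for (p in c("minimal_aerobic_glucose", "anaerobic_minimal",
              "anaerobic_sterol_supplemented")) {
    med <- medium_preset(p)
    expect_s3_class(med, "gem_medium")
    expect_true(all(med$bounds$lower_bound <= med$bounds$upper_bound))
  }
  # anaerobic: no oxygen uptake
  an <- medium_preset("anaerobic_minimal")
  expect_equal(an$bounds$lower_bound[an$bounds$reaction_id == "r_1992"], 0)
  # sterol supplementation: strictly negative lower bounds on 6 sterols
  st <- medium_preset("anaerobic_sterol_supplemented")
  extra <- setdiff(st$bounds$reaction_id, an$bounds$reaction_id)
  expect_length(extra, 6)
  expect_true(all(st$bounds$lower_bound[match(extra, st$bounds$reaction_id)]
                  < 0))
})

test_that("relax_reversibility mirrors the upper bound into the lower", {
  m <- tiny_chain_model()
  m <- constrain_reaction(m, "r_0002", c(0, 10))
  m2 <- relax_reversibility(m, "r_0002")
  expect_equal(unname(m2$reactions$lower_bound[2]), -10)
  # already-reversible reaction unchanged
  m3 <- constrain_reaction(m, "r_0003", c(-5, 5))
  m4 <- relax_reversibility(m3, "r_0003")
  expect_equal(unname(m4$reactions$lower_bound[3]), -5)
  expect_error(relax_reversibility(m, "nope"), "unknown reaction")
})

test_that("constrain_reaction validates input and replaces bounds", {
  m <- tiny_chain_model()
  m2 <- constrain_reaction(m, "r_0002", c(0, 0))
  expect_equal(unname(m2$reactions$upper_bound[2]), 0)
  expect_identical(constrain_reaction(m, "r_0002",
                                      c(m$reactions$lower_bound[2],
                                        m$reactions$upper_bound[2])), m)
  expect_error(constrain_reaction(m, "r_0002", c(2, 1)), "exceeds")
  expect_error(constrain_reaction(m, "r_9999", c(0, 1)), "unknown reaction")
})
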