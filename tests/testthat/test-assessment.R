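test_that("build_contingency matches direct counting and guards its inputs", {
  # perfect predictor on 10 genes, 3 essential
  uni <- paste0("g", 1:10)
  ess <- uni[1:3]
  t1 <- build_contingency(setdiff(uni, ess), ess, uni)
  expect_equal(unlist(t1[c("TP", "FP", "TN", "FN")]),
               c(TP = 7L, FP = 0L, TN = 3L, FN = 0L))
  # always-viable predictor
  t2 <- build_contingency(uni, ess, uni)
  expect_equal(t2$FP, length(ess))
  expect_equal(t2$FN, 0L)
  # random sets against an element-wise classification loop
  set.seed(31)
  for (i in 1:40) {
    uni <- paste0("g", seq_len(sample(3:60, 1)))
    ess <- sample(uni, sample(0:length(uni), 1))
    pred <- sample(uni, sample(0:length(uni), 1))
    t <- build_contingency(pred, ess, uni)
    ref <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (g in uni) {
      p <- g %in% pred; e <- g %in% ess
      ref[if (p && !e) "TP" else if (p && e) "FP"
          else if (!p && e) "TN" else "FN"] <-
        ref[if (p && !e) "TP" else if (p && e) "FP"
            else if (!p && e) "TN" else "FN"] + 1L
    }
    expect_equal(unlist(t[c("TP", "FP", "TN", "FN")]), ref)
    expect_equal(attr(t, "total"), length(uni))
  }
  expect_error(build_contingency(c("zz"), character(0), uni),
               "outside the universe")
  expect_error(build_contingency(character(0), character(0), character(0)),
               "empty universe")
})

test_that("ratio metrics match the binary-vector second path on random tables", {
  expect_equal(sensitivity(contingency_table(3, 0, 0, 1)), 0.75)
  expect_true(is.na(specificity(contingency_table(5, 0, 0, 5))))
  set.seed(32)
  for (i in 1:200) {
    t <- random_table()
    ref <- vec_metrics(t)
    expect_equal(sensitivity(t), ref$sensitivity)
    expect_equal(specificity(t), ref$specificity)
    expect_equal(ppv(t), ref$ppv)
    expect_equal(npv(t), ref$npv)
  }
})

test_that("MCC equals the Pearson correlation of the expanded vectors", {
  expect_equal(mcc(contingency_table(7, 0, 3, 0)), 1)
  expect_equal(mcc(contingency_table(0, 3, 0, 7)), -1)
  set.seed(33)
  checked <- 0
  while (checked < 100) {
    t <- random_table()
    f <- c(t$TP + t$FP, t$TP + t$FN, t$TN + t$FP, t$TN + t$FN)
    if (any(f == 0)) {
      expect_identical(mcc(t), 0)     # documented zero-factor convention
    } else {
      v <- expand_table(t)
      expect_equal(mcc(t), stats::cor(v$pred, v$obs), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
})

test_that("geometric-mean accuracy follows its formula and flags undefined", {
  expect_equal(geometric_mean_accuracy(contingency_table(5, 0, 5, 0)), 1)
  expect_equal(geometric_mean_accuracy(contingency_table(9, 6, 4, 1)),
               sqrt(0.9 * 0.4))
  expect_true(is.na(geometric_mean_accuracy(contingency_table(5, 0, 0, 5))))
  set.seed(34)
  for (i in 1:50) {
    t <- random_table()
    se <- sensitivity(t); sp <- specificity(t)
    expect_equal(geometric_mean_accuracy(t),
                 if (is.na(se) || is.na(sp)) NA_real_ else sqrt(se * sp))
  }
})

test_that("metric identities: scaling invariance and MCC swap symmetry", {
  set.seed(35)
  for (i in 1:30) {
    t <- random_table()
    k <- sample(2:5, 1)
    tk <- contingency_table(k * t$TP, k * t$FP, k * t$TN, k * t$FN)
    for (f in list(sensitivity, specificity, ppv, npv, mcc,
                   geometric_mean_accuracy))
      expect_equal(f(tk), f(t))
    swapped <- contingency_table(t$TN, t$FN, t$TP, t$FP)
    expect_equal(mcc(swapped), mcc(t))
  }
})

test_that("essentiality benchmark reproduces generator ground truth", {
  for (corner in fixture_corners()) {
    m <- corner$model
    bench <- essentiality_benchmark(m, corner$truth$minimal_medium,
                                    essential_genes = corner$truth$essential_genes)
    t <- bench$table
    n_ess <- length(corner$truth$essential_genes)
    expect_equal(t$TN, n_ess)
    expect_equal(t$FP, 0L)
    expect_equal(t$FN, 0L)
    expect_equal(t$TP, n_genes(m) - n_ess)
    # MCC of an error-free table is 1 when both classes occur; with a
    # one-class truth a marginal is zero and the documented convention is 0
    expect_equal(bench$metrics$mcc, if (t$TP > 0 && t$TN > 0) 1 else 0)
    # classifications equal the independent brute-force loop, bit for bit
    lethal <- bench$per_gene$gene[bench$per_gene$predicted == "lethal"]
    expect_setequal(lethal,
                    brute_force_essential(apply_medium(m,
                      corner$truth$minimal_medium)))
  }
})

test_that("essentiality benchmark handles degenerate inputs", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       n_isozyme_pairs = 1))
  m <- toy$model
  med <- toy$truth$minimal_medium
  # essential list disjoint from model genes: no negatives at all
  bench <- essentiality_benchmark(m, med, essential_genes = c("YXX1W"))
  expect_equal(bench$table$TN, 0L)
  expect_equal(bench$table$FP, 0L)
  expect_true("YXX1W" %in% bench$excluded_from_model)
  # threshold above wild-type growth: everything predicted lethal
  wt <- fba(apply_medium(m, med))$objective_value
  bench2 <- essentiality_benchmark(m, med,
                                   essential_genes = toy$truth$essential_genes,
                                   threshold = wt * 2)
  expect_equal(bench2$table$TP, 0L)
  expect_equal(bench2$table$FN + bench2$table$TN, n_genes(m))
  # restricting the universe restricts the table total
  uni <- gene_ids(m)[1:2]
  bench3 <- essentiality_benchmark(m, med,
                                   essential_genes = toy$truth$essential_genes,
                                   verified_orfs = uni)
  expect_equal(attr(bench3$table, "total"), 2L)
  expect_error(essentiality_benchmark(m, med, "x", verified_orfs = "absent"),
               "empty universe")
})

test_that("auxotrophy benchmark classifies rescue, false growth and misses", {
  toy <- make_toy_model(toy_model_spec(chain_length = 2,
                                       n_isozyme_pairs = 1,
                                       include_auxotroph_branch = TRUE))
  m <- toy$model
  minimal <- toy$truth$minimal_medium
  aux <- toy$truth$auxotroph_genes
  rep <- auxotrophy_benchmark(m, aux, minimal,
                              supplemented = toy$truth$supplements)
  expect_equal(rep$n_genes, 1L)
  expect_equal(rep$n_correct, 1L)
  expect_equal(rep$per_gene$class, "correct")

  # a gene with no growth impact is incorrectly viable in minimal medium
  iso <- toy$truth$inessential_genes[1]
  rep2 <- auxotrophy_benchmark(m, iso, minimal)
  expect_equal(rep2$n_incorrect_viable_minimal, 1L)

  # a chain gene is inviable even when supplemented
  chain_gene <- setdiff(toy$truth$essential_genes, aux)[1]
  rep3 <- auxotrophy_benchmark(m, chain_gene, minimal,
                               supplemented = gemqc:::default_supplement(m, minimal))
  expect_equal(rep3$n_incorrect_inviable_supplemented, 1L)

  # empty gene list: all counts zero
  rep4 <- auxotrophy_benchmark(m, character(0), minimal)
  expect_equal(rep4$n_genes + rep4$n_correct, 0L)

  # missing per-gene supplement is an error naming the gene
  expect_error(auxotrophy_benchmark(m, c(aux, iso), minimal,
                                    supplemented = toy$truth$supplements),
               paste0("no supplemented medium.*", iso))
  # non-growing wild type aborts
  closed <- constrain_reaction(m, toy$truth$glucose_exchange, c(0, 0))
  closed_med <- medium(data.frame(reaction_id = toy$truth$glucose_exchange,
                                  lower_bound = 0, upper_bound = 0), "closed")
  expect_error(auxotrophy_benchmark(m, aux, closed_med), "does not grow")
})
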