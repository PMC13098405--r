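test_that("the label scheme maps every pathotype onto a physiotype", {
  sc <- label_scheme()
  expect_setequal(names(sc$map), GROUPS7)
  expect_setequal(unique(unname(sc$map)), c("AD", "FTLD", "HC"))
  sc2 <- label_scheme(include_hc = FALSE)
  expect_false("HC" %in% sc2$pathotypes)
})

test_that("flat classifier predicts within the scheme with normalized rows", {
  tab <- make_toy_table(n_per_group = 6, shift = 3, seed = 41)
  folds <- make_folds(tab[, c("participant_id", "physiotype")], k = 3,
                      repeats = 1, label_col = "physiotype", seed = 1)
  m <- fit_flat(tab, folds, "physiotype",
                model_registry("logistic_regression"), budget = 1, seed = 2)
  pr <- predict(m, tab)
  expect_true(all(pr$class %in% c("AD", "FTLD", "HC")))
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-9))
  ## noiseless-limit sanity: near-perfect on its own training data
  expect_gt(mean(pr$class == tab$physiotype), 0.95)
})

test_that("propagation error follows the worked arithmetic", {
  sc <- label_scheme()
  truth <- rep("aAD", 51)
  gate <- c(rep("FTLD", 2), rep("AD", 49))
  pe <- propagation_error(truth, truth, sc, "hierarchical", gate_pred = gate)
  expect_equal(pe$rate, 2 / 51, tolerance = 1e-12)
  ## all-correct gate
  pe0 <- propagation_error(truth, truth, sc, "hierarchical",
                           gate_pred = rep("AD", 51))
  expect_equal(pe0$rate, 0)
  ## flat mode: lvPPA-AD vs lvPPA-FTLD confusion is a cross-branch error
  truth_f <- rep("lvPPA-AD", 20)
  pred_f <- c("lvPPA-FTLD", rep("lvPPA-AD", 19))
  expect_equal(propagation_error(truth_f, pred_f, sc, "flat")$rate, 0.05)
  expect_error(propagation_error(truth_f, pred_f[1:3], sc, "flat"), "length")
})

test_that("hierarchical routing confines errors to the gated branch", {
  tab <- make_toy_table(n_per_group = 7, shift = 3, seed = 42)
  folds <- make_folds(tab[, c("participant_id", "physiotype")], k = 3,
                      repeats = 1, label_col = "physiotype", seed = 1)
  hier <- fit_hierarchical(tab, folds, label_scheme(),
                           model_registry("logistic_regression"),
                           budget = 1, seed = 3)
  pr <- predict(hier, tab)
  sc <- label_scheme()
  ## the final label always lies inside the branch the gate chose
  expect_true(all(sc$map[pr$class] == pr$gate_class))
  ## pathotype accuracy can never beat gate accuracy
  expect_lte(mean(pr$class == tab$group), mean(pr$gate_class == tab$physiotype))
  ## single-pathotype branch (HC) acts as a constant predictor
  expect_equal(unname(hier$constant_branches[["HC"]]), "HC")
})

test_that("meta-feature layout is tasks x classes wide and OOF-clean", {
  spec <- cohort_spec(n_per_group = 6, seed = 43)
  co <- generate_cohort(spec)
  co <- co[co$physiotype != "HC", ]
  shifts <- list()
  for (g in GROUPS7) {
    ph <- physiotype_of(g)
    shifts[[g]] <- if (ph == "AD") c(s1 = 1.5, s2 = 1.5)
                   else if (ph == "FTLD") c(s1 = -1.5, s2 = -1.5)
                   else setNames(numeric(0), character(0))
  }
  tabs <- generate_feature_table(co, group_signature(shifts),
                                 n_features = 10, seed = 2,
                                 tasks = c("NEG", "POS", "SST", "MPT"))
  tabs <- lapply(tabs, function(t)
    cbind(t, physiotype = co$physiotype[match(t$participant_id,
                                              co$participant_id)]))
  folds <- make_folds(co, k = 3, repeats = 1, label_col = "physiotype",
                      seed = 1)
  reg <- model_registry("logistic_regression")
  winners <- lapply(tabs, function(t)
    fit_flat(t, folds, "physiotype", reg, budget = 1, seed = 4))
  mf <- build_meta_features(tabs, winners, "physiotype", k = 3, seed = 5)
  ## 4 tasks x 2 classes -> 8 meta-features
  expect_equal(ncol(mf$meta) - 2, 8)
  ## leakage audit: no predicted participant sat in its fold's training side
  expect_false(any(mf$audit$in_fold_training))
})

test_that("stacking consumes base probabilities and predicts the scheme", {
  tab <- make_toy_table(n_per_group = 8, shift = 3, seed = 44)
  tabs <- list(NEG = tab, POS = make_toy_table(n_per_group = 8, shift = 3,
                                               seed = 45))
  tabs$POS <- tabs$POS  # same cohort spec/seed ordering: align participants
  tabs$POS$participant_id <- tabs$NEG$participant_id
  tabs$POS$physiotype <- tabs$NEG$physiotype
  folds <- make_folds(tabs$NEG[, c("participant_id", "physiotype")], k = 3,
                      repeats = 1, label_col = "physiotype", seed = 1)
  reg <- model_registry("logistic_regression")
  winners <- lapply(tabs, function(t)
    fit_flat(t, folds, "physiotype", reg, budget = 1, seed = 2))
  stack <- fit_stacking(tabs, winners, "physiotype",
                        meta_candidates = model_registry("logistic_regression"),
                        k = 3, budget = 1, seed = 3)
  pr <- predict(stack, tabs)
  expect_true(all(pr$class %in% c("AD", "FTLD", "HC")))
  expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-9))
  expect_gt(mean(pr$class == tabs$NEG$physiotype), 0.9)
})
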