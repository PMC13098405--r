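test_that("degenerate difference vectors resolve to point-mass decisions", {
  post0 <- correlated_bayesian_ttest(rep(0.8, 25), rep(0.8, 25))
  expect_equal(post0$p_rope, 1)
  expect_equal(post0$decision, "equivalent")
  post_sup <- correlated_bayesian_ttest(rep(0.9, 25), rep(0.4, 25))
  expect_equal(post_sup$p_right, 1)
  expect_equal(post_sup$decision, "superior")
  post_inf <- correlated_bayesian_ttest(rep(0.4, 25), rep(0.9, 25))
  expect_equal(post_inf$decision, "inferior")
  expect_error(correlated_bayesian_ttest(1:3, 1:4), "length")
})

test_that("posterior masses agree with a direct Student-t CDF evaluation", {
  set.seed(21)
  d <- rnorm(25, 0.03, 0.01)
  a <- runif(25, 0.7, 0.9); b <- a - d
  post <- correlated_bayesian_ttest(a, b, k = 5, rope = 0.01)
  m <- 25; rho <- 1 / 4
  scale <- sqrt((1 / m + rho) * var(d))
  ## independent evaluation by numerical integration of the t density
  dens <- function(x) dt((x - mean(d)) / scale, m - 1) / scale
  p_right_num <- integrate(dens, 0.01, Inf, rel.tol = 1e-10)$value
  p_left_num <- integrate(dens, -Inf, -0.01, rel.tol = 1e-10)$value
  expect_equal(post$p_right, p_right_num, tolerance = 1e-6)
  expect_equal(post$p_left, p_left_num, tolerance = 1e-6)
  expect_equal(post$p_left + post$p_rope + post$p_right, 1, tolerance = 1e-9)
})

test_that("posterior mass conserves and swaps antisymmetrically", {
  set.seed(22)
  for (i in 1:300) {
    a <- runif(25); b <- runif(25)
    p_ab <- correlated_bayesian_ttest(a, b)
    p_ba <- correlated_bayesian_ttest(b, a)
    expect_equal(p_ab$p_left + p_ab$p_rope + p_ab$p_right, 1, tolerance = 1e-9)
    expect_equal(p_ab$p_left, p_ba$p_right, tolerance = 1e-12)
    expect_equal(p_ab$p_right, p_ba$p_left, tolerance = 1e-12)
  }
})

test_that("widening the ROPE never decreases its posterior mass", {
  set.seed(23)
  for (i in 1:50) {
    a <- runif(25); b <- runif(25)
    ropes <- c(0.005, 0.01, 0.05, 0.1)
    masses <- vapply(ropes, function(r)
      correlated_bayesian_ttest(a, b, rope = r)$p_rope, 0)
    expect_true(all(diff(masses) >= -1e-12))
  }
})

make_results <- function(auc_list, kappa_list = NULL, logloss_list = NULL) {
  ids <- names(auc_list)
  fm <- do.call(rbind, lapply(ids, function(id) {
    m <- length(auc_list[[id]])
    data.frame(candidate = id,
               repeat_idx = rep(1:5, each = m / 5),
               fold_idx = rep(1:(m / 5), 5),
               auc = auc_list[[id]],
               kappa = if (is.null(kappa_list)) auc_list[[id]] else kappa_list[[id]],
               logloss = if (is.null(logloss_list)) 1 - auc_list[[id]] else logloss_list[[id]])
  }))
  structure(list(fold_metrics = fm, folds = list(k = 5)),
            class = "candidate_results")
}

test_that("a dominating candidate wins by the superiority rule", {
  sel <- select_best(make_results(list(
    good = rep(0.95, 25) + seq(-0.01, 0.01, length.out = 25),
    bad = rep(0.65, 25) + seq(-0.01, 0.01, length.out = 25))))
  expect_equal(sel$winner, "good")
  expect_equal(sel$rule, "superior")
})

test_that("practically equivalent candidates tie-break on kappa then log loss", {
  auc <- rep(0.9, 25)
  sel <- select_best(make_results(
    list(a = auc, b = auc),
    kappa_list = list(a = rep(0.8, 25), b = rep(0.8, 25)),
    logloss_list = list(a = rep(0.30, 25), b = rep(0.25, 25))))
  expect_equal(sel$winner, "b")
  expect_equal(sel$rule, "equivalent")
  ## kappa dominates the tie-break before log loss
  sel2 <- select_best(make_results(
    list(a = auc, b = auc),
    kappa_list = list(a = rep(0.9, 25), b = rep(0.7, 25)),
    logloss_list = list(a = rep(0.5, 25), b = rep(0.1, 25))))
  expect_equal(sel2$winner, "a")
})

test_that("selection replays the stated rules and ignores candidate order", {
  set.seed(24)
  aucs <- list(a = 0.8 + rnorm(25, 0, 0.05),
               b = 0.82 + rnorm(25, 0, 0.05),
               c = 0.78 + rnorm(25, 0, 0.05))
  res <- make_results(aucs)
  sel <- select_best(res)
  ## independent replay of the rules
  ids <- names(aucs)
  post <- function(x, y) correlated_bayesian_ttest(aucs[[x]], aucs[[y]])
  superior <- Filter(function(x) all(vapply(setdiff(ids, x), function(y)
    post(x, y)$p_right > 0.95, TRUE)), ids)
  expected <- if (length(superior)) superior[[1]] else {
    top <- ids[which.max(vapply(aucs, mean, 0))]
    eq <- c(top, Filter(function(y) post(top, y)$p_rope > 0.95,
                        setdiff(ids, top)))
    if (length(eq) >= 2) {
      ## same kappa proxies -> falls back alphabetically among equals
      top
    } else top
  }
  expect_equal(sel$winner, expected)
  ## permuting candidate order leaves the winner unchanged
  res_perm <- make_results(aucs[c("c", "a", "b")])
  expect_equal(select_best(res_perm)$winner, sel$winner)
})

test_that("the zoo separates a separable task and stays at chance on noise", {
  tab <- make_toy_table(n_per_group = 6, shift = 3, seed = 31)
  folds <- make_folds(tab[, c("participant_id", "physiotype")], k = 3,
                      repeats = 1, label_col = "physiotype", seed = 1)
  reg <- model_registry(c("logistic_regression", "k_nearest_neighbors"))
  res <- train_candidates(tab, folds, "physiotype", reg, budget = 1, seed = 2)
  mean_auc <- tapply(res$fold_metrics$auc, res$fold_metrics$candidate, mean,
                     na.rm = TRUE)
  expect_true(all(mean_auc > 0.9))
  ## label permutation: chance-level validation AUC
  tab_null <- tab
  set.seed(3)
  tab_null$physiotype <- sample(tab_null$physiotype)
  folds_null <- make_folds(tab_null[, c("participant_id", "physiotype")],
                           k = 3, repeats = 2, label_col = "physiotype",
                           seed = 4)
  res_null <- train_candidates(tab_null, folds_null, "physiotype",
                               model_registry("logistic_regression"),
                               budget = 1, seed = 5)
  expect_lt(abs(mean(res_null$fold_metrics$auc, na.rm = TRUE) - 0.5), 0.15)
})

test_that("training is deterministic under a fixed seed and budget", {
  tab <- make_toy_table(n_per_group = 5, shift = 2, seed = 32)
  folds <- make_folds(tab[, c("participant_id", "physiotype")], k = 3,
                      repeats = 1, label_col = "physiotype", seed = 1)
  reg <- model_registry(c("logistic_regression", "random_forest"))
  r1 <- train_candidates(tab, folds, "physiotype", reg, budget = 2, seed = 9)
  r2 <- train_candidates(tab, folds, "physiotype", reg, budget = 2, seed = 9)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
})
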