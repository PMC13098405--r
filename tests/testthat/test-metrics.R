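test_that("perfectly separated classes score perfect metrics", {
  truth <- c("A", "A", "B", "B", "C", "C")
  prob <- rbind(c(.9, .05, .05), c(.8, .1, .1), c(.1, .8, .1),
                c(.05, .9, .05), c(.1, .1, .8), c(.05, .05, .9))
  colnames(prob) <- c("A", "B", "C")
  pred <- colnames(prob)[max.col(prob)]
  rep <- compute_metrics(truth, pred, prob)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc_macro_ovr, 1)
  expect_equal(rep$fpr_macro_ovr, 0)
  expect_equal(rep$fnr_macro_ovr, 0)
  expect_equal(rep$kappa, 1)
  expect_equal(rep$mcc, 1)
})

test_that("anti-ranked two-sample case gives zero AUC and accuracy", {
  truth <- c("A", "B")
  prob <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  colnames(prob) <- c("A", "B")
  pred <- colnames(prob)[max.col(prob)]
  rep <- compute_metrics(truth, pred, prob)
  expect_equal(rep$accuracy, 0)
  expect_equal(rep$auc_macro_ovr, 0)
})

test_that("uniform confusion yields zero kappa and MCC", {
  truth <- c("A", "A", "B", "B")
  pred <- c("A", "B", "A", "B")
  rep <- compute_metrics(truth, pred)
  expect_equal(rep$kappa, 0)
  expect_equal(rep$mcc, 0)
})

test_that("a fixed confusion matrix matches hand-computed values", {
  ## truth A x4, B x3; predictions giving confusion [[3,1],[1,2]]
  truth <- c("A", "A", "A", "A", "B", "B", "B")
  pred <- c("A", "A", "A", "B", "A", "B", "B")
  rep <- compute_metrics(truth, pred)
  expect_equal(rep$accuracy, 5 / 7, tolerance = 1e-12)
  ## per-class precision: A 3/4, B 2/3 ; recall: A 3/4, B 2/3
  expect_equal(rep$precision_macro, (3 / 4 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(rep$recall_macro, (3 / 4 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(rep$f1_macro, (3 / 4 + 2 / 3) / 2, tolerance = 1e-12)
  po <- 5 / 7; pe <- (4 / 7) * (4 / 7) + (3 / 7) * (3 / 7)
  expect_equal(rep$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_equal(rep$mcc, bf_mcc(truth, pred), tolerance = 1e-12)
  expect_equal(rep$fpr_macro_ovr, (1 / 3 + 1 / 4) / 2, tolerance = 1e-12)
  expect_equal(rep$fnr_macro_ovr, (1 / 4 + 1 / 3) / 2, tolerance = 1e-12)
})

test_that("macro AUC equals brute-force pair counting on a random toy", {
  set.seed(10)
  truth <- sample(c("A", "B", "C"), 200, replace = TRUE)
  prob <- matrix(runif(600), 200, 3, dimnames = list(NULL, c("A", "B", "C")))
  prob <- prob / rowSums(prob)
  expect_equal(macro_ovr_auc(truth, prob), bf_macro_auc(truth, prob),
               tolerance = 1e-12)
})

test_that("macro AUC is invariant under strictly monotone score transforms", {
  set.seed(11)
  truth <- sample(c("A", "B"), 80, replace = TRUE)
  score <- runif(80)
  prob <- cbind(A = score, B = 1 - score)
  a1 <- macro_ovr_auc(truth, prob)
  prob2 <- cbind(A = exp(3 * score), B = max(exp(3 * score)) + 1 - exp(3 * score))
  a2 <- macro_ovr_auc(truth, prob2)
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("permuted labels zero out kappa and MCC", {
  set.seed(12)
  truth <- sample(c("A", "B", "C"), 500, replace = TRUE)
  pred <- sample(truth)
  rep <- compute_metrics(truth, pred)
  expect_lt(abs(rep$kappa), 0.1)
  expect_lt(abs(rep$mcc), 0.1)
})

test_that("classes absent from truth are excluded from macro AUC with warning", {
  truth <- c("A", "A", "B")
  prob <- matrix(c(.6, .7, .2, .3, .2, .7, .1, .1, .1), 3, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  expect_warning(macro_ovr_auc(truth, prob), "absent")
})

test_that("log loss uses clipped probabilities", {
  truth <- c("A", "B")
  prob <- rbind(c(1, 0), c(0, 1))
  colnames(prob) <- c("A", "B")
  rep <- compute_metrics(truth, c("A", "B"), prob)
  expect_true(is.finite(rep$log_loss))
  expect_lt(rep$log_loss, 1e-10)
})

test_that("bootstrap CI is degenerate for all-correct predictions", {
  truth <- rep(c("A", "B"), 10)
  ci <- bootstrap_ci(truth, truth, metric = "accuracy", n_boot = 200, seed = 1)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
  expect_error(bootstrap_ci(truth, truth, n_boot = 10), ">= 100")
})

test_that("bootstrap resamples at the participant level", {
  ## two rows per participant; participant-level resampling keeps pairs intact
  truth <- rep(c("A", "B"), each = 20)
  pred <- truth; pred[c(1, 21)] <- c("B", "A")
  pid <- rep(sprintf("P%02d", 1:20), 2)
  ci <- bootstrap_ci(truth, pred, metric = "accuracy",
                     participant_ids = pid, n_boot = 200, seed = 2)
  expect_true(ci$lower <= 0.95 && ci$upper >= 0.9)
})

test_that("reclassification rate is matches over discordant count", {
  recs <- data.frame(participant_id = sprintf("P%d", 1:8),
                     discordant = c(rep(TRUE, 5), rep(FALSE, 3)),
                     predicted = c("AD", "AD", "FTLD", "AD", "AD", "AD", "AD", "AD"),
                     confirmed = c("AD", "AD", "FTLD", "AD", "FTLD", "AD", "FTLD", "AD"))
  rr <- reclassification_rate(recs)
  expect_equal(rr$rate, 0.8)
  expect_equal(rr$n_discordant, 5)
  ## all matching
  recs$predicted <- recs$confirmed
  expect_equal(reclassification_rate(recs)$rate, 1)
  ## zero discordant -> explicit NA, not 0
  recs$discordant <- FALSE
  expect_true(is.na(reclassification_rate(recs)$rate))
})
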