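test_that("Mann-Whitney U, Z and r match hand evaluation", {
  mw <- mann_whitney_r(c(1, 2), c(3, 4))
  expect_equal(mw$u, 0)
  expect_equal(mw$z, (0 - 2) / sqrt(4 * 5 / 12), tolerance = 1e-9)  # -1.549
  expect_equal(mw$r, abs(mw$z) / sqrt(4), tolerance = 1e-9)          # 0.775
  ## identical samples: constant across groups
  mw0 <- mann_whitney_r(c(2, 2, 2), c(2, 2))
  expect_equal(mw0$r, 0)
  expect_equal(mw0$p, 1)
  expect_equal(mw0$flag, "constant")
})

test_that("exact small-sample p agrees with the exact wilcox distribution", {
  set.seed(51)
  for (i in 1:50) {
    x <- rnorm(5); y <- rnorm(6)
    mw <- mann_whitney_r(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mw$p, ref, tolerance = 1e-12)
  }
})

test_that("large-sample p uses the continuity-corrected approximation", {
  set.seed(52)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  mw <- mann_whitney_r(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(mw$p, ref, tolerance = 1e-9)
})

test_that("effect size matches the enumeration-based permutation scale", {
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4, 1)
    mw <- mann_whitney_r(x, y)
    bf <- bf_mann_whitney(x, y)
    expect_equal(mw$u, bf$u, tolerance = 1e-12)
    expect_equal(mw$z, bf$z, tolerance = 1e-9)
    ## the tie-free normal sigma equals the exact permutation SD of U
    expect_equal(sqrt(4 * 4 / 12 * 9), bf_perm_sd_u(x, y), tolerance = 1e-9)
  }
})

test_that("BH correction follows the step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  adj <- p.adjust(p, "BH")
  expect_equal(adj, bf_bh(p), tolerance = 1e-12)
  expect_true(all(adj < 0.05))  # all four significant at q = 0.05
  set.seed(54)
  p2 <- runif(40)
  expect_equal(p.adjust(p2, "BH"), bf_bh(p2), tolerance = 1e-12)
  expect_true(all(p.adjust(p2, "BH") >= p2))
})

test_that("contrast matrices aggregate mean r and significance rate", {
  set.seed(55)
  n <- 100
  df <- data.frame(group = rep(c("g1", "g2"), each = n))
  for (j in 1:10) {
    shift <- if (j <= 5) 1 else 0  # half the features shifted
    df[[sprintf("f%02d", j)]] <- rnorm(2 * n) + shift * (df$group == "g2")
  }
  cm <- pairwise_contrasts(list(NEG = df), group_col = "group")
  expect_equal(dim(cm$mean_r), c(1, 1))
  expect_true(cm$sig_rate[1, 1] >= 40 && cm$sig_rate[1, 1] <= 60)
  expect_true(all(cm$results$p_adj >= cm$results$p))
})

test_that("exact Shapley matches the additive-model closed form", {
  set.seed(56)
  w <- c(2, -1, 0.5)
  f <- function(x) as.numeric(x %*% w)
  bg <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- matrix(c(1, 2, -1), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  at <- shap_values(f, bg, x)
  expect_equal(at$method, "exact")
  closed <- w * (x[1, ] - colMeans(bg))
  expect_equal(unname(at$values[1, ]), unname(closed), tolerance = 1e-9)
  ## local accuracy
  expect_equal(sum(at$values[1, ]) + at$baseline, f(x), tolerance = 1e-9)
})

test_that("Shapley axioms: symmetry and dummy features", {
  set.seed(57)
  ## duplicated features used symmetrically; third feature ignored
  f <- function(x) x[, 1] + x[, 2]
  bg <- matrix(rnorm(150 * 3), 150, 3)
  bg[, 2] <- bg[, 1]  # duplicated feature: identical in the background too
  z <- rnorm(1)
  x <- matrix(c(z, z, 5), 1, 3)
  at <- shap_values(f, bg, x)
  expect_equal(at$values[1, 1], at$values[1, 2], tolerance = 1e-9)
  expect_equal(at$values[1, 3], 0, tolerance = 1e-12)
})

test_that("sampled Shapley tracks exact enumeration within 0.01", {
  set.seed(58)
  p <- 6
  w <- rnorm(p)
  f <- function(x) as.numeric(tanh(x %*% w))
  bg <- matrix(rnorm(60 * p), 60, p)
  x <- matrix(rnorm(p), 1, p)
  exact <- shap_values(f, bg, x, exact_max = p)
  sampled <- shap_values(f, bg, x, exact_max = 0, n_samples = 2000, seed = 3)
  expect_equal(sampled$method, "sampling")
  expect_lt(max(abs(exact$values - sampled$values)), 0.01)
})

test_that("confound battery is quiet on null data and flags planted effects", {
  set.seed(59)
  n <- 40
  mk <- function(planted) {
    df <- data.frame(group = rep(c("A", "B"), each = n),
                     physiotype = rep(c("AD", "FTLD"), each = n),
                     age = runif(2 * n, 55, 85),
                     sex = sample(c("F", "M"), 2 * n, replace = TRUE))
    for (j in 1:5) df[[sprintf("f%d", j)]] <- rnorm(2 * n) +
      2 * (df$group == "A") * (j <= 2)
    if (planted) df$f1 <- df$f1 + 0.08 * (df$age - 70)  # rho ~ 0.6
    df
  }
  null_df <- mk(FALSE)
  cc <- confound_checks(null_df, null_df, sprintf("f%d", 1:5),
                        label_col = "physiotype")
  expect_equal(cc$n_significant_age_pairs, 0)
  planted_df <- mk(TRUE)
  cc2 <- confound_checks(planted_df, planted_df, sprintf("f%d", 1:5),
                         label_col = "physiotype")
  expect_gt(cc2$n_significant_age_pairs, 0)
  expect_true(is.finite(cc2$m1_m2$acc_delta))
  ## screening rule
  cc3 <- confound_checks(null_df, null_df, sprintf("f%d", 1:5),
                         label_col = "physiotype",
                         demo_attr = c(age = 0.002, sex = 0.5))
  expect_true(cc3$screening$below_screen[1])
  expect_false(cc3$screening$below_screen[2])
})
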