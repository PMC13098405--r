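#' Mann-Whitney U with effect size r = |Z|/sqrt(N)
#'
#' Two-sided Mann-Whitney test of `x` vs `y`. The standardized statistic Z
#' uses the tie-corrected normal approximation without continuity correction
#' (the effect size r = |Z|/sqrt(N) is defined on this plain Z); the p-value
#' uses exact enumeration when both samples have at most `exact_max`
#' observations and no ties are present, and the continuity-corrected normal
#' approximation otherwise. Samples constant across both groups yield
#' p = 1, r = 0, flagged.
#'
#' @param x,y Numeric samples (>= 2 observations each).
#' @param exact_max Exact-enumeration size limit per sample (default 8).
#' @return List `u`, `z`, `n`, `r`, `p`, `flag`.
#' @export
mann_whitney_r <- function(x, y, exact_max = 8) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stopf("need >= 2 observations per group")
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    return(list(u = n1 * n2 / 2, z = 0, n = n, r = 0, p = 1,
                flag = "constant"))
  }
  r_all <- rank(all_v, ties.method = "average")
  u <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  z <- (u - mu) / sigma
  has_ties <- any(ties > 1)
  p <- if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    ## exact two-sided p from the null distribution of U
    p_low <- pwilcox(u, n1, n2)
    p_high <- 1 - pwilcox(u - 1, n1, n2)
    min(1, 2 * min(p_low, p_high))
  } else {
    zc <- (abs(u - mu) - 0.5) / sigma
    2 * pnorm(-max(zc, 0))
  }
  list(u = u, z = z, n = n, r = abs(z) / sqrt(n), p = min(p, 1), flag = NA_character_)
}

#' Pairwise group contrasts: effect-size and significance-rate matrices
#'
#' For every feature, every pair of diagnostic groups, and every task: a
#' two-sided Mann-Whitney test with effect size r = |Z|/sqrt(N).
#' Benjamini-Hochberg FDR correction is applied across features within each
#' (group pair x task) family. Matrix cells aggregate the mean effect size
#' over all features and the percentage of features significant at
#' `p_adj < alpha`.
#'
#' @param tables Named list (task -> data frame with a group column +
#'   feature columns), e.g. from [generate_feature_table()] joined with the
#'   cohort.
#' @param group_col Column holding the group labels.
#' @param groups Optional subset/ordering of groups to contrast.
#' @param alpha Significance level after FDR (default 0.05).
#' @return Object of class `contrast_matrix`: `results` (long data frame),
#'   `mean_r` and `sig_rate` (pair x task matrices).
#' @export
pairwise_contrasts <- function(tables, group_col = "group", groups = NULL,
                               alpha = 0.05) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  results <- list()
  for (task in names(tables)) {
    df <- tables[[task]]
    assert_cols(df, group_col, sprintf("table '%s'", task))
    groups_t <- groups %||% sort(unique(df[[group_col]]))
    feats <- feature_cols(df)
    for (i in seq_along(groups_t)) for (j in seq_along(groups_t)) {
      if (i >= j) next
      g1 <- groups_t[i]; g2 <- groups_t[j]
      x1 <- df[df[[group_col]] == g1, , drop = FALSE]
      x2 <- df[df[[group_col]] == g2, , drop = FALSE]
      if (nrow(x1) < 2 || nrow(x2) < 2) next
      rows <- lapply(feats, function(f) {
        mw <- mann_whitney_r(x1[[f]], x2[[f]])
        data.frame(task = task, pair = paste(g1, g2, sep = " vs "),
                   feature = f, u = mw$u, z = mw$z, n = mw$n, r = mw$r,
                   p = mw$p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, rows)
      fam$p_adj <- p.adjust(fam$p, method = "BH")
      results[[length(results) + 1]] <- fam
    }
  }
  res <- do.call(rbind, results)
  pairs <- unique(res$pair); tasks <- unique(res$task)
  mean_r <- sig <- matrix(NA_real_, length(pairs), length(tasks),
                          dimnames = list(pairs, tasks))
  for (p_ in pairs) for (t_ in tasks) {
    sub <- res[res$pair == p_ & res$task == t_, ]
    if (nrow(sub)) {
      mean_r[p_, t_] <- mean(sub$r)
      sig[p_, t_] <- 100 * mean(sub$p_adj < alpha)
    }
  }
  structure(list(results = res, mean_r = mean_r, sig_rate = sig,
                 alpha = alpha),
            class = "contrast_matrix")
}

#' Plot the dual heatmap of a contrast matrix
#'
#' Renders the pair-by-task grids of mean effect size and significance rate
#' as two aligned heatmaps (requires ggplot2).
#'
#' @param x A `contrast_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.contrast_matrix <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
  long <- rbind(
    data.frame(pair = rownames(x$mean_r)[row(x$mean_r)],
               task = colnames(x$mean_r)[col(x$mean_r)],
               value = as.vector(x$mean_r), panel = "mean effect size (r)"),
    data.frame(pair = rownames(x$sig_rate)[row(x$sig_rate)],
               task = colnames(x$sig_rate)[col(x$sig_rate)],
               value = as.vector(x$sig_rate), panel = "significance rate (%)")
  )
  ggplot2::ggplot(long, ggplot2::aes(task, pair, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", value)), size = 3) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}

utils::globalVariables(c("task", "pair", "value", "panel"))

## ---- Shapley attributions -------------------------------------------------

shapley_weights <- function(p) {
  s <- 0:(p - 1)
  exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
}

#' Shapley feature attributions for a prediction function
#'
#' Model-agnostic interventional Shapley values: the value of a coalition S
#' is the mean model output over background rows with the coalition's
#' features replaced by the explained row's values. Exact subset enumeration
#' is used when the feature count is at most `exact_max` (local-accuracy
#' residual ~ 0); otherwise a permutation-sampling approximation with
#' `n_samples` permutations.
#'
#' @param predict_fun Function: numeric matrix -> numeric vector (e.g. the
#'   probability of one class).
#' @param background Background data matrix (rows = reference samples).
#' @param x_rows Matrix of rows to explain.
#' @param n_samples Permutations for the sampling approximation.
#' @param exact_max Maximum feature count for exact enumeration (default 10).
#' @param seed Integer seed (sampling mode).
#' @return Object of class `attribution_set`: `values` (rows x features),
#'   `baseline` (mean background prediction), `mean_abs` (per-feature mean
#'   absolute attribution, sorted), `method`.
#' @export
shap_values <- function(predict_fun, background, x_rows, n_samples = 200,
                        exact_max = 10, seed = 1L) {
  background <- as.matrix(background)
  x_rows <- as.matrix(x_rows)
  if (!nrow(background)) stopf("background must be non-empty")
  p <- ncol(x_rows)
  baseline <- mean(predict_fun(background))
  nb <- nrow(background)
  coalition_value <- function(x, members) {
    if (!length(members)) return(baseline)
    xb <- background
    xb[, members] <- matrix(rep(x[members], each = nb), nb)
    mean(predict_fun(xb))
  }
  vals <- matrix(0, nrow(x_rows), p, dimnames = list(NULL, colnames(x_rows)))
  if (p <= exact_max) {
    w <- shapley_weights(p)
    subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
    for (ri in seq_len(nrow(x_rows))) {
      x <- x_rows[ri, ]
      v <- vapply(subsets, function(s) coalition_value(x, s), 0)
      sizes <- lengths(subsets)
      for (j in seq_len(p)) {
        has_j <- vapply(subsets, function(s) j %in% s, TRUE)
        phi <- 0
        for (si in which(!has_j)) {
          with_j <- si - 1 + 2^(j - 1)   # subset mask + feature j
          phi <- phi + w[sizes[si] + 1] * (v[with_j + 1] - v[si])
        }
        vals[ri, j] <- phi
      }
    }
    method <- "exact"
  } else {
    set.seed(seed)
    for (ri in seq_len(nrow(x_rows))) {
      x <- x_rows[ri, ]
      acc <- numeric(p)
      for (s in seq_len(n_samples)) {
        perm <- sample(p)
        prev <- baseline
        members <- integer(0)
        for (j in perm) {
          members <- c(members, j)
          cur <- coalition_value(x, members)
          acc[j] <- acc[j] + (cur - prev)
          prev <- cur
        }
      }
      vals[ri, ] <- acc / n_samples
    }
    method <- "sampling"
  }
  mean_abs <- sort(colMeans(abs(vals)), decreasing = TRUE)
  structure(list(values = vals, baseline = baseline, mean_abs = mean_abs,
                 method = method),
            class = "attribution_set")
}

## ---- demographic confound checks ------------------------------------------

#' Demographic confound checks for a fitted model
#'
#' Runs the battery of demographic sensitivity analyses:
#' (i) within-group Spearman correlations between age and each top
#' discriminative feature, BH-corrected; (ii) an age-augmented logistic
#' regression (M2: top features + age) compared against the features-only
#' model (M1) on held-out accuracy with McNemar's paired test and maximum
#' coefficient change; (iii) within-group sex-by-feature Mann-Whitney tests,
#' BH-corrected; (iv) a chi-square audit of the model's error indicator
#' against age group and sex; (v) a screening flag for demographic features
#' whose mean absolute attribution falls below `shap_screen`.
#'
#' @param train,test Data frames with `age`, `sex`, the label column, and
#'   features (groups from `group_col` define the within-group analyses).
#' @param top_features Character vector of top discriminative features
#'   (e.g. the ten highest mean |attribution| features).
#' @param label_col Binary label column for the M1/M2 comparison (first
#'   level vs rest).
#' @param group_col Grouping column for within-group correlations.
#' @param test_errors Logical vector: was each test row misclassified by the
#'   model under audit? (for check iv; optional).
#' @param demo_attr Named numeric: mean |attribution| of demographic features
#'   if they were offered to a screening model (for check v; optional).
#' @param shap_screen Screening threshold (default 0.01).
#' @param alpha FDR level.
#' @return List with elements `age_correlations`, `m1_m2`, `sex_tests`,
#'   `error_audit`, `screening`.
#' @export
confound_checks <- function(train, test, top_features, label_col = "physiotype",
                            group_col = "group", test_errors = NULL,
                            demo_attr = NULL, shap_screen = 0.01,
                            alpha = 0.05) {
  ## (i) age x top features, within groups
  age_rows <- list()
  for (g in unique(test[[group_col]])) {
    sub <- test[test[[group_col]] == g, , drop = FALSE]
    if (nrow(sub) < 4) next  # too small for a meaningful correlation
    for (f in top_features) {
      ct <- suppressWarnings(cor.test(sub$age, sub[[f]], method = "spearman",
                                      exact = FALSE))
      age_rows[[length(age_rows) + 1]] <- data.frame(
        group = g, feature = f, rho = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  age_df <- if (length(age_rows)) do.call(rbind, age_rows) else
    data.frame(group = character(0), feature = character(0),
               rho = numeric(0), p = numeric(0))
  if (nrow(age_df)) age_df$p_adj <- p.adjust(age_df$p, "BH")
  n_sig_age <- if (nrow(age_df)) sum(age_df$p_adj < alpha) else 0L

  ## (ii) M1 (features only) vs M2 (features + age), binary logistic
  y_tr <- factor(train[[label_col]]); y_te <- factor(test[[label_col]],
                                                     levels = levels(y_tr))
  bin_tr <- as.integer(y_tr == levels(y_tr)[1])
  bin_te <- as.integer(y_te == levels(y_tr)[1])
  f_str <- paste("y ~", paste(sprintf("`%s`", top_features), collapse = " + "))
  d_tr <- train[, top_features, drop = FALSE]; d_tr$y <- bin_tr
  d_te <- test[, top_features, drop = FALSE]
  m1 <- suppressWarnings(glm(stats::as.formula(f_str), binomial(), d_tr))
  d_tr2 <- d_tr; d_tr2$age <- train$age
  d_te2 <- d_te; d_te2$age <- test$age
  m2 <- suppressWarnings(glm(stats::as.formula(paste(f_str, "+ age")),
                             binomial(), d_tr2))
  p1 <- as.integer(predict(m1, d_te, type = "response") > 0.5)
  p2 <- as.integer(predict(m2, d_te2, type = "response") > 0.5)
  correct1 <- p1 == bin_te; correct2 <- p2 == bin_te
  b <- sum(correct1 & !correct2); c_ <- sum(!correct1 & correct2)
  mcnemar_p <- if (b + c_ > 0) {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    1 - pchisq(stat, 1)
  } else 1
  shared <- intersect(names(coef(m1)), names(coef(m2)))
  m1_m2 <- list(
    acc_m1 = mean(correct1), acc_m2 = mean(correct2),
    acc_delta = mean(correct2) - mean(correct1),
    mcnemar_p = mcnemar_p,
    max_coef_change = max(abs(coef(m2)[shared] - coef(m1)[shared]), na.rm = TRUE),
    age_coef = unname(coef(m2)["age"]))

  ## (iii) sex x feature Mann-Whitney within groups
  sex_rows <- list()
  for (g in unique(test[[group_col]])) {
    sub <- test[test[[group_col]] == g, , drop = FALSE]
    if (length(unique(sub$sex)) < 2) next
    for (f in top_features) {
      xs <- sub[[f]][sub$sex == "F"]; ys <- sub[[f]][sub$sex == "M"]
      if (length(xs) < 2 || length(ys) < 2) next
      mw <- mann_whitney_r(xs, ys)
      sex_rows[[length(sex_rows) + 1]] <- data.frame(
        group = g, feature = f, r = mw$r, p = mw$p, stringsAsFactors = FALSE)
    }
  }
  sex_df <- if (length(sex_rows)) do.call(rbind, sex_rows) else
    data.frame(group = character(0), feature = character(0),
               r = numeric(0), p = numeric(0))
  if (nrow(sex_df)) sex_df$p_adj <- p.adjust(sex_df$p, "BH")

  ## (iv) error indicator vs age group and sex
  error_audit <- NULL
  if (!is.null(test_errors)) {
    safe_chisq <- function(tab) {
      if (any(dim(tab) < 2)) return(NA_real_)
      suppressWarnings(chisq.test(tab)$p.value)
    }
    error_audit <- list(
      p_age = safe_chisq(table(test_errors, age_group_of(test$age))),
      p_sex = safe_chisq(table(test_errors, test$sex)))
  }

  ## (v) screening rule for demographic features
  screening <- NULL
  if (!is.null(demo_attr)) {
    screening <- data.frame(feature = names(demo_attr),
                            mean_abs_attr = as.numeric(demo_attr),
                            below_screen = as.numeric(demo_attr) < shap_screen,
                            stringsAsFactors = FALSE)
  }
  list(age_correlations = age_df, n_significant_age_pairs = n_sig_age,
       m1_m2 = m1_m2, sex_tests = sex_df, error_audit = error_audit,
       screening = screening)
}
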