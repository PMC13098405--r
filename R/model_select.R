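## Stratified single inner split of fold-training participants, used by the
## inner randomized search. frac = inner validation fraction.
inner_split <- function(labels, frac = 0.25, seed = 1L) {
  set.seed(seed)
  val <- integer(0)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    n_val <- max(1L, round_half_up(frac * length(idx)))
    n_val <- min(n_val, length(idx) - 1L)
    if (n_val > 0) val <- c(val, sample(idx, n_val))
  }
  val
}

fit_one <- function(cand, x, y, params, seed) {
  suppressWarnings(cand$fit(as.matrix(x), y, params, seed = seed))
}

## Inner randomized search on one fold's training side; returns the best
## hyperparameter setting by inner-validation macro-OvR AUC.
search_params <- function(cand, x, y, budget, seed, strategy = "oversample") {
  if (budget <= 1) return(cand$default_params)
  set.seed(seed)
  settings <- cand$sample_params(budget)
  val_idx <- inner_split(y, 0.25, child_seed(seed, 1))
  x_tr <- x[-val_idx, , drop = FALSE]; y_tr <- droplevels(y[-val_idx])
  x_val <- x[val_idx, , drop = FALSE]; y_val <- y[val_idx]
  if (nlevels(y_tr) < 2) return(cand$default_params)
  ## balance the inner-training side only
  df_tr <- data.frame(.idx = seq_along(y_tr), label = y_tr)
  os <- oversample(tag_training_rows(df_tr), "label", strategy,
                   seed = child_seed(seed, 2))
  x_tr2 <- x_tr[os$rows$.idx, , drop = FALSE]
  y_tr2 <- factor(as.character(os$rows$label), levels = levels(y))
  best <- NULL; best_auc <- -Inf
  for (si in seq_along(settings)) {
    auc <- tryCatch({
      m <- fit_one(cand, x_tr2, y_tr2, settings[[si]], child_seed(seed, 10 + si))
      p <- cand$predict_prob(m, as.matrix(x_val))
      suppressWarnings(macro_ovr_auc(y_val, p))
    }, error = function(e) NA_real_)
    if (!is.na(auc) && auc > best_auc) { best_auc <- auc; best <- settings[[si]] }
  }
  best %||% cand$default_params
}

#' Train the candidate zoo over a repeated-CV fold plan
#'
#' For every candidate and every (repeat, fold) pair: preprocessing (median
#' imputation, z-scoring, collinearity filtering) is fit on the fold-training
#' rows only; an inner randomized search over the candidate's hyperparameter
#' space picks a setting on an inner split of the fold-training side; the
#' candidate is refit on the (oversampled) fold-training rows and its
#' validation macro-OvR AUC, Cohen's kappa and log loss are recorded.
#'
#' @param data Data frame: `participant_id`, the label column, features.
#' @param folds A [make_folds()] assignment.
#' @param label_col Label column name.
#' @param candidates Candidate registry subset (default: all seven).
#' @param budget Hyperparameter settings sampled per candidate per fold
#'   (default 8; 1 = use each candidate's default setting).
#' @param seed Integer seed.
#' @param strategy Class-imbalance strategy for fold-training rows.
#' @param filter Apply the collinearity filter inside each fold (default TRUE).
#' @return Object of class `candidate_results`: `fold_metrics` (long data
#'   frame candidate x fold with auc/kappa/logloss), `params` (chosen
#'   settings), `candidates`, `folds`.
#' @export
train_candidates <- function(data, folds, label_col = "label",
                             candidates = model_registry(), budget = 8,
                             seed = 1L, strategy = "oversample",
                             filter = TRUE) {
  assert_cols(data, c("participant_id", label_col), "data")
  y_all <- factor(data[[label_col]])
  feats <- feature_cols(data)
  metrics <- list(); params_log <- list()
  for (fi in seq_along(folds$folds)) {
    fold <- folds$folds[[fi]]
    tr_rows <- data$participant_id %in% fold$train
    va_rows <- data$participant_id %in% fold$validation
    prep <- fit_preprocess(data[tr_rows, , drop = FALSE], feats, filter = filter)
    x_tr <- as.matrix(apply_preprocess(prep, data[tr_rows, , drop = FALSE])[, prep$features, drop = FALSE])
    x_va <- as.matrix(apply_preprocess(prep, data[va_rows, , drop = FALSE])[, prep$features, drop = FALSE])
    y_tr <- y_all[tr_rows]; y_va <- y_all[va_rows]
    fold_seed <- child_seed(seed, fi)
    ## oversample fold-training rows (validation side untouched)
    df_tr <- data.frame(.idx = seq_along(y_tr), label = y_tr)
    os <- oversample(tag_training_rows(df_tr), "label", strategy,
                     seed = child_seed(fold_seed, 999))
    x_fit <- x_tr[os$rows$.idx, , drop = FALSE]
    y_fit <- factor(as.character(os$rows$label), levels = levels(y_all))
    for (ci in seq_along(candidates)) {
      cand <- candidates[[ci]]
      cand_seed <- child_seed(fold_seed, ci)
      best <- search_params(cand, x_tr, y_tr, budget, cand_seed, strategy)
      res <- tryCatch({
        m <- fit_one(cand, x_fit, y_fit, best, child_seed(cand_seed, 1))
        p <- cand$predict_prob(m, x_va)
        rep <- suppressWarnings(compute_metrics(y_va, colnames(p)[max.col(p, "first")], p))
        c(auc = rep$auc_macro_ovr, kappa = rep$kappa, logloss = rep$log_loss)
      }, error = function(e) c(auc = NA_real_, kappa = NA_real_, logloss = NA_real_))
      metrics[[length(metrics) + 1]] <- data.frame(
        candidate = cand$id, repeat_idx = fold$repeat_idx,
        fold_idx = fold$fold_idx, auc = res["auc"], kappa = res["kappa"],
        logloss = res["logloss"], row.names = NULL, stringsAsFactors = FALSE)
      params_log[[paste(cand$id, fi, sep = ".")]] <- best
    }
  }
  structure(list(fold_metrics = do.call(rbind, metrics), params = params_log,
                 candidates = candidates, folds = folds, budget = budget,
                 label_col = label_col, strategy = strategy, seed = seed),
            class = "candidate_results")
}

#' Bayesian correlated t-test between two cross-validated metric vectors
#'
#' The posterior of the mean paired difference is Student-t with location
#' `mean(d)`, scale `sqrt((1/m + rho) * var(d))` and `m - 1` degrees of
#' freedom, where `m` is the number of folds and `rho = 1/(k - 1)` is the
#' test/train size-ratio correlation correction for k-fold cross-validation.
#' `P_left`, `P_rope`, `P_right` are the posterior masses below, inside and
#' above the region of practical equivalence (ROPE) `[-rope, +rope]`.
#' Zero-variance differences resolve to a point mass at the mean difference.
#'
#' @param auc_a,auc_b Equal-length paired per-fold metrics from the same fold
#'   assignment (candidate A and B).
#' @param k Folds per repeat (rho = 1/(k-1); default 5 -> rho 0.25).
#' @param rope ROPE half-width on the metric scale (default 0.01).
#' @return Object of class `comparison_posterior` with `d_bar`, `scale`,
#'   `df`, `p_left`, `p_rope`, `p_right`, `decision` (superior / inferior /
#'   equivalent / undecided at the 0.95 posterior threshold).
#' @export
correlated_bayesian_ttest <- function(auc_a, auc_b, k = 5, rope = 0.01) {
  if (length(auc_a) != length(auc_b)) stopf("paired metric vectors differ in length")
  if (rope <= 0) stopf("rope half-width must be > 0")
  d <- auc_a - auc_b
  ok <- !is.na(d)
  d <- d[ok]
  m <- length(d)
  if (m < 2) stopf("need >= 2 paired differences")
  d_bar <- mean(d)
  rho <- 1 / (k - 1)
  s2 <- var(d)
  scale <- sqrt((1 / m + rho) * s2)
  df <- m - 1
  if (scale == 0) {
    p_left <- as.numeric(d_bar < -rope)
    p_right <- as.numeric(d_bar > rope)
    p_rope <- 1 - p_left - p_right
  } else {
    p_left <- pt((-rope - d_bar) / scale, df)
    p_right <- 1 - pt((rope - d_bar) / scale, df)
    p_rope <- 1 - p_left - p_right
  }
  decision <- if (p_right > 0.95) "superior"
    else if (p_left > 0.95) "inferior"
    else if (p_rope > 0.95) "equivalent"
    else "undecided"
  structure(list(d_bar = d_bar, scale = scale, df = df, rope = rope,
                 p_left = p_left, p_rope = p_rope, p_right = p_right,
                 decision = decision),
            class = "comparison_posterior")
}

#' @export
print.comparison_posterior <- function(x, ...) {
  cat(sprintf(paste0("Correlated Bayesian t-test: d_bar = %+0.4f, ",
                     "P(left|rope|right) = %.3f|%.3f|%.3f -> %s\n"),
              x$d_bar, x$p_left, x$p_rope, x$p_right, x$decision))
  invisible(x)
}

#' Select the best candidate from cross-validated results
#'
#' Pairwise Bayesian correlated t-tests on the per-fold AUC vectors drive the
#' decision: a candidate whose posterior probability of outperforming every
#' competitor exceeds 0.95 wins outright ("superior"). Otherwise, among the
#' practically-equivalent top set (pairwise `P_rope > 0.95` with the highest-
#' AUC candidate), the secondary metrics break the tie: higher mean
#' validation Cohen's kappa, then lower mean log loss ("equivalent"). If
#' neither rule applies the decision is "undecided" and the highest mean-AUC
#' candidate is returned, flagged in the trace. Selection is invariant to
#' candidate ordering.
#'
#' @param results A `candidate_results` from [train_candidates()].
#' @param rope ROPE half-width (default 0.01).
#' @return List `winner` (candidate id), `rule`, `trace` (pairwise
#'   posteriors + summary table).
#' @export
select_best <- function(results, rope = 0.01) {
  fm <- results$fold_metrics
  ids <- sort(unique(fm$candidate))
  if (length(ids) < 2) {
    return(list(winner = ids, rule = "single_candidate", trace = list()))
  }
  auc_of <- function(id) {
    sub <- fm[fm$candidate == id, ]
    sub <- sub[order(sub$repeat_idx, sub$fold_idx), ]
    sub$auc
  }
  summary_tab <- do.call(rbind, lapply(ids, function(id) {
    sub <- fm[fm$candidate == id, ]
    data.frame(candidate = id, mean_auc = mean(sub$auc, na.rm = TRUE),
               mean_kappa = mean(sub$kappa, na.rm = TRUE),
               mean_logloss = mean(sub$logloss, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  k <- results$folds$k %||% 5
  posteriors <- list()
  for (a in ids) for (b in ids) {
    if (a < b) posteriors[[paste(a, b, sep = " vs ")]] <-
      correlated_bayesian_ttest(auc_of(a), auc_of(b), k = k, rope = rope)
  }
  get_post <- function(a, b) {
    if (a < b) posteriors[[paste(a, b, sep = " vs ")]]
    else {
      p <- posteriors[[paste(b, a, sep = " vs ")]]
      ## antisymmetry: swapping the pair swaps left/right
      structure(list(d_bar = -p$d_bar, scale = p$scale, df = p$df,
                     rope = p$rope, p_left = p$p_right, p_rope = p$p_rope,
                     p_right = p$p_left,
                     decision = switch(p$decision, superior = "inferior",
                                       inferior = "superior", p$decision)),
                class = "comparison_posterior")
    }
  }
  ## rule 1: pairwise-superior to all competitors
  for (a in ids) {
    if (all(vapply(setdiff(ids, a),
                   function(b) get_post(a, b)$p_right > 0.95, TRUE))) {
      return(list(winner = a, rule = "superior",
                  trace = list(posteriors = posteriors, summary = summary_tab)))
    }
  }
  ## rule 2: practically-equivalent top set, tie-broken by kappa then logloss
  top <- summary_tab$candidate[which.max(summary_tab$mean_auc)]
  eq_set <- c(top, setdiff(ids, top)[vapply(setdiff(ids, top), function(b)
    get_post(top, b)$p_rope > 0.95, TRUE)])
  if (length(eq_set) >= 2) {
    sub <- summary_tab[summary_tab$candidate %in% eq_set, ]
    sub <- sub[order(-sub$mean_kappa, sub$mean_logloss, sub$candidate), ]
    return(list(winner = sub$candidate[1], rule = "equivalent",
                trace = list(posteriors = posteriors, summary = summary_tab,
                             equivalent_set = eq_set)))
  }
  list(winner = top, rule = "undecided",
       trace = list(posteriors = posteriors, summary = summary_tab,
                    note = "no candidate met the superiority or equivalence rule"))
}
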