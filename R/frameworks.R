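#' Label scheme: pathotypes, physiotypes, and their mapping
#'
#' @param include_hc Include healthy controls as a third physiotype-level
#'   class (default TRUE); `FALSE` restricts to the AD-vs-FTLD patient
#'   framing.
#' @return Object of class `label_scheme` with `pathotypes`, `physiotypes`,
#'   `map` (pathotype -> physiotype).
#' @export
label_scheme <- function(include_hc = TRUE) {
  pathos <- if (include_hc) GROUP_LABELS else setdiff(GROUP_LABELS, "HC")
  map <- setNames(physiotype_of(pathos), pathos)
  structure(list(pathotypes = pathos, physiotypes = unique(unname(map)),
                 map = map, include_hc = include_hc),
            class = "label_scheme")
}

## Final refit of the selected candidate on the full training data:
## preprocessing refit on all training rows, inner search re-run on the full
## training set, oversampling applied, model fit.
refit_winner <- function(data, label_col, cand, budget, seed,
                         strategy = "oversample", filter = TRUE) {
  feats <- feature_cols(data)
  y <- factor(data[[label_col]])
  prep <- fit_preprocess(data, feats, filter = filter)
  x <- as.matrix(apply_preprocess(prep, data)[, prep$features, drop = FALSE])
  params <- search_params(cand, x, y, budget, child_seed(seed, 77), strategy)
  df <- data.frame(.idx = seq_along(y), label = y)
  os <- oversample(tag_training_rows(df), "label", strategy,
                   seed = child_seed(seed, 78))
  x_fit <- x[os$rows$.idx, , drop = FALSE]
  y_fit <- factor(as.character(os$rows$label), levels = levels(y))
  model <- fit_one(cand, x_fit, y_fit, params, child_seed(seed, 79))
  list(prep = prep, model = model, cand = cand, params = params,
       levels = levels(y))
}

#' Fit a flat (single-step) multi-class classifier
#'
#' Runs the candidate zoo through the fold plan, selects the winner by the
#' Bayesian correlated t-test rules, and refits it on the full training set
#' with preprocessing refit on all training rows. Prediction assigns the
#' label with the highest output probability (argmax); no custom decision
#' threshold is applied.
#'
#' @param data Training data: `participant_id`, label column, features.
#' @param folds Fold plan from [make_folds()].
#' @param label_col Label column (`"physiotype"` or `"group"`).
#' @param candidates Candidate registry subset.
#' @param budget Inner search budget per candidate per fold.
#' @param seed Integer seed.
#' @param strategy Class-imbalance strategy.
#' @param rope ROPE half-width for selection.
#' @return Object of class `speech_clf`.
#' @export
fit_flat <- function(data, folds, label_col = "physiotype",
                     candidates = model_registry(), budget = 8, seed = 1L,
                     strategy = "oversample", rope = 0.01) {
  results <- train_candidates(data, folds, label_col, candidates, budget,
                              seed, strategy)
  sel <- select_best(results, rope = rope)
  cand <- candidates[[sel$winner]]
  final <- refit_winner(data, label_col, cand, budget, child_seed(seed, 5),
                        strategy)
  structure(list(type = "flat", label_col = label_col, winner = sel$winner,
                 rule = sel$rule, final = final, results = results,
                 selection = sel, levels = final$levels),
            class = "speech_clf")
}

#' Predict classes and probabilities from a fitted classifier
#'
#' @param object A `speech_clf` from [fit_flat()].
#' @param newdata Data frame with the training feature columns.
#' @param ... Unused.
#' @return List `class` (argmax labels) and `prob` (probability matrix).
#' @export
predict.speech_clf <- function(object, newdata, ...) {
  f <- object$final
  x <- as.matrix(apply_preprocess(f$prep, newdata)[, f$prep$features, drop = FALSE])
  p <- f$cand$predict_prob(f$model, x)
  list(class = colnames(p)[max.col(p, "first")], prob = p)
}

#' Fit the hierarchical (gate + branch) classifier
#'
#' A physiotype gate is trained on all training rows; within each physiotype
#' branch containing at least two pathotypes, a branch classifier is trained
#' only on the rows whose TRUE physiotype matches the branch. A branch with a
#' single pathotype becomes a constant predictor (logged). Prediction routes
#' each sample through the gate's argmax, then the matching branch.
#'
#' @param data Training data with `participant_id`, `group`, `physiotype`
#'   and features.
#' @param folds Fold plan (shared with the flat framework for comparability).
#' @param scheme A [label_scheme()].
#' @inheritParams fit_flat
#' @return Object of class `speech_hclf` with `gate`, `branches`,
#'   `constant_branches`.
#' @export
fit_hierarchical <- function(data, folds, scheme = label_scheme(),
                             candidates = model_registry(), budget = 8,
                             seed = 1L, strategy = "oversample", rope = 0.01) {
  assert_cols(data, c("participant_id", "group", "physiotype"), "data")
  gate <- fit_flat(data, folds, "physiotype", candidates, budget,
                   child_seed(seed, 1), strategy, rope)
  branches <- list(); constants <- list()
  for (ph in scheme$physiotypes) {
    rows <- data$physiotype == ph
    pathos <- unique(data$group[rows])
    if (length(pathos) < 2) {
      constants[[ph]] <- pathos
      next
    }
    sub <- data[rows, , drop = FALSE]
    k_branch <- min(folds$k, min(table(sub$group)))
    if (k_branch < 2) {
      constants[[ph]] <- names(which.max(table(sub$group)))
      next
    }
    bf <- make_folds(sub, k = k_branch, repeats = folds$repeats,
                     label_col = "group", seed = child_seed(seed, 100 + nchar(ph)))
    branches[[ph]] <- fit_flat(sub, bf, "group", candidates, budget,
                               child_seed(seed, 200 + nchar(ph)), strategy, rope)
  }
  structure(list(type = "hierarchical", gate = gate, branches = branches,
                 constant_branches = constants, scheme = scheme),
            class = "speech_hclf")
}

#' @rdname fit_hierarchical
#' @param object A `speech_hclf`.
#' @param newdata Feature rows to classify.
#' @param ... Unused.
#' @return List `class` (pathotype), `gate_class` (physiotype), `prob`
#'   (pathotype probabilities composed as gate prob x branch prob).
#' @export
predict.speech_hclf <- function(object, newdata, ...) {
  gp <- predict(object$gate, newdata)
  n <- nrow(newdata)
  prob <- matrix(0, n, length(object$scheme$pathotypes),
                 dimnames = list(NULL, object$scheme$pathotypes))
  final <- character(n)
  ## compose full pathotype distribution: P(patho) = P(physio) * P(patho|physio)
  for (ph in object$scheme$physiotypes) {
    pathos_ph <- names(object$scheme$map)[object$scheme$map == ph]
    if (!is.null(object$branches[[ph]])) {
      bp <- predict(object$branches[[ph]], newdata)
      prob[, colnames(bp$prob)] <- prob[, colnames(bp$prob)] +
        gp$prob[, ph] * bp$prob
    } else {
      const <- object$constant_branches[[ph]] %||% pathos_ph[1]
      prob[, const] <- prob[, const] + gp$prob[, ph]
    }
  }
  ## routing: the gate decides the branch, then the branch argmax decides
  for (i in seq_len(n)) {
    ph <- gp$class[i]
    if (!is.null(object$branches[[ph]])) {
      bp <- predict(object$branches[[ph]], newdata[i, , drop = FALSE])
      final[i] <- bp$class
    } else {
      final[i] <- object$constant_branches[[ph]] %||%
        names(object$scheme$map)[object$scheme$map == ph][1]
    }
  }
  list(class = final, gate_class = gp$class, prob = prob,
       gate_prob = gp$prob)
}

#' Propagation error of a classification framework
#'
#' Hierarchical mode: the fraction of evaluated samples whose gate physiotype
#' prediction is wrong (errors that necessarily force the final label into
#' the wrong branch). Flat mode: the fraction whose predicted pathotype maps
#' to the wrong physiotype (cross-branch error).
#'
#' @param truth True pathotype labels.
#' @param final_pred Final predicted pathotype labels.
#' @param scheme A [label_scheme()].
#' @param mode `"hierarchical"` or `"flat"`.
#' @param gate_pred Gate physiotype predictions (hierarchical mode).
#' @return List `rate`, `mode`, `n`.
#' @export
propagation_error <- function(truth, final_pred, scheme,
                              mode = c("hierarchical", "flat"),
                              gate_pred = NULL) {
  mode <- match.arg(mode)
  if (mode == "hierarchical") {
    if (is.null(gate_pred)) stopf("hierarchical mode needs gate_pred")
    if (length(gate_pred) != length(truth)) stopf("length mismatch")
    rate <- mean(gate_pred != scheme$map[truth])
  } else {
    if (length(final_pred) != length(truth)) stopf("length mismatch")
    rate <- mean(scheme$map[final_pred] != scheme$map[truth])
  }
  list(rate = rate, mode = mode, n = length(truth))
}

## ---- stacking -------------------------------------------------------------

#' Out-of-fold meta-feature matrix for stacking
#'
#' For each task, the selected base algorithm is refit inside each of k
#' cross-validation folds over the training participants (preprocessing and
#' oversampling refit per fold) and predicts the held-out fold, so every
#' training participant's meta-row holds only out-of-fold probabilities.
#' The per-task probability blocks are concatenated.
#'
#' @param data_by_task Named list (task -> training data frame with
#'   `participant_id`, label column, features).
#' @param base_winners Named list (task -> `speech_clf` from [fit_flat()]),
#'   providing the algorithm and search budget to refit per fold.
#' @param label_col Label column.
#' @param k Folds for the OOF construction (default 5).
#' @param seed Integer seed.
#' @param strategy Class-imbalance strategy.
#' @return List `meta` (data frame: participant_id, label, meta-features),
#'   `audit` (per (participant, task): the fold that predicted it and a flag
#'   confirming the participant was excluded from that fold's training side).
#' @export
build_meta_features <- function(data_by_task, base_winners, label_col,
                                k = 5, seed = 1L, strategy = "oversample") {
  tasks <- names(data_by_task)
  common <- Reduce(intersect, lapply(data_by_task, `[[`, "participant_id"))
  excluded <- setdiff(unique(unlist(lapply(data_by_task, `[[`, "participant_id"))),
                      common)
  ref <- data_by_task[[1]]
  ref <- ref[match(common, ref$participant_id), , drop = FALSE]
  parts <- data.frame(participant_id = common, label = ref[[label_col]],
                      stringsAsFactors = FALSE)
  names(parts)[2] <- label_col
  folds <- make_folds(parts, k = k, repeats = 1, label_col = label_col,
                      seed = child_seed(seed, 1))
  blocks <- list(); audit <- list()
  for (task in tasks) {
    td <- data_by_task[[task]]
    td <- td[match(common, td$participant_id), , drop = FALSE]
    cand <- base_winners[[task]]$final$cand
    budget <- base_winners[[task]]$results$budget
    y <- factor(td[[label_col]])
    block <- matrix(NA_real_, length(common), nlevels(y),
                    dimnames = list(common, paste(task, levels(y), sep = ".")))
    for (fold in folds$folds) {
      tr <- td$participant_id %in% fold$train
      va <- td$participant_id %in% fold$validation
      sub <- td[tr, , drop = FALSE]
      fit <- refit_winner(sub, label_col, cand, budget,
                          child_seed(seed, 1000 + fold$fold_idx), strategy)
      x_va <- as.matrix(apply_preprocess(fit$prep, td[va, , drop = FALSE])[, fit$prep$features, drop = FALSE])
      p <- fit$cand$predict_prob(fit$model, x_va)
      block[td$participant_id[va], ] <- p
      audit[[length(audit) + 1]] <- data.frame(
        task = task, fold = fold$fold_idx,
        participant_id = td$participant_id[va],
        in_fold_training = td$participant_id[va] %in% fold$train,
        stringsAsFactors = FALSE)
    }
    blocks[[task]] <- block
  }
  meta <- cbind(parts, do.call(cbind, blocks))
  rownames(meta) <- NULL
  list(meta = meta, audit = do.call(rbind, audit), excluded = excluded,
       folds = folds)
}

#' Fit the stacking ensemble over task-specific winners
#'
#' Base learners (the per-task selected models) produce out-of-fold class
#' probabilities on the training set; those are concatenated into the
#' meta-feature matrix, on which four candidate meta-models (SVM, logistic
#' regression, random forest, gradient boosting) are trained and compared
#' with the same fold-plan/Bayesian-selection machinery. Test-time
#' meta-features come from the base winners refit on the full training set
#' (the refits already inside each `speech_clf`).
#'
#' @param data_by_task Named list of per-task training data.
#' @param base_winners Named list of per-task fitted [fit_flat()] models.
#' @param label_col Label column.
#' @param meta_candidates Meta-model registry subset (default: the four).
#' @param k OOF folds (default 5).
#' @param budget Meta-model search budget.
#' @param seed Integer seed.
#' @param strategy Class-imbalance strategy.
#' @return Object of class `speech_stack`.
#' @export
fit_stacking <- function(data_by_task, base_winners, label_col,
                         meta_candidates = model_registry(
                           c("svm", "logistic_regression", "random_forest",
                             "gradient_boosting")),
                         k = 5, budget = 8, seed = 1L,
                         strategy = "oversample") {
  mf <- build_meta_features(data_by_task, base_winners, label_col, k,
                            child_seed(seed, 1), strategy)
  meta_folds <- make_folds(mf$meta, k = k, repeats = 2, label_col = label_col,
                           seed = child_seed(seed, 2))
  meta_fit <- fit_flat(mf$meta, meta_folds, label_col, meta_candidates,
                       budget, child_seed(seed, 3), strategy)
  structure(list(type = "stacking", base = base_winners, meta = meta_fit,
                 label_col = label_col, oof = mf),
            class = "speech_stack")
}

#' @rdname fit_stacking
#' @param object A `speech_stack`.
#' @param newdata_by_task Named list of per-task test data frames.
#' @param ... Unused.
#' @export
predict.speech_stack <- function(object, newdata_by_task, ...) {
  tasks <- names(object$base)
  common <- Reduce(intersect, lapply(newdata_by_task[tasks], `[[`, "participant_id"))
  blocks <- list()
  for (task in tasks) {
    td <- newdata_by_task[[task]]
    td <- td[match(common, td$participant_id), , drop = FALSE]
    p <- predict(object$base[[task]], td)$prob
    colnames(p) <- paste(task, colnames(p), sep = ".")
    blocks[[task]] <- p
  }
  meta_x <- data.frame(participant_id = common, do.call(cbind, blocks),
                       check.names = FALSE, stringsAsFactors = FALSE)
  out <- predict(object$meta, meta_x)
  out$participant_id <- common
  out
}
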