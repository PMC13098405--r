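## ---- candidate registry ---------------------------------------------------
## Each candidate wraps an established backend behind a uniform surface:
##   sample_params(n)  -> list of hyperparameter settings
##   fit(x, y, params, seed) -> fitted object
##   predict_prob(fit, x) -> probability matrix (rows sum to 1, columns =
##   class levels in the order of levels(y)).
## Every candidate must expose class probabilities; anything that cannot is
## rejected at registry load.

runif_log <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

prob_matrix <- function(p, levels) {
  p <- as.matrix(p)
  missing <- setdiff(levels, colnames(p))
  if (length(missing)) {
    p <- cbind(p, matrix(0, nrow(p), length(missing),
                         dimnames = list(NULL, missing)))
  }
  p <- p[, levels, drop = FALSE]
  p / pmax(rowSums(p), 1e-300)
}

candidate_logistic <- function() {
  list(
    id = "logistic_regression",
    sample_params = function(n) {
      lapply(seq_len(n), function(i) list(alpha = runif(1, 0, 1),
                                          lambda = runif_log(1, 1e-4, 1)))
    },
    default_params = list(alpha = 0, lambda = 1e-3),
    fit = function(x, y, params, seed = 1L) {
      set.seed(seed)
      fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
      fit <- glmnet::glmnet(x, y, family = fam, alpha = params$alpha,
                            lambda = params$lambda)
      list(fit = fit, levels = levels(y), family = fam)
    },
    predict_prob = function(model, x) {
      p <- predict(model$fit, x, type = "response")
      if (model$family == "binomial") {
        p <- cbind(1 - p[, 1], p[, 1])
        colnames(p) <- model$levels
      } else {
        p <- p[, , 1]
        if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
      }
      prob_matrix(p, model$levels)
    }
  )
}

candidate_svm <- function() {
  list(
    id = "svm",
    sample_params = function(n) {
      lapply(seq_len(n), function(i) list(cost = runif_log(1, 0.03, 30),
                                          gamma_scale = runif_log(1, 0.1, 10)))
    },
    default_params = list(cost = 1, gamma_scale = 1),
    fit = function(x, y, params, seed = 1L) {
      set.seed(seed)
      gamma <- params$gamma_scale / ncol(x)
      fit <- e1071::svm(x, y, kernel = "radial", cost = params$cost,
                        gamma = gamma, probability = TRUE)
      list(fit = fit, levels = levels(y))
    },
    predict_prob = function(model, x) {
      pred <- predict(model$fit, x, probability = TRUE)
      prob_matrix(attr(pred, "probabilities"), model$levels)
    }
  )
}

candidate_ranger <- function(id, extratrees = FALSE) {
  list(
    id = id,
    sample_params = function(n) {
      lapply(seq_len(n), function(i) list(
        num_trees = sample(100:400, 1),
        mtry_frac = runif(1, 0.2, 0.9),
        min_node = sample(1:5, 1)))
    },
    default_params = list(num_trees = 300, mtry_frac = 0.5, min_node = 1),
    fit = function(x, y, params, seed = 1L) {
      mtry <- max(1L, round(params$mtry_frac * sqrt(ncol(x)) * 2))
      mtry <- min(mtry, ncol(x))
      fit <- ranger::ranger(
        x = as.data.frame(x), y = y, probability = TRUE,
        num.trees = params$num_trees, mtry = mtry,
        min.node.size = params$min_node,
        splitrule = if (extratrees) "extratrees" else "gini",
        replace = !extratrees,
        sample.fraction = if (extratrees) 1 else 0.632,
        num.threads = 1, seed = seed)
      list(fit = fit, levels = levels(y))
    },
    predict_prob = function(model, x) {
      p <- predict(model$fit, data = as.data.frame(x),
                   num.threads = 1)$predictions
      prob_matrix(p, model$levels)
    }
  )
}

candidate_xgboost <- function(id = "xgboost", gbm_style = FALSE) {
  list(
    id = id,
    sample_params = function(n) {
      lapply(seq_len(n), function(i) {
        if (gbm_style) {
          list(nrounds = sample(50:200, 1), eta = runif_log(1, 0.03, 0.3),
               max_depth = sample(2:4, 1), subsample = 1, colsample = 1)
        } else {
          list(nrounds = sample(50:200, 1), eta = runif_log(1, 0.03, 0.4),
               max_depth = sample(2:8, 1), subsample = runif(1, 0.6, 1),
               colsample = runif(1, 0.5, 1))
        }
      })
    },
    default_params = list(nrounds = 100, eta = 0.1,
                          max_depth = if (gbm_style) 3 else 4,
                          subsample = 1, colsample = 1),
    fit = function(x, y, params, seed = 1L) {
      n_class <- nlevels(y)
      label <- as.integer(y) - 1L
      obj <- if (n_class == 2) "binary:logistic" else "multi:softprob"
      xp <- list(objective = obj, eta = params$eta,
                 max_depth = params$max_depth, subsample = params$subsample,
                 colsample_bytree = params$colsample, nthread = 1,
                 seed = seed)
      if (n_class > 2) xp$num_class <- n_class
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = label)
      fit <- xgboost::xgb.train(params = xp, data = dtrain,
                                nrounds = params$nrounds, verbose = 0)
      list(fit = fit, levels = levels(y), n_class = n_class)
    },
    predict_prob = function(model, x) {
      p <- predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x)))
      if (model$n_class == 2) {
        p <- cbind(1 - p, p)
      } else {
        p <- matrix(p, ncol = model$n_class, byrow = TRUE)
      }
      colnames(p) <- model$levels
      prob_matrix(p, model$levels)
    }
  )
}

candidate_knn <- function() {
  list(
    id = "k_nearest_neighbors",
    sample_params = function(n) {
      lapply(seq_len(n), function(i) list(k = sample(seq(3, 15, by = 2), 1)))
    },
    default_params = list(k = 5),
    fit = function(x, y, params, seed = 1L) {
      fit <- e1071::gknn(as.data.frame(x), y, k = params$k)
      list(fit = fit, levels = levels(y))
    },
    predict_prob = function(model, x) {
      votes <- predict(model$fit, as.data.frame(x), type = "votes")
      prob_matrix(votes, model$levels)
    }
  )
}

#' The candidate classifier registry
#'
#' The seven candidate algorithms evaluated per speech task: logistic
#' regression (elastic-net), RBF support vector machine, random forest,
#' extreme gradient boosting, gradient boosting (shallow-tree boosted
#' ensemble), extremely randomized trees, and k-nearest neighbours. Every
#' candidate exposes class-probability outputs; a candidate that cannot is
#' rejected when the registry is assembled.
#'
#' @param ids Candidate ids to include (default: all seven).
#' @return Named list of candidate definitions.
#' @export
model_registry <- function(ids = NULL) {
  all <- list(
    candidate_logistic(),
    candidate_svm(),
    candidate_ranger("random_forest"),
    candidate_xgboost("xgboost"),
    candidate_xgboost("gradient_boosting", gbm_style = TRUE),
    candidate_ranger("extra_trees", extratrees = TRUE),
    candidate_knn()
  )
  names(all) <- vapply(all, `[[`, "", "id")
  for (cand in all) {
    if (!is.function(cand$predict_prob)) {
      stopf("candidate '%s' does not expose probability outputs", cand$id)
    }
  }
  if (is.null(ids)) return(all)
  unknown <- setdiff(ids, names(all))
  if (length(unknown)) stopf("unknown candidate id(s): %s", paste(unknown, collapse = ", "))
  all[ids]
}
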