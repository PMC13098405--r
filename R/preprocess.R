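feature_cols <- function(df, exclude = c("participant_id", "group",
                                         "physiotype", "label", "age", "sex",
                                         "discordant", "task", ".role")) {
  setdiff(names(df), exclude)
}

#' Fit a median imputer on training rows only
#'
#' Missing values (unvoiced/absent features are explicit `NA`s) are replaced
#' by per-feature training medians; imputation parameters are frozen from the
#' training data and never re-estimated at apply time.
#'
#' @param train Data frame of training rows (feature columns numeric).
#' @param features Feature columns; default: all non-metadata columns.
#' @return Object of class `imputer_state`.
#' @export
fit_imputer <- function(train, features = feature_cols(train)) {
  med <- vapply(features, function(f) {
    v <- train[[f]]
    m <- median(v, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, 0)
  structure(list(medians = med, features = features, fitted = TRUE),
            class = "imputer_state")
}

#' @rdname fit_imputer
#' @param state A fitted `imputer_state`.
#' @param rows Data frame to impute.
#' @export
apply_imputer <- function(state, rows) {
  if (!inherits(state, "imputer_state") || !isTRUE(state$fitted)) {
    stopf("apply_imputer: state is not a fitted imputer")
  }
  for (f in state$features) {
    v <- rows[[f]]
    v[is.na(v)] <- state$medians[[f]]
    rows[[f]] <- v
  }
  rows
}

#' Fit a z-score scaler on training rows only
#'
#' Computes per-feature training mean and population SD (divide by n).
#' Constant training features are dropped and recorded. Application uses the
#' frozen parameters: `z = (x - mean_train) / sd_train`.
#'
#' @param train Data frame of training rows.
#' @param features Feature columns to scale.
#' @return Object of class `scaler_state` with fields `mean`, `sd`,
#'   `dropped_constant`, `features`, `fitted`.
#' @export
fit_scaler <- function(train, features = feature_cols(train)) {
  mu <- vapply(features, function(f) mean(train[[f]]), 0)
  sdv <- vapply(features, function(f) pop_sd(train[[f]]), 0)
  constant <- features[is.na(sdv) | sdv <= 0]
  keep <- setdiff(features, constant)
  structure(list(mean = mu[keep], sd = sdv[keep], features = keep,
                 dropped_constant = constant, fitted = TRUE),
            class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state A fitted `scaler_state`.
#' @param rows Data frame to scale (must contain every retained feature).
#' @export
apply_scaler <- function(state, rows) {
  if (!inherits(state, "scaler_state") || !isTRUE(state$fitted)) {
    stopf("apply_scaler: state is not a fitted scaler")
  }
  missing <- setdiff(state$features, names(rows))
  if (length(missing)) {
    stopf("apply_scaler: unknown feature(s) at apply time: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  for (f in state$features) {
    rows[[f]] <- (rows[[f]] - state$mean[[f]]) / state$sd[[f]]
  }
  rows[, setdiff(names(rows), state$dropped_constant), drop = FALSE]
}

## VIF per feature from regressing each feature on all the others.
## Uses QR; when rows <= features the fit is rank-deficient and the
## R^2 -> 1 path yields a large finite VIF (recorded as a warning upstream).
compute_vif <- function(x) {
  p <- ncol(x)
  if (p < 2) return(setNames(rep(1, p), colnames(x)))
  vif <- numeric(p)
  for (j in seq_len(p)) {
    yj <- x[, j]
    xj <- cbind(1, x[, -j, drop = FALSE])
    fit <- tryCatch(qr(xj), error = function(e) NULL)
    res <- if (is.null(fit)) yj - mean(yj) else qr.resid(fit, yj)
    ss_tot <- sum((yj - mean(yj))^2)
    r2 <- if (ss_tot > 0) max(0, 1 - sum(res^2) / ss_tot) else 0
    vif[j] <- 1 / max(1 - r2, 1e-12)
  }
  setNames(vif, colnames(x))
}

#' Iterative multicollinearity filter (VIF + pairwise correlation)
#'
#' While any feature has VIF above `vif_max` or belongs to a pair with
#' absolute Pearson correlation above `r_max`, the single violating feature
#' with the highest mean absolute correlation to all other features is
#' removed, and both statistics are recomputed (strict single-removal
#' iteration). Ties break to the lexicographically first feature name. The
#' filter is fit on training rows only.
#'
#' @param train Data frame of training rows.
#' @param features Feature columns to consider.
#' @param vif_max VIF threshold (default 5).
#' @param r_max Absolute pairwise correlation threshold (default 0.95).
#' @return Object of class `collinearity_report`: `removed` (data frame with
#'   feature, trigger, mean absolute correlation at removal), `kept`,
#'   final `vif` for survivors, `warnings`.
#' @export
collinearity_filter <- function(train, features = feature_cols(train),
                                vif_max = 5, r_max = 0.95) {
  if (nrow(train) < 3) stopf("collinearity_filter needs >= 3 training rows")
  x <- as.matrix(train[, features, drop = FALSE])
  storage.mode(x) <- "double"
  ## constant columns cannot enter a correlation; drop them up front
  sds <- apply(x, 2, pop_sd)
  warn <- character(0)
  if (any(sds <= 0 | is.na(sds))) {
    warn <- c(warn, sprintf("constant feature(s) excluded: %s",
                            paste(colnames(x)[sds <= 0 | is.na(sds)], collapse = ", ")))
    x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  }
  if (nrow(x) <= ncol(x)) {
    warn <- c(warn, "rows <= features: VIF from a rank-deficient fit")
  }
  removed <- list()
  repeat {
    p <- ncol(x)
    if (p < 2) break
    cm <- cor(x)
    vif <- compute_vif(x)
    pair_viol <- colnames(x)[apply(abs(cm) > r_max & !diag(p), 2, any)]
    vif_viol <- names(vif)[vif > vif_max]
    violating <- union(pair_viol, vif_viol)
    if (!length(violating)) break
    mean_abs_r <- (rowSums(abs(cm)) - 1) / (p - 1)
    cand <- mean_abs_r[violating]
    drop_name <- names(cand)[order(-cand, names(cand))][1]
    trigger <- if (drop_name %in% vif_viol && drop_name %in% pair_viol) "vif+r"
               else if (drop_name %in% vif_viol) "vif" else "r"
    removed[[length(removed) + 1]] <- data.frame(
      feature = drop_name, trigger = trigger,
      mean_abs_r = unname(cand[drop_name]), stringsAsFactors = FALSE)
    x <- x[, setdiff(colnames(x), drop_name), drop = FALSE]
  }
  final_vif <- if (ncol(x) >= 2) compute_vif(x) else setNames(rep(1, ncol(x)), colnames(x))
  structure(list(
    removed = if (length(removed)) do.call(rbind, removed)
              else data.frame(feature = character(0), trigger = character(0),
                              mean_abs_r = numeric(0)),
    kept = colnames(x), vif = final_vif,
    vif_max = vif_max, r_max = r_max, warnings = warn
  ), class = "collinearity_report")
}

#' @rdname collinearity_filter
#' @param report A `collinearity_report`.
#' @param rows Data frame to subset to the surviving features.
#' @export
apply_collinearity <- function(report, rows) {
  stopifnot(inherits(report, "collinearity_report"))
  drop <- intersect(report$removed$feature, names(rows))
  rows[, setdiff(names(rows), drop), drop = FALSE]
}

## Convenience: the full frozen preprocessing chain (impute -> scale ->
## filter), fit on training rows only, applied to anything.
fit_preprocess <- function(train, features = feature_cols(train),
                           vif_max = 5, r_max = 0.95, filter = TRUE) {
  imp <- fit_imputer(train, features)
  train_i <- apply_imputer(imp, train)
  sc <- fit_scaler(train_i, features)
  train_s <- apply_scaler(sc, train_i)
  rep <- if (filter) {
    suppressWarnings(collinearity_filter(train_s, sc$features, vif_max, r_max))
  } else NULL
  structure(list(imputer = imp, scaler = sc, collinearity = rep,
                 features = if (filter) rep$kept else sc$features),
            class = "preprocess_state")
}

apply_preprocess <- function(state, rows) {
  stopifnot(inherits(state, "preprocess_state"))
  rows <- apply_imputer(state$imputer, rows)
  rows <- apply_scaler(state$scaler, rows)
  if (!is.null(state$collinearity)) rows <- apply_collinearity(state$collinearity, rows)
  rows
}
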