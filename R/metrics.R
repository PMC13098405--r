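## One-vs-rest AUC for a single class, rank-based with midranks for ties.
ovr_auc <- function(pos, score) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUC
#'
#' Unweighted mean of per-class one-vs-rest AUCs (rank-based, midranks for
#' tied scores). Classes absent from the truth have undefined OvR AUC and are
#' excluded from the macro mean with a warning.
#'
#' @param truth Factor or character vector of true labels.
#' @param prob Probability matrix with one named column per class.
#' @return Macro-averaged AUC in `[0, 1]`.
#' @export
macro_ovr_auc <- function(truth, prob) {
  truth <- as.character(truth)
  classes <- colnames(prob)
  present <- intersect(classes, unique(truth))
  absent <- setdiff(classes, present)
  if (length(absent)) {
    warnf("class(es) absent from truth, excluded from macro AUC: %s",
          paste(absent, collapse = ", "))
  }
  aucs <- vapply(present, function(cl) ovr_auc(truth == cl, prob[, cl]), 0)
  mean(aucs)
}

confusion_matrix <- function(truth, pred, classes) {
  table(factor(truth, classes), factor(pred, classes), dnn = c("truth", "pred"))
}

#' Held-out metric report
#'
#' Computes the full evaluation suite on a held-out set: accuracy,
#' macro-averaged precision/recall/F1 (zero-division convention: a class
#' never predicted scores 0 precision), macro one-vs-rest AUC, log loss
#' (probabilities clipped at 1e-15), Cohen's kappa, Matthews correlation
#' coefficient, and macro one-vs-rest false positive / false negative rates.
#' For hierarchical predictions, pass `gate_truth`/`gate_pred` to add the
#' propagation error.
#'
#' @param truth True labels.
#' @param pred Predicted labels.
#' @param prob Probability matrix (named columns); optional — AUC and log
#'   loss are `NA` without it.
#' @param classes Label universe; defaults to the union of truth and
#'   prediction (or `colnames(prob)`).
#' @return Object of class `metric_report` (a named list; printable).
#' @export
compute_metrics <- function(truth, pred, prob = NULL, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stopf("truth/pred length mismatch")
  classes <- classes %||% (if (!is.null(prob)) colnames(prob)
                           else sort(union(truth, pred)))
  cm <- confusion_matrix(truth, pred, classes)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  tp <- diag(cm); fp <- colSums(cm) - tp; fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  present <- rowSums(cm) > 0
  fpr <- ifelse(fp + tn > 0, fp / (fp + tn), 0)
  fnr <- ifelse(tp + fn > 0, fn / (tp + fn), NA_real_)
  ## Cohen's kappa
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  ## multiclass Matthews correlation
  t_k <- rowSums(cm); p_k <- colSums(cm); c_ <- sum(diag(cm)); s <- n
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  mcc <- if (den > 0) num / den else 0
  auc <- ll <- NA_real_
  if (!is.null(prob)) {
    prob <- prob_matrix(prob, classes)
    auc <- macro_ovr_auc(truth, prob)
    p_true <- prob[cbind(seq_along(truth), match(truth, classes))]
    ll <- -mean(log(pmin(pmax(p_true, 1e-15), 1 - 1e-15)))
  }
  structure(list(
    accuracy = acc,
    precision_macro = mean(prec[present]),
    recall_macro = mean(rec[present]),
    f1_macro = mean(f1[present]),
    auc_macro_ovr = auc,
    log_loss = ll,
    kappa = kappa,
    mcc = mcc,
    fpr_macro_ovr = mean(fpr[present]),
    fnr_macro_ovr = mean(fnr[present], na.rm = TRUE),
    confusion = cm,
    n = n
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Held-out evaluation (n =", x$n, ")\n")
  for (m in c("accuracy", "precision_macro", "recall_macro", "f1_macro",
              "auc_macro_ovr", "log_loss", "kappa", "mcc",
              "fpr_macro_ovr", "fnr_macro_ovr", "propagation_error")) {
    if (!is.null(x[[m]]) && !is.na(x[[m]] %||% NA)) {
      cat(sprintf("  %-18s %.4f", m, x[[m]]))
      if (!is.null(x$ci) && m %in% names(x$ci)) {
        cat(sprintf("  [%.3f, %.3f]", x$ci[[m]][1], x$ci[[m]][2]))
      }
      cat("\n")
    }
  }
  invisible(x)
}

#' Participant-level bootstrap confidence interval for a metric
#'
#' Resamples test participants with replacement (all of a participant's
#' recordings move together), recomputes the metric per replicate, and
#' returns the percentile interval. Degenerate replicates in which the
#' metric is undefined (e.g., one class only for AUC) are skipped and
#' counted; more than 50% undefined replicates is an error.
#'
#' @param truth,pred True and predicted labels (per evaluation row).
#' @param prob Probability matrix (required for AUC/log loss metrics).
#' @param metric Metric name from [compute_metrics()] output (e.g.
#'   `"accuracy"`, `"f1_macro"`, `"auc_macro_ovr"`).
#' @param participant_ids Participant of each row (default: rows are
#'   independent participants).
#' @param n_boot Bootstrap replicates (default 1000; minimum 100).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return List `lower`, `upper`, `point`, `n_skipped`.
#' @export
bootstrap_ci <- function(truth, pred, prob = NULL, metric = "accuracy",
                         participant_ids = NULL, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  if (n_boot < 100) stopf("n_boot must be >= 100")
  truth <- as.character(truth)
  participant_ids <- participant_ids %||% as.character(seq_along(truth))
  uids <- unique(participant_ids)
  rows_of <- split(seq_along(truth), participant_ids)
  classes <- if (!is.null(prob)) colnames(prob) else sort(unique(c(truth, pred)))
  eval_metric <- function(idx) {
    tr <- truth[idx]
    if (metric == "auc_macro_ovr" && length(unique(tr)) < 2) return(NA_real_)
    rep <- suppressWarnings(compute_metrics(
      tr, pred[idx], if (!is.null(prob)) prob[idx, , drop = FALSE], classes))
    rep[[metric]]
  }
  point <- eval_metric(seq_along(truth))
  set.seed(seed)
  vals <- numeric(n_boot); skipped <- 0L
  for (b in seq_len(n_boot)) {
    ids <- sample(uids, length(uids), replace = TRUE)
    idx <- unlist(rows_of[ids], use.names = FALSE)
    v <- eval_metric(idx)
    if (is.na(v)) { skipped <- skipped + 1L; vals[b] <- NA } else vals[b] <- v
  }
  if (skipped > n_boot / 2) {
    stopf("metric '%s' undefined in %d/%d bootstrap replicates", metric,
          skipped, n_boot)
  }
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, type = 7)
  list(lower = unname(qs[1]), upper = unname(qs[2]), point = point,
       n_skipped = skipped)
}

#' Discordance reclassification rate
#'
#' Among held-out participants flagged as clinicopathologically discordant,
#' the fraction whose model-predicted etiology matches the biomarker-
#' confirmed one. Descriptive/exploratory: reported with a per-case audit
#' table. Zero discordant records yields an explicit `NA` rate, not 0.
#'
#' @param records Data frame with `participant_id`, `discordant` (logical),
#'   `predicted` and `confirmed` etiology columns.
#' @return List `rate`, `n_discordant`, `n_matched`, `cases` (audit table),
#'   `note`.
#' @export
reclassification_rate <- function(records) {
  assert_cols(records, c("participant_id", "discordant", "predicted",
                         "confirmed"), "records")
  disc <- records[records$discordant, , drop = FALSE]
  if (!nrow(disc)) {
    return(list(rate = NA_real_, n_discordant = 0L, n_matched = 0L,
                cases = disc, note = "no discordant participants in the test set"))
  }
  disc$matched <- disc$predicted == disc$confirmed
  list(rate = mean(disc$matched), n_discordant = nrow(disc),
       n_matched = sum(disc$matched), cases = disc,
       note = "descriptive/exploratory")
}
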