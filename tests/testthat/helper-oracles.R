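## Independent brute-force oracles. These deliberately avoid the package's
## own code paths: pair counting instead of ranks, explicit loops instead of
## matrix algebra, enumeration instead of closed forms.

## macro one-vs-rest AUC by concordant-pair counting (ties count 1/2)
bf_macro_auc <- function(truth, prob) {
  truth <- as.character(truth)
  classes <- colnames(prob)
  aucs <- c()
  for (cl in classes) {
    pos <- which(truth == cl); neg <- which(truth != cl)
    if (!length(pos) || !length(neg)) next
    conc <- 0
    for (i in pos) for (j in neg) {
      conc <- conc + (prob[i, cl] > prob[j, cl]) + 0.5 * (prob[i, cl] == prob[j, cl])
    }
    aucs <- c(aucs, conc / (length(pos) * length(neg)))
  }
  mean(aucs)
}

## Cohen's kappa from first principles (observed vs chance agreement)
bf_kappa <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- 0
  for (cl in classes) pe <- pe + mean(truth == cl) * mean(pred == cl)
  (po - pe) / (1 - pe)
}

## multiclass MCC as the Pearson correlation of one-hot indicator matrices
bf_mcc <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  X <- sapply(classes, function(cl) as.numeric(truth == cl))
  Y <- sapply(classes, function(cl) as.numeric(pred == cl))
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  num <- sum(cx * cy)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) 0 else num / den
}

## macro OvR FPR / FNR by explicit per-class counting
bf_fpr_fnr <- function(truth, pred, classes = sort(unique(truth))) {
  fprs <- c(); fnrs <- c()
  for (cl in classes) {
    if (!any(truth == cl)) next
    fp <- sum(pred == cl & truth != cl); tn <- sum(pred != cl & truth != cl)
    fn <- sum(pred != cl & truth == cl); tp <- sum(pred == cl & truth == cl)
    fprs <- c(fprs, if (fp + tn > 0) fp / (fp + tn) else 0)
    fnrs <- c(fnrs, fn / (fn + tp))
  }
  c(fpr = mean(fprs), fnr = mean(fnrs))
}

## Mann-Whitney U by pair counting; Z from the tie-corrected variance
bf_mann_whitney <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  list(u = u, z = z, r = abs(z) / sqrt(n))
}

## exact permutation SD of U for tiny samples (complete enumeration)
bf_perm_sd_u <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    u <- 0
    for (xi in xx) for (yi in yy) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  })
  sqrt(mean((us - mean(us))^2))
}

## Benjamini-Hochberg step-up by hand
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

## brute-force pause statistics by scanning every interval gap
bf_pause_stats <- function(words, threshold) {
  gaps <- c()
  if (nrow(words) > 1) {
    for (i in 2:nrow(words)) gaps <- c(gaps, words$tmin[i] - words$tmax[i - 1])
  }
  pauses <- gaps[gaps >= threshold]
  list(count = length(pauses),
       median = if (length(pauses)) median(pauses) else NA_real_,
       speech = sum(words$tmax - words$tmin))
}

## quick synthetic classification table for framework tests
make_toy_table <- function(n_per_group, shift = 1.5, n_features = 20,
                           n_signal = 10, seed = 1, groups = GROUPS7) {
  spec <- cohort_spec(n_per_group = n_per_group, seed = seed)
  cohort <- generate_cohort(spec)
  shifts <- lapply(cohort_spec()$group_labels, function(g) {
    ph <- physiotype_of(g)
    s <- setNames(numeric(0), character(0))
    if (ph == "AD") s <- setNames(rep(shift / 2, n_signal), sprintf("sig_%02d", 1:n_signal))
    if (ph == "FTLD") s <- setNames(rep(-shift / 2, n_signal), sprintf("sig_%02d", 1:n_signal))
    if (ph == "HC") s <- setNames(rep(shift / 2, 5), sprintf("hc_%02d", 1:5))
    s
  })
  names(shifts) <- cohort_spec()$group_labels
  sig <- group_signature(shifts)
  tabs <- generate_feature_table(cohort, sig, n_features = n_features,
                                 seed = seed, tasks = "NEG")
  tab <- tabs$NEG
  cbind(tab, cohort[match(tab$participant_id, cohort$participant_id),
                    c("group", "physiotype", "age", "sex", "discordant")])
}

GROUPS7 <- c("aAD", "lvPPA-AD", "bvFTLD", "lvPPA-FTLD",
             "svPPA-FTLD", "nfvPPA-FTLD", "HC")
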