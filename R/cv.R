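#' Age-group bins used for demographic stratification
#'
#' @param age Numeric ages in years.
#' @return Factor with levels `<65`, `65-75`, `>75`.
#' @export
age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 65, 75, Inf), labels = c("<65", "65-75", ">75"),
      right = TRUE)
}

#' Participant-level stratified train/test split
#'
#' Partitions participants into a training and a held-out test set at the
#' participant level (every recording of a participant stays on one side),
#' stratified by label x age group x sex. Within each stratification cell,
#' `round(test_frac * n_cell)` participants (round-half-up) go to the test
#' side. Cells with a single participant are assigned to training with a
#' warning.
#'
#' @param participants Data frame with `participant_id`, a label column, and
#'   (if demographic stratification is requested) `age` and `sex`.
#' @param test_frac Held-out fraction (default 0.2), in (0, 1).
#' @param label_col Column holding the classification label.
#' @param strata Stratification variables: any of `"label"`, `"age_group"`,
#'   `"sex"`.
#' @param seed Integer seed (deterministic assignment).
#' @return Object of class `split_plan`: `train`, `test` (participant ids),
#'   `cells` (per-cell bookkeeping), `seed`.
#' @export
make_split <- function(participants, test_frac = 0.2, label_col = "group",
                       strata = c("label", "age_group", "sex"), seed = 1L) {
  assert_cols(participants, c("participant_id", label_col), "participants")
  if (anyDuplicated(participants$participant_id)) {
    stopf("participants must have one row per participant")
  }
  if (test_frac <= 0 || test_frac >= 1) stopf("test_frac must be in (0, 1)")
  parts <- list()
  if ("label" %in% strata) parts$label <- participants[[label_col]]
  if ("age_group" %in% strata) {
    assert_cols(participants, "age", "participants")
    parts$age_group <- as.character(age_group_of(participants$age))
  }
  if ("sex" %in% strata) {
    assert_cols(participants, "sex", "participants")
    parts$sex <- participants$sex
  }
  cell <- if (length(parts)) do.call(paste, c(parts, sep = "|"))
          else rep("all", nrow(participants))
  set.seed(seed)
  test_ids <- character(0)
  cells <- list()
  for (cl in sort(unique(cell))) {
    ids <- participants$participant_id[cell == cl]
    n <- length(ids)
    if (n == 1) {
      warnf("stratification cell '%s' has a single participant; kept in training", cl)
      n_test <- 0L
    } else {
      n_test <- min(n - 1L, round_half_up(test_frac * n))
    }
    picked <- if (n_test > 0) sample(ids, n_test) else character(0)
    test_ids <- c(test_ids, picked)
    cells[[cl]] <- data.frame(cell = cl, n = n, n_test = n_test,
                              stringsAsFactors = FALSE)
  }
  structure(list(
    train = setdiff(participants$participant_id, test_ids),
    test = test_ids,
    cells = do.call(rbind, cells),
    seed = seed
  ), class = "split_plan")
}

#' Repeated stratified k-fold assignment over training participants
#'
#' Builds `repeats` independent label-stratified partitions of the training
#' participants into `k` validation folds (class members are shuffled and
#' dealt round-robin, so per-fold class counts differ by at most one).
#'
#' @param train_participants Data frame with `participant_id` and the label
#'   column.
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeats (default 5).
#' @param label_col Label column name.
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: `folds` is a list of
#'   `repeats * k` entries, each with `repeat_idx`, `fold_idx`, `train`,
#'   `validation` participant ids.
#' @export
make_folds <- function(train_participants, k = 5, repeats = 5,
                       label_col = "group", seed = 1L) {
  assert_cols(train_participants, c("participant_id", label_col),
              "train_participants")
  labels <- train_participants[[label_col]]
  sizes <- table(labels)
  if (any(sizes < k)) {
    small <- names(sizes)[sizes < k]
    stopf(paste0("class(es) smaller than k=%d folds: %s (n = %s). ",
                 "Reduce k or merge/augment these classes."),
          k, paste(small, collapse = ", "),
          paste(sizes[small], collapse = ", "))
  }
  ids <- train_participants$participant_id
  folds <- list()
  for (r in seq_len(repeats)) {
    set.seed(child_seed(seed, r))
    fold_of <- setNames(integer(length(ids)), ids)
    for (lv in names(sizes)) {
      members <- sample(ids[labels == lv])
      fold_of[members] <- rep_len(seq_len(k), length(members))
    }
    for (f in seq_len(k)) {
      val <- names(fold_of)[fold_of == f]
      folds[[length(folds) + 1]] <- list(
        repeat_idx = r, fold_idx = f,
        train = setdiff(ids, val), validation = val)
    }
  }
  structure(list(folds = folds, k = k, repeats = repeats, seed = seed,
                 participants = ids),
            class = "fold_assignment")
}

## Tag rows as fold-training rows so that oversample() can refuse anything
## else (validation/test rows are never oversampled).
tag_training_rows <- function(rows) {
  attr(rows, "split_role") <- "training"
  rows
}

#' In-fold minority oversampling (or class weights)
#'
#' Balances class counts within one fold's training rows: each minority
#' class is resampled with replacement up to the majority-class count
#' (strategy `"oversample"`, the default). Alternatives for sensitivity
#' analyses: `"class_weight"` leaves rows unchanged and emits
#' inverse-frequency weights normalized to the majority class;
#' `"none"` is the identity. Refuses rows not tagged as fold-training rows.
#'
#' @param rows Data frame of one fold's training rows, tagged by the fold
#'   machinery (see `tag_training_rows`).
#' @param label_col Class label column.
#' @param strategy One of `"oversample"`, `"class_weight"`, `"none"`.
#' @param seed Integer seed.
#' @return List `rows` (possibly augmented; duplicates flagged in the
#'   logical column `.oversampled`) and `weights` (named per-class weights,
#'   NULL unless `strategy = "class_weight"`).
#' @export
oversample <- function(rows, label_col = "label",
                       strategy = c("oversample", "class_weight", "none"),
                       seed = 1L) {
  strategy <- match.arg(strategy)
  if (!identical(attr(rows, "split_role"), "training")) {
    stopf("oversample() may only be applied to fold-training rows")
  }
  counts <- table(rows[[label_col]])
  if (strategy == "none") {
    rows$.oversampled <- FALSE
    return(list(rows = rows, weights = NULL))
  }
  if (strategy == "class_weight") {
    w <- max(counts) / counts
    rows$.oversampled <- FALSE
    return(list(rows = rows, weights = setNames(as.numeric(w), names(counts))))
  }
  set.seed(seed)
  target <- max(counts)
  extra <- list()
  for (lv in names(counts)) {
    deficit <- target - counts[[lv]]
    if (deficit > 0) {
      pool <- which(rows[[label_col]] == lv)
      dup <- rows[sample(pool, deficit, replace = TRUE), , drop = FALSE]
      dup$.oversampled <- TRUE
      extra[[lv]] <- dup
    }
  }
  rows$.oversampled <- FALSE
  out <- rbind(rows, do.call(rbind, extra))
  rownames(out) <- NULL
  out <- tag_training_rows(out)
  list(rows = out, weights = NULL)
}
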