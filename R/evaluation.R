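#' Build a cross-validation plan
#'
#' Supported schemes: `holdout` (single stratified train/val/test split),
#' `stratified_kfold` (class ratio preserved per fold within one sample),
#' `loso` (leave-one-supertrial-out: fold *i* tests the *i*-th repetition of
#' every subject), and `louo` (leave-one-user-out: fold *s* tests all trials
#' of subject *s*). In every scheme a stratified validation split
#' (`val_fraction`, default 0.1) is carved out of each fold's training set to
#' drive early stopping; test sets partition the eligible trials.
#'
#' @param ds a labelled [sequence_dataset()].
#' @param scheme one of `"holdout"`, `"stratified_kfold"`, `"loso"`, `"louo"`.
#' @param k fold count for `stratified_kfold` (default 10) or test fraction
#'   denominator for `holdout` (test = 1/k).
#' @param seed seed for the random splits.
#' @param val_fraction fraction of each fold's training trials set aside for
#'   validation.
#' @return An object of class `fold_plan`: a list of folds, each with
#'   `train`, `val` and `test` trial-id vectors.
#' @export
make_folds <- function(ds, scheme = c("stratified_kfold", "holdout", "loso",
                                      "louo"),
                       k = 10L, seed = 1L, val_fraction = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(ds, "sequence_dataset"))
  ids <- dataset_ids(ds)
  labels <- dataset_labels(ds)
  subjects <- dataset_subjects(ds)
  set.seed(seed)

  test_sets <- switch(scheme,
    stratified_kfold = {
      if (k < 2L) stop("stratified_kfold needs k >= 2")
      folds <- vector("list", k)
      for (cl in unique(labels)) {
        pool <- sample(ids[labels == cl])
        assign_to <- rep_len(seq_len(k), length(pool))
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], pool[assign_to == f])
        }
      }
      folds
    },
    holdout = {
      if (k < 2L) stop("holdout needs k >= 2 (test fraction 1/k)")
      test <- unlist(lapply(unique(labels), function(cl) {
        pool <- sample(ids[labels == cl])
        pool[seq_len(max(1L, round(length(pool) / k)))]
      }))
      list(test)
    },
    loso = {
      reps <- stats::ave(seq_along(ids), subjects, FUN = seq_along)
      k_rep <- max(reps)
      lapply(seq_len(k_rep), function(r) ids[reps == r])
    },
    louo = {
      subj <- unique(subjects)
      if (length(subj) < 2L) stop("louo needs at least two subjects")
      lapply(subj, function(s) ids[subjects == s])
    })

  folds <- lapply(test_sets, function(test) {
    rest <- setdiff(ids, test)
    if (length(rest) == 0L) stop("a fold has an empty training set")
    val <- stratified_take(rest, labels[match(rest, ids)], val_fraction)
    list(train = setdiff(rest, val), val = val, test = test)
  })
  structure(list(scheme = scheme, k = length(folds), seed = seed,
                 folds = folds),
            class = "fold_plan")
}

# deterministic stratified subsample (uses the current RNG stream)
stratified_take <- function(ids, labels, fraction) {
  take <- character(0)
  for (cl in unique(labels)) {
    pool <- sample(ids[labels == cl])
    n <- max(1L, round(length(pool) * fraction))
    take <- c(take, pool[seq_len(min(n, length(pool)))])
  }
  take
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %s, %d folds (seed %d)\n", x$scheme, x$k, x$seed))
  sizes <- vapply(x$folds, function(f) lengths(f[c("train", "val", "test")]),
                  integer(3))
  cat("  fold sizes (train/val/test):",
      paste(apply(sizes, 2, paste, collapse = "/"), collapse = ", "), "\n")
  invisible(x)
}

#' Run cross-validated training sessions of the full pipeline
#'
#' For each session (fresh derived seeds) and each fold of the plan: fit the
#' normalization on the fold's training split, train the autoencoder and the
#' requested heads via [skillnet()], and predict the held-out test trials.
#' Test predictions are pooled across folds - every trial is tested exactly
#' once per session - and metrics are computed from the pooled records, as
#' well as per fold.
#'
#' @param ds a raw [sequence_dataset()].
#' @param plan a [make_folds()] plan.
#' @param config a [skillnet_config()].
#' @param tasks heads to train, subset of
#'   `c("classification", "regression")`.
#' @param sessions number of independent training repetitions.
#' @param seed master seed; session `s`, fold `f` trains with a seed derived
#'   from `(seed, s, f)`.
#' @param keep_models keep each fold's fitted [skillnet()] (memory-heavy).
#' @return An object of class `skillseq_cv`: per-session pooled prediction
#'   records, per-session and per-fold metric reports, and a cross-session
#'   mean/sd summary.
#' @export
run_cv <- function(ds, plan, config = skillnet_config(),
                   tasks = c("classification", "regression"),
                   sessions = 1L, seed = 1L, keep_models = FALSE) {
  stopifnot(inherits(plan, "fold_plan"))
  tasks <- match.arg(tasks, several.ok = TRUE)
  if (any(lengths(lapply(plan$folds, `[[`, "test")) == 0L)) {
    stop("plan contains an empty test fold")
  }
  ds <- preprocess_dataset(ds, config$target_fps)
  out_sessions <- vector("list", sessions)
  for (s in seq_len(sessions)) {
    srec <- NULL
    models <- if (keep_models) vector("list", plan$k) else NULL
    for (f in seq_len(plan$k)) {
      fold <- plan$folds[[f]]
      fit <- skillnet(subset_dataset(ds, fold$train),
                      subset_dataset(ds, fold$val),
                      tasks = tasks, config = config,
                      seed = derive_seed(seed, s, f))
      rec <- predict(fit, subset_dataset(ds, fold$test))
      rec$fold <- f
      srec <- rbind(srec, rec)
      if (keep_models) models[[f]] <- fit
    }
    metrics <- list()
    if ("classification" %in% tasks) {
      metrics$classification <- classification_metrics(
        srec, positive_class = config$positive_class,
        class_names = ds$class_names)
      metrics$per_fold_accuracy <- vapply(seq_len(plan$k), function(f) {
        r <- srec[srec$fold == f, ]
        mean(r$pred_class == r$true_class)
      }, numeric(1))
    }
    if ("regression" %in% tasks) {
      metrics$regression <- regression_metrics(srec)
    }
    out_sessions[[s]] <- list(records = srec, metrics = metrics,
                              models = models)
  }
  structure(list(plan = plan, tasks = tasks, sessions = out_sessions,
                 summary = summarize_sessions(out_sessions, tasks),
                 config = config, seed = seed),
            class = "skillseq_cv")
}

summarize_sessions <- function(sessions, tasks) {
  pick <- function(fn) vapply(sessions, fn, numeric(1))
  out <- list()
  if ("classification" %in% tasks) {
    for (m in c("accuracy", "sensitivity", "specificity", "auc")) {
      v <- pick(function(s) s$metrics$classification[[m]])
      out[[m]] <- c(mean = mean(v), sd = stats::sd(v))
    }
  }
  if ("regression" %in% tasks) {
    v <- pick(function(s) s$metrics$regression$spearman_rho)
    out$spearman_rho <- c(mean = mean(v), sd = stats::sd(v))
  }
  out
}

#' @export
print.skillseq_cv <- function(x, ...) {
  cat(sprintf("<skillseq_cv> %s, %d folds, %d session(s)\n",
              x$plan$scheme, x$plan$k, length(x$sessions)))
  for (nm in names(x$summary)) {
    v <- x$summary[[nm]]
    cat(sprintf("  %-13s %.3f +/- %.3f\n", nm, v["mean"],
                if (is.na(v["sd"])) 0 else v["sd"]))
  }
  invisible(x)
}

#' Classification metrics from pooled prediction records
#'
#' Accuracy, sensitivity and specificity are read off the pooled confusion
#' matrix; the ROC curve and its AUC use the pooled probabilities of the
#' positive class.
#'
#' @param records a data frame with `true_class`, `pred_class` and
#'   `prob_<positive_class>` columns (as produced by [predict.skillnet()]).
#' @param positive_class label counted as positive.
#' @param class_names ordered class labels; defaults to those present.
#' @return A list of class `metric_report`.
#' @export
classification_metrics <- function(records, positive_class = "pass",
                                   class_names = NULL) {
  if (nrow(records) < 2L) stop("need at least two prediction records")
  if (is.null(class_names)) {
    class_names <- sort(unique(c(records$true_class, records$pred_class)))
  }
  truth <- factor(records$true_class, levels = class_names)
  pred <- factor(records$pred_class, levels = class_names)
  cm <- table(predicted = pred, true = truth)
  pos <- positive_class
  neg <- setdiff(class_names, pos)
  tp <- cm[pos, pos]; fn <- sum(cm[neg, pos])
  tn <- sum(cm[neg, neg]); fp <- sum(cm[pos, neg])
  prob_col <- paste0("prob_", pos)
  if (length(unique(records$true_class)) < 2L) {
    stop("AUC undefined: only one true class present in the pool")
  }
  roc <- pROC::roc(response = truth == pos,
                   predictor = records[[prob_col]],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  structure(list(accuracy = (tp + tn) / sum(cm),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = as.numeric(pROC::auc(roc)),
                 confusion = cm, positive_class = pos,
                 n = nrow(records)),
            class = "metric_report")
}

#' Score-regression metrics from pooled prediction records
#'
#' Spearman's rank correlation between true and predicted scores with a
#' two-sided p-value (exact permutation for fewer than 10 pairs, the
#' t-approximation otherwise).
#'
#' @param records data frame with `true_score` and `pred_score` columns.
#' @return A list of class `metric_report`.
#' @export
regression_metrics <- function(records) {
  ok <- stats::complete.cases(records[, c("true_score", "pred_score")])
  n <- sum(ok)
  if (n < 2L) stop("need at least two score pairs")
  ct <- suppressWarnings(
    stats::cor.test(records$true_score[ok], records$pred_score[ok],
                    method = "spearman", exact = n < 10))
  structure(list(spearman_rho = unname(ct$estimate),
                 p_value = ct$p.value, n = n),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  if (!is.null(x$accuracy)) {
    cat(sprintf(
      "accuracy %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f (n=%d)\n",
      x$accuracy, x$sensitivity, x$specificity, x$auc, x$n))
  }
  if (!is.null(x$spearman_rho)) {
    cat(sprintf("Spearman rho %.3f (p = %.3g, n = %d)\n",
                x$spearman_rho, x$p_value, x$n))
  }
  invisible(x)
}
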