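#' Bundle of hyperparameters for a full skill-assessment fit
#'
#' @param dae a [dae_config()].
#' @param block a [resblock_config()] for the heads.
#' @param clf_max_epochs,clf_patience head training controls (the patience
#'   default follows the pattern-cutting setting of 20 epochs; the
#'   autoencoder default is 4).
#' @param learning_rate Adam step size for the heads.
#' @param target_fps rate the sequences are downsampled to before modelling.
#' @param positive_class class treated as positive by binary metrics.
#' @param normalization_scope `"fold_train"` (fit stats on the training
#'   split, the default, leakage-safe) or `"global"`.
#' @param fine_tune continue gradients into the encoder while training the
#'   heads (default `FALSE`: frozen encoder).
#' @return A list of class `skillnet_config`.
#' @export
skillnet_config <- function(dae = dae_config(), block = resblock_config(),
                            clf_max_epochs = 50L, clf_patience = 20L,
                            learning_rate = 1e-3, target_fps = 1,
                            positive_class = "pass",
                            normalization_scope = c("fold_train", "global"),
                            fine_tune = FALSE) {
  structure(list(dae = dae, block = block,
                 clf_max_epochs = as.integer(clf_max_epochs),
                 clf_patience = as.integer(clf_patience),
                 learning_rate = learning_rate, target_fps = target_fps,
                 positive_class = positive_class,
                 normalization_scope = match.arg(normalization_scope),
                 fine_tune = isTRUE(fine_tune)),
            class = "skillnet_config")
}

#' Fit the full skill-assessment model
#'
#' End-to-end fit on a training/validation split: preprocesses the raw
#' sequences (gap interpolation, downsampling), fits normalization on the
#' training split, trains the denoising autoencoder, and trains the
#' requested heads (pass/fail classifier and/or score regressor) on the
#' embedded features. Returns a fitted model usable with [predict()].
#'
#' @param train,val [sequence_dataset()]s of raw trials; `val` drives early
#'   stopping for the autoencoder and the heads.
#' @param tasks subset of `c("classification", "regression")`.
#' @param config a [skillnet_config()].
#' @param seed master seed; the autoencoder and each head derive their own
#'   seeds from it so repeated fits are bit-identical.
#' @return An object of class `skillnet` with elements `stats`
#'   (normalization), `dae`, `heads`, `class_names`, `config`.
#' @export
skillnet <- function(train, val, tasks = c("classification", "regression"),
                     config = skillnet_config(), seed = 1L) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  stopifnot(inherits(train, "sequence_dataset"),
            inherits(val, "sequence_dataset"))
  train <- preprocess_dataset(train, config$target_fps)
  val <- preprocess_dataset(val, config$target_fps)
  stats <- fit_normalization(train, scope = config$normalization_scope)
  train_n <- apply_normalization(train, stats)
  val_n <- apply_normalization(val, stats)

  dcfg <- config$dae
  dcfg$seed <- derive_seed(seed, 1L)
  dae <- build_dae(dcfg, d_in = ncol(train_n$trials[[1]]$coords))
  dae <- train_dae(dae, train_n, val_n)
  emb_train <- encode(dae, train_n)
  emb_val <- encode(dae, val_n)

  heads <- list()
  # fine-tuning propagates gradients through the encoder, so the head then
  # consumes raw normalized sequences rather than fixed embeddings
  clf_train_x <- if (config$fine_tune) {
    lapply(train_n$trials, `[[`, "coords")
  } else {
    emb_train
  }
  clf_val_x <- if (config$fine_tune) {
    lapply(val_n$trials, `[[`, "coords")
  } else {
    emb_val
  }
  if ("classification" %in% tasks) {
    tgt <- encode_targets(train_n)
    head <- build_classifier(config$block, "classification",
                             n_classes = length(train_n$class_names),
                             d_in = dcfg$d_e, seed = derive_seed(seed, 2L))
    heads$classification <- train_classifier(
      head, clf_train_x, clf_val_x,
      dataset_labels(train_n), dataset_labels(val_n),
      class_names = train_n$class_names, class_weights = tgt$class_weights,
      max_epochs = config$clf_max_epochs, patience = config$clf_patience,
      learning_rate = config$learning_rate, seed = derive_seed(seed, 3L),
      encoder = dae, fine_tune = config$fine_tune)
    if (config$fine_tune) {
      dae <- attr(heads$classification, "encoder")
      emb_train <- encode(dae, train_n)
      emb_val <- encode(dae, val_n)
    }
  }
  if ("regression" %in% tasks) {
    head <- build_classifier(config$block, "regression",
                             d_in = dcfg$d_e, seed = derive_seed(seed, 4L))
    heads$regression <- train_classifier(
      head, emb_train, emb_val,
      dataset_scores(train_n), dataset_scores(val_n),
      max_epochs = config$clf_max_epochs, patience = config$clf_patience,
      learning_rate = config$learning_rate, seed = derive_seed(seed, 5L))
  }

  structure(list(stats = stats, dae = dae, heads = heads,
                 class_names = train$class_names, config = config,
                 seed = seed),
            class = "skillnet")
}

#' @export
print.skillnet <- function(x, ...) {
  cat("<skillnet> fitted skill-assessment model\n")
  cat("  heads:", paste(names(x$heads), collapse = ", "), "\n")
  cat("  embedded features:", x$dae$cfg$d_e,
      "| block filters:", x$config$block$filters,
      "| dilation:", x$config$block$dilation, "\n")
  if (!is.null(x$dae$history)) {
    cat(sprintf("  autoencoder: %d epochs, best val MSE %.3g\n",
                nrow(x$dae$history), min(x$dae$history$val_loss)))
  }
  for (nm in names(x$heads)) {
    h <- x$heads[[nm]]$history
    if (!is.null(h)) {
      cat(sprintf("  %s head: %d epochs, best val loss %.3g\n",
                  nm, nrow(h), min(h$val_loss)))
    }
  }
  invisible(x)
}

#' @export
summary.skillnet <- function(object, ...) {
  print(object)
  cat("  normalization: feature ranges [",
      paste(sprintf("%.0f-%.0f", object$stats$feature_min,
                    object$stats$feature_max), collapse = ", "), "]\n")
  if (!is.na(object$stats$score_mean)) {
    cat(sprintf("  score scale: mean %.1f sd %.1f\n",
                object$stats$score_mean, object$stats$score_sd))
  }
  invisible(object)
}

#' Predict skill class and/or score for new trials
#'
#' Applies the stored preprocessing (gap filling, downsampling,
#' normalization fitted on the training split), embeds the trials, and runs
#' every fitted head. Regression output is returned on the original score
#' scale.
#'
#' @param object a fitted [skillnet()].
#' @param newdata a [sequence_dataset()] of raw trials.
#' @param ... unused.
#' @return A data frame of prediction records: `trial_id`, `true_class`,
#'   `true_score`, and per-head predictions (`pred_class`, `confidence`,
#'   `prob_*`, `pred_score`).
#' @export
predict.skillnet <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "sequence_dataset"))
  ds <- preprocess_dataset(newdata, object$config$target_fps)
  truth <- data.frame(trial_id = dataset_ids(ds),
                      true_class = dataset_labels(ds),
                      true_score = dataset_scores(ds))
  ds_n <- apply_normalization(ds, object$stats)
  emb <- encode(object$dae, ds_n)
  out <- truth
  if (!is.null(object$heads$classification)) {
    out <- merge(out, predict_trials(object$heads$classification, emb),
                 by = "trial_id", sort = FALSE)
  }
  if (!is.null(object$heads$regression)) {
    out <- merge(out, predict_trials(object$heads$regression, emb,
                                     stats = object$stats),
                 by = "trial_id", sort = FALSE)
  }
  out[match(truth$trial_id, out$trial_id), , drop = FALSE]
}

# Small-integer seed derivation keeping everything inside 32-bit range.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483629
  as.integer(s)
}
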