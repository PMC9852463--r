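#' Residual-block configuration for the skill heads
#'
#' The head network is a single attention-infused residual block (two
#' same-padded convolutions with an identity shortcut and two concurrent
#' spatial/channel squeeze-and-excitation layers), followed by global
#' average pooling over time - which makes the network accept sequences of
#' any length - and a fully connected output: softmax over the skill classes
#' for classification, a single unconstrained node for score regression.
#' Convolutions are dilated (default 2) when the block serves the
#' classifier; the autoencoder uses the same block undilated.
#'
#' @param filters convolution width.
#' @param kernel_size odd kernel length.
#' @param dilation dilation factor of both convolutions (>= 1).
#' @param scse_reduction channel bottleneck ratio of the attention layers.
#' @return A list of class `resblock_config`.
#' @export
resblock_config <- function(filters = 16L, kernel_size = 5L, dilation = 2L,
                            scse_reduction = 2L) {
  stopifnot(filters >= 1, kernel_size %% 2 == 1, scse_reduction >= 1)
  if (dilation < 1) stop("dilation must be >= 1")
  structure(list(filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 dilation = as.integer(dilation),
                 scse_reduction = as.integer(scse_reduction)),
            class = "resblock_config")
}

#' Build an untrained classification or regression head
#'
#' @param block a [resblock_config()].
#' @param task `"classification"` or `"regression"`.
#' @param n_classes number of skill classes (classification only).
#' @param d_in input feature count (the autoencoder's `d_e`).
#' @param seed initialisation seed.
#' @return A list of class `skill_head`.
#' @export
build_classifier <- function(block = resblock_config(),
                             task = c("classification", "regression"),
                             n_classes = 2L, d_in = 8L, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(block, "resblock_config"), d_in >= 1)
  if (task == "classification" && n_classes < 2L) {
    stop("classification needs at least two classes")
  }
  n_out <- if (task == "classification") as.integer(n_classes) else 1L
  set.seed(seed)
  params <- list(block = nn_resblock_init(d_in, block$filters,
                                          block$kernel_size,
                                          block$scse_reduction),
                 dense = nn_dense_init(block$filters, n_out))
  structure(list(block_cfg = block, task = task, n_out = n_out,
                 d_in = as.integer(d_in), params = params,
                 trained = FALSE, history = NULL),
            class = "skill_head")
}

# forward through block + GAP + dense; keeps the pre-pooling activations,
# which are what the class activation map reads out.
head_fwd <- function(params, z, dilation) {
  rb <- nn_resblock_fwd(z, params$block, dilation)
  g <- colMeans(rb$y)
  logits <- drop(g %*% params$dense$W) + params$dense$b
  list(logits = logits, g = g, f = rb$y, rb_cache = rb$cache)
}

head_bwd <- function(params, fw, dlogits, dilation) {
  Tn <- nrow(fw$f)
  dW <- outer(fw$g, dlogits)
  db <- dlogits
  dg <- drop(params$dense$W %*% dlogits)
  df <- matrix(dg / Tn, Tn, length(dg), byrow = TRUE)
  rb <- nn_resblock_bwd(df, params$block, fw$rb_cache, dilation)
  list(grad = list(block = rb$grad, dense = list(W = dW, b = db)),
       dz = rb$dx)
}

#' Train a skill head on embedded sequences
#'
#' Batch size is one; the loss is class-weighted cross-entropy for
#' classification and mean squared error on z-normalized scores for
#' regression. Early stopping monitors validation loss with the configured
#' patience and restores the best parameters. With `encoder` supplied and
#' `fine_tune = TRUE`, gradients continue through the encoder and both are
#' updated; by default the encoder is frozen and `train_x` are embeddings.
#'
#' @param model a [build_classifier()] head.
#' @param train_x,val_x lists of `embedded_sequence` objects (or, when
#'   fine-tuning, normalized coordinate matrices).
#' @param train_y,val_y targets: class labels (character, in `class_names`)
#'   or z-normalized scores.
#' @param class_names ordered class labels (classification).
#' @param class_weights named per-class loss weights (classification;
#'   required).
#' @param max_epochs,patience,learning_rate,seed training controls.
#' @param encoder optional trained [dae_model][build_dae()] for fine-tuning.
#' @param fine_tune update the encoder jointly (default `FALSE`).
#' @param n_starts number of independent (deterministically seeded) training
#'   starts; the start with the lowest best validation loss is kept.
#'   Batch-size-one training on small folds is noisy enough that multi-start
#'   selection measurably stabilises the heads.
#' @param restarts with batch-size-one training a run occasionally collapses
#'   into predicting the class prior; when the best validation loss still
#'   fails to beat the trivial constant predictor after the `n_starts`
#'   starts, training restarts from further derived seeds, up to this many
#'   extra attempts (best attempt kept).
#' @return The trained head (with `history`); when fine-tuning, the updated
#'   encoder is attached as attribute `"encoder"`.
#' @export
train_classifier <- function(model, train_x, val_x, train_y, val_y,
                             class_names = NULL, class_weights = NULL,
                             max_epochs = 50L, patience = 20L,
                             learning_rate = 1e-3, seed = 1L,
                             encoder = NULL, fine_tune = FALSE,
                             n_starts = 2L, restarts = 2L) {
  stopifnot(inherits(model, "skill_head"))
  if (length(val_x) == 0L) stop("empty validation set")
  dilation <- model$block_cfg$dilation
  classification <- model$task == "classification"
  if (classification) {
    if (is.null(class_weights)) {
      stop("class_weights are required for classification")
    }
    if (is.null(class_names)) class_names <- names(class_weights)
    onehot_of <- function(lab) as.numeric(class_names == lab)
  }
  get_feat <- function(x) if (inherits(x, "embedded_sequence")) x$features else x

  fine_tune <- isTRUE(fine_tune) && !is.null(encoder)
  params <- list(head = model$params)
  if (fine_tune) params$enc <- encoder$params[c("enc_block", "emb")]

  embed <- function(p, x) {
    if (!fine_tune) return(list(z = x))
    dae_encode_matrix(p$enc, x)
  }
  sample_loss <- function(p, x, y) {
    em <- embed(p, get_feat(x))
    fw <- head_fwd(p$head, em$z, dilation)
    if (classification) {
      oh <- onehot_of(y)
      l <- nn_wce_loss(fw$logits, oh, class_weights[[y]])
      list(loss = l$loss, dlogits = l$dlogits, fw = fw, em = em)
    } else {
      l <- nn_mse_loss(fw$logits, y)
      list(loss = l$loss, dlogits = l$dy, fw = fw, em = em)
    }
  }

  # validation loss of the trivial constant predictor (training-pool class
  # frequencies, or the training-mean score): the collapse detector
  n <- length(train_x)
  if (classification) {
    prior <- vapply(class_names, function(cl) {
      mean(vapply(seq_len(n), function(i) identical(train_y[[i]], cl),
                  logical(1)))
    }, numeric(1))
    prior <- pmax(prior, 1e-12)
    baseline <- mean(vapply(seq_along(val_x), function(i) {
      y <- val_y[[i]]
      -class_weights[[y]] * log(prior[[y]])
    }, numeric(1)))
  } else {
    mu <- mean(unlist(train_y))
    baseline <- mean(vapply(seq_along(val_x), function(i) {
      (val_y[[i]] - mu)^2
    }, numeric(1)))
  }

  init_params <- params
  blk <- model$block_cfg
  run_once <- function(run_seed, reinit = FALSE) {
    set.seed(run_seed)
    params <- init_params
    if (reinit) {
      params$head <- list(
        block = nn_resblock_init(model$d_in, blk$filters, blk$kernel_size,
                                 blk$scse_reduction),
        dense = nn_dense_init(blk$filters, model$n_out))
    }
    opt <- nn_adam_init(params)
    best <- params; best_val <- Inf
    hist <- NULL; vl <- numeric(0)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      tl <- 0
      for (i in ord) {
        s <- sample_loss(params, train_x[[i]], train_y[[i]])
        tl <- tl + s$loss
        hb <- head_bwd(params$head, s$fw, s$dlogits, dilation)
        g <- list(head = hb$grad)
        if (fine_tune) {
          be <- nn_conv_bwd(hb$dz, params$enc$emb, s$em$emb_cache, 1L)
          bb <- nn_resblock_bwd(be$dx, params$enc$enc_block, s$em$enc_cache,
                                1L)
          g$enc <- list(enc_block = bb$grad, emb = be$grad)
        }
        st <- nn_adam_step(params, g, opt, lr = learning_rate)
        params <- st$p; opt <- st$st
      }
      v <- mean(vapply(seq_along(val_x), function(i) {
        sample_loss(params, val_x[[i]], val_y[[i]])$loss
      }, numeric(1)))
      vl <- c(vl, v)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                     val_loss = v))
      if (v < best_val) { best_val <- v; best <- params }
      if (nn_early_stop(vl, patience)) break
    }
    list(params = best, best_val = best_val, hist = hist)
  }

  attempt <- run_once(seed)
  for (extra in seq_len(max(0L, n_starts - 1L))) {
    again <- run_once(derive_seed(seed, 2000L + extra), reinit = TRUE)
    if (again$best_val < attempt$best_val) attempt <- again
  }
  tries <- 0L
  while (attempt$best_val > 0.95 * baseline && tries < restarts) {
    tries <- tries + 1L
    again <- run_once(derive_seed(seed, 1000L + tries), reinit = TRUE)
    if (again$best_val < attempt$best_val) attempt <- again
  }
  best <- attempt$params
  hist <- attempt$hist
  model$params <- best$head
  model$trained <- TRUE
  model$history <- hist
  model$class_names <- if (classification) class_names else NULL
  if (fine_tune) {
    encoder$params[c("enc_block", "emb")] <- best$enc
    attr(model, "encoder") <- encoder
  }
  model
}

#' Predict skill class probabilities or a score for embedded trials
#'
#' Deterministic inference. For classification the record carries the full
#' probability vector, the argmax class (ties break to the lowest-index
#' class) and the confidence (probability of the predicted class). For
#' regression the raw output is de-normalized with `stats` when given.
#'
#' @param model a trained [skill_head][build_classifier()].
#' @param embedded a list of `embedded_sequence` objects (from [encode()]).
#' @param stats optional `normalization_stats` to de-normalize regression
#'   output back to the score scale.
#' @return A data frame of prediction records, one row per trial.
#' @export
predict_trials <- function(model, embedded, stats = NULL) {
  stopifnot(inherits(model, "skill_head"), model$trained)
  rows <- lapply(embedded, function(e) {
    z <- if (inherits(e, "embedded_sequence")) e$features else e
    if (ncol(z) != model$d_in) {
      stop("embedded feature count ", ncol(z), " does not match the head (",
           model$d_in, ")")
    }
    fw <- head_fwd(model$params, z, model$block_cfg$dilation)
    if (model$task == "classification") {
      p <- nn_softmax(fw$logits)
      j <- which.max(p)  # which.max breaks ties toward the lowest index
      out <- data.frame(trial_id = e$trial_id,
                        pred_class = model$class_names[j],
                        confidence = p[j])
      probs <- as.data.frame(as.list(stats::setNames(
        p, paste0("prob_", model$class_names))))
      cbind(out, probs)
    } else {
      sc <- fw$logits
      if (!is.null(stats)) sc <- denormalize_score(sc, stats)
      data.frame(trial_id = e$trial_id, pred_score = sc)
    }
  })
  do.call(rbind, rows)
}
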