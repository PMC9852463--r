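#' Denoising autoencoder configuration
#'
#' The embedding network corrupts each normalized input sequence with
#' additive zero-mean Gaussian noise (`noise_alpha` is its standard
#' deviation, resampled every epoch) and learns to reconstruct the clean
#' sequence; the encoder half then supplies salient per-timestep features to
#' the downstream heads. Encoder and decoder share the attention-infused
#' residual block of the classifier, without dilation.
#'
#' @param noise_alpha noise scale on normalized inputs (default 0.001).
#' @param filters residual-block width.
#' @param kernel_size odd convolution kernel length.
#' @param d_e embedded feature count (encoder output channels).
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation loss (epochs).
#' @param learning_rate Adam step size.
#' @param scse_reduction channel bottleneck ratio of the attention layers.
#' @param seed seed for initialisation, shuffling and noise.
#' @return A list of class `dae_config`.
#' @export
dae_config <- function(noise_alpha = 0.001, filters = 16L, kernel_size = 5L,
                       d_e = 8L, max_epochs = 20L, patience = 4L,
                       learning_rate = 1e-3, scse_reduction = 2L, seed = 1L) {
  stopifnot(noise_alpha >= 0, filters >= 1, kernel_size %% 2 == 1,
            d_e >= 1, max_epochs >= 1, patience >= 1, learning_rate > 0)
  structure(list(noise_alpha = noise_alpha, filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size), d_e = as.integer(d_e),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 scse_reduction = as.integer(scse_reduction),
                 seed = as.integer(seed)),
            class = "dae_config")
}

#' Build an untrained denoising autoencoder
#'
#' @param cfg a [dae_config()].
#' @param d_in input feature count (4 for bimanual x/y traces).
#' @return A list of class `dae_model` mapping `T x d_in` to `T x d_e` and
#'   back; temporal length is preserved by same-padded convolutions.
#' @export
build_dae <- function(cfg = dae_config(), d_in = 4L) {
  stopifnot(inherits(cfg, "dae_config"), d_in >= 1)
  set.seed(cfg$seed)
  params <- list(
    enc_block = nn_resblock_init(d_in, cfg$filters, cfg$kernel_size,
                                 cfg$scse_reduction),
    emb = nn_conv_init(1L, cfg$filters, cfg$d_e),
    dec_block = nn_resblock_init(cfg$d_e, cfg$filters, cfg$kernel_size,
                                 cfg$scse_reduction),
    out = nn_conv_init(1L, cfg$filters, d_in))
  structure(list(cfg = cfg, d_in = as.integer(d_in), params = params,
                 trained = FALSE, history = NULL),
            class = "dae_model")
}

dae_encode_matrix <- function(params, x) {
  e <- nn_resblock_fwd(x, params$enc_block, 1L)
  z <- nn_conv_fwd(e$y, params$emb, 1L)
  list(z = z$y, enc_cache = e$cache, emb_cache = z$cache)
}

dae_fwd <- function(params, x_in, x_target) {
  enc <- dae_encode_matrix(params, x_in)
  d <- nn_resblock_fwd(enc$z, params$dec_block, 1L)
  xh <- nn_conv_fwd(d$y, params$out, 1L)
  diff <- xh$y - x_target
  list(loss = mean(diff^2), diff = diff, enc = enc, dec_cache = d$cache,
       out_cache = xh$cache)
}

dae_bwd <- function(params, fw) {
  dxh <- 2 * fw$diff / length(fw$diff)
  bo <- nn_conv_bwd(dxh, params$out, fw$out_cache, 1L)
  bd <- nn_resblock_bwd(bo$dx, params$dec_block, fw$dec_cache, 1L)
  be <- nn_conv_bwd(bd$dx, params$emb, fw$enc$emb_cache, 1L)
  bb <- nn_resblock_bwd(be$dx, params$enc_block, fw$enc$enc_cache, 1L)
  list(enc_block = bb$grad, emb = be$grad, dec_block = bd$grad, out = bo$grad)
}

#' Train the denoising autoencoder
#'
#' One trial per gradient step (trials have different lengths), Adam
#' optimiser, mean-squared reconstruction error against the clean sequence.
#' Validation loss is computed noise-free at the end of each epoch; training
#' stops once it has not improved for `patience` epochs and the
#' best-validation parameters are restored.
#'
#' @param model a [build_dae()] model.
#' @param train,val normalized [sequence_dataset()]s.
#' @return The trained model, with a `history` data frame (epoch, mean
#'   training loss, validation loss).
#' @export
train_dae <- function(model, train, val) {
  stopifnot(inherits(model, "dae_model"))
  if (!inherits(val, "sequence_dataset") || val$n_trials == 0L) {
    stop("train_dae requires a non-empty validation set")
  }
  xs <- lapply(train$trials, function(t) t$coords)
  vs <- lapply(val$trials, function(t) t$coords)
  cfg <- model$cfg
  set.seed(cfg$seed)
  params <- model$params
  opt <- nn_adam_init(params)
  val_loss <- function(p) {
    mean(vapply(vs, function(x) dae_fwd(p, x, x)$loss, numeric(1)))
  }
  best <- params; best_val <- Inf
  hist <- NULL; vl <- numeric(0)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(xs))
    tl <- 0
    for (i in ord) {
      x <- xs[[i]]
      xn <- if (cfg$noise_alpha > 0) {
        x + matrix(stats::rnorm(length(x), 0, cfg$noise_alpha), nrow(x))
      } else x
      fw <- dae_fwd(params, xn, x)
      tl <- tl + fw$loss
      g <- dae_bwd(params, fw)
      st <- nn_adam_step(params, g, opt, lr = cfg$learning_rate)
      params <- st$p; opt <- st$st
    }
    v <- val_loss(params)
    vl <- c(vl, v)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / length(xs),
                                   val_loss = v))
    if (v < best_val) { best_val <- v; best <- params }
    if (nn_early_stop(vl, cfg$patience)) break
  }
  model$params <- best
  model$trained <- TRUE
  model$history <- hist
  model
}

#' Encode a dataset into embedded sequences
#'
#' Inference is deterministic: no noise is injected. Temporal length is
#' preserved, so a trial with `T` timesteps yields a `T x d_e` feature
#' matrix.
#'
#' @param model a trained [dae_model][build_dae()].
#' @param ds a normalized [sequence_dataset()].
#' @return A list of `embedded_sequence` objects (fields `trial_id`,
#'   `features`), one per trial, in dataset order.
#' @export
encode <- function(model, ds) {
  stopifnot(inherits(model, "dae_model"), inherits(ds, "sequence_dataset"))
  lapply(ds$trials, function(tr) {
    if (ncol(tr$coords) != model$d_in) {
      stop("trial ", tr$trial_id, " has ", ncol(tr$coords),
           " features; the autoencoder was built for ", model$d_in)
    }
    structure(list(trial_id = tr$trial_id,
                   features = dae_encode_matrix(model$params, tr$coords)$z),
              class = "embedded_sequence")
  })
}
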