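# Minimal 1D convolutional network engine used by the embedding and
# classifier modules. Sequences are T x C matrices (time by channel); the
# batch size is one throughout because trials have different lengths, so all
# forward/backward passes operate on a single matrix. Gradients are derived
# by hand per layer; parameters live in nested named lists whose leaves are
# numeric matrices/vectors, and the optimiser walks that structure.

nn_glorot <- function(fan_in, fan_out, nrow, ncol) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -l, l), nrow, ncol)
}

## ---- convolution (same padding, optional dilation) -------------------------

# Weights are stored as a (k*cin) x cout matrix; rows are grouped by tap so
# tap j occupies rows (j-1)*cin + 1:cin. Kernel length must be odd.
nn_conv_init <- function(k, cin, cout) {
  stopifnot(k %% 2 == 1, cin >= 1, cout >= 1)
  list(W = nn_glorot(k * cin, cout, k * cin, cout), b = numeric(cout),
       k = k, cin = cin, cout = cout)
}

# Forward: y[t, ] = b + sum_j xpad[t + (j-1)*d, ] %*% W[rows of tap j], with
# zero padding of (k-1)/2 * d rows on each side. The heavy lifting lives in
# the compiled kernels (src/nn-kernels.cpp).
nn_conv_fwd <- function(x, p, dilation = 1L) {
  res <- cpp_conv_fwd(x, p$W, p$b, p$k, as.integer(dilation))
  list(y = res$y, cache = list(xcat = res$xcat))
}

nn_conv_bwd <- function(dy, p, cache, dilation = 1L) {
  res <- cpp_conv_bwd(dy, p$W, cache$xcat, p$k, p$cin, as.integer(dilation))
  list(grad = list(W = res$dW, b = drop(res$db)), dx = res$dx)
}

## ---- concurrent spatial & channel squeeze-and-excitation -------------------

# Channel branch: global average over time -> two-layer bottleneck -> sigmoid
# gate per channel. Spatial branch: 1x1 projection across channels -> sigmoid
# gate per timestep. The two recalibrated maps are fused elementwise by max.
nn_scse_init <- function(f, reduction = 2L) {
  fr <- max(1L, f %/% reduction)
  list(W1 = nn_glorot(f, fr, f, fr), b1 = numeric(fr),
       W2 = nn_glorot(fr, f, fr, f), b2 = numeric(f),
       v = nn_glorot(f, 1, f, 1), bv = 0)
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# Channel branch: s = sigmoid(W2' relu(W1' mean_t(x) + b1) + b2) scales
# columns; spatial branch: q = sigmoid(x v + bv) scales rows; fused by
# elementwise max. Compiled in src/nn-kernels.cpp.
nn_scse_fwd <- function(x, p) {
  res <- cpp_scse_fwd(x, p$W1, p$b1, p$W2, p$b2, p$v, p$bv)
  list(y = res$y,
       cache = list(x = x, z = res$z, a1pre = res$a1pre, a1 = res$a1,
                    s = res$s, q = res$q, m = res$m))
}

nn_scse_bwd <- function(dy, p, cache) {
  res <- cpp_scse_bwd(dy, cache$x, p$W1, p$W2, p$v, cache$z, cache$a1pre,
                      cache$a1, cache$s, cache$q, cache$m)
  list(grad = list(W1 = res$dW1, b1 = drop(res$db1), W2 = res$dW2,
                   b2 = drop(res$db2), v = res$dv, bv = res$dbv),
       dx = res$dx)
}

## ---- attention-infused residual block --------------------------------------

# conv -> ReLU -> scSE -> conv, plus an identity shortcut (1x1 projection
# when channel counts differ), ReLU after the addition, and a second scSE
# recalibrating the summed map.
nn_resblock_init <- function(cin, filters, kernel_size, scse_reduction = 2L) {
  proj <- if (cin != filters) nn_conv_init(1L, cin, filters) else NULL
  list(conv1 = nn_conv_init(kernel_size, cin, filters),
       se1 = nn_scse_init(filters, scse_reduction),
       conv2 = nn_conv_init(kernel_size, filters, filters),
       se2 = nn_scse_init(filters, scse_reduction),
       proj = proj)
}

# The whole block runs as a single compiled call per direction; the cache is
# the list the forward kernel returns.
nn_resblock_fwd <- function(x, p, dilation = 1L) {
  res <- cpp_resblock_fwd(x, p, as.integer(dilation))
  list(y = res$y, cache = res)
}

nn_resblock_bwd <- function(dy, p, cache, dilation = 1L) {
  res <- cpp_resblock_bwd(dy, p, cache, as.integer(dilation))
  if (!is.null(res$grad$proj)) {
    res$grad$proj$b <- drop(res$grad$proj$b)
  }
  res$grad$conv1$b <- drop(res$grad$conv1$b)
  res$grad$conv2$b <- drop(res$grad$conv2$b)
  list(grad = res$grad, dx = res$dx)
}

## ---- parameter-tree utilities ----------------------------------------------

nn_is_leaf <- function(x) !is.list(x)

# conv params carry scalar metadata (k, cin, cout) that must not be touched
# by the optimiser; only leaves named in .nn_weight_names are trainable.
.nn_weight_names <- c("W", "b", "W1", "b1", "W2", "b2", "v", "bv")

nn_map2 <- function(a, b, f) {
  if (is.null(a)) return(NULL)
  if (nn_is_leaf(a)) return(f(a, b))
  out <- lapply(seq_along(a), function(i) {
    nm <- names(a)[i]
    if (nn_is_leaf(a[[i]]) && !(nm %in% .nn_weight_names)) return(a[[i]])
    nn_map2(a[[i]], b[[i]], f)
  })
  names(out) <- names(a)
  out
}

# The optimiser works on a flattened view of the trainable leaves: the
# parameter tree is walked once at initialisation to record leaf paths and
# offsets, and every step is then three vectorised operations plus a scatter
# back into the tree.
nn_flat_spec <- function(p) {
  paths <- list()
  lens <- integer(0)
  rec <- function(node, path) {
    if (is.null(node)) return(invisible())
    if (nn_is_leaf(node)) {
      paths[[length(paths) + 1L]] <<- path
      lens[[length(lens) + 1L]] <<- length(node)
      return(invisible())
    }
    for (nm in names(node)) {
      child <- node[[nm]]
      if (nn_is_leaf(child) && !(nm %in% .nn_weight_names)) next
      rec(child, c(path, nm))
    }
  }
  rec(p, character())
  ends <- cumsum(lens)
  list(paths = paths, starts = ends - lens + 1L, ends = ends,
       total = if (length(ends)) ends[[length(ends)]] else 0L)
}

nn_flat_get <- function(p, spec) {
  out <- numeric(spec$total)
  for (i in seq_along(spec$paths)) {
    out[spec$starts[i]:spec$ends[i]] <- p[[spec$paths[[i]]]]
  }
  out
}

nn_flat_set <- function(p, spec, v) {
  for (i in seq_along(spec$paths)) {
    leaf <- p[[spec$paths[[i]]]]
    leaf[] <- v[spec$starts[i]:spec$ends[i]]
    p[[spec$paths[[i]]]] <- leaf
  }
  p
}

nn_adam_init <- function(p) {
  spec <- nn_flat_spec(p)
  list(spec = spec, m = numeric(spec$total), v = numeric(spec$total), t = 0L)
}

nn_adam_step <- function(p, g, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  st$t <- st$t + 1L
  gv <- nn_flat_get(g, st$spec)
  st$m <- beta1 * st$m + (1 - beta1) * gv
  st$v <- beta2 * st$v + (1 - beta2) * gv * gv
  step <- lr * (st$m / (1 - beta1^st$t)) /
    (sqrt(st$v / (1 - beta2^st$t)) + eps)
  list(p = nn_flat_set(p, st$spec, nn_flat_get(p, st$spec) - step), st = st)
}

## ---- heads and losses ------------------------------------------------------

nn_dense_init <- function(fin, fout) {
  list(W = nn_glorot(fin, fout, fin, fout), b = numeric(fout))
}

nn_softmax <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Class-weighted cross-entropy at the logits; returns loss and d(loss)/d(logits).
nn_wce_loss <- function(logits, onehot, weight) {
  p <- nn_softmax(logits)
  z <- which(onehot == 1)
  loss <- -weight * log(max(p[z], 1e-12))
  list(loss = loss, dlogits = weight * (p - onehot), prob = p)
}

nn_mse_loss <- function(yhat, y) {
  d <- yhat - y
  list(loss = mean(d^2), dy = 2 * d / length(d))
}

# Deterministic early stopping bookkeeping: returns TRUE when the loss has
# failed to improve (strictly) for `patience` consecutive epochs.
nn_early_stop <- function(val_losses, patience) {
  best <- which.min(val_losses)
  (length(val_losses) - best) >= patience
}
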