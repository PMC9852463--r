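#' Class activation map for one embedded trial
#'
#' The raw map at timestep `i` is the sum over convolutional units of the
#' pre-softmax head weight for the requested class times the unit's
#' activation at `i` (the activations entering global average pooling). The
#' normalized map rectifies the raw values and min-max scales them to
#' `[0, 1]` per trial; a degenerate (constant) rectified map normalizes to
#' all zeros.
#'
#' @param model a trained classification [skill_head][build_classifier()] or
#'   a fitted [skillnet()] (its classification head is used).
#' @param embedded an `embedded_sequence` (or bare `T x d_e` matrix).
#' @param class class label or index whose evidence is mapped.
#' @return An object of class `saliency_map` with `raw` and `norm` vectors
#'   of length `T`.
#' @export
compute_cam <- function(model, embedded, class) {
  if (inherits(model, "skillnet")) model <- model$heads$classification
  if (is.null(model) || !inherits(model, "skill_head")) {
    stop("compute_cam needs a classification head")
  }
  if (model$task != "classification") {
    stop("class activation maps are defined for classification models only")
  }
  z <- if (inherits(embedded, "embedded_sequence")) embedded$features else embedded
  tid <- if (inherits(embedded, "embedded_sequence")) embedded$trial_id else NA_character_
  ci <- if (is.character(class)) match(class, model$class_names) else as.integer(class)
  if (is.na(ci) || ci < 1L || ci > model$n_out) stop("unknown class: ", class)
  fw <- head_fwd(model$params, z, model$block_cfg$dilation)
  raw <- drop(fw$f %*% model$params$dense$W[, ci])
  structure(list(trial_id = tid,
                 class = if (is.character(class)) class else model$class_names[ci],
                 raw = raw, norm = normalize_cam(raw)),
            class = "saliency_map")
}

normalize_cam <- function(raw) {
  r <- pmax(raw, 0)
  rng <- max(r) - min(r)
  if (rng == 0) return(rep(0, length(r)))
  (r - min(r)) / rng
}

#' Resample a saliency map to a different temporal length
#'
#' Linear interpolation of the normalized values onto `target_length`
#' equally spaced timestamps; the identity when lengths already match. The
#' shipped networks preserve length (stride-1, same padding), so this is a
#' guard for strided variants and for overlaying maps on the original
#' frame-rate trajectory.
#'
#' @param map a [compute_cam()] result.
#' @param target_length desired number of timestamps (>= 1).
#' @return The map with `norm` (and `raw`) resampled.
#' @export
project_cam <- function(map, target_length) {
  stopifnot(inherits(map, "saliency_map"), target_length >= 1)
  n <- length(map$norm)
  if (n == target_length) return(map)
  at <- seq(1, n, length.out = target_length)
  map$norm <- stats::approx(seq_len(n), map$norm, xout = at)$y
  map$raw <- stats::approx(seq_len(n), map$raw, xout = at)$y
  map
}

#' Mask a dataset with per-trial saliency maps
#'
#' Multiplies every coordinate of each trial, timestep by timestep, with the
#' trial's normalized class-activation value (broadcast across the feature
#' columns), suppressing regions the classifier found uninformative.
#'
#' @param ds a [sequence_dataset()] (typically preprocessed to the model
#'   rate).
#' @param maps named list of [saliency_map][compute_cam()]s, one per trial,
#'   already projected to each trial's length.
#' @return The masked dataset.
#' @export
mask_inputs <- function(ds, maps) {
  stopifnot(inherits(ds, "sequence_dataset"))
  ds$trials <- lapply(ds$trials, function(tr) {
    m <- maps[[tr$trial_id]]
    if (is.null(m)) stop("no saliency map for trial ", tr$trial_id)
    v <- m$norm
    if (length(v) != nrow(tr$coords)) {
      stop("map length ", length(v), " does not match trial ", tr$trial_id,
           " (", nrow(tr$coords), " timesteps); project_cam() it first")
    }
    tr$coords <- tr$coords * v
    tr
  })
  ds
}

#' One-sided paired test for metric improvement
#'
#' Wilcoxon signed-rank test of `after` vs `before` with zero differences
#' dropped and the exact null distribution computed by convolution over the
#' (tie-averaged) ranks for up to 50 pairs, so tied magnitudes are handled
#' exactly; beyond that a normal approximation with tie correction is used.
#' `method = "sign"` gives the plain sign test instead. When every pair is
#' tied the test is degenerate and reports p = 1 with `all_ties = TRUE`.
#'
#' @param after,before paired metric values (e.g. per-fold accuracy).
#' @param alternative `"greater"` tests whether `after` exceeds `before`.
#' @param method `"signed_rank"` (default) or `"sign"`.
#' @return A list with `statistic`, `p_value`, `n_used`, `all_ties`.
#' @export
signed_rank_test <- function(after, before,
                             alternative = c("greater", "less"),
                             method = c("signed_rank", "sign")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(after) == length(before))
  d <- after - before
  if (alternative == "less") d <- -d
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                all_ties = TRUE, method = method))
  }
  if (method == "sign") {
    k <- sum(d > 0)
    p <- stats::binom.test(k, n, alternative = "greater")$p.value
    return(list(statistic = k, p_value = p, n_used = n, all_ties = FALSE,
                method = method))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 50L) {
    u <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
    coef <- 1
    for (ui in u) {
      ext <- c(coef, numeric(ui))
      ext[(ui + 1L):(ui + length(coef))] <-
        ext[(ui + 1L):(ui + length(coef))] + coef
      coef <- ext
    }
    w2 <- as.integer(round(2 * W))
    p <- sum(coef[(w2 + 1L):length(coef)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm(W - 0.5, mu, sqrt(sig2), lower.tail = FALSE)
  }
  list(statistic = W, p_value = min(1, p), n_used = n, all_ties = FALSE,
       method = method)
}

#' Statistical validation of class-activation saliency by masked retraining
#'
#' Runs one cross-validated training session on the raw inputs, computes
#' each trial's class activation map in the fold where it was held out,
#' masks the whole dataset with the normalized maps, retrains the pipeline
#' from scratch on the masked inputs with the identical fold plan and seeds,
#' and compares the per-fold metric before vs after masking with a one-sided
#' test of improvement. A significant result indicates the maps concentrate
#' on class-discriminative portions of the sequences.
#'
#' @param ds a raw labelled [sequence_dataset()].
#' @param plan a [make_folds()] plan (k >= 5 recommended; fewer folds leave
#'   the paired test underpowered and trigger a warning).
#' @param config a [skillnet_config()].
#' @param seed master seed shared by both pipeline runs.
#' @param metric per-fold metric to compare (`"accuracy"`).
#' @param class_source class whose map masks each trial: its `"true"` label
#'   (default) or the fold model's `"predicted"` class.
#' @param test `"signed_rank"` or `"sign"` (see [signed_rank_test()]).
#' @param maps optional named list of precomputed per-trial maps (bypasses
#'   the CAM computation; useful for control analyses such as all-ones
#'   masks).
#' @param alpha significance level for the reported decision.
#' @param before_cv optional precomputed baseline [run_cv()] on `ds` with
#'   the same `plan`, `config`, `seed`, one session, a classification task
#'   and `keep_models = TRUE`; avoids retraining the baseline when it
#'   already exists.
#' @return An object of class `masking_validation`: per-fold `before` and
#'   `after` values, the test result, the decision at `alpha`, and both
#'   [run_cv()] objects.
#' @export
validate_saliency <- function(ds, plan, config = skillnet_config(),
                              seed = 1L, metric = "accuracy",
                              class_source = c("true", "predicted"),
                              test = c("signed_rank", "sign"), maps = NULL,
                              alpha = 0.05, before_cv = NULL) {
  class_source <- match.arg(class_source)
  test <- match.arg(test)
  if (plan$k < 5L) {
    warning("fewer than 5 folds: the paired test is underpowered")
  }
  if (is.null(before_cv)) {
    before_cv <- run_cv(ds, plan, config = config, tasks = "classification",
                        sessions = 1L, seed = seed, keep_models = TRUE)
  } else if (is.null(before_cv$sessions[[1]]$models)) {
    stop("before_cv must be run with keep_models = TRUE")
  }
  pp <- preprocess_dataset(ds, config$target_fps)
  if (is.null(maps)) {
    maps <- trial_cams(before_cv, pp, class_source)
  }
  masked <- mask_inputs(pp, maps)
  after_cv <- run_cv(masked, plan, config = config, tasks = "classification",
                     sessions = 1L, seed = seed, keep_models = FALSE)
  before <- before_cv$sessions[[1]]$metrics$per_fold_accuracy
  after <- after_cv$sessions[[1]]$metrics$per_fold_accuracy
  tst <- signed_rank_test(after, before, "greater", method = test)
  structure(list(metric = metric, before = before, after = after,
                 test = tst, alpha = alpha,
                 decision = if (tst$p_value < alpha) "reject" else "fail-to-reject",
                 before_cv = before_cv, after_cv = after_cv),
            class = "masking_validation")
}

# CAM for every trial, computed in the fold where it was held out.
trial_cams <- function(cv, pp, class_source = "true") {
  session <- cv$sessions[[1]]
  if (is.null(session$models)) stop("run_cv must keep models for CAMs")
  rec <- session$records
  maps <- list()
  for (f in seq_len(cv$plan$k)) {
    fit <- session$models[[f]]
    ids <- cv$plan$folds[[f]]$test
    sub <- apply_normalization(subset_dataset(pp, ids), fit$stats)
    emb <- encode(fit$dae, sub)
    for (e in emb) {
      cl <- if (class_source == "true") {
        rec$true_class[rec$trial_id == e$trial_id][1]
      } else {
        rec$pred_class[rec$trial_id == e$trial_id][1]
      }
      maps[[e$trial_id]] <- compute_cam(fit, e, cl)
    }
  }
  maps
}

#' @export
print.masking_validation <- function(x, ...) {
  cat(sprintf("<masking_validation> per-fold %s, %d folds\n", x$metric,
              length(x$before)))
  cat(sprintf("  before %.3f +/- %.3f | after %.3f +/- %.3f\n",
              mean(x$before), stats::sd(x$before),
              mean(x$after), stats::sd(x$after)))
  cat(sprintf("  one-sided %s test: W = %s, p = %.4g -> %s at %.2f\n",
              x$test$method, format(x$test$statistic), x$test$p_value,
              x$decision, x$alpha))
  if (x$test$all_ties) cat("  note: all pairs tied\n")
  invisible(x)
}

#' Contrast of saliency inside vs outside planted struggle windows
#'
#' For synthetic datasets with ground-truth struggle windows: takes each
#' held-out trial of the target class, averages its normalized class
#' activation map inside and outside the planted windows, and tests the
#' paired difference (inside minus outside) one-sided. A correct saliency
#' method concentrates its mass on the planted windows.
#'
#' @param cv a [run_cv()] result with `keep_models = TRUE`.
#' @param ds the raw dataset the plan was built on.
#' @param truth the generator's ground truth (from [generate_dataset()]).
#' @param target_class class whose trials are examined (default `"fail"`,
#'   where struggle events concentrate).
#' @return A list with per-trial `inside`/`outside` means and the
#'   [signed_rank_test()] result.
#' @export
saliency_window_contrast <- function(cv, ds, truth, target_class = "fail") {
  pp <- preprocess_dataset(ds, cv$config$target_fps)
  maps <- trial_cams(cv, pp, "true")
  truth_by_id <- stats::setNames(truth, vapply(truth, `[[`, "", "trial_id"))
  inside <- outside <- numeric(0)
  ids <- character(0)
  for (tr in pp$trials) {
    if (is.na(tr$label) || tr$label != target_class) next
    tt <- truth_by_id[[tr$trial_id]]
    if (is.null(tt) || is.null(tt$windows)) next
    Tn <- nrow(tr$coords)
    w <- rep(FALSE, Tn)
    for (r in seq_len(nrow(tt$windows))) {
      i0 <- max(1L, floor(tt$windows[r, "start"] * tr$fps) + 1L)
      i1 <- min(Tn, ceiling(tt$windows[r, "end"] * tr$fps))
      if (i0 <= i1) w[i0:i1] <- TRUE
    }
    if (!any(w) || all(w)) next
    m <- maps[[tr$trial_id]]$norm
    ids <- c(ids, tr$trial_id)
    inside <- c(inside, mean(m[w]))
    outside <- c(outside, mean(m[!w]))
  }
  tst <- signed_rank_test(inside, outside, "greater")
  list(trial_id = ids, inside = inside, outside = outside, test = tst)
}
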