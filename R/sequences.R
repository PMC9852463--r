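#' Construct a single-trial tool-motion sequence
#'
#' A trial is the per-frame trace of the two instrument centroids (grasper
#' and scissors) extracted from task video: a `T x 4` matrix of pixel
#' coordinates with columns `grasper_x, grasper_y, scissors_x, scissors_y`,
#' plus a mask marking frames where the upstream detector produced no
#' coordinates (those rows are `NA` until [fill_gaps()] imputes them).
#'
#' @param trial_id,subject_id identifiers; `trial_id` must be unique within a
#'   dataset.
#' @param coords numeric matrix, one row per frame, one column per feature.
#' @param fps capture rate in frames per second.
#' @param missing_mask logical vector, `TRUE` where the frame had no
#'   detection. Defaults to rows of `coords` containing `NA`.
#' @param label skill class (e.g. `"pass"`/`"fail"`) or `NA` when unlabelled.
#' @param score continuous performance score or `NA`.
#' @return An object of class `trial_sequence`.
#' @export
trial_sequence <- function(trial_id, coords, fps = 30,
                           missing_mask = NULL, label = NA_character_,
                           score = NA_real_, subject_id = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) < 2L) stop("a trial needs at least two frames")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be a positive number")
  if (is.null(missing_mask)) missing_mask <- rowSums(is.na(coords)) > 0L
  if (length(missing_mask) != nrow(coords)) {
    stop("missing_mask length must equal the number of frames")
  }
  structure(list(trial_id = as.character(trial_id),
                 subject_id = as.character(subject_id),
                 fps = as.numeric(fps),
                 coords = coords,
                 missing_mask = as.logical(missing_mask),
                 label = label, score = as.numeric(score)),
            class = "trial_sequence")
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence %s> T=%d frames x D=%d features @ %g FPS",
              x$trial_id, nrow(x$coords), ncol(x$coords), x$fps))
  cat(sprintf(", %d missing", sum(x$missing_mask)))
  if (!is.na(x$label)) cat(sprintf(", label=%s", x$label))
  if (!is.na(x$score)) cat(sprintf(", score=%.1f", x$score))
  cat("\n")
  invisible(x)
}

#' Bundle trials into a dataset
#'
#' @param trials list of [trial_sequence()] objects with unique ids.
#' @param class_names ordered vector of admissible class labels; defaults to
#'   the sorted unique labels present.
#' @return An object of class `sequence_dataset`.
#' @export
sequence_dataset <- function(trials, class_names = NULL) {
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate trial_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels <- vapply(trials, function(t) as.character(t$label), character(1))
  if (is.null(class_names)) class_names <- sort(unique(labels[!is.na(labels)]))
  bad <- !is.na(labels) & !(labels %in% class_names)
  if (any(bad)) stop("labels outside class_names: ", paste(unique(labels[bad]), collapse = ", "))
  structure(list(trials = trials, class_names = class_names,
                 n_trials = length(trials)),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  labels <- dataset_labels(x)
  cat(sprintf("<sequence_dataset> N=%d trials, %d subjects\n", x$n_trials,
              length(unique(dataset_subjects(x)))))
  if (any(!is.na(labels))) {
    tab <- table(factor(labels, levels = x$class_names))
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.sequence_dataset <- function(x) x$n_trials

dataset_labels <- function(ds) {
  vapply(ds$trials, function(t) as.character(t$label), character(1))
}

dataset_subjects <- function(ds) {
  vapply(ds$trials, function(t) t$subject_id, character(1))
}

dataset_scores <- function(ds) {
  vapply(ds$trials, function(t) as.numeric(t$score), numeric(1))
}

dataset_ids <- function(ds) {
  vapply(ds$trials, function(t) t$trial_id, character(1))
}

#' Subset a dataset by trial ids
#'
#' @param ds a [sequence_dataset()].
#' @param ids trial ids to keep, in the requested order.
#' @return A [sequence_dataset()] with the selected trials.
#' @export
subset_dataset <- function(ds, ids) {
  keep <- match(ids, dataset_ids(ds))
  if (anyNA(keep)) stop("unknown trial ids requested")
  sequence_dataset(ds$trials[keep], class_names = ds$class_names)
}

## ---- readers / writers -----------------------------------------------------

.trial_header <- c("frame", "grasper_x", "grasper_y", "scissors_x", "scissors_y")

#' Read a dataset of trials from disk
#'
#' Reads a manifest (`trial_id,subject_id,file,label,score`) and one motion
#' file per trial. `csv` expects the per-trial header
#' `frame,grasper_x,grasper_y,scissors_x,scissors_y`; frames are sorted by
#' frame index and absent frame indices (gaps in the `frame` column) become
#' missing frames. `json` expects one object per trial with the same fields
#' as arrays. `jigsaws_txt` reads whitespace-delimited numeric kinematics,
#' one row per sample, and selects columns through `column_map`.
#'
#' @param manifest_path path to the manifest CSV; `file` entries are resolved
#'   relative to its directory.
#' @param format one of `"csv"`, `"json"`, `"jigsaws_txt"`.
#' @param column_map named integer vector mapping feature names to column
#'   indices (required for `jigsaws_txt`).
#' @param fps capture rate recorded on each trial.
#' @return A [sequence_dataset()].
#' @export
read_trials <- function(manifest_path, format = c("csv", "json", "jigsaws_txt"),
                        column_map = NULL, fps = 30) {
  format <- match.arg(format)
  if (!file.exists(manifest_path)) stop("cannot read manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(trial_id = "character",
                                        subject_id = "character"))
  if (anyDuplicated(man$trial_id)) stop("duplicate trial_id in manifest")
  base <- dirname(manifest_path)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    path <- file.path(base, man$file[i])
    if (!file.exists(path)) stop("cannot read trial file: ", path)
    coords <- switch(format,
      csv = read_trial_csv(path),
      json = read_trial_json(path),
      jigsaws_txt = read_trial_jigsaws(path, column_map))
    trial_sequence(man$trial_id[i], coords, fps = fps,
                   label = if ("label" %in% names(man)) man$label[i] else NA_character_,
                   score = if ("score" %in% names(man)) man$score[i] else NA_real_,
                   subject_id = man$subject_id[i])
  })
  sequence_dataset(trials)
}

read_trial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(.trial_header %in% names(d))) {
    stop("trial file ", path, " lacks columns ",
         paste(setdiff(.trial_header, names(d)), collapse = ", "))
  }
  d <- d[order(d$frame), , drop = FALSE]
  frames <- d$frame
  full <- seq(min(frames), max(frames))
  coords <- matrix(NA_real_, length(full), 4,
                   dimnames = list(NULL, .trial_header[-1]))
  coords[match(frames, full), ] <- as.matrix(d[, .trial_header[-1]])
  coords
}

read_trial_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(.trial_header %in% names(d))) {
    stop("trial file ", path, " lacks fields ",
         paste(setdiff(.trial_header, names(d)), collapse = ", "))
  }
  ord <- order(d$frame)
  frames <- d$frame[ord]
  full <- seq(min(frames), max(frames))
  coords <- matrix(NA_real_, length(full), 4,
                   dimnames = list(NULL, .trial_header[-1]))
  coords[match(frames, full), ] <-
    cbind(d$grasper_x, d$grasper_y, d$scissors_x, d$scissors_y)[ord, ]
  coords
}

read_trial_jigsaws <- function(path, column_map) {
  if (is.null(column_map) || is.null(names(column_map))) {
    stop("jigsaws_txt requires a named column_map")
  }
  d <- as.matrix(utils::read.table(path))
  if (max(column_map) > ncol(d)) stop("column_map exceeds columns in ", path)
  coords <- d[, column_map, drop = FALSE]
  colnames(coords) <- names(column_map)
  coords
}

#' Write a dataset as trial CSVs plus a manifest
#'
#' Inverse of [read_trials()] for the CSV format: writes one file per trial
#' (missing frames omitted, so a re-read reconstructs the missing mask) and a
#' manifest CSV. Coordinates are serialised at full precision.
#'
#' @param ds a [sequence_dataset()].
#' @param dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
write_trials <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(ds$n_trials)
  for (i in seq_len(ds$n_trials)) {
    tr <- ds$trials[[i]]
    files[i] <- paste0("trial_", tr$trial_id, ".csv")
    keep <- !tr$missing_mask
    d <- data.frame(frame = which(keep) - 1L, tr$coords[keep, , drop = FALSE])
    names(d) <- .trial_header
    utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(dir, files[i]), row.names = FALSE, quote = FALSE)
  }
  man <- data.frame(trial_id = dataset_ids(ds),
                    subject_id = dataset_subjects(ds),
                    file = files,
                    label = dataset_labels(ds),
                    score = dataset_scores(ds))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- preprocessing ---------------------------------------------------------

#' Impute detector drop-out frames
#'
#' Frames the tool detector missed are reconstructed from their temporal
#' neighbours: an isolated missing frame becomes the average of the preceding
#' and succeeding frames, a run of consecutive missing frames is filled by
#' linear interpolation between the flanking observed frames (the two-point
#' average is its special case), and missing frames at either boundary copy
#' the nearest observed frame. Observed coordinates are never altered and the
#' missing mask is preserved (it records provenance, not current state).
#'
#' @param seq a [trial_sequence()].
#' @return The trial with a complete coordinate matrix.
#' @export
fill_gaps <- function(seq) {
  stopifnot(inherits(seq, "trial_sequence"))
  miss <- seq$missing_mask | rowSums(is.na(seq$coords)) > 0L
  if (all(miss)) stop("all frames missing in trial ", seq$trial_id)
  if (!any(miss)) return(seq)
  Tn <- nrow(seq$coords)
  obs <- which(!miss)
  x <- seq$coords
  for (d in seq_len(ncol(x))) {
    x[miss, d] <- stats::approx(obs, x[obs, d], xout = which(miss),
                                method = "linear", rule = 2)$y
  }
  seq$coords <- x
  seq$missing_mask <- miss
  seq
}

#' Downsample a trial by stride sampling
#'
#' Keeps every `fps/target_fps`-th frame starting at frame 0, mirroring the
#' reduction of 30 FPS video traces to 1 FPS before model training. When the
#' rate ratio is not an integer the nearest frame index is taken.
#'
#' @param seq a [trial_sequence()].
#' @param target_fps desired rate; must not exceed `seq$fps`.
#' @return The downsampled trial with `fps` updated and the missing mask
#'   subsampled identically.
#' @export
downsample <- function(seq, target_fps) {
  stopifnot(inherits(seq, "trial_sequence"))
  if (!is.numeric(target_fps) || target_fps <= 0) {
    stop("target_fps must be positive")
  }
  if (target_fps > seq$fps) stop("target_fps exceeds the trial's fps")
  if (target_fps == seq$fps) return(seq)
  Tn <- nrow(seq$coords)
  step <- seq$fps / target_fps
  idx <- unique(pmin(Tn, round(seq.int(1, Tn, by = step))))
  seq$coords <- seq$coords[idx, , drop = FALSE]
  seq$missing_mask <- seq$missing_mask[idx]
  seq$fps <- target_fps
  seq
}

#' Preprocess every trial in a dataset
#'
#' Applies [fill_gaps()] then [downsample()] to each trial. Both operations
#' are idempotent, so a dataset already at the target rate passes through
#' unchanged.
#'
#' @param ds a [sequence_dataset()].
#' @param target_fps rate fed to the models (default 1 FPS).
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(ds, target_fps = 1) {
  ds$trials <- lapply(ds$trials, function(tr) {
    downsample(fill_gaps(tr), min(target_fps, tr$fps))
  })
  ds
}

## ---- normalization ---------------------------------------------------------

#' Fit per-feature min-max and score z-normalization statistics
#'
#' Coordinate features are later mapped to `[0, 1]` by the training-split
#' extrema and scores to zero mean / unit variance. Fit the statistics on the
#' training split of each cross-validation fold only, so no information from
#' test trials leaks into preprocessing (set `scope = "global"` to reproduce
#' a whole-dataset fit).
#'
#' @param train a [sequence_dataset()] (the training split).
#' @param scope `"fold_train"` (default) is a documentation-level marker; the
#'   statistics are always computed from `train` as given.
#' @return An object of class `normalization_stats`.
#' @export
fit_normalization <- function(train, scope = c("fold_train", "global")) {
  scope <- match.arg(scope)
  if (!inherits(train, "sequence_dataset") || train$n_trials == 0L) {
    stop("fit_normalization needs a non-empty training dataset")
  }
  all_coords <- do.call(rbind, lapply(train$trials, function(t) t$coords))
  if (anyNA(all_coords)) stop("fill gaps before fitting normalization")
  mins <- apply(all_coords, 2, min)
  maxs <- apply(all_coords, 2, max)
  scores <- dataset_scores(train)
  scores <- scores[!is.na(scores)]
  structure(list(feature_min = mins, feature_max = maxs,
                 score_mean = if (length(scores)) mean(scores) else NA_real_,
                 score_sd = if (length(scores) > 1L) stats::sd(scores) else NA_real_,
                 scope = scope),
            class = "normalization_stats")
}

#' Apply (or invert) normalization
#'
#' Features map to `(v - min) / (max - min)`; a degenerate feature with
#' `max == min` maps to 0. Scores map to `(s - mean) / sd`.
#'
#' @param ds a [sequence_dataset()].
#' @param stats a `normalization_stats` object from [fit_normalization()].
#' @return The transformed dataset.
#' @export
apply_normalization <- function(ds, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  rng <- stats$feature_max - stats$feature_min
  rng[rng == 0] <- Inf  # degenerate feature -> 0 everywhere
  ds$trials <- lapply(ds$trials, function(tr) {
    tr$coords <- sweep(sweep(tr$coords, 2, stats$feature_min, "-"), 2, rng, "/")
    if (!is.na(tr$score) && !is.na(stats$score_sd) && stats$score_sd > 0) {
      tr$score <- (tr$score - stats$score_mean) / stats$score_sd
    }
    tr
  })
  ds
}

#' @rdname apply_normalization
#' @export
invert_normalization <- function(ds, stats) {
  stopifnot(inherits(stats, "normalization_stats"))
  rng <- stats$feature_max - stats$feature_min
  ds$trials <- lapply(ds$trials, function(tr) {
    tr$coords <- sweep(sweep(tr$coords, 2, rng, "*"), 2, stats$feature_min, "+")
    if (!is.na(tr$score) && !is.na(stats$score_sd) && stats$score_sd > 0) {
      tr$score <- tr$score * stats$score_sd + stats$score_mean
    }
    tr
  })
  ds
}

denormalize_score <- function(score, stats) {
  if (is.na(stats$score_sd) || stats$score_sd == 0) return(score)
  score * stats$score_sd + stats$score_mean
}

## ---- targets ---------------------------------------------------------------

#' One-hot labels and balanced class weights
#'
#' Builds the one-hot label matrix in `class_names` order and inverse
#' frequency class weights `N / (n_classes * N_c)`, so a balanced dataset
#' gets unit weights and minority classes are up-weighted.
#'
#' @param ds a fully labelled [sequence_dataset()].
#' @return A list with `onehot` (N x n_classes matrix, rows named by trial)
#'   and `class_weights` (named numeric).
#' @export
encode_targets <- function(ds) {
  labels <- dataset_labels(ds)
  if (anyNA(labels)) stop("encode_targets requires every trial to be labelled")
  classes <- ds$class_names
  if (length(unique(labels)) < 2L) {
    stop("encode_targets needs at least two classes present")
  }
  onehot <- outer(labels, classes, "==") * 1
  dimnames(onehot) <- list(dataset_ids(ds), classes)
  counts <- colSums(onehot)
  weights <- ds$n_trials / (length(classes) * counts)
  names(weights) <- classes
  list(onehot = onehot, class_weights = weights)
}
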