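# Shared fixtures, built in code. The "tiny" generator keeps durations and
# window lengths short so unit tests that train networks stay fast; score
# weights are rescaled so the pass cut-off stays attainable at those
# durations.

tiny_generator <- function(seed = 1L, n_subjects = 4L, trials_per_subject = 5L,
                           ...) {
  generator_config(n_subjects = n_subjects,
                   trials_per_subject = trials_per_subject,
                   pass_duration = c(15, 30), fail_duration = c(45, 75),
                   duration_sd = 3, struggle_len = c(2, 5),
                   score_duration_weight = 2, seed = seed, ...)
}

tiny_net_config <- function(...) {
  skillnet_config(dae = dae_config(filters = 8L, kernel_size = 3L, d_e = 4L,
                                   max_epochs = 5L, patience = 4L),
                  block = resblock_config(filters = 8L, kernel_size = 3L),
                  clf_max_epochs = 8L, clf_patience = 8L, ...)
}

# a hand-sized trial: coords given row-wise
make_trial <- function(coords, id = "t1", fps = 30, ...) {
  trial_sequence(id, do.call(rbind, coords), fps = fps, ...)
}

# random prediction records over two classes
random_records <- function(n, p_correct = 0.8, classes = c("pass", "fail")) {
  true_class <- sample(classes, n, replace = TRUE)
  correct <- stats::runif(n) < p_correct
  pred_class <- ifelse(correct, true_class,
                       vapply(true_class, function(z) setdiff(classes, z)[1], ""))
  data.frame(trial_id = paste0("t", seq_len(n)),
             true_class = true_class, pred_class = pred_class,
             confidence = stats::runif(n, 0.5, 1))
}

# labelled toy dataset of constant-ish sequences, for fold-planning tests
toy_dataset <- function(n_subjects = 3L, reps = 4L, labels = NULL, fps = 2) {
  k <- 0L
  trials <- list()
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      coords <- matrix(stats::rnorm(8 * 4, mean = 100), 8, 4)
      lab <- if (is.null(labels)) c("pass", "fail")[1 + (k %% 2)] else labels[k]
      trials[[k]] <- trial_sequence(sprintf("S%d_T%d", s, r), coords,
                                    fps = fps, label = lab,
                                    score = 100 + k,
                                    subject_id = sprintf("S%d", s))
    }
  }
  sequence_dataset(trials, class_names = c("pass", "fail"))
}

# embedded toy sequences whose class is linearly separable from the feature
# mean, for head-training tests
separable_embeddings <- function(n = 30, Tn = 20, d = 4, seed = 0) {
  set.seed(seed)
  lab <- rep(c("pass", "fail"), length.out = n)
  x <- lapply(seq_len(n), function(i) {
    mu <- if (lab[i] == "pass") 0.25 else 0.75
    structure(list(trial_id = paste0("e", i),
                   features = matrix(stats::rnorm(Tn * d, mu, 0.1), Tn, d)),
              class = "embedded_sequence")
  })
  list(x = x, labels = lab)
}
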