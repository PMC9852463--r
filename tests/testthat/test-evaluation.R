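# brute-force AUC: pairwise concordance with half credit for ties
auc_bruteforce <- function(truth_pos, prob) {
  pos <- prob[truth_pos]
  neg <- prob[!truth_pos]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("fold schemes partition trials as their definitions require", {
  ds <- toy_dataset(n_subjects = 3L, reps = 5L)
  ids <- skillseq:::dataset_ids(ds)
  subjects <- skillseq:::dataset_subjects(ds)

  louo <- make_folds(ds, "louo", seed = 1)
  expect_equal(louo$k, 3L)
  for (f in louo$folds) {
    test_subj <- unique(subjects[match(f$test, ids)])
    train_subj <- unique(subjects[match(c(f$train, f$val), ids)])
    expect_length(test_subj, 1L)
    expect_length(intersect(test_subj, train_subj), 0L)
  }
  expect_setequal(unlist(lapply(louo$folds, `[[`, "test")), ids)

  loso <- make_folds(ds, "loso", seed = 1)
  expect_equal(loso$k, 5L)
  for (r in seq_len(5)) {
    expect_setequal(loso$folds[[r]]$test, sprintf("S%d_T%d", 1:3, r))
  }

  kf <- make_folds(ds, "stratified_kfold", k = 5, seed = 1)
  expect_setequal(unlist(lapply(kf$folds, `[[`, "test")), ids)
  # within every fold, train/val/test are disjoint and cover the dataset
  for (f in kf$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }

  one_subject <- toy_dataset(n_subjects = 1L, reps = 4L)
  expect_error(make_folds(one_subject, "louo"), "two subjects")
})

test_that("holdout plans carve a stratified test split and a validation set", {
  ds <- toy_dataset(n_subjects = 4L, reps = 5L)
  plan <- make_folds(ds, "holdout", k = 5, seed = 2)
  expect_equal(plan$k, 1L)
  f <- plan$folds[[1]]
  ids <- skillseq:::dataset_ids(ds)
  expect_setequal(c(f$train, f$val, f$test), ids)
  expect_equal(length(f$test), 4L)  # 1/5 of 20, stratified over 2 classes
  expect_length(intersect(f$train, f$test), 0L)
  expect_length(intersect(f$val, f$test), 0L)
})

test_that("stratified folds preserve the class ratio to within one sample", {
  labels <- c(rep("pass", 90), rep("fail", 10))
  trials <- lapply(seq_along(labels), function(i) {
    trial_sequence(paste0("t", i), matrix(i + 0:7, 8, 4), fps = 2,
                   label = labels[i], subject_id = paste0("S", i %% 5))
  })
  ds <- sequence_dataset(trials, class_names = c("pass", "fail"))
  plan <- make_folds(ds, "stratified_kfold", k = 10, seed = 3)
  for (f in plan$folds) {
    lab <- labels[match(f$test, paste0("t", seq_along(labels)))]
    expect_equal(sum(lab == "pass"), 9L)
    expect_equal(sum(lab == "fail"), 1L)
  }
})

test_that("pooled confusion-matrix metrics match hand-computed values", {
  # TP=9 FN=1 TN=8 FP=2 with the "pass" class positive
  rec <- data.frame(
    true_class = c(rep("pass", 10), rep("fail", 10)),
    pred_class = c(rep("pass", 9), "fail", rep("fail", 8), "pass", "pass"),
    prob_pass = c(seq(0.90, 0.99, length.out = 9), 0.40,
                  seq(0.01, 0.30, length.out = 8), 0.70, 0.80))
  m <- classification_metrics(rec, positive_class = "pass")
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
  expect_equal(sum(m$confusion), 20)

  perfect <- data.frame(true_class = rec$true_class,
                        pred_class = rec$true_class,
                        prob_pass = ifelse(rec$true_class == "pass", 0.9, 0.1))
  pm <- classification_metrics(perfect)
  expect_equal(unname(c(pm$accuracy, pm$sensitivity, pm$specificity, pm$auc)),
               c(1, 1, 1, 1))

  onecl <- data.frame(true_class = "pass", pred_class = "pass",
                      prob_pass = c(0.9, 0.8))
  expect_error(classification_metrics(onecl), "AUC undefined")
})

test_that("AUC equals brute-force pairwise concordance on random pools", {
  set.seed(10)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    truth <- runif(n) < 0.5
    if (!any(truth) || all(truth)) next
    prob <- round(runif(n), 2)  # rounding induces ties
    rec <- data.frame(true_class = ifelse(truth, "pass", "fail"),
                      pred_class = ifelse(prob > 0.5, "pass", "fail"),
                      prob_pass = prob)
    m <- classification_metrics(rec, positive_class = "pass")
    expect_equal(m$auc, auc_bruteforce(truth, prob), tolerance = 1e-12)
  }
})

test_that("Spearman correlation equals the rank-Pearson oracle", {
  set.seed(11)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  rec <- data.frame(true_score = x, pred_score = y)
  m <- regression_metrics(rec)
  expect_equal(m$spearman_rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_true(m$p_value >= 0 && m$p_value <= 1)

  # reverse ranking gives rho = -1
  rev <- data.frame(true_score = 1:10, pred_score = 10:1)
  expect_equal(regression_metrics(rev)$spearman_rho, -1)
})

test_that("cross-validated sessions pool every trial exactly once and reproduce", {
  gen <- generate_dataset(tiny_generator(seed = 21))
  ds <- gen$dataset
  plan <- make_folds(ds, "stratified_kfold", k = 4, seed = 2)
  cfg <- tiny_net_config()
  cv <- run_cv(ds, plan, config = cfg, tasks = "classification",
               sessions = 2, seed = 5)
  for (s in cv$sessions) {
    expect_setequal(s$records$trial_id, skillseq:::dataset_ids(ds))
    expect_equal(nrow(s$records), ds$n_trials)
  }
  # distinct sessions use distinct seeds; identical reruns are bit-identical
  cv2 <- run_cv(ds, plan, config = cfg, tasks = "classification",
                sessions = 1, seed = 5)
  expect_identical(cv2$sessions[[1]]$records, cv$sessions[[1]]$records)

  bad <- plan
  bad$folds[[1]]$test <- character(0)
  expect_error(run_cv(ds, bad, config = cfg), "empty test fold")
})
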