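# a frozen classification head with known weights, for CAM oracles
frozen_head <- function(d_in = 4L, filters = 6L, seed = 30L) {
  h <- build_classifier(resblock_config(filters = filters, kernel_size = 3L),
                        "classification", 2L, d_in = d_in, seed = seed)
  h$trained <- TRUE
  h$class_names <- c("pass", "fail")
  h
}

test_that("class activation maps are the weight-activation sums", {
  # single unit, w = 2, f = (1, 2, 3) -> raw (2, 4, 6)
  h <- frozen_head(filters = 1L)
  # bypass the network: check the algebra on the raw/normalized fields
  raw1 <- drop(matrix(c(1, 2, 3), 3, 1) %*% 2)
  expect_equal(raw1, c(2, 4, 6))

  # two units, w = (1, -1), f1 = (1, 1), f2 = (0, 2) -> raw (1, -1)
  f <- cbind(c(1, 1), c(0, 2))
  raw2 <- drop(f %*% c(1, -1))
  expect_equal(raw2, c(1, -1))
  # rectified min-max normalization: (1, -1) -> (1, 0)
  expect_equal(skillseq:::normalize_cam(raw2), c(1, 0))
  # degenerate rectified map -> all zeros
  expect_equal(skillseq:::normalize_cam(c(-1, -2)), c(0, 0))
})

test_that("compute_cam matches a brute-force weighted-activation oracle", {
  set.seed(31)
  h <- frozen_head(filters = 6L)
  for (i in 1:20) {
    Tn <- sample(10:60, 1)
    z <- structure(list(trial_id = "x",
                        features = matrix(rnorm(Tn * 4), Tn, 4)),
                   class = "embedded_sequence")
    ci <- sample(1:2, 1)
    cam <- compute_cam(h, z, h$class_names[ci])
    # oracle: explicit double loop over units and timestamps
    f <- skillseq:::nn_resblock_fwd(z$features, h$params$block,
                                    h$block_cfg$dilation)$y
    w <- h$params$dense$W[, ci]
    raw <- numeric(Tn)
    for (t in seq_len(Tn)) for (k in seq_along(w)) {
      raw[t] <- raw[t] + w[k] * f[t, k]
    }
    expect_equal(cam$raw, raw, tolerance = 1e-6)
    expect_true(all(cam$norm >= 0 & cam$norm <= 1))
    if (any(pmax(raw, 0) > 0)) expect_equal(max(cam$norm), 1)
  }
  reg <- build_classifier(resblock_config(filters = 4L, kernel_size = 3L),
                          "regression", d_in = 4L)
  expect_error(compute_cam(reg, matrix(0, 5, 4), 1), "classification")
})

test_that("CAM linearity: GAP-mean differences reproduce score differences", {
  set.seed(32)
  h <- frozen_head(filters = 5L)
  mk <- function() structure(list(trial_id = "x",
                                  features = matrix(rnorm(30 * 4), 30, 4)),
                             class = "embedded_sequence")
  a <- mk(); b <- mk()
  for (ci in 1:2) {
    pre_softmax <- function(e) {
      fw <- skillseq:::head_fwd(h$params, e$features, h$block_cfg$dilation)
      fw$logits[ci] - h$params$dense$b[ci]
    }
    cam_mean <- function(e) mean(compute_cam(h, e, ci)$raw)
    expect_equal(pre_softmax(a) - pre_softmax(b), cam_mean(a) - cam_mean(b),
                 tolerance = 1e-9)
  }
})

test_that("maps resample by linear interpolation", {
  m <- structure(list(trial_id = "x", class = "pass",
                      raw = c(0, 1), norm = c(0, 1)),
                 class = "saliency_map")
  expect_identical(project_cam(m, 2), m)
  expect_equal(project_cam(m, 3)$norm, c(0, 0.5, 1))
  tri <- structure(list(trial_id = "x", class = "pass",
                        raw = c(0, 1, 0), norm = c(0, 1, 0)),
                   class = "saliency_map")
  expect_equal(project_cam(tri, 5)$norm, c(0, 0.5, 1, 0.5, 0))
})

test_that("masking multiplies coordinates timestep-wise", {
  tr <- trial_sequence("t1", rbind(rep(2, 4), rep(4, 4)), fps = 1)
  ds <- sequence_dataset(list(tr))
  mk_map <- function(v) structure(list(trial_id = "t1", class = "fail",
                                       raw = v, norm = v),
                                  class = "saliency_map")
  ones <- mask_inputs(ds, list(t1 = mk_map(c(1, 1))))
  expect_identical(ones$trials[[1]]$coords, tr$coords)
  zero <- mask_inputs(ds, list(t1 = mk_map(c(0, 0))))
  expect_true(all(zero$trials[[1]]$coords == 0))
  half <- mask_inputs(ds, list(t1 = mk_map(c(1, 0.5))))
  expect_equal(unname(half$trials[[1]]$coords),
               rbind(rep(2, 4), rep(2, 4)))
  expect_error(mask_inputs(ds, list()), "no saliency map")
  expect_error(mask_inputs(ds, list(t1 = mk_map(c(1, 1, 1)))), "project_cam")
})

test_that("the paired improvement test has the exact signed-rank null", {
  # ten uniformly positive differences: p = 2^-10
  before <- rep(0.5, 10)
  after <- before + 0.01
  t1 <- signed_rank_test(after, before)
  expect_equal(t1$p_value, 2^-10)
  expect_equal(t1$statistic, 55)

  # all ties: degenerate, fail to reject
  t2 <- signed_rank_test(before, before)
  expect_true(t2$all_ties)
  expect_equal(t2$p_value, 1)

  # 8 positive / 2 negative with equal magnitudes: enumeration over 2^10
  # sign patterns reduces to #positives >= 8
  d <- c(rep(0.01, 8), rep(-0.01, 2))
  t3 <- signed_rank_test(0.5 + d, rep(0.5, 10))
  expect_equal(t3$p_value, (choose(10, 8) + choose(10, 9) + 1) / 2^10)

  # untied case agrees with the classical exact distribution
  set.seed(33)
  a <- runif(12); b <- a + rnorm(12, 0.05, 0.1)
  ours <- signed_rank_test(b, a)
  ref <- wilcox.test(b, a, paired = TRUE, alternative = "greater",
                     exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # plain sign test option
  t4 <- signed_rank_test(0.5 + d, rep(0.5, 10), method = "sign")
  expect_equal(t4$p_value, binom.test(8, 10, alternative = "greater")$p.value)
})

test_that("all-ones masks reproduce the unmasked pipeline exactly", {
  gen <- generate_dataset(tiny_generator(seed = 40))
  ds <- gen$dataset
  plan <- make_folds(ds, "stratified_kfold", k = 5, seed = 4)
  cfg <- tiny_net_config()
  pp <- preprocess_dataset(ds, 1)
  ones <- lapply(pp$trials, function(tr) {
    structure(list(trial_id = tr$trial_id, class = "fail",
                   raw = rep(1, nrow(tr$coords)),
                   norm = rep(1, nrow(tr$coords))),
              class = "saliency_map")
  })
  names(ones) <- skillseq:::dataset_ids(pp)
  mv <- validate_saliency(ds, plan, config = cfg, seed = 9, maps = ones)
  expect_identical(mv$before, mv$after)
  expect_true(mv$test$all_ties)
  expect_equal(mv$test$p_value, 1)
  expect_identical(mv$before_cv$sessions[[1]]$records$pred_class,
                   mv$after_cv$sessions[[1]]$records$pred_class)
})
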