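test_that("gap filling averages neighbours, interpolates runs, copies edges", {
  # isolated gap: mean of flanking frames
  tr <- make_trial(list(c(10, 20, 30, 40), rep(NA_real_, 4), c(14, 24, 34, 44)))
  filled <- fill_gaps(tr)
  expect_identical(filled$coords[2, ], c(12, 22, 32, 42))
  expect_identical(filled$coords[c(1, 3), ], tr$coords[c(1, 3), ])

  # run of two missing frames: linear interpolation between flanks
  tr2 <- make_trial(list(rep(10, 4), rep(NA_real_, 4), rep(NA_real_, 4),
                         rep(40, 4)))
  expect_equal(unname(fill_gaps(tr2)$coords[, 1]), c(10, 20, 30, 40))

  # boundary gap copies the nearest observed frame
  tr3 <- make_trial(list(rep(NA_real_, 4), rep(5, 4), rep(7, 4)))
  expect_equal(unname(fill_gaps(tr3)$coords[1, ]), rep(5, 4))

  # all-missing trial is rejected
  tr4 <- make_trial(list(rep(NA_real_, 4), rep(NA_real_, 4)))
  expect_error(fill_gaps(tr4), "all frames missing")
})

test_that("gap filling is idempotent and never touches observed frames", {
  set.seed(7)
  coords <- matrix(rnorm(40 * 4, 100, 20), 40, 4)
  miss <- c(1, 5, 6, 7, 22, 40)
  coords[miss, ] <- NA
  tr <- trial_sequence("x", coords, fps = 30)
  f1 <- fill_gaps(tr)
  f2 <- fill_gaps(f1)
  expect_identical(f1$coords, f2$coords)
  expect_identical(f1$coords[-miss, ], coords[-miss, ])
  expect_identical(f1$missing_mask, seq_len(40) %in% miss)
})

test_that("downsampling keeps every k-th frame from index zero", {
  coords <- matrix(as.numeric(seq_len(300 * 4)), 300, 4)
  tr <- trial_sequence("x", coords, fps = 30)
  d <- downsample(tr, 1)
  expect_equal(nrow(d$coords), 10)
  expect_identical(d$coords, coords[seq(1, 271, by = 30), ])
  expect_equal(d$fps, 1)

  # identity at equal rates
  expect_identical(downsample(tr, 30), tr)

  # T = 305 picks indices 0, 30, ..., 300 -> 11 frames
  tr305 <- trial_sequence("y", matrix(1, 305, 4), fps = 30)
  expect_equal(nrow(downsample(tr305, 1)$coords), 11)

  expect_error(downsample(tr, 0), "positive")
  expect_error(downsample(tr, 60), "exceeds")
})

test_that("downsampling composes: two stage reductions equal one", {
  set.seed(1)
  tr <- trial_sequence("x", matrix(rnorm(360 * 4), 360, 4), fps = 30)
  two_step <- downsample(downsample(tr, 6), 2)
  one_step <- downsample(tr, 2)
  expect_identical(two_step$coords, one_step$coords)
})

test_that("normalization maps features to [0,1] and scores to z-scale", {
  trials <- list(
    trial_sequence("a", matrix(c(0, 5, 10), 3, 4), fps = 1, score = 1,
                   label = "pass"),
    trial_sequence("b", matrix(c(0, 5, 10), 3, 4), fps = 1, score = 2,
                   label = "fail"),
    trial_sequence("c", matrix(c(0, 5, 10), 3, 4), fps = 1, score = 3,
                   label = "pass"))
  ds <- sequence_dataset(trials)
  st <- fit_normalization(ds)
  out <- apply_normalization(ds, st)
  expect_equal(unname(out$trials[[1]]$coords[, 1]), c(0, 0.5, 1))
  sc <- vapply(out$trials, function(t) t$score, numeric(1))
  expect_equal(mean(sc), 0)
  expect_equal(sd(sc), 1)

  # constant feature maps to zero
  cds <- sequence_dataset(list(trial_sequence("k", matrix(7, 2, 4), fps = 1)))
  cst <- fit_normalization(cds)
  expect_true(all(apply_normalization(cds, cst)$trials[[1]]$coords == 0))

  expect_error(fit_normalization(sequence_dataset(list())), "non-empty")
})

test_that("normalization round-trips within 1e-9 when ranges are non-degenerate", {
  set.seed(3)
  trials <- lapply(1:4, function(i) {
    trial_sequence(paste0("t", i), matrix(runif(20 * 4, 0, 640), 20, 4),
                   fps = 1, score = rnorm(1, 100, 25))
  })
  ds <- sequence_dataset(trials)
  st <- fit_normalization(ds)
  back <- invert_normalization(apply_normalization(ds, st), st)
  for (i in 1:4) {
    expect_equal(back$trials[[i]]$coords, ds$trials[[i]]$coords,
                 tolerance = 1e-9)
    expect_equal(back$trials[[i]]$score, ds$trials[[i]]$score,
                 tolerance = 1e-9)
  }
})

test_that("target encoding one-hots labels and balances class weights", {
  labels <- c(rep("pass", 90), rep("fail", 10))
  trials <- lapply(seq_along(labels), function(i) {
    trial_sequence(paste0("t", i), matrix(i, 2, 4), fps = 1, label = labels[i])
  })
  ds <- sequence_dataset(trials, class_names = c("pass", "fail"))
  tgt <- encode_targets(ds)
  expect_true(all(rowSums(tgt$onehot) == 1))
  expect_identical(unname(tgt$onehot[1, ]), c(1, 0))
  expect_identical(unname(tgt$onehot[100, ]), c(0, 1))
  expect_equal(unname(tgt$class_weights["pass"]), 100 / (2 * 90))
  expect_equal(unname(tgt$class_weights["fail"]), 5)

  ds1 <- sequence_dataset(trials[1:5], class_names = "pass")
  expect_error(encode_targets(ds1), "two classes")
})

test_that("CSV round-trip reproduces coordinates bit-identically", {
  set.seed(11)
  trials <- lapply(1:3, function(i) {
    coords <- matrix(runif(50 * 4, 0, 640), 50, 4)
    coords[c(4, 17, 18, 31), ] <- NA  # interior detector drop-outs
    trial_sequence(paste0("t", i), coords, fps = 30,
                   label = c("pass", "fail", "pass")[i],
                   score = rnorm(1, 100, 10), subject_id = "S1")
  })
  src <- sequence_dataset(trials)
  dir <- withr::local_tempdir()
  manifest <- write_trials(src, dir)
  back <- read_trials(manifest, format = "csv", fps = 30)
  expect_equal(back$n_trials, src$n_trials)
  for (i in seq_len(back$n_trials)) {
    a <- src$trials[[i]]
    b <- back$trials[[match(a$trial_id, sapply(back$trials, `[[`, "trial_id"))]]
    keep <- !a$missing_mask
    # interior missing frames come back as missing; observed rows bit-equal
    expect_identical(unname(b$coords[keep, ]), unname(a$coords[keep, ]))
    expect_identical(b$missing_mask, a$missing_mask)
    expect_equal(b$score, a$score)
    expect_identical(b$label, a$label)
  }
})

test_that("reader marks absent frame rows as missing and validates input", {
  dir <- withr::local_tempdir()
  writeLines(c("frame,grasper_x,grasper_y,scissors_x,scissors_y",
               "0,1,2,3,4", "1,5,6,7,8", "3,9,10,11,12"),
             file.path(dir, "trial_A.csv"))
  writeLines(c("trial_id,subject_id,file,label,score",
               "A,S1,trial_A.csv,pass,100"),
             file.path(dir, "manifest.csv"))
  ds <- read_trials(file.path(dir, "manifest.csv"), "csv")
  expect_equal(ds$n_trials, 1)
  expect_identical(ds$trials[[1]]$missing_mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(read_trials(file.path(dir, "nope.csv"), "csv"), "manifest")

  writeLines(c("trial_id,subject_id,file,label,score",
               "A,S1,trial_A.csv,pass,100", "A,S1,trial_A.csv,pass,100"),
             file.path(dir, "dup.csv"))
  expect_error(read_trials(file.path(dir, "dup.csv"), "csv"), "duplicate")
})

test_that("JSON trials load with gaps reconstructed from frame indices", {
  dir <- withr::local_tempdir()
  jsonlite::write_json(
    list(frame = c(0, 1, 3), grasper_x = c(1, 5, 9),
         grasper_y = c(2, 6, 10), scissors_x = c(3, 7, 11),
         scissors_y = c(4, 8, 12)),
    file.path(dir, "trial_J.json"))
  writeLines(c("trial_id,subject_id,file,label,score",
               "J,S1,trial_J.json,fail,55"),
             file.path(dir, "manifest.csv"))
  ds <- read_trials(file.path(dir, "manifest.csv"), "json")
  tr <- ds$trials[[1]]
  expect_identical(tr$missing_mask, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(unname(tr$coords[4, ]), c(9, 10, 11, 12))
  expect_identical(tr$label, "fail")
})

test_that("whitespace-delimited kinematics load through a column map", {
  dir <- withr::local_tempdir()
  set.seed(5)
  mat <- matrix(rnorm(10 * 76), 10, 76)
  write.table(mat, file.path(dir, "kin.txt"), row.names = FALSE,
              col.names = FALSE)
  writeLines(c("trial_id,subject_id,file", "K1,S1,kin.txt"),
             file.path(dir, "manifest.csv"))
  ds <- read_trials(file.path(dir, "manifest.csv"), "jigsaws_txt",
                    column_map = c(tool1_x = 1L, tool1_y = 2L,
                                   tool2_x = 39L, tool2_y = 40L))
  expect_equal(dim(ds$trials[[1]]$coords), c(10L, 4L))
  expect_equal(unname(ds$trials[[1]]$coords[, 3]), mat[, 39],
               tolerance = 1e-6)
  expect_error(read_trials(file.path(dir, "manifest.csv"), "jigsaws_txt"),
               "column_map")
})
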