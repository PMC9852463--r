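#' Configuration for the synthetic pattern-cutting trial generator
#'
#' Emulates 30 FPS bimanual instrument-centroid traces in a 640 x 480 video
#' frame for a circle-cutting task: the scissors travel a smoothed circular
#' arc (radius 100 px around the frame centre) whose angular speed is set by
#' the trial duration, while the grasper holds traction near a gauze corner
#' with occasional repositioning jumps. Lower skill lengthens the trial,
#' raises path jitter and triggers more "struggle" events - short windows of
#' high-frequency jitter and local back-tracking that are recorded as
#' ground-truth salient regions. A transparent surrogate score, linear in
#' duration and struggle-event count, stands in for the proprietary
#' certification score (it is a surrogate, not the certification formula);
#' the pass/fail label is the score against a declared cut-off.
#'
#' Durations, jitter and event rates follow the class-anchored values
#' above: a logistic transition in skill (centre `transition_center`, width
#' `transition_width`) switches between the fail-regime and pass-regime
#' parameters, so clearly skilled and clearly struggling subjects produce
#' trials squarely inside the respective parameter ranges while the few
#' borderline subjects produce genuinely borderline trials. The mapping is
#' strictly monotone in skill. The transition is a property of the task;
#' the cohort's skill distribution is independent of it, so skewing the
#' Beta shapes moves the class ratio.
#'
#' @param n_subjects,trials_per_subject cohort size.
#' @param fps capture rate (frames/second).
#' @param frame_size video frame in pixels, `c(width, height)`.
#' @param pass_duration,fail_duration duration anchors in seconds for skill 1
#'   and skill 0; a trial's expected duration interpolates between the range
#'   midpoints and is then jittered by `duration_sd`.
#' @param duration_sd standard deviation of the per-trial duration draw (s).
#' @param struggle_rate_pass,struggle_rate_fail Poisson means of the number
#'   of struggle events at skill 1 and skill 0.
#' @param struggle_len struggle window length range in seconds (uniform).
#' @param jitter_sd_pass,jitter_sd_fail Gaussian path jitter (px) at skill 1
#'   and skill 0.
#' @param struggle_jitter_sd extra jitter inside struggle windows (px).
#' @param missing_prob i.i.d. probability a frame has no detection.
#' @param score_base,score_duration_weight,score_event_weight,score_noise_sd
#'   surrogate score model: `base - w_d * duration_s - w_e * events + noise`.
#' @param pass_cutoff score at or above which a trial is labelled `"pass"`.
#' @param skill_shape1,skill_shape2 Beta parameters of the per-subject skill
#'   distribution; the U-shaped default reflects a certification cohort of
#'   mostly clear passes and clear fails with few borderline trainees, and
#'   its median sits at the skill level whose expected score equals the
#'   cut-off, so the default class ratio is balanced. Skew them to study
#'   imbalance.
#' @param trial_skill_sd within-subject variability of skill across trials.
#' @param transition_center,transition_width centre and width (in skill
#'   units) of the logistic switch between the fail-regime and pass-regime
#'   parameter anchors. The default centre is calibrated so that, under the
#'   default score model, the skill at which a trial's expected score
#'   crosses the pass cut-off coincides with the default cohort's median
#'   skill - making the default class ratio balanced.
#' @param seed integer seed making generation fully reproducible.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 12L, trials_per_subject = 25L,
                             fps = 30, frame_size = c(640, 480),
                             pass_duration = c(60, 120),
                             fail_duration = c(180, 300),
                             duration_sd = 12,
                             struggle_rate_pass = 0.5, struggle_rate_fail = 4,
                             struggle_len = c(5, 15),
                             jitter_sd_pass = 3, jitter_sd_fail = 15,
                             struggle_jitter_sd = 25,
                             missing_prob = 0.01,
                             score_base = 200, score_duration_weight = 0.5,
                             score_event_weight = 10, score_noise_sd = 5,
                             pass_cutoff = 70,
                             skill_shape1 = 0.6, skill_shape2 = 0.8,
                             trial_skill_sd = 0.05,
                             transition_center = 0.447,
                             transition_width = 0.06,
                             seed = 0L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, fps > 0,
            all(pass_duration > 0), all(fail_duration > 0),
            diff(pass_duration) >= 0, diff(fail_duration) >= 0,
            struggle_rate_pass >= 0, struggle_rate_fail >= 0,
            jitter_sd_pass >= 0, jitter_sd_fail >= 0,
            missing_prob >= 0, missing_prob < 1,
            score_noise_sd >= 0, duration_sd >= 0,
            skill_shape1 > 0, skill_shape2 > 0)
  # the cut-off must be attainable from both directions
  lo <- cfg$score_base - cfg$score_duration_weight * max(fail_duration) -
    cfg$score_event_weight * 2 * struggle_rate_fail
  hi <- cfg$score_base - cfg$score_duration_weight * min(pass_duration)
  if (cfg$pass_cutoff <= lo || cfg$pass_cutoff >= hi) {
    stop("pass_cutoff lies outside the achievable score range")
  }
  structure(cfg, class = "generator_config")
}

# logistic switch between the fail (skill 0) and pass (skill 1) anchors;
# strictly increasing in skill
.skill_mix <- function(skill, at0, at1, cfg) {
  w <- stats::plogis((skill - cfg$transition_center) / cfg$transition_width)
  at0 + w * (at1 - at0)
}

#' Generate one synthetic trial
#'
#' @param cfg a [generator_config()].
#' @param subject_skill skill level in `[0, 1]` (1 = expert).
#' @param trial_id,subject_id identifiers stamped on the trial.
#' @return A list with `trial` (a [trial_sequence()]) and `truth` (true
#'   score, label, duration and the planted struggle windows in seconds).
#' @export
generate_trial <- function(cfg, subject_skill, trial_id = "t1",
                           subject_id = "s1") {
  stopifnot(inherits(cfg, "generator_config"),
            subject_skill >= 0, subject_skill <= 1)
  skill <- min(1, max(0, subject_skill + stats::rnorm(1, 0, cfg$trial_skill_sd)))
  dur_mean <- .skill_mix(skill, mean(cfg$fail_duration),
                         mean(cfg$pass_duration), cfg)
  duration <- stats::rnorm(1, dur_mean, cfg$duration_sd)
  duration <- min(max(cfg$pass_duration[1], duration), cfg$fail_duration[2])
  Tn <- max(2L, as.integer(round(duration * cfg$fps)))

  lambda <- .skill_mix(skill, cfg$struggle_rate_fail, cfg$struggle_rate_pass,
                       cfg)
  n_events <- stats::rpois(1, lambda)
  windows <- NULL
  in_window <- rep(FALSE, Tn)
  if (n_events > 0) {
    starts <- sort(stats::runif(n_events, 0, duration))
    lens <- stats::runif(n_events, cfg$struggle_len[1], cfg$struggle_len[2])
    ends <- pmin(starts + lens, duration)
    windows <- cbind(start = starts, end = ends)
    for (w in seq_len(n_events)) {
      i0 <- max(1L, as.integer(floor(starts[w] * cfg$fps)) + 1L)
      i1 <- min(Tn, as.integer(ceiling(ends[w] * cfg$fps)))
      in_window[i0:i1] <- TRUE
    }
  }

  jit_sd <- .skill_mix(skill, cfg$jitter_sd_fail, cfg$jitter_sd_pass, cfg)
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  centre <- c(w / 2, h / 2)

  # scissors: progress along the circle; stalls/back-tracks inside windows
  inc <- rep(1, Tn)
  inc[in_window] <- stats::rnorm(sum(in_window), -0.3, 1.2)
  prog <- cumsum(inc)
  if (prog[Tn] <= 1e-6) prog <- as.numeric(seq_len(Tn))  # degenerate: all-window trial
  prog <- prog / prog[Tn]
  theta <- 2 * pi * prog
  sx <- centre[1] + 100 * cos(theta)
  sy <- centre[2] + 100 * sin(theta)

  # grasper: traction near the gauze corner with a jump at each event start
  anchor <- c(0.72 * w, 0.3 * h)
  gx <- rep(anchor[1], Tn)
  gy <- rep(anchor[2], Tn)
  if (n_events > 0) {
    for (s in windows[, "start"]) {
      i0 <- max(1L, as.integer(floor(s * cfg$fps)) + 1L)
      jump <- stats::rnorm(2, 0, 40)
      gx[i0:Tn] <- gx[i0:Tn] + jump[1]
      gy[i0:Tn] <- gy[i0:Tn] + jump[2]
    }
  }

  noise_sd <- rep(jit_sd, Tn)
  noise_sd[in_window] <- noise_sd[in_window] + cfg$struggle_jitter_sd
  coords <- cbind(
    grasper_x = gx + stats::rnorm(Tn, 0, noise_sd),
    grasper_y = gy + stats::rnorm(Tn, 0, noise_sd),
    scissors_x = sx + stats::rnorm(Tn, 0, noise_sd),
    scissors_y = sy + stats::rnorm(Tn, 0, noise_sd))
  coords[, c(1, 3)] <- pmin(pmax(coords[, c(1, 3)], 0), w - 1)
  coords[, c(2, 4)] <- pmin(pmax(coords[, c(2, 4)], 0), h - 1)

  score <- cfg$score_base - cfg$score_duration_weight * duration -
    cfg$score_event_weight * n_events + stats::rnorm(1, 0, cfg$score_noise_sd)
  label <- if (score >= cfg$pass_cutoff) "pass" else "fail"

  miss <- stats::runif(Tn) < cfg$missing_prob
  # the interpolation step needs observed frames at hand; never drop them all
  if (all(miss)) miss[1] <- FALSE
  coords[miss, ] <- NA_real_

  trial <- trial_sequence(trial_id, coords, fps = cfg$fps,
                          missing_mask = miss, label = label, score = score,
                          subject_id = subject_id)
  truth <- list(trial_id = trial_id, subject_id = subject_id,
                skill = skill, duration = duration, n_events = n_events,
                windows = windows, score = score, label = label)
  list(trial = trial, truth = truth)
}

#' Generate a full synthetic dataset
#'
#' Draws one skill level per subject from the configured Beta distribution
#' (so subjects differ and leave-one-user-out validation is meaningful) and
#' `trials_per_subject` trials per subject around it. Subject skills are
#' sampled by stratified inversion (one uniform draw per equal-probability
#' stratum of the Beta), mirroring a study cohort recruited to span the
#' skill range; with the default shapes this keeps the realised class ratio
#' close to balanced at any seed.
#'
#' @param cfg a [generator_config()].
#' @return A list with `dataset` (a [sequence_dataset()]) and `truth` (one
#'   entry per trial, plus the realised class ratio as an attribute).
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  u <- (seq_len(n) - stats::runif(n)) / n
  skills <- sample(stats::qbeta(u, cfg$skill_shape1, cfg$skill_shape2))
  trials <- vector("list", cfg$n_subjects * cfg$trials_per_subject)
  truths <- vector("list", length(trials))
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (r in seq_len(cfg$trials_per_subject)) {
      k <- k + 1L
      g <- generate_trial(cfg, skills[s],
                          trial_id = sprintf("%s_T%02d", sid, r),
                          subject_id = sid)
      trials[[k]] <- g$trial
      truths[[k]] <- g$truth
    }
  }
  ds <- sequence_dataset(trials, class_names = c("pass", "fail"))
  labels <- dataset_labels(ds)
  attr(truths, "class_ratio") <- sum(labels == "pass") / max(1, sum(labels == "fail"))
  attr(truths, "subject_skills") <- stats::setNames(skills, sprintf("S%02d", seq_len(cfg$n_subjects)))
  list(dataset = ds, truth = truths)
}
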