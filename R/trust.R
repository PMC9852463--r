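#' Trust-quantification settings
#'
#' @param alpha reward exponent applied to the confidence of correct
#'   predictions (> 0).
#' @param beta penalty exponent applied to the confidence of incorrect
#'   predictions (> 0).
#' @param kde_bandwidth `"scott"`, `"silverman"`, or a fixed numeric
#'   bandwidth for the trust-density curves.
#' @return A list of class `trust_config`.
#' @export
trust_config <- function(alpha = 1, beta = 1, kde_bandwidth = "scott") {
  stopifnot(alpha > 0, beta > 0)
  if (is.character(kde_bandwidth)) {
    kde_bandwidth <- match.arg(kde_bandwidth, c("scott", "silverman"))
  } else {
    stopifnot(is.numeric(kde_bandwidth), kde_bandwidth > 0)
  }
  structure(list(alpha = alpha, beta = beta, kde_bandwidth = kde_bandwidth),
            class = "trust_config")
}

#' Question-answer trust of a single prediction
#'
#' A prediction with confidence `C` contributes `C^alpha` when correct and
#' `1 - C^beta` when incorrect, so confident correct answers and hesitant
#' wrong answers both read as trustworthy behaviour.
#'
#' @param confidence softmax probability of the predicted class, in `[0, 1]`.
#' @param correct logical, whether predicted and true class match.
#' @param cfg a [trust_config()].
#' @return Trust value(s) in `[0, 1]`; vectorised over records.
#' @export
question_answer_trust <- function(confidence, correct, cfg = trust_config()) {
  stopifnot(all(confidence >= 0 & confidence <= 1))
  ifelse(correct, confidence^cfg$alpha, 1 - confidence^cfg$beta)
}

#' Trust density curve
#'
#' Gaussian kernel density estimate of a set of question-answer trust
#' values, evaluated on a grid that covers at least `[-0.2, 1.2]` (extended
#' by three bandwidths past the data so the curve integrates to one on its
#' own grid). Diagnostic only - the scalar trust metrics never depend on it.
#'
#' @param q_values numeric vector of trust values (at least two).
#' @param cfg a [trust_config()].
#' @param n grid resolution.
#' @return A data frame with columns `q` and `density`.
#' @export
trust_density <- function(q_values, cfg = trust_config(), n = 512L) {
  if (length(q_values) < 2L) stop("need at least two trust values")
  bw <- if (is.numeric(cfg$kde_bandwidth)) {
    cfg$kde_bandwidth
  } else if (stats::sd(q_values) == 0) {
    0.05  # degenerate sample: a narrow fixed kernel keeps the mass on-grid
  } else if (cfg$kde_bandwidth == "scott") {
    stats::bw.nrd(q_values)
  } else {
    stats::bw.nrd0(q_values)
  }
  from <- min(-0.2, min(q_values) - 3 * bw)
  to <- max(1.2, max(q_values) + 3 * bw)
  d <- stats::density(q_values, bw = bw, kernel = "gaussian",
                      from = from, to = to, n = n)
  data.frame(q = d$x, density = d$y)
}

#' Trust spectrum and NetTrustScore from prediction records
#'
#' The trust spectrum is the per-class mean question-answer trust (the
#' discrete estimator of the trust integral over a finite record set) and
#' the NetTrustScore is its average weighted by the empirical class
#' prevalence. Conditional summaries restrict the mean to correct
#' (question-answer space where prediction and truth match) and incorrect
#' records of each class, and the density curves are attached as
#' diagnostics.
#'
#' @param records data frame with `true_class`, `pred_class`, `confidence`
#'   (as produced by [predict.skillnet()]).
#' @param cfg a [trust_config()].
#' @param densities compute the per-class (and conditional) trust-density
#'   curves as well.
#' @return A list of class `trust_report`: `per_class` (data frame with
#'   `class`, `n`, `prevalence`, `trust_spectrum`, `nts_correct`,
#'   `nts_incorrect`), `nts`, `q_values`, and optionally `densities`.
#' @export
trust_report <- function(records, cfg = trust_config(), densities = TRUE) {
  need <- c("true_class", "pred_class", "confidence")
  if (!all(need %in% names(records))) {
    stop("records must carry columns ", paste(need, collapse = ", "))
  }
  if (anyNA(records$true_class)) stop("every record needs a true class")
  correct <- records$pred_class == records$true_class
  q <- question_answer_trust(records$confidence, correct, cfg)
  classes <- sort(unique(records$true_class))
  per_class <- do.call(rbind, lapply(classes, function(z) {
    in_z <- records$true_class == z
    data.frame(class = z, n = sum(in_z),
               prevalence = mean(in_z),
               trust_spectrum = mean(q[in_z]),
               nts_correct = if (any(in_z & correct))
                 mean(q[in_z & correct]) else NA_real_,
               nts_incorrect = if (any(in_z & !correct))
                 mean(q[in_z & !correct]) else NA_real_)
  }))
  nts <- sum(per_class$prevalence * per_class$trust_spectrum)
  dens <- NULL
  if (densities) {
    dens <- lapply(stats::setNames(classes, classes), function(z) {
      in_z <- records$true_class == z
      out <- list(all = if (sum(in_z) >= 2) trust_density(q[in_z], cfg))
      if (sum(in_z & correct) >= 2) {
        out$correct <- trust_density(q[in_z & correct], cfg)
      }
      if (sum(in_z & !correct) >= 2) {
        out$incorrect <- trust_density(q[in_z & !correct], cfg)
      }
      out
    })
  }
  structure(list(per_class = per_class, nts = nts,
                 q_values = data.frame(trial = seq_along(q),
                                       true_class = records$true_class,
                                       correct = correct, q = q),
                 densities = dens, cfg = cfg),
            class = "trust_report")
}

#' @export
print.trust_report <- function(x, ...) {
  cat(sprintf("<trust_report> NetTrustScore %.3f\n", x$nts))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-6s T_M %.3f (n=%d, P=%.2f) | correct %.3f | incorrect %s\n",
                pc$class[i], pc$trust_spectrum[i], pc$n[i], pc$prevalence[i],
                pc$nts_correct[i],
                ifelse(is.na(pc$nts_incorrect[i]), "-",
                       sprintf("%.3f", pc$nts_incorrect[i]))))
  }
  invisible(x)
}
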