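#' Parameters of a simulated observer
#'
#' A generative model of one participant in the two-interval numerosity
#' comparison.  Each stimulus evokes a noisy percept with mean `b * N`; the
#' noise standard deviation is `s` times the *standard* numerosity of the
#' comparison, so internal noise scales with the magnitude regime of the
#' session (scalar variability across standards, a common noise scale
#' within a comparison).  This makes the implied psychometric function an
#' exact cumulative Gaussian on the test-numerosity axis — the analysis
#' model — so parameter recovery through the fitting pipeline is unbiased.
#' The multiplicative distortion `b` applies only to the symmetric standard
#' stimulus and may differ across task levels (single task `ST`, single task
#' with to-be-ignored distractor `ST_WD`, dual task `DT`), as may the noise
#' coefficient `s`.  A lapse probability replaces the comparison with a fair
#' coin, and a per-condition accuracy governs responses to the concurrent
#' colour-orientation conjunction task.
#'
#' @param s Named numeric: noise coefficient per task (`ST`, `ST_WD`, `DT`),
#'   all strictly positive.  A single unnamed value is recycled.
#' @param b_sym Named numeric: bias multiplier applied to the symmetric
#'   standard, per task; in (0, 1.5].  A single value is recycled.
#' @param lapse Lapse probability, in \\[0, 0.1].
#' @param conj_accuracy Named numeric in \\[0.5, 1]: probability of a correct
#'   conjunction response when the numerical stimuli are `random` /
#'   `symmetry`.
#' @param id Participant label.
#' @param seed Optional integer recorded for bookkeeping.
#'
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(s = 0.2096, b_sym = 1, lapse = 0.02,
                            conj_accuracy = c(random = 0.96, symmetry = 0.94),
                            id = "obs1", seed = NULL) {
  tasks <- c("ST", "ST_WD", "DT")
  s <- .per_task(s, tasks, "s")
  b_sym <- .per_task(b_sym, tasks, "b_sym")
  if (any(s <= 0)) stop("noise coefficient s must be > 0")
  if (any(b_sym <= 0 | b_sym > 1.5)) stop("b_sym must lie in (0, 1.5]")
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]")
  conds <- c("random", "symmetry")
  conj_accuracy <- .per_task(conj_accuracy, conds, "conj_accuracy")
  if (any(conj_accuracy < 0.5 | conj_accuracy > 1)) {
    stop("conj_accuracy must lie in [0.5, 1]")
  }
  structure(list(s = s, b_sym = b_sym, lapse = lapse,
                 conj_accuracy = conj_accuracy, id = id, seed = seed),
            class = "observer_params")
}

.per_task <- function(x, keys, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), length(keys)), keys)
  }
  if (!all(keys %in% names(x))) {
    stop(sprintf("%s must be named with all of: %s", what,
                 paste(keys, collapse = ", ")))
  }
  x[keys]
}

#' Specification of one comparison trial
#'
#' @param standard_n Standard numerosity, one of 8, 12, 24, 50 in the default
#'   design (any integer >= 2 is accepted).
#' @param test_n Test numerosity, integer >= 2.
#' @param condition `"symmetry"` (symmetric standard, random test) or
#'   `"random"` (both arrays random).
#' @param task `"ST"`, `"ST_WD"` or `"DT"`.
#' @param standard_interval `"first"` or `"second"` — bookkeeping only; no
#'   order effect is modelled.
#' @param conj_is_target Logical or `NA` (no conjunction stimulus in `ST`).
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(standard_n, test_n, condition = "random", task = "ST",
                       standard_interval = "first", conj_is_target = NA) {
  condition <- match.arg(condition, c("random", "symmetry"))
  task <- match.arg(task, c("ST", "ST_WD", "DT"))
  standard_interval <- match.arg(standard_interval, c("first", "second"))
  stopifnot(standard_n >= 2, test_n >= 2)
  structure(list(standard_n = as.integer(standard_n),
                 test_n = as.integer(test_n), condition = condition,
                 task = task, standard_interval = standard_interval,
                 conj_is_target = conj_is_target),
            class = "trial_spec")
}

#' Draw a noisy numerosity percept
#'
#' Scalar-variability percept: Gaussian with mean `multiplier * n_true` and
#' standard deviation `s * noise_ref`, truncated below at 0.01.  By default
#' the noise reference is the stimulus's own numerosity; within a
#' two-interval comparison [simulate_choice()] uses the standard numerosity
#' as the common reference for both intervals, which keeps the implied
#' psychometric function exactly Gaussian on the test axis while preserving
#' Weber-law scaling across standards.
#'
#' @param n_true True numerosity (>= 1).
#' @param multiplier Multiplicative distortion of the mean percept.
#' @param s Noise coefficient.
#' @param noise_ref Reference numerosity setting the noise scale (SD of the
#'   percept is `s * noise_ref`).
#' @param n_draws Number of independent percepts to draw.
#' @return Numeric vector of `n_draws` percepts.
#' @export
perceived_numerosity <- function(n_true, multiplier = 1, s = 0.2,
                                 noise_ref = n_true, n_draws = 1) {
  stopifnot(n_true >= 1, s >= 0, noise_ref >= 1)
  pmax(0.01, stats::rnorm(n_draws, multiplier * n_true, s * noise_ref))
}

# bias multiplier in force on a given trial: only the symmetric standard is
# distorted; the (random) test array is always veridical on average
.trial_b <- function(trial, params) {
  if (trial$condition == "symmetry") params$b_sym[[trial$task]] else 1
}

#' Closed-form probability of a "test more numerous" response
#'
#' Under the generative model the decision variable is the difference of two
#' independent Gaussian percepts whose common noise SD is `s * n_std`,
#' giving `P(test more) = lapse/2 + (1 - lapse) * pnorm((n_test - b * n_std)
#' / (s * sqrt(2) * n_std))`, with `b` applied only when the standard is
#' symmetric.  This is the analytic oracle for [simulate_choice()]; the
#' `n_test` solving `P = 0.5` (at zero lapse) is exactly `b * n_std`, which
#' anchors the bias-index recovery, and the implied spread maps the noise
#' coefficient to a Weber fraction `qnorm(0.75) * sqrt(2) * s`.
#'
#' @param trial A [trial_spec()].
#' @param params An [observer_params()].
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(trial, params) {
  s <- params$s[[trial$task]]
  b <- .trial_b(trial, params)
  lam <- params$lapse
  z <- (trial$test_n - b * trial$standard_n) /
    (s * sqrt(2) * trial$standard_n)
  lam / 2 + (1 - lam) * stats::pnorm(z)
}

#' Simulate one two-interval choice
#'
#' Draws a percept for the standard (with the symmetric-standard bias
#' multiplier when applicable) and one for the test — both with noise SD
#' `s * standard_n` — and reports whether the test percept is larger.  With
#' probability `lapse` the comparison is replaced by a fair coin.
#'
#' @inheritParams choice_probability
#' @return Logical: `TRUE` if the observer reports "test more numerous".
#' @export
simulate_choice <- function(trial, params) {
  if (params$lapse > 0 && stats::runif(1) < params$lapse) {
    return(stats::runif(1) < 0.5)
  }
  s <- params$s[[trial$task]]
  b <- .trial_b(trial, params)
  p_std <- perceived_numerosity(trial$standard_n, b, s,
                                noise_ref = trial$standard_n)
  p_test <- perceived_numerosity(trial$test_n, 1, s,
                                 noise_ref = trial$standard_n)
  p_test > p_std
}

#' Simulate a conjunction-task response
#'
#' Correctness of the colour-orientation conjunction judgement is Bernoulli
#' with the observer's per-condition accuracy, independent of the numerosity
#' response.
#'
#' @param is_target Whether the conjunction stimulus was a target (unused by
#'   the accuracy model, retained for schedule bookkeeping).
#' @param p_correct Probability of a correct response.
#' @return Logical: `TRUE` if the response is correct.
#' @export
simulate_conjunction_response <- function(is_target, p_correct) {
  stopifnot(p_correct >= 0, p_correct <= 1)
  stats::runif(1) < p_correct
}
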