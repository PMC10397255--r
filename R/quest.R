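#' Initialise a QUEST adaptive staircase
#'
#' Bayesian adaptive procedure operating on the log10 ratio of test to
#' standard numerosity.  The state keeps a gridded posterior over candidate
#' log-ratio thresholds; the psychometric likelihood assumed for updating is
#' a cumulative Gaussian `psi(x - t) = gamma + (1 - gamma - delta) *
#' pnorm((x - t) / beta)` for a "test more numerous" response (its complement
#' otherwise).
#'
#' @param prior_mean,prior_sd Gaussian prior over the log10 threshold ratio.
#' @param grid Strictly increasing vector of candidate log-ratios.
#' @param slope_beta Assumed psychometric spread in log10 units.
#' @param lapse_delta Assumed lapse rate.
#' @param guess_gamma Lower asymptote (0 for the two-interval "test more"
#'   response variable, which spans the full 0-1 range).
#' @param target_p Criterion probability targeted by the placement rule.
#' @return An object of class `quest_state`.
#' @examples
#' q <- quest_init()
#' quest_estimate(q) # prior mean
#' @export
quest_init <- function(prior_mean = 0, prior_sd = 0.3,
                       grid = seq(-0.5, 0.5, length.out = 201),
                       slope_beta = 0.15, lapse_delta = 0.02,
                       guess_gamma = 0, target_p = 0.5) {
  stopifnot(prior_sd > 0, length(grid) >= 2)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (target_p < 0 || target_p > 1) stop("target_p must lie in [0, 1]")
  post <- stats::dnorm(grid, prior_mean, prior_sd)
  post <- post / sum(post)
  structure(list(grid = grid, posterior = post, slope_beta = slope_beta,
                 lapse_delta = lapse_delta, guess_gamma = guess_gamma,
                 target_p = target_p,
                 history = list(log_ratio = numeric(0), response = logical(0))),
            class = "quest_state")
}

# single Bayes step on a bare posterior vector (shared with the hot loop in
# run_simulated_experiment)
.quest_update_core <- function(posterior, grid, log_ratio, response,
                               beta, delta, gamma) {
  psi <- gamma + (1 - gamma - delta) * stats::pnorm((log_ratio - grid) / beta)
  posterior <- posterior * (if (response) psi else 1 - psi)
  posterior / sum(posterior)
}

#' Update a QUEST posterior with one trial
#'
#' Multiplies the posterior by the assumed psychometric likelihood of the
#' observed response at the presented log-ratio and renormalises.
#'
#' @param state A `quest_state`.
#' @param log_ratio Presented log10(test / standard) ratio.
#' @param response Logical: `TRUE` for "test more numerous".
#' @return The updated `quest_state` (history appended).
#' @export
quest_update <- function(state, log_ratio, response) {
  stopifnot(is.finite(log_ratio), is.logical(response), length(response) == 1)
  state$posterior <- .quest_update_core(state$posterior, state$grid, log_ratio,
                                        response, state$slope_beta,
                                        state$lapse_delta, state$guess_gamma)
  state$history$log_ratio <- c(state$history$log_ratio, log_ratio)
  state$history$response <- c(state$history$response, response)
  state
}

#' Posterior-mean threshold estimate
#'
#' @param state A `quest_state`.
#' @return Posterior mean of the log10 threshold ratio.
#' @export
quest_estimate <- function(state) {
  sum(state$grid * state$posterior)
}

#' Recommend the next test numerosity
#'
#' Places the next trial at the posterior-mean log-ratio plus (optionally) a
#' uniform jitter in `[-jitter, +jitter]` log10 units.  Jittered placement
#' spreads trials across the psychometric function so that its slope — and
#' hence the just-noticeable difference — is estimable from the final fit;
#' placing every trial exactly at threshold would leave the slope
#' unidentified.  The recommendation is converted to an integer numerosity,
#' clamped to `[max(2, round(standard_n / 3)), 3 * standard_n]`, and bumped
#' one step away from `standard_n` (in the direction of the jitter) if it
#' lands exactly on it, because an equal-numerosity comparison is
#' uninformative.
#'
#' @param state A `quest_state`.
#' @param standard_n Standard numerosity (integer >= 2).
#' @param jitter Half-width of the uniform placement jitter, log10 units.
#'   Set to 0 for deterministic threshold-targeting.
#' @return Integer test numerosity.
#' @export
quest_next <- function(state, standard_n, jitter = 0.15) {
  stopifnot(standard_n >= 2)
  j <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
  ratio <- quest_estimate(state) + j
  lo <- max(2L, as.integer(round(standard_n / 3)))
  hi <- 3L * as.integer(standard_n)
  n <- as.integer(round(standard_n * 10^ratio))
  n <- max(lo, min(hi, n))
  if (n == standard_n) {
    dir <- if (j > 0) 1L else if (j < 0) -1L else 1L
    n <- max(lo, min(hi, n + dir))
    if (n == standard_n) n <- standard_n - dir   # clamp pushed it back
  }
  n
}

#' Serialize / restore a QUEST state
#'
#' JSON round-trip for audit trails: the grid, posterior, assumed
#' psychometric parameters and trial history are preserved exactly
#' (doubles are written in full precision).
#'
#' @param state A `quest_state`.
#' @param path File to write (`quest_to_json`) or read (`quest_from_json`).
#' @return `quest_to_json` returns `path` invisibly; `quest_from_json`
#'   returns a `quest_state`.
#' @export
quest_to_json <- function(state, path) {
  jsonlite::write_json(unclass(state), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname quest_to_json
#' @export
quest_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$history <- list(log_ratio = as.numeric(x$history$log_ratio),
                    response = as.logical(x$history$response))
  class(x) <- "quest_state"
  x
}

#' @export
print.quest_state <- function(x, ...) {
  cat(sprintf(
    "<quest_state: %d grid points in [%.3g, %.3g], %d trials, estimate %.4f>\n",
    length(x$grid), min(x$grid), max(x$grid),
    length(x$history$log_ratio), quest_estimate(x)))
  invisible(x)
}
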