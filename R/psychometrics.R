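#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood (binomial) fit of
#' `P(test more | x) = lapse/2 + (1 - lapse) * pnorm((x - mu) / sigma)`
#' to the trials of one analysis cell, where `x` is the test numerosity.
#' `mu` is the point of subjective equality (PSE) and `sigma` the spread on
#' the numerosity axis.  The lapse rate is fixed (default 0), matching the
#' two-parameter cumulative-Gaussian analysis model.  Optimisation is
#' deterministic: Nelder-Mead over `(mu, log sigma)` from a fixed grid of
#' starts (`mu` at the trial-weighted median test level; `sigma` at 0.1, 0.2
#' and 0.4 times that), relative tolerance 1e-8.
#'
#' @param test_n Integer vector of test numerosities, one per trial.
#' @param response Logical (or 0/1) vector: "test more numerous" responses.
#' @param lapse Fixed lapse rate in \\[0, 0.1].
#' @param min_trials Minimum number of trials required.
#' @param cell Optional named list identifying the analysis cell
#'   (participant, task, condition, standard numerosity); carried through to
#'   the result.
#'
#' @return An object of class `psychometric_fit` with elements `mu`, `sigma`,
#'   `lapse`, `loglik`, `n_trials`, `converged`, `cell`.
#' @section Degenerate data:
#' An error of class `numsym_degenerate_data` is signalled when there are
#' fewer than `min_trials` trials, fewer than 3 distinct test levels, or only
#' one response category — such cells cannot constrain both parameters.
#' @examples
#' set.seed(1)
#' x <- rep(seq(16, 32, by = 2), each = 30)
#' r <- runif(length(x)) < pnorm((x - 24) / 4)
#' fit <- fit_psychometric(x, r)
#' c(fit$mu, fit$sigma)
#' @export
fit_psychometric <- function(test_n, response, lapse = 0, min_trials = 20,
                             cell = NULL) {
  response <- as.logical(response)
  stopifnot(length(test_n) == length(response), lapse >= 0, lapse <= 0.1)
  if (length(test_n) < min_trials) {
    .degenerate("too few trials (", length(test_n), " < ", min_trials, ")")
  }
  agg <- .aggregate_levels(test_n, response)
  if (nrow(agg) < 3L) {
    .degenerate("fewer than 3 distinct test numerosities")
  }
  if (all(response) || !any(response)) {
    .degenerate("responses are constant (all one category)")
  }

  nll <- function(par) {
    p <- lapse / 2 +
      (1 - lapse) * stats::pnorm((agg$x - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$m - agg$k) * log1p(-p))
  }
  gr <- function(par) {
    sg <- exp(par[2])
    z <- (agg$x - par[1]) / sg
    p <- lapse / 2 + (1 - lapse) * stats::pnorm(z)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    w <- (agg$k / p - (agg$m - agg$k) / (1 - p)) * (1 - lapse) *
      stats::dnorm(z)
    c(sum(w) / sg, sum(w * z))                # d/d mu, d/d log sigma
  }

  # bounded optimisation keeps the search inside the region where the data
  # can identify the parameters (spread no larger than a few times the
  # sampled range); quasi-flat cells then hit the bound and are caught by
  # the identifiability gate in aggregate_cells() instead of diverging
  mu0 <- .weighted_median(agg$x, agg$m)
  rng <- max(diff(range(agg$x)), 1)
  lower <- c(min(agg$x) - 2 * rng, log(0.01 * rng))
  upper <- c(max(agg$x) + 2 * rng, log(5 * rng))
  best <- NULL
  conv <- FALSE
  for (f in c(0.1, 0.2, 0.4)) {
    start <- pmin(pmax(c(mu0, log(f * mu0)), lower), upper)
    fit <- stats::optim(start, nll, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1e7, maxit = 500))
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  structure(list(mu = best$par[1], sigma = exp(best$par[2]), lapse = lapse,
                 loglik = -best$value, n_trials = length(test_n),
                 converged = conv, cell = cell),
            class = "psychometric_fit")
}

.degenerate <- function(...) {
  stop(structure(class = c("numsym_degenerate_data", "error", "condition"),
                 list(message = paste0("degenerate cell: ", ...),
                      call = sys.call(-1))))
}

.aggregate_levels <- function(test_n, response) {
  k <- tapply(as.integer(response), test_n, sum)
  m <- tapply(response, test_n, length)
  data.frame(x = as.numeric(names(k)), k = as.vector(k), m = as.vector(m))
}

.weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit: PSE %.3f, sigma %.3f, lapse %.3g, n %d, logLik %.2f>\n",
    x$mu, x$sigma, x$lapse, x$n_trials, x$loglik))
  invisible(x)
}

#' Just-noticeable difference of a fitted psychometric function
#'
#' The numerosity difference between the 50% and 75% points of the fitted
#' cumulative Gaussian, i.e. `qnorm(0.75) * sigma` (about `0.6745 * sigma`).
#' The lapse-free core function is used even when the fit held a nonzero
#' lapse, so the 50%/75% definition is always well-posed.
#'
#' @param fit A `psychometric_fit`, or a bare numeric `sigma`.
#' @return JND in numerosity units.
#' @export
jnd <- function(fit) {
  sigma <- if (inherits(fit, "psychometric_fit")) fit$sigma else fit
  stats::qnorm(0.75) * sigma
}

#' Bias index
#'
#' Percentage deviation of the point of subjective equality from the
#' standard numerosity: `(pse / standard_n - 1) * 100`.  Negative values mean
#' the standard (here the symmetric array) needed fewer test dots to match,
#' i.e. its numerosity was underestimated.
#'
#' @param pse Point of subjective equality, numerosity units.
#' @param standard_n Standard numerosity.
#' @return Bias in percent.
#' @examples
#' bias_index(7.37, 8) # about -7.9: strong underestimation
#' @export
bias_index <- function(pse, standard_n) {
  stopifnot(all(standard_n >= 1), all(pse > 0))
  (pse / standard_n - 1) * 100
}

#' Weber fraction
#'
#' Dimensionless precision index: `jnd / standard_n`.  Constant across
#' standard numerosities under Weber's-law (scalar-variability) behaviour.
#'
#' @param jnd Just-noticeable difference, numerosity units.
#' @param standard_n Standard numerosity.
#' @return Weber fraction.
#' @export
weber_fraction <- function(jnd, standard_n) {
  stopifnot(all(jnd > 0), all(standard_n >= 1))
  jnd / standard_n
}

#' Fit every analysis cell of a trial table
#'
#' Groups a simulated (or recorded) trial table by participant, task,
#' condition and standard numerosity, fits the psychometric function in each
#' cell, and derives the PSE, spread, JND, bias index and Weber fraction.
#' Cells whose data are degenerate (see [fit_psychometric()]) are flagged
#' with `converged = FALSE` and `NA` estimates rather than aborting the run;
#' downstream summaries drop them.
#'
#' @param trials Data frame with columns `participant_id`, `task`,
#'   `condition`, `standard_n`, `test_n`, `response_test_more`.
#' @param lapse Fixed lapse rate passed to the fitter.
#' @param min_trials Minimum trials per cell.
#' @return A tibble with one row per cell: identifiers plus `pse`, `sigma`,
#'   `jnd`, `bias_pct`, `wf`, `n_trials`, `converged`.
#' @export
aggregate_cells <- function(trials, lapse = 0, min_trials = 20) {
  req <- c("participant_id", "task", "condition", "standard_n", "test_n",
           "response_test_more")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials table lacks columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(trials$participant_id, trials$task, trials$condition,
                     trials$standard_n, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    cell <- trials[idx[1], c("participant_id", "task", "condition",
                             "standard_n")]
    x <- trials$test_n[idx]
    fit <- tryCatch(
      fit_psychometric(x, trials$response_test_more[idx],
                       lapse = lapse, min_trials = min_trials),
      numsym_degenerate_data = function(e) NULL)
    # parameters far outside the sampled test range are not identified
    # (quasi-flat response data lets the ML spread diverge); such cells are
    # flagged and excluded from cohort averages, like degenerate ones
    rng <- diff(range(x))
    unidentified <- !is.null(fit) &&
      (fit$sigma > 3 * rng || fit$mu < min(x) - 2 * rng ||
         fit$mu > max(x) + 2 * rng)
    if (is.null(fit) || fit$mu <= 0 || !fit$converged || unidentified) {
      return(tibble::tibble(cell, pse = NA_real_, sigma = NA_real_,
                            jnd = NA_real_, bias_pct = NA_real_,
                            wf = NA_real_, n_trials = length(idx),
                            converged = FALSE))
    }
    j <- jnd(fit)
    tibble::tibble(cell, pse = fit$mu, sigma = fit$sigma, jnd = j,
                   bias_pct = bias_index(fit$mu, cell$standard_n),
                   wf = weber_fraction(j, cell$standard_n),
                   n_trials = length(idx), converged = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$participant_id, out$task, out$condition, out$standard_n), ]
}
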