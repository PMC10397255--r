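# Independent reference implementations used to cross-check the package.
# These deliberately use naive, definitional algorithms (edge-testing hull,
# direct Bayes products, exhaustive grids and enumerations) and never call
# the code paths they verify.

# convex-hull area by brute force: (i, j) is a hull edge iff every other
# point lies on one side of the directed line i -> j; hull vertices are then
# ordered by angle about the centroid and the shoelace formula applied
oracle_hull_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cr <= 1e-12) || all(cr >= -1e-12)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  hx <- x[on_hull]
  hy <- y[on_hull]
  if (length(hx) < 3) return(0)
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  hx <- hx[o]
  hy <- hy[o]
  k <- c(seq_along(hx)[-1], 1L)
  abs(sum(hx * hy[k] - hx[k] * hy)) / 2
}

# posterior over the grid recomputed in one pass from the prior and the full
# response history
oracle_quest_posterior <- function(grid, prior_mean, prior_sd, history,
                                   beta, delta, gamma) {
  post <- dnorm(grid, prior_mean, prior_sd)
  for (i in seq_along(history$log_ratio)) {
    psi <- gamma + (1 - gamma - delta) *
      pnorm((history$log_ratio[i] - grid) / beta)
    post <- post * if (history$response[i]) psi else 1 - psi
  }
  post / sum(post)
}

# exhaustive (mu, sigma) grid search for the binomial cumulative-Gaussian
# likelihood; returns the grid optimum and the grid steps
oracle_grid_mle <- function(test_n, response, n_grid = 161) {
  k <- tapply(as.integer(response), test_n, sum)
  m <- tapply(response, test_n, length)
  x <- as.numeric(names(k))
  rng <- diff(range(x))
  mus <- seq(min(x) - 0.5 * rng, max(x) + 0.5 * rng, length.out = n_grid)
  sigmas <- exp(seq(log(0.02 * rng), log(4 * rng), length.out = n_grid))
  nll <- outer(mus, sigmas, function(mu, sg) {
    vapply(seq_along(mu), function(i) {
      p <- pmin(pmax(pnorm((x - mu[i]) / sg[i]), 1e-12), 1 - 1e-12)
      -sum(k * log(p) + (m - k) * log1p(-p))
    }, numeric(1))
  })
  ij <- arrayInd(which.min(nll), dim(nll))
  list(mu = mus[ij[1]], sigma = sigmas[ij[2]], nll = min(nll),
       mu_step = diff(mus)[1],
       sigma_ratio = sigmas[2] / sigmas[1])
}

# definitional balanced decomposition: for every non-empty subset T of the
# factors (subject included), the effect estimate at each observation is the
# Moebius-alternating sum of marginal means, and SS_T is the sum of its
# squares; error stratum for effect E is E + subject
oracle_rm_decomposition <- function(y, subj, factors) {
  fac <- c(list(.subj = factor(subj)), lapply(factors, factor))
  nms <- names(fac)
  n <- length(y)
  marg <- function(subset_nms) {
    if (length(subset_nms) == 0) return(rep(mean(y), n))
    key <- interaction(fac[subset_nms], drop = TRUE)
    ave(y, key)
  }
  subsets <- unlist(lapply(seq_along(nms), function(k) {
    utils::combn(nms, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- list()
  for (T in subsets) {
    est <- rep(0, n)
    for (k in 0:length(T)) {
      for (U in utils::combn(T, k, simplify = FALSE)) {
        est <- est + (-1)^(length(T) - k) * marg(U)
      }
    }
    df <- prod(vapply(T, function(f) nlevels(fac[[f]]) - 1L, integer(1)))
    out[[paste(T, collapse = ":")]] <- list(ss = sum(est^2), df = df)
  }
  out
}

# full 2^n sign-flip enumeration of the signed-rank statistic, applying the
# same smaller-sum / doubled-tail convention as wilcoxon_signed_rank()
oracle_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo power of the paired t-test, vectorised over replicates
oracle_mc_power <- function(n, d, alpha = 0.05, tails = 2, B = 20000) {
  x <- matrix(rnorm(n * B, mean = d), nrow = n)
  tt <- colMeans(x) / (apply(x, 2, sd) / sqrt(n))
  if (tails == 2) {
    mean(abs(tt) > qt(1 - alpha / 2, n - 1))
  } else {
    mean(tt > qt(1 - alpha, n - 1))
  }
}
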