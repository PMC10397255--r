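test_that("the MLE recovers generating parameters at large n", {
  set.seed(3)
  x <- rep(seq(14, 34, 2), 9100)  # ~1e5 trials
  r <- runif(length(x)) < pnorm((x - 24) / 4)
  fit <- fit_psychometric(x, r)
  expect_true(fit$converged)
  expect_equal(fit$mu, 24, tolerance = 0.1 / 24)
  expect_equal(fit$sigma, 4, tolerance = 0.1 / 4)
  expect_lte(fit$loglik, 0)
})

test_that("the MLE agrees with an exhaustive grid search", {
  set.seed(5)
  for (i in 1:20) {
    mu <- runif(1, 15, 30)
    sg <- runif(1, 2, 8)
    x <- rep(round(seq(mu - 2 * sg, mu + 2 * sg, length.out = 9)), 8)
    r <- runif(length(x)) < pnorm((x - mu) / sg)
    if (all(r) || !any(r)) next
    fit <- fit_psychometric(x, r, min_trials = 20)
    g <- oracle_grid_mle(x, r)
    expect_lte(-fit$loglik, g$nll + 1e-6)
    expect_lt(abs(fit$mu - g$mu), g$mu_step)
    expect_lt(abs(log(fit$sigma) - log(g$sigma)), log(g$sigma_ratio))
  }
})

test_that("degenerate cells are refused with a typed error", {
  x <- rep(20:28, 5)
  expect_error(fit_psychometric(x, rep(TRUE, length(x))),
               class = "numsym_degenerate_data")
  expect_error(fit_psychometric(rep(c(20, 24), 20),
                                rep(c(FALSE, TRUE), 20)),
               class = "numsym_degenerate_data")
  expect_error(fit_psychometric(c(20, 24, 28), c(FALSE, TRUE, TRUE)),
               class = "numsym_degenerate_data")
})

test_that("the JND is the 50-to-75 percent span of the fitted curve", {
  expect_equal(jnd(1), qnorm(0.75), tolerance = 1e-9)
  expect_equal(jnd(1), 0.67449, tolerance = 1e-5)
  expect_equal(jnd(4), 2.69796, tolerance = 1e-5)
  # root-finding oracle: x with Phi((x - mu)/sigma) = 0.75, minus mu
  mu <- 24; sg <- 3.7
  x75 <- uniroot(function(x) pnorm((x - mu) / sg) - 0.75, c(mu, mu + 5 * sg),
                 tol = 1e-12)$root
  expect_equal(jnd(sg), x75 - mu, tolerance = 1e-8)
})

test_that("bias and Weber indices follow their defining ratios", {
  expect_equal(bias_index(8, 8), 0)
  expect_equal(bias_index(50, 50), 0)
  expect_equal(bias_index(7.37, 8), -7.875)
  expect_equal(bias_index(12, 8), 50)
  expect_equal(weber_fraction(2, 8), 0.25)
  expect_equal(weber_fraction(12.5, 50), 0.25)
  expect_equal(weber_fraction(0.6745, 1), 0.6745)
  expect_error(bias_index(-1, 8))
  expect_error(weber_fraction(0, 8))
})

test_that("fitting is deterministic and scale-equivariant", {
  set.seed(6)
  x <- rep(seq(16, 32, 2), each = 10)
  r <- runif(length(x)) < pnorm((x - 24) / 5)
  f1 <- fit_psychometric(x, r)
  f2 <- fit_psychometric(x, r)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)

  # scaling numerosities scales mu and sigma, leaving bias and wf unchanged
  f3 <- fit_psychometric(3 * x, r)
  expect_equal(f3$mu / 3, f1$mu, tolerance = 1e-4)
  expect_equal(f3$sigma / 3, f1$sigma, tolerance = 1e-3)
  expect_equal(bias_index(f3$mu, 72), bias_index(f1$mu, 24),
               tolerance = 1e-3)
  expect_equal(weber_fraction(jnd(f3), 72), weber_fraction(jnd(f1), 24),
               tolerance = 1e-4)
})

test_that("aggregate_cells fits every cell and derives exact identities", {
  pop <- fixed_population(b = c(ST = 0.95, ST_WD = 1, DT = 1))
  cells <- sim_cells(4, c("ST", "DT"), c(12, 24), 25, pop, seed = 21)
  expect_identical(nrow(cells), 4L * 2L * 2L * 2L)
  ok <- cells[cells$converged, ]
  expect_gt(nrow(ok), 0)
  # Eq. identities hold exactly on every emitted row
  expect_equal(ok$bias_pct, (ok$pse / ok$standard_n - 1) * 100)
  expect_equal(ok$wf, ok$jnd / ok$standard_n)
  expect_equal(ok$jnd, qnorm(0.75) * ok$sigma)
})

test_that("a noiseless unbiased cohort recovers the standards to the dot", {
  pop <- fixed_population(s = c(ST = 1e-4, ST_WD = 1e-4, DT = 1e-4),
                          lapse = 0)
  cells <- sim_cells(3, "ST", c(8, 12, 24, 50), 50, pop, seed = 31,
                     sessions = 2L)
  ok <- cells[cells$converged, ]
  expect_gt(nrow(ok), 0.9 * nrow(cells))
  # integer test numerosities constrain the PSE only to the gap between the
  # sampled levels flanking the standard; at N = 50 the nearest levels are
  # occasionally unsampled, so the bound is a couple of dots
  expect_lt(max(abs(ok$pse - ok$standard_n)), 2.5)
  expect_lt(mean(abs(ok$pse - ok$standard_n)), 0.5)
})
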