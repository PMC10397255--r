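test_that("a factor the data ignore gets zero SS and F", {
  # opposite one-point effects across subjects cancel: SS_A = 0, error > 0
  d <- data.frame(subj = rep(c("s1", "s2"), each = 2),
                  A = rep(c("a1", "a2"), 2),
                  y = c(0, 1, 1, 0))
  res <- rm_anova(d, "y", "A", "subj")
  expect_equal(res$ss[res$effect == "A"], 0, tolerance = 1e-12)
  expect_equal(res$F[res$effect == "A"], 0, tolerance = 1e-12)
})

test_that("a two-level factor gives F equal to the squared paired t", {
  set.seed(1)
  d <- expand.grid(subj = paste0("s", 1:9), A = c("a1", "a2"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 0.8 * (d$A == "a2")
  res <- rm_anova(d, "y", "A", "subj")
  w <- reshape(d, idvar = "subj", timevar = "A", direction = "wide")
  tt <- paired_t(w$y.a2, w$y.a1)
  expect_equal(res$F[res$effect == "A"], tt$t^2, tolerance = 1e-10)
  expect_equal(res$p[res$effect == "A"], tt$p, tolerance = 1e-10)
  expect_equal(res$gg_epsilon[res$effect == "A"], 1)
})

test_that("the decomposition matches the definitional oracle and conserves SS", {
  set.seed(2)
  d <- expand.grid(subj = paste0("s", 1:6), A = c("a1", "a2"),
                   B = c("b1", "b2", "b3"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + (d$A == "a2") * 0.5 +
    (d$B == "b2") * 0.3 + (d$A == "a2" & d$B == "b3") * 0.7
  res <- rm_anova(d, "y", c("A", "B"), "subj")
  orc <- oracle_rm_decomposition(d$y, d$subj,
                                 list(A = d$A, B = d$B))
  for (eff in c("A", "B", "A:B")) {
    row <- res[res$effect == eff, ]
    expect_equal(row$ss, orc[[eff]]$ss, tolerance = 1e-10)
    expect_identical(as.integer(row$df), as.integer(orc[[eff]]$df))
    err <- orc[[paste0(".subj:", eff)]]
    expect_equal(row$ss_error, err$ss, tolerance = 1e-10)
    expect_equal(row$F, (row$ss / row$df) / (err$ss / err$df),
                 tolerance = 1e-10)
  }
  # conservation: total SS equals the sum over the full decomposition
  total <- sum(vapply(orc, `[[`, numeric(1), "ss"))
  expect_equal(attr(res, "ss_total"), total, tolerance = 1e-10)
  expect_equal(total, sum((d$y - mean(d$y))^2), tolerance = 1e-10)
  # classical eta squared uses the total-SS denominator
  expect_equal(res$eta_squared, res$ss / total, tolerance = 1e-12)
})

test_that("replicates are collapsed to cell means before decomposition", {
  set.seed(3)
  d <- expand.grid(subj = paste0("s", 1:5), A = c("a1", "a2"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  res <- rm_anova(d, "y", "A", "subj")
  agg <- aggregate(y ~ subj + A, d, mean)
  res2 <- rm_anova(agg, "y", "A", "subj")
  expect_equal(res$F, res2$F, tolerance = 1e-12)
  # a fully missing cell is refused
  d2 <- d[!(d$subj == "s1" & d$A == "a1"), ]
  expect_error(rm_anova(d2, "y", "A", "subj"), "unbalanced")
})

test_that("Greenhouse-Geisser epsilon has its analytic anchors", {
  set.seed(4)
  expect_equal(gg_epsilon(matrix(rnorm(20), 10, 2)), 1, tolerance = 1e-12)

  # data engineered to have an exactly compound-symmetric sample covariance
  k <- 4; n <- 12
  cs <- diag(k) + matrix(0.4, k, k)
  raw <- matrix(rnorm(n * k), n, k)
  cen <- scale(raw, scale = FALSE)
  z <- cen %*% solve(chol(cov(cen)))
  xc <- z %*% chol(cs)
  expect_equal(cov(xc), cs, tolerance = 1e-10)
  expect_equal(gg_epsilon(xc), 1, tolerance = 1e-9)

  # lower bound 1/(k - 1) for any 4-level input
  for (i in 1:10) {
    e <- gg_epsilon(matrix(rnorm(6 * 4), 6, 4))
    expect_gte(e, 1 / 3 - 1e-12)
    expect_lte(e, 1 + 1e-12)
  }
})

test_that("GG-corrected p-values agree with car's multivariate machinery", {
  skip_if_not_installed("car")
  set.seed(5)
  n <- 10
  wide <- matrix(rnorm(n * 6), n)
  colnames(wide) <- paste0("c", 1:6)
  idata <- expand.grid(B = c("b1", "b2", "b3"), A = c("a1", "a2"))
  idata <- idata[, c("A", "B")]
  # column order: A slowest, B fastest — matches c1..c6 construction
  mod <- lm(wide ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = ~ A * B, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))  # HF eps cap
  long <- data.frame(subj = rep(seq_len(n), 6),
                     A = rep(idata$A, each = n),
                     B = rep(idata$B, each = n),
                     y = as.vector(wide))
  res <- rm_anova(long, "y", c("A", "B"), "subj")
  gg <- s$pval.adjustments
  for (eff in rownames(gg)) {
    expect_equal(res$gg_epsilon[res$effect == eff],
                 unname(gg[eff, "GG eps"]), tolerance = 1e-8)
    expect_equal(res$p_gg[res$effect == eff],
                 unname(gg[eff, "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("paired t reports the hand-computed effect size", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$cohen_d, 2)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, 2L)
  expect_error(paired_t(1:5, 1:5), "zero-variance")
})

test_that("parametric paired-t p matches a sign-flip null on normal data", {
  set.seed(6)
  for (i in 1:4) {
    x <- rnorm(20, 0.3)
    y <- rnorm(20)
    tt <- paired_t(x, y)
    d <- x - y
    B <- 4000
    tperm <- vapply(seq_len(B), function(b) {
      ds <- d * sample(c(-1, 1), 20, replace = TRUE)
      mean(ds) / (sd(ds) / sqrt(20))
    }, numeric(1))
    pp <- mean(abs(tperm) >= abs(tt$t))
    se <- sqrt(max(pp * (1 - pp), 1e-4) / B)
    expect_lt(abs(tt$p - pp), 2 * se + 0.01)
  }
})

test_that("Bonferroni adjustment is the capped product", {
  expect_equal(bonferroni(0.002, m = 4), 0.008)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  p <- runif(10)
  expect_true(all(bonferroni(p) >= p))
})

test_that("Wilcoxon signed-rank follows the smaller-sum convention", {
  # all positive differences: negative-rank sum is zero
  r <- wilcoxon_signed_rank(c(3, 5, 8, 2, 9), c(1, 1, 1, 1, 1))
  expect_identical(r$W, 0)
  expect_equal(r$p, 2 / 32)
  r1 <- wilcoxon_signed_rank(c(3, 5, 8, 2, 9), c(1, 1, 1, 1, 1),
                             alternative = "greater")
  expect_equal(r1$p, 1 / 32)

  # swapping the samples leaves W and p unchanged
  set.seed(7)
  x <- rnorm(10); y <- rnorm(10)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(y, x)
  expect_identical(a$W, b$W)
  expect_equal(a$p, b$p)

  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
})

test_that("exact Wilcoxon p equals the full sign enumeration", {
  set.seed(8)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    x <- sample(1:8, n, replace = TRUE)  # integer data force ties
    y <- sample(1:8, n, replace = TRUE)
    if (all(x == y)) next
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p, oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
  # agreement with wilcox.test in the tie-free exact case
  set.seed(9)
  x <- rnorm(12); y <- rnorm(12)
  r <- wilcoxon_signed_rank(x, y)
  wt <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(r$p, wt$p.value, tolerance = 1e-12)
})

test_that("exact and approximate Wilcoxon branches agree at n = 25", {
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(25, 0.4)
    y <- rnorm(25)
    pe <- wilcoxon_signed_rank(x, y, exact_n = 25)$p
    pa <- wilcoxon_signed_rank(x, y, exact_n = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("noncentral-t power behaves analytically", {
  expect_equal(power_paired_t(20, 0), 0.05, tolerance = 1e-6)
  pw <- vapply(5:60, power_paired_t, numeric(1), d = 0.5)
  expect_true(all(diff(pw) > 0))
  expect_equal(power_paired_t(26, 0.75),
               1 - pt(qt(0.975, 25), 25, ncp = 0.75 * sqrt(26)) +
                 pt(-qt(0.975, 25), 25, ncp = 0.75 * sqrt(26)))
  # cross-check against the recommended-package solver
  ref <- power.t.test(n = 26, delta = 0.75, sd = 1, type = "paired")$power
  expect_equal(power_paired_t(26, 0.75), ref, tolerance = 1e-6)
})

test_that("the sample-size solver is monotone and one-sided needs fewer", {
  ns <- vapply(c(0.4, 0.5, 0.6, 0.75, 1, 1.5),
               required_sample_size_paired_t, numeric(1))
  expect_true(all(diff(ns) <= 0))
  n2 <- required_sample_size_paired_t(0.75, tails = 2)
  n1 <- required_sample_size_paired_t(0.75, tails = 1)
  expect_lt(n1, n2)
  # the returned n is minimal
  expect_gte(power_paired_t(n2, 0.75), 0.95)
  expect_lt(power_paired_t(n2 - 1, 0.75), 0.95)
})
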