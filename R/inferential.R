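#' Fully within-subject repeated-measures ANOVA
#'
#' Factorial repeated-measures ANOVA for balanced, fully crossed
#' within-subject designs: every main effect and interaction is tested
#' against its own subject-by-effect error stratum (univariate mixed-model
#' decomposition, via [stats::aov()] with an `Error(subject/...)` term).
#' If the table holds replicates, cell means per subject x factor-level
#' combination are taken first.  For every effect the output reports the sum
#' of squares, degrees of freedom, F, uncorrected p, classical eta squared
#' (`SS_effect / SS_total`, with `SS_total` the corrected total over the full
#' decomposition — not partial eta squared), the Greenhouse-Geisser epsilon
#' estimated from the sample covariance of the effect's orthonormal
#' contrasts, and the sphericity-corrected p-value obtained by multiplying
#' both degrees of freedom by epsilon.
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject-identifier column.
#' @return A tibble of class `anova_result`: one row per effect with columns
#'   `effect`, `ss`, `df`, `ms`, `ss_error`, `df_error`, `F`, `p`,
#'   `eta_squared`, `gg_epsilon`, `p_gg`, plus an attribute `ss_total`.
#' @examples
#' d <- expand.grid(subj = factor(1:8), cond = c("a", "b"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "b")
#' rm_anova(d, "y", "cond", "subj")
#' @export
rm_anova <- function(data, dv, within, subject) {
  stopifnot(all(c(dv, within, subject) %in% names(data)), length(within) >= 1)
  df <- data.frame(.y = data[[dv]], .subj = factor(data[[subject]]))
  for (w in within) df[[w]] <- factor(data[[w]])

  # collapse replicates to cell means; require complete, balanced crossing
  agg <- stats::aggregate(df$.y, by = c(list(.subj = df$.subj),
                                        df[, within, drop = FALSE]),
                          FUN = mean)
  names(agg)[ncol(agg)] <- ".y"
  n_subj <- nlevels(df$.subj)
  k_lev <- vapply(within, function(w) nlevels(df[[w]]), integer(1))
  if (nrow(agg) != n_subj * prod(k_lev)) {
    stop("design is unbalanced or has missing cells: expected ",
         n_subj * prod(k_lev), " subject-cell means, got ", nrow(agg))
  }

  fml <- stats::as.formula(paste(
    ".y ~", paste(within, collapse = " * "),
    "+ Error(.subj/(", paste(within, collapse = " * "), "))"))
  fit <- stats::aov(fml, data = agg)
  smry <- summary(fit)

  rows <- list()
  ss_total <- 0
  for (stratum in smry) {
    tab <- stratum[[1]]
    ss_total <- ss_total + sum(tab[["Sum Sq"]])
    effs <- trimws(rownames(tab))
    res_i <- which(effs == "Residuals")
    for (r in setdiff(seq_along(effs), res_i)) {
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effs[r], ss = tab[["Sum Sq"]][r], df = tab[["Df"]][r],
        ms = tab[["Mean Sq"]][r],
        ss_error = tab[["Sum Sq"]][res_i], df_error = tab[["Df"]][res_i],
        F = tab[["F value"]][r], p = tab[["Pr(>F)"]][r])
    }
  }
  out <- dplyr::bind_rows(rows)

  # subject x cell matrix, columns ordered with the last factor fastest to
  # match the Kronecker construction of the effect contrasts
  ord <- do.call(order, c(lapply(within, function(w) agg[[w]]),
                          list(agg$.subj)))
  wide <- matrix(agg$.y[ord], nrow = n_subj, byrow = FALSE)
  # after ordering, rows vary by subject fastest
  S <- stats::cov(wide)

  eps <- vapply(out$effect, function(eff) {
    fs <- strsplit(eff, ":", fixed = TRUE)[[1]]
    M <- 1
    for (w in within) {
      k <- k_lev[[w]]
      Mf <- if (w %in% fs) .orthonormal_contrasts(k) else
        matrix(1 / sqrt(k), 1, k)
      M <- kronecker(M, Mf)
    }
    A <- M %*% S %*% t(M)
    d <- nrow(A)
    (sum(diag(A)))^2 / (d * sum(A^2))
  }, numeric(1))

  out$eta_squared <- out$ss / ss_total
  out$gg_epsilon <- unname(eps)
  out$p_gg <- stats::pf(out$F, out$df * eps, out$df_error * eps,
                        lower.tail = FALSE)
  out <- tibble::as_tibble(out)
  attr(out, "ss_total") <- ss_total
  class(out) <- c("anova_result", class(out))
  out
}

# (k-1) x k orthonormal contrast matrix (normalised Helmert)
.orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  t(C) / sqrt(colSums(C^2))
}

#' Greenhouse-Geisser epsilon for one within-subject factor
#'
#' Box's epsilon-hat computed from the sample covariance of the level
#' columns: with `A = M S M'` for an orthonormal contrast matrix `M`,
#' `epsilon = tr(A)^2 / ((k - 1) * tr(A^2))`.  Equals 1 exactly when
#' sphericity holds (e.g. any 2-level factor, or compound-symmetric
#' covariance) and is bounded below by `1 / (k - 1)`.
#'
#' @param cell_data Numeric matrix, subjects in rows, factor levels in
#'   columns.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
gg_epsilon <- function(cell_data) {
  cell_data <- as.matrix(cell_data)
  k <- ncol(cell_data)
  stopifnot(k >= 2)
  if (nrow(cell_data) < k) {
    warning("fewer subjects than levels: covariance is singular, ",
            "epsilon estimate is unstable")
  }
  M <- .orthonormal_contrasts(k)
  A <- M %*% stats::cov(cell_data) %*% t(M)
  (sum(diag(A)))^2 / ((k - 1) * sum(A^2))
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test on the differences `x - y`, reporting the effect
#' size `d = mean(diff) / sd(diff)`.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @return A list: `t`, `df`, `p`, `cohen_d`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero-variance differences: paired t is undefined")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, df = n - 1L,
       p = 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE),
       cohen_d = mean(d) / sdd, mean_diff = mean(d))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` elementwise; `m` defaults to the family size
#' `length(p_values)`.
#'
#' @param p_values Numeric vector of p-values in \\[0, 1].
#' @param m Number of comparisons in the family.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1), m >= 1)
  pmin(1, m * p_values)
}

#' Wilcoxon signed-rank test
#'
#' Matched-pairs signed-rank test reporting `W` as the smaller of the two
#' signed-rank sums.  Zero differences are dropped; absolute differences are
#' midranked.  For `n <= exact_n` (default 25) remaining pairs the p-value
#' is exact, from the full sign-flip distribution of the positive-rank sum
#' (computed by convolution, so ties are handled exactly); beyond that a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y Paired numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to the location of `x - y`).
#' @param exact_n Largest n for which the exact distribution is used.
#' @return A list: `W`, `p`, `n` (pairs after zero removal), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = "two.sided",
                                 exact_n = 25L) {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: signed-rank test is undefined")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)

  if (n <= exact_n) {
    # distribution of 2*W+ under random signs, by convolution over doubled
    # (hence integer, even with midranks) ranks
    r2 <- as.integer(round(2 * r))
    dist <- .signed_rank_dist(r2)
    tot <- sum(dist)
    p_le <- function(w) sum(dist[seq_len(round(2 * w) + 1L)]) / tot
    p_ge <- function(w) sum(dist[(round(2 * w) + 1L):length(dist)]) / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le(w_pos), p_ge(w_pos))),
                greater = p_ge(w_pos),
                less = p_le(w_pos))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5
    z_gr <- (w_pos - mu - cc) / sqrt(sig2)
    z_le <- (w_pos - mu + cc) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(stats::pnorm(z_le),
                                           stats::pnorm(z_gr,
                                                        lower.tail = FALSE))),
                greater = stats::pnorm(z_gr, lower.tail = FALSE),
                less = stats::pnorm(z_le))
    method <- "normal-approximation"
  }
  list(W = W, p = p, n = n, method = method)
}

# counts over values 0..sum(r2) of the positive-rank sum, all 2^n sign
# assignments; dist[v + 1] = number of assignments with 2*W+ == v
.signed_rank_dist <- function(r2) {
  dist <- numeric(sum(r2) + 1L)
  dist[1L] <- 1
  top <- 0L
  for (ri in r2) {
    new <- dist
    new[(ri + 1L):(top + ri + 1L)] <- new[(ri + 1L):(top + ri + 1L)] +
      dist[1L:(top + 1L)]
    dist <- new
    top <- top + ri
  }
  dist
}

#' Exact power of a paired t-test
#'
#' Noncentral-t power for a paired (matched) t-test at effect size `d`
#' (mean difference over SD of differences): with `df = n - 1` and
#' noncentrality `|d| * sqrt(n)`, power is the probability that the test
#' statistic exceeds the critical value.
#'
#' @param n Number of pairs (>= 2).
#' @param d Cohen's d for the paired differences.
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
power_paired_t <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- n - 1
  ncp <- abs(d) * sqrt(n)
  if (tails == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Required sample size for a paired t-test
#'
#' Smallest `n >= 2` whose exact noncentral-t power reaches the target.
#'
#' @param d Cohen's d for the paired differences (nonzero).
#' @param alpha Significance level.
#' @param power Target power.
#' @param tails 1 or 2.
#' @return Integer sample size.
#' @examples
#' required_sample_size_paired_t(0.75, 0.05, 0.95) # 26
#' @export
required_sample_size_paired_t <- function(d, alpha = 0.05, power = 0.95,
                                          tails = 2) {
  stopifnot(d != 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2L
  while (power_paired_t(n, d, alpha, tails) < power) {
    n <- n + 1L
    if (n > 1e6) stop("sample size exceeds 1e6; check the inputs")
  }
  n
}
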