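#' Run the full analysis battery on a trial table
#'
#' Reproduces the study's analysis plan on a (simulated or recorded) trial
#' table:
#' \enumerate{
#'   \item per-cell psychometric fits and the derived bias index and Weber
#'     fraction ([aggregate_cells()]);
#'   \item a repeated-measures ANOVA on the bias with factors numerosity x
#'     condition x task over the two single-task levels (`ST`, `ST_WD`) —
#'     the passive-sensory-load comparison;
#'   \item the same ANOVA over `ST_WD` and `DT` — the divided-attention
#'     comparison — with post-hoc paired t-tests (symmetry DT vs `ST_WD`,
#'     random DT vs `ST_WD`, symmetry vs random within DT), Bonferroni
#'     corrected as one family;
#'   \item a numerosity x condition x task ANOVA on the Weber fraction over
#'     all tasks present, with task post-hocs;
#'   \item a Wilcoxon signed-rank test comparing dual-task conjunction
#'     accuracy between random and symmetric numerical stimuli.
#' }
#' Steps are skipped gracefully when the table lacks the required task
#' levels; participants with any unfit cell in a battery are dropped from
#' that battery (the ANOVA requires complete data).
#'
#' @param trials Trial table as produced by [run_simulated_experiment()].
#' @param lapse,min_trials Passed to [aggregate_cells()].
#' @return An object of class `numsym_analysis`: a list with elements
#'   `cells`, `bias_anova_single`, `bias_anova_attention`, `bias_posthoc`,
#'   `wf_anova`, `wf_posthoc`, `conjunction`, `summary` (a per task x
#'   condition x numerosity table of cohort means with bootstrap 95% CIs).
#' @export
analyze_trials <- function(trials, lapse = 0, min_trials = 20) {
  cells <- aggregate_cells(trials, lapse = lapse, min_trials = min_trials)
  tasks <- unique(trials$task)
  out <- list(cells = cells)

  out$bias_anova_single <-
    if (all(c("ST", "ST_WD") %in% tasks)) {
      .battery_anova(cells, c("ST", "ST_WD"), "bias_pct")
    }
  out$bias_anova_attention <-
    if (all(c("ST_WD", "DT") %in% tasks)) {
      .battery_anova(cells, c("ST_WD", "DT"), "bias_pct")
    }
  if (!is.null(out$bias_anova_attention)) {
    out$bias_posthoc <- .attention_posthocs(cells)
  }
  if (length(tasks) >= 2) {
    out$wf_anova <- .battery_anova(cells, tasks, "wf")
    out$wf_posthoc <- .wf_posthocs(cells, tasks)
  }
  if ("DT" %in% tasks) {
    out$conjunction <- .conjunction_test(trials)
  }
  out$summary <- .cohort_summary(cells)
  structure(out, class = "numsym_analysis")
}

# complete-case RM ANOVA on one derived measure over a task subset
.battery_anova <- function(cells, tasks, dv) {
  d <- cells[cells$task %in% tasks & cells$converged, ]
  n_cell <- length(unique(d$standard_n)) * length(unique(d$condition)) *
    length(tasks)
  cnt <- table(d$participant_id)
  keep <- names(cnt)[cnt == n_cell]
  d <- d[d$participant_id %in% keep, ]
  if (length(keep) < 3) return(NULL)
  within <- c("standard_n", "condition", "task")[
    c(length(unique(d$standard_n)) > 1, length(unique(d$condition)) > 1,
      length(tasks) > 1)]
  res <- rm_anova(d, dv, within, "participant_id")
  attr(res, "n_participants") <- length(keep)
  res
}

.pair_wide <- function(cells, task, condition) {
  d <- cells[cells$task == task & cells$condition == condition &
               cells$converged, ]
  stats::aggregate(d$bias_pct, list(participant_id = d$participant_id), mean)
}

.attention_posthocs <- function(cells) {
  combos <- list(
    c("symmetry DT vs ST_WD", "DT", "symmetry", "ST_WD", "symmetry"),
    c("random DT vs ST_WD", "DT", "random", "ST_WD", "random"),
    c("DT symmetry vs random", "DT", "symmetry", "DT", "random"))
  rows <- lapply(combos, function(cm) {
    a <- .pair_wide(cells, cm[2], cm[3])
    b <- .pair_wide(cells, cm[4], cm[5])
    m <- merge(a, b, by = "participant_id")
    tt <- paired_t(m$x.x, m$x.y)
    tibble::tibble(comparison = cm[1], t = tt$t, df = tt$df, p = tt$p,
                   cohen_d = tt$cohen_d, mean_diff = tt$mean_diff)
  })
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_bonf <- bonferroni(out$p, nrow(out))
  out
}

.wf_posthocs <- function(cells, tasks) {
  per_task <- function(tk) {
    d <- cells[cells$task == tk & cells$converged, ]
    stats::aggregate(d$wf, list(participant_id = d$participant_id), mean)
  }
  prs <- utils::combn(sort(tasks), 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    m <- merge(per_task(pr[1]), per_task(pr[2]), by = "participant_id")
    tt <- paired_t(m$x.x, m$x.y)
    tibble::tibble(comparison = paste(pr[1], "vs", pr[2]), t = tt$t,
                   df = tt$df, p = tt$p, cohen_d = tt$cohen_d,
                   mean_diff = tt$mean_diff)
  })
  out <- dplyr::bind_rows(rows)
  out$m <- nrow(out)
  out$p_bonf <- bonferroni(out$p, nrow(out))
  out
}

.conjunction_test <- function(trials) {
  d <- trials[trials$task == "DT" & !is.na(trials$conj_correct), ]
  if (nrow(d) == 0) return(NULL)
  acc <- stats::aggregate(d$conj_correct,
                          list(participant_id = d$participant_id,
                               condition = d$condition), mean)
  wide <- merge(acc[acc$condition == "random", c("participant_id", "x")],
                acc[acc$condition == "symmetry", c("participant_id", "x")],
                by = "participant_id")
  wt <- wilcoxon_signed_rank(wide$x.x, wide$x.y)
  list(W = wt$W, p = wt$p, n = wt$n, method = wt$method,
       mean_random = mean(wide$x.x), sd_random = stats::sd(wide$x.x),
       mean_symmetry = mean(wide$x.y), sd_symmetry = stats::sd(wide$x.y))
}

# cohort means with percentile-bootstrap 95% CIs over participants
.cohort_summary <- function(cells, n_boot = 1000) {
  d <- cells[cells$converged, ]
  key <- interaction(d$task, d$condition, d$standard_n, drop = TRUE,
                     sep = "\r")
  rows <- lapply(split(seq_len(nrow(d)), key), function(idx) {
    sub <- d[idx, ]
    ci_b <- .boot_ci(sub$bias_pct, n_boot)
    ci_w <- .boot_ci(sub$wf, n_boot)
    tibble::tibble(task = sub$task[1], condition = sub$condition[1],
                   standard_n = sub$standard_n[1], n = nrow(sub),
                   bias_mean = mean(sub$bias_pct), bias_lo = ci_b[1],
                   bias_hi = ci_b[2], wf_mean = mean(sub$wf),
                   wf_lo = ci_w[1], wf_hi = ci_w[2])
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$task, out$condition, out$standard_n), ]
}

.boot_ci <- function(x, n_boot = 1000, conf = 0.95) {
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(n_boot), function(b) {
    mean(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  unname(stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' @export
print.numsym_analysis <- function(x, ...) {
  cat("<numsym_analysis>\n")
  cat(sprintf("  %d fitted cells (%d converged)\n", nrow(x$cells),
              sum(x$cells$converged)))
  for (nm in c("bias_anova_single", "bias_anova_attention", "wf_anova")) {
    if (!is.null(x[[nm]])) {
      cond <- x[[nm]][x[[nm]]$effect == "condition", ]
      if (nrow(cond)) {
        cat(sprintf("  %s: condition F(%d,%d) = %.2f, p = %.3g\n", nm,
                    cond$df, cond$df_error, cond$F, cond$p))
      }
    }
  }
  if (!is.null(x$conjunction)) {
    cat(sprintf("  conjunction (DT): W = %g, p = %.3g\n", x$conjunction$W,
                x$conjunction$p))
  }
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Persists `cells.csv`, `anova.json` (all ANOVA tables), `posthoc.csv`,
#' `conjunction.json` and `summary.md` under `dir`.
#'
#' @param analysis A `numsym_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  anovas <- Filter(Negate(is.null),
                   analysis[c("bias_anova_single", "bias_anova_attention",
                              "wf_anova")])
  jsonlite::write_json(lapply(anovas, as.data.frame),
                       file.path(dir, "anova.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  ph <- dplyr::bind_rows(
    if (!is.null(analysis$bias_posthoc))
      dplyr::mutate(analysis$bias_posthoc, family = "bias_attention"),
    if (!is.null(analysis$wf_posthoc))
      dplyr::mutate(analysis$wf_posthoc, family = "wf_task"))
  if (!is.null(ph) && nrow(ph)) {
    utils::write.csv(ph, file.path(dir, "posthoc.csv"), row.names = FALSE)
  }
  if (!is.null(analysis$conjunction)) {
    jsonlite::write_json(analysis$conjunction,
                         file.path(dir, "conjunction.json"), digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  writeLines(.summary_md(analysis), file.path(dir, "summary.md"))
  invisible(dir)
}

.summary_md <- function(analysis) {
  s <- analysis$summary
  lines <- c("# Cohort summary", "",
             "Cohort-mean bias (%) and Weber fraction with bootstrap 95% CIs",
             "", paste("| task | condition | N | bias mean | bias 95% CI |",
                       "Wf mean | Wf 95% CI |"),
             "|---|---|---|---|---|---|---|")
  for (r in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %d | %.2f | [%.2f, %.2f] | %.3f | [%.3f, %.3f] |",
      s$task[r], s$condition[r], s$standard_n[r], s$bias_mean[r],
      s$bias_lo[r], s$bias_hi[r], s$wf_mean[r], s$wf_lo[r], s$wf_hi[r]))
  }
  lines
}

#' Plot cohort-mean bias by numerosity
#'
#' Simple summary figure of the cohort-mean bias index per standard
#' numerosity, condition and task, with bootstrap CIs.  Requires ggplot2.
#'
#' @param analysis A `numsym_analysis`.
#' @return A ggplot object.
#' @export
plot_bias_summary <- function(analysis) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bias_summary requires the ggplot2 package")
  }
  s <- analysis$summary
  s$standard_n <- factor(s$standard_n)
  ggplot2::ggplot(s, ggplot2::aes(x = .data[["standard_n"]],
                                  y = .data[["bias_mean"]],
                                  colour = .data[["condition"]],
                                  group = .data[["condition"]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data[["bias_lo"]],
                                          ymax = .data[["bias_hi"]])) +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(x = "standard numerosity", y = "bias (%)",
                  colour = "condition")
}
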