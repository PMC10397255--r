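#' Experimental design specification
#'
#' The within-subject design of the dual-task numerosity study: every
#' participant completes, for each task level, two 50-trial sessions per
#' combination of standard numerosity (8, 12, 24, 50) and condition
#' (symmetry, random), i.e. 4 x 2 x 2 x 50 = 800 trials per task, 400 per
#' condition.
#'
#' @param standard_numerosities Integer vector of standard numerosities.
#' @param conditions Character vector, subset of `c("symmetry", "random")`.
#' @param tasks Character vector, subset of `c("ST", "ST_WD", "DT")`.
#' @param sessions_per_cell Sessions per (task, standard, condition) cell.
#' @param trials_per_session Trials per session (one fresh QUEST staircase
#'   per session).
#' @param n_participants Cohort size.
#' @param seed Master seed for the simulated experiment.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(standard_numerosities = c(8L, 12L, 24L, 50L),
                        conditions = c("symmetry", "random"),
                        tasks = c("ST", "ST_WD", "DT"),
                        sessions_per_cell = 2L, trials_per_session = 50L,
                        n_participants = 26L, seed = 20230801L) {
  conditions <- match.arg(conditions, c("symmetry", "random"),
                          several.ok = TRUE)
  tasks <- match.arg(tasks, c("ST", "ST_WD", "DT"), several.ok = TRUE)
  stopifnot(all(standard_numerosities >= 2),
            sessions_per_cell >= 1, trials_per_session >= 1,
            n_participants >= 1, seed == round(seed))
  structure(list(standard_numerosities = as.integer(standard_numerosities),
                 conditions = conditions, tasks = tasks,
                 sessions_per_cell = as.integer(sessions_per_cell),
                 trials_per_session = as.integer(trials_per_session),
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Build one participant's trial schedule
#'
#' Enumerates every session block (task x standard numerosity x condition x
#' session) with sequential trial indices, randomises which interval holds
#' the standard on each trial, and marks 50% of `ST_WD` / `DT` trials as
#' conjunction targets (four of the eight possible colour arrangements are
#' targets).  Test numerosities are not scheduled here — they are chosen
#' on-line by the QUEST staircase during [run_simulated_experiment()].
#'
#' @param design A [design_spec()].
#' @return A tibble with one row per trial: `task`, `standard_n`,
#'   `condition`, `session`, `trial_index`, `standard_interval`,
#'   `conj_is_target`.  Uses the global RNG stream for the per-trial
#'   randomisations.
#' @export
build_schedule <- function(design = design_spec()) {
  blocks <- expand.grid(session = seq_len(design$sessions_per_cell),
                        condition = design$conditions,
                        standard_n = design$standard_numerosities,
                        task = design$tasks,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tps <- design$trials_per_session
  n_tot <- nrow(blocks) * tps
  sched <- tibble::tibble(
    task = rep(blocks$task, each = tps),
    standard_n = rep(blocks$standard_n, each = tps),
    condition = rep(blocks$condition, each = tps),
    session = rep(blocks$session, each = tps),
    trial_index = rep(seq_len(tps), nrow(blocks)),
    standard_interval = ifelse(stats::runif(n_tot) < 0.5, "first", "second"),
    conj_is_target = ifelse(rep(blocks$task, each = tps) == "ST", NA,
                            stats::runif(n_tot) < 0.5))
  sched
}

#' Population parameters for cohort sampling
#'
#' Generative population from which simulated participants are drawn.  Bias
#' multipliers and noise coefficients are task-specific Gaussians (truncated
#' to the observer-parameter ranges).  Individual symmetry susceptibility is
#' correlated across tasks: each participant's multiplier deviations share a
#' common factor with loading `cor_loading`, so that observers strongly
#' biased in the single task tend to stay biased in the dual task (cross-task
#' correlation `cor_loading^2`), as the single- vs dual-task scatter of
#' individual biases suggests.  Defaults encode the study conditions: a
#' ~7.9% symmetric-standard underestimation in the single task, ~6.4% with a
#' to-be-ignored distractor, ~3% under divided attention, and noise
#' coefficients yielding Weber fractions near 0.20 (single) and 0.38 (dual).
#' The between-subject bias-multiplier SDs are calibrated so that the
#' *total* between-participant dispersion of recovered biases (generative
#' spread plus the pipeline's measurement noise) reproduces the observed
#' dispersions of about 5.9, 5.3 and 4.8 bias points in the three tasks;
#' see the methods vignette for the calibration.
#'
#' @param b_sym_mean,b_sym_sd Named numeric (tasks `ST`, `ST_WD`, `DT`):
#'   population mean / SD of the symmetric-standard bias multiplier.
#' @param s_mean,s_sd Named numeric: population mean / SD of the noise
#'   coefficient per task.
#' @param cor_loading Loading of the shared susceptibility factor, in
#'   \\[0, 1]; 0 makes tasks independent, 1 perfectly correlated.
#' @param lapse Common lapse rate.
#' @param conj_mean,conj_sd Named numeric (`random`, `symmetry`): population
#'   mean / SD of conjunction-task accuracy.
#' @return An object of class `population_params`.
#' @export
population_params <- function(
    b_sym_mean = c(ST = 0.9213, ST_WD = 0.936, DT = 0.97),
    b_sym_sd = c(ST = 0.054, ST_WD = 0.049, DT = 0.033),
    s_mean = c(ST = 0.2096, ST_WD = 0.2096, DT = 0.3984),
    s_sd = c(ST = 0.03, ST_WD = 0.03, DT = 0.06),
    cor_loading = 0.85,
    lapse = 0.02,
    conj_mean = c(random = 0.96, symmetry = 0.94),
    conj_sd = c(random = 0.03, symmetry = 0.04)) {
  tasks <- c("ST", "ST_WD", "DT")
  conds <- c("random", "symmetry")
  pop <- list(b_sym_mean = .per_task(b_sym_mean, tasks, "b_sym_mean"),
              b_sym_sd = .per_task(b_sym_sd, tasks, "b_sym_sd"),
              s_mean = .per_task(s_mean, tasks, "s_mean"),
              s_sd = .per_task(s_sd, tasks, "s_sd"),
              cor_loading = cor_loading, lapse = lapse,
              conj_mean = .per_task(conj_mean, conds, "conj_mean"),
              conj_sd = .per_task(conj_sd, conds, "conj_sd"))
  stopifnot(all(pop$b_sym_sd >= 0), all(pop$s_sd >= 0), all(pop$s_mean > 0),
            cor_loading >= 0, cor_loading <= 1, all(pop$conj_sd >= 0))
  structure(pop, class = "population_params")
}

# truncated-normal draw by rejection (narrow truncation never bites at the
# population defaults; the loop is a safety net)
.rtrunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Sample a simulated cohort
#'
#' Draws `n` observers from a [population_params()] model.  Bias multipliers
#' are built as `mean + sd * (rho * g_i + sqrt(1 - rho^2) * e_it)` with a
#' shared standard-normal susceptibility factor `g_i` per participant and
#' independent task residuals `e_it`, then truncated to (0, 1.5]; noise
#' coefficients use the same construction truncated to (0.02, Inf).
#'
#' @param n Cohort size.
#' @param population A [population_params()].
#' @return A list of `n` [observer_params()] objects.  Uses the global RNG
#'   stream.
#' @export
sample_cohort <- function(n, population = population_params()) {
  stopifnot(n >= 1)
  pop <- population
  rho <- pop$cor_loading
  tasks <- c("ST", "ST_WD", "DT")
  lapply(seq_len(n), function(i) {
    g_b <- stats::rnorm(1)
    g_s <- stats::rnorm(1)
    b <- vapply(tasks, function(tk) {
      z <- rho * g_b + sqrt(1 - rho^2) * stats::rnorm(1)
      x <- pop$b_sym_mean[[tk]] + pop$b_sym_sd[[tk]] * z
      min(1.5, max(1e-6, x))
    }, numeric(1))
    s <- vapply(tasks, function(tk) {
      z <- rho * g_s + sqrt(1 - rho^2) * stats::rnorm(1)
      max(0.02, pop$s_mean[[tk]] + pop$s_sd[[tk]] * z)
    }, numeric(1))
    pc <- c(random = .rtrunc(1, pop$conj_mean[["random"]],
                             pop$conj_sd[["random"]], 0.5, 1),
            symmetry = .rtrunc(1, pop$conj_mean[["symmetry"]],
                               pop$conj_sd[["symmetry"]], 0.5, 1))
    observer_params(s = s, b_sym = b, lapse = pop$lapse, conj_accuracy = pc,
                    id = sprintf("P%02d", i))
  })
}

#' Run a full simulated experiment
#'
#' Drives every scheduled trial of every participant through the closed
#' loop: a fresh QUEST staircase per (participant, task, condition, standard
#' numerosity, session) proposes the test numerosity, the generative
#' observer produces the two-interval response (and, in `ST_WD` / `DT`
#' blocks, the conjunction response), and the staircase ingests the outcome.
#' Stimulus dot arrays are not materialised by default because the observer
#' model depends only on numerosities; set `materialize_stimuli = TRUE` to
#' generate and validate the actual arrays for geometric audits (slower).
#'
#' Reproducibility: the design's master seed spawns one independent substream
#' per participant x task, so results are invariant to the order in which
#' participants are simulated.
#'
#' @param design A [design_spec()].
#' @param cohort List of [observer_params()], length `design$n_participants`.
#'   Default draws one from [population_params()] under the master seed.
#' @param geom A [field_geometry()] (used only when materialising stimuli).
#' @param materialize_stimuli Logical; also generate the dot arrays.
#' @param quest_config Named list overriding [quest_init()] arguments
#'   (`prior_mean`, `prior_sd`, `slope_beta`, `lapse_delta`, `jitter`).
#' @return A tibble (the trial table) with columns `participant_id`, `task`,
#'   `condition`, `standard_n`, `test_n`, `standard_interval`,
#'   `response_test_more`, `conj_is_target`, `conj_correct`, `session`,
#'   `trial_index`, `quest_posterior_mean`; when stimuli are materialised,
#'   an attribute `"stimuli"` holds the per-trial arrays.
#' @export
run_simulated_experiment <- function(design = design_spec(), cohort = NULL,
                                     geom = field_geometry(),
                                     materialize_stimuli = FALSE,
                                     quest_config = list()) {
  qc <- utils::modifyList(list(prior_mean = 0, prior_sd = 0.3,
                               slope_beta = 0.15, lapse_delta = 0.02,
                               jitter = 0.15), quest_config)
  if (is.null(cohort)) {
    set.seed(design$seed)
    cohort <- sample_cohort(design$n_participants)
  }
  if (length(cohort) != design$n_participants) {
    stop("cohort length must equal design$n_participants")
  }
  n_tasks <- length(design$tasks)
  set.seed(design$seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max,
                                 design$n_participants * n_tasks),
                      nrow = design$n_participants)
  out <- vector("list", design$n_participants * n_tasks)
  stim <- if (materialize_stimuli) list() else NULL
  k <- 0L
  for (i in seq_len(design$n_participants)) {
    prm <- cohort[[i]]
    for (ti in seq_len(n_tasks)) {
      task <- design$tasks[ti]
      set.seed(sub_seeds[i, ti])
      res <- .run_participant_task(design, prm, task, qc)
      k <- k + 1L
      out[[k]] <- res$table
      if (materialize_stimuli) {
        stim <- c(stim, .materialize_block(res$table, geom))
      }
    }
  }
  tab <- dplyr::bind_rows(out)
  if (materialize_stimuli) attr(tab, "stimuli") <- stim
  tab
}

# all sessions of one participant x task, on the current RNG stream.
# Each session block runs through the compiled closed loop (src/), whose
# staircase arithmetic matches quest_update()/quest_next(); equivalence is
# asserted in the tests by replaying recorded sessions through the R path.
.run_participant_task <- function(design, prm, task, qc) {
  grid <- seq(-0.5, 0.5, length.out = 201)
  prior <- stats::dnorm(grid, qc$prior_mean, qc$prior_sd)
  prior <- prior / sum(prior)
  s_task <- prm$s[[task]]
  has_conj <- task != "ST"
  tps <- design$trials_per_session

  blocks <- list()
  meta <- list()
  for (std in design$standard_numerosities) {
    for (cond in design$conditions) {
      b <- if (cond == "symmetry") prm$b_sym[[task]] else 1
      p_conj <- prm$conj_accuracy[[if (cond == "symmetry") "symmetry"
                                   else "random"]]
      for (sess in seq_len(design$sessions_per_cell)) {
        r <- .run_session_cpp(as.integer(std), tps, grid, prior,
                              qc$slope_beta, qc$lapse_delta, 0, qc$jitter,
                              b, s_task, prm$lapse, has_conj, p_conj)
        blocks[[length(blocks) + 1L]] <- r
        meta[[length(meta) + 1L]] <- list(std = std, cond = cond,
                                          sess = sess)
      }
    }
  }
  nb <- length(blocks)
  pull <- function(field) unlist(lapply(blocks, `[[`, field),
                                 use.names = FALSE)
  list(table = tibble::tibble(
    participant_id = prm$id, task = task,
    condition = rep(vapply(meta, `[[`, "", "cond"), each = tps),
    standard_n = rep(vapply(meta, function(m) as.integer(m$std),
                            integer(1)), each = tps),
    test_n = pull("test_n"),
    standard_interval = ifelse(pull("interval_first"), "first", "second"),
    response_test_more = pull("response"),
    conj_is_target = if (has_conj) pull("conj_target") else NA,
    conj_correct = if (has_conj) pull("conj_correct") else NA,
    session = rep(vapply(meta, function(m) as.integer(m$sess), integer(1)),
                  each = tps),
    trial_index = rep(seq_len(tps), nb),
    quest_posterior_mean = pull("posterior_mean")))
}

# generate and validate the two dot arrays of each trial in a block result
.materialize_block <- function(tab, geom) {
  lapply(seq_len(nrow(tab)), function(r) {
    std_arr <- if (tab$condition[r] == "symmetry") {
      sample_symmetric_array(tab$standard_n[r], geom)
    } else {
      sample_random_array(tab$standard_n[r], geom)
    }
    test_arr <- sample_random_array(tab$test_n[r], geom)
    stopifnot(length(validate_array(std_arr, geom)) == 0,
              length(validate_array(test_arr, geom)) == 0)
    list(standard = std_arr, test = test_arr)
  })
}
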