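# Shared simulation helpers for the test suite: build small cohorts and run
# them through the full closed loop, returning fitted cells.

# population with all between-subject SDs zero: every observer has exactly
# the stated parameters
fixed_population <- function(b = c(ST = 1, ST_WD = 1, DT = 1),
                             s = c(ST = 0.2096, ST_WD = 0.2096, DT = 0.3984),
                             lapse = 0.02) {
  population_params(b_sym_mean = b, b_sym_sd = c(ST = 0, ST_WD = 0, DT = 0),
                    s_mean = s, s_sd = c(ST = 0, ST_WD = 0, DT = 0),
                    cor_loading = 0, lapse = lapse)
}

# simulate one cohort and fit every cell
sim_cells <- function(n_subj, tasks, stds, tps, pop, seed,
                      sessions = 1L, conditions = c("symmetry", "random")) {
  des <- design_spec(standard_numerosities = stds, conditions = conditions,
                     tasks = tasks, sessions_per_cell = sessions,
                     trials_per_session = tps, n_participants = n_subj,
                     seed = seed)
  set.seed(des$seed)
  coh <- sample_cohort(n_subj, pop)
  aggregate_cells(run_simulated_experiment(des, coh))
}

# keep only participants with a full set of converged cells (the RM ANOVA
# needs complete data)
complete_cells <- function(cells, n_cell) {
  d <- cells[cells$converged, ]
  cnt <- table(d$participant_id)
  d[d$participant_id %in% names(cnt)[cnt == n_cell], ]
}

# per-participant mean of a cell statistic for one task x condition
participant_means <- function(cells, task, condition, col = "bias_pct") {
  d <- cells[cells$task == task & cells$condition == condition &
               cells$converged, ]
  tapply(d[[col]], d$participant_id, mean)
}
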