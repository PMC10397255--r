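test_that("the default schedule reproduces the design totals", {
  set.seed(1)
  sched <- build_schedule(design_spec())
  expect_identical(nrow(sched), 3L * 800L)
  counts <- table(sched$task)
  expect_true(all(counts == 800))
  by_cond <- table(sched$task, sched$condition)
  expect_true(all(by_cond == 400))
  # interval randomisation: binomial 99% interval around one half
  frac <- mean(sched$standard_interval == "first")
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / nrow(sched)))
  # conjunction stimuli only outside the plain single task
  expect_true(all(is.na(sched$conj_is_target[sched$task == "ST"])))
  expect_false(anyNA(sched$conj_is_target[sched$task != "ST"]))
})

test_that("schedule counts hold for arbitrary valid designs", {
  set.seed(2)
  for (i in 1:5) {
    des <- design_spec(
      standard_numerosities = sample(5:60, sample(2:4, 1)),
      tasks = sample(c("ST", "ST_WD", "DT"), sample(1:3, 1)),
      sessions_per_cell = sample(1:3, 1),
      trials_per_session = sample(10:60, 1))
    sched <- build_schedule(des)
    per_task <- length(des$standard_numerosities) * 2 *
      des$sessions_per_cell * des$trials_per_session
    expect_true(all(table(sched$task) == per_task))
    expect_true(all(table(sched$session) ==
                      nrow(sched) / des$sessions_per_cell))
  }
})

test_that("cohort sampling respects the population model", {
  pop <- fixed_population(b = c(ST = 0.9213, ST_WD = 0.936, DT = 0.97))
  set.seed(3)
  coh <- sample_cohort(5, pop)
  expect_length(coh, 5)
  b_st <- vapply(coh, function(o) o$b_sym[["ST"]], numeric(1))
  expect_true(all(b_st == 0.9213))  # zero SD: identical participants

  set.seed(4)
  coh26 <- sample_cohort(26)
  expect_length(coh26, 26)
  for (o in coh26) {
    expect_true(all(o$s > 0))
    expect_true(all(o$b_sym > 0 & o$b_sym <= 1.5))
    expect_true(all(o$conj_accuracy >= 0.5 & o$conj_accuracy <= 1))
  }

  # moments of the marginal bias-multiplier distribution
  set.seed(5)
  big <- sample_cohort(10000)
  pop_def <- population_params()
  b_dt <- vapply(big, function(o) o$b_sym[["DT"]], numeric(1))
  expect_lt(abs(mean(b_dt) - pop_def$b_sym_mean[["DT"]]),
            3 * pop_def$b_sym_sd[["DT"]] / sqrt(10000))
  expect_lt(abs(sd(b_dt) - pop_def$b_sym_sd[["DT"]]),
            3 * pop_def$b_sym_sd[["DT"]] / sqrt(2 * 10000))
})

test_that("identical seeds give identical trial tables", {
  des <- design_spec(standard_numerosities = c(12, 24), tasks = "ST",
                     sessions_per_cell = 1L, trials_per_session = 10L,
                     n_participants = 2L, seed = 99L)
  t1 <- run_simulated_experiment(des)
  t2 <- run_simulated_experiment(des)
  expect_identical(t1, t2)
})

test_that("the compiled session loop matches the R-level staircase", {
  des <- design_spec(standard_numerosities = c(8, 50), tasks = "DT",
                     sessions_per_cell = 1L, trials_per_session = 40L,
                     n_participants = 1L, seed = 7L)
  tr <- run_simulated_experiment(des)
  for (std in c(8, 50)) {
    for (cond in c("symmetry", "random")) {
      blk <- tr[tr$standard_n == std & tr$condition == cond, ]
      q <- quest_init()
      for (i in seq_len(nrow(blk))) {
        expect_equal(quest_estimate(q), blk$quest_posterior_mean[i],
                     tolerance = 1e-12)
        q <- quest_update(q, log10(blk$test_n[i] / std),
                          blk$response_test_more[i])
      }
      # every placement obeys the clamp and never equals the standard
      expect_true(all(blk$test_n >= max(2, round(std / 3))))
      expect_true(all(blk$test_n <= 3 * std))
      expect_false(any(blk$test_n == std))
    }
  }
})

test_that("the full default experiment runs quickly and is well formed", {
  t0 <- Sys.time()
  tr <- run_simulated_experiment(design_spec(seed = 1L))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_identical(nrow(tr), 26L * 2400L)
  expect_identical(length(unique(tr$participant_id)), 26L)
  expect_true(all(is.na(tr$conj_correct[tr$task == "ST"])))
  expect_false(anyNA(tr$conj_correct[tr$task != "ST"]))

  # a biased symmetric standard shifts responses: below the implied PSE the
  # observer should mostly answer "standard more numerous"
  pop <- fixed_population(b = c(ST = 0.9213, ST_WD = 1, DT = 1))
  des <- design_spec(tasks = "ST", seed = 12L)
  set.seed(des$seed)
  tr2 <- run_simulated_experiment(des, sample_cohort(26, pop))
  sym <- tr2[tr2$condition == "symmetry", ]
  low <- sym[sym$test_n < 0.9213 * sym$standard_n, ]
  expect_gt(nrow(low), 1000)
  expect_lt(mean(low$response_test_more), 0.5)
})

test_that("stimulus materialisation yields valid arrays", {
  des <- design_spec(standard_numerosities = 12L, tasks = "ST",
                     sessions_per_cell = 1L, trials_per_session = 5L,
                     n_participants = 1L, seed = 8L)
  tr <- run_simulated_experiment(des, materialize_stimuli = TRUE)
  stim <- attr(tr, "stimuli")
  expect_length(stim, nrow(tr))
  expect_identical(stim[[1]]$standard$arrangement, "symmetric")
  expect_identical(stim[[1]]$standard$n, 12L)
  expect_identical(stim[[1]]$test$n, as.integer(tr$test_n[1]))
})
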