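# numsym

Simulation and analysis of **symmetry-induced numerosity underestimation**
in dual-task two-interval experiments.

Mirror-symmetric dot arrays are judged less numerous than random arrays of
the same count — a signature of Gestalt grouping feeding the approximate
number system — and the effect shrinks by about half when attention is
occupied by a concurrent task.  `numsym` is a complete in-silico laboratory
for this paradigm, written for perceptual scientists who want to study the
estimation pipeline itself (adaptive placement, psychometric fitting,
within-subject statistics) by parameter recovery on synthetic cohorts:

* **Stimuli** — random and vertically mirror-symmetric dot arrays in a 10°
  field (0.3° dots, 0.3° minimum edge separation, central 1.6° × 1.6°
  exclusion zone), with convex-hull audits.
* **Observers** — generative participants with a multiplicative
  underestimation `b` of the symmetric standard, scalar internal noise
  `s`, lapses, and conjunction-task accuracy; the implied choice rule is
  `P(test more) = λ/2 + (1−λ)·Φ((x − bN)/(√2·s·N))`, so PSE = `bN` and
  Weber fraction → `0.954·s` exactly.
* **QUEST** — a gridded Bayesian staircase on the log test/standard ratio
  with jittered placement, one fresh state per session.
* **Psychometrics** — deterministic binomial MLE of the cumulative
  Gaussian per cell; PSE, JND (50%→75% span), Bias = (PSE/N − 1)·100 and
  Wf = JND/N.
* **Inference** — fully within-subject RM ANOVA with Greenhouse–Geisser
  correction and classical η², Bonferroni-corrected paired t-tests with
  Cohen's d, exact Wilcoxon signed-rank, and exact noncentral-t power
  analysis.

The default synthetic population encodes the study conditions: 26
participants; standards 8/12/24/50; symmetric-standard underestimation of
~7.9% (single task), ~6.4% (ignored distractor) and ~3% (dual task); noise
yielding Weber fractions ~0.20 (single) and ~0.38 (dual); 800 trials per
task per participant (two 50-trial sessions per standard × condition).

## Worked example

```r
library(numsym)

# how many participants does the design need?
cli_power(d = 0.75, alpha = 0.05, power = 0.95, tails = 2)
#> required n = 26 (achieved power 0.9567)

# simulate the full default experiment and run the analysis battery
des <- design_spec(seed = 2026L)
set.seed(des$seed)
cohort <- sample_cohort(26)
trials <- run_simulated_experiment(des, cohort)   # 62,400 trials, ~1 s
analysis <- analyze_trials(trials)
analysis
#> <numsym_analysis>
#>   624 fitted cells (624 converged)
#>   bias_anova_single: condition F(1,25) = 66.91, p = 1.56e-08
#>   bias_anova_attention: condition F(1,25) = 16.86, p = 0.000377
#>   wf_anova: condition F(1,25) = 0.10, p = 0.756
#>   conjunction (DT): W = 64.5, p = 0.005

aggregate(cbind(bias_mean, wf_mean) ~ task + condition, analysis$summary, mean)
#>    task condition bias_mean wf_mean
#> 1    DT    random     0.340   0.367
#> 2    ST    random     0.745   0.201
#> 3 ST_WD    random    -0.403   0.204
#> 4    DT  symmetry    -1.995   0.377
#> 5    ST  symmetry    -7.787   0.204
#> 6 ST_WD  symmetry    -5.494   0.198
```

Read the table as the experiment would be reported: random-condition
biases hover near zero (accurate baseline); symmetric standards are
underestimated by ~7.8% in the single task, less with a passive
distractor, and the effect is reduced — but still negative — under divided
attention, while precision (Wf) degrades from ~0.20 to ~0.37 in the dual
task independently of condition.  The condition main effect of the
single-task bias ANOVA (`F(1,25) = 66.9`) and the significant
condition × task interaction in the attention ANOVA carry the two
headline inferences; the Wilcoxon test shows conjunction accuracy is
slightly worse alongside symmetric stimuli.

A JSON config drives the same pipeline from files (see
`inst/extdata/config_small.json`):

```r
cfg <- read_config(system.file("extdata", "config_small.json", package = "numsym"))
cli_simulate(cfg, out_dir = "out")      # trials.csv, cohort.json, config.json
cli_analyze("out/trials.csv", "out")    # cells.csv, anova.json, posthoc.csv, summary.md
```

or from a shell via `Rscript inst/cli/numsym.R simulate|analyze|power ...`.

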