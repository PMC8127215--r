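# Career simulation engine: plans, jitter, sampling, condition careers,
# cohort cubes, and their statistical properties against the analytic oracle.

test_that("configuration invariants are enforced", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(sim_config(n_clinicians = 0), "n_clinicians")
  expect_error(sim_config(years = 0), "years")
  expect_error(sim_config(max_job_changes = 30, years = 30), "years")
  expect_error(sim_config(min_job_changes = 5, max_job_changes = 2), "max_job_changes")
  expect_error(sim_config(attrition_rate = 1), "attrition_rate")
  expect_error(sim_config(jitter_fraction = -0.1), "jitter_fraction")
  expect_error(sim_config(sampling_mode = "poisson"))
})

test_that("career plans respect the job-change range and exclude year 1", {
  cfg0 <- tiny_config(min_job_changes = 0, max_job_changes = 0)
  set.seed(1)
  expect_identical(draw_career_plan(cfg0, 1)$job_change_years, integer(0))

  cfg_all <- tiny_config(years = 6, min_job_changes = 5, max_job_changes = 5)
  set.seed(1)
  expect_identical(draw_career_plan(cfg_all, 1)$job_change_years, 2:6)

  cfg <- sim_config(n_clinicians = 97, years = 30, min_job_changes = 2,
                    max_job_changes = 10, seed = 1)
  set.seed(42)
  for (i in 1:50) {
    plan <- draw_career_plan(cfg, i)
    jc <- plan$job_change_years
    expect_gte(length(jc), 2)
    expect_lte(length(jc), 10)
    expect_true(all(jc >= 2 & jc <= 30))
    expect_identical(anyDuplicated(jc), 0L)
  }
})

test_that("prevalence jitter is bounded, unbiased, and exact at zero", {
  expect_identical(jittered_prevalence(0.3, 0), 0.3)
  set.seed(7)
  draws <- jittered_prevalence(rep(0.01, 1e5), 0.15)
  expect_true(all(draws >= 0.0085 & draws <= 0.0115))
  # uniform jitter has zero mean; SE of the mean = p * j / sqrt(3 * n)
  se <- 0.01 * 0.15 / sqrt(3 * 1e5)
  expect_lt(abs(mean(draws) - 0.01), 3 * se)
  expect_error(jittered_prevalence(1.2, 0.15), "0, 1")
})

test_that("new patients: full panel in year 1 and at changes, attrition share otherwise", {
  cfg <- tiny_config(panel_size = 1500, attrition_rate = 0.10, years = 10)
  plan <- structure(list(clinician_index = 1L, job_change_years = c(4L, 7L)),
                    class = "career_plan")
  expect_identical(new_patient_count(plan, 1, cfg), 1500L)
  expect_identical(new_patient_count(plan, 4, cfg), 1500L)
  expect_identical(new_patient_count(plan, 5, cfg), 150L)
  cfg2000 <- tiny_config(panel_size = 2000, years = 10)
  expect_identical(new_patient_count(plan, 7, cfg2000), 2000L)
  expect_error(new_patient_count(plan, 11, cfg), "out of range")
})

test_that("case-count sampling has the right support and mean in both modes", {
  set.seed(3)
  expect_identical(sample_case_count(1000, 0, "binomial"), 0L)
  expect_identical(sample_case_count(1000, 0, "expected_branch"), 0L)
  expect_identical(sample_case_count(57, 1, "binomial"), 57L)

  # one case/year at the rare-disease threshold on a 2000-patient panel
  for (mode in c("binomial", "expected_branch")) {
    reps <- sample_case_count(rep(2000, 1e4), 1 / 2000, mode)
    se <- sqrt(2000 * (1 / 2000)) / sqrt(1e4) # binomial sd ~ sqrt(np)
    expect_lt(abs(mean(reps) - 1), 3 * se)
  }

  # expected-cases branch: lambda = 2.4 gives only {2, 3}, mean 2.4
  reps <- sample_case_count(rep(240, 1e4), 0.01, "expected_branch")
  expect_setequal(unique(reps), c(2L, 3L))
  se <- sqrt(0.4 * 0.6) / sqrt(1e4)
  expect_lt(abs(mean(reps) - 2.4), 3 * se)
})

test_that("spontaneous careers: counts equal new counts; zero prevalence is silent", {
  cfg <- tiny_config(years = 12)
  plan <- structure(list(clinician_index = 1L, job_change_years = 5L),
                    class = "career_plan")
  set.seed(5)
  res <- simulate_condition_career(
    list(prevalence = 0.02, acquisition_class = "spontaneous"), plan, cfg)
  expect_length(res$counts, 12)
  expect_identical(res$counts, res$new_counts)
  res0 <- simulate_condition_career(
    list(prevalence = 0, acquisition_class = "spontaneous"), plan, cfg)
  expect_identical(res0$counts, rep(0L, 12))
})

test_that("congenital caseload accumulates, resets only at practice changes", {
  # no changes, no attrition: nothing new after year 1
  cfg_static <- tiny_config(years = 10, min_job_changes = 0,
                            max_job_changes = 0, attrition_rate = 0)
  plan0 <- structure(list(clinician_index = 1L, job_change_years = integer(0)),
                     class = "career_plan")
  set.seed(8)
  res <- simulate_condition_career(
    list(prevalence = 0.05, acquisition_class = "congenital"), plan0, cfg_static)
  expect_identical(res$counts, rep(res$counts[1], 10))
  expect_identical(res$new_counts[-1], rep(0L, 9))

  # with changes: non-decreasing between changes, fresh draw at each change
  cfg <- tiny_config(years = 20, panel_size = 500)
  plan <- structure(list(clinician_index = 1L, job_change_years = c(6L, 13L)),
                    class = "career_plan")
  set.seed(9)
  for (rep in 1:20) {
    res <- simulate_condition_career(
      list(prevalence = 0.01, acquisition_class = "congenital"), plan, cfg)
    runs <- split(seq_len(20), findInterval(seq_len(20), c(1, 6, 13)))
    for (run in runs) {
      expect_true(all(diff(res$counts[run]) >= 0))
    }
    # newly acquired cannot exceed the new-patient intake
    intake <- vapply(1:20, function(y) new_patient_count(plan, y, cfg), 1L)
    expect_true(all(res$new_counts <= intake))
  }
})

test_that("cohort simulation is bit-deterministic and prefix-stable in cohort size", {
  dl <- build_disease_list(n_conditions = 25, n_congenital = 6, seed = 2)
  cfg <- tiny_config(seed = 21)
  a <- simulate_cohort(cfg, dl)
  b <- simulate_cohort(cfg, dl)
  expect_identical(a$counts, b$counts)
  expect_identical(a$new_counts, b$new_counts)
  # growing the cohort leaves earlier clinicians untouched
  bigger <- simulate_cohort(tiny_config(seed = 21, n_clinicians = 7), dl)
  expect_identical(a$counts, bigger$counts[1:4, , ])
  # different seed, different realisation
  expect_false(identical(a$counts,
                         simulate_cohort(tiny_config(seed = 22), dl)$counts))
})

test_that("cube respects structural invariants", {
  dl <- build_disease_list(n_conditions = 25, n_congenital = 6, seed = 2)
  cfg <- tiny_config(seed = 31, panel_size = 50)
  cube <- simulate_cohort(cfg, dl)
  expect_true(all(cube$counts >= 0))
  expect_true(all(cube$counts <= cfg$panel_size))
  spont <- which(dl$acquisition_class == "spontaneous")
  expect_identical(cube$counts[, , spont], cube$new_counts[, , spont])
  # congenital: counts non-decreasing between practice changes
  cong <- which(dl$acquisition_class == "congenital")
  for (i in seq_len(cfg$n_clinicians)) {
    jc <- cube$plans[[i]]$job_change_years
    segs <- split(seq_len(cfg$years), findInterval(seq_len(cfg$years), c(1, jc)))
    for (j in cong) {
      for (seg in segs) {
        expect_true(all(diff(cube$counts[i, seg, j]) >= 0))
      }
    }
  }
})

test_that("an all-zero-prevalence condition yields an all-zero cube", {
  cfg <- sim_config(n_clinicians = 1, years = 1, panel_size = 100,
                    min_job_changes = 0, max_job_changes = 0, seed = 1)
  cube <- simulate_cohort(cfg, single_condition_list(0))
  expect_true(all(cube$counts == 0))
  expect_true(all(cube$new_counts == 0))
})

test_that("simulated means match the analytic expectation oracle across a prevalence grid", {
  # 200 replicate seeds; totals of a spontaneous condition are
  # Binomial(C * Y * panel, p) when jitter = 0, so the Monte Carlo SE of the
  # replicate mean is sqrt(n p (1 - p) / R)
  cfg_base <- list(n_clinicians = 5L, years = 4L, panel_size = 400L,
                   min_job_changes = 0L, max_job_changes = 2L,
                   jitter_fraction = 0)
  for (p in c(1e-2, 1e-3, 2.5e-4)) {
    dl <- single_condition_list(p)
    totals <- vapply(1:200, function(r) {
      cfg <- do.call(sim_config, c(cfg_base, list(seed = 1000L + r)))
      sum(simulate_cohort(cfg, dl)$counts)
    }, 0)
    n_trials <- 5 * 4 * 400
    expected <- expected_cohort_cases(p, 400, 4, 5)
    se <- sqrt(n_trials * p * (1 - p) / 200)
    expect_lt(abs(mean(totals) - expected), 3 * se)
  }
})

test_that("with no jitter, spontaneous totals have binomial spread", {
  p <- 5e-3
  dl <- single_condition_list(p)
  totals <- vapply(1:200, function(r) {
    cfg <- sim_config(n_clinicians = 4, years = 5, panel_size = 300,
                      min_job_changes = 0, max_job_changes = 0,
                      jitter_fraction = 0, seed = 5000L + r)
    sum(simulate_cohort(cfg, dl)$counts)
  }, 0)
  n_trials <- 4 * 5 * 300
  sigma2 <- n_trials * p * (1 - p)
  # s^2 / sigma^2 ~ chi2_{R-1} / (R-1): sd ~ sqrt(2/199) ~ 0.1; 4-sd band
  expect_gt(var(totals) / sigma2, 0.6)
  expect_lt(var(totals) / sigma2, 1.4)
})

test_that("expected-branch mode preserves the mean", {
  p <- 2e-3
  dl <- single_condition_list(p)
  totals <- vapply(1:200, function(r) {
    cfg <- sim_config(n_clinicians = 4, years = 3, panel_size = 300,
                      min_job_changes = 0, max_job_changes = 0,
                      jitter_fraction = 0, sampling_mode = "expected_branch",
                      seed = 7000L + r)
    sum(simulate_cohort(cfg, dl)$counts)
  }, 0)
  expected <- expected_cohort_cases(p, 300, 3, 4)
  # per-year count is Bernoulli(0.6); replicate total over 12 cells
  se <- sqrt(12 * 0.6 * 0.4 / 200)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("attrition_also mode erodes congenital caseloads between changes", {
  dl <- single_condition_list(0.05, "congenital")
  cfg <- sim_config(n_clinicians = 1, years = 15, panel_size = 1000,
                    min_job_changes = 0, max_job_changes = 0,
                    attrition_rate = 0.2, jitter_fraction = 0,
                    congenital_loss = "attrition_also", seed = 77)
  cube <- simulate_cohort(cfg, dl)
  series <- cube$counts[1, , 1]
  # steady state balances intake (200 * 0.05 = 10/yr) against 20% loss:
  # year-1 load ~50 decays toward ~50; here just check losses do occur
  expect_true(any(diff(series) < 0))
  # and in job_change_only mode they never do
  cfg2 <- sim_config(n_clinicians = 1, years = 15, panel_size = 1000,
                     min_job_changes = 0, max_job_changes = 0,
                     attrition_rate = 0.2, jitter_fraction = 0,
                     congenital_loss = "job_change_only", seed = 77)
  expect_true(all(diff(simulate_cohort(cfg2, dl)$counts[1, , 1]) >= 0))
})

test_that("long export matches the cube cell-by-cell", {
  dl <- build_disease_list(n_conditions = 10, n_congenital = 3, seed = 4)
  cube <- simulate_cohort(tiny_config(seed = 13, panel_size = 100), dl)
  lg <- cube_to_long(cube, drop_zero = FALSE)
  expect_identical(nrow(lg), 4L * 8L * 10L)
  for (k in sample(nrow(lg), 25)) {
    row <- lg[k, ]
    expect_identical(row$cases,
                     cube$counts[row$clinician, row$year, as.character(row$code)])
  }
  # zero-dropped view loses no cases
  lgz <- cube_to_long(cube, drop_zero = TRUE)
  expect_identical(sum(lgz$cases), sum(cube$counts))
})
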