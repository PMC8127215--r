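# Career simulation engine.
#
# Outer loop over clinicians, inner loop over conditions. Each clinician gets
# an independent L'Ecuyer-CMRG RNG substream derived from the master seed, so
# enlarging the cohort never perturbs earlier clinicians' careers.

#' Simulation configuration
#'
#' Bundles and validates every knob of the career simulation. Defaults follow
#' the reference cohort scenario: 97 clinicians practising 30 years on
#' 1500-patient dental panels, changing practice 2 to 10 times, with a
#' +/-15\% per-clinician prevalence jitter.
#'
#' @param n_clinicians Cohort size (>= 1).
#' @param years Career length in years (>= 1).
#' @param panel_size Patients per clinician panel (~2000 medical, ~1500
#'   dental).
#' @param min_job_changes,max_job_changes Range for the number of new
#'   practices started after the first; `max_job_changes <= years - 1`.
#' @param attrition_rate Fraction of the panel replaced by new patients in a
#'   year without a practice change (in `[0, 1)`). Not pinned by the source
#'   scenario; 0.10/year is a plausible panel turnover and the headline
#'   quantities (year-1 and spontaneous arithmetic) do not depend on it.
#' @param jitter_fraction Maximum relative prevalence perturbation; one
#'   uniform draw on `[-jitter_fraction, +jitter_fraction]` per
#'   (clinician, condition), mimicking fixed local demographics.
#' @param sampling_mode `"binomial"` draws case counts as
#'   Binomial(n_exposed, p); `"expected_branch"` reconstructs the
#'   expected-cases-below-1 branching (floor of the expectation plus a
#'   Bernoulli remainder). Both have mean `n_exposed * p`.
#' @param congenital_loss `"job_change_only"`: congenital caseloads persist
#'   until the clinician changes practice. `"attrition_also"`: each active
#'   congenital case is additionally lost each year with probability
#'   `attrition_rate`, conserving caseload with panel turnover.
#' @param seed Master integer seed.
#' @return A validated `sim_config` list.
#' @examples
#' sim_config(n_clinicians = 5, years = 10, panel_size = 1500)
#' @export
sim_config <- function(n_clinicians = 97L, years = 30L, panel_size = 1500L,
                       min_job_changes = 2L, max_job_changes = 10L,
                       attrition_rate = 0.10, jitter_fraction = 0.15,
                       sampling_mode = c("binomial", "expected_branch"),
                       congenital_loss = c("job_change_only", "attrition_also"),
                       seed = 1L) {
  sampling_mode <- match.arg(sampling_mode)
  congenital_loss <- match.arg(congenital_loss)
  stop_if_not(is_count(n_clinicians) && n_clinicians >= 1,
              "`n_clinicians` must be a positive integer")
  stop_if_not(is_count(years) && years >= 1, "`years` must be a positive integer")
  stop_if_not(is_count(panel_size) && panel_size >= 1,
              "`panel_size` must be a positive integer")
  stop_if_not(is_count(min_job_changes) && min_job_changes >= 0,
              "`min_job_changes` must be a non-negative integer")
  stop_if_not(is_count(max_job_changes) && max_job_changes >= min_job_changes,
              "`max_job_changes` must be an integer >= `min_job_changes`")
  stop_if_not(max_job_changes <= years - 1,
              "`max_job_changes` cannot exceed `years` - 1")
  stop_if_not(is_number(attrition_rate) && attrition_rate >= 0 && attrition_rate < 1,
              "`attrition_rate` must lie in [0, 1)")
  stop_if_not(is_number(jitter_fraction) && jitter_fraction >= 0 && jitter_fraction < 1,
              "`jitter_fraction` must lie in [0, 1)")
  stop_if_not(is_count(seed), "`seed` must be an integer")
  structure(
    list(n_clinicians = as.integer(n_clinicians), years = as.integer(years),
         panel_size = as.integer(panel_size),
         min_job_changes = as.integer(min_job_changes),
         max_job_changes = as.integer(max_job_changes),
         attrition_rate = attrition_rate, jitter_fraction = jitter_fraction,
         sampling_mode = sampling_mode, congenital_loss = congenital_loss,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Draw one clinician's career plan
#'
#' The number of practice changes is uniform on
#' `[min_job_changes, max_job_changes]`; change years are drawn uniformly
#' without replacement from years `2..years`. Year 1 is always a fresh panel
#' and never a "change" year. Consumes the current RNG stream; call within
#' [simulate_cohort()] or after `set.seed()` for reproducibility.
#'
#' @param config A [sim_config()].
#' @param clinician_index 1-based clinician id recorded in the plan.
#' @return A `career_plan`: list with `clinician_index` and sorted
#'   `job_change_years`.
#' @export
draw_career_plan <- function(config, clinician_index = 1L) {
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  stop_if_not(is_count(clinician_index) && clinician_index >= 1,
              "`clinician_index` must be a positive integer")
  n_changes <- sample_from(config$min_job_changes:config$max_job_changes, 1L)
  change_years <- if (n_changes > 0) {
    sort(sample_from(2:config$years, n_changes))
  } else {
    integer(0)
  }
  structure(list(clinician_index = as.integer(clinician_index),
                 job_change_years = as.integer(change_years)),
            class = "career_plan")
}

#' Jitter a prevalence value
#'
#' Adds or subtracts a uniform random fraction of up to `jitter_fraction` of
#' the prevalence: returns `p * (1 + u)` with
#' `u ~ Uniform(-jitter_fraction, jitter_fraction)`, clamped to `[0, 1]`.
#' Drawn once per (clinician, condition) pair by the engine and held fixed
#' over that career. Vectorised over `p` (one draw per element).
#'
#' @param p Prevalence value(s) in `[0, 1]`.
#' @param jitter_fraction Maximum relative perturbation (default 0.15).
#' @return Perturbed prevalence value(s).
#' @export
jittered_prevalence <- function(p, jitter_fraction = 0.15) {
  stop_if_not(all(p >= 0 & p <= 1), "`p` must lie in [0, 1]")
  stop_if_not(is_number(jitter_fraction) && jitter_fraction >= 0 && jitter_fraction < 1,
              "`jitter_fraction` must lie in [0, 1)")
  if (jitter_fraction == 0) return(p)
  u <- stats::runif(length(p), -jitter_fraction, jitter_fraction)
  pmin(pmax(p * (1 + u), 0), 1)
}

#' Number of new patients entering a panel in a given year
#'
#' The whole panel is new in year 1 and in any practice-change year;
#' otherwise only the attrition replacement fraction
#' `round(attrition_rate * panel_size)` (half away from zero) is new. New
#' patients are the only route by which congenital/persistent cases enter.
#'
#' @param plan A `career_plan`.
#' @param year Year of practice, `1..years`.
#' @param config A [sim_config()].
#' @return Integer count of new patients.
#' @export
new_patient_count <- function(plan, year, config) {
  stop_if_not(inherits(plan, "career_plan"), "`plan` must be a career_plan")
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  stop_if_not(is_count(year) && year >= 1 && year <= config$years,
              "`year` out of range")
  if (year == 1L || year %in% plan$job_change_years) {
    config$panel_size
  } else {
    as.integer(round_half_up(config$attrition_rate * config$panel_size))
  }
}

#' Sample a case count among exposed patients
#'
#' `"binomial"` mode draws Binomial(`n_exposed`, `p`) — the exact
#' patient-level model. `"expected_branch"` mode reproduces the branch on
#' whether the expected case number is below one: with
#' `lambda = n_exposed * p`, the count is `floor(lambda)` plus a
#' Bernoulli(`lambda - floor(lambda)`) remainder (for `lambda < 1` this is a
#' single Bernoulli(`lambda`) trial). Both modes have mean `n_exposed * p`.
#' Vectorised over `n_exposed`.
#'
#' @param n_exposed Number(s) of exposed patients (non-negative integers).
#' @param p Per-patient probability in `[0, 1]`.
#' @param mode `"binomial"` or `"expected_branch"`.
#' @return Integer case count(s).
#' @export
sample_case_count <- function(n_exposed, p,
                              mode = c("binomial", "expected_branch")) {
  mode <- match.arg(mode)
  stop_if_not(all(n_exposed >= 0 & n_exposed == floor(n_exposed)),
              "`n_exposed` must be non-negative integers")
  stop_if_not(is_number(p) && p >= 0 && p <= 1, "`p` must lie in [0, 1]")
  n_exposed <- as.integer(n_exposed)
  if (mode == "binomial") {
    stats::rbinom(length(n_exposed), n_exposed, p)
  } else {
    lambda <- n_exposed * p
    fl <- floor(lambda)
    as.integer(fl + stats::rbinom(length(lambda), 1L, lambda - fl))
  }
}

#' Simulate one condition across one clinician's career
#'
#' Draws the jittered prevalence once, then fills per-year counts.
#' Spontaneous conditions arise independently in the standing panel each
#' year, so `counts == new_counts`. Congenital/persistent conditions are
#' only found among new patients: the active caseload accumulates the yearly
#' newly-acquired cases, resets to the fresh intake in year 1 and at every
#' practice change, and (under `congenital_loss = "job_change_only"`) is
#' never otherwise reduced. The caseload is capped at `panel_size`.
#'
#' @param condition A list or one-row data frame with `prevalence` and
#'   `acquisition_class`.
#' @param plan A `career_plan`.
#' @param config A [sim_config()].
#' @return List with integer vectors `counts` and `new_counts`, one entry per
#'   year.
#' @export
simulate_condition_career <- function(condition, plan, config) {
  stop_if_not(inherits(plan, "career_plan"), "`plan` must be a career_plan")
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  p_local <- jittered_prevalence(condition$prevalence, config$jitter_fraction)
  yrs <- config$years
  if (condition$acquisition_class == "spontaneous") {
    counts <- sample_case_count(rep.int(config$panel_size, yrs), p_local,
                                config$sampling_mode)
    return(list(counts = as.integer(counts), new_counts = as.integer(counts)))
  }
  # congenital/persistent
  reset <- logical(yrs)
  reset[1L] <- TRUE
  reset[plan$job_change_years] <- TRUE
  intake <- ifelse(reset, config$panel_size,
                   as.integer(round_half_up(config$attrition_rate * config$panel_size)))
  new_counts <- sample_case_count(intake, p_local, config$sampling_mode)
  active <- integer(yrs)
  for (y in seq_len(yrs)) {
    carried <- if (reset[y]) {
      0L
    } else if (config$congenital_loss == "attrition_also" && active[y - 1L] > 0L) {
      stats::rbinom(1L, active[y - 1L], 1 - config$attrition_rate)
    } else {
      active[y - 1L]
    }
    active[y] <- min(carried + new_counts[y], config$panel_size)
  }
  list(counts = active, new_counts = as.integer(new_counts))
}

#' Simulate a full cohort of clinical careers
#'
#' Runs the double loop — clinicians outer, conditions inner — and returns a
#' `case_cube`: integer case counts indexed (clinician, year, code), with a
#' parallel newly-acquired count. Bit-identical output for identical
#' `(config, disease_list)`; per-clinician RNG substreams mean a larger
#' cohort extends, rather than reshuffles, a smaller one.
#'
#' @param config A [sim_config()].
#' @param disease_list A disease list from [build_disease_list()] or
#'   [read_disease_list()].
#' @return A `case_cube` with arrays `counts` and `new_counts`
#'   (`clinician x year x code`), the career `plans`, the `config`, and a
#'   disease-list `fingerprint`.
#' @examples
#' cfg <- sim_config(n_clinicians = 3, years = 5, panel_size = 200,
#'                   min_job_changes = 0, max_job_changes = 2, seed = 42)
#' cube <- simulate_cohort(cfg, build_disease_list(n_conditions = 20,
#'                                                 n_congenital = 5))
#' dim(cube$counts)
#' @export
simulate_cohort <- function(config, disease_list) {
  stop_if_not(inherits(config, "sim_config"), "`config` must be a sim_config")
  validate_disease_list(disease_list)
  n_cond <- nrow(disease_list)
  cc <- config$n_clinicians
  yrs <- config$years

  # isolate our RNG use (kind + state) from the caller
  old_seed <- rng_snapshot()
  on.exit(rng_restore(old_seed), add = TRUE)
  suppressWarnings(set.seed(config$seed, kind = "L'Ecuyer-CMRG"))
  stream <- get(".Random.seed", envir = globalenv())

  dn <- list(clinician = seq_len(cc), year = seq_len(yrs),
             code = disease_list$code)
  counts <- array(0L, dim = c(cc, yrs, n_cond), dimnames = dn)
  new_counts <- counts
  plans <- vector("list", cc)

  classes <- disease_list$acquisition_class
  prevs <- disease_list$prevalence
  for (i in seq_len(cc)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    plan <- draw_career_plan(config, i)
    plans[[i]] <- plan
    for (j in seq_len(n_cond)) {
      res <- simulate_condition_career(
        list(prevalence = prevs[j], acquisition_class = classes[j]),
        plan, config)
      counts[i, , j] <- res$counts
      new_counts[i, , j] <- res$new_counts
    }
  }

  structure(
    list(counts = counts, new_counts = new_counts, plans = plans,
         config = config,
         fingerprint = disease_list_fingerprint(disease_list)),
    class = "case_cube"
  )
}

disease_list_fingerprint <- function(dl) {
  sprintf("n_conditions=%d;n_congenital=%d;sum_prevalence=%.12e",
          nrow(dl), sum(dl$acquisition_class == "congenital"),
          sum(dl$prevalence))
}

#' @export
print.case_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Case cube: %d clinicians x %d years x %d conditions (%d cases; seed %d)\n",
              d[1], d[2], d[3], sum(x$counts), x$config$seed))
  invisible(x)
}

#' Flatten a case cube to long format
#'
#' One row per (clinician, year, code) cell, matching the CSV export schema
#' `clinician,year,code,cases,new_cases`.
#'
#' @param cube A `case_cube`.
#' @param drop_zero Drop all-zero cells (default `TRUE`; scattergram-style).
#' @return A data frame with columns `clinician`, `year`, `code`, `cases`,
#'   `new_cases`.
#' @export
cube_to_long <- function(cube, drop_zero = TRUE) {
  stop_if_not(inherits(cube, "case_cube"), "`cube` must be a case_cube")
  d <- dim(cube$counts)
  idx <- expand.grid(clinician = seq_len(d[1]), year = seq_len(d[2]),
                     code = as.integer(dimnames(cube$counts)$code))
  out <- data.frame(idx, cases = as.vector(cube$counts),
                    new_cases = as.vector(cube$new_counts))
  if (drop_zero) out <- out[out$cases > 0 | out$new_cases > 0, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$clinician, out$year, out$code), , drop = FALSE]
}
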