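# Closed-form expected encounter counts: the deterministic oracle for the
# simulator. Expectations are linear in panel, years and cohort size — no
# finite-panel depletion correction, matching the back-of-envelope arithmetic
# the simulation illustrates (a 2000-patient panel meets ~1 case/year of a
# 1/2000 condition; one career case at 1/60,000 over 30 years; 12 cases
# across a 200-clinician cohort at 1/1,000,000).

check_expectation_args <- function(prevalence, panel_size, years = 1,
                                   n_clinicians = 1) {
  stop_if_not(all(prevalence >= 0 & prevalence <= 1),
              "`prevalence` must lie in [0, 1]")
  stop_if_not(all(panel_size >= 0), "`panel_size` must be non-negative")
  stop_if_not(all(years >= 0), "`years` must be non-negative")
  stop_if_not(all(n_clinicians >= 0), "`n_clinicians` must be non-negative")
}

#' Expected cases per clinician per year
#'
#' @param prevalence Condition prevalence, used as the annual per-patient
#'   encounter probability for spontaneous conditions.
#' @param panel_size Patients in the clinician's panel.
#' @return `prevalence * panel_size`.
#' @examples
#' expected_annual_cases(1 / 2000, 2000) # 1 case/year at the rare threshold
#' @export
expected_annual_cases <- function(prevalence, panel_size) {
  check_expectation_args(prevalence, panel_size)
  prevalence * panel_size
}

#' Expected cases per clinician over a career
#'
#' @inheritParams expected_annual_cases
#' @param years Career length in years.
#' @return `prevalence * panel_size * years`.
#' @examples
#' expected_career_cases(1 / 60000, 2000, 30) # one case per career
#' @export
expected_career_cases <- function(prevalence, panel_size, years) {
  check_expectation_args(prevalence, panel_size, years)
  prevalence * panel_size * years
}

#' Expected cases across a graduating cohort
#'
#' @inheritParams expected_career_cases
#' @param n_clinicians Number of clinicians in the cohort.
#' @return `prevalence * panel_size * years * n_clinicians`.
#' @examples
#' expected_cohort_cases(1e-6, 2000, 30, 200) # 12 one-in-a-million cases
#' @export
expected_cohort_cases <- function(prevalence, panel_size, years, n_clinicians) {
  check_expectation_args(prevalence, panel_size, years, n_clinicians)
  prevalence * panel_size * years * n_clinicians
}

#' Expectation table over a prevalence grid
#'
#' Annual, career and cohort expectations for each prevalence value; the
#' table behind the `expect` CLI subcommand.
#'
#' @param prevalence Vector of prevalence values.
#' @param panel_size,years,n_clinicians Scenario parameters.
#' @return Data frame with columns `prevalence`, `annual`, `career`, `cohort`.
#' @export
expectation_table <- function(prevalence, panel_size = 2000, years = 30,
                              n_clinicians = 200) {
  check_expectation_args(prevalence, panel_size, years, n_clinicians)
  data.frame(
    prevalence = prevalence,
    annual = expected_annual_cases(prevalence, panel_size),
    career = expected_career_cases(prevalence, panel_size, years),
    cohort = expected_cohort_cases(prevalence, panel_size, years, n_clinicians)
  )
}
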