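# Shared fixtures, built in code.

# In-class survey counts: estimated first-year cohort cases of a 1/10,000
# condition, before and after the simulation (89 and 77 respondents).
table1_fixture <- function() {
  likert_table(
    categories = c("0 to 5", "6 to 9", "10 to 14", "15 to 19", "20 to 25"),
    before = c(35, 16, 20, 15, 3),
    after = c(7, 6, 17, 25, 22)
  )
}

# A one-condition disease list with arbitrary prevalence/class.
single_condition_list <- function(prevalence, class = "spontaneous") {
  structure(
    data.frame(code = 1L, prevalence = prevalence,
               acquisition_class = class, stringsAsFactors = FALSE),
    class = c("disease_list", "data.frame")
  )
}

# Small, fast configuration for engine tests.
tiny_config <- function(...) {
  defaults <- list(n_clinicians = 4L, years = 8L, panel_size = 200L,
                   min_job_changes = 1L, max_job_changes = 3L,
                   attrition_rate = 0.1, jitter_fraction = 0.15, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
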