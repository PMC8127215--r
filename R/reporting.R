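# Aggregation of a case cube into its presentation surfaces: cohort
# per-condition totals, first-year cohort totals, per-clinician career
# tables, and scattergram rows with colour bins.

#' Cohort-wide per-condition case totals
#'
#' Sums cases over all clinicians and years for each condition code. By
#' default newly-acquired counts are totalled, so a congenital patient is
#' counted once per entry into a panel rather than once per year carried;
#' `mode = "all"` totals patient-years instead.
#'
#' @param cube A `case_cube` from [simulate_cohort()].
#' @param mode `"new"` (unique patient entries, default) or `"all"`
#'   (patient-years).
#' @return Data frame with columns `code` and `cases`.
#' @export
cohort_condition_totals <- function(cube, mode = c("new", "all")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(cube, "case_cube"), "`cube` must be a case_cube")
  a <- if (mode == "new") cube$new_counts else cube$counts
  data.frame(code = as.integer(dimnames(a)$code),
             cases = as.integer(apply(a, 3, sum)))
}

#' First-year cohort totals per condition
#'
#' Sums cases over all clinicians in their first year of practice. In year 1
#' the full panel is new, so `counts` and `new_counts` coincide.
#'
#' @inheritParams cohort_condition_totals
#' @return Data frame with columns `code` and `cases`.
#' @export
first_year_totals <- function(cube, mode = c("new", "all")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(cube, "case_cube"), "`cube` must be a case_cube")
  a <- if (mode == "new") cube$new_counts else cube$counts
  yr1 <- a[, 1L, , drop = FALSE]
  data.frame(code = as.integer(dimnames(a)$code),
             cases = as.integer(apply(yr1, 3, sum)))
}

#' One clinician's career table
#'
#' The year-by-code slice of the cube for a single clinician. Congenital
#' persistence shows up as runs of consecutive years carrying the same
#' (non-decreasing) caseload, broken only at practice changes.
#'
#' @param cube A `case_cube`.
#' @param clinician_index 1-based clinician id.
#' @param mode `"all"` (active caseload, default — how a career table reads)
#'   or `"new"` (newly-acquired only).
#' @return Integer matrix, years in rows, condition codes in columns.
#' @export
clinician_career_table <- function(cube, clinician_index,
                                   mode = c("all", "new")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(cube, "case_cube"), "`cube` must be a case_cube")
  d <- dim(cube$counts)
  stop_if_not(is_count(clinician_index) && clinician_index >= 1 &&
                clinician_index <= d[1], "`clinician_index` out of range")
  a <- if (mode == "all") cube$counts else cube$new_counts
  m <- a[clinician_index, , , drop = TRUE]
  m <- matrix(m, nrow = d[2], ncol = d[3],
              dimnames = dimnames(cube$counts)[c("year", "code")])
  m
}

# colour-code bins; only the extremes are fixed by convention (1 case =
# black, >= 300 = magenta), interior edges are geometric and cosmetic
.colour_bin_edges <- c(1, 2, 5, 15, 50, 150, 300)
.colour_bin_labels <- c("1", "2-4", "5-14", "15-49", "50-149", "150-299",
                        ">=300")

#' Colour bin for a case count
#'
#' Maps positive case counts onto the ordered scattergram colour scale: the
#' lowest bin is exactly 1 case, the top bin is 300 or more, interior bins
#' are geometric (`2-4`, `5-14`, `15-49`, `50-149`, `150-299`).
#'
#' @param cases Positive integer case count(s).
#' @return Ordered factor of bin labels.
#' @export
colour_bin <- function(cases) {
  stop_if_not(all(cases >= 1 & cases == floor(cases)),
              "`cases` must be integers >= 1")
  idx <- findInterval(cases, .colour_bin_edges)
  factor(.colour_bin_labels[idx], levels = .colour_bin_labels, ordered = TRUE)
}

#' Scattergram rows for a reporting view
#'
#' Long-format rows (zero cells omitted, as on a scattergram) with the colour
#' bin attached. Views mirror the standard panels: cohort totals by code,
#' first-year totals by code, every (clinician, year, code) cell, or one
#' clinician's career.
#'
#' @param cube A `case_cube`.
#' @param view One of `"cohort"`, `"first_year"`, `"all_cells"`,
#'   `"clinician"`.
#' @param clinician_index Required for `view = "clinician"`.
#' @return Data frame of emitted points with `cases >= 1` and a `bin` column.
#' @export
scatter_table <- function(cube,
                          view = c("cohort", "first_year", "all_cells",
                                   "clinician"),
                          clinician_index = NULL) {
  view <- match.arg(view)
  out <- switch(view,
    cohort = cohort_condition_totals(cube),
    first_year = first_year_totals(cube),
    all_cells = {
      lg <- cube_to_long(cube, drop_zero = TRUE)
      data.frame(clinician = lg$clinician, year = lg$year, code = lg$code,
                 cases = lg$cases)
    },
    clinician = {
      stop_if_not(!is.null(clinician_index),
                  "`clinician_index` is required for view = 'clinician'")
      m <- clinician_career_table(cube, clinician_index)
      idx <- which(m > 0, arr.ind = TRUE)
      data.frame(year = as.integer(rownames(m))[idx[, 1]],
                 code = as.integer(colnames(m))[idx[, 2]],
                 cases = as.integer(m[idx]))
    })
  out <- out[out$cases >= 1, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$bin <- colour_bin(out$cases) else {
    out$bin <- factor(character(0), levels = .colour_bin_labels, ordered = TRUE)
  }
  out
}
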