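# Prevalence curve and theoretical disease list.
#
# Conditions are indexed by a 1-based Condition Code Number (CCN); prevalence
# falls off as a single-rate decaying exponential anchored at the first and
# last codes.

#' Exponential decay rate between two prevalence anchors
#'
#' Rate `k` of the per-code exponential `p(c) = p_max * exp(-k * (c - 1))`,
#' chosen so that code 1 has prevalence `p_max` and code `n_conditions` has
#' prevalence `p_min`.
#'
#' @param p_max Prevalence at code 1 (proportion of the population, in (0, 1]).
#' @param p_min Prevalence at the last code; must not exceed `p_max`.
#' @param n_conditions Number of condition codes (at least 2).
#' @return The decay rate per code step, `log(p_max / p_min) / (n_conditions - 1)`.
#' @examples
#' decay_rate(0.641, 1e-6, 462)
#' decay_rate(0.5, 0.5, 462) # flat curve
#' @export
decay_rate <- function(p_max, p_min, n_conditions) {
  stop_if_not(is_number(p_max) && p_max > 0 && p_max <= 1,
              "`p_max` must be a prevalence in (0, 1]")
  stop_if_not(is_number(p_min) && p_min > 0, "`p_min` must be positive")
  stop_if_not(p_min <= p_max, "`p_min` must not exceed `p_max`")
  stop_if_not(is_count(n_conditions) && n_conditions >= 2,
              "`n_conditions` must be an integer >= 2")
  log(p_max / p_min) / (n_conditions - 1)
}

#' Construct a prevalence curve
#'
#' The default arguments give the curve used throughout: 462 conditions with
#' prevalence decaying from 0.641 at code 1 to 1e-6 at code 462. Code 200
#' falls at prevalence 2e-3, the EU rare-disease threshold (1/2000 halved per
#' panel arithmetic conventions aside, simply: codes above 200 are rare).
#'
#' @param p_max Prevalence at code 1.
#' @param p_min Prevalence at the last code.
#' @param n_conditions Number of condition codes.
#' @return An object of class `prevalence_curve` with fields `p_max`, `p_min`,
#'   `n_conditions` and the derived `decay_rate`.
#' @examples
#' curve <- prevalence_curve()
#' prevalence_for_code(curve, c(1, 200, 462))
#' @export
prevalence_curve <- function(p_max = 0.641, p_min = 1e-6, n_conditions = 462L) {
  stop_if_not(is_count(n_conditions) && n_conditions >= 1,
              "`n_conditions` must be a positive integer")
  if (n_conditions == 1L) {
    stop_if_not(is_number(p_max) && p_max > 0 && p_max <= 1,
                "`p_max` must be a prevalence in (0, 1]")
    k <- 0
    p_min <- p_max
  } else {
    k <- decay_rate(p_max, p_min, n_conditions)
  }
  structure(
    list(p_max = p_max, p_min = p_min,
         n_conditions = as.integer(n_conditions), decay_rate = k),
    class = "prevalence_curve"
  )
}

#' @export
print.prevalence_curve <- function(x, ...) {
  cat(sprintf(
    "Prevalence curve: %d conditions, p(1) = %g .. p(%d) = %g (rate %.6f/code)\n",
    x$n_conditions, x$p_max, x$n_conditions, x$p_min, x$decay_rate))
  invisible(x)
}

#' Prevalence for a condition code
#'
#' Evaluates `p_max * exp(-decay_rate * (code - 1))`; the endpoints reproduce
#' `p_max` and `p_min` to full floating precision. Vectorised over `code`.
#'
#' @param curve A [prevalence_curve()].
#' @param code Integer condition code(s) in `1..n_conditions`.
#' @return Prevalence value(s).
#' @export
prevalence_for_code <- function(curve, code) {
  stop_if_not(inherits(curve, "prevalence_curve"), "`curve` must be a prevalence_curve")
  stop_if_not(length(code) >= 1 && all(is.finite(code)) && all(code == floor(code)),
              "`code` must be integer-valued")
  stop_if_not(all(code >= 1 & code <= curve$n_conditions),
              sprintf("`code` must lie in 1..%d", curve$n_conditions))
  p <- curve$p_max * exp(-curve$decay_rate * (code - 1))
  # pin the far anchor exactly despite exp/log round-trip
  p[code == curve$n_conditions] <- curve$p_min
  p
}

#' Randomly assign acquisition classes to condition codes
#'
#' Exactly `n_congenital` codes are labelled congenital/persistent, chosen
#' uniformly without replacement; the rest are spontaneous. Deterministic for
#' a given seed.
#'
#' @param n_conditions Number of condition codes.
#' @param n_congenital Number of congenital/persistent conditions (default 73
#'   of 462, the split used for the theoretical list).
#' @param seed Integer RNG seed.
#' @return Character vector of length `n_conditions` with values
#'   `"spontaneous"` or `"congenital"`.
#' @export
assign_acquisition_classes <- function(n_conditions, n_congenital, seed = 1L) {
  stop_if_not(is_count(n_conditions) && n_conditions >= 1,
              "`n_conditions` must be a positive integer")
  stop_if_not(is_count(n_congenital) && n_congenital >= 0,
              "`n_congenital` must be a non-negative integer")
  stop_if_not(n_congenital <= n_conditions,
              "`n_congenital` cannot exceed `n_conditions`")
  classes <- rep("spontaneous", n_conditions)
  if (n_congenital > 0) {
    idx <- with_preserved_rng(seed, sample.int(n_conditions, n_congenital))
    classes[idx] <- "congenital"
  }
  classes
}

#' Build a theoretical disease list
#'
#' Constructs the full disease list: contiguous 1-based codes, prevalence from
#' the exponential curve, and a random split into spontaneous and
#' congenital/persistent conditions. Defaults reproduce the 462-condition
#' list (389 spontaneous, 73 congenital) with prevalence from 0.641 down to
#' 1e-6.
#'
#' @param p_max,p_min,n_conditions Curve parameters; see [prevalence_curve()].
#' @param n_congenital Number of congenital/persistent conditions.
#' @param seed Integer RNG seed for the class assignment.
#' @return A `disease_list`: a data frame with columns `code`, `prevalence`,
#'   `acquisition_class`, carrying the generating curve as attribute `curve`
#'   (`NULL` for user-supplied lists read from file).
#' @examples
#' dl <- build_disease_list()
#' table(dl$acquisition_class)
#' @export
build_disease_list <- function(p_max = 0.641, p_min = 1e-6,
                               n_conditions = 462L, n_congenital = 73L,
                               seed = 1L) {
  curve <- prevalence_curve(p_max, p_min, n_conditions)
  code <- seq_len(curve$n_conditions)
  dl <- data.frame(
    code = as.integer(code),
    prevalence = prevalence_for_code(curve, code),
    acquisition_class = assign_acquisition_classes(curve$n_conditions,
                                                   n_congenital, seed),
    stringsAsFactors = FALSE
  )
  structure(dl, curve = curve, class = c("disease_list", "data.frame"))
}

validate_disease_list <- function(dl) {
  stop_if_not(is.data.frame(dl) &&
                all(c("code", "prevalence", "acquisition_class") %in% names(dl)),
              "disease list needs columns code, prevalence, acquisition_class")
  stop_if_not(nrow(dl) >= 1, "disease list is empty")
  stop_if_not(identical(as.integer(dl$code), seq_len(nrow(dl))),
              "codes must be contiguous and 1-based")
  stop_if_not(all(dl$prevalence >= 0 & dl$prevalence <= 1),
              "prevalence must lie in [0, 1]")
  stop_if_not(all(dl$acquisition_class %in% c("spontaneous", "congenital")),
              "acquisition_class must be 'spontaneous' or 'congenital'")
  invisible(dl)
}

#' Write a disease list to CSV
#'
#' Plain CSV with header `code,prevalence,acquisition_class`; the round trip
#' through [read_disease_list()] reproduces the list exactly.
#'
#' @param dl A disease list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_disease_list <- function(dl, path) {
  validate_disease_list(dl)
  out <- data.frame(code = dl$code,
                    prevalence = format(dl$prevalence, digits = 17),
                    acquisition_class = dl$acquisition_class)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a disease list from CSV
#'
#' Accepts user-supplied lists (for example real diseases with known
#' prevalence) in the same three-column format produced by
#' [write_disease_list()]. No curve is attached to lists read from file.
#'
#' @param path CSV file with header `code,prevalence,acquisition_class`.
#' @return A `disease_list` data frame.
#' @export
read_disease_list <- function(path) {
  dl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(identical(sort(names(dl)),
                        sort(c("code", "prevalence", "acquisition_class"))),
              "expected header: code,prevalence,acquisition_class")
  dl <- dl[c("code", "prevalence", "acquisition_class")]
  dl$code <- as.integer(dl$code)
  dl$prevalence <- as.numeric(dl$prevalence)
  validate_disease_list(dl)
  structure(dl, curve = NULL, class = c("disease_list", "data.frame"))
}
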