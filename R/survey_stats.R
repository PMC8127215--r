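# Before/after survey analysis: ordered response categories are collapsed
# into a 2x2 table at a chosen split and compared with Pearson's chi-squared
# test. The bundled fixture (inst/extdata/table1.csv) holds the in-class
# responses to "how many first-year cases of a 1/10,000 condition will your
# class see?" before and after the simulation.

#' Construct a Likert response table
#'
#' @param categories Ordered response category labels.
#' @param before,after Non-negative respondent counts per category for the
#'   two survey administrations.
#' @return A `likert_table` data frame with columns `category`, `before`,
#'   `after`.
#' @export
likert_table <- function(categories, before, after) {
  stop_if_not(length(categories) >= 2, "need at least two categories")
  stop_if_not(length(before) == length(categories) &&
                length(after) == length(categories),
              "`before` and `after` must match `categories` in length")
  stop_if_not(all(before >= 0) && all(after >= 0) &&
                all(before == floor(before)) && all(after == floor(after)),
              "counts must be non-negative integers")
  structure(data.frame(category = as.character(categories),
                       before = as.integer(before), after = as.integer(after),
                       stringsAsFactors = FALSE),
            class = c("likert_table", "data.frame"))
}

#' Read a Likert table from CSV
#'
#' @param path CSV with header `category,before,after`, categories in order.
#' @return A `likert_table`.
#' @export
read_likert_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_not(identical(names(x), c("category", "before", "after")),
              "expected header: category,before,after")
  likert_table(x$category, x$before, x$after)
}

#' Collapse an ordered table into a 2x2 contingency table
#'
#' Groups categories `1..split_after` into a "low" column and the rest into a
#' "high" column, with survey administrations (before, after) as rows. Grand
#' totals are preserved.
#'
#' @param table A [likert_table()].
#' @param split_after Index of the last category in the low group
#'   (`1 <= split_after < n_categories`).
#' @return 2x2 integer matrix with rows `before`/`after` and columns
#'   `low`/`high`.
#' @export
group_to_2x2 <- function(table, split_after) {
  stop_if_not(inherits(table, "likert_table"), "`table` must be a likert_table")
  n <- nrow(table)
  stop_if_not(is_count(split_after) && split_after >= 1 && split_after < n,
              sprintf("`split_after` must lie in 1..%d", n - 1))
  lo <- seq_len(split_after)
  m <- matrix(c(sum(table$before[lo]), sum(table$before[-lo]),
                sum(table$after[lo]), sum(table$after[-lo])),
              nrow = 2, byrow = TRUE,
              dimnames = list(survey = c("before", "after"),
                              group = c("low", "high")))
  storage.mode(m) <- "integer"
  m
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Computes the Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins, referred to the chi-squared distribution with 1 degree
#' of freedom. The Yates continuity correction is off by default and
#' available by flag.
#'
#' @param table2x2 2x2 matrix of non-negative counts with positive margins.
#' @param yates Apply the continuity correction (subtract 0.5 from each
#'   `|O - E|`, floored at 0)?
#' @return List with `statistic`, `df` (always 1) and `p_value`.
#' @examples
#' pearson_chi2(matrix(c(51, 13, 38, 64), 2))
#' @export
pearson_chi2 <- function(table2x2, yates = FALSE) {
  stop_if_not(is.matrix(table2x2) && all(dim(table2x2) == 2),
              "`table2x2` must be a 2x2 matrix")
  stop_if_not(all(table2x2 >= 0), "counts must be non-negative")
  rs <- rowSums(table2x2)
  cs <- colSums(table2x2)
  stop_if_not(all(rs > 0) && all(cs > 0),
              "chi-squared test undefined: a row or column margin is zero")
  e <- outer(rs, cs) / sum(table2x2)
  dev <- abs(table2x2 - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Relative percentages of column totals
#'
#' Each count as a percentage of its survey administration's total, rounded
#' to one decimal — the "(relative percentage)" presentation of the response
#' table.
#'
#' @param table A [likert_table()].
#' @return Data frame with `category`, `before_pct`, `after_pct`.
#' @export
relative_percentages <- function(table) {
  stop_if_not(inherits(table, "likert_table"), "`table` must be a likert_table")
  tb <- sum(table$before)
  ta <- sum(table$after)
  stop_if_not(tb > 0 && ta > 0, "column totals must be positive")
  data.frame(category = table$category,
             before_pct = round(table$before / tb * 100, 1),
             after_pct = round(table$after / ta * 100, 1))
}

#' Grouped chi-squared analysis of a Likert table
#'
#' Convenience wrapper: collapse at `split_after` and run [pearson_chi2()];
#' apply over a list of tables to test several prevalence levels in turn.
#'
#' @inheritParams group_to_2x2
#' @inheritParams pearson_chi2
#' @return List with the `grouped` 2x2 table and the `test` result.
#' @export
survey_chi2 <- function(table, split_after, yates = FALSE) {
  grouped <- group_to_2x2(table, split_after)
  list(grouped = grouped, test = pearson_chi2(grouped, yates = yates))
}
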