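#' Welch t-test on two dialogue-level proportion samples
#'
#' Treats each sample as n 0/1 indicators (dialogue mentions the unit or
#' not) and runs the unpooled two-sample t-test: the "independent samples
#' t-test on SOV" of the study design. With the counts typical here this
#' is numerically close to the unpooled two-proportion z-test.
#'
#' When both samples are constant with equal means the statistic is 0 and
#' the p-value 1 (degenerate-variance rule).
#'
#' @param x1,n1 Successes and size of the first sample.
#' @param x2,n2 Successes and size of the second sample.
#' @return A one-row tibble: `x1`, `n1`, `x2`, `n2`, `estimate1`,
#'   `estimate2`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' two_proportion_test(30, 100, 50, 100)
two_proportion_test <- function(x1, n1, x2, n2) {
  if (any(c(n1, n2) < 2)) {
    abort("Sample sizes must be >= 2.", class = "pdvoice_validation_error")
  }
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("Counts must satisfy 0 <= x <= n.",
          class = "pdvoice_validation_error")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  # sample variance of a 0/1 vector with mean p: n p (1 - p) / (n - 1)
  v1 <- p1 * (1 - p1) * n1 / (n1 - 1)
  v2 <- p2 * (1 - p2) * n2 / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    stat <- if (p1 == p2) 0 else sign(p1 - p2) * Inf
    df <- n1 + n2 - 2
    p <- if (p1 == p2) 1 else 0
  } else {
    stat <- (p1 - p2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(stat), df)
  }
  tibble(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
         estimate1 = p1, estimate2 = p2,
         statistic = stat, df = df, p_value = p)
}

#' Trend test: same unit, two years
#'
#' Compares a unit's SOV between two years with [two_proportion_test()]
#' on the per-year numerator/denominator pairs.
#'
#' @param sov_row_start,sov_row_end One-row tibbles from [sov_table()] /
#'   [compute_sov()] for the same unit in different years.
#' @return A one-row tibble as in [two_proportion_test()], with `unit`,
#'   `year1`, `year2` prepended.
#' @export
trend_test <- function(sov_row_start, sov_row_end) {
  check_sov_row(sov_row_start)
  check_sov_row(sov_row_end)
  if (!identical(sov_row_start$unit, sov_row_end$unit)) {
    abort("Trend test rows must describe the same unit.",
          class = "pdvoice_validation_error")
  }
  if (identical(sov_row_start$year, sov_row_end$year)) {
    abort("Trend test rows must come from different years.",
          class = "pdvoice_validation_error")
  }
  res <- two_proportion_test(sov_row_start$numerator,
                             sov_row_start$denominator,
                             sov_row_end$numerator,
                             sov_row_end$denominator)
  tibble(unit = sov_row_start$unit, year1 = sov_row_start$year,
         year2 = sov_row_end$year, res)
}

#' Between-group test: two units, same year
#'
#' Compares the SOV of two units (e.g. the motor and non-motor categories)
#' within one year with [two_proportion_test()]. Mirrors the study design,
#' which treats the two indicator samples as independent even though they
#' are measured on the same dialogues.
#'
#' @param sov_row_a,sov_row_b One-row tibbles from [sov_table()] for the
#'   same year.
#' @return A one-row tibble as in [two_proportion_test()], with `unit_a`,
#'   `unit_b`, `year` prepended.
#' @export
between_group_test <- function(sov_row_a, sov_row_b) {
  check_sov_row(sov_row_a)
  check_sov_row(sov_row_b)
  if (!identical(sov_row_a$year, sov_row_b$year)) {
    abort("Between-group test rows must come from the same year.",
          class = "pdvoice_validation_error")
  }
  res <- two_proportion_test(sov_row_a$numerator, sov_row_a$denominator,
                             sov_row_b$numerator, sov_row_b$denominator)
  tibble(unit_a = sov_row_a$unit, unit_b = sov_row_b$unit,
         year = sov_row_a$year, res)
}

check_sov_row <- function(row) {
  need <- c("unit", "year", "numerator", "denominator")
  if (!is.data.frame(row) || nrow(row) != 1 || !all(need %in% names(row))) {
    abort("Expected a one-row SOV table row (unit, year, numerator, denominator).",
          class = "pdvoice_validation_error")
  }
}
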