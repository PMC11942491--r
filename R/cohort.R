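## Cohort-level accounting: reportable-case distribution by variant type and
## sequencing tier, and per-locus tier counts.

#' Summarize a cohort's reportable cases by variant type and sequencing tier
#'
#' Cases whose reportable variants include an STR (alone or in combination
#' with another variant type) count in the STR row. Percentages are of total
#' reportable cases, rounded half-away-from-zero to one decimal;
#' `pct_reportable_of_cohort` uses the full cohort size as denominator. With
#' zero reportable records the percentages are undefined (`NA`).
#'
#' @param records a `cohort_records` data.frame (see [simulate_cohort()]):
#'   columns `has_reportable`, `variant_types`, `required_long_read`
#' @param n_total_cohort total cases in the cohort (>= number of reportable
#'   records); negatives need not be present as records
#' @return object of class `cohort_summary`
#' @export
summarize_cohort <- function(records, n_total_cohort) {
  stopifnot(is.data.frame(records))
  rep_ <- records[records$has_reportable, , drop = FALSE]
  if (n_total_cohort < nrow(rep_))
    stop_input("n_total_cohort (%d) < number of reportable records (%d)",
               n_total_cohort, nrow(rep_))
  is_str <- grepl("STR", rep_$variant_types, fixed = TRUE)
  lr <- rep_$required_long_read
  cells <- matrix(c(sum(is_str & !lr), sum(is_str & lr),
                    sum(!is_str & !lr), sum(!is_str & lr)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("STR", "other"),
                                  c("no_long_read", "long_read")))
  total_reportable <- sum(cells)
  pct <- function(n) if (total_reportable > 0)
    round_half_away(100 * n / total_reportable, 1) else NA_real_
  structure(list(
    cells = cells,
    row_totals = rowSums(cells),
    col_totals = colSums(cells),
    total_reportable = total_reportable,
    pct_cells = apply(cells, c(1, 2), pct),
    pct_row_totals = vapply(rowSums(cells), pct, numeric(1)),
    pct_col_totals = vapply(colSums(cells), pct, numeric(1)),
    n_total_cohort = n_total_cohort,
    n_negative = n_total_cohort - total_reportable,
    pct_reportable_of_cohort = if (n_total_cohort > 0)
      round_half_away(100 * total_reportable / n_total_cohort, 1)
      else NA_real_),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt <- function(n, p) sprintf("%d (%s%%)", n,
                                ifelse(is.na(p), "-", format(p, nsmall = 1)))
  cat("<cohort_summary> reportable cases by variant type and tier\n")
  cat(sprintf("  %-22s %-18s %-18s %s\n", "", "no long read", "long read",
              "total"))
  for (r in rownames(x$cells))
    cat(sprintf("  %-22s %-18s %-18s %s\n", r,
                fmt(x$cells[r, 1], x$pct_cells[r, 1]),
                fmt(x$cells[r, 2], x$pct_cells[r, 2]),
                fmt(x$row_totals[r], x$pct_row_totals[r])))
  cat(sprintf("  %-22s %-18s %-18s %d\n", "total",
              fmt(x$col_totals[1], x$pct_col_totals[1]),
              fmt(x$col_totals[2], x$pct_col_totals[2]),
              x$total_reportable))
  cat(sprintf("  cohort %d cases; %d reportable (%s%%); %d negative\n",
              x$n_total_cohort, x$total_reportable,
              format(x$pct_reportable_of_cohort, nsmall = 1), x$n_negative))
  invisible(x)
}

#' Per-locus counts of cases by sequencing tier
#'
#' @param cases data.frame with columns `locus_id` and `tier`
#'   (`"no_long_read"` or `"long_read"`); order-invariant
#' @return data.frame with one row per locus: `locus_id`, `no_long_read`,
#'   `long_read`, `total`, sorted by `locus_id`
#' @export
per_locus_table <- function(cases) {
  stopifnot(is.data.frame(cases))
  if (!nrow(cases))
    return(data.frame(locus_id = character(), no_long_read = integer(),
                      long_read = integer(), total = integer()))
  stopifnot(all(cases$tier %in% c("no_long_read", "long_read")))
  tab <- table(factor(cases$locus_id),
               factor(cases$tier, levels = c("no_long_read", "long_read")))
  out <- data.frame(locus_id = rownames(tab),
                    no_long_read = as.integer(tab[, "no_long_read"]),
                    long_read = as.integer(tab[, "long_read"]))
  out$total <- out$no_long_read + out$long_read
  out <- out[order(out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
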