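#' Cronbach's alpha
#'
#' Internal consistency of a multi-item composite:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sum))`.
#' Rows with any missing item are dropped (listwise deletion).
#'
#' @param items numeric matrix or data.frame, units in rows, k >= 2 items in
#'   columns.
#' @return alpha (scalar).
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("alpha needs at least 2 items")
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (nrow(items) < 3L) stop("alpha needs at least 3 complete units")
  k <- ncol(items)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) stop("zero variance of the item sum; alpha undefined")
  k / (k - 1) * (1 - sum(apply(items, 2L, stats::var)) / total_var)
}

#' Odd/even-day split-half reliability with Spearman-Brown correction
#'
#' For each person, the variable is averaged over odd study days and over
#' even study days (both slots contribute); `r` is the Pearson correlation
#' of the two half-scores across persons, and the Spearman-Brown coefficient
#' `SB = 2r / (1 + r)` steps the half-length reliability up to the full
#' series. With `unit = "occasion"`, occasions (not persons) are split by
#' day parity within person and pooled -- an alternative reading exposed for
#' sensitivity checks.
#'
#' @param panel an [ema_panel()].
#' @param variable variable to assess.
#' @param unit `"person"` (default) or `"occasion"`.
#' @return list with `r`, `sb` and `n` (persons used).
#' @export
split_half_sb <- function(panel, variable, unit = c("person", "occasion")) {
  unit <- match.arg(unit)
  sub <- panel[panel$variable == variable & !is.na(panel$value), ,
               drop = FALSE]
  if (nrow(sub) == 0L) stop("variable '", variable, "' absent from panel")
  sub$parity <- ifelse(sub$day %% 2L == 1L, "odd", "even")
  if (unit == "person") {
    odd <- tapply(sub$value[sub$parity == "odd"],
                  sub$person[sub$parity == "odd"], mean)
    even <- tapply(sub$value[sub$parity == "even"],
                   sub$person[sub$parity == "even"], mean)
    both <- intersect(names(odd), names(even))
    if (length(both) < 3L) {
      stop("fewer than 3 persons with both odd- and even-day observations")
    }
    x <- odd[both]; y <- even[both]
  } else {
    # occasion-level: pair each person-day's AM/PM... parity split by day
    # within person, person-demeaned to avoid trait confounding
    pm_mean <- tapply(sub$value, sub$person, mean)
    sub$dev <- sub$value - pm_mean[sub$person]
    odd <- tapply(sub$dev[sub$parity == "odd"],
                  sub$person[sub$parity == "odd"], mean)
    even <- tapply(sub$dev[sub$parity == "even"],
                   sub$person[sub$parity == "even"], mean)
    both <- intersect(names(odd), names(even))
    if (length(both) < 3L) stop("fewer than 3 usable persons")
    x <- odd[both]; y <- even[both]
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a half-score; split-half undefined")
  }
  r <- stats::cor(x, y)
  list(r = r, sb = 2 * r / (1 + r), n = length(both))
}

#' Reliability report for composites and task outcomes
#'
#' Cronbach's alpha per composite (occasions as units, items as columns) and
#' odd/even-day Spearman-Brown split-half per listed outcome.
#'
#' @param panel an [ema_panel()] containing the item variables.
#' @param specs list of [composite_spec()] for the alpha rows.
#' @param split_half_vars variables for the split-half rows.
#' @return data.frame with columns `statistic`, `variable`, `value`, `n`.
#' @export
reliability_report <- function(panel, specs = default_composites(),
                               split_half_vars = character()) {
  rows <- list()
  for (spec in specs) {
    wide <- panel_to_wide(panel, spec$items)
    vals <- as.matrix(wide[spec$items])
    rev_idx <- match(spec$reverse, spec$items)
    if (length(rev_idx) > 0L) vals[, rev_idx] <- 100 - vals[, rev_idx]
    cc <- sum(stats::complete.cases(vals))
    rows[[length(rows) + 1L]] <-
      data.frame(statistic = "cronbach_alpha", variable = spec$name,
                 value = cronbach_alpha(vals), n = cc)
  }
  for (v in split_half_vars) {
    sh <- split_half_sb(panel, v)
    rows[[length(rows) + 1L]] <-
      data.frame(statistic = c("split_half_r", "spearman_brown"),
                 variable = v, value = c(sh$r, sh$sb), n = sh$n)
  }
  do.call(rbind, rows)
}
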