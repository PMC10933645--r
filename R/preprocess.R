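#' Define a composite score
#'
#' A composite is the mean of several 0-100 items measured at the same
#' occasion. Reverse-coded items are flipped (`value -> 100 - value`) before
#' averaging. By default all listed items must be answered for the composite
#' to be scored (`min_items = length(items)`); a lower threshold makes
#' scoring tolerant of partial item response.
#'
#' @param name name of the composite variable to create.
#' @param items character vector of item variable names.
#' @param reverse subset of `items` that are reverse-coded.
#' @param min_items minimum number of answered items required to score.
#' @return object of class `composite_spec`.
#' @export
composite_spec <- function(name, items, reverse = character(),
                           min_items = length(items)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(items), length(items) >= 1L)
  if (!all(reverse %in% items)) {
    stop("reverse-coded items must be a subset of the composite's items")
  }
  if (min_items < 1L || min_items > length(items)) {
    stop("min_items must be between 1 and the number of items")
  }
  structure(list(name = name, items = items, reverse = reverse,
                 min_items = as.integer(min_items)),
            class = "composite_spec")
}

#' Default composite specifications
#'
#' Self-control is the mean of four items with the loss-of-control item
#' reverse-coded; anger rumination is the mean of two items. Momentary anger
#' is a single item and needs no composite.
#'
#' @return list of [composite_spec()] objects.
#' @export
default_composites <- function() {
  list(
    composite_spec("self_control",
                   items = c("sc_focus", "sc_plans", "sc_lost_control",
                             "sc_resist_temptation"),
                   reverse = "sc_lost_control"),
    composite_spec("anger_rumination",
                   items = c("rum_past_anger", "rum_analyzed_events"))
  )
}

#' Score composites onto a panel
#'
#' Adds one record per occasion and composite: the mean of the available
#' reverse-corrected items when at least `min_items` were answered, missing
#' otherwise.
#'
#' @param panel an [ema_panel()].
#' @param specs list of [composite_spec()] objects (a single spec is also
#'   accepted).
#' @return the panel with composite records appended.
#' @export
score_composites <- function(panel, specs) {
  if (inherits(specs, "composite_spec")) specs <- list(specs)
  known <- unique(panel$variable)
  validate_range <- all(is.na(panel$value) |
                          (panel$value >= 0 & panel$value <= 100))
  out <- as.data.frame(panel)
  registry <- attr(panel, "registry")
  for (spec in specs) {
    unknown <- setdiff(spec$items, known)
    if (length(unknown) > 0L) {
      stop("composite '", spec$name, "' references unknown item(s): ",
           paste(unknown, collapse = ", "))
    }
    wide <- panel_to_wide(panel, spec$items)
    vals <- as.matrix(wide[spec$items])
    for (rv in spec$reverse) wide[[rv]] <- NULL  # only used via vals
    rev_idx <- match(spec$reverse, spec$items)
    if (length(rev_idx) > 0L) vals[, rev_idx] <- 100 - vals[, rev_idx]
    n_ans <- rowSums(!is.na(vals))
    score <- rowMeans(vals, na.rm = TRUE)
    score[n_ans < spec$min_items] <- NA_real_
    score[n_ans == 0L] <- NA_real_
    new <- data.frame(person = wide$person, day = wide$day, slot = wide$slot,
                      variable = spec$name, value = score)
    out <- rbind(out, new)
    registry <- rbind(registry,
                      data.frame(variable = spec$name, role = "composite"))
  }
  ema_panel(out, registry = registry, validate_range = validate_range)
}

#' Compliance rates
#'
#' Fraction of scheduled occasions actually answered, per person and on
#' average. An occasion counts as answered for the given modality when at
#' least one of `variables` carries a non-missing value there.
#'
#' @param panel an [ema_panel()].
#' @param variables variables defining the modality (e.g. the self-report
#'   composites, or `"response_inhibition"` for the task).
#' @param expected scheduled occasions per person (default 18: 9 days x 2
#'   slots), either a single number or a named vector keyed by person.
#' @return list with `per_person` (data.frame person, n_answered, expected,
#'   rate) and `overall` (mean of per-person rates, in percent).
#' @export
compliance <- function(panel, variables, expected = 18) {
  sub <- panel[panel$variable %in% variables & !is.na(panel$value), ,
               drop = FALSE]
  persons <- sort(unique(panel$person))
  occ <- unique(sub[c("person", "day", "slot")])
  n_answered <- table(factor(occ$person, levels = persons))
  if (length(expected) == 1L && is.null(names(expected))) {
    exp_vec <- rep(expected, length(persons))
  } else {
    exp_vec <- unname(expected[persons])
  }
  if (any(is.na(exp_vec)) || any(exp_vec <= 0)) {
    stop("expected occasion count must be positive for every person")
  }
  per_person <- data.frame(person = persons,
                           n_answered = as.integer(n_answered),
                           expected = exp_vec,
                           rate = 100 * as.integer(n_answered) / exp_vec)
  list(per_person = per_person, overall = mean(per_person$rate))
}

#' Descriptive statistics by slot
#'
#' Mean and SD of each variable over all occasions, morning only and
#' afternoon only, plus a morning-vs-afternoon comparison: a paired t-test
#' on person-level AM vs PM means (persons contribute one pair each).
#'
#' @param panel an [ema_panel()].
#' @param variables variables to describe.
#' @return data.frame with one row per variable.
#' @export
descriptives <- function(panel, variables) {
  absent <- setdiff(variables, unique(panel$variable))
  if (length(absent) > 0L) {
    stop("variable(s) absent from panel: ", paste(absent, collapse = ", "))
  }
  rows <- lapply(variables, function(v) {
    sub <- panel[panel$variable == v & !is.na(panel$value), , drop = FALSE]
    am <- sub[sub$slot == "AM", , drop = FALSE]
    pm <- sub[sub$slot == "PM", , drop = FALSE]
    # person-level means for the paired comparison
    am_means <- tapply(am$value, am$person, mean)
    pm_means <- tapply(pm$value, pm$person, mean)
    both <- intersect(names(am_means), names(pm_means))
    p_val <- NA_real_
    if (length(both) >= 2L) {
      d <- am_means[both] - pm_means[both]
      # a constant difference defeats the t statistic: zero difference is
      # trivially nonsignificant, a nonzero constant shift maximally so
      p_val <- tryCatch(
        stats::t.test(am_means[both], pm_means[both], paired = TRUE)$p.value,
        error = function(e) NaN)
      if (is.nan(p_val)) {
        p_val <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
      }
    }
    data.frame(variable = v,
               mean_all = mean(sub$value), sd_all = stats::sd(sub$value),
               mean_am = mean(am$value), sd_am = stats::sd(am$value),
               mean_pm = mean(pm$value), sd_pm = stats::sd(pm$value),
               n_all = nrow(sub), n_persons = length(both),
               p_am_vs_pm = p_val)
  })
  do.call(rbind, rows)
}

#' Build within-day morning-to-afternoon lag pairs
#'
#' The estimator only regresses afternoon (PM) measures on the same day's
#' morning (AM) measures: pairs never span a night, which keeps overnight
#' carry-over out of the lag-1 coefficients. Person means are computed over
#' ALL of a person's observed occasions (both slots), and morning predictors
#' are person-mean centered, so lagged effects capture momentary deviations
#' while the person means carry the between-person signal.
#'
#' @param panel a scored [ema_panel()] (composites present).
#' @param variables the network's node variables.
#' @return object of class `ema_lag_pairs`: a data.frame with one row per
#'   (person, day) having at least one AM and one PM record among
#'   `variables`, and columns `y_<v>` (PM value), `c_<v>` (centered AM
#'   value) and `m_<v>` (person mean) per variable; attribute
#'   `person_means` holds the person-by-variable mean table.
#' @export
build_lag_pairs <- function(panel, variables) {
  absent <- setdiff(variables, unique(panel$variable))
  if (length(absent) > 0L) {
    stop("variable(s) absent from panel: ", paste(absent, collapse = ", "))
  }
  wide <- panel_to_wide(panel, variables)
  obs_per_person <- rowsum(as.numeric(rowSums(!is.na(wide[variables]))),
                           wide$person)
  empty <- rownames(obs_per_person)[obs_per_person[, 1L] == 0]
  if (length(empty) > 0L) {
    stop("person(s) with zero observed values: ",
         paste(empty, collapse = ", "))
  }
  means <- do.call(cbind, lapply(variables, function(v) {
    tapply(wide[[v]], wide$person, mean, na.rm = TRUE)
  }))
  colnames(means) <- variables

  am <- wide[wide$slot == "AM", , drop = FALSE]
  pm <- wide[wide$slot == "PM", , drop = FALSE]
  merged <- merge(am[c("person", "day", variables)],
                  pm[c("person", "day", variables)],
                  by = c("person", "day"), suffixes = c("_AM", "_PM"))
  merged <- merged[order(merged$person, merged$day), , drop = FALSE]
  out <- data.frame(person = merged$person, day = merged$day)
  pidx <- match(merged$person, rownames(means))
  for (v in variables) {
    m_v <- means[pidx, v]
    out[[paste0("y_", v)]] <- merged[[paste0(v, "_PM")]]
    out[[paste0("c_", v)]] <- merged[[paste0(v, "_AM")]] - m_v
    out[[paste0("m_", v)]] <- m_v
  }
  rownames(out) <- NULL
  structure(out,
            variables = variables,
            person_means = means,
            class = c("ema_lag_pairs", "data.frame"))
}

#' @export
print.ema_lag_pairs <- function(x, ...) {
  cat("Lag-pair set: ", nrow(x), " AM->PM day pairs, ",
      length(unique(x$person)), " persons, nodes: ",
      paste(attr(x, "variables"), collapse = ", "), "\n", sep = "")
  invisible(x)
}
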