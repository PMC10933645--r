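#' Score one Go/No-go session
#'
#' The ambulatory task presents 4 main blocks of 50 trials, 10 no-go per
#' block (20% of trials), after a short training block (block 0). The
#' primary outcome is no-go accuracy: the percentage of no-go trials on
#' which the response was successfully withheld. Responses slower than the
#' 1200 ms stimulus window count as no response. Go accuracy and mean go RT
#' are returned as descriptives only.
#'
#' @param log an `ema_trial_log`.
#' @param person,day,slot occasion key selecting the session to score.
#' @param rt_window_ms response window in ms; responses with `rt_ms` above
#'   it are treated as withheld.
#' @return list of class `gonogo_score` with `nogo_accuracy`,
#'   `go_accuracy` (percent), `n_nogo`, `n_go`, `mean_go_rt_ms`, or `NULL`
#'   (with a warning) when the session has no scorable no-go trials.
#' @export
score_gonogo_session <- function(log, person, day, slot,
                                 rt_window_ms = 1200) {
  rows <- log$person == person & log$day == day & log$slot == slot &
    log$block >= 1L
  trials <- as.data.frame(log)[rows, , drop = FALSE]
  responded <- trials$responded &
    (is.na(trials$rt_ms) | trials$rt_ms <= rt_window_ms)
  nogo <- trials$stimulus == "nogo"
  if (sum(nogo) == 0L) {
    warning("occasion (", person, ", day ", day, ", ", slot,
            ") has no no-go trials; unscorable")
    return(NULL)
  }
  go_rt <- trials$rt_ms[!nogo & responded]
  structure(list(
    person = person, day = day, slot = slot,
    nogo_accuracy = 100 * sum(!responded[nogo]) / sum(nogo),
    go_accuracy = if (sum(!nogo) > 0L)
      100 * sum(responded[!nogo]) / sum(!nogo) else NA_real_,
    n_nogo = sum(nogo), n_go = sum(!nogo),
    mean_go_rt_ms = if (length(go_rt) > 0L) mean(go_rt, na.rm = TRUE)
      else NA_real_
  ), class = "gonogo_score")
}

#' Score all sessions of a trial log into a panel fragment
#'
#' One `response_inhibition` record (no-go accuracy, 0-100) per occasion
#' present in the log. Occasions without main-block no-go trials (e.g. a
#' training block only) produce no record and a warning.
#'
#' @param log an `ema_trial_log`.
#' @param rt_window_ms see [score_gonogo_session()].
#' @return an [ema_panel()] with the variable `response_inhibition`
#'   (registry role `"task-score"`).
#' @export
sessions_to_panel <- function(log, rt_window_ms = 1200) {
  occ <- unique(as.data.frame(log)[c("person", "day", "slot")])
  recs <- lapply(seq_len(nrow(occ)), function(i) {
    s <- score_gonogo_session(log, occ$person[i], occ$day[i], occ$slot[i],
                              rt_window_ms = rt_window_ms)
    if (is.null(s)) return(NULL)
    data.frame(person = s$person, day = s$day, slot = s$slot,
               variable = "response_inhibition", value = s$nogo_accuracy)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) {
    stop("no scorable occasions in trial log")
  }
  ema_panel(recs,
            registry = data.frame(variable = "response_inhibition",
                                  role = "task-score"))
}

#' Merge panels sharing the occasion key
#'
#' Binds records of several panels (e.g. self-report plus task scores) into
#' one panel; occasion keys must not collide on the same variable.
#'
#' @param ... [ema_panel()] objects.
#' @return an [ema_panel()].
#' @export
merge_panels <- function(...) {
  panels <- list(...)
  records <- do.call(rbind, lapply(panels, as.data.frame))
  registry <- unique(do.call(rbind, lapply(panels, attr, "registry")))
  validate <- all(vapply(panels, function(p) {
    all(is.na(p$value) | (p$value >= 0 & p$value <= 100))
  }, logical(1L)))
  ema_panel(records, registry = registry, validate_range = validate)
}
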