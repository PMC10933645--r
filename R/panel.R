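#' Construct an EMA panel
#'
#' An EMA panel holds long-format experience-sampling records keyed by
#' occasion: one row per (person, day, slot, variable). A slot is one of the
#' two daily measurement occasions, `"AM"` (morning) or `"PM"` (afternoon).
#' Values live on the instrument's 0-100 scale; missing responses are kept as
#' `NA`, never imputed or zero-filled.
#'
#' @param records data.frame with columns `person`, `day`, `slot`,
#'   `variable`, `value`.
#' @param registry optional data.frame with columns `variable` and `role`
#'   (one of `"item"`, `"composite"`, `"task-score"`) declaring what each
#'   variable is. Variables absent from the registry are allowed.
#' @param validate_range if `TRUE`, values outside \[0, 100\] are an error.
#'   File readers always validate; simulated panels may be built unclipped
#'   (see [simulate_panel()]) and therefore skip range validation.
#' @return object of class `ema_panel` (a data.frame with a `registry`
#'   attribute).
#' @export
ema_panel <- function(records, registry = NULL, validate_range = TRUE) {
  required <- c("person", "day", "slot", "variable", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("panel records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$person <- as.character(records$person)
  records$day <- as.integer(records$day)
  records$slot <- as.character(records$slot)
  records$variable <- as.character(records$variable)
  records$value <- as.numeric(records$value)

  bad_slot <- !records$slot %in% c("AM", "PM")
  if (any(bad_slot)) {
    stop("malformed slot label(s) in row(s) ",
         paste(utils::head(which(bad_slot), 5L), collapse = ", "),
         ": slot must be 'AM' or 'PM'")
  }
  if (any(is.na(records$day)) || any(records$day < 1L)) {
    stop("day must be an integer >= 1")
  }
  key <- paste(records$person, records$day, records$slot, records$variable,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (person, day, slot, variable) record(s) in row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  if (validate_range) {
    out <- !is.na(records$value) &
      (records$value < 0 | records$value > 100)
    if (any(out)) {
      stop("value out of [0, 100] in row(s) ",
           paste(utils::head(which(out), 5L), collapse = ", "),
           " (e.g. value = ", records$value[which(out)[1L]], ")")
    }
  }
  if (!is.null(registry)) {
    registry <- as.data.frame(registry)
    stopifnot(all(c("variable", "role") %in% names(registry)))
    bad_role <- !registry$role %in% c("item", "composite", "task-score")
    if (any(bad_role)) {
      stop("registry role must be one of 'item', 'composite', 'task-score'")
    }
  }
  structure(records,
            registry = registry,
            class = c("ema_panel", "data.frame"))
}

#' @export
print.ema_panel <- function(x, ...) {
  vars <- sort(unique(x$variable))
  cat("EMA panel: ", length(unique(x$person)), " persons, ",
      nrow(x), " records, ", length(vars), " variables\n", sep = "")
  cat("  variables: ", paste(vars, collapse = ", "), "\n", sep = "")
  cat("  days ", min(x$day), "-", max(x$day),
      ", slots AM/PM, missing values: ", sum(is.na(x$value)), "\n", sep = "")
  invisible(x)
}

#' Read an EMA panel from CSV
#'
#' Expects a header `person,day,slot,variable,value`; empty fields and the
#' literal string `"NA"` are read as missing. Values outside \[0, 100\] and
#' malformed slot labels are rejected with the offending row named.
#'
#' @param path path to a CSV file.
#' @param registry optional variable registry, see [ema_panel()].
#' @return an [ema_panel()].
#' @export
read_ema_panel <- function(path, registry = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), strip.white = TRUE)
  required <- c("person", "day", "slot", "variable", "value")
  if (!all(required %in% names(raw))) {
    stop("panel CSV must have columns ", paste(required, collapse = ", "))
  }
  raw$day <- as.integer(raw$day)
  raw$value <- as.numeric(raw$value)
  ema_panel(raw, registry = registry, validate_range = TRUE)
}

#' Write an EMA panel to CSV
#'
#' Missing values are written as empty fields, so
#' `read_ema_panel(write_ema_panel(p, f))` round-trips `p` exactly (up to
#' row order).
#'
#' @param panel an [ema_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ema_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert a wide occasion-by-variable table to an EMA panel
#'
#' Convenience importer for tables with one row per (person, day, slot) and
#' one column per variable.
#'
#' @param wide data.frame with columns `person`, `day`, `slot` plus one
#'   numeric column per variable.
#' @param registry optional variable registry.
#' @param validate_range see [ema_panel()].
#' @return an [ema_panel()].
#' @export
panel_from_wide <- function(wide, registry = NULL, validate_range = TRUE) {
  keys <- c("person", "day", "slot")
  stopifnot(all(keys %in% names(wide)))
  vars <- setdiff(names(wide), keys)
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(person = wide$person, day = wide$day, slot = wide$slot,
               variable = v, value = as.numeric(wide[[v]]))
  }))
  ema_panel(long, registry = registry, validate_range = validate_range)
}

# Wide occasion table (person, day, slot, <one col per variable>) from a
# panel; internal workhorse for scoring and lag construction.
panel_to_wide <- function(panel, variables = NULL) {
  if (is.null(variables)) variables <- sort(unique(panel$variable))
  sub <- panel[panel$variable %in% variables, , drop = FALSE]
  occ <- unique(sub[c("person", "day", "slot")])
  occ <- occ[order(occ$person, occ$day, occ$slot), , drop = FALSE]
  rownames(occ) <- NULL
  okey <- paste(occ$person, occ$day, occ$slot, sep = "\r")
  for (v in variables) {
    occ[[v]] <- NA_real_
    rows <- sub$variable == v
    idx <- match(paste(sub$person[rows], sub$day[rows], sub$slot[rows],
                       sep = "\r"), okey)
    occ[[v]][idx] <- sub$value[rows]
  }
  occ
}

#' Read a Go/No-go trial log from CSV
#'
#' One row per trial: `person,day,slot,block,trial,stimulus,responded,rt_ms`.
#' `block` 0 denotes the training block (kept but flagged; scoring drops it),
#' main blocks are 1-4 of up to 50 trials each. `stimulus` is `"go"` or
#' `"nogo"`; `responded` is logical (or 0/1); `rt_ms` may be empty for
#' withheld responses.
#'
#' @param path path to a CSV file.
#' @return object of class `ema_trial_log` (a data.frame).
#' @export
read_trial_log <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("", "NA"), strip.white = TRUE)
  required <- c("person", "day", "slot", "block", "trial", "stimulus",
                "responded", "rt_ms")
  if (!all(required %in% names(raw))) {
    stop("trial log CSV must have columns ", paste(required, collapse = ", "))
  }
  raw$day <- as.integer(raw$day)
  raw$block <- as.integer(raw$block)
  raw$trial <- as.integer(raw$trial)
  raw$responded <- as.logical(ifelse(raw$responded %in% c("0", "1"),
                                     as.integer(raw$responded),
                                     toupper(raw$responded) %in%
                                       c("TRUE", "T")))
  raw$rt_ms <- as.numeric(raw$rt_ms)
  trial_log(raw)
}

#' Construct a trial log
#'
#' @param rows data.frame of trials, see [read_trial_log()] for columns.
#' @return object of class `ema_trial_log`.
#' @export
trial_log <- function(rows) {
  rows <- as.data.frame(rows)
  rows$person <- as.character(rows$person)
  rows$slot <- as.character(rows$slot)
  rows$stimulus <- as.character(rows$stimulus)
  bad_slot <- !rows$slot %in% c("AM", "PM")
  if (any(bad_slot)) {
    stop("malformed slot label in trial row(s) ",
         paste(utils::head(which(bad_slot), 5L), collapse = ", "))
  }
  bad_stim <- !rows$stimulus %in% c("go", "nogo")
  if (any(bad_stim)) {
    stop("unknown stimulus label in trial row(s) ",
         paste(utils::head(which(bad_stim), 5L), collapse = ", "),
         " (must be 'go' or 'nogo')")
  }
  if (any(rows$trial < 1L | rows$trial > 50L)) {
    stop("trial index out of 1-50 in trial row(s) ",
         paste(utils::head(which(rows$trial < 1L | rows$trial > 50L), 5L),
               collapse = ", "))
  }
  if (any(rows$block < 0L | rows$block > 4L)) {
    stop("block must be 0 (training) or 1-4")
  }
  if (any(!is.na(rows$rt_ms) & rows$rt_ms <= 0)) {
    stop("rt_ms must be positive or missing")
  }
  structure(rows, class = c("ema_trial_log", "data.frame"))
}

#' Write a trial log to CSV
#' @param log an `ema_trial_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, na = "")
  invisible(path)
}
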