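#' Observation window
#'
#' Calendar window over which stay records are reconciled: admissions
#' after the end or discharges before the start fall outside it. Stays
#' begun before `start` are left-truncated; stays open at `end` are
#' right-censored.
#'
#' @param start,end `Date`s (or ISO-8601 strings), `start < end`.
#' @return list of class `"observation_window"`.
#' @export
observation_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("window start must precede window end", call. = FALSE)
  structure(list(start = start, end = end), class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat("Observation window:", format(x$start), "to", format(x$end), "\n")
  invisible(x)
}

.RECORD_FIELDS <- c("patient_id", "care_group", "care_type",
                    "admission_date", "discharge_date", "discharge_reason",
                    "age_at_admission", "weekly_cost")

.CARE_GROUPS <- c("PF", "Palliative", "PDA", "OMH", "FMH", "LD")
.CARE_TYPES <- c("placement", "home_care")

#' Read raw stay records
#'
#' Parses a delimited text file (comma or tab autodetected, or forced
#' via `delim`) with one row per funded care episode. The header must
#' name the seven episode fields (`patient_id`, `care_group`,
#' `care_type`, `admission_date`, `discharge_date`, `discharge_reason`,
#' `age_at_admission`, `weekly_cost`); differently named source columns
#' can be mapped via `col_map`. Dates are ISO-8601. Rows with
#' unparseable dates or a discharge preceding the admission are flagged
#' in an `invalid` column and logged, never silently dropped.
#'
#' @param path path to the delimited file.
#' @param col_map optional named character vector mapping canonical
#'   field names to source column names, e.g.
#'   `c(patient_id = "ClientID")`.
#' @param delim `","`, `"\t"`, or `NULL` to autodetect from the header.
#' @return data.frame of class `"stay_records"` with canonical columns,
#'   an `invalid` flag column, and an `issues` attribute (row-level log
#'   of parse problems).
#' @export
read_stay_records <- function(path, col_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", na.strings = c("", "NA"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map))
    for (canon in names(col_map))
      names(raw)[names(raw) == col_map[[canon]]] <- canon
  missing_cols <- setdiff(setdiff(.RECORD_FIELDS, "discharge_date"),
                          names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"discharge_date" %in% names(raw)) raw$discharge_date <- NA_character_

  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  rec <- data.frame(
    patient_id = raw$patient_id,
    care_group = raw$care_group,
    care_type = raw$care_type,
    admission_date = parse_date(raw$admission_date),
    discharge_date = parse_date(raw$discharge_date),
    discharge_reason = raw$discharge_reason,
    age_at_admission = suppressWarnings(as.numeric(raw$age_at_admission)),
    weekly_cost = suppressWarnings(as.numeric(raw$weekly_cost)),
    stringsAsFactors = FALSE)

  issues <- character(0)
  bad_adm <- is.na(rec$admission_date)
  bad_dis <- !is.na(raw$discharge_date) & is.na(rec$discharge_date)
  reversed <- !is.na(rec$discharge_date) & !is.na(rec$admission_date) &
    rec$discharge_date < rec$admission_date
  for (i in which(bad_adm))
    issues <- c(issues, sprintf("row %d: unparseable admission_date '%s'",
                                i, raw$admission_date[i]))
  for (i in which(bad_dis))
    issues <- c(issues, sprintf("row %d: unparseable discharge_date '%s'",
                                i, raw$discharge_date[i]))
  for (i in which(reversed))
    issues <- c(issues, sprintf("row %d: discharge before admission", i))
  rec$invalid <- bad_adm | bad_dis | reversed
  attr(rec, "issues") <- issues
  class(rec) <- c("stay_records", "data.frame")
  rec
}

#' Clean stay records
#'
#' Applies the study's cleaning rules relative to an observation window
#' and returns the surviving records together with a per-rule exclusion
#' tally, so every input row is accounted for:
#' * `invalid`: rows flagged unparseable/reversed at read time;
#' * `out_of_window`: admitted after the window end, or discharged
#'   before the window start;
#' * `missing_care_type`;
#' * `missing_discharge_reason`: only for records claiming a discharge —
#'   a censored record legitimately has no reason.
#'
#' Patients with episodes in both placement and home care are treated as
#' independent: each episode keeps the natural key but is assigned a
#' distinct working id (suffixing the care type), and the split is
#' logged. Cleaning is idempotent.
#'
#' @param records a `stay_records` data.frame (from [read_stay_records]
#'   or [generate_cohort]).
#' @param window an [observation_window].
#' @return the cleaned `stay_records`, with attributes `exclusions`
#'   (named integer tally) and `dual_care_ids` (natural keys split
#'   across care types).
#' @export
clean_stay_records <- function(records, window) {
  stopifnot(is.data.frame(records), inherits(window, "observation_window"))
  n_in <- nrow(records)
  tally <- c(invalid = 0L, out_of_window = 0L, missing_care_type = 0L,
             missing_discharge_reason = 0L)

  keep <- rep(TRUE, n_in)
  inv <- if ("invalid" %in% names(records)) records$invalid else
    rep(FALSE, n_in)
  inv <- inv | is.na(records$admission_date)
  tally["invalid"] <- sum(inv & keep)
  keep <- keep & !inv

  oow <- (records$admission_date > window$end) |
    (!is.na(records$discharge_date) & records$discharge_date < window$start)
  tally["out_of_window"] <- sum(oow & keep, na.rm = TRUE)
  keep <- keep & !(oow %in% TRUE)

  mct <- is.na(records$care_type) | !(records$care_type %in% .CARE_TYPES)
  tally["missing_care_type"] <- sum(mct & keep)
  keep <- keep & !mct

  mdr <- !is.na(records$discharge_date) & is.na(records$discharge_reason)
  tally["missing_discharge_reason"] <- sum(mdr & keep)
  keep <- keep & !mdr

  out <- records[keep, , drop = FALSE]

  # split dual-care patients into independent records with distinct ids
  base_id <- sub("/(placement|home_care)$", "", out$patient_id)
  types_per_id <- tapply(out$care_type, base_id,
                         function(x) length(unique(x)))
  dual <- names(types_per_id)[types_per_id > 1]
  if (length(dual)) {
    hit <- base_id %in% dual
    out$patient_id[hit] <- paste(base_id[hit], out$care_type[hit], sep = "/")
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- tally
  attr(out, "dual_care_ids") <- dual
  attr(out, "issues") <- attr(records, "issues")
  class(out) <- c("stay_records", "data.frame")
  out
}

#' Build likelihood-ready observations from cleaned records
#'
#' For each record: `duration` is days from admission to discharge, or
#' to the window end for stays still open (zero-day stays are set to
#' 0.5 days, since a continuous-duration likelihood cannot take
#' `t = 0`); `event` is `TRUE` when a discharge on or before the window
#' end is recorded; `truncation` is `max(0, window start - admission)`
#' in days. Stratum labels `(care_type, care_group)` are carried along.
#'
#' @param records cleaned `stay_records`.
#' @param window an [observation_window].
#' @return a [stay_observations] data.frame with `care_type` and
#'   `care_group` columns; attribute `excluded_after_window` counts
#'   records admitted after the window end (these should not survive
#'   [clean_stay_records]).
#' @export
build_observations <- function(records, window) {
  stopifnot(is.data.frame(records), inherits(window, "observation_window"))
  late <- records$admission_date > window$end
  if (any(late)) records <- records[!late, , drop = FALSE]
  end_date <- pmin(records$discharge_date, window$end, na.rm = TRUE)
  event <- !is.na(records$discharge_date) &
    records$discharge_date <= window$end
  duration <- as.numeric(end_date - records$admission_date)
  duration[duration == 0] <- 0.5
  truncation <- pmax(0, as.numeric(window$start - records$admission_date))
  # whole-day dates can put a discharge exactly on the window start; the
  # stay reached into the window by part of a day
  half_in <- duration <= truncation
  duration[half_in] <- truncation[half_in] + 0.5
  obs <- stay_observations(duration, event, truncation,
                           care_type = records$care_type,
                           care_group = records$care_group,
                           patient_id = records$patient_id)
  attr(obs, "excluded_after_window") <- sum(late)
  obs
}

#' Write cleaned records and their exclusion tally
#'
#' @param records cleaned `stay_records`.
#' @param csv_path output CSV path for the records.
#' @param tally_path optional JSON path for the exclusion tally.
#' @export
write_stay_records <- function(records, csv_path, tally_path = NULL) {
  out <- records
  out$invalid <- NULL
  out$admission_date <- format(out$admission_date)
  out$discharge_date <- ifelse(is.na(out$discharge_date), "",
                               format(out$discharge_date))
  utils::write.csv(out, csv_path, row.names = FALSE, na = "")
  if (!is.null(tally_path)) {
    tl <- attr(records, "exclusions") %||% integer(0)
    writeLines(jsonlite::toJSON(as.list(tl), auto_unbox = TRUE), tally_path)
  }
  invisible(csv_path)
}
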