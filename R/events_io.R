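#' Read a trial-level behavioral event table
#'
#' Reads the long-format CSV event dialect used throughout the package: one
#' row per timestamped event with columns `subject_id, cohort, sex, task,
#' session, trial, event, time_s`. `time_s` is seconds from session start at
#' millisecond precision; trial numbering is 1-based with trial 0 reserved for
#' events outside any CS trial (inter-trial interval). Every structural
#' invariant of the dialect is enforced on read; malformed rows raise a
#' validation error naming the offending data row, never a silent coercion.
#'
#' For Pavlovian conditioned approach (`task = "pavca"`) the reader
#' additionally checks that each trial has exactly one `cs_onset` and one
#' `cs_offset`, that the CS window has the expected duration, and that every
#' lever deflection or food-cup entry attributed to a trial falls inside that
#' trial's CS window. CS windows are half-open `[onset, offset)`: a contact
#' at exactly the offset belongs to the inter-trial interval.
#'
#' @param path path to a CSV file in the event dialect.
#' @param task task schema to validate against: `"pavca"` or `"crf"`.
#' @param cs_duration_s CS (lever presentation) duration in seconds used to
#'   check PavCA trial windows. Default 8 s.
#' @return a `data.table` of events, time-sorted within subject-session and
#'   keyed by `subject_id, session`, with attribute `task`.
#' @seealso [write_event_table()], [derive_trial_windows()]
#' @export
read_event_table <- function(path, task = c("pavca", "crf"), cs_duration_s = 8) {
  task <- match.arg(task)
  if (!file.exists(path)) pv_stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "cohort", "sex", "task", "event")),
    na.strings = c("NA", ""))
  miss <- setdiff(EVENT_COLS, names(dt))
  if (length(miss))
    pv_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  dt <- dt[, EVENT_COLS, with = FALSE]
  validate_events(dt, task = task, cs_duration_s = cs_duration_s)
}

#' @rdname read_event_table
#' @param events a data.frame of events in the dialect (e.g. built in memory
#'   or produced by a simulator) to validate and normalize.
#' @export
validate_events <- function(events, task = c("pavca", "crf"), cs_duration_s = 8) {
  task <- match.arg(task)
  dt <- data.table::as.data.table(events)
  miss <- setdiff(EVENT_COLS, names(dt))
  if (length(miss))
    pv_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  n <- nrow(dt)

  bad <- function(ok, what) if (!all(ok)) pv_stop(what, row = which(!ok)[1])
  if (n) {
    bad(!is.na(dt$subject_id) & nzchar(dt$subject_id), "missing subject_id")
    bad(dt$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
    bad(dt$task == task, sprintf("task column must equal '%s'", task))
    bad(is.finite(dt$time_s) & dt$time_s >= 0, "time_s must be finite and >= 0")
    bad(is.finite(dt$session) & dt$session >= 1 & dt$session == floor(dt$session),
        "session must be an integer >= 1")
    bad(is.finite(dt$trial) & dt$trial >= 0 & dt$trial == floor(dt$trial),
        "trial must be an integer >= 0")
    bad(dt$event %in% PAVCA_EVENTS,
        sprintf("unknown event (expected one of: %s)",
                paste(PAVCA_EVENTS, collapse = ", ")))
  }
  dt[, `:=`(session = as.integer(session), trial = as.integer(trial),
            time_s = as.numeric(time_s))]
  data.table::setorder(dt, subject_id, session, time_s, event)

  if (task == "pavca" && n) {
    win <- dt[event %in% c("cs_onset", "cs_offset") & trial > 0,
              .(n_on = sum(event == "cs_onset"),
                n_off = sum(event == "cs_offset"),
                onset = time_s[event == "cs_onset"][1],
                offset = time_s[event == "cs_offset"][1]),
              by = .(subject_id, session, trial)]
    if (nrow(win)) {
      if (any(win$n_on != 1L | win$n_off != 1L))
        pv_stop(sprintf(
          "each PavCA trial needs exactly one cs_onset and one cs_offset (subject %s session %d trial %d)",
          win$subject_id[win$n_on != 1 | win$n_off != 1][1],
          win$session[win$n_on != 1 | win$n_off != 1][1],
          win$trial[win$n_on != 1 | win$n_off != 1][1]))
      wbad <- abs(win$offset - win$onset - cs_duration_s) > 1e-6
      if (any(wbad))
        pv_stop(sprintf(
          "CS window of trial %d (subject %s session %d) is %.3f s, expected %.3f s",
          win$trial[wbad][1], win$subject_id[wbad][1], win$session[wbad][1],
          (win$offset - win$onset)[wbad][1], cs_duration_s))
    }
    cs_ev <- dt[event %in% c("lever_deflection", "foodcup_entry") & trial > 0]
    if (nrow(cs_ev)) {
      cs_ev <- win[cs_ev, on = c("subject_id", "session", "trial")]
      if (anyNA(cs_ev$onset))
        pv_stop(sprintf("CS-period event in trial %d of subject %s session %d has no CS window",
                        cs_ev$trial[is.na(cs_ev$onset)][1],
                        cs_ev$subject_id[is.na(cs_ev$onset)][1],
                        cs_ev$session[is.na(cs_ev$onset)][1]))
      out <- cs_ev$time_s < cs_ev$onset - 1e-9 | cs_ev$time_s >= cs_ev$offset - 1e-9
      if (any(out))
        pv_stop(sprintf(
          "%s at %.3f s lies outside the CS window [%.3f, %.3f) of trial %d (subject %s session %d)",
          cs_ev$event[out][1], cs_ev$time_s[out][1], cs_ev$onset[out][1],
          cs_ev$offset[out][1], cs_ev$trial[out][1], cs_ev$subject_id[out][1],
          cs_ev$session[out][1]))
    }
  }
  data.table::setkey(dt, subject_id, session)
  data.table::setattr(dt, "task", task)
  dt[]
}

#' Write a trial-level event table
#'
#' Serializes events in the canonical dialect: fixed column order, rows
#' sorted by subject, session, time and event, and `time_s` printed with
#' exactly three decimals (millisecond grain). Output is byte-stable:
#' writing the same records twice yields identical files, and
#' `read_event_table()` on the result reproduces the records field for field.
#'
#' @param events a validated event table (see [read_event_table()]).
#' @param path output CSV path.
#' @param task task schema of the records.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path, task = attr(events, "task") %||% "pavca") {
  dt <- validate_events(events, task = task)
  out <- data.table::copy(dt)
  out[, time_s := sprintf("%.3f", time_s)]
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' Trial windows of a PavCA event stream
#'
#' @param events a validated PavCA event table.
#' @return a `data.table` with one row per subject-session-trial and the CS
#'   window `onset`/`offset` times (seconds from session start).
#' @export
derive_trial_windows <- function(events) {
  dt <- data.table::as.data.table(events)
  win <- dt[event == "cs_onset" & trial > 0,
            .(subject_id, session, trial, onset = time_s)]
  off <- dt[event == "cs_offset" & trial > 0,
            .(subject_id, session, trial, offset = time_s)]
  out <- off[win, on = c("subject_id", "session", "trial")]
  data.table::setcolorder(out, c("subject_id", "session", "trial", "onset", "offset"))
  data.table::setorder(out, subject_id, session, trial)
  out[]
}

#' Read a session-summary table (cue-preference or contextual conditioning)
#'
#' Validates the per-session summary dialects. For cocaine conditioned cue
#' preference (`kind = "ccp"`) rows carry the phase (habituation, pretest,
#' conditioning, posttest), conditioning trial 1-4, the injected drug, the
#' floor the subject was tested on (`both` during preference tests), the time
#' spent on each floor half during tests, and the distance travelled. For
#' cocaine contextual conditioning (`kind = "ccc"`) rows carry the day (1-8),
#' the injection, distance travelled and headwaving bouts; the fixed schedule
#' (day 1 no injection, days 2 and 8 saline, days 3-7 cocaine) is enforced.
#'
#' Subjects missing any day (CCC) or any required phase/trial (CCP) are not
#' an error: they are flagged in the `"incomplete_subjects"` attribute and
#' excluded casewise by the downstream scoring functions.
#'
#' @param path CSV path.
#' @param kind `"ccp"` or `"ccc"`.
#' @param session_duration_s duration of CCP preference tests, used to check
#'   that the two floor times do not exceed the session. Default 1800 s.
#' @return a validated `data.table` with attribute `incomplete_subjects`.
#' @export
read_summary_table <- function(path, kind = c("ccp", "ccc"),
                               session_duration_s = 1800) {
  kind <- match.arg(kind)
  if (!file.exists(path)) pv_stop(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, na.strings = c("NA", ""))
  validate_summary_table(dt, kind = kind, session_duration_s = session_duration_s)
}

#' @rdname read_summary_table
#' @param rows a data.frame in one of the summary dialects to validate.
#' @export
validate_summary_table <- function(rows, kind = c("ccp", "ccc"),
                                   session_duration_s = 1800) {
  kind <- match.arg(kind)
  dt <- data.table::as.data.table(rows)
  cols <- if (kind == "ccp") CCP_COLS else CCC_COLS
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    pv_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  dt <- dt[, cols, with = FALSE]
  bad <- function(ok, what) if (!all(ok)) pv_stop(what, row = which(!ok)[1])

  if (kind == "ccp") {
    bad(dt$phase %in% c("habituation", "pretest", "conditioning", "posttest"),
        "unknown phase")
    bad(dt$drug %in% c("saline", "cocaine", "none"), "unknown drug")
    bad(dt$floor %in% c("grid", "hole", "both", "smooth"), "unknown floor")
    bad(is.finite(dt$distance_mm) & dt$distance_mm >= 0,
        "distance_mm must be finite and >= 0")
    cond <- dt$phase == "conditioning"
    bad(!cond | (dt$trial >= 1 & dt$trial <= 4 & !is.na(dt$trial)),
        "conditioning trial must be 1-4")
    bad(!cond | dt$floor %in% c("grid", "hole"),
        "conditioning rows must use exactly one of the grid/hole floors")
    bad(!cond | dt$drug %in% c("saline", "cocaine"),
        "conditioning rows must be saline or cocaine")
    test <- dt$phase %in% c("pretest", "posttest")
    bad(!test | dt$floor == "both", "preference tests use both floor halves")
    bad(!test | (is.finite(dt$time_on_grid_s) & is.finite(dt$time_on_hole_s) &
                   dt$time_on_grid_s >= 0 & dt$time_on_hole_s >= 0),
        "preference tests need non-negative floor times")
    bad(!test | dt$time_on_grid_s + dt$time_on_hole_s <= session_duration_s + 1e-6,
        sprintf("floor times exceed the %g s session", session_duration_s))
    need <- data.table::CJ(subject_id = unique(dt$subject_id),
                           what = c("pretest", "posttest",
                                    paste0("cond_", rep(1:4, each = 2),
                                           c("_saline", "_cocaine"))))
    have <- rbind(
      dt[test, .(subject_id, what = phase)],
      dt[cond, .(subject_id, what = paste0("cond_", trial, "_", drug))])
    lack <- need[!have, on = c("subject_id", "what")]
    incomplete <- sort(unique(lack$subject_id))
  } else {
    bad(is.finite(dt$day) & dt$day >= 1 & dt$day <= 8 & dt$day == floor(dt$day),
        "day must be an integer 1-8")
    bad(dt$injection %in% c("none", "saline", "cocaine"), "unknown injection")
    sched <- ifelse(dt$day == 1, "none",
                    ifelse(dt$day %in% c(2, 8), "saline", "cocaine"))
    bad(dt$injection == sched,
        "injection violates the schedule (day 1 none; days 2 and 8 saline; days 3-7 cocaine)")
    bad(is.finite(dt$distance_mm) & dt$distance_mm >= 0,
        "distance_mm must be finite and >= 0")
    bad(is.finite(dt$headwave_bouts) & dt$headwave_bouts >= 0 &
          dt$headwave_bouts == floor(dt$headwave_bouts),
        "headwave_bouts must be a non-negative integer")
    dup <- dt[, .N, by = .(subject_id, day)][N > 1]
    if (nrow(dup))
      pv_stop(sprintf("duplicated day %d for subject %s", dup$day[1], dup$subject_id[1]))
    cover <- dt[, .(ok = all(1:8 %in% day)), by = subject_id]
    incomplete <- sort(cover$subject_id[!cover$ok])
  }
  data.table::setorderv(dt, intersect(c("subject_id", "day", "phase", "trial"), names(dt)))
  data.table::setattr(dt, "kind", kind)
  data.table::setattr(dt, "incomplete_subjects", incomplete)
  dt[]
}

#' Write a session-summary table
#'
#' @param rows a validated summary table.
#' @param path output CSV path.
#' @param kind `"ccp"` or `"ccc"`.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path, kind = attr(rows, "kind")) {
  dt <- validate_summary_table(rows, kind = kind)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the schema version, MD5 checksums of the listed files, the seed
#' and an arbitrary configuration snapshot, so a scoring run can be checked
#' for byte-identical reproduction.
#'
#' @param files character vector of file paths to checksum.
#' @param path output JSON path.
#' @param config optional configuration list to embed.
#' @param seed optional master seed to record.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(files, path, config = NULL, seed = NULL) {
  files <- sort(files)
  manifest <- list(
    schema_version = SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("pavca")),
    seed = seed,
    config = config,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)),
           bytes = file.info(f)$size))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
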