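#' Per-session CS-period aggregates for Pavlovian conditioned approach
#'
#' Collapses a trial-level PavCA event stream to one row per subject-session
#' with the six raw measures the index is built from:
#' the probability of at least one lever contact (and of at least one
#' food-cup entry) on a CS trial, the CS-period lever deflection and food-cup
#' entry counts, the mean per-trial latency to first contact for each target,
#' and the number of food-cup entries during the inter-trial interval.
#'
#' Latencies are censored: a trial with no contact with a given target
#' contributes the full CS duration to that target's mean latency, which
#' keeps the derived latency score bounded in \[-1, 1\].
#'
#' @param events a validated PavCA event table (one or many subject-sessions).
#' @param cs_duration_s CS duration in seconds (default 8).
#' @return a `data.table` with one row per subject-session:
#'   `subject_id, session, n_trials, lever_contact_prob, foodcup_contact_prob,
#'   lever_deflections, foodcup_entries_cs, lever_latency_s,
#'   foodcup_latency_s, iti_foodcup_entries`.
#' @export
summarize_sessions <- function(events, cs_duration_s = 8) {
  dt <- data.table::as.data.table(events)
  win <- derive_trial_windows(dt)
  if (!nrow(win)) pv_stop("no CS trials found")
  cs <- dt[event %in% c("lever_deflection", "foodcup_entry") & trial > 0]
  agg <- if (nrow(cs)) {
    cs[, .(count = .N, first_s = min(time_s)),
       by = .(subject_id, session, trial, event)]
  } else {
    data.table::data.table(subject_id = character(0), session = integer(0),
                           trial = integer(0), event = character(0),
                           count = integer(0), first_s = numeric(0))
  }
  per_trial <- data.table::dcast(agg, subject_id + session + trial ~ event,
                                 value.var = c("count", "first_s"))
  for (cn in c("count_lever_deflection", "count_foodcup_entry",
               "first_s_lever_deflection", "first_s_foodcup_entry"))
    if (!cn %in% names(per_trial)) per_trial[, (cn) := NA_real_]
  per_trial <- per_trial[win, on = c("subject_id", "session", "trial")]
  for (cn in c("count_lever_deflection", "count_foodcup_entry"))
    data.table::set(per_trial, which(is.na(per_trial[[cn]])), cn, 0)
  ## censor trials without contact at the full CS duration
  per_trial[, lever_first := data.table::fifelse(
    count_lever_deflection > 0, first_s_lever_deflection - onset, cs_duration_s)]
  per_trial[, foodcup_first := data.table::fifelse(
    count_foodcup_entry > 0, first_s_foodcup_entry - onset, cs_duration_s)]
  per_trial[, `:=`(lever_hit = count_lever_deflection > 0,
                   foodcup_hit = count_foodcup_entry > 0)]

  out <- per_trial[, .(
    n_trials = .N,
    lever_contact_prob = mean(lever_hit),
    foodcup_contact_prob = mean(foodcup_hit),
    lever_deflections = sum(count_lever_deflection),
    foodcup_entries_cs = sum(count_foodcup_entry),
    lever_latency_s = mean(lever_first),
    foodcup_latency_s = mean(foodcup_first)
  ), by = .(subject_id, session)]
  iti <- dt[event == "foodcup_entry" & trial == 0,
            .(iti_foodcup_entries = .N), by = .(subject_id, session)]
  out <- iti[out, on = c("subject_id", "session")]
  data.table::set(out, which(is.na(out$iti_foodcup_entries)), "iti_foodcup_entries", 0L)
  sx <- unique(dt[, .(subject_id, sex)])
  out <- sx[out, on = "subject_id"]
  data.table::setcolorder(out, c("subject_id", "sex", "session", "n_trials"))
  data.table::setorder(out, subject_id, session)
  out[]
}

#' @rdname summarize_sessions
#' @details `summarize_session()` is the single-group form: it requires the
#'   events of exactly one subject-session and returns a one-row summary.
#' @export
summarize_session <- function(events, cs_duration_s = 8) {
  out <- summarize_sessions(events, cs_duration_s = cs_duration_s)
  if (nrow(out) != 1L)
    pv_stop("summarize_session() expects the events of exactly one subject-session")
  out
}

#' PavCA index components
#'
#' The three components of the Pavlovian conditioned approach index, each
#' bounded in \[-1, 1\] with positive values indicating lever-directed
#' (sign-tracking) behavior:
#' * probability differential: lever contact probability minus food-cup
#'   contact probability;
#' * response bias: (lever deflections - food-cup entries) / (lever
#'   deflections + food-cup entries), defined as 0 when both counts are 0;
#' * latency score: (food-cup latency - lever latency) / CS duration.
#'
#' @param s a session summary from [summarize_sessions()].
#' @param cs_duration_s CS duration in seconds (default 8).
#' @return `pavca_components()` returns `s` with `prob_diff`, `response_bias`,
#'   `latency_score` and `index` columns appended; the scalar helpers return
#'   numeric vectors.
#' @export
pavca_components <- function(s, cs_duration_s = 8) {
  dt <- data.table::as.data.table(s)
  dt[, prob_diff := prob_differential(dt)]
  dt[, response_bias := response_bias(dt)]
  dt[, latency_score := latency_score(dt, cs_duration_s = cs_duration_s)]
  dt[, index := (prob_diff + response_bias + latency_score) / 3]
  dt[]
}

#' @rdname pavca_components
#' @export
prob_differential <- function(s) {
  s <- as.data.frame(s)
  s$lever_contact_prob - s$foodcup_contact_prob
}

#' @rdname pavca_components
#' @export
response_bias <- function(s) {
  s <- as.data.frame(s)
  tot <- s$lever_deflections + s$foodcup_entries_cs
  ifelse(tot == 0, 0, (s$lever_deflections - s$foodcup_entries_cs) / tot)
}

#' @rdname pavca_components
#' @export
latency_score <- function(s, cs_duration_s = 8) {
  s <- as.data.frame(s)
  (s$foodcup_latency_s - s$lever_latency_s) / cs_duration_s
}

#' @rdname pavca_components
#' @param prob_diff,bias,latency the three components (recycled vectors).
#' @export
pavca_index <- function(prob_diff, bias, latency) {
  comp <- cbind(prob_diff, bias, latency)
  if (any(abs(comp) > 1 + 1e-9, na.rm = TRUE))
    pv_stop("index components must lie in [-1, 1]")
  rowMeans(comp)
}

#' Terminal PavCA index
#'
#' The phenotyping score: the mean of the per-session indices from the last
#' two training sessions (4 and 5 under the default 5-session protocol).
#' Subjects missing either terminal session get `NA` and are reported in the
#' `"flagged_subjects"` attribute for casewise exclusion downstream.
#'
#' @param index per-session index values for one subject, or a data.frame
#'   with `subject_id`, `session` and `index` columns for many subjects.
#' @param session session numbers aligned with `index` (vector form).
#' @param terminal_sessions sessions averaged into the terminal score.
#' @return a numeric scalar (vector form) or a `data.table` with one row per
#'   subject (`subject_id`, `terminal_index`).
#' @export
terminal_index <- function(index, session = seq_along(index),
                           terminal_sessions = c(4L, 5L)) {
  if (is.data.frame(index)) {
    dt <- data.table::as.data.table(index)
    out <- dt[, .(terminal_index = {
      got <- match(terminal_sessions, session)
      if (anyNA(got)) NA_real_ else mean(index[got])
    }), by = subject_id]
    flagged <- out$subject_id[is.na(out$terminal_index)]
    data.table::setattr(out, "flagged_subjects", flagged)
    return(out[])
  }
  got <- match(terminal_sessions, session)
  if (anyNA(got)) return(NA_real_)
  mean(index[got])
}

#' Classify the sign-/goal-tracking phenotype
#'
#' Terminal index of -1 to -0.5 is a goal-tracker (GT), +0.5 to +1 a
#' sign-tracker (ST), anything strictly between the thresholds an
#' intermediate (IN). The boundary values +/-0.5 are assigned to the extreme
#' phenotypes; the three intervals partition \[-1, 1\] exactly.
#'
#' @param terminal terminal index values in \[-1, 1\] (`NA` allowed,
#'   propagated).
#' @return a factor with levels `GT`, `IN`, `ST`.
#' @export
classify_phenotype <- function(terminal) {
  ok <- is.na(terminal) | (terminal >= -1 - 1e-9 & terminal <= 1 + 1e-9)
  if (!all(ok))
    pv_stop(sprintf("terminal index out of [-1, 1]: %g", terminal[!ok][1]))
  out <- ifelse(terminal <= -0.5, "GT", ifelse(terminal >= 0.5, "ST", "IN"))
  factor(out, levels = c("GT", "IN", "ST"))
}

#' Score a PavCA event stream end to end
#'
#' Runs [summarize_sessions()], computes the three components and the
#' per-session index, the terminal index (mean of sessions 4 and 5) and the
#' phenotype for every subject.
#'
#' @param events a validated PavCA event table.
#' @param cs_duration_s CS duration in seconds.
#' @param terminal_sessions sessions averaged into the terminal index.
#' @return a list with `sessions` (per subject-session measures, components
#'   and index) and `subjects` (per-subject `terminal_index` and `phenotype`,
#'   with flagged incomplete subjects carrying `NA`).
#' @export
score_pavca <- function(events, cs_duration_s = 8, terminal_sessions = c(4L, 5L)) {
  sess <- pavca_components(summarize_sessions(events, cs_duration_s), cs_duration_s)
  subj <- terminal_index(sess[, .(subject_id, session, index)],
                         terminal_sessions = terminal_sessions)
  flagged <- attr(subj, "flagged_subjects") %||% character(0)
  subj[, phenotype := classify_phenotype(terminal_index)]
  sx <- unique(sess[, .(subject_id, sex)])
  subj <- sx[subj, on = "subject_id"]
  list(sessions = sess[], subjects = subj[], flagged_subjects = flagged)
}
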