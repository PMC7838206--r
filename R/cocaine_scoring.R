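#' Counter-conditioned floor assignment for cue preference
#'
#' Assigns the cocaine-paired floor as the floor the subject spent the least
#' time on during the pre-test. Exact ties are broken by a seeded uniform
#' draw so the assignment is reproducible.
#'
#' @param time_on_grid_s,time_on_hole_s pre-test floor times in seconds
#'   (vectors are recycled).
#' @param seed integer seed used only to break exact ties.
#' @return a character vector of `"grid"` / `"hole"`.
#' @export
assign_cocaine_floor <- function(time_on_grid_s, time_on_hole_s, seed = 1L) {
  if (anyNA(time_on_grid_s) || anyNA(time_on_hole_s))
    pv_stop("pre-test floor times must be non-missing")
  out <- ifelse(time_on_grid_s < time_on_hole_s, "grid",
                ifelse(time_on_hole_s < time_on_grid_s, "hole", NA))
  ties <- is.na(out)
  if (any(ties)) {
    rs <- .Random.seed_save()
    on.exit(.Random.seed_restore(rs))
    set.seed(as.integer(seed))
    out[ties] <- c("grid", "hole")[1L + (stats::runif(sum(ties)) < 0.5)]
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(rs) {
  if (is.null(rs)) return(invisible())
  assign(".Random.seed", rs, envir = globalenv())
}

#' Change in preference for the cocaine-paired floor
#'
#' Post-test minus pre-test time on the cocaine-paired floor, in seconds.
#' Positive values mean the subject increased its time on the cocaine floor
#' after conditioning.
#'
#' @param pre_time_s,post_time_s time on the cocaine floor during the pre-
#'   and post-test.
#' @return seconds (vectorized).
#' @export
ccp_preference_change <- function(pre_time_s, post_time_s) {
  post_time_s - pre_time_s
}

#' Per-trial locomotion and sensitization during cue-preference conditioning
#'
#' @param rows conditioning rows of a validated CCP table for one subject.
#' @return a one-row `data.table` with `cocaine_t1`..`cocaine_t4`,
#'   `saline_t1`..`saline_t4` distances (mm) and `locomotor_sensitization_mm`
#'   (cocaine trial 4 minus trial 1).
#' @export
ccp_locomotor_measures <- function(rows) {
  dt <- data.table::as.data.table(rows)[phase == "conditioning"]
  if (!all(table(dt$drug, dt$trial) == 1) || nrow(dt) != 8L)
    pv_stop("need exactly one cocaine and one saline session per trial 1-4")
  coc <- dt[drug == "cocaine"][order(trial), distance_mm]
  sal <- dt[drug == "saline"][order(trial), distance_mm]
  out <- data.table::as.data.table(
    c(stats::setNames(as.list(coc), paste0("cocaine_t", 1:4)),
      stats::setNames(as.list(sal), paste0("saline_t", 1:4))))
  out[, locomotor_sensitization_mm := cocaine_t4 - cocaine_t1]
  out[]
}

#' Score a cocaine conditioned cue preference table
#'
#' One row per subject: the cocaine-paired floor (taken from the
#' conditioning rows and checked against the counter-conditioning rule),
#' pre- and post-test time on that floor, the preference change, per-trial
#' cocaine and saline distances, the locomotor sensitization contrast
#' (cocaine trial 4 minus trial 1) and the post-test locomotion. Subjects
#' missing either preference test or any conditioning session are excluded
#' casewise and reported in the `"excluded"` attribute.
#'
#' @param ccp a validated CCP summary table (see [read_summary_table()]).
#' @return a `data.table` with class attribute `"excluded"` (a data.frame of
#'   subject/reason pairs).
#' @export
score_ccp <- function(ccp) {
  dt <- validate_summary_table(ccp, kind = "ccp")
  incomplete <- attr(dt, "incomplete_subjects")
  subj <- unique(dt$subject_id)
  keep <- setdiff(subj, incomplete)
  excl <- data.table::data.table(subject_id = incomplete,
                                 reason = rep("incomplete CCP phases", length(incomplete)))
  dt <- dt[subject_id %in% keep]
  if (!nrow(dt)) {
    out <- data.table::data.table(subject_id = character(0))
    data.table::setattr(out, "excluded", excl)
    return(out)
  }
  cfloor <- dt[phase == "conditioning" & drug == "cocaine",
               .(cocaine_floor = unique(floor)[1],
                 n_floors = data.table::uniqueN(floor)), by = subject_id]
  if (any(cfloor$n_floors > 1))
    pv_stop(sprintf("subject %s has cocaine paired with more than one floor",
                    cfloor$subject_id[cfloor$n_floors > 1][1]))
  tests <- dt[phase %in% c("pretest", "posttest")]
  tests <- cfloor[, .(subject_id, cocaine_floor)][tests, on = "subject_id"]
  tests[, time_on_cocaine := ifelse(cocaine_floor == "grid",
                                    time_on_grid_s, time_on_hole_s)]
  pp <- data.table::dcast(tests, subject_id + cocaine_floor ~ phase,
                          value.var = c("time_on_cocaine", "distance_mm"))
  pp[, delta_preference_s := ccp_preference_change(time_on_cocaine_pretest,
                                                   time_on_cocaine_posttest)]
  ## counter-conditioning check: cocaine floor should be the pre-test minority floor
  pre <- tests[phase == "pretest"]
  least <- ifelse(pre$time_on_grid_s < pre$time_on_hole_s, "grid",
                  ifelse(pre$time_on_hole_s < pre$time_on_grid_s, "hole", NA))
  off <- !is.na(least) & least != pre$cocaine_floor
  if (any(off))
    warning(sprintf("%d subject(s) have cocaine paired with the pre-test preferred floor",
                    sum(off)))
  cond <- dt[phase == "conditioning"]
  cond[, dcol := paste0(drug, "_t", trial)]
  loco <- data.table::dcast(cond, subject_id ~ dcol, value.var = "distance_mm")
  loco[, locomotor_sensitization_mm := cocaine_t4 - cocaine_t1]
  out <- loco[pp, on = "subject_id"]
  data.table::setnames(out,
    c("time_on_cocaine_pretest", "time_on_cocaine_posttest", "distance_mm_posttest"),
    c("pre_time_cocaine_floor_s", "post_time_cocaine_floor_s", "posttest_locomotion_mm"))
  out[, distance_mm_pretest := NULL]
  data.table::setcolorder(out, c("subject_id", "cocaine_floor",
                                 "pre_time_cocaine_floor_s",
                                 "post_time_cocaine_floor_s",
                                 "delta_preference_s"))
  data.table::setorder(out, subject_id)
  data.table::setattr(out, "excluded", excl)
  out[]
}

#' Contextual-conditioning day contrasts
#'
#' The three locomotion and three headwaving contrasts of the 8-day
#' contextual conditioning protocol, each a signed later-minus-earlier
#' difference:
#' * acute: day 3 (first cocaine) minus day 2 (saline baseline);
#' * sensitization: day 7 (last cocaine) minus day 3;
#' * conditioned: day 8 (drug-free test in the cocaine context) minus day 2.
#'
#' @param rows validated CCC rows for one subject (days 2, 3, 7, 8 required).
#' @return a one-row `data.table` with the six contrasts.
#' @export
ccc_contrasts <- function(rows) {
  dt <- data.table::as.data.table(rows)
  need <- c(2L, 3L, 7L, 8L)
  if (!all(need %in% dt$day))
    pv_stop(sprintf("missing day(s): %s",
                    paste(setdiff(need, dt$day), collapse = ", ")))
  d <- function(day_) dt$distance_mm[match(day_, dt$day)]
  h <- function(day_) dt$headwave_bouts[match(day_, dt$day)]
  data.table::data.table(
    acute_locomotion_mm = d(3) - d(2),
    sensitization_locomotion_mm = d(7) - d(3),
    conditioned_locomotion_mm = d(8) - d(2),
    acute_headwaves = h(3) - h(2),
    sensitized_headwaves = h(7) - h(3),
    conditioned_headwaves = h(8) - h(2))
}

#' Score a cocaine contextual conditioning table
#'
#' Computes [ccc_contrasts()] per subject. Subjects flagged incomplete (any
#' of days 1-8 missing) are excluded casewise, mirroring the data-collection
#' exclusions applied to such protocols; they are listed in the
#' `"excluded"` attribute and counted in `"n_excluded"`.
#'
#' @param ccc a validated CCC summary table (see [read_summary_table()]).
#' @return a `data.table`, one row per retained subject, with per-day
#'   distance columns `distance_d1`..`d8`, headwave columns and the six
#'   contrasts.
#' @export
score_ccc <- function(ccc) {
  dt <- validate_summary_table(ccc, kind = "ccc")
  incomplete <- attr(dt, "incomplete_subjects")
  excl <- data.table::data.table(subject_id = incomplete,
                                 reason = rep("incomplete CCC days", length(incomplete)))
  dt <- dt[!subject_id %in% incomplete]
  if (!nrow(dt)) {
    out <- data.table::data.table(subject_id = character(0))
  } else {
    tmp <- data.table::copy(dt)
    tmp[, dcol := paste0("d", day)]
    wide_d <- data.table::dcast(tmp, subject_id ~ dcol, value.var = "distance_mm")
    data.table::setnames(wide_d, paste0("d", 1:8), paste0("distance_d", 1:8))
    wide_h <- data.table::dcast(tmp, subject_id ~ dcol, value.var = "headwave_bouts")
    data.table::setnames(wide_h, paste0("d", 1:8), paste0("headwaves_d", 1:8))
    out <- wide_d[wide_h, on = "subject_id"]
    out[, `:=`(
      acute_locomotion_mm = distance_d3 - distance_d2,
      sensitization_locomotion_mm = distance_d7 - distance_d3,
      conditioned_locomotion_mm = distance_d8 - distance_d2,
      acute_headwaves = headwaves_d3 - headwaves_d2,
      sensitized_headwaves = headwaves_d7 - headwaves_d3,
      conditioned_headwaves = headwaves_d8 - headwaves_d2)]
    data.table::setorder(out, subject_id)
  }
  data.table::setattr(out, "excluded", excl)
  data.table::setattr(out, "n_excluded", nrow(excl))
  out[]
}
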