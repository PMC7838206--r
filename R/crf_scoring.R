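#' Score a conditioned reinforcement (CRF) session
#'
#' Tallies a 40-min CRF event stream per subject: nosepokes into the active
#' and inactive ports, earned reinforcers (3-s lever-CS presentations; an
#' active poke during an ongoing presentation counts as a poke but does not
#' queue another presentation), and lever deflections during the
#' presentations. Two composite measures are derived:
#' * presses per reinforcer: lever deflections / earned reinforcers, the
#'   most direct read-out of the cue's incentive value. Subjects that earned
#'   no reinforcer get `NA` and are excluded casewise from analyses of this
#'   measure;
#' * incentive value index: (active pokes - inactive pokes) + lever
#'   deflections.
#'
#' @param events a validated CRF event table (one or many subjects).
#' @return a `data.table` with one row per subject: `subject_id, sex,
#'   active_pokes, inactive_pokes, earned_reinforcers, lever_deflections,
#'   presses_per_reinforcer, incentive_value_index`.
#' @export
crf_summary <- function(events) {
  dt <- data.table::as.data.table(events)
  out <- dt[, .(
    active_pokes = sum(event == "poke_active"),
    inactive_pokes = sum(event == "poke_inactive"),
    earned_reinforcers = sum(event == "lever_presentation"),
    lever_deflections = sum(event == "lever_deflection")
  ), by = .(subject_id, sex)]
  out[, presses_per_reinforcer :=
        presses_per_reinforcer(lever_deflections, earned_reinforcers)]
  out[, incentive_value_index :=
        incentive_value_index(active_pokes, inactive_pokes, lever_deflections)]
  data.table::setorder(out, subject_id)
  out[]
}

#' @rdname crf_summary
#' @param lever_deflections,earned_reinforcers,active_pokes,inactive_pokes
#'   count vectors (recycled).
#' @export
presses_per_reinforcer <- function(lever_deflections, earned_reinforcers) {
  ifelse(earned_reinforcers == 0, NA_real_,
         lever_deflections / earned_reinforcers)
}

#' @rdname crf_summary
#' @export
incentive_value_index <- function(active_pokes, inactive_pokes, lever_deflections) {
  (active_pokes - inactive_pokes) + lever_deflections
}
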