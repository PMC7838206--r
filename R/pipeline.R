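#' Score all tasks of a cohort into a per-subject trait table
#'
#' Joins the PavCA terminal index and phenotype with the
#' conditioned-reinforcement, cue-preference and contextual-conditioning
#' measures. Subjects present in one task but missing from another are
#' retained with `NA` fields (each downstream analysis excludes them
#' casewise); every exclusion is logged with its reason.
#'
#' @param pavca_events validated PavCA event table (required).
#' @param crf_events validated CRF event table, or NULL.
#' @param ccp validated CCP summary table, or NULL.
#' @param ccc validated CCC summary table, or NULL.
#' @param cs_duration_s CS duration for PavCA scoring.
#' @return a list of class `pavca_scored`: `subjects` (one row per subject),
#'   `pavca_sessions` (per-session measures and index) and `exclusions`
#'   (data.frame of subject/task/reason).
#' @export
run_score <- function(pavca_events, crf_events = NULL, ccp = NULL, ccc = NULL,
                      cs_duration_s = 8) {
  if (!nrow(data.table::as.data.table(pavca_events))) {
    warning("empty event table: no subjects to score")
    out <- list(subjects = data.table::data.table(subject_id = character(0)),
                pavca_sessions = data.table::data.table(subject_id = character(0)),
                exclusions = data.table::data.table(
                  subject_id = character(0), task = character(0),
                  reason = character(0)))
    class(out) <- "pavca_scored"
    return(out)
  }
  pv <- score_pavca(pavca_events, cs_duration_s = cs_duration_s)
  subj <- data.table::copy(pv$subjects)
  excl <- list()
  note <- function(ids, task, reason) {
    if (length(ids))
      excl[[length(excl) + 1L]] <<- data.table::data.table(
        subject_id = ids, task = task, reason = reason)
  }
  note(pv$flagged_subjects, "pavca", "missing terminal session")

  if (!is.null(crf_events)) {
    crf <- crf_summary(crf_events)
    note(crf$subject_id[crf$earned_reinforcers == 0], "crf",
         "no earned reinforcer (presses per reinforcer undefined)")
    subj <- merge(subj, crf[, !"sex"], by = "subject_id", all = TRUE)
  }
  if (!is.null(ccp)) {
    sc <- score_ccp(ccp)
    ex <- attr(sc, "excluded")
    note(ex$subject_id, "ccp", ex$reason)
    subj <- merge(subj, sc, by = "subject_id", all = TRUE)
  }
  if (!is.null(ccc)) {
    sc <- score_ccc(ccc)
    ex <- attr(sc, "excluded")
    note(ex$subject_id, "ccc", ex$reason)
    subj <- merge(subj, sc, by = "subject_id", all = TRUE)
  }
  exclusions <- if (length(excl)) data.table::rbindlist(excl) else
    data.table::data.table(subject_id = character(0), task = character(0),
                           reason = character(0))
  if (!nrow(subj)) warning("empty cohort: no subjects scored")
  out <- list(subjects = subj[], pavca_sessions = pv$sessions,
              exclusions = exclusions[])
  class(out) <- "pavca_scored"
  out
}

#' Run the inferential battery on a scored cohort
#'
#' The standard analysis plan: mixed RM-ANOVAs per task (Sex and phenotype
#' between subjects; Session, Port, Drug-by-Trial or Day as repeated
#' factors), Tukey HSD probes of the phenotype effect, the per-sex
#' correlation panel between terminal index and the cocaine measures, the
#' raw-measure correlation panel (terminal-session lever contacts and
#' food-cup entries against the cue-preference measures), and
#' eigenvalue-1 varimax PCA over the trait panel. Models with too few
#' complete subjects are skipped with a logged reason.
#'
#' @param scored a `pavca_scored` object from [run_score()].
#' @param min_n minimum complete subjects for a model to run.
#' @return a list of class `pavca_stats` with elements `anova` (named list
#'   of `pavca_anova` tables), `tukey`, `correlations` (one tidy table),
#'   `pca` (named list of `pavca_pca`), and `skipped`.
#' @export
run_stats <- function(scored, min_n = 12) {
  subj <- data.table::as.data.table(scored$subjects)
  sess <- data.table::as.data.table(scored$pavca_sessions)
  skipped <- character(0)
  anovas <- list(); tukeys <- list(); pcas <- list(); cors <- list()
  has <- function(v) v %in% names(subj)

  meta <- subj[, .(subject_id, sex, phenotype)]
  sess2 <- meta[sess[, !"sex"], on = "subject_id"]
  sess2 <- sess2[!is.na(phenotype)]

  try_anova <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) skipped <<- c(skipped, sprintf("%s: %s", name, res))
    else anovas[[name]] <<- res
  }
  if (data.table::uniqueN(sess2$subject_id) >= min_n) {
    try_anova("pavca_index", mixed_rm_anova(
      sess2, dv = "index", between = c("sex", "phenotype"),
      within = "session"))
  } else skipped <- c(skipped, "pavca_index: too few subjects")

  if (has("active_pokes")) {
    long <- data.table::melt(
      subj[!is.na(active_pokes) & !is.na(phenotype),
           .(subject_id, sex, phenotype, active = active_pokes,
             inactive = inactive_pokes)],
      id.vars = c("subject_id", "sex", "phenotype"),
      variable.name = "port", value.name = "pokes")
    if (data.table::uniqueN(long$subject_id) >= min_n)
      try_anova("crf_port", mixed_rm_anova(
        long, dv = "pokes", between = c("sex", "phenotype"), within = "port"))
    ppr <- subj[!is.na(presses_per_reinforcer) & !is.na(phenotype)]
    if (nrow(ppr) >= min_n) {
      try_anova("crf_ppr", mixed_rm_anova(
        ppr, dv = "presses_per_reinforcer", between = c("sex", "phenotype")))
      tukeys$crf_ppr_phenotype <- tukey_hsd_groups(
        ppr$presses_per_reinforcer, ppr$phenotype)
    }
  }
  if (has("cocaine_t1")) {
    cc <- subj[!is.na(cocaine_t1) & !is.na(phenotype)]
    if (nrow(cc) >= min_n) {
      long <- data.table::melt(
        cc[, c("subject_id", "sex", "phenotype",
               paste0("cocaine_t", 1:4), paste0("saline_t", 1:4)),
           with = FALSE],
        id.vars = c("subject_id", "sex", "phenotype"))
      long[, drug := ifelse(grepl("^cocaine", variable), "cocaine", "saline")]
      long[, trial := as.integer(sub(".*_t", "", variable))]
      try_anova("ccp_locomotion", mixed_rm_anova(
        long, dv = "value", between = c("sex", "phenotype"),
        within = c("drug", "trial")))
      pref <- data.table::melt(
        cc[, .(subject_id, sex, phenotype,
               pre = pre_time_cocaine_floor_s, post = post_time_cocaine_floor_s)],
        id.vars = c("subject_id", "sex", "phenotype"),
        variable.name = "test", value.name = "time_on_cocaine_s")
      try_anova("ccp_preference", mixed_rm_anova(
        pref, dv = "time_on_cocaine_s", between = c("sex", "phenotype"),
        within = "test"))
    }
  }
  if (has("acute_locomotion_mm")) {
    cc <- subj[!is.na(acute_locomotion_mm) & !is.na(phenotype)]
    if (nrow(cc) >= min_n) {
      for (ct in list(c("ccc_acute", "distance_d2", "distance_d3"),
                      c("ccc_sensitization", "distance_d3", "distance_d7"),
                      c("ccc_conditioned", "distance_d2", "distance_d8"),
                      c("ccc_headwave_acute", "headwaves_d2", "headwaves_d3"),
                      c("ccc_headwave_sens", "headwaves_d3", "headwaves_d7"))) {
        long <- data.table::melt(
          cc[, c("subject_id", "sex", "phenotype", ct[2], ct[3]), with = FALSE],
          id.vars = c("subject_id", "sex", "phenotype"),
          variable.name = "day", value.name = "measure")
        try_anova(ct[1], mixed_rm_anova(
          long, dv = "measure", between = c("sex", "phenotype"),
          within = "day"))
      }
    }
  }

  ## per-sex correlation panel: terminal index vs cocaine measures,
  ## pooled index vs conditioned-reinforcement coupling
  add_cor <- function(panel, xvar, yvar, data, by_sex = TRUE) {
    grps <- if (by_sex) c("female", "male") else "all"
    for (gx in grps) {
      d <- if (gx == "all") data else data[sex == gx]
      d <- d[stats::complete.cases(d[, c(xvar, yvar), with = FALSE])]
      if (nrow(d) < 3) next
      res <- pearson_with_r2(d[[xvar]], d[[yvar]])
      cors[[length(cors) + 1L]] <<- data.table::data.table(
        panel = panel, x = xvar, y = yvar, group = gx, res)
    }
  }
  if (has("presses_per_reinforcer"))
    add_cor("crf", "terminal_index", "presses_per_reinforcer", subj,
            by_sex = TRUE)
  if (has("presses_per_reinforcer"))
    add_cor("crf", "terminal_index", "presses_per_reinforcer", subj,
            by_sex = FALSE)
  if (has("cocaine_t4")) {
    add_cor("ccp", "terminal_index", "cocaine_t1", subj)
    add_cor("ccp", "terminal_index", "cocaine_t4", subj)
    add_cor("ccp", "terminal_index", "delta_preference_s", subj)
    add_cor("ccp", "terminal_index", "posttest_locomotion_mm", subj)
  }
  if (has("conditioned_locomotion_mm")) {
    add_cor("ccc", "terminal_index", "acute_locomotion_mm", subj)
    add_cor("ccc", "terminal_index", "conditioned_locomotion_mm", subj)
    add_cor("ccc", "terminal_index", "conditioned_headwaves", subj)
  }
  ## raw-measure panel: terminal-session raw behavior vs cue-preference
  if (has("delta_preference_s") && nrow(sess2)) {
    raw5 <- sess2[session == max(session),
                  .(subject_id, lever_deflections, foodcup_entries_cs)]
    rawj <- raw5[subj, on = "subject_id"]
    add_cor("raw_ccp", "lever_deflections", "delta_preference_s", rawj)
    add_cor("raw_ccp", "foodcup_entries_cs", "delta_preference_s", rawj)
    add_cor("raw_ccp", "lever_deflections", "cocaine_t4", rawj)
  }
  correlations <- if (length(cors)) data.table::rbindlist(cors) else NULL

  ## trait-panel PCA (eigenvalue >= 1, normalized varimax)
  if (has("cocaine_t4") && has("presses_per_reinforcer")) {
    pan <- subj[, .(terminal_index, presses_per_reinforcer,
                    cocaine_t1, cocaine_t4, delta_preference_s)]
    if (sum(stats::complete.cases(pan)) >= min_n)
      pcas$ccp_panel <- pca_varimax(pan)
  }
  if (has("conditioned_locomotion_mm") && has("incentive_value_index")) {
    pan <- subj[, .(terminal_index, incentive_value_index,
                    acute_locomotion_mm, conditioned_locomotion_mm,
                    sensitized_headwaves)]
    if (sum(stats::complete.cases(pan)) >= min_n)
      pcas$ccc_panel <- pca_varimax(pan)
  }
  out <- list(anova = anovas, tukey = tukeys, correlations = correlations,
              pca = pcas, skipped = skipped)
  class(out) <- "pavca_stats"
  out
}

#' Descriptive summary tables and a machine-readable results bundle
#'
#' Per phenotype-by-sex descriptives of the key measures (mean, SEM, median,
#' quartiles by linear interpolation, and the boxplot notch half-width
#' `1.58 * IQR / sqrt(n)` behind the usual 95 percent notch convention),
#' plus flat exports of the ANOVA, correlation and PCA results.
#'
#' @param stats a `pavca_stats` object.
#' @param scored the matching `pavca_scored` object.
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV plus a single `results.json` bundle (stable key order).
#' @return a list: `descriptives`, `anova`, `correlations`, `pca_loadings`,
#'   `exclusions`; invisibly writes files when `out_dir` is set.
#' @export
run_report <- function(stats, scored, out_dir = NULL) {
  subj <- data.table::as.data.table(scored$subjects)
  meas <- intersect(c("terminal_index", "presses_per_reinforcer",
                      "incentive_value_index", "delta_preference_s",
                      "cocaine_t1", "cocaine_t4", "locomotor_sensitization_mm",
                      "acute_locomotion_mm", "conditioned_locomotion_mm",
                      "sensitized_headwaves"), names(subj))
  desc <- data.table::rbindlist(lapply(meas, function(m) {
    subj[!is.na(get(m)) & !is.na(phenotype),
         {
           v <- as.numeric(get(m))
           .(measure = m, n = .N,
             mean = mean(v),
             sem = if (.N > 1) stats::sd(v) / sqrt(.N) else NA_real_,
             median = as.numeric(stats::median(v)),
             q1 = unname(stats::quantile(v, 0.25, type = 7)),
             q3 = unname(stats::quantile(v, 0.75, type = 7)),
             notch = 1.58 * stats::IQR(v, type = 7) / sqrt(.N))
         },
         by = .(phenotype, sex)]
  }))
  if (nrow(desc)) data.table::setorder(desc, measure, phenotype, sex)
  an <- if (length(stats$anova)) data.table::rbindlist(
    lapply(names(stats$anova), function(nm)
      data.table::data.table(model = nm,
                             data.table::as.data.table(stats$anova[[nm]]))))
  else NULL
  pca_l <- if (length(stats$pca)) data.table::rbindlist(
    lapply(names(stats$pca), function(nm) {
      L <- stats$pca[[nm]]$loadings
      data.table::data.table(panel = nm, variable = rownames(L),
                             data.table::as.data.table(as.data.frame(L)),
                             communality = stats$pca[[nm]]$communality)
    }), fill = TRUE)
  else NULL
  out <- list(descriptives = desc, anova = an,
              correlations = stats$correlations, pca_loadings = pca_l,
              exclusions = scored$exclusions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]]) && nrow(out[[nm]]))
        data.table::fwrite(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    bundle <- lapply(out, function(x) if (is.null(x)) NULL else as.data.frame(x))
    bundle$pca_variance <- lapply(stats$pca, function(p)
      list(n_retained = p$n_retained, eigenvalues = p$eigenvalues,
           prop_variance = p$prop_variance, cum_variance = p$cum_variance))
    bundle$skipped_models <- stats$skipped
    jsonlite::write_json(bundle, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
    files <- list.files(out_dir, full.names = TRUE, pattern = "\\.(csv|json)$")
    write_manifest(setdiff(files, file.path(out_dir, "manifest.json")),
                   file.path(out_dir, "manifest.json"))
  }
  out
}
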