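#' Synthetic cohort configuration
#'
#' Bundles every schedule parameter and generative setting of the synthetic
#' cohort. Schedule defaults are the study conditions of the emulated
#' protocol: 5 Pavlovian sessions of 25 trials with an 8-s lever CS and
#' variable intervals drawn uniformly on 30-150 s (mean 90 s, so the mean
#' cumulative inter-trial time is 37.5 min per session); a 40-min
#' conditioned-reinforcement session with 3-s lever presentations; 4
#' cue-preference trials at 10 mg/kg cocaine; 8 contextual-conditioning
#' days at 15 mg/kg (doses are metadata only).
#'
#' The cohort is driven by two standardized latent traits per subject:
#' incentive salience (drives lever- vs food-cup-directed behavior and the
#' conditioned reinforcing value of the cue) and cocaine responsivity
#' (drives cocaine-induced locomotion and conditioned responses). Their
#' population correlation is `trait_correlation_rho`; the default 0 encodes
#' the independence structure the generator is built to emulate.
#' `crf_coupling` is the target share of variance in presses per reinforcer
#' explained by the terminal index (cohort level). `sex_index_shift` moves
#' the female incentive-salience mean upward (females more lever-directed);
#' `sex_locomotor_multiplier` scales female cocaine locomotion.
#'
#' @param n_subjects cohort size.
#' @param sex_ratio proportion of females.
#' @param n_sessions,trials_per_session,cs_duration_s,iti_range_s PavCA
#'   schedule.
#' @param crf_duration_min,crf_presentation_s CRF schedule.
#' @param ccp_trials,ccp_test_duration_s,ccp_dose_mg_kg cue-preference
#'   schedule.
#' @param ccc_days,ccc_dose_mg_kg contextual-conditioning schedule.
#' @param trait_correlation_rho latent trait correlation in \[-1, 1\].
#' @param sex_index_shift female shift of the incentive-salience mean (SD
#'   units).
#' @param sex_locomotor_multiplier female multiplier on cocaine locomotion.
#' @param crf_coupling target r^2 between terminal index and presses per
#'   reinforcer.
#' @param cohort cohort label (`"A"` or `"B"`).
#' @param master_seed integer master seed; all stage streams derive from it.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 100, sex_ratio = 0.5,
                          n_sessions = 5, trials_per_session = 25,
                          cs_duration_s = 8, iti_range_s = c(30, 150),
                          crf_duration_min = 40, crf_presentation_s = 3,
                          ccp_trials = 4, ccp_test_duration_s = 1800,
                          ccp_dose_mg_kg = 10,
                          ccc_days = 8, ccc_dose_mg_kg = 15,
                          trait_correlation_rho = 0,
                          sex_index_shift = 0.3,
                          sex_locomotor_multiplier = 1.3,
                          crf_coupling = 0.43,
                          cohort = "A",
                          master_seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
              n_sessions = as.integer(n_sessions),
              trials_per_session = as.integer(trials_per_session),
              cs_duration_s = cs_duration_s, iti_range_s = iti_range_s,
              crf_duration_min = crf_duration_min,
              crf_presentation_s = crf_presentation_s,
              ccp_trials = as.integer(ccp_trials),
              ccp_test_duration_s = ccp_test_duration_s,
              ccp_dose_mg_kg = ccp_dose_mg_kg,
              ccc_days = as.integer(ccc_days), ccc_dose_mg_kg = ccc_dose_mg_kg,
              trait_correlation_rho = trait_correlation_rho,
              sex_index_shift = sex_index_shift,
              sex_locomotor_multiplier = sex_locomotor_multiplier,
              crf_coupling = crf_coupling,
              cohort = match.arg(cohort, c("A", "B")),
              master_seed = as.integer(master_seed))
  stopifnot(cfg$n_subjects >= 1, cfg$sex_ratio >= 0, cfg$sex_ratio <= 1,
            cfg$n_sessions >= 1, cfg$trials_per_session >= 1,
            cfg$cs_duration_s > 0, length(cfg$iti_range_s) == 2,
            cfg$iti_range_s[1] > 0, diff(cfg$iti_range_s) >= 0,
            cfg$crf_duration_min > 0, cfg$crf_presentation_s > 0,
            cfg$ccp_trials >= 1, cfg$ccc_days == 8,
            abs(cfg$trait_correlation_rho) <= 1,
            cfg$crf_coupling >= 0, cfg$crf_coupling < 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' @rdname cohort_config
#' @param path path to a YAML file whose keys are `cohort_config()`
#'   arguments.
#' @export
cohort_config_from_yaml <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' Draw latent traits for a synthetic cohort
#'
#' One row per subject: sex (fixed proportions, shuffled order), a
#' standardized incentive-salience trait `theta_is` (bivariate normal with
#' `theta_cr`, correlation `trait_correlation_rho`, female mean shifted up
#' by `sex_index_shift`) and a standardized cocaine-responsivity trait
#' `theta_cr`.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed for this stage (defaults to the trait stream of the
#'   master seed).
#' @return a `data.table`: `subject_id, cohort, sex, batch, theta_is,
#'   theta_cr`.
#' @export
draw_traits <- function(config, seed = stage_seed(config$master_seed, "traits")) {
  set.seed(seed)
  n <- config$n_subjects
  nf <- round(n * config$sex_ratio)
  sex <- sample(rep(c("female", "male"), c(nf, n - nf)))
  z1 <- stats::rnorm(n)
  z2 <- config$trait_correlation_rho * z1 +
    sqrt(1 - config$trait_correlation_rho^2) * stats::rnorm(n)
  data.table::data.table(
    subject_id = sprintf("S%05d", seq_len(n)),
    cohort = config$cohort,
    sex = sex,
    batch = as.integer(ceiling(seq_len(n) / 16)),
    theta_is = z1 + config$sex_index_shift * (sex == "female"),
    theta_cr = z2)
}

#' Variable-interval trial schedule for PavCA sessions
#'
#' Draws the inter-trial intervals (uniform on `iti_range_s`) and CS onset
#' times for `n_sessions` sessions; the same routine feeds
#' [simulate_pavca()]. Under the default VI-90 schedule the expected
#' cumulative inter-trial time is `trials_per_session * 90` s = 37.5 min.
#'
#' @param config a [cohort_config()].
#' @param n_sessions number of sessions to draw.
#' @param seed RNG seed.
#' @return a `data.table`: `session, trial, iti_s, onset_s`.
#' @export
pavca_session_schedule <- function(config, n_sessions = config$n_sessions,
                                   seed = stage_seed(config$master_seed, "misc")) {
  set.seed(seed)
  nT <- config$trials_per_session
  dt <- data.table::CJ(session = seq_len(n_sessions), trial = seq_len(nT))
  dt[, iti_s := stats::runif(.N, config$iti_range_s[1], config$iti_range_s[2])]
  dt[, onset_s := cumsum(iti_s) + (trial - 1) * config$cs_duration_s,
     by = session]
  dt[]
}

## generative constants of the acquisition model; see the methods vignette
.pavca_gen <- list(
  contact_base = 0.85, contact_gain = 1.6,   # logit of CS contact probability
  count_base = 0.9, count_gain = 0.45,       # log extra-contact Poisson mean
  lat_base = -0.4, lat_gain = 0.5,           # log first-contact hazard
  iti_entry_rate = 1.5, iti_female_mult = 1.3)

#' Simulate trial-level PavCA event streams
#'
#' Per trial, lever contact is Bernoulli with probability
#' `plogis(a0 + a1 * s * theta_is)` where `s` scales session 1 to 0 (cue
#' learning not yet expressed: behavior near-indifferent) and the final
#' session to 1 (trait-saturated); food-cup behavior mirrors it with
#' `-theta_is`. Contact trials add `1 + Poisson` deflections/entries with a
#' trait-scaled log-mean, first-contact latencies are truncated-exponential
#' on the CS window with a trait-scaled hazard, and inter-trial food-cup
#' entries are Poisson with a female-elevated rate. Inter-trial intervals
#' come from [pavca_session_schedule()]'s uniform draw. All times are
#' written at millisecond grain in the event dialect.
#'
#' @param traits from [draw_traits()].
#' @param config a [cohort_config()].
#' @param seed RNG seed for this stage.
#' @param validate run the full dialect validation on the result (default
#'   TRUE).
#' @return a validated PavCA event `data.table`.
#' @export
simulate_pavca <- function(traits, config,
                           seed = stage_seed(config$master_seed, "pavca"),
                           validate = TRUE) {
  set.seed(seed)
  g <- .pavca_gen
  cs <- config$cs_duration_s
  nS <- config$n_sessions; nT <- config$trials_per_session
  tr <- data.table::as.data.table(traits)
  grid <- data.table::CJ(subject_id = tr$subject_id, session = seq_len(nS),
                         trial = seq_len(nT), sorted = TRUE)
  grid <- tr[, .(subject_id, sex, theta_is)][grid, on = "subject_id"]
  N <- nrow(grid)
  s_sc <- if (nS > 1) (grid$session - 1) / (nS - 1) else 1
  grid[, iti_s := stats::runif(N, config$iti_range_s[1], config$iti_range_s[2])]
  grid[, onset := round(cumsum(iti_s) + (trial - 1) * cs, 3),
       by = .(subject_id, session)]

  drive <- s_sc * grid$theta_is
  p_lev <- stats::plogis(g$contact_base + g$contact_gain * drive)
  p_fc  <- stats::plogis(g$contact_base - g$contact_gain * drive)
  hit_lev <- stats::rbinom(N, 1, p_lev) == 1
  hit_fc  <- stats::rbinom(N, 1, p_fc) == 1
  n_lev <- ifelse(hit_lev, 1L + stats::rpois(N, exp(g$count_base + g$count_gain * drive)), 0L)
  n_fc  <- ifelse(hit_fc,  1L + stats::rpois(N, exp(g$count_base - g$count_gain * drive)), 0L)
  lat_lev <- pmin(round(rtrunc_exp(N, exp(g$lat_base + g$lat_gain * drive), cs), 3),
                  cs - 0.001)
  lat_fc  <- pmin(round(rtrunc_exp(N, exp(g$lat_base - g$lat_gain * drive), cs), 3),
                  cs - 0.001)
  fem <- grid$sex == "female"
  n_iti <- stats::rpois(N, g$iti_entry_rate *
                          ifelse(fem, g$iti_female_mult, 1) * grid$iti_s / 90)

  base_cols <- c("subject_id", "session", "trial")
  mk <- function(rows, event, time) {
    out <- grid[rows, base_cols, with = FALSE]
    out[, `:=`(event = event, time_s = time)]
    out
  }
  expand_contacts <- function(counts, lat) {
    idx <- rep.int(seq_len(N), counts)
    lower <- lat[idx]
    within <- lower + stats::runif(length(idx)) * (cs - 0.002 - lower)
    within[!duplicated(idx)] <- lower[!duplicated(idx)]
    list(idx = idx, time = grid$onset[idx] + pmin(round(within, 3), cs - 0.001))
  }
  lev <- expand_contacts(n_lev, lat_lev)
  fc <- expand_contacts(n_fc, lat_fc)
  idx_iti <- rep.int(seq_len(N), n_iti)
  t_iti <- grid$onset[idx_iti] -
    round(stats::runif(length(idx_iti), 0.001, 1) * (grid$iti_s[idx_iti] - 0.002), 3)
  t_iti <- pmax(round(t_iti, 3), 0)

  ev <- data.table::rbindlist(list(
    mk(seq_len(N), "cs_onset", grid$onset),
    mk(seq_len(N), "cs_offset", grid$onset + cs),
    mk(seq_len(N), "pellet_delivery", grid$onset + cs),
    mk(lev$idx, "lever_deflection", lev$time),
    mk(fc$idx, "foodcup_entry", fc$time),
    {
      out <- grid[idx_iti, base_cols, with = FALSE]
      out[, `:=`(trial = 0L, event = "foodcup_entry", time_s = t_iti)]
      out
    }))
  ev <- tr[, .(subject_id, cohort, sex)][ev, on = "subject_id"]
  ev[, task := "pavca"]
  data.table::setcolorder(ev, EVENT_COLS)
  if (validate) validate_events(ev, task = "pavca", cs_duration_s = cs)
  else {
    data.table::setorder(ev, subject_id, session, time_s, event)
    data.table::setattr(ev, "task", "pavca"); ev[]
  }
}

## conditioned-reinforcement generative constants
.crf_gen <- list(active_base = 4.0, active_theta = 0.25, active_noise = 0.3,
                 inactive_mean = 10,
                 pp_mean = 2.5, pp_scale = 1.0, pp_floor = 0.05,
                 pp_poisson_var = 0.05)

#' Simulate conditioned-reinforcement event streams
#'
#' Active-port nosepokes arrive as a Poisson process over the session with
#' a rate increasing in incentive salience; each poke outside an ongoing
#' 3-s lever presentation earns a presentation (fixed-ratio-1 with lockout:
#' pokes during a presentation count as pokes but queue nothing, so earned
#' reinforcers never exceed active pokes). Lever deflections per
#' presentation are Poisson with a subject-level mean coupled to the
#' cohort-standardized terminal index so that the cohort r^2 between index
#' and presses per reinforcer matches `crf_coupling` up to sampling error
#' (the Poisson measurement variance is budgeted into the residual).
#'
#' @param traits from [draw_traits()].
#' @param terminal a data.frame with `subject_id` and `terminal_index`
#'   (e.g. `score_pavca(...)$subjects`).
#' @param config a [cohort_config()].
#' @param seed RNG seed for this stage.
#' @return a validated CRF event `data.table`.
#' @export
simulate_crf <- function(traits, terminal, config,
                         seed = stage_seed(config$master_seed, "crf")) {
  set.seed(seed)
  g <- .crf_gen
  tr <- data.table::as.data.table(traits)
  term <- data.table::as.data.table(terminal)[, .(subject_id, terminal_index)]
  tr <- term[tr, on = "subject_id"]
  if (anyNA(tr$terminal_index))
    pv_stop("terminal index missing for some subjects")
  n <- nrow(tr)
  dur <- config$crf_duration_min * 60
  pres_s <- config$crf_presentation_s
  z <- if (n > 1 && stats::sd(tr$terminal_index) > 0)
    as.numeric(scale(tr$terminal_index)) else rep(0, n)

  cc <- config$crf_coupling
  gain <- g$pp_scale * sqrt(cc)
  resid_sd <- g$pp_scale * sqrt(max(0.01, 1 - cc - g$pp_poisson_var))
  mu_pp <- pmax(g$pp_floor, g$pp_mean + gain * z + resid_sd * stats::rnorm(n))

  n_act <- stats::rpois(n, exp(g$active_base + g$active_theta * tr$theta_is +
                                 g$active_noise * stats::rnorm(n)))
  n_inact <- stats::rpois(n, g$inactive_mean)

  idx_a <- rep.int(seq_len(n), n_act)
  t_act <- round(stats::runif(length(idx_a)) * (dur - pres_s), 3)
  act <- data.table::data.table(i = idx_a, time_s = t_act)
  data.table::setorder(act, i, time_s)
  act[, earned := lockout_earned_flag(time_s, pres_s), by = i]
  pres <- act[earned == TRUE]
  pres[, pres_no := seq_len(.N), by = i]
  n_earned <- tabulate(pres$i, nbins = n)

  n_defl <- stats::rpois(n, n_earned * mu_pp)
  idx_d <- rep.int(seq_len(n), n_defl)
  pick <- ceiling(stats::runif(length(idx_d)) * n_earned[idx_d])
  dd <- data.table::data.table(i = idx_d, pres_no = pick)
  dd <- pres[, .(i, pres_no, pt = time_s)][dd, on = c("i", "pres_no")]
  t_defl <- round(dd$pt + stats::runif(nrow(dd), 0.001, pres_s - 0.002), 3)

  idx_i <- rep.int(seq_len(n), n_inact)
  t_inact <- round(stats::runif(length(idx_i)) * dur, 3)

  mk <- function(i, event, time) data.table::data.table(
    subject_id = tr$subject_id[i], session = 1L, trial = 0L,
    event = event, time_s = time)
  ev <- data.table::rbindlist(list(
    mk(act$i, "poke_active", act$time_s),
    mk(idx_i, "poke_inactive", t_inact),
    mk(pres$i, "lever_presentation", pres$time_s),
    mk(dd$i, "lever_deflection", t_defl)))
  ev <- tr[, .(subject_id, cohort, sex)][ev, on = "subject_id"]
  ev[, task := "crf"]
  data.table::setcolorder(ev, EVENT_COLS)
  validate_events(ev, task = "crf")
}

## TRUE for pokes that start a presentation under the 3-s lockout
lockout_earned_flag <- function(times, dur) {
  n <- length(times)
  out <- logical(n)
  free_at <- -Inf
  for (j in seq_len(n)) {
    if (times[j] >= free_at) {
      out[j] <- TRUE
      free_at <- times[j] + dur
    }
  }
  out
}

## cue-preference generative constants
.ccp_gen <- list(bias_mean = 120, bias_sd = 80, bias_gt_gain = 60, bias_max = 800,
                 persistence = 0.5,
                 shift_mean = 150, shift_cr_gain = 40, shift_female = 25,
                 shift_sd = 100,
                 log_base = log(4000), base_sd = 0.2, noise_sd = 0.2,
                 acute_factor = 1.8, cocaine_gain = 0.35, sens_per_trial = 0.12,
                 posttest_boost = 1.15, posttest_cr_gain = 0.2)

#' Simulate a cocaine conditioned cue preference table
#'
#' Pre-test floor preference is asymmetric around 50/50 with a bias
#' component that grows as incentive salience falls (goal-trackers carry
#' the strongest initial bias); the cocaine floor is the counter-conditioned
#' (less preferred) one via [assign_cocaine_floor()]. The post-test only
#' partially retains the initial bias (regression to the mean) and adds a
#' conditioned shift toward the cocaine floor scaled by cocaine
#' responsivity, so the preference change is positive on average and
#' largest in goal-trackers. Cocaine-trial locomotion is log-normal around
#' a subject baseline, multiplied by the female factor, a per-trial
#' sensitization increment, and `exp(b * theta_cr)`; saline trials stay at
#' baseline.
#'
#' @inheritParams simulate_crf
#' @return a validated CCP summary `data.table`.
#' @export
simulate_ccp <- function(traits, config,
                         seed = stage_seed(config$master_seed, "ccp")) {
  set.seed(seed)
  g <- .ccp_gen
  tr <- data.table::as.data.table(traits)
  n <- nrow(tr)
  fem <- tr$sex == "female"
  half <- config$ccp_test_duration_s / 2

  bias <- pmin(g$bias_max,
               abs(stats::rnorm(n, g$bias_mean, g$bias_sd)) +
                 g$bias_gt_gain * pmax(0, -tr$theta_is))
  less <- sample(c("grid", "hole"), n, replace = TRUE)
  pre_grid <- round(ifelse(less == "grid", half - bias, half + bias), 1)
  pre_hole <- config$ccp_test_duration_s - pre_grid
  cocaine_floor <- assign_cocaine_floor(pre_grid, pre_hole, seed = seed + 1L)

  shift <- g$shift_mean + g$shift_cr_gain * tr$theta_cr +
    g$shift_female * fem + stats::rnorm(n, 0, g$shift_sd)
  post_coc <- pmin(pmax(half - g$persistence * bias + shift, 0),
                   config$ccp_test_duration_s)
  post_grid <- round(ifelse(cocaine_floor == "grid", post_coc,
                            config$ccp_test_duration_s - post_coc), 1)
  post_hole <- config$ccp_test_duration_s - post_grid

  base <- exp(stats::rnorm(n, g$log_base, g$base_sd))
  sexmult <- ifelse(fem, config$sex_locomotor_multiplier, 1)
  dist_noise <- function() exp(stats::rnorm(n, 0, g$noise_sd))
  hab_dist <- base * dist_noise()
  pre_dist <- base * dist_noise()
  post_dist <- base * g$posttest_boost *
    exp(g$posttest_cr_gain * tr$theta_cr) * dist_noise()

  rows <- list(
    data.table::data.table(subject_id = tr$subject_id, phase = "habituation",
                           trial = NA_integer_, drug = "saline",
                           floor = "smooth", time_on_grid_s = NA_real_,
                           time_on_hole_s = NA_real_,
                           distance_mm = round(hab_dist, 1)),
    data.table::data.table(subject_id = tr$subject_id, phase = "pretest",
                           trial = NA_integer_, drug = "saline",
                           floor = "both",
                           time_on_grid_s = pre_grid,
                           time_on_hole_s = pre_hole,
                           distance_mm = round(pre_dist, 1)))
  other_floor <- ifelse(cocaine_floor == "grid", "hole", "grid")
  for (t in seq_len(config$ccp_trials)) {
    coc_dist <- base * sexmult * g$acute_factor *
      (1 + g$sens_per_trial * (t - 1)) *
      exp(g$cocaine_gain * tr$theta_cr) * dist_noise()
    sal_dist <- base * dist_noise()
    rows[[length(rows) + 1L]] <- data.table::data.table(
      subject_id = tr$subject_id, phase = "conditioning", trial = t,
      drug = "cocaine", floor = cocaine_floor,
      time_on_grid_s = NA_real_, time_on_hole_s = NA_real_,
      distance_mm = round(coc_dist, 1))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      subject_id = tr$subject_id, phase = "conditioning", trial = t,
      drug = "saline", floor = other_floor,
      time_on_grid_s = NA_real_, time_on_hole_s = NA_real_,
      distance_mm = round(sal_dist, 1))
  }
  rows[[length(rows) + 1L]] <- data.table::data.table(
    subject_id = tr$subject_id, phase = "posttest", trial = NA_integer_,
    drug = "saline", floor = "both",
    time_on_grid_s = post_grid, time_on_hole_s = post_hole,
    distance_mm = round(post_dist, 1))
  out <- data.table::rbindlist(rows)
  validate_summary_table(out, kind = "ccp",
                         session_duration_s = config$ccp_test_duration_s)
}

## contextual-conditioning generative constants
.ccc_gen <- list(log_base = log(4000), base_sd = 0.2, noise_sd = 0.15,
                 novelty = 1.1, acute_factor = 2.2, decay = 0.25,
                 decay_female = 0.4, cocaine_gain = 0.4,
                 cond_gain = 0.5, cond_female = 0.3, cond_cr_gain = 0.25,
                 hw_base = 1.5, hw_day3 = 4, hw_growth = 1.8,
                 hw_cr_gain = 0.3, hw_female = 0.4, hw_cond = 2.0)

#' Simulate a cocaine contextual conditioning table
#'
#' Eight-day profiles: habituation (day 1), saline baseline (day 2), five
#' cocaine days (3-7) and a drug-free test in the cocaine-paired context
#' (day 8). Day 3 locomotion is acutely elevated (scaled by cocaine
#' responsivity and sex); across days 3-7 forward locomotion declines while
#' headwaving bouts grow geometrically (the stereotypy trade-off, steeper
#' in females); day 8 exceeds the day-2 baseline by a conditioned-locomotion
#' term scaled by cocaine responsivity.
#'
#' @inheritParams simulate_crf
#' @param n_incomplete number of subjects to degrade by deleting one random
#'   day from days 2-8 (emulating data-collection loss; such subjects are
#'   flagged incomplete on read and excluded casewise downstream).
#' @return a validated CCC summary `data.table`.
#' @export
simulate_ccc <- function(traits, config,
                         seed = stage_seed(config$master_seed, "ccc"),
                         n_incomplete = 0) {
  set.seed(seed)
  g <- .ccc_gen
  tr <- data.table::as.data.table(traits)
  n <- nrow(tr)
  fem <- tr$sex == "female"
  base <- exp(stats::rnorm(n, g$log_base, g$base_sd))
  sexmult <- ifelse(fem, config$sex_locomotor_multiplier, 1)
  slope <- g$decay * (1 + g$decay_female * fem)
  hw_mult <- (1 + g$hw_female * fem) * exp(g$hw_cr_gain * tr$theta_cr)

  rows <- vector("list", 8)
  for (d in 1:8) {
    inj <- if (d == 1) "none" else if (d %in% c(2, 8)) "saline" else "cocaine"
    noise <- exp(stats::rnorm(n, 0, g$noise_sd))
    dist <- if (d == 1) {
      base * g$novelty * noise
    } else if (d == 2) {
      base * noise
    } else if (d <= 7) {
      fac <- pmax(0.3, g$acute_factor - slope * (d - 3))
      base * sexmult * fac * exp(g$cocaine_gain * tr$theta_cr) * noise
    } else {
      base * (1 + g$cond_gain * (1 + g$cond_female * fem)) *
        exp(g$cond_cr_gain * tr$theta_cr) * noise
    }
    hw <- if (d <= 2) {
      stats::rpois(n, g$hw_base)
    } else if (d <= 7) {
      stats::rpois(n, g$hw_day3 * g$hw_growth^(d - 3) * hw_mult)
    } else {
      stats::rpois(n, g$hw_base + g$hw_cond)
    }
    rows[[d]] <- data.table::data.table(
      subject_id = tr$subject_id, day = d, injection = inj,
      distance_mm = round(dist, 1), headwave_bouts = hw)
  }
  out <- data.table::rbindlist(rows)
  if (n_incomplete > 0) {
    n_incomplete <- min(n_incomplete, n)
    drop_subj <- sample(tr$subject_id, n_incomplete)
    drop_day <- sample(2:8, n_incomplete, replace = TRUE)
    out <- out[!data.table::data.table(subject_id = drop_subj, day = drop_day),
               on = c("subject_id", "day")]
  }
  validate_summary_table(out, kind = "ccc")
}

#' Simulate a complete synthetic cohort
#'
#' Draws latent traits, generates the requested task data with independent
#' per-stage RNG streams derived from `master_seed`, and scores the PavCA
#' stream (the terminal index feeds the conditioned-reinforcement
#' generator). Identical configuration and master seed reproduce the cohort
#' byte for byte.
#'
#' @param config a [cohort_config()].
#' @param tasks subset of `c("pavca", "crf", "ccp", "ccc")`; `crf` requires
#'   `pavca`.
#' @param ccc_incomplete passed to [simulate_ccc()] as `n_incomplete`.
#' @param validate_events validate the generated event streams against the
#'   dialect (default TRUE; generation is invariant to this switch).
#' @return a list: `config`, `subjects` (traits), `pavca_events`,
#'   `crf_events`, `ccp`, `ccc` (NULL when not requested).
#' @export
simulate_cohort <- function(config, tasks = c("pavca", "crf", "ccp", "ccc"),
                            ccc_incomplete = 0, validate_events = TRUE) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  if ("crf" %in% tasks && !"pavca" %in% tasks)
    pv_stop("the crf generator needs the pavca task (terminal index)")
  traits <- draw_traits(config)
  out <- list(config = config, subjects = traits,
              pavca_events = NULL, crf_events = NULL, ccp = NULL, ccc = NULL)
  if ("pavca" %in% tasks) {
    out$pavca_events <- simulate_pavca(traits, config, validate = validate_events)
    if ("crf" %in% tasks) {
      term <- score_pavca(out$pavca_events,
                          cs_duration_s = config$cs_duration_s)$subjects
      out$crf_events <- simulate_crf(traits, term, config)
    }
  }
  if ("ccp" %in% tasks) out$ccp <- simulate_ccp(traits, config)
  if ("ccc" %in% tasks) out$ccc <- simulate_ccc(traits, config,
                                                n_incomplete = ccc_incomplete)
  out
}
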