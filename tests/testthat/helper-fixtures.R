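# fixtures are built in code; all times at millisecond grain

# one subject-session of PavCA events from a per-trial specification:
# lever / foodcup: list of numeric vectors of within-CS contact times
# (first element = first contact), one per trial; NULL = no contact
make_session_events <- function(subject_id = "S1", session = 1L,
                                lever = vector("list", 25),
                                foodcup = vector("list", 25),
                                iti = rep(90, max(length(lever), length(foodcup))),
                                sex = "female", cohort = "A", cs = 8) {
  n_trials <- max(length(lever), length(foodcup))
  length(lever) <- n_trials; length(foodcup) <- n_trials
  onset <- cumsum(iti) + (seq_len(n_trials) - 1) * cs
  rows <- list()
  add <- function(trial, event, time) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject_id = subject_id, cohort = cohort, sex = sex, task = "pavca",
      session = session, trial = trial, event = event, time_s = round(time, 3))
  }
  for (t in seq_len(n_trials)) {
    add(t, "cs_onset", onset[t])
    for (w in lever[[t]]) add(t, "lever_deflection", onset[t] + w)
    for (w in foodcup[[t]]) add(t, "foodcup_entry", onset[t] + w)
    add(t, "cs_offset", onset[t] + cs)
    add(t, "pellet_delivery", onset[t] + cs)
  }
  do.call(rbind, rows)
}

# multi-session builder from per-session lever/foodcup specs
make_subject_events <- function(subject_id, specs, ...) {
  do.call(rbind, lapply(seq_along(specs), function(s)
    make_session_events(subject_id, session = s, lever = specs[[s]]$lever,
                        foodcup = specs[[s]]$foodcup, ...)))
}

# the worked 25-trial session: lever contact on trials 1-20 (4 deflections
# each = 80, first contact always 2.0 s), food-cup on trials 1-10 (3 entries
# each = 30, first always 5.0 s)
fixture_session_804030 <- function(subject_id = "S1", session = 1L) {
  lever <- c(rep(list(c(2.0, 3.0, 4.0, 5.5)), 20), vector("list", 5))
  foodcup <- c(rep(list(c(5.0, 6.0, 7.0)), 10), vector("list", 15))
  make_session_events(subject_id, session, lever, foodcup)
}

# subject with exclusively lever-directed CS behavior at zero latency
# (dir = +1) or the mirror image (dir = -1), for the given sessions
make_pure_subject <- function(subject_id, dir = 1, sessions = 1:5,
                              n_trials = 25) {
  contact <- rep(list(0), n_trials)  # first contact at CS onset
  none <- vector("list", n_trials)
  do.call(rbind, lapply(sessions, function(s)
    make_session_events(subject_id, session = s,
                        lever = if (dir > 0) contact else none,
                        foodcup = if (dir > 0) none else contact)))
}

# random well-formed subject-session for property tests
random_session_events <- function(subject_id = "S1", session = 1L,
                                  n_trials = 10) {
  lever <- lapply(seq_len(n_trials), function(i)
    if (runif(1) < 0.6) round(sort(runif(1 + rpois(1, 2), 0.001, 7.99)), 3))
  foodcup <- lapply(seq_len(n_trials), function(i)
    if (runif(1) < 0.6) round(sort(runif(1 + rpois(1, 2), 0.001, 7.99)), 3))
  make_session_events(subject_id, session, lever, foodcup,
                      iti = runif(n_trials, 30, 150))
}

# complete CCP table for hand-specified subjects
make_ccp_rows <- function(subject_id, pre_grid, pre_hole, post_grid, post_hole,
                          cocaine_floor = "grid",
                          coc_dist = c(8000, 8500, 9000, 9500),
                          sal_dist = rep(4000, 4)) {
  other <- if (cocaine_floor == "grid") "hole" else "grid"
  rbind(
    data.frame(subject_id = subject_id, phase = "pretest", trial = NA_integer_,
               drug = "saline", floor = "both", time_on_grid_s = pre_grid,
               time_on_hole_s = pre_hole, distance_mm = 4000),
    do.call(rbind, lapply(1:4, function(t) rbind(
      data.frame(subject_id = subject_id, phase = "conditioning", trial = t,
                 drug = "cocaine", floor = cocaine_floor,
                 time_on_grid_s = NA_real_, time_on_hole_s = NA_real_,
                 distance_mm = coc_dist[t]),
      data.frame(subject_id = subject_id, phase = "conditioning", trial = t,
                 drug = "saline", floor = other,
                 time_on_grid_s = NA_real_, time_on_hole_s = NA_real_,
                 distance_mm = sal_dist[t])))),
    data.frame(subject_id = subject_id, phase = "posttest", trial = NA_integer_,
               drug = "saline", floor = "both", time_on_grid_s = post_grid,
               time_on_hole_s = post_hole, distance_mm = 4500))
}

# complete 8-day CCC table for one subject
make_ccc_rows <- function(subject_id, distance = seq(4000, 7500, by = 500),
                          headwaves = c(1, 2, 10, 15, 25, 32, 40, 6)) {
  data.frame(subject_id = subject_id, day = 1:8,
             injection = c("none", "saline", rep("cocaine", 5), "saline"),
             distance_mm = distance, headwave_bouts = headwaves)
}
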