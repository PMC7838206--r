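test_that("session aggregates follow the definitions on forced fixtures", {
  ## lever contact at +1.0 s on every trial, no CS food-cup entries
  ev <- make_session_events("S1", lever = rep(list(1.0), 25),
                            foodcup = vector("list", 25))
  s <- summarize_session(ev)
  expect_equal(s$lever_contact_prob, 1.0)
  expect_equal(s$lever_latency_s, 1.0)
  expect_equal(s$foodcup_contact_prob, 0.0)
  expect_equal(s$foodcup_latency_s, 8.0)
  expect_equal(s$n_trials, 25L)

  ## no events at all in any CS window: probabilities 0, latencies censored
  ev0 <- make_session_events("S1", lever = vector("list", 25),
                             foodcup = vector("list", 25))
  s0 <- summarize_session(ev0)
  expect_equal(s0$lever_contact_prob, 0)
  expect_equal(s0$foodcup_contact_prob, 0)
  expect_equal(s0$lever_latency_s, 8.0)
  expect_equal(s0$foodcup_latency_s, 8.0)
  expect_equal(s0$lever_deflections, 0)
})

test_that("the worked session reproduces its hand-computed measures and index", {
  ## 20/25 lever trials (80 deflections, first contact 2.0 s), 10/25 food-cup
  ## trials (30 entries, first 5.0 s); values recomputed independently:
  ## lever latency (20*2 + 5*8)/25 = 3.2, food-cup (10*5 + 15*8)/25 = 6.8
  ev <- fixture_session_804030()
  s <- summarize_session(ev)
  expect_equal(s$lever_contact_prob, 0.80)
  expect_equal(s$foodcup_contact_prob, 0.40)
  expect_equal(s$lever_deflections, 80)
  expect_equal(s$foodcup_entries_cs, 30)
  expect_equal(s$lever_latency_s, 3.2)
  expect_equal(s$foodcup_latency_s, 6.8)
  cm <- pavca_components(s)
  expect_equal(cm$prob_diff, 0.40)
  expect_equal(cm$response_bias, 50 / 110)
  expect_equal(cm$latency_score, 0.45)
  expect_equal(cm$index, mean(c(0.40, 50 / 110, 0.45)))
})

test_that("component formulas handle their documented degenerate cases", {
  s <- function(lp, fp, ld, fe, ll, fl)
    data.frame(lever_contact_prob = lp, foodcup_contact_prob = fp,
               lever_deflections = ld, foodcup_entries_cs = fe,
               lever_latency_s = ll, foodcup_latency_s = fl)
  expect_equal(prob_differential(s(1, 0, 0, 0, 0, 0)), 1.0)
  expect_equal(prob_differential(s(0.5, 0.5, 0, 0, 0, 0)), 0.0)
  expect_equal(response_bias(s(0, 0, 80, 30, 0, 0)), 50 / 110)
  expect_equal(response_bias(s(0, 0, 0, 0, 0, 0)), 0.0)
  expect_equal(response_bias(s(0, 0, 0, 40, 0, 0)), -1.0)
  expect_equal(latency_score(s(0, 0, 0, 0, 0, 8)), 1.0)
  expect_equal(latency_score(s(0, 0, 0, 0, 3.2, 6.8)), 0.45)
  expect_equal(latency_score(s(0, 0, 0, 0, 4, 4)), 0.0)
  expect_equal(pavca_index(1, 1, 1), 1.0)
  expect_equal(pavca_index(-1, -1, -1), -1.0)
  expect_error(pavca_index(1.2, 0, 0), "components")
})

test_that("terminal index averages sessions 4 and 5 only and flags missing ones", {
  expect_equal(terminal_index(c(0, 0, 0, 0.2, 0.4)), 0.3)
  expect_equal(terminal_index(c(0.9, 0.9, 0.9, -0.6, -0.6)), -0.6)
  expect_true(is.na(terminal_index(c(0.1, 0.2, 0.3, 0.4), session = 1:4)))
  df <- data.frame(subject_id = rep(c("A", "B"), c(5, 4)),
                   session = c(1:5, 1:4),
                   index = c(rep(0.2, 3), 0.2, 0.4, rep(0, 4)))
  out <- terminal_index(df)
  expect_equal(out$terminal_index[out$subject_id == "A"], 0.3)
  expect_true(is.na(out$terminal_index[out$subject_id == "B"]))
  expect_identical(attr(out, "flagged_subjects"), "B")
})

test_that("phenotype thresholds partition [-1, 1] with boundaries at the extremes", {
  expect_identical(as.character(classify_phenotype(-0.75)), "GT")
  expect_identical(as.character(classify_phenotype(0)), "IN")
  expect_identical(as.character(classify_phenotype(0.5)), "ST")
  expect_identical(as.character(classify_phenotype(-0.5)), "GT")
  expect_error(classify_phenotype(1.2), "out of")
  ## partition: every value gets exactly one label; classification idempotent
  x <- seq(-1, 1, by = 0.01)
  lab <- classify_phenotype(x)
  expect_false(anyNA(lab))
  expect_identical(classify_phenotype(x), lab)
  expect_true(all(x[lab == "GT"] <= -0.5))
  expect_true(all(abs(x[lab == "IN"]) < 0.5))
  expect_true(all(x[lab == "ST"] >= 0.5))
})

test_that("components and index stay in [-1, 1] on random sessions", {
  set.seed(101)
  for (i in 1:40) {
    s <- summarize_session(random_session_events(n_trials = sample(3:25, 1)))
    cm <- pavca_components(s)
    expect_true(all(abs(c(cm$prob_diff, cm$response_bias, cm$latency_score,
                          cm$index)) <= 1 + 1e-12))
  }
})

test_that("index matches the raw-event oracle on random fixtures", {
  set.seed(202)
  for (i in 1:100) {
    ev <- random_session_events(n_trials = sample(3:15, 1))
    cm <- pavca_components(summarize_session(ev))
    expect_equal(cm$index, oracle_index_from_events(ev), tolerance = 1e-12)
  }
})

test_that("adding lever contact never lowers the index; food-cup never raises it", {
  set.seed(303)
  for (i in 1:25) {
    ev <- random_session_events(n_trials = 8)
    idx0 <- pavca_components(summarize_session(ev))$index
    tr <- sample(1:8, 1)
    onset <- ev$time_s[ev$event == "cs_onset" & ev$trial == tr]
    extra <- ev[1, ]
    extra$trial <- tr
    extra$time_s <- round(onset + runif(1, 0, 7.99), 3)
    extra$event <- "lever_deflection"
    idx_lev <- pavca_components(summarize_session(rbind(ev, extra)))$index
    expect_gte(idx_lev, idx0 - 1e-12)
    extra$event <- "foodcup_entry"
    idx_fc <- pavca_components(summarize_session(rbind(ev, extra)))$index
    expect_lte(idx_fc, idx0 + 1e-12)
  }
})

test_that("score_pavca flags subjects missing a terminal session", {
  ev <- rbind(make_pure_subject("A", dir = 1, sessions = 1:5),
              make_pure_subject("B", dir = -1, sessions = 1:4))
  sc <- score_pavca(ev)
  expect_identical(sc$flagged_subjects, "B")
  expect_equal(sc$subjects$terminal_index[sc$subjects$subject_id == "A"], 1)
  expect_true(is.na(sc$subjects$terminal_index[sc$subjects$subject_id == "B"]))
})
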