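test_that("a well-formed event file round-trips identically", {
  ev <- rbind(fixture_session_804030("S1"), fixture_session_804030("S2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, f, task = "pavca")
  back <- read_event_table(f, task = "pavca")
  expect_equal(nrow(back), nrow(ev))
  expect_equal(length(unique(paste(back$subject_id, back$session))), 2L)
  ## round-trip identity field for field (canonical order on both sides)
  canon <- validate_events(ev, "pavca")
  expect_equal(as.data.frame(back), as.data.frame(canon))
})

test_that("serialization is byte-stable and an empty table gives a header-only file", {
  set.seed(11)
  ev <- random_session_events("S1", n_trials = 25)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, f1, task = "pavca")
  write_event_table(ev, f2, task = "pavca")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  ## and re-serializing the parsed table reproduces the bytes
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_event_table(read_event_table(f1, "pavca"), f3, task = "pavca")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f3)))

  fe <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev[0, ], fe, task = "pavca")
  expect_identical(readLines(fe), paste(c("subject_id", "cohort", "sex", "task",
                                          "session", "trial", "event", "time_s"),
                                        collapse = ","))
})

test_that("malformed event tables are rejected with a located error", {
  ev <- fixture_session_804030()
  bad <- ev; bad$time_s[5] <- -1
  expect_error(validate_events(bad, "pavca"), "time_s",
               class = "pavca_validation_error")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_event_table(f, "pavca"), "row")

  bad <- ev[ev$event != "cs_offset" | ev$trial != 3, ]  # drop one cs_offset
  expect_error(validate_events(bad, "pavca"), "cs_offset")

  bad <- ev
  bad$time_s[bad$event == "cs_offset" & bad$trial == 2] <-
    bad$time_s[bad$event == "cs_onset" & bad$trial == 2] + 9
  expect_error(validate_events(bad, "pavca"), "expected 8")

  bad <- ev
  i <- which(bad$event == "lever_deflection" & bad$trial == 1)[1]
  bad$time_s[i] <- bad$time_s[bad$event == "cs_offset" & bad$trial == 1] + 0.5
  expect_error(validate_events(bad, "pavca"), "outside the CS window")

  bad <- ev; bad$sex <- "unknown"
  expect_error(validate_events(bad, "pavca"), "sex")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(ev[, -8], f2, row.names = FALSE)
  expect_error(read_event_table(f2, "pavca"), "missing column")
})

test_that("trial windows match an independent line scan of the file", {
  ev <- fixture_session_804030("S9")
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, f, task = "pavca")
  ## independent oracle: count cs_onset rows by scanning raw lines
  lines <- readLines(f)[-1]
  n_onsets <- sum(vapply(strsplit(lines, ","), function(p) p[7] == "cs_onset", TRUE))
  win <- derive_trial_windows(read_event_table(f, "pavca"))
  expect_equal(nrow(win), n_onsets)
  expect_equal(nrow(win), 25L)
  expect_true(all(abs(win$offset - win$onset - 8) < 1e-9))
})

test_that("CS windows are half-open: a contact at exactly cs_offset is ITI", {
  ev <- make_session_events("S1", lever = list(c(0.5)), foodcup = list(NULL),
                            iti = 90)
  ## an entry at exactly the offset must be declared outside the trial
  off <- ev$time_s[ev$event == "cs_offset"]
  extra <- ev[1, ]
  extra$trial <- 0L; extra$event <- "foodcup_entry"; extra$time_s <- off
  expect_silent(validate_events(rbind(ev, extra), "pavca"))
  inside <- extra; inside$trial <- 1L
  expect_error(validate_events(rbind(ev, inside), "pavca"), "outside")
})

test_that("summary tables validate schedules and flag incomplete subjects", {
  ccc <- rbind(make_ccc_rows("R1"), make_ccc_rows("R2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(ccc, f, row.names = FALSE)
  tab <- read_summary_table(f, "ccc")
  expect_equal(nrow(tab), 16L)
  expect_length(attr(tab, "incomplete_subjects"), 0L)

  ## subject missing day 7: flagged, then excluded casewise downstream
  ccc2 <- rbind(make_ccc_rows("R1"), make_ccc_rows("R2")[-7, ])
  tab2 <- validate_summary_table(ccc2, "ccc")
  expect_identical(attr(tab2, "incomplete_subjects"), "R2")
  scored <- score_ccc(tab2)
  expect_identical(scored$subject_id, "R1")
  expect_equal(attr(scored, "n_excluded"), 1L)

  ## schedule violation: cocaine on day 2 is an error, not a flag
  bad <- make_ccc_rows("R1"); bad$injection[2] <- "cocaine"
  expect_error(validate_summary_table(bad, "ccc"), "schedule")

  ccp <- make_ccp_rows("R1", pre_grid = 700, pre_hole = 1100,
                       post_grid = 950, post_hole = 850)
  tabp <- validate_summary_table(ccp, "ccp")
  expect_length(attr(tabp, "incomplete_subjects"), 0L)
  expect_equal(sum(tabp$phase == "pretest"), 1L)
  expect_equal(sum(tabp$phase == "posttest"), 1L)
  ## floor times exceeding the session are rejected
  bad <- ccp; bad$time_on_grid_s[1] <- 1900
  expect_error(validate_summary_table(bad, "ccp"), "exceed")
})

test_that("the run manifest records checksums that reproduce on rerun", {
  d <- withr::local_tempdir()
  ev <- fixture_session_804030()
  write_event_table(ev, file.path(d, "events.csv"), task = "pavca")
  m1 <- write_manifest(file.path(d, "events.csv"), file.path(d, "m.json"),
                       seed = 42)
  m2 <- write_manifest(file.path(d, "events.csv"), file.path(d, "m2.json"),
                       seed = 42)
  expect_identical(m1$files[[1]]$md5, m2$files[[1]]$md5)
  expect_equal(jsonlite::read_json(file.path(d, "m.json"))$seed, 42)
})
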