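test_that("stop-feeding-only trials are excluded from responses", {
  expect_false(is_response(character(0)))
  expect_false(is_response(NA_character_))
  expect_false(is_response("stop_feeding"))
  expect_true(is_response(c("stop_feeding", "partial_eyestalk_withdrawal")))
  expect_true(is_response("full_proboscis_withdrawal"))
  # monotone: adding events never un-responds a trial
  evs <- transition_categories()
  for (i in seq_len(length(evs) - 1))
    if (is_response(evs[seq_len(i)]))
      expect_true(is_response(evs[seq_len(i + 1)]))
})

test_that("trial tables validate their schema and ordering", {
  tr <- tiny_trials()
  expect_silent(validate_trials(tr))
  bad <- tr; bad$event_category[1] <- "leap"
  expect_error(validate_trials(bad), "unknown event categories")
  bad <- tr; bad$event_time_s[1:2] <- c(3, 1)
  expect_error(validate_trials(bad), "decrease")
  expect_error(validate_trials(tr[, -3]), "lacks columns")
})

test_that("responder tables count trials per level with one control", {
  tab <- build_response_table(tiny_trials(), tiny_manifest(), "resolution")
  expect_s3_class(tab, "response_table")
  expect_equal(tab$k[tab$is_control], 0L)       # stop-feeding-only excluded
  expect_equal(tab$k[!tab$is_control], 1L)      # one true responder
  expect_equal(tab$n, c(2L, 2L))
  # k is invariant to trial order (events stay sorted within each trial)
  tr <- tiny_trials()
  tab2 <- build_response_table(tr[c(6, 5, 4, 1, 2, 3), ], tiny_manifest(),
                               "resolution")
  expect_equal(tab2$k, tab$k)
  # empty input gives an empty table
  expect_equal(nrow(build_response_table(tr[0, ], tiny_manifest(),
                                         "resolution")), 0)
  # paper-scale rates: 8/40 and 25/40
  expect_equal(8 / 40, 0.20)
  man <- tiny_manifest()
  man$is_control <- FALSE
  expect_error(build_response_table(tr, man, "resolution"), "control")
})

test_that("per-individual collapse scores a responder in either repeat", {
  tr <- tiny_trials()
  tr2 <- tr; tr2$repeat_index <- 2L
  tr2$event_category[tr2$individual_id == "a"] <- NA  # a responds only in rep 1
  tr2$event_time_s[tr2$individual_id == "a"] <- NA
  tr2$reemergence_s <- NA
  both <- rbind(tr, tr2)
  by_trial <- build_response_table(both, tiny_manifest(), "resolution")
  by_ind <- build_response_table(both, tiny_manifest(), "resolution",
                                 by = "individual")
  expect_equal(by_trial$k[!by_trial$is_control], 1L)  # 1 of 4 trials
  expect_equal(by_ind$k[!by_ind$is_control], 1L)      # 1 of 2 individuals
  expect_equal(by_ind$n, c(2L, 2L))
})

test_that("transition fractions beyond an angular size behave as constructed", {
  prof <- fast_loom()
  tr <- tiny_trials()
  # all events beyond any threshold below alpha_max -> 1; threshold 0 -> 1
  late <- tr[!is.na(tr$event_category), ]
  late$event_time_s <- 5
  expect_equal(transitions_by_angle(late, prof, 37.9), 1)
  expect_equal(transitions_by_angle(late, prof, 0), 1)
  # constructed half-split via time_to_reach
  half <- late[c(1, 1, 2, 2), ]
  half$event_time_s <- time_to_reach(prof, c(10, 20, 50, 60))
  half$repeat_index <- c(1L, 2L, 1L, 2L)  # keep times sorted within trials
  expect_equal(transitions_by_angle(half, prof, 37.9), 0.5)
  # no events -> 0 with a warning
  none <- tr[is.na(tr$event_category), ]
  expect_warning(f <- transitions_by_angle(none, prof, 10), "no transition")
  expect_equal(f, 0)
})

test_that("re-emergence summaries take per-level medians of responders only", {
  tr <- tiny_trials()
  out <- reemergence_summary(tr, tiny_manifest(), "resolution")
  expect_equal(out$reemergence_s, 60)
  expect_equal(out$n_obs, 1L)
  # {10, 20, 40} -> 20
  tr3 <- tr[rep(1, 3), ]
  tr3$individual_id <- c("a", "b", "c")
  tr3$reemergence_s <- c(10, 20, 40)
  expect_equal(reemergence_summary(tr3, tiny_manifest(),
                                   "resolution")$reemergence_s, 20)
  # all missing -> empty
  none <- tr[is.na(tr$reemergence_s), ]
  expect_equal(nrow(reemergence_summary(none, tiny_manifest(), "resolution")), 0)
})

test_that("trials CSV round-trips unchanged", {
  tr <- tiny_trials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, path)
  back <- read_trials(path)
  expect_equal(back, tr, ignore_attr = TRUE)
})
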