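spec_fr4 <- schedule_spec("FR", 4, session_duration = 1800)

test_that("PR requirement reproduces the exponential progression", {
  expect_identical(pr_requirement(1:10),
                   c(1L, 2L, 4L, 6L, 9L, 12L, 15L, 20L, 25L, 32L))
  expect_identical(pr_requirement(1L), as.integer(round(5 * exp(0.2) - 5)))
  expect_error(pr_requirement(0), class = "ghbsa_usage_error")
  expect_error(pr_requirement(1.5), class = "ghbsa_usage_error")
})

test_that("FR replay follows dipper/cue semantics on hand-traced logs", {
  log1 <- dplyr::bind_rows(press_log(1:4), ev(6, "head_entry"))
  s1 <- replay_schedule(dplyr::arrange(log1, t), spec_fr4)
  expect_equal(s1$presentations, 1L)
  expect_equal(s1$consumed_presentations, 1L)
  expect_equal(s1$alp, 4L)
  expect_equal(s1$timeout_presses, 0L)

  # presses 5..18 fall in the 15-s cue window opened at t = 4
  s2 <- replay_schedule(press_log(c(1:4, 5:18)), spec_fr4)
  expect_equal(s2$presentations, 1L)
  expect_equal(s2$alp, 18L)
  expect_equal(s2$timeout_presses, 14L)
  expect_equal(s2$consumed_presentations, 0L)

  # head entry after the 10-s dipper window does not consume
  log3 <- dplyr::bind_rows(press_log(1:4), ev(14.5, "head_entry"))
  s3 <- replay_schedule(dplyr::arrange(log3, t), spec_fr4)
  expect_equal(s3$presentations, 1L)
  expect_equal(s3$consumed_presentations, 0L)
})

test_that("NR sessions never produce presentations", {
  spec_nr <- schedule_spec("NR", session_duration = 1800)
  s <- replay_schedule(press_log(seq(1, 100, by = 1)), spec_nr)
  expect_equal(s$presentations, 0L)
  expect_equal(s$consumed_presentations, 0L)
  expect_equal(s$alp, 100L)
})

test_that("replay validates its inputs", {
  expect_error(replay_schedule(press_log(c(5, 3)), spec_fr4),
               class = "ghbsa_data_error")
  expect_error(replay_schedule(press_log(1e6), spec_fr4),
               class = "ghbsa_data_error")
  expect_error(replay_schedule(ev(1, "jump"), spec_fr4),
               class = "ghbsa_data_error")
  empty <- ev(numeric(0), character(0))
  expect_equal(replay_schedule(empty, spec_fr4)$presentations, 0L)
})

test_that("FR presentations equal floor(alp/ratio) without timeout presses", {
  set.seed(5)
  for (i in 1:20) {
    ratio <- sample(c(1, 2, 4), 1)
    n <- sample(5:40, 1)
    # gaps wider than the cue timeout: no press can fall in a cue window
    times <- cumsum(runif(n, 15.01, 30))
    spec <- schedule_spec("FR", ratio, session_duration = max(times) + 1)
    s <- replay_schedule(press_log(times), spec)
    expect_equal(s$presentations, floor(n / ratio))
    expect_equal(s$timeout_presses, 0L)
  }
})

test_that("PR breakpoint is the last completed requirement, nondecreasing", {
  times <- cumsum(rep(16, 3)) # 3 spaced presses: completes n=1 (1), n=2 (2)
  spec <- schedule_spec("PR", session_duration = 1e4)
  s <- replay_schedule(press_log(times), spec)
  expect_equal(s$presentations, 2L)
  expect_equal(s$breakpoint, 2L)
  more <- c(times, max(times) + cumsum(rep(16, 10)))
  s2 <- replay_schedule(press_log(more),
                        schedule_spec("PR", session_duration = 1e4))
  expect_gte(s2$breakpoint, s$breakpoint)
})

test_that("adding a head entry in the dipper window never lowers consumption", {
  base <- press_log(c(1:4, 20:23))
  spec <- schedule_spec("FR", 4, session_duration = 100)
  s0 <- replay_schedule(base, spec)
  with_entry <- dplyr::arrange(
    dplyr::bind_rows(base, ev(24, "head_entry")), t
  )
  s1 <- replay_schedule(with_entry, spec)
  expect_gte(s1$consumed_presentations, s0$consumed_presentations)
  expect_equal(s1$consumed_presentations, 1L)
})

test_that("session dose converts consumed presentations to mg/kg", {
  spec7 <- schedule_spec("FR", 4, 10800, reward_volume = 0.1,
                         concentration = 7)
  expect_equal(session_dose(10, spec7, 350), 200)
  expect_equal(session_dose(0, spec7, 350), 0)
  spec2 <- schedule_spec("FR", 4, 10800, reward_volume = 0.1,
                         concentration = 2)
  expect_equal(session_dose(1, spec2, 200), 10)
  expect_error(session_dose(1, spec7, 0), class = "ghbsa_data_error")
})

test_that("habit ratio divides non-reinforced by reinforced responding", {
  expect_equal(habit_ratio(81, 100), 0.81)
  expect_equal(habit_ratio(0, 50), 0)
  expect_equal(habit_ratio(33, 33), 1)
  expect_warning(h <- habit_ratio(10, 0), "undefined")
  expect_true(is.na(h))
})

test_that("quinine AUC integrates over the dose axis", {
  expect_equal(quinine_auc(c(0, 1), c(100, 0)), 50)
  expect_equal(quinine_auc(c(0, 0.1, 0.3, 1), rep(100, 4)), 100)
  expect_equal(quinine_auc(c(0, 0.1, 0.3, 1), c(100, 80, 40, 0)),
               0.1 * 90 + 0.2 * 60 + 0.7 * 20)
  expect_error(quinine_auc(c(0.3, 0.1), c(1, 2)), class = "ghbsa_data_error")
})

test_that("acquisition rule: exclusion first, then three-session runs", {
  expect_equal(acquisition_status(c(0, 0, 0)), "excluded")
  expect_equal(acquisition_status(c(1, 2, 1)), "acquired")
  expect_equal(acquisition_status(c(1, 0, 0, 1)), "in_progress")
  # exclusion takes precedence even after an acquired run
  expect_equal(acquisition_status(c(1, 1, 1, 0, 0, 0)), "excluded")
  expect_equal(acquisition_status(c(1, 1)), "in_progress")
})

test_that("replay is a pure function of (events, spec)", {
  set.seed(9)
  times <- sort(runif(50, 0, 1800))
  log <- press_log(times)
  expect_identical(replay_schedule(log, spec_fr4),
                   replay_schedule(log, spec_fr4))
})
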