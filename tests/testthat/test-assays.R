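objects2 <- tibble::tibble(
  object_id = c("old", "novel"),
  center_x = c(100, 300),
  center_y = c(100, 100),
  area_radius = 30
)

traj_frames <- function(nose_x, nose_y, body_x, body_y) {
  tibble::tibble(
    frame = seq_along(nose_x) - 1L,
    nose_x = nose_x, nose_y = nose_y, body_x = body_x, body_y = body_y
  )
}

test_that("exploration time counts qualifying frames at the frame rate", {
  far <- traj_frames(rep(500, 40), rep(500, 40), rep(500, 40), rep(500, 40))
  expect_equal(exploration_time(far, objects2, "old", fps = 30), 0)

  # 30 frames with the nose 5 px away and the body outside the object area
  near <- traj_frames(rep(105, 30), rep(100, 30), rep(150, 30), rep(100, 30))
  expect_equal(exploration_time(near, objects2, "old", fps = 30), 1.0)

  # nose close but body centre on the object: excluded entirely
  sitting <- traj_frames(rep(105, 30), rep(100, 30), rep(110, 30),
                         rep(100, 30))
  expect_equal(exploration_time(sitting, objects2, "old", fps = 30), 0)

  # the 8-px threshold is inclusive
  at8 <- traj_frames(108, 100, 150, 100)
  expect_equal(exploration_time(at8, objects2, "old", fps = 1), 1)
  at8.5 <- traj_frames(108.5, 100, 150, 100)
  expect_equal(exploration_time(at8.5, objects2, "old", fps = 1), 0)
})

test_that("exploration time is monotone as the threshold tightens", {
  set.seed(20)
  traj <- traj_frames(runif(300, 80, 120), runif(300, 80, 120),
                      rep(200, 300), rep(200, 300))
  ths <- c(20, 12, 8, 4, 2)
  times <- vapply(
    ths, function(th) exploration_time(traj, objects2, "old", 30, th),
    numeric(1)
  )
  expect_true(all(diff(times) <= 0))
})

test_that("missing nose coordinates beyond tolerance raise a data error", {
  traj <- traj_frames(c(rep(NA, 30), rep(500, 70)), rep(500, 100),
                      rep(500, 100), rep(500, 100))
  expect_error(exploration_time(traj, objects2, "old", 30),
               class = "ghbsa_data_error")
  ok <- traj_frames(c(rep(NA, 5), rep(500, 95)), rep(500, 100),
                    rep(500, 100), rep(500, 100))
  expect_equal(exploration_time(ok, objects2, "old", 30), 0)
})

test_that("discrimination index is the normalised novel-old difference", {
  expect_equal(discrimination_index(30, 10), 0.5)
  expect_equal(discrimination_index(12, 12), 0)
  expect_equal(discrimination_index(7, 0), 1)
  expect_warning(di <- discrimination_index(0, 0), "undefined")
  expect_true(is.na(di))
  # antisymmetric under swapping novel/old labels
  expect_equal(discrimination_index(21, 8), -discrimination_index(8, 21))
  expect_true(abs(discrimination_index(runif(1, 0, 60), runif(1, 0, 60))) <= 1)
})

test_that("EPM metrics assign zones by body centre and track latency", {
  geom <- epm_geometry()
  # entire trial inside a closed arm
  closed <- tibble::tibble(frame = 0:99, body_x = 250, body_y = 100)
  m <- epm_metrics(closed, geom, fps = 10)
  expect_equal(m$closed_fraction, 100)
  expect_equal(m$open_latency, 10) # never entered: trial duration
  expect_equal(m$t_open, 0)

  # equal thirds closed/open/center
  thirds <- tibble::tibble(
    frame = 0:89,
    body_x = c(rep(250, 30), rep(100, 30), rep(250, 30)),
    body_y = c(rep(100, 30), rep(250, 30), rep(250, 30))
  )
  m3 <- epm_metrics(thirds, geom, fps = 10)
  expect_equal(m3$closed_fraction, 100 / 3, tolerance = 1e-6)
  expect_equal(m3$t_open, 3)
  expect_equal(m3$t_center, 3)
  expect_equal(m3$open_latency, 3.0) # first open frame is frame 30

  # frames outside every zone fall to the nearest zone and are reported
  outside <- tibble::tibble(frame = 0:9, body_x = 600, body_y = 600)
  mo <- epm_metrics(outside, geom, fps = 10)
  expect_equal(mo$n_outside_frames, 10)
  expect_equal(mo$t_open + mo$t_closed + mo$t_center, 1)
})

test_that("bin counts conserve totals under the half-open convention", {
  set.seed(21)
  evs <- tibble::tibble(
    t_seconds = runif(12, 0, 10800),
    behavior = "wet_dog_shake"
  )
  b <- bin_counts(evs, 600, session_duration = 10800)
  expect_equal(nrow(b), 18)
  expect_equal(sum(b$count), 12)
  for (w in c(60, 600, 3600)) {
    expect_equal(sum(bin_counts(evs, w, 10800)$count), 12)
  }
  # boundary event goes to the upper bin
  edge <- tibble::tibble(t_seconds = 600, behavior = "x")
  be <- bin_counts(edge, 600, session_duration = 1200)
  expect_equal(be$count[be$bin == 1], 1)
  expect_equal(be$count[be$bin == 0], 0)
  # empty stream: all-zero bins
  none <- tibble::tibble(t_seconds = numeric(0), behavior = character(0))
  b0 <- bin_counts(none, 600, session_duration = 1800)
  expect_equal(sum(b0$count), 0)
  expect_error(bin_counts(tibble::tibble(t_seconds = -1, behavior = "x")),
               class = "ghbsa_data_error")
})
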