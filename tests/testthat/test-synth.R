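small_cfg <- function(..., seed = 1) {
  cohort_config(n_animals = 4, n_days_homecage = 6, seed = seed,
                nor_trial_duration = 20, epm_trial_duration = 20,
                behavior_session_duration = 1800, ...)
}

test_that("config validation names the offending field", {
  expect_error(cohort_config(sex_ratio = 1.5), "sex_ratio")
  expect_error(cohort_config(dose_cv = 0), "dose_cv")
  expect_error(cohort_config(prone_fraction = -0.1), "prone_fraction")
  expect_error(cohort_config(drug_concentration = 0), "drug_concentration")
  expect_s3_class(cohort_config(), "cohort_config")
})

test_that("simulation is byte-identical under a fixed seed", {
  ds1 <- simulate_cohort(small_cfg())
  ds2 <- simulate_cohort(small_cfg())
  expect_identical(ds1, ds2)
  ds3 <- simulate_cohort(small_cfg(seed = 2))
  expect_false(identical(ds1$bottle_readings, ds3$bottle_readings))
})

test_that("adding animals does not perturb existing animals' records", {
  ds4 <- simulate_cohort(cohort_config(
    n_animals = 4, sex_ratio = 0, group_ratio = 1, n_days_homecage = 6,
    seed = 5
  ), include = "homecage")
  ds6 <- simulate_cohort(cohort_config(
    n_animals = 6, sex_ratio = 0, group_ratio = 1, n_days_homecage = 6,
    seed = 5
  ), include = "homecage")
  ids <- ds4$animals$animal_id
  expect_identical(
    dplyr::filter(ds4$bottle_readings, animal_id %in% ids),
    dplyr::filter(ds6$bottle_readings, animal_id %in% ids)
  )
})

test_that("a zero drug-group cohort has no drug bottles or operant logs", {
  ds <- simulate_cohort(small_cfg(group_ratio = 0),
                        include = c("homecage", "operant"))
  real <- dplyr::filter(ds$bottle_readings, animal_id != "sentinel")
  expect_false(any(real$fluid == "drug"))
  expect_equal(nrow(ds$operant_events), 0)
})

test_that("home-cage day simulation enforces its preconditions", {
  cfg <- small_cfg()
  drug <- fake_trait()
  ctrl <- fake_trait(group = "control")
  expect_error(simulate_homecage_day(ctrl, 1, cfg),
               class = "ghbsa_usage_error")
  expect_error(simulate_homecage_day(drug, 99, cfg),
               class = "ghbsa_usage_error")
  rd <- simulate_homecage_day(drug, 3, cfg, bodyweight_g = 320)
  expect_equal(nrow(rd), 2)
  expect_true(all(rd$end_mass <= rd$start_mass))
})

test_that("zero noise makes bottle mass loss exactly the consumed volume", {
  cfg <- small_cfg(evaporation_sd = 0, dose_cv = 1e-9)
  a <- fake_trait(daily_dose_mean = 700)
  rd <- simulate_homecage_day(a, 1, cfg, bodyweight_g = 300)
  drug_loss <- rd$start_mass[rd$fluid == "drug"] -
    rd$end_mass[rd$fluid == "drug"]
  # 700 mg/kg at 300 g and 7% w/v is exactly 3 mL = 3 g at density 1
  expect_equal(drug_loss, 3, tolerance = 1e-6)
})

test_that("susceptibility raises expected intake monotonically", {
  cfg <- small_cfg()
  lo <- fake_trait(animal_id = "lo", susceptibility = 0,
                   daily_dose_mean = 800 * exp(cfg$intake_susceptibility_gain * (0 - 0.5)))
  hi <- fake_trait(animal_id = "hi", susceptibility = 1,
                   daily_dose_mean = 800 * exp(cfg$intake_susceptibility_gain * (1 - 0.5)))
  loss <- function(a) {
    mean(vapply(1:1000, function(i) {
      rd <- simulate_homecage_day(a, (i %% 6) + 1, cfg, bodyweight_g = 320,
                                  seed = i)
      rd$start_mass[1] - rd$end_mass[1]
    }, numeric(1)))
  }
  expect_gt(loss(hi), loss(lo))
})

test_that("zero press rate yields an empty press log and zero presentations", {
  cfg <- small_cfg()
  a <- fake_trait(press_rate = 0, animal_id = "mute")
  spec <- schedule_spec("FR", 4, 1800)
  sim <- simulate_operant_session(a, spec, cfg)
  expect_equal(sum(sim$events$kind == "active_press"), 0)
  expect_equal(replay_schedule(sim$events, spec)$presentations, 0L)
  expect_equal(sim$truth$presentations, 0L)
})

test_that("quinine at the animal's IC50 halves the expected press rate", {
  cfg <- small_cfg()
  a <- fake_trait(press_rate = 0.05, quinine_ic50 = 0.2)
  spec0 <- schedule_spec("FR", 4, 600, concentration = 2, quinine_dose = 0)
  spec_ic <- schedule_spec("FR", 4, 600, concentration = 2,
                           quinine_dose = 0.2)
  alp <- function(spec, tag) {
    mean(vapply(1:1000, function(i) {
      simulate_operant_session(a, spec, cfg, seed = i + tag)$truth$alp
    }, numeric(1)))
  }
  ratio <- alp(spec_ic, 20000) / alp(spec0, 10000)
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("generated logs replay to the generator's internal tallies", {
  cfg <- cohort_config(n_animals = 6, sex_ratio = 0.5, group_ratio = 1,
                       n_days_homecage = 6, seed = 8)
  ds <- simulate_cohort(cfg, include = "operant")
  replayed <- replay_sessions(ds$operant_events, ds$operant_manifest)
  cmp <- dplyr::inner_join(
    dplyr::select(replayed, session_id, presentations,
                  consumed_presentations, alp),
    ds$operant_truth, by = "session_id",
    suffix = c("_replay", "_truth")
  )
  expect_equal(cmp$presentations_replay, cmp$presentations_truth)
  expect_equal(cmp$consumed_presentations_replay,
               cmp$consumed_presentations_truth)
  expect_equal(cmp$alp_replay, cmp$alp_truth)
})

test_that("unknown schedules are rejected", {
  expect_error(schedule_spec("VR", 4, 1800), "arg")
  cfg <- small_cfg()
  expect_error(
    simulate_operant_session(fake_trait(), list(kind = "FR"), cfg),
    class = "ghbsa_usage_error"
  )
})

test_that("NOR trials realise their configured discrimination index", {
  cfg <- cohort_config(n_animals = 4, seed = 2, nor_trial_duration = 600)
  # configured DI 0: recovered DI within sampling error of zero
  a0 <- fake_trait(di_pre = 0)
  tr0 <- simulate_nor_trial(a0, "pre", cfg)
  s0 <- nor_score(tr0$trajectory, tr0$objects, cfg$nor_fps)
  expect_lt(abs(s0$di), 0.12)
  # configured DI 0.5, long trial: recovered within 0.05
  a5 <- fake_trait(di_pre = 0.5)
  tr5 <- simulate_nor_trial(a5, "pre", cfg)
  s5 <- nor_score(tr5$trajectory, tr5$objects, cfg$nor_fps)
  expect_equal(s5$di, 0.5, tolerance = 0.1)
  expect_equal(s5$t_novel, tr5$truth$t_novel)
  expect_equal(s5$t_old, tr5$truth$t_old)
  # a drop equal to the baseline pushes the post-phase DI to zero
  am <- fake_trait(di_pre = 0.4, di_post = 0)
  trm <- simulate_nor_trial(am, "post", cfg)
  sm <- nor_score(trm$trajectory, trm$objects, cfg$nor_fps)
  expect_lt(abs(sm$di), 0.12)
})

test_that("EPM trials realise the latent closed-arm occupancy", {
  cfg <- cohort_config(n_animals = 4, seed = 3, epm_trial_duration = 600)
  a <- fake_trait(closed_frac_pre = 0.7)
  # occupancy is bout-structured, so a single trial is noisy; average trials
  fracs <- vapply(1:6, function(s) {
    tr <- simulate_epm_trial(a, "pre", cfg, seed = s)
    m <- epm_metrics(tr$trajectory, tr$geometry, cfg$epm_fps)
    expect_equal(m$n_outside_frames, 0)
    m$closed_fraction / 100
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.7), 0.08)
})

test_that("cohort tables round-trip through CSV and the reader", {
  ds <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(ds, dir)
  expect_true(file.exists(file.path(dir, "config.txt")))
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  back <- read_cohort(dir)
  expect_equal(nrow(back$bottle_readings), nrow(ds$bottle_readings))
  expect_equal(back$bottle_readings$end_mass, ds$bottle_readings$end_mass)
  expect_false("susceptibility" %in% names(back$animals))
  expect_equal(back$config$seed, 1)
  # the reread tables drive the same pipeline
  an <- run_pipeline(back)
  expect_s3_class(an$intake, "tbl_df")
})
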