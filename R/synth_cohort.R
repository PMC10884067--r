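# Synthetic-cohort simulator: generates every input table the analysis
# consumes (animals, home-cage bottle readings, body weights, operant event
# logs, NOR/EPM trajectories, behavior-event streams) with the statistical
# structure the pipeline assumes, deterministically under a seed. One
# substream per animal and context, so adding animals never perturbs the
# records of existing ones.

#' Configuration for a synthetic self-administration cohort
#'
#' Holds the study-design presets: cohort composition, home-cage access,
#' calibration of daily intake (sex-specific means, between-day CV), the
#' latent-susceptibility structure (a minority "prone" subpopulation with
#' elevated intake, operant responding, non-reinforced persistence and
#' quinine resistance), logistic quinine dose suppression, and the
#' recognition-memory effect (male-specific post-exposure DI drop).
#'
#' @param n_animals Number of animals.
#' @param sex_ratio Fraction female in `[0, 1]`.
#' @param group_ratio Fraction assigned to the drug group.
#' @param n_days_homecage Days of home-cage two-bottle access.
#' @param drug_concentration Home-cage drug concentration, % w/v.
#' @param prone_fraction Fraction of drug animals with elevated
#'   susceptibility.
#' @param mean_daily_dose_male,mean_daily_dose_female Target cohort mean
#'   daily dose, mg/kg/day.
#' @param dose_cv Between-day coefficient of variation of daily dose.
#' @param preference_male,preference_female Target drug preference, %.
#' @param quinine_ic50_base,quinine_ic50_prone Quinine dose (g/L) halving
#'   operant responding for non-prone / prone animals.
#' @param nor_di_baseline True discrimination index before exposure.
#' @param nor_di_male_post_drop DI drop in drug-exposed males after
#'   exposure.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param evaporation_sd SD (g) of the additive half-normal
#'   evaporation/spillage loss per bottle per day.
#' @param intake_susceptibility_gain,press_susceptibility_gain Log-scale
#'   gain linking the latent susceptibility multiplicatively to intake and
#'   press rate.
#' @param press_rate_base Baseline active-press rate, presses/s.
#' @param press_rate_cv Between-animal CV of press rate.
#' @param quinine_hill Hill exponent of the logistic quinine suppression.
#' @param head_entry_prob Probability a presentation is followed by a head
#'   entry inside the dipper window.
#' @param inactive_rate_frac Inactive-press rate as a fraction of the
#'   active-press rate.
#' @param nr_persistence Mean non-reinforced / reinforced response ratio.
#' @param nor_fps,nor_trial_duration NOR tracking frame rate (frames/s) and
#'   trial length (s).
#' @param nor_explore_prob Per-frame probability of object exploration.
#' @param epm_fps,epm_trial_duration EPM frame rate and trial length.
#' @param behavior_session_duration Behavior-stream session length (s).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_animals = 40,
                          sex_ratio = 0.5,
                          group_ratio = 0.5,
                          n_days_homecage = 84,
                          drug_concentration = 7,
                          prone_fraction = 0.25,
                          mean_daily_dose_male = 809.7,
                          mean_daily_dose_female = 660.6,
                          dose_cv = 0.25,
                          preference_male = 20,
                          preference_female = 15,
                          quinine_ic50_base = 0.1,
                          quinine_ic50_prone = 0.4,
                          nor_di_baseline = 0.35,
                          nor_di_male_post_drop = 0.35,
                          seed = 1,
                          evaporation_sd = 0.5,
                          intake_susceptibility_gain = 0.4,
                          press_susceptibility_gain = 0.8,
                          press_rate_base = 0.004,
                          press_rate_cv = 0.35,
                          quinine_hill = 2,
                          head_entry_prob = 0.9,
                          inactive_rate_frac = 0.2,
                          nr_persistence = 0.81,
                          nor_fps = 10,
                          nor_trial_duration = 600,
                          nor_explore_prob = 0.15,
                          epm_fps = 10,
                          epm_trial_duration = 300,
                          behavior_session_duration = 10800) {
  check_number(n_animals, "n_animals", min = 1)
  if (n_animals != floor(n_animals)) {
    stop_config("config field `n_animals` must be an integer")
  }
  check_number(sex_ratio, "sex_ratio", min = 0, max = 1)
  check_number(group_ratio, "group_ratio", min = 0, max = 1)
  check_number(prone_fraction, "prone_fraction", min = 0, max = 1)
  check_number(n_days_homecage, "n_days_homecage", min = 1)
  check_number(drug_concentration, "drug_concentration", min = 0,
               strict_min = TRUE)
  check_number(mean_daily_dose_male, "mean_daily_dose_male", min = 0,
               strict_min = TRUE)
  check_number(mean_daily_dose_female, "mean_daily_dose_female", min = 0,
               strict_min = TRUE)
  check_number(dose_cv, "dose_cv", min = 0, strict_min = TRUE)
  check_number(preference_male, "preference_male", min = 0, max = 100)
  check_number(preference_female, "preference_female", min = 0, max = 100)
  check_number(quinine_ic50_base, "quinine_ic50_base", min = 0,
               strict_min = TRUE)
  check_number(quinine_ic50_prone, "quinine_ic50_prone", min = 0,
               strict_min = TRUE)
  check_number(nor_di_baseline, "nor_di_baseline", min = -1, max = 1)
  check_number(nor_di_male_post_drop, "nor_di_male_post_drop",
               min = 0, max = 2)
  check_number(seed, "seed")
  check_number(evaporation_sd, "evaporation_sd", min = 0)
  check_number(press_rate_base, "press_rate_base", min = 0)
  check_number(head_entry_prob, "head_entry_prob", min = 0, max = 1)
  check_number(nr_persistence, "nr_persistence", min = 0)
  check_number(nor_explore_prob, "nor_explore_prob", min = 0, max = 1)
  cfg <- as.list(environment())
  cfg$n_animals <- as.integer(n_animals)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

# ---- latent traits -------------------------------------------------------

# Deterministic sex/group assignment: females first within the id order,
# drug animals first within each sex (counterbalanced design).
assign_animals <- function(config) {
  n <- config$n_animals
  id <- sprintf("rat_%03d", seq_len(n))
  n_f <- round(n * config$sex_ratio)
  sex <- c(rep("female", n_f), rep("male", n - n_f))
  group <- unlist(lapply(split(seq_len(n), sex)[unique(sex)], function(ix) {
    nd <- round(length(ix) * config$group_ratio)
    rep(c("drug", "control"), c(nd, length(ix) - nd))
  }), use.names = FALSE)
  # restore id order (split() regrouped by sex)
  ord <- order(unlist(split(seq_len(n), sex)[unique(sex)], use.names = FALSE))
  tibble::tibble(animal_id = id, sex = sex, group = group[ord])
}

# E[exp(g (S - 0.5))] under the susceptibility mixture: prone animals draw
# S = 0.5 + 0.5 B, non-prone S = 0.5 B, with B ~ Beta(2, 2). Used to centre
# the multiplicative intake link at mean 1.
expected_intake_mult <- function(config) {
  g <- config$intake_susceptibility_gain
  p <- config$prone_fraction
  m_half <- stats::integrate(
    function(b) exp(0.5 * g * b) * stats::dbeta(b, 2, 2), 0, 1
  )$value
  p * m_half + (1 - p) * exp(-0.5 * g) * m_half
}

# Latent per-animal parameters (simulation ground truth, withheld from the
# analysis input tables).
derive_traits <- function(animals, config) {
  traits <- purrr::map_dfr(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    with_seed(substream_seed(config$seed, "traits", a$animal_id), {
      prone <- a$group == "drug" && runif(1) < config$prone_fraction
      susceptibility <- if (prone) {
        0.5 + 0.5 * rbeta(1, 2, 2)
      } else {
        0.5 * rbeta(1, 2, 2)
      }
      pref0 <- if (a$sex == "male") config$preference_male else
        config$preference_female
      tibble::tibble(
        animal_id = a$animal_id,
        prone = prone,
        susceptibility = susceptibility,
        intake_mult_raw = exp(config$intake_susceptibility_gain *
                                (susceptibility - 0.5)),
        preference_target = min(95, max(2, pref0 + rnorm(1, 0, 3))),
        press_rate = config$press_rate_base *
          exp(config$press_susceptibility_gain * (susceptibility - 0.5)) *
          rlnorm(1, -log(1 + config$press_rate_cv^2) / 2,
                 sqrt(log(1 + config$press_rate_cv^2))),
        quinine_ic50 = (if (prone) config$quinine_ic50_prone else
          config$quinine_ic50_base) * exp(rnorm(1, 0, 0.15)),
        nr_persistence = max(0.05, config$nr_persistence *
                               exp(0.3 * (susceptibility - 0.5)) *
                               exp(rnorm(1, 0, 0.1))),
        di_pre = max(-0.95, min(0.95,
                                config$nor_di_baseline + rnorm(1, 0, 0.05))),
        closed_frac_pre = min(0.9, max(0.05, rnorm(1, 0.55, 0.12))),
        closed_frac_post = min(0.9, max(0.05, rnorm(1, 0.55, 0.12)))
      )
    })
  })
  traits <- dplyr::left_join(traits, animals, by = "animal_id")
  # normalise the intake multiplier by its analytic expectation under the
  # Beta-mixture susceptibility model, so the cohort mean daily dose is the
  # configured preset in expectation while each animal stays independent of
  # the rest (adding animals never perturbs existing records)
  norm <- expected_intake_mult(config)
  traits |>
    dplyr::mutate(
      intake_mult = .data$intake_mult_raw / norm,
      daily_dose_mean = dplyr::if_else(
        .data$sex == "male",
        config$mean_daily_dose_male,
        config$mean_daily_dose_female
      ) * .data$intake_mult,
      di_post = .data$di_pre - dplyr::if_else(
        .data$group == "drug" & .data$sex == "male",
        config$nor_di_male_post_drop, 0
      )
    ) |>
    dplyr::select(-"intake_mult_raw")
}

simulate_bodyweights <- function(animals, config) {
  n_weeks <- ceiling(config$n_days_homecage / 7)
  purrr::map_dfr(seq_len(nrow(animals)), function(i) {
    a <- animals[i, ]
    with_seed(substream_seed(config$seed, "bodyweight", a$animal_id), {
      w0 <- if (a$sex == "male") 320 else 220
      gain <- if (a$sex == "male") 5 else 2.5
      weeks <- 0:n_weeks
      tibble::tibble(
        animal_id = a$animal_id,
        week = weeks,
        day = weeks * 7,
        weight_g = pmax(50, w0 + gain * weeks + rnorm(length(weeks), 0, 3))
      )
    })
  })
}

# ---- home cage -----------------------------------------------------------

#' Simulate one home-cage two-bottle-choice day for a drug animal
#'
#' Draws the intended daily dose from a lognormal around the animal's
#' (susceptibility- and sex-modulated) daily mean, converts it to a drug
#' volume at the animal's interpolated body weight, derives the paired
#' water volume from the animal's preference target, and adds half-normal
#' evaporation/spillage loss to each bottle. At zero noise the consumed
#' volume is exactly recoverable from the reading pair (density 1 g/mL).
#'
#' @param animal One row of a cohort's trait table (needs `animal_id`,
#'   `group`, `daily_dose_mean`, `preference_target`).
#' @param day Day index in `1..n_days_homecage`.
#' @param config The [cohort_config()].
#' @param bodyweight_g Body weight on that day (grams).
#' @param seed Substream seed; defaults to the cohort convention.
#' @return Tibble of two `BottleReading` rows (drug and water).
#' @export
simulate_homecage_day <- function(animal, day, config, bodyweight_g = NULL,
                                  seed = NULL) {
  if (!identical(animal$group, "drug")) {
    stop_usage("simulate_homecage_day applies to drug-group animals only")
  }
  if (day < 1 || day > config$n_days_homecage) {
    stop_usage(sprintf(
      "day %s is outside the access period 1..%d",
      day, config$n_days_homecage
    ))
  }
  seed <- seed %||% substream_seed(config$seed, "homecage",
                                  animal$animal_id, day)
  bodyweight_g <- bodyweight_g %||%
    (if (animal$sex == "male") 320 else 220)
  with_seed(seed, {
    sdlog <- sqrt(log(1 + config$dose_cv^2))
    dose <- rlnorm(1, log(animal$daily_dose_mean) - sdlog^2 / 2, sdlog)
    drug_vol <- dose * (bodyweight_g / 1000) /
      (config$drug_concentration * 10)
    p <- animal$preference_target
    water_vol <- drug_vol * (100 / p - 1) *
      rlnorm(1, -log(1 + 0.2^2) / 2, sqrt(log(1 + 0.2^2)))
    evap <- abs(rnorm(2, 0, config$evaporation_sd))
    drug_left <- (day - 1) %/% 7 %% 2 == 0
    start <- 150
    tibble::tibble(
      animal_id = animal$animal_id,
      day = day,
      fluid = c("drug", "water"),
      start_mass = start,
      end_mass = start - c(drug_vol + evap[1], water_vol + evap[2]),
      concentration = c(config$drug_concentration, 0),
      side = if (drug_left) c("left", "right") else c("right", "left")
    )
  })
}

simulate_homecage_control_day <- function(animal, day, config) {
  with_seed(substream_seed(config$seed, "homecage", animal$animal_id, day), {
    total <- rlnorm(1, log(30) - 0.15^2 / 2, 0.15)
    frac <- rbeta(1, 20, 20)
    evap <- abs(rnorm(2, 0, config$evaporation_sd))
    tibble::tibble(
      animal_id = animal$animal_id,
      day = day,
      fluid = c("water", "water"),
      start_mass = 150,
      end_mass = 150 - c(total * frac + evap[1],
                         total * (1 - frac) + evap[2]),
      concentration = 0,
      side = c("left", "right")
    )
  })
}

simulate_sentinel_day <- function(day, config) {
  with_seed(substream_seed(config$seed, "sentinel", day), {
    evap <- abs(rnorm(2, 0, config$evaporation_sd))
    tibble::tibble(
      animal_id = "sentinel",
      day = day,
      fluid = c("drug", "water"),
      start_mass = 150,
      end_mass = 150 - evap,
      concentration = c(config$drug_concentration, 0),
      side = c("left", "right")
    )
  })
}

# ---- operant -------------------------------------------------------------

# Full training/testing session plan (habituation excluded): FR1 -> FR2 ->
# FR4 at 30 min, FR4 at 1 h and 3 h, a 2% w/v FR4 series, PR, NR, a
# reminder, then the ascending quinine series in 2% drug solution.
session_plan <- function(config) {
  plan <- tibble::tribble(
    ~phase,         ~kind, ~ratio, ~session_duration, ~concentration, ~quinine_dose, ~n,
    "fr1",          "FR",  1,      1800,              7,              0,             7,
    "fr2",          "FR",  2,      1800,              7,              0,             7,
    "fr4_30min",    "FR",  4,      1800,              7,              0,             7,
    "fr4_1h",       "FR",  4,      3600,              7,              0,             3,
    "fr4_3h_7pct",  "FR",  4,      10800,             7,              0,             3,
    "fr4_3h_2pct",  "FR",  4,      10800,             2,              0,             7,
    "pr",           "PR",  NA,     10800,             7,              0,             1,
    "nr",           "NR",  NA,     10800,             7,              0,             1,
    "reminder",     "FR",  4,      1800,              7,              0,             1,
    "quinine_0.0",  "FR",  4,      10800,             2,              0,             1,
    "quinine_0.1",  "FR",  4,      10800,             2,              0.1,           1,
    "quinine_0.3",  "FR",  4,      10800,             2,              0.3,           1,
    "quinine_1.0",  "FR",  4,      10800,             2,              1.0,           1
  )
  plan <- plan[rep(seq_len(nrow(plan)), plan$n), ]
  plan$session_index <- seq_len(nrow(plan))
  plan$dipper_duration <- 10
  plan$cue_timeout <- 15
  plan$reward_volume <- 0.1
  dplyr::select(plan, -"n")
}

quinine_suppression <- function(dose, ic50, hill) {
  if (dose <= 0) return(1)
  1 / (1 + (dose / ic50)^hill)
}

#' Simulate one operant session for an animal
#'
#' Generates a time-ordered event log (active/inactive presses, head
#' entries) under the given schedule. The active-press process is Poisson
#' with an animal-specific rate that scales with latent susceptibility, is
#' multiplied by a logistic suppression term with an animal-specific IC50
#' under quinine adulteration, and by the animal's persistence factor under
#' non-reinforced conditions. Head entries follow a configurable fraction
#' of presentations inside the dipper window. The generator keeps its own
#' independent tally of presentations/consumptions for cross-checking
#' against [replay_schedule()].
#'
#' @param animal One row of a cohort trait table (needs `animal_id`,
#'   `press_rate`, `quinine_ic50`, `nr_persistence`).
#' @param spec A [schedule_spec()].
#' @param config The [cohort_config()].
#' @param seed Substream seed (default derived from the cohort seed,
#'   animal and schedule).
#' @return List with `events` (tibble `t`, `kind`) and `truth` (one-row
#'   tibble of the generator's internal tallies).
#' @export
simulate_operant_session <- function(animal, spec, config, seed = NULL) {
  if (!inherits(spec, "schedule_spec")) {
    stop_usage("`spec` must be a schedule_spec")
  }
  seed <- seed %||% substream_seed(
    config$seed, "operant", animal$animal_id, spec$kind,
    round(spec$session_duration), round(100 * spec$quinine_dose)
  )
  with_seed(seed, {
    rate <- animal$press_rate *
      quinine_suppression(spec$quinine_dose, animal$quinine_ic50,
                          config$quinine_hill)
    if (spec$kind == "NR") rate <- rate * animal$nr_persistence

    t <- 0
    press_t <- numeric(0)
    entry_t <- numeric(0)
    counter <- 0L
    reward_n <- 1L
    requirement <- if (spec$kind == "PR") pr_requirement(1L) else spec$ratio
    cue_end <- -Inf
    presentations <- 0L
    consumed <- 0L
    alp <- 0L
    while (rate > 0) {
      t <- t + rexp(1, rate)
      if (t > spec$session_duration) break
      alp <- alp + 1L
      press_t <- c(press_t, t)
      if (spec$kind == "NR") next
      if (t < cue_end) next # cue timeout: press has no consequences
      counter <- counter + 1L
      if (counter >= requirement) {
        presentations <- presentations + 1L
        cue_end <- t + spec$cue_timeout
        counter <- 0L
        if (runif(1) < config$head_entry_prob) {
          he <- t + runif(1, 0.5, spec$dipper_duration - 0.5)
          if (he <= spec$session_duration) {
            entry_t <- c(entry_t, he)
            consumed <- consumed + 1L
          }
        }
        if (spec$kind == "PR") {
          reward_n <- reward_n + 1L
          requirement <- pr_requirement(reward_n)
        }
      }
    }
    n_inactive <- rpois(1, animal$press_rate * config$inactive_rate_frac *
                          spec$session_duration)
    inactive_t <- sort(runif(n_inactive, 0, spec$session_duration))
    events <- tibble::tibble(
      t = c(press_t, inactive_t, entry_t),
      kind = c(rep("active_press", length(press_t)),
               rep("inactive_press", length(inactive_t)),
               rep("head_entry", length(entry_t)))
    )
    events <- events[order(events$t), ]
    list(
      events = events,
      truth = tibble::tibble(
        animal_id = animal$animal_id,
        alp = alp,
        presentations = presentations,
        consumed_presentations = consumed
      )
    )
  })
}

simulate_operant_all <- function(traits, config) {
  plan <- session_plan(config)
  drug <- traits[traits$group == "drug", ]
  out <- purrr::map(seq_len(nrow(drug)), function(i) {
    a <- drug[i, ]
    purrr::map(seq_len(nrow(plan)), function(j) {
      p <- plan[j, ]
      spec <- schedule_spec(
        kind = p$kind, ratio = if (is.na(p$ratio)) 1 else p$ratio,
        session_duration = p$session_duration,
        dipper_duration = p$dipper_duration, cue_timeout = p$cue_timeout,
        reward_volume = p$reward_volume, concentration = p$concentration,
        quinine_dose = p$quinine_dose
      )
      sim <- simulate_operant_session(
        a, spec, config,
        seed = substream_seed(config$seed, "operant", a$animal_id,
                              p$session_index)
      )
      sid <- sprintf("%s_s%02d_%s", a$animal_id, p$session_index, p$phase)
      list(
        manifest = dplyr::bind_cols(
          tibble::tibble(session_id = sid, animal_id = a$animal_id), p
        ),
        events = dplyr::bind_cols(
          tibble::tibble(session_id = sid, animal_id = a$animal_id),
          sim$events
        ),
        truth = dplyr::bind_cols(tibble::tibble(session_id = sid),
                                 sim$truth["presentations"],
                                 sim$truth["consumed_presentations"],
                                 sim$truth["alp"])
      )
    })
  })
  flat <- purrr::flatten(out)
  list(
    manifest = purrr::map_dfr(flat, "manifest"),
    events = purrr::map_dfr(flat, "events"),
    truth = purrr::map_dfr(flat, "truth")
  )
}

# ---- NOR / EPM / behavior ------------------------------------------------

nor_objects_default <- function() {
  tibble::tibble(
    object_id = c("old", "novel"),
    center_x = c(200, 600),
    center_y = c(400, 400),
    area_radius = 30
  )
}

#' Simulate a novel-object-recognition trial trajectory
#'
#' Per-frame nose/body positions realising a configured true
#' discrimination index: exploration frames put the nose within the 8-px
#' scoring distance of one object (novel vs old split according to the
#' animal's true DI for the phase), occasional sitting frames put the body
#' centre on an object (so the exclusion rule is exercised), and remaining
#' frames wander away from both objects. Drug-exposed males lose
#' `nor_di_male_post_drop` in the post phase.
#'
#' @param animal One row of a cohort trait table (needs `animal_id`,
#'   `di_pre`, `di_post`).
#' @param phase `"pre"` or `"post"`.
#' @param config The [cohort_config()].
#' @param seed Substream seed (default derived from cohort seed).
#' @return List with `trajectory` (tibble `frame`, `nose_x`, `nose_y`,
#'   `body_x`, `body_y`), `objects`, and `truth` (intended exploration
#'   seconds and realised DI).
#' @export
simulate_nor_trial <- function(animal, phase = c("pre", "post"), config,
                               seed = NULL) {
  phase <- match.arg(phase)
  seed <- seed %||% substream_seed(config$seed, "nor", animal$animal_id,
                                  phase)
  objects <- nor_objects_default()
  di_true <- if (phase == "pre") animal$di_pre else animal$di_post
  n <- round(config$nor_trial_duration * config$nor_fps)
  with_seed(seed, {
    p_explore <- config$nor_explore_prob
    p_sit <- 0.01
    u <- runif(n)
    state <- character(n)
    p_novel <- p_explore * (1 + di_true) / 2
    state[u < p_novel] <- "novel"
    state[u >= p_novel & u < p_explore] <- "old"
    state[u >= p_explore & u < p_explore + p_sit] <- "sit_old"
    state[u >= p_explore + p_sit & u < p_explore + 2 * p_sit] <- "sit_novel"
    state[state == ""] <- "wander"

    nose_x <- numeric(n); nose_y <- numeric(n)
    body_x <- numeric(n); body_y <- numeric(n)
    place_near <- function(idx, obj, on_object) {
      m <- length(idx)
      if (m == 0) return()
      ang <- runif(m, 0, 2 * pi)
      r_nose <- runif(m, 0, 8)
      nose_x[idx] <<- obj$center_x + r_nose * cos(ang)
      nose_y[idx] <<- obj$center_y + r_nose * sin(ang)
      ang_b <- runif(m, 0, 2 * pi)
      r_body <- if (on_object) {
        runif(m, 0, obj$area_radius * 0.8)
      } else {
        obj$area_radius + runif(m, 5, 50)
      }
      body_x[idx] <<- obj$center_x + r_body * cos(ang_b)
      body_y[idx] <<- obj$center_y + r_body * sin(ang_b)
    }
    old <- objects[objects$object_id == "old", ]
    nov <- objects[objects$object_id == "novel", ]
    place_near(which(state == "old"), old, FALSE)
    place_near(which(state == "novel"), nov, FALSE)
    place_near(which(state == "sit_old"), old, TRUE)
    place_near(which(state == "sit_novel"), nov, TRUE)
    wander <- which(state == "wander")
    if (length(wander) > 0) {
      bx <- runif(length(wander), 0, 800)
      by <- runif(length(wander), 0, 800)
      nx <- bx + runif(length(wander), -15, 15)
      ny <- by + runif(length(wander), -15, 15)
      # keep wander noses clear of the 8-px scoring zone of either object
      for (k in 1:5) {
        too_close <- sqrt((nx - old$center_x)^2 + (ny - old$center_y)^2) <= 9 |
          sqrt((nx - nov$center_x)^2 + (ny - nov$center_y)^2) <= 9
        if (!any(too_close)) break
        bx[too_close] <- runif(sum(too_close), 0, 800)
        by[too_close] <- runif(sum(too_close), 0, 800)
        nx[too_close] <- bx[too_close] + runif(sum(too_close), -15, 15)
        ny[too_close] <- by[too_close] + runif(sum(too_close), -15, 15)
      }
      nose_x[wander] <- nx; nose_y[wander] <- ny
      body_x[wander] <- bx; body_y[wander] <- by
    }
    t_novel <- sum(state == "novel") / config$nor_fps
    t_old <- sum(state == "old") / config$nor_fps
    list(
      trajectory = tibble::tibble(
        frame = seq_len(n) - 1L,
        nose_x = nose_x, nose_y = nose_y,
        body_x = body_x, body_y = body_y
      ),
      objects = objects,
      truth = tibble::tibble(
        animal_id = animal$animal_id, phase = phase,
        di_true = di_true, t_novel = t_novel, t_old = t_old,
        di_realised = if (t_novel + t_old > 0) {
          (t_novel - t_old) / (t_novel + t_old)
        } else {
          NA_real_
        }
      )
    )
  })
}

#' Simulate an elevated-plus-maze occupancy trajectory
#'
#' Body-centre positions generated as alternating zone bouts (exponential
#' dwell, mean 5 s) whose zone probabilities realise the animal's latent
#' closed-arm fraction; the trial starts in the centre, as in the assay.
#'
#' @param animal One row of a cohort trait table (needs `animal_id`,
#'   `closed_frac_pre`, `closed_frac_post`).
#' @param phase `"pre"` or `"post"`.
#' @param config The [cohort_config()].
#' @param seed Substream seed.
#' @return List with `trajectory` (tibble `frame`, `body_x`, `body_y`),
#'   `geometry`, and `truth` (target closed fraction).
#' @export
simulate_epm_trial <- function(animal, phase = c("pre", "post"), config,
                               seed = NULL) {
  phase <- match.arg(phase)
  seed <- seed %||% substream_seed(config$seed, "epm", animal$animal_id,
                                  phase)
  geometry <- epm_geometry()
  c_target <- if (phase == "pre") animal$closed_frac_pre else
    animal$closed_frac_post
  n <- round(config$epm_trial_duration * config$epm_fps)
  with_seed(seed, {
    p_closed <- c_target
    p_open <- (1 - c_target) * 0.6
    p_center <- 1 - p_closed - p_open
    zone_seq <- character(0)
    total <- 0L
    first <- TRUE
    while (total < n) {
      z <- if (first) {
        "center"
      } else {
        sample(c("closed", "open", "center"), 1,
               prob = c(p_closed, p_open, p_center))
      }
      first <- FALSE
      len <- max(1L, as.integer(round(rexp(1, 1 / 5) * config$epm_fps)))
      zone_seq <- c(zone_seq, rep(z, len))
      total <- total + len
    }
    zone_seq <- zone_seq[seq_len(n)]
    rects <- split(geometry, geometry$zone)
    body_x <- numeric(n)
    body_y <- numeric(n)
    for (z in unique(zone_seq)) {
      idx <- which(zone_seq == z)
      g <- rects[[z]]
      pick <- sample.int(nrow(g), length(idx), replace = TRUE)
      body_x[idx] <- runif(length(idx), g$xmin[pick], g$xmax[pick])
      body_y[idx] <- runif(length(idx), g$ymin[pick], g$ymax[pick])
    }
    list(
      trajectory = tibble::tibble(
        frame = seq_len(n) - 1L,
        body_x = body_x, body_y = body_y
      ),
      geometry = geometry,
      truth = tibble::tibble(
        animal_id = animal$animal_id, phase = phase,
        closed_frac_target = c_target
      )
    )
  })
}

# Time-stamped behavior-event streams (sensor-platform exports): aberrant
# behaviors at stable Poisson rates (no withdrawal syndrome by default) and
# drinking events with two binge windows for drug animals.
simulate_behavior_stream <- function(animal, session, config, seed = NULL) {
  seed <- seed %||% substream_seed(config$seed, "behavior", animal$animal_id,
                                  session)
  dur <- config$behavior_session_duration
  rates_per_s <- c(
    wet_dog_shake = 1.2 / 600, head_shake = 0.8 / 600,
    head_twitch = 0.5 / 600, scratching = 2 / 600
  )
  with_seed(seed, {
    ev <- purrr::map_dfr(names(rates_per_s), function(b) {
      k <- rpois(1, rates_per_s[[b]] * dur)
      tibble::tibble(t_seconds = sort(runif(k, 0, dur)), behavior = b)
    })
    drink_rate <- 4 / 600
    base_k <- rpois(1, drink_rate * dur)
    drink_t <- runif(base_k, 0, dur)
    if (animal$group == "drug") {
      binge_starts <- runif(2, 0, dur - 600)
      extra <- purrr::map(binge_starts, function(s) {
        runif(rpois(1, 8 * drink_rate * 600), s, s + 600)
      })
      drink_t <- c(drink_t, unlist(extra))
    }
    ev <- dplyr::bind_rows(
      ev, tibble::tibble(t_seconds = sort(drink_t), behavior = "drinking")
    )
    dplyr::arrange(
      dplyr::mutate(ev, animal_id = animal$animal_id, session = session),
      .data$t_seconds
    )
  })
}

# ---- cohort assembly -----------------------------------------------------

#' Simulate a complete synthetic self-administration study
#'
#' Generates every input the analysis pipeline consumes: the animal roster
#' and weekly body weights, daily two-bottle readings (plus sentinel
#' evaporation bottles), the full operant session sequence for every drug
#' animal, pre/post NOR and EPM trajectories for all animals, and
#' behavior-event streams. Deterministic under the config seed, with one
#' substream per animal and context.
#'
#' @param config A [cohort_config()].
#' @param include Character subset of
#'   `c("homecage", "operant", "nor", "epm", "behavior")` to generate
#'   (defaults to all).
#' @return A `cohort_dataset` list: `config`, `animals`, `traits`
#'   (simulation-only latent parameters), `bodyweights`,
#'   `bottle_readings`, `operant_manifest`, `operant_events`,
#'   `operant_truth`, `nor_trajectories`, `nor_objects`, `nor_truth`,
#'   `epm_trajectories`, `epm_geometry`, `epm_truth`, `behavior_events`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            include = c("homecage", "operant", "nor",
                                        "epm", "behavior")) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be created with cohort_config()")
  }
  include <- match.arg(include, several.ok = TRUE)
  animals <- assign_animals(config)
  traits <- derive_traits(animals, config)
  bodyweights <- simulate_bodyweights(animals, config)

  ds <- list(config = config, animals = animals, traits = traits,
             bodyweights = bodyweights)

  if ("homecage" %in% include) {
    days <- seq_len(config$n_days_homecage)
    bw_daily <- interpolate_bodyweight(bodyweights, days)
    readings <- purrr::map_dfr(seq_len(nrow(traits)), function(i) {
      a <- traits[i, ]
      if (a$group == "drug") {
        purrr::map_dfr(days, function(d) {
          bw <- bw_daily$weight_g[bw_daily$animal_id == a$animal_id &
                                    bw_daily$day == d]
          simulate_homecage_day(a, d, config, bodyweight_g = bw)
        })
      } else {
        purrr::map_dfr(days, function(d) {
          simulate_homecage_control_day(a, d, config)
        })
      }
    })
    sentinels <- purrr::map_dfr(days, simulate_sentinel_day, config = config)
    ds$bottle_readings <- dplyr::bind_rows(readings, sentinels)
  }

  if ("operant" %in% include) {
    op <- simulate_operant_all(traits, config)
    ds$operant_manifest <- op$manifest
    ds$operant_events <- op$events
    ds$operant_truth <- op$truth
  }

  if ("nor" %in% include) {
    trials <- purrr::map(seq_len(nrow(traits)), function(i) {
      purrr::map(c("pre", "post"), function(ph) {
        tr <- simulate_nor_trial(traits[i, ], ph, config)
        list(
          trajectory = dplyr::bind_cols(
            tibble::tibble(animal_id = traits$animal_id[i], phase = ph),
            tr$trajectory
          ),
          truth = tr$truth
        )
      })
    })
    flat <- purrr::flatten(trials)
    ds$nor_trajectories <- purrr::map_dfr(flat, "trajectory")
    ds$nor_objects <- nor_objects_default()
    ds$nor_truth <- purrr::map_dfr(flat, "truth")
  }

  if ("epm" %in% include) {
    trials <- purrr::map(seq_len(nrow(traits)), function(i) {
      purrr::map(c("pre", "post"), function(ph) {
        tr <- simulate_epm_trial(traits[i, ], ph, config)
        list(
          trajectory = dplyr::bind_cols(
            tibble::tibble(animal_id = traits$animal_id[i], phase = ph),
            tr$trajectory
          ),
          truth = tr$truth
        )
      })
    })
    flat <- purrr::flatten(trials)
    ds$epm_trajectories <- purrr::map_dfr(flat, "trajectory")
    ds$epm_geometry <- epm_geometry()
    ds$epm_truth <- purrr::map_dfr(flat, "truth")
  }

  if ("behavior" %in% include) {
    sessions <- c("intoxication_1", "intoxication_2", "abstinence")
    ds$behavior_events <- purrr::map_dfr(seq_len(nrow(traits)), function(i) {
      purrr::map_dfr(sessions, function(s) {
        simulate_behavior_stream(traits[i, ], s, config)
      })
    })
  }

  structure(ds, class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d animals (%d drug / %d control), seed %d\n",
    nrow(x$animals), sum(x$animals$group == "drug"),
    sum(x$animals$group == "control"), x$config$seed
  ))
  for (nm in setdiff(names(x), c("config", "animals"))) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  %-18s %8d rows\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}

#' Write a synthetic cohort to CSV input tables
#'
#' Writes the analysis input tables with headers (animal roster without the
#' latent susceptibility, body weights, bottle readings, operant manifest
#' and event log, NOR/EPM trajectories and geometry, behavior events), the
#' config as `key: value` text, and a manifest recording config and seed.
#'
#' @param dataset A `cohort_dataset` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  wr(dataset$animals, "animals.csv")
  wr(dataset$bodyweights, "bodyweights.csv")
  if (!is.null(dataset$bottle_readings)) {
    wr(dataset$bottle_readings, "bottle_readings.csv")
  }
  if (!is.null(dataset$operant_manifest)) {
    wr(dataset$operant_manifest, "operant_sessions.csv")
    wr(dataset$operant_events, "operant_events.csv")
  }
  if (!is.null(dataset$nor_trajectories)) {
    wr(dataset$nor_trajectories, "nor_trajectories.csv")
    wr(dataset$nor_objects, "nor_objects.csv")
  }
  if (!is.null(dataset$epm_trajectories)) {
    wr(dataset$epm_trajectories, "epm_trajectories.csv")
    wr(dataset$epm_geometry, "epm_geometry.csv")
  }
  if (!is.null(dataset$behavior_events)) {
    wr(dataset$behavior_events, "behavior_events.csv")
  }
  cfg <- dataset$config
  cfg_lines <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, format(cfg[[k]], scientific = FALSE))
  }, character(1))
  writeLines(cfg_lines, file.path(dir, "config.txt"))
  writeLines(
    c(sprintf("seed: %d", cfg$seed),
      sprintf("generated_tables: %s",
              paste(basename(paths), collapse = ", "))),
    file.path(dir, "manifest.txt")
  )
  invisible(c(paths, file.path(dir, c("config.txt", "manifest.txt"))))
}
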