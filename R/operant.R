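#' Progressive-ratio response requirement
#'
#' Number of active lever presses required for reward `n` under the
#' exponential progressive-ratio schedule F(n) = 5 exp(0.2 n) - 5, rounded to
#' the nearest integer and floored at 1. Reproduces the canonical progression
#' 1, 2, 4, 6, 9, 12, 15, 20, 25, 32, ...
#'
#' @param n Reward index (integer >= 1, vectorised).
#' @return Integer press requirement(s).
#' @export
pr_requirement <- function(n) {
  if (any(n < 1) || any(n != floor(n))) {
    stop_usage("`n` must be an integer >= 1")
  }
  as.integer(pmax(1, round(5 * exp(0.2 * n) - 5)))
}

#' Operant schedule specification
#'
#' @param kind One of `"FR"` (fixed ratio), `"PR"` (progressive ratio),
#'   `"NR"` (non-reinforced: presses recorded, no programmed consequences).
#' @param ratio Presses per reward (FR only, integer >= 1).
#' @param session_duration Session length in seconds.
#' @param dipper_duration Seconds the dipper cup stays raised (default 10).
#' @param cue_timeout Seconds the cue light stays lit after a completed
#'   ratio, during which additional active presses have no consequences
#'   (default 15). Both windows start at the completing press.
#' @param reward_volume Dipper cup volume in mL (default 0.1).
#' @param concentration Drug concentration in % w/v.
#' @param quinine_dose Quinine adulteration in g/L (0 for none).
#' @return A `schedule_spec` list.
#' @export
schedule_spec <- function(kind = c("FR", "PR", "NR"), ratio = 1,
                          session_duration = 1800, dipper_duration = 10,
                          cue_timeout = 15, reward_volume = 0.1,
                          concentration = 7, quinine_dose = 0) {
  kind <- match.arg(kind)
  if (kind == "FR" && (ratio < 1 || ratio != floor(ratio))) {
    stop_usage("FR `ratio` must be an integer >= 1")
  }
  for (d in c(session_duration, dipper_duration, cue_timeout)) {
    if (!is.finite(d) || d <= 0) stop_usage("durations must be positive")
  }
  if (quinine_dose < 0) stop_usage("`quinine_dose` must be >= 0")
  structure(
    list(
      kind = kind, ratio = as.integer(ratio),
      session_duration = session_duration,
      dipper_duration = dipper_duration, cue_timeout = cue_timeout,
      reward_volume = reward_volume, concentration = concentration,
      quinine_dose = quinine_dose
    ),
    class = "schedule_spec"
  )
}

#' Replay an operant event log under its schedule semantics
#'
#' Deterministically re-derives session measures from a time-ordered event
#' log. A ratio counter accumulates active presses made outside cue-timeout
#' windows; when it reaches the current requirement a presentation starts
#' (dipper up for `dipper_duration`, cue lit for `cue_timeout`, both from the
#' completing press), the counter resets, and the requirement advances (PR)
#' or stays (FR). Under NR, presses are recorded but never reinforced. A
#' presentation counts as consumed if at least one head entry falls inside
#' its dipper window. Active presses during a cue timeout count in `alp` and
#' `timeout_presses` but never toward the ratio.
#'
#' @param events Tibble with columns `t` (seconds from session start,
#'   sorted) and `kind` (`"active_press"`, `"inactive_press"`,
#'   `"head_entry"`).
#' @param spec A [schedule_spec()].
#' @param head_entry_grace Extra seconds after dipper retraction during which
#'   a head entry still counts as consumption (default 0).
#' @return One-row tibble: `alp`, `alp_excluding_timeout`, `ilp`,
#'   `head_entries`, `presentations`, `consumed_presentations`,
#'   `timeout_presses`, `breakpoint` (last completed PR requirement; `NA`
#'   for FR/NR).
#' @export
replay_schedule <- function(events, spec, head_entry_grace = 0) {
  if (!inherits(spec, "schedule_spec")) {
    stop_usage("`spec` must be a schedule_spec")
  }
  check_columns(events, c("t", "kind"), "events")
  t <- events$t
  kind <- as.character(events$kind)
  if (is.unsorted(t)) stop_data("event log must be time-ordered")
  if (length(t) > 0 && (min(t) < 0 || max(t) > spec$session_duration)) {
    stop_data("events must lie within [0, session_duration]")
  }
  bad <- setdiff(kind, c("active_press", "inactive_press", "head_entry"))
  if (length(bad) > 0) {
    stop_data(paste("unknown event kind(s):", paste(bad, collapse = ", ")))
  }

  alp <- 0L; ilp <- 0L; he <- 0L
  timeout_presses <- 0L
  presentations <- 0L; consumed <- 0L
  counter <- 0L
  reward_n <- 1L
  requirement <- if (spec$kind == "PR") pr_requirement(1L) else spec$ratio
  cue_end <- -Inf
  dipper_start <- NA_real_
  dipper_consumed <- TRUE
  breakpoint <- if (spec$kind == "PR") 0L else NA_integer_

  for (i in seq_along(t)) {
    k <- kind[i]
    if (k == "inactive_press") {
      ilp <- ilp + 1L
    } else if (k == "head_entry") {
      he <- he + 1L
      if (!dipper_consumed && !is.na(dipper_start) &&
          t[i] >= dipper_start &&
          t[i] <= dipper_start + spec$dipper_duration + head_entry_grace) {
        consumed <- consumed + 1L
        dipper_consumed <- TRUE
      }
    } else { # active press
      alp <- alp + 1L
      if (spec$kind == "NR") next
      if (t[i] < cue_end) {
        timeout_presses <- timeout_presses + 1L
      } else {
        counter <- counter + 1L
        if (counter >= requirement) {
          presentations <- presentations + 1L
          if (spec$kind == "PR") breakpoint <- requirement
          dipper_start <- t[i]
          dipper_consumed <- FALSE
          cue_end <- t[i] + spec$cue_timeout
          counter <- 0L
          if (spec$kind == "PR") {
            reward_n <- reward_n + 1L
            requirement <- pr_requirement(reward_n)
          }
        }
      }
    }
  }

  tibble::tibble(
    alp = alp,
    alp_excluding_timeout = alp - timeout_presses,
    ilp = ilp,
    head_entries = he,
    presentations = presentations,
    consumed_presentations = consumed,
    timeout_presses = timeout_presses,
    breakpoint = breakpoint
  )
}

#' Replay many sessions from a long event log
#'
#' @param events Tibble with `session_id`, `t`, `kind` (optionally
#'   `animal_id`).
#' @param manifest Tibble with one row per session: `session_id`, schedule
#'   columns (`kind`, `ratio`, `session_duration`, `dipper_duration`,
#'   `cue_timeout`, `reward_volume`, `concentration`, `quinine_dose`) and any
#'   annotation columns (e.g. `animal_id`, `phase`), which are carried
#'   through.
#' @return Tibble: one summary row per manifest session.
#' @export
replay_sessions <- function(events, manifest) {
  check_columns(events, c("session_id", "t", "kind"), "events")
  check_columns(manifest, c("session_id", "kind", "session_duration"),
                "manifest")
  ev_split <- split(events, events$session_id)
  col_or <- function(row, name, default) {
    if (name %in% names(row) && !is.na(row[[name]])) row[[name]] else default
  }
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    spec <- schedule_spec(
      kind = row$kind,
      ratio = col_or(row, "ratio", 1),
      session_duration = row$session_duration,
      dipper_duration = col_or(row, "dipper_duration", 10),
      cue_timeout = col_or(row, "cue_timeout", 15),
      reward_volume = col_or(row, "reward_volume", 0.1),
      concentration = col_or(row, "concentration", 7),
      quinine_dose = col_or(row, "quinine_dose", 0)
    )
    ev <- ev_split[[as.character(row$session_id)]] %||%
      tibble::tibble(t = numeric(), kind = character())
    dplyr::bind_cols(row, replay_schedule(ev, spec))
  })
}

#' Session drug dose from consumed presentations
#'
#' @param consumed_presentations Number of presentations with a head entry
#'   in the dipper window.
#' @param spec A [schedule_spec()] (uses `reward_volume` and
#'   `concentration`).
#' @param bodyweight_g Body weight in grams.
#' @return Dose in mg/kg.
#' @export
session_dose <- function(consumed_presentations, spec, bodyweight_g) {
  if (any(!is.finite(bodyweight_g)) || any(bodyweight_g <= 0)) {
    stop_data("`bodyweight_g` must be strictly positive")
  }
  consumed_presentations * spec$reward_volume * spec$concentration * 10 /
    (bodyweight_g / 1000)
}

#' Habit ratio: non-reinforced over reinforced responding
#'
#' Active lever presses under non-reinforced conditions divided by active
#' lever presses under the preceding reinforced schedule; values near 1
#' index habitual drug-seeking.
#'
#' @param nr_alp Active presses in the non-reinforced session.
#' @param reinforced_alp Active presses in the reference reinforced session.
#' @return Ratio, or `NA` with a warning when `reinforced_alp` is 0.
#' @export
habit_ratio <- function(nr_alp, reinforced_alp) {
  out <- nr_alp / reinforced_alp
  zero <- !is.na(reinforced_alp) & reinforced_alp == 0
  if (any(zero)) {
    warn("habit ratio undefined for zero reinforced responding; set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' AUC of intake over increasing quinine doses
#'
#' Trapezoidal area of session drug intake (mg/kg) against quinine dose
#' (g/L); resistance to suppression yields larger areas (use despite
#' negative consequences).
#'
#' @param doses Quinine doses in g/L, strictly increasing.
#' @param intakes Session intakes in mg/kg, same length.
#' @return AUC in mg/kg x g/L.
#' @export
quinine_auc <- function(doses, intakes) {
  if (length(doses) < 2) stop_data("need at least 2 quinine dose levels")
  if (length(doses) != length(intakes)) {
    stop_data("`doses` and `intakes` must have equal length")
  }
  if (any(diff(doses) <= 0)) {
    stop_data("`doses` must be strictly increasing")
  }
  pracma::trapz(doses, intakes)
}

#' Acquisition status from a sequence of training sessions
#'
#' An animal is `excluded` if it earned no reward in three subsequent
#' sessions, `acquired` once it earned at least one reward in three
#' subsequent sessions, and `in_progress` otherwise. Exclusion is checked
#' first.
#'
#' @param presentations Per-session presentation counts, in session order.
#' @return One of `"excluded"`, `"acquired"`, `"in_progress"`.
#' @export
acquisition_status <- function(presentations) {
  if (length(presentations) < 1) stop_data("need at least one session")
  runs_of_3 <- function(x) {
    n <- length(x)
    n >= 3 && any(vapply(
      seq_len(n - 2), function(i) all(x[i:(i + 2)]), logical(1)
    ))
  }
  if (runs_of_3(presentations == 0)) return("excluded")
  if (runs_of_3(presentations >= 1)) return("acquired")
  "in_progress"
}
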