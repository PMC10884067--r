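#' Daily drug dose from a bottle mass loss
#'
#' Converts the mass lost from a drug bottle into a body-weight-normalised
#' dose. Dilute aqueous solutions are taken at density 1.00 g/mL, so grams of
#' mass loss equal millilitres consumed; a concentration of c % w/v equals
#' 10 c mg/mL.
#'
#' @param mass_loss_g Numeric vector, bottle mass loss in grams (start minus
#'   end mass). Negative values are clamped to zero with a warning.
#' @param concentration_pct Drug concentration in % w/v (e.g. 7 for 7%).
#' @param bodyweight_g Body weight in grams on the day of reading.
#' @return Dose in mg per kg body weight, same length as `mass_loss_g`.
#' @examples
#' compute_daily_dose(3, 7, 300) # 700 mg/kg
#' @export
compute_daily_dose <- function(mass_loss_g, concentration_pct, bodyweight_g) {
  if (any(!is.finite(bodyweight_g)) || any(bodyweight_g <= 0)) {
    stop_data("`bodyweight_g` must be strictly positive")
  }
  if (any(concentration_pct < 0)) {
    stop_data("`concentration_pct` must be non-negative")
  }
  neg <- !is.na(mass_loss_g) & mass_loss_g < 0
  if (any(neg)) {
    warn(sprintf(
      "%d negative bottle mass loss(es) clamped to 0", sum(neg)
    ))
    mass_loss_g[neg] <- 0
  }
  mass_loss_g * concentration_pct * 10 / (bodyweight_g / 1000)
}

#' Drug preference over a window
#'
#' Preference is the drug share of total fluid intake, in percent:
#' 100 * sum(drug) / (sum(drug) + sum(water)).
#'
#' @param drug_volume,water_volume Volumes in mL over the window (vectors are
#'   summed).
#' @return Preference in percent, or `NA` (with a warning) if total fluid is
#'   zero.
#' @export
compute_preference <- function(drug_volume, water_volume) {
  d <- sum(drug_volume, na.rm = TRUE)
  w <- sum(water_volume, na.rm = TRUE)
  if (d + w <= 0) {
    warn("total fluid intake is zero; preference undefined")
    return(NA_real_)
  }
  100 * d / (d + w)
}

#' Trapezoidal area under a daily-dose curve
#'
#' Integrates dose (mg/kg) over the day index. Missing doses are linearly
#' interpolated (and reported via a message) before integration.
#'
#' @param dose Daily doses in mg/kg.
#' @param day Day indices (default `0, 1, ...`). Must be strictly increasing
#'   after ordering.
#' @return AUC in mg.day/kg.
#' @export
intake_auc <- function(dose, day = seq_along(dose) - 1) {
  if (length(dose) != length(day)) {
    stop_data("`dose` and `day` must have equal length")
  }
  ord <- order(day)
  dose <- dose[ord]
  day <- day[ord]
  ok <- is.finite(dose)
  if (sum(ok) < 2) {
    stop_data("intake_auc needs at least 2 non-missing days")
  }
  if (any(!ok)) {
    inform(sprintf(
      "intake_auc: %d missing day(s) linearly interpolated", sum(!ok)
    ))
    dose[!ok] <- approx(day[ok], dose[ok], xout = day[!ok], rule = 2)$y
  }
  pracma::trapz(day, dose)
}

#' Pharmacological relevance of an acute dose
#'
#' Flags doses above the 87.5 mg/kg acute-dose threshold used to judge
#' whether voluntary intake reaches pharmacologically active levels.
#'
#' @param dose Dose(s) in mg/kg.
#' @param threshold Threshold in mg/kg (default 87.5). The comparison is
#'   strict (`dose > threshold`).
#' @return Logical vector.
#' @export
flag_pharmacological_relevance <- function(dose, threshold = 87.5) {
  if (any(dose < 0, na.rm = TRUE)) stop_data("`dose` must be non-negative")
  dose > threshold
}

#' Detect binge-like drinking bins
#'
#' Operationalises "distinct consumption peaks": a 10-min bin is a binge if
#' its drinking time exceeds the session mean by more than `threshold_sd`
#' standard deviations and exceeds `min_seconds` in absolute terms.
#'
#' @param drinking_time Seconds of drinking per bin (>= 6 bins).
#' @param threshold_sd SD multiplier above the mean (default 2).
#' @param min_seconds Absolute floor in seconds (default 10).
#' @return Integer vector of binge bin indices (possibly empty).
#' @export
detect_binges <- function(drinking_time, threshold_sd = 2, min_seconds = 10) {
  if (length(drinking_time) < 6) {
    stop_data("detect_binges needs at least 6 bins")
  }
  m <- mean(drinking_time)
  s <- sd(drinking_time)
  cut <- m + threshold_sd * s
  which(drinking_time > cut & drinking_time > min_seconds)
}

#' Interpolate weekly body weights to daily values
#'
#' Body weight is measured weekly; daily doses use linear interpolation
#' between weighings, held flat beyond the first/last measurement.
#'
#' @param bodyweights Tibble with columns `animal_id`, `day`, `weight_g`.
#' @param days Integer vector of days to interpolate at.
#' @return Tibble with `animal_id`, `day`, `weight_g` for every requested day.
#' @export
interpolate_bodyweight <- function(bodyweights, days) {
  check_columns(bodyweights, c("animal_id", "day", "weight_g"), "bodyweights")
  bodyweights |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::reframe(
      weight_g = approx(.data$day, .data$weight_g, xout = days, rule = 2)$y,
      day = days
    ) |>
    dplyr::select("animal_id", "day", "weight_g")
}

#' Per-animal-day intake series from bottle readings
#'
#' Converts raw two-bottle-choice readings plus weekly body weights into the
#' daily intake series: drug and water volumes (mL), dose (mg/kg), daily
#' preference (%), and a pharmacological-relevance flag. Readings with
#' `animal_id == "sentinel"` are bottles in an unoccupied cage that measure
#' evaporation/spillage only; with `evaporation_correction = TRUE` the mean
#' daily sentinel mass loss is subtracted from every bottle before volumes
#' are computed (default off).
#'
#' @param readings Tibble with columns `animal_id`, `day`, `fluid`
#'   (`"drug"`/`"water"`), `start_mass`, `end_mass`, `concentration`, and
#'   optionally `side`.
#' @param bodyweights Tibble with `animal_id`, `day`, `weight_g` (weekly).
#' @param evaporation_correction Subtract mean daily sentinel bottle loss
#'   (requires sentinel readings). Default `FALSE`.
#' @return Tibble keyed by (`animal_id`, `day`) with columns `drug_volume`,
#'   `water_volume`, `dose`, `preference`, `relevant`.
#' @export
homecage_intake <- function(readings, bodyweights,
                            evaporation_correction = FALSE) {
  check_columns(
    readings,
    c("animal_id", "day", "fluid", "start_mass", "end_mass", "concentration"),
    "readings"
  )
  sentinel <- dplyr::filter(readings, .data$animal_id == "sentinel")
  readings <- dplyr::filter(readings, .data$animal_id != "sentinel")

  evap <- 0
  if (isTRUE(evaporation_correction)) {
    if (nrow(sentinel) == 0) {
      stop_data(
        "evaporation_correction = TRUE requires sentinel bottle readings"
      )
    }
    evap <- sentinel |>
      dplyr::mutate(loss = .data$start_mass - .data$end_mass) |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(evap_g = mean(.data$loss), .groups = "drop")
  }

  losses <- readings |>
    dplyr::mutate(loss = .data$start_mass - .data$end_mass)
  if (isTRUE(evaporation_correction)) {
    losses <- losses |>
      dplyr::left_join(evap, by = "day") |>
      dplyr::mutate(loss = .data$loss - dplyr::coalesce(.data$evap_g, 0))
  }
  losses <- dplyr::mutate(losses, loss = pmax(.data$loss, 0))

  daily <- losses |>
    dplyr::group_by(.data$animal_id, .data$day) |>
    dplyr::summarise(
      drug_volume = sum(.data$loss[.data$fluid == "drug"]),
      water_volume = sum(.data$loss[.data$fluid == "water"]),
      concentration = if (any(.data$fluid == "drug")) {
        .data$concentration[.data$fluid == "drug"][1]
      } else {
        0
      },
      .groups = "drop"
    )

  bw <- interpolate_bodyweight(bodyweights, sort(unique(daily$day)))
  daily |>
    dplyr::inner_join(bw, by = c("animal_id", "day")) |>
    dplyr::mutate(
      dose = compute_daily_dose(
        .data$drug_volume, .data$concentration, .data$weight_g
      ),
      total = .data$drug_volume + .data$water_volume,
      preference = dplyr::if_else(
        .data$total > 0, 100 * .data$drug_volume / .data$total, NA_real_
      ),
      relevant = flag_pharmacological_relevance(.data$dose)
    ) |>
    dplyr::select(
      "animal_id", "day", "drug_volume", "water_volume", "dose",
      "preference", "relevant"
    ) |>
    dplyr::arrange(.data$animal_id, .data$day)
}

#' Per-animal home-cage intake summary
#'
#' Collapses a daily intake series into one row per animal: mean daily dose,
#' overall preference, intake AUC, and the fraction of days at a
#' pharmacologically relevant dose.
#'
#' @param intake Output of [homecage_intake()].
#' @return Tibble with one row per animal: `mean_dose`, `preference`,
#'   `auc_intake`, `frac_relevant`, `n_days`.
#' @export
homecage_summary <- function(intake) {
  check_columns(
    intake, c("animal_id", "day", "drug_volume", "water_volume", "dose"),
    "intake"
  )
  intake |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      mean_dose = mean(.data$dose, na.rm = TRUE),
      preference = compute_preference(.data$drug_volume, .data$water_volume),
      auc_intake = intake_auc(.data$dose, .data$day),
      frac_relevant = mean(flag_pharmacological_relevance(.data$dose)),
      n_days = dplyr::n(),
      .groups = "drop"
    )
}
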