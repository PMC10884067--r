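# End-to-end analysis: home-cage intake, operant replay, the four
# addiction-like measures, severity classification, assay scoring, and the
# study-defined statistics, assembled from a cohort's input tables.

#' Derive the four addiction-like measures from pipeline outputs
#'
#' Per drug animal: home-cage intake AUC (mg.day/kg), active lever presses
#' during the progressive-ratio session, habit ratio (non-reinforced over
#' the last preceding reinforced FR4 session), and the AUC of session
#' intake over the ascending quinine series.
#'
#' @param intake_summary Output of [homecage_summary()].
#' @param session_summaries Output of [replay_sessions()] on the operant
#'   log; needs `animal_id`, `phase`, `session_index`, `alp`,
#'   `consumed_presentations`, plus the schedule columns.
#' @param bodyweights Weekly body weights (`animal_id`, `day`, `weight_g`);
#'   the last measurement is used for operant session doses.
#' @return Tibble with `animal_id`, `auc_intake`, `pr_alp`, `habit_ratio`,
#'   `quinine_auc`, `acquisition`.
#' @export
severity_measures <- function(intake_summary, session_summaries,
                              bodyweights) {
  check_columns(session_summaries,
                c("animal_id", "phase", "session_index", "alp",
                  "consumed_presentations", "presentations"),
                "session_summaries")
  last_bw <- bodyweights |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::slice_max(.data$day, n = 1, with_ties = FALSE) |>
    dplyr::select("animal_id", weight_g = "weight_g")

  per_animal <- session_summaries |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$session_index)
      training <- df[grepl("^fr", df$phase), ]
      status <- acquisition_status(training$presentations)
      pr <- df[df$phase == "pr", ]
      nr <- df[df$phase == "nr", ]
      nr_idx <- if (nrow(nr) > 0) nr$session_index[1] else Inf
      reinforced <- df[df$kind == "FR" & !is.na(df$ratio) & df$ratio == 4 &
                         df$session_index < nr_idx, ]
      quinine <- df[grepl("^quinine", df$phase), ]
      bw <- last_bw$weight_g[last_bw$animal_id == key$animal_id]
      q_auc <- if (nrow(quinine) >= 2 && length(bw) == 1) {
        quinine <- dplyr::arrange(quinine, .data$quinine_dose)
        spec_q <- schedule_spec(
          "FR", 4, quinine$session_duration[1],
          reward_volume = quinine$reward_volume[1],
          concentration = quinine$concentration[1]
        )
        quinine_auc(
          quinine$quinine_dose,
          session_dose(quinine$consumed_presentations, spec_q, bw)
        )
      } else {
        NA_real_
      }
      tibble::tibble(
        animal_id = key$animal_id,
        pr_alp = if (nrow(pr) > 0) as.numeric(pr$alp[1]) else NA_real_,
        habit_ratio = if (nrow(nr) > 0 && nrow(reinforced) > 0) {
          habit_ratio(nr$alp[1], tail(reinforced$alp, 1))
        } else {
          NA_real_
        },
        quinine_auc = q_auc,
        acquisition = status
      )
    }) |>
    dplyr::bind_rows()

  intake_summary |>
    dplyr::select("animal_id", "auc_intake") |>
    dplyr::inner_join(per_animal, by = "animal_id") |>
    dplyr::select("animal_id", "auc_intake", "pr_alp", "habit_ratio",
                  "quinine_auc", "acquisition")
}

#' Score all NOR trials in a cohort
#'
#' @param nor_trajectories Long tibble (`animal_id`, `phase`, `frame`,
#'   `nose_x`, `nose_y`, `body_x`, `body_y`).
#' @param objects Object geometry (see [nor_score()]).
#' @param fps Frames per second.
#' @return Tibble per (`animal_id`, `phase`): `t_novel`, `t_old`, `di`.
#' @export
score_nor_trials <- function(nor_trajectories, objects, fps) {
  nor_trajectories |>
    dplyr::group_by(.data$animal_id, .data$phase) |>
    dplyr::group_modify(~ nor_score(.x, objects, fps)) |>
    dplyr::ungroup()
}

#' Score all EPM trials in a cohort
#'
#' @param epm_trajectories Long tibble (`animal_id`, `phase`, `frame`,
#'   `body_x`, `body_y`).
#' @param geometry Zone rectangles ([epm_geometry()]).
#' @param fps Frames per second.
#' @return Tibble per (`animal_id`, `phase`) of [epm_metrics()] columns.
#' @export
score_epm_trials <- function(epm_trajectories, geometry, fps) {
  epm_trajectories |>
    dplyr::group_by(.data$animal_id, .data$phase) |>
    dplyr::group_modify(~ epm_metrics(.x, geometry, fps)) |>
    dplyr::ungroup()
}

#' Run the full analysis pipeline on a cohort dataset
#'
#' Executes, in order: home-cage intake conversion and per-animal
#' summaries; operant event-log replay and the four addiction-like
#' measures; the severity classification; NOR and EPM scoring; the
#' Bonferroni-corrected correlation set; and the baseline-anxiety
#' regression.
#'
#' @param dataset A `cohort_dataset` (or a list with the same tables).
#' @param evaporation_correction Passed to [homecage_intake()].
#' @return A `ghbsa_analysis` list of result tables.
#' @export
run_pipeline <- function(dataset, evaporation_correction = FALSE) {
  res <- list(config = dataset$config)

  if (!is.null(dataset$bottle_readings)) {
    res$intake <- homecage_intake(
      dataset$bottle_readings, dataset$bodyweights,
      evaporation_correction = evaporation_correction
    )
    res$intake_summary <- homecage_summary(res$intake)
  }

  if (!is.null(dataset$operant_events)) {
    res$sessions <- replay_sessions(dataset$operant_events,
                                    dataset$operant_manifest)
    if (!is.null(res$intake_summary)) {
      res$measures <- severity_measures(res$intake_summary, res$sessions,
                                        dataset$bodyweights)
      complete <- res$measures[res$measures$acquisition != "excluded", ]
      if (sum(stats::complete.cases(
        complete[c("auc_intake", "pr_alp", "habit_ratio", "quinine_auc")]
      )) >= 4) {
        res$severity <- severity_table(complete)
        res$correlations <- correlation_set(complete)
      }
    }
  }

  if (!is.null(dataset$nor_trajectories)) {
    res$nor <- score_nor_trials(dataset$nor_trajectories,
                                dataset$nor_objects,
                                dataset$config$nor_fps)
  }
  if (!is.null(dataset$epm_trajectories)) {
    res$epm <- score_epm_trials(dataset$epm_trajectories,
                                dataset$epm_geometry,
                                dataset$config$epm_fps)
  }
  if (!is.null(res$epm) && !is.null(res$intake_summary)) {
    baseline <- res$epm[res$epm$phase == "pre", ]
    df <- dplyr::inner_join(res$intake_summary, baseline, by = "animal_id")
    if (nrow(df) >= 3 && sd(df$closed_fraction) > 0) {
      res$anxiety <- anxiety_regression(df)
    }
  }
  if (!is.null(dataset$behavior_events)) {
    res$behavior_bins <- dataset$behavior_events |>
      dplyr::group_by(.data$animal_id, .data$session) |>
      dplyr::group_modify(
        ~ bin_counts(.x, bin_width = 600,
                     session_duration =
                       dataset$config$behavior_session_duration)
      ) |>
      dplyr::ungroup()
  }
  structure(res, class = "ghbsa_analysis")
}

#' @export
print.ghbsa_analysis <- function(x, ...) {
  cat("GHB self-administration analysis\n")
  for (nm in setdiff(names(x), "config")) {
    obj <- x[[nm]]
    if (is.data.frame(obj)) {
      cat(sprintf("  %-16s %6d rows\n", nm, nrow(obj)))
    } else {
      cat(sprintf("  %-16s <%s>\n", nm, class(obj)[1]))
    }
  }
  invisible(x)
}

#' Assemble a report directory from an analysis
#'
#' Writes every result table as CSV, per-figure CSVs mirroring the study's
#' panel structure (intake over weeks, preference by sex, operant
#' acquisition, quinine dose-response, severity distribution, NOR DI by
#' sex and phase, EPM metrics), and run metadata (config, seed, analysis
#' decisions in force). Missing sections are noted, not fatal.
#'
#' @param analysis A `ghbsa_analysis` from [run_pipeline()].
#' @param dir Output directory.
#' @param animals Optional animal roster to annotate figure tables with sex
#'   and group.
#' @return Invisibly, the written paths.
#' @export
build_report <- function(analysis, dir, animals = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  notes <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  annotate <- function(df) {
    if (!is.null(animals)) {
      dplyr::left_join(df, animals, by = "animal_id")
    } else {
      df
    }
  }

  if (!is.null(analysis$intake)) {
    wr(analysis$intake, "intake_series.csv")
    weekly <- analysis$intake |>
      dplyr::mutate(week = (.data$day - 1) %/% 7 + 1) |>
      dplyr::group_by(.data$animal_id, .data$week) |>
      dplyr::summarise(
        mean_dose = mean(.data$dose, na.rm = TRUE),
        mean_preference = mean(.data$preference, na.rm = TRUE),
        .groups = "drop"
      )
    wr(annotate(weekly), "fig_intake_by_week.csv")
    wr(annotate(analysis$intake_summary), "fig_preference_by_sex.csv")
  } else {
    notes <- c(notes, "home-cage section empty: no bottle readings")
  }

  if (!is.null(analysis$sessions)) {
    wr(analysis$sessions, "operant_sessions_summary.csv")
    quin <- analysis$sessions[grepl("^quinine", analysis$sessions$phase), ]
    if (nrow(quin) > 0) {
      wr(annotate(dplyr::select(
        quin, "animal_id", "phase", "quinine_dose", "alp",
        "presentations", "consumed_presentations"
      )), "fig_quinine_dose_response.csv")
    }
  } else {
    notes <- c(notes, "operant section empty: no event logs")
  }

  if (!is.null(analysis$measures)) {
    wr(annotate(analysis$measures), "severity_measures.csv")
  }
  if (!is.null(analysis$severity)) {
    wr(tidy(analysis$severity), "severity_table.csv")
    wr(annotate(analysis$severity$consistency), "fig_severity_distribution.csv")
  } else {
    notes <- c(notes, "severity section empty: too few complete animals")
  }
  if (!is.null(analysis$correlations)) {
    wr(tibble::as_tibble(analysis$correlations), "correlation_set.csv")
  }
  if (!is.null(analysis$nor)) {
    wr(annotate(analysis$nor), "fig_nor_di.csv")
  } else {
    notes <- c(notes, "NOR section empty: no trajectories")
  }
  if (!is.null(analysis$epm)) {
    wr(annotate(analysis$epm), "fig_epm_metrics.csv")
  } else {
    notes <- c(notes, "EPM section empty: no trajectories")
  }
  if (!is.null(analysis$anxiety)) {
    wr(dplyr::bind_cols(tidy(analysis$anxiety)), "anxiety_regression.csv")
  }
  if (!is.null(analysis$behavior_bins)) {
    wr(analysis$behavior_bins, "fig_behavior_bins.csv")
  }

  meta <- c(
    sprintf("generated: run_pipeline, package ghbsa %s",
            as.character(utils::packageVersion("ghbsa"))),
    if (!is.null(analysis$config)) {
      c(sprintf("seed: %s", analysis$config$seed),
        vapply(names(analysis$config), function(k) {
          sprintf("config %s: %s",
                  k, format(analysis$config[[k]], scientific = FALSE))
        }, character(1)))
    },
    "decision: sample SD (n-1) for z-scores and outliers",
    "decision: quartile size floor(n/4); ties by raw triple total then id",
    "decision: preference = 100 * drug / (drug + water)",
    "decision: head entry consumes within the 10-s dipper window (grace 0 s)",
    "decision: nose-object threshold 8 px, inclusive",
    if (length(notes) > 0) paste("note:", notes)
  )
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(c(paths, file.path(dir, "run_metadata.txt")))
}

#' Weekly intake curve by sex
#'
#' @param intake Daily intake series from [homecage_intake()].
#' @param animals Animal roster with `animal_id`, `sex`, `group`.
#' @return A ggplot of weekly mean daily dose (mg/kg) by sex (drug group).
#' @export
plot_intake <- function(intake, animals) {
  df <- intake |>
    dplyr::inner_join(animals, by = "animal_id") |>
    dplyr::filter(.data$group == "drug") |>
    dplyr::mutate(week = (.data$day - 1) %/% 7 + 1) |>
    dplyr::group_by(.data$sex, .data$week) |>
    dplyr::summarise(
      mean_dose = mean(.data$dose, na.rm = TRUE),
      sem = sd(.data$dose, na.rm = TRUE) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$week, .data$mean_dose,
                                   colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_dose - .data$sem,
      ymax = .data$mean_dose + .data$sem
    )) +
    ggplot2::labs(x = "week", y = "daily intake (mg/kg)",
                  title = "Home-cage drug intake") +
    ggplot2::theme_minimal()
}

#' Quinine dose-response of operant intake
#'
#' @param sessions Session summaries from [replay_sessions()] (quinine
#'   phases).
#' @return A ggplot of per-animal presentations against quinine dose.
#' @export
plot_quinine <- function(sessions) {
  df <- sessions[grepl("^quinine", sessions$phase), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$quinine_dose,
                                   .data$consumed_presentations,
                                   group = .data$animal_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "quinine (g/L)", y = "consumed presentations",
                  title = "Use despite negative consequences") +
    ggplot2::theme_minimal()
}

#' NOR discrimination index by phase and sex
#'
#' @param nor NOR results from [score_nor_trials()].
#' @param animals Animal roster with `animal_id`, `sex`, `group`.
#' @return A ggplot of DI by phase, faceted by sex, coloured by group.
#' @export
plot_nor <- function(nor, animals) {
  df <- dplyr::inner_join(nor, animals, by = "animal_id") |>
    dplyr::mutate(phase = factor(.data$phase, levels = c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(.data$phase, .data$di,
                                   colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1
    )) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = "discrimination index",
                  title = "Novel object recognition") +
    ggplot2::theme_minimal()
}
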