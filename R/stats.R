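# Study-defined statistics: the Bonferroni-corrected correlation set over
# the four addiction-like measures and the baseline-anxiety regression.

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level in (0, 1) (default 0.05).
#' @param m Number of comparisons (>= 1); six for all unordered pairs of
#'   the four addiction-like measures (0.05 / 6 = 0.0083).
#' @return Corrected per-comparison level `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_usage("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(m) || m < 1 || m != floor(m)) {
    stop_usage("`m` must be an integer >= 1")
  }
  alpha / m
}

#' Pairwise correlations among the four addiction-like measures
#'
#' Pearson correlation (two-sided test) for every unordered pair of the
#' four measures -- six analyses -- flagged significant at the
#' Bonferroni-corrected level `alpha / 6`. Before correlating, animals that
#' are outliers on the motivation measure (deviating more than `outlier_k`
#' SD from the group mean of `pr_alp`) are excluded, mirroring the study's
#' exclusion rule for analyses involving motivation.
#'
#' @param measures Tibble with `animal_id` and numeric columns
#'   `auc_intake`, `pr_alp`, `habit_ratio`, `quinine_auc`; rows with missing
#'   values are dropped.
#' @param alpha Family-wise significance level (default 0.05).
#' @param exclude_outliers Apply the motivation-measure outlier exclusion
#'   (default `TRUE`).
#' @param outlier_k SD multiplier for the exclusion rule (default 2).
#' @return A `ghbsa_correlation_set`: tibble with one row per pair
#'   (`measure_1`, `measure_2`, `n`, `r`, `p`, `significant`) and
#'   attributes `corrected_alpha` and `excluded` (animal ids).
#' @export
correlation_set <- function(measures, alpha = 0.05, exclude_outliers = TRUE,
                            outlier_k = 2) {
  cols <- c("auc_intake", "pr_alp", "habit_ratio", "quinine_auc")
  check_columns(measures, c("animal_id", cols), "measures")
  measures <- measures[stats::complete.cases(measures[cols]), , drop = FALSE]

  excluded <- character(0)
  if (isTRUE(exclude_outliers) && nrow(measures) >= 3) {
    out <- outlier_flag(measures$pr_alp, k = outlier_k)
    excluded <- as.character(measures$animal_id[out])
    measures <- measures[!out, , drop = FALSE]
  }
  if (nrow(measures) < 4) {
    stop_data("correlation_set needs at least 4 complete animals")
  }

  pairs <- utils::combn(cols, 2)
  corrected <- bonferroni_alpha(alpha, ncol(pairs))
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- measures[[pairs[1, j]]]
    b <- measures[[pairs[2, j]]]
    if (sd(a) == 0 || sd(b) == 0) {
      return(tibble::tibble(
        measure_1 = pairs[1, j], measure_2 = pairs[2, j],
        n = length(a), r = NA_real_, p = NA_real_, significant = NA
      ))
    }
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    tibble::tibble(
      measure_1 = pairs[1, j], measure_2 = pairs[2, j],
      n = length(a), r = unname(ct$estimate), p = ct$p.value,
      significant = ct$p.value < corrected
    )
  })
  structure(
    res,
    corrected_alpha = corrected,
    alpha = alpha,
    excluded = excluded,
    class = c("ghbsa_correlation_set", class(res))
  )
}

#' @export
print.ghbsa_correlation_set <- function(x, ...) {
  cat(sprintf(
    "Correlation set: %d pairs, corrected alpha = %.4f\n",
    nrow(x), attr(x, "corrected_alpha")
  ))
  if (length(attr(x, "excluded")) > 0) {
    cat("Excluded (motivation outlier):",
        paste(attr(x, "excluded"), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Baseline-anxiety regression on home-cage intake
#'
#' Ordinary least squares with the 3-month home-cage intake AUC as the
#' dependent variable and the relative time spent in the closed arms of the
#' elevated plus maze (baseline anxiety) as the predictor; the slope is
#' tested two-sided.
#'
#' @param data Tibble containing the two columns below.
#' @param intake_col Name of the intake-AUC column (default `"auc_intake"`).
#' @param predictor_col Name of the closed-arm-fraction column (default
#'   `"closed_fraction"`).
#' @return Object of class `ghbsa_anxiety_regression` wrapping the `lm`
#'   fit; `tidy()` and `glance()` give slope/intercept and fit summaries.
#' @export
anxiety_regression <- function(data, intake_col = "auc_intake",
                               predictor_col = "closed_fraction") {
  check_columns(data, c(intake_col, predictor_col), "data")
  df <- tibble::tibble(
    y = data[[intake_col]], x = data[[predictor_col]]
  )
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < 3) stop_data("anxiety_regression needs at least 3 animals")
  if (sd(df$x) == 0) stop_data("predictor (closed-arm fraction) is constant")
  fit <- lm(y ~ x, data = df)
  structure(
    list(fit = fit, n = nrow(df),
         intake_col = intake_col, predictor_col = predictor_col),
    class = "ghbsa_anxiety_regression"
  )
}

#' @export
print.ghbsa_anxiety_regression <- function(x, ...) {
  s <- summary(x$fit)
  cat(sprintf(
    "Anxiety regression (%s ~ %s), n = %d\n  slope = %.3f (p = %.3g), R^2 = %.3f\n",
    x$intake_col, x$predictor_col, x$n,
    coef(x$fit)[2], s$coefficients[2, 4], s$r.squared
  ))
  invisible(x)
}

#' @rdname anxiety_regression
#' @param x A `ghbsa_anxiety_regression` object.
#' @param ... Unused.
#' @export
tidy.ghbsa_anxiety_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std_error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p_value = unname(s[, 4])
  )
}

#' @rdname anxiety_regression
#' @export
glance.ghbsa_anxiety_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n = x$n,
    r_squared = s$r.squared,
    slope = unname(coef(x$fit)[2]),
    p_value = unname(s$coefficients[2, 4]),
    sigma = s$sigma
  )
}

#' Scatter plot of a correlation-set pair
#'
#' @param object A `ghbsa_correlation_set`.
#' @param measures The measures tibble the set was computed from.
#' @param pair Integer row index of the pair to plot (default: smallest p).
#' @param ... Unused.
#' @return A ggplot with a least-squares line and 95% confidence band.
#' @export
autoplot.ghbsa_correlation_set <- function(object, measures, pair = NULL,
                                           ...) {
  pair <- pair %||% which.min(object$p)
  m1 <- object$measure_1[pair]
  m2 <- object$measure_2[pair]
  keep <- !(as.character(measures$animal_id) %in% attr(object, "excluded"))
  df <- measures[keep, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[m1]], y = .data[[m2]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(
      title = sprintf("%s vs %s: r = %.2f, p = %.4f",
                      m1, m2, object$r[pair], object$p[pair]),
      x = m1, y = m2
    ) +
    ggplot2::theme_minimal()
}
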