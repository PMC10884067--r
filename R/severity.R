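# Addiction-severity classification: z-normalise the four addiction-like
# measures, sum every leave-one-out triple, flag the top quartile per
# combination, count per-animal consistency.

#' Z-normalise a measure across animals
#'
#' Subtracts the group mean and divides by the group standard deviation
#' (sample SD, n - 1 denominator).
#'
#' @param x Numeric vector, one value per animal (n >= 2).
#' @param name Measure name used in error messages.
#' @return Z-scores with mean 0 and sample SD 1.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2) stop_data("zscore needs at least 2 animals")
  if (anyNA(x)) stop_data(sprintf("measure `%s` has missing values", name))
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop_data(sprintf("measure `%s` is degenerate (zero SD)", name))
  }
  (x - mean(x)) / s
}

#' Three-of-four combination sums
#'
#' For each of the four leave-one-out triples of measures, the per-animal
#' sum of the three z-scores. Combination `j` drops measure `j` (columns in
#' input order).
#'
#' @param z Numeric matrix or data frame, animals x 4 z-scored measures.
#' @return Matrix animals x 4; column `j` named `drop_<measure j>`.
#' @export
combination_sums <- function(z) {
  z <- as.matrix(z)
  if (ncol(z) != 4) stop_data("combination_sums requires exactly 4 measures")
  if (anyNA(z)) {
    bad <- which(rowSums(is.na(z)) > 0)
    stop_data(paste(
      "missing z-scores for animal row(s):", paste(bad, collapse = ", ")
    ))
  }
  nms <- colnames(z) %||% paste0("m", 1:4)
  out <- matrix(
    vapply(1:4, function(j) rowSums(z[, -j, drop = FALSE]),
           numeric(nrow(z))),
    nrow = nrow(z), ncol = 4
  )
  colnames(out) <- paste0("drop_", nms)
  rownames(out) <- rownames(z)
  out
}

#' Top-quartile flags per combination
#'
#' Flags, for every combination, the `floor(q * n)` animals with the largest
#' combination sums (n = 3 of 12 at the default quartile). Ties at the
#' cutoff are broken by the higher raw (unnormalised) total of the same
#' triple, then by lexicographic animal id; tie-break events are recorded in
#' the `"ties"` attribute and messaged.
#'
#' @param sums Animals x 4 matrix of combination sums ([combination_sums()]).
#' @param raw_sums Optional animals x 4 matrix of raw-measure triple totals
#'   used as first tie-breaker.
#' @param ids Animal identifiers (default row names or row index).
#' @param q Flagged fraction (default 0.25).
#' @return Logical matrix animals x 4, each column with exactly
#'   `floor(q * n)` `TRUE`s; attribute `"ties"` lists tie-break events.
#' @export
top_quartile_flags <- function(sums, raw_sums = NULL, ids = NULL, q = 0.25) {
  sums <- as.matrix(sums)
  n <- nrow(sums)
  if (n < 4) stop_data("top_quartile_flags needs at least 4 animals")
  ids <- ids %||% rownames(sums) %||% sprintf("animal_%03d", seq_len(n))
  k <- floor(q * n)
  flags <- matrix(FALSE, n, ncol(sums),
                  dimnames = list(ids, colnames(sums)))
  ties <- character(0)
  for (j in seq_len(ncol(sums))) {
    tie_raw <- if (is.null(raw_sums)) rep(0, n) else as.numeric(raw_sums[, j])
    ord <- order(-sums[, j], -tie_raw, ids)
    chosen <- ord[seq_len(k)]
    if (k > 0 && k < n) {
      cut_val <- sums[ord[k], j]
      if (any(abs(sums[ord[(k + 1):n], j] - cut_val) < .Machine$double.eps^0.5)) {
        ties <- c(ties, sprintf(
          "combination %s: tie at the quartile cutoff resolved by raw total, then animal id",
          colnames(sums)[j] %||% j
        ))
      }
    }
    flags[chosen, j] <- TRUE
  }
  if (length(ties) > 0) inform(paste(ties, collapse = "\n"))
  attr(flags, "ties") <- ties
  flags
}

#' Per-animal consistency count
#'
#' Number of combinations (0-4) in which an animal sits in the top quartile.
#'
#' @param flags Logical animals x 4 matrix from [top_quartile_flags()].
#' @return Integer vector, one count per animal.
#' @export
consistency_count <- function(flags) {
  as.integer(rowSums(as.matrix(flags)))
}

#' Flag outliers deviating from the group mean
#'
#' An animal is an outlier on a measure if it deviates more than `k`
#' standard deviations (sample SD, computed including the candidate) from
#' the group mean.
#'
#' @param x Numeric vector, one value per animal (n >= 3).
#' @param k SD multiplier (default 2).
#' @return Logical vector.
#' @export
outlier_flag <- function(x, k = 2) {
  if (length(x) < 3) stop_data("outlier_flag needs at least 3 animals")
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - mean(x)) > k * s
}

#' Addiction-severity table
#'
#' Full severity classification from the four addiction-like measures:
#' home-cage intake AUC, progressive-ratio active lever presses, habit
#' ratio, and quinine intake AUC. Measures are z-normalised, summed over
#' every three-of-four combination, the top quartile of each combination is
#' flagged, and the per-animal consistency (0-4) is counted. Animals with
#' any missing measure are dropped (with a message) rather than imputed.
#'
#' @param measures Tibble with `animal_id` and numeric columns `auc_intake`,
#'   `pr_alp`, `habit_ratio`, `quinine_auc`.
#' @param q Flagged fraction per combination (default 0.25).
#' @return An object of class `ghbsa_severity`; see [tidy.ghbsa_severity()]
#'   and [glance.ghbsa_severity()].
#' @export
severity_table <- function(measures, q = 0.25) {
  cols <- c("auc_intake", "pr_alp", "habit_ratio", "quinine_auc")
  check_columns(measures, c("animal_id", cols), "measures")
  complete <- stats::complete.cases(measures[cols])
  dropped <- measures$animal_id[!complete]
  if (length(dropped) > 0) {
    inform(paste(
      "severity_table: dropping animal(s) with missing measures:",
      paste(dropped, collapse = ", ")
    ))
  }
  measures <- measures[complete, , drop = FALSE]
  if (nrow(measures) < 4) {
    stop_data("severity_table needs at least 4 complete animals")
  }

  raw <- as.matrix(measures[cols])
  rownames(raw) <- measures$animal_id
  z <- vapply(cols, function(cc) zscore(raw[, cc], cc), numeric(nrow(raw)))
  rownames(z) <- measures$animal_id
  sums <- combination_sums(z)
  raw_sums <- combination_sums(raw) # raw triple totals, tie-breaking only
  flags <- top_quartile_flags(sums, raw_sums = raw_sums,
                              ids = measures$animal_id, q = q)
  tie_log <- attr(flags, "ties")
  attr(flags, "ties") <- NULL
  structure(
    list(
      measures = tibble::as_tibble(measures),
      z = z,
      combo_sums = sums,
      flags = flags,
      consistency = tibble::tibble(
        animal_id = measures$animal_id,
        consistency = consistency_count(flags)
      ),
      q = q,
      k = floor(q * nrow(measures)),
      dropped = as.character(dropped),
      tie_breaks = tie_log,
      metadata = list(
        sd_denominator = "n-1 (sample SD)",
        quartile_size = "floor(q * n)",
        tie_break = "combination sum, then raw triple total, then animal_id"
      )
    ),
    class = "ghbsa_severity"
  )
}

#' @export
print.ghbsa_severity <- function(x, ...) {
  cat(sprintf(
    "Addiction-severity table: %d animals, top-%d flagged per combination\n",
    nrow(x$measures), x$k
  ))
  tab <- table(factor(x$consistency$consistency, levels = 0:4))
  cat("Consistency counts (0-4):",
      paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

#' Tidy an addiction-severity table
#'
#' @param x A `ghbsa_severity` object.
#' @param ... Unused.
#' @return One row per animal: the four raw measures, their z-scores
#'   (`z_*`), per-combination quartile flags (`flag_drop_*`), and the
#'   consistency count.
#' @export
tidy.ghbsa_severity <- function(x, ...) {
  z <- tibble::as_tibble(x$z, .name_repair = ~ paste0("z_", .x))
  fl <- tibble::as_tibble(x$flags, .name_repair = ~ paste0("flag_", .x))
  dplyr::bind_cols(x$measures, z, fl) |>
    dplyr::left_join(x$consistency, by = "animal_id")
}

#' One-row summary of a severity classification
#'
#' @param x A `ghbsa_severity` object.
#' @param ... Unused.
#' @return Tibble with `n_animals`, `n_flagged_per_combination`, counts per
#'   consistency level and the fraction never flagged.
#' @export
glance.ghbsa_severity <- function(x, ...) {
  cons <- x$consistency$consistency
  tibble::tibble(
    n_animals = length(cons),
    n_flagged_per_combination = x$k,
    n_consistency_4 = sum(cons == 4),
    n_consistency_3 = sum(cons == 3),
    n_consistency_2 = sum(cons == 2),
    n_consistency_1 = sum(cons == 1),
    n_consistency_0 = sum(cons == 0),
    frac_not_classified = mean(cons == 0)
  )
}

#' Plot the distribution of addiction-severity consistency
#'
#' @param object A `ghbsa_severity` object.
#' @param ... Unused.
#' @return A ggplot: count of animals at each consistency level (0-4).
#' @export
autoplot.ghbsa_severity <- function(object, ...) {
  df <- object$consistency |>
    dplyr::mutate(consistency = factor(.data$consistency, levels = 0:4))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$consistency)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(
      x = "severity-score computations in which the animal is top quartile",
      y = "number of animals",
      title = "Addiction-severity consistency"
    ) +
    ggplot2::theme_minimal()
}
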