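# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's vectorised code paths:
# explicit loops, explicit sorts.

# Brute-force severity classification: explicit loops over the four
# leave-one-out triples and an explicit sorted quartile selection with the
# same tie-break policy (combination sum, then raw triple total, then id).
brute_severity <- function(measures, q = 0.25) {
  cols <- c("auc_intake", "pr_alp", "habit_ratio", "quinine_auc")
  X <- as.matrix(measures[cols])
  ids <- as.character(measures$animal_id)
  n <- nrow(X)
  Z <- matrix(0, n, 4)
  for (j in 1:4) {
    m <- sum(X[, j]) / n
    s <- sqrt(sum((X[, j] - m)^2) / (n - 1))
    Z[, j] <- (X[, j] - m) / s
  }
  sums <- matrix(0, n, 4)
  raws <- matrix(0, n, 4)
  for (j in 1:4) {
    keep <- setdiff(1:4, j)
    for (i in 1:n) {
      sums[i, j] <- sum(Z[i, keep])
      raws[i, j] <- sum(X[i, keep])
    }
  }
  k <- floor(q * n)
  flags <- matrix(FALSE, n, 4)
  for (j in 1:4) {
    ord <- order(-sums[, j], -raws[, j], ids)
    if (k > 0) flags[ord[1:k], j] <- TRUE
  }
  cons <- integer(n)
  for (i in 1:n) cons[i] <- sum(flags[i, ])
  list(z = Z, sums = sums, flags = flags, consistency = cons)
}

# Random four-measure table on plausible scales.
random_measures <- function(n = 12) {
  tibble::tibble(
    animal_id = sprintf("rat_%03d", seq_len(n)),
    auc_intake = stats::runif(n, 30000, 90000),
    pr_alp = stats::runif(n, 10, 90),
    habit_ratio = stats::runif(n, 0.2, 1.4),
    quinine_auc = stats::runif(n, 0, 60)
  )
}

# Event-log builder.
ev <- function(t, kind) tibble::tibble(t = t, kind = kind)

press_log <- function(times) ev(times, rep("active_press", length(times)))

# A trait row sufficient for the simulate_* entry points.
fake_trait <- function(animal_id = "rat_901", sex = "male", group = "drug",
                       susceptibility = 0.5, daily_dose_mean = 800,
                       preference_target = 20, press_rate = 0.01,
                       quinine_ic50 = 0.2, nr_persistence = 0.8,
                       di_pre = 0.35, di_post = 0.35,
                       closed_frac_pre = 0.5, closed_frac_post = 0.5) {
  tibble::tibble(
    animal_id = animal_id, sex = sex, group = group,
    susceptibility = susceptibility, daily_dose_mean = daily_dose_mean,
    preference_target = preference_target, press_rate = press_rate,
    quinine_ic50 = quinine_ic50, nr_persistence = nr_persistence,
    di_pre = di_pre, di_post = di_post,
    closed_frac_pre = closed_frac_pre, closed_frac_post = closed_frac_post
  )
}
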