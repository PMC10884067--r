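test_that("z-scores use the sample SD and centre to zero", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  x <- rnorm(15, 50, 9)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sd(z), 1)
  expect_error(zscore(c(5, 5, 5), "pr_alp"), "pr_alp")
  expect_error(zscore(3), class = "ghbsa_data_error")
})

test_that("combination sums enumerate the four leave-one-out triples", {
  z1 <- matrix(1, 1, 4)
  expect_equal(unname(combination_sums(z1))[1, ], rep(3, 4))
  z2 <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(unname(combination_sums(z2))[1, ], c(0, 1, 1, 1))
  set.seed(3)
  z <- matrix(rnorm(16), 4, 4)
  brute <- matrix(0, 4, 4)
  for (j in 1:4) for (i in 1:4) brute[i, j] <- sum(z[i, setdiff(1:4, j)])
  expect_equal(unname(combination_sums(z)), brute)
  expect_error(combination_sums(matrix(1, 2, 3)), class = "ghbsa_data_error")
})

test_that("top-quartile flags select floor(q n) animals per combination", {
  set.seed(4)
  s12 <- matrix(rnorm(48), 12, 4)
  f12 <- top_quartile_flags(s12)
  expect_equal(unname(colSums(f12)), rep(3, 4))
  s8 <- matrix(rnorm(32), 8, 4)
  expect_equal(unname(colSums(top_quartile_flags(s8))), rep(2, 4))
  s4 <- matrix(c(0, 0, 0, 10), 4, 4)
  f4 <- top_quartile_flags(s4)
  expect_true(all(f4[4, ]))
  expect_equal(sum(f4), 4)
  expect_error(top_quartile_flags(matrix(1, 3, 4)),
               class = "ghbsa_data_error")
})

test_that("quartile ties resolve by raw total then animal id", {
  sums <- matrix(c(5, 1, 1, 0), 4, 4) # three-way tie below the top
  raw <- matrix(c(0, 2, 9, 0), 4, 4) # row 3 wins the tie on raw total
  f <- suppressMessages(
    top_quartile_flags(sums, raw_sums = raw, ids = sprintf("r%d", 1:4))
  )
  expect_true(all(f[1, ]))
  expect_false(any(f[2, ]))
  expect_false(any(f[4, ]))
  expect_length(attr(f, "ties"), 0) # k = 1: the tie sits below the cutoff
  # with k = 2 the tie crosses the cutoff: raw total decides, and the
  # event is logged
  f2 <- suppressMessages(
    top_quartile_flags(sums, raw_sums = raw, ids = sprintf("r%d", 1:4),
                       q = 0.5)
  )
  expect_true(all(f2[3, ]))
  expect_gt(length(attr(f2, "ties")), 0)
})

test_that("consistency counts combinations flagged per animal", {
  f <- rbind(rep(TRUE, 4), rep(FALSE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(consistency_count(f), c(4L, 0L, 2L))
})

test_that("outlier rule flags > k SD deviation from the group mean", {
  # a single extreme value among 12 (with the candidate included in mean
  # and SD, an extreme can exceed 2 SD only when n is large enough:
  # max |z| = (n - 1) / sqrt(n))
  x <- c(rep(1, 11), 100)
  expect_identical(outlier_flag(x), c(rep(FALSE, 11), TRUE))
  # direct check of the rule
  expect_identical(outlier_flag(x), abs(x - mean(x)) > 2 * sd(x))
  expect_false(any(outlier_flag(rep(3, 6))))
  expect_false(any(outlier_flag(rnorm(10), k = Inf)))
  expect_error(outlier_flag(c(1, 2)), class = "ghbsa_data_error")
})

test_that("severity pipeline matches the brute-force oracle", {
  set.seed(10)
  for (i in 1:25) {
    m <- random_measures(12)
    sv <- severity_table(m)
    br <- brute_severity(m)
    expect_equal(unname(sv$z), br$z)
    expect_equal(unname(sv$combo_sums), br$sums)
    expect_equal(unname(sv$flags), br$flags)
    expect_identical(sv$consistency$consistency, as.integer(br$consistency))
  }
})

test_that("severity is permutation-equivariant and scale-invariant", {
  set.seed(11)
  m <- random_measures(12)
  sv <- severity_table(m)
  perm <- sample(12)
  sv_p <- severity_table(m[perm, ])
  expect_equal(sv_p$consistency$consistency,
               sv$consistency$consistency[perm])
  # affine rescaling of any raw measure leaves the classification unchanged
  m2 <- dplyr::mutate(m, pr_alp = 1000 * pr_alp + 77,
                      auc_intake = auc_intake / 3 - 5)
  sv2 <- severity_table(m2)
  expect_equal(sv2$z, sv$z)
  expect_identical(sv2$consistency, sv$consistency)
})

test_that("severity drops animals with missing measures and reports them", {
  m <- random_measures(6)
  m$pr_alp[2] <- NA
  expect_message(sv <- severity_table(m), "rat_002")
  expect_equal(nrow(sv$measures), 5)
  expect_identical(sv$dropped, "rat_002")
})

test_that("tidy and glance summarise the severity object", {
  set.seed(12)
  sv <- suppressMessages(severity_table(random_measures(12)))
  td <- tidy(sv)
  expect_equal(nrow(td), 12)
  expect_true(all(c("z_pr_alp", "flag_drop_pr_alp", "consistency") %in%
                    names(td)))
  gl <- glance(sv)
  expect_equal(gl$n_animals, 12)
  expect_equal(gl$n_flagged_per_combination, 3)
  expect_equal(
    gl$n_consistency_0 + gl$n_consistency_1 + gl$n_consistency_2 +
      gl$n_consistency_3 + gl$n_consistency_4, 12
  )
  expect_s3_class(autoplot(sv), "ggplot")
})
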