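test_that("median split partitions at the sample median with >= ties", {
  sp <- median_split(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  expect_equal(sp$median, 2.5)
  expect_equal(sp$ge_ids, c("c", "d"))
  expect_equal(sp$lt_ids, c("a", "b"))
  # 97 distinct values: 49 at-or-above, 48 below
  set.seed(8)
  v <- rnorm(97)
  sp97 <- median_split(v)
  expect_equal(length(sp97$ge_ids), 49)
  expect_equal(length(sp97$lt_ids), 48)
  # partition-complete and idempotent under re-split of the same data
  expect_setequal(c(sp97$ge_ids, sp97$lt_ids), seq_len(97))
  expect_identical(sp97, median_split(v))
  # ties at the median go to the ">=" group
  spt <- median_split(c(1, 2, 2, 2, 5))
  expect_equal(length(spt$ge_ids), 4)
  expect_error(median_split(rep(3, 10)), "degenerate")
  expect_error(median_split(7), "at least 2")
})

test_that("group comparison gates on normality and reports moments", {
  set.seed(21)
  x <- rnorm(49)
  y <- rnorm(48, mean = 2)
  cmp <- compare_groups(x, y)
  expect_s3_class(cmp, "subgroup_comparison")
  expect_equal(cmp$group_ge$n + cmp$group_lt$n, 97)
  expect_equal(cmp$group_ge$mean, mean(x))
  expect_equal(cmp$group_lt$sd, sd(y))
  expect_true(cmp$significant)
  # identical non-constant samples: p = 1, not significant
  same <- compare_groups(x, x)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # grossly non-normal data routes to the rank test
  skewed <- compare_groups(exp(rnorm(49, sd = 2)), exp(rnorm(48, sd = 2)))
  expect_equal(skewed$test_used, "mann_whitney_u")
  expect_error(compare_groups(x, c(1, 2)), "< median")
})

test_that("the Shapiro-Wilk gate fires at the expected rates", {
  set.seed(3001)
  reps <- 1000
  t_normal <- 0
  mwu_skewed <- 0
  for (i in seq_len(reps)) {
    cmp_n <- compare_groups(rnorm(49), rnorm(48))
    if (cmp_n$test_used == "student_t") t_normal <- t_normal + 1
    cmp_s <- compare_groups(exp(rnorm(49)), exp(rnorm(48)))
    if (cmp_s$test_used == "mann_whitney_u") mwu_skewed <- mwu_skewed + 1
  }
  # both groups pass an alpha = 0.05 screen about (1 - 0.05)^2 of the time
  expect_equal(t_normal / reps, 0.95^2, tolerance = 0.04)
  expect_gt(mwu_skewed / reps, 0.90)
})

test_that("the gated procedure keeps its type-I error near nominal", {
  set.seed(1402)
  reps <- 1000
  rej_normal <- 0
  rej_lognormal <- 0
  for (i in seq_len(reps)) {
    if (compare_groups(rnorm(49), rnorm(48))$significant) {
      rej_normal <- rej_normal + 1
    }
    if (compare_groups(rlnorm(49), rlnorm(48))$significant) {
      rej_lognormal <- rej_lognormal + 1
    }
  }
  expect_gt(rej_normal / reps, 0.03)
  expect_lt(rej_normal / reps, 0.07)
  expect_gt(rej_lognormal / reps, 0.03)
  expect_lt(rej_lognormal / reps, 0.07)
})

test_that("the procedure detects the reported volume-index effect size", {
  # normal draws at the subgroup summary statistics of the strongest
  # median-split contrast; analytic power at these settings is ~0.98
  set.seed(555)
  rej <- 0
  reps <- 400
  for (i in seq_len(reps)) {
    if (compare_groups(rnorm(49, 37.66, 11.63),
                       rnorm(48, 28.40, 10.53))$significant) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.95)
})

test_that("correlation table matches a two-pass covariance oracle", {
  d <- derive_indices(generate_cohort(default_spec(seed = 12)))
  tab <- correlation_table(d)
  expect_equal(dim(tab), c(4, 3))
  expect_true(all(tab >= -1 & tab <= 1))
  two_pass_r <- function(x, y) {
    cx <- x - mean(x); cy <- y - mean(y)
    sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  }
  for (i in rownames(tab)) {
    for (j in colnames(tab)) {
      expect_equal(tab[i, j], two_pass_r(d[[i]], d[[j]]), tolerance = 1e-12)
    }
  }
  # exact linear relationships
  d2 <- d
  d2$eat_thickness <- 2 * d2$ao_stiffness_index + 1
  d2$eat_volume <- -3 * d2$ao_stiffness_index + 5
  tab2 <- correlation_table(d2)
  expect_equal(tab2["eat_thickness", "ao_stiffness_index"], 1)
  expect_equal(tab2["eat_volume", "ao_stiffness_index"], -1)
  # zero-variance column is an explicit error
  d3 <- d
  d3$eat_volume <- 7
  expect_error(correlation_table(d3), "zero variance")
  # Spearman option is rank-based
  expect_equal(correlation_table(d, "spearman")[1, 1],
               cor(d$eat_thickness, d$ao_stiffness_index,
                   method = "spearman"))
})

test_that("descriptive table summarises quantitative and categorical fields", {
  d <- derive_indices(generate_cohort(default_spec(seed = 4)))
  tab <- descriptive_table(d)
  expect_equal(tab$quantitative$mean[tab$quantitative$variable == "age"],
               mean(d$age))
  expect_equal(sum(tab$categorical$n), 97)
  expect_equal(sum(tab$categorical$percent), 100)
  # single record: SD undefined
  one <- descriptive_table(d[1, ])
  expect_true(all(is.na(one$quantitative$sd)))
  # constant column: SD zero
  dc <- d
  dc$age <- 60
  tabc <- descriptive_table(dc)
  expect_equal(tabc$quantitative$sd[tabc$quantitative$variable == "age"], 0)
})

test_that("subgroup table covers every split/outcome pair consistently", {
  d <- derive_indices(generate_cohort(default_spec(seed = 12)))
  tab <- subgroup_table(d, split_vars = c("eat_volume_index"),
                        outcome_vars = c("ao_stiffness_index", "ao_strain"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$n_ge + tab$n_lt, rep(97L, 2))
  expect_equal(tab$split_median, rep(median(d$eat_volume_index), 2))
  # means agree with a direct subgroup computation
  ge <- d$eat_volume_index >= median(d$eat_volume_index)
  expect_equal(tab$mean_ge[1], mean(d$ao_stiffness_index[ge]))
  expect_equal(tab$mean_lt[2], mean(d$ao_strain[!ge]))
  expect_true(all(tab$test_used %in% c("student_t", "mann_whitney_u")))
})
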