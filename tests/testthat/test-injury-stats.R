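test_that("the packaged cohort parses to the published structure", {
  co <- cohort_table1()
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 17)
  expect_equal(sum(co$armor), 6)
  expect_equal(sum(!co$armor), 11)

  # remark parsing: animal 12 carries lung hemorrhage only
  a12 <- co[co$id == 12, ]
  expect_true(a12$LH)
  expect_false(any(unlist(a12[c("hemothorax", "splenic", "liver", "IAH",
                                "BR")])))
  # the '&'-joined remark of animal 17 yields both splenic and liver flags
  a17 <- co[co$id == 17, ]
  expect_true(a17$splenic && a17$liver && a17$BR && a17$IAH)

  # structural law of the cohort: every death follows respiratory arrest
  expect_true(all(co$respiratory_arrest[co$outcome == "Death"]))
})

test_that("cohort parsing errors are informative", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,body_weight_kg,body_armor,respiratory_arrest,outcome",
               "1,38,No,No,Survival"), f)
  expect_error(read_cohort(f), "organ_damage")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,body_weight_kg,body_armor,organ_damage,respiratory_arrest,outcome",
               "1,38,No,LH,No,Survival",
               "1,39,No,LH,No,Survival"), f2)
  expect_error(read_cohort(f2), "duplicate")

  # empty data section parses to an empty cohort
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,body_weight_kg,body_armor,organ_damage,respiratory_arrest,outcome",
             f3)
  expect_equal(nrow(read_cohort(f3)), 0)
})

test_that("contingency tabulation reproduces the published tables", {
  co <- cohort_table1()
  t2 <- tabulate_2x2(co, !respiratory_arrest, outcome == "Survival")
  expect_equal(unclass(t2)[1:4], c(9L, 3L, 0L, 5L))  # column-major

  ta <- tabulate_2x2(co, armor, outcome == "Survival")
  expect_equal(unclass(ta)[1:4], c(6L, 6L, 0L, 5L))

  empty <- co[0, ]
  t0 <- tabulate_2x2(empty, armor, outcome == "Survival")
  expect_true(all(t0 == 0))
})

test_that("fisher exact matches enumeration, the base oracle, and symmetry", {
  t2 <- matrix(c(9, 0, 3, 5), 2, byrow = TRUE)
  res <- fisher_exact(t2)
  expect_equal(round(res$p_value, 3), 0.009)

  # brute-force enumeration oracle on assorted small tables
  set.seed(7)
  for (k in 1:25) {
    m <- matrix(stats::rpois(4, 3), 2)
    if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p_value, enumerate_fisher_p(m),
                 tolerance = 1e-12)
    # independent cross-check against the stock implementation
    expect_equal(fisher_exact(m)$p_value, stats::fisher.test(m)$p.value,
                 tolerance = 1e-7)
    # invariance to row and column swaps
    expect_equal(fisher_exact(m)$p_value,
                 fisher_exact(m[2:1, ])$p_value, tolerance = 1e-12)
    expect_equal(fisher_exact(m)$p_value,
                 fisher_exact(m[, 2:1])$p_value, tolerance = 1e-12)
  }

  # perfectly balanced table
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # degenerate margin flagged with p = 1
  deg <- fisher_exact(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
  # zero-cell odds ratio escapes to infinity
  expect_equal(fisher_exact(matrix(c(9, 0, 3, 5), 2, byrow = TRUE))$odds_ratio,
               Inf)
})

test_that("survival summary reports the published group rates and counts", {
  co <- cohort_table1()
  s <- survival_summary(co)
  armor <- s$by_group[s$by_group$group == "armor", ]
  ctrl <- s$by_group[s$by_group$group == "non_armor", ]
  expect_equal(armor$survival_pct, 100)
  expect_equal(ctrl$survivors, 6)
  expect_equal(ctrl$n, 11)
  expect_equal(ctrl$survival_pct, 55)  # 6/11 rounded half away from zero

  expect_equal(sum(co$splenic & co$IAH), 14)
  expect_equal(s$organ_counts$count[s$organ_counts$flag == "LH"], 17L)
  expect_equal(s$n_arrest, 8)
  expect_equal(s$n_recovered, 3)
  expect_equal(round(s$mean_body_weight_kg), 38)
})

test_that("split-plot ANOVA agrees with the cell-means oracle", {
  set.seed(11)
  make_design <- function(n_per_group, k) {
    expand.grid(subject = seq_len(2 * n_per_group), time = seq_len(k)) |>
      transform(group = ifelse(subject <= n_per_group, "A", "B"),
                value = stats::rnorm(2 * n_per_group * k) +
                  as.numeric(subject) * 0.3)
  }
  for (rep in 1:3) {
    d <- make_design(n_per_group = 4 + rep, k = 3 + rep)
    fit <- rm_anova(d)
    orc <- splitplot_oracle(d)
    td <- tidy(fit)
    expect_equal(td$statistic[td$effect == "group"], orc$F_group,
                 tolerance = 1e-9)
    expect_equal(td$statistic[td$effect == "time"], orc$F_time,
                 tolerance = 1e-9)
    expect_equal(td$statistic[td$effect == "group:time"], orc$F_gt,
                 tolerance = 1e-9)
  }
})

test_that("duplicated groups give a null group effect and censoring warns", {
  k <- 5; n <- 6
  base <- expand.grid(subject = seq_len(n), time = seq_len(k))
  base$value <- stats::rnorm(nrow(base), mean = base$time)
  d <- rbind(transform(base, group = "A"),
             transform(base, subject = subject + n, group = "B",
                       value = base$value))  # identical values per subject
  fit <- rm_anova(d)
  expect_lt(abs(tidy(fit)$statistic[1]), 1e-8)

  d2 <- d[!(d$subject == 1 & d$time > 1), ]
  expect_warning(rm_anova(d2), "< 2 timepoints")
})

test_that("pooled t-test matches the closed form and handles degeneracy", {
  x <- c(1.1, 2.3, 3.1); y <- c(2.0, 2.2, 4.0)
  r <- two_group_t(x, y)
  sp2 <- (2 * stats::var(x) + 2 * stats::var(y)) / 4
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_manual, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_manual), 4), tolerance = 1e-12)

  same <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- two_group_t(c(1, 2, 3), c(1, 2, 3) + 50)
  expect_lt(sep$p_value, 1e-6)

  degen <- two_group_t(c(2, 2), c(5, 5))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
  eq <- two_group_t(c(2, 2), c(2, 2))
  expect_equal(eq$p_value, 1)
})
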