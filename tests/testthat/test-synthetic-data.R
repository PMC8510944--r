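test_that("cohort generation is reproducible and obeys the structural laws", {
  m <- cohort_model()
  a <- generate_cohort(m, dose = 100, seed = 99)
  b <- generate_cohort(m, dose = 100, seed = 99)
  expect_identical(a, b)                      # bit-reproducible
  expect_false(identical(a, generate_cohort(m, dose = 100, seed = 100)))

  # death implies unrecovered arrest, always; lung hemorrhage universal
  for (seed in 1:20) {
    co <- generate_cohort(m, dose = 100, seed = seed)
    dead <- co$outcome == "Death"
    expect_true(all(co$respiratory_arrest[dead]))
    expect_true(all(!co$recovered[dead]))
    expect_true(all(co$LH))
  }
  expect_error(generate_cohort(m, dose = -5), "dose")
})

test_that("forced recovery eliminates deaths", {
  m <- cohort_model(rho = 1)
  for (seed in 1:10) {
    co <- generate_cohort(m, dose = 150, seed = seed)
    expect_true(all(co$outcome == "Survival"))
  }
})

test_that("defaults are calibrated to the published outcome margins", {
  # closed-form expectation: 11 unprotected + 6 armored at the default dose
  m <- cohort_model()
  e_arrest <- 11 * arrest_probability(m, 100, FALSE) +
    6 * arrest_probability(m, 100, TRUE)
  expect_equal(e_arrest, 8, tolerance = 0.01)
  expect_equal(m$rho, 3 / 8)

  # Monte-Carlo: mean arrest count over many cohorts hits the expectation
  counts <- vapply(1:800, function(s) {
    sum(generate_cohort(m, dose = 100, seed = s)$respiratory_arrest)
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 8), 3.5 * se + 0.01)
})

test_that("no-effect models produce equal arrest rates across groups", {
  m <- cohort_model(n = 400, armor_fraction = 0.5, alpha = 1, beta1 = 0,
                    beta0 = 0)
  co <- generate_cohort(m, dose = 100, seed = 5)
  tab <- table(co$armor, co$respiratory_arrest)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("expected armor-group arrest rate rises monotonically with alpha", {
  m <- cohort_model()
  alphas <- seq(0.2, 1, by = 0.1)
  p <- vapply(alphas, function(a) {
    arrest_probability(cohort_model(alpha = a), 100, TRUE)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("the armor attenuation factor is recoverable by ML", {
  m <- cohort_model(n = 100, armor_fraction = 0.5, alpha = 0.5)
  doses <- seq(40, 160, length.out = 20)
  pooled <- purrr::map2_dfr(doses, seq_along(doses), function(d, s) {
    generate_cohort(m, dose = d, seed = 1000 + s)
  })
  fit <- recover_armor_effect(pooled)
  expect_true(fit$converged)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$alpha - 0.5), 0.08)

  td <- tidy(fit)
  expect_identical(td$term, c("beta0", "beta1", "alpha"))
})

test_that("a null dose effect flags alpha as unidentifiable", {
  m <- cohort_model(n = 200, armor_fraction = 0.5, beta1 = 0, beta0 = 0.2)
  pooled <- dplyr::bind_rows(lapply(1:10, function(s) {
    generate_cohort(m, dose = 60 + s * 10, seed = s)
  }))
  fit <- recover_armor_effect(pooled)
  expect_false(fit$identifiable)
})

test_that("physiology generation respects means, censoring and seeds", {
  co <- generate_cohort(cohort_model(), dose = 100, seed = 3)
  mdl <- physiology_model(noise_sd = c(SBP = 0, pulse = 0, SpO2 = 0,
                                       Hb = 0, PaO2 = 0, PaCO2 = 0, pH = 0))
  ph <- generate_physiology(co, mdl, seed = 1)
  # zero noise: values equal the stratum mean trajectories exactly
  for (v in names(mdl$means)) {
    sub <- ph[ph$variable == v, ]
    mu <- mdl$means[[v]]
    expect_equal(sub$value,
                 mu[cbind(match(sub$outcome, rownames(mu)),
                          as.integer(sub$time))],
                 ignore_attr = TRUE)
  }
  # the dead contribute only pre and 5 min records
  dead_ids <- co$id[co$outcome == "Death"]
  if (length(dead_ids)) {
    dead_rows <- ph[ph$id %in% dead_ids, ]
    expect_true(all(dead_rows$time %in% c("pre", "5min")))
    expect_equal(nrow(dead_rows), length(dead_ids) * 7 * 2)
  }
  # survivors have the full five
  surv <- ph[!(ph$id %in% dead_ids) & ph$variable == "pH", ]
  expect_equal(nrow(surv), sum(co$outcome == "Survival") * 5)

  phA <- generate_physiology(co, physiology_model(), seed = 7)
  phB <- generate_physiology(co, physiology_model(), seed = 7)
  expect_identical(phA, phB)
})

test_that("trace generation closes the loop with the waveform module", {
  tr <- generate_trace(peak = 90e3, t_plus = 4e-3, b = 1.1, noise_sd = 0,
                       sample_rate = 5e5, seed = 4)
  m <- trace_metrics(tr, threshold = 1e3)
  expect_equal(m$peak_pa, 90e3, tolerance = 1e-3)
  expect_equal(m$duration_s, 4e-3, tolerance = 1e-3)

  t1 <- generate_trace(seed = 12, noise_sd = 2e3)
  t2 <- generate_trace(seed = 12, noise_sd = 2e3)
  expect_identical(t1, t2)

  expect_error(generate_trace(t_plus = 1e-3, sample_rate = 5e4),
               "under-resolve")
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_cohort(cohort_model(), dose = 100, seed = 1))
  invisible(generate_trace(seed = 1))
  expect_identical(.Random.seed, before)
})
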