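test_that("cohort generation is deterministic under a fixed seed", {
  spec <- egt_cohort_spec(arms = data.frame(dose_mg_per_day = 5, n = 3,
                                            C_p0_mean = 3.42, C_RBC0 = 624),
                          sampling_days = c(0, 8, 14))
  p <- test_params()
  a <- egt_cohort(spec, p, seed = 17)
  b <- egt_cohort(spec, p, seed = 17)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- egt_cohort(spec, p, seed = 18)
  expect_false(identical(a$concentration_uM, c2$concentration_uM))
})

test_that("a degenerate spec without variability reproduces the mean model exactly", {
  spec <- egt_cohort_spec(arms = data.frame(dose_mg_per_day = 5, n = 3,
                                            C_p0_mean = 3.42, C_RBC0 = 624),
                          sampling_days = c(0, 8, 14, 28),
                          cv_baseline = 0, cv_R = 0, cv_assay = 0)
  p <- test_params()
  coh <- egt_cohort(spec, p, seed = 1)
  ref <- egt_simulate(egt_regimen(5, weeks = 4), egt_initialize(3.42, 624, p), p,
                      output_times = c(0, 8, 14, 28) * 24)
  for (sid in unique(coh$subject_id)) {
    d <- coh[coh$subject_id == sid & coh$matrix == "plasma", ]
    expect_equal(d$concentration_uM, egt_conc_at(ref, d$time_h, "plasma"),
                 tolerance = 1e-10)
  }
  # arm means of a noise-free cohort equal the deterministic trajectory
  m <- egt_cohort_means(coh)
  mp <- m[m$matrix == "rbc", ]
  expect_equal(mp$mean_concentration_uM, egt_conc_at(ref, mp$time_h, "rbc"),
               tolerance = 1e-10)
})

test_that("large-cohort baselines reproduce the specified dispersion", {
  spec <- egt_cohort_spec(arms = data.frame(dose_mg_per_day = 5, n = 500,
                                            C_p0_mean = 3.42, C_RBC0 = 624),
                          sampling_days = c(0, 8))
  p <- test_params()
  coh <- egt_cohort(spec, p, seed = 23)
  base <- coh$concentration_uM[coh$time_h == 0 & coh$matrix == "plasma"]
  expect_length(base, 500)
  se <- 1.74 / sqrt(500)
  expect_lt(abs(mean(base) - 3.42), 3 * se)
  expect_lt(abs(stats::sd(base) / 1.74 - 1), 0.15)
})

test_that("missing-at-random drops post-baseline visits only", {
  spec <- egt_cohort_spec(arms = data.frame(dose_mg_per_day = 5, n = 20,
                                            C_p0_mean = 3.42, C_RBC0 = 624),
                          sampling_days = c(0, 8, 14), p_missing = 0.3)
  coh <- egt_cohort(spec, test_params(), seed = 5)
  expect_equal(sum(coh$time_h == 0 & coh$matrix == "plasma"), 20)
  expect_lt(sum(coh$time_h > 0 & coh$matrix == "plasma"), 40)
})

test_that("cohort means feed the fit interface directly", {
  spec <- egt_cohort_spec(arms = data.frame(dose_mg_per_day = c(5, 10), n = c(4, 4),
                                            C_p0_mean = c(3.42, 3.51),
                                            C_RBC0 = c(624, 562)),
                          sampling_days = c(0, 8, 14, 28))
  coh <- egt_cohort(spec, test_params(), seed = 2)
  m <- egt_cohort_means(coh)
  expect_named(m, c("dose_mg_per_day", "time_h", "matrix",
                    "mean_concentration_uM", "sd_concentration_uM", "n"))
  expect_true(all(m$n == 4))
  expect_silent(egtpbpk:::.check_fit_data(
    m, data.frame(dose_mg_per_day = c(5, 10), C_p0 = c(3.42, 3.51),
                  C_RBC0 = c(624, 562))))
})
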