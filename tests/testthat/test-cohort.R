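test_that("Welch test matches the hand-computed statistic", {
  a <- c(0.34, 0.35, 0.33)
  b <- c(0.30, 0.31, 0.32)
  w <- welch_test(a, b)
  # independent hand evaluation of the Welch formulas
  t_hand <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$t, 3.674, tolerance = 1e-3)
  expect_equal(w$df, 4, tolerance = 1e-9)
  # identical groups: t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # antisymmetry
  w2 <- welch_test(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("delta f_soma is a simple translation-invariant difference", {
  expect_equal(delta_fsoma(list(lesion_fsoma_mean = 0.36,
                                perilesion_fsoma_mean = 0.33)), 0.03)
  expect_equal(delta_fsoma(list(lesion_fsoma_mean = 0.3,
                                perilesion_fsoma_mean = 0.3)), 0)
  d1 <- delta_fsoma(list(lesion_fsoma_mean = 0.36,
                         perilesion_fsoma_mean = 0.33))
  d2 <- delta_fsoma(list(lesion_fsoma_mean = 0.46,
                         perilesion_fsoma_mean = 0.43))
  expect_equal(d1, d2)
  expect_equal(
    delta_fsoma(list(lesion_fsoma_mean = 0.33,
                     perilesion_fsoma_mean = 0.36)), -d1)
  miss <- delta_fsoma(list(lesion_fsoma_mean = NA,
                           perilesion_fsoma_mean = 0.3))
  expect_true(is.na(miss))
  expect_true(attr(miss, "missing"))
})

test_that("cohort generation is seeded and calibrated", {
  c1 <- generate_cohort(cohort_config(seed = 5))
  c2 <- generate_cohort(cohort_config(seed = 5))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(c1$subjects$cortex_fsoma_mean,
                         c3$subjects$cortex_fsoma_mean))
  # HC sample mean near its configured population mean
  hc <- c1$subjects[c1$subjects$group == "HC", ]
  expect_lt(abs(mean(hc$cortex_fsoma_mean) - 0.34),
            3 * 0.01 / sqrt(nrow(hc)))
  # healthy controls carry no lesion burden
  expect_true(all(is.na(hc$wm_lesion_volume)))
  expect_false(any(c1$lesions$subject_id %in% hc$id))
  expect_true(all(c1$lesions$lesion_type %in%
                    c("subpial", "leukocortical")))
  expect_true(all(c1$subjects$cortex_fsoma_mean >= 0 &
                    c1$subjects$cortex_fsoma_mean <= 1))
})

test_that("cohort tables round-trip through CSV", {
  co <- generate_cohort(cohort_config(seed = 8))
  fs <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  write_cohort_csv(co, fs, fl)
  co2 <- read_cohort_csv(fs, fl)
  expect_equal(co2$subjects$cortex_fsoma_mean,
               co$subjects$cortex_fsoma_mean, tolerance = 1e-12)
  expect_equal(nrow(co2$lesions), nrow(co$lesions))
})

test_that("the lesion-wise mixed model recovers its generating contrast", {
  co <- generate_cohort(cohort_config(seed = 33))
  m <- lesionwise_model(co$lesions, co$subjects, group = "RRMS")
  ci <- m$estimate + c(-1.96, 1.96) * m$se
  expect_gt(0.03, ci[1])
  expect_lt(0.03, ci[2])
  expect_lt(m$p, 0.05)
  # sign-flip of the response negates the contrast
  fl <- co$lesions
  fl$lesion_fsoma_mean <- 2 * fl$perilesion_fsoma_mean -
    fl$lesion_fsoma_mean
  m2 <- lesionwise_model(fl, co$subjects, group = "RRMS")
  expect_equal(m2$estimate, -m$estimate, tolerance = 1e-6)
})

test_that("with no between-patient variance the mixed model matches OLS", {
  set.seed(41)
  n_sub <- 30
  subjects <- data.frame(
    id = sprintf("P%02d", 1:n_sub), group = "RRMS",
    age = round(runif(n_sub, 25, 60)),
    sex = sample(c("M", "F"), n_sub, TRUE),
    treatment = sample(c("untreated", "oral", "monoclonal"), n_sub, TRUE),
    stringsAsFactors = FALSE)
  les <- do.call(rbind, lapply(1:n_sub, function(i) {
    k <- 4
    type <- sample(c("subpial", "leukocortical"), k, TRUE)
    peri <- rep(0.33, k)
    lesion <- peri + ifelse(type == "subpial", 0.02, 0) +
      rnorm(k, 0, 0.01)  # iid noise, no subject effect
    data.frame(subject_id = subjects$id[i], lesion_type = type,
               lesion_fsoma_mean = lesion, perilesion_fsoma_mean = peri,
               stringsAsFactors = FALSE)
  }))
  m <- suppressMessages(lesionwise_model(les, subjects))
  d <- merge(les, subjects, by.x = "subject_id", by.y = "id")
  d$delta <- d$lesion_fsoma_mean - d$perilesion_fsoma_mean
  d$lesion_type <- factor(d$lesion_type,
                          levels = c("leukocortical", "subpial"))
  ols <- lm(delta ~ lesion_type + age + sex + treatment, data = d)
  expect_equal(m$estimate, unname(coef(ols)["lesion_typesubpial"]),
               tolerance = 1e-4)
})

test_that("Pearson correlation handles exact and generated relationships", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(1, 10)), "zero variance")
  # generator correlations land near their configured strengths
  co <- generate_cohort(cohort_config(seed = 44))
  r_qt1 <- pearson_corr(co$lesions$lesion_fsoma_mean, co$lesions$qT1)
  r_mts <- pearson_corr(co$lesions$lesion_fsoma_mean, co$lesions$MTsat)
  expect_lt(abs(r_qt1$r - (-0.5)), 0.1)
  expect_lt(abs(r_mts$r - 0.5), 0.1)
})

test_that("the sNfL model recovers noise-free slopes exactly", {
  co <- generate_cohort(cohort_config(seed = 9, snfl_noise_sd = 0))
  m <- suppressWarnings(snfl_model(co$subjects))
  expect_equal(m$slope_fsoma, 0.738, tolerance = 1e-6)
  expect_equal(m$slope_wm, 0.334, tolerance = 1e-6)
})

test_that("sNfL coefficients rescale exactly with their units", {
  co <- generate_cohort(cohort_config(seed = 10))
  m1 <- snfl_model(co$subjects)
  s2 <- co$subjects
  s2$wm_lesion_volume <- s2$wm_lesion_volume * 10
  m2 <- snfl_model(s2)
  expect_equal(m2$slope_wm, m1$slope_wm / 10, tolerance = 1e-9)
  expect_equal(m2$slope_fsoma, m1$slope_fsoma, tolerance = 1e-9)
})

test_that("a constant f_soma column degenerates to the reduced model", {
  co <- generate_cohort(cohort_config(seed = 12))
  s <- co$subjects
  s$cl_fsoma_mean[!is.na(s$cl_fsoma_mean)] <- 0.33
  m <- snfl_model(s)
  expect_true(is.na(m$slope_fsoma))
  expect_equal(m$delta_adj_r2, 0, tolerance = 1e-9)
  expect_equal(m$lr_p, 1, tolerance = 1e-9)
})

test_that("the full analysis pipeline runs end to end", {
  co <- generate_cohort(cohort_config(seed = 20))
  res <- suppressMessages(cohort_analysis(co))
  expect_lt(res$welch_cortex$p, 0.05)   # configured group difference
  expect_lt(res$qt1$r, 0)
  expect_gt(res$mtsat$r, 0)
  expect_false(is.null(res$snfl))
})
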