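## Synthetic patient/control cohort with the printed effect structure of
## the clinical study, and the statistical stages run on it: whole-cortex
## Welch comparison, lesion/perilesion contrasts with patient-level
## random intercepts, qMRI correlations, and the serum neurofilament
## (sNfL) linear-model variance decomposition.

#' Cohort generator configuration
#'
#' Defaults emulate the study's printed effect structure: cortical
#' f_soma 0.34 +/- 0.01 in healthy controls and 0.33 +/- 0.02 in MS, a
#' positive outer-layer offset largest in progressive MS, a negative
#' inner-layer offset in MS, a positive subpial-vs-leukocortical
#' delta-f_soma shift in relapsing-remitting MS only, and sNfL z-scores
#' built from slopes 0.334 per 10 cl white-matter lesion volume and
#' 0.738 per 5% f_soma.
#'
#' @param n_hc,n_rrms,n_pms group sizes.
#' @param fsoma_mean named means of cortical f_soma per group.
#' @param fsoma_sd named SDs per group.
#' @param outer_offset,inner_offset named per-group layer offsets added
#'   to the cortical mean.
#' @param subpial_effect named per-group delta-f_soma shift of subpial
#'   relative to leukocortical lesions.
#' @param lesion_delta baseline lesion-minus-perilesion f_soma shift.
#' @param lesion_noise_sd within-patient lesion noise SD.
#' @param subject_delta_sd SD of the per-patient random intercept of
#'   the lesion delta (the mixed model's random effect).
#' @param p_subpial probability that a cortical lesion is subpial.
#' @param lesions_lambda Poisson mean lesion count per patient with
#'   lesions.
#' @param p_has_lesions probability an MS patient has cortical lesions.
#' @param qt1_rho,mtsat_rho target correlations of lesion f_soma with
#'   qT1 and MTsat.
#' @param snfl_slope_wm,snfl_slope_fsoma sNfL z slopes per 10 cl WM
#'   lesion volume and per 5% lesion f_soma.
#' @param snfl_noise_sd residual SD of the sNfL z-score.
#' @param n_snfl number of MS patients with an sNfL measurement.
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 80, n_rrms = 98, n_pms = 56,
                          fsoma_mean = c(HC = 0.34, RRMS = 0.33, PMS = 0.33),
                          fsoma_sd = c(HC = 0.01, RRMS = 0.02, PMS = 0.02),
                          outer_offset = c(HC = 0, RRMS = 0.005,
                                           PMS = 0.010),
                          inner_offset = c(HC = 0, RRMS = -0.005,
                                           PMS = -0.005),
                          subpial_effect = c(RRMS = 0.03, PMS = 0),
                          lesion_delta = -0.01, lesion_noise_sd = 0.02,
                          subject_delta_sd = 0.005,
                          p_subpial = 0.07, lesions_lambda = 8.7,
                          p_has_lesions = 98 / 154,
                          qt1_rho = -0.5, mtsat_rho = 0.5,
                          snfl_slope_wm = 0.334, snfl_slope_fsoma = 0.738,
                          snfl_noise_sd = 1, n_snfl = 113, seed = 1L) {
  stopifnot(all(fsoma_sd > 0), n_hc >= 2, n_rrms >= 2, n_pms >= 2)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic patient/control cohort
#'
#' Draws per-subject cortical, inner- and outer-layer f_soma means,
#' white-matter lesion volumes, treatment and demographics per group,
#' then per-patient cortical lesion records (subpial/leukocortical) with
#' lesion and perilesion f_soma, correlated qT1/MTsat values, and sNfL
#' z-scores with the configured slope structure. Deterministic by seed.
#'
#' @param config a `cohort_config`.
#' @return list with `subjects` and `lesions` data.frames.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  with_seed(cfg$seed, {
    groups <- c(rep("HC", cfg$n_hc), rep("RRMS", cfg$n_rrms),
                rep("PMS", cfg$n_pms))
    n <- length(groups)
    is_ms <- groups != "HC"
    age <- round(ifelse(is_ms, stats::rnorm(n, 46, 15),
                        stats::rnorm(n, 37, 13)))
    age <- pmin(pmax(age, 18), 80)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.4, 0.6))
    treatment <- ifelse(is_ms,
                        sample(c("untreated", "oral", "monoclonal"), n,
                               replace = TRUE),
                        NA_character_)
    cortex <- stats::rnorm(n, cfg$fsoma_mean[groups], cfg$fsoma_sd[groups])
    outer <- cortex + cfg$outer_offset[groups] +
      stats::rnorm(n, 0, cfg$fsoma_sd[groups] / 2)
    inner <- cortex + cfg$inner_offset[groups] +
      stats::rnorm(n, 0, cfg$fsoma_sd[groups] / 2)
    wm_vol <- ifelse(is_ms, stats::rlnorm(n, log(8), 0.8), NA_real_)
    subjects <- data.frame(
      id = sprintf("S%03d", seq_len(n)), group = groups, age = age,
      sex = sex, treatment = treatment,
      cortex_fsoma_mean = pmin(pmax(cortex, 0), 1),
      inner_fsoma_mean = pmin(pmax(inner, 0), 1),
      outer_fsoma_mean = pmin(pmax(outer, 0), 1),
      wm_lesion_volume = wm_vol, stringsAsFactors = FALSE)

    # cortical lesions for a subset of MS patients
    les <- list()
    for (i in which(is_ms)) {
      if (stats::runif(1) > cfg$p_has_lesions) next
      k <- stats::rpois(1, cfg$lesions_lambda)
      if (k == 0) next
      type <- ifelse(stats::runif(k) < cfg$p_subpial, "subpial",
                     "leukocortical")
      peri <- subjects$cortex_fsoma_mean[i] +
        stats::rnorm(k, 0, cfg$lesion_noise_sd / 2)
      shift <- cfg$lesion_delta + stats::rnorm(1, 0, cfg$subject_delta_sd) +
        ifelse(type == "subpial", cfg$subpial_effect[groups[i]], 0) +
        stats::rnorm(k, 0, cfg$lesion_noise_sd)
      lesion <- peri + shift
      les[[length(les) + 1]] <- data.frame(
        subject_id = subjects$id[i], lesion_type = type,
        lesion_fsoma_mean = pmin(pmax(lesion, 0), 1),
        perilesion_fsoma_mean = pmin(pmax(peri, 0), 1),
        stringsAsFactors = FALSE)
    }
    lesions <- if (length(les)) do.call(rbind, les) else
      data.frame(subject_id = character(0), lesion_type = character(0),
                 lesion_fsoma_mean = numeric(0),
                 perilesion_fsoma_mean = numeric(0))
    # qMRI values correlated with lesion f_soma at the configured
    # population strengths (mixed from the pooled standardised f_soma)
    if (nrow(lesions) > 1) {
      z <- scale(lesions$lesion_fsoma_mean)[, 1]
      if (any(!is.finite(z))) z <- rep(0, nrow(lesions))
      mix <- function(rho) rho * z +
        sqrt(1 - rho^2) * stats::rnorm(nrow(lesions))
      lesions$qT1 <- 1.5 + 0.25 * mix(cfg$qt1_rho)
      lesions$MTsat <- 1.5 + 0.5 * mix(cfg$mtsat_rho)
    } else {
      lesions$qT1 <- numeric(nrow(lesions))
      lesions$MTsat <- numeric(nrow(lesions))
    }

    # per-subject lesion f_soma summary; cortex mean where no lesions
    cl_mean <- tapply(lesions$lesion_fsoma_mean, lesions$subject_id, mean)
    subjects$cl_fsoma_mean <- ifelse(
      subjects$id %in% names(cl_mean),
      as.numeric(cl_mean[subjects$id]), subjects$cortex_fsoma_mean)
    subjects$cl_fsoma_mean[!is_ms] <- NA_real_

    # sNfL z-scores for a subset of MS patients
    ms_idx <- which(is_ms)
    snfl_idx <- sample(ms_idx, min(cfg$n_snfl, length(ms_idx)))
    snfl <- rep(NA_real_, n)
    snfl[snfl_idx] <-
      cfg$snfl_slope_wm * subjects$wm_lesion_volume[snfl_idx] / 10 +
      cfg$snfl_slope_fsoma *
        (subjects$cl_fsoma_mean[snfl_idx] - 0.33) / 0.05 +
      stats::rnorm(length(snfl_idx), 0, cfg$snfl_noise_sd)
    subjects$snfl_z <- snfl
    subjects$edss <- ifelse(is_ms, round(stats::runif(n, 0, 8) * 2) / 2,
                            NA_real_)
    list(subjects = subjects, lesions = lesions)
  })
}

#' Welch's two-sample t test
#'
#' Unequal-variance comparison of two groups (two-tailed), as used for
#' the whole-cortex f_soma contrast between patients and controls.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @return list with `t`, `df` (Welch-Satterthwaite) and `p`.
#' @export
welch_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Lesion-minus-perilesion f_soma difference
#'
#' @param lesion one row of the lesion table (or a list with
#'   `lesion_fsoma_mean` and `perilesion_fsoma_mean`).
#' @return the difference, or NA with a "missing" attribute when either
#'   mean is absent.
#' @export
delta_fsoma <- function(lesion) {
  a <- lesion$lesion_fsoma_mean
  b <- lesion$perilesion_fsoma_mean
  if (is.null(a) || is.null(b) || any(is.na(c(a, b)))) {
    return(structure(NA_real_, missing = TRUE))
  }
  a - b
}

#' Lesion-wise mixed model of delta f_soma
#'
#' Random-intercept-per-patient linear model of the lesion-minus-
#' perilesion f_soma difference with lesion type, age, sex and
#' medication as fixed covariates, fitted by maximum likelihood;
#' Satterthwaite two-tailed p-values.
#'
#' @param lesions lesion table (as from [generate_cohort()]).
#' @param subjects subject table.
#' @param group optional group to restrict to ("RRMS" or "PMS").
#' @param reml fit by REML instead of ML.
#' @return list with the full coefficient table (`coefficients`) and
#'   the subpial-vs-leukocortical contrast (`estimate`, `se`, `t`,
#'   `df`, `p`).
#' @export
lesionwise_model <- function(lesions, subjects, group = NULL,
                             reml = FALSE) {
  d <- merge(lesions, subjects, by.x = "subject_id", by.y = "id")
  if (!is.null(group)) d <- d[d$group %in% group, ]
  d$delta <- d$lesion_fsoma_mean - d$perilesion_fsoma_mean
  d$lesion_type <- factor(d$lesion_type,
                          levels = c("leukocortical", "subpial"))
  if (nrow(d) < 4 || length(unique(d$lesion_type)) < 2) {
    stop("need lesions of both types to estimate the contrast")
  }
  # drop constant covariates (e.g. single-sex subsets) to avoid
  # singular designs
  covs <- c("lesion_type", "age", "sex", "treatment")
  covs <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1,
                      logical(1))]
  fml <- stats::as.formula(paste(
    "delta ~", paste(covs, collapse = " + "), "+ (1 | subject_id)"))
  fit <- lmerTest::lmer(fml, data = d, REML = reml)
  ct <- stats::coef(summary(fit))
  row <- ct["lesion_typesubpial", ]
  list(coefficients = ct,
       estimate = unname(row["Estimate"]),
       se = unname(row["Std. Error"]),
       t = unname(row["t value"]),
       df = unname(row["df"]),
       p = unname(row["Pr(>|t|)"]),
       model = fit)
}

#' Pearson correlation with a two-tailed t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return list with `r` and `p`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Serum neurofilament linear model and nested comparison
#'
#' Ordinary linear model of the sNfL z-score on lesion f_soma (scaled
#' per 5%), white-matter lesion volume (per 10 cl), MS subtype and
#' treatment, plus the f_soma-free reduced model: reports coefficients,
#' both adjusted R-squared values, their difference, and the
#' likelihood-ratio test p-value for the nested pair.
#'
#' @param subjects subject table; MS subjects with `snfl_z` are used.
#' @param fsoma_ref,fsoma_unit centring and scaling of the f_soma
#'   predictor (default: per 5% increase above 0.33).
#' @return list with `coefficients`, `slope_fsoma`, `slope_wm`,
#'   `adj_r2_full`, `adj_r2_reduced`, `delta_adj_r2`, `lr_p`, `model`.
#' @export
snfl_model <- function(subjects, fsoma_ref = 0.33, fsoma_unit = 0.05) {
  d <- subjects[subjects$group != "HC" & !is.na(subjects$snfl_z), ]
  if (nrow(d) < 5) stop("too few sNfL measurements")
  d$fsoma5 <- (d$cl_fsoma_mean - fsoma_ref) / fsoma_unit
  d$wm10 <- d$wm_lesion_volume / 10
  d$subtype <- factor(ifelse(d$group == "RRMS", "RRMS", "PMS"),
                      levels = c("RRMS", "PMS"))
  covs <- c("wm10", "subtype", "treatment")
  covs <- covs[vapply(covs, function(v) length(unique(d[[v]])) > 1,
                      logical(1))]
  # a constant f_soma column degenerates to the reduced model (NA
  # coefficient); only covariate collinearity is an error
  Xr <- stats::model.matrix(
    stats::as.formula(paste("~", paste(covs, collapse = "+"))), d)
  if (kappa(Xr) > 1e10) {
    stop(sprintf("collinear design (condition number %.2e)", kappa(Xr)))
  }
  full <- stats::lm(stats::as.formula(
    paste("snfl_z ~ fsoma5 +", paste(covs, collapse = " + "))), data = d)
  red <- stats::lm(stats::as.formula(
    paste("snfl_z ~", paste(covs, collapse = " + "))), data = d)
  lr <- as.numeric(2 * (stats::logLik(full) - stats::logLik(red)))
  lr_p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  sf <- summary(full)
  list(coefficients = stats::coef(sf),
       slope_fsoma = unname(stats::coef(full)["fsoma5"]),
       slope_wm = unname(stats::coef(full)["wm10"]),
       adj_r2_full = sf$adj.r.squared,
       adj_r2_reduced = summary(red)$adj.r.squared,
       delta_adj_r2 = sf$adj.r.squared - summary(red)$adj.r.squared,
       lr_p = lr_p, model = full)
}

#' Write the two cohort tables as CSV
#'
#' @param cohort list with `subjects` and `lesions`.
#' @param subjects_path,lesions_path output paths.
#' @export
write_cohort_csv <- function(cohort, subjects_path, lesions_path) {
  utils::write.csv(cohort$subjects, subjects_path, row.names = FALSE)
  utils::write.csv(cohort$lesions, lesions_path, row.names = FALSE)
  invisible(NULL)
}

#' Read cohort tables written by [write_cohort_csv()]
#'
#' @param subjects_path,lesions_path CSV paths.
#' @return list with `subjects` and `lesions`.
#' @export
read_cohort_csv <- function(subjects_path, lesions_path) {
  list(subjects = utils::read.csv(subjects_path, stringsAsFactors = FALSE),
       lesions = utils::read.csv(lesions_path, stringsAsFactors = FALSE))
}

#' Run the full cohort analysis
#'
#' Applies the study's statistical stages to a cohort: whole-cortex
#' Welch comparison (MS vs HC), lesion-type contrasts per group, qMRI
#' correlations in lesions, and the sNfL model.
#'
#' @param cohort list with `subjects` and `lesions`.
#' @return list of stage results.
#' @export
cohort_analysis <- function(cohort) {
  s <- cohort$subjects
  l <- cohort$lesions
  ms <- s$group != "HC"
  out <- list(
    welch_cortex = welch_test(s$cortex_fsoma_mean[ms],
                              s$cortex_fsoma_mean[!ms]),
    qt1 = pearson_corr(l$lesion_fsoma_mean, l$qT1),
    mtsat = pearson_corr(l$lesion_fsoma_mean, l$MTsat))
  out$lesion_rrms <- tryCatch(
    lesionwise_model(l, s, group = "RRMS"), error = function(e) NULL)
  out$lesion_pms <- tryCatch(
    lesionwise_model(l, s, group = "PMS"), error = function(e) NULL)
  out$snfl <- tryCatch(snfl_model(s), error = function(e) NULL)
  out
}
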