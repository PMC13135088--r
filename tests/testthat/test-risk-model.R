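make_model <- function(intercept = 0, coefs = NULL, offsets = c(F = 0, M = 0),
                       traits = c("age", "strength")) {
  cf <- setNames(rep(0, length(traits)), traits)
  if (!is.null(coefs)) cf[names(coefs)] <- coefs
  structure(list(intercept = intercept, coefficients = cf,
                 sex_offset = offsets, high_risk_threshold = 75,
                 traits = traits, calibrated = FALSE),
            class = "bct_risk_model")
}

test_that("logit and score follow the logistic algebra", {
  m <- make_model()
  x <- data.frame(sex = "F", age = 80, strength = 3000)
  expect_equal(compute_logit(m, x), 0)
  expect_equal(risk_score(m, x), 50)

  # logit ln(3) -> score 75; saturation at the extremes
  m2 <- make_model(intercept = log(3))
  expect_equal(risk_score(m2, x), 75)
  expect_equal(risk_score(make_model(intercept = 50), x), 100, tolerance = 1e-9)
  expect_equal(risk_score(make_model(intercept = -50), x), 0, tolerance = 1e-9)

  # adding delta to a sex offset adds exactly delta to that sex's logits
  m3 <- make_model(intercept = 0.4, coefs = c(age = 0.01),
                   offsets = c(F = 0.7, M = -0.2))
  xs <- data.frame(sex = c("F", "M"), age = c(70, 80), strength = 1)
  base <- make_model(intercept = 0.4, coefs = c(age = 0.01))
  expect_equal(compute_logit(m3, xs) - compute_logit(base, xs), c(0.7, -0.2))

  # hand-computed dot product on a printed configuration
  m4 <- make_model(intercept = -2, coefs = c(age = 0.05, strength = -0.001),
                   traits = c("age", "strength"))
  x4 <- data.frame(sex = "M", age = 75, strength = 4000)
  expect_equal(compute_logit(m4, x4), -2 + 0.05 * 75 - 0.001 * 4000)

  expect_error(compute_logit(m, data.frame(sex = "F", age = 70)), "strength")
  expect_error(compute_logit(m, data.frame(sex = "F", age = NA,
                                           strength = 1)), "missing")

  # display rounding is half-up to an integer
  m5 <- make_model(intercept = qlogis(0.905))
  expect_equal(risk_score(m5, x, display = TRUE), 91)
})

test_that("logistic fit recovers generating coefficients on source data", {
  # a sex-homogeneous population: both sexes share marginals and base rate,
  # so the generating model has the exact functional form the fit assumes
  # (one intercept, no sex term)
  spec <- cohort_spec(n_per_sex = c(F = 10000, M = 10000), seed = 42)
  spec$trait_means$M <- spec$trait_means$F
  spec$trait_sds$M <- spec$trait_sds$F
  spec$base_rate[] <- 0.058
  gen <- generate_cohort(spec, include_source = TRUE)
  expect_lt(abs(diff(gen$ground_truth$intercepts)), 0.02)
  src <- gen$source
  src$case <- !is.na(src$fracture_time) & src$fracture_time <= 5
  fit <- fit_logistic(src, traits = setdiff(trait_names(), "strength"))
  truth <- gen$ground_truth$coefficients_unit
  # standardised scale so the coefficients are comparable across units
  sds <- vapply(names(truth), function(t) sd(src[[t]]), numeric(1))
  err_std <- (fit$coefficients[names(truth)] - truth) * sds
  # the coefficient vector is recovered within 10% in norm; individual
  # small coefficients carry proportionally more sampling noise
  expect_lt(sqrt(sum(err_std^2)) / sqrt(sum((truth * sds)^2)), 0.10)
  expect_true(all(abs(err_std) / abs(truth * sds) < 0.25))
  expect_equal(sign(fit$coefficients[names(truth)]), sign(truth))

  # duplicating the data leaves the MLE unchanged
  fit2 <- fit_logistic(rbind(src, src),
                       traits = setdiff(trait_names(), "strength"))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-6)

  # degenerate outcomes are rejected
  src0 <- src
  src0$case <- FALSE
  expect_error(fit_logistic(src0), "one class")
  # perfect separation is caught
  sep <- src[1:200, ]
  sep$case <- sep$age > median(sep$age)
  sep$age2 <- sep$age
  expect_error(fit_logistic(sep, traits = character(0)), "separation")
})

test_that("trait selection applies the three statistical criteria", {
  gen <- small_cohort(seed = 12, F = 20000, M = 10000)
  sp <- split_development_validation(gen$table)
  dev <- recode_outcomes(sp$development, 5)

  sel <- select_traits(dev)
  expect_true(all(c("trab_cort_ratio", "intramuscular_fat", "muscle_area") %in%
                    sel$selected))
  expect_true(all(sel$audit$r2_age <= 0.25 | !sel$audit$selected))

  # a candidate collinear with strength fails the weak-correlation criterion
  dev$strength_proxy <- dev$strength * 1.01 + rnorm(nrow(dev), 0, 30)
  sel2 <- select_traits(dev, candidates = c("strength_proxy",
                                            setdiff(trait_names(), "strength")))
  aud <- sel2$audit[sel2$audit$trait == "strength_proxy", ]
  expect_gt(aud$r2_strength, 0.25)
  expect_false(aud$pass_weak_correlation)
  expect_false("strength_proxy" %in% sel2$selected)

  # pure-noise candidates are rejected by the univariate criterion
  set.seed(77)
  rejected <- 0
  for (i in 1:20) {
    dev$noise_trait <- rnorm(nrow(dev))
    s <- select_traits(dev, candidates = "noise_trait")
    if (!"noise_trait" %in% s$selected) rejected <- rejected + 1
  }
  expect_gte(rejected, 19)
})

test_that("sex-offset calibration matches the FRAX positive rate exactly in rank", {
  gen <- small_cohort(seed = 9, F = 12000, M = 6000)
  sp <- split_development_validation(gen$table)
  dev <- recode_outcomes(sp$development, 5)
  val <- recode_outcomes(sp$validation, 5)
  model <- fit_logistic(dev, select_traits(dev)$selected)
  rs <- gen$table[gen$table$random_sample, ]
  cal <- calibrate_sex_offsets(model, rs)

  for (sex in c("F", "M")) {
    rows <- rs[rs$sex == sex, ]
    target <- mean(rows$frax_hip_risk >= 3.0)
    achieved <- mean(risk_score(cal, rows) >= 75)
    expect_lte(abs(achieved - target), 1 / nrow(rows))
  }

  # calibration is rank-preserving per sex: AUC and sens/spec unchanged
  for (sex in c("F", "M")) {
    v <- val[val$sex == sex, ]
    pre <- risk_score(model, v)
    post <- risk_score(cal, v)
    expect_equal(auc(post, v$case)$auc, auc(pre, v$case)$auc)
    # the threshold maps through the same offset, so the binary rule agrees
    off <- cal$sex_offset[[sex]]
    thr_pre <- 100 * plogis(qlogis(0.75) - off)
    m_pre <- sensitivity_specificity(pre, v$case, thr_pre, "ge")
    m_post <- sensitivity_specificity(post, v$case, 75, "ge")
    expect_equal(m_post$sensitivity, m_pre$sensitivity)
    expect_equal(m_post$specificity, m_pre$specificity)
    expect_equal(order(post), order(pre))
  }

  # a target equal to the pre-calibration rate gives an offset near zero
  rs_fixed <- rs[rs$sex == "F", ]
  rate0 <- mean(risk_score(model, rs_fixed) >= 75)
  k <- round(rate0 * nrow(rs_fixed))
  rs_fixed$frax_hip_risk <- 3.0 - 1 + 2 * (rank(-compute_logit(model, rs_fixed),
                                                ties.method = "first") <= k)
  cal0 <- calibrate_sex_offsets(model, rbind(rs_fixed, rs[rs$sex == "M", ]))
  expect_lt(abs(cal0$sex_offset[["F"]]), 0.5)

  # degenerate target prevalence pins the offset at the bound with a warning
  rs_all <- rs
  rs_all$frax_hip_risk <- 99
  w <- capture_warnings(cal_hi <- calibrate_sex_offsets(model, rs_all))
  expect_match(w, "bound", all = TRUE)
  expect_length(w, 2)  # one warning per sex
  expect_equal(unname(cal_hi$sex_offset[["F"]]), 50)
})

test_that("z-score references regress traits on age with stated exclusions", {
  set.seed(31)
  n <- 5000
  rs <- data.frame(sex = rep(c("F", "M"), each = n),
                   age = runif(2 * n, 65, 89),
                   random_sample = TRUE)
  slope <- c(F = -0.6, M = -0.4)
  sigma <- c(F = 4, M = 3)
  rs$muscle_area <- 70 + slope[rs$sex] * rs$age +
    rnorm(2 * n, 0, sigma[rs$sex])
  rs$fat_thickness <- rnorm(2 * n, 20, 5)  # independent of age
  ref <- fit_zscore_reference(rs, traits = c("muscle_area", "fat_thickness"))

  rF <- ref$by_sex$F$muscle_area
  expect_lt(abs(rF$slope - (-0.6)) / 0.6, 0.10)
  expect_lt(abs(rF$se - 4) / 4, 0.05)
  # age-independent trait: slope ~ 0, residual SE ~ marginal SD
  rI <- ref$by_sex$F$fat_thickness
  expect_lt(abs(rI$slope), 0.05)
  expect_lt(abs(rI$se - 5) / 5, 0.05)

  # z-score definition and antisymmetry
  mu80 <- rF$intercept + rF$slope * 80
  expect_equal(as.numeric(zscore(ref, "F", 80, mu80, "muscle_area")), 0)
  expect_equal(as.numeric(zscore(ref, "F", 80, mu80 + 2 * rF$se,
                                 "muscle_area")), 2)
  expect_equal(as.numeric(zscore(ref, "F", 80, mu80 - 1.3 * rF$se, "muscle_area")),
               -as.numeric(zscore(ref, "F", 80, mu80 + 1.3 * rF$se,
                                  "muscle_area")))
  # adverse flag follows the risk direction (low muscle area raises risk)
  expect_true(attr(zscore(ref, "F", 80, mu80 - 8, "muscle_area"), "adverse"))
  expect_false(attr(zscore(ref, "F", 80, mu80 + 8, "muscle_area"), "adverse"))

  # records with age coded 90 or any imputed trait are excluded from the fit
  rs2 <- rs
  rs2$age[1:500] <- 90
  rs2$imputed_muscle_area <- FALSE
  rs2$imputed_muscle_area[501:800] <- TRUE
  ref2 <- fit_zscore_reference(rs2, traits = "muscle_area")
  expect_equal(ref2$by_sex$F$muscle_area$n, n - 800)

  # an exactly age-determined trait is flagged degenerate
  rs$linear_trait <- 2 * rs$age
  ref3 <- fit_zscore_reference(rs, traits = "linear_trait")
  expect_true(ref3$by_sex$F$linear_trait$degenerate)
  expect_error(zscore(ref3, "F", 80, 160, "linear_trait"), "degenerate")

  expect_error(fit_zscore_reference(rs[1:5, ], traits = "muscle_area"),
               "insufficient")
})

test_that("imputation uses the sex- and age-based random-sample regressions", {
  gen <- small_cohort(seed = 21)
  rs <- gen$table[gen$table$random_sample, ]
  tab <- gen$table[1:50, ]
  before <- tab
  tab$fat_thickness[c(3, 7)] <- NA

  out <- impute_missing_traits(tab, rs)
  # untouched records are unchanged
  expect_equal(out$fat_thickness[-c(3, 7)], before$fat_thickness[-c(3, 7)])
  expect_false(any(out$imputed_fat_thickness[-c(3, 7)]))
  # imputed value equals the regression prediction at that age
  for (i in c(3, 7)) {
    fit <- lm(fat_thickness ~ age, data = rs[rs$sex == tab$sex[i], ])
    expect_equal(out$fat_thickness[i],
                 unname(predict(fit, newdata = tab[i, ])))
    expect_true(out$imputed_fat_thickness[i])
  }
  # masking a known value recovers the prediction, not the original
  expect_false(isTRUE(all.equal(out$fat_thickness[3], before$fat_thickness[3])))
})

test_that("risk model round-trips through its text serialization", {
  gen <- small_cohort(seed = 14)
  sp <- split_development_validation(gen$table)
  dev <- recode_outcomes(sp$development, 5)
  model <- fit_logistic(dev, select_traits(dev)$selected)
  model <- calibrate_sex_offsets(model, gen$table[gen$table$random_sample, ])
  path <- tempfile(fileext = ".json")
  write_risk_model(model, path, training_table = dev)
  back <- read_risk_model(path)
  x <- dev[1:20, ]
  expect_equal(compute_logit(back, x), compute_logit(model, x),
               tolerance = 1e-12)
  expect_equal(back$sex_offset, model$sex_offset, tolerance = 1e-12)
  expect_false(is.null(back$provenance_md5))
})

test_that("score responds monotonically in the documented risk directions", {
  gen <- small_cohort(seed = 10, F = 15000, M = 8000)
  sp <- split_development_validation(gen$table)
  dev <- recode_outcomes(sp$development, 5)
  model <- fit_logistic(dev, setdiff(trait_names(), "strength"))
  dirs <- c(age = 1, strength = -1, trab_cort_ratio = -1, fat_thickness = -1,
            muscle_area = -1, intramuscular_fat = 1, fn_volume = 1,
            hip_width = 1)
  expect_equal(sign(model$coefficients[names(dirs)]), dirs)
  x <- dev[5, ]
  s0 <- risk_score(model, x)
  for (t in names(dirs)) {
    x2 <- x
    x2[[t]] <- x2[[t]] * 1.10
    delta <- risk_score(model, x2) - s0
    if (dirs[[t]] > 0) expect_gte(delta, 0) else expect_lte(delta, 0)
  }
})
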