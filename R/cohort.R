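trait_names <- function() {
  c("strength", "trab_cort_ratio", "fat_thickness", "muscle_area",
    "intramuscular_fat", "fn_volume", "hip_width")
}

covariate_names <- function() c("age", trait_names())

# direction each covariate moves fracture risk (+1 increases)
risk_directions <- function() {
  c(age = 1, strength = -1, trab_cort_ratio = -1, fat_thickness = -1,
    muscle_area = -1, intramuscular_fat = 1, fn_volume = 1, hip_width = 1)
}

#' Specification of a synthetic case-cohort study
#'
#' Configures the cohort simulator: per-sex trait marginals, target
#' coefficients of determination of each trait against age and femoral
#' strength, a logistic outcome model (the same functional form the risk
#' model fits, enabling parameter-recovery tests), and the sampling design —
#' an age-matched random sample of the source population plus all fracture
#' cases, with dropouts, late (post-horizon) fractures, and treated patients.
#'
#' Traits follow a Gaussian copula: each trait's latent variable loads on the
#' age and strength latents so that its squared correlations match
#' `target_r2_age` / `target_r2_strength` (signs per the stated risk/ageing
#' directions), with traits conditionally independent given age and strength.
#'
#' @param n_per_sex source-population size per sex (named `F`, `M`).
#' @param age_range years; ages are truncated to this range and ages above 90
#'   are coded as 90.
#' @param age_mean,age_sd normal age parameters before truncation.
#' @param trait_means,trait_sds per-sex named lists of trait marginals
#'   (units: strength N, ratio unitless, fat thickness mm, muscle area cm2,
#'   intramuscular fat %, neck volume cm3, hip width mm).
#' @param target_r2_age named targets for R-squared of each trait (and
#'   strength) against age.
#' @param target_r2_strength named targets for R-squared of each image trait
#'   against femoral strength.
#' @param outcome_coefficients per-standard-deviation logit coefficients for
#'   the eight covariates; signs must match the stated risk directions.
#' @param base_rate per-sex 5-yr population fracture risk.
#' @param late_fracture_rate probability a 5-yr non-case fractures in years
#'   5-10.
#' @param dropout_rate probability a never-fracturing patient lacks 5-yr
#'   follow-up.
#' @param treated_rate probability of >= 180 days of osteoporosis
#'   medication.
#' @param frax_mu,frax_sigma,frax_rho log-normal FRAX 10-yr hip-risk model:
#'   per-sex log-scale location/scale, and the correlation of its latent with
#'   the standardised true risk logit.
#' @param t_mean,t_sd,t_rho per-sex hip BMD T-score marginals and their
#'   latent correlation with the strength latent.
#' @param n_sites number of synthetic sites; each patient gets one.
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_sex = c(F = 40000, M = 20000),
                        age_range = c(65, 90),
                        age_mean = 73, age_sd = 6,
                        trait_means = list(
                          F = c(strength = 3460, trab_cort_ratio = 0.35,
                                fat_thickness = 25, muscle_area = 28,
                                intramuscular_fat = 25, fn_volume = 12,
                                hip_width = 175),
                          M = c(strength = 4570, trab_cort_ratio = 0.32,
                                fat_thickness = 15, muscle_area = 32,
                                intramuscular_fat = 25, fn_volume = 14,
                                hip_width = 183)),
                        trait_sds = list(
                          F = c(strength = 860, trab_cort_ratio = 0.08,
                                fat_thickness = 8, muscle_area = 6,
                                intramuscular_fat = 8, fn_volume = 2,
                                hip_width = 10),
                          M = c(strength = 1120, trab_cort_ratio = 0.08,
                                fat_thickness = 6, muscle_area = 7,
                                intramuscular_fat = 8, fn_volume = 2.5,
                                hip_width = 10)),
                        target_r2_age = c(strength = 0.050,
                                          trab_cort_ratio = 0.033,
                                          fat_thickness = 0.019,
                                          muscle_area = 0.108,
                                          intramuscular_fat = 0.115,
                                          fn_volume = 0.012, hip_width = 0.002),
                        target_r2_strength = c(trab_cort_ratio = 0.147,
                                               fat_thickness = 0.012,
                                               muscle_area = 0.134,
                                               intramuscular_fat = 0.063,
                                               fn_volume = 0.008,
                                               hip_width = 0.011),
                        outcome_coefficients = c(age = 0.30, strength = -1.0,
                                                 trab_cort_ratio = -0.50,
                                                 fat_thickness = -0.35,
                                                 muscle_area = -0.45,
                                                 intramuscular_fat = 0.50,
                                                 fn_volume = 0.55,
                                                 hip_width = 0.35),
                        base_rate = c(F = 0.058, M = 0.034),
                        late_fracture_rate = 0.02,
                        dropout_rate = 0.10,
                        treated_rate = 0.05,
                        frax_mu = c(F = log(1.7), M = log(1.1)),
                        frax_sigma = c(F = 1.328, M = 1.193),
                        frax_rho = 0.75,
                        t_mean = c(F = -1.5, M = -0.7),
                        t_sd = c(F = 1.1, M = 1.2),
                        t_rho = 0.8,
                        n_sites = 28L,
                        seed = 1L) {
  spec <- list(n_per_sex = n_per_sex, age_range = age_range,
               age_mean = age_mean, age_sd = age_sd,
               trait_means = trait_means, trait_sds = trait_sds,
               target_r2_age = target_r2_age,
               target_r2_strength = target_r2_strength,
               outcome_coefficients = outcome_coefficients,
               base_rate = base_rate,
               late_fracture_rate = late_fracture_rate,
               dropout_rate = dropout_rate, treated_rate = treated_rate,
               frax_mu = frax_mu, frax_sigma = frax_sigma,
               frax_rho = frax_rho, t_mean = t_mean, t_sd = t_sd,
               t_rho = t_rho, n_sites = as.integer(n_sites),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  probs <- c(spec$base_rate, spec$late_fracture_rate, spec$dropout_rate,
             spec$treated_rate)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  assert_that(all(spec$target_r2_age >= 0 & spec$target_r2_age <= 0.25) &&
              all(spec$target_r2_strength >= 0 & spec$target_r2_strength <= 0.25),
              "R-squared targets must lie in [0, 0.25]")
  dirs <- risk_directions()
  b <- spec$outcome_coefficients[names(dirs)]
  bad <- names(dirs)[!is.na(b) & b != 0 & sign(b) != dirs]
  assert_that(length(bad) == 0,
              "outcome coefficient sign contradicts the risk direction for: %s",
              paste(bad, collapse = ", "))
  invisible(spec)
}

# signs of each trait's correlation with age / with strength
r2_signs <- function() {
  list(age = c(strength = -1, trab_cort_ratio = -1, fat_thickness = -1,
               muscle_area = -1, intramuscular_fat = 1, fn_volume = 1,
               hip_width = 1),
       strength = c(trab_cort_ratio = 1, fat_thickness = 1, muscle_area = 1,
                    intramuscular_fat = -1, fn_volume = 1, hip_width = 1))
}

# latent standard-normal draws for one sex: returns matrix with columns
# z_age, z_strength, z_<trait>, with the target correlation structure
draw_latents <- function(n, spec) {
  sg <- r2_signs()
  rho_as <- sg$age[["strength"]] * sqrt(spec$target_r2_age[["strength"]])
  z_age <- rnorm(n)
  z_str <- rho_as * z_age + sqrt(1 - rho_as^2) * rnorm(n)
  out <- cbind(age = z_age, strength = z_str)
  for (t in setdiff(trait_names(), "strength")) {
    r1 <- sg$age[[t]] * sqrt(spec$target_r2_age[[t]])
    r2 <- sg$strength[[t]] * sqrt(spec$target_r2_strength[[t]])
    a <- (r1 - r2 * rho_as) / (1 - rho_as^2)
    b <- (r2 - r1 * rho_as) / (1 - rho_as^2)
    ve <- 1 - (a^2 + b^2 + 2 * a * b * rho_as)
    if (ve < 0)
      stop_bct("infeasible correlation targets for trait '%s': implied latent covariance is not positive definite", t)
    out <- cbind(out, a * z_age + b * z_str + sqrt(ve) * rnorm(n))
    colnames(out)[ncol(out)] <- t
  }
  out
}

# physiologic clamping ranges for raw trait values
trait_ranges <- function() {
  list(strength = c(500, 9000), trab_cort_ratio = c(0.05, 0.9),
       fat_thickness = c(0, 80), muscle_area = c(5, 70),
       intramuscular_fat = c(2, 80), fn_volume = c(3, 30),
       hip_width = c(120, 240))
}

# per-unit generating coefficients shared across sexes (standardised
# coefficients divided by the sex-averaged trait SD)
generating_coefficients <- function(spec) {
  sds <- c(age = spec$age_sd,
           (unlist(spec$trait_sds$F) + unlist(spec$trait_sds$M))[trait_names()] / 2)
  names(sds) <- covariate_names()
  spec$outcome_coefficients[covariate_names()] / sds
}

pooled_centers <- function(spec) {
  c(age = spec$age_mean,
    (unlist(spec$trait_means$F) + unlist(spec$trait_means$M))[trait_names()] / 2)
}

#' Generate a synthetic case-cohort table
#'
#' Draws a source population per sex, assigns 5-yr fracture outcomes from the
#' logistic model in [cohort_spec()], then forms the case-cohort sample: all
#' fracture cases (within 10 yr) plus an age-matched random sample of the
#' source population sized to the per-sex case counts, giving an approximate
#' 1:1 fracture:control ratio per sex. Non-fracturing patients may lack 5-yr
#' follow-up (dropouts); treated patients carry >= 180 medication days; ages
#' above 90 are coded as 90.
#'
#' @param spec a [cohort_spec()].
#' @param include_source also return the full source table (bypassing
#'   case-cohort sampling), for parameter-recovery checks.
#' @return A list with `table` (the case-cohort data frame), `ground_truth`
#'   (generating coefficients and intercepts, per-row true logits and
#'   probabilities — never consumed by the fitting path), and optionally
#'   `source`.
#' @export
generate_cohort <- function(spec, include_source = FALSE) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  beta_unit <- generating_coefficients(spec)
  centers <- pooled_centers(spec)
  ranges <- trait_ranges()

  per_sex <- lapply(c("F", "M"), function(sex) {
    n <- spec$n_per_sex[[sex]]
    z <- draw_latents(n, spec)
    age <- pmin(pmax(spec$age_mean + spec$age_sd * z[, "age"],
                     spec$age_range[1]), spec$age_range[2])
    age <- pmin(age, 90)  # ages above 90 coded as 90
    x <- sapply(trait_names(), function(t) {
      raw <- spec$trait_means[[sex]][[t]] + spec$trait_sds[[sex]][[t]] * z[, t]
      pmin(pmax(raw, ranges[[t]][1]), ranges[[t]][2])
    })
    covar <- cbind(age = age, x)
    eta0 <- as.numeric(covar[, covariate_names()] %*%
                         beta_unit[covariate_names()]) -
      sum(beta_unit * centers)
    intercept <- uniroot(function(c0) mean(plogis(c0 + eta0)) -
                           spec$base_rate[[sex]],
                         c(-30, 10), tol = 1e-10)$root
    eta <- intercept + eta0
    p5 <- plogis(eta)
    frac5 <- rbinom(n, 1, p5) == 1
    late <- !frac5 & rbinom(n, 1, spec$late_fracture_rate) == 1
    fracture_time <- rep(NA_real_, n)
    fracture_time[frac5] <- runif(sum(frac5), 0, 5)
    fracture_time[late] <- runif(sum(late), 5, 10)
    never <- !frac5 & !late
    dropout <- never & rbinom(n, 1, spec$dropout_rate) == 1
    followup <- ifelse(!never, fracture_time,
                       ifelse(dropout, runif(n, 0.5, 4.999), runif(n, 5, 10)))
    treated <- rbinom(n, 1, spec$treated_rate) == 1
    treated_days <- ifelse(treated, round(runif(n, 180, 1200)), 0)
    eta_sd <- sd(eta)
    u <- spec$frax_rho * (eta - mean(eta)) / eta_sd +
      sqrt(1 - spec$frax_rho^2) * rnorm(n)
    frax <- pmin(exp(spec$frax_mu[[sex]] + spec$frax_sigma[[sex]] * u), 60)
    z_str <- z[, "strength"]
    hip_t <- spec$t_mean[[sex]] +
      spec$t_sd[[sex]] * (spec$t_rho * z_str + sqrt(1 - spec$t_rho^2) * rnorm(n))
    fn_t <- hip_t - 0.2 + 0.3 * rnorm(n)
    tab_sex <- data.frame(sex = sex, site = sample.int(spec$n_sites, n, replace = TRUE),
               age = age, covar[, trait_names()],
               hip_t_score = hip_t, fn_t_score = fn_t, frax_hip_risk = frax,
               fracture_time = fracture_time, followup_time = followup,
               treated_days = treated_days,
               true_logit = eta, true_p5 = p5,
               stringsAsFactors = FALSE)
    list(tab = tab_sex, intercept = intercept)
  })
  intercepts <- c(F = per_sex[[1]]$intercept, M = per_sex[[2]]$intercept)
  source_tab <- do.call(rbind, lapply(per_sex, `[[`, "tab"))
  source_tab$id <- seq_len(nrow(source_tab))

  # random sample: per sex, as many patients as there are fracture cases
  # (age-matched across sexes by construction: both share the age marginal)
  source_tab$random_sample <- FALSE
  for (sex in c("F", "M")) {
    rows <- which(source_tab$sex == sex)
    n_cases <- sum(!is.na(source_tab$fracture_time[rows]))
    picked <- sample(rows, min(n_cases, length(rows)))
    source_tab$random_sample[picked] <- TRUE
  }
  is_case <- !is.na(source_tab$fracture_time)
  sample_tab <- source_tab[is_case | source_tab$random_sample, ]
  sample_tab$dropout <- !is_case[is_case | source_tab$random_sample] &
    sample_tab$followup_time < 5
  rownames(sample_tab) <- NULL

  gt_cols <- c("true_logit", "true_p5")
  ground_truth <- list(
    coefficients_std = spec$outcome_coefficients,
    coefficients_unit = beta_unit,
    intercepts = intercepts,
    centers = centers,
    base_rate = spec$base_rate,
    true_logit = setNames(sample_tab$true_logit, sample_tab$id),
    true_p5 = setNames(sample_tab$true_p5, sample_tab$id),
    n_source = spec$n_per_sex,
    source_case_rate = vapply(c("F", "M"), function(s) {
      rows <- source_tab$sex == s
      mean(!is.na(source_tab$fracture_time[rows]) &
             source_tab$fracture_time[rows] <= 5)
    }, numeric(1)))

  tab <- sample_tab[, setdiff(names(sample_tab), gt_cols)]
  out <- list(table = tab, ground_truth = ground_truth, spec = spec)
  if (include_source) {
    src <- source_tab[, setdiff(names(source_tab), gt_cols)]
    out$source <- src
    out$ground_truth$source_logit <- setNames(source_tab$true_logit,
                                              source_tab$id)
  }
  out
}

#' Split a cohort into development and validation sets by site
#'
#' Geographic split: membership is a pure function of the site label, so the
#' two sets are disjoint and jointly exhaustive.
#'
#' @param cohort a cohort data frame carrying a `site` column.
#' @param dev_sites site labels assigned to the development set; all others
#'   form the validation set.
#' @return A list with `development` and `validation` data frames.
#' @export
split_development_validation <- function(cohort, dev_sites = 1:12) {
  assert_that("site" %in% names(cohort), "cohort must carry a site label")
  in_dev <- cohort$site %in% dev_sites
  assert_that(any(in_dev), "development side of the site partition is empty")
  assert_that(!all(in_dev), "validation side of the site partition is empty")
  list(development = cohort[in_dev, , drop = FALSE],
       validation = cohort[!in_dev, , drop = FALSE])
}
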