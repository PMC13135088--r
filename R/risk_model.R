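#' Trait selection against the published criteria
#'
#' Screens candidate physical traits for inclusion in the risk score. Three
#' statistical criteria are applied (the remaining two — biomechanical
#' plausibility and reliable measurability — are curation decisions recorded
#' in the audit only): (iii) weak correlation with age and femoral strength
#' in the random sample (R-squared <= `r2_cutoff`), (iv) predicting fracture
#' when used alone (Wald p < `p_cutoff`), and (v) predicting fracture
#' alongside all other candidate traits plus age and strength.
#'
#' @param dev_table development table carrying a logical/0-1 `case` column
#'   (see [recode_outcomes()]) and a `random_sample` flag.
#' @param candidates candidate trait column names (default the six image
#'   traits plus nothing else; age and strength are always retained).
#' @param r2_cutoff criterion (iii) bound on R-squared.
#' @param p_cutoff criteria (iv)/(v) Wald significance level.
#' @return A list with `selected` (character vector) and `audit` (one row per
#'   candidate: R-squared vs age and strength, univariate and full-model
#'   Wald p, per-criterion pass flags).
#' @export
select_traits <- function(dev_table, candidates = setdiff(trait_names(), "strength"),
                          r2_cutoff = 0.25, p_cutoff = 1e-4) {
  assert_that("case" %in% names(dev_table),
              "dev_table must carry a 'case' outcome column (run recode_outcomes first)")
  assert_that("random_sample" %in% names(dev_table),
              "dev_table must carry a 'random_sample' flag")
  rs <- dev_table[dev_table$random_sample, , drop = FALSE]
  assert_that(nrow(rs) > 3, "too few random-sample records to assess correlations")
  r2 <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    suppressWarnings(stats::cor(a[ok], b[ok]))^2
  }
  full_formula <- stats::reformulate(c("age", "strength", candidates),
                                     response = "case")
  full_fit <- glm(full_formula, family = binomial(), data = dev_table)
  full_p <- summary(full_fit)$coefficients[, 4]
  audit <- do.call(rbind, lapply(candidates, function(t) {
    r2a <- r2(rs[[t]], rs$age)
    r2s <- r2(rs[[t]], rs$strength)
    uni <- glm(stats::reformulate(t, response = "case"),
               family = binomial(), data = dev_table)
    p_uni <- summary(uni)$coefficients[t, 4]
    p_full <- unname(full_p[t])
    data.frame(trait = t, r2_age = r2a, r2_strength = r2s,
               p_univariate = p_uni, p_full = p_full,
               pass_weak_correlation = max(r2a, r2s) <= r2_cutoff,
               pass_univariate = p_uni < p_cutoff,
               pass_full = p_full < p_cutoff,
               stringsAsFactors = FALSE)
  }))
  audit$selected <- audit$pass_weak_correlation & audit$pass_univariate &
    audit$pass_full
  list(selected = audit$trait[audit$selected], audit = audit)
}

#' Fit the logistic risk model
#'
#' Maximum-likelihood logistic regression of the fracture outcome on age,
#' femoral strength and the selected physical traits, with no sex term. The
#' problem is convex, so the fit is deterministic given the data; the IRLS
#' convergence criterion is a relative deviance change below 1e-10.
#'
#' @param dev_table development table with a `case` column and complete
#'   covariates (impute first).
#' @param traits physical trait columns to include (age and strength are
#'   always included).
#' @param high_risk_threshold score threshold stored with the model
#'   (default 75).
#' @return An object of class `bct_risk_model`: intercept, per-unit
#'   coefficients, per-sex logit offsets (zero until
#'   [calibrate_sex_offsets()]), the score threshold, and fit diagnostics.
#' @export
fit_logistic <- function(dev_table, traits = setdiff(trait_names(), "strength"),
                         high_risk_threshold = 75) {
  assert_that("case" %in% names(dev_table),
              "dev_table must carry a 'case' outcome column")
  y <- dev_table$case
  assert_that(length(unique(y[!is.na(y)])) == 2,
              "outcomes are all one class; cannot fit a logistic model")
  covars <- c("age", "strength", traits)
  missing_cov <- covars[!covars %in% names(dev_table)]
  assert_that(length(missing_cov) == 0, "missing covariate column(s): %s",
              paste(missing_cov, collapse = ", "))
  assert_that(all(complete.cases(dev_table[, covars])),
              "covariates contain missing values; run impute_missing_traits first")
  fml <- stats::reformulate(covars, response = "case")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dev_table,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    stop_bct(paste("logistic fit did not converge (possible perfect separation);",
                   "reduce the trait set or add data"))
  cf <- coef(fit)
  structure(list(intercept = unname(cf["(Intercept)"]),
                 coefficients = cf[covars],
                 sex_offset = c(F = 0, M = 0),
                 high_risk_threshold = high_risk_threshold,
                 traits = covars,
                 p_values = summary(fit)$coefficients[covars, 4],
                 n = nrow(dev_table), deviance = fit$deviance,
                 calibrated = FALSE),
            class = "bct_risk_model")
}

#' @export
print.bct_risk_model <- function(x, ...) {
  cat("<bct_risk_model>", if (x$calibrated) "(sex-calibrated)" else "(uncalibrated)", "\n")
  cat(sprintf("  intercept  %.4g\n", x$intercept))
  for (t in x$traits)
    cat(sprintf("  %-18s %.4g\n", t, x$coefficients[[t]]))
  cat(sprintf("  sex offsets F %.4g  M %.4g; high-risk threshold %g\n",
              x$sex_offset[["F"]], x$sex_offset[["M"]], x$high_risk_threshold))
  invisible(x)
}

#' Linear predictor of the risk model
#'
#' `intercept + sum(coefficient * covariate) + sex_offset[sex]`, in logit
#' units.
#'
#' @param model a [fit_logistic()] model.
#' @param x data frame with a `sex` column and all model covariates (or a
#'   single named list).
#' @return Numeric logits, one per row.
#' @export
compute_logit <- function(model, x) {
  assert_that(inherits(model, "bct_risk_model"), "model must be a bct_risk_model")
  if (!is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cov <- model$traits[!model$traits %in% names(x)]
  assert_that(length(missing_cov) == 0, "missing covariate(s): %s",
              paste(missing_cov, collapse = ", "))
  assert_that(all(complete.cases(x[, model$traits])),
              "covariates contain missing values")
  xm <- as.matrix(x[, model$traits, drop = FALSE])
  eta <- model$intercept + as.numeric(xm %*% model$coefficients[model$traits])
  if ("sex" %in% names(x)) eta <- eta + model$sex_offset[as.character(x$sex)]
  unname(eta)
}

#' The 0-100 risk score
#'
#' `100 * plogis(logit)`. The continuous value is retained for ROC work;
#' clinical display uses half-up integer rounding (see `display`).
#'
#' @inheritParams compute_logit
#' @param display round half-up to an integer for reporting.
#' @return Scores in `[0, 100]`.
#' @export
risk_score <- function(model, x, display = FALSE) {
  s <- 100 * plogis(compute_logit(model, x))
  if (display) round_half_up(s, 0) else s
}

#' Calibrate per-sex logit offsets to match the FRAX positive rate
#'
#' For each sex, sets the additive logit constant so that the proportion of
#' random-sample patients scoring at or above the high-risk threshold equals
#' the proportion with FRAX hip risk at or above `frax_threshold`, as closely
#' as the empirical score distribution allows (|rate difference| <= 1/n per
#' sex barring score ties). Solved by bisection: the positive rate is
#' monotone non-decreasing in the offset. Adding a constant to the logit is
#' rank-preserving within sex, so per-sex AUC, sensitivity and specificity
#' are unchanged.
#'
#' @param model an uncalibrated [fit_logistic()] model.
#' @param random_table random-sample table with `sex`, `frax_hip_risk` and
#'   all model covariates.
#' @param frax_threshold FRAX 10-yr hip-risk positivity threshold (%).
#' @param score_threshold risk-score positivity threshold.
#' @param bound offset search bracket in logit units.
#' @return The model with `sex_offset` set, plus a `calibration` element
#'   recording target and achieved rates per sex.
#' @export
calibrate_sex_offsets <- function(model, random_table, frax_threshold = 3.0,
                                  score_threshold = 75, bound = 50) {
  assert_that("frax_hip_risk" %in% names(random_table),
              "random_table must carry frax_hip_risk")
  cutoff <- qlogis(score_threshold / 100)
  calib <- list()
  for (sex in c("F", "M")) {
    rows <- random_table[random_table$sex == sex, , drop = FALSE]
    assert_that(nrow(rows) > 0, "no random-sample records for sex %s", sex)
    target <- mean(rows$frax_hip_risk >= frax_threshold)
    base <- model
    base$sex_offset[] <- 0
    eta <- compute_logit(base, rows)
    rate <- function(c0) mean(eta + c0 >= cutoff)
    if (target <= 0 || target >= 1) {
      warning(sprintf("target positive rate for sex %s is %g; offset pinned at bound",
                      sex, target))
      off <- if (target <= 0) -bound else bound
    } else {
      lo <- -bound; hi <- bound
      if (rate(lo) > target || rate(hi) < target) {
        warning(sprintf("target rate for sex %s unreachable within +/-%g logit units",
                        sex, bound))
      }
      while (hi - lo > 1e-8) {
        mid <- (lo + hi) / 2
        if (rate(mid) >= target) hi <- mid else lo <- mid
      }
      off <- hi  # smallest offset achieving rate >= target
    }
    model$sex_offset[[sex]] <- off
    calib[[sex]] <- c(target = target, achieved = rate(off), offset = off,
                      n = nrow(rows))
  }
  model$calibrated <- TRUE
  model$calibration <- calib
  model$high_risk_threshold <- score_threshold
  model
}

#' Fit sex-specific age-regression references for trait Z-scores
#'
#' Ordinary least-squares regressions of each physical trait on age, per sex,
#' using random-sample records only. Records with age coded as 90 (the
#' over-90 privacy coding) and records with any imputed trait are excluded.
#'
#' @param random_table random-sample table.
#' @param traits trait columns to fit (default strength plus the six image
#'   traits).
#' @param min_n minimum records per sex.
#' @return An object of class `zscore_reference`: per sex per trait slope,
#'   intercept, residual standard error, and fit n.
#' @export
fit_zscore_reference <- function(random_table, traits = trait_names(),
                                 min_n = 10) {
  tab <- random_table
  imputed_cols <- grep("^imputed_", names(tab), value = TRUE)
  if (length(imputed_cols) > 0) {
    any_imputed <- Reduce(`|`, lapply(imputed_cols, function(c) tab[[c]]))
    tab <- tab[!any_imputed, , drop = FALSE]
  }
  tab <- tab[tab$age < 90, , drop = FALSE]
  ref <- list()
  for (sex in c("F", "M")) {
    rows <- tab[tab$sex == sex, , drop = FALSE]
    assert_that(nrow(rows) >= min_n,
                "insufficient random-sample records for sex %s (%d < %d)",
                sex, nrow(rows), min_n)
    ref[[sex]] <- lapply(setNames(traits, traits), function(t) {
      fit <- lm(stats::reformulate("age", response = t), data = rows)
      # a perfect fit is reported through the degenerate flag below
      se <- suppressWarnings(summary(fit)$sigma)
      list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
           se = se, n = nrow(rows),
           degenerate = !is.finite(se) || se < 1e-8)
    })
  }
  structure(list(by_sex = ref, traits = traits), class = "zscore_reference")
}

#' Age-referenced trait Z-score
#'
#' Deviation of a patient's trait value from the sex-specific age-predicted
#' mean, in units of the age-regression residual standard error. The raw
#' signed Z is returned; the `adverse` attribute flags whether the deviation
#' lies in the risk-increasing direction for that trait, for starring in
#' clinical displays.
#'
#' @param ref a [fit_zscore_reference()].
#' @param sex `"F"` or `"M"`.
#' @param age years.
#' @param value trait value.
#' @param trait trait name.
#' @return Z (unitless) with attribute `adverse` (logical).
#' @export
zscore <- function(ref, sex, age, value, trait) {
  assert_that(inherits(ref, "zscore_reference"), "ref must be a zscore_reference")
  r <- ref$by_sex[[as.character(sex)]][[trait]]
  assert_that(!is.null(r), "no reference fitted for sex %s, trait %s", sex, trait)
  assert_that(!r$degenerate,
              "degenerate age-regression reference for %s (residual SE ~ 0)", trait)
  z <- (value - (r$intercept + r$slope * age)) / r$se
  dir <- risk_directions()[[trait]]
  structure(z, adverse = (z * dir) > 0)
}

#' Impute missing traits from sex- and age-based regressions
#'
#' Replaces missing trait values with predictions from per-sex linear
#' regressions of that trait on age, fitted in the random sample. Imputed
#' cells are flagged in `imputed_<trait>` columns, which downstream
#' exclusion rules consult.
#'
#' @param table table to complete (must carry `sex` and `age`).
#' @param random_table random-sample table supplying the regressions.
#' @param traits trait columns to consider.
#' @return `table` with missing values filled and flag columns set.
#' @export
impute_missing_traits <- function(table, random_table, traits = trait_names()) {
  for (t in traits) {
    flag_col <- paste0("imputed_", t)
    if (!flag_col %in% names(table)) table[[flag_col]] <- FALSE
    miss <- is.na(table[[t]])
    if (!any(miss)) next
    for (sex in unique(table$sex[miss])) {
      rs <- random_table[random_table$sex == sex & !is.na(random_table[[t]]), ]
      assert_that(nrow(rs) >= 3,
                  "trait %s is missing for essentially all random-sample records of sex %s",
                  t, sex)
      fit <- lm(stats::reformulate("age", response = t), data = rs)
      rows <- which(miss & table$sex == sex)
      table[[t]][rows] <- predict(fit, newdata = table[rows, , drop = FALSE])
      table[[flag_col]][rows] <- TRUE
    }
  }
  table
}

#' Serialize / restore a risk model as structured text
#'
#' Writes the model (coefficients, offsets, threshold, and an MD5 provenance
#' hash of the training table when supplied) as JSON.
#'
#' @param model a [fit_logistic()] model.
#' @param path output file.
#' @param training_table optional table whose MD5 is recorded as provenance.
#' @return `write_risk_model()` returns `path` invisibly; `read_risk_model()`
#'   the model.
#' @export
write_risk_model <- function(model, path, training_table = NULL) {
  provenance <- NULL
  if (!is.null(training_table)) {
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp))
    write.table(training_table, tmp, sep = "\t", row.names = FALSE,
                quote = FALSE)
    provenance <- unname(tools::md5sum(tmp))
  }
  payload <- unclass(model)
  # named atomic vectors serialise as JSON objects, not bare arrays
  for (f in c("coefficients", "sex_offset", "p_values"))
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  payload$provenance_md5 <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  assert_that(file.exists(path), "risk model file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- raw[setdiff(names(raw), "provenance_md5")]
  for (f in c("coefficients", "sex_offset", "p_values"))
    if (!is.null(model[[f]])) model[[f]] <- unlist(model[[f]])
  model$provenance_md5 <- raw$provenance_md5
  class(model) <- "bct_risk_model"
  model
}
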