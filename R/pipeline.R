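#' Pipeline configuration
#'
#' Central configuration for the end-to-end analysis. Defaults are the
#' standard clinical thresholds: hip BMD T-score <= -2.5, FRAX hip risk
#' >= 3.0% (high) / 4.5% (very high), risk score >= 75 with a 75-95 sweep.
#' Loading from YAML rejects unknown keys.
#'
#' @param horizon outcome horizon in years (5 primary, 2 secondary).
#' @param dev_sites site labels forming the development set.
#' @param t_score_threshold BMD T-score positivity threshold (<=).
#' @param frax_threshold,frax_veryhigh_threshold FRAX positivity thresholds
#'   (%, >=).
#' @param score_threshold nominal high-risk score threshold (>=).
#' @param score_sweep score thresholds for the effectiveness sweep.
#' @param efficacy assumed treatment risk reduction.
#' @param seed integer seed for the simulation stages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(horizon = 5, dev_sites = 1:12,
                            t_score_threshold = -2.5,
                            frax_threshold = 3.0,
                            frax_veryhigh_threshold = 4.5,
                            score_threshold = 75,
                            score_sweep = c(75, 80, 85, 90, 95),
                            efficacy = 0.53, seed = 1L) {
  assert_that(horizon %in% c(2, 5), "horizon must be 2 or 5")
  assert_that(score_threshold > 0 && score_threshold < 100,
              "score threshold must lie in (0, 100)")
  structure(list(horizon = horizon, dev_sites = dev_sites,
                 t_score_threshold = t_score_threshold,
                 frax_threshold = frax_threshold,
                 frax_veryhigh_threshold = frax_veryhigh_threshold,
                 score_threshold = score_threshold,
                 score_sweep = score_sweep, efficacy = efficacy,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override the defaults.
#' @export
load_pipeline_config <- function(path) {
  assert_that(file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  assert_that(length(unknown) == 0, "unknown config key(s): %s",
              paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Write / read cohort tables as TSV
#'
#' UTF-8, tab-delimited, one header row, missing values as empty strings.
#'
#' @param table data frame.
#' @param path file path.
#' @return The path (write) or the table (read).
#' @export
write_cohort_table <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  assert_that(file.exists(path), "cohort table not found: %s", path)
  read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE,
             fileEncoding = "UTF-8")
}

#' Analyse a case-cohort table end to end
#'
#' Runs the full modelling and evaluation chain on a cohort table:
#' development/validation split by site, horizon recoding, trait selection,
#' logistic fit, sex-offset calibration against FRAX in the random sample,
#' scoring, per-sex AUC comparison of score vs BMD T-score vs FRAX (DeLong),
#' sensitivity/specificity/DOR at the clinical thresholds, and the
#' effectiveness report per stratum.
#'
#' @param table cohort data frame (see [generate_cohort()] for the schema).
#' @param config a [pipeline_config()].
#' @return A list with the fitted `model`, recoded `development` /
#'   `validation` tables (with a `score` column), `selection` audit,
#'   per-sex `auc`, `delong`, `classification`, and `effectiveness` blocks,
#'   plus the exclusion `ledgers`.
#' @export
analyse_cohort <- function(table, config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config")
  split <- split_development_validation(table, config$dev_sites)
  dev <- recode_outcomes(split$development, config$horizon)
  val <- recode_outcomes(split$validation, config$horizon)
  sel <- select_traits(dev)
  model <- fit_logistic(dev, sel$selected)
  random_tab <- table[table$random_sample, , drop = FALSE]
  model <- calibrate_sex_offsets(model, random_tab,
                                 frax_threshold = config$frax_threshold,
                                 score_threshold = config$score_threshold)
  dev$score <- risk_score(model, dev)
  val$score <- risk_score(model, val)
  random_tab$score <- risk_score(model, random_tab)

  per_sex <- lapply(c(F = "F", M = "M"), function(sex) {
    v <- val[val$sex == sex, , drop = FALSE]
    list(
      auc_bct = auc(v$score, v$case),
      auc_bmd = auc(-v$hip_t_score, v$case),
      auc_frax = auc(v$frax_hip_risk, v$case),
      delong_bct_vs_bmd = delong_test(v$score, -v$hip_t_score, v$case),
      delong_bct_vs_frax = delong_test(v$score, v$frax_hip_risk, v$case),
      metrics_bct = sensitivity_specificity(v$score, v$case,
                                            config$score_threshold, "ge"),
      metrics_bmd = sensitivity_specificity(v$hip_t_score, v$case,
                                            config$t_score_threshold, "le"),
      metrics_frax = sensitivity_specificity(v$frax_hip_risk, v$case,
                                             config$frax_threshold, "ge"))
  })

  strata <- list(women_ge65 = list(sex = "F", min_age = 65),
                 women_ge70 = list(sex = "F", min_age = 70),
                 men_ge65 = list(sex = "M", min_age = 65),
                 men_ge70 = list(sex = "M", min_age = 70))
  effectiveness <- lapply(strata, function(st) {
    rs <- random_tab[random_tab$sex == st$sex & random_tab$age >= st$min_age, ]
    v <- val[val$sex == st$sex & val$age >= st$min_age, ]
    frax_hi <- estimate_inputs(rs, v, "frax_hip_risk", config$frax_threshold,
                               "ge", config$horizon, config$efficacy)
    frax_vh <- estimate_inputs(rs, v, "frax_hip_risk",
                               config$frax_veryhigh_threshold, "ge",
                               config$horizon, config$efficacy)
    bmd <- estimate_inputs(rs, v, "hip_t_score", config$t_score_threshold,
                           "le", config$horizon, config$efficacy)
    sweep <- threshold_sweep(rs, v, "score", config$score_sweep, "ge",
                             config$horizon, config$efficacy)
    refs <- c(high = ppv(frax_hi), very_high = ppv(frax_vh))
    sweep$risk_class <- vapply(sweep$ppv, classify_risk, character(1),
                               refs[["high"]], refs[["very_high"]])
    list(pop_fr = frax_hi$pop_fr,
         frax_high = frax_hi, frax_veryhigh = frax_vh, bmd = bmd,
         frax_high_ppv = ppv(frax_hi), frax_veryhigh_ppv = ppv(frax_vh),
         bmd_ppv = ppv(bmd),
         bmd_class = classify_risk(ppv(bmd), refs[["high"]],
                                   refs[["very_high"]]),
         sweep = sweep)
  })

  pooled_dev <- auc(dev$score, dev$case)
  pooled_val <- auc(val$score, val$case)
  list(model = model, selection = sel, development = dev, validation = val,
       random_sample = random_tab, per_sex = per_sex,
       effectiveness = effectiveness,
       pooled_auc = c(development = pooled_dev$auc,
                      validation = pooled_val$auc),
       ledgers = list(development = attr(dev, "ledger"),
                      validation = attr(val, "ledger")),
       config = config)
}

#' Simulate a cohort and analyse it end to end
#'
#' @param cohort a [cohort_spec()]; its seed is overridden by the config
#'   seed.
#' @param config a [pipeline_config()].
#' @return As [analyse_cohort()], plus `ground_truth` from the generator.
#' @export
run_pipeline <- function(cohort = cohort_spec(), config = pipeline_config()) {
  cohort$seed <- config$seed
  gen <- generate_cohort(cohort)
  out <- analyse_cohort(gen$table, config)
  out$ground_truth <- gen$ground_truth
  out
}

#' Effectiveness report as a delimited table
#'
#' Flattens the effectiveness block of [analyse_cohort()] into one table
#' (per stratum: FRAX references, BMD, and the score sweep) with a
#' provenance header recording the assumptions.
#'
#' @param analysis result of [analyse_cohort()].
#' @param path optional output TSV; a `#`-prefixed provenance block precedes
#'   the header.
#' @return The report data frame (invisibly if written).
#' @export
effectiveness_report <- function(analysis, path = NULL) {
  rows <- list()
  for (st in names(analysis$effectiveness)) {
    e <- analysis$effectiveness[[st]]
    mk <- function(test, threshold, inp, cls) {
      data.frame(stratum = st, test = test, threshold = threshold,
                 positive_rate = round_half_up(100 * inp$test_pr, 1),
                 sensitivity = round_half_up(100 * inp$S, 1),
                 ppv = ppv(inp), risk_class = cls,
                 preventable_per_1000 = preventable_per_1000(inp))
    }
    rows[[length(rows) + 1]] <- mk("frax", analysis$config$frax_threshold,
                                   e$frax_high, "high")
    rows[[length(rows) + 1]] <- mk("frax",
                                   analysis$config$frax_veryhigh_threshold,
                                   e$frax_veryhigh, "very_high")
    rows[[length(rows) + 1]] <- mk("bmd", analysis$config$t_score_threshold,
                                   e$bmd, e$bmd_class)
    sw <- e$sweep
    rows[[length(rows) + 1]] <- data.frame(
      stratum = st, test = "bct", threshold = sw$threshold,
      positive_rate = sw$positive_rate, sensitivity = sw$sensitivity,
      ppv = sw$ppv, risk_class = sw$risk_class,
      preventable_per_1000 = sw$preventable_per_1000)
  }
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
      "# effectiveness report",
      sprintf("# horizon_years: %g", analysis$config$horizon),
      sprintf("# treatment_efficacy: %g (all high-risk patients assumed treated)",
              analysis$config$efficacy),
      "# rounding: half-up at display precision (1 d.p. for %, integer counts)"),
      con)
    write.table(report, con, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(report))
  }
  report
}
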