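#' Clinical-effectiveness inputs
#'
#' The four quantities behind the effectiveness arithmetic, all fractions in
#' `[0, 1]`: `S` the test sensitivity (from the validation set, which
#' excludes treated patients); `pop_fr` the population fracture risk over the
#' horizon (from untreated random-sample patients, dropouts excluded);
#' `test_pr` the baseline positive-test rate in the random sample (dropouts
#' included, mirroring clinical care where future status is unknown); and
#' `efficacy` the assumed treatment risk reduction (0.53, representing
#' alendronate).
#'
#' @param S sensitivity fraction.
#' @param pop_fr population fracture risk fraction.
#' @param test_pr baseline positive-test rate fraction.
#' @param efficacy treatment risk-reduction fraction.
#' @return List of class `effectiveness_inputs`.
#' @export
effectiveness_inputs <- function(S, pop_fr, test_pr, efficacy = 0.53) {
  vals <- c(S = S, pop_fr = pop_fr, test_pr = test_pr, efficacy = efficacy)
  assert_that(all(vals >= 0 & vals <= 1),
              "all effectiveness inputs must be fractions in [0, 1]")
  structure(as.list(vals), class = "effectiveness_inputs")
}

#' Positive predictive value
#'
#' `PPV = S x PopFR / TestPR`, the risk of fracturing within the horizon
#' given a positive test, expressed in percent and display-rounded half-up
#' to one decimal (pass `digits = NULL` for the unrounded value).
#'
#' @param inputs an [effectiveness_inputs()].
#' @param digits display decimals (default 1; `NULL` = unrounded).
#' @return PPV in percent.
#' @export
ppv <- function(inputs, digits = 1) {
  assert_that(inherits(inputs, "effectiveness_inputs"),
              "inputs must be effectiveness_inputs")
  assert_that(inputs$test_pr > 0, "PPV undefined: positive-test rate is zero")
  out <- 100 * inputs$S * inputs$pop_fr / inputs$test_pr
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Preventable hip fractures per 1000 tested patients
#'
#' `S x PopFR x E x 1000`, assuming all positive-testing (high-risk) patients
#' are treated with an agent of efficacy `E`. Display-rounded half-up to an
#' integer (pass `digits = NULL` for the unrounded value).
#'
#' @inheritParams ppv
#' @return Preventable fractures per 1000 tests.
#' @export
preventable_per_1000 <- function(inputs, digits = 0) {
  assert_that(inherits(inputs, "effectiveness_inputs"),
              "inputs must be effectiveness_inputs")
  out <- inputs$S * inputs$pop_fr * inputs$efficacy * 1000
  if (is.null(digits)) out else round_half_up(out, digits)
}

#' Estimate effectiveness inputs from study tables
#'
#' Measures the three empirical inputs the effectiveness formulas need:
#' population fracture risk from untreated random-sample patients excluding
#' dropouts; the baseline positive-test rate from *all* random-sample
#' patients (future dropouts included); and sensitivity from the validation
#' set after horizon recoding.
#'
#' @param random_table random-sample table (pre-recoding; must carry
#'   `fracture_time`, `followup_time`, `treated_days`).
#' @param val_table recoded validation table with a `case` column (see
#'   [recode_outcomes()]).
#' @param value_col predictor column name (present in both tables).
#' @param threshold positivity threshold.
#' @param direction `"ge"` or `"le"`.
#' @param horizon years.
#' @param efficacy treatment risk reduction.
#' @return An [effectiveness_inputs()] with attribute `sensitivity_metrics`.
#' @export
estimate_inputs <- function(random_table, val_table, value_col, threshold,
                            direction = "ge", horizon = 5, efficacy = 0.53) {
  need <- c("fracture_time", "followup_time", "treated_days")
  assert_that(all(need %in% names(random_table)),
              "random_table lacks outcome/flag columns")
  assert_that("case" %in% names(val_table),
              "val_table must be recoded (carry a 'case' column)")
  case <- !is.na(random_table$fracture_time) &
    random_table$fracture_time <= horizon
  dropout <- !case & random_table$followup_time < horizon
  untreated <- random_table$treated_days < 180
  pop_fr <- mean(case[untreated & !dropout])
  pos <- if (direction == "ge") random_table[[value_col]] >= threshold
         else random_table[[value_col]] <= threshold
  test_pr <- mean(pos)  # baseline: everyone, dropouts included
  cm <- sensitivity_specificity(val_table[[value_col]], val_table$case,
                                threshold, direction)
  out <- effectiveness_inputs(cm$sensitivity / 100, pop_fr, test_pr, efficacy)
  attr(out, "sensitivity_metrics") <- cm
  out
}

#' Effectiveness report across score thresholds
#'
#' One report row per threshold: baseline positive rate, sensitivity, PPV and
#' preventable fractures per 1000 tests. Positive rate and sensitivity are
#' non-increasing in the threshold (nested positives). The identity
#' `PPV x TestPR = S x PopFR` holds on the unrounded columns.
#'
#' @inheritParams estimate_inputs
#' @param thresholds vector of score thresholds (default 75 to 95 by 5).
#' @return Data frame with rounded display columns and unrounded `.raw`
#'   columns.
#' @export
threshold_sweep <- function(random_table, val_table, value_col = "score",
                            thresholds = c(75, 80, 85, 90, 95),
                            direction = "ge", horizon = 5, efficacy = 0.53) {
  rows <- lapply(thresholds, function(th) {
    inp <- estimate_inputs(random_table, val_table, value_col, th, direction,
                           horizon, efficacy)
    data.frame(threshold = th,
               positive_rate = round_half_up(100 * inp$test_pr, 1),
               sensitivity = round_half_up(100 * inp$S, 1),
               ppv = ppv(inp),
               preventable_per_1000 = preventable_per_1000(inp),
               positive_rate.raw = 100 * inp$test_pr,
               sensitivity.raw = 100 * inp$S,
               ppv.raw = ppv(inp, digits = NULL),
               preventable.raw = preventable_per_1000(inp, digits = NULL),
               pop_fr = inp$pop_fr)
  })
  do.call(rbind, rows)
}

#' Classify a PPV against FRAX reference PPVs
#'
#' FRAX thresholds of 3.0% and 4.5% define the clinically acceptable risk
#' levels for high-risk and very-high-risk status; a test's PPV is classified
#' against those reference PPVs from the same patient stratum. Comparison is
#' on values rounded half-up to one decimal, and a PPV equal to a reference
#' attains that class.
#'
#' @param ppv_value PPV (%) of the test under classification.
#' @param frax_high_ppv reference PPV (%) at FRAX >= 3.0%.
#' @param frax_veryhigh_ppv reference PPV (%) at FRAX >= 4.5%.
#' @return `"very_high"`, `"high"`, or `"below_high"`.
#' @export
classify_risk <- function(ppv_value, frax_high_ppv, frax_veryhigh_ppv) {
  assert_that(is.finite(frax_high_ppv) && is.finite(frax_veryhigh_ppv),
              "reference PPVs are missing")
  p <- round_half_up(ppv_value, 1)
  if (p >= round_half_up(frax_veryhigh_ppv, 1)) "very_high"
  else if (p >= round_half_up(frax_high_ppv, 1)) "high"
  else "below_high"
}

#' Relative improvement between two preventable-fracture counts
#'
#' `100 x (a - b) / b`, rounded half-up to an integer. Note the asymmetry:
#' `relative_improvement(a, b)` and `relative_improvement(b, a)` differ, as
#' the second argument is the baseline.
#'
#' @param a,b preventable fractures per 1000 (b is the reference, > 0).
#' @return Percent improvement of a over b.
#' @export
relative_improvement <- function(a, b) {
  assert_that(b > 0, "reference count must be positive")
  round_half_up(100 * (a - b) / b, 0)
}
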