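#' Recode outcomes to a fixed prediction horizon
#'
#' Applies the case-cohort recoding rules for a 5-yr (or 2-yr) horizon:
#' patients with >= 180 days of osteoporosis medication are excluded;
#' fractures within the horizon are cases; fractures beyond it are recoded to
#' no-fracture controls if the patient is in the random sample and excluded
#' otherwise; non-fracturing patients without follow-up to the horizon are
#' dropped. Returns the analysis table plus an exclusion ledger whose counts
#' partition the input.
#'
#' @param table cohort table with `fracture_time`, `followup_time`,
#'   `treated_days` and `random_sample`.
#' @param horizon years, 5 (primary) or 2 (secondary).
#' @return Data frame of analysed records with a logical `case` column;
#'   attribute `ledger` is a data frame of per-rule counts.
#' @export
recode_outcomes <- function(table, horizon = 5) {
  assert_that(horizon %in% c(2, 5), "horizon must be 2 or 5 years")
  need <- c("fracture_time", "followup_time", "treated_days", "random_sample")
  missing_cols <- setdiff(need, names(table))
  assert_that(length(missing_cols) == 0, "table lacks column(s): %s",
              paste(missing_cols, collapse = ", "))
  n_in <- nrow(table)
  treated <- table$treated_days >= 180
  has_fx <- !is.na(table$fracture_time)
  assert_that(all(has_fx | !is.na(table$followup_time)),
              "missing follow-up time on a non-fracture record")
  case <- has_fx & table$fracture_time <= horizon
  late <- has_fx & table$fracture_time > horizon
  excl_late <- !treated & late & !table$random_sample
  recoded <- !treated & late & table$random_sample
  noncase <- !has_fx | recoded
  dropped <- !treated & !excl_late & noncase & table$followup_time < horizon &
    !late  # a late fracture documents survival past the horizon
  keep <- !treated & !excl_late & !dropped
  out <- table[keep, , drop = FALSE]
  out$case <- case[keep]
  ledger <- data.frame(
    rule = c("input", "excluded_treated", "excluded_late_fracture",
             "recoded_to_control", "dropped_no_followup", "analyzed"),
    n = c(n_in, sum(treated), sum(excl_late), sum(recoded & keep),
          sum(dropped), sum(keep)))
  attr(out, "ledger") <- ledger
  attr(out, "horizon") <- horizon
  out
}

# midrank placements: for each case, the fraction of controls it outscores
# (ties count half), and symmetrically for controls
delong_placements <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  cases <- scores[y]
  controls <- scores[!y]
  m <- length(cases); n <- length(controls)
  assert_that(m > 0 && n > 0, "both outcome classes must be present")
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_case <- rank(cases, ties.method = "average")
  r_ctrl <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Rank-based AUC with DeLong confidence interval
#'
#' Area under the ROC curve by the Mann-Whitney formulation with midrank tie
#' correction — identical to the ROC area of a univariate logistic model,
#' whose fitted probability is monotone in the single predictor. The 95% CI
#' uses the DeLong placement variance, truncated to `[0, 1]`.
#'
#' @param scores numeric predictor values.
#' @param outcomes logical/0-1 outcomes (`TRUE` = case).
#' @param conf confidence level.
#' @return List of class `auc_estimate`: `auc`, `se`, `ci`, `m` (cases),
#'   `n` (controls).
#' @export
auc <- function(scores, outcomes, conf = 0.95) {
  pl <- delong_placements(scores, outcomes)
  v <- var(pl$v10) / pl$m + var(pl$v01) / pl$n
  se <- sqrt(v)
  zq <- qnorm(1 - (1 - conf) / 2)
  structure(list(auc = pl$auc, se = se,
                 ci = pmin(pmax(pl$auc + c(-1, 1) * zq * se, 0), 1),
                 m = pl$m, n = pl$n),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f; %d cases, %d controls)\n",
              x$auc, x$ci[1], x$ci[2], x$m, x$n))
  invisible(x)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same patients, using the
#' DeLong covariance of the paired placement values and a two-sided normal
#' p-value.
#'
#' @param scores_a,scores_b paired predictor values (same patients, same
#'   order).
#' @param outcomes logical/0-1 outcomes.
#' @return List of class `auc_comparison`: both AUCs and CIs, `difference`
#'   (a - b), `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  assert_that(length(scores_a) == length(scores_b) &&
              length(scores_a) == length(outcomes),
              "inputs must be paired: equal lengths required")
  pa <- delong_placements(scores_a, outcomes)
  pb <- delong_placements(scores_b, outcomes)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / pa$m + s01 / pa$n
  vdiff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- pa$auc - pb$auc
  if (vdiff <= 0) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(vdiff)
  }
  p <- if (z == 0) 1 else 2 * pnorm(-abs(z))
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 ci_a = auc(scores_a, outcomes)$ci,
                 ci_b = auc(scores_b, outcomes)$ci,
                 difference = d, z = z, p_value = p,
                 var_difference = max(vdiff, 0)),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("AUC %.3f vs %.3f, difference %+.3f, z = %.2f, p = %.2g (DeLong)\n",
              x$auc_a, x$auc_b, x$difference, x$z, x$p_value))
  invisible(x)
}

#' Sensitivity, specificity and diagnostic odds ratio at a threshold
#'
#' Binary classification metrics at a clinical threshold. Ties at the
#' threshold follow the stated inequality: `direction = "ge"` counts values
#' at or above the threshold as positive (risk scores, FRAX), `"le"` counts
#' values at or below as positive (BMD T-scores). 95% CIs for sensitivity
#' and specificity use the normal approximation to the binomial, truncated
#' to `[0, 100]`; the DOR CI is a log-odds Wald interval with a
#' Haldane-Anscombe 0.5 correction when any cell is empty. An empty outcome
#' class yields an error rather than a silent zero.
#'
#' @param values predictor values.
#' @param outcomes logical/0-1 outcomes.
#' @param threshold clinical threshold.
#' @param direction `"ge"` or `"le"` (which side is positive).
#' @return List of class `classification_metrics`: sensitivity/specificity
#'   (%), their CIs, `dor` and its CI, the 2x2 counts, threshold and
#'   direction.
#' @export
sensitivity_specificity <- function(values, outcomes, threshold,
                                    direction = c("ge", "le")) {
  direction <- match.arg(direction)
  y <- as.logical(outcomes)
  assert_that(any(y) && any(!y),
              "both outcome classes must be present; a metric would be undefined")
  pos <- if (direction == "ge") values >= threshold else values <= threshold
  tp <- sum(pos & y); fn <- sum(!pos & y)
  fp <- sum(pos & !y); tn <- sum(!pos & !y)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  wald <- function(p, n) {
    half <- 1.96 * sqrt(p * (1 - p) / n)
    100 * pmin(pmax(p + c(-1, 1) * half, 0), 1)
  }
  cells <- c(tp, fn, fp, tn)
  if (any(cells == 0)) {
    h <- cells + 0.5
    dor <- (h[1] / h[2]) / (h[3] / h[4])
    log_se <- sqrt(sum(1 / h))
  } else {
    dor <- (tp / fn) / (fp / tn)
    log_se <- sqrt(1 / tp + 1 / fn + 1 / fp + 1 / tn)
  }
  structure(list(sensitivity = sens, specificity = spec,
                 sensitivity_ci = wald(tp / (tp + fn), tp + fn),
                 specificity_ci = wald(tn / (tn + fp), tn + fp),
                 dor = dor,
                 dor_ci = exp(log(dor) + c(-1, 1) * 1.96 * log_se),
                 counts = c(tp = tp, fn = fn, fp = fp, tn = tn),
                 threshold = threshold, direction = direction),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "threshold %s%g: sens %.1f%% [%.1f-%.1f], spec %.1f%% [%.1f-%.1f], DOR %.1f [%.1f-%.1f]\n",
    if (x$direction == "ge") ">=" else "<=", x$threshold,
    x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2],
    x$specificity, x$specificity_ci[1], x$specificity_ci[2],
    x$dor, x$dor_ci[1], x$dor_ci[2]))
  invisible(x)
}

#' Net gain of sensitivity versus specificity
#'
#' `(sens_a - sens_b) - (spec_b - spec_a)`: the sensitivity gained by test a
#' over test b, net of the specificity conceded.
#'
#' @param sens_a,spec_a,sens_b,spec_b percentages.
#' @return Net gain in percentage points.
#' @export
net_gain <- function(sens_a, spec_a, sens_b, spec_b) {
  (sens_a - sens_b) - (spec_b - spec_a)
}
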