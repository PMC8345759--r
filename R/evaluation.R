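#' Diet affordability
#'
#' Weekly diet cost as a percentage of the OECD-adjusted weekly household
#' income.
#'
#' @param cost_week Weekly diet cost, NZD.
#' @param adjusted_income Adjusted household income, NZD/week; positive.
#' @return Percentage.
#' @export
#' @examples
#' affordability(191.0, 808) # 23.6
affordability <- function(cost_week, adjusted_income) {
  if (any(adjusted_income <= 0)) stop("non-positive income", call. = FALSE)
  if (any(cost_week < 0)) stop("negative cost", call. = FALSE)
  100 * cost_week / adjusted_income
}

#' Remove GST from a price
#'
#' NZ applies 15% GST to all foods; the GST-exclusive counterfactual price
#' is `price / (1 + gst_rate)`.
#'
#' @param price Price, NZD.
#' @param gst_rate GST rate in `[0, 1)`.
#' @return GST-exclusive price.
#' @export
#' @examples
#' remove_gst(4.33, 0.15) # 3.765..., the skim-milk 2L counterfactual
remove_gst <- function(price, gst_rate = 0.15) {
  if (any(price < 0)) stop("negative price", call. = FALSE)
  if (gst_rate < 0 || gst_rate >= 1) stop("gst_rate must be in [0, 1)",
                                          call. = FALSE)
  price / (1 + gst_rate)
}

#' Percent decrease from current to healthier value
#'
#' @param current Baseline value, positive.
#' @param healthier Comparison value.
#' @return Percent decrease, `100 * (current - healthier) / current`.
#' @export
#' @examples
#' percent_change(155.7, 120.3) # 22.7
percent_change <- function(current, healthier) {
  if (any(current <= 0)) stop("non-positive baseline", call. = FALSE)
  100 * (current - healthier) / current
}

#' Compare a metric between current and healthier diets
#'
#' Two-sided unpaired Student's t-test with pooled variance (Welch by
#' flag), reporting group means and standard errors of the mean. When both
#' arms have zero variance and equal means the p-value is 1 by convention.
#'
#' @param current_samples,healthier_samples Numeric vectors, length >= 2.
#' @param metric Metric name carried into the result.
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return One-row tibble: `metric`, `mean_current`, `sem_current`,
#'   `mean_healthier`, `sem_healthier`, `p_raw`.
#' @export
compare_metric <- function(current_samples, healthier_samples,
                           metric = "metric", welch = FALSE) {
  if (length(current_samples) < 2 || length(healthier_samples) < 2) {
    stop("need at least 2 observations per arm", call. = FALSE)
  }
  sem <- function(x) sd(x) / sqrt(length(x))
  if (sd(current_samples) == 0 && sd(healthier_samples) == 0) {
    if (mean(current_samples) == mean(healthier_samples)) {
      message("zero variance in both arms with equal means; p = 1")
      p <- 1
    } else {
      p <- 0
    }
  } else {
    p <- t.test(current_samples, healthier_samples,
                var.equal = !welch)$p.value
  }
  tibble::tibble(metric = metric,
                 mean_current = mean(current_samples),
                 sem_current = sem(current_samples),
                 mean_healthier = mean(healthier_samples),
                 sem_healthier = sem(healthier_samples),
                 p_raw = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, applied per report table. Adjusted values
#' are monotone, never below the raw p, and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Compare a table of metrics with FDR adjustment
#'
#' Runs [compare_metric()] for each metric, adjusts the p-values with
#' [fdr_adjust()] across the table, and flags significance at the 0.005
#' threshold.
#'
#' @param current,healthier Data frames with one column per metric and one
#'   row per replicate household.
#' @param group Label (e.g. ethnicity x SES) carried into the result.
#' @param alpha Significance threshold on the adjusted p (default 0.005).
#' @param welch Passed to [compare_metric()].
#' @return Tibble with one row per metric and `p_fdr`, `significant`.
#' @export
compare_table <- function(current, healthier, group = NA_character_,
                          alpha = 0.005, welch = FALSE) {
  metrics <- intersect(names(current), names(healthier))
  res <- dplyr::bind_rows(lapply(metrics, function(m) {
    compare_metric(current[[m]], healthier[[m]], metric = m, welch = welch)
  }))
  res$p_fdr <- fdr_adjust(res$p_raw)
  res$significant <- res$p_fdr < alpha
  res$group <- group
  dplyr::relocate(res, "group")
}

#' Linear model for individual change scores
#'
#' Fits `change ~ (ethnicity + ses + age_sex_group)^2` by least squares:
#' all main effects and two-way interactions of ethnicity, SES and age-sex
#' group on the healthier-minus-current change values.
#'
#' @param change Numeric change values (healthier minus current).
#' @param ethnicity,ses,age_sex_group Factors (or coercible), same length.
#' @return Tibble of coefficients: `term`, `estimate`, `std_error`,
#'   `p_value`. Aliased (rank-deficient) terms raise an error naming them.
#' @export
fit_change_model <- function(change, ethnicity, ses, age_sex_group) {
  dat <- data.frame(change = change,
                    ethnicity = factor(ethnicity),
                    ses = factor(ses),
                    age_sex_group = factor(age_sex_group))
  drop1_terms <- vapply(dat[-1], function(f) nlevels(droplevels(f)) > 1,
                        logical(1))
  if (!any(drop1_terms)) {
    stop("design is rank-deficient: single cell (no varying factors)",
         call. = FALSE)
  }
  rhs <- paste0("(", paste(names(drop1_terms)[drop1_terms],
                           collapse = " + "), ")",
                if (sum(drop1_terms) > 1) "^2" else "")
  fit <- lm(stats::as.formula(paste("change ~", rhs)), data = dat)
  cf <- summary(fit)$coefficients
  aliased <- names(which(is.na(stats::coef(fit))))
  if (length(aliased)) {
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                 std_error = unname(cf[, 2]), p_value = unname(cf[, 4]))
}

#' Round half up at report time
#'
#' Monetary and percentage values are carried at full precision and only
#' rounded for report parity, half-up (so 23.65 prints as 23.7).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}
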