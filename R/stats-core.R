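#' Pearson chi-square test on a contingency table
#'
#' Pearson's statistic `sum((O - E)^2 / E)` without continuity correction,
#' with the p-value from the upper tail of the chi-square distribution on
#' `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table An r x c matrix of non-negative counts with positive row and
#'   column sums.
#'
#' @return List of class `chisq_result` with `statistic`, `df`, `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) {
    abort("Counts must be non-negative", class = "stratburden_degenerate_table")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("Degenerate table: a row or column sum is zero",
          class = "stratburden_degenerate_table")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Two-sample Wilcoxon rank (Mann-Whitney) test
#'
#' Two-sided test of equality of distributions. Uses exact enumeration when
#' the pooled sample size is at most 12 and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#'
#' @return The two-sided p-value.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  exact <- (length(pooled) <= 12) && !any(duplicated(pooled))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  wt$p.value
}

#' Tukey Honest Significant Differences
#'
#' Simultaneous pairwise comparisons of group means using the studentized
#' range distribution, generalised to unbalanced groups (Tukey-Kramer).
#' Confidence intervals are simultaneous at `conf_level`.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param conf_level Simultaneous confidence level (default 0.95).
#'
#' @return Tibble of class `tukey_result` with one row per group pair:
#'   `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    abort("tukey_hsd() needs at least two groups",
          class = "stratburden_insufficient_df")
  }
  if (length(values) - nlevels(groups) < 1) {
    abort("No residual degrees of freedom: every group is a singleton",
          class = "stratburden_insufficient_df")
  }
  fit <- aov(values ~ groups, data = data.frame(values = values, groups = groups))
  tk <- TukeyHSD(fit, conf.level = conf_level)$groups
  out <- tibble::tibble(
    pair = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  class(out) <- c("tukey_result", class(out))
  out
}

#' Eta-squared variance decomposition of lesion-level response
#'
#' Sequential (Type I) ANOVA of percent changes in the fixed order
#' location, patient, location:patient. Eta-squared for a term is its sum of
#' squares divided by the total sum of squares; the residual share is the
#' remainder. With singleton patient x location cells the interaction and
#' residual are partially confounded; the decomposition is reported as
#' defined, with terms that are fully aliased contributing zero.
#'
#' @param records Tibble with `change`, `location`, `patient_id`.
#'
#' @return List of class `variance_decomposition` with `eta_location`,
#'   `eta_patient`, `eta_interaction`, `residual` (all in `[0, 1]`,
#'   summing to 1 when the total sum of squares is positive) and `ss_total`.
#' @export
anova_eta_squared <- function(records) {
  d <- data.frame(
    change = records$change,
    location = factor(records$location),
    patient = factor(records$patient_id)
  )
  if (nlevels(d$location) < 2) {
    abort("Need at least two locations", class = "stratburden_insufficient_df")
  }
  if (nlevels(d$patient) < 2) {
    abort("Need at least two patients", class = "stratburden_insufficient_df")
  }
  ss_total <- sum((d$change - mean(d$change))^2)
  if (ss_total <= .Machine$double.eps * length(d$change)) {
    return(structure(list(eta_location = 0, eta_patient = 0,
                          eta_interaction = 0, residual = 0, ss_total = 0),
                     class = "variance_decomposition"))
  }
  fit <- aov(change ~ location + patient + location:patient, data = d)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  terms <- trimws(rownames(summary(fit)[[1]]))
  get_ss <- function(term) {
    i <- match(term, terms)
    if (is.na(i)) 0 else ss[i]
  }
  eta <- function(term) get_ss(term) / ss_total
  structure(
    list(
      eta_location = eta("location"),
      eta_patient = eta("patient"),
      eta_interaction = eta("location:patient"),
      residual = eta("Residuals"),
      ss_total = ss_total
    ),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Eta-squared variance decomposition of response:\n")
  cat(sprintf("  location            %5.1f%%\n", 100 * x$eta_location))
  cat(sprintf("  patient             %5.1f%%\n", 100 * x$eta_patient))
  cat(sprintf("  location:patient    %5.1f%%\n", 100 * x$eta_interaction))
  cat(sprintf("  residual            %5.1f%%\n", 100 * x$residual))
  invisible(x)
}

#' Levene's test for homogeneity of variances
#'
#' Median-centred Levene test (the Brown-Forsythe variant), the usual
#' prerequisite check before an ANOVA on heavy-tailed response data.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#'
#' @return List with `statistic` (F), `df`, `p`.
#' @export
levene <- function(values, groups) {
  groups <- factor(groups)
  lt <- car::leveneTest(values, groups, center = median)
  f <- lt[1, "F value"]
  list(statistic = if (is.na(f)) 0 else f,
       df = c(lt[1, "Df"], lt[2, "Df"]),
       p = if (is.na(lt[1, "Pr(>F)"])) 1 else lt[1, "Pr(>F)"])
}

#' Jarque-Bera normality test
#'
#' Tests normality from sample skewness `S` and excess kurtosis `K`:
#' the statistic `n (S^2/6 + K^2/24)` is asymptotically chi-square with 2
#' degrees of freedom under normality.
#'
#' @param x Numeric sample, length >= 4.
#'
#' @return List with `statistic`, `df = 2`, `p`.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 4)
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) return(list(statistic = 0, df = 2, p = 1))
  s <- mean(m^3) / m2^1.5
  k <- mean(m^4) / m2^2 - 3
  stat <- n * (s^2 / 6 + k^2 / 24)
  list(statistic = stat, df = 2, p = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Flag outliers by the k x IQR rule
#'
#' Flags observations below `Q1 - k * IQR` or above `Q3 + k * IQR`.
#' Quartiles use linear interpolation of order statistics (R's default,
#' type 7) unless another `type` is requested.
#'
#' @param x Numeric sample.
#' @param k Fence multiplier, > 0 (default 1.5).
#' @param type Quantile algorithm passed to [stats::quantile()].
#'
#' @return Logical vector, `TRUE` where `x` is an outlier. `NA` values are
#'   never flagged.
#' @export
iqr_outlier_mask <- function(x, k = 1.5, type = 7) {
  stopifnot(k > 0)
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = type)
  iqr <- q[2] - q[1]
  out <- x < q[1] - k * iqr | x > q[2] + k * iqr
  out[is.na(out)] <- FALSE
  out
}
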