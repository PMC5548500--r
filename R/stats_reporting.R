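#' Shapiro-Wilk normality test
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return A list with `W` and `p.value`.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(values) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(values))
  if (diff(range(values)) == 0) stopf("normality test undefined for constant input")
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p.value = ht$p.value)
}

#' Two-tailed paired t test of affected vs unaffected volumes
#'
#' @param affected,unaffected equal-length paired samples (n >= 2) with
#'   non-constant differences.
#' @return A list with `t`, `df`, `p.value` (two-tailed) and
#'   `mean_difference`.
#' @export
paired_comparison <- function(affected, unaffected) {
  if (length(affected) != length(unaffected))
    stopf("paired samples must have equal length")
  if (length(affected) < 2) stopf("paired test requires n >= 2")
  d <- affected - unaffected
  if (sd(d) == 0)
    stopf("zero variance of paired differences; t statistic undefined")
  ht <- t.test(affected, unaffected, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, mean_difference = unname(ht$estimate))
}

#' Pearson or Spearman correlation, with a linear fit for Pearson
#'
#' Pearson correlation for linear relationships between volume sets, with the
#' least-squares line and its 95% confidence band; Spearman rank correlation
#' (exact p for n <= 10 without ties, asymptotic otherwise) for clinical
#' covariates that may not be normally distributed.
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list of class `correlation_result`: `estimate`, `p.value`,
#'   `method`, `n`, and for Pearson `slope`, `intercept` and `conf_band` (a
#'   data frame `x`, `fit`, `lwr`, `upr`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stopf("correlation requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stopf("correlation undefined for constant input")
  out <- list(method = method, n = length(x))
  if (method == "pearson") {
    ht <- cor.test(x, y, method = "pearson")
    fit <- lm(y ~ x)
    grid <- data.frame(x = seq(min(x), max(x), length.out = 50))
    band <- predict(fit, grid, interval = "confidence", level = 0.95)
    out$estimate <- unname(ht$estimate)
    out$p.value <- ht$p.value
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
    out$conf_band <- data.frame(x = grid$x, fit = band[, "fit"],
                                lwr = band[, "lwr"], upr = band[, "upr"])
  } else {
    exact <- length(x) <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
    ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
    out$estimate <- unname(ht$estimate)
    out$p.value <- ht$p.value
  }
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.3f (n = %d, p = %.4g)\n",
              x$method, x$estimate, x$n, x$p.value))
  if (!is.null(x$slope))
    cat(sprintf("  linear fit: y = %.3f x + %.3f\n", x$slope, x$intercept))
  invisible(x)
}

#' Relative excess volumes of a cohort table
#'
#' Divides each subject's epifascial, fat and fluid excess volume by the
#' epifascial volume of the unaffected arm, normalizing differences in arm
#' size across patients.
#'
#' @param cohort data frame with columns `epifascial_unaffected_ml` (> 0) and
#'   `epifascial_excess_ml`, `fat_excess_ml`, `fluid_excess_ml`.
#' @return The cohort with `relative_epifascial_excess`,
#'   `relative_fat_excess` and `relative_fluid_excess` columns appended.
#' @export
relative_excess_table <- function(cohort) {
  need <- c("epifascial_unaffected_ml", "epifascial_excess_ml",
            "fat_excess_ml", "fluid_excess_ml")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stopf("cohort table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  denom <- cohort$epifascial_unaffected_ml
  if (any(!is.finite(denom)) || any(denom <= 0))
    stopf("unaffected epifascial volume must be positive for every subject")
  cohort$relative_epifascial_excess <- cohort$epifascial_excess_ml / denom
  cohort$relative_fat_excess <- cohort$fat_excess_ml / denom
  cohort$relative_fluid_excess <- cohort$fluid_excess_ml / denom
  cohort
}

#' Cohort summary statistics report
#'
#' For each of the six volume sets: means of the affected and unaffected
#' arms, the mean difference, Shapiro-Wilk normality p-values, and the
#' two-tailed paired t test. Also reports the Pearson correlation between
#' fat and fluid excess volumes with its linear fit. Degenerate sets (zero
#' difference variance) are flagged rather than raising.
#'
#' @param cohort data frame with per-subject columns `<metric>_affected_ml`
#'   and `<metric>_unaffected_ml` for the six metrics (as produced by
#'   [run_cohort()]).
#' @return A list of class `cohort_report`: `volume_tests` (data frame) and
#'   `fat_fluid_correlation` (a [correlate()] result, or `NULL` when
#'   degenerate).
#' @export
cohort_report <- function(cohort) {
  metrics <- c("total_arm", "subfascial", "epifascial", "muscle_subfascial",
               "fat_epifascial", "fluid_epifascial")
  rows <- lapply(metrics, function(m) {
    a <- cohort[[paste0(m, "_affected_ml")]]
    u <- cohort[[paste0(m, "_unaffected_ml")]]
    if (is.null(a) || is.null(u)) stopf("cohort table lacks columns for %s", m)
    degenerate <- sd(a - u) == 0
    sw_p <- function(v) if (diff(range(v)) == 0) NA_real_ else
      test_normality(v)$p.value
    if (degenerate) {
      data.frame(metric = m, mean_affected_ml = mean(a),
                 mean_unaffected_ml = mean(u), mean_difference_ml = mean(a - u),
                 shapiro_p_affected = sw_p(a), shapiro_p_unaffected = sw_p(u),
                 t = NA_real_, p.value = NA_real_, degenerate = TRUE)
    } else {
      pt <- paired_comparison(a, u)
      data.frame(metric = m, mean_affected_ml = mean(a),
                 mean_unaffected_ml = mean(u),
                 mean_difference_ml = pt$mean_difference,
                 shapiro_p_affected = sw_p(a), shapiro_p_unaffected = sw_p(u),
                 t = pt$t, p.value = pt$p.value, degenerate = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  fat <- cohort$fat_epifascial_affected_ml - cohort$fat_epifascial_unaffected_ml
  fluid <- cohort$fluid_epifascial_affected_ml -
    cohort$fluid_epifascial_unaffected_ml
  corr <- if (sd(fat) > 0 && sd(fluid) > 0 && length(fat) >= 3)
    correlate(fat, fluid, "pearson") else NULL
  structure(list(volume_tests = tab, fat_fluid_correlation = corr),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  tab <- x$volume_tests
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  if (!is.null(x$fat_fluid_correlation)) {
    cat("fat vs fluid excess: ")
    print(x$fat_fluid_correlation)
  }
  invisible(x)
}

#' Write a cohort report as JSON and readable text
#'
#' @param report a [cohort_report()] result.
#' @param json_path,text_path output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_cohort_report <- function(report, json_path = NULL, text_path = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  if (!is.null(json_path)) {
    x <- list(volume_tests = report$volume_tests)
    if (!is.null(report$fat_fluid_correlation)) {
      cc <- report$fat_fluid_correlation
      x$fat_fluid_correlation <- list(estimate = cc$estimate,
                                      p.value = cc$p.value, slope = cc$slope,
                                      intercept = cc$intercept, n = cc$n)
    }
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}
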