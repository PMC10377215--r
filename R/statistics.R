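#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation between two vectors with the 95% (or
#' `1 - alpha`) confidence interval from the Fisher z-transform and a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List of class `correlation_result`: `n`, `r`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
pearson_r_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3)
    stop_physari("need equal-length x, y with n >= 3", class = "physari_validation_error")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_physari("x and y must be finite", class = "physari_validation_error")
  if (sd(x) == 0 || sd(y) == 0)
    stop_physari("zero variance: correlation undefined",
                 class = "physari_validation_error")
  n <- length(x)
  r <- cor(x, y)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    hw <- qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else {
    ci <- c(-1, 1)  # the Fisher interval is undefined at n = 3 or |r| = 1
    if (abs(r) == 1) ci <- c(r, r)
  }
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(
    list(n = n, r = r, ci_low = ci[1], ci_high = ci[2],
         p = 2 * pt(-abs(t_stat), n - 2)),
    class = "correlation_result"
  )
}

#' Cohen's kappa from a 2 x 2 agreement table
#'
#' Chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)` from the cell counts of a two-rater,
#' two-category contingency table (`a` = both positive, `b` = A positive
#' only, `c` = B positive only, `d` = both negative), with the standard
#' large-sample confidence interval.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return List of class `kappa_result`: `kappa`, `ci_low`, `ci_high`,
#'   `p_o`, `p_e`, `n`.
#' @examples
#' kappa_from_table(40, 10, 10, 40)$kappa # 0.6
#' @export
kappa_from_table <- function(a, b, c, d, alpha = 0.05) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  n <- a + b + c + d
  if (n == 0) stop_physari("empty agreement table", class = "physari_validation_error")
  p_o <- (a + d) / n
  pA <- (a + b) / n; pB <- (a + c) / n
  p_e <- pA * pB + (1 - pA) * (1 - pB)
  if (p_e == 1)
    stop_physari("both raters constant and identical: kappa undefined",
                 class = "physari_undefined_kappa")
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- qnorm(1 - alpha / 2)
  structure(
    list(kappa = kappa, ci_low = kappa - z * se, ci_high = min(1, kappa + z * se),
         p_o = p_o, p_e = p_e, n = n,
         counts = c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))),
    class = "kappa_result"
  )
}

#' Pixel-wise Cohen's kappa between two segmentation masks
#'
#' Scores two raters' binary pixel labels over a common domain. By default
#' the domain is restricted to the cropped ROI rather than the full frame,
#' since the vast all-background periphery would otherwise inflate observed
#' agreement.
#'
#' @param maskA,maskB Equal-shape binary matrices (or lists of matrices,
#'   pooled into one table).
#' @param domain `NULL` (full frame), a logical/binary matrix selecting the
#'   scored pixels, or a [bounding_box()].
#' @param alpha CI level passed to [kappa_from_table()].
#' @return A `kappa_result` (see [kappa_from_table()]).
#' @export
cohen_kappa <- function(maskA, maskB, domain = NULL, alpha = 0.05) {
  if (!is.list(maskA)) { maskA <- list(maskA); maskB <- list(maskB) }
  if (length(maskA) != length(maskB))
    stop_physari("mask lists differ in length", class = "physari_validation_error")
  counts <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_along(maskA)) {
    A <- as_binary_mask(maskA[[i]]); B <- as_binary_mask(maskB[[i]])
    if (!all(dim(A) == dim(B)))
      stop_physari("masks must have equal shape", class = "physari_validation_error")
    sel <- if (is.null(domain)) {
      rep(TRUE, length(A))
    } else if (inherits(domain, "bounding_box")) {
      as.vector(embed_roi(matrix(1L, domain$height, domain$width), domain, dim(A)) == 1L)
    } else {
      as.vector(as_binary_mask(domain) == 1L)
    }
    av <- A[sel]; bv <- B[sel]
    counts <- counts + c(a = sum(av == 1 & bv == 1), b = sum(av == 1 & bv == 0),
                         c = sum(av == 0 & bv == 1), d = sum(av == 0 & bv == 0))
  }
  kappa_from_table(counts["a"], counts["b"], counts["c"], counts["d"], alpha = alpha)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic for the first group (`U = R_A - nA(nA+1)/2` with
#' midranks for ties), with an exact p-value for small untied samples and
#' the tie-corrected normal approximation otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param groupA,groupB Non-empty numeric vectors.
#' @return List: `U` (for group A), `p`, `nA`, `nB`.
#' @export
mann_whitney_u <- function(groupA, groupB) {
  if (length(groupA) < 1 || length(groupB) < 1)
    stop_physari("both groups must be non-empty", class = "physari_validation_error")
  wt <- suppressWarnings(wilcox.test(groupA, groupB, exact = NULL, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       nA = length(groupA), nB = length(groupB))
}

#' Kolmogorov-Smirnov normality test (Lilliefors-corrected)
#'
#' Tests a sample against a normal distribution with mean and SD estimated
#' from the sample itself. Because the parameters are estimated, the plain
#' KS null distribution is too conservative; the Lilliefors correction
#' (via `nortest::lillie.test`) is used.
#'
#' @param x Numeric vector, n >= 4, nonzero variance.
#' @return List: `D`, `p`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 4)
    stop_physari("need n >= 4 for the normality test", class = "physari_validation_error")
  if (sd(x) == 0)
    stop_physari("zero variance: normality test undefined",
                 class = "physari_validation_error")
  lt <- nortest::lillie.test(x)
  list(D = unname(lt$statistic), p = lt$p.value)
}

#' Multiple regression of ARI on subject and device characteristics
#'
#' Ordinary least squares of a response on a predictor table, reporting per
#' predictor the coefficient, SE, partial correlation
#' (`t / sqrt(t^2 + df)`), t and two-sided p, plus the intercept, R^2, the
#' model F-ratio and its p-value. The default predictor set in the pipeline
#' mirrors the device-influence analysis: age, sex, field strength, pixel
#' size, image-matrix area, pixel count, slice thickness, visible-slice
#' count and the total width of the study area (`Ts x Ns`).
#'
#' @param y Numeric response (e.g., per-subject mean ARI).
#' @param X Data frame of numeric predictors (factors must be pre-coded).
#' @return List of class `regression_table`: `table` (data frame with
#'   term, coefficient, se, r_partial, t, p), `r_squared`, `f`, `df1`,
#'   `df2`, `model_p`, `n`.
#' @section Errors: a rank-deficient design raises a diagnostics error
#'   naming the collinear columns.
#' @export
multiple_regression <- function(y, X) {
  X <- as.data.frame(X)
  if (length(y) != nrow(X))
    stop_physari("y and X disagree in length", class = "physari_validation_error")
  if (length(y) <= ncol(X) + 1)
    stop_physari("need n > p + 1 observations", class = "physari_validation_error")
  fit <- lm(y ~ ., data = X)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_physari("rank-deficient design; collinear columns: ",
                 paste(bad, collapse = ", "), class = "physari_rank_error")
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  df2 <- fit$df.residual
  terms <- rownames(ct)
  r_partial <- ifelse(terms == "(Intercept)", NA_real_,
                      ct[, "t value"] / sqrt(ct[, "t value"]^2 + df2))
  tab <- data.frame(
    term = terms, coefficient = ct[, "Estimate"], se = ct[, "Std. Error"],
    r_partial = r_partial, t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  f <- sm$fstatistic
  structure(
    list(table = tab, r_squared = sm$r.squared,
         f = unname(f[1]), df1 = unname(f[2]), df2 = unname(f[3]),
         model_p = unname(pf(f[1], f[2], f[3], lower.tail = FALSE)),
         n = length(y)),
    class = "regression_table"
  )
}

#' Descriptive summary row
#'
#' N, mean, sample SD (n-1 denominator), 95% CI of the mean
#' (t-distribution), SEM, median (midpoint convention for even n), min and
#' max -- the descriptive layout used for cohort and device tables.
#'
#' @param values Numeric vector, n >= 2.
#' @param label Row label.
#' @return One-row data frame.
#' @examples
#' cohort_summary(rep(c(3, 1.5, 1), c(11, 30, 9)), "Field strength (T)")
#' @export
cohort_summary <- function(values, label = "") {
  n <- length(values)
  if (n < 2)
    stop_physari("need n >= 2 for a descriptive summary",
                 class = "physari_validation_error")
  m <- mean(values); s <- sd(values); sem <- s / sqrt(n)
  tq <- qt(0.975, n - 1)
  data.frame(
    label = label, n = n, mean = m, sd = s,
    ci_low = m - tq * sem, ci_high = m + tq * sem, sem = sem,
    median = median(values), min = min(values), max = max(values),
    stringsAsFactors = FALSE
  )
}

#' Average ARI over observers, per subject
#'
#' The arithmetic mean of the observers' ARI values for each subject --
#' the response used in the correlation and regression analyses.
#'
#' @param morph_table Data frame from [morphometry_table()] (columns
#'   subject_id, observer_id, ARI; covariates are carried through).
#' @return Data frame with one row per subject: subject_id, age, sex,
#'   device covariates, Ns, Ts, total_width and `ARI` (the observer mean).
#' @section Errors: a subject missing under some observer raises a
#'   completeness error.
#' @export
average_over_observers <- function(morph_table) {
  obs <- unique(morph_table$observer_id)
  counts <- table(morph_table$subject_id)
  if (any(counts != length(obs)))
    stop_physari("incomplete observer coverage for subject(s): ",
                 paste(names(counts)[counts != length(obs)], collapse = ", "),
                 class = "physari_completeness_error")
  agg <- aggregate(ARI ~ subject_id, data = morph_table, FUN = mean)
  keep_cols <- intersect(
    c("subject_id", "age", "sex", "device", "field_strength", "pixel_size_mm2",
      "n_pixels", "matrix_area_mm2", "Ns", "Ts", "total_width"),
    names(morph_table))
  first <- morph_table[!duplicated(morph_table$subject_id), keep_cols, drop = FALSE]
  out <- merge(first, agg, by = "subject_id", sort = TRUE)
  out[order(out$subject_id), , drop = FALSE]
}
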