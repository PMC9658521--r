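#' Two-group comparison with normality and variance screening
#'
#' The decision procedure used for male-versus-female trait comparisons:
#' each group is screened with a Shapiro-Wilk normality test; if both are
#' non-significant at `alpha`, Levene's test decides between equal and
#' unequal variances; equal variances lead to a Student's t-test, unequal
#' to a Welch's t-test. A significant Shapiro test flags the result
#' `nonparametric_needed` rather than silently switching test — no
#' nonparametric fallback is applied (all groups in the motivating study
#' were parametric), but the t-test is still reported for inspection.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param alpha screening significance level.
#' @param levene_center `"mean"` (original Levene, default) or `"median"`
#'   (Brown-Forsythe).
#' @return An object of class `nectar_test_result`: `test_name`
#'   (`"student_t"` or `"welch_t"`), `statistic`, `p_value`, `n` (per
#'   group), `decision_path` (character vector of branches taken),
#'   `stars`, `shapiro_p`, `levene_p`, `nonparametric_needed`.
#' @export
compare_groups <- function(a, b, alpha = 0.05,
                           levene_center = c("mean", "median")) {
  levene_center <- match.arg(levene_center)
  if (length(a) < 3 || length(b) < 3) stop("each sample needs n >= 3")
  sh_a <- stats::shapiro.test(a)$p.value
  sh_b <- stats::shapiro.test(b)$p.value
  nonpar <- sh_a < alpha || sh_b < alpha
  path <- if (nonpar) "shapiro_significant" else "shapiro_ok"
  centre_fun <- if (levene_center == "mean") mean else stats::median
  lev <- car::leveneTest(c(a, b),
                         factor(rep(c("a", "b"), c(length(a), length(b)))),
                         center = centre_fun)
  lev_p <- lev$`Pr(>F)`[1]
  equal_var <- lev_p >= alpha
  path <- c(path, if (equal_var) "levene_equal" else "levene_unequal")
  tt <- stats::t.test(a, b, var.equal = equal_var)
  test_name <- if (equal_var) "student_t" else "welch_t"
  path <- c(path, test_name)
  structure(list(test_name = test_name,
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n = c(a = length(a), b = length(b)),
                 decision_path = path,
                 stars = significance_stars(tt$p.value),
                 shapiro_p = c(a = sh_a, b = sh_b),
                 levene_p = lev_p,
                 nonparametric_needed = nonpar),
            class = "nectar_test_result")
}

#' @export
print.nectar_test_result <- function(x, ...) {
  cat(sprintf("<%s> t = %.4g, p = %.4g %s  [%s]%s\n", x$test_name,
              x$statistic, x$p_value, x$stars,
              paste(x$decision_path, collapse = " -> "),
              if (x$nonparametric_needed) "  (nonparametric needed)" else ""))
  invisible(x)
}

#' Significance-star label for a p-value
#'
#' Strict-inequality bins: `p < 0.001` gives `"***"`, `p < 0.01` `"**"`,
#' `p < 0.05` `"*"`, otherwise `"N.S."` (not significant; `p = 0.05`
#' exactly is not significant).
#'
#' @param p p-value in `[0, 1]`.
#' @return One of `"N.S."`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1)
    stop("p must lie in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "N.S."
}

#' Ordinary least-squares fit with Pearson correlation
#'
#' Closed-form simple linear regression: slope `Sxy/Sxx`, intercept from
#' the means, Pearson r, `R^2 = r^2`, and a two-sided p-value for the
#' correlation from the t transform `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom. An exact permutation p-value is available for small
#' samples.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; `var(x) > 0`.
#' @param permutation_p if `TRUE`, additionally compute a permutation
#'   p-value (exact up to `n = 7`, otherwise 10,000 seeded resamples).
#' @return An object of class `regression_result`: `slope`, `intercept`,
#'   `r`, `r_squared`, `p_value`, `n` (and `p_permutation` on request).
#' @export
linear_fit <- function(x, y, permutation_p = FALSE) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("need equal-length x, y with n >= 3")
  if (stats::var(x) == 0) stop("x is constant; slope undefined")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  r2 <- r^2
  p <- if (r2 >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  out <- list(slope = slope, intercept = intercept, r = r, r_squared = r2,
              p_value = p, n = n)
  if (permutation_p) {
    stat <- abs(r)
    perm_r <- function(yy) {
      s <- sum((x - mean(x)) * (yy - mean(yy)))
      if (syy == 0) 0 else abs(s / sqrt(sxx * syy))
    }
    if (n <= 7) {
      perms <- .permutations(n)
      vals <- apply(perms, 1, function(p_) perm_r(y[p_]))
      out$p_permutation <- mean(vals >= stat - 1e-12)
    } else {
      restore <- .restore_seed(); on.exit(restore())
      set.seed(sum(utf8ToInt("permute")))
      vals <- replicate(10000, perm_r(sample(y)))
      out$p_permutation <- (sum(vals >= stat - 1e-12) + 1) / (10000 + 1)
    }
  }
  structure(out, class = "regression_result")
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression> y = %.4g x + %.4g; r = %.3f, R2 = %.3f, p = %.4g (n = %d)\n",
              x$slope, x$intercept, x$r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regression between two measurement fields over a cohort
#'
#' Filters a cohort of per-flower measurement records by sex group, drops
#' rows where either field is missing (counting them), and delegates to
#' [linear_fit()].
#'
#' @param records data.frame of measurement records (e.g. rows from
#'   [measure_flower()] or [make_synthetic_cohort()]).
#' @param x_field,y_field column names to regress (y on x).
#' @param group `"male"`, `"female"` or `"pooled"`.
#' @param ... passed to [linear_fit()].
#' @return A `regression_result` with extra fields `group` and
#'   `n_dropped`.
#' @export
correlate_cohort <- function(records, x_field, y_field,
                             group = c("pooled", "male", "female"), ...) {
  group <- match.arg(group)
  stopifnot(all(c(x_field, y_field) %in% names(records)))
  df <- if (group == "pooled") records else records[records$sex == group, ]
  ok <- stats::complete.cases(df[, c(x_field, y_field)])
  n_dropped <- sum(!ok)
  df <- df[ok, ]
  if (nrow(df) < 3)
    stop("fewer than 3 usable records in group '", group, "'")
  fit <- linear_fit(df[[x_field]], df[[y_field]], ...)
  fit$group <- group
  fit$n_dropped <- n_dropped
  fit
}
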