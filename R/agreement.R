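# Multi-scorer and multi-device agreement statistics: Cohen's kappa with
# confusion matrices, ICC(3,1) (two-way mixed, consistency, single
# measurement), Mann-Whitney U, pooled-variance t-test and one-way
# repeated-measures ANOVA.

new_agreement_result <- function(method, estimate, ci95, p, n,
                                 interpretation = NA_character_,
                                 extra = list()) {
  structure(c(list(method = method, estimate = estimate, ci95 = ci95,
                   p = p, n = n, interpretation = interpretation), extra),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<%s> estimate = %.4f, 95%% CI [%.4f, %.4f], p = %.4g, n = %d\n",
              x$method, x$estimate, x$ci95[1], x$ci95[2], x$p, x$n))
  if (!is.na(x$interpretation)) {
    cat("  interpretation:", x$interpretation, "\n")
  }
  invisible(x)
}

#' @rdname cohen_kappa
#' @param x an `agreement_result`.
#' @param ... unused.
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate,
         conf.low = x$ci95[1], conf.high = x$ci95[2],
         p.value = x$p, n = x$n, interpretation = x$interpretation)
}

#' @rdname cohen_kappa
#' @export
glance.agreement_result <- function(x, ...) tidy(x, ...)

#' Cohen's kappa between two scorers
#'
#' Unweighted kappa over the five sleep stages with marginal-product
#' chance agreement: `kappa = (p_o - p_e) / (1 - p_e)`. The 5x5 confusion
#' matrix (rows = scorer `a`, columns = scorer `b`) is attached, along
#' with its row-normalized version for display. Epoch pairs where either
#' label is missing are dropped and the effective `n` reported. The
#' p-value tests kappa = 0 with the large-sample null variance; the CI is
#' the large-sample Wald interval. Both raters constant and equal
#' (`p_e = 1`) yields a missing kappa.
#'
#' @param a,b equal-length character vectors of stage labels.
#' @return An `agreement_result` with elements `confusion` and
#'   `confusion_row_norm`; use [tidy()] for a tibble.
#' @export
#' @examples
#' k <- cohen_kappa(c("W", "W", "N2", "N2"), c("W", "N2", "W", "N2"))
#' tidy(k)
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) abort("need at least 2 scored epochs")
  assert_stages(a, "a"); assert_stages(b, "b")
  fa <- factor(a, levels = SLEEP_STAGES)
  fb <- factor(b, levels = SLEEP_STAGES)
  tab <- table(fa, fb)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  pe <- sum(pr * pc)
  if (1 - pe < 1e-12) {
    k <- NA_real_; ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    k <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    ci <- k + c(-1, 1) * qnorm(0.975) * se
    var0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
    z <- k / sqrt(var0)
    p <- 2 * pnorm(-abs(z))
  }
  new_agreement_result(
    "cohen_kappa", k, ci, p, as.integer(n),
    extra = list(confusion = unclass(tab),
                 confusion_row_norm = sweep(unclass(tab), 1,
                                            pmax(rowSums(tab), 1), "/"),
                 p_o = po, p_e = pe))
}

#' ICC(3,1): two-way mixed, consistency, single measurement
#'
#' Computed from the two-way ANOVA mean squares:
#' `ICC = (MS_rows - MS_error) / (MS_rows + (k - 1) MS_error)`, where rows
#' are subjects and columns raters/devices. The 95% CI uses the standard
#' F-distribution bounds and the p-value the F test of `MS_rows /
#' MS_error`. Being a consistency coefficient it ignores fixed
#' rater offsets. The qualitative interpretation follows the conventional
#' bands (see [interpret_icc()]).
#'
#' @param ratings data frame or matrix, subjects x raters (`n >= 3`,
#'   `k >= 2`, complete).
#' @return An `agreement_result`; use [tidy()] for a tibble.
#' @export
icc_consistency <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) abort("`ratings` must be numeric")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) abort("need at least 3 subjects and 2 raters")
  if (any(is.na(m))) abort("missing cells are not supported")
  g <- mean(m)
  rmeans <- rowMeans(m)
  cmeans <- colMeans(m)
  ssr <- k * sum((rmeans - g)^2)
  ssc <- n * sum((cmeans - g)^2)
  sst <- sum((m - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- max(sse, 0) / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse <= 0) {
    return(new_agreement_result("icc_consistency", NA_real_,
                                c(NA_real_, NA_real_), NA_real_, n))
  }
  if (mse == 0) {
    # raters agree perfectly up to a constant offset
    return(new_agreement_result(
      "icc_consistency", 1, c(1, 1), 0, n,
      interpretation = "excellent",
      extra = list(ms_rows = msr, ms_error = 0, k = k, F = Inf,
                   df1 = n - 1, df2 = (n - 1) * (k - 1))))
  }
  # guard against icc = 1 + eps from floating-point cancellation
  icc <- min((msr - mse) / (msr + (k - 1) * mse), 1)
  f <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  fl <- f / qf(0.975, df1, df2)
  fu <- f * qf(0.975, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  new_agreement_result("icc_consistency", icc, ci, p, n,
                       interpretation = interpret_icc(icc),
                       extra = list(ms_rows = msr, ms_error = mse,
                                    k = k, F = f, df1 = df1, df2 = df2))
}

#' Qualitative interpretation of an ICC value
#'
#' Below 0.5: poor; 0.5 to below 0.75: moderate; 0.75 to below 0.9: good;
#' 0.9 and above: excellent.
#'
#' @param value ICC estimate (`<= 1`).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(value) {
  if (is.na(value)) return(NA_character_)
  if (value > 1) abort("ICC cannot exceed 1")
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.9) "good"
  else "excellent"
}

#' Mann-Whitney U test
#'
#' Nonparametric two-sample location test via [stats::wilcox.test()]: the
#' exact null distribution for small tie-free samples, otherwise the
#' tie-corrected normal approximation with continuity correction. `U`
#' counts pairs `(x_i, y_j)` with `x_i > y_j` (+ 1/2 per tie), so
#' identical multisets give `U = n_x n_y / 2` and fully separated samples
#' (all x below all y) give `U = 0`.
#'
#' @param x,y numeric samples (non-empty).
#' @return Tibble with `U`, `p`, `n_x`, `n_y`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble(U = unname(wt$statistic), p = wt$p.value,
         n_x = length(x), n_y = length(y))
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided independent-samples t-test assuming equal variances.
#'
#' @param x,y numeric samples with `n >= 2` each.
#' @return Tibble with `t`, `df`, `p`.
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("need n >= 2 in each sample")
  tt <- t.test(x, y, var.equal = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject ANOVA with `F = MS_condition / MS_(condition x subject)`
#' on `(k - 1, (k - 1)(n - 1))` degrees of freedom, fitted with
#' [stats::aov()] using a subject error stratum.
#'
#' @param values data frame or matrix, subjects x conditions (complete,
#'   `n >= 2`, `k >= 2`).
#' @return Tibble with `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(values) {
  m <- as.matrix(values)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) abort("need at least 2 subjects and 2 conditions")
  if (any(is.na(m))) abort("missing cells are not supported")
  df <- tibble(
    value = as.numeric(m),
    subject = factor(rep(seq_len(n), times = k)),
    condition = factor(rep(seq_len(k), each = n)))
  fit <- aov(value ~ condition + Error(subject), data = df)
  s <- summary(fit)[["Error: Within"]][[1]]
  ms_cond <- s["condition", "Mean Sq"]
  ms_err <- s["Residuals", "Mean Sq"]
  # guard against rounding residue masquerading as variance
  tol <- 1e-12 * sum((m - mean(m))^2) / length(m) + 1e-300
  if (ms_cond < tol) {
    return(tibble(F = 0, df1 = k - 1, df2 = (k - 1) * (n - 1), p = 1))
  }
  if (!is.finite(ms_err) || ms_err < tol) {
    abort("degenerate table: zero error mean square")
  }
  tibble(F = ms_cond / ms_err, df1 = k - 1, df2 = (k - 1) * (n - 1),
         p = pf(ms_cond / ms_err, k - 1, (k - 1) * (n - 1),
                lower.tail = FALSE))
}
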