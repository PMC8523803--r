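#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, used for
#' donor-vs-HF comparisons of composition fractions.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return List with `statistic`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) stop("each group needs n >= 2")
  if (sd(group_a) == 0 && sd(group_b) == 0) stop("both groups have zero variance")
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    mean_a = mean(group_a),
    mean_b = mean(group_b)
  )
}

#' Group comparison: one-way ANOVA plus pairwise variance F tests
#'
#' @param values numeric vector.
#' @param groups group labels (e.g. donor/IC/NIC), same length as `values`.
#' @return List with `anova_F`, `anova_p`, and `f_tests`, a data frame of
#'   pairwise variance-ratio tests (ratio, p).
#' @export
group_tests <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  pairs <- utils::combn(levels(groups), 2)
  f_rows <- apply(pairs, 2, function(pr) {
    a <- values[groups == pr[1]]
    b <- values[groups == pr[2]]
    vt <- var.test(a, b)
    data.frame(
      group1 = pr[1], group2 = pr[2],
      variance_ratio = unname(vt$estimate), p = vt$p.value
    )
  })
  list(
    anova_F = tab[["F value"]][1],
    anova_p = tab[["Pr(>F)"]][1],
    f_tests = do.call(rbind, f_rows)
  )
}

#' Linear regression y = A x + B with comparison to a constant model
#'
#' Least-squares fit reporting the slope, intercept, coefficient of
#' determination, and the F-test p value against the intercept-only model
#' (the form used to relate conduction-velocity summaries to fibrosis
#' measures).
#'
#' @param x,y numeric vectors, `n >= 3`, `x` not constant.
#' @return List of class `regression_fit`: `A` (slope), `B` (intercept),
#'   `R2`, `p_vs_constant`, `n`.
#' @export
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite observations")
  if (diff(range(x)) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  structure(
    list(
      A = unname(coef(fit)[2]),
      B = unname(coef(fit)[1]),
      R2 = sm$r.squared,
      p_vs_constant = p,
      n = length(x)
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4g x + %.4g   (R2 = %.3f, p vs constant = %.3g, n = %d)\n",
              x$A, x$B, x$R2, x$p_vs_constant, x$n))
  invisible(x)
}
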