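#' Simple linear regression with F-test
#'
#' Ordinary least squares of `y` on a single predictor, reported the way
#' the experiment summaries need it: slope, intercept, the overall
#' F-statistic with (1, n-2) degrees of freedom, its tail p-value and R^2.
#'
#' @param x,y numeric vectors of equal length (n >= 3); `x` must not be
#'   constant.
#' @return an object of class `mcl_regression`.
#' @export
#' @examples
#' linear_regression_f(1:5, 2 * (1:5) + 1)
linear_regression_f <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("insufficient data: need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate predictor: x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  df2 <- n - 2
  if (ss_res <= 1e-12 * max(ss_tot, 1)) {
    f <- Inf; p <- 0; r2 <- 1
  } else {
    f <- ss_reg / (ss_res / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
    r2 <- ss_reg / ss_tot
  }
  if (ss_tot == 0) { f <- 0; p <- 1; r2 <- 0 }
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 n = n, f_statistic = f, df = c(1, df2), p_value = p,
                 r_squared = r2),
            class = "mcl_regression")
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition across k groups
#' (fixed effects, equal-variance F-test), as used to compare outcome
#' variables between experimental conditions.
#'
#' @param groups list of numeric vectors (k >= 2 groups, each with at
#'   least 2 values); names are used as group labels.
#' @return an object of class `mcl_anova` with group means, F, df and p.
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
one_way_anova <- function(groups) {
  if (length(groups) < 2)
    stop("insufficient data: need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2))
    stop("insufficient data: every group needs at least 2 values",
         call. = FALSE)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, vapply(groups, length, 0L)), levels = labels)
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  f <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  ss_b <- tab[1, "Sum Sq"]; ss_w <- tab[2, "Sum Sq"]
  tot <- ss_b + ss_w
  if (ss_b <= 1e-12 * max(tot, 1)) {
    f <- 0; p <- 1
  } else if (ss_w <= 1e-12 * max(tot, 1)) {
    f <- Inf; p <- 0
  }
  structure(list(labels = labels,
                 group_means = vapply(groups, mean, 0),
                 f_statistic = unname(f),
                 df = unname(c(tab[1, "Df"], tab[2, "Df"])),
                 p_value = unname(p)),
            class = "mcl_anova")
}

#' Multiple linear regression with overall F-test
#'
#' OLS with intercept on a design matrix of predictors; reports the
#' coefficient vector and the overall F-test against the intercept-only
#' model.
#'
#' @param design numeric matrix (n x p) of predictors, optionally with
#'   column names; must have full column rank.
#' @param y response vector of length n (n > p + 1).
#' @return an object of class `mcl_mreg` with `coefficients` (intercept
#'   first), `f_statistic`, `df`, `p_value`, `r_squared`, `n`.
#' @export
multiple_regression <- function(design, y) {
  design <- as.matrix(design)
  n <- length(y)
  p <- ncol(design)
  stopifnot(nrow(design) == n)
  if (n <= p + 1)
    stop("insufficient data: need n > number of predictors + 1",
         call. = FALSE)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(p))
  X <- cbind(`(Intercept)` = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinearity error: rank-deficient design (columns: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  df2 <- n - p - 1
  if (ss_res <= 1e-12 * max(ss_tot, 1)) {
    f <- Inf; pv <- 0; r2 <- 1
  } else {
    f <- ((ss_tot - ss_res) / p) / (ss_res / df2)
    pv <- stats::pf(f, p, df2, lower.tail = FALSE)
    r2 <- 1 - ss_res / ss_tot
  }
  structure(list(coefficients = beta, f_statistic = f, df = c(p, df2),
                 p_value = pv, r_squared = r2, n = n),
            class = "mcl_mreg")
}

#' @export
print.mcl_regression <- function(x, ...) {
  cat(sprintf("slope %.4g, intercept %.4g; F(%d, %d) = %.3f, p = %.3g, R^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$df[1], x$df[2], x$f_statistic,
              x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' @export
print.mcl_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value))
  cat("group means:", paste(sprintf("%s = %.3f", x$labels, x$group_means),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mcl_mreg <- function(x, ...) {
  cat(sprintf("multiple regression (n = %d): overall F(%d, %d) = %.3f, p = %.3g, R^2 = %.3f\n",
              x$n, x$df[1], x$df[2], x$f_statistic, x$p_value, x$r_squared))
  print(round(x$coefficients, 6))
  invisible(x)
}
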