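new_assoc_test <- function(kind, statistic, p, df, n, extra = list()) {
  structure(c(list(kind = kind, statistic = unname(statistic),
                   p = unname(p), df = unname(df), n = n), extra),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("<assoc_test> %s: statistic = %.4g, df = %s, p = %.3g\n",
              x$kind, x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Paired two-tailed t-test
#'
#' Matched tumor/normal comparison: two-tailed paired Student t with
#' df = n - 1, where n is the number of pairs. Degenerate inputs
#' (all differences equal) raise an error rather than returning NaN.
#'
#' @param x,y Equal-length numeric vectors in matching pair order.
#' @return An `assoc_test` with `kind = "paired_t"`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("paired test needs equal lengths",
                                   call. = FALSE)
  if (length(x) < 2L) stop("need >= 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::var(d) == 0) {
    stop("differences have zero variance; paired t undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  new_assoc_test("paired_t", ht$statistic, ht$p.value, ht$parameter,
                 length(x), list(mean_difference = unname(ht$estimate)))
}

#' Unpaired two-tailed t-test
#'
#' Two-tailed Student t for independent groups. Defaults to the classical
#' pooled-variance form; Welch's unequal-variance form via `var_equal =
#' FALSE`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (classical Student test, default).
#' @return An `assoc_test` with `kind = "unpaired_t"`.
#' @export
unpaired_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups are constant; t-test degenerate", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  new_assoc_test("unpaired_t", ht$statistic, ht$p.value, ht$parameter,
                 c(length(x), length(y)),
                 list(mean_x = mean(x), mean_y = mean(y),
                      pooled = var_equal))
}

#' Pearson correlation with least-squares line and 95% confidence band
#'
#' Pearson r with its two-sided P value (t = r * sqrt((n-2)/(1-r^2))),
#' the least-squares regression of y on x, and the pointwise 95% confidence
#' band for the conditional mean evaluated on a grid over the x-range — the
#' standard "regression line with gray band" display for score-vs-score
#' panels.
#'
#' @param x,y Numeric vectors of equal length >= 3; both nonconstant.
#' @param grid Numeric vector of x positions for the band, or an integer
#'   count of evenly spaced points over `range(x)` (default 100).
#' @param conf_level Confidence level for the band (default 0.95).
#' @return Object of class `correlation_result`: `r`, `p`, `n`, `df`,
#'   `slope`, `intercept`, `band` (data frame `x`, `fit`, `lower`, `upper`,
#'   `half_width`), `degenerate` (TRUE when |r| = 1, where p is reported
#'   as 0).
#' @export
pearson_with_regression <- function(x, y, grid = 100L, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need >= 3 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  degenerate <- abs(r) >= 1 - 1e-12
  if (degenerate) {
    p <- 0
  } else {
    p <- stats::cor.test(x, y, method = "pearson")$p.value
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  if (length(grid) == 1L && grid == round(grid)) {
    grid <- seq(min(x), max(x), length.out = as.integer(grid))
  }
  pr <- stats::predict(fit, newdata = data.frame(x = grid),
                       interval = "confidence", level = conf_level)
  band <- data.frame(x = grid, fit = pr[, "fit"], lower = pr[, "lwr"],
                     upper = pr[, "upr"],
                     half_width = (pr[, "upr"] - pr[, "lwr"]) / 2)
  structure(list(r = r, p = p, n = n, df = n - 2,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 band = band, conf_level = conf_level,
                 degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f, p = %.3g, n = %d\n",
              x$r, x$p, x$n))
  cat(sprintf("  y = %.4g + %.4g x (%g%% pointwise band over %d grid points)\n",
              x$intercept, x$slope, 100 * x$conf_level, nrow(x$band)))
  invisible(x)
}
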