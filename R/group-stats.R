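#' Two-group comparison of a trait statistic
#'
#' Compares two groups of values (e.g. per-sample abundance-weighted mean
#' copy numbers in disturbed vs stable periods) by Welch's t test
#' (default) or the Mann-Whitney U test, two-sided.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @param method `"welch"` or `"mann-whitney"`.
#' @return list with `method`, `statistic`, `p_value`, `n`, group means.
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("welch", "mann-whitney")) {
  method <- match.arg(method)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 non-missing values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      method == "welch")
    stop("both groups are constant; Welch's t is undefined")
  res <- if (method == "welch") stats::t.test(values_a, values_b)
         else stats::wilcox.test(values_a, values_b, exact = FALSE)
  list(method = method, statistic = unname(res$statistic),
       p_value = res$p.value, n = c(length(values_a), length(values_b)),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Normality check of replication-index values
#'
#' One-sample Kolmogorov-Smirnov test of the values against
#' Normal(`mu`, `sigma`). When `mu`/`sigma` are not supplied they are
#' fitted from the sample and the Lilliefors-corrected test is used
#' instead (the plain KS null distribution is not valid with estimated
#' parameters). Also returns theoretical-vs-empirical quantile pairs for
#' a QQ plot.
#'
#' @param values numeric vector (>= 20 values).
#' @param mu,sigma optional mean and sd of the reference normal.
#' @return list with `p_value`, `statistic`, `mu`, `sigma`, `fitted`
#'   (logical) and `qq` (data.frame `theoretical`, `empirical`).
#' @export
irep_normality <- function(values, mu = NULL, sigma = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 20) stop("need at least 20 values")
  fitted <- is.null(mu) || is.null(sigma)
  if (is.null(mu)) mu <- mean(values)
  if (is.null(sigma)) sigma <- stats::sd(values)
  if (sigma <= 0) stop("sigma must be positive")
  test <- if (fitted) nortest::lillie.test(values)
          else suppressWarnings(stats::ks.test(values, "pnorm", mu, sigma))
  qq <- data.frame(
    theoretical = stats::qnorm(stats::ppoints(length(values)), mu, sigma),
    empirical = sort(values))
  list(p_value = test$p.value, statistic = unname(test$statistic),
       mu = mu, sigma = sigma, fitted = fitted, qq = qq)
}

# midrank Spearman correlation with t-approximation p-value
spearman_midrank <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = min(p, 1), n = n)
}

#' Spearman correlation of rrn copy number and mean replication index
#'
#' Rank correlation (midranks for ties) between per-MAG copy numbers and
#' per-MAG mean iRep values, with a two-sided t-approximation p-value.
#'
#' @param copy_numbers numeric vector of per-MAG copy numbers.
#' @param mean_irep numeric vector of per-MAG mean iRep values (same
#'   order/names).
#' @return list with `rho`, `p_value`, `n`; errors on constant input.
#' @export
rrn_vs_irep <- function(copy_numbers, mean_irep) {
  keep <- !is.na(copy_numbers) & !is.na(mean_irep)
  x <- copy_numbers[keep]; y <- mean_irep[keep]
  if (length(x) < 5) stop("need at least 5 paired values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant vector; rank correlation undefined")
  s <- spearman_midrank(x, y)
  list(rho = s$rho, p_value = s$p, n = s$n)
}
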