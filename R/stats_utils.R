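#' Correlation with a t-based p-value
#'
#' Pearson product-moment correlation, or Spearman's rank correlation
#' computed as the Pearson correlation of average ranks. In both cases the
#' two-sided p-value comes from `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y Equal-length finite numeric vectors, `n >= 3`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r`, `n`, `p_two_sided`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L)
    stop_vtbci("correlation needs n >= 3", "vtbci_bad_input")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_vtbci("correlation inputs must be finite", "vtbci_bad_input")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_vtbci("correlation undefined: zero variance", "vtbci_zero_variance")
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, n = n, p_two_sided = p, method = method)
}

#' Sample size for detecting a correlation
#'
#' Fisher-z approximation:
#' \deqn{n = \lceil ((z_{1-\alpha/2} + z_{power}) / \mathrm{atanh}(\rho))^2
#'   + 3 \rceil}
#' following the classical sample-size tables, whose normal quantiles are
#' conventionally taken to two decimals (1.96 and 0.84 for two-sided
#' alpha = 0.05 at 80% power). For a medium-large effect of 0.5 at 80%
#' power and two-sided alpha = 0.05 this gives the standard tabled value
#' of 29 participants.
#'
#' @param rho Hypothesised correlation, in (0, 1).
#' @param alpha Significance level, default 0.05.
#' @param power Target power, default 0.80.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return The minimal sample size (integer).
#' @export
#' @examples
#' corr_sample_size(0.5, 0.05, 0.80)  # 29
corr_sample_size <- function(rho, alpha = 0.05, power = 0.80,
                             two_sided = TRUE) {
  stopifnot(rho > 0, rho < 1, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- round(stats::qnorm(1 - alpha / (if (two_sided) 2 else 1)), 2)
  zb <- round(stats::qnorm(power), 2)
  as.integer(ceiling(((za + zb) / atanh(rho))^2 + 3))
}
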