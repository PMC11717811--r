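#' Two-group t-test
#'
#' Thin, validated wrapper around the standard t statistic: unpaired
#' (pooled-variance by default) or paired, two-sided.
#'
#' @param x,y numeric samples (n >= 2 each; equal lengths when paired).
#' @param paired paired test?
#' @param var_equal pooled variance for the unpaired test (default TRUE).
#' @return List with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference). Errors when the data are constant (zero variance in both
#'   groups).
#' @export
two_group_ttest <- function(x, y, paired = FALSE, var_equal = TRUE) {
  check_flag_(paired, "paired")
  if (length(x) < 2L || length(y) < 2L)
    stop("need n >= 2 per group", call. = FALSE)
  if (paired && length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  ht <- tryCatch(
    t.test(x, y, paired = paired, var.equal = var_equal),
    error = function(e)
      stop("t-test undefined: ", conditionMessage(e), call. = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       estimate = if (paired) unname(ht$estimate)
       else unname(diff(rev(ht$estimate))))
}

#' Power of a paired t-test
#'
#' Exact noncentral-t power for a paired design: `n` pairs, standardized
#' effect size `d` (mean difference over the SD of differences), so the
#' noncentrality parameter is `d * sqrt(n)` with `n - 1` degrees of freedom.
#' At `d = 0` the two-sided power equals `alpha`.
#'
#' @param n number of pairs (>= 2).
#' @param d standardized effect size (>= 0).
#' @param alpha significance level (default 0.05).
#' @param two_sided two-sided test (default TRUE).
#' @return Power in `[0, 1]`.
#' @examples
#' paired_t_power(5, 1.68)  # ~0.80
#' @export
paired_t_power <- function(n, d, alpha = 0.05, two_sided = TRUE) {
  check_number_(n, "n", lower = 2, integer = TRUE)
  check_number_(d, "d", lower = 0)
  check_number_(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_flag_(two_sided, "two_sided")
  df <- n - 1
  ncp <- d * sqrt(n)
  if (two_sided) {
    crit <- qt(1 - alpha / 2, df)
    pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
  } else {
    pt(qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Smallest detectable standardized effect of a paired t-test
#'
#' The smallest standardized effect size `d` whose paired-t power reaches
#' the target, found by root-finding on the exact noncentral-t power curve.
#' With `n = 5`, `alpha = 0.05` two-sided and 80% power this is about 1.7;
#' with `n = 3`, about 3.3.
#'
#' @inheritParams paired_t_power
#' @param power target power in `(alpha, 1)`.
#' @return Standardized effect size `d`.
#' @export
paired_t_detectable_effect <- function(n, alpha = 0.05, power = 0.80,
                                       two_sided = TRUE) {
  check_number_(n, "n", lower = 2, integer = TRUE)
  check_number_(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  check_number_(power, "power", lower = 0, upper = 1, strict_lower = TRUE)
  if (power >= 1 || power <= alpha)
    stop("`power` must lie in (alpha, 1)", call. = FALSE)
  f <- function(d) paired_t_power(n, d, alpha, two_sided) - power
  upper <- 10
  while (f(upper) < 0 && upper < 1e4) upper <- upper * 2
  if (f(upper) < 0)
    stop("detectable-effect search failed to bracket the target power",
         call. = FALSE)
  uniroot(f, c(0, upper), tol = 1e-9)$root
}
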