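#' Achieved power of a two-sided two-sample t-test
#'
#' Exact noncentral-t power for a pooled-variance two-sample t-test at
#' effect size `d` (Cohen's d) and significance level `alpha`.
#'
#' @param n1,n2 Group sizes (each at least 2).
#' @param d Standardized effect size (Cohen's d).
#' @param alpha Two-sided type-I error probability.
#' @return Power in \[0, 1\].
#' @export
achieved_power <- function(n1, n2, d = 0.5, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) abort("Need at least 2 observations per group.")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Required per-group sample size for a target power
#'
#' Smallest equal group size whose [achieved_power()] reaches the
#' target.
#'
#' @param power Target power in (0, 1).
#' @param d Effect size (Cohen's d).
#' @param alpha Two-sided type-I error probability.
#' @param n_max Search ceiling.
#' @return Integer per-group sample size.
#' @export
required_n_per_group <- function(power = 0.80, d = 0.5, alpha = 0.05,
                                 n_max = 1e5) {
  if (power <= 0 || power >= 1) abort("`power` must lie in (0, 1).")
  if (d == 0) abort("Power cannot reach the target at d = 0.")
  for (n in 2:n_max) {
    if (achieved_power(n, n, d, alpha) >= power) return(n)
  }
  abort("No sample size up to `n_max` reaches the target power.")
}
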