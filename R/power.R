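## Power and sample-size calculations from noncentral t and F
## distributions, as used for post-hoc and a-priori design of the
## mouse experiments (two-sided alpha 0.05, minimum power 80%).

#' Power of a two-sided two-sample t-test
#'
#' Exact power from the noncentral t distribution: with Cohen's d, the
#' noncentrality is \code{delta = d * sqrt(n1 * n2 / (n1 + n2))} on
#' \code{n1 + n2 - 2} degrees of freedom, and power is
#' \code{P(|T'| > t_{1 - alpha/2, df})}.
#'
#' @param cohenD standardized mean difference (>= 0).
#' @param n1,n2 group sizes (each >= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in [0, 1].
#' @export
ttestPower <- function(cohenD, n1, n2, alpha = 0.05) {
  stopifnot(cohenD >= 0, n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- cohenD * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' A-priori sample size for a two-sample t-test
#'
#' Smallest balanced design (equal n per group, searched upward from 2)
#' whose two-sided noncentral-t power reaches the target.
#'
#' @param cohenD standardized effect size (> 0).
#' @param targetPower required power in (0, 1) (default 0.80).
#' @param alpha two-sided significance level.
#' @param nMax search cap on n per group.
#' @return list with \code{nPerGroup}, \code{totalN},
#'   \code{achievedPower}.
#' @export
ttestSampleSize <- function(cohenD, targetPower = 0.80, alpha = 0.05,
                            nMax = 10000L) {
  stopifnot(cohenD > 0, targetPower > 0, targetPower < 1)
  for (n in 2:nMax) {
    pw <- ttestPower(cohenD, n, n, alpha)
    if (pw >= targetPower)
      return(list(nPerGroup = n, totalN = 2L * n, achievedPower = pw))
  }
  stop("target power not reachable within nMax per group")
}

#' Power of a one-way fixed-effects ANOVA
#'
#' Exact power from the noncentral F distribution: with Cohen's f and
#' total N, the noncentrality is \code{lambda = f^2 * N} on
#' \code{(k - 1, N - k)} degrees of freedom.
#'
#' @param cohenF effect size (>= 0).
#' @param groupSizes integer vector of k >= 2 group sizes (each >= 2);
#'   unbalanced post-hoc designs are given explicitly.
#' @param alpha significance level.
#' @return Power in [0, 1].
#' @export
anovaPower <- function(cohenF, groupSizes, alpha = 0.05) {
  stopifnot(cohenF >= 0, length(groupSizes) >= 2, all(groupSizes >= 2),
            alpha > 0, alpha < 1)
  k <- length(groupSizes)
  N <- sum(groupSizes)
  fc <- stats::qf(1 - alpha, k - 1, N - k)
  stats::pf(fc, k - 1, N - k, ncp = cohenF^2 * N, lower.tail = FALSE)
}

#' A-priori sample size for a one-way ANOVA
#'
#' Smallest equal-allocation design (n per group from 2 upward) whose
#' noncentral-F power reaches the target.
#'
#' @param cohenF effect size (> 0).
#' @param k number of groups.
#' @param targetPower required power (default 0.80).
#' @param alpha significance level.
#' @param nMax search cap on n per group.
#' @return list with \code{nPerGroup}, \code{totalN},
#'   \code{achievedPower}.
#' @export
anovaSampleSize <- function(cohenF, k, targetPower = 0.80, alpha = 0.05,
                            nMax = 10000L) {
  stopifnot(cohenF > 0, k >= 2, targetPower > 0, targetPower < 1)
  for (n in 2:nMax) {
    pw <- anovaPower(cohenF, rep(n, k), alpha)
    if (pw >= targetPower)
      return(list(nPerGroup = n, totalN = as.integer(k * n),
                  achievedPower = pw))
  }
  stop("target power not reachable within nMax per group")
}
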