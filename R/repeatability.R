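## Bland-Altman repeatability, agreement regression, Welch t-tests.

dropSingletons <- function(subject, value) {
  tab <- table(subject)
  bad <- names(tab)[tab < 2]
  if (length(bad)) {
    warning("dropping subject(s) with a single measurement: ",
            paste(bad, collapse = ", "))
    keep <- !(subject %in% bad)
    subject <- subject[keep]; value <- value[keep]
  }
  list(subject = factor(subject), value = value)
}

#' Within-subject standard deviation (sw)
#'
#' One-way ANOVA with subject as the factor; sw is the square root of
#' the residual mean square, i.e. \code{sqrt(residual SS / (N - k))}.
#' Unbalanced designs are supported; subjects contributing a single
#' measurement are dropped with a warning since they carry no
#' within-subject information.
#'
#' @param subject subject identifiers (repeated scans of one mouse
#'   share an id).
#' @param value repeated measurements (aerated volume in voxels or
#'   mm^3).
#' @return sw, a single non-negative number.
#' @export
withinSubjectSD <- function(subject, value) {
  stopifnot(length(subject) == length(value))
  d <- dropSingletons(subject, value)
  if (nlevels(d$subject) < 2L)
    stop("at least 2 subjects with repeated measurements are required")
  fit <- stats::aov(d$value ~ d$subject)
  sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
}

#' 95\% repeatability coefficient
#'
#' \code{1.96 * sqrt(2) * sw}: the range within which 95\% of paired
#' repeat measurements on the same subject are expected to fall.
#'
#' @param sw within-subject standard deviation.
#' @return The repeatability coefficient, same units as sw.
#' @export
repeatabilityCoefficient <- function(sw) {
  if (!is.numeric(sw) || any(sw < 0)) stop("sw must be non-negative")
  1.96 * sqrt(2) * sw
}

#' Heteroscedasticity check: per-subject mean vs SD
#'
#' Spearman rank correlation between each subject's mean and standard
#' deviation.  A strong correlation indicates that measurement error
#' scales with magnitude and sw is not a uniform error summary.
#'
#' @inheritParams withinSubjectSD
#' @return list with \code{spearmanR} and \code{spearmanP}.
#' @export
varianceMagnitudeCheck <- function(subject, value) {
  d <- dropSingletons(subject, value)
  if (nlevels(d$subject) < 3L)
    stop("at least 3 subjects are required for the mean-vs-SD check")
  m <- tapply(d$value, d$subject, mean)
  s <- tapply(d$value, d$subject, stats::sd)
  ct <- suppressWarnings(stats::cor.test(m, s, method = "spearman"))
  list(spearmanR = unname(ct$estimate), spearmanP = ct$p.value)
}

#' Full repeatability report
#'
#' Convenience wrapper combining [withinSubjectSD()],
#' [repeatabilityCoefficient()] and [varianceMagnitudeCheck()].
#'
#' @inheritParams withinSubjectSD
#' @return A [RepeatabilityReport-class].
#' @export
repeatabilityReport <- function(subject, value) {
  d <- suppressWarnings(dropSingletons(subject, value))
  sw <- withinSubjectSD(subject, value)
  vc <- varianceMagnitudeCheck(subject, value)
  new("RepeatabilityReport", sw = sw,
      repeatabilityCoefficient = repeatabilityCoefficient(sw),
      spearmanR = vc$spearmanR, spearmanP = vc$spearmanP,
      nSubjects = nlevels(d$subject), nMeasurements = length(d$value))
}

#' Agreement between two measurement methods by linear regression
#'
#' Ordinary least squares of y on x with R-squared, the two-sided
#' p-value for the slope, and the half-width of the 95\% prediction
#' interval at each observed x (from residual variance and leverage).
#'
#' @param x reference measurements (e.g. Ashcroft score, hydroxyproline
#'   content).
#' @param y imaging-derived measurements (e.g. EEV).
#' @return An [AgreementFit-class].
#' @export
agreementRegression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L)
    stop("at least 3 points are required for a prediction band")
  if (length(unique(x)) < 2L) stop("x must not be constant")
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  sm <- summary(fit)
  pred <- stats::predict(fit, newdata = df, interval = "prediction",
                         level = 0.95)
  pv <- sm$coefficients["x", "Pr(>|t|)"]
  new("AgreementFit", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = sm$r.squared, pValue = pv,
      predictionHalfWidth = unname((pred[, "upr"] - pred[, "lwr"]) / 2),
      fit = fit)
}

#' Welch two-sample t-test
#'
#' Two-sided t-test with the Welch correction for unequal variances,
#' applied unconditionally.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTTest <- function(groupA, groupB) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values")
  ht <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
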