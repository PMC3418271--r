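test_that("within-subject SD is the root residual mean square", {
  # hand ANOVA: subjects {1,3} and {5,7}: residual SS 4 on 2 df -> MS 2
  sw <- withinSubjectSD(c("a", "a", "b", "b"), c(1, 3, 5, 7))
  expect_equal(sw, sqrt(2))

  # identical repeats -> sw = 0
  expect_equal(withinSubjectSD(rep(1:3, each = 2), c(4, 4, 9, 9, 2, 2)), 0)

  # balanced design: sw^2 equals the mean of per-subject variances
  set.seed(17)
  subj <- rep(1:6, each = 4)
  val <- rnorm(24, mean = rep(c(10, 20, 30, 40, 50, 60), each = 4))
  sw2 <- withinSubjectSD(subj, val)^2
  expect_equal(sw2, mean(tapply(val, subj, var)))

  # unbalanced designs supported (4 or 5 measurements per subject)
  subjU <- c(rep(1, 4), rep(2, 5), rep(3, 4))
  expect_silent(withinSubjectSD(subjU, rnorm(13)))

  # location invariance: shifting one subject's measurements leaves sw
  valShift <- val + ifelse(subj == 2, 100, 0)
  expect_equal(withinSubjectSD(subj, valShift), sqrt(sw2))

  # singleton subjects dropped with a warning; too few subjects error
  expect_warning(swd <- withinSubjectSD(c(1, 1, 2, 2, 3), c(1, 3, 5, 7, 9)),
                 "single measurement")
  expect_equal(swd, sqrt(2))
  expect_error(suppressWarnings(withinSubjectSD(c(1, 1, 2), c(1, 3, 5))),
               "at least 2 subjects")
})

test_that("the repeatability coefficient is 1.96 sqrt(2) sw", {
  expect_equal(repeatabilityCoefficient(0), 0)
  expect_equal(repeatabilityCoefficient(1), 2.7719, tolerance = 1e-4)
  # printed mantissa check: sw 5.3 -> 14.69 (1.47 x 10^1)
  expect_equal(repeatabilityCoefficient(5.3), 14.69, tolerance = 1e-3)
  expect_error(repeatabilityCoefficient(-1), "non-negative")

  # linear in sw: scaling measurements scales sw and the coefficient
  set.seed(23)
  subj <- rep(1:4, each = 3); val <- rnorm(12)
  sw <- withinSubjectSD(subj, val)
  expect_equal(withinSubjectSD(subj, 10 * val), 10 * sw)
  expect_equal(repeatabilityCoefficient(10 * sw),
               10 * repeatabilityCoefficient(sw))
})

test_that("mean-vs-SD Spearman check matches rank computation", {
  # three subjects with perfectly increasing mean and SD
  s <- rep(1:3, each = 3)
  v <- c(1, 2, 3, 10, 12, 14, 100, 104, 108)
  chk <- varianceMagnitudeCheck(s, v)
  expect_equal(chk$spearmanR, 1)

  # reversed ranks: means increase while SDs decrease
  v2 <- c(1, 4, 7, 10, 12, 14, 100, 101, 102)
  expect_equal(varianceMagnitudeCheck(s, v2)$spearmanR, -1)

  # seeded subjects against a brute-force rank correlation
  set.seed(29)
  s8 <- rep(1:8, each = 4); v8 <- rnorm(32, sd = rep(runif(8, 1, 5), each = 4))
  chk8 <- varianceMagnitudeCheck(s8, v8)
  m <- tapply(v8, s8, mean); sd8 <- tapply(v8, s8, sd)
  expect_equal(chk8$spearmanR, cor(rank(m), rank(sd8)))

  expect_error(varianceMagnitudeCheck(rep(1:2, each = 3), rnorm(6)),
               "at least 3 subjects")
})

test_that("agreement regression reports OLS, R^2 and prediction bands", {
  # perfectly collinear: R^2 = 1, zero-width prediction band
  fitP <- suppressWarnings(agreementRegression(1:5, 2 + 3 * (1:5)))
  expect_equal(fitP@slope, 3)
  expect_equal(fitP@intercept, 2)
  expect_equal(fitP@rSquared, 1)
  expect_equal(max(fitP@predictionHalfWidth), 0, tolerance = 1e-8)

  # seeded data against the closed-form normal equations
  set.seed(37)
  x <- rnorm(10); y <- 1.5 + 0.8 * x + rnorm(10, sd = 0.3)
  fit <- agreementRegression(x, y)
  slopeHat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit@slope, slopeHat)
  expect_equal(fit@intercept, mean(y) - slopeHat * mean(x))
  expect_equal(fit@rSquared, cor(x, y)^2)
  expect_equal(sum(residuals(fit@fit)), 0, tolerance = 1e-10)

  expect_error(agreementRegression(c(1, 2), c(1, 2)), "at least 3 points")
  expect_error(agreementRegression(rep(1, 5), rnorm(5)), "constant")
})

test_that("Welch t-test matches the hand formulas", {
  same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- c(1, 2, 3); b <- c(2, 3, 4)
  got <- welchTTest(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  tHand <- (mean(a) - mean(b)) / se
  dfHand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(got$t, tHand)
  expect_equal(got$df, dfHand)
  expect_equal(got$p, 2 * pt(-abs(tHand), dfHand))

  expect_error(welchTTest(numeric(0), b), "at least 2 values")
  expect_error(welchTTest(a, 5), "at least 2 values")
})

test_that("the combined repeatability report is internally consistent", {
  set.seed(41)
  subj <- rep(1:5, times = c(5, 5, 4, 4, 5))
  val <- 5e5 + rnorm(23, sd = 2e4) + rep(rnorm(5, sd = 2e5), times = c(5, 5, 4, 4, 5))
  rep1 <- repeatabilityReport(subj, val)
  expect_equal(rep1@repeatabilityCoefficient,
               1.96 * sqrt(2) * rep1@sw)
  expect_equal(rep1@nSubjects, 5L)
  expect_equal(rep1@nMeasurements, 23L)
  expect_gte(rep1@spearmanP, 0)
})
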