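# Cross-species time normalization and stimulus-curve fitting/sampling.

test_that("growth time constant is recovered from noiseless data", {
  truth <- syntheticTruth(curveParams = list(LVM = c(A = 0.4, k = 1)),
                          speciesTau = c(rat = 283))
  d <- generateGrowthObservations(truth, nStudies = 1, betweenSd = 0,
                                  seed = 1)
  sts <- fitGrowthTimescale(d)
  expect_equal(unname(sts@tau["rat"]), 283, tolerance = 0.01)
  expect_equal(unname(sts@amplitude["rat"]), 0.4, tolerance = 0.01)
})

test_that("two-species tau ratio is recovered within 2% at near-zero scatter", {
  truth <- syntheticTruth()  # dog 1095 h, rat 283 h
  d <- generateGrowthObservations(truth, nStudies = 6, betweenSd = 0.002,
                                  seed = 5)
  sts <- fitGrowthTimescale(d)
  expect_equal(tauRatio(sts, "dog", "rat"), 1095 / 283, tolerance = 0.02)
})

test_that("tau-ratio error shrinks as study scatter shrinks", {
  truth <- syntheticTruth()
  err <- vapply(c(0.15, 0.01), function(s) {
    d <- generateGrowthObservations(truth, nStudies = 6, betweenSd = s,
                                    seed = 31)
    abs(tauRatio(fitGrowthTimescale(d), "dog", "rat") - 1095 / 283)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("constant fold changes make the growth fit degenerate", {
  d <- data.frame(variable = "LVM/BM", species = "rat",
                  time_hours = c(10, 100, 400, 900), mean = 1,
                  sd = 0.1, source = "x")
  expect_error(fitGrowthTimescale(d), "degenerate")
  expect_error(fitGrowthTimescale(d[1:2, ]), "distinct time points")
})

test_that("time normalization is per-species, flagged, and idempotent", {
  sts <- speciesTimeScale(c(dog = 1095, rat = 283))
  d <- data.frame(variable = "AngII", species = c("dog", "rat"),
                  time_hours = c(1095, 566), mean = c(2, 2.1),
                  sd = 0.2, source = c("a", "b"))
  n1 <- normalizeTime(d, sts)
  expect_equal(n1$t_over_tau, c(1, 2))
  expect_false("time_hours" %in% names(n1))
  # idempotent: renormalizing changes nothing
  expect_identical(normalizeTime(n1, sts), n1)
  d$species[2] <- "mouse"
  expect_error(normalizeTime(d, sts), "mouse")
})

test_that("mixed-species tables align for joint fitting", {
  truth <- syntheticTruth()
  d <- generateGrowthObservations(truth, nStudies = 6, seed = 9)
  sts <- fitGrowthTimescale(d)
  n <- normalizeTime(d, sts)
  # after normalization, dog and rat values at matched t/tau are
  # statistically indistinguishable
  dog <- n[n$species == "dog", ]
  rat <- n[n$species == "rat", ]
  ks <- suppressWarnings(stats::ks.test(dog$mean, rat$mean))
  expect_gt(ks$p.value, 0.01)
})

test_that("linear fits recover a noiseless slope exactly", {
  d <- data.frame(t_over_tau = c(0.2, 0.5, 1, 2, 3),
                  mean = 1 + 0.5 * c(0.2, 0.5, 1, 2, 3), sd = 0.1)
  fam <- fitStimulusCurve(d, "linear")
  expect_equal(unname(fam@paramMean["b"]), 0.5, tolerance = 1e-9)
  expect_equal(meanCurve(fam)(0), 1)
})

test_that("constant-at-one hormones yield near-zero trend parameters", {
  set.seed(3)
  d <- data.frame(t_over_tau = rep(c(0.2, 0.5, 1, 2, 3), 3),
                  mean = 1 + rnorm(15, 0, 0.02), sd = 0.1)
  fam <- fitStimulusCurve(d, "linear")
  expect_lt(abs(fam@paramMean["b"]), 0.05)
})

test_that("saturating-exponential refits recover truth within CIs", {
  set.seed(21)
  truthP <- c(A = 1.2, k = 0.8)
  tgrid <- rep(c(0.1, 0.3, 0.6, 1, 1.5, 2, 3), 3)
  cover <- 0L
  nRep <- 100
  for (r in seq_len(nRep)) {
    y <- evalCurveForm("satexp", truthP, tgrid) + rnorm(length(tgrid), 0, 0.1)
    fam <- fitStimulusCurve(data.frame(t_over_tau = tgrid, mean = y,
                                       sd = 0.1), "satexp")
    se <- sqrt(diag(fam@paramCov))
    ok <- all(abs(fam@paramMean[c("A", "k")] - truthP) < 1.96 * se + 1e-9)
    cover <- cover + ok
  }
  # joint 95% coverage of two parameters: expect most fits to bracket both
  expect_gt(cover / nRep, 0.80)
})

test_that("curve samples respect the parameter PDF", {
  d <- data.frame(t_over_tau = rep(c(0.2, 0.5, 1, 2, 3), 4),
                  mean = 1 + 0.4 * rep(c(0.2, 0.5, 1, 2, 3), 4), sd = 0.1)
  fam <- fitStimulusCurve(d, "linear")
  # zero covariance degenerates to the mean curve
  fam0 <- fam
  fam0@paramCov <- matrix(0, 1, 1, dimnames = list("b", "b"))
  f <- sampleCurve(fam0)
  expect_equal(f(2), meanCurve(fam)(2), tolerance = 1e-12)
  # analytic propagation for the linear form: at time t the sampled curve
  # value is N(1 + mean(b) t, t^2 var(b))
  set.seed(14)
  vals <- replicate(4000, sampleCurve(fam)(2))
  expect_equal(mean(vals), 1 + 2 * fam@paramMean[["b"]], tolerance = 0.01)
  expect_equal(sd(vals), 2 * sqrt(fam@paramCov[1, 1]), tolerance = 0.05)
})

test_that("curve sampling is seed-reproducible through withSeed", {
  d <- data.frame(t_over_tau = c(0.2, 0.5, 1, 2, 3),
                  mean = c(1.1, 1.3, 1.5, 1.9, 2.2), sd = 0.1)
  fam <- fitStimulusCurve(d, "satexp")
  ws <- voHypertrophyNet:::withSeed
  f1 <- ws(99, sampleCurve(fam))
  f2 <- ws(99, sampleCurve(fam))
  f3 <- ws(100, sampleCurve(fam))
  tt <- seq(0, 3, 0.5)
  expect_identical(f1(tt), f2(tt))
  expect_false(isTRUE(all.equal(f1(tt), f3(tt))))
})

test_that("all curve forms are anchored at fold one and stay positive", {
  set.seed(6)
  fams <- list(
    new("CurveFamily", form = "satexp", paramMean = c(A = 1.5, k = 0.5),
        paramCov = diag(c(0.04, 0.01)), domain = c(0, 5)),
    new("CurveFamily", form = "expdecay", paramMean = c(A = 2, k = 0.8),
        paramCov = diag(c(0.09, 0.01)), domain = c(0, 5)),
    new("CurveFamily", form = "linear", paramMean = c(b = 0.2),
        paramCov = diag(0.01, 1), domain = c(0, 5)),
    new("CurveFamily", form = "constant", paramMean = numeric(),
        paramCov = matrix(numeric(), 0, 0), domain = c(0, 5)))
  for (fam in fams) for (r in 1:20) {
    f <- sampleCurve(fam)
    expect_lt(abs(f(0) - 1), 1e-9)
    expect_true(all(f(seq(0, 5, 0.1)) > 0))
  }
})

test_that("curve sets round-trip through JSON serialization", {
  skip_if_not_installed("jsonlite")
  d <- data.frame(t_over_tau = c(0.2, 0.5, 1, 2, 3),
                  mean = c(1.1, 1.3, 1.5, 1.9, 2.2), sd = 0.1,
                  variable = "AngII")
  set <- fitStimulusSet(d)
  f <- tempfile(fileext = ".json")
  writeStimulusSet(set, f)
  back <- readStimulusSet(f)
  expect_equal(back@curves$AngII@paramMean, set@curves$AngII@paramMean)
  expect_equal(back@curves$AngII@paramCov, set@curves$AngII@paramCov,
               tolerance = 1e-12)
  expect_equal(back@curves$AngII@form, "satexp")
})
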