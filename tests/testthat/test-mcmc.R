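# Calibration likelihood, Metropolis/Gibbs machinery, filtering and
# posterior summaries.

twoParamPrior <- function() {
  b <- rbind(a = c(0, 1), b = c(0, 1))
  colnames(b) <- c("lower", "upper")
  new("PriorSpec", bounds = b, wMyoStrain0 = 0.06)
}

test_that("log-likelihood attains the Gaussian maximum at exact predictions", {
  qs <- quickCalibSetup(seed = 31)
  truthP <- qs$truth@weights[c("wAngII", "wNE", "wET1", "wBackground",
                               "Cmyo")]
  draw <- drawVOCurves(qs$curveSet, qs$config, seed = 12)
  tpts <- c(0.25, 1, 2.5)
  sim <- simulateVO(qs$model, truthP, 0.06, draw, qs$config,
                    times = c(0, tpts))
  pred <- predictFoldChanges(sim, c("FAK", "Ras"), tpts)
  data <- data.frame(variable = rep(c("FAK", "Ras"), each = 3),
                     t_over_tau = rep(tpts, 2),
                     mean = c(pred[, "FAK"], pred[, "Ras"]), sd = 0.2)
  ll <- calibLogLik(truthP, draw, qs$model, data, qs$config, 0.06)
  ca0 <- sim$baseline[["CellArea"]]
  expected <- 6 * log(1 / (0.2 * sqrt(2 * pi))) -
    (ca0 - 0.5)^2 / (2 * qs$config$sigmaB^2)
  expect_equal(ll, expected, tolerance = 1e-6)
  # doubling a dataset's sd raises the log-density of an off-mean point
  dataOff <- data
  dataOff$mean <- dataOff$mean + 0.5
  llOff <- calibLogLik(truthP, draw, qs$model, dataOff, qs$config, 0.06)
  dataWide <- dataOff
  dataWide$sd <- 0.4
  llWide <- calibLogLik(truthP, draw, qs$model, dataWide, qs$config, 0.06)
  expect_gt(llWide, llOff)
})

test_that("the likelihood surface peaks near the true weights", {
  qs <- quickCalibSetup(seed = 55, nStudies = 4)
  truthP <- qs$truth@weights[c("wAngII", "wNE", "wET1", "wBackground",
                               "Cmyo")]
  draws <- lapply(1:4, function(s) drawVOCurves(qs$curveSet, qs$config,
                                                seed = s))
  avgLL <- function(p) mean(vapply(draws, function(d)
    calibLogLik(p, d, qs$model, qs$calibData, qs$config, 0.06),
    numeric(1)))
  # 1-D scans through the truth in the two best-identified directions
  grid <- seq(0.01, 0.4, length.out = 9)
  llBg <- vapply(grid, function(v) {
    p <- truthP; p["wBackground"] <- v; avgLL(p)
  }, numeric(1))
  best <- grid[which.max(llBg)]
  expect_lt(abs(best - truthP[["wBackground"]]), 0.1)
  gridE <- seq(0.01, 0.17, length.out = 9)
  llE <- vapply(gridE, function(v) {
    p <- truthP; p["wET1"] <- v; avgLL(p)
  }, numeric(1))
  expect_lt(abs(gridE[which.max(llE)] - truthP[["wET1"]]), 0.06)
})

test_that("Gibbs proposals respect bounds and accept freely on flat targets", {
  set.seed(2)
  flat <- function(p) 0
  st <- mhGibbsStep(c(a = 0.5, b = 0.5), 0, flat,
                    lower = c(a = 0, b = 0), upper = c(a = 1, b = 1),
                    scales = c(0.1, 0.1))
  # on a flat likelihood nearly every in-bounds proposal is accepted
  acc <- replicate(50, mhGibbsStep(c(a = 0.5, b = 0.5), 0, flat,
                                   c(a = 0, b = 0), c(a = 1, b = 1),
                                   c(0.05, 0.05))$accepted)
  expect_gt(mean(acc), 1.8)
  # a proposal that would land far out of bounds is never taken
  stuck <- replicate(20, mhGibbsStep(c(a = 0.001, b = 0.999), 0, flat,
                                     c(a = 0, b = 0), c(a = 1, b = 1),
                                     c(1e4, 1e4))$params)
  expect_true(all(stuck[1, ] == 0.001 & stuck[2, ] == 0.999))
})

test_that("the chain reproduces an analytic two-parameter posterior", {
  target <- function(params, curveSeed)
    stats::dnorm(params[["a"]], 0.3, 0.05, log = TRUE) +
    stats::dnorm(params[["b"]], 0.6, 0.08, log = TRUE)
  set.seed(77)
  ens <- runMCMC(target, twoParamPrior(), nIter = 4000, refresh = FALSE,
                 checkEvery = 2000)
  s <- posteriorSamples(ens)
  keep <- s[seq(501, 4000, by = 7), ]
  expect_equal(mean(keep$a), 0.3, tolerance = 0.01)
  expect_equal(sd(keep$a), 0.05, tolerance = 0.015)
  expect_equal(mean(keep$b), 0.6, tolerance = 0.015)
  ks <- suppressWarnings(stats::ks.test(keep$a, "pnorm", 0.3, 0.05))
  expect_gt(ks$p.value, 0.001)
  # moment error shrinks with chain length
  set.seed(11)
  short <- posteriorSamples(runMCMC(target, twoParamPrior(), nIter = 150,
                                    refresh = FALSE, checkEvery = 150))
  errShort <- abs(mean(short$a[-(1:50)]) - 0.3)
  errLong <- abs(mean(keep$a) - 0.3)
  expect_lt(errLong, errShort + 0.01)
})

test_that("zero-information data return the uniform prior", {
  set.seed(6)
  ens <- runMCMC(function(p, cs) 0, twoParamPrior(), nIter = 2000,
                 refresh = FALSE, checkEvery = 1000)
  a <- posteriorSamples(ens)$a[seq(101, 2000, by = 5)]
  ks <- suppressWarnings(stats::ks.test(a, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds give identical ensembles", {
  target <- function(p, cs) stats::dnorm(p[["a"]], 0.4, 0.1, log = TRUE)
  run <- function() {
    set.seed(123)
    posteriorSamples(runMCMC(target, twoParamPrior(), nIter = 50,
                             checkEvery = 50))
  }
  expect_identical(run(), run())
})

test_that("convergence diagnostics are recorded per block", {
  target <- function(p, cs) 0
  set.seed(1)
  ens <- runMCMC(target, twoParamPrior(), nIter = 300, refresh = FALSE,
                 checkEvery = 100)
  expect_equal(length(ens@diagnostics), 3)
  expect_true(is.na(ens@diagnostics[[1]]$relChange))
  expect_true(is.finite(ens@diagnostics[[3]]$relChange))
})

test_that("filtering removes reversal and runaway trajectories only", {
  tt <- seq(0, 5, 0.25)
  mk <- function(f) function(row) list(times = tt, cellArea = f(tt),
                                       baseline = 0.5)
  samples <- data.frame(wAngII = c(0.02, 0.03, 0.04), logLik = 0,
                        curveSeed = 1:3)
  ens <- new("PosteriorEnsemble", samples = samples, stage = 2L,
             filtered = FALSE)
  # monotone saturating: kept
  sat <- mk(function(t) 0.5 * (1 + 0.4 * (1 - exp(-t))))
  kept <- filterUnlikely(ens, sat)
  expect_equal(nrow(posteriorSamples(kept)), 3)
  expect_true(kept@filtered)
  # still rising at the horizon: removed as runaway
  run <- mk(function(t) 0.5 * (1 + 0.1 * t))
  expect_error(filterUnlikely(ens, run), "runaway")
  # dipping below baseline mid-course: removed as reversal
  rev <- mk(function(t) 0.5 * (1 - 0.2 * sin(pmin(t, pi))))
  expect_error(filterUnlikely(ens, rev), "reversal")
  # mixed trajectory functions: only the settled one survives
  mixed <- function(row) {
    if (row[["curveSeed"]] == 2) run(NULL) else sat(NULL)
  }
  out <- filterUnlikely(ens, mixed)
  expect_equal(posteriorSamples(out)$curveSeed, c(1, 3))
  cnt <- attr(out, "filterCounts")
  expect_equal(unname(cnt["runaway"]), 1)
})

test_that("posterior summaries handle degeneracy and match constructions", {
  s <- data.frame(wAngII = rep(0.05, 10), wNE = rep(0.1, 10), logLik = 0,
                  curveSeed = 1:10)
  ens <- new("PosteriorEnsemble", samples = s, stage = 1L,
             filtered = FALSE)
  ps <- posteriorSummary(ens)
  expect_equal(unname(ps$sd), c(0, 0))
  expect_true(all(is.na(ps$pcc)))
  # correlated Gaussian ensemble reproduces its correlation
  set.seed(10)
  n <- 4000
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- -0.42
  s2 <- data.frame(wET1 = 0.05 + 0.01 * z1,
                   wBackground = 0.03 + 0.01 * (rho * z1 +
                                                  sqrt(1 - rho^2) * z2),
                   logLik = 0, curveSeed = seq_len(n))
  ens2 <- new("PosteriorEnsemble", samples = s2, stage = 2L,
              filtered = FALSE)
  ps2 <- posteriorSummary(ens2)
  expect_equal(unname(ps2$pcc["wET1", "wBackground"]), rho,
               tolerance = 0.05)
  # summaries are invariant to sample order
  ens3 <- new("PosteriorEnsemble", samples = s2[sample.int(n), ],
              stage = 2L, filtered = FALSE)
  expect_equal(posteriorSummary(ens3)$mean, ps2$mean)
  expect_equal(posteriorSummary(ens3)$pcc, ps2$pcc)
})

test_that("the wMyoStrain0 scan reports one row per scanned value", {
  qs <- quickCalibSetup(seed = 47)
  expect_error(scanWmyoStrain(c(0.05, 0.25), qs$model, qs$calibData,
                              qs$curveSet, qs$config),
               "0, 0.2")
  set.seed(4)
  res <- scanWmyoStrain(c(0.04, 0.06), qs$model, qs$calibData, qs$curveSet,
                        qs$config, nIter1 = 15, nIter2 = 30,
                        filterMax = 10)
  expect_equal(res$wMyoStrain0, c(0.04, 0.06))
  expect_true(all(is.finite(res$meanLogLik)))
  expect_true(all(res$unlikelyFraction >= 0 & res$unlikelyFraction <= 1))
})

test_that("ensembles export as flat CSV", {
  s <- data.frame(wNE = c(0.1, 0.2), logLik = c(-1, -2), curveSeed = 1:2)
  ens <- new("PosteriorEnsemble", samples = s, stage = 2L,
             filtered = TRUE)
  f <- tempfile(fileext = ".csv")
  writeEnsemble(ens, f)
  back <- read.csv(f)
  expect_equal(back$wNE, s$wNE)
  expect_true(all(back$filtered))
  expect_equal(back$stage, c(2, 2))
})
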