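# Monte Carlo scenario engine and ensemble statistics.

# a small hand-made posterior ensemble clustered near the truth weights
fakePosterior <- function(n = 40, seed = 5, jitter = 0.1) {
  set.seed(seed)
  tw <- syntheticTruth()@weights
  s <- data.frame(
    wAngII = pmin(pmax(tw[["wAngII"]] * (1 + rnorm(n, 0, jitter)), 0.01), 0.15),
    wNE = pmin(pmax(tw[["wNE"]] * (1 + rnorm(n, 0, jitter)), 0.01), 0.24),
    wET1 = pmin(pmax(tw[["wET1"]] * (1 + rnorm(n, 0, jitter)), 0.01), 0.17),
    wBackground = pmin(pmax(tw[["wBackground"]] * (1 + rnorm(n, 0, jitter)),
                            0.01), 0.4),
    Cmyo = pmax(tw[["Cmyo"]] * (1 + rnorm(n, 0, jitter)), 0.5),
    logLik = 0, curveSeed = seq_len(n))
  new("PosteriorEnsemble", samples = s, stage = 2L, filtered = TRUE)
}

toyCurveSet <- function(seed = 77) {
  qs <- quickCalibSetup(seed = seed)
  qs$curveSet
}

test_that("normalized growth and drug effect follow their definitions", {
  expect_equal(normalizedGrowth(0.5, 0.735), 0.47)
  expect_equal(normalizedGrowth(0.5, 0.5), 0)
  expect_equal(normalizedGrowth(0.5, 0.25), -0.5)
  expect_error(normalizedGrowth(0, 1), "positive")
  expect_equal(normalizedDrugEffect(0.60, 0.70, 0.5), -0.2)
  expect_equal(normalizedDrugEffect(0.7, 0.7, 0.5), 0)
  expect_error(normalizedDrugEffect(c(1, 2), 1, 0.5), "mismatched")
})

test_that("confidence intervals are interpolated percentiles and nest", {
  ci <- confidenceIntervals(1:100)
  expect_equal(unname(ci["CI50", ]), c(25.75, 75.25))
  expect_equal(unname(ci["CI90", ]), c(5.95, 95.05))
  # constant samples give zero-width intervals
  expect_equal(unname(confidenceIntervals(rep(3, 30))["CI90", ]), c(3, 3))
  # nesting property for random samples
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(50)
    ci <- confidenceIntervals(x)
    expect_true(ci["CI50", 1] >= ci["CI90", 1])
    expect_true(ci["CI50", 2] <= ci["CI90", 2])
  }
  expect_error(confidenceIntervals(1:10), "at least 20")
})

test_that("the 75% classification rule is inclusive at the boundary", {
  expect_equal(classifyChange(c(rep(1, 800), rep(-1, 200))), "increase")
  expect_equal(classifyChange(c(rep(1, 700), rep(-1, 300))), "mixed")
  expect_equal(classifyChange(c(rep(1, 750), rep(-1, 250))), "increase")
  expect_equal(classifyChange(c(rep(-1, 750), rep(1, 250))), "decrease")
  # exact zeros count toward neither direction
  expect_equal(classifyChange(c(rep(1, 750), rep(0, 250))), "increase")
  expect_equal(classifyChange(c(rep(1, 740), rep(0, 260))), "mixed")
})

test_that("coverage counts respect interval nesting", {
  set.seed(12)
  samples <- rnorm(500)
  ci <- confidenceIntervals(samples)
  means <- c(median(samples), ci["CI90", 2] + 1, ci["CI50", 1] - 1e-6)
  cc <- coverageCounts(samples, means)
  expect_equal(unname(cc$counts["total"]), 3)
  expect_true(all(!cc$perStudy$inCI50 | cc$perStudy$inCI90))
  expect_true(cc$perStudy$inCI50[1] && cc$perStudy$inCI90[1])
  expect_false(cc$perStudy$inCI90[2])
})

test_that("sensitivity PCC matches analytic constructions", {
  set.seed(4)
  x <- rnorm(1000)
  out <- sensitivityMatrix(cbind(x = x),
                           cbind(y = 2 * x, z = -x + rnorm(1000, 0, 1e-8)))
  expect_equal(unname(out$pcc["x", "y"]), 1, tolerance = 1e-12)
  expect_equal(unname(out$pcc["x", "z"]), -1, tolerance = 1e-6)
  expect_equal(unname(out$slope["x", "y"]), 2, tolerance = 1e-12)
  # bivariate normal with rho = 0.5
  n <- 10000
  u <- matrix(rnorm(2 * n), n)
  v <- cbind(u[, 1], 0.5 * u[, 1] + sqrt(1 - 0.25) * u[, 2])
  out2 <- sensitivityMatrix(cbind(a = v[, 1]), cbind(b = v[, 2]))
  expect_lt(abs(out2$pcc["a", "b"] - 0.5), 0.02)
  # zero-variance input gives NA, not an error
  out3 <- sensitivityMatrix(cbind(c0 = rep(1, 100), x = rnorm(100)),
                            cbind(y = rnorm(100)))
  expect_true(is.na(out3$pcc["c0", "y"]))
  expect_false(is.na(out3$pcc["x", "y"]))
  expect_error(sensitivityMatrix(cbind(1:10), cbind(1:10)), "30")
})

test_that("saturating infusion grows every iteration; reruns are identical", {
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  post <- fakePosterior()
  spec <- scenarioSpec("infusion", agonist = "ISO",
                       doseType = "saturation", horizon = 5, nIter = 20)
  res <- simulateScenario(spec, post, model, config, seed = 3)
  expect_true(all(growthSamples(res) > 0))
  expect_equal(res@nFailed, 0L)
  res2 <- simulateScenario(spec, post, model, config, seed = 3)
  expect_identical(growthSamples(res), growthSamples(res2))
  # N = 1 reproducibility
  s1 <- scenarioSpec("infusion", agonist = "ISO", nIter = 1)
  r1 <- simulateScenario(s1, post, model, config, seed = 9)
  r2 <- simulateScenario(s1, post, model, config, seed = 9)
  expect_identical(r1@terminal, r2@terminal)
})

test_that("a blocker alone never grows and barely shrinks the toy cell", {
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  post <- fakePosterior()
  # knocking out the least-weighted receptor without any stimulus:
  # growth can only go slightly negative (loss of its baseline drive)
  spec <- scenarioSpec("infusion", agonist = "ISO", doseType = "fold",
                       doseMean = 1, doseSd = 0, blocker = "ARB",
                       horizon = 5, nIter = 10)
  res <- simulateScenario(spec, post, model, config, seed = 21)
  expect_true(all(growthSamples(res) <= 1e-6))
  expect_true(all(abs(growthSamples(res)) < 0.2))
})

test_that("paired arms give exactly zero drug effect when the receptor is disconnected", {
  # receptor R2 feeds only the gene output G, never CellArea
  nd <- data.frame(id = c("R1", "R2", "G", "CellArea"), ymax = 1,
                   tau = c(0.05, 0.05, 0.05, 1), y0 = 0,
                   category = c("input", "input", "gene-output",
                                "growth-output"))
  rx <- data.frame(id = c("in_R1", "in_R2", "rx_G", "rx_CA"),
                   rule = c("=> R1", "=> R2", "R2 => G", "R1 => CellArea"),
                   w = c(0.4, 0.3, 1, 1), n = 1.4, EC50 = 0.4)
  m <- parseModelTables(nd, rx)
  cfg <- voConfig(inputs = c(NE = "in_R1"), inputParams = c(NE = "wNE"),
                  cellAreaNode = "CellArea", outputs = c("G", "CellArea"),
                  receptors = c(blk = "R2"), horizon = 5)
  post <- fakePosterior(n = 15)
  base <- scenarioSpec("infusion", agonist = "NE", doseType = "fold",
                       doseMean = 2, doseSd = 0.3, nIter = 15)
  withB <- scenarioSpec("infusion", agonist = "NE", doseType = "fold",
                        doseMean = 2, doseSd = 0.3, blocker = "blk",
                        nIter = 15)
  r0 <- simulateScenario(base, post, m, cfg, seed = 4)
  r1 <- simulateScenario(withB, post, m, cfg, seed = 4, draws = r0@draws)
  eff <- normalizedDrugEffect(r1, r0)
  expect_equal(unname(eff), rep(0, 15), tolerance = 1e-9)
  # but the blocked receptor's own target does change
  expect_lt(mean(r1@terminal[, "G"]), mean(r0@terminal[, "G"]))
})

test_that("a blocker on the driving receptor reduces growth in paired arms", {
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  post <- fakePosterior()
  inf <- scenarioSpec("infusion", agonist = "ISO",
                      doseType = "saturation", nIter = 12)
  infB <- scenarioSpec("infusion+blocker", agonist = "ISO",
                       doseType = "saturation", blocker = "betaB",
                       nIter = 12)
  r0 <- simulateScenario(inf, post, model, config, seed = 6)
  r1 <- simulateScenario(infB, post, model, config, seed = 6,
                         draws = r0@draws)
  eff <- normalizedDrugEffect(r1, r0)
  expect_true(all(eff < 0))
})

test_that("volume-overload ensembles respond to stimuli and classify outputs", {
  qs <- quickCalibSetup(seed = 18)
  post <- fakePosterior()
  spec <- scenarioSpec("vo", horizon = 5, nIter = 25)
  res <- simulateScenario(spec, post, qs$model, qs$config,
                          curveSet = qs$curveSet, seed = 11)
  expect_gt(mean(growthSamples(res)), 0)
  cls <- classifyOutputs(res)
  expect_setequal(cls$output, c("ANPg", "SERCA", "CellArea"))
  expect_equal(cls$call[cls$output == "CellArea"], "increase")
  # gene-program direction: ANP-like up, SERCA-like down
  expect_equal(cls$call[cls$output == "ANPg"], "increase")
  expect_equal(cls$call[cls$output == "SERCA"], "decrease")
})

test_that("ensemble means are stable and SEM shrinks with more iterations", {
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  post <- fakePosterior(n = 100, jitter = 0.3)
  spec <- function(n) scenarioSpec("infusion", agonist = "AngII",
                                   doseType = "fold", doseMean = 3.5,
                                   doseSd = 1.5, nIter = n)
  rA <- simulateScenario(spec(40), post, model, config, seed = 1)
  rB <- simulateScenario(spec(40), post, model, config, seed = 2)
  rC <- simulateScenario(spec(160), post, model, config, seed = 3)
  # iteration order cannot matter for the mean
  g <- growthSamples(rA)
  expect_equal(mean(g), mean(rev(g)))
  # a 4x larger ensemble should have roughly halved standard error;
  # compare spread of means loosely via the sample SDs
  expect_lt(sd(growthSamples(rC)) / sqrt(160),
            sd(growthSamples(rA)) / sqrt(40) * 0.9)
  expect_gt(mean(growthSamples(rC)), 0)
  expect_false(isTRUE(all.equal(mean(g), mean(growthSamples(rB)))))
})
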