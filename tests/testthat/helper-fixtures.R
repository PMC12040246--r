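# Shared fixtures built in code: small models and data generators.

# single self-contained node driven by an input reaction
singleNodeModel <- function(w = 1, tau = 1) {
  nd <- data.frame(id = "A", ymax = 1, tau = tau, y0 = 0,
                   category = "growth-output")
  rx <- data.frame(id = "in_A", rule = "=> A", w = w, n = 1.4, EC50 = 0.4)
  parseModelTables(nd, rx)
}

# random valid acyclic model for property tests
randomModel <- function(nNodes = 5, seed = 1) {
  set.seed(seed)
  ids <- paste0("N", seq_len(nNodes))
  nd <- data.frame(id = ids, ymax = 1,
                   tau = stats::runif(nNodes, 0.05, 1),
                   y0 = stats::runif(nNodes, 0, 0.3),
                   category = "intermediate")
  rules <- c("=> N1")
  for (k in 2:nNodes) {
    up <- sample(ids[seq_len(k - 1)], 1)
    neg <- sample(c("", "!"), 1)
    rules <- c(rules, paste0(neg, up, " => ", ids[k]))
  }
  # one extra convergent (OR) edge
  rules <- c(rules, paste0(ids[1], " => ", ids[nNodes]))
  rx <- data.frame(rule = rules,
                   w = stats::runif(length(rules), 0.2, 1),
                   n = stats::runif(length(rules), 1, 3),
                   EC50 = stats::runif(length(rules), 0.2, 0.8))
  parseModelTables(nd, rx)
}

# fixed-small-step explicit Euler oracle, independent of deSolve
eulerOracle <- function(model, times, perturb = NULL, init = NULL,
                        dt = 1e-4) {
  cmp <- voHypertrophyNet:::compileNetwork(model, perturb)
  y <- if (is.null(init)) model@nodes$y0 else as.numeric(init)
  grid <- seq(min(times), max(times), by = dt)
  out <- matrix(NA_real_, length(times), length(y))
  ti <- 1L
  for (g in grid) {
    if (ti <= length(times) && g >= times[ti] - dt / 2) {
      out[ti, ] <- y
      ti <- ti + 1L
    }
    y <- y + dt * cmp$rhs(g, y)
  }
  if (ti <= length(times)) out[ti, ] <- y
  colnames(out) <- model@nodes$id
  out
}

# truth and small observation set for calibration tests
quickCalibSetup <- function(seed = 42, nStudies = 2,
                            timepoints = c(0.25, 0.75, 1.5, 3)) {
  truth <- syntheticTruth()
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  obs <- generateObservations(truth, model, config,
                              timepoints = timepoints,
                              nStudies = nStudies, seed = seed)
  sts <- speciesTimeScale(truth@speciesTau)
  norm <- normalizeTime(obs, sts)
  hormones <- norm[norm$variable %in% c("AngII", "NE", "ET1"), ]
  growth <- generateGrowthObservations(truth, nStudies = nStudies,
                                       seed = seed + 1)
  ved <- data.frame(variable = "VED", species = "dog",
                    t_over_tau = rep(timepoints, 2),
                    mean = evalCurveForm("satexp", truth@curveParams$VED,
                                         rep(timepoints, 2)) +
                      withr::with_seed(seed + 2,
                        stats::rnorm(2 * length(timepoints), 0,
                                     truth@betweenSd)),
                    sd = truth@withinSd,
                    source = "ved")
  lvm <- norm[norm$variable == "LVM/BM", ]
  lvm$variable <- "LVM"
  curveData <- rbind(hormones[c("variable", "t_over_tau", "mean", "sd")],
                     ved[c("variable", "t_over_tau", "mean", "sd")],
                     lvm[c("variable", "t_over_tau", "mean", "sd")])
  curveSet <- fitStimulusSet(curveData)
  calib <- norm[norm$variable %in% names(config$varNodes),
                c("variable", "t_over_tau", "mean", "sd")]
  list(truth = truth, model = model, config = config, obs = obs,
       curveSet = curveSet, calibData = calib, sts = sts)
}

# one synthetic calibration problem with known ground truth, used by the
# end-to-end parameter-recovery checks
recoveryCase <- function(seed, weights = c(wAngII = 0.03, wNE = 0.033,
                                           wET1 = 0.056,
                                           wBackground = 0.031,
                                           Cmyo = 5.86)) {
  set.seed(seed)
  truth <- syntheticTruth(weights = weights)
  model <- makeToyNetwork("vo")
  config <- toyVOConfig()
  obs <- generateObservations(truth, model, config,
                              timepoints = c(0.1, 0.25, 0.5, 1, 2, 3),
                              nStudies = 4, seed = seed)
  norm <- normalizeTime(obs, speciesTimeScale(truth@speciesTau))
  hormones <- norm[norm$variable %in% c("AngII", "NE", "ET1"), ]
  lvm <- norm[norm$variable == "LVM/BM", ]
  lvm$variable <- "LVM"
  ved <- lvm
  ved$variable <- "VED"
  ved$mean <- pmax(evalCurveForm("satexp", truth@curveParams$VED,
                                 ved$t_over_tau) +
                     rnorm(nrow(ved), 0, truth@betweenSd), 0.05)
  curveSet <- fitStimulusSet(
    rbind(hormones, ved, lvm)[, c("variable", "t_over_tau", "mean", "sd")])
  calib <- norm[norm$variable %in% names(config$varNodes),
                c("variable", "t_over_tau", "mean", "sd")]
  list(truth = truth, weights = weights, model = model, config = config,
       curveSet = curveSet, calibData = calib)
}
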