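# Synthetic-data module: toy networks with hand-computable steady states,
# a ground-truth object emulating the calibrated volume-overload regime,
# and generators for literature-like observation tables (one mean +/- SD
# "study" per row) so every pipeline stage is testable self-contained.

#' Build a toy signaling network
#'
#' Small networks with closed-form steady states for constant inputs:
#' \describe{
#'   \item{chain}{input -> receptor -> kinase -> CellArea; every steady
#'     activity is a nested normalized-Hill composition of the input
#'     weight.}
#'   \item{crosstalk}{two inputs AND-gated into a kinase driving
#'     CellArea; output is 0 whenever either input is 0.}
#'   \item{runaway}{a chain with positive feedback from CellArea onto the
#'     kinase, prone to non-settling growth.}
#'   \item{vo}{an eight-node volume-overload analogue: AngII, NE/ISO and
#'     ET1 input reactions onto their receptors, a mechanical input onto
#'     FAK, a background input, all OR-converging on a Ras-like hub that
#'     drives a slow CellArea output, an ANP-like gene output, and an
#'     inhibited SERCA-like gene output.}
#' }
#' Intracellular toy time constants are set explicitly (0.02 t/tau for
#' receptors and the hub, 0.05 for gene outputs, 1 for CellArea) to keep
#' the system mildly stiff.
#'
#' @param variant one of "chain", "crosstalk", "runaway", "vo".
#' @return a \linkS4class{NetworkModel}.
#' @export
makeToyNetwork <- function(variant = c("chain", "crosstalk", "runaway",
                                       "vo")) {
  variant <- match.arg(variant)
  if (variant == "chain") {
    nd <- data.frame(id = c("R", "K", "CellArea"), ymax = 1,
                     tau = c(0.05, 0.05, 1), y0 = 0,
                     category = c("input", "intermediate", "growth-output"))
    rx <- data.frame(id = c("in_drive", "rx_RK", "rx_KCA"),
                     rule = c("=> R", "R => K", "K => CellArea"),
                     w = c(0.5, 1, 1), n = 1.4, EC50 = 0.5)
  } else if (variant == "crosstalk") {
    nd <- data.frame(id = c("A", "B", "K", "G", "CellArea"), ymax = 1,
                     tau = c(0.05, 0.05, 0.05, 0.05, 1), y0 = 0,
                     category = c("input", "input", "intermediate",
                                  "gene-output", "growth-output"))
    rx <- data.frame(id = c("in_A", "in_B", "rx_AND", "rx_KCA", "rx_KG"),
                     rule = c("=> A", "=> B", "A & B => K",
                              "K => CellArea", "!K => G"),
                     w = c(0.5, 0.7, 1, 1, 1), n = 1.4, EC50 = 0.5)
  } else if (variant == "runaway") {
    nd <- data.frame(id = c("R", "K", "CellArea"), ymax = 1,
                     tau = c(0.05, 0.05, 1), y0 = 0,
                     category = c("input", "intermediate", "growth-output"))
    rx <- data.frame(id = c("in_drive", "rx_RK", "rx_CAK", "rx_KCA"),
                     rule = c("=> R", "R => K", "CellArea => K",
                              "K => CellArea"),
                     w = c(0.2, 1, 1, 1), n = c(1.4, 1.4, 2, 2),
                     EC50 = c(0.5, 0.5, 0.3, 0.3))
  } else {
    nd <- data.frame(
      id = c("AT1R", "bAR", "ETAR", "FAK", "Ras", "ANPg", "SERCA",
             "CellArea"),
      ymax = 1,
      tau = c(0.02, 0.02, 0.02, 0.02, 0.02, 0.05, 0.05, 1),
      y0 = 0,
      category = c("input", "input", "input", "input", "intermediate",
                   "gene-output", "gene-output", "growth-output"))
    rx <- data.frame(
      id = c("in_AngII", "in_NE", "in_ISO", "in_ET1", "in_myoStrain",
             "in_background", "rx_AT1R", "rx_bAR", "rx_ETAR", "rx_FAK",
             "rx_CA", "rx_ANP", "rx_SERCA"),
      rule = c("=> AT1R", "=> bAR", "=> bAR", "=> ETAR", "=> FAK",
               "=> Ras", "AT1R => Ras", "bAR => Ras", "ETAR => Ras",
               "FAK => Ras", "Ras => CellArea", "Ras => ANPg",
               "!Ras => SERCA"),
      w = c(0.010, 0.033, 0, 0.056, 0.06, 0.031, 1, 1, 1, 1, 1, 1, 1),
      n = c(rep(1, 6), 1, 1, 1, 1, 1.4, 1.4, 1.4),
      EC50 = c(rep(0.5, 6), 0.15, 0.15, 0.15, 0.15, 0.5, 0.5, 0.5))
  }
  parseModelTables(nd, rx)
}

#' Scenario configuration for the toy volume-overload network
#'
#' @inheritParams voConfig
#' @return a \code{\link{voConfig}} wired to
#'   \code{makeToyNetwork("vo")}'s reaction and node ids.
#' @export
toyVOConfig <- function(horizon = 5, sigmaB = 0.1,
                        lambdaED0Mean = 1.10, lambdaED0Sd = 0.02) {
  voConfig(
    inputs = c(AngII = "in_AngII", NE = "in_NE", ET1 = "in_ET1"),
    inputParams = c(AngII = "wAngII", NE = "wNE", ET1 = "wET1"),
    backgroundReactions = "in_background",
    myoStrainReaction = "in_myoStrain",
    cellAreaNode = "CellArea",
    outputs = c("ANPg", "SERCA", "CellArea"),
    varNodes = c(FAK = "FAK", Ras = "Ras", CellArea = "CellArea"),
    receptors = c(betaB = "bAR", ARB = "AT1R", ERA = "ETAR"),
    exogenous = c(ISO = "in_ISO"),
    lambdaED0Mean = lambdaED0Mean, lambdaED0Sd = lambdaED0Sd,
    horizon = horizon, sigmaB = sigmaB)
}

#' Ground truth for synthetic-data generation
#'
#' Defaults place the truth in the calibrated volume-overload regime:
#' input weights at the reported posterior means (wAngII 0.010, wNE
#' 0.033, wET1 0.056, wBackground 0.031, Cmyo 5.86, wMyoStrain0 0.06),
#' saturating-exponential stimulus curves reaching literature-scale
#' chronic fold changes (LVM +36\%, VED +67\%, hormones 2-2.5x), species
#' growth time constants of 1095 h (dog) and 283 h (rat), and study-level
#' noise typical of the collected fold-change reports.
#'
#' @param weights,curveParams,withinSd,betweenSd,speciesTau,lambdaED0
#'   overrides of the defaults.
#' @return a \linkS4class{SyntheticTruth}.
#' @export
syntheticTruth <- function(weights = NULL, curveParams = NULL,
                           withinSd = 0.25, betweenSd = 0.15,
                           speciesTau = c(dog = 1095, rat = 283),
                           lambdaED0 = 1.10) {
  w <- c(wAngII = 0.010, wNE = 0.033, wET1 = 0.056, wBackground = 0.031,
         Cmyo = 5.86, wMyoStrain0 = 0.06)
  if (!is.null(weights)) w[names(weights)] <- weights
  cp <- list(AngII = c(A = 1.0, k = 0.5), NE = c(A = 1.5, k = 0.8),
             ET1 = c(A = 1.0, k = 1.0), ANP = c(A = 2.5, k = 0.3),
             BNP = c(A = 2.0, k = 0.3), LVM = c(A = 0.36, k = 1.0),
             VED = c(A = 0.67, k = 0.7))
  if (!is.null(curveParams)) cp[names(curveParams)] <- curveParams
  new("SyntheticTruth", weights = w, curveParams = cp,
      withinSd = withinSd, betweenSd = betweenSd,
      speciesTau = speciesTau, lambdaED0 = lambdaED0)
}

# True (noise-free) fold-change functions and strain implied by a truth.
truthCurves <- function(truth, horizon = 5) {
  folds <- lapply(truth@curveParams, function(p) {
    pl <- p
    function(t) evalCurveForm("satexp", pl, t)
  })
  grid <- seq(0, horizon, length.out = 201)
  sc <- strainTrajectory(grid, folds$VED, folds$LVM, truth@lambdaED0)
  list(folds = folds, strain = sc,
       epsF = stats::approxfun(grid, sc@epsF, rule = 2),
       epsF0 = lagrangianStrain(truth@lambdaED0))
}

#' Deterministic reference trajectories for a synthetic truth
#'
#' Simulates volume overload under the truth's weights and mean stimulus
#' curves: the noise-free reference against which recovery is judged.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param model the network (typically \code{makeToyNetwork("vo")}).
#' @param config matching \code{\link{voConfig}}.
#' @return list with \code{sim} (baseline + \linkS4class{Trajectory}),
#'   \code{strain} (\linkS4class{StrainCurve}) and \code{folds}.
#' @export
generateVOTruth <- function(truth, model, config = toyVOConfig()) {
  tc <- truthCurves(truth, config$horizon)
  draw <- list(folds = tc$folds, epsF = tc$epsF, epsF0 = tc$epsF0,
               lambdaED0 = truth@lambdaED0)
  params <- truth@weights[c("wAngII", "wNE", "wET1", "wBackground", "Cmyo")]
  sim <- simulateVO(model, params, truth@weights[["wMyoStrain0"]], draw,
                    config)
  list(sim = sim, strain = tc$strain, folds = tc$folds)
}

#' Generate literature-like observation tables
#'
#' Emits one row per "study": the true fold change of a variable at a
#' time point plus a between-study normal offset as the reported mean,
#' with the within-study scale as the reported SD.  Species alternate
#' between dog and rat, with raw-hour time axes derived from the species
#' growth time constants (so the output exercises
#' \code{\link{normalizeTime}}).
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param model network used for intracellular/growth variables.
#' @param config matching \code{\link{voConfig}}.
#' @param variables which variables to emit; defaults to the config's
#'   observed nodes plus the hormones and LVM/BM.
#' @param timepoints t/tau sampling times.
#' @param nStudies studies per variable-timepoint pair.
#' @param betweenSd,withinSd noise overrides (defaults from the truth);
#'   a zero \code{betweenSd} gives noise-free means.
#' @param seed RNG seed.
#' @return observation data.frame (variable, species, time_hours, mean,
#'   sd, source).
#' @export
generateObservations <- function(truth, model, config = toyVOConfig(),
                                 variables = NULL,
                                 timepoints = c(0.1, 0.25, 0.5, 1, 2, 3),
                                 nStudies = 3, betweenSd = NULL,
                                 withinSd = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(betweenSd)) betweenSd <- truth@betweenSd
  if (is.null(withinSd)) withinSd <- truth@withinSd
  if (is.null(variables))
    variables <- c(names(config$varNodes), "AngII", "NE", "ET1", "LVM/BM")
  ref <- generateVOTruth(truth, model, config)
  tt <- trajTimes(ref$sim$traj)
  act <- activities(ref$sim$traj)
  trueFold <- function(v, t) {
    if (v %in% names(config$varNodes)) {
      node <- config$varNodes[[v]]
      stats::approx(tt, act[, node], xout = t, rule = 2)$y /
        ref$sim$baseline[[node]]
    } else if (v == "LVM/BM") ref$folds$LVM(t)
    else if (v %in% names(ref$folds)) ref$folds[[v]](t)
    else stop("no truth available for variable ", v)
  }
  sp <- c("dog", "rat")
  rows <- list()
  for (v in variables) for (ti in timepoints) for (s in seq_len(nStudies)) {
    species <- sp[(s - 1L) %% 2L + 1L]
    m <- trueFold(v, ti) + stats::rnorm(1, 0, betweenSd)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, species = species,
      time_hours = ti * truth@speciesTau[[species]],
      mean = max(m, 0.05), sd = withinSd,
      source = paste0(v, "_t", ti, "_s", s))
  }
  validateObservations(do.call(rbind, rows))
}

#' Generate two-species mass-growth observations
#'
#' LVM/BM fold-change time courses for dog and rat drawn from the truth's
#' species time constants and growth amplitude, used to exercise the
#' growth-time-constant fit and cross-species normalization.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param timepoints t/tau sampling times.
#' @param nStudies studies per species-timepoint pair.
#' @param betweenSd,withinSd noise overrides.
#' @param seed RNG seed.
#' @return observation data.frame with raw \code{time_hours}.
#' @export
generateGrowthObservations <- function(truth,
                                       timepoints = c(0.1, 0.25, 0.5, 0.75,
                                                      1, 1.5, 2, 3),
                                       nStudies = 3, betweenSd = NULL,
                                       withinSd = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(betweenSd)) betweenSd <- truth@betweenSd
  if (is.null(withinSd)) withinSd <- truth@withinSd
  p <- truth@curveParams$LVM
  rows <- list()
  for (species in names(truth@speciesTau))
    for (ti in timepoints) for (s in seq_len(nStudies)) {
      m <- evalCurveForm("satexp", p, ti) + stats::rnorm(1, 0, betweenSd)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = "LVM/BM", species = species,
        time_hours = ti * truth@speciesTau[[species]],
        mean = max(m, 0.05), sd = withinSd,
        source = paste0("LVM_", species, "_t", ti, "_s", s))
    }
  validateObservations(do.call(rbind, rows))
}
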