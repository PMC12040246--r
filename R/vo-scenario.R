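# Volume-overload scenario plumbing: wiring a calibrated parameter vector
# plus sampled stimulus curves into a time-varying Perturbation, and
# simulating from the pre-overload baseline steady state.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate expr under a given RNG seed, restoring the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration tying stimuli to network reactions
#'
#' Names the input reactions of a model that carry each hormonal stimulus,
#' the background input reactions, the mechanical (myoStrain) input
#' reaction, the observable variable-to-node map, and the baseline stretch
#' PDF.  This is the single place where stimulus names (AngII, NE, ET1,
#' ...) are keyed to reaction ids of a particular network.
#'
#' @param inputs named character: stimulus name -> input reaction id, for
#'   stimuli with their own calibrated weight and fold-change curve.
#' @param inputParams named character: stimulus name -> calibrated
#'   parameter carrying its baseline weight (e.g. AngII -> "wAngII";
#'   stimuli mapped to "wBackground" ride the shared background weight).
#' @param backgroundReactions reaction ids driven by the constant
#'   background weight with no fold-change curve.
#' @param myoStrainReaction reaction id of the mechanical input.
#' @param cellAreaNode node id of the growth output.
#' @param outputs node ids reported by scenario ensembles.
#' @param varNodes named character: observation variable -> node id, for
#'   likelihood evaluation.
#' @param receptors named character: blocker label -> receptor node id
#'   (e.g. c(betaB = "bAR", ARB = "AT1R", ERA = "ETAR")).
#' @param exogenous named character: exogenous agonist -> input reaction
#'   id with null baseline weight (e.g. ISO).
#' @param lambdaED0Mean,lambdaED0Sd normal PDF of baseline end-diastolic
#'   stretch, sampled per Monte Carlo iteration.
#' @param horizon default scenario horizon in t/tau.
#' @param sigmaB width of the baseline-CellArea-near-0.5 likelihood
#'   preference.
#' @param atol,rtol solver tolerances used for scenario and calibration
#'   runs driven by this config.
#' @param engine integration engine for scenario and calibration runs;
#'   the compiled fixed-step integrator is the default because these
#'   workloads run thousands of short simulations.
#' @return a list of class \code{voConfig}.
#' @export
voConfig <- function(inputs, inputParams, backgroundReactions = character(),
                     myoStrainReaction = NULL, cellAreaNode = "CellArea",
                     outputs = cellAreaNode, varNodes = character(),
                     receptors = character(), exogenous = character(),
                     lambdaED0Mean = 1.10, lambdaED0Sd = 0.02,
                     horizon = 5, sigmaB = 0.1,
                     atol = 1e-7, rtol = 1e-5,
                     engine = c("rk4", "lsoda")) {
  engine <- match.arg(engine)
  stopifnot(length(inputs) == length(inputParams),
            all(names(inputs) == names(inputParams)))
  structure(list(inputs = inputs, inputParams = inputParams,
                 backgroundReactions = backgroundReactions,
                 myoStrainReaction = myoStrainReaction,
                 cellAreaNode = cellAreaNode, outputs = outputs,
                 varNodes = varNodes, receptors = receptors,
                 exogenous = exogenous,
                 lambdaED0Mean = lambdaED0Mean, lambdaED0Sd = lambdaED0Sd,
                 horizon = horizon, sigmaB = sigmaB,
                 atol = atol, rtol = rtol, engine = engine),
            class = "voConfig")
}

#' Draw one set of volume-overload input curves
#'
#' Samples, from their fitted PDFs, one fold-change curve per hormonal
#' stimulus plus the LVM and VED fold curves, a baseline stretch from its
#' normal PDF, and assembles the end-diastolic strain time course.
#'
#' @param curveSet a \linkS4class{StimulusCurveSet} containing families
#'   for the stimuli named in the config plus "LVM" and "VED".
#' @param config a \code{\link{voConfig}}.
#' @param seed optional seed making the draw reproducible without
#'   disturbing the caller's RNG stream.
#' @return list with \code{folds} (named list of fold functions),
#'   \code{epsF} (strain function of t/tau), \code{epsF0}, and
#'   \code{lambdaED0}.
#' @export
drawVOCurves <- function(curveSet, config, seed = NULL) {
  doDraw <- function() {
    fams <- curveSet@curves
    stimNames <- intersect(names(config$inputs), names(fams))
    dom <- c(0, config$horizon)
    folds <- lapply(fams[stimNames], sampleCurve, domain = dom)
    lambda0 <- max(1.0, stats::rnorm(1, config$lambdaED0Mean,
                                     config$lambdaED0Sd))
    epsFfun <- NULL
    if (all(c("LVM", "VED") %in% names(fams))) {
      fcLVM <- sampleCurve(fams[["LVM"]], domain = dom)
      fcVED <- sampleCurve(fams[["VED"]], domain = dom)
      grid <- seq(0, config$horizon, length.out = 201)
      sc <- strainTrajectory(grid, fcVED, fcLVM, lambda0)
      epsFfun <- stats::approxfun(grid, sc@epsF, rule = 2)
      folds$LVM <- fcLVM
      folds$VED <- fcVED
    }
    list(folds = folds, epsF = epsFfun,
         epsF0 = lagrangianStrain(lambda0), lambdaED0 = lambda0)
  }
  if (is.null(seed)) doDraw() else withSeed(seed, doDraw())
}

# Named weight lookup for a stimulus: its calibrated parameter.
stimWeight <- function(stim, params, config) {
  pn <- config$inputParams[[stim]]
  if (is.null(pn) || !pn %in% names(params))
    stop("no calibrated weight parameter for stimulus ", stim)
  unname(params[[pn]])
}

#' Build the volume-overload perturbation
#'
#' Each hormonal input reaction's weight becomes w0 * fold(t); background
#' reactions stay at the constant background weight; the mechanical input
#' follows the exponential strain mapping evaluated along the sampled
#' strain curve.  All weights are clamped to [0, 1].
#'
#' @param params named numeric calibrated parameters (wAngII, wNE, wET1,
#'   wBackground, Cmyo).
#' @param wMyoStrain0 fixed baseline myoStrain weight.
#' @param draw a curve draw from \code{\link{drawVOCurves}}; pass
#'   \code{NULL} for the pre-overload baseline (all folds 1, strain at
#'   baseline).
#' @param config a \code{\link{voConfig}}.
#' @param knockouts receptor node ids forced to zero activity.
#' @return a \linkS4class{Perturbation}.
#' @export
voPerturbation <- function(params, wMyoStrain0, draw, config,
                           knockouts = character()) {
  # time-varying weights are tabulated on a fine grid once, so the ODE
  # right-hand side only pays for a C-level linear interpolation
  grid <- seq(0, config$horizon * 1.05, length.out = 256)
  ov <- list()
  for (stim in names(config$inputs)) {
    rid <- config$inputs[[stim]]
    w0 <- stimWeight(stim, params, config)
    if (!is.null(draw) && !is.null(draw$folds[[stim]])) {
      ov[[rid]] <- stats::approxfun(grid,
                                    clamp01(w0 * draw$folds[[stim]](grid)),
                                    rule = 2)
    } else ov[[rid]] <- clamp01(w0)
  }
  for (rid in config$backgroundReactions)
    ov[[rid]] <- clamp01(unname(params[["wBackground"]]))
  if (!is.null(config$myoStrainReaction)) {
    if (!is.null(draw) && !is.null(draw$epsF)) {
      map <- myoStrainMap(unname(params[["Cmyo"]]), wMyoStrain0, draw$epsF0)
      ov[[config$myoStrainReaction]] <-
        stats::approxfun(grid, clamp01(myoStrain(draw$epsF(grid), map)),
                         rule = 2)
    } else ov[[config$myoStrainReaction]] <- clamp01(wMyoStrain0)
  }
  perturbation(ov, knockouts = knockouts)
}

#' Simulate volume overload from the baseline steady state
#'
#' Computes the pre-overload steady state under constant baseline weights,
#' then integrates the overload scenario from that state.
#'
#' @inheritParams voPerturbation
#' @param model a \linkS4class{NetworkModel}.
#' @param times t/tau output grid (defaults to 81 points over the config
#'   horizon).
#' @param baseline optional precomputed baseline steady state (it depends
#'   on the parameters but not on the curve draw, so pooled-likelihood
#'   evaluations share it).
#' @return list with \code{baseline} (named steady state) and \code{traj}
#'   (a \linkS4class{Trajectory}).
#' @export
simulateVO <- function(model, params, wMyoStrain0, draw, config,
                       knockouts = character(), times = NULL,
                       baseline = NULL) {
  if (is.null(times)) times <- seq(0, config$horizon, length.out = 81)
  base <- if (is.null(baseline)) {
    basePert <- voPerturbation(params, wMyoStrain0, NULL, config)
    steadyState(model, basePert)
  } else baseline
  voPert <- voPerturbation(params, wMyoStrain0, draw, config,
                           knockouts = knockouts)
  traj <- simulateNetwork(model, times, voPert, init = base,
                          atol = config$atol, rtol = config$rtol,
                          engine = config$engine)
  list(baseline = base, traj = traj)
}

#' Predicted fold changes of observed nodes
#'
#' Model fold change of a node's activity relative to its baseline
#' activity, interpolated at requested times; this is the quantity
#' compared to experimental fold-change observations.
#'
#' @param sim result of \code{\link{simulateVO}}.
#' @param vars node ids.
#' @param at t/tau times.
#' @return numeric matrix (length(at) x length(vars)).
#' @export
predictFoldChanges <- function(sim, vars, at) {
  a <- activities(sim$traj)
  tt <- trajTimes(sim$traj)
  out <- matrix(NA_real_, length(at), length(vars),
                dimnames = list(NULL, vars))
  for (v in vars) {
    b <- sim$baseline[[v]]
    if (!is.finite(b) || b < 1e-9)
      stop("baseline activity of node '", v, "' is ~0; fold change undefined")
    out[, v] <- stats::approx(tt, a[, v], xout = at, rule = 2)$y / b
  }
  out
}
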