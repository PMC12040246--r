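#' @import methods
NULL

#' Logic-based signaling network model
#'
#' A normalized-Hill logic network: a node table (id, ymax, tau, y0,
#' category) and a reaction table (rule, target, w, n, EC50).  Reactions
#' sharing a target are OR-combined; operands prefixed with \code{!} act as
#' inhibitors.  Node activities are dimensionless and bounded in
#' \code{[0, ymax]}; time is measured in units of the species growth time
#' constant (t/tau).
#'
#' @slot nodes data.frame with columns \code{id}, \code{ymax}, \code{tau},
#'   \code{y0}, \code{category}.
#' @slot reactions data.frame with columns \code{id}, \code{rule},
#'   \code{target}, \code{w}, \code{n}, \code{EC50}.
#' @slot ops list, one element per reaction: integer operand indices and a
#'   logical inhibition mask, precompiled for the ODE right-hand side.
#'
#' @export
setClass("NetworkModel",
  representation(nodes = "data.frame", reactions = "data.frame",
                 ops = "list"))

setValidity("NetworkModel", function(object) {
  nd <- object@nodes; rx <- object@reactions
  msg <- character()
  if (anyDuplicated(nd$id))
    msg <- c(msg, paste0("duplicate node id: ",
                         paste(unique(nd$id[duplicated(nd$id)]), collapse = ", ")))
  if (any(nd$ymax < 0 | nd$ymax > 1)) msg <- c(msg, "ymax must lie in [0, 1]")
  if (any(nd$tau <= 0)) msg <- c(msg, "tau must be positive")
  if (any(nd$y0 < 0 | nd$y0 > nd$ymax)) msg <- c(msg, "y0 must lie in [0, ymax]")
  if (nrow(rx)) {
    if (any(rx$w < 0 | rx$w > 1)) msg <- c(msg, "reaction weights must lie in [0, 1]")
    if (any(rx$n <= 0)) msg <- c(msg, "Hill coefficient n must be positive")
    if (any(rx$EC50 <= 0 | rx$EC50 >= 1)) msg <- c(msg, "EC50 must lie in (0, 1)")
    bad <- setdiff(c(rx$target, unlist(lapply(object@ops, function(o) nd$id[o$idx]))),
                   nd$id)
    if (length(bad)) msg <- c(msg, paste0("unknown node reference: ",
                                          paste(bad, collapse = ", ")))
    if (anyDuplicated(rx$id)) msg <- c(msg, "reaction ids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Perturbation of a network model
#'
#' Weight overrides (constant or a function of time) keyed by reaction id,
#' plus receptor knockouts implemented by forcing the node's ymax to zero.
#'
#' @slot weightOverrides named list; each element a single number in [0, 1]
#'   or a function of time returning such a number.
#' @slot knockouts character vector of node ids forced to ymax = 0.
#'
#' @export
setClass("Perturbation",
  representation(weightOverrides = "list", knockouts = "character"),
  prototype(weightOverrides = list(), knockouts = character()))

#' Simulated network trajectory
#'
#' @slot times numeric t/tau grid.
#' @slot activities numeric matrix, one row per time, one column per node.
#'
#' @export
setClass("Trajectory",
  representation(times = "numeric", activities = "matrix"))

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@activities))
    "times and activity rows disagree" else TRUE
})

#' End-diastolic stretch/strain time course
#'
#' @slot times numeric t/tau grid.
#' @slot lambda fiber stretch relative to the unloaded state.
#' @slot epsF Lagrangian strain, 0.5 * (lambda^2 - 1).
#'
#' @export
setClass("StrainCurve",
  representation(times = "numeric", lambda = "numeric", epsF = "numeric"))

setValidity("StrainCurve", function(object) {
  if (length(object@times) != length(object@lambda) ||
      length(object@times) != length(object@epsF))
    return("times, lambda, epsF must have equal length")
  if (max(abs(object@epsF - 0.5 * (object@lambda^2 - 1))) > 1e-8)
    return("epsF inconsistent with lambda (epsF = (lambda^2 - 1)/2)")
  TRUE
})

#' Exponential strain-to-myoStrain mapping
#'
#' Maps organ-scale end-diastolic Lagrangian strain onto the network's
#' mechanical input weight: w(eps) = Cmyo * (exp(Dmyo * eps / epsF0) - 1).
#' Dmyo is always solved so that w(epsF0) = w0 exactly, and w(0) = 0 by
#' construction.
#'
#' @slot Cmyo mapping gain (> 0).
#' @slot Dmyo exponent coefficient, solved from Cmyo and w0.
#' @slot w0 baseline myoStrain weight at baseline strain.
#' @slot epsF0 baseline end-diastolic Lagrangian strain.
#'
#' @export
setClass("MyoStrainMap",
  representation(Cmyo = "numeric", Dmyo = "numeric", w0 = "numeric",
                 epsF0 = "numeric"))

#' Species growth time scales
#'
#' Fitted exponential growth time constants (hours) used to place dog and
#' rat time courses on a common normalized t/tau axis.
#'
#' @slot tau named numeric, time constant in hours per species.
#' @slot amplitude named numeric, fitted saturating amplitude per species
#'   (fold change above 1; NA when not fitted).
#'
#' @export
setClass("SpeciesTimeScale",
  representation(tau = "numeric", amplitude = "numeric"))

setValidity("SpeciesTimeScale", function(object) {
  if (is.null(names(object@tau)) || any(!nzchar(names(object@tau))))
    return("tau must be named by species")
  if (any(object@tau <= 0)) return("tau must be positive")
  TRUE
})

#' A family of time-varying fold-change curves
#'
#' A parametric curve form with a Gaussian parameter PDF (mean vector and
#' covariance), fitted to normalized fold-change observations.  All forms
#' are anchored at fold change 1 at t/tau = 0 by construction.
#'
#' @slot form one of "constant", "linear", "satexp" (saturating
#'   exponential), "expdecay" (fast-onset exponential decay).
#' @slot paramMean named numeric parameter means.
#' @slot paramCov parameter covariance matrix.
#' @slot domain numeric length-2 t/tau range over which samples must stay
#'   positive.
#'
#' @export
setClass("CurveFamily",
  representation(form = "character", paramMean = "numeric",
                 paramCov = "matrix", domain = "numeric"))

setValidity("CurveFamily", function(object) {
  if (!object@form %in% c("constant", "linear", "satexp", "expdecay"))
    return(paste0("unknown curve form: ", object@form))
  p <- length(object@paramMean)
  if (p && !isTRUE(all.equal(dim(object@paramCov), c(p, p))))
    return("paramCov dimension disagrees with paramMean")
  if (p) {
    ev <- eigen(object@paramCov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) return("paramCov must be positive semidefinite")
  }
  if (length(object@domain) != 2 || diff(object@domain) <= 0)
    return("domain must be an increasing length-2 range")
  TRUE
})

#' Per-stimulus curve families
#'
#' @slot curves named list of \linkS4class{CurveFamily} objects, keyed by
#'   stimulus (AngII, NE, ET1, ANP, BNP, LVM, VED, ...).
#'
#' @export
setClass("StimulusCurveSet", representation(curves = "list"))

setValidity("StimulusCurveSet", function(object) {
  if (length(object@curves) &&
      (!all(vapply(object@curves, is, logical(1), "CurveFamily")) ||
       is.null(names(object@curves))))
    "curves must be a named list of CurveFamily objects" else TRUE
})

#' Prior specification for input-weight calibration
#'
#' Uniform bounds on the calibrated parameters (input reaction weights and
#' the strain-mapping gain Cmyo), with the baseline myoStrain weight held
#' fixed per run.
#'
#' @slot bounds numeric matrix with rownames = parameter names and columns
#'   \code{lower}, \code{upper}.
#' @slot wMyoStrain0 fixed baseline myoStrain weight for this run.
#'
#' @export
setClass("PriorSpec",
  representation(bounds = "matrix", wMyoStrain0 = "numeric"))

setValidity("PriorSpec", function(object) {
  b <- object@bounds
  if (ncol(b) != 2 || is.null(rownames(b))) return("bounds must be a named n x 2 matrix")
  if (any(b[, 2] <= b[, 1])) return("upper bounds must exceed lower bounds")
  if (object@wMyoStrain0 < 0 || object@wMyoStrain0 >= 0.2)
    return("wMyoStrain0 must lie in [0, 0.2)")
  TRUE
})

#' Posterior sample ensemble from MCMC calibration
#'
#' @slot samples data.frame, one row per saved sample: parameter columns,
#'   \code{logLik}, and \code{curveSeed} (the RNG seed of the stimulus-curve
#'   draw used for that sample's likelihood evaluation).
#' @slot stage integer MCMC stage (1 = uniform prior, 2 = stage-1 posterior
#'   as prior).
#' @slot filtered logical; TRUE after runaway/reversal filtering.
#' @slot diagnostics list of convergence diagnostics per 5,000-iteration
#'   block (or the configured check interval).
#'
#' @export
setClass("PosteriorEnsemble",
  representation(samples = "data.frame", stage = "integer",
                 filtered = "logical", diagnostics = "list"),
  prototype(stage = 1L, filtered = FALSE, diagnostics = list()))

#' Monte Carlo scenario specification
#'
#' @slot kind one of "vo", "infusion", "infusion+blocker", "vo+blocker".
#' @slot agonist stimulus name of the infused agonist ("" when none).
#' @slot doseType "saturation" (input weight forced to 1) or "fold"
#'   (input weight multiplied by a normal fold-change draw, truncated at 1).
#' @slot doseMean,doseSd parameters of the fold-change PDF (ignored for
#'   saturation doses).
#' @slot blocker receptor node id knocked out ("" when none).
#' @slot horizon terminal time in t/tau units.
#' @slot nIter number of Monte Carlo iterations.
#'
#' @export
setClass("ScenarioSpec",
  representation(kind = "character", agonist = "character",
                 doseType = "character", doseMean = "numeric",
                 doseSd = "numeric", blocker = "character",
                 horizon = "numeric", nIter = "integer"),
  prototype(agonist = "", doseType = "saturation", doseMean = 1,
            doseSd = 0, blocker = "", horizon = 5, nIter = 1000L))

setValidity("ScenarioSpec", function(object) {
  if (!object@kind %in% c("vo", "infusion", "infusion+blocker", "vo+blocker"))
    return(paste0("unknown scenario kind: ", object@kind))
  if (!object@doseType %in% c("saturation", "fold"))
    return("doseType must be 'saturation' or 'fold'")
  if (object@nIter < 1L) return("nIter must be at least 1")
  if (object@horizon <= 0) return("horizon must be positive")
  TRUE
})

#' Monte Carlo ensemble result
#'
#' @slot times t/tau grid of the stored CellArea trajectories.
#' @slot cellArea matrix of CellArea activity, one row per iteration.
#' @slot terminal matrix of terminal output-node activities (one row per
#'   iteration; columns named by output node).
#' @slot baseline matrix of baseline (pre-scenario steady state) activities
#'   for the same outputs.
#' @slot growth numeric vector of normalized CellArea growth per iteration.
#' @slot draws data.frame recording the posterior row index, curve seed and
#'   dose draw used on each iteration (enables paired drug/no-drug arms).
#' @slot nFailed number of iterations dropped for integration failure.
#'
#' @export
setClass("EnsembleResult",
  representation(times = "numeric", cellArea = "matrix", terminal = "matrix",
                 baseline = "matrix", growth = "numeric", draws = "data.frame",
                 nFailed = "integer"))

#' Ground truth for synthetic-data generation
#'
#' Known input weights, stimulus-curve parameters, noise scales and species
#' time constants from which literature-like observation tables are
#' generated.  Defaults emulate the calibrated volume-overload regime.
#'
#' @slot weights named numeric: wAngII, wNE, wET1, wBackground, Cmyo,
#'   wMyoStrain0.
#' @slot curveParams named list of true stimulus-curve parameter vectors.
#' @slot withinSd within-study standard deviation of a fold-change report.
#' @slot betweenSd between-study standard deviation of reported means.
#' @slot speciesTau named numeric growth time constants (hours).
#' @slot lambdaED0 baseline end-diastolic stretch.
#'
#' @export
setClass("SyntheticTruth",
  representation(weights = "numeric", curveParams = "list",
                 withinSd = "numeric", betweenSd = "numeric",
                 speciesTau = "numeric", lambdaED0 = "numeric"))
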