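# Thin-walled-sphere left-ventricular geometry: fiber stretch and
# Lagrangian strain from cavity volumes, the growth feedback of mass gain
# on the unloaded volume, and the exponential strain-to-myoStrain mapping
# that drives the network's mechanical input.

#' Fiber stretch from cavity volumes
#'
#' For a thin-walled sphere the circumferential stretch relative to the
#' unloaded state is lambda = (VED / V0)^(1/3).
#'
#' @param VED end-diastolic cavity volume (any consistent unit, or fold).
#' @param V0 unloaded cavity volume (same unit).
#' @return stretch lambda (dimensionless).
#' @examples
#' stretchFromVolumes(8, 1)      # 2
#' stretchFromVolumes(1.728, 1)  # 1.2
#' @export
stretchFromVolumes <- function(VED, V0) {
  if (any(VED <= 0) || any(V0 <= 0))
    stop("volumes must be positive", call. = FALSE)
  (VED / V0)^(1 / 3)
}

#' Lagrangian strain from stretch
#'
#' eps_f = (lambda^2 - 1) / 2, the large-deformation strain measure
#' relative to the fixed unloaded reference.
#'
#' @param lambda stretch (> 0).
#' @return Lagrangian strain.
#' @seealso \code{\link{stretchFromStrain}} for the inverse.
#' @examples
#' lagrangianStrain(sqrt(3))  # 1
#' @export
lagrangianStrain <- function(lambda) {
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  0.5 * (lambda^2 - 1)
}

#' @rdname lagrangianStrain
#' @param epsF Lagrangian strain (> -0.5).
#' @export
stretchFromStrain <- function(epsF) {
  if (any(epsF <= -0.5)) stop("strain must exceed -0.5", call. = FALSE)
  sqrt(2 * epsF + 1)
}

#' Unloaded-volume fold change implied by eccentric growth
#'
#' During eccentric hypertrophy myocytes lengthen by series sarcomere
#' addition, enlarging the unloaded radius and volume.  The default rule
#' assumes a constant-wall-thickness thin sphere, where wall mass scales
#' with r0^2, hence V0 fold = (LVM fold)^(3/2).  The rule is pluggable so
#' an alternative mass-to-volume relation can be substituted.
#'
#' @param lvmFold fold change in left-ventricular mass (> 0).
#' @param rule a function mapping LVM fold to V0 fold; the default is the
#'   constant-thickness power law.
#' @return fold change in unloaded volume V0.
#' @examples
#' unloadedVolumeFold(4)  # 8
#' @export
unloadedVolumeFold <- function(lvmFold, rule = function(m) m^1.5) {
  if (any(lvmFold <= 0)) stop("mass fold change must be positive", call. = FALSE)
  rule(lvmFold)
}

#' Strain time course from volume and mass fold-change curves
#'
#' Combines an end-diastolic volume fold curve and an LVM fold curve into
#' stretch and Lagrangian strain trajectories:
#' lambda(t) = lambdaED0 * (fcVED(t) / V0fold(fcLVM(t)))^(1/3).
#' At t = 0 (both folds 1) the strain equals the baseline strain
#' (lambdaED0^2 - 1)/2.  Growth enters only through the unloaded-volume
#' rule, so rising mass at fixed volume strictly lowers strain.
#'
#' @param times numeric t/tau grid.
#' @param fcVED,fcLVM fold-change curves: functions of time, or numeric
#'   vectors on \code{times}.
#' @param lambdaED0 baseline end-diastolic stretch (>= 1).
#' @param v0Rule unloaded-volume growth rule, see
#'   \code{\link{unloadedVolumeFold}}.
#' @return a \linkS4class{StrainCurve}.
#' @export
strainTrajectory <- function(times, fcVED, fcLVM, lambdaED0,
                             v0Rule = function(m) m^1.5) {
  evalFC <- function(fc, what) {
    v <- if (is.function(fc)) fc(times) else as.numeric(fc)
    if (length(v) != length(times))
      stop(what, " fold curve not aligned with the time grid", call. = FALSE)
    if (any(v <= 0)) stop(what, " fold curve must stay positive", call. = FALSE)
    v
  }
  ved <- evalFC(fcVED, "VED")
  lvm <- evalFC(fcLVM, "LVM")
  lambda <- lambdaED0 * (ved / unloadedVolumeFold(lvm, v0Rule))^(1 / 3)
  new("StrainCurve", times = as.numeric(times), lambda = lambda,
      epsF = lagrangianStrain(lambda))
}

#' Solve the myoStrain mapping exponent
#'
#' Inverts the exponential mapping w = Cmyo * (exp(Dmyo * eps/eps0) - 1)
#' at the baseline anchor w(epsF0) = w0, giving Dmyo = log(1 + w0/Cmyo).
#'
#' @param Cmyo mapping gain (> 0).
#' @param w0 baseline myoStrain weight (>= 0).
#' @return Dmyo.
#' @examples
#' solveDmyo(5.86, 0.06)  # ~0.010187
#' @export
solveDmyo <- function(Cmyo, w0) {
  if (any(Cmyo <= 0)) stop("Cmyo must be positive", call. = FALSE)
  if (any(w0 < 0)) stop("w0 must be nonnegative", call. = FALSE)
  log(1 + w0 / Cmyo)
}

#' Construct a strain-to-myoStrain mapping
#'
#' @param Cmyo mapping gain (> 0).
#' @param w0 baseline myoStrain weight.
#' @param epsF0 baseline Lagrangian strain (> 0).
#' @return a \linkS4class{MyoStrainMap} with Dmyo solved so that
#'   \code{myoStrain(epsF0, map) == w0} exactly.
#' @examples
#' m <- myoStrainMap(5.86, 0.06, 0.1)
#' myoStrain(c(0, 0.1, 0.2), m)
#' @export
myoStrainMap <- function(Cmyo, w0, epsF0) {
  if (epsF0 <= 0) stop("baseline strain epsF0 must be positive", call. = FALSE)
  new("MyoStrainMap", Cmyo = Cmyo, Dmyo = solveDmyo(Cmyo, w0),
      w0 = w0, epsF0 = epsF0)
}

#' Map strain onto the network's mechanical input weight
#'
#' w(eps) = Cmyo * (exp(Dmyo * eps / epsF0) - 1): zero in the fully
#' unloaded state, equal to w0 at baseline strain, and strictly
#' increasing.  Negative strain (stretch below the unloaded length) maps
#' to a negative value by the same formula; downstream users clamp input
#' weights to [0, 1].
#'
#' @param epsF Lagrangian strain (scalar or vector).
#' @param map a \linkS4class{MyoStrainMap}.
#' @return mapped myoStrain input weight(s).
#' @export
myoStrain <- function(epsF, map) {
  map@Cmyo * (exp(map@Dmyo * epsF / map@epsF0) - 1)
}

#' Export a strain curve as a tidy table
#'
#' @param curve a \linkS4class{StrainCurve}.
#' @param file optional CSV path.
#' @return data.frame with columns \code{t_over_tau}, \code{lambda},
#'   \code{eps_f}.
#' @export
strainCurveToTidy <- function(curve, file = NULL) {
  out <- data.frame(t_over_tau = curve@times, lambda = curve@lambda,
                    eps_f = curve@epsF)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Monte Carlo summary of the end-diastolic strain ensemble
#'
#' Samples LVM and VED fold-change curves (and the baseline stretch) from
#' their PDFs, propagates each draw through the sphere model, and
#' summarizes the chronic strain distribution: the fraction of cases in
#' which chronic strain falls below its baseline level, and the Pearson
#' correlation between chronic strain and the chronic LVM fold change.
#'
#' @param curveSet \linkS4class{StimulusCurveSet} containing "LVM" and
#'   "VED" families.
#' @param n number of Monte Carlo draws.
#' @param lambdaED0Mean,lambdaED0Sd normal PDF of baseline stretch.
#' @param chronicTime t/tau at which "chronic" is evaluated.
#' @param v0Rule unloaded-volume growth rule.
#' @param seed RNG seed.
#' @return list: \code{fracBelowBaseline}, \code{fracBelowByTime}
#'   (fraction below baseline at each grid time), \code{pccStrainLVM},
#'   \code{chronicEpsF}, \code{chronicLVMFold}, \code{times}.
#' @export
strainEnsembleSummary <- function(curveSet, n = 1000, lambdaED0Mean = 1.10,
                                  lambdaED0Sd = 0.02, chronicTime = 5,
                                  v0Rule = function(m) m^1.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- curveSet@curves
  if (!all(c("LVM", "VED") %in% names(fams)))
    stop("curve set must contain LVM and VED families")
  grid <- seq(0, chronicTime, length.out = 101)
  below <- matrix(FALSE, n, length(grid))
  chronicEps <- chronicLVM <- numeric(n)
  for (i in seq_len(n)) {
    fcLVM <- sampleCurve(fams[["LVM"]], domain = c(0, chronicTime))
    fcVED <- sampleCurve(fams[["VED"]], domain = c(0, chronicTime))
    lambda0 <- max(1.0, stats::rnorm(1, lambdaED0Mean, lambdaED0Sd))
    sc <- strainTrajectory(grid, fcVED, fcLVM, lambda0, v0Rule)
    eps0 <- lagrangianStrain(lambda0)
    below[i, ] <- sc@epsF < eps0
    chronicEps[i] <- sc@epsF[length(grid)]
    chronicLVM[i] <- fcLVM(chronicTime)
  }
  list(fracBelowBaseline = mean(below[, length(grid)]),
       fracBelowByTime = colMeans(below),
       pccStrainLVM = stats::cor(chronicEps, chronicLVM),
       chronicEpsF = chronicEps, chronicLVMFold = chronicLVM,
       times = grid)
}
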