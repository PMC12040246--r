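# Monte Carlo scenario engine and ensemble statistics: untreated volume
# overload, agonist infusion (saturation or fold-change dose), receptor
# blockade and combinations; normalized growth and drug effect, CI50/CI90
# summaries, the >=75% classification rule, experimental coverage counts
# and the Pearson-correlation sensitivity matrix.

#' Construct a scenario specification
#'
#' @param kind "vo", "infusion", "infusion+blocker" or "vo+blocker".
#' @param agonist infused stimulus name (calibrated stimulus or an
#'   exogenous agonist named in the config, e.g. "ISO").
#' @param doseType "saturation" (input weight forced to 1) or "fold".
#' @param doseMean,doseSd normal PDF of the fold-change dose, truncated at
#'   fold >= 1.
#' @param blocker blocker label resolved through the config's receptor
#'   table (e.g. "betaB"), or a receptor node id.
#' @param horizon terminal time, t/tau.
#' @param nIter Monte Carlo iterations.
#' @return a \linkS4class{ScenarioSpec}.
#' @examples
#' scenarioSpec("infusion", agonist = "ISO", doseType = "saturation",
#'              nIter = 100)
#' @export
scenarioSpec <- function(kind, agonist = "", doseType = "saturation",
                         doseMean = 1, doseSd = 0, blocker = "",
                         horizon = 5, nIter = 1000L) {
  new("ScenarioSpec", kind = kind, agonist = agonist, doseType = doseType,
      doseMean = doseMean, doseSd = doseSd, blocker = blocker,
      horizon = horizon, nIter = as.integer(nIter))
}

resolveBlocker <- function(blocker, config, model) {
  if (!nzchar(blocker)) return(character())
  node <- if (blocker %in% names(config$receptors))
    config$receptors[[blocker]] else blocker
  if (!node %in% model@nodes$id)
    stop("blocker target node not in model: ", node)
  node
}

resolveAgonistReaction <- function(agonist, config) {
  if (agonist %in% names(config$exogenous)) return(config$exogenous[[agonist]])
  if (agonist %in% names(config$inputs)) return(config$inputs[[agonist]])
  stop("unknown agonist: ", agonist)
}

#' Monte Carlo simulation of a scenario
#'
#' On each iteration a set of baseline reaction weights is drawn from the
#' calibrated posterior ensemble; volume-overload kinds additionally draw
#' time-varying stimulus curves (hormone folds and the mapped strain
#' input), infusions override the agonist's input weight (to 1 at
#' saturation, or to weight x a truncated-normal fold draw), and blockers
#' zero the receptor's maximum activity.  Each iteration integrates from
#' the pre-intervention baseline steady state to the horizon.
#'
#' Passing the \code{draws} table of a previous result reruns the same
#' posterior rows, curve seeds and dose draws (common random numbers),
#' which is how the paired with-drug/without-drug arms of
#' \code{\link{normalizedDrugEffect}} are generated.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param posterior a \linkS4class{PosteriorEnsemble}.
#' @param model a \linkS4class{NetworkModel}.
#' @param config a \code{\link{voConfig}}.
#' @param curveSet \linkS4class{StimulusCurveSet}; required for "vo"
#'   kinds.
#' @param wMyoStrain0 fixed baseline myoStrain weight (used by "vo"
#'   kinds).
#' @param seed optional integer seed for the iteration draws.
#' @param draws optional draw table from a previous EnsembleResult.
#' @param nTimes number of stored trajectory points.
#' @return an \linkS4class{EnsembleResult}.
#' @export
simulateScenario <- function(spec, posterior, model, config,
                             curveSet = NULL, wMyoStrain0 = 0.06,
                             seed = NULL, draws = NULL, nTimes = 41) {
  validObject(spec)
  s <- posteriorSamples(posterior)
  if (!nrow(s)) stop("posterior ensemble is empty")
  pn <- setdiff(names(s), c("logLik", "curveSeed"))
  needsVO <- spec@kind %in% c("vo", "vo+blocker")
  if (needsVO && is.null(curveSet))
    stop("volume-overload scenarios require a curve set")
  if (!is.null(seed)) set.seed(seed)
  n <- spec@nIter
  if (is.null(draws)) {
    draws <- data.frame(
      row = sample.int(nrow(s), n, replace = TRUE),
      curveSeed = sample.int(.Machine$integer.max, n),
      doseFold = if (spec@doseType == "fold")
        pmax(stats::rnorm(n, spec@doseMean, spec@doseSd), 1) else
        rep(1, n))
  } else {
    if (nrow(draws) != n)
      stop("supplied draws do not match nIter")
  }
  knock <- resolveBlocker(spec@blocker, config, model)
  times <- seq(0, spec@horizon, length.out = nTimes)
  # cell-size output stored last so paired-arm statistics can find it
  outs <- c(setdiff(unique(config$outputs), config$cellAreaNode),
            config$cellAreaNode)

  ca <- matrix(NA_real_, n, nTimes)
  term <- base <- matrix(NA_real_, n, length(outs),
                         dimnames = list(NULL, outs))
  ok <- logical(n)
  for (i in seq_len(n)) {
    params <- unlist(s[draws$row[i], pn, drop = FALSE])
    res <- tryCatch({
      if (needsVO) {
        draw <- drawVOCurves(curveSet, config, seed = draws$curveSeed[i])
        simulateVO(model, params, wMyoStrain0, draw, config,
                   knockouts = knock, times = times)
      } else {
        basePert <- voPerturbation(params, wMyoStrain0, NULL, config)
        bstate <- steadyState(model, basePert)
        ov <- basePert@weightOverrides
        rid <- resolveAgonistReaction(spec@agonist, config)
        ov[[rid]] <- if (spec@doseType == "saturation") 1 else {
          w0 <- if (spec@agonist %in% names(config$inputs))
            stimWeight(spec@agonist, params, config) else
              model@reactions$w[match(rid, model@reactions$id)]
          clamp01(w0 * draws$doseFold[i])
        }
        pert <- perturbation(ov, knockouts = knock)
        list(baseline = bstate,
             traj = simulateNetwork(model, times, pert, init = bstate,
                                    atol = config$atol, rtol = config$rtol,
                                    engine = config$engine))
      }
    }, error = function(e) NULL)
    if (is.null(res)) next
    a <- activities(res$traj)
    ca[i, ] <- a[, config$cellAreaNode]
    term[i, ] <- a[nrow(a), outs]
    base[i, ] <- res$baseline[outs]
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("every scenario iteration failed to integrate")
  growth <- normalizedGrowth(base[ok, config$cellAreaNode],
                             ca[ok, nTimes])
  new("EnsembleResult", times = times,
      cellArea = ca[ok, , drop = FALSE],
      terminal = term[ok, , drop = FALSE],
      baseline = base[ok, , drop = FALSE],
      growth = growth, draws = draws[ok, , drop = FALSE],
      nFailed = sum(!ok))
}

#' Normalized growth
#'
#' Relative growth of the cell-size output with respect to baseline:
#' (final - initial) / initial.
#'
#' @param initial,final CellArea activity (or LVM/BM) at baseline and at
#'   the endpoint; vectors recycle elementwise.
#' @return normalized growth fraction(s).
#' @examples
#' normalizedGrowth(0.5, 0.735)  # 0.47
#' @export
normalizedGrowth <- function(initial, final) {
  if (any(initial <= 0)) stop("initial dimension must be positive")
  (final - initial) / initial
}

#' Normalized drug effect
#'
#' Difference between growth with and without the drug at the same
#' endpoint, normalized to the initial dimension:
#' (final_with_drug - final_without) / initial.  The two arms must be
#' paired (same posterior and curve draws per iteration).
#'
#' @param withDrug,without \linkS4class{EnsembleResult} arms sharing
#'   draws, or numeric terminal values.
#' @param initial baseline values (ignored when ensembles are supplied).
#' @return per-iteration drug-effect fractions.
#' @examples
#' normalizedDrugEffect(0.60, 0.70, 0.5)  # -0.2
#' @export
normalizedDrugEffect <- function(withDrug, without, initial = NULL) {
  if (is(withDrug, "EnsembleResult")) {
    if (!is(without, "EnsembleResult"))
      stop("both arms must be EnsembleResult objects")
    if (!isTRUE(all.equal(withDrug@times, without@times)))
      stop("arms were simulated to different endpoints")
    shared <- intersect(rownames2id(withDrug), rownames2id(without))
    iW <- match(shared, rownames2id(withDrug))
    iO <- match(shared, rownames2id(without))
    if (!length(shared)) stop("arms share no successful draws")
    ca <- colnames(withDrug@terminal)
    caName <- ca[length(ca)]  # cellArea stored last
    init <- without@baseline[iO, caName]
    return((withDrug@terminal[iW, caName] - without@terminal[iO, caName]) /
             init)
  }
  if (is.null(initial)) stop("initial values required for numeric arms")
  if (length(withDrug) != length(without))
    stop("arms have mismatched endpoints")
  if (any(initial <= 0)) stop("initial dimension must be positive")
  (withDrug - without) / initial
}

# identify iterations by their draw signature (posterior row + curve seed)
rownames2id <- function(res) {
  paste(res@draws$row, res@draws$curveSeed, res@draws$doseFold, sep = "_")
}

#' Central confidence intervals of a Monte Carlo sample
#'
#' CI50 = [25th, 75th] and CI90 = [5th, 95th] percentiles
#' (linear-interpolation quantiles).
#'
#' @param samples numeric vector (at least 20 values).
#' @param levels central interval levels, in percent.
#' @return matrix with one row per level and columns \code{lower},
#'   \code{upper}.
#' @examples
#' confidenceIntervals(1:100)
#' @export
confidenceIntervals <- function(samples, levels = c(50, 90)) {
  if (length(samples) < 20)
    stop("need at least 20 samples for interval estimates")
  out <- t(vapply(levels, function(l) {
    a <- (1 - l / 100) / 2
    stats::quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  }, numeric(2)))
  dimnames(out) <- list(paste0("CI", levels), c("lower", "upper"))
  out
}

#' Classify an ensemble of output changes
#'
#' A model-predicted increase requires at least \code{threshold} of the
#' iterations to predict an increase (the threshold is inclusive);
#' decreases are handled symmetrically; anything else is "mixed".
#' Exact-zero deltas count toward neither direction.
#'
#' @param deltas per-iteration changes (terminal minus baseline).
#' @param threshold classification fraction, default 0.75.
#' @return "increase", "decrease" or "mixed".
#' @examples
#' classifyChange(c(rep(1, 80), rep(-1, 20)) / 10)  # increase
#' @export
classifyChange <- function(deltas, threshold = 0.75) {
  n <- length(deltas)
  if (!n) stop("no deltas to classify")
  if (mean(deltas > 0) >= threshold) "increase"
  else if (mean(deltas < 0) >= threshold) "decrease"
  else "mixed"
}

#' Classification table for ensemble outputs
#'
#' Applies \code{\link{classifyChange}} to every output of an ensemble
#' (terminal minus baseline activity).
#'
#' @param result an \linkS4class{EnsembleResult}.
#' @param threshold classification fraction.
#' @param file optional CSV path; the table doubles as the
#'   increase/decrease/mixed heatmap export.
#' @return data.frame with columns \code{output}, \code{fracIncrease},
#'   \code{fracDecrease}, \code{call}.
#' @export
classifyOutputs <- function(result, threshold = 0.75, file = NULL) {
  d <- result@terminal - result@baseline
  out <- data.frame(
    output = colnames(d),
    fracIncrease = colMeans(d > 0),
    fracDecrease = colMeans(d < 0),
    call = vapply(seq_len(ncol(d)),
                  function(j) classifyChange(d[, j], threshold),
                  character(1)),
    row.names = NULL)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Count experimental means inside model confidence intervals
#'
#' @param samples model ensemble values on the normalized-growth or
#'   drug-effect scale.
#' @param experimentalMeans reported study means on the same scale.
#' @return list with \code{counts} (inside CI50, inside CI90, total) and
#'   \code{perStudy} boolean table.
#' @export
coverageCounts <- function(samples, experimentalMeans) {
  ci <- confidenceIntervals(samples, c(50, 90))
  in50 <- experimentalMeans >= ci["CI50", 1] & experimentalMeans <= ci["CI50", 2]
  in90 <- experimentalMeans >= ci["CI90", 1] & experimentalMeans <= ci["CI90", 2]
  list(counts = c(CI50 = sum(in50), CI90 = sum(in90),
                  total = length(experimentalMeans)),
       perStudy = data.frame(mean = experimentalMeans, inCI50 = in50,
                             inCI90 = in90))
}

#' Sensitivity of ensemble outputs to ensemble inputs
#'
#' Pearson correlation coefficients (and linear-regression slopes) of each
#' output against each input across Monte Carlo iterations, the standard
#' sampling-based sensitivity measure for a calibrated ensemble.
#'
#' @param inputs data.frame/matrix of per-iteration input values.
#' @param outputs data.frame/matrix of per-iteration output values.
#' @return list of matrices \code{pcc} and \code{slope}
#'   (inputs x outputs); zero-variance inputs give NA rows.
#' @export
sensitivityMatrix <- function(inputs, outputs) {
  inputs <- as.matrix(inputs); outputs <- as.matrix(outputs)
  if (nrow(inputs) != nrow(outputs))
    stop("inputs and outputs must pair by iteration")
  if (nrow(inputs) < 30)
    stop("need at least 30 paired samples for sensitivity estimates")
  pcc <- slope <- matrix(NA_real_, ncol(inputs), ncol(outputs),
                         dimnames = list(colnames(inputs), colnames(outputs)))
  for (i in seq_len(ncol(inputs))) {
    x <- inputs[, i]
    if (stats::sd(x) == 0) next
    for (j in seq_len(ncol(outputs))) {
      y <- outputs[, j]
      if (stats::sd(y) == 0) next
      pcc[i, j] <- stats::cor(x, y)
      slope[i, j] <- stats::cov(x, y) / stats::var(x)
    }
  }
  list(pcc = pcc, slope = slope)
}
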