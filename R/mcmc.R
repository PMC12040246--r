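# Two-stage Metropolis-Hastings / Gibbs calibration of input reaction
# weights and the strain-mapping gain against mean +/- SD literature
# observations, with unlikely-solution filtering and the wMyoStrain0
# grid scan.

#' Default prior bounds for input-weight calibration
#'
#' Uniform bounds on the calibrated parameters: the ranges over which the
#' CellArea output is sensitive to each hormonal input, a shared
#' background weight, and the strain-mapping gain Cmyo (whose printed
#' bounds are not available; the default [0.5, 20] is configuration-
#' exposed).
#'
#' @param wMyoStrain0 fixed baseline myoStrain weight for the run.
#' @param cmyoBounds lower/upper bounds for Cmyo.
#' @return a \linkS4class{PriorSpec}.
#' @export
defaultPrior <- function(wMyoStrain0 = 0.06, cmyoBounds = c(0.5, 20)) {
  b <- rbind(wAngII = c(0.01, 0.15),
             wNE = c(0.01, 0.24),
             wET1 = c(0.01, 0.17),
             wBackground = c(0.01, 0.4),
             Cmyo = cmyoBounds)
  colnames(b) <- c("lower", "upper")
  new("PriorSpec", bounds = b, wMyoStrain0 = wMyoStrain0)
}

#' Calibration log-likelihood
#'
#' Sum over observation rows of the normal log-density of the model's
#' predicted fold change (node activity at t/tau relative to baseline
#' activity) at the row's mean and SD, plus a penalty preferring a
#' baseline CellArea activity near 0.5 (the most responsive region of the
#' sigmoid): -(CellArea0 - 0.5)^2 / (2 sigmaB^2).  Integration failures
#' yield -Inf, so the proposal is rejected.
#'
#' @param params named numeric parameters (wAngII, wNE, wET1, wBackground,
#'   Cmyo).
#' @param curveDraw a stimulus-curve draw from \code{\link{drawVOCurves}}.
#' @param model a \linkS4class{NetworkModel}.
#' @param calibData normalized observation table with columns
#'   \code{variable}, \code{t_over_tau}, \code{mean}, \code{sd}; variables
#'   must appear in \code{config$varNodes}.
#' @param config a \code{\link{voConfig}}.
#' @param wMyoStrain0 fixed baseline myoStrain weight.
#' @param baseline optional precomputed baseline steady state.
#' @param times optional integration grid (defaults to the data times).
#' @return scalar log-likelihood.
#' @export
calibLogLik <- function(params, curveDraw, model, calibData, config,
                        wMyoStrain0, baseline = NULL, times = NULL) {
  if (is.null(times)) times <- sort(unique(c(0, calibData$t_over_tau)))
  sim <- tryCatch(
    simulateVO(model, params, wMyoStrain0, curveDraw, config,
               times = times, baseline = baseline),
    error = function(e) NULL)
  if (is.null(sim)) return(-Inf)
  ll <- 0
  for (v in unique(calibData$variable)) {
    node <- config$varNodes[[v]]
    if (is.null(node)) stop("no node mapped to variable ", v)
    rows <- calibData[calibData$variable == v, , drop = FALSE]
    pred <- predictFoldChanges(sim, node, rows$t_over_tau)[, 1]
    ll <- ll + sum(stats::dnorm(rows$mean, pred, rows$sd, log = TRUE))
  }
  ca0 <- sim$baseline[[config$cellAreaNode]]
  ll - (ca0 - 0.5)^2 / (2 * config$sigmaB^2)
}

#' One Metropolis-within-Gibbs sweep
#'
#' Updates each parameter in turn with a Gaussian random-walk proposal;
#' proposals outside the prior bounds are rejected outright, otherwise the
#' Metropolis rule accepts an improvement always and a worsening with
#' probability exp(delta log-posterior).
#'
#' @param params current named parameter vector.
#' @param logPost current log-posterior value of \code{params}.
#' @param evalFn function(params) returning the log-posterior (it may
#'   carry attributes, e.g. the curve seed used).
#' @param lower,upper named bound vectors.
#' @param scales proposal standard deviations (defaults to 5\% of each
#'   prior range).
#' @return list with updated \code{params}, \code{logPost}, \code{aux}
#'   (attributes of the accepted evaluation) and \code{accepted} count.
#' @export
mhGibbsStep <- function(params, logPost, evalFn, lower, upper,
                        scales = 0.05 * (upper - lower)) {
  acc <- 0L
  aux <- NULL
  for (j in seq_along(params)) {
    prop <- params
    prop[j] <- params[j] + stats::rnorm(1, 0, scales[j])
    if (prop[j] < lower[j] || prop[j] > upper[j]) next
    lp <- evalFn(prop)
    if (is.finite(lp) && log(stats::runif(1)) < (lp - logPost)) {
      params <- prop
      logPost <- lp
      aux <- attributes(lp)
      acc <- acc + 1L
    }
  }
  list(params = params, logPost = logPost, aux = aux, accepted = acc)
}

# Product of per-parameter Gaussian-kernel densities (stage-2 prior
# built from the stage-1 ensemble; Silverman bandwidths).  Returns the
# log-density and a matching sampler (resample + jitter per parameter),
# so independence proposals can be drawn from exactly this prior.
kdeLogPrior <- function(samples) {
  cols <- colnames(samples)
  bw <- vapply(cols, function(j) max(stats::bw.nrd0(samples[, j]), 1e-8),
               numeric(1))
  m <- as.matrix(samples)
  n <- nrow(m)
  logDensity <- function(params) {
    lp <- 0
    for (j in seq_along(cols)) {
      d <- mean(stats::dnorm(params[j], m[, j], bw[j]))
      if (d <= 0) return(-Inf)
      lp <- lp + log(d)
    }
    lp
  }
  sampleFun <- function() {
    idx <- sample.int(n, length(cols), replace = TRUE)
    setNames(m[cbind(idx, seq_along(cols))] +
               stats::rnorm(length(cols), 0, bw), cols)
  }
  list(logDensity = logDensity, sample = sampleFun)
}

#' Run one MCMC stage
#'
#' Metropolis-within-Gibbs chain over the prior box.  The log-likelihood
#' of each proposal is evaluated with a fresh stimulus-curve draw whose
#' seed is recorded with the sample, so any saved sample's trajectory can
#' be reproduced.  Convergence is monitored every \code{checkEvery}
#' iterations as the relative change of block means of the log-likelihood
#' and of each parameter.
#'
#' @param logLikFn function(params, curveSeed) -> log-likelihood.
#' @param prior a \linkS4class{PriorSpec}.
#' @param nIter number of Gibbs sweeps.
#' @param init optional starting parameter vector (defaults to the prior
#'   box midpoint or a draw from \code{initSamples}).
#' @param logPriorFn optional log-prior function (stage 2); stage 1 uses
#'   the flat prior implied by the bounds.
#' @param scales proposal SDs, default 5\% of each prior range.
#' @param checkEvery convergence-check block length.
#' @param stage stage label stored on the ensemble.
#' @param refresh when TRUE (default) the current sample's likelihood is
#'   re-evaluated with a fresh stimulus-curve draw at the start of every
#'   sweep, mirroring an algorithm that re-runs the model on each
#'   iteration; without it a lucky curve draw can freeze the chain.
#'   Turn it off when \code{logLikFn} is deterministic.
#' @param indepProposal optional independence-proposal distribution: a
#'   list with elements \code{sample} (function() -> parameter vector)
#'   and \code{logDensity} (function(params) -> log proposal density).
#'   When supplied, every sweep starts with a Metropolis independence
#'   move with the proper proposal-density correction; these global
#'   jumps let the chain cross likelihood ridges that defeat small
#'   random-walk steps.  Defaults to uniform draws over the bounds.
#' @param jointSigma optional covariance matrix for an additional joint
#'   random-walk move per sweep (scaled by 2.38^2/d), which travels
#'   along correlated parameter ridges that axis-aligned Gibbs updates
#'   cross only slowly.
#' @return a \linkS4class{PosteriorEnsemble} (one saved sample per sweep).
#' @export
runMCMC <- function(logLikFn, prior, nIter, init = NULL, logPriorFn = NULL,
                    scales = NULL, checkEvery = 5000, stage = 1L,
                    refresh = TRUE, indepProposal = NULL,
                    jointSigma = NULL) {
  b <- prior@bounds
  lower <- b[, 1]; upper <- b[, 2]
  pn <- rownames(b)
  d <- length(pn)
  if (is.null(scales)) scales <- 0.05 * (upper - lower)
  if (is.null(init)) init <- (lower + upper) / 2
  init <- setNames(as.numeric(init[pn]), pn)
  if (is.null(indepProposal))
    indepProposal <- list(
      sample = function() setNames(stats::runif(d, lower, upper), pn),
      logDensity = function(params) 0)
  jointChol <- if (!is.null(jointSigma)) {
    sig <- jointSigma * 2.38^2 / d + diag(1e-12, d)
    chol(sig)
  }

  evalFn <- function(params) {
    cs <- sample.int(.Machine$integer.max, 1)
    ll <- logLikFn(params, cs)
    lp <- ll + if (is.null(logPriorFn)) 0 else logPriorFn(params)
    attr(lp, "logLik") <- ll
    attr(lp, "curveSeed") <- cs
    lp
  }

  cur <- evalFn(init)
  curLL <- attr(cur, "logLik"); curSeed <- attr(cur, "curveSeed")
  params <- init
  out <- matrix(NA_real_, nIter, length(pn), dimnames = list(NULL, pn))
  llv <- numeric(nIter); seeds <- integer(nIter)
  diagn <- list()
  prevBlock <- NULL
  for (i in seq_len(nIter)) {
    if (refresh) {
      cur <- evalFn(params)
      curLL <- attr(cur, "logLik")
      curSeed <- attr(cur, "curveSeed")
    }
    # global independence move with proposal-density correction
    prop <- indepProposal$sample()
    if (all(prop >= lower & prop <= upper)) {
      e <- evalFn(prop)
      ratio <- as.numeric(e) - as.numeric(cur) +
        indepProposal$logDensity(params) - indepProposal$logDensity(prop)
      if (is.finite(ratio) && log(stats::runif(1)) < ratio) {
        params <- setNames(as.numeric(prop[pn]), pn)
        cur <- e
        curLL <- attr(e, "logLik")
        curSeed <- attr(e, "curveSeed")
      }
    }
    # joint correlated random-walk move
    if (!is.null(jointChol)) {
      prop <- params + drop(stats::rnorm(d) %*% jointChol)
      if (all(prop >= lower & prop <= upper)) {
        e <- evalFn(prop)
        if (is.finite(e) && log(stats::runif(1)) < as.numeric(e) -
              as.numeric(cur)) {
          params <- setNames(as.numeric(prop[pn]), pn)
          cur <- e
          curLL <- attr(e, "logLik")
          curSeed <- attr(e, "curveSeed")
        }
      }
    }
    st <- mhGibbsStep(params, as.numeric(cur), evalFn, lower, upper, scales)
    params <- st$params
    cur <- st$logPost
    if (!is.null(st$aux)) {
      curLL <- st$aux$logLik
      curSeed <- st$aux$curveSeed
    }
    out[i, ] <- params
    llv[i] <- curLL
    seeds[i] <- curSeed
    if (i %% checkEvery == 0 || i == nIter) {
      blk <- colMeans(out[max(1, i - checkEvery + 1):i, , drop = FALSE])
      rel <- if (is.null(prevBlock)) NA_real_ else
        max(abs(blk - prevBlock) / pmax(abs(prevBlock), 1e-8))
      diagn[[length(diagn) + 1L]] <-
        list(iter = i, blockMeans = blk,
             meanLogLik = mean(llv[max(1, i - checkEvery + 1):i]),
             relChange = rel)
      prevBlock <- blk
    }
  }
  samples <- as.data.frame(out)
  samples$logLik <- llv
  samples$curveSeed <- seeds
  new("PosteriorEnsemble", samples = samples, stage = as.integer(stage),
      filtered = FALSE, diagnostics = diagn)
}

#' Two-stage calibration of network input weights
#'
#' Stage 1 samples from a uniform prior over the bounds.  Its posterior
#' ensemble then drives stage 2 as a continuation: a Gaussian
#' kernel-density representation (Silverman bandwidths) of the stage-1
#' posterior supplies the independence-proposal distribution and the
#' joint random-walk covariance, and the chain restarts from the stage-1
#' maximum-likelihood sample.  The stage-2 target remains likelihood
#' times the original uniform prior — re-multiplying by the stage-1
#' posterior would use the same data twice and artificially narrow the
#' final credible intervals.
#'
#' Stimulus-curve uncertainty is marginalized by Monte Carlo: a pool of
#' \code{nPool} curve draws is fixed for the run (seeded from the current
#' RNG stream) and each likelihood evaluation averages the per-draw
#' likelihoods (log-mean-exp).  A fixed pool makes the chain's target
#' deterministic, which keeps Metropolis acceptance meaningful; drawing a
#' fresh curve on every iteration instead makes the acceptance decision a
#' lottery over curve draws and stalls mixing badly at realistic
#' curve-PDF widths.  The baseline steady state depends only on the
#' parameters, so it is shared across the pool.
#'
#' @param model a \linkS4class{NetworkModel}.
#' @param calibData normalized observation table (see
#'   \code{\link{calibLogLik}}).
#' @param curveSet fitted \linkS4class{StimulusCurveSet}.
#' @param config a \code{\link{voConfig}}.
#' @param prior a \linkS4class{PriorSpec}.
#' @param nIter1,nIter2 sweep counts for the two stages.
#' @param burn1 fraction of stage 1 discarded before building the stage-2
#'   prior.
#' @param checkEvery convergence-check block length.
#' @param nPool number of curve draws over which the likelihood is
#'   averaged.
#' @return the stage-2 \linkS4class{PosteriorEnsemble}; the stage-1
#'   ensemble is attached as attribute \code{"stage1"}.
#' @export
calibrateNetwork <- function(model, calibData, curveSet, config, prior,
                             nIter1 = 10000, nIter2 = 20000, burn1 = 0.2,
                             checkEvery = 5000, nPool = 6) {
  poolSeeds <- sample.int(.Machine$integer.max, nPool)
  pool <- lapply(poolSeeds, function(s) drawVOCurves(curveSet, config,
                                                     seed = s))
  dataTimes <- sort(unique(c(0, calibData$t_over_tau)))
  logLikFn <- function(params, curveSeed) {
    basePert <- voPerturbation(params, prior@wMyoStrain0, NULL, config)
    base <- tryCatch(steadyState(model, basePert), error = function(e) NULL)
    if (is.null(base)) return(-Inf)
    lls <- vapply(pool, function(d)
      calibLogLik(params, d, model, calibData, config, prior@wMyoStrain0,
                  baseline = base, times = dataTimes), numeric(1))
    m <- max(lls)
    if (!is.finite(m)) return(-Inf)
    m + log(mean(exp(lls - m)))
  }
  s1 <- runMCMC(logLikFn, prior, nIter1, checkEvery = checkEvery,
                stage = 1L, refresh = FALSE)
  keep <- posteriorSamples(s1)
  keep <- keep[-seq_len(floor(burn1 * nrow(keep))), , drop = FALSE]
  pn <- rownames(prior@bounds)
  kde <- kdeLogPrior(keep[, pn, drop = FALSE])
  init <- unlist(keep[which.max(keep$logLik), pn])
  s2 <- runMCMC(logLikFn, prior, nIter2, init = init,
                indepProposal = kde,
                jointSigma = stats::cov(keep[, pn, drop = FALSE]),
                checkEvery = checkEvery, stage = 2L, refresh = FALSE)
  attr(s2, "stage1") <- s1
  s2
}

#' Build a CellArea-trajectory function for filtering
#'
#' Returns a function that, given one saved posterior sample (parameters +
#' curve seed), regenerates its stimulus-curve draw and volume-overload
#' CellArea trajectory.
#'
#' @inheritParams calibrateNetwork
#' @param wMyoStrain0 fixed baseline myoStrain weight.
#' @return function(sampleRow) -> list(times, cellArea, baseline).
#' @export
makeVOTrajFun <- function(model, curveSet, config, wMyoStrain0) {
  function(row) {
    params <- unlist(row[setdiff(names(row), c("logLik", "curveSeed"))])
    draw <- drawVOCurves(curveSet, config, seed = row[["curveSeed"]])
    sim <- simulateVO(model, params, wMyoStrain0, draw, config)
    ca <- activities(sim$traj)[, config$cellAreaNode]
    list(times = trajTimes(sim$traj), cellArea = ca,
         baseline = sim$baseline[[config$cellAreaNode]])
  }
}

#' Filter unlikely calibration solutions
#'
#' Long-term experiments agree that ventricular mass plateaus in chronic
#' overload, so two behaviours are treated as very unlikely and removed:
#' growth reversal (CellArea falling below baseline by more than
#' \code{deltaRev}, relative) at any time, and runaway growth (relative
#' CellArea slope above \code{deltaRun} per unit t/tau at the horizon).
#'
#' @param ensemble a \linkS4class{PosteriorEnsemble}.
#' @param trajFun per-sample trajectory function, see
#'   \code{\link{makeVOTrajFun}}.
#' @param deltaRev reversal tolerance, fraction of baseline CellArea.
#' @param deltaRun runaway slope threshold (fraction of baseline per unit
#'   t/tau, evaluated at the horizon).
#' @param maxSamples evaluate at most this many (evenly thinned) samples.
#' @return the filtered \linkS4class{PosteriorEnsemble}; removal counts in
#'   attribute \code{"filterCounts"}.
#' @export
filterUnlikely <- function(ensemble, trajFun, deltaRev = 0.01,
                           deltaRun = 0.005, maxSamples = Inf) {
  s <- posteriorSamples(ensemble)
  idx <- seq_len(nrow(s))
  if (is.finite(maxSamples) && nrow(s) > maxSamples)
    idx <- unique(round(seq(1, nrow(s), length.out = maxSamples)))
  keep <- logical(length(idx))
  nRev <- nRun <- 0L
  for (k in seq_along(idx)) {
    tr <- trajFun(s[idx[k], ])
    rel <- tr$cellArea / tr$baseline
    nt <- length(tr$times)
    slope <- (rel[nt] - rel[nt - 1L]) / (tr$times[nt] - tr$times[nt - 1L])
    reversal <- any(rel < 1 - deltaRev)
    runaway <- slope > deltaRun
    if (reversal) nRev <- nRev + 1L
    if (runaway) nRun <- nRun + 1L
    keep[k] <- !reversal && !runaway
  }
  if (!any(keep))
    stop("all ", length(idx), " samples filtered as unlikely (",
         nRev, " reversal, ", nRun, " runaway)")
  out <- new("PosteriorEnsemble", samples = s[idx[keep], , drop = FALSE],
             stage = ensemble@stage, filtered = TRUE,
             diagnostics = ensemble@diagnostics)
  attr(out, "filterCounts") <- c(kept = sum(keep), reversal = nRev,
                                 runaway = nRun)
  out
}

#' Grid scan over the fixed baseline myoStrain weight
#'
#' Repeats the two-stage calibration at each fixed wMyoStrain0 value and
#' reports the mean log-likelihood and the fraction of solutions filtered
#' as unlikely (reversal or runaway), the quantities used to select the
#' working wMyoStrain0.
#'
#' @param values wMyoStrain0 grid (each in (0, 0.2)).
#' @inheritParams calibrateNetwork
#' @param filterMax samples per run passed to \code{\link{filterUnlikely}}.
#' @return data.frame with one row per scanned value: \code{wMyoStrain0},
#'   \code{meanLogLik}, \code{unlikelyFraction}.
#' @export
scanWmyoStrain <- function(values, model, calibData, curveSet, config,
                           nIter1 = 1000, nIter2 = 2000, filterMax = 100,
                           cmyoBounds = c(0.5, 20)) {
  if (any(values <= 0 | values >= 0.2))
    stop("wMyoStrain0 values must lie in (0, 0.2)")
  res <- lapply(values, function(w0) {
    pr <- defaultPrior(wMyoStrain0 = w0, cmyoBounds = cmyoBounds)
    ens <- calibrateNetwork(model, calibData, curveSet, config, pr,
                            nIter1 = nIter1, nIter2 = nIter2,
                            checkEvery = max(nIter2, 1))
    trajFun <- makeVOTrajFun(model, curveSet, config, w0)
    frac <- tryCatch({
      f <- filterUnlikely(ens, trajFun, maxSamples = filterMax)
      cnt <- attr(f, "filterCounts")
      1 - cnt[["kept"]] / min(filterMax, nrow(posteriorSamples(ens)))
    }, error = function(e) 1)
    data.frame(wMyoStrain0 = w0,
               meanLogLik = mean(posteriorSamples(ens)$logLik),
               unlikelyFraction = frac)
  })
  do.call(rbind, res)
}

#' Posterior means, SDs and parameter correlations
#'
#' @param ensemble a \linkS4class{PosteriorEnsemble}.
#' @return list with \code{mean}, \code{sd} (named vectors) and \code{pcc}
#'   (Pearson correlation matrix; entries involving a zero-variance
#'   parameter are NA).
#' @export
posteriorSummary <- function(ensemble) {
  s <- posteriorSamples(ensemble)
  pn <- setdiff(names(s), c("logLik", "curveSeed"))
  m <- as.matrix(s[, pn, drop = FALSE])
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  pcc <- suppressWarnings(stats::cor(m))
  pcc[outer(sdv == 0, sdv == 0, "|")] <- NA_real_
  diag(pcc)[sdv > 0] <- 1
  list(mean = mu, sd = sdv, pcc = pcc)
}

#' Write a posterior ensemble as CSV
#'
#' One row per saved sample (parameters, log-likelihood, curve seed);
#' the stage and filtered flag are recorded as comment-free extra
#' columns so the file round-trips with plain readers.
#'
#' @param ensemble a \linkS4class{PosteriorEnsemble}.
#' @param file CSV path.
#' @return \code{file}, invisibly.
#' @export
writeEnsemble <- function(ensemble, file) {
  s <- posteriorSamples(ensemble)
  s$stage <- ensemble@stage
  s$filtered <- ensemble@filtered
  utils::write.csv(s, file, row.names = FALSE)
  invisible(file)
}
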