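# Cross-species time normalization and fitting/sampling of time-varying
# hormonal fold-change curves.  Observation tables are plain data.frames
# with columns: variable, species, time_hours (or t_over_tau once
# normalized), mean, sd, source.

obsRequired <- c("variable", "species", "time_hours", "mean", "sd", "source")

#' Validate an observation table
#'
#' Checks the delimited-text observation schema: required columns,
#' positive SDs, and positive fold changes.
#'
#' @param data a data.frame (or CSV path) of observations.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validateObservations <- function(data) {
  if (is.character(data)) data <- utils::read.csv(data, stringsAsFactors = FALSE)
  miss <- setdiff(obsRequired, names(data))
  # a normalized table carries t_over_tau instead of time_hours
  if ("time_hours" %in% miss && "t_over_tau" %in% names(data))
    miss <- setdiff(miss, "time_hours")
  if (length(miss))
    stop("observation table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(data$sd <= 0)) stop("observation sd must be positive")
  if (any(data$mean <= 0)) stop("fold-change means must be positive")
  data
}

#' Fit the species growth time constant
#'
#' Fits the left-ventricular mass fold-change time course of each species
#' with the saturating exponential FC(t) = 1 + A (1 - exp(-t / tau)) by
#' weighted nonlinear least squares (weights 1/sd^2), returning the fitted
#' time constant tau (hours) and amplitude A per species.  Normalizing all
#' time courses by tau aligns dog and rat data on a common t/tau axis.
#'
#' @param data observation table with raw \code{time_hours}; typically the
#'   LVM/BM rows.
#' @param minPoints minimum number of distinct time points per species.
#' @return a \linkS4class{SpeciesTimeScale}.
#' @export
fitGrowthTimescale <- function(data, minPoints = 3) {
  data <- validateObservations(data)
  sp <- unique(data$species)
  tau <- amp <- setNames(numeric(length(sp)), sp)
  for (s in sp) {
    d <- data[data$species == s, ]
    if (length(unique(d$time_hours)) < minPoints)
      stop("species '", s, "' has fewer than ", minPoints,
           " distinct time points")
    if (diff(range(d$mean)) < 1e-6)
      stop("species '", s, "' fold changes are constant; ",
           "growth-time-constant fit is degenerate")
    fit <- minpack.lm::nlsLM(
      mean ~ 1 + A * (1 - exp(-time_hours / tau)),
      data = d, weights = 1 / d$sd^2,
      start = list(A = max(d$mean) - 1,
                   tau = stats::median(d$time_hours)),
      lower = c(A = 1e-6, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    tau[s] <- cf[["tau"]]
    amp[s] <- cf[["A"]]
  }
  new("SpeciesTimeScale", tau = tau, amplitude = amp)
}

#' Construct a SpeciesTimeScale from known time constants
#'
#' @param tau named numeric vector of growth time constants (hours).
#' @param amplitude optional named numeric of growth amplitudes.
#' @return a \linkS4class{SpeciesTimeScale}.
#' @examples
#' speciesTimeScale(c(dog = 1095, rat = 283))
#' @export
speciesTimeScale <- function(tau, amplitude = NULL) {
  if (is.null(amplitude))
    amplitude <- setNames(rep(NA_real_, length(tau)), names(tau))
  new("SpeciesTimeScale", tau = tau, amplitude = amplitude)
}

#' Ratio of two species' growth time constants
#'
#' @param scale a \linkS4class{SpeciesTimeScale}.
#' @param num,den species names for numerator and denominator.
#' @return tau[num] / tau[den].
#' @export
tauRatio <- function(scale, num, den) {
  if (!all(c(num, den) %in% names(scale@tau)))
    stop("unknown species in tau ratio")
  unname(scale@tau[num] / scale@tau[den])
}

#' Normalize observation times by the species growth time constant
#'
#' Replaces \code{time_hours} with \code{t_over_tau}; the added flag
#' column \code{.normalized} makes the operation idempotent (an already
#' normalized table passes through unchanged).
#'
#' @param data observation table.
#' @param scale a \linkS4class{SpeciesTimeScale} covering every species in
#'   the table.
#' @return the table on the t/tau axis.
#' @export
normalizeTime <- function(data, scale) {
  if (isTRUE(attr(data, "normalized")) || "t_over_tau" %in% names(data))
    return(data)
  data <- validateObservations(data)
  unknown <- setdiff(unique(data$species), names(scale@tau))
  if (length(unknown))
    stop("no time scale for species: ", paste(unknown, collapse = ", "))
  data$t_over_tau <- data$time_hours / scale@tau[data$species]
  data$time_hours <- NULL
  attr(data, "normalized") <- TRUE
  data
}

# --- curve families ---------------------------------------------------

# Fast-onset time constant for the expdecay family, in t/tau units: keeps
# the curve anchored at fold 1 at t = 0 while peaking early.
.expdecayOnset <- 0.02

#' Evaluate a curve family at given parameters
#'
#' Functional forms (all anchored at fold change 1 at t = 0):
#' \itemize{
#'   \item constant: FC(t) = 1 (no parameters)
#'   \item linear: FC(t) = 1 + b t
#'   \item satexp: FC(t) = 1 + A (1 - exp(-t / k))
#'   \item expdecay: FC(t) = 1 + A exp(-t / k) (1 - exp(-t / 0.02)),
#'     an acute surge that decays back toward baseline
#' }
#'
#' @param form one of "constant", "linear", "satexp", "expdecay".
#' @param params named numeric parameters (b; or A, k).
#' @param t time(s) in t/tau units.
#' @return fold-change value(s).
#' @export
evalCurveForm <- function(form, params, t) {
  switch(form,
    constant = rep(1, length(t)),
    linear   = 1 + params[["b"]] * t,
    satexp   = 1 + params[["A"]] * (1 - exp(-t / params[["k"]])),
    expdecay = 1 + params[["A"]] * exp(-t / params[["k"]]) *
                 (1 - exp(-t / .expdecayOnset)),
    stop("unknown curve form: ", form))
}

#' Fit a stimulus fold-change curve family
#'
#' Weighted nonlinear least squares (weights 1/sd^2) of the chosen
#' functional form to normalized, baseline-anchored fold-change data.
#' The parameter covariance is the linearized covariance of the fit and
#' defines the Gaussian parameter PDF from which curves are later sampled.
#'
#' @param data normalized observation table (column \code{t_over_tau}) for
#'   a single variable.
#' @param form curve form, see \code{\link{evalCurveForm}}.
#' @param domain t/tau range of validity (defaults to [0, 1.1 * max t]).
#' @param fixK optional fixed time constant for the exponential forms.
#'   The mass-growth (LVM) family should use \code{fixK = 1}: the t/tau
#'   axis is defined by normalizing time with the fitted exponential
#'   growth constant of that very curve, so its shape parameter is 1 by
#'   construction and letting it float only re-creates the amplitude/
#'   time-constant ridge the normalization removed.
#' @param pdf which parameter PDF the family carries: "mean" (default)
#'   is the fit's linearized covariance, i.e. uncertainty of the pooled
#'   mean curve; "predictive" inflates the amplitude (A or b) variance
#'   by the number of observations — putting the amplitude spread at
#'   the study-to-study scatter instead of the standard error of the
#'   pooled mean — while keeping the shape parameter at its fitted
#'   precision.  Use it when each Monte Carlo draw should represent one
#'   possible study-level outcome rather than the population mean.
#' @return a \linkS4class{CurveFamily}.
#' @export
fitStimulusCurve <- function(data, form = c("satexp", "linear", "constant",
                                            "expdecay"),
                             domain = NULL, fixK = NULL,
                             pdf = c("mean", "predictive")) {
  pdf <- match.arg(pdf)
  form <- match.arg(form)
  if (!"t_over_tau" %in% names(data))
    stop("data must be normalized first (normalizeTime)")
  if (any(data$sd <= 0)) stop("observation sd must be positive")
  if (is.null(domain)) domain <- c(0, max(data$t_over_tau) * 1.1)
  t <- data$t_over_tau
  y <- data$mean
  w <- 1 / data$sd^2
  if (form == "constant") {
    fam <- new("CurveFamily", form = form, paramMean = numeric(),
               paramCov = matrix(numeric(), 0, 0), domain = domain)
    return(fam)
  }
  if (form == "linear") {
    fit <- stats::lm(I(y - 1) ~ 0 + t, weights = w)
    pm <- c(b = unname(stats::coef(fit)[1]))
    # a noiseless fit triggers the "essentially perfect fit" warning;
    # its zero covariance is exactly what we want
    pc <- suppressWarnings(as.matrix(stats::vcov(fit)))
  } else {
    if (is.null(fixK)) {
      starts <- list(
        list(A = max(abs(y - 1)) + 0.05, k = max(stats::median(t), 0.05)),
        list(A = mean(y[t >= stats::median(t)]) - 1 + 0.01, k = 1),
        list(A = 0.5, k = 0.3))
      rhs <- if (form == "satexp")
        y ~ 1 + A * (1 - exp(-t / k))
      else
        y ~ 1 + A * exp(-t / k) * (1 - exp(-t / 0.02))
      lowerB <- c(A = -0.99, k = 1e-3)
    } else {
      starts <- list(list(A = max(abs(y - 1)) + 0.05), list(A = 0.3))
      rhs <- if (form == "satexp")
        y ~ 1 + A * (1 - exp(-t / fixK))
      else
        y ~ 1 + A * exp(-t / fixK) * (1 - exp(-t / 0.02))
      lowerB <- c(A = -0.99)
    }
    fit <- NULL
    for (start in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(rhs, data = data.frame(t = t, y = y),
                          weights = w, start = start,
                          lower = lowerB,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("stimulus-curve fit failed (", form, ") from every start",
           call. = FALSE)
    pm <- stats::coef(fit)
    pc <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) {
      diag(1e-12, length(pm))
    })
    if (!is.null(fixK)) {
      pm <- c(pm, k = fixK)
      pc <- rbind(cbind(pc, 0), 0)
    }
  }
  if (pdf == "predictive") {
    ai <- match(c("A", "b"), names(pm))
    ai <- ai[!is.na(ai)][1]
    n <- nrow(data)
    pc[ai, ] <- pc[ai, ] * sqrt(n)
    pc[, ai] <- pc[, ai] * sqrt(n)
  }
  dimnames(pc) <- list(names(pm), names(pm))
  # guard tiny negative eigenvalues from the linearization
  ev <- eigen(pc, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0)
  pc <- ev$vectors %*% diag(ev$values, length(pm)) %*% t(ev$vectors)
  dimnames(pc) <- list(names(pm), names(pm))
  new("CurveFamily", form = form, paramMean = pm, paramCov = pc,
      domain = domain)
}

#' Draw one curve from a family's parameter PDF
#'
#' Samples parameters from the multivariate normal (mean, covariance) of
#' the family, rejecting draws whose curve goes nonpositive anywhere on
#' the domain, and returns an evaluable fold-change function of time.
#' With a zero covariance the mean curve is returned.
#'
#' @param family a \linkS4class{CurveFamily}.
#' @param maxTries rejection-sampling budget.
#' @param domain t/tau range over which the sampled curve must stay
#'   positive (defaults to the family's fitted domain; widen it when the
#'   curve will be evaluated beyond the data range).
#' @return a function \code{fc(t)}; its parameter draw is attached as
#'   attribute \code{params}.
#' @export
sampleCurve <- function(family, maxTries = 100, domain = family@domain) {
  p <- length(family@paramMean)
  grid <- seq(domain[1], domain[2], length.out = 101)
  for (i in seq_len(maxTries)) {
    par <- if (p == 0) numeric() else
      drop(MASS::mvrnorm(1, family@paramMean, family@paramCov))
    vals <- evalCurveForm(family@form, par, grid)
    if (all(vals > 0)) {
      frm <- family@form
      fn <- function(t) evalCurveForm(frm, par, t)
      attr(fn, "params") <- par
      return(fn)
    }
  }
  stop("sampleCurve: no positive curve in ", maxTries, " draws")
}

#' Curve family at its mean parameters
#'
#' @param family a \linkS4class{CurveFamily}.
#' @return function \code{fc(t)} evaluating the mean curve.
#' @export
meanCurve <- function(family) {
  frm <- family@form
  pm <- family@paramMean
  function(t) evalCurveForm(frm, pm, t)
}

#' Fit a set of stimulus curves
#'
#' @param data normalized observation table covering several variables.
#' @param forms named character vector mapping variable name to curve
#'   form; variables absent from \code{forms} default to "satexp".
#' @param fixK named numeric vector of fixed time constants per variable
#'   (default: the LVM family is pinned at k = 1, which the t/tau
#'   normalization implies; see \code{\link{fitStimulusCurve}}).
#' @param pdf "mean" or "predictive", applied to every family; see
#'   \code{\link{fitStimulusCurve}}.
#' @return a \linkS4class{StimulusCurveSet}.
#' @export
fitStimulusSet <- function(data, forms = character(), fixK = c(LVM = 1),
                           pdf = "mean") {
  vars <- unique(data$variable)
  curves <- lapply(vars, function(v) {
    f <- if (v %in% names(forms)) forms[[v]] else "satexp"
    kf <- if (v %in% names(fixK)) fixK[[v]] else NULL
    fitStimulusCurve(data[data$variable == v, , drop = FALSE], form = f,
                     fixK = kf, pdf = pdf)
  })
  names(curves) <- vars
  new("StimulusCurveSet", curves = curves)
}

#' Serialize / restore a stimulus curve set
#'
#' Curve families (form, parameter means, covariance, domain) are stored
#' as a structured JSON file so a fitted set can be shared between the
#' calibration and validation steps without refitting.
#'
#' @param set a \linkS4class{StimulusCurveSet}.
#' @param file path of the JSON file.
#' @return \code{writeStimulusSet} returns \code{file} invisibly;
#'   \code{readStimulusSet} returns the restored
#'   \linkS4class{StimulusCurveSet}.
#' @export
writeStimulusSet <- function(set, file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to serialize curve sets")
  out <- lapply(set@curves, function(f)
    list(form = f@form, paramMean = as.list(f@paramMean),
         paramCov = f@paramCov, domain = f@domain))
  jsonlite::write_json(out, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' @rdname writeStimulusSet
#' @export
readStimulusSet <- function(file) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read curve sets")
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  curves <- lapply(raw, function(x) {
    pm <- unlist(x$paramMean)
    pc <- if (length(pm)) {
      m <- matrix(unlist(x$paramCov), length(pm), length(pm),
                  byrow = TRUE)
      dimnames(m) <- list(names(pm), names(pm))
      m
    } else matrix(numeric(), 0, 0)
    new("CurveFamily", form = x$form,
        paramMean = if (length(pm)) pm else numeric(),
        paramCov = pc, domain = as.numeric(x$domain))
  })
  new("StimulusCurveSet", curves = curves)
}
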