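# Generics and simple accessors / show methods.

#' @rdname NetworkModel-class
#' @param object,x a \linkS4class{NetworkModel}
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname NetworkModel-class
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname NetworkModel-class
#' @export
setMethod("nodes", "NetworkModel", function(x) x@nodes)

#' @rdname NetworkModel-class
#' @export
setMethod("reactions", "NetworkModel", function(x) x@reactions)

setMethod("show", "NetworkModel", function(object) {
  cat("NetworkModel:", nrow(object@nodes), "nodes,",
      nrow(object@reactions), "reactions\n")
  cat("  categories:",
      paste(names(table(object@nodes$category)),
            table(object@nodes$category), collapse = ", "), "\n")
})

#' @rdname Trajectory-class
#' @param x a \linkS4class{Trajectory}
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname Trajectory-class
#' @export
setMethod("activities", "Trajectory", function(x) x@activities)

#' @rdname Trajectory-class
#' @export
setGeneric("trajTimes", function(x) standardGeneric("trajTimes"))

#' @rdname Trajectory-class
#' @export
setMethod("trajTimes", "Trajectory", function(x) x@times)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points x",
      ncol(object@activities), "nodes over t/tau = [",
      min(object@times), ",", max(object@times), "]\n")
})

setMethod("show", "StrainCurve", function(object) {
  cat("StrainCurve:", length(object@times), "points; eps_f range [",
      signif(min(object@epsF), 3), ",", signif(max(object@epsF), 3), "]\n")
})

setMethod("show", "MyoStrainMap", function(object) {
  cat("MyoStrainMap: Cmyo =", signif(object@Cmyo, 4),
      "Dmyo =", signif(object@Dmyo, 4),
      "w0 =", object@w0, "epsF0 =", signif(object@epsF0, 4), "\n")
})

setMethod("show", "SpeciesTimeScale", function(object) {
  cat("SpeciesTimeScale (hours):\n")
  for (s in names(object@tau))
    cat("  ", s, ": tau =", signif(object@tau[[s]], 5),
        " amplitude =", signif(object@amplitude[[s]], 4), "\n")
})

setMethod("show", "CurveFamily", function(object) {
  cat("CurveFamily <", object@form, "> params:",
      paste(names(object@paramMean), signif(object@paramMean, 4),
            sep = "=", collapse = ", "), "\n")
})

setMethod("show", "StimulusCurveSet", function(object) {
  cat("StimulusCurveSet:", paste(names(object@curves), collapse = ", "), "\n")
})

setMethod("show", "PosteriorEnsemble", function(object) {
  cat("PosteriorEnsemble: stage", object@stage, "-",
      nrow(object@samples), "samples",
      if (object@filtered) "(filtered)" else "", "\n")
})

setMethod("show", "EnsembleResult", function(object) {
  cat("EnsembleResult:", nrow(object@terminal), "iterations;",
      "mean normalized growth =", signif(mean(object@growth), 3), "\n")
})

#' @rdname PosteriorEnsemble-class
#' @param x a \linkS4class{PosteriorEnsemble}
#' @export
setGeneric("posteriorSamples", function(x) standardGeneric("posteriorSamples"))

#' @rdname PosteriorEnsemble-class
#' @export
setMethod("posteriorSamples", "PosteriorEnsemble", function(x) x@samples)

#' @rdname EnsembleResult-class
#' @param x an \linkS4class{EnsembleResult}
#' @export
setGeneric("growthSamples", function(x) standardGeneric("growthSamples"))

#' @rdname EnsembleResult-class
#' @export
setMethod("growthSamples", "EnsembleResult", function(x) x@growth)
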