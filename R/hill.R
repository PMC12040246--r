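#' Normalized Hill activation
#'
#' Sigmoidal transfer function f(x) = B x^n / (K^n + x^n) with the
#' normalization constants B and K^n fixed so that f(0) = 0, f(EC50) = 0.5
#' and f(1) = 1.  This is the activation kinetics used by every reaction in
#' the logic network: each operand activity is passed through the
#' reaction's Hill function (or its complement 1 - f for inhibitors) before
#' the logic gates combine them.
#'
#' Closed form of the constants: with E = EC50^n,
#' B = (E - 1) / (2E - 1) and K^n = B - 1.  The constants are undefined
#' when EC50^n = 0.5 (and whenever EC50 lies outside (0, 1)); such
#' parameters are rejected.
#'
#' @param x activity in [0, 1] (values are clamped to [0, 1] to guard
#'   against solver overshoot).
#' @param EC50 half-maximal input, in (0, 1).
#' @param n Hill coefficient, > 0.
#' @return activation in [0, 1], monotone nondecreasing in \code{x}.
#' @examples
#' hillActivation(0.25, EC50 = 0.5, n = 2)   # 1/6
#' hillActivation(c(0, 0.5, 1), 0.5, 2)      # 0, 0.5, 1
#' @export
hillActivation <- function(x, EC50, n) {
  k <- hillConstants(EC50, n)
  x <- pmin(pmax(x, 0), 1)
  xn <- x^n
  k$B * xn / (k$Kn + xn)
}

# Normalization constants for the Hill form; shared by the compiled RHS.
hillConstants <- function(EC50, n) {
  if (any(EC50 <= 0) || any(EC50 >= 1))
    stop("EC50 must lie strictly inside (0, 1): normalization constants ",
         "are undefined otherwise", call. = FALSE)
  if (any(n <= 0)) stop("Hill coefficient n must be positive", call. = FALSE)
  E <- EC50^n
  if (any(abs(2 * E - 1) < 1e-12))
    stop("EC50^n = 0.5 makes the Hill normalization singular", call. = FALSE)
  B <- (E - 1) / (2 * E - 1)
  list(B = B, Kn = B - 1)
}

#' Evaluate a logic rule on node activities
#'
#' Applies the gate conventions of the normalized-Hill logic formulation:
#' each operand activity is transformed by the reaction's Hill function,
#' inhibitors (prefixed \code{!}) contribute 1 - f, AND (\code{&}) is the
#' product of operand activations, and multiple reactions converging on one
#' target are OR-combined as a + b - a*b (see \code{\link{logicOR}}).
#' An input rule with no operands (\code{"=> X"}) evaluates to 1 and is
#' scaled only by its (possibly time-varying) weight.
#'
#' @param rule a rule string such as \code{"!A & B => C"}.
#' @param activities named numeric vector of node activities in [0, 1].
#' @param EC50,n Hill parameters applied to every operand of this rule.
#' @return the gated activation in [0, 1] (weight not applied).
#' @examples
#' combineLogic("A & B => C", c(A = 1, B = 0), 0.5, 2)  # 0
#' combineLogic("!A => C", c(A = 0), 0.5, 2)            # 1
#' @export
combineLogic <- function(rule, activities, EC50, n) {
  p <- parseRule(rule)
  if (!length(p$operands)) return(1)
  missing <- setdiff(p$operands, names(activities))
  if (length(missing))
    stop("rule references undefined node(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  f <- hillActivation(activities[p$operands], EC50, n)
  f[p$inhib] <- 1 - f[p$inhib]
  prod(f)
}

#' Probabilistic OR of activations
#'
#' Inclusion-exclusion combination used when several reactions share a
#' target: OR(a, b) = a + b - a*b, applied left to right.
#'
#' @param ... activation values in [0, 1] (each may be a vector; vectors
#'   are combined elementwise).
#' @return combined activation in [0, 1].
#' @examples
#' logicOR(0.5, 0.5)  # 0.75
#' @export
logicOR <- function(...) {
  vals <- list(...)
  out <- vals[[1]]
  for (v in vals[-1]) out <- out + v - out * v
  out
}
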