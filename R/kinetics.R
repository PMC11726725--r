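#' Rate constants of the two reversible binding reactions
#'
#' The chemical network couples an active RNA species A (the "agent") to a
#' short inhibitor X and the inhibitor to its complementary anti-inhibitor Y:
#' \deqn{A + X \rightleftharpoons AX, \qquad X + Y \rightleftharpoons XY}
#' with association rates \code{k1}, \code{k3} and dissociation rates
#' \code{k2}, \code{k4} under mass-action kinetics.  The dissociation
#' (equilibrium) constants \eqn{K = k_2/k_1} and \eqn{k = k_4/k_3} are always
#' recomputed from the four rates, never stored.
#'
#' Concentrations and rates are treated as dimensionless: the model's worked
#' parameter sets carry no units.
#'
#' @param k1,k2 association/dissociation rates of the agent-inhibitor
#'   reaction (both > 0).
#' @param k3,k4 association/dissociation rates of the
#'   inhibitor-anti-inhibitor reaction (both > 0).
#' @return An object of class \code{rate_constants}.
#' @examples
#' r <- rate_constants(1, 1, 1, 1)
#' dissociation_constants(r) # K = k = 1
#' @export
rate_constants <- function(k1, k2, k3, k4) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (!all(is.finite(ks)) || any(ks <= 0))
    stop("all four rate constants must be finite and strictly positive")
  structure(as.list(ks), class = "rate_constants")
}

#' @rdname rate_constants
#' @param rates a \code{rate_constants} object.
#' @export
dissociation_constants <- function(rates) {
  stopifnot(inherits(rates, "rate_constants"))
  list(K = rates$k2 / rates$k1, k = rates$k4 / rates$k3)
}

#' @export
print.rate_constants <- function(x, ...) {
  kk <- dissociation_constants(x)
  cat(sprintf("rate constants: k1=%g k2=%g k3=%g k4=%g  (K=%g, k=%g)\n",
              x$k1, x$k2, x$k3, x$k4, kk$K, kk$k))
  invisible(x)
}

#' Conserved total concentrations
#'
#' Totals of the three basic molecules, free plus complexed:
#' \eqn{c_A = [A] + [AX]}, \eqn{c_X = [X] + [AX] + [XY]},
#' \eqn{c_Y = [Y] + [XY]}.  They are conserved by the binding reactions.
#' \code{cX = 0} and/or \code{cY = 0} select the reduced models (no
#' inhibitor, or no anti-inhibitor).
#'
#' @param cA total agent concentration (> 0).
#' @param cX total inhibitor concentration (>= 0).
#' @param cY total anti-inhibitor concentration (>= 0).
#' @return An object of class \code{totals}.
#' @export
totals <- function(cA, cX, cY = 0) {
  if (!all(is.finite(c(cA, cX, cY))))
    stop("totals must be finite")
  if (cA <= 0) stop("cA must be strictly positive")
  if (cX < 0 || cY < 0) stop("cX and cY must be nonnegative")
  structure(list(cA = cA, cX = cX, cY = cY), class = "totals")
}

#' @export
print.totals <- function(x, ...) {
  cat(sprintf("totals: cA=%g cX=%g cY=%g\n", x$cA, x$cX, x$cY))
  invisible(x)
}

#' Full mixture state of the five species
#'
#' @param A,X,Y free concentrations of agent, inhibitor, anti-inhibitor.
#' @param AX,XY concentrations of the two complexes.
#' @return An object of class \code{mixture_state} (named list of five
#'   nonnegative concentrations).
#' @export
mixture_state <- function(A, X, Y, AX, XY) {
  s <- c(A = A, X = X, Y = Y, AX = AX, XY = XY)
  if (!all(is.finite(s))) stop("concentrations must be finite")
  if (any(s < 0)) stop("concentrations must be nonnegative")
  structure(as.list(s), class = "mixture_state")
}

#' @export
print.mixture_state <- function(x, ...) {
  cat(sprintf("[A]=%g [X]=%g [Y]=%g [AX]=%g [XY]=%g\n",
              x$A, x$X, x$Y, x$AX, x$XY))
  invisible(x)
}

#' Conserved totals of a mixture state
#'
#' Sums free and complexed concentrations.  A state whose agent total is zero
#' is chemically empty of A; the result then violates the \code{cA > 0}
#' requirement of \code{\link{totals}} and a warning flags it (the sums are
#' still returned, unclassed, for inspection).
#'
#' @param state a \code{\link{mixture_state}}.
#' @return A \code{\link{totals}} object (or a plain list, with a warning,
#'   when \code{cA} is not positive).
#' @export
totals_of <- function(state) {
  stopifnot(inherits(state, "mixture_state"))
  cA <- state$A + state$AX
  cX <- state$X + state$AX + state$XY
  cY <- state$Y + state$XY
  if (cA <= 0) {
    warning("state has cA = ", cA, ": violates the cA > 0 invariant of totals")
    return(list(cA = cA, cX = cX, cY = cY))
  }
  totals(cA, cX, cY)
}

#' Reconstruct the full state from the two free concentrations
#'
#' Given the conserved totals, the free agent and free anti-inhibitor
#' concentrations determine everything else:
#' \eqn{[AX] = c_A - [A]}, \eqn{[XY] = c_Y - [Y]},
#' \eqn{[X] = c_X - c_A + [A] - c_Y + [Y]}.
#'
#' @param A_free free agent concentration.
#' @param Y_free free anti-inhibitor concentration.
#' @param tot a \code{\link{totals}} object.
#' @return A \code{\link{mixture_state}}.  Signals an error when any derived
#'   concentration would be negative (infeasible pair of free values).
#' @export
state_from_free <- function(A_free, Y_free, tot) {
  stopifnot(inherits(tot, "totals"))
  AX <- tot$cA - A_free
  XY <- tot$cY - Y_free
  X  <- tot$cX - tot$cA + A_free - tot$cY + Y_free
  lowest <- min(A_free, Y_free, AX, XY, X)
  if (lowest < 0) {
    # tolerate pure rounding noise relative to the concentration scale
    scale <- max(abs(c(tot$cA, tot$cX, tot$cY, 1)))
    if (lowest < -1e-12 * scale)
      stop("infeasible free concentrations: a derived concentration is negative (",
           signif(lowest, 6), ")")
    A_free <- max(A_free, 0); Y_free <- max(Y_free, 0)
    AX <- max(AX, 0); XY <- max(XY, 0); X <- max(X, 0)
  }
  mixture_state(A = A_free, X = X, Y = Y_free, AX = AX, XY = XY)
}

#' Mass-action right-hand side of the binding network
#'
#' Time derivatives of the five concentrations under mass action:
#' \deqn{d[A]/dt = k_2[AX] - k_1[A][X]}
#' \deqn{d[AX]/dt = -d[A]/dt}
#' \deqn{d[Y]/dt = k_4[XY] - k_3[X][Y]}
#' \deqn{d[XY]/dt = -d[Y]/dt}
#' \deqn{d[X]/dt = k_2[AX] - k_1[A][X] + k_4[XY] - k_3[X][Y]}
#' The three conservation identities \eqn{\dot A + \dot{AX} = 0},
#' \eqn{\dot Y + \dot{XY} = 0}, \eqn{\dot X + \dot{AX} + \dot{XY} = 0} hold
#' exactly at the level of the returned values.
#'
#' @param state a \code{\link{mixture_state}}.
#' @param rates a \code{\link{rate_constants}} object.
#' @return Named numeric vector \code{c(A, X, Y, AX, XY)} of derivatives.
#' @export
mass_action_rhs <- function(state, rates) {
  stopifnot(inherits(state, "mixture_state"), inherits(rates, "rate_constants"))
  fAX <- rates$k2 * state$AX - rates$k1 * state$A * state$X
  fXY <- rates$k4 * state$XY - rates$k3 * state$X * state$Y
  c(A = fAX, X = fAX + fXY, Y = fXY, AX = -fAX, XY = -fXY)
}
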