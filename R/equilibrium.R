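# Equilibrium analysis: the inhibitor-only quadratic, the full-model cubic,
# the system capacity beta = (d x / d cA)^{-1}, and inverse design of totals.

#' Equilibrium of the inhibitor-only model
#'
#' With anti-inhibitors absent (\code{cY = 0}) the equilibrium free-agent
#' concentration \eqn{x = e_A} solves
#' \deqn{x^2 + (c_X - c_A + K)x - K c_A = 0,}
#' which has exactly one root in \eqn{(0, c_A)}; the larger quadratic root is
#' the physical one.  The remaining equilibrium concentrations follow from the
#' conservation relations \eqn{e_{AX} = c_A - x}, \eqn{e_X = c_X - c_A + x}.
#'
#' @param cA total agent concentration (> 0).
#' @param cX total inhibitor concentration (>= 0); \code{cX = 0} gives
#'   \eqn{x = c_A} exactly.
#' @param K dissociation constant \eqn{k_2/k_1} (> 0).
#' @return An object of class \code{simple_equilibrium}: list with \code{x}
#'   (= \code{eA}), \code{eX}, \code{eAX}, \code{beta} (system capacity) and
#'   \code{discriminant}.
#' @seealso [simple_capacity()], [simple_required_cX()], [full_equilibrium()]
#' @examples
#' simple_equilibrium(cA = 100, cX = 99, K = 1) # x = 10, eAX = 90
#' @export
simple_equilibrium <- function(cA, cX, K) {
  if (!all(is.finite(c(cA, cX, K))) || cA <= 0 || K <= 0)
    stop("require finite cA > 0 and K > 0")
  if (cX < 0) stop("cX must be nonnegative")
  p <- cX - cA + K                      # linear coefficient
  disc <- p * p + 4 * K * cA            # always > 0
  if (cX == 0) {
    x <- cA                             # quadratic factors as (x - cA)(x + K)
  } else if (p >= 0) {
    x <- 2 * K * cA / (p + sqrt(disc))  # stable form, avoids cancellation
  } else {
    x <- (-p + sqrt(disc)) / 2
  }
  structure(list(
    x = x, eA = x, eX = cX - cA + x, eAX = cA - x,
    beta = simple_capacity(min(x, cA * (1 - 1e-15)), cA, K),
    discriminant = disc
  ), class = "simple_equilibrium")
}

#' @export
print.simple_equilibrium <- function(x, ...) {
  cat(sprintf("inhibitor-only equilibrium: eA=%g eX=%g eAX=%g  (beta=%g)\n",
              x$x, x$eX, x$eAX, x$beta))
  invisible(x)
}

#' System capacity of the inhibitor-only model
#'
#' The capacity \eqn{\beta = (\partial x/\partial c_A)^{-1}} measures how
#' strongly the equilibrium buffers the free-agent concentration against
#' changes in the total: after a perturbation \eqn{\delta} of \eqn{c_A}, the
#' equilibrium \eqn{x} shifts by about \eqn{\delta/\beta}.  In closed form
#' \deqn{\beta = \frac{x^2 + K c_A}{x^2 + K x},}
#' bounded by \eqn{1 < \beta < c_A/x}, diverging as \eqn{x \to 0}.
#'
#' @param x equilibrium free-agent concentration, in \eqn{(0, c_A)}.
#' @inheritParams simple_equilibrium
#' @return The capacity (dimensionless scalar).
#' @export
simple_capacity <- function(x, cA, K) {
  if (!all(is.finite(c(x, cA, K))) || cA <= 0 || K <= 0)
    stop("require finite cA > 0 and K > 0")
  if (x <= 0 || x >= cA)
    stop("x must lie strictly inside (0, cA)")
  (x * x + K * cA) / (x * x + K * x)
}

#' Inhibitor total required for a target set point (no anti-inhibitors)
#'
#' Inverts the inhibitor-only equilibrium: the total inhibitor concentration
#' that pins the equilibrium free agent at \code{target_x} is
#' \deqn{c_X = \frac{(c_A - x)(x + K)}{x},}
#' always positive for \eqn{0 < x < c_A}.  Round trip:
#' \code{simple_equilibrium(cA, simple_required_cX(x, cA, K), K)$x == x}.
#'
#' @param target_x desired equilibrium free-agent concentration, in
#'   \eqn{(0, c_A)}.
#' @inheritParams simple_equilibrium
#' @return The required total inhibitor concentration.
#' @examples
#' simple_required_cX(10, cA = 100, K = 1) # 99
#' @export
simple_required_cX <- function(target_x, cA, K) {
  if (!all(is.finite(c(target_x, cA, K))) || cA <= 0 || K <= 0)
    stop("require finite cA > 0 and K > 0")
  if (target_x <= 0 || target_x >= cA)
    stop("target_x must lie strictly inside (0, cA)")
  (cA - target_x) * (target_x + K) / target_x
}

#' Coefficients of the full-model equilibrium cubic
#'
#' With anti-inhibitors present, the equilibrium free-agent concentration is
#' the unique root in \eqn{(0, c_A)} of
#' \deqn{L(x) = a x^3 + b x^2 + c x + d}
#' with
#' \deqn{a = k - K}
#' \deqn{b = (k - K)(c_X + K - c_A) + K(c_A + c_Y)}
#' \deqn{c = K c_A (2K - k - c_A + c_X - c_Y)}
#' \deqn{d = -K^2 c_A^2.}
#' The coefficients \code{e}, \code{f}, \code{g} of the relation obtained by
#' differentiating \eqn{L(x) = 0} with respect to \eqn{c_A} (used by the
#' capacity formula) are also returned:
#' \eqn{e = -\partial b/\partial c_A = k - 2K},
#' \eqn{f = -\partial c/\partial c_A = -K(2K - k - 2c_A + c_X - c_Y)},
#' \eqn{g = -\partial d/\partial c_A = 2K^2 c_A}.
#'
#' @param K,k dissociation constants of the AX and XY reactions (> 0).
#' @param cA,cX,cY conserved totals (\code{cA > 0}, others >= 0).
#' @return List with components \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{e}, \code{f}, \code{g}.
#' @export
cubic_coefficients <- function(K, k, cA, cX, cY) {
  if (!all(is.finite(c(K, k, cA, cX, cY))) || K <= 0 || k <= 0 || cA <= 0 ||
      cX < 0 || cY < 0)
    stop("invalid parameters for the equilibrium cubic")
  list(
    a = k - K,
    b = (k - K) * (cX + K - cA) + K * (cA + cY),
    c = K * cA * (2 * K - k - cA + cX - cY),
    d = -K^2 * cA^2,
    e = k - 2 * K,
    f = -K * (2 * K - k - 2 * cA + cX - cY),
    g = 2 * K^2 * cA
  )
}

# Evaluate L(x) = a x^3 + b x^2 + c x + d (Horner form).
eval_cubic <- function(co, x) ((co$a * x + co$b) * x + co$c) * x + co$d

# Stable positive root of b x^2 + c x + d = 0 with b > 0, d < 0
# (the k = K degenerate case of the equilibrium cubic).
stable_quadratic_root <- function(b, c, d) {
  s <- sqrt(c * c - 4 * b * d)
  if (c >= 0) -2 * d / (c + s) else (-c + s) / (2 * b)
}

#' Equilibrium of the full inhibitor/anti-inhibitor model
#'
#' Solves the equilibrium cubic \eqn{L(x) = 0} (see
#' \code{\link{cubic_coefficients}}) for the free-agent concentration
#' \eqn{x = [A]} by bracketed root finding on \eqn{(0, c_A)}, where
#' \eqn{L(0) = -K^2 c_A^2 < 0} and \eqn{L(c_A) = k c_X c_A^2 > 0} guarantee a
#' sign change; a Lyapunov argument guarantees the root (hence the
#' equilibrium) is unique.  The full state follows from
#' \eqn{[AX] = c_A - x}, \eqn{[X] = K(c_A - x)/x},
#' \eqn{[Y] = [X] + c_A - x - c_X + c_Y}, \eqn{[XY] = c_Y - [Y]}.
#'
#' Degenerate cases: \code{cX = 0} short-circuits to \eqn{x = c_A} with no
#' complexes; \eqn{k = K} collapses the cubic to a quadratic, solved in
#' closed form.  The bracketed root is polished by Newton iterations to full
#' floating-point precision.
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param tot a \code{\link{totals}} object.
#' @return An object of class \code{full_equilibrium}: list with \code{x},
#'   \code{state} (a \code{\link{mixture_state}}), \code{beta} (system
#'   capacity), and \code{coefficients}.
#' @examples
#' eq <- full_equilibrium(rate_constants(1, 1, 1, 1), totals(7, 100, 24.45))
#' eq$x    # ~ 0.1
#' eq$beta # ~ 63.7
#' @export
full_equilibrium <- function(rates, tot) {
  stopifnot(inherits(rates, "rate_constants"), inherits(tot, "totals"))
  kk <- dissociation_constants(rates)
  K <- kk$K; k <- kk$k
  cA <- tot$cA; cX <- tot$cX; cY <- tot$cY

  if (cX == 0) {
    # no inhibitor: A stays free, Y stays free, no complexes form
    st <- mixture_state(A = cA, X = 0, Y = cY, AX = 0, XY = 0)
    out <- structure(list(x = cA, state = st, beta = 1,
                          coefficients = cubic_coefficients(K, k, cA, cX, cY)),
                     class = "full_equilibrium")
    return(out)
  }

  co <- cubic_coefficients(K, k, cA, cX, cY)
  if (co$a == 0) {
    x <- stable_quadratic_root(co$b, co$c, co$d)
  } else {
    root <- uniroot(function(z) eval_cubic(co, z),
                    lower = 0, upper = cA,
                    f.lower = co$d, f.upper = k * cX * cA^2,
                    tol = 1e-12 * cA, maxiter = 1000L)
    x <- root$root
  }
  # Newton polish (L' > 0 at the root since L crosses from - to +)
  for (i in 1:4) {
    Lx <- eval_cubic(co, x)
    dL <- (3 * co$a * x + 2 * co$b) * x + co$c
    if (dL <= 0) break
    step <- Lx / dL
    x_new <- x - step
    if (x_new <= 0 || x_new >= cA) break
    x <- x_new
    if (abs(step) < 1e-16 * cA) break
  }

  AX <- cA - x
  X  <- K * AX / x
  Y  <- X + cA - x - cX + cY
  XY <- cY - Y
  # tolerate rounding at the boundaries of feasibility
  eps <- 1e-12 * max(cA, cX, cY, 1)
  if (min(X, Y, AX, XY) < -eps)
    stop("internal error: equilibrium reconstruction produced a negative concentration")
  st <- mixture_state(A = x, X = max(X, 0), Y = max(Y, 0),
                      AX = max(AX, 0), XY = max(XY, 0))
  beta <- capacity_from_coefficients(co, x)
  structure(list(x = x, state = st, beta = beta, coefficients = co),
            class = "full_equilibrium")
}

#' @export
print.full_equilibrium <- function(x, ...) {
  cat(sprintf("full-model equilibrium: [A]=%g  (beta=%g)\n", x$x, x$beta))
  print(x$state)
  invisible(x)
}

# beta = L'(x) / (e x^2 + f x + g), the implicit-differentiation form.
capacity_from_coefficients <- function(co, x) {
  num <- (3 * co$a * x + 2 * co$b) * x + co$c
  den <- (co$e * x + co$f) * x + co$g
  num / den
}

#' System capacity of the full model
#'
#' The capacity \eqn{\beta = (\partial x/\partial c_A)^{-1}} of the full
#' inhibitor/anti-inhibitor model, obtained by implicit differentiation of
#' the equilibrium cubic:
#' \deqn{\beta = \frac{3 a x^2 + 2 b x + c}{e x^2 + f x + g}}
#' evaluated at the equilibrium root \eqn{x}.  It satisfies
#' \eqn{0 < \beta < c_A/x}.
#'
#' @inheritParams full_equilibrium
#' @return The capacity (dimensionless scalar).
#' @examples
#' full_capacity(rate_constants(1, 1, 1, 1), totals(7, 100, 24.45)) # ~ 63.7
#' @export
full_capacity <- function(rates, tot) {
  full_equilibrium(rates, tot)$beta
}

#' Coefficients of the linear design relation
#'
#' For a desired equilibrium free-agent concentration \eqn{x}, the totals of
#' inhibitor and anti-inhibitor must satisfy the linear relation
#' \deqn{S c_X - T c_Y = U}
#' with
#' \deqn{S = x[kx + K(c_A - x)], \quad T = K x (c_A - x),}
#' \deqn{U = (K - k)x^3 + [(K - k)(K - c_A) - K c_A]x^2 - K c_A(2K - k - c_A)x + K^2 c_A^2.}
#' Both \eqn{S} and \eqn{T} are positive for \eqn{0 < x < c_A}, so any set
#' point is attainable with suitable totals.
#'
#' @param K,k dissociation constants (> 0).
#' @param cA total agent concentration (> 0).
#' @param x target equilibrium free-agent concentration, in \eqn{(0, c_A)}.
#' @return List with components \code{S}, \code{T}, \code{U}.
#' @export
design_coefficients <- function(K, k, cA, x) {
  if (!all(is.finite(c(K, k, cA, x))) || K <= 0 || k <= 0 || cA <= 0)
    stop("require finite K, k, cA > 0")
  if (x <= 0 || x >= cA) stop("x must lie strictly inside (0, cA)")
  list(
    S = x * (k * x + K * (cA - x)),
    T = K * x * (cA - x),
    U = (K - k) * x^3 + ((K - k) * (K - cA) - K * cA) * x^2 -
      K * cA * (2 * K - k - cA) * x + K^2 * cA^2
  )
}

#' Design inhibitor/anti-inhibitor totals for a target set point
#'
#' Solves the design relation \eqn{S c_X - T c_Y = U} (see
#' \code{\link{design_coefficients}}) for the free total, holding the other
#' fixed, so that \code{\link{full_equilibrium}} at the returned totals has
#' free-agent concentration \code{target_x}.
#'
#' @param rates a \code{\link{rate_constants}} object.
#' @param cA total agent concentration.
#' @param target_x desired equilibrium free-agent concentration, in
#'   \eqn{(0, c_A)}.
#' @param cX,cY exactly one of the two must be supplied; the other is
#'   computed.  An error signals infeasibility when the computed total would
#'   be negative (the fixed value is too small or too large for the target).
#' @return A \code{\link{totals}} object on the design line.
#' @examples
#' r <- rate_constants(1, 1, 1, 1)
#' design_concentrations(r, cA = 100, target_x = 10, cY = 0)   # cX = 99
#' design_concentrations(r, cA = 7, target_x = 0.1, cX = 100)  # cY ~ 24.45
#' @export
design_concentrations <- function(rates, cA, target_x, cX = NULL, cY = NULL) {
  stopifnot(inherits(rates, "rate_constants"))
  if (is.null(cX) == is.null(cY))
    stop("supply exactly one of cX, cY as the fixed total")
  kk <- dissociation_constants(rates)
  co <- design_coefficients(kk$K, kk$k, cA, target_x)
  if (is.null(cY)) {
    if (cX < 0) stop("fixed cX must be nonnegative")
    cY <- (co$S * cX - co$U) / co$T
    if (cY < 0) {
      if (cY > -1e-12 * max(1, cX)) cY <- 0
      else stop("infeasible: fixed cX = ", cX, " is too small for target_x = ",
                target_x, " (required cY = ", signif(cY, 6), ")")
    }
  } else {
    if (cY < 0) stop("fixed cY must be nonnegative")
    cX <- (co$U + co$T * cY) / co$S
    if (cX < 0)
      stop("infeasible: fixed cY = ", cY, " is too large for target_x = ",
           target_x, " (required cX = ", signif(cX, 6), ")")
  }
  totals(cA = cA, cX = cX, cY = cY)
}
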