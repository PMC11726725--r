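# Deterministic forward-Euler dynamics of the binding network, with the
# scenario forcings (random jump noise, ramp noise, agent self-replication)
# and Lyapunov convergence diagnostics.

#' Scenario forcings on the agent balance
#'
#' A forcing perturbs the free-agent concentration (and hence the conserved
#' total \eqn{c_A}) on top of the mass-action binding dynamics:
#' \describe{
#'   \item{\code{forcing_none()}}{closed system; all three totals conserved.}
#'   \item{\code{forcing_jump_noise(p_event, lo, hi)}}{at each Euler step,
#'     with probability \code{p_event}, a uniform draw from
#'     \code{[lo, hi]} is added to \eqn{[A]} (clipped so \eqn{[A]} stays
#'     nonnegative); \eqn{c_A} changes by the applied amount.  Defaults are
#'     the spreadsheet-scenario values: probability 0.002 and interval
#'     \code{[-0.075, 0.075]}.}
#'   \item{\code{forcing_ramp_noise(s)}}{a constant signed rate \code{s}
#'     (concentration per unit time) added to \eqn{d[A]/dt}; \code{s < 0} is
#'     a falling, \code{s > 0} a rising noise function.}
#'   \item{\code{forcing_replication(kRR, dR)}}{the agent self-replicates
#'     (\eqn{2A \to 3A} at rate \code{kRR}) and decays at rate \code{dR}:
#'     \eqn{d[A]/dt} gains \eqn{k_{RR}[A]^2 - d_R[A]}.}
#' }
#'
#' @param p_event per-step event probability in \code{[0, 1]}.
#' @param lo,hi bounds of the uniform jump (\code{lo <= hi}).
#' @param s signed ramp rate (concentration/time).
#' @param kRR replication rate constant (>= 0).
#' @param dR first-order decay rate (>= 0).
#' @return An object of class \code{forcing}.
#' @name forcing
NULL

#' @rdname forcing
#' @export
forcing_none <- function() {
  structure(list(kind = "none"), class = "forcing")
}

#' @rdname forcing
#' @export
forcing_jump_noise <- function(p_event = 0.002, lo = -0.075, hi = 0.075) {
  if (p_event < 0 || p_event > 1) stop("p_event must lie in [0, 1]")
  if (lo > hi) stop("need lo <= hi")
  structure(list(kind = "jump_noise", p_event = p_event, lo = lo, hi = hi),
            class = "forcing")
}

#' @rdname forcing
#' @export
forcing_ramp_noise <- function(s) {
  if (!is.finite(s)) stop("s must be finite")
  structure(list(kind = "ramp_noise", s = s), class = "forcing")
}

#' @rdname forcing
#' @export
forcing_replication <- function(kRR, dR) {
  if (kRR < 0 || dR < 0) stop("kRR and dR must be nonnegative")
  structure(list(kind = "replication", kRR = kRR, dR = dR), class = "forcing")
}

#' @export
print.forcing <- function(x, ...) {
  cat("forcing:", x$kind, "\n")
  invisible(x)
}

#' Forward-Euler integration of the binding network
#'
#' Integrates the mass-action equations (see \code{\link{mass_action_rhs}})
#' by the explicit Euler update \code{state <- state + rhs * dt}, the direct
#' discretisation of the differential equations, with an optional scenario
#' forcing applied each step before the chemical update.  Forward Euler is
#' the reference scheme here because it conserves the three totals exactly in
#' exact arithmetic; only rounding drift is admissible along a trajectory.
#'
#' Negative-concentration guard: values below zero are clipped only when they
#' exceed \code{-1e-12} (pure rounding); a genuinely negative value aborts
#' with an error, since the continuous dynamics provably stay nonnegative and
#' real negativity indicates a step-size problem.  Exception: under
#' \code{forcing_replication} the run is instead terminated and labelled
#' diverged, because the blow-up of \eqn{[A]} that scenario is designed to
#' exhibit invalidates the explicit step.  A run is also labelled diverged
#' when \eqn{[A]} exceeds \code{divergence_factor} times the initial
#' \eqn{c_A} or any value becomes non-finite; it then stops cleanly with the
#' divergence step recorded.
#'
#' @param state initial \code{\link{mixture_state}}.
#' @param rates a \code{\link{rate_constants}} object.
#' @param forcing a \code{\link{forcing}} object (default none).
#' @param dt Euler step (> 0); the worked scenarios use 0.001.
#' @param n_steps number of steps to integrate.
#' @param seed optional integer seed for the forcing's random draws; recorded
#'   in the result.  Identical seed and arguments give identical output.
#' @param record_every keep every \code{record_every}-th step in the returned
#'   table (step 0 and the final step are always kept).
#' @param equilibrium_ref optional \code{\link{full_equilibrium}} for the same
#'   totals; when supplied, the Lyapunov value \code{V} is recorded along the
#'   trajectory.
#' @param divergence_factor multiple of the initial \eqn{c_A} beyond which
#'   \eqn{[A]} is declared diverged (default 1000).
#' @return An object of class \code{mixture_trajectory}: a data frame with
#'   columns \code{step}, \code{t}, \code{A}, \code{X}, \code{Y}, \code{AX},
#'   \code{XY}, \code{cA}, \code{cX}, \code{cY} (and \code{V} when a
#'   reference is given), with attributes \code{seed}, \code{dt},
#'   \code{forcing}, \code{diverged}, \code{divergence_step},
#'   \code{final_state}.
#' @examples
#' tot <- totals(7, 100, 24.45)
#' r <- rate_constants(1, 1, 1, 1)
#' s0 <- state_from_free(tot$cA, tot$cY, tot) # all molecules uncomplexed
#' tr <- integrate_mixture(s0, r, dt = 1e-3, n_steps = 5000)
#' tail(tr$A, 1) # ~ 0.1
#' @export
integrate_mixture <- function(state, rates, forcing = forcing_none(),
                              dt = 1e-3, n_steps, seed = NULL,
                              record_every = 1L, equilibrium_ref = NULL,
                              divergence_factor = 1e3) {
  stopifnot(inherits(state, "mixture_state"),
            inherits(rates, "rate_constants"),
            inherits(forcing, "forcing"))
  if (dt <= 0) stop("dt must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("n_steps must be >= 1")
  record_every <- max(1L, as.integer(record_every))
  if (!is.null(seed)) set.seed(seed)

  ref <- c(0, 0, 0, 0)
  has_ref <- !is.null(equilibrium_ref)
  if (has_ref) {
    stopifnot(inherits(equilibrium_ref, "full_equilibrium"))
    check_totals_match(state, equilibrium_ref)
    ref <- c(equilibrium_ref$state$A, equilibrium_ref$state$Y,
             rates$k1, rates$k3)
  }

  fkind <- switch(forcing$kind, none = 0L, jump_noise = 1L,
                  ramp_noise = 2L, replication = 3L)
  fpar <- switch(forcing$kind,
                 none = c(0, 0, 0),
                 jump_noise = c(forcing$p_event, forcing$lo, forcing$hi),
                 ramp_noise = c(forcing$s, 0, 0),
                 replication = c(forcing$kRR, forcing$dR, 0))

  res <- euler_integrate_cpp(
    c(state$A, state$X, state$Y, state$AX, state$XY),
    c(rates$k1, rates$k2, rates$k3, rates$k4),
    fkind, fpar, dt, n_steps, record_every,
    has_ref, ref, divergence_factor)

  m <- res$records
  df <- data.frame(step = m[, 1], t = m[, 1] * dt,
                   A = m[, 2], X = m[, 3], Y = m[, 4],
                   AX = m[, 5], XY = m[, 6],
                   cA = m[, 2] + m[, 5],
                   cX = m[, 3] + m[, 5] + m[, 6],
                   cY = m[, 4] + m[, 6])
  if (has_ref) df$V <- m[, 7]
  fs <- m[nrow(m), 2:6]
  structure(df,
            class = c("mixture_trajectory", "data.frame"),
            seed = seed, dt = dt, forcing = forcing,
            diverged = res$diverged,
            divergence_step = if (res$diverged) res$divergence_step else NA_integer_,
            final_state = mixture_state(fs[1], fs[2], fs[3], fs[4], fs[5]))
}

#' Final state of a trajectory
#' @param trajectory a \code{mixture_trajectory}.
#' @return The \code{\link{mixture_state}} at the last integrated step.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "mixture_trajectory"))
  attr(trajectory, "final_state")
}

#' Did the run diverge?
#' @param trajectory a \code{mixture_trajectory}.
#' @return \code{TRUE} when the run was terminated as diverged (blow-up of
#'   \eqn{[A]} or a non-finite value); the step is in
#'   \code{attr(trajectory, "divergence_step")}.
#' @export
diverged <- function(trajectory) {
  stopifnot(inherits(trajectory, "mixture_trajectory"))
  isTRUE(attr(trajectory, "diverged"))
}

#' Single jump-noise perturbation of a state
#'
#' With probability \code{p_event}, adds a uniform draw from
#' \code{[lo, hi]} to the free-agent concentration (the perturbation the
#' spreadsheet scenario applies at every step).  A negative draw that would
#' push \eqn{[A]} below zero is clipped at zero, since concentrations cannot
#' be negative.  The total \eqn{c_A} changes by the amount actually applied.
#'
#' @param state a \code{\link{mixture_state}}.
#' @param p_event event probability in \code{[0, 1]}.
#' @param lo,hi bounds of the uniform jump.
#' @return The (possibly) perturbed \code{\link{mixture_state}}, with
#'   attribute \code{applied} holding the concentration change actually made
#'   (0 when no event fired).
#' @export
jump_noise_step <- function(state, p_event, lo, hi) {
  stopifnot(inherits(state, "mixture_state"))
  if (p_event < 0 || p_event > 1) stop("p_event must lie in [0, 1]")
  if (lo > hi) stop("need lo <= hi")
  applied <- 0
  if (runif(1) < p_event) {
    jump <- runif(1, lo, hi)
    applied <- max(jump, -state$A)
    state$A <- state$A + applied
  }
  attr(state, "applied") <- applied
  state
}

check_totals_match <- function(state, equilibrium_ref, tol = 1e-8) {
  te <- totals_of(equilibrium_ref$state)
  ts <- totals_of(state)
  scale <- max(te$cA, te$cX, te$cY, 1)
  if (max(abs(c(ts$cA - te$cA, ts$cX - te$cX, ts$cY - te$cY))) > tol * scale)
    stop("state and equilibrium reference have different conserved totals")
  invisible(TRUE)
}

#' Lyapunov function of the deviation from equilibrium
#'
#' The scalar
#' \deqn{V(x, y) = k_3 y_0 x^2 + k_1 x_0 y^2,}
#' where \eqn{x = [A] - x_0} and \eqn{y = [Y] - y_0} are the deviations of
#' the two free concentrations from their equilibrium values \eqn{x_0, y_0}.
#' \eqn{V} is zero exactly at the equilibrium and strictly decreases along
#' every unforced trajectory, certifying that the equilibrium is unique and
#' globally attracting.
#'
#' @param state a \code{\link{mixture_state}} with the same conserved totals
#'   as the reference (checked; mismatched totals are an error).
#' @param equilibrium_ref a \code{\link{full_equilibrium}} for those totals.
#' @param rates the \code{\link{rate_constants}} of the system.
#' @return Nonnegative scalar, zero iff the free A and Y equal the
#'   equilibrium's.
#' @export
lyapunov_value <- function(state, equilibrium_ref, rates) {
  stopifnot(inherits(state, "mixture_state"),
            inherits(equilibrium_ref, "full_equilibrium"),
            inherits(rates, "rate_constants"))
  check_totals_match(state, equilibrium_ref)
  x0 <- equilibrium_ref$state$A
  y0 <- equilibrium_ref$state$Y
  x <- state$A - x0
  y <- state$Y - y0
  rates$k3 * y0 * x^2 + rates$k1 * x0 * y^2
}

#' Time derivative of the Lyapunov function
#'
#' The total derivative of \code{\link{lyapunov_value}} along the unforced
#' dynamics, in closed form:
#' \deqn{\frac{dV}{dt} = -2k_2k_3 y_0 x^2 - 2k_1k_4 x_0 y^2
#'   - 2k_1k_3 x_0 y_0 (x+y)^2 - 2k_1k_3 (y_0 x^2 + x_0 y^2)[X],}
#' a sum of nonpositive terms, strictly negative everywhere except at the
#' equilibrium.
#'
#' @inheritParams lyapunov_value
#' @return Nonpositive scalar; zero iff the state is at equilibrium.
#' @export
lyapunov_derivative <- function(state, equilibrium_ref, rates) {
  stopifnot(inherits(state, "mixture_state"),
            inherits(equilibrium_ref, "full_equilibrium"),
            inherits(rates, "rate_constants"))
  check_totals_match(state, equilibrium_ref)
  x0 <- equilibrium_ref$state$A
  y0 <- equilibrium_ref$state$Y
  x <- state$A - x0
  y <- state$Y - y0
  Xf <- state$X
  -2 * rates$k2 * rates$k3 * y0 * x^2 -
    2 * rates$k1 * rates$k4 * x0 * y^2 -
    2 * rates$k1 * rates$k3 * x0 * y0 * (x + y)^2 -
    2 * rates$k1 * rates$k3 * (y0 * x^2 + x0 * y^2) * Xf
}
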