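# Stochastic spatial multi-agent simulation of replicase-parasite-inhibitor
# populations on a toroidal 2D arena.

#' Parameters of the multi-agent simulation
#'
#' Defaults are the multi-agent scenario's published parameter set: a
#' 1050 x 675 arena, 2250 replicases, 112 parasites, agent radius 3, at most
#' 4 neighbours around a replicating template, decay probability 0.1 per
#' step, replication affinities 0.8, parasite folding probability 0.2,
#' diffusion constants 400 for simple agents and complexes alike, parasite
#' mutation rate 0.1, unit time step, replication constant 1, and binding
#' rate constants k1 = 10, k2 = 5 (inhibitor-target) and k3 = 10, k4 = 5
#' (inhibitor-anti-inhibitor).  Inhibitors and anti-inhibitors are added via
#' \code{n_inhibitors}/\code{n_anti_inhibitors} (the published sweeps keep
#' them equal).
#'
#' \code{target_mode} selects which RNA species plays the controlled agent:
#' \code{"only_P"} lets inhibitors bind parasites only, \code{"only_R"}
#' replicases only.
#'
#' @param sizeX,sizeY arena dimensions (> 0).
#' @param init_R,init_P initial replicase/parasite counts (>= 0).
#' @param agent_size agent radius; two agents interact when their centre
#'   distance is at most \code{2 * agent_size}.
#' @param Nmax crowding cap: a replication attempt is rejected when the
#'   template has \code{Nmax} or more RNA neighbours within the interaction
#'   radius.  \code{Inf} disables the cap.
#' @param d per-step decay probability (times \code{dt}) for replicases and
#'   parasites, free or bound; when a bound target decays the inhibitor is
#'   released.  Inhibitors and anti-inhibitors never decay.
#' @param aR,aP replication probability when the template is a replicase or
#'   a parasite, respectively (given a free replicase in range).
#' @param lP per-step probability that a free parasite folds
#'   (irreversibly).  The fold sequesters the short region an inhibitor
#'   would pair with, so a folded parasite cannot be bound; it is still
#'   copied by replicases and still decays.
#' @param D,Dprime diffusion constants for simple agents and for complexes;
#'   each step every agent takes a Gaussian displacement with variance
#'   \code{D * dt} (or \code{Dprime * dt}) per axis, wrapped on the torus.
#' @param delta probability that the offspring of a replicase template is a
#'   parasite (mutation).
#' @param dt time step length.
#' @param K_repl global multiplier on the replication probability.
#' @param k1,k2,k3,k4 binding/unbinding rate constants; each is converted to
#'   a per-step probability by \code{\link{reaction_probability}}.
#' @param n_inhibitors,n_anti_inhibitors initial counts of free inhibitors
#'   and anti-inhibitors; their totals (free plus complexed) are conserved
#'   exactly for the whole run since they never decay.
#' @param target_mode \code{"only_P"} or \code{"only_R"}.
#' @return An object of class \code{mas_params}.
#' @export
mas_params <- function(sizeX = 1050, sizeY = 675, init_R = 2250, init_P = 112,
                       agent_size = 3.0, Nmax = 4, d = 0.1, aR = 0.8,
                       aP = 0.8, lP = 0.2, D = 400, Dprime = 400,
                       delta = 0.1, dt = 1, K_repl = 1,
                       k1 = 10, k2 = 5, k3 = 10, k4 = 5,
                       n_inhibitors = 0, n_anti_inhibitors = n_inhibitors,
                       target_mode = c("only_P", "only_R")) {
  target_mode <- match.arg(target_mode)
  probs <- c(d = d * dt, aR = aR, aP = aP, lP = lP, delta = delta)
  if (any(probs < 0) || any(probs > 1))
    stop("d*dt, aR, aP, lP and delta must all lie in [0, 1]")
  if (sizeX <= 0 || sizeY <= 0) stop("arena dimensions must be positive")
  if (agent_size <= 0) stop("agent_size must be positive")
  if (min(init_R, init_P, n_inhibitors, n_anti_inhibitors) < 0)
    stop("counts must be nonnegative")
  if (min(k1, k2, k3, k4) < 0) stop("rate constants must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  if (D < 0 || Dprime < 0) stop("diffusion constants must be nonnegative")
  if (is.infinite(Nmax)) Nmax <- .Machine$integer.max
  structure(list(
    sizeX = sizeX, sizeY = sizeY,
    init_R = as.integer(init_R), init_P = as.integer(init_P),
    agent_size = agent_size, Nmax = as.integer(Nmax), d = d,
    aR = aR, aP = aP, lP = lP, D = D, Dprime = Dprime, delta = delta,
    dt = dt, K_repl = K_repl, k1 = k1, k2 = k2, k3 = k3, k4 = k4,
    n_inhibitors = as.integer(n_inhibitors),
    n_anti_inhibitors = as.integer(n_anti_inhibitors),
    target_mode = target_mode
  ), class = "mas_params")
}

#' @export
print.mas_params <- function(x, ...) {
  cat(sprintf(
    "multi-agent parameters: %g x %g arena, %d replicases, %d parasites,\n",
    x$sizeX, x$sizeY, x$init_R, x$init_P))
  cat(sprintf("  %d inhibitors / %d anti-inhibitors, mode %s\n",
              x$n_inhibitors, x$n_anti_inhibitors, x$target_mode))
  invisible(x)
}

#' Rescale the arena and all counts, preserving densities
#'
#' Multiplies the arena area by \code{area_factor} (each dimension by its
#' square root) and every agent count by the same factor, so all densities
#' -- and hence the local interaction rates -- are unchanged.  Useful for
#' running the published scenario at desk scale.
#'
#' @param params a \code{\link{mas_params}} object.
#' @param area_factor positive area scale factor (e.g. \code{1/9}).
#' @return A rescaled \code{mas_params} object.
#' @export
scale_mas_params <- function(params, area_factor) {
  stopifnot(inherits(params, "mas_params"), area_factor > 0)
  lin <- sqrt(area_factor)
  p <- unclass(params)
  p$sizeX <- p$sizeX * lin
  p$sizeY <- p$sizeY * lin
  for (f in c("init_R", "init_P", "n_inhibitors", "n_anti_inhibitors"))
    p[[f]] <- as.integer(round(p[[f]] * area_factor))
  do.call(mas_params, p)
}

#' Per-step reaction probability of a rate constant
#'
#' Converts a first-order rate constant into the probability that the
#' reaction fires at least once within a time step of length \code{dt},
#' assuming exponentially (Poisson) distributed waiting times:
#' \deqn{p_i = 1 - e^{-k_i \Delta t}.}
#' The value lies in \code{[0, 1)} and is monotone increasing in both
#' arguments.
#'
#' @param k rate constant(s), nonnegative (vectorised).
#' @param dt time step length(s), positive (vectorised).
#' @return Probability (or vector of probabilities) in \code{[0, 1)}.
#' @examples
#' reaction_probability(10, 1) # 1 - exp(-10)
#' @export
reaction_probability <- function(k, dt) {
  if (any(k < 0)) stop("rate constants must be nonnegative")
  if (any(dt <= 0)) stop("dt must be positive")
  -expm1(-k * dt)
}

#' Initial world of the multi-agent simulation
#'
#' Places \code{init_R} replicases, \code{init_P} parasites,
#' \code{n_inhibitors} inhibitors and \code{n_anti_inhibitors}
#' anti-inhibitors uniformly at random on the arena; inhibitors and
#' anti-inhibitors start free, parasites unfolded.  Uses the current RNG
#' state (call \code{set.seed} first for reproducibility).
#'
#' @param params a \code{\link{mas_params}} object.
#' @return An object of class \code{mas_world}: list with integer vector
#'   \code{species} (1 replicase, 2 parasite, 3 inhibitor, 4 anti-inhibitor,
#'   5 inhibitor-anti-inhibitor complex, 6 inhibitor-target complex),
#'   numeric \code{x}, \code{y}, logical \code{folded}.
#' @export
mas_world <- function(params) {
  stopifnot(inherits(params, "mas_params"))
  species <- rep.int(
    c(1L, 2L, 3L, 4L),
    c(params$init_R, params$init_P, params$n_inhibitors,
      params$n_anti_inhibitors))
  n <- length(species)
  structure(list(
    species = species,
    x = runif(n, 0, params$sizeX),
    y = runif(n, 0, params$sizeY),
    folded = rep(FALSE, n)
  ), class = "mas_world")
}

#' Advance the multi-agent world by one step
#'
#' Applies, in fixed order: diffusion of every agent, decay of replicases
#' and parasites (bound targets included), replication attempts (a template
#' is copied at most once per step; a replicase may catalyse several
#' copies), parasite folding, and the inhibition reactions (dissociation of
#' complexes, then binding, with released agents free to rebind at once).
#' Uses the current RNG state.
#'
#' @param world a \code{\link{mas_world}}.
#' @param params the \code{\link{mas_params}} it runs under.
#' @return The updated \code{mas_world}.
#' @export
mas_step <- function(world, params) {
  stopifnot(inherits(world, "mas_world"), inherits(params, "mas_params"))
  res <- mas_simulate_cpp(world$species, world$x, world$y, world$folded,
                          mas_cpp_params(params), 1L)
  structure(list(species = res$species, x = res$x, y = res$y,
                 folded = res$folded), class = "mas_world")
}

mas_cpp_params <- function(params) {
  list(sizeX = params$sizeX, sizeY = params$sizeY,
       agent_size = params$agent_size, Nmax = params$Nmax, d = params$d,
       aR = params$aR, aP = params$aP, lP = params$lP, D = params$D,
       Dprime = params$Dprime, delta = params$delta, dt = params$dt,
       K_repl = params$K_repl, k1 = params$k1, k2 = params$k2,
       k3 = params$k3, k4 = params$k4,
       mode = if (params$target_mode == "only_P") 0L else 1L)
}

#' Run the multi-agent simulation
#'
#' Simulates \code{n_steps} steps from a fresh uniformly placed world and
#' records a per-step census of every species.  The run stops early when the
#' replicases go extinct (free replicases, plus those bound in
#' inhibitor-target complexes in \code{only_R} mode): with no replication
#' source left, the remaining parasites simply decay.
#'
#' Identical \code{seed} and parameters give an identical series.
#'
#' @param params a \code{\link{mas_params}} object.
#' @param n_steps maximum number of steps.
#' @param seed integer seed for the run.
#' @return An object of class \code{mas_series}: a data frame with columns
#'   \code{step}, \code{R} (free replicases), \code{P} (free unfolded
#'   parasites), \code{P_folded}, \code{X_free}, \code{Y_free}, \code{XY},
#'   \code{XT}, with attributes \code{seed}, \code{params},
#'   \code{extinction_step} (\code{NA} if the replicases survived),
#'   \code{final_world} and \code{reaction_probs}.
#' @examples
#' p <- scale_mas_params(mas_params(), 1 / 36)
#' s <- mas_run(p, n_steps = 50, seed = 1)
#' tail(s, 2)
#' @export
mas_run <- function(params, n_steps, seed) {
  stopifnot(inherits(params, "mas_params"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("n_steps must be >= 1")
  set.seed(as.integer(seed))
  world <- mas_world(params)
  res <- mas_simulate_cpp(world$species, world$x, world$y, world$folded,
                          mas_cpp_params(params), n_steps)
  m <- res$counts
  df <- data.frame(step = m[, 1], R = m[, 2], P = m[, 3], P_folded = m[, 4],
                   X_free = m[, 5], Y_free = m[, 6], XY = m[, 7], XT = m[, 8])
  structure(df,
            class = c("mas_series", "data.frame"),
            seed = as.integer(seed), params = params,
            extinction_step = res$extinction_step,
            final_world = structure(list(species = res$species, x = res$x,
                                         y = res$y, folded = res$folded),
                                    class = "mas_world"),
            reaction_probs = stats::setNames(res$reaction_probs,
                                             c("p1", "p2", "p3", "p4")))
}

#' Did the replicase population survive a run?
#' @param series a \code{mas_series} from \code{\link{mas_run}}.
#' @return \code{TRUE} when no extinction was recorded.
#' @export
mas_survived <- function(series) {
  stopifnot(inherits(series, "mas_series"))
  is.na(attr(series, "extinction_step"))
}

#' Survival frequency over seeds
#'
#' Runs the simulation once per seed and reports the fraction of runs in
#' which the replicase population survived to the horizon.
#'
#' @param params a \code{\link{mas_params}} object.
#' @param n_steps run horizon.
#' @param seeds integer vector of seeds (one run each).
#' @return Fraction in \code{[0, 1]}.
#' @export
mas_survival_frequency <- function(params, n_steps, seeds) {
  mean(vapply(seeds, function(s) mas_survived(mas_run(params, n_steps, s)),
              logical(1)))
}
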