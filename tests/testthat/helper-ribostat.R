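# Shared fixtures and independent reference implementations for the tests.

# published deterministic parameter set (spreadsheet scenario)
table1_rates <- function() rate_constants(1, 1, 1, 1)
table1_totals <- function() totals(cA = 7, cX = 100, cY = 24.45)

# a random feasible parameter set: rates in [0.3, 3], totals of moderate size
random_system <- function() {
  list(rates = rate_constants(runif(1, 0.3, 3), runif(1, 0.3, 3),
                              runif(1, 0.3, 3), runif(1, 0.3, 3)),
       tot = totals(cA = runif(1, 0.5, 10), cX = runif(1, 0.1, 20),
                    cY = runif(1, 0, 10)))
}

# a random feasible state with the given totals (free A and Y drawn so that
# all derived concentrations stay nonnegative)
random_state <- function(tot) {
  repeat {
    A <- runif(1, 0, tot$cA)
    Y <- runif(1, 0, tot$cY)
    st <- try(state_from_free(A, Y, tot), silent = TRUE)
    if (!inherits(st, "try-error")) return(st)
  }
}

# plain-R forward Euler, the independent oracle for the compiled integrator
reference_euler <- function(state, rates, dt, n_steps,
                            kRR = 0, dR = 0) {
  v <- c(A = state$A, X = state$X, Y = state$Y, AX = state$AX, XY = state$XY)
  out <- matrix(NA_real_, n_steps + 1, 5,
                dimnames = list(NULL, names(v)))
  out[1, ] <- v
  for (i in seq_len(n_steps)) {
    fAX <- rates$k2 * v["AX"] - rates$k1 * v["A"] * v["X"]
    fXY <- rates$k4 * v["XY"] - rates$k3 * v["X"] * v["Y"]
    extra <- kRR * v["A"]^2 - dR * v["A"]
    v <- v + dt * c(fAX + extra, fAX + fXY, fXY, -fAX, -fXY)
    out[i + 1, ] <- v
  }
  out
}

# tiny multi-agent parameter set for fast structural tests
tiny_mas <- function(...) {
  mas_params(sizeX = 150, sizeY = 100, init_R = 60, init_P = 5,
             ...)
}
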