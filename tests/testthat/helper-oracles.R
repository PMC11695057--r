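# Independent brute-force oracles. These deliberately avoid the closed-form
# and bisection code paths used by the package: the competitive oracle
# solves the scalar conservation equation for the free (shared) receptor
# with stats::uniroot, and the ODE oracle integrates mass-action kinetics
# to steady state with deSolve.

# Fraction of ligand sites bound when ligand (total a) and competitor
# (total x) compete for a shared receptor pool (total r): solve for free
# receptor from r_free * (1 + a/(ka + r_free) + x/(kb + r_free)) = r.
oracle_competitive <- function(a, r, ka, kb, x) {
  if (r == 0) return(0)
  f <- function(rf) rf * (1 + a / (ka + rf) + x / (kb + rf)) - r
  rf <- stats::uniroot(f, c(0, r), tol = 1e-15)$root
  rf / (ka + rf)
}

# Two-species exact depletion oracle: free ligand from
# l + r*l/(ka + l) = a, bound fraction (r*l/(ka+l))/a.
oracle_binary <- function(a, ka, r) {
  if (r == 0) return(0)
  f <- function(l) l + r * l / (ka + l) - a
  l <- stats::uniroot(f, c(0, a), tol = 1e-15)$root
  r * l / ((ka + l) * a)
}

# Relax the affinity-shift ternary system (L, R, C, LR, LC, LRC) to
# equilibrium by integrating mass-action ODEs. All forward rates are 1;
# reverse rates equal the dissociation constants, with the ternary cycle
# closed by detailed balance (alpha scales both LC + R and LR + C).
oracle_affinity_shift_ode <- function(a, r, ka, kb, alpha, x,
                                      t_end = 2e5) {
  rates <- function(t, y, p) {
    L <- y[1]; R <- y[2]; C <- y[3]; LR <- y[4]; LC <- y[5]; LRC <- y[6]
    v1 <- L * R - ka * LR            # L + R <-> LR
    v2 <- L * C - kb * LC            # L + C <-> LC
    v3 <- LC * R - alpha * ka * LRC  # LC + R <-> LRC
    v4 <- LR * C - alpha * kb * LRC  # LR + C <-> LRC
    list(c(-v1 - v2, -v1 - v3, -v2 - v4, v1 - v4, v2 - v3, v3 + v4))
  }
  y0 <- c(L = a, R = r, C = x, LR = 0, LC = 0, LRC = 0)
  out <- deSolve::lsoda(y0, c(0, t_end), rates, parms = NULL,
                        rtol = 1e-12, atol = 1e-12)
  y <- out[nrow(out), -1]
  (y[["LR"]] + y[["LRC"]]) / a
}

# Deterministic random system draws used by the oracle-equivalence sweeps.
draw_random_systems <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    a = stats::runif(n, 1, 500),
    r = stats::runif(n, 1, 500),
    ka = 10^stats::runif(n, -1, 4),
    kb = 10^stats::runif(n, -1, 4),
    x = stats::runif(n, 0, 1e6)
  )
}

# Phase extraction mirroring the package convention: time re-zeroed at the
# boundary sample (last point of the preceding phase).
.trace_phase_for_test <- function(trace, which) {
  idx <- trace$phase == which
  first <- which(idx)[1]
  origin <- if (first > 1) trace$time[first - 1] else trace$time[first]
  list(time = trace$time[idx] - origin, signal = trace$signal[idx])
}
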