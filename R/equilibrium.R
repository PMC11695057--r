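#' Steady-state binding parameters (one-site model with variable Hill slope)
#'
#' @param bmax Maximal specific signal, in signal units (> 0).
#' @param kd Equilibrium dissociation constant (nM, > 0). With the
#'   parameterization used throughout this package, `kd` is the
#'   half-saturation concentration for any Hill slope.
#' @param hill Hill slope (dimensionless, > 0); 1 for independent sites.
#' @return An object of class `equilibrium_parameters`.
#' @export
equilibrium_parameters <- function(bmax, kd, hill = 1) {
  stopifnot(is.numeric(bmax), is.numeric(kd), is.numeric(hill))
  if (bmax <= 0) stop("bmax must be > 0")
  if (kd <= 0) stop("kd must be > 0")
  if (hill <= 0) stop("hill must be > 0")
  structure(list(bmax = bmax, kd = kd, hill = hill),
            class = "equilibrium_parameters")
}

#' @export
print.equilibrium_parameters <- function(x, ...) {
  cat(sprintf("Equilibrium parameters: Bmax = %g, K_D = %g nM, Hill = %g\n",
              x$bmax, x$kd, x$hill))
  invisible(x)
}

# Exact-depletion bound fraction for the binary system, quadratic root.
# Numerically stable form: the small root of A*f^2 - (A+KA+R)*f + R = 0.
.bound_fraction <- function(a, ka, r) {
  if (r == 0) return(0)
  s <- a + ka + r
  disc <- s^2 - 4 * a * r
  if (disc < 0) {
    if (disc > -1e-9 * s^2) disc <- 0
    else stop("negative discriminant: internal inconsistency in binding system")
  }
  (s - sqrt(disc)) / (2 * a)
}

#' Fraction of ligand sites bound in the absence of competitor
#'
#' Exact mass-action solution of the two-species equilibrium
#' \eqn{L + R \rightleftharpoons LR} at total site concentration A, total
#' receptor R and dissociation constant \eqn{K_A}, accounting fully for
#' depletion of both species:
#' \deqn{Y_0 = \frac{A + K_A + R - \sqrt{(A + K_A + R)^2 - 4AR}}{2A}.}
#'
#' @param system A [competition_system()] (only `a_total`, `r_total`, `ka`
#'   are used).
#' @return Fraction of ligand sites occupied, in \[0, min(1, R/A)\].
#' @examples
#' bound_fraction_no_competitor(competition_system(64, 50, 10.4))
#' @export
bound_fraction_no_competitor <- function(system) {
  stopifnot(inherits(system, "competition_system"))
  .bound_fraction(system$a_total, system$ka, system$r_total)
}

#' Exact competitive-binding curve (trigonometric root of the cubic)
#'
#' Closed-form equilibrium fraction of ligand bound to receptor when the
#' ligand (total sites A, constant \eqn{K_A}) and a competitor (total X,
#' constant \eqn{K_B}) compete for a shared limited receptor pool (total R).
#' This is the exact analytical solution of the underlying cubic in
#' trigonometric form (Wang 1995, FEBS Lett 360:111-114):
#' \deqn{h = K_A + K_B + A + X - R}
#' \deqn{k = K_B (A - R) + K_A (X - R) + K_A K_B}
#' \deqn{l = -K_A K_B R}
#' \deqn{\theta = \arccos\frac{-2h^3 + 9hk - 27l}{2\sqrt{(h^2 - 3k)^3}}}
#' \deqn{Y = \frac{2\sqrt{h^2 - 3k}\cos(\theta/3) - h}
#'                {3 K_A + 2\sqrt{h^2 - 3k}\cos(\theta/3) - h}.}
#'
#' At `x = 0` the curve reduces exactly to
#' [bound_fraction_no_competitor()]; it is non-increasing in `x` and decays
#' to 0 as `x` grows without bound.
#'
#' @param system A [competition_system()] with a finite `kb`.
#' @param x Competitor concentration(s), nM (vectorized, each >= 0).
#' @param kb Optional override for the competitor constant (nM); used by the
#'   fitting layer. Defaults to `system$kb`.
#' @return Fraction of ligand sites bound to receptor, same length as `x`.
#' @examples
#' sys <- competition_system(64, 50, 10.4, kb = 200)
#' wang_competition_curve(sys, c(0, 100, 1600, 1e5))
#' @export
wang_competition_curve <- function(system, x, kb = system$kb) {
  stopifnot(inherits(system, "competition_system"))
  if (is.na(kb)) stop("system has no kb; supply kb explicitly")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("x must be finite and >= 0")
  }
  a <- system$a_total; r <- system$r_total; ka <- system$ka
  vapply(x, function(xi) .wang_point(a, r, ka, kb, xi), numeric(1))
}

.wang_point <- function(a, r, ka, kb, x) {
  if (r == 0) return(0)
  h <- ka + kb + a + x - r
  k <- kb * (a - r) + ka * (x - r) + ka * kb
  l <- -ka * kb * r
  d <- h^2 - 3 * k
  if (d <= 0) stop("invalid competition system: non-positive cubic discriminant")
  arg <- (-2 * h^3 + 9 * h * k - 27 * l) / (2 * sqrt(d^3))
  # guard against floating-point excursions just outside [-1, 1]
  if (arg > 1) {
    if (arg > 1 + 1e-9) stop("invalid competition system: arccos argument > 1")
    arg <- 1
  } else if (arg < -1) {
    if (arg < -1 - 1e-9) stop("invalid competition system: arccos argument < -1")
    arg <- -1
  }
  # the trigonometric root of z^3 + h z^2 + k z + l is the free receptor
  # concentration; polish it with Newton steps on the cubic, which removes
  # the catastrophic cancellation the raw trig expression suffers when the
  # root is many orders of magnitude below h (large competitor excess)
  rf <- (2 * sqrt(d) * cos(acos(arg) / 3) - h) / 3
  rf <- min(max(rf, .Machine$double.xmin), r)
  # safeguarded Newton on the cubic, bracketed on (0, r]: f(0) = l < 0 and
  # f(r) >= 0, since the free receptor cannot exceed the total
  cubic <- function(z) ((z + h) * z + k) * z + l
  lo <- 0; hi <- r
  for (i in 1:200) {
    f <- cubic(rf)
    if (f > 0) hi <- rf else lo <- rf
    fp <- (3 * rf + 2 * h) * rf + k
    step <- f / fp
    cand <- rf - step
    if (!is.finite(cand) || cand <= lo || cand >= hi) cand <- (lo + hi) / 2
    if (abs(cand - rf) <= 1e-15 * max(cand, .Machine$double.xmin)) {
      rf <- cand
      break
    }
    rf <- cand
  }
  rf / (ka + rf)
}

#' One-site specific binding with variable Hill slope
#'
#' \deqn{S(c) = B_{max} \frac{c^h}{c^h + K_D^h}}
#' so that `kd` is the half-saturation concentration for any `hill`.
#'
#' @param conc Analyte concentration(s), nM (vectorized, >= 0).
#' @param params An [equilibrium_parameters()] object.
#' @return Signal, same units as `params$bmax`.
#' @examples
#' hill_binding(10.4, equilibrium_parameters(1, 10.4, 2)) # Bmax/2
#' @export
hill_binding <- function(conc, params) {
  stopifnot(inherits(params, "equilibrium_parameters"))
  if (any(conc < 0)) stop("conc must be >= 0")
  ch <- conc^params$hill
  params$bmax * ch / (ch + params$kd^params$hill)
}

#' Cheng-Prusoff conversion of an IC50 to an inhibition constant
#'
#' \deqn{K_i = \frac{IC_{50}}{1 + [L]/K_D}}
#' Valid when reactant depletion is negligible; under depletion the IC50 is
#' inflated and the converted value overestimates the true competitor
#' constant (see the package vignette).
#'
#' @param ic50 Half-maximal inhibitory concentration (nM, > 0).
#' @param ligand_conc Tracer ligand concentration \eqn{[L]} (nM, >= 0).
#' @param kd Tracer-receptor dissociation constant (nM, > 0).
#' @return \eqn{K_i} in nM.
#' @examples
#' cheng_prusoff_ki(138600, 32, 10.4) # ~ 34000 nM
#' @export
cheng_prusoff_ki <- function(ic50, ligand_conc, kd) {
  stopifnot(ic50 > 0, ligand_conc >= 0, kd > 0)
  ic50 / (1 + ligand_conc / kd)
}

#' Allosteric (affinity-shift) competition model parameters
#'
#' Parameters of the allosteric ternary-complex model in which competitor
#' binding to the ligand does not block receptor binding outright but
#' rescales the ligand-receptor affinity by a cooperativity factor `alpha`:
#' species L, LR, LC and LRC with constants \eqn{K_A} (L + R),
#' \eqn{K_B} (L + C), \eqn{\alpha K_A} (LC + R) and, by detailed balance,
#' \eqn{\alpha K_B} (LR + C). `alpha > 1` encodes negative cooperativity
#' (competitor weakens receptor binding), producing a non-zero displacement
#' plateau; `alpha = 1` makes the competitor silent.
#'
#' @param system A [competition_system()] with finite `kb` giving A, R,
#'   \eqn{K_A} and \eqn{K_B}.
#' @param alpha Cooperativity factor (> 0).
#' @return An object of class `affinity_shift_parameters`.
#' @export
affinity_shift_parameters <- function(system, alpha) {
  stopifnot(inherits(system, "competition_system"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single finite value > 0")
  }
  if (is.na(system$kb)) stop("system must have a finite kb")
  structure(list(system = system, alpha = as.numeric(alpha)),
            class = "affinity_shift_parameters")
}

#' @export
print.affinity_shift_parameters <- function(x, ...) {
  print(x$system)
  cat(sprintf("  alpha          : %g (affinity-shift cooperativity)\n",
              x$alpha))
  invisible(x)
}

# Vectorized deterministic solver for the affinity-shift ternary equilibrium.
# Outer bisection on free ligand l in [0, A]; for fixed l the free-competitor
# balance reduces to a quadratic with an explicit stable positive root.
.affinity_shift_solve <- function(a, r, ka, kb, alpha, x, iterations = 64L) {
  akk <- alpha * ka * kb
  free_c <- function(l, x) {
    u <- 1 + l / kb
    v <- l / akk
    w <- 1 + l / ka
    aa <- u * v
    bb <- u * w + v * r - x * v
    qq <- x * w
    ifelse(bb >= 0,
           2 * qq / (bb + sqrt(bb^2 + 4 * aa * qq)),
           (-bb + sqrt(bb^2 + 4 * aa * qq)) /
             (2 * pmax(aa, .Machine$double.xmin)))
  }
  residual <- function(l, x) {
    cc <- free_c(l, x)
    rr <- r / (1 + l / ka + l * cc / akk)
    l * (1 + rr / ka + cc / kb + rr * cc / akk) - a
  }
  lo <- rep(0, length(x))
  hi <- rep(a, length(x))
  for (i in seq_len(max(iterations, 120L))) {
    mid <- (lo + hi) / 2
    up <- residual(mid, x) > 0
    hi <- ifelse(up, mid, hi)
    lo <- ifelse(up, lo, mid)
    if (i >= iterations &&
        all(hi - lo <= 1e-11 * pmax(lo, a * .Machine$double.eps))) break
  }
  l <- (lo + hi) / 2
  cc <- free_c(l, x)
  rr <- r / (1 + l / ka + l * cc / akk)
  y <- (l * rr / ka + l * rr * cc / akk) / a
  # convergence guard: interval must have shrunk below relative tolerance
  if (any(hi - lo > 1e-10 * pmax(l, a * .Machine$double.eps))) {
    stop("affinity-shift root-finder failed to converge")
  }
  y
}

#' Affinity-shift (allosteric ternary complex) competition curve
#'
#' Fraction of ligand sites bound to receptor — in either binary (LR) or
#' ternary (LRC) form — at exact mass-action equilibrium of the allosteric
#' ternary-complex model defined by [affinity_shift_parameters()]. The
#' coupled conservation equations are solved by deterministic bracketed
#' bisection to 1e-10 relative tolerance.
#'
#' Limits: `Y(0)` equals [bound_fraction_no_competitor()]; as
#' `x` grows, `Y` plateaus at the binary bound fraction evaluated with
#' \eqn{K_A} replaced by \eqn{\alpha K_A} (non-zero for finite `alpha`).
#'
#' @param params An [affinity_shift_parameters()] object.
#' @param x Competitor concentration(s), nM (vectorized, >= 0).
#' @return Fraction bound, same length as `x`.
#' @examples
#' sys <- competition_system(64, 50, 10.4, kb = 200)
#' affinity_shift_competition(affinity_shift_parameters(sys, 5), c(0, 1600))
#' @export
affinity_shift_competition <- function(params, x) {
  stopifnot(inherits(params, "affinity_shift_parameters"))
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("x must be finite and >= 0")
  }
  s <- params$system
  if (s$r_total == 0) return(rep(0, length(x)))
  .affinity_shift_solve(s$a_total, s$r_total, s$ka, s$kb, params$alpha, x)
}

#' High-competitor plateau of the affinity-shift model
#'
#' @param params An [affinity_shift_parameters()] object.
#' @return The limiting bound fraction as competitor concentration grows
#'   without bound: the binary bound fraction with \eqn{K_A} replaced by
#'   \eqn{\alpha K_A}.
#' @export
affinity_shift_plateau <- function(params) {
  stopifnot(inherits(params, "affinity_shift_parameters"))
  s <- params$system
  .bound_fraction(s$a_total, params$alpha * s$ka, s$r_total)
}
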