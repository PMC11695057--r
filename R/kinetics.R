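#' Kinetic rate constants for 1:1 Langmuir binding
#'
#' @param kon Association rate constant (nM^-1 s^-1, > 0).
#' @param koff Dissociation rate constant (s^-1, > 0).
#' @param kon_sem,koff_sem Standard errors (optional, `NA` if unknown).
#' @return An object of class `kinetic_parameters` with fields `kon`,
#'   `koff`, `kd_kinetic` (= koff/kon, nM) and the SEMs, including the
#'   quadrature-propagated `kd_sem`.
#' @export
kinetic_parameters <- function(kon, koff, kon_sem = NA_real_,
                               koff_sem = NA_real_) {
  if (!is.finite(kon) || kon <= 0) stop("kon must be > 0")
  if (!is.finite(koff) || koff <= 0) stop("koff must be > 0")
  kd <- kinetic_kd(kon, koff, kon_sem, koff_sem)
  structure(
    list(kon = kon, koff = koff, kd_kinetic = kd$kd,
         kon_sem = kon_sem, koff_sem = koff_sem, kd_sem = kd$kd_sem),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  fmt <- function(v, s) {
    if (is.na(s)) sprintf("%.4g", v) else sprintf("%.4g ± %.2g", v, s)
  }
  cat("1:1 kinetic parameters\n")
  cat("  K_on :", fmt(x$kon, x$kon_sem), "nM^-1 s^-1\n")
  cat("  K_off:", fmt(x$koff, x$koff_sem), "s^-1\n")
  cat("  K_D  :", fmt(x$kd_kinetic, x$kd_sem), "nM (kinetic)\n")
  invisible(x)
}

#' Kinetic dissociation constant from rate constants
#'
#' \eqn{K_D = K_{off}/K_{on}}, with uncertainty propagated in quadrature
#' from the relative SEMs of the two rate constants.
#'
#' @param kon Association rate constant (nM^-1 s^-1, > 0).
#' @param koff Dissociation rate constant (s^-1).
#' @param kon_sem,koff_sem Optional SEMs.
#' @return List with `kd` (nM) and `kd_sem` (NA when either SEM is absent).
#' @examples
#' kinetic_kd(0.00019, 0.0014) # 7.4 nM at two significant figures
#' @export
kinetic_kd <- function(kon, koff, kon_sem = NA_real_, koff_sem = NA_real_) {
  stopifnot(kon > 0)
  kd <- koff / kon
  kd_sem <- if (is.na(kon_sem) || is.na(koff_sem)) NA_real_ else {
    kd * sqrt((kon_sem / kon)^2 + (koff_sem / koff)^2)
  }
  list(kd = kd, kd_sem = kd_sem)
}

#' 1:1 Langmuir association-phase model
#'
#' \deqn{R(t) = R_{eq} (1 - e^{-K_{obs} t}),\quad
#'       K_{obs} = K_{on} C + K_{off},\quad
#'       R_{eq} = B_{max} \frac{C}{C + K_D}.}
#'
#' @param t Time since association start (s, >= 0; vectorized).
#' @param conc Analyte concentration C (nM).
#' @param kinetics A [kinetic_parameters()] object.
#' @param bmax Maximal response (nm).
#' @return Signal (nm).
#' @export
association_model <- function(t, conc, kinetics, bmax) {
  stopifnot(inherits(kinetics, "kinetic_parameters"), all(t >= 0),
            conc >= 0, bmax >= 0)
  kobs <- kinetics$kon * conc + kinetics$koff
  req <- bmax * conc / (conc + kinetics$kd_kinetic)
  req * (1 - exp(-kobs * t))
}

#' One-phase exponential dissociation model
#'
#' @param t Time since dissociation start (s, >= 0; vectorized).
#' @param r0 Signal at the start of dissociation (nm, >= 0).
#' @param koff Dissociation rate constant (s^-1).
#' @return Signal `r0 * exp(-koff * t)`.
#' @export
dissociation_model <- function(t, r0, koff) {
  stopifnot(all(t >= 0), r0 >= 0)
  r0 * exp(-koff * t)
}

#' Fit the observed association rate constant of one trace
#'
#' Least-squares fit of the one-phase exponential association model
#' `plateau * (1 - exp(-kobs * t))` to the association phase of a trace
#' (time re-zeroed at the phase start). Initial values come from the mean of
#' the last 5% of the phase (plateau) and a log-linear regression on the
#' approach to plateau (kobs).
#'
#' @param trace A [bli_trace()] with an association phase of >= 5 points.
#' @return An object of class `kobs_record`: list with `analyte_conc`,
#'   `kobs` (s^-1), `plateau` (nm), `fit_r2`.
#' @export
fit_kobs <- function(trace) {
  stopifnot(inherits(trace, "bli_trace"))
  ph <- .trace_phase(trace, "association")
  if (is.null(ph) || length(ph$time) < 5L) {
    stop("trace needs an association phase with at least 5 points")
  }
  t <- ph$time; y <- ph$signal
  if (stats::sd(y) == 0 || max(abs(y)) < 1e-12) {
    stop("no association signal in trace '", trace$sensor_id, "'")
  }
  n_tail <- max(2L, ceiling(0.05 * length(y)))
  plateau0 <- mean(utils::tail(y, n_tail))
  if (plateau0 <= 0) plateau0 <- max(y)
  # log-linear init on the early rise: log(1 - y/plateau) = -kobs * t
  frac <- 1 - y / plateau0
  ok <- frac > 0.05 & t > 0
  kobs0 <- if (sum(ok) >= 2) {
    max(1e-8, -stats::coef(stats::lm(log(frac[ok]) ~ 0 + t[ok]))[[1]])
  } else 1 / max(t)
  fit <- minpack.lm::nlsLM(
    y ~ plateau * (1 - exp(-kobs * t)),
    start = list(plateau = plateau0, kobs = kobs0),
    lower = c(plateau = 0, kobs = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  co <- stats::coef(fit)
  if (co[["kobs"]] <= 1e-12) stop("fitted kobs is not positive")
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(analyte_conc = trace$analyte_conc, kobs = co[["kobs"]],
         plateau = co[["plateau"]], fit_r2 = max(0, min(1, r2))),
    class = "kobs_record"
  )
}

#' @export
print.kobs_record <- function(x, ...) {
  cat(sprintf("kobs = %.4g s^-1 at %g nM (plateau %.4g nm, R^2 %.3f)\n",
              x$kobs, x$analyte_conc, x$plateau, x$fit_r2))
  invisible(x)
}

#' Association rate constant from the kobs-versus-concentration line
#'
#' For 1:1 binding the observed association rate is linear in analyte
#' concentration, \eqn{K_{obs} = K_{on} C + K_{off}}; the slope of an
#' ordinary least-squares line through the (C, kobs) points estimates
#' \eqn{K_{on}}. The intercept is reported as an independent check on the
#' dissociation-fit \eqn{K_{off}}, not constrained to equal it.
#'
#' @param records List of `kobs_record` objects (>= 3 distinct
#'   concentrations).
#' @return List with `kon`, `kon_sem`, `intercept`, `intercept_sem`,
#'   `r_squared`, `slope_p_value`, `concentration_dependent` (TRUE when the
#'   slope differs from zero at p < 0.05) and the points used.
#' @export
kon_from_kobs <- function(records) {
  if (inherits(records, "kobs_record")) records <- list(records)
  stopifnot(all(vapply(records, inherits, logical(1), "kobs_record")))
  conc <- vapply(records, `[[`, numeric(1), "analyte_conc")
  kobs <- vapply(records, `[[`, numeric(1), "kobs")
  if (length(unique(conc)) < 3L) {
    stop("need kobs at >= 3 distinct concentrations")
  }
  fit <- stats::lm(kobs ~ conc)
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  slope <- sm["conc", "Estimate"]
  p <- sm["conc", "Pr(>|t|)"]
  list(kon = slope, kon_sem = sm["conc", "Std. Error"],
       intercept = sm["(Intercept)", "Estimate"],
       intercept_sem = sm["(Intercept)", "Std. Error"],
       r_squared = sfit$r.squared,
       slope_p_value = p,
       concentration_dependent = is.finite(p) && p < 0.05 && slope > 0,
       points = data.frame(analyte_nM = conc, kobs = kobs))
}

#' Mean dissociation rate constant with an R-squared quality filter
#'
#' Fits a one-phase exponential decay to the dissociation phase of each
#' trace and averages the fitted rate constants over traces whose decay fit
#' has R-squared above `r2_threshold` — discarding low-signal conditions
#' (typically the lowest analyte concentrations) whose decays are noise
#' dominated.
#'
#' @param traces List of [bli_trace()] objects with dissociation phases.
#' @param r2_threshold Traces with fit R-squared <= this value are excluded
#'   (default 0.8); a value <= 0 disables the filter.
#' @return List with `koff` (mean, s^-1), `koff_sem` (NA when a single
#'   trace survives), `n_used`, `n_excluded`, and a per-trace data frame
#'   `fits` (sensor_id, analyte_nM, koff, r_squared, used).
#' @export
mean_koff <- function(traces, r2_threshold = 0.8) {
  if (inherits(traces, "bli_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "bli_trace")))
  fits <- lapply(traces, function(tr) {
    ph <- .trace_phase(tr, "dissociation")
    if (is.null(ph) || length(ph$time) < 3L) {
      stop("trace '", tr$sensor_id, "' has no usable dissociation phase")
    }
    out <- tryCatch(.fit_decay(ph$time, ph$signal),
                    error = function(e) list(koff = NA_real_, r2 = 0))
    data.frame(sensor_id = tr$sensor_id, analyte_nM = tr$analyte_conc,
               koff = out$koff, r_squared = out$r2)
  })
  fits <- do.call(rbind, fits)
  # threshold <= 0 disables the quality filter entirely
  fits$used <- !is.na(fits$koff) &
    (r2_threshold <= 0 | fits$r_squared > r2_threshold)
  if (!any(fits$used)) stop("no dissociation fit passed the R^2 filter")
  surv <- fits$koff[fits$used]
  list(koff = mean(surv),
       koff_sem = if (length(surv) > 1) stats::sd(surv) / sqrt(length(surv))
                  else NA_real_,
       n_used = length(surv), n_excluded = sum(!fits$used), fits = fits)
}

# One-phase exponential decay fit with log-linear initialization.
.fit_decay <- function(t, y) {
  r0_init <- max(y[1], max(abs(y)) * 0.1, 1e-12)
  pos <- y > 0.01 * r0_init
  koff0 <- if (sum(pos) >= 2) {
    max(1e-8, -stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[[2]])
  } else 1 / max(t)
  fit <- minpack.lm::nlsLM(
    y ~ r0 * exp(-koff * t),
    start = list(r0 = r0_init, koff = koff0),
    lower = c(r0 = 0, koff = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ss_tot
  list(koff = stats::coef(fit)[["koff"]], r2 = max(0, min(1, r2)))
}

#' Joint association-then-dissociation fit at a single concentration
#'
#' For experiments measured at one analyte concentration, fits both phases
#' of a trace jointly by least squares with shared `kon`, `koff` and `bmax`
#' and continuity of signal at the phase boundary:
#' association `Req (1 - exp(-kobs t))` followed by exponential decay from
#' the association end-point signal.
#'
#' @param trace A [bli_trace()] containing both an association and a
#'   dissociation phase, with `analyte_conc > 0`.
#' @return A [kinetic_parameters()] object with asymptotic SEs from the fit
#'   covariance.
#' @export
fit_association_then_dissociation <- function(trace) {
  stopifnot(inherits(trace, "bli_trace"))
  assoc <- .trace_phase(trace, "association")
  dissoc <- .trace_phase(trace, "dissociation")
  if (is.null(assoc)) stop("trace has no association phase")
  if (is.null(dissoc)) stop("trace has no dissociation phase")
  conc <- trace$analyte_conc
  if (conc <= 0) stop("analyte_conc must be > 0 for a kinetic fit")
  t_a <- assoc$time; y_a <- assoc$signal
  t_end <- max(t_a)
  t_d <- dissoc$time; y_d <- dissoc$signal
  # initialization from the single-phase fits
  ka0 <- fit_kobs(trace)
  kd0 <- .fit_decay(t_d, y_d)
  koff0 <- max(kd0$koff, 1e-8)
  kon0 <- max((ka0$kobs - koff0) / conc, 1e-3 * koff0 / conc)
  bmax0 <- ka0$plateau * (conc + koff0 / kon0) / conc
  t_all <- c(t_a, t_end + t_d)
  y_all <- c(y_a, y_d)
  in_assoc <- c(rep(TRUE, length(t_a)), rep(FALSE, length(t_d)))
  model <- function(kon, koff, bmax) {
    req <- bmax * conc / (conc + koff / kon)
    kobs <- kon * conc + koff
    end_sig <- req * (1 - exp(-kobs * t_end))
    ifelse(in_assoc,
           req * (1 - exp(-kobs * t_all)),
           end_sig * exp(-koff * (t_all - t_end)))
  }
  fit <- minpack.lm::nlsLM(
    y_all ~ model(kon, koff, bmax),
    start = list(kon = kon0, koff = koff0, bmax = bmax0),
    lower = c(kon = 1e-12, koff = 1e-12, bmax = 0),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kon = NA_real_, koff = NA_real_))
  kinetic_parameters(co[["kon"]], co[["koff"]],
                     kon_sem = se[["kon"]], koff_sem = se[["koff"]])
}

#' Full multi-concentration kinetic analysis of a BLI trace family
#'
#' The standard 1:1 analysis pipeline: per-trace preprocessing (optional
#' reference subtraction and smoothing), per-trace kobs fits, the
#' kobs-versus-concentration line for \eqn{K_{on}}, R-squared-filtered mean
#' dissociation fits for \eqn{K_{off}}, and the kinetic
#' \eqn{K_D = K_{off}/K_{on}}.
#'
#' @param traces List of sample [bli_trace()] objects (distinct analyte
#'   concentrations).
#' @param references Optional list of matched reference traces; each sample
#'   trace is paired with the reference of equal `analyte_conc` (or the
#'   single reference supplied).
#' @param smoothing Passed to [preprocess_trace()]; `NULL` disables.
#' @param r2_threshold Dissociation-fit filter, see [mean_koff()].
#' @return List with `kinetics` ([kinetic_parameters()]), `kobs_line`
#'   (from [kon_from_kobs()]), `koff_stats` (from [mean_koff()]), and the
#'   per-trace `kobs_records`.
#' @export
fit_kinetics <- function(traces, references = NULL, smoothing = NULL,
                         r2_threshold = 0.8) {
  if (inherits(traces, "bli_trace")) traces <- list(traces)
  pre <- lapply(traces, function(tr) {
    ref <- NULL
    if (!is.null(references)) {
      if (inherits(references, "bli_trace")) ref <- references
      else {
        match <- vapply(references, function(r) {
          r$analyte_conc == tr$analyte_conc
        }, logical(1))
        if (any(match)) ref <- references[[which(match)[1]]]
      }
    }
    preprocess_trace(tr, ref, smoothing = smoothing)
  })
  records <- lapply(pre, fit_kobs)
  line <- kon_from_kobs(records)
  koff_stats <- mean_koff(pre, r2_threshold = r2_threshold)
  kin <- kinetic_parameters(line$kon, koff_stats$koff,
                            kon_sem = line$kon_sem,
                            koff_sem = koff_stats$koff_sem)
  list(kinetics = kin, kobs_line = line, koff_stats = koff_stats,
       kobs_records = records)
}
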