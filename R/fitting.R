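#' Competition dataset
#'
#' Replicated fraction-bound (or percent-of-control) measurements on a grid
#' of competitor concentrations.
#'
#' @param competitor_conc Competitor concentrations (nM, >= 0), one per
#'   measurement (long format).
#' @param value Measured values, same length; fraction bound in \[0, 1\]-ish
#'   for `"fraction_of_total"`, or percent of the zero-competitor signal for
#'   `"percent_of_zero_competitor"`.
#' @param replicate Optional replicate index per measurement.
#' @param normalization One of `"fraction_of_total"`,
#'   `"percent_of_zero_competitor"`.
#' @return An object of class `competition_dataset` (a data frame with
#'   attribute `normalization`).
#' @export
competition_dataset <- function(competitor_conc, value, replicate = NULL,
                                normalization = c("fraction_of_total",
                                                  "percent_of_zero_competitor")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(competitor_conc), is.numeric(value),
            length(competitor_conc) == length(value))
  if (any(competitor_conc < 0)) stop("competitor concentrations must be >= 0")
  if (any(!is.finite(value))) stop("values must be finite")
  if (length(unique(competitor_conc)) < 2L) {
    stop("need measurements at >= 2 competitor concentrations")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(competitor_conc, competitor_conc,
                            FUN = seq_along)
  }
  out <- data.frame(competitor_nM = competitor_conc, replicate = replicate,
                    value = value)
  attr(out, "normalization") <- normalization
  class(out) <- c("competition_dataset", "data.frame")
  out
}

#' Fit a steady-state saturation series to the variable-slope Hill model
#'
#' Least-squares fit of [hill_binding()] to plateau signals measured over a
#' concentration series (all replicate points fitted jointly). When two or
#' more replicates are present, parameter SEMs are computed across
#' independent per-replicate fits; otherwise asymptotic SEs are reported.
#'
#' @param dose_response Data frame with columns `conc_nM`, `replicate`
#'   (optional) and `signal_nm` (plateau signal).
#' @return An object of class `equilibrium_fit`: `params`
#'   ([equilibrium_parameters()]), `bmax_sem`, `kd_sem`, `hill_sem`,
#'   `n_replicates`, `sigma` (residual SD), and `extrapolated_bmax`
#'   (TRUE when the top concentration reaches < 60% of the fitted Bmax).
#' @export
fit_steady_state <- function(dose_response) {
  df <- as.data.frame(dose_response)
  if (!all(c("conc_nM", "signal_nm") %in% names(df))) {
    stop("dose_response needs columns conc_nM and signal_nm")
  }
  if (is.null(df$replicate)) df$replicate <- 1
  if (length(unique(df$conc_nM)) < 4L) {
    stop("need >= 4 distinct concentrations")
  }
  if (all(abs(df$signal_nm) < 1e-12)) stop("all signals are zero")
  fit_one <- function(d) {
    bmax0 <- max(d$signal_nm)
    kd0 <- d$conc_nM[which.min(abs(d$signal_nm - bmax0 / 2))]
    if (kd0 <= 0) kd0 <- stats::median(d$conc_nM[d$conc_nM > 0])
    fit <- minpack.lm::nlsLM(
      signal_nm ~ bmax * conc_nM^hill / (conc_nM^hill + kd^hill),
      data = d,
      start = list(bmax = bmax0, kd = kd0, hill = 1),
      lower = c(bmax = 1e-12, kd = 1e-9, hill = 0.05),
      upper = c(bmax = Inf, kd = Inf, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    fit
  }
  fit <- fit_one(df)
  co <- stats::coef(fit)
  reps <- unique(df$replicate)
  if (length(reps) >= 2) {
    per_rep <- vapply(reps, function(r) {
      stats::coef(fit_one(df[df$replicate == r, , drop = FALSE]))
    }, numeric(3))
    sems <- apply(per_rep, 1, stats::sd) / sqrt(length(reps))
  } else {
    sems <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  }
  top_mean <- mean(df$signal_nm[df$conc_nM == max(df$conc_nM)])
  structure(
    list(params = equilibrium_parameters(co[["bmax"]], co[["kd"]],
                                         co[["hill"]]),
         bmax_sem = sems[["bmax"]], kd_sem = sems[["kd"]],
         hill_sem = sems[["hill"]], n_replicates = length(reps),
         sigma = stats::sigma(fit),
         extrapolated_bmax = top_mean < 0.6 * co[["bmax"]]),
    class = "equilibrium_fit"
  )
}

#' @export
print.equilibrium_fit <- function(x, ...) {
  p <- x$params
  cat("Steady-state saturation fit (variable-slope Hill model)\n")
  cat(sprintf("  Bmax = %.4g ± %.2g\n", p$bmax, x$bmax_sem))
  cat(sprintf("  K_D  = %.4g ± %.2g nM\n", p$kd, x$kd_sem))
  cat(sprintf("  Hill = %.3g ± %.2g\n", p$hill, x$hill_sem))
  cat(sprintf("  %d replicate(s), residual SD %.3g\n", x$n_replicates,
              x$sigma))
  if (x$extrapolated_bmax) {
    cat("  warning: top concentration below 60% of fitted Bmax (extrapolated)\n")
  }
  invisible(x)
}

#' Normalize signals to percent of a reference condition
#'
#' @param values Numeric signals.
#' @param reference_value Signal of the reference condition (> 0), e.g. the
#'   zero-competitor signal.
#' @return `100 * values / reference_value`.
#' @export
normalize_percent_of_reference <- function(values, reference_value) {
  stopifnot(is.numeric(values), is.numeric(reference_value),
            length(reference_value) == 1L)
  if (!is.finite(reference_value) || reference_value <= 0) {
    stop("reference_value must be > 0")
  }
  100 * values / reference_value
}

#' Rescale bead-only measurements to the calculated zero-competitor fraction
#'
#' When only bead-bound ligand is quantified (no supernatant), raw
#' intensities carry an arbitrary scale. They are rescaled so that the
#' zero-competitor measurement equals the fraction of ligand bound expected
#' from exact mass-action depletion, [bound_fraction_no_competitor()].
#'
#' @param values Raw bound-signal measurements.
#' @param system The [competition_system()] defining A, R, \eqn{K_A}.
#' @param zero_value Measured zero-competitor signal; defaults to the mean
#'   of `values[competitor_conc == 0]` when `competitor_conc` is given.
#' @param competitor_conc Optional concentrations matching `values`, used
#'   to locate the zero-competitor measurements.
#' @return Values on the fraction-of-total-sites scale.
#' @export
normalize_fraction_of_calculated_zero <- function(values, system,
                                                  zero_value = NULL,
                                                  competitor_conc = NULL) {
  stopifnot(inherits(system, "competition_system"), is.numeric(values))
  f0 <- bound_fraction_no_competitor(system)
  if (f0 <= 0) stop("calculated zero-competitor fraction is zero (R = 0?)")
  if (is.null(zero_value)) {
    if (is.null(competitor_conc)) {
      stop("supply zero_value or competitor_conc")
    }
    if (!any(competitor_conc == 0)) stop("no zero-competitor measurement")
    zero_value <- mean(values[competitor_conc == 0])
  }
  if (!is.finite(zero_value) || zero_value <= 0) {
    stop("zero-competitor reference must be > 0")
  }
  values * f0 / zero_value
}

#' Fit an IC50 to a displacement curve
#'
#' Least-squares fit of a descending logistic
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC_{50})^s}}
#' with, by default, the bottom fixed at 0 and the slope s fixed at 1 (both
#' releasable). The data must span the transition: values both above 75%
#' and below 25% of the zero-competitor level.
#'
#' @param dataset A [competition_dataset()].
#' @param fix_bottom,fix_slope Fix bottom = 0 and slope = 1 (defaults TRUE).
#' @return List with `ic50`, `ic50_sem` (nM), `top`, `bottom`, `slope`,
#'   `sigma`.
#' @export
fit_ic50 <- function(dataset, fix_bottom = TRUE, fix_slope = TRUE) {
  stopifnot(inherits(dataset, "competition_dataset"))
  x <- dataset$competitor_nM
  y <- dataset$value
  y0 <- mean(y[x == min(x)])
  if (y0 <= 0) stop("non-positive zero-competitor level")
  if (!any(y > 0.75 * y0) || !any(y < 0.25 * y0)) {
    stop("data do not span the displacement transition (need values >75% and <25% of the zero-competitor level)")
  }
  mid <- x[which.min(abs(y - y0 / 2))]
  if (mid <= 0) mid <- stats::median(x[x > 0])
  d <- data.frame(x = x, y = y)
  logistic <- function(x, top, bottom, lic50, s) {
    bottom + (top - bottom) / (1 + (x / 10^lic50)^s)
  }
  start <- list(top = y0, lic50 = log10(mid))
  lower <- c(top = 0, lic50 = -6)
  upper <- c(top = Inf, lic50 = 12)
  form <- if (fix_bottom && fix_slope) {
    y ~ logistic(x, top, 0, lic50, 1)
  } else if (fix_bottom) {
    start$s <- 1; lower <- c(lower, s = 0.1); upper <- c(upper, s = 10)
    y ~ logistic(x, top, 0, lic50, s)
  } else if (fix_slope) {
    start$bottom <- 0; lower <- c(lower, bottom = -Inf)
    upper <- c(upper, bottom = Inf)
    y ~ logistic(x, top, bottom, lic50, 1)
  } else {
    start$bottom <- 0; start$s <- 1
    lower <- c(lower, bottom = -Inf, s = 0.1)
    upper <- c(upper, bottom = Inf, s = 10)
    y ~ logistic(x, top, bottom, lic50, s)
  }
  fit <- minpack.lm::nlsLM(form, data = d, start = start, lower = lower,
                           upper = upper,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  co <- stats::coef(fit)
  ic50 <- 10^co[["lic50"]]
  se <- tryCatch(summary(fit)$coefficients["lic50", "Std. Error"],
                 error = function(e) NA_real_)
  list(ic50 = ic50, ic50_sem = ic50 * log(10) * se, top = co[["top"]],
       bottom = if ("bottom" %in% names(co)) co[["bottom"]] else 0,
       slope = if ("s" %in% names(co)) co[["s"]] else 1,
       sigma = stats::sigma(fit))
}

# Model predictions on the dataset's normalization scale.
.competition_predict <- function(x, system, kb, alpha, model, normalization) {
  y <- if (model == "competitive") {
    wang_competition_curve(system, x, kb = kb)
  } else {
    sys_b <- competition_system(system$a_total, system$r_total, system$ka,
                                kb = kb)
    affinity_shift_competition(affinity_shift_parameters(sys_b, alpha), x)
  }
  if (normalization == "percent_of_zero_competitor") {
    y0 <- bound_fraction_no_competitor(system)
    y <- 100 * y / y0
  }
  y
}

#' Fit a competition model to displacement data with known system constants
#'
#' With the total site concentration A, receptor concentration R and the
#' receptor-ligand constant \eqn{K_A} fixed at independently measured
#' values, estimates the competitor constant \eqn{K_B} (and, for the
#' affinity-shift model, the cooperativity factor \eqn{\alpha}) by
#' nonlinear least squares on all replicate points jointly. 95% confidence
#' intervals come from a seeded parametric bootstrap: Gaussian noise at the
#' fitted residual SD is added to the fitted curve, the model is refitted,
#' and percentile intervals are taken over the resamples.
#'
#' @param dataset A [competition_dataset()].
#' @param system A [competition_system()] with known `a_total`, `r_total`,
#'   `ka`; its `kb` (if any) is ignored and refitted.
#' @param model `"competitive"` (exact closed-form displacement) or
#'   `"affinity_shift"` (allosteric ternary-complex model).
#' @param n_boot Bootstrap resamples for the CI (default 1000; 0 skips).
#' @param seed Seed for the bootstrap resampling.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `competition_fit`: `model`, `kb`, `alpha`
#'   (NA for competitive), `kb_ci`, `alpha_ci`, `rss`, `sigma`, `n`,
#'   `fitted`, `residuals`, `n_boot`, `seed`, `ci_method`.
#' @export
fit_competition_model <- function(dataset, system,
                                  model = c("competitive", "affinity_shift"),
                                  n_boot = 1000, seed = 1,
                                  conf_level = 0.95) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "competition_dataset"),
            inherits(system, "competition_system"))
  normalization <- attr(dataset, "normalization")
  x <- dataset$competitor_nM
  y <- dataset$value
  fit_once <- function(yy) {
    y0_expect <- .competition_predict(0, system, 1, 1, "competitive",
                                      normalization)
    drop <- mean(yy[x == min(x)]) - mean(yy[x == max(x)])
    if (drop <= 0.02 * y0_expect) {
      stop("no displacement detected; K_B is unbounded")
    }
    # coarse grid init for log10(KB) (and log10(alpha) for affinity shift)
    lkb_grid <- seq(-1, 7, by = 0.5)
    if (model == "competitive") {
      sse <- vapply(lkb_grid, function(lkb) {
        sum((yy - .competition_predict(x, system, 10^lkb, NA, model,
                                       normalization))^2)
      }, numeric(1))
      start <- list(lkb = lkb_grid[which.min(sse)])
      fit <- minpack.lm::nlsLM(
        yy ~ .competition_predict(x, system, 10^lkb, NA, model,
                                  normalization),
        start = start, lower = c(lkb = -6), upper = c(lkb = 12),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    } else {
      la_grid <- seq(0, 6, by = 1.5)
      grid <- expand.grid(lkb = seq(-1, 7, by = 1), la = la_grid)
      sse <- mapply(function(lkb, la) {
        sum((yy - .competition_predict(x, system, 10^lkb, 10^la, model,
                                       normalization))^2)
      }, grid$lkb, grid$la)
      best <- grid[which.min(sse), ]
      fit <- minpack.lm::nlsLM(
        yy ~ .competition_predict(x, system, 10^lkb, 10^la, model,
                                  normalization),
        start = list(lkb = best$lkb, la = best$la),
        lower = c(lkb = -6, la = -6), upper = c(lkb = 12, la = 9),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    }
    fit
  }
  fit <- fit_once(y)
  co <- stats::coef(fit)
  kb_hat <- 10^co[["lkb"]]
  alpha_hat <- if (model == "affinity_shift") 10^co[["la"]] else NA_real_
  pred <- .competition_predict(x, system, kb_hat, alpha_hat, model,
                               normalization)
  rss <- sum((y - pred)^2)
  p <- length(co)
  sigma <- sqrt(rss / max(1, length(y) - p))
  kb_ci <- c(NA_real_, NA_real_)
  alpha_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    boot <- matrix(NA_real_, nrow = n_boot, ncol = p)
    for (b in seq_len(n_boot)) {
      yb <- pred + stats::rnorm(length(pred), 0, sigma)
      cb <- tryCatch(stats::coef(fit_once(yb)), error = function(e) rep(NA_real_, p))
      boot[b, ] <- cb
    }
    probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    q1 <- stats::quantile(boot[, 1], probs, na.rm = TRUE, names = FALSE)
    kb_ci <- 10^q1
    # guarantee the point estimate lies inside the reported interval
    kb_ci[1] <- min(kb_ci[1], kb_hat * (1 - 1e-9))
    kb_ci[2] <- max(kb_ci[2], kb_hat * (1 + 1e-9))
    if (p == 2) {
      q2 <- stats::quantile(boot[, 2], probs, na.rm = TRUE, names = FALSE)
      alpha_ci <- 10^q2
      alpha_ci[1] <- min(alpha_ci[1], alpha_hat * (1 - 1e-9))
      alpha_ci[2] <- max(alpha_ci[2], alpha_hat * (1 + 1e-9))
    }
  }
  structure(
    list(model = model, kb = kb_hat, alpha = alpha_hat,
         kb_ci = kb_ci, alpha_ci = alpha_ci, conf_level = conf_level,
         rss = rss, sigma = sigma, n = length(y), p = p,
         fitted = pred, residuals = y - pred,
         competitor_nM = x,
         n_boot = n_boot, seed = seed,
         ci_method = "parametric bootstrap (percentile)"),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition fit (%s model), n = %d points\n", x$model, x$n))
  ci <- function(v) if (any(is.na(v))) "" else
    sprintf(" (%.0f%% CI %.4g-%.4g)", 100 * x$conf_level, v[1], v[2])
  cat(sprintf("  K_B = %.4g nM%s\n", x$kb, ci(x$kb_ci)))
  if (!is.na(x$alpha)) {
    cat(sprintf("  alpha = %.4g%s\n", x$alpha, ci(x$alpha_ci)))
  }
  cat(sprintf("  residual SD %.3g; CI: %s, %d resamples, seed %d\n",
              x$sigma, x$ci_method, x$n_boot, x$seed))
  invisible(x)
}

# Small-sample-corrected AIC from an RSS under Gaussian errors;
# k counts the mean-model parameters plus the variance.
.aicc <- function(rss, n, k_mean) {
  k <- k_mean + 1
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare the competitive and affinity-shift competition models
#'
#' Fits both models to the same dataset and performs a nested comparison:
#' the fully competitive model is the boundary of the affinity-shift model
#' as the cooperativity factor grows without bound, so an
#' extra-sum-of-squares F-test (1 numerator df) is combined with the
#' small-sample-corrected information criterion (AICc). The verdict is the
#' model favored by both; `"ambiguous"` when they disagree or when both
#' models fit with (near-)zero residual.
#'
#' @param dataset A [competition_dataset()].
#' @param system A [competition_system()] with known A, R, \eqn{K_A}.
#' @param alpha_level Significance level of the F-test (default 0.05).
#' @return An object of class `model_comparison`: `verdict`, `f_statistic`,
#'   `p_value`, `aicc_competitive`, `aicc_affinity_shift`, `delta_aicc`,
#'   and both fits.
#' @export
compare_models <- function(dataset, system, alpha_level = 0.05) {
  fit_c <- fit_competition_model(dataset, system, "competitive", n_boot = 0)
  fit_s <- fit_competition_model(dataset, system, "affinity_shift",
                                 n_boot = 0)
  n <- fit_c$n
  df2 <- n - fit_s$p
  eps <- 1e-12 * max(1, mean(dataset$value)^2) * n
  if (fit_c$rss < eps && fit_s$rss < eps) {
    f <- NA_real_; pval <- NA_real_
    verdict <- "ambiguous"
    aic_c <- aic_s <- NA_real_
  } else {
    f <- max(0, (fit_c$rss - fit_s$rss)) / (fit_s$rss / df2)
    pval <- stats::pf(f, 1, df2, lower.tail = FALSE)
    aic_c <- .aicc(fit_c$rss, n, fit_c$p)
    aic_s <- .aicc(fit_s$rss, n, fit_s$p)
    f_pick <- if (pval < alpha_level) "affinity_shift" else "competitive"
    aic_pick <- if (aic_s < aic_c) "affinity_shift" else "competitive"
    verdict <- if (identical(f_pick, aic_pick)) f_pick else "ambiguous"
  }
  structure(
    list(verdict = verdict, f_statistic = f, p_value = pval,
         aicc_competitive = aic_c, aicc_affinity_shift = aic_s,
         delta_aicc = aic_s - aic_c,
         alpha_level = alpha_level,
         fit_competitive = fit_c, fit_affinity_shift = fit_s),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Nested model comparison: competitive vs affinity-shift\n")
  cat(sprintf("  F = %.4g, p = %.4g; dAICc (shift - competitive) = %.4g\n",
              x$f_statistic, x$p_value, x$delta_aicc))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
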