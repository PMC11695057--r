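#' Design of a simulated binding experiment
#'
#' Captures everything needed to generate a synthetic dataset
#' deterministically: the experiment mode, the ground-truth parameters, the
#' concentration grid, replication, the noise model and the seed. Defaults
#' mirror the designs of the experiments this package analyzes: a 3.16-fold
#' (half-log) dilution ladder for saturation series, analyte concentrations
#' {3.2, 10, 32, 100} nM for kinetic trace families, and the competitor
#' grid {0, 0.1, 0.4, 1.6, 25, 100} uM (in nM) with triplicates for
#' bead-competition assays.
#'
#' @param mode One of `"bli_kinetic"`, `"steady_state"`, `"competition"`.
#' @param truth Ground-truth parameters. For `bli_kinetic`: list with
#'   `kon`, `koff`, `bmax`. For `steady_state`: an
#'   [equilibrium_parameters()] or list with `bmax`, `kd`, `hill`. For
#'   `competition`: list with `system` ([competition_system()] including
#'   `kb`), `model` (`"competitive"` or `"affinity_shift"`), and `alpha`
#'   (affinity-shift only). Mode-specific defaults are supplied.
#' @param grid Concentration grid (nM): analyte concentrations for traces
#'   and saturation series, competitor concentrations for competition.
#' @param n_replicates Replicates per grid point.
#' @param noise_sd Additive Gaussian noise SD, in signal units (nm) for
#'   traces and saturation series, in fraction-bound units for competition.
#' @param noise_model `"additive"` (homoscedastic, default) or
#'   `"proportional"` (SD scales with the noiseless signal).
#' @param drift_rate Linear baseline drift (nm/s) added to traces and their
#'   references.
#' @param sampling_hz Trace sampling rate (Hz).
#' @param phase_durations Named numeric: seconds of `baseline`,
#'   `association`, `dissociation`.
#' @param seed Integer seed; recorded in all generated outputs.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(mode = c("bli_kinetic", "steady_state",
                                       "competition"),
                              truth = NULL, grid = NULL, n_replicates = NULL,
                              noise_sd = NULL,
                              noise_model = c("additive", "proportional"),
                              drift_rate = 0, sampling_hz = 1,
                              phase_durations = c(baseline = 60,
                                                  association = 300,
                                                  dissociation = 600),
                              seed = 1) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  defaults <- switch(mode,
    bli_kinetic = list(
      truth = list(kon = 0.00019, koff = 0.0014, bmax = 1),
      grid = c(3.2, 10, 32, 100), n_replicates = 1, noise_sd = 0.02),
    steady_state = list(
      truth = list(bmax = 1, kd = 10.4, hill = 1),
      grid = 10^seq(-1, 3, by = 0.5), n_replicates = 3, noise_sd = 0.03),
    competition = list(
      truth = list(system = competition_system(64, 50, 10.4, kb = 200),
                   model = "competitive", alpha = NA_real_),
      grid = c(0, 100, 400, 1600, 25000, 100000), n_replicates = 3,
      noise_sd = 0.03)
  )
  truth <- utils::modifyList(defaults$truth, as.list(truth %||% list()))
  grid <- grid %||% defaults$grid
  n_replicates <- n_replicates %||% defaults$n_replicates
  noise_sd <- noise_sd %||% defaults$noise_sd
  stopifnot(noise_sd >= 0, length(grid) >= 1, all(grid >= 0),
            n_replicates >= 1, sampling_hz > 0)
  if (mode == "competition") {
    stopifnot(inherits(truth$system, "competition_system"))
    truth$model <- match.arg(truth$model, c("competitive", "affinity_shift"))
    if (truth$model == "affinity_shift" &&
        (is.null(truth$alpha) || is.na(truth$alpha))) {
      stop("affinity_shift truth needs alpha")
    }
  }
  if (!is.null(seed)) stopifnot(is.finite(seed))
  structure(
    list(mode = mode, truth = truth, grid = grid,
         n_replicates = n_replicates, noise_sd = noise_sd,
         noise_model = noise_model, drift_rate = drift_rate,
         sampling_hz = sampling_hz, phase_durations = phase_durations,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design: %s, %d grid point(s) x %d replicate(s)\n",
              x$mode, length(x$grid), x$n_replicates))
  cat(sprintf("  noise SD %g (%s), seed %s\n", x$noise_sd, x$noise_model,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

.design_noise <- function(design, truth_values) {
  sd <- design$noise_sd
  if (design$noise_model == "proportional") {
    sd <- sd * abs(truth_values)
  }
  stats::rnorm(length(truth_values), 0, sd)
}

#' Generate a family of synthetic BLI traces
#'
#' Simulates one sensor per analyte concentration and replicate: a zero
#' baseline, a 1:1 Langmuir association phase and an exponential
#' dissociation phase, with additive Gaussian noise and optional linear
#' baseline drift. Each sample trace is paired with a receptor-free
#' reference trace containing drift and noise only, emulating a parallel
#' control channel.
#'
#' @param design An [experiment_design()] with `mode = "bli_kinetic"`.
#' @return List with `traces` (list of [bli_trace()]), `references`
#'   (matched receptor-free traces) and `design`.
#' @export
generate_bli_traces <- function(design) {
  stopifnot(inherits(design, "experiment_design"),
            design$mode == "bli_kinetic")
  set.seed(design$seed)
  tr <- design$truth
  kin <- kinetic_parameters(tr$kon, tr$koff)
  dur <- design$phase_durations
  dt <- 1 / design$sampling_hz
  t_base <- seq(0, dur[["baseline"]], by = dt)
  t_assoc <- seq(dt, dur[["association"]], by = dt)
  t_dissoc <- seq(dt, dur[["dissociation"]], by = dt)
  time <- c(t_base, max(t_base) + t_assoc,
            max(t_base) + max(t_assoc) + t_dissoc)
  phase <- c(rep("baseline", length(t_base)),
             rep("association", length(t_assoc)),
             rep("dissociation", length(t_dissoc)))
  traces <- list(); references <- list()
  i <- 0
  for (conc in design$grid) {
    for (rep_i in seq_len(design$n_replicates)) {
      i <- i + 1
      assoc_sig <- association_model(t_assoc, conc, kin, tr$bmax)
      r_end <- association_model(max(t_assoc), conc, kin, tr$bmax)
      clean <- c(rep(0, length(t_base)), assoc_sig,
                 dissociation_model(t_dissoc, r_end, tr$koff))
      drift <- design$drift_rate * time
      id <- sprintf("S%02d_c%g_r%d", i, conc, rep_i)
      traces[[i]] <- bli_trace(
        time, clean + drift + .design_noise(design, clean), phase, conc,
        sensor_id = id, is_reference = FALSE)
      references[[i]] <- bli_trace(
        time, drift + .design_noise(design, clean * 0), phase, conc,
        sensor_id = paste0(id, "_ref"), is_reference = TRUE)
    }
  }
  list(traces = traces, references = references, design = design)
}

#' Generate a synthetic steady-state dose-response table
#'
#' Hill-model plateau signals on the design grid plus Gaussian noise,
#' `n_replicates` measurements per concentration.
#'
#' @param design An [experiment_design()] with `mode = "steady_state"`.
#' @return Data frame with columns `conc_nM`, `replicate`, `signal_nm`;
#'   attributes `truth` and `design`.
#' @export
generate_dose_response <- function(design) {
  stopifnot(inherits(design, "experiment_design"),
            design$mode == "steady_state")
  set.seed(design$seed)
  tr <- design$truth
  params <- if (inherits(tr, "equilibrium_parameters")) tr else
    equilibrium_parameters(tr$bmax, tr$kd, tr$hill)
  df <- expand.grid(replicate = seq_len(design$n_replicates),
                    conc_nM = design$grid)[, 2:1]
  clean <- hill_binding(df$conc_nM, params)
  df$signal_nm <- clean + .design_noise(design, clean)
  df <- df[order(df$conc_nM, df$replicate), ]
  rownames(df) <- NULL
  attr(df, "truth") <- params
  attr(df, "design") <- design
  df
}

#' Generate a synthetic bead-competition dataset
#'
#' Fraction-bound values from the chosen equilibrium model (exact
#' competitive displacement or affinity-shift ternary-complex) on the
#' competitor grid, plus Gaussian noise, with replicates per grid point.
#'
#' @param design An [experiment_design()] with `mode = "competition"`.
#' @param normalization Output scale, see [competition_dataset()].
#' @return A [competition_dataset()] with attributes `truth` and `design`.
#' @export
generate_competition <- function(design,
                                 normalization = "fraction_of_total") {
  stopifnot(inherits(design, "experiment_design"),
            design$mode == "competition")
  set.seed(design$seed)
  tr <- design$truth
  x <- rep(design$grid, each = design$n_replicates)
  rep_i <- rep(seq_len(design$n_replicates), times = length(design$grid))
  clean <- if (tr$model == "competitive") {
    wang_competition_curve(tr$system, x)
  } else {
    affinity_shift_competition(affinity_shift_parameters(tr$system,
                                                         tr$alpha), x)
  }
  if (normalization == "percent_of_zero_competitor") {
    clean <- 100 * clean / bound_fraction_no_competitor(tr$system)
    noise <- .design_noise(design, clean / 100) * 100
  } else {
    noise <- .design_noise(design, clean)
  }
  out <- competition_dataset(x, clean + noise, replicate = rep_i,
                             normalization = normalization)
  attr(out, "truth") <- tr
  attr(out, "design") <- design
  out
}
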