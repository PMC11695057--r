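# ground truth used throughout: kon = 1.9e-4 nM^-1 s^-1, koff = 1.4e-3 s^-1
TRUE_KON <- 0.00019
TRUE_KOFF <- 0.0014

test_that("bli_trace validates structure and phase order", {
  tr <- bli_trace(0:9, rep(0, 10), c(rep("baseline", 4), rep("association", 6)),
                  analyte_conc = 32)
  expect_s3_class(tr, "bli_trace")
  expect_error(bli_trace(c(0, 1, 1), rep(0, 3), rep("baseline", 3), 1),
               "strictly increasing")
  expect_error(bli_trace(0:2, c(0, NA, 0), rep("baseline", 3), 1), "finite")
  expect_error(bli_trace(0:2, rep(0, 3), c("association", "baseline",
                                           "baseline"), 1), "order")
  expect_error(bli_trace(0:2, rep(0, 3), c("baseline", "wash", "baseline"),
                         1), "unknown phase")
  expect_error(bli_trace(0:3, rep(0, 4),
                         c("baseline", "association", "baseline",
                           "association"), 1), "contiguous")
})

test_that("association and dissociation models evaluate the 1:1 forms", {
  kin <- kinetic_parameters(TRUE_KON, TRUE_KOFF)
  expect_equal(kin$kd_kinetic, TRUE_KOFF / TRUE_KON, tolerance = 1e-12)
  # Req at 32 nM with KD = 7.368 nM
  expect_equal(association_model(1e7, 32, kin, bmax = 1), 32 / 39.368421052,
               tolerance = 1e-6)
  expect_equal(association_model(0, 32, kin, 1), 0)
  # kobs slope check through the model: signal at small t ~ Req * kobs * t
  t <- 1e-6
  req <- 32 / (32 + kin$kd_kinetic)
  expect_equal(association_model(t, 32, kin, 1) / (req * t), 0.00748,
               tolerance = 1e-6)
  expect_equal(dissociation_model(0, 0.8, TRUE_KOFF), 0.8)
  expect_equal(dissociation_model(1 / TRUE_KOFF, 0.8, TRUE_KOFF), 0.8 / exp(1))
})

make_trace <- function(conc, noise_sd = 0, seed = NULL, bmax = 1,
                       kon = TRUE_KON, koff = TRUE_KOFF, hz = 1) {
  if (!is.null(seed)) set.seed(seed)
  design <- experiment_design("bli_kinetic",
                              truth = list(kon = kon, koff = koff,
                                           bmax = bmax),
                              grid = conc, noise_sd = noise_sd,
                              sampling_hz = hz,
                              seed = if (is.null(seed)) 1 else seed)
  generate_bli_traces(design)$traces[[1]]
}

test_that("fit_kobs recovers noiseless association parameters", {
  tr <- make_trace(32)
  rec <- fit_kobs(tr)
  expect_equal(rec$kobs, TRUE_KON * 32 + TRUE_KOFF, tolerance = 1e-8)
  expect_equal(rec$plateau, 32 / (32 + TRUE_KOFF / TRUE_KON),
               tolerance = 1e-8)
  expect_gt(rec$fit_r2, 0.999999)
  # degenerate input: no signal
  flat <- bli_trace(0:99, rep(0, 100),
                    c(rep("baseline", 20), rep("association", 80)), 32)
  expect_error(fit_kobs(flat), "no association signal")
  # noisy recovery at fixed seed
  rec_n <- fit_kobs(make_trace(32, noise_sd = 0.02 * 0.8128, seed = 11))
  expect_equal(rec_n$kobs, 0.00748, tolerance = 0.05)
})

test_that("kon_from_kobs extracts the slope of the kobs line", {
  concs <- c(3.2, 10, 32, 100)
  recs <- lapply(concs, function(cc) {
    structure(list(analyte_conc = cc, kobs = TRUE_KON * cc + TRUE_KOFF,
                   plateau = 1, fit_r2 = 1), class = "kobs_record")
  })
  line <- kon_from_kobs(recs)
  expect_equal(line$kon, TRUE_KON, tolerance = 1e-10)
  expect_equal(line$intercept, TRUE_KOFF, tolerance = 1e-10)
  expect_true(line$concentration_dependent)
  # concentration-independent kobs is flagged
  flat <- lapply(concs, function(cc) {
    structure(list(analyte_conc = cc, kobs = TRUE_KOFF, plateau = 1,
                   fit_r2 = 1), class = "kobs_record")
  })
  expect_false(kon_from_kobs(flat)$concentration_dependent)
  expect_error(kon_from_kobs(recs[1:2]), "3 distinct")
})

test_that("mean_koff filters on dissociation-fit R-squared", {
  good <- lapply(c(32, 100), function(cc) make_trace(cc))
  set.seed(5)
  noise <- lapply(1:2, function(i) {
    tr <- good[[1]]
    bli_trace(tr$time, rnorm(length(tr$time), 0, 0.05), tr$phase,
              tr$analyte_conc, sensor_id = paste0("noise", i))
  })
  res <- mean_koff(c(good, noise))
  expect_equal(res$koff, TRUE_KOFF, tolerance = 1e-6)
  expect_equal(res$n_excluded, 2)
  expect_equal(res$n_used, 2)
  # invariance: adding filtered-out traces does not change the mean
  res_clean <- mean_koff(good)
  expect_equal(res$koff, res_clean$koff, tolerance = 1e-12)
  # threshold 0 includes everything
  expect_equal(mean_koff(c(good, noise), r2_threshold = 0)$n_excluded, 0)
  # single trace: SEM undefined
  res1 <- mean_koff(good[1])
  expect_true(is.na(res1$koff_sem))
  expect_equal(res1$koff, TRUE_KOFF, tolerance = 1e-8)
  expect_error(mean_koff(noise), "no dissociation fit passed")
})

test_that("kinetic_kd computes the ratio with quadrature uncertainty", {
  res <- kinetic_kd(0.00019, 0.0014, 0.00003, 0.00016)
  expect_equal(res$kd, 7.368421052632, tolerance = 1e-10)
  expect_equal(signif(res$kd, 2), 7.4)
  expect_equal(res$kd_sem, 1.43621796670, tolerance = 1e-8)
  expect_equal(kinetic_kd(1, 1)$kd, 1)
  expect_true(is.na(kinetic_kd(1, 1)$kd_sem))
})

test_that("preprocess_trace subtracts reference, drift, and baseline", {
  # identical trace and reference cancel exactly
  tr <- make_trace(32)
  zero <- preprocess_trace(tr, reference = tr, smoothing = NULL)
  expect_equal(zero$signal, rep(0, length(tr$time)), tolerance = 1e-12)
  # smoothing off + no reference: output equals input minus baseline mean
  shifted <- bli_trace(tr$time, tr$signal + 0.25, tr$phase, 32)
  out <- preprocess_trace(shifted, smoothing = NULL)
  expect_equal(out$signal, tr$signal, tolerance = 1e-12)
  # linear drift removed via the reference channel
  design <- experiment_design("bli_kinetic", grid = 32, noise_sd = 0.01,
                              drift_rate = 5e-4, seed = 21)
  fam <- generate_bli_traces(design)
  clean <- preprocess_trace(fam$traces[[1]], fam$references[[1]],
                            smoothing = NULL)
  truth <- preprocess_trace(make_trace(32), smoothing = NULL)
  resid <- clean$signal - truth$signal
  expect_lt(max(abs(resid)), 5 * 0.01 * sqrt(2))
  # smoothing reduces noise without biasing the curve
  sm <- preprocess_trace(fam$traces[[1]], fam$references[[1]],
                         smoothing = list(window = 11, order = 3))
  expect_lt(sd(sm$signal - truth$signal), sd(resid))
  expect_error(preprocess_trace(tr, smoothing = list(window = 10, order = 3)),
               "odd")
})

test_that("joint association-then-dissociation fit recovers both constants", {
  tr <- make_trace(32)
  kin <- fit_association_then_dissociation(tr)
  expect_equal(kin$kon, TRUE_KON, tolerance = 1e-6)
  expect_equal(kin$koff, TRUE_KOFF, tolerance = 1e-6)
  # missing dissociation phase errors
  idx <- tr$phase != "dissociation"
  assoc_only <- bli_trace(tr$time[idx], tr$signal[idx], tr$phase[idx], 32)
  expect_error(fit_association_then_dissociation(assoc_only),
               "no dissociation phase")
  # noisy fit at fixed seed: KD within 10% of truth
  kin_n <- fit_association_then_dissociation(
    make_trace(32, noise_sd = 0.02, seed = 31))
  expect_equal(kin_n$kd_kinetic, TRUE_KOFF / TRUE_KON, tolerance = 0.1)
})

test_that("kobs-line pipeline and steady-state plateaus agree (noiseless)", {
  for (pars in list(c(kon = 2e-4, koff = 1.5e-3), c(kon = 1e-3, koff = 5e-3),
                    c(kon = 5e-5, koff = 5e-4))) {
    kd_true <- pars[["koff"]] / pars[["kon"]]
    design <- experiment_design(
      "bli_kinetic",
      truth = list(kon = pars[["kon"]], koff = pars[["koff"]], bmax = 1),
      grid = kd_true * c(0.32, 1, 3.2, 10), noise_sd = 0, seed = 1)
    fam <- generate_bli_traces(design)
    res <- fit_kinetics(fam$traces)
    # noiseless round-trip to 1e-6 relative
    expect_equal(res$kinetics$kon, pars[["kon"]], tolerance = 1e-6)
    expect_equal(res$kinetics$koff, pars[["koff"]], tolerance = 1e-6)
    # kobs linearity: each fitted kobs on the kon*C + koff line
    for (rec in res$kobs_records) {
      expect_equal(rec$kobs,
                   pars[["kon"]] * rec$analyte_conc + pars[["koff"]],
                   tolerance = 1e-6)
    }
    # steady-state KD from the same family's fitted plateaus
    plateaus <- data.frame(
      conc_nM = vapply(res$kobs_records, `[[`, numeric(1), "analyte_conc"),
      signal_nm = vapply(res$kobs_records, `[[`, numeric(1), "plateau"))
    ss <- fit_steady_state(plateaus)
    expect_equal(ss$params$kd, res$kinetics$kd_kinetic, tolerance = 1e-6)
  }
})

test_that("noisy end-to-end kinetics recovers KD within tolerance", {
  design <- experiment_design("bli_kinetic", noise_sd = 0.02, seed = 1)
  fam <- generate_bli_traces(design)
  res <- fit_kinetics(fam$traces, references = fam$references)
  expect_equal(res$kinetics$kd_kinetic, TRUE_KOFF / TRUE_KON,
               tolerance = 0.2)
  expect_equal(res$kinetics$kon, TRUE_KON,
               tolerance = 3 * res$kobs_line$kon_sem / TRUE_KON)
})
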