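test_that("cell_trace validates its invariants", {
  t <- seq(0, 600, 60)
  n <- length(t)
  expect_s3_class(cell_trace("c1", t, rep(0.4, n), rep(1, n),
                             rep("activation", n)), "cell_trace")
  expect_error(cell_trace("c1", rev(t), rep(0.4, n), rep(1, n),
                          rep("activation", n)), "strictly increasing")
  expect_error(cell_trace("c1", t, rep(1.4, n), rep(1, n),
                          rep("activation", n)), "exceed")
  expect_error(cell_trace("c1", t[1:3], c(0.1, 0.2, 0.3), rep(1, 3),
                          c("activation", "recovery", "recovery")),
               "at least 3 frames")
})

test_that("initial-condition correction recovers a bi-exponential exactly", {
  t_abs <- seq(0, 3300, 60)
  phase <- c(rep("activation", 11), rep("recovery", 45))
  t_rec <- t_abs[phase == "recovery"] - t_abs[12]
  nuc_rec <- 0.2 * exp(-0.002 * t_rec) + 0.8 * (1 - exp(-0.002 * t_rec))
  nuc <- c(seq(0.9, 0.2, length.out = 11), nuc_rec)
  tr <- cell_trace("c1", t_abs, nuc, rep(2, length(nuc)), phase)
  corr <- correct_initial_conditions(tr)
  expect_true(corr$converged)
  # parameters recovered to high relative precision (k reported in ks^-1)
  expect_equal(corr$n0, 0.2, tolerance = 1e-6)
  expect_equal(corr$ne, 0.8, tolerance = 1e-6)
  expect_equal(corr$k, 2.0, tolerance = 1e-6)
  # corrected series is the pure rise, starting at 0
  expect_equal(corr$corrected, 0.8 * (1 - exp(-0.002 * t_rec)),
               tolerance = 1e-6)
  expect_equal(corr$corrected[1], 0, tolerance = 1e-8)
})

test_that("correction leaves a residual-free trace unchanged", {
  cfg <- clean_import_config(seed = 4)
  tr <- generate_cell_trace(list(Ke = 2, kI = 1.5, v = 0.3, n0 = 0), cfg)
  corr <- correct_initial_conditions(tr)
  rec <- recovery_frames(tr)
  expect_equal(corr$corrected, rec$nuc, tolerance = 1e-6)
})

test_that("noise-free round trip recovers (Ke, kI) to 1e-6 relative", {
  cfg <- clean_import_config(seed = 5)
  tr <- generate_cell_trace(list(Ke = 2, kI = 1.5, v = 0.3, n0 = 0), cfg)
  expect_equal(nrow(recovery_frames(tr)), 45)
  f <- fit_recovery(tr)
  expect_true(f$converged)
  expect_equal(f$Ke, 2, tolerance = 1e-6)
  expect_equal(f$kI, 1.5, tolerance = 1e-6)
  # with a residual pool the shared-rate correction keeps the fit exact
  tr2 <- generate_cell_trace(list(Ke = 2, kI = 1.5, v = 0.3, n0 = 0.2,
                                  k_act = 6), cfg)
  f2 <- fit_recovery(tr2)
  expect_equal(f2$Ke, 2, tolerance = 1e-6)
  expect_equal(f2$kI, 1.5, tolerance = 1e-6)
  expect_equal(f2$n0, 0.2, tolerance = 1e-4)
})

test_that("kI estimator is accurate at 5% noise (Monte Carlo)", {
  # 300 cells, fixed generating parameters; spec-level bars are bias < 2%
  # and SD < 10% -- checked here at reduced n to keep the suite fast
  cfg <- synthetic_config(seed = 6, n_cells = 300, intercell_sigma = 0,
                          noise_cv = 0.05, recovery_duration = 2640)
  pop <- generate_population(cfg)
  fits <- lapply(pop$traces, fit_recovery)
  kI <- vapply(fits, function(f) f$kI, numeric(1))
  expect_lt(abs(mean(kI) / 1.62 - 1), 0.02)
  expect_lt(sd(kI) / 1.62, 0.10)
  expect_lt(abs(median(kI) / 1.62 - 1), 0.05)
})

test_that("degenerate steady-state trace is flagged, not fatal", {
  t <- seq(0, 3000, 60)
  phase <- c(rep("activation", 5), rep("recovery", length(t) - 5))
  tr <- cell_trace("flat", t, rep(0.5, length(t)), rep(1, length(t)), phase)
  f <- fit_recovery(tr, correct = FALSE)
  expect_false(f$converged)
  expect_true("unphysical" %in% f$qc_flags)
})

test_that("fit_recovery errors without recovery frames", {
  t <- seq(0, 600, 60)
  tr <- cell_trace("act_only", t, rep(0.4, length(t)), rep(1, length(t)),
                   rep("activation", length(t)))
  expect_error(fit_recovery(tr), "recovery")
})

test_that("export fits mirror the model and enforce direction", {
  cfg <- synthetic_config(seed = 7, noise_cv = 0, direction = "export",
                          recovery_duration = 2640)
  tr <- generate_cell_trace(list(Ke = 1.5, kI = 1.0, v = 0.3, n0 = 0), cfg)
  f <- fit_export(tr)
  expect_true(f$converged)
  expect_equal(f$kE, 1.0, tolerance = 1e-6)
  expect_equal(f$Ke, 1.5, tolerance = 1e-6)
  expect_true(is.na(f$kI))
  imp <- generate_cell_trace(list(Ke = 2, kI = 1.5, v = 0.3, n0 = 0),
                             clean_import_config(seed = 8))
  expect_error(fit_export(imp), "export-direction")
  expect_error(fit_recovery(tr), "import")
})

test_that("coupled traces round-trip through the aggregate fit", {
  cfg <- synthetic_config(seed = 9, noise_cv = 0)
  ct <- generate_coupled_trace(2, 1, 0.5, cfg)
  f <- fit_recovery(ct, v = 0.5, correct = FALSE)
  r <- rates_from_coupled_fit(f$Ke, f$kI, 0.5)
  expect_equal(unname(r), c(2, 1), tolerance = 1e-6)
  # noisy ensemble: median recovered rates within 5%
  kIs <- kEs <- numeric(100)
  for (i in 1:100) {
    cfg_i <- synthetic_config(seed = 1000 + i, noise_cv = 0.05)
    ct_i <- generate_coupled_trace(2, 1, 0.5, cfg_i)
    f_i <- fit_recovery(ct_i, v = 0.5, correct = FALSE)
    r_i <- rates_from_coupled_fit(f_i$Ke, f_i$kI, 0.5)
    kIs[i] <- r_i["kI"]; kEs[i] <- r_i["kE"]
  }
  expect_lt(abs(median(kIs) / 2 - 1), 0.05)
  expect_lt(abs(median(kEs) / 1 - 1), 0.05)
})

test_that("two coupled channels give the constructed normalized rate", {
  cfg <- synthetic_config(seed = 10, noise_cv = 0)
  ch <- generate_coupled_trace(1.6, 0.8, 0.25, cfg, kI_ref = 2, kE_ref = 1)
  fg <- fit_recovery(ch$gfp, v = 0.25, correct = FALSE)
  fm <- fit_recovery(ch$mcherry, v = 0.25, correct = FALSE)
  rg <- rates_from_coupled_fit(fg$Ke, fg$kI, 0.25)
  rm <- rates_from_coupled_fit(fm$Ke, fm$kI, 0.25)
  expect_equal(normalized_import_rate(rg["kI"], rm["kI"]),
               c(kI = 0.8), tolerance = 1e-6)
})

test_that("trace and fit CSV round trips preserve content", {
  cfg <- clean_import_config(seed = 11)
  trs <- list(generate_cell_trace(list(Ke = 2, kI = 1.5, v = 0.3, n0 = 0),
                                  cfg, cell_id = "a"),
              generate_cell_trace(list(Ke = 1, kI = 1.0, v = 0.3, n0 = 0),
                                  cfg, cell_id = "b", use_seed = FALSE))
  tmp <- tempfile(fileext = ".csv")
  write_traces(trs, tmp)
  back <- read_traces(tmp)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$nuc, trs[[1]]$nuc)
  expect_equal(attr(back$b, "direction"), "import")
  fits <- lapply(trs, fit_recovery)
  tmp2 <- tempfile(fileext = ".csv")
  write_fits(fits, tmp2)
  tab <- read.csv(tmp2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$Ke[1], 2, tolerance = 1e-6)
})
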