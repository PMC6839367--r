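test_that("the phantom regenerates bit-exactly from its configuration", {
  cfg <- phantom_config(n_per_region = 2, n_vessel = 2, seed = 13)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$signal, p2$signal)
  expect_identical(p1$vfa, p2$vfa)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_phantom(phantom_config(n_per_region = 2, n_vessel = 2,
                                        seed = 14))
  expect_false(identical(p1$signal$signal, p3$signal$signal))
})

test_that("generated arterial voxels satisfy the dual-AIF criteria", {
  ph <- generate_phantom(phantom_config(n_per_region = 2, seed = 5))
  cur <- phantom_arterial_curves(ph)
  rep <- check_dual_aif_criteria(cur$pulmonary, cur$systemic)
  expect_true(rep$onset_earlier)
  expect_true(rep$peak_higher)
  expect_true(rep$washout_similar)
})

test_that("the truth table is definitional and survives a CSV round trip", {
  ph <- generate_phantom(phantom_config(n_per_region = 2, n_vessel = 1,
                                        seed = 3))
  tt <- truth_table(ph)
  expect_equal(nrow(tt), 2)
  # derived columns equal derive_parameters applied to the truth
  for (i in seq_len(nrow(tt))) {
    d <- derive_parameters(
      kin_params(tt$model[i], tt$f_over_vp[i], tt$ps_over_vp[i], tt$v_p[i],
                 tt$v_i[i], tt$t_lag[i], tt$gamma[i]),
      physio_constants(h_lv = ph$config$h_lv))
    expect_equal(tt$bf[i], d$bf)
    expect_equal(tt$ktrans[i], d$ktrans)
  }
  path <- withr::local_tempfile(fileext = ".csv")
  truth_table(ph, file = path)
  back <- utils::read.csv(path)
  expect_equal(back$bf, tt$bf, tolerance = 1e-9)
  expect_equal(back$gamma, tt$gamma, tolerance = 1e-9)
})

test_that("a noiseless phantom closes the full measurement loop exactly", {
  ph <- generate_phantom(phantom_config(n_per_region = 1, n_vessel = 1,
                                        noise_sd = 0, seed = 2))
  # T1 mapping recovers each region's native T1
  t1map <- fit_vfa_t1(ph$vfa, ph$acq)
  truth_t1 <- dplyr::distinct(ph$signal, .data$voxel) |>
    dplyr::left_join(dplyr::bind_rows(
      dplyr::distinct(ph$truth, .data$voxel, t1 = 1400)), by = "voxel")
  tumor_rows <- t1map$voxel %in% ph$truth$voxel
  expect_equal(t1map$t1[tumor_rows], rep(1400, sum(tumor_rows)),
               tolerance = 1e-6)
  # signal -> concentration recovers the generating concentration
  conc <- signals_to_concentration(
    dplyr::select(ph$signal, "voxel", "frame", "signal"), t1map, ph$acq)
  j <- dplyr::inner_join(conc, ph$signal[c("voxel", "frame", "conc_true")],
                         by = c("voxel", "frame"))
  expect_lt(max(abs(j$conc - j$conc_true)), 1e-8)
  # kinetic fit initialized at truth recovers the truth
  tr <- ph$truth[1, ]
  d <- dplyr::filter(conc, .data$voxel == tr$voxel)
  fit <- fit_voxel(dplyr::select(d, "t_min", "conc"), ph$inputs, tr$model,
                   fit_config(n_multistart = 1, oversample = 8),
                   start = c(f_over_vp = tr$f_over_vp,
                             ps_over_vp = tr$ps_over_vp, v_p = tr$v_p,
                             v_i = tr$v_i, t_lag = tr$t_lag,
                             gamma = tr$gamma))
  expect_lt(fit$sse, 1e-10)
  expect_equal(fit$params$gamma, tr$gamma, tolerance = 1e-3)
  expect_equal(fit$params$f_over_vp, tr$f_over_vp, tolerance = 1e-3)
})

test_that("baseline concentration noise is mean-zero after conversion", {
  # where the inversion is locally linear (moderate noise), baseline
  # concentrations are mean-zero to well within their own spread
  ph <- generate_phantom(phantom_config(n_per_region = 8, n_vessel = 1,
                                        noise_sd = 0.01, seed = 19))
  t1map <- fit_vfa_t1(ph$vfa, ph$acq)
  conc <- suppressWarnings(signals_to_concentration(
    dplyr::select(ph$signal, "voxel", "frame", "signal"), t1map, ph$acq))
  base <- dplyr::filter(conc, .data$frame <= 8,
                        .data$voxel %in% ph$truth$voxel)
  expect_lt(abs(mean(base$conc)), 0.3 * sd(base$conc))
  expect_lt(abs(mean(base$conc)), 0.005)
  # at high noise the nonlinear inversion leaves only a small (second-order)
  # baseline bias, bounded in absolute terms
  ph2 <- generate_phantom(phantom_config(n_per_region = 8, n_vessel = 1,
                                         noise_sd = 0.05, seed = 19))
  t1map2 <- fit_vfa_t1(ph2$vfa, ph2$acq)
  conc2 <- suppressWarnings(signals_to_concentration(
    dplyr::select(ph2$signal, "voxel", "frame", "signal"), t1map2, ph2$acq))
  base2 <- dplyr::filter(conc2, .data$frame <= 8,
                         .data$voxel %in% ph2$truth$voxel)
  expect_lt(abs(mean(base2$conc)), 0.02)
})

test_that("phantom truth validation rejects impossible regions", {
  bad <- phantom_default_regions()
  bad$v_p[1] <- 0.8
  bad$v_i[1] <- 0.5
  expect_error(phantom_config(regions = bad), class = "dualflow_invalid")
})
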