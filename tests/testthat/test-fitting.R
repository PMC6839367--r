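inp <- test_aif_pair()
tg <- seq(0, 4.3, by = 2 / 60)

test_that("noiseless data fitted from the truth returns the exact optimum", {
  truth <- c(f_over_vp = 3, ps_over_vp = 0.8, v_p = 0.12, v_i = 0.35,
             t_lag = 0.05, gamma = 0.7)
  kp <- kin_params("AATH", truth[1], truth[2], truth[3], truth[4], truth[5],
                   truth[6])
  cfg <- fit_config(n_multistart = 1, seed = 1, oversample = 8)
  conc <- tissue_curve("AATH", kp, inp, tg, oversample = 8)
  fit <- fit_voxel(tibble::tibble(t_min = tg, conc = conc), inp, "AATH",
                   cfg, start = truth)
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-12 * length(tg))
  est <- unlist(unclass(fit$params)[names(truth)])
  expect_equal(unname(est), unname(truth), tolerance = 1e-4)
})

test_that("an all-zero curve is flagged non-enhancing, not fitted", {
  d <- tibble::tibble(t_min = tg, conc = rep(0, length(tg)))
  fit <- fit_voxel(d, inp, "2CX", fit_config(n_multistart = 2))
  expect_false(fit$enhancing)
  expect_true(fit$converged)
  expect_equal(fit$sse, 0)
  expect_equal(fit$params$f_over_vp, fit_config()$bounds$f_over_vp[1])
})

test_that("returned SSE equals the independently recomputed residual", {
  kp <- kin_params("2CX", 5, 1, 0.1, 0.3, 0.05, 0.7)
  conc <- tissue_curve("2CX", kp, inp, tg)
  d <- withr::with_seed(3, tibble::tibble(
    t_min = tg, conc = conc + rnorm(length(tg), 0, 0.05 * max(conc))))
  cfg <- fit_config(n_multistart = 4, seed = 5)
  fit <- fit_voxel(d, inp, "2CX", cfg)
  pred <- tissue_curve("2CX", fit$params, inp, tg,
                       oversample = cfg$oversample)
  expect_equal(fit$sse, sum((pred - d$conc)^2), tolerance = 1e-10)
})

test_that("fits are reproducible and improve with more starts", {
  kp <- kin_params("2CX", 5, 1, 0.1, 0.3, 0.05, 0.7)
  conc <- tissue_curve("2CX", kp, inp, tg)
  d <- withr::with_seed(4, tibble::tibble(
    t_min = tg, conc = conc + rnorm(length(tg), 0, 0.05 * max(conc))))
  f1 <- fit_voxel(d, inp, "2CX", fit_config(n_multistart = 3, seed = 9))
  f2 <- fit_voxel(d, inp, "2CX", fit_config(n_multistart = 3, seed = 9))
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$sse, f2$sse)
  f4 <- fit_voxel(d, inp, "2CX", fit_config(n_multistart = 6, seed = 9))
  expect_lte(f4$sse, f1$sse * (1 + 1e-8))
})

test_that("volume fitting is pure bookkeeping across models and modes", {
  ph <- generate_phantom(phantom_config(protocol = "mpm", n_per_region = 1,
                                        n_vessel = 1, noise_sd = 0.03,
                                        seed = 21))
  tumor <- ph$masks$voxel[ph$masks$type == "tumor"]
  conc <- dplyr::filter(ph$signal, .data$voxel %in% tumor) |>
    dplyr::transmute(voxel = voxel, t_min = t_min, conc = conc_true)
  fits <- fit_voxels(conc, ph$inputs, models = KINETIC_MODELS,
                     modes = c("pulmonary", "systemic", "dual"),
                     config = fit_config(n_multistart = 2, seed = 2,
                                         max_evals = 400))
  expect_equal(nrow(fits), length(tumor) * 5 * 3)
  expect_true(all(is.finite(fits$sse)))
  expect_s3_class(fits, "voxel_fit_set")
  # single-input rows carry the pinned gamma
  expect_true(all(fits$gamma[fits$mode == "pulmonary"] == 1))
  expect_true(all(fits$gamma[fits$mode == "systemic"] == 0))
  expect_error(fit_voxels(conc[0, ], ph$inputs), class = "dualflow_invalid")
})

test_that("regions with distinct pulmonary flow fractions are separated", {
  ph <- generate_phantom(phantom_config(n_per_region = 2, n_vessel = 1,
                                        noise_sd = 0.05, seed = 31))
  tumor <- dplyr::filter(ph$masks, .data$type == "tumor")
  conc <- dplyr::semi_join(ph$signal, tumor, by = "voxel") |>
    dplyr::transmute(voxel = voxel, t_min = t_min, conc = conc_true)
  # clean curves; the shallow gamma ridge needs the full multistart depth
  fits <- fit_voxels(conc, ph$inputs, models = "2CX", modes = "dual",
                     config = fit_config(n_multistart = 8, seed = 6))
  got <- dplyr::inner_join(fits, tumor, by = "voxel") |>
    dplyr::group_by(.data$region) |>
    dplyr::summarize(gamma_hat = mean(.data$gamma), .groups = "drop")
  hi <- got$gamma_hat[got$region == "tumor_high_gamma"]
  lo <- got$gamma_hat[got$region == "tumor_low_gamma"]
  expect_gt(hi - lo, 0.3)
})

test_that("fit configuration validates its bounds", {
  expect_error(fit_config(bounds = list(v_p = c(0.5, 0.1))),
               class = "dualflow_invalid")
  expect_error(fit_config(n_multistart = 0), class = "dualflow_invalid")
  cfg <- fit_config(bounds = list(t_lag = c(0, 0.2)))
  expect_equal(cfg$bounds$t_lag, c(0, 0.2))
  expect_equal(cfg$bounds$v_p, c(0.001, 0.7))
})
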