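ref_params <- aif_params(a_b = 60, mu_b = 6, a_g = 1.0, mu_g = 0.2,
                         t_onset = 0.1, tau_rc = 0.25, kappa_rc = 0.3)

test_that("two-pass AIF matches an independent sum-of-terms evaluation", {
  tt <- seq(0, 5, by = 0.01)
  expect_lt(max(abs(eval_aif(ref_params, tt) - oracle_aif(ref_params, tt))),
            1e-12)
})

test_that("AIF is zero before onset and reduces to a single pass", {
  expect_equal(eval_aif(ref_params, seq(0, 0.099, by = 0.01)),
               rep(0, 10))
  p0 <- aif_params(60, 6, 1.0, 0.2, t_onset = 0.1, tau_rc = 0.25,
                   kappa_rc = 0)
  tt <- seq(0, 5, by = 0.05)
  one_pass <- function(u) ifelse(u >= 0, 60 * u * exp(-6 * u) +
                                   1.0 * (exp(-0.2 * u) - exp(-6 * u)), 0)
  expect_equal(eval_aif(p0, tt), one_pass(tt - 0.1), tolerance = 1e-14)
})

test_that("AIF parameter validation enforces the documented invariants", {
  expect_error(aif_params(60, 0.1, 1, 0.2), class = "dualflow_invalid")
  expect_error(aif_params(-1, 6, 1, 0.2), class = "dualflow_invalid")
  expect_error(aif_params(60, 6, 1, 0.2, kappa_rc = 1.5),
               class = "dualflow_invalid")
})

test_that("AIF integrates finitely, matching the analytic integral", {
  quad <- integrate(function(t) eval_aif(ref_params, t), 0, Inf,
                    rel.tol = 1e-10)$value
  analytic <- (1 + ref_params$kappa_rc) *
    (ref_params$a_b / ref_params$mu_b^2 +
       ref_params$a_g * (1 / ref_params$mu_g - 1 / ref_params$mu_b))
  expect_equal(quad, analytic, tolerance = 1e-6)
})

test_that("AIF fitting recovers known parameters from a noiseless curve", {
  tt <- seq(0, 4.3, by = 2 / 60)
  d <- tibble::tibble(t_min = tt, conc = eval_aif(ref_params, tt))
  fit <- fit_aif(d, n_starts = 8, seed = 1)
  truth <- unlist(unclass(ref_params))
  est <- unlist(unclass(fit$params))[names(truth)]
  expect_true(all(abs(est - truth) / pmax(abs(truth), 1e-6) < 0.02))
  expect_lt(fit$sse, 1e-10 * length(tt))
})

test_that("degenerate arterial curves are rejected with diagnostics", {
  tt <- seq(0, 4.3, by = 2 / 60)
  expect_error(fit_aif(tibble::tibble(t_min = tt, conc = rep(0, length(tt)))),
               class = "dualflow_flat_curve")
  expect_error(fit_aif(tibble::tibble(t_min = tt[1:5], conc = 1:5)),
               class = "dualflow_invalid")
})

test_that("fitted AIF peak is robust to noise across replicates", {
  tt <- seq(0, 4.3, by = 2 / 60)
  clean <- eval_aif(ref_params, tt)
  peak_true <- max(clean)
  errs <- withr::with_seed(7, {
    vapply(1:100, function(i) {
      d <- tibble::tibble(t_min = tt,
                          conc = clean + rnorm(length(tt), 0, 0.05 * peak_true))
      fit <- fit_aif(d, n_starts = 2, seed = i)
      abs(max(eval_aif(fit$params, tt)) - peak_true) / peak_true
    }, numeric(1))
  })
  expect_lt(median(errs), 0.05)
})

test_that("dual-AIF quality criteria flag the documented failure modes", {
  tt <- seq(0, 4.3, by = 2 / 60)
  pa <- tibble::tibble(t_min = tt,
                       conc = oracle_aif(aif_params(90, 6, 1.2, 0.15, 0.10), tt))
  ao <- tibble::tibble(t_min = tt,
                       conc = oracle_aif(aif_params(60, 6, 1.2, 0.15, 0.15), tt))
  rep <- check_dual_aif_criteria(pa, ao)
  expect_true(rep$onset_earlier)
  expect_true(rep$peak_higher)
  expect_true(rep$washout_similar)
  expect_true(rep$all_pass)

  same <- check_dual_aif_criteria(pa, pa)
  expect_false(same$onset_earlier)   # not strictly earlier

  ao_big <- dplyr::mutate(pa, conc = 2 * conc)
  rep2 <- check_dual_aif_criteria(pa, ao_big)
  expect_false(rep2$peak_higher)
})

test_that("net plasma input follows the hematocrit-corrected mixing rule", {
  pa <- aif_params(90, 6, 1.2, 0.15, 0.10)
  ao <- aif_params(65, 5.5, 1.2, 0.15, 0.18)
  tt <- seq(0, 4, by = 0.1)
  inp <- dual_input(pa, ao, mode = "dual", h_lv = 0.45)
  expect_equal(net_plasma_input(inp, 1, tt), eval_aif(pa, tt) / 0.55,
               tolerance = 1e-14)
  expect_equal(net_plasma_input(inp, 0, tt), eval_aif(ao, tt) / 0.55,
               tolerance = 1e-14)
  # worked arithmetic identity at gamma = 0.5 with C_PA = 2, C_A = 1 mM
  expect_equal((0.5 * 2 + 0.5 * 1) / (1 - 0.45), 2.727272727, tolerance = 1e-9)
  # affine in gamma at fixed t
  g <- seq(0, 1, by = 0.25)
  vals <- vapply(g, function(gg) net_plasma_input(inp, gg, 2), numeric(1))
  expect_equal(diff(vals, differences = 2), rep(0, 3), tolerance = 1e-12)
  expect_error(net_plasma_input(inp, 1.2, tt), class = "dualflow_invalid")
  # single-input modes pin gamma
  inp_pa <- dual_input(pa, ao, mode = "pulmonary")
  expect_equal(net_plasma_input(inp_pa, NA, tt), eval_aif(pa, tt) / 0.55)
})

test_that("bolus arrival detection finds the first sustained rise", {
  conc <- c(rep(0, 10), 0.05, 2, 5, 6, 4, 3)
  expect_equal(detect_bolus_arrival(conc), 11L)
  expect_true(is.na(detect_bolus_arrival(rep(0, 20))))
})
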