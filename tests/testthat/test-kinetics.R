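# small parameter grid shared by the residue property tests
res_grid <- tidyr::crossing(f_over_vp = c(0.5, 2, 8),
                            ps_over_vp = c(0, 1, 5),
                            v_p = c(0.05, 0.2),
                            v_i = c(0.1, 0.5))

test_that("vascular-phase residues start at 1 and never increase", {
  tt <- seq(0, 6, length.out = 400)
  for (i in seq_len(nrow(res_grid))) {
    g <- res_grid[i, ]
    for (m in c("2CX", "AATH", "DP")) {
      kp <- kin_params(m, g$f_over_vp, g$ps_over_vp, g$v_p, g$v_i)
      r <- residue_function(m, kp, tt)
      expect_equal(r[1], 1, tolerance = 1e-9)
      expect_true(all(diff(r) <= 1e-9))
      expect_true(all(r >= -1e-12))
    }
  }
})

test_that("residue integral equals the transit-time identity (vp+vi)/ft", {
  # the identity needs an exchanging interstitium: with PS = 0 the tracer
  # never samples v_i and the integral is v_p/f_t instead
  grid <- dplyr::filter(res_grid, ps_over_vp > 0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expected <- (g$v_p + g$v_i) / (g$f_over_vp * g$v_p)
    for (m in c("2CX", "AATH", "DP")) {
      kp <- kin_params(m, g$f_over_vp, g$ps_over_vp, g$v_p, g$v_i)
      # finite horizon chosen where the residue has decayed to ~0, and the
      # narrow vascular plateau integrated as its own piece so adaptive
      # quadrature cannot step over it
      tc <- 1 / g$f_over_vp
      upper <- tc + 1
      while (residue_function(m, kp, upper) > 1e-9 && upper < 1e4)
        upper <- upper * 2
      got <- integrate(function(t) residue_function(m, kp, t), 0, tc,
                       subdivisions = 500L, rel.tol = 1e-7)$value +
        integrate(function(t) residue_function(m, kp, t), tc, upper,
                  subdivisions = 2000L, rel.tol = 1e-6)$value
      expect_lt(abs(got - expected) / expected, 0.005)
    }
  }
})

test_that("2CX residue matches step-by-step integration of the mass balance", {
  kp <- kin_params("2CX", 5, 1, 0.1, 0.3)
  expect_equal(residue_function("2CX", kp, 1),
               oracle_residue_2cx_rk4(5, 1, 0.1, 0.3, 1, dt = 1e-4),
               tolerance = 1e-8)
  tt <- seq(0, 5, by = 0.02)
  expect_lt(max(abs(residue_function("2CX", kp, tt) -
                      oracle_residue_2cx(5, 1, 0.1, 0.3, tt))), 1e-9)
})

test_that("DP residue matches the finite-volume capillary solution", {
  o <- oracle_residue_dp(5, 1, 0.1, 0.3, t_max = 5, n_seg = 200)
  kp <- kin_params("DP", 5, 1, 0.1, 0.3)
  expect_lt(max(abs(residue_function("DP", kp, o$t) - o$r)), 0.01)
})

test_that("limit cases of the residues behave as documented", {
  # AATH with no extraction: pure intravascular transit, zero after Tc
  kp <- kin_params("AATH", 5, 0, 0.1, 0.3)
  tc <- 0.1 / (5 * 0.1)
  expect_equal(residue_function("AATH", kp, c(tc + 1e-9, 1, 3)), rep(0, 3))
  expect_equal(residue_function("AATH", kp, tc * 0.999), 1)
  # 2CX at t -> 0+ keeps all tracer
  kp2 <- kin_params("2CX", 2, 0.5, 0.15, 0.4)
  expect_equal(residue_function("2CX", kp2, 1e-12), 1, tolerance = 1e-9)
  # ps = 0 handled as E = 0 without division errors
  expect_equal(residue_function("TK", kin_params("TK", 2, 0, 0.1, 0.3), 1), 0)
  expect_error(residue_function("XX", kp2, 1))
})

test_that("derived parameters reproduce the hand-computed conversions", {
  p <- kin_params("2CX", f_over_vp = 2, ps_over_vp = 0.5, v_p = 0.1,
                  v_i = 0.3)
  d <- derive_parameters(p, physio_constants(h_lv = 0.45, h_sv = 0.25,
                                             rho = 1),
                         mode = "pulmonary")
  expect_equal(d$bf, 36.3636, tolerance = 1e-4)
  expect_equal(d$ps, 5)
  expect_equal(d$ktrans, (1 - exp(-0.25)) * 0.2, tolerance = 1e-9)
  expect_equal(d$ktrans, 0.04424, tolerance = 1e-3)
  expect_equal(d$mtt, 0.4 / 0.2)
  expect_equal(d$bv, 0.1 / 0.75 * 100)
  # flow partition at the single-input limits
  p2 <- kin_params("2CX", 2, 0.5, 0.1, 0.3, gamma = 1)
  d2 <- derive_parameters(p2)
  expect_equal(d2$bf_a, 0)
  expect_equal(d2$bf_pa, d2$bf)
  # gamma must come from somewhere
  expect_error(derive_parameters(p), class = "dualflow_invalid")
})

test_that("Ktrans decomposition is consistent with published medians", {
  # dual-supply two-compartment exchange medians for lung tumors:
  # BF 27.65 and PS 2.404 mL/min/100g imply Ktrans = E * f_t of the same
  # order as the printed 0.021 mL/min/mL (medians do not commute exactly)
  f_t <- 27.65 * (1 - 0.45) / 100
  ps_t <- 2.404 / 100
  ktrans <- (1 - exp(-ps_t / f_t)) * f_t
  expect_lt(abs(ktrans - 0.021) / 0.021, 0.25)
})

test_that("tissue curves obey linearity and the single-input reductions", {
  inp <- test_aif_pair()
  tg <- seq(0, 4.3, by = 2 / 60)
  kp <- kin_params("2CX", 5, 1, 0.1, 0.3, t_lag = 0.05, gamma = 1)
  ct_dual <- tissue_curve("2CX", kp, inp, tg)
  ct_pa <- tissue_curve("2CX", kin_params("2CX", 5, 1, 0.1, 0.3, 0.05),
                        test_aif_pair("pulmonary"), tg)
  expect_lt(max(abs(ct_dual - ct_pa)), 1e-12)

  kp0 <- kin_params("2CX", 5, 1, 0.1, 0.3, 0.05, gamma = 0)
  ct_ao <- tissue_curve("2CX", kin_params("2CX", 5, 1, 0.1, 0.3, 0.05),
                        test_aif_pair("systemic"), tg)
  expect_lt(max(abs(tissue_curve("2CX", kp0, inp, tg) - ct_ao)), 1e-12)

  # zero AIF -> zero curve
  null_aif <- aif_params(0, 6, 0, 0.2)
  inp0 <- dual_input(null_aif, null_aif, "dual")
  expect_equal(tissue_curve("2CX", kp, inp0, tg), rep(0, length(tg)))

  # linearity in AIF amplitude
  pa2 <- aif_params(180, 6, 2.4, 0.15, 0.10, 0.25, 0.3)
  ao2 <- aif_params(72, 4, 2.4, 0.15, 0.18, 0.25, 0.3)
  inp2 <- dual_input(pa2, ao2, "dual")
  kp7 <- kin_params("2CX", 5, 1, 0.1, 0.3, 0.05, 0.7)
  expect_equal(tissue_curve("2CX", kp7, inp2, tg),
               2 * tissue_curve("2CX", kp7, inp, tg), tolerance = 1e-10)
})

test_that("ETK's intravascular term is analytic and vanishes with vp", {
  inp <- test_aif_pair()
  tg <- seq(0, 4.3, by = 2 / 60)
  f_t <- 0.3; ps_t <- 0.06
  # ETK equals its interstitial part plus vp * lagged plasma input, exactly
  vp <- 0.05
  etk <- tissue_curve("ETK", kin_params("ETK", f_t / vp, ps_t / vp, vp, 0.3,
                                        0.05, 0.7), inp, tg)
  tk_like <- tissue_curve("TK", kin_params("TK", f_t / vp, ps_t / vp, vp, 0.3,
                                           0.05, 0.7), inp, tg)
  delta_term <- vp * net_plasma_input(inp, 0.7, tg - 0.05) * (tg >= 0)
  expect_equal(etk - tk_like, delta_term, tolerance = 1e-12)

  # as vp -> 0 at fixed f_t and ps_t, ETK converges to TK
  vps <- c(0.01, 2e-4)
  errs <- vapply(vps, function(vp0) {
    tk_ref <- tissue_curve("TK", kin_params("TK", f_t / vp0, ps_t / vp0,
                                            vp0, 0.3, 0.05, 0.7), inp, tg)
    etk_small <- tissue_curve("ETK", kin_params("ETK", f_t / vp0, ps_t / vp0,
                                                vp0, 0.3, 0.05, 0.7), inp, tg)
    max(abs(etk_small - tk_ref)) / max(tk_ref)
  }, numeric(1))
  expect_lt(errs[2], 0.01)
  expect_lt(errs[2], errs[1])  # convergence as vp shrinks
})

test_that("high-permeability limits collapse to flow-limited kinetics", {
  inp <- test_aif_pair()
  tg <- seq(0, 4.3, by = 2 / 60)
  # E -> 1 as PS -> infinity
  r <- dualflow:::kin_rates(kin_params("AATH", 2, 1e4, 0.1, 0.4))
  expect_equal(r$e, 1, tolerance = 1e-12)
  # 2CX tissue curve approaches the one-compartment flow-limited curve
  kp_hi <- kin_params("2CX", 2, 45, 0.1, 0.4, 0, 0.7)
  ct_hi <- tissue_curve("2CX", kp_hi, inp, tg)
  f_t <- 0.2
  flow_limited <- function(u) ifelse(u >= 0, exp(-f_t * u / 0.5), 0)
  cin <- function(u) oracle_net_input(inp, 0.7, u)
  ref <- oracle_conv(function(u) f_t * flow_limited(u), cin, tg)
  expect_lt(max(abs(ct_hi - ref)) / max(ref), 0.05)
  # and tightens as PS grows (checked against the AATH E = 1 form too)
  kp_aath <- kin_params("AATH", 2, 45, 0.1, 0.4, 0, 0.7)
  ct_aath <- tissue_curve("AATH", kp_aath, inp, tg)
  q_fun <- function(u) f_t * oracle_residue_aath(2, 45, 0.1, 0.4, u)
  ref_aath <- oracle_conv(q_fun, cin, tg, breaks = 0.1 / f_t)
  expect_lt(max(abs(ct_aath - ref_aath)) / max(ref_aath), 0.001)
})

test_that("forward evaluation is grid-independent at the default setting", {
  inp <- test_aif_pair()
  tg <- seq(0, 4.3, by = 2 / 60)
  for (m in KINETIC_MODELS) {
    kp <- kin_params(m, 5, 1, 0.1, 0.3, 0.05, 0.7)
    c1 <- tissue_curve(m, kp, inp, tg, oversample = 8)
    c2 <- tissue_curve(m, kp, inp, tg, oversample = 32)
    expect_lt(max(abs(c1 - c2)) / max(c1), 0.001)
  }
})
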