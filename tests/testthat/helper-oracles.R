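# Independent oracles for the forward models.  Everything here is coded
# directly from the defining equations (sum of terms, ODE mass balance,
# upwind finite-volume PDE, brute-force quadrature convolution) and shares
# no numerical machinery with the package implementation.

# two-pass AIF as a literal sum of terms
oracle_aif <- function(p, t) {
  one_pass <- function(u) {
    ifelse(u >= 0,
           p$a_b * u * exp(-p$mu_b * u) +
             p$a_g * (exp(-p$mu_g * u) - exp(-p$mu_b * u)),
           0)
  }
  one_pass(t - p$t_onset) + p$kappa_rc * one_pass(t - p$t_onset - p$tau_rc)
}

# mixed plasma input of the dual-supply model
oracle_net_input <- function(inputs, gamma, t) {
  (gamma * oracle_aif(inputs$pulmonary, t) +
     (1 - gamma) * oracle_aif(inputs$systemic, t)) / (1 - inputs$h_lv)
}

# 2CX residue by numerical integration of the two-compartment mass balance
# (impulse deposited in plasma at t = 0); deSolve's lsoda, tight tolerances
oracle_residue_2cx <- function(f_over_vp, ps_over_vp, v_p, v_i, t_out) {
  f_t <- f_over_vp * v_p
  ps_t <- ps_over_vp * v_p
  rhs <- function(t, y, parms) {
    dcp <- (-(f_t + ps_t) * y[1] + ps_t * y[2]) / v_p
    dci <- if (v_i > 0) ps_t * (y[1] - y[2]) / v_i else 0
    list(c(dcp, dci))
  }
  tt <- sort(unique(c(0, t_out)))
  sol <- deSolve::lsoda(c(cp = 1 / v_p, ci = 0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  r <- v_p * sol[, "cp"] + v_i * sol[, "ci"]
  r[match(t_out, tt)]
}

# fourth-order Runge-Kutta version for single-point spot checks
oracle_residue_2cx_rk4 <- function(f_over_vp, ps_over_vp, v_p, v_i, t_end,
                                   dt = 1e-4) {
  f_t <- f_over_vp * v_p
  ps_t <- ps_over_vp * v_p
  deriv <- function(y) {
    c((-(f_t + ps_t) * y[1] + ps_t * y[2]) / v_p,
      if (v_i > 0) ps_t * (y[1] - y[2]) / v_i else 0)
  }
  y <- c(1 / v_p, 0)
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v_p * y[1] + v_i * y[2]
}

# DP residue by finite-volume integration of the plug-flow capillary with
# distributed exchange:
#   v_p dCp/dt + f_t dCp/ds = ps_t (Ci - Cp),  v_i dCi/dt = ps_t (Cp - Ci)
# on s in [0, 1]; an impulse enters the inlet at t = 0.  Advection is
# advanced at unit CFL (dt = ds / f_over_vp), where the upwind shift is the
# exact transport operator, and the pointwise exchange system is advanced
# with its exact matrix exponential in a Strang split, so the scheme has no
# numerical diffusion at the plug front.  Returns R(t) on the scheme's own
# time grid as list(t, r).
oracle_residue_dp <- function(f_over_vp, ps_over_vp, v_p, v_i, t_max,
                              n_seg = 400) {
  f_t <- f_over_vp * v_p
  ps_t <- ps_over_vp * v_p
  ds <- 1 / n_seg
  dt <- ds / f_over_vp
  n_steps <- ceiling(t_max / dt)
  cp <- numeric(n_seg)
  ci <- numeric(n_seg)
  cp[1] <- 1 / (v_p * ds)
  vtot <- v_p + v_i
  mu <- if (v_i > 0) ps_t / v_p + ps_t / v_i else 0
  decay_half <- exp(-mu * dt / 2)
  exchange_half <- function() {
    if (v_i <= 0 || ps_t <= 0) return()
    m <- v_p * cp + v_i * ci
    q <- (cp - ci) * decay_half
    cp <<- m / vtot + v_i / vtot * q
    ci <<- m / vtot - v_p / vtot * q
  }
  r <- numeric(n_steps + 1)
  r[1] <- sum(v_p * cp + v_i * ci) * ds
  for (k in seq_len(n_steps)) {
    exchange_half()
    cp <- c(0, cp[-n_seg])        # exact advection by one cell at CFL = 1
    exchange_half()
    r[k + 1] <- sum(v_p * cp + v_i * ci) * ds
  }
  list(t = (0:n_steps) * dt, r = r)
}

# independently coded closed-form residues for the compartmental models
oracle_residue_tk <- function(f_over_vp, ps_over_vp, v_p, v_i, t) {
  f_t <- f_over_vp * v_p
  ps_t <- ps_over_vp * v_p
  e <- 1 - exp(-ps_t / f_t)
  ktrans <- e * f_t
  ifelse(t >= 0, e * exp(-ktrans * t / v_i), 0)
}

oracle_residue_aath <- function(f_over_vp, ps_over_vp, v_p, v_i, t) {
  f_t <- f_over_vp * v_p
  ps_t <- ps_over_vp * v_p
  e <- 1 - exp(-ps_t / f_t)
  tc <- v_p / f_t
  ifelse(t < 0, 0,
         ifelse(t < tc, 1, e * exp(-e * f_t * (t - tc) / v_i)))
}

# brute-force quadrature convolution: for each output time, integrate
# q(u) * cin(t - u) du on sub-grids split at the residue's breakpoints so a
# plug-flow discontinuity never straddles a quadrature cell
oracle_conv <- function(q_fun, cin_fun, t_out, breaks = numeric(0),
                        dt = 1 / 600) {
  vapply(t_out, function(tk) {
    if (tk <= 0) return(0)
    edges <- sort(unique(c(0, breaks[breaks > 0 & breaks < tk], tk)))
    total <- 0
    for (j in seq_len(length(edges) - 1)) {
      a <- edges[j]; b <- edges[j + 1]
      m <- max(2L, ceiling((b - a) / dt) + 1L)
      u <- seq(a, b, length.out = m)
      # evaluate just inside the piece so one-sided limits are used at jumps
      eps <- (b - a) * 1e-9
      uq <- pmin(pmax(u, a + eps), b - eps)
      y <- q_fun(uq) * cin_fun(tk - u)
      h <- (b - a) / (m - 1)
      total <- total + h * (sum(y) - (y[1] + y[m]) / 2)
    }
    total
  }, numeric(1))
}

# standard AIF pair + inputs used across kinetic tests; the aortic bolus is
# delayed and dispersed relative to the pulmonary trunk (transpulmonary
# passage widens the first pass), which is also what makes the pulmonary
# flow fraction identifiable
test_aif_pair <- function(mode = "dual", h_lv = 0.45) {
  dual_input(
    aif_params(a_b = 90, mu_b = 6, a_g = 1.2, mu_g = 0.15,
               t_onset = 0.10, tau_rc = 0.25, kappa_rc = 0.3),
    aif_params(a_b = 36, mu_b = 4, a_g = 1.2, mu_g = 0.15,
               t_onset = 0.18, tau_rc = 0.25, kappa_rc = 0.3),
    mode = mode, h_lv = h_lv
  )
}
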