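#' Kinetic fitting parameters
#'
#' The per-voxel fitting vector shared by all five kinetic models so that
#' every model has the same complexity: plasma flow and permeability-surface
#' product per unit plasma volume, the plasma and interstitial volume
#' fractions, the bolus-arrival lag of the tissue, and (dual input only) the
#' pulmonary flow fraction.
#'
#' Derived per-tissue rates used throughout: plasma flow per tissue volume
#' `f_t = f_over_vp * v_p` (min^-1), permeability-surface product per tissue
#' volume `ps_t = ps_over_vp * v_p` (min^-1), capillary transit time
#' `Tc = v_p / f_t`, and extraction fraction `E = 1 - exp(-ps_t / f_t)`
#' (Renkin-Crone).
#'
#' @param model One of `"TK"`, `"ETK"`, `"2CX"`, `"AATH"`, `"DP"`.
#' @param f_over_vp Plasma flow per plasma volume, F/V_P (min^-1), > 0.
#' @param ps_over_vp Permeability-surface product per plasma volume (min^-1),
#'   >= 0.
#' @param v_p Plasma volume fraction in (0, 1).
#' @param v_i Interstitial volume fraction in `[0, 1)`; `v_p + v_i < 1`.
#' @param t_lag Bolus arrival lag of the tissue (min), >= 0.
#' @param gamma Pulmonary flow fraction in `[0, 1]`; `NA` for single-input use.
#' @return An object of class `kin_params`.
#' @export
#' @examples
#' kin_params("2CX", f_over_vp = 5, ps_over_vp = 1, v_p = 0.1, v_i = 0.3)
kin_params <- function(model, f_over_vp, ps_over_vp, v_p, v_i,
                       t_lag = 0, gamma = NA_real_) {
  model <- match.arg(model, KINETIC_MODELS)
  if (!is.finite(f_over_vp) || f_over_vp <= 0)
    abort("f_over_vp must be > 0 (min^-1).", class = "dualflow_invalid")
  if (!is.finite(ps_over_vp) || ps_over_vp < 0)
    abort("ps_over_vp must be >= 0 (min^-1).", class = "dualflow_invalid")
  if (!is.finite(v_p) || v_p <= 0 || v_p >= 1)
    abort("v_p must lie in (0, 1).", class = "dualflow_invalid")
  if (!is.finite(v_i) || v_i < 0 || v_i >= 1)
    abort("v_i must lie in [0, 1).", class = "dualflow_invalid")
  if (v_p + v_i >= 1)
    abort("v_p + v_i must be < 1.", class = "dualflow_invalid")
  if (!is.finite(t_lag) || t_lag < 0)
    abort("t_lag must be >= 0 (min).", class = "dualflow_invalid")
  if (!is.na(gamma) && (gamma < 0 || gamma > 1))
    abort("gamma must lie in [0, 1].", class = "dualflow_invalid")
  structure(list(model = model, f_over_vp = f_over_vp,
                 ps_over_vp = ps_over_vp, v_p = v_p, v_i = v_i,
                 t_lag = t_lag, gamma = gamma),
            class = "kin_params")
}

#' @export
print.kin_params <- function(x, ...) {
  cat(sprintf("<kin_params> %s F/Vp=%.3g PS/Vp=%.3g vp=%.3g vi=%.3g tlag=%.3g gamma=%s\n",
              x$model, x$f_over_vp, x$ps_over_vp, x$v_p, x$v_i, x$t_lag,
              ifelse(is.na(x$gamma), "NA", format(x$gamma, digits = 3))))
  invisible(x)
}

# per-tissue rates used everywhere
kin_rates <- function(params) {
  f_t <- params$f_over_vp * params$v_p
  ps_t <- params$ps_over_vp * params$v_p
  e <- 1 - exp(-ps_t / f_t)          # -> 0 cleanly when ps_t = 0
  list(f_t = f_t, ps_t = ps_t, e = e, tc = params$v_p / f_t)
}

# 2CX biexponential residue: exact solution of the well-mixed two-compartment
# mass balance for an impulse deposited in plasma.
residue_2cx <- function(params, t) {
  r <- kin_rates(params)
  vp <- params$v_p; vi <- params$v_i
  kp <- (r$f_t + r$ps_t) / vp
  ke <- if (vi > 0) r$ps_t / vi else 0
  tr_m <- -(kp + ke)
  det_m <- r$f_t * r$ps_t / (vp * max(vi, .Machine$double.xmin))
  if (vi == 0) det_m <- 0
  disc <- tr_m^2 - 4 * det_m
  rp0 <- -r$f_t / vp                 # R'(0)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  if (disc > 1e-12 * tr_m^2) {
    sq <- sqrt(disc)
    l1 <- (tr_m + sq) / 2
    l2 <- (tr_m - sq) / 2
    a <- (rp0 - l2) / (l1 - l2)
    out[pos] <- a * exp(l1 * tp) + (1 - a) * exp(l2 * tp)
  } else {
    l <- tr_m / 2                    # (near-)repeated root
    out[pos] <- exp(l * tp) * (1 + (rp0 - l) * tp)
  }
  out
}

# DP tail residue for s = t - Tc >= 0 (Sangren-Sheppard form):
# R(Tc + s) = 1 - e^-a - e^-a * int_0^s g(u) du,
# g(u) = sqrt(ab/u) e^{-bu} I1(2 sqrt(abu)), a = PS/F, b = ps_t/v_i.
# The integral is accumulated by trapezoid on the supplied (fine) grid, with
# the exact limit g(0+) = ab at the origin.
dp_tail_residue <- function(params, s) {
  r <- kin_rates(params)
  a <- r$ps_t / r$f_t
  b <- if (params$v_i > 0) r$ps_t / params$v_i else 0
  if (a == 0 || b == 0) return(rep(0, length(s)))
  g <- function(u) {
    out <- rep(a * b, length(u))
    pos <- u > 0
    up <- u[pos]
    x <- 2 * sqrt(a * b * up)
    # scaled Bessel keeps large arguments finite: I1(x) = e^x * besselI(,scaled)
    out[pos] <- sqrt(a * b / up) * exp(-b * up + x) * besselI(x, 1, expon.scaled = TRUE)
    out
  }
  stopifnot(!is.unsorted(s))
  n <- length(s)
  s_max <- s[n]
  # accumulate on the caller's grid when it is already fine (the forward
  # model's convolution grid); otherwise integrate the complementary tail
  # int_s^inf g on an internal grid, which avoids the 1 - e^-a(1 + cum)
  # cancellation that destroys small residue values at large PS/F
  if (n > 512 && s[1] < 1e-9 && s_max / n < 1e-2) {
    gv <- g(s)
    cum <- c(0, cumsum(diff(s) * (gv[-1] + gv[-n]) / 2))
    return(pmax(1 - exp(-a) * (1 + cum), 0))
  }
  s_far <- max(s_max, (sqrt(a) + 7)^2 / b, 1e-9)
  sf <- seq(0, s_far, length.out = 8192)
  gf <- g(sf)
  seg <- diff(sf) * (gf[-1] + gf[-length(sf)]) / 2
  tail_int <- c(rev(cumsum(rev(seg))), 0)   # int_{sf_i}^{s_far} g
  pmax(exp(-a) * approx(sf, tail_int, xout = pmin(s, s_far))$y, 0)
}

#' Tissue residue functions of the five kinetic models
#'
#' Returns the continuous part of the tissue residue function R_T(t) (the
#' fraction of an arterial impulse still in tissue at time t); the total
#' impulse response is `Q_T(t) = f_t * R_T(t)`.  For the extended Tofts-Kety
#' model the intravascular delta term is not representable pointwise and is
#' added analytically by [tissue_curve()]; here ETK returns its continuous
#' (interstitial) component, identical in form to TK.
#'
#' Model forms (f_t, ps_t, E, Tc as in [kin_params()]):
#' * `TK`: `E * exp(-E f_t t / v_i)` (distribution volume v_i alone; v_p
#'   enters only through f_t and ps_t).
#' * `ETK`: continuous part `E * exp(-E f_t t / v_i)`; plus `v_p delta(t)`.
#' * `2CX`: biexponential solution of the two-compartment exchange ODEs.
#' * `AATH`: 1 for `t < Tc`; `E * exp(-E f_t (t - Tc)/v_i)` for `t >= Tc`.
#' * `DP`: 1 for `t < Tc`; plug-flow capillary with distributed exchange
#'   (Bessel-integral solution) for `t >= Tc`.
#'
#' @param model Model tag; see [kin_params()].
#' @param params A [kin_params()] object (its own `model` field is ignored in
#'   favor of `model`).
#' @param t Times (minutes), non-decreasing for `"DP"`.
#' @return Dimensionless residue values, zero for `t < 0`.
#' @export
residue_function <- function(model, params, t) {
  model <- match.arg(model, KINETIC_MODELS)
  stopifnot(inherits(params, "kin_params"))
  r <- kin_rates(params)
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  kep <- if (params$v_i > 0) r$e * r$f_t / params$v_i else Inf
  out[pos] <- switch(
    model,
    TK = ,
    ETK = if (is.finite(kep)) r$e * exp(-kep * tp) else 0 * tp,
    `2CX` = residue_2cx(params, tp),
    AATH = ifelse(tp < r$tc, 1,
                  if (is.finite(kep)) r$e * exp(-kep * (tp - r$tc)) else 0),
    DP = {
      v <- numeric(length(tp))
      v[tp < r$tc] <- 1
      late <- which(tp >= r$tc)
      if (length(late) > 0) {
        ord <- late[order(tp[late])]     # cumulative Bessel integral needs
        v[ord] <- dp_tail_residue(params, tp[ord] - r$tc)  # sorted times
      }
      v
    }
  )
  out
}
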