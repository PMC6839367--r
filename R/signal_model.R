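#' Spoiled gradient-echo steady-state signal
#'
#' Evaluates the SPGR equation
#' \deqn{S(\alpha) = M_0 \sin\alpha \, (1 - E_1) / (1 - E_1\cos\alpha),
#'   \quad E_1 = e^{-TR/T_1}.}
#' Vectorized over every argument.
#'
#' @param t1 Longitudinal relaxation time (ms).
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @param fa_deg Flip angle (degrees).
#' @param tr Repetition time (ms).
#' @return Signal intensity, same units as `m0`.
#' @export
spgr_signal <- function(t1, m0, fa_deg, tr) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Longitudinal relaxation time of tissue carrying contrast agent
#'
#' Fast-exchange linear model: 1/T1(C) = 1/T1_native + r1 C, with T1 in ms
#' and r1 in s^-1 mM^-1.
#'
#' @param conc Contrast agent concentration (mM).
#' @param t1_native Native T1 (ms).
#' @param r1 Longitudinal relaxivity (s^-1 mM^-1).
#' @return T1 (ms).
#' @export
t1_with_contrast <- function(conc, t1_native, r1) {
  1000 / (1000 / t1_native + r1 * conc)
}

#' Forward-simulate a dynamic SPGR signal from a concentration series
#'
#' @param conc Concentration series (mM).
#' @param t1_native Native T1 (ms).
#' @param m0 Equilibrium magnetization.
#' @param acq An [acq_params()] object; the dynamic flip angle and TR are used.
#' @return Signal series, same length as `conc`.
#' @export
concentration_to_signal <- function(conc, t1_native, m0, acq) {
  stopifnot(inherits(acq, "acq_params"))
  spgr_signal(t1_with_contrast(conc, t1_native, acq$r1), m0, acq$fa_deg, acq$tr)
}

# single-voxel VFA estimate; returns list(t1, m0, flagged, rss)
vfa_fit_one <- function(signal, fa_deg, tr, refine = TRUE) {
  # an (almost) identical signal at every angle has no SPGR solution
  if (diff(range(signal)) <= 1e-9 * max(abs(signal), 1e-300)) {
    return(list(t1 = NA_real_, m0 = NA_real_, flagged = TRUE, rss = NA_real_))
  }
  a <- fa_deg * pi / 180
  # linearization: S/sin(a) = E1 * S/tan(a) + M0 (1 - E1)
  y <- signal / sin(a)
  x <- signal / tan(a)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= .Machine$double.eps * sum(x^2)) {
    return(list(t1 = NA_real_, m0 = NA_real_, flagged = TRUE, rss = NA_real_))
  }
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icpt <- mean(y) - slope * mean(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1 || icpt <= 0) {
    return(list(t1 = NA_real_, m0 = NA_real_, flagged = TRUE, rss = NA_real_))
  }
  t1 <- -tr / log(slope)
  m0 <- icpt / (1 - slope)
  if (refine) {
    # nonlinear least squares on log-parameters against the same equation
    obj <- function(p) {
      s_hat <- spgr_signal(exp(p[1]), exp(p[2]), fa_deg, tr)
      sum((s_hat - signal)^2)
    }
    opt <- tryCatch(
      nlminb(c(log(t1), log(m0)), obj,
             lower = c(log(1), log(1e-12)), upper = c(log(1e5), log(1e12))),
      error = function(e) NULL
    )
    if (!is.null(opt) && is.finite(opt$objective)) {
      t1 <- exp(opt$par[1])
      m0 <- exp(opt$par[2])
      rss <- opt$objective
    } else {
      rss <- sum((spgr_signal(t1, m0, fa_deg, tr) - signal)^2)
    }
  } else {
    rss <- sum((spgr_signal(t1, m0, fa_deg, tr) - signal)^2)
  }
  list(t1 = t1, m0 = m0, flagged = FALSE, rss = rss)
}

#' Variable flip angle T1 mapping
#'
#' Estimates native T1 and equilibrium magnetization per voxel from a
#' multi-flip-angle SPGR acquisition, by linearizing the SPGR equation
#' (S/sin a versus S/tan a) to seed a nonlinear least-squares refinement of
#' the same equation.  Voxels whose linearized slope falls outside (0, 1)
#' (no physical SPGR solution, e.g. an identical signal at every angle) are
#' flagged rather than returned as silent NaNs.
#'
#' @param data Data frame with one row per voxel x flip angle; columns named
#'   by `voxel`, `fa`, `signal`.
#' @param acq An [acq_params()] object (TR is taken from it).
#' @param voxel,fa,signal Column names (strings).
#' @param refine Refine the linearized estimate by nonlinear least squares
#'   (default `TRUE`).
#' @return A tibble with one row per voxel: `voxel`, `t1` (ms), `m0`,
#'   `flagged`, `rss`.
#' @export
#' @examples
#' acq <- acq_params()
#' d <- tidyr::crossing(voxel = 1:2, fa = acq$vfa_deg)
#' d$signal <- spgr_signal(1000, 1000, d$fa, acq$tr)
#' fit_vfa_t1(d, acq)
fit_vfa_t1 <- function(data, acq, voxel = "voxel", fa = "fa",
                       signal = "signal", refine = TRUE) {
  stopifnot(inherits(acq, "acq_params"))
  data <- as_tibble(data)
  if (!all(c(voxel, fa, signal) %in% names(data)))
    abort("`data` must contain the voxel, fa and signal columns.",
          class = "dualflow_invalid")
  if (any(data[[signal]] < 0, na.rm = TRUE))
    abort("signals must be non-negative.", class = "dualflow_invalid")
  dplyr::group_by(data, .data[[voxel]]) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g[[fa]])) < 2)
        abort("VFA fitting needs at least 2 distinct flip angles.",
              class = "dualflow_invalid")
      as_tibble(vfa_fit_one(g[[signal]], g[[fa]], acq$tr, refine = refine))
    }) |>
    dplyr::ungroup()
}

# invert SPGR at one flip angle: signal + m0 -> T1 (ms); NA where unphysical
spgr_invert_t1 <- function(signal, m0, fa_deg, tr) {
  a <- fa_deg * pi / 180
  x <- signal / (m0 * sin(a))
  e1 <- (1 - x) / (1 - x * cos(a))
  out <- rep(NA_real_, length(e1))
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  out[ok] <- -tr / log(e1[ok])
  out
}

#' Convert a dynamic signal series to contrast-agent concentration
#'
#' Per frame, the SPGR equation is inverted at the dynamic flip angle to give
#' T1(t), and the concentration follows from the change in relaxation rate,
#' C(t) = (1/T1(t) - 1/T1_native)/r1.  The equilibrium magnetization is
#' calibrated so the mean signal over the baseline (precontrast) frames maps
#' exactly to the native T1, which forces C of an unenhanced series to zero.
#'
#' Frames whose signal admits no physical SPGR inversion (saturation or
#' non-positive T1) are flagged; their concentration is handled per `clamp`.
#'
#' @param signal Dynamic signal series (one voxel).
#' @param acq An [acq_params()] object.
#' @param t1_native Native T1 for the voxel (ms).
#' @param baseline_frames Number of leading precontrast frames used for M0
#'   calibration.  The default (`NULL`) uses all frames before the detected
#'   bolus arrival, with a minimum of 3; M0 calibration error is a dominant
#'   error source near the arterial peak, so the longest available baseline
#'   is preferred.  Must be >= 1 and < the number of frames.
#' @param m0 Optional externally calibrated equilibrium magnetization;
#'   overrides baseline calibration.
#' @param clamp Handling of unphysical frames: carry the last valid value
#'   (default), set to zero, or leave `NA`.
#' @param signal_floor Signals below this fraction of the baseline mean are
#'   treated as unphysical rather than inverted (default 1e-6).
#' @return A tibble with `frame`, `t_min`, `signal`, `t1_ms`, `conc`
#'   (mM), and `flagged`.
#' @export
signal_to_concentration <- function(signal, acq, t1_native,
                                    baseline_frames = NULL, m0 = NULL,
                                    clamp = c("last_valid", "zero", "na"),
                                    signal_floor = 1e-6) {
  stopifnot(inherits(acq, "acq_params"))
  clamp <- match.arg(clamp)
  n <- length(signal)
  if (is.null(baseline_frames)) {
    enh <- signal - mean(signal[seq_len(min(3, n))])
    # first enhancement above the baseline noise floor; exact (any rise)
    # for noiseless data
    thr <- max(5 * sd(enh[seq_len(min(3, n))]), 1e-9 * max(enh), 1e-12)
    first_rise <- which(enh > thr)[1]
    baseline_frames <- if (is.na(first_rise)) n - 1L
                       else min(max(3L, first_rise - 1L), n - 1L)
  }
  if (baseline_frames < 1 || baseline_frames >= n)
    abort("`baseline_frames` must be in [1, n_frames).", class = "dualflow_invalid")
  if (!is.finite(t1_native) || t1_native <= 0)
    abort("`t1_native` must be positive (ms).", class = "dualflow_invalid")
  s_base <- mean(signal[seq_len(baseline_frames)])
  if (is.null(m0)) {
    s_unit <- spgr_signal(t1_native, 1, acq$fa_deg, acq$tr)
    if (s_base <= 0)
      abort("baseline signal is non-positive; cannot calibrate M0.",
            class = "dualflow_invalid")
    m0 <- s_base / s_unit
  }
  low <- signal < signal_floor * s_base
  t1_t <- spgr_invert_t1(signal, m0, acq$fa_deg, acq$tr)
  t1_t[low] <- NA_real_
  conc <- (1000 / t1_t - 1000 / t1_native) / acq$r1
  flagged <- !is.finite(conc)
  if (any(flagged)) {
    warn(sprintf("%d of %d frames had no physical SPGR inversion; clamp = '%s'.",
                 sum(flagged), n, clamp))
    if (clamp == "zero") {
      conc[flagged] <- 0
    } else if (clamp == "last_valid") {
      last <- 0
      for (k in seq_len(n)) {
        if (flagged[k]) conc[k] <- last else last <- conc[k]
      }
    }
  }
  t_all <- (seq_len(n) - 1) * acq$frame_interval / 60
  tibble(frame = seq_len(n), t_min = t_all, signal = signal,
         t1_ms = t1_t, conc = conc, flagged = flagged)
}

#' Convert many voxel signal series to concentration
#'
#' Data-frame front end to [signal_to_concentration()]: joins a T1 map onto
#' long dynamic data and converts each voxel's series.
#'
#' @param data Long data frame with columns `voxel`, `frame`, `signal`.
#' @param t1map Data frame with columns `voxel`, `t1` (ms) as returned by
#'   [fit_vfa_t1()]; flagged voxels are dropped with a warning.
#' @param acq An [acq_params()] object.
#' @inheritParams signal_to_concentration
#' @return Long tibble `voxel`, `frame`, `t_min`, `conc`, `flagged`.
#' @export
signals_to_concentration <- function(data, t1map, acq,
                                     baseline_frames = NULL,
                                     clamp = "last_valid") {
  data <- as_tibble(data)
  t1map <- as_tibble(t1map)
  if ("flagged" %in% names(t1map) && any(t1map$flagged)) {
    warn(sprintf("dropping %d voxels with flagged T1 fits.", sum(t1map$flagged)))
    t1map <- dplyr::filter(t1map, !.data$flagged)
  }
  dplyr::inner_join(data, dplyr::select(t1map, "voxel", "t1"), by = "voxel") |>
    dplyr::arrange(.data$voxel, .data$frame) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::group_modify(function(g, key) {
      out <- signal_to_concentration(g$signal, acq, g$t1[1],
                                     baseline_frames = baseline_frames,
                                     clamp = clamp)
      dplyr::select(out, "frame", "t_min", "conc", "flagged")
    }) |>
    dplyr::ungroup()
}
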