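#' Acquisition parameters for a dynamic SPGR protocol
#'
#' Bundles the pulse-sequence and sampling constants needed to move between
#' signal and gadolinium concentration: repetition time, the dynamic flip
#' angle, the multi-flip-angle set used for native T1 mapping, the frame
#' interval, the number of dynamic frames, and the longitudinal relaxivity of
#' the contrast agent.
#'
#' Defaults correspond to a free-breathing thoracic protocol: TR 4.2 ms,
#' dynamic flip angle 15 degrees, precontrast flip angles 5/15/20/25/30
#' degrees, 130 frames at 2 s, and r1 = 4.5 s^-1 mM^-1 at 3 T.
#'
#' @param tr Repetition time (ms).
#' @param fa_deg Flip angle of the dynamic series (degrees).
#' @param vfa_deg Flip angles of the precontrast variable-flip-angle stack
#'   (degrees); at least two distinct angles.
#' @param frame_interval Time between dynamic frames (seconds).
#' @param n_frames Number of dynamic frames.
#' @param r1 Longitudinal relaxivity of the contrast agent (s^-1 mM^-1).
#'
#' @return An object of class `acq_params`.
#' @export
#' @examples
#' acq_params()
acq_params <- function(tr = 4.2, fa_deg = 15,
                       vfa_deg = c(5, 15, 20, 25, 30),
                       frame_interval = 2, n_frames = 130, r1 = 4.5) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    abort("`tr` must be a positive scalar (ms).", class = "dualflow_invalid")
  ang <- c(fa_deg, vfa_deg)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang > 90))
    abort("flip angles must lie in (0, 90] degrees.", class = "dualflow_invalid")
  if (length(frame_interval) != 1L || frame_interval <= 0)
    abort("`frame_interval` must be a positive scalar (s).", class = "dualflow_invalid")
  if (length(n_frames) != 1L || n_frames < 2)
    abort("`n_frames` must be at least 2.", class = "dualflow_invalid")
  if (length(r1) != 1L || r1 <= 0)
    abort("`r1` must be positive (s^-1 mM^-1).", class = "dualflow_invalid")
  structure(
    list(tr = tr, fa_deg = fa_deg, vfa_deg = vfa_deg,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         r1 = r1),
    class = "acq_params"
  )
}

#' @export
print.acq_params <- function(x, ...) {
  cat("<acq_params> TR", x$tr, "ms | dynamic FA", x$fa_deg,
      "deg | VFA {", paste(x$vfa_deg, collapse = ", "), "} deg |",
      x$n_frames, "frames @", x$frame_interval, "s | r1", x$r1, "s^-1 mM^-1\n")
  invisible(x)
}

#' Time grid of the dynamic series
#'
#' Frame midpoint convention: frame k is acquired at (k-1) * frame_interval,
#' returned in minutes so it composes directly with the kinetic models.
#'
#' @param acq An [acq_params()] object.
#' @return Numeric vector of frame times (minutes), length `n_frames`.
#' @export
frame_times <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  (seq_len(acq$n_frames) - 1) * acq$frame_interval / 60
}

#' Physiologic constants for unit conversions
#'
#' @param h_lv Large-vessel hematocrit, used to convert whole-blood to plasma
#'   concentration in the feeding arteries (default 0.45).
#' @param h_sv Small-vessel (capillary) hematocrit, used to convert the
#'   plasma volume fraction to blood volume (default 0.25).
#' @param rho Tissue density (g/mL), used for per-100 g normalization
#'   (default 1.0).
#'
#' @return An object of class `physio_constants`.
#' @export
physio_constants <- function(h_lv = 0.45, h_sv = 0.25, rho = 1.0) {
  if (!(h_lv > 0 && h_lv < 1) || !(h_sv > 0 && h_sv <= h_lv))
    abort("require 0 < h_sv <= h_lv < 1.", class = "dualflow_invalid")
  if (rho <= 0)
    abort("`rho` must be positive (g/mL).", class = "dualflow_invalid")
  structure(list(h_lv = h_lv, h_sv = h_sv, rho = rho),
            class = "physio_constants")
}
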