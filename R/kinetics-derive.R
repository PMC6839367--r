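#' Physiologic outputs from fitted kinetic parameters
#'
#' Converts a fitted parameter vector to the standard perfusion outputs,
#' using the per-tissue rates `f_t = f_over_vp * v_p` and
#' `ps_t = ps_over_vp * v_p`:
#' * `bf = f_t / (1 - h_lv) * 100 / rho` — total blood flow (mL/min/100 g);
#' * `bf_pa = gamma * bf`, `bf_a = (1 - gamma) * bf` — pulmonary and systemic
#'   arterial blood flow (dual input; for single-input modes gamma is 1 or 0);
#' * `bv = v_p / (1 - h_sv) * 100 / rho` — blood volume (mL/100 g);
#' * `mtt = (v_p + v_i) / f_t` — mean transit time (min), the total tracer
#'   distribution volume over plasma flow;
#' * `ps = ps_t * 100 / rho` — permeability-surface area product
#'   (mL/min/100 g);
#' * `ktrans = E * f_t` with `E = 1 - exp(-ps_t / f_t)` — volume transfer
#'   constant (mL/min/mL) under the mixed flow- and permeability-limited
#'   decomposition;
#' * `v_i`, `gamma` — passed through.
#'
#' @param params A [kin_params()] object.  `gamma` may be `NA` only if
#'   `mode` is given.
#' @param consts A [physio_constants()] object.
#' @param mode Optional input mode used to pin gamma for single-input fits
#'   (`"pulmonary"` -> 1, `"systemic"` -> 0).
#' @return One-row tibble of derived parameters with the units above.
#' @export
#' @examples
#' p <- kin_params("2CX", f_over_vp = 2, ps_over_vp = 0.5, v_p = 0.1, v_i = 0.3)
#' derive_parameters(p, mode = "pulmonary")
derive_parameters <- function(params, consts = physio_constants(),
                              mode = NULL) {
  stopifnot(inherits(params, "kin_params"), inherits(consts, "physio_constants"))
  r <- kin_rates(params)
  if (r$f_t <= 0)
    abort("plasma flow per tissue volume must be positive.",
          class = "dualflow_invalid")
  gamma <- params$gamma
  if (!is.null(mode) && mode != "dual") gamma <- resolve_gamma(mode, gamma)
  if (is.na(gamma))
    abort("gamma is missing; supply `mode` or fit with a dual input.",
          class = "dualflow_invalid")
  scale <- 100 / consts$rho
  bf <- r$f_t / (1 - consts$h_lv) * scale
  tibble(
    bf = bf,
    gamma = gamma,
    bf_pa = gamma * bf,
    bf_a = (1 - gamma) * bf,
    bv = params$v_p / (1 - consts$h_sv) * scale,
    mtt = (params$v_p + params$v_i) / r$f_t,
    ps = r$ps_t * scale,
    v_i = params$v_i,
    ktrans = r$e * r$f_t
  )
}
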