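#' Plot a fitted AIF over the measured arterial curve
#'
#' @param object An [fit_aif()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aif_fit <- function(object, ...) {
  d <- object$data
  tt <- seq(min(d$t_min), max(d$t_min), length.out = 400)
  fit <- tibble(t_min = tt, conc = eval_aif(object$params, tt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$conc)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = fit, color = "firebrick") +
    ggplot2::labs(x = "time (min)", y = "blood concentration (mM)",
                  title = "Two-pass AIF fit") +
    ggplot2::theme_minimal()
}

#' Plot the gamma kernel density estimate
#'
#' @param object A [gamma_density()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gamma_density <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(gamma), y = "density",
                  title = sprintf("Pulmonary flow fraction density (h = %g)",
                                  object$h)) +
    ggplot2::theme_minimal()
}

#' Plot best-model percentages from a model selection
#'
#' @param object A [select_models()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.model_selection <- function(object, ...) {
  pct <- model_percentages(object)
  pct$model <- factor(pct$model, levels = KINETIC_MODELS)
  ggplot2::ggplot(pct, ggplot2::aes(x = .data$model, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = NULL, y = "% of voxels with minimum cAIC") +
    ggplot2::theme_minimal()
}

#' Plot tissue curves and model fits for chosen voxels
#'
#' @param conc Long concentration tibble (`voxel`, `t_min`, `conc`).
#' @param fits A [fit_voxels()] result.
#' @param inputs The [dual_input()] used for fitting.
#' @param voxels Voxels to display (default: first one).
#' @return A ggplot object.
#' @export
plot_voxel_fits <- function(conc, fits, inputs, voxels = NULL) {
  conc <- as_tibble(conc)
  voxels <- voxels %||% conc$voxel[1]
  d <- dplyr::filter(conc, .data$voxel %in% voxels)
  f <- dplyr::filter(as_tibble(fits), .data$voxel %in% voxels)
  curves <- purrr::pmap_dfr(
    f[c("voxel", "model", "mode", "f_over_vp", "ps_over_vp", "v_p", "v_i",
        "t_lag", "gamma")],
    function(voxel, model, mode, f_over_vp, ps_over_vp, v_p, v_i, t_lag,
             gamma) {
      pr <- kin_params(model, f_over_vp, ps_over_vp, v_p, v_i, t_lag,
                       gamma = if (mode == "dual") gamma else NA_real_)
      inp <- dual_input(inputs$pulmonary, inputs$systemic, mode = mode,
                        h_lv = inputs$h_lv)
      tt <- seq(0, max(d$t_min), length.out = 300)
      tibble(voxel = voxel, model = model, mode = mode, t_min = tt,
             conc = tissue_curve(model, pr, inp, tt))
    })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$conc)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(color = .data$model,
                                    linetype = .data$mode)) +
    ggplot2::facet_wrap(~voxel) +
    ggplot2::labs(x = "time (min)", y = "tissue concentration (mM)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
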