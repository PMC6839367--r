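#' Tidy an AIF fit
#'
#' @param x An [fit_aif()] result.
#' @param ... Unused.
#' @return One row per AIF parameter: `term`, `estimate`.
#' @export
tidy.aif_fit <- function(x, ...) {
  p <- unclass(x$params)
  tibble(term = names(p), estimate = unname(unlist(p)))
}

#' @rdname tidy.aif_fit
#' @export
glance.aif_fit <- function(x, ...) {
  tibble(sse = x$sse, n = x$n, converged = x$converged,
         rmse = sqrt(x$sse / x$n))
}

#' Tidy a single voxel fit
#'
#' @param x A [fit_voxel()] result.
#' @param ... Unused.
#' @return One row per fitted kinetic parameter: `term`, `estimate`.
#' @export
tidy.voxel_fit <- function(x, ...) {
  p <- unclass(x$params)
  p$model <- NULL
  keep <- !vapply(p, is.na, logical(1))
  tibble(term = names(p)[keep], estimate = unname(unlist(p[keep])))
}

#' @rdname tidy.voxel_fit
#' @export
glance.voxel_fit <- function(x, ...) {
  tibble(model = x$model, mode = x$mode, sse = x$sse, n = x$n_points,
         converged = x$converged, n_evals = x$n_evals,
         enhancing = x$enhancing,
         caic = if (is.finite(x$sse) && x$sse > 0)
           caic(x$sse, x$n_points, if (x$mode == "dual") 6L else 5L)
         else NA_real_)
}

#' Predicted tissue curve of a voxel fit
#'
#' @param object A [fit_voxel()] result.
#' @param inputs The [dual_input()] used for fitting.
#' @param t_min Times (minutes) at which to evaluate.
#' @param ... Unused.
#' @return Tibble `t_min`, `conc_fit`.
#' @export
predict.voxel_fit <- function(object, inputs, t_min, ...) {
  tibble(t_min = t_min,
         conc_fit = tissue_curve(object$model, object$params, inputs, t_min))
}
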