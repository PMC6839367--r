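#' Corrected Akaike information criterion for a least-squares fit
#'
#' Small-sample-corrected AIC under the Gaussian least-squares likelihood,
#' \deqn{cAIC = n \ln(SSE/n) + 2K + \frac{2K(K+1)}{n - K - 1},}
#' where `K = p + 1` counts the fitted parameters plus the residual
#' variance.  Counting the variance term follows the least-squares AIC
#' convention; since every kinetic model here shares the same `p`, per-voxel
#' model ranking is insensitive to the convention, but the value itself is
#' documented.
#'
#' @param sse Sum of squared residuals (> 0).  Vectorized.
#' @param n Number of fitted data points (frames).
#' @param p Number of fitted model parameters (excluding the residual
#'   variance).
#' @return The cAIC value(s).
#' @export
#' @examples
#' caic(1.0, n = 130, p = 6)
#' caic(0.5, 130, 6) - caic(1.0, 130, 6)  # = -130 * log(2)
caic <- function(sse, n, p) {
  k <- p + 1
  if (any(n <= k + 1))
    abort("cAIC correction undefined: need n > p + 2.",
          class = "dualflow_invalid")
  if (any(!is.na(sse) & sse <= 0))
    abort("SSE must be positive.", class = "dualflow_invalid")
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of cAIC values
#'
#' The evidence weight of model m is
#' \deqn{w_m = \exp(-\Delta_m/2) / \sum_j \exp(-\Delta_j/2), \quad
#'   \Delta_m = cAIC_m - \min_j cAIC_j,}
#' interpretable as the probability for the model to be the best of the set.
#' Subtracting the minimum first makes the computation stable for large
#' differences (weights underflow to exactly 0, never NaN).
#'
#' @param caics Named numeric vector of cAIC values (>= 2 models).
#' @return Named vector of weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(TK = 10, `2CX` = 8))
akaike_weights <- function(caics) {
  if (length(caics) < 2)
    abort("need at least 2 models.", class = "dualflow_invalid")
  d <- caics - min(caics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Per-voxel model selection by minimum cAIC
#'
#' Given a [fit_voxels()] result (or any tibble with `voxel`, `model`,
#' `sse`, `n_points` and optionally `mode`), computes per-voxel cAIC for
#' every model, Akaike weights, and the best (minimum-cAIC) model label.
#' Ties are broken by the fixed model order TK, ETK, 2CX, AATH, DP.
#' Comparison requires every model of a voxel to be fitted on the identical
#' number of frames; voxels violating this, or with any missing/failed
#' model, are excluded and counted.
#'
#' @param fits Tibble of per-voxel per-model fits.
#' @param n_par Fitted-parameter count per model; defaults to 5 for
#'   single-input and 6 for dual-input fits.
#' @return A list of class `model_selection`: `$table` (long tibble `voxel`,
#'   `mode`, `model`, `caic`, `delta`, `weight`, `best`), `$best` (one row
#'   per voxel with the winning model), `$excluded` (voxel count excluded per
#'   mode).  See [model_percentages()].
#' @export
select_models <- function(fits, n_par = NULL) {
  fits <- as_tibble(fits)
  need <- c("voxel", "model", "sse", "n_points")
  if (!all(need %in% names(fits)))
    abort("`fits` must have columns voxel, model, sse, n_points.",
          class = "dualflow_invalid")
  if (!"mode" %in% names(fits)) fits$mode <- "dual"

  expected_models <- unique(fits$model)
  if (!"converged" %in% names(fits)) fits$converged <- TRUE

  # a voxel is excluded when a model's fit is missing from the input or the
  # models were fitted on different frame counts; a present-but-failed fit
  # is merely dropped from that voxel's comparison
  usable <- dplyr::group_by(fits, .data$voxel, .data$mode) |>
    dplyr::mutate(
      usable_row = .data$converged & is.finite(.data$sse) & .data$sse > 0,
      ok = all(expected_models %in% .data$model) &&
        dplyr::n_distinct(.data$n_points[.data$usable_row]) <= 1 &&
        sum(.data$usable_row) >= 1
    ) |>
    dplyr::ungroup()
  excluded <- dplyr::filter(usable, !.data$ok) |>
    dplyr::distinct(.data$voxel, .data$mode) |>
    dplyr::count(.data$mode, name = "n_excluded")
  keep <- dplyr::filter(usable, .data$ok, .data$usable_row)

  tab <- dplyr::group_by(keep, .data$voxel, .data$mode) |>
    dplyr::group_modify(function(g, key) {
      p <- n_par %||% (if (key$mode == "dual") 6L else 5L)
      cv <- caic(g$sse, g$n_points, p)
      w <- if (nrow(g) >= 2) akaike_weights(cv) else 1
      ord <- match(g$model, KINETIC_MODELS)
      best_idx <- order(cv, ord)[1]
      tibble(model = g$model, caic = cv, delta = cv - min(cv), weight = w,
             best = seq_along(cv) == best_idx)
    }) |>
    dplyr::ungroup()

  best <- dplyr::filter(tab, .data$best) |>
    dplyr::select("voxel", "mode", best_model = "model", caic_min = "caic",
                  best_weight = "weight")
  structure(list(table = tab, best = best, excluded = excluded),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection>", nrow(x$best), "voxel/mode decisions;",
      sum(x$excluded$n_excluded %||% 0), "excluded\n")
  print(model_percentages(x))
  invisible(x)
}

#' Percentage of voxels for which each model attains the minimum cAIC
#'
#' @param selection A [select_models()] result.
#' @return Tibble `mode`, `model`, `n`, `pct` (percentages over decided
#'   voxels per mode; together with exclusions they account for all voxels).
#' @export
model_percentages <- function(selection) {
  stopifnot(inherits(selection, "model_selection"))
  dplyr::count(selection$best, .data$mode, .data$best_model, name = "n") |>
    dplyr::group_by(.data$mode) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::rename(model = "best_model")
}
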