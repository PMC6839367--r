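# NIfTI interfaces are thin wrappers around the tabular core; RNifti is an
# optional dependency, checked at call time.
need_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE))
    abort("NIfTI input/output requires the RNifti package.",
          class = "dualflow_missing_dep")
}

#' Convert a masked 4D dynamic volume to long voxel curves
#'
#' @param dyn4d 4D array (x, y, z, frame) or path to a NIfTI file.
#' @param mask 3D logical/0-1 array or NIfTI path selecting voxels.
#' @param acq An [acq_params()] giving the frame interval.
#' @param value Name of the value column (`"signal"` or `"conc"`).
#' @return Long tibble `voxel`, `frame`, `t_min`, `<value>`, plus an
#'   attribute `voxel_index` (matrix of array indices per voxel).
#' @export
nifti_to_curves <- function(dyn4d, mask, acq, value = "signal") {
  if (is.character(dyn4d)) { need_rnifti(); dyn4d <- RNifti::readNifti(dyn4d) }
  if (is.character(mask)) { need_rnifti(); mask <- RNifti::readNifti(mask) }
  dyn4d <- as.array(dyn4d); mask <- as.array(mask) > 0
  stopifnot(length(dim(dyn4d)) == 4, all(dim(dyn4d)[1:3] == dim(mask)))
  idx <- which(mask)
  if (length(idx) == 0)
    abort("empty mask.", class = "dualflow_invalid")
  n_frames <- dim(dyn4d)[4]
  vol <- matrix(dyn4d, ncol = n_frames)[idx, , drop = FALSE]
  out <- tibble(
    voxel = rep(seq_along(idx), each = n_frames),
    frame = rep(seq_len(n_frames), times = length(idx)),
    t_min = rep((seq_len(n_frames) - 1) * acq$frame_interval / 60,
                times = length(idx)),
    value = as.vector(t(vol))
  )
  names(out)[names(out) == "value"] <- value
  attr(out, "voxel_index") <- arrayInd(idx, dim(mask))
  out
}

#' Write per-voxel parameter maps as NIfTI volumes
#'
#' One 3D volume per parameter per model per input mode, named
#' `{param}_{model}_{mode}.nii.gz`.
#'
#' @param fits A [fit_voxels()] result.
#' @param voxel_index Matrix of (x, y, z) array indices per voxel, as
#'   produced by [nifti_to_curves()].
#' @param dim3 Dimensions of the target volume.
#' @param out_dir Output directory.
#' @param params Parameter columns to export.
#' @return Invisibly, the vector of file paths written.
#' @export
write_param_maps <- function(fits, voxel_index, dim3, out_dir,
                             params = c("bf", "gamma", "bf_pa", "bf_a", "bv",
                                        "mtt", "ps", "v_i", "ktrans",
                                        "sse")) {
  need_rnifti()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- as_tibble(fits)
  paths <- character(0)
  for (md in unique(fits$model)) {
    for (mo in unique(fits$mode)) {
      sub <- dplyr::filter(fits, .data$model == md, .data$mode == mo)
      for (pm in intersect(params, names(sub))) {
        vol <- array(NA_real_, dim3)
        vol[voxel_index[sub$voxel, , drop = FALSE]] <- sub[[pm]]
        path <- file.path(out_dir, sprintf("%s_%s_%s.nii.gz", pm, md, mo))
        RNifti::writeNifti(RNifti::asNifti(vol), path)
        paths <- c(paths, path)
      }
    }
  }
  invisible(paths)
}

#' Write fitted AIF parameters to JSON or YAML
#'
#' @param fit An [fit_aif()] result (or a bare [aif_params()] object).
#' @param path Output file; the extension selects the format (`.json`
#'   default, `.yaml`/`.yml` for YAML).
#' @return Invisibly, `path`.
#' @export
write_aif <- function(fit, path) {
  params <- if (inherits(fit, "aif_fit")) fit$params else fit
  stopifnot(inherits(params, "aif_params"))
  payload <- c(unclass(params),
               if (inherits(fit, "aif_fit"))
                 list(sse = fit$sse, n = fit$n, converged = fit$converged))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("YAML output requires the yaml package.",
            class = "dualflow_missing_dep")
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write model-selection maps as NIfTI volumes
#'
#' Writes the best-model label volume (integer codes, with a JSON legend),
#' one cAIC and one Akaike-weight volume per model, and the per-model
#' percentage table as CSV.
#'
#' @param selection A [select_models()] result.
#' @param voxel_index Matrix of (x, y, z) array indices per voxel.
#' @param dim3 Dimensions of the target volume.
#' @param out_dir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_selection_maps <- function(selection, voxel_index, dim3, out_dir) {
  need_rnifti()
  stopifnot(inherits(selection, "model_selection"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  codes <- setNames(seq_along(KINETIC_MODELS), KINETIC_MODELS)
  for (mo in unique(selection$best$mode)) {
    best <- dplyr::filter(selection$best, .data$mode == mo)
    lab <- array(0L, dim3)
    lab[voxel_index[best$voxel, , drop = FALSE]] <-
      codes[best$best_model]
    RNifti::writeNifti(RNifti::asNifti(lab),
                       file.path(out_dir, sprintf("best_model_%s.nii.gz", mo)))
    tab <- dplyr::filter(selection$table, .data$mode == mo)
    for (md in unique(tab$model)) {
      sub <- dplyr::filter(tab, .data$model == md)
      for (what in c("caic", "weight")) {
        vol <- array(NA_real_, dim3)
        vol[voxel_index[sub$voxel, , drop = FALSE]] <- sub[[what]]
        RNifti::writeNifti(RNifti::asNifti(vol),
                           file.path(out_dir,
                                     sprintf("%s_%s_%s.nii.gz", what, md, mo)))
      }
    }
  }
  jsonlite::write_json(as.list(codes), file.path(out_dir, "legend.json"),
                       auto_unbox = TRUE)
  write.csv(model_percentages(selection),
            file.path(out_dir, "percentages.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Export a digital phantom as NIfTI volumes plus truth files
#'
#' Lays the phantom voxels out on a flat grid and writes the 4D dynamic
#' series, one 3D volume per precontrast flip angle, integer label masks
#' (tumor / pulmonary artery / aorta), the truth table as CSV, and the
#' generating configuration as YAML.
#'
#' @param phantom A [generate_phantom()] result.
#' @param out_dir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_phantom <- function(phantom, out_dir) {
  need_rnifti()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_vox <- nrow(phantom$masks)
  nx <- ceiling(sqrt(n_vox))
  ny <- ceiling(n_vox / nx)
  dim3 <- c(nx, ny, 1)
  coord <- cbind((phantom$masks$voxel - 1) %% nx + 1,
                 (phantom$masks$voxel - 1) %/% nx + 1, 1)

  sig <- tidyr::pivot_wider(
    dplyr::select(phantom$signal, "voxel", "frame", "signal"),
    names_from = "frame", values_from = "signal")
  dyn <- array(0, c(dim3, phantom$acq$n_frames))
  for (k in seq_len(phantom$acq$n_frames))
    dyn[cbind(coord[sig$voxel, , drop = FALSE], k)] <- sig[[as.character(k)]]
  RNifti::writeNifti(RNifti::asNifti(dyn), file.path(out_dir, "dynamic.nii.gz"))

  for (fa in phantom$acq$vfa_deg) {
    vf <- dplyr::filter(phantom$vfa, .data$fa == !!fa)
    vol <- array(0, dim3)
    vol[coord[vf$voxel, , drop = FALSE]] <- vf$signal
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(out_dir, sprintf("vfa_fa%02d.nii.gz", fa)))
  }

  types <- c(tumor = 1L, pulmonary_artery = 2L, aorta = 3L)
  lab <- array(0L, dim3)
  lab[coord] <- types[phantom$masks$type]
  RNifti::writeNifti(RNifti::asNifti(lab), file.path(out_dir, "labels.nii.gz"))

  write.csv(truth_table(phantom), file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  if (requireNamespace("yaml", quietly = TRUE)) {
    cfg <- phantom$config
    yaml::write_yaml(
      list(protocol = cfg$protocol, n_per_region = cfg$n_per_region,
           n_vessel = cfg$n_vessel, noise_sd = cfg$noise_sd,
           h_lv = cfg$h_lv, seed = cfg$seed,
           aif = list(pulmonary = unclass(cfg$aif$pulmonary),
                      systemic = unclass(cfg$aif$systemic))),
      file.path(out_dir, "phantom.yaml"))
  }
  invisible(out_dir)
}
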