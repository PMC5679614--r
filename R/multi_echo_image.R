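#' Multi-echo image container
#'
#' A 4D multi-echo gradient-echo volume stored as magnitude and phase arrays
#' (x, y, z, echo), with acquisition metadata, a voxel-to-world affine and a
#' brain mask. Phase may be \code{NULL} for magnitude-only data, in which
#' case phase-dependent operations (navigator correction, field estimation)
#' are unavailable.
#'
#' @param magnitude 4D numeric array (x, y, z, echo) of signal magnitudes.
#' @param phase Optional 4D numeric array of signal phases in radians, same
#'   dimensions as \code{magnitude}.
#' @param acq An \code{\link{acq_params}} object; the echo axis length must
#'   equal \code{acq$n_echoes}.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by the voxel size.
#' @param brain_mask 3D logical array matching the spatial dimensions;
#'   defaults to all \code{TRUE}.
#' @return An object of class \code{multi_echo_image}.
#' @export
multi_echo_image <- function(magnitude, phase = NULL, acq = acq_params(),
                             affine = NULL, brain_mask = NULL) {
  stopifnot(length(dim(magnitude)) == 4)
  dm <- dim(magnitude)
  if (dm[4] != acq$n_echoes)
    stop("echo axis length (", dm[4], ") != acq$n_echoes (", acq$n_echoes, ")")
  if (!is.null(phase) && !identical(dim(phase), dm))
    stop("phase dimensions must match magnitude dimensions")
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dm[1:3])
  } else if (!identical(dim(brain_mask), dm[1:3])) {
    stop("brain_mask dimensions must match the spatial dimensions")
  }
  if (is.null(affine)) {
    affine <- diag(c(acq$voxel_size, 1))
  }
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(magnitude = magnitude, phase = phase, acq = acq,
                 affine = affine, brain_mask = brain_mask),
            class = "multi_echo_image")
}

#' @export
print.multi_echo_image <- function(x, ...) {
  dm <- dim(x$magnitude)
  cat("multi_echo_image:", paste(dm[1:3], collapse = " x "), "voxels,",
      dm[4], "echoes,", ifelse(is.null(x$phase), "magnitude only", "magnitude+phase"),
      "\n  TE:", paste(signif(echo_times(x$acq) * 1000, 3), collapse = ", "), "ms\n",
      " mask:", sum(x$brain_mask), "voxels\n")
  invisible(x)
}

#' Complex voxel data of a multi-echo image
#'
#' @param image A \code{\link{multi_echo_image}} with phase data.
#' @return 4D complex array \code{magnitude * exp(i * phase)}.
#' @export
complex_data <- function(image) {
  stopifnot(inherits(image, "multi_echo_image"))
  if (is.null(image$phase))
    stop("complex data requires phase; image is magnitude-only")
  image$magnitude * exp(1i * image$phase)
}

#' Write a multi-echo image to NIfTI files with a metadata sidecar
#'
#' Writes \code{<prefix>_mag.nii} (4D magnitude), \code{<prefix>_phase.nii}
#' (4D phase, if present), \code{<prefix>_mask.nii} and a JSON sidecar
#' \code{<prefix>.json} carrying \code{"EchoTimes"} in seconds plus the other
#' acquisition fields.
#'
#' @param image A \code{\link{multi_echo_image}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_multi_echo <- function(image, prefix) {
  stopifnot(inherits(image, "multi_echo_image"))
  vs <- image$acq$voxel_size
  files <- character(0)
  wr <- function(arr, path) {
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(vs, 1)), path)
    path
  }
  files <- c(files, wr(image$magnitude, paste0(prefix, "_mag.nii")))
  if (!is.null(image$phase))
    files <- c(files, wr(image$phase, paste0(prefix, "_phase.nii")))
  files <- c(files, wr(image$brain_mask + 0L, paste0(prefix, "_mask.nii")))
  meta <- list(EchoTimes = echo_times(image$acq),
               RepetitionTime = image$acq$tr,
               FlipAngle = image$acq$flip_angle,
               VoxelSize = image$acq$voxel_size)
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(meta, json_path, digits = NA, auto_unbox = FALSE)
  invisible(c(files, json_path))
}

#' Read a multi-echo image written by \code{\link{write_multi_echo}}
#'
#' @param prefix Path prefix used at write time.
#' @return A \code{\link{multi_echo_image}}.
#' @export
read_multi_echo <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  te <- as.numeric(meta$EchoTimes)
  acq <- acq_params(te_first = te[1],
                    te_spacing = if (length(te) > 1) te[2] - te[1] else 0.004,
                    n_echoes = length(te),
                    tr = as.numeric(meta$RepetitionTime),
                    flip_angle = as.numeric(meta$FlipAngle),
                    voxel_size = as.numeric(meta$VoxelSize))
  mag <- array(as.numeric(RNifti::readNifti(paste0(prefix, "_mag.nii"))),
               dim = dim(RNifti::readNifti(paste0(prefix, "_mag.nii"))))
  phase_path <- paste0(prefix, "_phase.nii")
  phase <- NULL
  if (file.exists(phase_path)) {
    p <- RNifti::readNifti(phase_path)
    phase <- array(as.numeric(p), dim = dim(p))
  }
  mask_path <- paste0(prefix, "_mask.nii")
  mask <- NULL
  if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m) > 0.5, dim = dim(m))
  }
  multi_echo_image(mag, phase, acq = acq, brain_mask = mask)
}
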