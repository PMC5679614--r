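#' Default limbic region set
#'
#' The eleven limbic-system regions summarized by default, using
#' FreeSurfer-convention names: hippocampus, amygdala, parahippocampal
#' cortex, insula, entorhinal cortex, lateral and medial orbitofrontal
#' cortices, caudal and rostral anterior cingulate cortices, isthmus of
#' cingulate and posterior cingulate.
#'
#' @return Character vector of region names.
#' @export
limbic_regions <- function() {
  c("hippocampus", "amygdala", "parahippocampal", "insula", "entorhinal",
    "lateralorbitofrontal", "medialorbitofrontal",
    "caudalanteriorcingulate", "rostralanteriorcingulate",
    "isthmuscingulate", "posteriorcingulate")
}

#' ROI label map
#'
#' An integer label volume plus its label table. Every nonzero label present
#' in the array must appear in the table, and label ids must be unique.
#'
#' @param labels 3D integer array; 0 = unlabeled.
#' @param label_table data.frame with columns \code{label_id},
#'   \code{region_name}, \code{hemisphere} (one of "left", "right", "none").
#' @return An object of class \code{roi_label_map}.
#' @export
roi_label_map <- function(labels, label_table) {
  stopifnot(length(dim(labels)) == 3)
  req <- c("label_id", "region_name", "hemisphere")
  if (!all(req %in% names(label_table)))
    stop("label_table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(label_table$label_id))
    stop("label_ids must be unique")
  if (!all(label_table$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be one of left/right/none")
  present <- setdiff(unique(as.vector(labels)), 0)
  missing <- setdiff(present, label_table$label_id)
  if (length(missing) > 0)
    stop("labels present in the array but absent from label_table: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, label_table = label_table),
            class = "roi_label_map")
}

#' Read an ROI label map from NIfTI + TSV
#'
#' @param nifti_path Path to an integer label NIfTI volume.
#' @param tsv_path Path to a tab-separated label table with header
#'   \code{label_id, region_name, hemisphere}.
#' @return An \code{\link{roi_label_map}}.
#' @export
read_label_map <- function(nifti_path, tsv_path) {
  img <- RNifti::readNifti(nifti_path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  tab <- utils::read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE)
  roi_label_map(labels, tab)
}

#' Write an ROI label map to NIfTI + TSV
#'
#' @param label_map An \code{\link{roi_label_map}}.
#' @param nifti_path,tsv_path Output paths.
#' @param voxel_size Voxel dimensions in mm for the NIfTI header.
#' @return Invisibly, the two paths.
#' @export
write_label_map <- function(label_map, nifti_path, tsv_path,
                            voxel_size = c(1, 1, 2)) {
  RNifti::writeNifti(RNifti::asNifti(label_map$labels + 0L,
                                     pixdim = c(voxel_size, 1)), nifti_path)
  utils::write.table(label_map$label_table, tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(nifti_path, tsv_path))
}

#' Median of a map over one labeled region
#'
#' Median of the map values over voxels carrying the given label and lying
#' inside the quality mask. Medians rather than means damp the influence of
#' segmentation errors and stray misfit voxels. Even voxel counts average
#' the two central order statistics. An empty selection yields \code{NA}
#' with a zero count, not an error.
#'
#' @param map 3D numeric array.
#' @param label_map An \code{\link{roi_label_map}}.
#' @param label_id Integer label to select.
#' @param quality_mask Optional 3D logical array; only voxels inside it
#'   contribute to the median (all voxels when \code{NULL}).
#' @return List with \code{median} and \code{n_voxels} (the count entering
#'   the median).
#' @export
region_median <- function(map, label_map, label_id, quality_mask = NULL) {
  stopifnot(identical(dim(map), dim(label_map$labels)))
  sel <- label_map$labels == label_id
  if (!is.null(quality_mask)) {
    stopifnot(identical(dim(quality_mask), dim(map)))
    sel <- sel & quality_mask
  }
  vals <- map[sel]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) return(list(median = NA_real_, n_voxels = 0L))
  list(median = stats::median(vals), n_voxels = length(vals))
}

#' Skull-normalized volume
#'
#' Regional volume scaled by a per-subject skull-size normalization factor
#' (as produced by volumetric skull-scaling tools):
#' \code{n_voxels * voxel_volume * scaling_factor}.
#'
#' @param n_voxels Non-negative voxel count.
#' @param voxel_volume Voxel volume in mm^3.
#' @param scaling_factor Positive dimensionless scaling factor.
#' @return Normalized volume in mm^3.
#' @export
normalized_volume <- function(n_voxels, voxel_volume, scaling_factor) {
  stopifnot(n_voxels >= 0, voxel_volume >= 0, scaling_factor > 0)
  n_voxels * voxel_volume * scaling_factor
}

#' Summarize one subject's quantitative maps by region
#'
#' One row per (region, hemisphere) in the requested region set: median
#' R2t* over quality-passing voxels, raw volume and skull-normalized
#' volume. Volumes count ALL labeled voxels regardless of fit quality, so
#' atrophy measurement does not depend on the fit; the R2t* median is
#' restricted to the quality mask. Regions absent from the label volume
#' produce rows with missing markers and a warning.
#'
#' @param qmaps A \code{qmaps} object from \code{\link{fit_volume}}, or any
#'   list with \code{r2t_star_map} and optionally \code{quality_mask}.
#' @param label_map An \code{\link{roi_label_map}}.
#' @param scaling_factor Per-subject skull-size scaling factor (> 0).
#' @param subject_id Subject identifier recorded in the output rows.
#' @param region_set Character vector of region names to summarize;
#'   defaults to \code{\link{limbic_regions}()}.
#' @param voxel_volume Voxel volume in mm^3; defaults to the product of the
#'   acquisition voxel size when available.
#' @return data.frame with columns \code{subject_id}, \code{region_name},
#'   \code{hemisphere}, \code{median_r2t_star}, \code{n_voxels},
#'   \code{volume_mm3}, \code{normalized_volume}.
#' @export
summarize_subject <- function(qmaps, label_map, scaling_factor,
                              subject_id = "subject",
                              region_set = limbic_regions(),
                              voxel_volume = NULL) {
  stopifnot(inherits(label_map, "roi_label_map"), scaling_factor > 0)
  if (is.null(voxel_volume)) {
    voxel_volume <- if (!is.null(qmaps$acq)) prod(qmaps$acq$voxel_size) else 1
  }
  qmask <- qmaps$quality_mask
  tab <- label_map$label_table
  hemis <- c("left", "right")
  rows <- list()
  for (region in region_set) {
    for (hemi in hemis) {
      entry <- tab[tab$region_name == region & tab$hemisphere == hemi, ]
      if (nrow(entry) == 0) {
        warning("region not in label table: ", region, " (", hemi, ")",
                call. = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = subject_id, region_name = region, hemisphere = hemi,
          median_r2t_star = NA_real_, n_voxels = 0L, volume_mm3 = NA_real_,
          normalized_volume = NA_real_, stringsAsFactors = FALSE)
        next
      }
      lid <- entry$label_id[1]
      med <- region_median(qmaps$r2t_star_map, label_map, lid, qmask)
      n_all <- sum(label_map$labels == lid)
      if (n_all == 0)
        warning("region absent from label array: ", region, " (", hemi, ")",
                call. = FALSE)
      vol <- n_all * voxel_volume
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = subject_id, region_name = region, hemisphere = hemi,
        median_r2t_star = med$median, n_voxels = med$n_voxels,
        volume_mm3 = if (n_all == 0) NA_real_ else vol,
        normalized_volume = if (n_all == 0) NA_real_
                            else vol * scaling_factor,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
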