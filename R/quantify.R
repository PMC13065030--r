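#' Voxelwise delta-T1 map
#'
#' Post-contrast minus pre-contrast T1 (ms); negative values indicate
#' enhancement. Voxels with nonpositive T1 in either input (background or
#' invalid fits) are set to `NA`.
#'
#' @param pre registered pre-contrast T1 map ([volume()] or array, ms).
#' @param post post-contrast T1 map on the same grid (ms).
#' @return A [volume()] (or array) of delta-T1 values with `NA` outside the
#'   common foreground.
#' @export
compute_delta_t1 <- function(pre, post) {
  a <- vol_data(pre)
  b <- vol_data(post)
  if (!all(dim(a) == dim(b))) {
    stop("pre and post volumes are on different grids", call. = FALSE)
  }
  delta <- b - a
  delta[a <= 0 | b <= 0] <- NA_real_
  if (inherits(post, "t1gad_volume")) return(volume(delta, post$voxel_size))
  delta
}

# region name -> list of phantom label names (parcellation-derived regions)
region_label_sets <- function() {
  lobes <- c("frontal_cortex", "parietal_cortex", "temporal_cortex",
             "occipital_cortex")
  lr <- function(x) c(paste0(x, "_left"), paste0(x, "_right"))
  sets <- list(cerebral_cortex = unlist(lapply(lobes, lr)))
  for (l in lobes) sets[[l]] <- lr(l)
  sets$cerebellar_cortex <- "cerebellar_cortex"
  sets$cerebral_white_matter <- lr("cerebral_white_matter")
  sets$cerebellar_white_matter <- "cerebellar_white_matter"
  sets
}

summarize_region <- function(vals, region) {
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    return(data.frame(region = region, n_voxels = 0L, median = NA_real_,
                      q1 = NA_real_, q3 = NA_real_, missing = TRUE,
                      stringsAsFactors = FALSE))
  }
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(region = region, n_voxels = length(vals), median = q[2],
             q1 = q[1], q3 = q[3], missing = FALSE, stringsAsFactors = FALSE)
}

#' Regional delta-T1 medians
#'
#' Median and interquartile range of the delta-T1 map over each analyzed
#' region: cerebral cortex (union of the eight lobar labels), each cortical
#' lobe, cerebellar cortex, cerebral and cerebellar white matter from the
#' parcellation, plus basal-ganglia PVS (left-right union) and choroid
#' plexus from the supplied segmentation masks. `NA` delta-T1 voxels are
#' skipped; an empty region is flagged `missing` rather than reported as
#' zero.
#'
#' By default the PVS and CP rows summarize the segmented masks (the main
#' analysis path); pass the ground-truth masks instead to obtain
#' truth-based summaries for validation.
#'
#' @param delta delta-T1 map from [compute_delta_t1()].
#' @param labels `t1gad_labels` parcellation on the same grid.
#' @param pvs a `pvs_segmentation` (or logical mask) for the PVS row, or
#'   `NULL` to fall back to the ground-truth tube labels.
#' @param cp a `cp_segmentation` (or logical mask) for the CP row, or
#'   `NULL` to fall back to the choroid-plexus label.
#' @return data.frame with one row per region: `region`, `n_voxels`,
#'   `median`, `q1`, `q3`, `missing`.
#' @export
regional_medians <- function(delta, labels, pvs = NULL, cp = NULL) {
  dvals <- vol_data(delta)
  if (!all(dim(dvals) == dim(labels$data))) {
    stop("delta map and labels are on different grids", call. = FALSE)
  }
  sets <- region_label_sets()
  rows <- lapply(names(sets), function(rn) {
    summarize_region(dvals[label_mask(labels, sets[[rn]])], rn)
  })

  pvs_mask <- if (is.null(pvs)) {
    label_mask(labels, c("pvs_truth_left", "pvs_truth_right"))
  } else if (inherits(pvs, "pvs_segmentation")) {
    pvs$mask_left | pvs$mask_right
  } else {
    pvs
  }
  rows <- c(rows, list(summarize_region(dvals[pvs_mask], "bg_pvs")))

  cp_mask <- if (is.null(cp)) {
    label_mask(labels, "choroid_plexus")
  } else if (inherits(cp, "cp_segmentation")) {
    cp$mask
  } else {
    cp
  }
  rows <- c(rows, list(summarize_region(dvals[cp_mask], "choroid_plexus")))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
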