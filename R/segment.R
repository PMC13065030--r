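#' Histogram-based intensity standardization
#'
#' Maps within-mask intensities through their empirical CDF onto `[0, 1]`
#' (histogram equalization restricted to the mask): the output value of a
#' voxel is the fraction of in-mask voxels with intensity less than or equal
#' to its own. Rank order is preserved exactly; voxels outside the mask are
#' set to 0.
#'
#' @param t1w a [volume()] or 3-D array.
#' @param mask logical array of the same dimensions; must be nonempty.
#' @return Object of the same type as `t1w` with in-mask values in
#'   `(0, 1]`.
#' @export
standardize_histogram <- function(t1w, mask) {
  data <- vol_data(t1w)
  stopifnot(is.logical(mask))
  if (!all(dim(mask) == dim(data))) {
    stop("mask and volume dimensions differ", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  v <- data[mask]
  n <- length(v)
  # empirical CDF value: rank with ties sharing their maximum rank
  cdf_vals <- rank(v, ties.method = "max") / n
  out <- array(0, dim = dim(data))
  out[mask] <- cdf_vals
  if (inherits(t1w, "t1gad_volume")) return(volume(out, t1w$voxel_size))
  out
}

#' Mean-plus-one-SD vesselness threshold
#'
#' The PVS classification threshold: the mean of the vesselness responses
#' within the (refined) basal-ganglia mask plus one standard deviation.
#' The population SD (divisor `n`) is used, a fixed convention so the
#' threshold is exactly recomputable from the saved vesselness volume.
#'
#' @param values vesselness responses within the mask.
#' @return List: `tau` (= `mean + sd`), `mean`, `sd`.
#' @export
vesselness_threshold <- function(values) {
  if (!length(values)) stop("no in-mask vesselness values", call. = FALSE)
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(tau = m + s, mean = m, sd = s)
}

#' Segment basal-ganglia perivascular spaces
#'
#' The rule-based multi-step algorithm: (1) the T1-weighted image is
#' standardized by within-brain histogram equalization; (2) a multiscale
#' dark-tube vesselness filter is applied; (3) the basal-ganglia mask is
#' refined by binary closing followed by dilation with a spherical
#' structuring element; (4) the threshold is the mean vesselness response
#' within the refined mask plus one (population) standard deviation; voxels
#' strictly exceeding it inside the refined mask are classified as PVS;
#' (5) the PVS voxels are split into left/right at the mid-sagittal grid
#' midplane.
#'
#' If the in-mask vesselness has zero variance the threshold equals the
#' mean and, by strict inequality, the PVS masks are empty (logged as a
#' warning).
#'
#' @param t1w pre-contrast T1-weighted [volume()] (co-registered).
#' @param bg_mask logical basal-ganglia mask on the same grid.
#' @param params [vesselness_params()] for the tube filter.
#' @param radius structuring-element radius (voxels) for mask refinement.
#' @param brain_mask logical mask defining the standardization domain;
#'   default: all positive voxels of `t1w`.
#' @return List of class `pvs_segmentation`: `mask_left`, `mask_right`,
#'   `threshold_tau`, `mask_mean`, `mask_sd`, `refined_bg_mask`, and the
#'   `vesselness` volume (so that `tau` is recomputable from the outputs).
#' @export
segment_pvs <- function(t1w, bg_mask, params = vesselness_params(),
                        radius = 2, brain_mask = NULL) {
  data <- vol_data(t1w)
  stopifnot(is.logical(bg_mask), all(dim(bg_mask) == dim(data)))
  if (is.null(brain_mask)) brain_mask <- data > 0
  std <- standardize_histogram(data, brain_mask)
  vess <- frangi_vesselness(std, params)
  refined <- refine_bg_mask(bg_mask, radius)

  thr <- vesselness_threshold(vess[refined])
  tau <- thr$tau
  m <- thr$mean
  s <- thr$sd
  if (s == 0) {
    warning("zero-variance vesselness inside the refined mask; empty PVS masks")
  }
  pvs <- refined & vess > tau

  d <- dim(data)
  x_mid <- (d[1] + 1) / 2
  xs <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  left <- xs < x_mid
  structure(list(mask_left = pvs & left,
                 mask_right = pvs & !left,
                 threshold_tau = tau, mask_mean = m, mask_sd = s,
                 refined_bg_mask = refined,
                 vesselness = vess),
            class = "pvs_segmentation")
}

#' @export
print.pvs_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<pvs_segmentation> tau = %.4g (mean %.4g + sd %.4g); ",
                     "%d left + %d right voxels\n"),
              x$threshold_tau, x$mask_mean, x$mask_sd,
              sum(x$mask_left), sum(x$mask_right)))
  invisible(x)
}

#' Refine a choroid-plexus mask by Gaussian-mixture intensity clustering
#'
#' Within an initial mask covering choroid plexus plus ventricle, fits a
#' `K`-component Gaussian mixture to the post-contrast T1-weighted
#' intensities and assigns voxels by maximum posterior responsibility. The
#' component with the highest mean is returned as choroid plexus (the CP
#' enhances strongly post-contrast while ventricular CSF stays dark). If the
#' in-mask intensities are constant the whole mask is returned (single
#' effective component). When the top-two component means are separated by
#' less than half their pooled SD a warning is raised but the assignment is
#' still returned.
#'
#' @param t1w_post post-contrast T1-weighted [volume()].
#' @param initial_mask logical array (CP + ventricle); must be nonempty.
#' @param K mixture components (default 2: CP vs CSF).
#' @return List of class `cp_segmentation`: `mask` (logical CP mask),
#'   `model` (the [fit_gmm_1d()] fit or `NULL` for a constant mask),
#'   `separable` flag.
#' @export
segment_cp <- function(t1w_post, initial_mask, K = 2L) {
  data <- vol_data(t1w_post)
  stopifnot(is.logical(initial_mask), all(dim(initial_mask) == dim(data)))
  if (!any(initial_mask)) stop("empty initial mask", call. = FALSE)
  v <- data[initial_mask]
  if (stats::sd(v) == 0 || length(v) < 2L * K) {
    return(structure(list(mask = initial_mask, model = NULL, separable = FALSE),
                     class = "cp_segmentation"))
  }
  model <- fit_gmm_1d(v, K = K)
  resp <- gmm_responsibilities(model, v)
  assign <- max.col(resp)
  cp_comp <- which.max(model$means)

  ord <- order(model$means, decreasing = TRUE)
  gap <- model$means[ord[1]] - model$means[ord[2]]
  pooled_sd <- sqrt(mean(model$variances[ord[1:2]]))
  separable <- gap >= 0.5 * pooled_sd
  if (!separable) {
    warning("mixture components are poorly separated (mean gap < 0.5 pooled SD)")
  }

  mask <- array(FALSE, dim = dim(data))
  mask[initial_mask] <- assign == cp_comp
  structure(list(mask = mask, model = model, separable = separable),
            class = "cp_segmentation")
}

#' @export
print.cp_segmentation <- function(x, ...) {
  cat(sprintf("<cp_segmentation> %d voxels, separable: %s\n",
              sum(x$mask), x$separable))
  invisible(x)
}
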