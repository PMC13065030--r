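#' Vesselness filter parameters
#'
#' Defaults follow the standard tubularity-filter constants with the scale
#' range restricted to 1-2 voxels, matched to thin perivascular tubes:
#' scales `{1, 1.5, 2}` voxels, plate/line discriminator `alpha = 0.5`,
#' blob discriminator `beta = 0.5`, and a per-scale structureness constant
#' `c` set from the data (half the maximum Frobenius norm of the Hessian
#' over the volume) when `NULL`. Polarity `"dark_tubes"` targets tubes
#' darker than their surroundings (CSF-filled spaces on T1-weighted
#' images); `"bright_tubes"` is the classical bright-vessel condition.
#'
#' @param scales Gaussian scales (sigma, voxels).
#' @param alpha,beta positive discriminator constants.
#' @param c structureness constant, or `NULL` for the data-driven default.
#' @param polarity `"dark_tubes"` or `"bright_tubes"`.
#' @return List of class `vesselness_params`.
#' @export
vesselness_params <- function(scales = c(1, 1.5, 2), alpha = 0.5, beta = 0.5,
                              c = NULL, polarity = c("dark_tubes",
                                                     "bright_tubes")) {
  polarity <- match.arg(polarity)
  if (!length(scales)) stop("at least one scale is required", call. = FALSE)
  if (any(scales <= 0) || alpha <= 0 || beta <= 0 ||
      (!is.null(c) && c <= 0)) {
    stop("scales, alpha, beta, and c must be positive", call. = FALSE)
  }
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 polarity = polarity),
            class = "vesselness_params")
}

# eigenvalues of the symmetric 3x3 field (closed-form, vectorized),
# returned sorted by absolute value |l1| <= |l2| <= |l3|
symmetric_eigenvalues_sorted <- function(hxx, hyy, hzz, hxy, hxz, hyz) {
  p1 <- hxy^2 + hxz^2 + hyz^2
  q <- (hxx + hyy + hzz) / 3
  p2 <- (hxx - q)^2 + (hyy - q)^2 + (hzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  safe_p <- ifelse(p > 0, p, 1)
  bxx <- (hxx - q) / safe_p; byy <- (hyy - q) / safe_p; bzz <- (hzz - q) / safe_p
  bxy <- hxy / safe_p; bxz <- hxz / safe_p; byz <- hyz / safe_p
  detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  # sorting network on absolute value
  swap <- abs(e1) > abs(e2)
  tmp <- e1; e1 <- ifelse(swap, e2, e1); e2 <- ifelse(swap, tmp, e2)
  swap <- abs(e2) > abs(e3)
  tmp <- e2; e2 <- ifelse(swap, e3, e2); e3 <- ifelse(swap, tmp, e3)
  swap <- abs(e1) > abs(e2)
  tmp <- e1; e1 <- ifelse(swap, e2, e1); e2 <- ifelse(swap, tmp, e2)
  list(l1 = e1, l2 = e2, l3 = e3)
}

#' Scale-normalized Hessian eigenvalues
#'
#' Computes the Gaussian-derivative Hessian of the volume at scale `sigma`
#' (second derivatives of the sigma-smoothed image, multiplied by `sigma^2`
#' for scale normalization) and returns its eigenvalues at every voxel,
#' sorted by absolute value.
#'
#' @param vol a [volume()] or 3-D array with finite values.
#' @param sigma Gaussian scale in voxels, `> 0`.
#' @return List of three arrays `l1`, `l2`, `l3` with
#'   `|l1| <= |l2| <= |l3|` voxelwise.
#' @export
hessian_eigenvalues <- function(vol, sigma) {
  data <- vol_data(vol)
  if (any(!is.finite(data))) {
    stop("volume contains non-finite values", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  s2 <- sigma^2
  hxx <- gaussian_separable(data, sigma, c(2L, 0L, 0L)) * s2
  hyy <- gaussian_separable(data, sigma, c(0L, 2L, 0L)) * s2
  hzz <- gaussian_separable(data, sigma, c(0L, 0L, 2L)) * s2
  hxy <- gaussian_separable(data, sigma, c(1L, 1L, 0L)) * s2
  hxz <- gaussian_separable(data, sigma, c(1L, 0L, 1L)) * s2
  hyz <- gaussian_separable(data, sigma, c(0L, 1L, 1L)) * s2
  ev <- symmetric_eigenvalues_sorted(hxx, hyy, hzz, hxy, hxz, hyz)
  d <- dim(data)
  lapply(ev, function(e) array(e, dim = d))
}

#' Multiscale Frangi vesselness
#'
#' Hessian-based tubularity: at each scale the response is
#' `(1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#' (1 - exp(-S^2 / 2 c^2))` with `Ra = |l2|/|l3|`,
#' `Rb = |l1|/sqrt(|l2 l3|)`, and `S` the Frobenius norm of the
#' eigenvalues, zeroed where the tube-polarity sign condition fails
#' (dark tubes: `l2 > 0` and `l3 > 0`; bright tubes: both negative).
#' The output is the voxelwise maximum over scales, in `[0, 1]`.
#'
#' @param vol a [volume()] or 3-D array.
#' @param params a [vesselness_params()] list.
#' @return Object of the same type as `vol` with values in `[0, 1]`.
#' @export
frangi_vesselness <- function(vol, params = vesselness_params()) {
  if (!inherits(params, "vesselness_params")) {
    stop("`params` must come from vesselness_params()", call. = FALSE)
  }
  data <- vol_data(vol)
  d <- dim(data)
  out <- array(0, dim = d)
  for (sg in params$scales) {
    ev <- hessian_eigenvalues(data, sg)
    l1 <- ev$l1; l2 <- ev$l2; l3 <- ev$l3
    s2 <- l1^2 + l2^2 + l3^2
    smax <- sqrt(max(s2))
    # featureless at this scale (e.g. constant input up to rounding)
    if (smax <= 1e-9 * max(1, max(abs(data)))) next
    cpar <- params$c
    if (is.null(cpar)) cpar <- 0.5 * smax
    a3 <- abs(l3)
    a23 <- abs(l2 * l3)
    ra2 <- ifelse(a3 > 0, (l2 / l3)^2, 0)
    rb2 <- ifelse(a23 > 0, l1^2 / a23, 0)
    v <- (1 - exp(-ra2 / (2 * params$alpha^2))) *
      exp(-rb2 / (2 * params$beta^2)) *
      (1 - exp(-s2 / (2 * cpar^2)))
    ok <- if (params$polarity == "dark_tubes") l2 > 0 & l3 > 0 else
      l2 < 0 & l3 < 0
    v[!ok | a3 == 0] <- 0
    v[s2 < (1e-8 * smax)^2] <- 0   # no structure, no response
    out <- pmax(out, v)
  }
  out <- array(pmin(pmax(out, 0), 1), dim = d)
  if (inherits(vol, "t1gad_volume")) return(volume(out, vol$voxel_size))
  out
}
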