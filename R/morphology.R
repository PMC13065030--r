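# integer offsets of a spherical structuring element of the given radius
ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2 + 1e-9, , drop = FALSE]
}

shift_or <- function(acc, mask, off, d) {
  # acc <- acc | shift(mask, off), zero-padded
  sx <- off[1]; sy <- off[2]; sz <- off[3]
  xi <- max(1, 1 + sx):min(d[1], d[1] + sx)
  yi <- max(1, 1 + sy):min(d[2], d[2] + sy)
  zi <- max(1, 1 + sz):min(d[3], d[3] + sz)
  acc[xi, yi, zi] <- acc[xi, yi, zi] | mask[xi - sx, yi - sy, zi - sz]
  acc
}

#' Binary morphology with a spherical structuring element
#'
#' Dilation, erosion, and closing of a 3-D logical mask with a ball of the
#' given radius (in voxels). Voxels outside the grid count as background.
#'
#' @param mask logical 3-D array.
#' @param radius structuring-element radius in voxels, `>= 1`.
#' @return Logical array of the same dimensions.
#' @export
binary_dilate <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  d <- dim(mask)
  off <- ball_offsets(radius)
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(off))) {
    out <- shift_or(out, mask, as.integer(off[i, ]), d)
  }
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  !binary_dilate(!mask, radius)
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

#' Refine a basal-ganglia mask by closing then dilation
#'
#' Morphological closing (fills interior holes and narrow gaps) followed by
#' dilation with the same spherical structuring element, to ensure the mask
#' comprehensively covers the perivascular territory. The output is always a
#' superset of the input.
#'
#' @param bg_mask logical 3-D array (basal-ganglia labels as a mask).
#' @param radius structuring-element radius in voxels (default 2).
#' @return Refined logical mask.
#' @export
refine_bg_mask <- function(bg_mask, radius = 2) {
  stopifnot(is.logical(bg_mask), length(dim(bg_mask)) == 3L)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  if (!any(bg_mask)) {
    warning("empty input mask; returning an empty mask")
    return(bg_mask)
  }
  binary_dilate(binary_close(bg_mask, radius), radius)
}
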