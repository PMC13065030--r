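#' 3-D scalar volume
#'
#' Lightweight container for a 3-D image: a numeric array plus its voxel size
#' in millimetres. World coordinates follow a RAS-like convention: voxel
#' `(i, j, k)` (1-based) sits at `((i-1) * dx, (j-1) * dy, (k-1) * dz)` mm,
#' axis 1 running left to right, axis 2 posterior to anterior, axis 3
#' inferior to superior. The mid-sagittal plane is at the grid midpoint of
#' axis 1.
#'
#' @param data numeric 3-D array.
#' @param voxel_size voxel edge lengths in mm; scalar or length-3 vector.
#' @return An object of class `t1gad_volume` with elements `data` and
#'   `voxel_size`.
#' @export
volume <- function(data, voxel_size = 1) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive and finite", call. = FALSE)
  }
  structure(list(data = data, voxel_size = voxel_size),
            class = "t1gad_volume")
}

#' @export
print.t1gad_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<t1gad_volume> %d x %d x %d voxels @ %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.t1gad_volume <- function(x) dim(x$data)

# Accept either a t1gad_volume or a bare 3-D array; return the array.
vol_data <- function(x) {
  if (inherits(x, "t1gad_volume") || inherits(x, "t1gad_labels")) {
    return(x$data)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    return(x)
  }
  stop("expected a t1gad_volume, t1gad_labels, or 3-D array", call. = FALSE)
}

vol_voxel_size <- function(x, default = 1) {
  if (inherits(x, "t1gad_volume") || inherits(x, "t1gad_labels")) {
    return(x$voxel_size)
  }
  rep_len(default, 3L)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks on the same
#' grid. Returns `NA` when both masks are empty.
#'
#' @param a,b logical arrays (or volumes coercible to logical).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(vol_data_or_mask(a))
  b <- as.logical(vol_data_or_mask(b))
  if (length(a) != length(b)) stop("masks differ in size", call. = FALSE)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(NA_real_)
  2 * sum(a & b) / (na + nb)
}

vol_data_or_mask <- function(x) {
  if (is.logical(x)) return(x)
  vol_data(x)
}
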