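#' Six-parameter rigid-body transform
#'
#' Rotation (degrees, intrinsic x-y-z Euler angles) and translation (mm)
#' about a rotation center in world coordinates. The transform maps
#' moving-space world coordinates `x` to fixed-space coordinates
#' `y = R (x - c) + c + t`.
#'
#' @param rotations degrees about the x, y, z axes (length 3).
#' @param translations mm along x, y, z (length 3).
#' @param center rotation center in world mm (length 3).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotations = c(0, 0, 0), translations = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotations) == 3L, length(translations) == 3L,
            length(center) == 3L)
  structure(list(rotations = as.numeric(rotations),
                 translations = as.numeric(translations),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s | center: %s\n",
              paste(signif(x$rotations, 4), collapse = ", "),
              paste(signif(x$translations, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  ca <- cos(r[1]); sa <- sin(r[1])
  cb <- cos(r[2]); sb <- sin(r[2])
  cg <- cos(r[3]); sg <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  rz <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3, 3)
  rx %*% ry %*% rz
}

# Euler angles (degrees) of R = Rx(a) Ry(b) Rz(g)
euler_from_matrix <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  g <- atan2(-R[1, 2], R[1, 1])
  c(a, b, g) * 180 / pi
}

#' Homogeneous matrix of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return 4x4 matrix acting on homogeneous world coordinates (mm).
#' @export
transform_matrix <- function(transform) {
  R <- rotation_matrix(transform$rotations)
  c0 <- transform$center
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- c0 + transform$translations - R %*% c0
  m
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$rotations)
  rigid_transform(rotations = euler_from_matrix(t(R)),
                  translations = as.numeric(-t(R) %*% transform$translations),
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` then `b` (i.e.
#' `x -> b(a(x))`), expressed about the center of `b`.
#'
#' @param a,b [rigid_transform()]s.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  m <- transform_matrix(b) %*% transform_matrix(a)
  R <- m[1:3, 1:3]
  c0 <- b$center
  # m x = R x + d ; want R (x - c) + c + t  =>  t = d - c + R c
  t0 <- m[1:3, 4] - c0 + as.numeric(R %*% c0)
  rigid_transform(rotations = euler_from_matrix(R), translations = t0,
                  center = c0)
}

#' Write / read a transform as a plain-text 4x4 matrix
#'
#' World-coordinate (mm) homogeneous matrix, whitespace-separated, four
#' numbers per line.
#'
#' @param transform a [rigid_transform()].
#' @param path file path.
#' @return `write_transform()` returns `path` invisibly; `read_transform()`
#'   returns the 4x4 matrix.
#' @export
write_transform <- function(transform, path) {
  m <- transform_matrix(transform)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4L, 4L))) stop("not a 4x4 transform file: ", path,
                                      call. = FALSE)
  m
}

# world coordinates of the grid center (rotation center used throughout)
grid_center_world <- function(dim3, voxel_size) {
  (dim3 - 1) / 2 * voxel_size
}

# Trilinear/nearest sampling of `data` at continuous voxel indices
# (1-based). Out-of-field points return `background`. Returns list(values,
# valid) where valid marks in-field points.
sample_volume <- function(data, fx, fy, fz, interpolation, background = 0) {
  d <- dim(data)
  if (interpolation == "nearest") {
    i <- round(fx); j <- round(fy); k <- round(fz)
    valid <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    idx <- pmin(pmax(i, 1), d[1]) +
      (pmin(pmax(j, 1), d[2]) - 1) * d[1] +
      (pmin(pmax(k, 1), d[3]) - 1) * d[1] * d[2]
    vals <- data[idx]
    vals[!valid] <- background
    return(list(values = vals, valid = valid))
  }
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  valid <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] &
    fz >= 1 & fz <= d[3]
  i0c <- pmin(pmax(i0, 1), d[1] - 1)
  j0c <- pmin(pmax(j0, 1), d[2] - 1)
  k0c <- pmin(pmax(k0, 1), d[3] - 1)
  wx <- fx - i0c; wy <- fy - j0c; wz <- fz - k0c
  base <- i0c + (j0c - 1) * d[1] + (k0c - 1) * d[1] * d[2]
  sx <- 1L; sy <- d[1]; sz <- d[1] * d[2]
  vals <-
    data[base]                * (1 - wx) * (1 - wy) * (1 - wz) +
    data[base + sx]           * wx       * (1 - wy) * (1 - wz) +
    data[base + sy]           * (1 - wx) * wy       * (1 - wz) +
    data[base + sx + sy]      * wx       * wy       * (1 - wz) +
    data[base + sz]           * (1 - wx) * (1 - wy) * wz +
    data[base + sx + sz]      * wx       * (1 - wy) * wz +
    data[base + sy + sz]      * (1 - wx) * wy       * wz +
    data[base + sx + sy + sz] * wx       * wy       * wz
  vals[!valid] <- background
  list(values = vals, valid = valid)
}

#' Resample a volume through a rigid transform
#'
#' Pulls each output-grid voxel from the moving volume at the
#' inverse-transformed location, so that `resample(moving, t)` aligns a
#' volume that was physically displaced by `t` back onto the fixed grid.
#' Out-of-field voxels are set to the background value (0). Label volumes
#' must use nearest-neighbour interpolation.
#'
#' @param vol a [volume()], `t1gad_labels`, or 3-D array.
#' @param transform a [rigid_transform()].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return Object of the same class as `vol`, on the same grid.
#' @export
resample <- function(vol, transform, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_labels <- inherits(vol, "t1gad_labels")
  if (is_labels && interpolation != "nearest") {
    stop("label volumes must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  }
  data <- vol_data(vol)
  vox <- vol_voxel_size(vol)
  d <- dim(data)
  co <- coord_arrays_dim(d)
  # output world coords -> moving world coords through the inverse map
  inv <- invert_transform(transform)
  R <- rotation_matrix(inv$rotations)
  c0 <- inv$center
  t0 <- inv$translations
  wx <- (co$x - 1) * vox[1] - c0[1]
  wy <- (co$y - 1) * vox[2] - c0[2]
  wz <- (co$z - 1) * vox[3] - c0[3]
  mx <- R[1, 1] * wx + R[1, 2] * wy + R[1, 3] * wz + c0[1] + t0[1]
  my <- R[2, 1] * wx + R[2, 2] * wy + R[2, 3] * wz + c0[2] + t0[2]
  mz <- R[3, 1] * wx + R[3, 2] * wy + R[3, 3] * wz + c0[3] + t0[3]
  s <- sample_volume(data, mx / vox[1] + 1, my / vox[2] + 1, mz / vox[3] + 1,
                     interpolation)
  out <- array(s$values, dim = d)
  if (is_labels) {
    res <- vol
    res$data <- array(as.integer(out), dim = d)
    return(res)
  }
  if (inherits(vol, "t1gad_volume")) return(volume(out, vox))
  out
}

coord_arrays_dim <- function(d) {
  list(
    x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
    y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}
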