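# Gaussian pyramid: smooth (sigma ~ 1 voxel) then decimate by 2 along each
# axis; world coordinates are preserved (voxel size doubles, origin fixed).
downsample_volume <- function(data, vox) {
  sm <- gaussian_smooth(data, sigma = 1)
  d <- dim(sm)
  idx <- lapply(d, function(n) seq(1L, n, by = 2L))
  list(data = sm[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], vox = vox * 2)
}

# Mean squared intensity difference between fixed and the moving volume
# pulled through the transform with parameters p = (rx, ry, rz, tx, ty, tz),
# evaluated over in-field voxels of the fixed grid.
rigid_cost <- function(p, ctx) {
  inv <- invert_transform(rigid_transform(p[1:3], p[4:6], ctx$center))
  R <- rotation_matrix(inv$rotations)
  t0 <- inv$translations
  c0 <- inv$center
  mx <- R[1, 1] * ctx$wx + R[1, 2] * ctx$wy + R[1, 3] * ctx$wz + c0[1] + t0[1]
  my <- R[2, 1] * ctx$wx + R[2, 2] * ctx$wy + R[2, 3] * ctx$wz + c0[2] + t0[2]
  mz <- R[3, 1] * ctx$wx + R[3, 2] * ctx$wy + R[3, 3] * ctx$wz + c0[3] + t0[3]
  s <- sample_volume(ctx$moving, mx / ctx$vox[1] + 1, my / ctx$vox[2] + 1,
                     mz / ctx$vox[3] + 1, "trilinear")
  if (sum(s$valid) < 0.1 * length(s$valid)) return(Inf)
  diff <- s$values[s$valid] - ctx$fixed[s$valid]
  mean(diff * diff)
}

cost_context <- function(moving, fixed, vox, center) {
  d <- dim(fixed)
  co <- coord_arrays_dim(d)
  list(moving = moving, fixed = as.vector(fixed), vox = vox, center = center,
       wx = as.vector((co$x - 1) * vox[1] - center[1]),
       wy = as.vector((co$y - 1) * vox[2] - center[2]),
       wz = as.vector((co$z - 1) * vox[3] - center[3]))
}

# one cyclic coordinate-descent pass over the 6 parameters
coordinate_sweep <- function(p, cur, ctx, bracket, tol) {
  for (k in seq_along(p)) {
    f1 <- function(v) {
      q <- p
      q[k] <- v
      rigid_cost(q, ctx)
    }
    opt <- stats::optimize(f1, interval = c(p[k] - bracket[k], p[k] + bracket[k]),
                           tol = tol[k])
    if (opt$objective < cur) {
      p[k] <- opt$minimum
      cur <- opt$objective
    }
  }
  list(p = p, cost = cur)
}

#' Rigid registration by least-squares intensity matching
#'
#' Estimates the 6-parameter rigid-body transform (3 rotations, 3
#' translations about the volume center) that minimizes the mean squared
#' intensity difference between the transformed moving volume and the fixed
#' volume, using cyclic coordinate descent with golden-section line searches
#' on a multi-resolution Gaussian pyramid. Initialization is the identity;
#' the capture range is about +/-10 mm and +/-10 degrees, suitable for
#' same-session scan pairs.
#'
#' @param moving,fixed [volume()]s on the same voxel grid.
#' @param levels number of pyramid levels (coarsest is decimated by
#'   `2^(levels-1)`).
#' @param tol relative cost-improvement tolerance that ends the sweeps at
#'   each level.
#' @param max_sweeps maximum coordinate-descent sweeps per level.
#' @param bracket initial search half-widths: degrees for rotations, mm for
#'   translations (length 2: `c(rot, trans)`).
#' @param polish run a short derivative-free simplex refinement at full
#'   resolution after the coordinate sweeps (recommended; coordinate descent
#'   alone converges slowly when rotations and translations are coupled).
#' @return List of class `rigid_registration`: `transform` (the estimated
#'   [rigid_transform()]), `cost_initial` and `cost_final` (full-resolution
#'   mean squared difference), `cost_by_level` (full-resolution cost after
#'   each level, coarse to fine), `converged`, and `status` (`"ok"`, or
#'   `"no_improvement"` with the identity returned).
#' @export
register_rigid <- function(moving, fixed, levels = 3L, tol = 1e-4,
                           max_sweeps = 6L, bracket = c(10, 10),
                           polish = TRUE) {
  mv <- vol_data(moving)
  fx <- vol_data(fixed)
  vox_m <- vol_voxel_size(moving)
  vox_f <- vol_voxel_size(fixed)
  if (any(abs(vox_m - vox_f) > 1e-9)) {
    stop("moving and fixed volumes must share a voxel size", call. = FALSE)
  }
  if (!all(dim(mv) == dim(fx))) {
    stop("moving and fixed volumes must share a grid", call. = FALSE)
  }
  center <- grid_center_world(dim(fx), vox_f)

  pyr <- list(list(moving = mv, fixed = fx, vox = vox_f))
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    dm <- downsample_volume(prev$moving, prev$vox)
    df <- downsample_volume(prev$fixed, prev$vox)
    pyr[[l + 1L]] <- list(moving = dm$data, fixed = df$data, vox = dm$vox)
  }
  pyr <- rev(pyr)  # coarse to fine

  full_ctx <- cost_context(mv, fx, vox_f, center)
  cost0 <- rigid_cost(rep(0, 6), full_ctx)
  if (cost0 <= 1e-12) {
    # already perfectly aligned (e.g. a volume registered to itself)
    return(structure(list(transform = rigid_transform(center = center),
                          cost_initial = cost0, cost_final = cost0,
                          cost_by_level = rep(cost0, length(pyr)),
                          converged = TRUE, status = "ok"),
                     class = "rigid_registration"))
  }

  p <- rep(0, 6)
  cost_by_level <- numeric(0)
  for (l in seq_along(pyr)) {
    lvl <- pyr[[l]]
    ctx <- cost_context(lvl$moving, lvl$fixed, lvl$vox, center)
    # shrink the search bracket as resolution increases
    shrink <- 2^(l - 1L)
    br <- c(rep(bracket[1], 3), rep(bracket[2], 3)) / shrink
    line_tol <- pmax(br * 5e-3, 1e-4)
    cur <- rigid_cost(p, ctx)
    for (s in seq_len(max_sweeps)) {
      sw <- coordinate_sweep(p, cur, ctx, br, line_tol)
      p <- sw$p
      if (cur - sw$cost <= tol * max(cur, .Machine$double.eps)) {
        cur <- sw$cost
        break
      }
      cur <- sw$cost
    }
    if (l == length(pyr) && polish) {
      # simplex polish at full resolution: coordinate descent converges
      # slowly when rotations and translations trade off against each other
      op <- stats::optim(p, rigid_cost, ctx = ctx, method = "Nelder-Mead",
                         control = list(maxit = 150L, reltol = 1e-8,
                                        parscale = rep(0.25, 6)))
      if (op$value < cur) p <- op$par
    }
    cost_by_level <- c(cost_by_level, rigid_cost(p, full_ctx))
  }

  cost_final <- rigid_cost(p, full_ctx)
  if (!is.finite(cost_final) || cost_final >= cost0) {
    warning("registration failed to improve on the identity; returning identity")
    return(structure(list(transform = rigid_transform(center = center),
                          cost_initial = cost0, cost_final = cost0,
                          cost_by_level = cost_by_level,
                          converged = FALSE, status = "no_improvement"),
                     class = "rigid_registration"))
  }
  structure(list(transform = rigid_transform(p[1:3], p[4:6], center),
                 cost_initial = cost0, cost_final = cost_final,
                 cost_by_level = cost_by_level,
                 converged = TRUE, status = "ok"),
            class = "rigid_registration")
}

#' @export
print.rigid_registration <- function(x, ...) {
  cat(sprintf("<rigid_registration> status: %s\n", x$status))
  print(x$transform)
  cat(sprintf("  cost: %.6g -> %.6g\n", x$cost_initial, x$cost_final))
  invisible(x)
}
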