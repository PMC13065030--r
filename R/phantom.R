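#' Phantom label codebook
#'
#' Integer codes and names of the structures in the deterministic brain
#' phantom: four lobar cortices per hemisphere, cerebral white matter per
#' hemisphere, cerebellar cortex and white matter, basal ganglia per
#' hemisphere, ventricle, choroid plexus, and ground-truth perivascular-space
#' tubes per hemisphere. Code 0 is background.
#'
#' @return data.frame with columns `code` and `name`.
#' @export
phantom_codebook <- function() {
  data.frame(
    code = 1:18,
    name = c("frontal_cortex_left", "frontal_cortex_right",
             "parietal_cortex_left", "parietal_cortex_right",
             "temporal_cortex_left", "temporal_cortex_right",
             "occipital_cortex_left", "occipital_cortex_right",
             "cerebral_white_matter_left", "cerebral_white_matter_right",
             "cerebellar_cortex", "cerebellar_white_matter",
             "basal_ganglia_left", "basal_ganglia_right",
             "ventricle", "choroid_plexus",
             "pvs_truth_left", "pvs_truth_right"),
    stringsAsFactors = FALSE
  )
}

#' Default phantom geometry
#'
#' Structure positions and sizes as fractions of the (cubic) grid, chosen so
#' the phantom is exactly mirror-symmetric about the mid-sagittal plane.
#' Axis 1 runs left-right, axis 2 posterior-anterior, axis 3
#' inferior-superior.
#'
#' @param n grid size per axis (voxels); at least 48.
#' @param voxel_size voxel edge length in mm.
#' @return Geometry list consumed by [build_label_volume()].
#' @export
phantom_geometry <- function(n = 128L, voxel_size = 1.5) {
  list(
    n = as.integer(n), voxel_size = voxel_size,
    cerebrum = list(center = c(0.50, 0.55, 0.58), semi = c(0.40, 0.40, 0.34),
                    shell = 0.80),
    cerebellum = list(center = c(0.50, 0.30, 0.22), semi = c(0.22, 0.16, 0.13),
                      shell = 0.75),
    ventricle = list(center = c(0.50, 0.57, 0.58), semi = c(0.09, 0.14, 0.08)),
    # choroid plexus: spheres straddling the posterior ventricle wall
    cp = list(dx = 0.05, y = 0.45, z = 0.58, radius = 0.045),
    bg = list(dx = 0.20, y = 0.58, z = 0.58, semi = c(0.08, 0.11, 0.08)),
    # PVS tubes inside each basal-ganglia blob: offsets (fractions of grid,
    # x relative to the blob center and mirrored for the left side),
    # direction, and half-length as a fraction of the blob semi-axis along
    # the tube direction; radius is in voxels (thin tubes, ~1 voxel).
    pvs = list(
      radius = 1.1,
      tubes = list(
        list(offset = c(-0.030, -0.040, 0.000), dir = c(0, 0, 1), half = 0.55),
        list(offset = c( 0.030,  0.000, 0.030), dir = c(0, 1, 0), half = 0.55),
        list(offset = c( 0.000,  0.020, -0.030), dir = c(0, 1, 1), half = 0.45)
      )
    )
  )
}

coord_arrays <- function(n) {
  d <- c(n, n, n)
  list(
    x = array(rep(seq_len(n), times = n * n), d),
    y = array(rep(rep(seq_len(n), each = n), times = n), d),
    z = array(rep(seq_len(n), each = n * n), d)
  )
}

ellipsoid_r2 <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 +
    ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2
}

# squared distance from each coordinate to a finite line segment
segment_dist2 <- function(co, p0, dir, half) {
  dir <- dir / sqrt(sum(dir^2))
  dx <- co$x - p0[1]; dy <- co$y - p0[2]; dz <- co$z - p0[3]
  t <- dx * dir[1] + dy * dir[2] + dz * dir[3]
  t <- pmin(pmax(t, -half), half)
  (dx - t * dir[1])^2 + (dy - t * dir[2])^2 + (dz - t * dir[3])^2
}

#' Build the phantom label volume
#'
#' Deterministic 3-D parcellation: a cerebral ellipsoid whose outer shell is
#' cortex, subdivided into four lobes per hemisphere by angular sectors
#' (anterior/posterior by superior/inferior about the cerebral center) and
#' split left/right at the mid-sagittal plane; interior cerebral white
#' matter per hemisphere; a cerebellar ellipsoid (shell = cortex, core =
#' white matter); a midline ventricle; choroid-plexus blobs attached to the
#' posterior ventricle wall; one basal-ganglia blob per hemisphere, each
#' containing three thin tubes (radius about one voxel, varied orientations)
#' labelled as ground-truth perivascular spaces.
#'
#' @param geometry geometry list from [phantom_geometry()].
#' @return An object of class `t1gad_labels`: integer array `data`,
#'   `voxel_size`, and the `codebook` data.frame.
#' @export
build_label_volume <- function(geometry = phantom_geometry()) {
  n <- geometry$n
  if (is.null(n) || n < 48L) {
    stop("grid too small: the phantom needs at least 48 voxels per axis",
         call. = FALSE)
  }
  cb <- phantom_codebook()
  code <- function(nm) cb$code[match(nm, cb$name)]
  co <- coord_arrays(n)
  pos <- function(frac) frac * (n + 1)   # grid-fraction -> voxel coordinate
  len <- function(frac) frac * n
  cx <- pos(0.5)
  left <- co$x < cx

  lab <- array(0L, dim = c(n, n, n))

  # cerebrum: cortex shell + white matter core
  g <- geometry$cerebrum
  ctr <- pos(g$center); semi <- len(g$semi)
  r2 <- ellipsoid_r2(co, ctr, semi)
  in_cer <- r2 <= 1
  shell <- in_cer & r2 > g$shell^2
  ant <- co$y >= ctr[2]; sup <- co$z >= ctr[3]
  lobe <- array("", dim = dim(lab))
  lobe[shell & ant & sup] <- "frontal_cortex"
  lobe[shell & !ant & sup] <- "parietal_cortex"
  lobe[shell & ant & !sup] <- "temporal_cortex"
  lobe[shell & !ant & !sup] <- "occipital_cortex"
  for (l in c("frontal_cortex", "parietal_cortex",
              "temporal_cortex", "occipital_cortex")) {
    lab[lobe == l & left] <- code(paste0(l, "_left"))
    lab[lobe == l & !left] <- code(paste0(l, "_right"))
  }
  core <- in_cer & !shell
  lab[core & left] <- code("cerebral_white_matter_left")
  lab[core & !left] <- code("cerebral_white_matter_right")

  # cerebellum (only where outside the cerebrum)
  g <- geometry$cerebellum
  r2cb <- ellipsoid_r2(co, pos(g$center), len(g$semi))
  in_cb <- r2cb <= 1 & !in_cer
  lab[in_cb & r2cb > g$shell^2] <- code("cerebellar_cortex")
  lab[in_cb & r2cb <= g$shell^2] <- code("cerebellar_white_matter")

  # basal ganglia, one blob per hemisphere
  g <- geometry$bg
  bg_r <- ellipsoid_r2(co, c(pos(0.5 + g$dx), pos(g$y), pos(g$z)),
                       len(g$semi)) <= 1
  bg_l <- ellipsoid_r2(co, c(pos(0.5 - g$dx), pos(g$y), pos(g$z)),
                       len(g$semi)) <= 1
  lab[bg_l] <- code("basal_ganglia_left")
  lab[bg_r] <- code("basal_ganglia_right")

  # ventricle + choroid plexus (CP overrides the ventricle wall region)
  g <- geometry$ventricle
  in_vent <- ellipsoid_r2(co, pos(g$center), len(g$semi)) <= 1
  lab[in_vent] <- code("ventricle")
  g <- geometry$cp
  for (s in c(-1, 1)) {
    ctr_cp <- c(pos(0.5 + s * g$dx), pos(g$y), pos(g$z))
    d2 <- (co$x - ctr_cp[1])^2 + (co$y - ctr_cp[2])^2 + (co$z - ctr_cp[3])^2
    lab[d2 <= len(g$radius)^2 & in_cer] <- code("choroid_plexus")
  }

  # PVS truth tubes, strictly inside each basal-ganglia blob
  g <- geometry$pvs
  bgg <- geometry$bg
  for (s in c(-1, 1)) {
    bctr <- c(pos(0.5 + s * bgg$dx), pos(bgg$y), pos(bgg$z))
    inside <- if (s < 0) bg_l else bg_r
    pvs_code <- code(if (s < 0) "pvs_truth_left" else "pvs_truth_right")
    for (tb in g$tubes) {
      off <- tb$offset * c(s, 1, 1)
      dir <- tb$dir * c(s, 1, 1)
      axis_semi <- len(sqrt(sum((bgg$semi * tb$dir / sqrt(sum(tb$dir^2)))^2)))
      d2 <- segment_dist2(co, bctr + len(off), dir, tb$half * axis_semi)
      lab[d2 <= g$radius^2 & inside] <- pvs_code
    }
  }

  structure(list(data = lab, voxel_size = rep(geometry$voxel_size, 3L),
                 codebook = cb),
            class = "t1gad_labels")
}

#' @export
print.t1gad_labels <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<t1gad_labels> %d x %d x %d voxels @ %g mm, %d labels\n",
              d[1], d[2], d[3], x$voxel_size[1],
              length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' Binary mask for one or more phantom labels
#'
#' @param labels a `t1gad_labels` object.
#' @param names label names from [phantom_codebook()].
#' @return Logical array, `TRUE` where the voxel carries any of the labels.
#' @export
label_mask <- function(labels, names) {
  cb <- labels$codebook
  unknown <- setdiff(names, cb$name)
  if (length(unknown)) {
    stop("unknown label name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  array(labels$data %in% cb$code[cb$name %in% names], dim = dim(labels$data))
}

#' Default pre-contrast tissue T1 values
#'
#' Plausible 3T longitudinal relaxation times in ms per phantom structure.
#' These are phantom placeholders, not acquisition values: only the
#' post-minus-pre difference matters downstream.
#'
#' @return Named numeric vector (ms) over the codebook names.
#' @export
default_tissue_t1 <- function() {
  c(frontal_cortex_left = 1400, frontal_cortex_right = 1400,
    parietal_cortex_left = 1400, parietal_cortex_right = 1400,
    temporal_cortex_left = 1400, temporal_cortex_right = 1400,
    occipital_cortex_left = 1400, occipital_cortex_right = 1400,
    cerebral_white_matter_left = 850, cerebral_white_matter_right = 850,
    cerebellar_cortex = 1350, cerebellar_white_matter = 850,
    basal_ganglia_left = 1300, basal_ganglia_right = 1300,
    ventricle = 4000, choroid_plexus = 2200,
    pvs_truth_left = 4000, pvs_truth_right = 4000)
}

#' Default enhancement magnitudes per label
#'
#' Enhancement magnitude (ms of T1 shortening; the rendered delta-T1 equals
#' minus this value) per phantom label, taken from the period-specific
#' regional medians of the generative model: the global cortical magnitude
#' is applied to all lobar cortex labels, the perivascular-space magnitude
#' to the ground-truth tubes, and the choroid-plexus magnitude to the CP
#' blob. The ventricle (CSF) is left unenhanced and the basal-ganglia
#' parenchyma gets a small white-matter-like magnitude (neither region's
#' enhancement is part of the reported region set).
#'
#' @param period `"day"` or `"night"`.
#' @param params generative parameters, see [default_generative_params()].
#' @return Named numeric vector of magnitudes (ms, nonnegative).
#' @export
default_enhancement <- function(period = c("day", "night"),
                                params = default_generative_params()) {
  period <- match.arg(period)
  mu <- function(rn) {
    r <- params$regions[[rn]]
    -(if (period == "day") r$mu_day else r$mu_night)
  }
  cortex <- mu("cerebral_cortex")
  c(frontal_cortex_left = cortex, frontal_cortex_right = cortex,
    parietal_cortex_left = cortex, parietal_cortex_right = cortex,
    temporal_cortex_left = cortex, temporal_cortex_right = cortex,
    occipital_cortex_left = cortex, occipital_cortex_right = cortex,
    cerebral_white_matter_left = mu("cerebral_white_matter"),
    cerebral_white_matter_right = mu("cerebral_white_matter"),
    cerebellar_cortex = mu("cerebellar_cortex"),
    cerebellar_white_matter = mu("cerebellar_white_matter"),
    basal_ganglia_left = 40, basal_ganglia_right = 40,
    ventricle = 0,
    choroid_plexus = mu("choroid_plexus"),
    pvs_truth_left = mu("bg_pvs"), pvs_truth_right = mu("bg_pvs"))
}

# monotone decreasing T1 -> T1-weighted intensity map, fixed anchors so pre
# and post images share one intensity scale; CSF-like (long T1) voxels dark
t1w_from_t1 <- function(t1, fg) {
  s_lo <- 1 / 4500
  s_hi <- 1 / 600
  w <- array(0, dim = dim(t1))
  t1_fg <- pmax(t1[fg], 600)
  w[fg] <- 1000 * pmax((1 / t1_fg - s_lo) / (s_hi - s_lo), 0)
  w
}

#' Render pre/post-contrast T1 maps and T1-weighted images
#'
#' Builds the pre-contrast T1 map from per-label tissue T1 values, the
#' post-contrast map as `pre - enhancement_magnitude(label) + Normal(0,
#' noise_sd)` on foreground voxels, and T1-weighted images by a fixed
#' monotone decreasing map of (noisy) T1, so CSF-filled spaces
#' (ventricle, perivascular tubes) are hypointense. Background stays 0.
#'
#' @param labels a `t1gad_labels` phantom parcellation.
#' @param enhancement named magnitudes (ms) keyed by codebook label names;
#'   see [default_enhancement()].
#' @param noise_sd Gaussian voxel noise SD (ms) added to the post-contrast
#'   map; 0 gives an exact noiseless rendering.
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @param tissue_t1 named pre-contrast T1 values per label (ms).
#' @return List of [volume()]s: `t1_pre`, `t1_post`, `t1w_pre`, `t1w_post`.
#' @export
render_t1_pair <- function(labels, enhancement = default_enhancement("day"),
                           noise_sd = 0, seed = 1L,
                           tissue_t1 = default_tissue_t1()) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  cb <- labels$codebook
  unknown <- setdiff(names(enhancement), cb$name)
  if (length(unknown)) {
    stop("unknown region key(s) in `enhancement`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lab <- labels$data
  fg <- lab > 0L

  # per-code lookup tables (code i at position i)
  t1_by_code <- numeric(max(cb$code))
  t1_by_code[cb$code] <- tissue_t1[cb$name]
  enh_by_code <- numeric(max(cb$code))
  enh_by_code[cb$code[match(names(enhancement), cb$name)]] <- enhancement

  pre <- array(0, dim = dim(lab))
  pre[fg] <- t1_by_code[lab[fg]]
  post <- array(0, dim = dim(lab))
  post[fg] <- pre[fg] - enh_by_code[lab[fg]]
  if (noise_sd > 0) {
    set.seed(seed)
    post[fg] <- post[fg] + stats::rnorm(sum(fg), 0, noise_sd)
  }
  vx <- labels$voxel_size
  list(t1_pre = volume(pre, vx),
       t1_post = volume(post, vx),
       t1w_pre = volume(t1w_from_t1(pre, fg), vx),
       t1w_post = volume(t1w_from_t1(post, fg), vx))
}
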