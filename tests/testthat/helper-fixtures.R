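# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_labels <- function(n = 64L) {
  memo(paste0("labels_", n), build_label_volume(phantom_geometry(n)))
}

fixture_rendered <- function(n = 64L, period = "day", noise_sd = 20,
                             seed = 7L) {
  key <- sprintf("render_%d_%s_%g_%d", n, period, noise_sd, seed)
  memo(key, render_t1_pair(fixture_labels(n),
                           enhancement = default_enhancement(period),
                           noise_sd = noise_sd, seed = seed))
}

fixture_pvs <- function(n = 64L) {
  key <- sprintf("pvs_%d", n)
  memo(key, {
    lab <- fixture_labels(n)
    imgs <- fixture_rendered(n)
    bg <- label_mask(lab, c("basal_ganglia_left", "basal_ganglia_right",
                            "pvs_truth_left", "pvs_truth_right"))
    segment_pvs(imgs$t1w_pre, bg)
  })
}

# a smooth synthetic dark tube along `dir` in a constant background
make_tube_volume <- function(n = 33L, radius = 1.5, dir = c(0, 0, 1),
                             contrast = 100, background = 200) {
  dir <- dir / sqrt(sum(dir^2))
  c0 <- rep((n + 1) / 2, 3)
  co <- list(
    x = array(rep(seq_len(n), times = n * n), rep(n, 3)),
    y = array(rep(rep(seq_len(n), each = n), times = n), rep(n, 3)),
    z = array(rep(seq_len(n), each = n * n), rep(n, 3))
  )
  dx <- co$x - c0[1]; dy <- co$y - c0[2]; dz <- co$z - c0[3]
  t <- dx * dir[1] + dy * dir[2] + dz * dir[3]
  d2 <- (dx - t * dir[1])^2 + (dy - t * dir[2])^2 + (dz - t * dir[3])^2
  background - contrast * exp(-d2 / (2 * radius^2))
}

make_plate_volume <- function(n = 33L, thickness = 1.5, contrast = 100,
                              background = 200) {
  c0 <- (n + 1) / 2
  z <- array(rep(seq_len(n), each = n * n), rep(n, 3))
  background - contrast * exp(-(z - c0)^2 / (2 * thickness^2))
}

make_blob_volume <- function(n = 33L, radius = 1.5, contrast = 100,
                             background = 200) {
  c0 <- rep((n + 1) / 2, 3)
  co <- list(
    x = array(rep(seq_len(n), times = n * n), rep(n, 3)),
    y = array(rep(rep(seq_len(n), each = n), times = n), rep(n, 3)),
    z = array(rep(seq_len(n), each = n * n), rep(n, 3))
  )
  d2 <- (co$x - c0[1])^2 + (co$y - c0[2])^2 + (co$z - c0[3])^2
  background - contrast * exp(-d2 / (2 * radius^2))
}

center_value <- function(vol) {
  d <- dim(vol)
  c0 <- (d + 1) / 2
  vol[c0[1], c0[2], c0[3]]
}

# generative parameters with all regions sharing one configuration; used to
# build small targeted simulations
flat_params <- function(mu_day = -100, mu_night = -100, beta_day = 0,
                        beta_night = 0, sd = 0) {
  p <- default_generative_params()
  for (rn in names(p$regions)) {
    p$regions[[rn]] <- list(mu_day = mu_day, mu_night = mu_night,
                            beta_age_day = beta_day,
                            beta_age_night = beta_night, subject_sd = sd)
  }
  p
}
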