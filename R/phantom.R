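# Synthetic 3D B-mode finger-joint phantoms with ground-truth synovium masks.
#
# Each phantom emulates, top to bottom along the axial (H) axis: a bright
# skin band, echogenic background tissue with low-frequency intensity
# inhomogeneity, a hypoechoic synovium blob with a smoothly deformed
# boundary, a curved hyperechoic bone interface, and an acoustic shadow
# decaying below the bone. Multiplicative gamma speckle (unit mean) is
# applied everywhere. All randomness is driven by the config seed.

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# stable per-case seed derived from (global seed, index); stays below 2^31
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(s %% m)
}

# smooth random field in [-1, 1]: coarse uniform grid upsampled trilinearly
smooth_field <- function(dims, coarse = c(6, 6, 4)) {
  coarse <- pmax(2L, pmin(as.integer(coarse), as.integer(dims)))
  g <- array(stats::runif(prod(coarse), -1, 1), dim = coarse)
  resize_array(g, dims)
}

#' Phantom generator configuration
#'
#' @param shape target grid extents (H, W, D); the study's working
#'   resolution is 256 x 256 x 64.
#' @param synovium_fraction_range `(lo, hi)` admissible mask volume fraction,
#'   `0 < lo < hi < 0.5`.
#' @param speckle_scale standard deviation of the unit-mean multiplicative
#'   gamma speckle.
#' @param shadow_strength attenuation depth of the acoustic shadow in
#'   `[0, 1]` (0 = no shadow).
#' @param bone_depth_range bone-interface depth as a fraction of H.
#' @param contrast_gap hypoechoic-to-background mean intensity ratio in
#'   (0, 1); smaller = darker synovium.
#' @param seed integer RNG seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(256, 256, 64),
                           synovium_fraction_range = c(0.02, 0.10),
                           speckle_scale = 0.3,
                           shadow_strength = 0.7,
                           bone_depth_range = c(0.55, 0.75),
                           contrast_gap = 0.45,
                           seed = 1L) {
  shape <- as.integer(shape)
  fr <- as.numeric(synovium_fraction_range)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be three extents of at least 8 voxels")
  if (length(fr) != 2L || !(0 < fr[1] && fr[1] < fr[2] && fr[2] < 0.5))
    stop("synovium_fraction_range must satisfy 0 < lo < hi < 0.5")
  if (speckle_scale <= 0) stop("speckle_scale must be positive")
  if (shadow_strength < 0 || shadow_strength > 1)
    stop("shadow_strength must be in [0, 1]")
  bd <- as.numeric(bone_depth_range)
  if (length(bd) != 2L || bd[1] > bd[2] || bd[1] <= 0 || bd[2] >= 1)
    stop("bone_depth_range must be an ordered pair inside (0, 1)")
  if (contrast_gap <= 0 || contrast_gap >= 1)
    stop("contrast_gap must be in (0, 1)")
  if (prod(shape) * fr[1] < 8)
    stop("fraction range infeasible for this shape (target below 8 voxels)")
  structure(list(shape = shape, synovium_fraction_range = fr,
                 speckle_scale = speckle_scale,
                 shadow_strength = shadow_strength,
                 bone_depth_range = bd, contrast_gap = contrast_gap,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate one synthetic ultrasound phantom
#'
#' Fully determined by `config$seed` (or the `seed` override). With
#' `diagnostics = TRUE` the returned case carries an attribute `regions`
#' (list of logical arrays: `background` = echogenic tissue above the bone
#' and outside skin/synovium, `shadow`, `bone`) used by the hypoechoic
#' contrast contract.
#'
#' @param config a [phantom_config()].
#' @param seed optional seed override.
#' @param id case id.
#' @param diagnostics attach region maps.
#' @return A [us_case()] with volume in `[0, 1]` and binary synovium mask
#'   whose volume fraction lies inside `config$synovium_fraction_range`.
#' @export
generate_phantom <- function(config, seed = config$seed, id = "phantom",
                             diagnostics = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    dm <- config$shape
    H <- dm[1]; W <- dm[2]; D <- dm[3]
    hh <- slice.index(array(0, dm), 1L)
    ww <- slice.index(array(0, dm), 2L)
    dd <- slice.index(array(0, dm), 3L)

    # echogenic background with low-frequency inhomogeneity
    vol <- 0.45 + 0.10 * smooth_field(dm)

    # bright skin band at the top
    n_skin <- max(2L, round(0.04 * H))
    skin <- hh <= n_skin
    vol[skin] <- 0.85

    # curved hyperechoic bone interface + shadow below
    depth <- stats::runif(1, config$bone_depth_range[1], config$bone_depth_range[2])
    curve <- smooth_field(c(W, D, 2L), coarse = c(4, 3, 2))[, , 1]
    zb2 <- depth * H + 0.05 * H * curve          # W x D depth map
    zb <- aperm(array(zb2, dim = c(W, D, H)), c(3, 1, 2))
    thick <- max(2, round(0.03 * H))
    bone <- hh >= zb & hh < zb + thick
    below <- hh >= zb + thick
    tau <- 0.10 * H
    atten <- (1 - config$shadow_strength) +
      config$shadow_strength * exp(-pmax(hh - zb - thick, 0) / tau)
    vol[below] <- vol[below] * atten[below]
    vol[bone] <- 0.9

    # hypoechoic synovium: union of deformed ellipsoids above the bone
    top_room <- max(n_skin + 2, min(zb2) - 2)
    hc <- stats::runif(1, 0.35, 0.75) * top_room
    wc <- stats::runif(1, 0.35, 0.65) * W
    dc <- stats::runif(1, 0.35, 0.65) * D
    ne <- sample.int(3L, 1L)
    q <- array(Inf, dm)
    for (e in seq_len(ne)) {
      ce <- c(hc, wc, dc) +
        c(0.06 * H, 0.08 * W, 0.08 * D) * stats::runif(3, -1, 1)
      r <- c(0.10 * H, 0.16 * W, 0.16 * D) * stats::runif(3, 0.7, 1.3)
      qe <- sqrt(((hh - ce[1]) / r[1])^2 + ((ww - ce[2]) / r[2])^2 +
                 ((dd - ce[3]) / r[3])^2)
      q <- pmin(q, qe)
    }
    q <- q + 0.18 * smooth_field(dm)             # ambiguous, deformed boundary
    feasible <- hh > n_skin & hh < zb - 1        # strictly above the bone
    fr <- config$synovium_fraction_range
    frac_at <- function(s) mean(q < s & feasible)
    lo_s <- 0.02; hi_s <- 6
    if (frac_at(hi_s) < fr[1])
      stop("fraction range infeasible: not enough room above the bone")
    # per-phantom target drawn inside the range (5% margin guards the
    # discretization error of the bisection)
    target <- stats::runif(1, fr[1] + 0.05 * diff(fr),
                           fr[2] - 0.05 * diff(fr))
    for (i in 1:48) {                            # bisection on blob scale
      mid <- (lo_s + hi_s) / 2
      if (frac_at(mid) < target) lo_s <- mid else hi_s <- mid
    }
    s <- (lo_s + hi_s) / 2
    mask <- (q < s & feasible) * 1
    if (mean(mask) < fr[1] || mean(mask) > fr[2])
      stop("fraction range infeasible for this shape")
    vol[mask == 1] <- vol[mask == 1] * config$contrast_gap

    # unit-mean multiplicative gamma speckle
    a <- 1 / config$speckle_scale^2
    vol <- vol * array(stats::rgamma(prod(dm), shape = a, rate = a), dm)
    vol <- pmin(pmax(vol, 0), 1)

    cs <- us_case(id, us_volume(vol), us_mask(mask))
    if (diagnostics) {
      attr(cs, "regions") <- list(
        background = !skin & !bone & !below & mask == 0,
        shadow = below & mask == 0,
        bone = bone)
    }
    cs
  })
}

#' Generate a reproducible phantom dataset
#'
#' Per-case seeds are derived by stable hashing of `(config$seed, index)`.
#'
#' @param config a [phantom_config()].
#' @param n number of phantoms (>= 1).
#' @return List of [us_case()] with unique ids.
#' @export
generate_dataset <- function(config, n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  lapply(seq_len(n), function(i)
    generate_phantom(config, seed = derive_seed(config$seed, i),
                     id = sprintf("phantom_%04d", i)))
}

#' Write a phantom dataset as NIfTI pairs plus a CSV manifest
#'
#' @param cases list of [us_case()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame
#'   (id, volume, mask, mask_fraction).
#' @export
write_dataset <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cases, function(cs) {
    vp <- file.path(dir, paste0(cs$id, "_vol.nii.gz"))
    mp <- file.path(dir, paste0(cs$id, "_mask.nii.gz"))
    write_case(cs, vp, mp)
    data.frame(id = cs$id, volume = vp, mask = mp,
               mask_fraction = mean(cs$mask$data))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# ---- augmentation ----------------------------------------------------------

#' Augmentation configuration
#'
#' The family mirrors standard ultrasound training augmentation: random
#' flips, small rotation about the elevation axis (probe angle), random
#' brightness/contrast (gain/dynamic range), Gaussian blur, and additive
#' Gaussian noise. Parameter ranges are configurable; the defaults are
#' conservative placeholders.
#'
#' @param flip_axes axes eligible for flipping (subset of 1:3; default
#'   lateral + elevation).
#' @param flip_prob per-axis flip probability.
#' @param rotation_max_deg maximal rotation magnitude about the elevation
#'   axis, degrees.
#' @param rotation_prob probability of applying a rotation.
#' @param brightness_delta maximal additive intensity shift.
#' @param contrast_range multiplicative contrast factor range.
#' @param intensity_prob probability of applying brightness/contrast.
#' @param blur_sigma_range Gaussian blur sigma range, voxels.
#' @param blur_prob probability of blurring.
#' @param noise_std additive Gaussian noise standard deviation.
#' @param noise_prob probability of adding noise.
#' @param seed integer RNG seed.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(flip_axes = c(2L, 3L), flip_prob = 0.5,
                                rotation_max_deg = 15, rotation_prob = 0.5,
                                brightness_delta = 0.1,
                                contrast_range = c(0.9, 1.1),
                                intensity_prob = 0.5,
                                blur_sigma_range = c(0.25, 1),
                                blur_prob = 0.25,
                                noise_std = 0.02, noise_prob = 0.5,
                                seed = 1L) {
  stopifnot(all(flip_axes %in% 1:3), rotation_max_deg >= 0,
            brightness_delta >= 0, diff(contrast_range) >= 0,
            all(blur_sigma_range >= 0), diff(blur_sigma_range) >= 0,
            noise_std >= 0)
  probs <- c(flip_prob, rotation_prob, intensity_prob, blur_prob, noise_prob)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(list(flip_axes = as.integer(flip_axes), flip_prob = flip_prob,
                 rotation_max_deg = rotation_max_deg,
                 rotation_prob = rotation_prob,
                 brightness_delta = brightness_delta,
                 contrast_range = as.numeric(contrast_range),
                 intensity_prob = intensity_prob,
                 blur_sigma_range = as.numeric(blur_sigma_range),
                 blur_prob = blur_prob, noise_std = noise_std,
                 noise_prob = noise_prob, seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Sample one concrete augmentation transform
#'
#' @param config an [augmentation_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return List of sampled transform parameters.
#' @export
sample_augmentation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "augmentation_config"))
  with_seed(seed, {
    flips <- config$flip_axes[stats::runif(length(config$flip_axes)) <
                                config$flip_prob]
    angle <- if (stats::runif(1) < config$rotation_prob)
      stats::runif(1, -config$rotation_max_deg, config$rotation_max_deg) else 0
    if (stats::runif(1) < config$intensity_prob) {
      contrast <- stats::runif(1, config$contrast_range[1],
                               config$contrast_range[2])
      brightness <- stats::runif(1, -config$brightness_delta,
                                 config$brightness_delta)
    } else {
      contrast <- 1; brightness <- 0
    }
    sigma <- if (stats::runif(1) < config$blur_prob)
      stats::runif(1, config$blur_sigma_range[1],
                   config$blur_sigma_range[2]) else 0
    noise_seed <- sample.int(.Machine$integer.max, 1L)
    noise <- if (stats::runif(1) < config$noise_prob) config$noise_std else 0
    list(flips = flips, angle = angle, contrast = contrast,
         brightness = brightness, sigma = sigma, noise = noise,
         noise_seed = noise_seed)
  })
}

# rotate the H-W plane of a 3D array about the volume center (elevation axis)
rotate_hw <- function(a, angle_deg, nearest = FALSE) {
  if (angle_deg == 0) return(a)
  dm <- dim(a)
  th <- angle_deg * pi / 180
  hc <- (dm[1] + 1) / 2; wc <- (dm[2] + 1) / 2
  gh <- rep(seq_len(dm[1]), times = dm[2])
  gw <- rep(seq_len(dm[2]), each = dm[1])
  sh <- cos(th) * (gh - hc) - sin(th) * (gw - wc) + hc
  sw <- sin(th) * (gh - hc) + cos(th) * (gw - wc) + wc
  out <- array(0, dm)
  if (nearest) {
    ih <- round(sh); iw <- round(sw)
    ok <- ih >= 1 & ih <= dm[1] & iw >= 1 & iw <= dm[2]
    for (d in seq_len(dm[3])) {
      sl <- a[, , d]
      res <- numeric(length(gh))
      res[ok] <- sl[cbind(ih[ok], iw[ok])]
      out[, , d] <- res
    }
  } else {
    h0 <- floor(sh); w0 <- floor(sw)
    fh <- sh - h0; fw <- sw - w0
    ok <- h0 >= 1 & h0 + 1 <= dm[1] & w0 >= 1 & w0 + 1 <= dm[2]
    for (d in seq_len(dm[3])) {
      sl <- a[, , d]
      res <- numeric(length(gh))
      res[ok] <-
        sl[cbind(h0[ok], w0[ok])] * (1 - fh[ok]) * (1 - fw[ok]) +
        sl[cbind(h0[ok] + 1, w0[ok])] * fh[ok] * (1 - fw[ok]) +
        sl[cbind(h0[ok], w0[ok] + 1)] * (1 - fh[ok]) * fw[ok] +
        sl[cbind(h0[ok] + 1, w0[ok] + 1)] * fh[ok] * fw[ok]
      out[, , d] <- res
    }
  }
  out
}

gaussian_blur3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  dm <- dim(a)
  r <- max(1L, ceiling(2.5 * sigma))
  k <- 2L * r + 1L
  k1 <- stats::dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  ker <- outer(outer(k1, k1), k1)           # (kh, kw, kd), kh fastest
  Wc <- array(as.vector(ker), dim = c(1L, 1L, k^3))
  x <- a; dim(x) <- c(prod(dm), 1L)
  y <- cpp_conv3d_fwd(x, as.integer(dm), Wc, 0, as.integer(k), 1L)
  dim(y) <- dm
  y
}

#' Apply a sampled augmentation transform to a case
#'
#' Geometric parts (flips, rotation) are applied identically to volume
#' (trilinear) and mask (nearest); intensity parts (brightness/contrast,
#' blur, noise) to the volume only. Output intensities are clipped to
#' `[0, 1]`; the mask stays exactly binary.
#'
#' @param case a [us_case()].
#' @param transform output of [sample_augmentation()].
#' @return The augmented [us_case()].
#' @export
apply_augmentation <- function(case, transform) {
  v <- case$volume$data
  m <- case$mask$data
  for (ax in transform$flips) {
    idx <- rev(seq_len(dim(v)[ax]))
    if (ax == 1L) { v <- v[idx, , , drop = FALSE]; m <- m[idx, , , drop = FALSE] }
    if (ax == 2L) { v <- v[, idx, , drop = FALSE]; m <- m[, idx, , drop = FALSE] }
    if (ax == 3L) { v <- v[, , idx, drop = FALSE]; m <- m[, , idx, drop = FALSE] }
  }
  if (transform$angle != 0) {
    v <- rotate_hw(v, transform$angle, nearest = FALSE)
    m <- rotate_hw(m, transform$angle, nearest = TRUE)
  }
  if (transform$contrast != 1 || transform$brightness != 0) {
    mu <- mean(v)
    v <- (v - mu) * transform$contrast + mu + transform$brightness
  }
  if (transform$sigma > 0) v <- gaussian_blur3(v, transform$sigma)
  if (transform$noise > 0)
    v <- v + with_seed(transform$noise_seed,
                       array(stats::rnorm(length(v), 0, transform$noise),
                             dim(v)))
  v <- pmin(pmax(v, 0), 1)
  us_case(case$id, us_volume(v, case$volume$spacing), us_mask(m))
}

#' Randomly augment a case (sample + apply)
#'
#' Deterministic given `seed`.
#'
#' @param case a [us_case()].
#' @param config an [augmentation_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return The augmented [us_case()].
#' @export
augment_case <- function(case, config, seed = config$seed) {
  apply_augmentation(case, sample_augmentation(config, seed))
}
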