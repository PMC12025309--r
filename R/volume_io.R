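#' @useDynLib swindaf3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils head read.csv write.csv
NULL

# ---- domain containers -----------------------------------------------------

#' Construct a 3D ultrasound volume
#'
#' A volume is a 3D grid of finite intensities (arbitrary units before
#' normalization, `[0,1]` after) with per-axis voxel spacing in mm. The axis
#' order is fixed as (H, W, D) = (axial depth, lateral, elevation).
#'
#' @param intensities 3D numeric array.
#' @param spacing positive numeric length-3 voxel size in mm.
#' @return An object of class `us_volume` with fields `data` and `spacing`.
#' @export
us_volume <- function(intensities, spacing = c(1, 1, 1)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L)
    stop("volume must be a 3D array, got ", length(dim(intensities)), " dims")
  if (!all(is.finite(intensities)))
    stop("volume intensities must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(list(data = intensities, spacing = spacing), class = "us_volume")
}

#' Construct a binary label mask
#'
#' @param labels 3D array with values exactly 0 or 1 (logical accepted).
#' @return An object of class `us_mask`.
#' @export
us_mask <- function(labels) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(labels) <- "double"
  if (!all(labels %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  structure(list(data = labels), class = "us_mask")
}

#' Construct a case (volume + aligned ground-truth mask)
#'
#' @param id character identifier.
#' @param volume a [us_volume()].
#' @param mask a [us_mask()] with the same extents.
#' @return An object of class `us_case`.
#' @export
us_case <- function(id, volume, mask) {
  stopifnot(inherits(volume, "us_volume"), inherits(mask, "us_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("volume and mask shapes differ: ",
         paste(dim(volume$data), collapse = "x"), " vs ",
         paste(dim(mask$data), collapse = "x"))
  structure(list(id = as.character(id), volume = volume, mask = mask),
            class = "us_case")
}

#' @export
print.us_case <- function(x, ...) {
  d <- dim(x$volume$data)
  cat(sprintf("<us_case '%s'> %dx%dx%d, mask fraction %.4f\n",
              x$id, d[1], d[2], d[3], mean(x$mask$data)))
  invisible(x)
}

# ---- NIfTI I/O -------------------------------------------------------------

#' Read a volume/mask pair from NIfTI files
#'
#' Mask intensities above 0.5 are mapped to 1 (so `{0, 255}`-coded masks read
#' as binary). Voxel spacing is taken from the volume header.
#'
#' @param volume_path,mask_path paths to 3D single-channel NIfTI images.
#' @param id case identifier; defaults to the volume file name.
#' @return A [us_case()].
#' @export
read_case <- function(volume_path, mask_path,
                      id = sub("\\.nii(\\.gz)?$", "", basename(volume_path))) {
  for (p in c(volume_path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  v <- RNifti::readNifti(volume_path)
  m <- RNifti::readNifti(mask_path)
  vd <- drop(as.array(v)); md <- drop(as.array(m))
  if (length(dim(vd)) != 3L || length(dim(md)) != 3L)
    stop("expected 3D single-channel images")
  sp <- RNifti::pixdim(v)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  vol <- us_volume(vd, spacing = sp)
  mask <- us_mask((md > 0.5) * 1)
  us_case(id, vol, mask)
}

#' Write a case to a NIfTI volume/mask pair
#'
#' @param case a [us_case()].
#' @param volume_path,mask_path output paths (`.nii` or `.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_case <- function(case, volume_path, mask_path) {
  stopifnot(inherits(case, "us_case"))
  sp <- case$volume$spacing
  hdr <- RNifti::niftiHeader(RNifti::asNifti(case$volume$data))
  hdr$pixdim[2:4] <- sp
  vi <- RNifti::asNifti(case$volume$data, reference = hdr)
  mi <- RNifti::asNifti(case$mask$data, reference = hdr, datatype = "uint8")
  RNifti::writeNifti(vi, volume_path)
  RNifti::writeNifti(mi, mask_path)
  invisible(c(volume_path, mask_path))
}

# ---- deterministic preprocessing -------------------------------------------

#' Central crop of a case
#'
#' The crop window is centered with floor-based offsets on odd remainders,
#' and applied identically to volume and mask.
#'
#' @param case a [us_case()].
#' @param target_extent integer length-3, each no larger than the case shape.
#' @return The cropped [us_case()].
#' @export
central_crop <- function(case, target_extent) {
  stopifnot(inherits(case, "us_case"))
  d <- dim(case$volume$data)
  t <- as.integer(target_extent)
  if (length(t) != 3L || any(t < 1L)) stop("target_extent must be 3 positive integers")
  if (any(t > d))
    stop("target extent ", paste(t, collapse = "x"),
         " exceeds input ", paste(d, collapse = "x"))
  off <- (d - t) %/% 2L
  ih <- (off[1] + 1L):(off[1] + t[1])
  iw <- (off[2] + 1L):(off[2] + t[2])
  id_ <- (off[3] + 1L):(off[3] + t[3])
  us_case(case$id,
          us_volume(case$volume$data[ih, iw, id_, drop = FALSE],
                    case$volume$spacing),
          us_mask(case$mask$data[ih, iw, id_, drop = FALSE]))
}

# internal: resize a plain 3D array
resize_array <- function(a, target, nearest = FALSE) {
  din <- dim(a)
  if (identical(as.integer(din), as.integer(target))) return(a)
  x <- a
  dim(x) <- c(prod(din), 1L)
  y <- cpp_resize3_fwd(x, as.integer(din), as.integer(target), nearest)
  dim(y) <- as.integer(target)
  y
}

#' Resize a case to a target shape
#'
#' The volume is resampled with trilinear interpolation and the mask with
#' nearest-neighbor interpolation (so it stays exactly binary); the study's
#' working resolution is 256 x 256 x 64.
#'
#' @param case a [us_case()].
#' @param target_shape positive integer length-3.
#' @return The resized [us_case()]; voxel spacing is rescaled accordingly.
#' @export
resize_case <- function(case, target_shape = c(256, 256, 64)) {
  stopifnot(inherits(case, "us_case"))
  t <- as.integer(target_shape)
  if (length(t) != 3L || any(t < 1L)) stop("target_shape must be 3 positive integers")
  d <- dim(case$volume$data)
  sp <- case$volume$spacing * d / t
  us_case(case$id,
          us_volume(resize_array(case$volume$data, t, nearest = FALSE), sp),
          us_mask(resize_array(case$mask$data, t, nearest = TRUE)))
}

#' Min-max intensity normalization to [0, 1]
#'
#' Constant volumes map to all zeros.
#'
#' @param volume a [us_volume()] (or plain 3D array).
#' @return A [us_volume()] with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  a <- if (inherits(volume, "us_volume")) volume$data else as.array(volume)
  sp <- if (inherits(volume, "us_volume")) volume$spacing else c(1, 1, 1)
  if (!all(is.finite(a))) stop("volume contains NaN/Inf")
  rng <- range(a)
  out <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else a * 0
  us_volume(out, sp)
}

#' Full deterministic preprocessing: central crop, resize, normalize
#'
#' @param case a [us_case()].
#' @param crop_extent optional central-crop extents (default: no crop).
#' @param target_shape resize target, default 256 x 256 x 64.
#' @return Preprocessed [us_case()] with intensities in `[0, 1]`.
#' @export
preprocess_case <- function(case, crop_extent = NULL,
                            target_shape = c(256, 256, 64)) {
  if (!is.null(crop_extent)) case <- central_crop(case, crop_extent)
  case <- resize_case(case, target_shape)
  us_case(case$id, normalize_intensity(case$volume), case$mask)
}
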