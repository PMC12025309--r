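# Volumetric and surface segmentation metrics, fold summaries, and the
# exact paired Wilcoxon signed-rank test with Bonferroni correction.

as_mask_array <- function(x) {
  a <- if (inherits(x, "us_mask")) x$data else as.array(x)
  if (!all(a %in% c(0, 1))) stop("mask must be binary")
  a
}

check_pair <- function(A, B) {
  a <- as_mask_array(A); b <- as_mask_array(B)
  if (!identical(dim(a), dim(b)))
    stop("mask extent mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  list(a = a, b = b)
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param A,B binary 3D arrays or [us_mask()] objects of equal extents.
#' @return DSC in `[0, 1]`.
#' @export
dice_score <- function(A, B) {
  p <- check_pair(A, B)
  den <- sum(p$a) + sum(p$b)
  if (den == 0) return(1)
  2 * sum(p$a * p$b) / den
}

#' Intersection over union (Jaccard) between two binary masks
#'
#' `|A n B| / |A u B|`; 1 when both masks are empty.
#'
#' @inheritParams dice_score
#' @return IoU in `[0, 1]`.
#' @export
iou_score <- function(A, B) {
  p <- check_pair(A, B)
  uni <- sum(pmax(p$a, p$b))
  if (uni == 0) return(1)
  sum(p$a * p$b) / uni
}

#' Extract the surface voxels of a binary mask
#'
#' The surface is the mask minus its binary erosion by the 6-connected
#' structuring element (zero padding outside the grid, so voxels on the
#' grid boundary count as surface); isolated voxels are their own surface.
#'
#' @param mask binary 3D array or [us_mask()].
#' @return Integer matrix of 1-based surface voxel coordinates (n x 3).
#' @export
extract_surface <- function(mask) {
  a <- as_mask_array(mask)
  dm <- dim(a)
  er <- cpp_erode6(as.integer(a), as.integer(dm))
  surf <- as.integer(a) == 1L & er == 0L
  which(array(surf, dm), arr.ind = TRUE)
}

#' Surface Dice score with distance tolerance
#'
#' Fraction of surface voxels of each mask lying within Euclidean distance
#' `d` (voxel units) of the other mask's surface:
#' `(|Sp within d of Sg| + |Sg within d of Sp|) / (|Sp| + |Sg|)`.
#' Defined as 1 when both surfaces are empty.
#'
#' @inheritParams dice_score
#' @param d tolerance distance in voxels (default 1).
#' @return SDSC in `[0, 1]`.
#' @export
surface_dice <- function(A, B, d = 1) {
  p <- check_pair(A, B)
  if (d < 0) stop("d must be >= 0")
  sp <- extract_surface(p$a)
  sg <- extract_surface(p$b)
  if (nrow(sp) + nrow(sg) == 0L) return(1)
  if (nrow(sp) == 0L || nrow(sg) == 0L) return(0)
  (cpp_surface_within(sp, sg, d) + cpp_surface_within(sg, sp, d)) /
    (nrow(sp) + nrow(sg))
}

#' Per-case segmentation metrics
#'
#' @inheritParams dice_score
#' @param d surface-Dice tolerance.
#' @return Named list `dsc`, `iou`, `sdsc`.
#' @export
seg_metrics <- function(A, B, d = 1) {
  list(dsc = dice_score(A, B), iou = iou_score(A, B),
       sdsc = surface_dice(A, B, d))
}

#' Summarize per-fold metric values
#'
#' Arithmetic mean and population (divide-by-n) standard deviation, the
#' convention under which the published six-fold summary rows reproduce
#' exactly from their per-fold values.
#'
#' @param values numeric vector of at least 2 per-fold values.
#' @return List with `mean` and `std`.
#' @export
summarize_folds <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 fold values")
  m <- mean(values)
  list(mean = m, std = sqrt(mean((values - m)^2)))
}

#' Exact Wilcoxon signed-rank test with Bonferroni correction
#'
#' Paired test on `values_a - values_b`. Zero differences are dropped; ties
#' in absolute differences are mid-ranked; the null distribution of the
#' positive-rank sum W+ is enumerated exactly over all sign assignments
#' (supported up to n = 20 non-zero pairs). The two-sided p doubles the
#' smaller tail; `sided = "one"` tests the alternative that `values_a`
#' tends larger. Bonferroni: `p_adjusted = min(1, m * p_raw)`.
#'
#' @param values_a,values_b equal-length paired numeric vectors (>= 5 pairs).
#' @param m number of comparisons for the Bonferroni correction.
#' @param sided "two" (default) or "one".
#' @return List: `statistic` (W+), `p_raw`, `p_adjusted`, `m`, `sided`,
#'   `n_nonzero`.
#' @export
wilcoxon_compare <- function(values_a, values_b, m = 1L,
                             sided = c("two", "one")) {
  sided <- match.arg(sided)
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 5L) stop("need at least 5 pairs")
  if (m < 1L) stop("m must be >= 1")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    p <- 1
    return(list(statistic = 0, p_raw = 1, p_adjusted = 1, m = as.integer(m),
                sided = sided, n_nonzero = 0L))
  }
  if (n > 20L) stop("exact enumeration supported up to 20 non-zero pairs")
  r <- rank(abs(d))                       # mid-ranks under ties
  W <- sum(r[d > 0])
  # exact null distribution of W+ via convolution over doubled ranks
  r2 <- as.integer(round(2 * r))
  counts <- c(1, numeric(sum(r2)))        # counts[s+1] = #assignments, sum s
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  total <- 2^n
  w2 <- as.integer(round(2 * W))
  p_ge <- sum(counts[(w2 + 1L):length(counts)]) / total
  p_le <- sum(counts[seq_len(w2 + 1L)]) / total
  p <- if (sided == "two") min(1, 2 * min(p_ge, p_le)) else p_ge
  list(statistic = W, p_raw = p, p_adjusted = min(1, m * p),
       m = as.integer(m), sided = sided, n_nonzero = n)
}

# ---- fold tables -----------------------------------------------------------

#' Published six-fold benchmark values (synovium segmentation ablation)
#'
#' Per-fold DSC/IoU/SDSC of the six-fold cross-validation for the six
#' models of the ablation study, as published; input data for the summary
#' and paired-statistics harness.
#'
#' @return Long data frame: `model`, `fold`, `metric`, `value`.
#' @export
benchmark_fold_table <- function() {
  vals <- list(
    unet3d     = list(dsc = c(0.723, 0.747, 0.784, 0.713, 0.721, 0.763),
                      iou = c(0.566, 0.596, 0.638, 0.555, 0.563, 0.617),
                      sdsc = c(0.639, 0.675, 0.638, 0.623, 0.687, 0.701)),
    daf3d      = list(dsc = c(0.835, 0.814, 0.801, 0.833, 0.788, 0.811),
                      iou = c(0.715, 0.697, 0.673, 0.714, 0.653, 0.683),
                      sdsc = c(0.838, 0.826, 0.814, 0.821, 0.798, 0.805)),
    swin_unetr = list(dsc = c(0.829, 0.768, 0.802, 0.835, 0.831, 0.785),
                      iou = c(0.706, 0.628, 0.674, 0.704, 0.708, 0.645),
                      sdsc = c(0.863, 0.798, 0.823, 0.822, 0.869, 0.755)),
    unetrpp    = list(dsc = c(0.833, 0.791, 0.808, 0.801, 0.821, 0.807),
                      iou = c(0.711, 0.659, 0.685, 0.671, 0.701, 0.675),
                      sdsc = c(0.876, 0.801, 0.818, 0.811, 0.857, 0.814)),
    transunet  = list(dsc = c(0.842, 0.817, 0.805, 0.807, 0.824, 0.812),
                      iou = c(0.722, 0.690, 0.674, 0.677, 0.703, 0.683),
                      sdsc = c(0.823, 0.789, 0.796, 0.822, 0.831, 0.828)),
    swindaf3d  = list(dsc = c(0.854, 0.815, 0.841, 0.832, 0.849, 0.835),
                      iou = c(0.745, 0.684, 0.723, 0.709, 0.733, 0.719),
                      sdsc = c(0.887, 0.845, 0.821, 0.851, 0.864, 0.841)))
  do.call(rbind, lapply(names(vals), function(mo)
    do.call(rbind, lapply(names(vals[[mo]]), function(me)
      data.frame(model = mo, fold = 1:6, metric = me,
                 value = vals[[mo]][[me]])))))
}

#' Mean/std summary rows of a fold table
#'
#' @param fold_table long data frame (`model`, `fold`, `metric`, `value`)
#'   such as [benchmark_fold_table()] or the output of
#'   [run_cross_validation()].
#' @return Data frame with one row per model x metric: `mean`, `std`
#'   (population convention, via [summarize_folds()]).
#' @export
fold_summary_table <- function(fold_table) {
  sp <- split(fold_table, list(fold_table$model, fold_table$metric),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    s <- summarize_folds(g$value)
    data.frame(model = g$model[1], metric = g$metric[1],
               mean = s$mean, std = s$std)
  }))
  rownames(out) <- NULL
  out[order(out$model, out$metric), ]
}
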