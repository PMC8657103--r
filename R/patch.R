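#' Masked voxel patch
#'
#' Container for a lesion's intensity patch: a 3D array of CT attenuation
#' values (HU), a binary mask of the same shape marking the lesion, and the
#' physical voxel spacing.  Axis order is fixed as (slice, row, column) and
#' `spacing` is given in the same order, in millimetres.
#'
#' @param intensities 3D numeric array of HU values, axes (slice, row, column).
#' @param mask 3D array (logical or 0/1) of the same shape; at least one
#'   foreground voxel.
#' @param spacing numeric length-3, (slice thickness, row spacing, column
#'   spacing) in mm; strictly positive.
#' @return An object of class `voxel_patch`.
#' @examples
#' arr <- array(c(-40, 10, 20, 35), dim = c(1, 2, 2))
#' p <- voxel_patch(arr, array(1, dim = dim(arr)), spacing = c(2.5, 0.7, 0.7))
#' compute_volume(p$mask, p$spacing)
#' @export
voxel_patch <- function(intensities, mask, spacing) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array (slice, row, column)")
  if (!identical(dim(intensities), dim(mask)))
    stop("`mask` shape must match `intensities`")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must be binary with no missing values")
  if (!any(mask)) stop("`mask` must contain at least one foreground voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)")
  structure(list(intensities = intensities, mask = mask, spacing = spacing),
            class = "voxel_patch")
}

#' @export
print.voxel_patch <- function(x, ...) {
  cat("<voxel_patch> ", paste(dim(x$intensities), collapse = "x"),
      " voxels, ", sum(x$mask), " in mask, spacing ",
      paste(format(x$spacing), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

#' Segmented volume of a binary mask
#'
#' Volume is the foreground voxel count times the physical voxel volume.
#'
#' @param mask 3D binary array.
#' @param spacing voxel spacing in mm, (slice, row, column).
#' @return Volume in mm^3.
#' @export
compute_volume <- function(mask, spacing) {
  n <- sum(mask != 0)
  if (n == 0L) stop("empty mask: volume undefined")
  n * prod(spacing)
}

#' 2.5D area of a binary mask
#'
#' Slice-wise lateral surface proxy: for every axial slice, the in-plane
#' boundary perimeter of the foreground region is multiplied by the slice
#' thickness and the products are summed over slices.
#'
#' Perimeter convention: voxel faces are square; the perimeter of a slice is
#' the total length of foreground pixel edges exposed to background (or the
#' image border).  A single voxel at in-plane spacing (1, 1) mm therefore has
#' perimeter 4 mm, not the marching-squares diamond of 2*sqrt(2) mm.
#'
#' @inheritParams compute_volume
#' @return Area in mm^2.
#' @export
area_2_5d <- function(mask, spacing) {
  if (!any(mask != 0)) stop("empty mask: area undefined")
  dz <- spacing[1]; dr <- spacing[2]; dc <- spacing[3]
  m <- array(mask != 0, dim = dim(mask))
  total <- 0
  for (k in seq_len(dim(m)[1])) {
    sl <- m[k, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = dim(m)[2])
    if (!any(sl)) next
    nr <- nrow(sl); nc <- ncol(sl)
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- sl
    core <- pad[2:(nr + 1L), 2:(nc + 1L)]
    # vertical neighbours (row above/below) expose horizontal edges: length dc
    nh <- sum(core & !pad[1:nr, 2:(nc + 1L)]) +
          sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)])
    # horizontal neighbours expose vertical edges: length dr
    nv <- sum(core & !pad[2:(nr + 1L), 1:nc]) +
          sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
    total <- total + (nh * dc + nv * dr) * dz
  }
  total
}

#' Fixed-bin-width intensity discretization
#'
#' Histogram of in-mask intensities with bin edges anchored at the in-mask
#' minimum: voxel x falls in bin `floor((x - min) / bin_width) + 1`, so every
#' voxel is assigned to exactly one half-open bin `[edge, edge + w)` and the
#' counts sum to the foreground voxel count.
#'
#' @param values numeric vector of in-mask intensities (HU).
#' @param bin_width bin width in HU, > 0.
#' @return List with `counts`, `edges` (length `nbins + 1`) and `probs`.
#' @examples
#' discretize(c(0, 24.9, 25, 49), bin_width = 25)$counts  # 2 2
#' @export
discretize <- function(values, bin_width) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty mask: nothing to discretize")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number")
  lo <- min(values)
  idx <- floor((values - lo) / bin_width) + 1L
  nb <- max(idx)
  counts <- tabulate(idx, nbins = nb)
  list(counts = counts,
       edges = lo + bin_width * (0:nb),
       probs = counts / length(values))
}

.lk_feature_names <- c(
  "energy", "entropy", "minimum", "percentile_2_5", "percentile_10",
  "median", "mean", "percentile_90", "percentile_97_5", "maximum",
  "interquartile_range", "range", "mean_absolute_deviation",
  "robust_mean_absolute_deviation", "root_mean_square",
  "standard_deviation", "variance", "skewness", "kurtosis", "uniformity")

#' Names of the first-order histogram feature set
#'
#' The 19 intensity-histogram features computed by [extract_features()],
#' in registry order.  `volume` and `area_2_5d` are reported in addition.
#' @return Character vector of length 19.
#' @export
histogram_feature_names <- function() .lk_feature_names

#' First-order histogram radiomics features of a masked patch
#'
#' Computes the 19 intensity-histogram features plus segmented volume (mm^3)
#' and 2.5D area (mm^2) from the in-mask voxels of a patch.  Conventions:
#' percentiles use linear interpolation between closest order statistics
#' (`quantile` type 7); variance and standard deviation use the population
#' (1/n) convention; skewness is the third standardized moment and kurtosis
#' the Pearson (non-excess) fourth standardized moment; uniformity and
#' entropy are computed from the fixed-bin-width discretized histogram
#' (`uniformity = sum(p^2)`, `entropy = -sum(p * log2(p))`); RMS uses the raw
#' values so that RMS^2 = mean^2 + variance.
#'
#' With fewer than 2 in-mask voxels (or a constant patch) skewness and
#' kurtosis are undefined and returned as `NaN`; all other features are
#' still computed.
#'
#' @param patch a [voxel_patch()].
#' @param bin_width discretization bin width in HU (default 25, a common CT
#'   radiomics convention).
#' @return Named numeric vector of the 19 features plus `volume` and
#'   `area_2_5d`, with attribute `bin_width`.
#' @export
extract_features <- function(patch, bin_width = 25) {
  stopifnot(inherits(patch, "voxel_patch"))
  v <- patch$intensities[patch$mask]
  f <- histogram_features(v, bin_width = bin_width)
  f <- c(f,
         volume = compute_volume(patch$mask, patch$spacing),
         area_2_5d = area_2_5d(patch$mask, patch$spacing))
  attr(f, "bin_width") <- bin_width
  f
}

#' Histogram features of a value vector
#'
#' Workhorse behind [extract_features()]; operates directly on the in-mask
#' intensity values.
#' @param values numeric vector (>= 1 finite value).
#' @inheritParams extract_features
#' @return Named numeric vector of the 19 histogram features.
#' @export
histogram_features <- function(values, bin_width = 25) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n == 0L) stop("no finite in-mask values")
  q <- stats::quantile(v, c(0.025, 0.10, 0.25, 0.50, 0.75, 0.90, 0.975),
                       names = FALSE, type = 7)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)           # population variance
  m3 <- mean((v - mu)^3)
  m4 <- mean((v - mu)^4)
  skew <- if (n >= 2L && m2 > 0) m3 / m2^1.5 else NaN
  kurt <- if (n >= 2L && m2 > 0) m4 / m2^2 else NaN
  # robust MAD: mean absolute deviation of the values inside [P10, P90],
  # about their own mean (IBSI convention)
  inr <- v[v >= q[2] & v <= q[6]]
  rmad <- mean(abs(inr - mean(inr)))
  h <- discretize(v, bin_width)
  p <- h$probs[h$probs > 0]
  out <- c(
    energy = sum(v^2),
    entropy = -sum(p * log2(p)),
    minimum = min(v),
    percentile_2_5 = q[1],
    percentile_10 = q[2],
    median = q[4],
    mean = mu,
    percentile_90 = q[6],
    percentile_97_5 = q[7],
    maximum = max(v),
    interquartile_range = q[5] - q[3],
    range = max(v) - min(v),
    mean_absolute_deviation = mean(abs(v - mu)),
    robust_mean_absolute_deviation = rmad,
    root_mean_square = sqrt(mean(v^2)),
    standard_deviation = sqrt(m2),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    uniformity = sum(p^2))
  out[.lk_feature_names]
}

#' Write / read a voxel patch as plain text
#'
#' Serializes a patch to a CSV long voxel table (columns slice, row, column,
#' intensity, mask) preceded by `#`-prefixed header lines carrying the array
#' dimensions and voxel spacing.  A plain-text stand-in for NIfTI/NRRD
#' image+mask pairs so patches can travel with text-only repositories.
#'
#' @param patch a [voxel_patch()].
#' @param path file path.
#' @return `write_patch` returns `path` invisibly; `read_patch` returns a
#'   [voxel_patch()].
#' @export
write_patch <- function(patch, path) {
  stopifnot(inherits(patch, "voxel_patch"))
  d <- dim(patch$intensities)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dim: %d %d %d", d[1], d[2], d[3]),
               sprintf("# spacing: %.10g %.10g %.10g",
                       patch$spacing[1], patch$spacing[2], patch$spacing[3]),
               "slice,row,column,intensity,mask"), con)
  idx <- which(array(TRUE, dim = d), arr.ind = TRUE)
  utils::write.table(
    data.frame(idx[, 1], idx[, 2], idx[, 3],
               as.vector(patch$intensities), as.integer(patch$mask)),
    con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_patch
#' @export
read_patch <- function(path) {
  hdr <- readLines(path, n = 2L)
  d <- as.integer(strsplit(sub("^# dim: *", "", hdr[1]), " ")[[1]])
  sp <- as.numeric(strsplit(sub("^# spacing: *", "", hdr[2]), " ")[[1]])
  tab <- utils::read.csv(path, comment.char = "#")
  intens <- array(NA_real_, dim = d)
  msk <- array(0L, dim = d)
  ii <- cbind(tab$slice, tab$row, tab$column)
  intens[ii] <- tab$intensity
  msk[ii] <- tab$mask
  voxel_patch(intens, msk, sp)
}
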