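#' A reconstructed micro-CT gray volume
#'
#' @param gray 3D numeric array of reconstructed gray values.
#' @param voxel_size Isotropic voxel size in um.
#' @param description Free-text provenance note.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(gray, voxel_size = 2.78, description = "") {
  stopifnot(is.array(gray), length(dim(gray)) == 3, all(is.finite(gray)),
            voxel_size > 0)
  structure(list(gray = gray, voxel_size = voxel_size,
                 description = description), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels @ %.3g um, gray in [%.4g, %.4g]%s\n",
              paste(dim(x$gray), collapse = " x "), x$voxel_size,
              min(x$gray), max(x$gray),
              if (nzchar(x$description)) paste0(" (", x$description, ")") else ""))
  invisible(x)
}

#' Otsu's threshold of a set of gray values
#'
#' Thin wrapper around the histogram-based Otsu implementation in EBImage,
#' applied to an arbitrary numeric vector: values are rescaled to \[0, 1\],
#' thresholded at 256 levels, and the threshold mapped back to the input
#' gray scale. Shift- and scale-equivariant by construction.
#'
#' @param values Numeric vector (finite, length >= 2, non-constant).
#' @param levels Number of histogram levels (default 256).
#' @return Threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, levels = 256) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(lo)
  norm <- (values - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(matrix(norm, ncol = 1)),
                      range = c(0, 1), levels = levels)
  lo + th * (hi - lo)
}

# binary closing with a 6-connected structuring element of radius `r`
# (r successive dilations then r erosions), via array shifting
.shift3 <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  okx <- fx >= 1 & fx <= d[1]; oky <- fy >= 1 & fy <= d[2]; okz <- fz >= 1 & fz <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[fx[okx], fy[oky], fz[okz]]
  out
}

.dilate3 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out | .shift3(mask, s[1], s[2], s[3], FALSE)
  out
}

.erode3 <- function(mask) {
  out <- mask
  for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & .shift3(mask, s[1], s[2], s[3], TRUE)
  out
}

.close3 <- function(mask, radius = 1) {
  for (i in seq_len(radius)) mask <- .dilate3(mask)
  for (i in seq_len(radius)) mask <- .erode3(mask)
  mask
}

#' Segment the leaf (sample) from the air background
#'
#' Otsu's threshold on the full volume separates sample from air; the
#' foreground is then closed (radius 1 voxel) to heal thin gaps and the
#' largest 6-connected component is kept, so loose debris and noise specks
#' do not enter the volume-fraction denominator.
#'
#' @param vol A [volume3d()].
#' @return Logical 3D array, `TRUE` inside the leaf.
#' @export
segment_leaf <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  th <- otsu_threshold(as.vector(vol$gray))
  fg <- vol$gray > th
  if (!any(fg)) stop("empty foreground: no voxels above the air/sample threshold")
  # an air-only volume has no real class separation: Otsu then just splits
  # the noise, with the class means closer than their spreads
  mu_fg <- mean(vol$gray[fg]); mu_bg <- mean(vol$gray[!fg])
  if (!any(!fg) ||
      (mu_fg - mu_bg) <= 1.5 * (stats::sd(vol$gray[fg]) + stats::sd(vol$gray[!fg])))
    stop("empty foreground: no air/sample contrast in the volume")
  fg <- .close3(fg, radius = 1)
  labels <- .label_components_3d(as.vector(fg), dim(fg))
  if (max(labels) == 0) stop("empty foreground after closing")
  biggest <- which.max(tabulate(labels[labels > 0]))
  mask <- labels == biggest
  dim(mask) <- dim(vol$gray)
  mask
}

#' Semi-automated threshold segmentation of nanoparticle-densified regions
#'
#' Labels the voxels, inside the leaf, whose gray value exceeds a
#' threshold. By default the threshold is Otsu's threshold computed on the
#' gray values restricted to the leaf (the automated part); a caller-chosen
#' threshold overrides it (the manual part) and is recorded as such. The
#' volume fraction is |np voxels| / |leaf voxels| -- the leaf, not its
#' bounding box, is the denominator.
#'
#' @param vol A [volume3d()].
#' @param leaf_mask Logical array from [segment_leaf()].
#' @param threshold Optional manual threshold in gray units.
#' @return An object of class `ct_segmentation` with `leaf_mask`,
#'   `np_mask`, `threshold`, `method` (`"otsu_seeded"` or `"manual"`) and
#'   `volume_fraction`.
#' @export
segment_np <- function(vol, leaf_mask, threshold = NULL) {
  stopifnot(inherits(vol, "volume3d"), is.logical(leaf_mask),
            all(dim(leaf_mask) == dim(vol$gray)))
  if (!any(leaf_mask)) stop("leaf mask is empty")
  method <- if (is.null(threshold)) "otsu_seeded" else "manual"
  if (is.null(threshold))
    threshold <- otsu_threshold(vol$gray[leaf_mask])
  np_mask <- leaf_mask & vol$gray > threshold
  structure(list(leaf_mask = leaf_mask, np_mask = np_mask,
                 threshold = threshold, method = method,
                 volume_fraction = sum(np_mask) / sum(leaf_mask)),
            class = "ct_segmentation")
}

#' @export
print.ct_segmentation <- function(x, ...) {
  cat(sprintf("ct_segmentation (%s): threshold %.5g, volume fraction %.4g (%d / %d voxels)\n",
              x$method, x$threshold, x$volume_fraction,
              sum(x$np_mask), sum(x$leaf_mask)))
  invisible(x)
}

#' Histogram of gray values inside the nanoparticle-labelled region
#'
#' @param vol A [volume3d()].
#' @param seg A `ct_segmentation` for the same volume.
#' @param breaks Bin edges (use common edges across a time series for
#'   comparable histograms), or a bin count passed to [graphics::hist()].
#' @return The `histogram` object (counts sum to the np-region voxel
#'   count), with attribute `empty = TRUE` if the mask is empty.
#' @export
np_region_histogram <- function(vol, seg, breaks = 64) {
  stopifnot(inherits(vol, "volume3d"), inherits(seg, "ct_segmentation"))
  vals <- vol$gray[seg$np_mask]
  if (length(vals) == 0) {
    h <- list(breaks = numeric(0), counts = integer(0), mids = numeric(0))
    class(h) <- "histogram"
    attr(h, "empty") <- TRUE
    warning("np_mask is empty: returning an empty histogram")
    return(h)
  }
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  attr(h, "empty") <- FALSE
  h
}

#' Threshold / volume-fraction report over a CT time series
#'
#' Runs leaf segmentation and automatic nanoparticle segmentation on each
#' volume and tabulates the threshold, volume fraction and np-region mean
#' gray. On a dispersing system the thresholds fall and the fractions rise
#' with time.
#'
#' @param volumes List of [volume3d()] objects.
#' @param labels Labels (e.g. day numbers), default `seq_along(volumes)`.
#' @return A data frame with one row per volume: `label`, `threshold`,
#'   `volume_fraction`, `np_mean_gray`, `leaf_voxels`, `np_voxels`.
#' @export
ct_timeseries_report <- function(volumes, labels = NULL) {
  stopifnot(length(volumes) >= 1)
  if (is.null(labels)) labels <- as.character(seq_along(volumes))
  rows <- lapply(seq_along(volumes), function(i) {
    vol <- volumes[[i]]
    leaf <- segment_leaf(vol)
    seg <- segment_np(vol, leaf)
    data.frame(label = labels[i], threshold = seg$threshold,
               volume_fraction = seg$volume_fraction,
               np_mean_gray = if (any(seg$np_mask)) mean(vol$gray[seg$np_mask]) else NA_real_,
               leaf_voxels = sum(leaf), np_voxels = sum(seg$np_mask),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
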