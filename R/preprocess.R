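# Preprocessing: HU windowing, local entropy texture maps, channel fusion,
# mask morphology and left/right lung separation.

#' Window-normalize a CT volume
#'
#' Clip-and-rescale contrast enhancement: maps HU linearly onto \[0,1\]
#' across the window `[center - width/2, center + width/2]`, clipping
#' outside.  Monotone nondecreasing in HU.
#'
#' @param x a [CTScan-class] or numeric array of HU.
#' @param center,width window centre and width in HU (`width > 0`).
#' @return numeric array in \[0,1\] with the input dimensions.
#' @examples
#' applyWindow(array(-600, c(1, 1, 1)), center = -600, width = 1500) # 0.5
#' @export
applyWindow <- function(x, center, width) {
  if (is(x, "CTScan")) x <- x@values
  if (width <= 0) stop("window width must be > 0")
  if (any(!is.finite(x))) stop("non-finite HU values")
  pmin(pmax((x - (center - width / 2)) / width, 0), 1)
}

#' Standard window presets
#'
#' Lung window (centre -600 HU, width 1500 HU) and mediastinal window
#' (centre 40 HU, width 400 HU), the standard radiology conventions.
#' @return list with `center` and `width` (HU).
#' @export
lungWindow <- function() list(center = -600, width = 1500)

#' @rdname lungWindow
#' @export
mediastinalWindow <- function() list(center = 40, width = 400)

#' Local entropy texture filter
#'
#' Per-voxel Shannon entropy (bits) of the intensity histogram within a
#' disk-shaped in-plane neighbourhood, computed slice by slice (axial slices
#' are 2.5 mm apart, so mixing slices would blur texture).  The histogram
#' uses `nBins` equal-width bins on \[0,1\]; output range is
#' \[0, log2(nBins)\].  Neighbourhoods are clipped at the slice border.
#'
#' @param img numeric array (3-D) or matrix (one slice) with values in \[0,1\].
#' @param radius disk radius in voxels (>= 1); the neighbourhood is
#'   `{(dx, dy): dx^2 + dy^2 <= radius^2}`.
#' @param nBins histogram bin count.
#' @param mask optional logical region of interest: the histogram is then
#'   restricted to in-mask neighbours, so tissue texture is not polluted by
#'   the sharp lung/chest-wall edge, and masked-out voxels get entropy 0.
#' @return entropy map with the input dimensions.
#' @export
localEntropy <- function(img, radius = 4, nBins = 32L, mask = NULL) {
  stopifnot(radius >= 1, nBins >= 2)
  if (min(img) < 0 || max(img) > 1) stop("image values must lie in [0,1]")
  isMat <- is.matrix(img)
  if (isMat) {
    img <- array(img, dim = c(dim(img), 1L))
    if (!is.null(mask)) mask <- array(mask, dim = dim(img))
  }
  d <- dim(img)
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("mask and image shapes differ")
  if (2 * floor(radius) + 1 > min(d[1], d[2]))
    stop("entropy radius larger than the slice")
  out <- array(0, dim = d)
  for (z in seq_len(d[3]))
    out[, , z] <- cpp_local_entropy(img[, , z], radius, as.integer(nBins),
                                    if (is.null(mask)) NULL else mask[, , z])
  if (isMat) out <- out[, , 1L]
  out
}

#' Fuse windowed intensities and entropy maps into a composite image
#'
#' Channel stacking (not blending): the four co-registered images become the
#' four channels `lung`, `med`, `lungEntropy`, `medEntropy`, in that fixed
#' order.  Entropy channels are rescaled to \[0,1\] by dividing by
#' `log2(entropyBins)`.
#'
#' @param lungImg,medImg window-normalized intensity arrays in \[0,1\].
#' @param lungEnt,medEnt local-entropy arrays in \[0, log2(entropyBins)\].
#' @param spacing voxel spacing (mm).
#' @param entropyBins bin count used by the entropy filter.
#' @return a [CompositeImage-class].
#' @export
fuseChannels <- function(lungImg, medImg, lungEnt, medEnt,
                         spacing = c(1, 1, 2.5), entropyBins = 32L) {
  d <- dim(lungImg)
  if (!identical(d, dim(medImg)) || !identical(d, dim(lungEnt)) ||
      !identical(d, dim(medEnt)))
    stop("all four channels must share the same shape")
  sc <- log2(entropyBins)
  ch <- array(c(lungImg, medImg, lungEnt / sc, medEnt / sc), dim = c(d, 4L))
  new("CompositeImage", channels = ch,
      channelNames = c("lung", "med", "lungEntropy", "medEntropy"),
      spacing = as.numeric(spacing), entropyBins = as.integer(entropyBins))
}

#' Build the composite image from a CT scan in one call
#'
#' Applies both windows, runs the local entropy filter on each windowed
#' image, and stacks the four channels.
#'
#' @param scan a [CTScan-class].
#' @param mask optional lung mask passed to [localEntropy()] so texture is
#'   computed on the lung ROI only.
#' @param lungWin,medWin window specs (lists with `center`, `width`).
#' @param entropyRadius,entropyBins entropy-filter parameters.
#' @return a [CompositeImage-class].
#' @export
makeComposite <- function(scan, mask = NULL, lungWin = lungWindow(),
                          medWin = mediastinalWindow(),
                          entropyRadius = 4, entropyBins = 32L) {
  li <- applyWindow(scan, lungWin$center, lungWin$width)
  mi <- applyWindow(scan, medWin$center, medWin$width)
  fuseChannels(li, mi,
               localEntropy(li, entropyRadius, entropyBins, mask),
               localEntropy(mi, entropyRadius, entropyBins, mask),
               spacing = scan@spacing, entropyBins = entropyBins)
}

# binary dilation/erosion by a ball structuring element, via voxel shifts
ballOffsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

shiftArray <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  rng <- function(n, s) {
    lo <- max(1, 1 + s); hi <- min(n, n + s)
    if (lo > hi) integer(0) else lo:hi
  }
  sx <- rng(d[1], dx); sy <- rng(d[2], dy); sz <- rng(d[3], dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

dilateMask <- function(mask, radius = 1) {
  off <- ballOffsets(radius)
  out <- array(FALSE, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shiftArray(mask, off$dx[i], off$dy[i], off$dz[i])
  out
}

erodeMask <- function(mask, radius = 1) {
  off <- ballOffsets(radius)
  out <- array(TRUE, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shiftArray(mask, off$dx[i], off$dy[i], off$dz[i], fill = TRUE)
  out
}

#' Smooth a binary mask by morphological closing
#'
#' Dilation followed by erosion with the same ball structuring element.
#' Fills boundary notches and small interior gaps; idempotent on
#' already-closed masks (e.g. a solid ball is unchanged).
#'
#' @param mask logical 3-D array.
#' @param radius ball radius in voxels.
#' @return smoothed logical array.
#' @export
smoothMask <- function(mask, radius = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) return(mask)
  erodeMask(dilateMask(mask, radius), radius)
}

#' Split a lung mask into left and right lungs
#'
#' Labels 6-connected components; the two largest become the lungs (smaller
#' components are discarded with a message).  "Left" is the component with
#' the smaller x centroid (image left).  A single fused component triggers a
#' warning and a fallback split at the mask's x-centroid midline.
#'
#' @param mask logical 3-D array.
#' @return list with logical arrays `left` and `right` (disjoint, covering
#'   the retained mask).
#' @export
splitLungs <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("empty mask")
  comp <- cpp_label_components(mask)
  sizes <- tabulate(comp[comp > 0])
  ord <- order(sizes, decreasing = TRUE)
  if (length(sizes) > 2L) {
    message(sprintf("splitLungs: discarding %d small component(s) (%s voxels)",
                    length(sizes) - 2L,
                    paste(sizes[ord[-(1:2)]], collapse = ", ")))
  }
  if (length(sizes) == 1L) {
    warning("splitLungs: single fused component; falling back to a midline split")
    xs <- slice.index(mask, 1)[mask]
    cut <- mean(xs)
    left <- mask & slice.index(mask, 1) <= cut
    right <- mask & !left
    return(list(left = left, right = right))
  }
  keep <- ord[1:2]
  cx <- vapply(keep, function(k) mean(slice.index(mask, 1)[comp == k]), 0)
  leftComp <- keep[which.min(cx)]
  rightComp <- keep[which.max(cx)]
  list(left = array(comp == leftComp, dim = dim(mask)),
       right = array(comp == rightComp, dim = dim(mask)))
}
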