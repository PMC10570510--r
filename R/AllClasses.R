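#' @useDynLib HabitatCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' CTScan: a CT volume in Hounsfield units
#'
#' Container for a 3-D CT grid in Hounsfield units (HU) together with its
#' voxel spacing in millimetres.  Axial slices run along the third axis;
#' voxel indices are 1-based in R convention.
#'
#' @slot values 3-D numeric array of HU, finite, within \[-1024, 3071\].
#' @slot spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @export
setClass("CTScan",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3-D array")
    if (any(!is.finite(v))) return("HU values must be finite")
    if (min(v) < -1024 || max(v) > 3071)
      return("HU values must lie within [-1024, 3071]")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  }
)

#' CompositeImage: the fused four-channel image that habitat clustering consumes
#'
#' Channel-stacked composite of lung-window intensity, mediastinal-window
#' intensity, and the two corresponding local-entropy maps (entropy rescaled
#' to \[0,1\] by log2(nBins)).  Channels are kept distinct (stacking, not
#' blending) because superpixel statistics are extracted per channel.
#'
#' @slot channels 4-D numeric array (x, y, z, channel), 4 channels in \[0,1\].
#' @slot channelNames character of length 4.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot entropyBins integer, histogram bin count used by the entropy filter.
#' @export
setClass("CompositeImage",
  representation(channels = "array", channelNames = "character",
                 spacing = "numeric", entropyBins = "integer"),
  validity = function(object) {
    d <- dim(object@channels)
    if (length(d) != 4L || d[4] != 4L)
      return("channels must be a 4-D array with exactly 4 channels")
    if (any(!is.finite(object@channels))) return("channel values must be finite")
    if (length(object@channelNames) != 4L) return("need 4 channel names")
    TRUE
  }
)

#' SuperpixelMap: per-voxel SLIC superpixel labels
#'
#' @slot labels 3-D integer array; 0 outside the lung mask, 1..S inside with
#'   contiguous labels.  Each superpixel is connected within one axial slice.
#' @slot nSuperpixels integer, number of superpixels S.
#' @export
setClass("SuperpixelMap",
  representation(labels = "array", nSuperpixels = "integer"),
  validity = function(object) {
    lab <- object@labels
    if (length(dim(lab)) != 3L) return("labels must be a 3-D array")
    u <- sort(unique(as.integer(lab[lab > 0])))
    if (length(u) != object@nSuperpixels ||
        (length(u) && !identical(u, seq_len(object@nSuperpixels))))
      return("superpixel labels must be contiguous 1..S")
    TRUE
  }
)

#' HabitatModel: the population-level habitat clustering model
#'
#' Holds the standardisation parameters and the K cluster centroids (in
#' standardised feature space) that map superpixel feature rows to habitat
#' labels, plus fit metadata.  Habitat labels are canonically ordered by
#' ascending mean lung-window intensity, so label 1 is the most air-like
#' habitat (parenchyma) and label K the densest (consolidation).
#'
#' @slot K integer habitat count (>= 2).
#' @slot centers K x P numeric matrix of centroids in standardised space.
#' @slot featureNames character, the P feature column names.
#' @slot featureCenter,featureScale numeric length-P z-scoring parameters.
#' @slot metadata list: seed, linkage, gap diagnostics, dendrogram suggestion,
#'   subsample size, cohort fingerprint.
#' @export
setClass("HabitatModel",
  representation(K = "integer", centers = "matrix", featureNames = "character",
                 featureCenter = "numeric", featureScale = "numeric",
                 metadata = "list"),
  validity = function(object) {
    if (object@K < 2L) return("K must be >= 2")
    if (nrow(object@centers) != object@K) return("centers must have K rows")
    if (ncol(object@centers) != length(object@featureNames))
      return("centers columns must match featureNames")
    if (anyDuplicated(object@centers) > 0)
      return("centroids must be pairwise distinct")
    TRUE
  }
)

#' HabitatMap: per-voxel habitat (subregion) labels
#'
#' @slot labels 3-D integer array, 0 outside the lung mask and 1..K inside
#'   (subregions SR1..SRK).
#' @slot K integer habitat count.
#' @export
setClass("HabitatMap",
  representation(labels = "array", K = "integer"),
  validity = function(object) {
    lab <- object@labels
    if (length(dim(lab)) != 3L) return("labels must be a 3-D array")
    u <- unique(as.integer(lab))
    if (any(u < 0L) || any(u > object@K))
      return("labels must lie in 0..K")
    TRUE
  }
)

setMethod("show", "CTScan", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTScan: %d x %d x %d voxels, spacing %s mm, HU [%d, %d]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = " x "),
              round(min(object@values)), round(max(object@values))))
})

setMethod("show", "CompositeImage", function(object) {
  d <- dim(object@channels)
  cat(sprintf("CompositeImage: %d x %d x %d voxels, channels: %s\n",
              d[1], d[2], d[3], paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "SuperpixelMap", function(object) {
  cat(sprintf("SuperpixelMap: %s superpixels over %d mask voxels\n",
              object@nSuperpixels, sum(object@labels > 0)))
})

setMethod("show", "HabitatModel", function(object) {
  cat(sprintf("HabitatModel: K = %d habitats, %d features, linkage %s\n",
              object@K, length(object@featureNames),
              object@metadata$linkage %||% "ward.D2"))
})

setMethod("show", "HabitatMap", function(object) {
  tab <- tabulate(object@labels[object@labels > 0], nbins = object@K)
  cat(sprintf("HabitatMap: K = %d; voxels per subregion: %s\n",
              object@K, paste(tab, collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accessors for imaging containers
#'
#' `scanValues()` returns the HU array of a [CTScan-class];
#' `voxelSpacing()` its spacing; `compositeChannels()` the 4-D channel array
#' of a [CompositeImage-class]; `superpixelLabels()` / `habitatLabels()` the
#' integer label arrays; `nHabitats()` the habitat count K.
#'
#' @param x an object of the relevant class.
#' @return The slot contents (array, numeric, or integer).
#' @name accessors
NULL

#' @rdname accessors
#' @export
scanValues <- function(x) {
  stopifnot(is(x, "CTScan"))
  x@values
}

#' @rdname accessors
#' @export
voxelSpacing <- function(x) {
  if (is(x, "CTScan") || is(x, "CompositeImage")) return(x@spacing)
  stop("no voxel spacing for this object")
}

#' @rdname accessors
#' @export
compositeChannels <- function(x) {
  stopifnot(is(x, "CompositeImage"))
  x@channels
}

#' @rdname accessors
#' @export
superpixelLabels <- function(x) {
  stopifnot(is(x, "SuperpixelMap"))
  x@labels
}

#' @rdname accessors
#' @export
habitatLabels <- function(x) {
  stopifnot(is(x, "HabitatMap"))
  x@labels
}

#' @rdname accessors
#' @export
nHabitats <- function(x) {
  if (is(x, "HabitatMap") || is(x, "HabitatModel")) return(x@K)
  stop("no habitat count for this object")
}
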