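# Multiregional spatial interaction (MSI) features computed on habitat maps:
# second-order co-occurrence statistics, subregion volumes, border and
# pairwise adjacency interactions (absolute and normalized), and the
# left/right symmetric-difference block, plus a whole-lung classical
# radiomics comparator.

# unordered subregion pairs in canonical order: (1,2) (1,3) ... (4,5)
habitatPairs <- function(K) {
  p <- utils::combn(K, 2)
  data.frame(i = p[1, ], j = p[2, ])
}

#' Gray-level co-occurrence statistics on a habitat map
#'
#' Builds the co-occurrence matrix of habitat labels over in-plane
#' distance-1 offsets (right and down, symmetrized — equivalently the four
#' axial unit directions), restricted to voxel pairs both inside the mask,
#' normalizes it, and returns the standard Haralick statistics: contrast
#' `sum p (i-j)^2`, correlation, homogeneity `sum p / (1 + (i-j)^2)` and
#' energy `sum p^2`.  A constant map has zero marginal variance; its
#' correlation is defined as 0.
#'
#' @param labels integer array (3-D) or matrix of labels in 0..K (0 treated
#'   as outside).
#' @param mask optional logical array; defaults to `labels > 0`.
#' @param levels label levels spanning the co-occurrence axes (default
#'   `1:max(labels)`); fixing `levels = 1:K` keeps subregion identities
#'   stable when some habitat is absent.
#' @param offsets list of in-plane integer offsets; default
#'   `list(c(1,0), c(0,1))`, symmetrized.
#' @return named numeric: contrast, correlation, homogeneity, energy.
#' @export
glcmStats <- function(labels, mask = NULL, levels = NULL,
                      offsets = list(c(1L, 0L), c(0L, 1L))) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  if (is.null(mask)) mask <- labels > 0L
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!any(mask)) stop("empty mask")
  if (is.null(levels)) levels <- seq_len(max(labels))
  L <- length(levels)
  P <- matrix(0, L, L, dimnames = list(levels, levels))
  d <- dim(labels)
  for (off in offsets) {
    dx <- off[1]; dy <- off[2]
    xa <- seq_len(d[1] - max(dx, 0)); xb <- xa + dx
    ya <- seq_len(d[2] - max(dy, 0)); yb <- ya + dy
    if (dx < 0) { xa <- seq(1 - dx, d[1]); xb <- xa + dx }
    if (dy < 0) { ya <- seq(1 - dy, d[2]); yb <- ya + dy }
    a <- labels[xa, ya, , drop = FALSE]
    b <- labels[xb, yb, , drop = FALSE]
    ok <- mask[xa, ya, , drop = FALSE] & mask[xb, yb, , drop = FALSE] &
      a > 0L & b > 0L
    if (!any(ok)) next
    tt <- table(factor(a[ok], levels = levels), factor(b[ok], levels = levels))
    P <- P + tt + t(tt) # symmetrized
  }
  if (sum(P) == 0)
    return(c(contrast = 0, correlation = 0, homogeneity = 1, energy = 1))
  P <- P / sum(P)
  iv <- as.numeric(levels)
  I <- matrix(iv, L, L)
  J <- t(I)
  mu <- sum(I * P)
  sig2 <- sum((I - mu)^2 * P)
  contrast <- sum(P * (I - J)^2)
  correlation <- if (sig2 > 0) sum((I - mu) * (J - mu) * P) / sig2 else 0
  c(contrast = contrast, correlation = correlation,
    homogeneity = sum(P / (1 + (I - J)^2)), energy = sum(P^2))
}

#' Subregion volumes
#'
#' Absolute voxel counts per subregion SR1..SRK and their fractions of the
#' mask voxel count.  Absent habitats count 0; fractions sum to 1 on a
#' nonempty mask.
#'
#' @param labels habitat label array (0 outside).
#' @param mask logical mask; defaults to `labels > 0`.
#' @param K habitat count.
#' @return list with `absolute` and `fraction`, each length K.
#' @export
regionVolumes <- function(labels, mask = NULL, K = 5L) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  if (is.null(mask)) mask <- labels > 0L
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  inlab <- labels[mask]
  if (any(inlab > K)) stop("labels exceed K")
  absolute <- tabulate(inlab, nbins = K)
  total <- sum(mask)
  list(absolute = as.numeric(absolute),
       fraction = if (total > 0) absolute / total else rep(0, K))
}

# face-adjacent (6-connected) voxel pair tabulation along the 3 positive axes
adjacentPairs <- function(labels, mask) {
  d <- dim(labels)
  pairs <- list()
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    idxA <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idxB <- idxA
    idxA[[ax]] <- seq_len(n - 1L)
    idxB[[ax]] <- seq(2L, n)
    a <- labels[idxA[[1]], idxA[[2]], idxA[[3]], drop = FALSE]
    b <- labels[idxB[[1]], idxB[[2]], idxB[[3]], drop = FALSE]
    ok <- mask[idxA[[1]], idxA[[2]], idxA[[3]], drop = FALSE] &
      mask[idxB[[1]], idxB[[2]], idxB[[3]], drop = FALSE]
    pairs[[ax]] <- cbind(a[ok], b[ok])
  }
  do.call(rbind, pairs)
}

#' Subregion interaction counts
#'
#' Pairwise interaction SRi-SRj = number of face-adjacent (6-connected, 3-D)
#' voxel pairs with one voxel in SRi and the other in SRj.  Border
#' interaction of SRi = number of SRi faces touching a non-mask voxel
#' (including the grid boundary).  Normalized pairwise interactions divide
#' by the total count of adjacent in-mask pairs (mixed and pure); normalized
#' border interactions divide by the total mask-boundary face count.
#'
#' @param labels habitat label array.
#' @param mask logical mask; defaults to `labels > 0`.
#' @param K habitat count.
#' @return list: `border`, `pairwise` (counts, pairs ordered
#'   (1,2),(1,3),...,(K-1,K)), `borderNorm`, `pairwiseNorm`, and the
#'   `pairs` index table.
#' @export
interactionCounts <- function(labels, mask = NULL, K = 5L) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  if (is.null(mask)) mask <- labels > 0L
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (!identical(dim(labels), dim(mask))) stop("labels/mask shape mismatch")
  d <- dim(labels)
  pr <- adjacentPairs(labels, mask)
  pairsTab <- habitatPairs(K)
  pairCounts <- numeric(nrow(pairsTab))
  totalAdj <- if (is.null(pr)) 0 else nrow(pr)
  if (totalAdj > 0) {
    lo <- pmin(pr[, 1], pr[, 2])
    hi <- pmax(pr[, 1], pr[, 2])
    mixed <- lo != hi
    if (any(mixed)) {
      code <- lo[mixed] * (K + 1L) + hi[mixed]
      for (p in seq_len(nrow(pairsTab)))
        pairCounts[p] <- sum(code == pairsTab$i[p] * (K + 1L) + pairsTab$j[p])
    }
  }
  # border faces: in-mask voxel face-adjacent to outside voxel, 6 directions
  border <- numeric(K)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- c(0L, 0L, 0L); sh[ax] <- s
    nb <- shiftArray(mask, sh[1], sh[2], sh[3], fill = FALSE)
    exposed <- mask & !nb
    border <- border + tabulate(labels[exposed], nbins = K)
  }
  totalBorder <- sum(border)
  list(border = border, pairwise = pairCounts,
       borderNorm = if (totalBorder > 0) border / totalBorder else border,
       pairwiseNorm = if (totalAdj > 0) pairCounts / totalAdj else pairCounts,
       pairs = pairsTab)
}

#' The 44-feature MSI block of one region
#'
#' Concatenates, in the canonical order of the feature dictionary:
#' 4 co-occurrence statistics (contrast, correlation, homogeneity, energy),
#' 5 absolute subregion volumes, 5 absolute border interactions, 10 absolute
#' pairwise interactions, 5 volume percentages, 5 normalized border
#' interactions and 10 normalized pairwise interactions.
#'
#' @param map a [HabitatMap-class] or habitat label array.
#' @param mask logical mask (defaults to labels > 0).
#' @param K habitat count (the canonical bank uses K = 5; other K regenerate
#'   feature names accordingly).
#' @return named numeric of length `4 + 4*K + 2*choose(K,2)` (44 when K=5),
#'   names `MSI1..MSI44` for K = 5.
#' @export
msiWhole <- function(map, mask = NULL, K = NULL) {
  if (is(map, "HabitatMap")) {
    if (is.null(K)) K <- map@K
    map <- map@labels
  }
  if (is.null(K)) K <- 5L
  if (is.matrix(map)) map <- array(map, dim = c(dim(map), 1L))
  if (is.null(mask)) mask <- map > 0L
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  g <- glcmStats(map, mask, levels = seq_len(K))
  vol <- regionVolumes(map, mask, K)
  ic <- interactionCounts(map, mask, K)
  v <- c(g, vol$absolute, ic$border, ic$pairwise,
         vol$fraction, ic$borderNorm, ic$pairwiseNorm)
  names(v) <- paste0("MSI", seq_along(v))
  v
}

#' Left/right symmetric-difference block
#'
#' Elementwise `|MSI_L - MSI_W| * |MSI_R - MSI_W|`, quantifying left/right
#' asymmetry of each feature relative to the whole lung.  Exchange-symmetric
#' in (L, R) and zero whenever one side equals the whole.
#'
#' @param msiL,msiR,msiW aligned 44-value blocks from [msiWhole()].
#' @return named numeric, names continuing the bank (`MSI45..MSI88` for the
#'   canonical 44-value blocks).
#' @export
symmetricDifference <- function(msiL, msiR, msiW) {
  n <- length(msiW)
  if (length(msiL) != n || length(msiR) != n)
    stop("block length mismatch")
  v <- abs(msiL - msiW) * abs(msiR - msiW)
  names(v) <- paste0("MSI", n + seq_len(n))
  v
}

#' The full 88-feature MSI vector
#'
#' MSI1-44 computed on the whole lung mask; MSI45-88 the symmetric
#' difference of the blocks computed on the left lung, right lung and whole
#' lung (the whole-lung block is computed on the whole mask, not derived
#' from the sides).
#'
#' @param map a [HabitatMap-class] or label array.
#' @param leftMask,rightMask disjoint logical masks partitioning the whole
#'   lung mask.
#' @param K habitat count (default from the map, else 5).
#' @return named numeric of length 88 (`MSI1..MSI88` for K = 5).
#' @export
fullMSI <- function(map, leftMask, rightMask, K = NULL) {
  if (is(map, "HabitatMap")) {
    if (is.null(K)) K <- map@K
    map <- map@labels
  }
  if (is.null(K)) K <- 5L
  if (any(leftMask & rightMask)) stop("left and right masks overlap")
  whole <- leftMask | rightMask
  w <- msiWhole(map, whole, K)
  l <- msiWhole(map, leftMask, K)
  r <- msiWhole(map, rightMask, K)
  c(w, symmetricDifference(l, r, w))
}

#' MSI feature dictionary
#'
#' Machine-readable mapping from feature names (MSI1..MSI88 for K = 5) to
#' their definitions: feature family, subregions involved, and whether the
#' entry is an absolute count, a normalized share, or a left/right
#' symmetric difference.
#'
#' @param K habitat count.
#' @return data.frame: name, index, family, description.
#' @export
msiDictionary <- function(K = 5L) {
  pairsTab <- habitatPairs(K)
  base <- c(
    paste0("co-occurrence ", c("contrast", "correlation", "homogeneity", "energy"),
           " of habitat labels"),
    sprintf("absolute volume of SR%d (voxels)", seq_len(K)),
    sprintf("absolute border interaction of SR%d (mask-boundary faces)", seq_len(K)),
    sprintf("absolute interaction SR%d-SR%d (adjacent voxel pairs)",
            pairsTab$i, pairsTab$j),
    sprintf("volume fraction of SR%d", seq_len(K)),
    sprintf("normalized border interaction of SR%d", seq_len(K)),
    sprintf("normalized interaction SR%d-SR%d", pairsTab$i, pairsTab$j))
  family <- c(rep("glcm", 4), rep("volume", K), rep("border", K),
              rep("pairwise", nrow(pairsTab)), rep("volume_norm", K),
              rep("border_norm", K), rep("pairwise_norm", nrow(pairsTab)))
  n <- length(base)
  data.frame(
    name = paste0("MSI", seq_len(2 * n)),
    index = seq_len(2 * n),
    family = c(family, paste0("dsym_", family)),
    description = c(base, paste0("left/right symmetric difference of: ", base)),
    stringsAsFactors = FALSE)
}

#' Extract per-patient MSI vectors for a cohort
#'
#' @param maps list of [HabitatMap-class] objects.
#' @param leftMasks,rightMasks matching lists of side masks.
#' @return matrix, one row per patient, columns MSI1..MSI88.
#' @export
msiMatrix <- function(maps, leftMasks, rightMasks) {
  t(mapply(function(m, l, r) fullMSI(m, l, r),
           maps, leftMasks, rightMasks))
}

#' Whole-lung classical radiomics comparator
#'
#' First-order statistics (the same ten-statistic bank as the superpixel
#' features) over all mask voxels of each composite channel, plus the four
#' co-occurrence statistics on the 32-level quantized lung-window channel —
#' 44 values.  This comparator profiles the lung as one entity and is blind
#' to the spatial arrangement of disease, which is the contrast the habitat
#' features are designed to expose.
#'
#' @param composite a [CompositeImage-class].
#' @param mask logical lung mask.
#' @param glcmLevels quantization level count for the texture block.
#' @return named numeric of length 44.
#' @export
wholeLungRadiomics <- function(composite, mask, glcmLevels = 32L) {
  stopifnot(is(composite, "CompositeImage"))
  if (!any(mask)) stop("empty mask")
  ch <- composite@channels
  if (!identical(dim(ch)[1:3], dim(mask))) stop("composite/mask mismatch")
  out <- numeric(0)
  for (c in seq_len(4L)) {
    v <- ch[, , , c][mask]
    s <- firstOrderStats(v)
    names(s) <- paste0(composite@channelNames[c], "_", names(s))
    out <- c(out, s)
  }
  q <- array(0L, dim = dim(mask))
  lungCh <- ch[, , , 1L]
  q[mask] <- pmin(floor(lungCh[mask] * glcmLevels), glcmLevels - 1L) + 1L
  g <- glcmStats(q, mask, levels = seq_len(glcmLevels))
  names(g) <- paste0("glcm_", names(g))
  c(out, g)
}
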