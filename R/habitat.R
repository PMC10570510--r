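# Two-level habitat detection: patient-level SLIC oversegmentation, then
# population-level hierarchical clustering of superpixel statistics with
# gap-criterion selection of the habitat count.

#' SLIC oversegmentation of a composite image
#'
#' Runs simple linear iterative clustering per axial slice, restricted to
#' the lung mask, on all four composite channels.  The per-slice superpixel
#' target is the global target apportioned by slice mask area.  Labels are
#' relabelled contiguously 1..S across the volume; every superpixel is
#' connected within its slice.  The algorithm is deterministic (grid
#' initialisation, fixed iteration count); `seed` is accepted for interface
#' symmetry and recorded but not consumed.
#'
#' @param composite a [CompositeImage-class].
#' @param mask logical 3-D lung mask, co-registered with `composite`.
#' @param nSuperpixels global superpixel target; default one superpixel per
#'   ~25 mask voxels in-plane.
#' @param compactness SLIC compactness on \[0,1\] channels (default 0.1,
#'   colour-driven boundaries).
#' @param maxIter SLIC iterations.
#' @param seed unused (determinism); kept for call-site uniformity.
#' @return a [SuperpixelMap-class].
#' @export
oversegment <- function(composite, mask, nSuperpixels = NULL,
                        compactness = 0.1, maxIter = 10L, seed = NULL) {
  stopifnot(is(composite, "CompositeImage"))
  ch <- composite@channels
  d <- dim(ch)[1:3]
  if (!identical(d, dim(mask))) stop("composite and mask are not co-registered")
  total <- sum(mask)
  if (total == 0) stop("fully empty mask")
  if (is.null(nSuperpixels)) nSuperpixels <- max(2, round(total / 25))
  if (nSuperpixels < 1) stop("nSuperpixels must be >= 1")
  labels <- array(0L, dim = d)
  offset <- 0L
  for (z in seq_len(d[3])) {
    mz <- mask[, , z]
    nz <- sum(mz)
    if (nz == 0) next # empty mask slice skipped
    target <- max(1L, round(nSuperpixels * nz / total))
    sl <- cpp_slic_slice(ch[, , z, , drop = TRUE], mz,
                         as.integer(target), compactness, as.integer(maxIter))
    pos <- sl > 0L
    labels[, , z][pos] <- sl[pos] + offset
    offset <- offset + max(sl)
  }
  new("SuperpixelMap", labels = labels, nSuperpixels = offset)
}

# the ten first-order statistics of one value vector; degenerate (constant)
# inputs get skewness = kurtosis = 0 by policy
firstOrderStats <- function(v) {
  n <- length(v)
  m <- mean(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  va <- if (n > 1) stats::var(v) else 0
  s <- sqrt(va)
  m2 <- mean((v - m)^2)
  if (m2 > 0) {
    skew <- mean((v - m)^3) / m2^1.5
    kurt <- mean((v - m)^4) / m2^2
  } else {
    skew <- 0; kurt <- 0
  }
  c(skewness = skew, kurtosis = kurt, mean = m, median = q[2],
    q1 = q[1], q3 = q[3], iqr = q[3] - q[1], sd = s, variance = va,
    energy = mean(v^2))
}

#' Superpixel feature table: ten statistics on four channels
#'
#' For every superpixel, computes skewness, kurtosis, mean, median, first
#' and third quartiles, interquartile range, standard deviation, variance
#' and energy (mean of squares) on each of the four composite channels —
#' 40 columns named `<channel>_<statistic>`.  Quantiles use linear
#' interpolation; variance and sd are the sample (n-1) versions; constant
#' superpixels get skewness = kurtosis = 0.
#'
#' @param composite a [CompositeImage-class].
#' @param spmap a [SuperpixelMap-class] on the same lattice.
#' @return data.frame: `superpixel` id column plus the 40 feature columns.
#' @export
superpixelFeatures <- function(composite, spmap) {
  stopifnot(is(composite, "CompositeImage"), is(spmap, "SuperpixelMap"))
  lab <- spmap@labels
  S <- spmap@nSuperpixels
  idx <- which(lab > 0L)
  labs <- as.integer(lab[idx])
  if (!identical(sort(unique(labs)), seq_len(S)))
    stop("superpixel label gaps")
  chNames <- composite@channelNames
  ch <- composite@channels
  nvox <- prod(dim(ch)[1:3])
  out <- matrix(NA_real_, nrow = S, ncol = 40L)
  statNames <- c("skewness", "kurtosis", "mean", "median", "q1", "q3",
                 "iqr", "sd", "variance", "energy")
  colnames(out) <- as.vector(t(outer(chNames, statNames, paste, sep = "_")))
  for (c in seq_len(4L)) {
    vals <- ch[idx + (c - 1L) * nvox]
    groups <- split(vals, labs)
    stats40 <- vapply(groups, firstOrderStats, numeric(10L))
    out[, (c - 1L) * 10L + seq_len(10L)] <- t(stats40)
  }
  data.frame(superpixel = seq_len(S), out, check.names = FALSE)
}

# pooled within-cluster sum of squared distances to cluster centroids
withinSS <- function(X, cl) {
  tot <- 0
  for (k in unique(cl)) {
    rows <- X[cl == k, , drop = FALSE]
    mu <- colMeans(rows)
    tot <- tot + sum(sweep(rows, 2, mu)^2)
  }
  tot
}

#' Gap-statistic selection of the cluster count
#'
#' Tibshirani's gap statistic with uniform-over-bounding-box reference
#' datasets and the same clustering routine as the population clustering
#' (Ward-linkage agglomerative clustering on Euclidean distances).  Returns
#' the smallest K in `kRange` with `Gap(K) >= Gap(K+1) - s(K+1)`; if no K
#' qualifies, the largest K in the range is returned.  All-identical rows
#' return 1 with a warning.
#'
#' @param X numeric matrix of (standardized) feature rows.
#' @param kRange candidate cluster counts (the rule also evaluates
#'   `max(kRange) + 1`).
#' @param B number of reference datasets (>= 5).
#' @param seed RNG seed for the reference draws.
#' @param linkage hclust linkage.
#' @return integer K, with a `"gap"` attribute holding the diagnostic table
#'   (k, logW, expected logW, gap, s) and a `"fired"` attribute saying
#'   whether the stopping rule was satisfied inside `kRange` (when it is
#'   not, the largest candidate is returned and `fired` is `FALSE`).
#' @export
selectKGap <- function(X, kRange = 2:8, B = 10L, seed = 1L,
                       linkage = "ward.D2") {
  X <- as.matrix(X)
  if (B < 5) stop("B must be >= 5")
  if (nrow(X) < max(kRange) * 5)
    stop("need at least 5 rows per candidate cluster")
  if (all(apply(X, 2, function(col) max(col) - min(col)) == 0)) {
    warning("degenerate input: all rows identical; returning K = 1")
    return(1L)
  }
  # k = 1 is always evaluated so that structureless (single-cluster) data
  # can be flagged: if the rule already holds at k = 1 the function returns
  # 1 and the caller decides how to enforce its k_min
  ks <- sort(unique(c(1L, kRange, max(kRange) + 1L)))
  tree <- stats::hclust(stats::dist(X), method = linkage)
  logW <- vapply(ks, function(k) log(withinSS(X, stats::cutree(tree, k))), 0)
  rng <- apply(X, 2, range)
  logWref <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      ref <- vapply(seq_len(ncol(X)),
                    function(j) stats::runif(nrow(X), rng[1, j], rng[2, j]),
                    numeric(nrow(X)))
      rtree <- stats::hclust(stats::dist(ref), method = linkage)
      vapply(ks, function(k) log(withinSS(ref, stats::cutree(rtree, k))), 0)
    }, numeric(length(ks)))
  })
  gap <- rowMeans(logWref) - logW
  s <- apply(logWref, 1, stats::sd) * sqrt(1 + 1 / B)
  K <- NA_integer_
  for (i in seq_along(ks)) {
    if (!(ks[i] %in% c(1L, kRange))) next
    if (i < length(ks) && gap[i] >= gap[i + 1] - s[i + 1]) { K <- ks[i]; break }
  }
  fired <- !is.na(K)
  if (fired && K == 1L)
    warning("gap criterion favours a single cluster (structureless input)")
  if (is.na(K)) K <- max(kRange)
  structure(as.integer(K), fired = fired,
            gap = data.frame(k = ks, logW = logW,
                             ElogW = rowMeans(logWref), gap = gap, s = s))
}

# Consensus dendrogram read: over R seeded subsample draws, find the finest
# partition whose every branch still holds at least minShare of the rows
# (habitats are population-level subregions; smaller branches are outlier
# superpixels, not habitats), and take the median across draws.
dendrogramConsensusK <- function(Z, kRange, R = 15L, drawSize = 1500L,
                                 minShare = 0.05, seed = 1L,
                                 linkage = "ward.D2") {
  kMin <- min(kRange); kMax <- max(kRange)
  ks <- withSeed(seed, {
    vapply(seq_len(R), function(d) {
      rows <- if (nrow(Z) > drawSize) sample(nrow(Z), drawSize) else seq_len(nrow(Z))
      tree <- stats::hclust(stats::dist(Z[rows, , drop = FALSE]),
                            method = linkage)
      frac <- vapply(kMin:kMax, function(k)
        min(tabulate(stats::cutree(tree, k), k)) / length(rows), 0)
      ok <- which(frac >= minShare)
      if (!length(ok)) kMin else (kMin:kMax)[max(ok)]
    }, 0L)
  })
  structure(as.integer(round(stats::median(ks))), draws = ks)
}

#' Fit the population-level habitat model
#'
#' Pools superpixel feature rows across patients, z-scores each feature on
#' the pooled table, optionally subsamples (stratified by patient) for
#' tractability, clusters with Ward-linkage agglomerative clustering on
#' Euclidean distances, and stores per-cluster centroids in standardized
#' space.  The habitat count K is decided by the gap criterion together
#' with the hierarchical structure of the dendrogram: when the gap
#' statistic's stopping rule fires inside `kRange` its K is used; when the
#' gap curve rises monotonically (its known behaviour on bridged imaging
#' features, where no K satisfies the rule) the consensus dendrogram read
#' decides — over seeded subsample draws, the finest partition whose every
#' branch keeps at least 5\% of the superpixels, aggregated by the median.
#' Both diagnostics are recorded in the model metadata.
#' Habitat labels are canonically reordered by ascending mean lung-window
#' intensity so subregion indices are stable across runs (SR1 most
#' air-like, SRK densest).
#'
#' @param tables list of [superpixelFeatures()] data.frames (one per
#'   patient), or a single pooled data.frame with a `patient` column.
#' @param kRange candidate habitat counts (minimum enforced at 2).
#' @param gapRefs reference-set count B for [selectKGap()].
#' @param seed RNG seed (subsampling and gap references).
#' @param maxRows subsampling cap on pooled rows.
#' @param linkage hclust linkage.
#' @return a [HabitatModel-class].
#' @export
fitPopulationClusters <- function(tables, kRange = 2:8, gapRefs = 10L,
                                  seed = 1L, maxRows = 20000L,
                                  linkage = "ward.D2") {
  if (is.data.frame(tables)) {
    patient <- tables$patient
    if (is.null(patient)) patient <- rep("P1", nrow(tables))
    feat <- tables[, setdiff(colnames(tables), c("patient", "superpixel")),
                   drop = FALSE]
  } else {
    if (length(tables) < 2) stop("need at least 2 patients")
    feat <- do.call(rbind, lapply(tables, function(t)
      t[, setdiff(colnames(t), c("patient", "superpixel")), drop = FALSE]))
    patient <- rep(seq_along(tables), vapply(tables, nrow, 0L))
  }
  kRange <- sort(unique(pmax(as.integer(kRange), 2L)))
  if (nrow(feat) < max(kRange) * 10)
    stop("too few pooled superpixels for the requested kRange")
  X <- as.matrix(feat)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  keep <- seq_len(nrow(Z))
  if (nrow(Z) > maxRows) {
    keep <- withSeed(seed, {
      unlist(lapply(split(seq_len(nrow(Z)), patient), function(rows) {
        take <- max(1L, round(length(rows) * maxRows / nrow(Z)))
        if (take >= length(rows)) rows else sort(sample(rows, take))
      }), use.names = FALSE)
    })
  }
  Zs <- Z[keep, , drop = FALSE]

  gapK <- selectKGap(Zs, kRange = kRange, B = gapRefs, seed = seed,
                     linkage = linkage)
  gapTable <- attr(gapK, "gap")
  gapFired <- isTRUE(attr(gapK, "fired"))
  dendroK <- dendrogramConsensusK(Zs, kRange, seed = seed, linkage = linkage)
  # the habitat count comes from the gap criterion when its stopping rule
  # fires inside the candidate range; on bridged imaging features the gap
  # curve can rise monotonically (the rule never fires), and the consensus
  # dendrogram read decides instead
  K <- if (gapFired) as.integer(gapK) else as.integer(dendroK)
  if (K < 2L) {
    warning("cluster-count criteria favour a single cluster; enforcing K = 2 (k_min)")
    K <- 2L
  }
  tree <- stats::hclust(stats::dist(Zs), method = linkage)
  cl <- stats::cutree(tree, k = K)
  centers <- t(vapply(seq_len(K),
                      function(k) colMeans(Zs[cl == k, , drop = FALSE]),
                      numeric(ncol(Zs))))
  # canonical ordering: ascending mean lung-window intensity (original units)
  lungMeanCol <- match("lung_mean", colnames(X))
  if (is.na(lungMeanCol)) lungMeanCol <- 1L
  ord <- order(centers[, lungMeanCol] * scl[lungMeanCol] + ctr[lungMeanCol])
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- paste0("SR", seq_len(K))
  new("HabitatModel", K = as.integer(K), centers = centers,
      featureNames = colnames(X), featureCenter = ctr, featureScale = scl,
      metadata = list(seed = as.integer(seed), linkage = linkage,
                      gap = gapTable, gapK = as.integer(gapK),
                      gapFired = gapFired,
                      dendrogramK = as.integer(dendroK),
                      dendrogramDraws = attr(dendroK, "draws"),
                      nPooled = nrow(Z), nClustered = nrow(Zs),
                      cohortFingerprint = sprintf("%dx%d:%.6g", nrow(Z),
                                                  ncol(Z), sum(Z^2))))
}

#' Assign habitat labels to a superpixel map
#'
#' Standardizes the feature rows with the model's parameters and maps every
#' superpixel to its nearest centroid (Euclidean distance in standardized
#' space); all voxels of the superpixel inherit that habitat label.  Ties go
#' to the lowest label id.
#'
#' @param spmap a [SuperpixelMap-class].
#' @param features the matching [superpixelFeatures()] table.
#' @param model a [HabitatModel-class].
#' @return a [HabitatMap-class].
#' @export
assignHabitats <- function(spmap, features, model) {
  stopifnot(is(spmap, "SuperpixelMap"), is(model, "HabitatModel"))
  featCols <- setdiff(colnames(features), c("patient", "superpixel"))
  if (!setequal(featCols, model@featureNames))
    stop("feature columns do not match the habitat model")
  X <- as.matrix(features[, model@featureNames, drop = FALSE])
  Z <- sweep(sweep(X, 2, model@featureCenter), 2, model@featureScale, "/")
  # squared distances to each centroid; which.max of negatives keeps the
  # lowest-index winner on ties
  d2 <- outer(rowSums(Z^2), rowSums(model@centers^2), `+`) -
    2 * Z %*% t(model@centers)
  hab <- max.col(-d2, ties.method = "first")
  ord <- order(features$superpixel)
  lut <- integer(spmap@nSuperpixels)
  lut[features$superpixel[ord]] <- hab[ord]
  lab <- spmap@labels
  out <- array(0L, dim = dim(lab))
  pos <- lab > 0L
  out[pos] <- lut[lab[pos]]
  new("HabitatMap", labels = out, K = model@K)
}
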