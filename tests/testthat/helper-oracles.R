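# Independent oracles and small fixture builders used across the test files.

# Brute-force 6-connected adjacency enumeration: loops over every voxel and
# its +x/+y/+z neighbour, independent of the vectorised implementation.
bruteInteractions <- function(labels, mask, K) {
  d <- dim(labels)
  pairs <- matrix(0, K, K)
  border <- numeric(K)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    lab <- labels[x, y, z]
    for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      nx <- x + step[1]; ny <- y + step[2]; nz <- z + step[3]
      inGrid <- nx >= 1 && nx <= d[1] && ny >= 1 && ny <= d[2] &&
        nz >= 1 && nz <= d[3]
      if (!inGrid || !mask[nx, ny, nz]) {
        border[lab] <- border[lab] + 1
      } else if (any(step > 0)) { # count each unordered pair once
        nl <- labels[nx, ny, nz]
        pairs[lab, nl] <- pairs[lab, nl] + 1
      }
    }
  }
  pairTab <- utils::combn(K, 2)
  pairCounts <- apply(pairTab, 2, function(ij)
    pairs[ij[1], ij[2]] + pairs[ij[2], ij[1]])
  totalAdj <- sum(pairs)
  list(border = border, pairwise = pairCounts,
       borderNorm = if (sum(border) > 0) border / sum(border) else border,
       pairwiseNorm = if (totalAdj > 0) pairCounts / totalAdj else pairCounts)
}

# Brute-force co-occurrence statistics over explicit offset loops.
bruteGLCM <- function(labels, mask, levels,
                      offsets = list(c(1L, 0L), c(0L, 1L))) {
  d <- dim(labels)
  L <- length(levels)
  P <- matrix(0, L, L)
  for (off in offsets) for (x in seq_len(d[1])) for (y in seq_len(d[2]))
    for (z in seq_len(d[3])) {
      nx <- x + off[1]; ny <- y + off[2]
      if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2]) next
      if (!mask[x, y, z] || !mask[nx, ny, z]) next
      a <- labels[x, y, z]; b <- labels[nx, ny, z]
      if (a < 1 || b < 1) next
      i <- match(a, levels); j <- match(b, levels)
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
  if (sum(P) == 0)
    return(c(contrast = 0, correlation = 0, homogeneity = 1, energy = 1))
  P <- P / sum(P)
  iv <- as.numeric(levels)
  contrast <- 0; hom <- 0; ene <- 0; mu <- 0
  for (i in 1:L) for (j in 1:L) {
    contrast <- contrast + P[i, j] * (iv[i] - iv[j])^2
    hom <- hom + P[i, j] / (1 + (iv[i] - iv[j])^2)
    ene <- ene + P[i, j]^2
    mu <- mu + iv[i] * P[i, j]
  }
  sig2 <- 0; cor <- 0
  for (i in 1:L) for (j in 1:L) {
    sig2 <- sig2 + (iv[i] - mu)^2 * P[i, j]
    cor <- cor + (iv[i] - mu) * (iv[j] - mu) * P[i, j]
  }
  c(contrast = contrast,
    correlation = if (sig2 > 0) cor / sig2 else 0,
    homogeneity = hom, energy = ene)
}

# Direct first-order formulas written sum-by-sum (independent of
# firstOrderStats' vectorised code path).
directStats <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  dev <- v - m
  m2 <- sum(dev^2) / n
  sorted <- sort(v)
  qAt <- function(p) { # linear-interpolation (type 7) quantile, by hand
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  va <- if (n > 1) sum(dev^2) / (n - 1) else 0
  c(skewness = if (m2 > 0) (sum(dev^3) / n) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) (sum(dev^4) / n) / m2^2 else 0,
    mean = m, median = qAt(0.5), q1 = qAt(0.25), q3 = qAt(0.75),
    iqr = qAt(0.75) - qAt(0.25), sd = sqrt(va), variance = va,
    energy = sum(v^2) / n)
}

# Build a CompositeImage whose four channels are copies (or a list) of the
# supplied array; handy for feature-extraction fixtures.
makeTestComposite <- function(values, channels = NULL) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  d <- dim(values)
  if (is.null(channels)) channels <- list(values, values, values, values)
  ch <- array(0, dim = c(d, 4L))
  for (c in 1:4) ch[, , , c] <- channels[[c]]
  new("CompositeImage", channels = ch,
      channelNames = c("lung", "med", "lungEntropy", "medEntropy"),
      spacing = c(1, 1, 2.5), entropyBins = 32L)
}

# Tiny phantom settings used when only plumbing (not cluster recovery) is
# under test.
tinyPhantomParams <- function(...) {
  phantomParams(gridShape = c(32L, 32L, 16L), lesionRadiusRange = c(3, 5),
                lesionCountRange = c(1L, 2L), ...)
}
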