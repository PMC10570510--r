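# SLIC oversegmentation, superpixel statistics, gap criterion, population
# clustering and habitat assignment.

test_that("oversegmentation partitions the mask with contiguous labels", {
  ph <- generatePhantom(tinyPhantomParams(seed = 1), 0L)
  comp <- makeComposite(ph$scan, ph$mask, entropyRadius = 2, entropyBins = 64)
  target <- round(sum(ph$mask) / 25)
  sp <- oversegment(comp, ph$mask, nSuperpixels = target)
  lab <- superpixelLabels(sp)
  expect_true(all((lab > 0L) == ph$mask))
  u <- sort(unique(as.integer(lab[lab > 0L])))
  expect_identical(u, seq_len(sp@nSuperpixels))
  # achieved count within +/- 50% of the target
  expect_gte(sp@nSuperpixels, 0.5 * target)
  expect_lte(sp@nSuperpixels, 1.5 * target)
  # deterministic
  sp2 <- oversegment(comp, ph$mask, nSuperpixels = target)
  expect_identical(superpixelLabels(sp2), lab)
})

test_that("a one-voxel mask yields exactly one superpixel", {
  mask <- array(FALSE, c(16, 16, 16))
  mask[8, 8, 8] <- TRUE
  comp <- makeTestComposite(array(0.5, c(16, 16, 16)))
  sp <- oversegment(comp, mask, nSuperpixels = 4)
  expect_equal(sp@nSuperpixels, 1L)
  expect_error(oversegment(comp, array(FALSE, c(16, 16, 16))), "empty mask")
})

test_that("superpixels respect strong intensity boundaries", {
  vals <- array(0.2, c(40, 40, 1))
  vals[21:40, , 1] <- 0.8
  comp <- makeTestComposite(vals)
  mask <- array(TRUE, c(40, 40, 1))
  sp <- oversegment(comp, mask, nSuperpixels = 50)
  lab <- superpixelLabels(sp)
  purity <- vapply(split(as.vector(vals), as.vector(lab)), function(v)
    max(table(v)) / length(v), 0)
  expect_gte(mean(purity >= 1), 0.95)
})

test_that("superpixel statistics match direct formulas", {
  vals <- array(0, c(4, 1, 1))
  vals[, 1, 1] <- c(1, 2, 3, 4)
  comp <- makeTestComposite(vals)
  lab <- array(1L, c(4, 1, 1))
  sp <- new("SuperpixelMap", labels = lab, nSuperpixels = 1L)
  ft <- superpixelFeatures(comp, sp)
  expect_equal(ncol(ft), 41) # superpixel id + 10 stats x 4 channels
  expect_equal(ft$lung_mean, 2.5)
  expect_equal(ft$lung_median, 2.5)
  expect_equal(ft$lung_sd, 1.2910, tolerance = 1e-4)
  expect_equal(ft$lung_variance, 5 / 3)
  expect_equal(ft$lung_energy, 7.5) # (1 + 4 + 9 + 16) / 4
  expect_equal(ft$lung_q1, 1.75)
  expect_equal(ft$lung_q3, 3.25)
  expect_equal(ft$lung_iqr, 1.5)
  expect_equal(ft$lung_skewness, 0)
  expect_equal(ft$lung_kurtosis, directStats(c(1, 2, 3, 4))[["kurtosis"]])
})

test_that("degenerate and symmetric superpixels follow the stated policies", {
  vals <- array(0.3, c(5, 1, 1))
  comp <- makeTestComposite(vals)
  sp <- new("SuperpixelMap", labels = array(1L, c(5, 1, 1)), nSuperpixels = 1L)
  ft <- superpixelFeatures(comp, sp)
  expect_equal(ft$lung_mean, 0.3)
  expect_equal(ft$lung_q1, 0.3)
  expect_equal(ft$lung_iqr, 0)
  expect_equal(ft$lung_sd, 0)
  expect_equal(ft$lung_variance, 0)
  expect_equal(ft$lung_energy, 0.09)
  expect_equal(ft$lung_skewness, 0) # constant: defined as 0
  expect_equal(ft$lung_kurtosis, 0)

  sym <- array(0, c(3, 1, 1)); sym[, 1, 1] <- c(0.2, 0.5, 0.8)
  ftSym <- superpixelFeatures(makeTestComposite(sym),
                              new("SuperpixelMap",
                                  labels = array(1L, c(3, 1, 1)),
                                  nSuperpixels = 1L))
  expect_equal(ftSym$lung_skewness, 0)
})

test_that("superpixel statistics agree with the oracle on random sets", {
  set.seed(31)
  for (i in 1:100) {
    v <- stats::runif(sample(3:40, 1))
    expect_equal(unname(HabitatCT:::firstOrderStats(v)), unname(directStats(v)),
                 tolerance = 1e-12)
  }
})

test_that("the gap criterion recovers well-separated Gaussian clusters", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    ctr <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10), ncol = 2, byrow = TRUE)
    X <- do.call(rbind, lapply(1:4, function(k)
      cbind(stats::rnorm(30, ctr[k, 1]), stats::rnorm(30, ctr[k, 2]))))
    K <- selectKGap(X, kRange = 2:8, B = 10, seed = s)
    hits <- hits + (as.integer(K) == 4L)
  }
  expect_gte(hits, 18L) # >= 90% of seeds
})

test_that("gap criterion edge cases: single cluster, duplicated points", {
  set.seed(2)
  X1 <- matrix(stats::rnorm(200), 100, 2)
  expect_warning(K1 <- selectKGap(X1, 2:6, B = 10, seed = 2),
                 "single cluster")
  expect_equal(as.integer(K1), 1L)
  Xdup <- matrix(rep(c(0, 0, 5, 5), times = 60), ncol = 2, byrow = TRUE)
  expect_equal(as.integer(selectKGap(Xdup, 2:6, B = 5, seed = 1)), 2L)
  Xsame <- matrix(1, 50, 3)
  expect_warning(Ks <- selectKGap(Xsame, 2:6, B = 5, seed = 1), "degenerate")
  expect_equal(as.integer(Ks), 1L)
  expect_error(selectKGap(X1, 2:30, B = 5), "5 rows per")
  expect_error(selectKGap(X1, 2:6, B = 2), "B must be")
})

test_that("our gap internals agree with cluster::clusGap on the same routine", {
  skip_if_not_installed("cluster")
  set.seed(5)
  X <- rbind(matrix(stats::rnorm(60), 30, 2),
             matrix(stats::rnorm(60, 6), 30, 2))
  K <- selectKGap(X, 2:4, B = 10, seed = 1)
  ours <- attr(K, "gap")
  cg <- cluster::clusGap(X, FUNcluster = function(x, k)
    list(cluster = stats::cutree(stats::hclust(stats::dist(x), "ward.D2"), k)),
    K.max = 5, B = 10, d.power = 2, spaceH0 = "original", verbose = FALSE)
  # the data term logW is deterministic; clusGap's W is half the pooled
  # within-cluster sum of squares, so the curves differ by exactly log(2)
  expect_equal(ours$logW[ours$k %in% 1:5] - log(2), unname(cg$Tab[, "logW"]),
               tolerance = 1e-10)
})

test_that("population clustering recovers Gaussian structure, duplication-invariantly", {
  set.seed(9)
  ctr <- matrix(c(0, 0, 0, 12, 4, 8, 2, 12, 14), ncol = 3, byrow = TRUE)
  n <- 300 # per cluster; within-cluster sd 1, separation > 10 sd
  rows <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(stats::rnorm(n * 3), n, 3), 2, ctr[k, ], `+`)))
  tbl <- data.frame(superpixel = seq_len(3 * n), lung_mean = rows[, 1],
                    f2 = rows[, 2], f3 = rows[, 3])
  half <- seq_len(3 * n) <= 1.5 * n
  tables <- list(tbl[half, ], tbl[!half, ])
  m <- fitPopulationClusters(tables, kRange = 2:6, gapRefs = 10, seed = 1)
  expect_equal(nHabitats(m), 3L)
  expect_true(m@metadata$gapFired)
  # centroid recovery in original units: at 10-sigma separation every row
  # is assigned to its generating component, so each centroid equals the
  # empirical class mean; error far below 0.1 within-cluster sd
  orig <- sweep(sweep(m@centers, 2, m@featureScale, `*`), 2,
                m@featureCenter, `+`)
  empirical <- rowsum(rows, rep(1:3, each = n)) / n
  err <- apply(empirical, 1, function(cc)
    min(sqrt(rowSums(sweep(orig, 2, cc)^2))))
  expect_true(all(err < 0.1))
  expect_lt(max(err), 1e-6)
  # two identical patients pooled = one patient duplicated: identical
  # centroids in original units (the z-scale itself shifts infinitesimally
  # with the duplicated sample size)
  m2 <- fitPopulationClusters(c(tables, tables), kRange = 2:6,
                              gapRefs = 10, seed = 1)
  expect_equal(nHabitats(m2), 3L)
  orig2 <- sweep(sweep(m2@centers, 2, m2@featureScale, `*`), 2,
                 m2@featureCenter, `+`)
  expect_equal(orig2, orig, tolerance = 1e-8)
})

test_that("habitat assignment maps superpixels to nearest centroids", {
  centers <- matrix(c(0, 0, 4, 0), 2, 2, byrow = TRUE)
  rownames(centers) <- c("SR1", "SR2")
  colnames(centers) <- c("lung_mean", "lung_sd")
  model <- new("HabitatModel", K = 2L, centers = centers,
               featureNames = c("lung_mean", "lung_sd"),
               featureCenter = c(0, 0), featureScale = c(1, 1),
               metadata = list())
  lab <- array(0L, c(3, 1, 1)); lab[, 1, 1] <- c(1L, 2L, 3L)
  sp <- new("SuperpixelMap", labels = lab, nSuperpixels = 3L)
  feats <- data.frame(superpixel = 1:3,
                      lung_mean = c(0, 4, 2), lung_sd = c(0, 0, 0))
  hm <- assignHabitats(sp, feats, model)
  out <- habitatLabels(hm)[, 1, 1]
  expect_equal(out[1], 1L) # exactly at centroid 1
  expect_equal(out[2], 2L) # exactly at centroid 2
  expect_equal(out[3], 1L) # equidistant: tie goes to the lowest label
  bad <- feats; colnames(bad)[2] <- "other"
  expect_error(assignHabitats(sp, bad, model), "do not match")
})

test_that("the fitted habitat model recovers the planted tissue classes", {
  # one synthetic cohort under the study noise conditions; habitat labels
  # are canonically ordered by density, like the planted classes
  co <- generateCohort(15, 5, phantomParams(), seed = 1003)
  tables <- list(); spmaps <- list()
  for (i in seq_along(co$patients)) {
    p <- co$patients[[i]]
    comp <- makeComposite(p$scan, p$mask, entropyRadius = 2, entropyBins = 64)
    sp <- oversegment(comp, p$mask)
    spmaps[[i]] <- sp
    tables[[i]] <- superpixelFeatures(comp, sp)
  }
  model <- fitPopulationClusters(tables, kRange = 2:8, gapRefs = 10,
                                 seed = 1003, maxRows = 2000)
  expect_equal(nHabitats(model), 5L)
  densityOrder <- c(1L, 4L, 2L, 3L, 5L) # truth ids by ascending HU
  agr <- vapply(seq_along(co$patients), function(i) {
    p <- co$patients[[i]]
    hm <- assignHabitats(spmaps[[i]], tables[[i]], model)
    expect_true(all((habitatLabels(hm) > 0L) == p$mask)) # partition property
    mean(habitatLabels(hm)[p$mask] == match(p$truth, densityOrder)[p$mask])
  }, 0)
  expect_gt(mean(agr), 0.8)
  # semantic ordering: highest-intensity habitat is consolidation-like,
  # lowest is parenchyma-like
  p1 <- co$patients[[1]]
  hm1 <- assignHabitats(spmaps[[1]], tables[[1]], model)
  hu <- scanValues(p1$scan)
  meanHU <- vapply(1:5, function(k) mean(hu[habitatLabels(hm1) == k]), 0)
  expect_equal(which.min(meanHU), 1L)
  expect_equal(which.max(meanHU), 5L)
  # determinism of the whole fit
  model2 <- fitPopulationClusters(tables, kRange = 2:8, gapRefs = 10,
                                  seed = 1003, maxRows = 2000)
  expect_identical(model2@centers, model@centers)
})
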