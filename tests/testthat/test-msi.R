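# The multiregional spatial interaction feature bank.

test_that("co-occurrence statistics match hand-built matrices", {
  # single-offset strip [1,2,1,2]: all mass on the (1,2)/(2,1) cells
  strip <- matrix(c(1L, 2L, 1L, 2L), 4, 1)
  g <- glcmStats(strip, levels = 1:2, offsets = list(c(1L, 0L)))
  expect_equal(unname(g["contrast"]), 1)
  expect_equal(unname(g["energy"]), 0.5)
  expect_equal(unname(g["homogeneity"]), 0.5)
  expect_equal(unname(g["correlation"]), -1)
  # single-label map
  g1 <- glcmStats(matrix(1L, 5, 5), levels = 1:3)
  expect_equal(unname(g1["contrast"]), 0)
  expect_equal(unname(g1["homogeneity"]), 1)
  expect_equal(unname(g1["energy"]), 1)
  expect_equal(unname(g1["correlation"]), 0) # constant map policy
  # checkerboard is strictly rougher than a constant map
  cb <- matrix(rep(c(1L, 2L), 13)[1:25], 5, 5)
  expect_gt(unname(glcmStats(cb, levels = 1:2)["contrast"]),
            unname(g1["contrast"]))
  expect_error(glcmStats(matrix(0L, 3, 3)), "empty mask")
})

test_that("interaction counts match pair enumeration on the 2x3 fixture", {
  m <- matrix(c(1L, 1L, 1L, 2L, 2L, 2L), 2, 3) # [[1,1,2],[1,2,2]] layout
  m[1, ] <- c(1L, 1L, 2L); m[2, ] <- c(1L, 2L, 2L)
  ic <- interactionCounts(m, K = 2L)
  # 7 face-adjacent pairs in a 2x3 grid; 3 of them cross the 1|2 boundary
  expect_equal(ic$pairwise[1], 3)
  expect_equal(sum(ic$pairwiseNorm), 3 / 7)
  # full mask border: the surface faces of the 2x3x1 block
  expect_equal(sum(ic$border), 2 * (2 * 3) + 2 * (2 * 1) + 2 * (3 * 1))
})

test_that("single-habitat regions have zero pairwise and pure border counts", {
  ball <- array(FALSE, c(9, 9, 5))
  ball[3:7, 3:7, 2:4] <- TRUE
  lab <- array(0L, dim = dim(ball)); lab[ball] <- 1L
  ic <- interactionCounts(lab, ball, K = 5L)
  expect_true(all(ic$pairwise == 0))
  expect_equal(ic$border[1], 2 * 25 + 4 * 15) # cuboid surface faces
  expect_true(all(ic$border[2:5] == 0))
})

test_that("interaction and co-occurrence agree with brute force on random grids", {
  set.seed(17)
  for (i in 1:20) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:5, 1))
    K <- sample(2:5, 1)
    lab <- array(sample(0:K, prod(d), replace = TRUE), dim = d)
    mask <- lab > 0L
    if (!any(mask)) next
    ic <- interactionCounts(lab, mask, K)
    oracle <- bruteInteractions(lab, mask, K)
    expect_equal(ic$border, oracle$border)
    expect_equal(ic$pairwise, oracle$pairwise)
    expect_equal(ic$pairwiseNorm, oracle$pairwiseNorm)
    g <- glcmStats(lab, mask, levels = 1:K)
    expect_equal(g, bruteGLCM(lab, mask, 1:K), tolerance = 1e-12)
  }
})

test_that("region volumes count and normalize correctly", {
  lab <- array(0L, c(10, 10, 1))
  lab[1:3, 1:10, 1] <- 1L  # 30 voxels SR1
  lab[4:10, 1:10, 1] <- 4L # 70 voxels SR4
  v <- regionVolumes(lab, K = 5L)
  expect_equal(v$absolute, c(30, 0, 0, 70, 0))
  expect_equal(v$fraction, c(0.3, 0, 0, 0.7, 0))
  expect_equal(sum(v$fraction), 1)
  expect_error(regionVolumes(array(6L, c(2, 2, 1)), K = 5L), "exceed")
})

test_that("the whole-lung block has 44 entries in the documented order", {
  lab <- array(1L, c(6, 6, 2))
  v <- msiWhole(lab, K = 5L)
  expect_length(v, 44)
  expect_identical(names(v), paste0("MSI", 1:44))
  # all-SR1 map: only volume and border entries for SR1 are nonzero,
  # beyond the trivial co-occurrence values
  expect_equal(unname(v["MSI5"]), 72)  # absolute SR1 volume
  expect_true(all(v[paste0("MSI", 6:9)] == 0))
  expect_gt(unname(v["MSI10"]), 0)
  expect_true(all(v[paste0("MSI", 11:24)] == 0))
  expect_equal(unname(v["MSI25"]), 1)
  expect_true(all(v[paste0("MSI", 26:29)] == 0))
  expect_equal(unname(v["MSI30"]), 1)
  expect_true(all(v[paste0("MSI", 31:44)] == 0))
  expect_equal(sum(v[paste0("MSI", 25:29)]), 1)
})

test_that("the symmetric difference block follows its defining identity", {
  expect_equal(unname(symmetricDifference(2, 6, 4)), 4) # |2-4| x |6-4|
  w <- c(a = 3, b = 5)
  expect_equal(unname(symmetricDifference(c(3, 1), c(9, 9), w)),
               c(0, abs(1 - 5) * abs(9 - 5)))
  l <- stats::runif(44); r <- stats::runif(44); m <- stats::runif(44)
  expect_equal(symmetricDifference(l, r, m), symmetricDifference(r, l, m))
  expect_true(all(symmetricDifference(l, r, m) >= 0))
  expect_error(symmetricDifference(1:3, 1:2, 1:3), "length")
})

# mirror-symmetric fixture: two separated lung fields with identical content
mirrorFixture <- function(lesion = c("left", "both")) {
  lesion <- match.arg(lesion)
  lab <- array(0L, c(12, 8, 2))
  left <- array(FALSE, c(12, 8, 2)); left[2:5, 2:7, ] <- TRUE
  right <- array(FALSE, c(12, 8, 2)); right[8:11, 2:7, ] <- TRUE
  lab[left | right] <- 1L
  if (lesion %in% c("left", "both")) lab[3:4, 3:5, 1] <- 2L
  if (lesion == "both") lab[9:10, 3:5, 1] <- 2L
  list(lab = lab, left = left, right = right)
}

test_that("mirror-symmetric maps zero out the normalized asymmetry features", {
  fx <- mirrorFixture("both")
  v <- fullMSI(fx$lab, fx$left, fx$right, K = 5L)
  expect_length(v, 88)
  expect_identical(names(v), paste0("MSI", 1:88))
  # left and right blocks are equal and the fields are not adjacent, so
  # every normalized (percentage) feature matches the whole lung exactly
  expect_true(all(v[paste0("MSI", 69:88)] == 0))
  expect_true(all(v[paste0("MSI", 45:48)] == 0)) # co-occurrence matches too
  expect_true(all(v[paste0("MSI", 49:88)] >= 0))
  expect_error(fullMSI(fx$lab, fx$left, fx$left), "overlap")
})

test_that("unilateral disease has larger asymmetry interactions than bilateral", {
  uni <- mirrorFixture("left")
  bil <- mirrorFixture("both")
  vU <- fullMSI(uni$lab, uni$left, uni$right, K = 5L)
  vB <- fullMSI(bil$lab, bil$left, bil$right, K = 5L)
  # MSI79 = asymmetry of the normalized SR1-SR2 interaction
  expect_gt(vU["MSI79"], vB["MSI79"])
  # and of the SR2 volume fraction
  expect_gt(vU["MSI70"], vB["MSI70"])
})

test_that("MSI vectors are translation- and relabeling-invariant", {
  fx <- mirrorFixture("left")
  v <- fullMSI(fx$lab, fx$left, fx$right, K = 5L)
  # translation: embed everything one voxel deeper in a larger grid
  pad <- function(a, fill) {
    out <- array(fill, dim = dim(a) + 2L)
    out[2:(dim(a)[1] + 1), 2:(dim(a)[2] + 1), 2:(dim(a)[3] + 1)] <- a
    out
  }
  vT <- fullMSI(pad(fx$lab, 0L), pad(fx$left, FALSE), pad(fx$right, FALSE),
                K = 5L)
  expect_equal(vT, v)
  # relabeling: swap SR2 and SR3 everywhere, then read the swapped entries
  swapped <- fx$lab
  swapped[fx$lab == 2L] <- 3L
  vS <- fullMSI(swapped, fx$left, fx$right, K = 5L)
  expect_equal(unname(vS["MSI7"]), unname(v["MSI6"]))   # absolute volume
  expect_equal(unname(vS["MSI27"]), unname(v["MSI26"])) # volume fraction
  expect_equal(unname(vS["MSI16"]), unname(v["MSI15"])) # SR1-SR3 vs SR1-SR2
  expect_equal(unname(vS["MSI36"]), unname(v["MSI35"]))
})

test_that("normalized interactions are bounded as shares", {
  set.seed(4)
  lab <- array(sample(0:5, 6 * 6 * 4, replace = TRUE), c(6, 6, 4))
  mask <- lab > 0L
  v <- msiWhole(lab, mask, K = 5L)
  expect_equal(sum(v[paste0("MSI", 25:29)]), 1)
  expect_lte(sum(v[paste0("MSI", 30:34)]), 1 + 1e-12)
  expect_lte(sum(v[paste0("MSI", 35:44)]), 1 + 1e-12)
  expect_true(all(v[paste0("MSI", 5:24)] >= 0))
})

test_that("the feature dictionary documents all 88 entries", {
  d <- msiDictionary(5L)
  expect_equal(nrow(d), 88)
  expect_identical(d$name, paste0("MSI", 1:88))
  expect_equal(sum(grepl("symmetric difference", d$description)), 44)
})

test_that("whole-lung radiomics profiles intensity but not arrangement", {
  ph <- generatePhantom(tinyPhantomParams(seed = 8), 0L)
  comp <- makeComposite(ph$scan, ph$mask, entropyRadius = 2, entropyBins = 64)
  v <- wholeLungRadiomics(comp, ph$mask)
  expect_length(v, 44) # 10 statistics x 4 channels + 4 texture values
  # constant lung: dispersion statistics vanish
  flat <- makeTestComposite(array(0.5, c(16, 16, 4)))
  mask <- array(TRUE, c(16, 16, 4))
  vf <- wholeLungRadiomics(flat, mask)
  expect_equal(unname(vf["lung_sd"]), 0)
  expect_equal(unname(vf["lung_iqr"]), 0)
  expect_equal(unname(vf["lung_variance"]), 0)
  # histogram-matched rearrangement: identical first-order block
  set.seed(3)
  a <- array(stats::runif(16 * 16 * 2), c(16, 16, 2))
  b <- array(sample(a), c(16, 16, 2)) # same multiset, scrambled layout
  va <- wholeLungRadiomics(makeTestComposite(a), array(TRUE, c(16, 16, 2)))
  vb <- wholeLungRadiomics(makeTestComposite(b), array(TRUE, c(16, 16, 2)))
  expect_equal(va[1:40], vb[1:40])
  expect_error(wholeLungRadiomics(flat, array(FALSE, c(16, 16, 4))), "empty")
})
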