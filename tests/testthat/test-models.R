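# Feature ranking, SMOTE, boosting, nested LOOCV, benchmark, cascade,
# composite.

test_that("chi-square ranking reproduces the hand contingency table", {
  # perfectly separating binary feature, 20 + 20 patients
  x <- rep(c(0, 1), each = 20)
  y <- rep(c(0L, 1L), each = 20)
  X <- data.frame(perfect = x, noise = rep(c(0.3, 0.7), 20))
  r <- chi2Rank(X, y)
  pExpect <- stats::pchisq(40, df = 1, lower.tail = FALSE) # X2 = 40, df 1
  expect_equal(r$p[r$feature == "perfect"], pExpect, tolerance = 1e-12)
  expect_equal(r$score[r$feature == "perfect"], -log(pExpect),
               tolerance = 1e-9)
  expect_equal(round(r$score[r$feature == "perfect"], 1), 22.1)
  expect_identical(r$feature[1], "perfect")
})

test_that("scores behave as -log(p) with deterministic tie-breaking", {
  y <- rep(c(0L, 1L), each = 10)
  X <- data.frame(b = stats::runif(20), a = 1) # constant feature -> p = 1
  r <- chi2Rank(X, y)
  expect_equal(r$score[r$feature == "a"], 0) # -log(1)
  expect_true(all(r$score >= 0))
  # equal-score features sort lexicographically
  X2 <- data.frame(zeta = 1, alpha = 1)
  r2 <- chi2Rank(X2, y)
  expect_identical(r2$feature, c("alpha", "zeta"))
  expect_error(chi2Rank(X, rep(0L, 20)), "2 patients per class")
})

test_that("ranking is invariant to monotone transforms preserving bins", {
  set.seed(8)
  y <- rep(c(0L, 1L), each = 15)
  x <- stats::rnorm(30) + 0.8 * y
  p1 <- chi2Rank(data.frame(f = x), y)$p
  p2 <- chi2Rank(data.frame(f = exp(x)), y)$p
  expect_equal(p1, p2)
})

test_that("SMOTE balances classes with on-segment synthetic points", {
  set.seed(2)
  X <- rbind(matrix(stats::rnorm(40), 20, 2),
             matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  y <- c(rep(0L, 20), 1L, 1L)
  out <- smoteOversample(X, y, k = 5, seed = 1)
  expect_equal(sum(out$y == 1L), sum(out$y == 0L)) # balance contract
  expect_identical(out$X[1:22, ], X) # originals preserved
  syn <- out$X[out$y == 1L, ][-(1:2), , drop = FALSE]
  # minority is {(0,0),(1,1)} with k reduced to 1: synthetics are (t,t)
  expect_equal(syn[, 1], syn[, 2], tolerance = 1e-12)
  expect_true(all(syn >= 0 & syn <= 1))
  # already balanced input returns unchanged
  same <- smoteOversample(X[1:20, ], rep(c(0L, 1L), 10))
  expect_identical(same$X, X[1:20, ])
  expect_error(smoteOversample(X[1:21, ], c(rep(0L, 20), 1L)),
               "at least 2")
})

test_that("the boosted tree ensemble separates learnable data", {
  set.seed(5)
  X <- data.frame(a = c(stats::rnorm(30, 0), stats::rnorm(30, 3)),
                  b = stats::rnorm(60))
  y <- rep(c(0L, 1L), each = 30)
  fit <- fitBoostedTrees(X, y, boostSpec(nTrees = 25))
  expect_lte(length(fit$trees), 25)
  expect_gte(mean(predict(fit, X) == y), 0.95)
  expect_true(all(predict(fit, X) %in% c(0L, 1L)))
  sc <- predict(fit, X, type = "score")
  expect_length(sc, 60)
})

test_that("LOOCV runs one fold per patient with in-fold nesting", {
  set.seed(11)
  X <- data.frame(a = stats::rnorm(12), b = stats::rnorm(12))
  y <- rep(c(0L, 1L), each = 6)
  rep12 <- loocvEvaluate(X, y, nTop = 2, spec = boostSpec(nTrees = 10),
                         seed = 1)
  expect_equal(nrow(rep12$predictions), 12)
  expect_equal(sum(rep12$confusion), 12)
  expect_equal(unname(rep12$metrics["accuracy"]),
               unname((rep12$confusion["TP"] + rep12$confusion["TN"]) / 12))
})

test_that("LOOCV recovers a strong class difference", {
  set.seed(21)
  n <- 20
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(f1 = stats::rnorm(n) + 4 * y, # d' = 4
                  f2 = stats::rnorm(n), f3 = stats::rnorm(n))
  r <- loocvEvaluate(X, y, nTop = 2, seed = 3)
  expect_gte(r$metrics["accuracy"], 0.9)
})

test_that("feature-count selection scans the grid and prefers small k on ties", {
  set.seed(31)
  n <- 20
  y <- rep(c(0L, 1L), each = n / 2)
  X <- data.frame(info = stats::rnorm(n) + 3 * y,
                  matrix(stats::rnorm(n * 9), n, 9))
  sel <- selectTopK(X, y, kGrid = c(1, 2, 5, 10),
                    spec = boostSpec(nTrees = 20), seed = 1)
  expect_equal(nrow(sel$report), 4)
  expect_true(10 %in% sel$report$k) # k = n_features evaluated
  expect_equal(sel$bestK, sel$report$k[which.max(sel$report$accuracy)])
  expect_error(selectTopK(X, y, kGrid = integer(0)), "empty")
  expect_error(selectTopK(X, y, kGrid = c(1, 99)), "n_features")
})

test_that("a single informative feature keeps the selected count small", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 20
    y <- rep(c(0L, 1L), each = n / 2)
    X <- data.frame(info = stats::rnorm(n) + 3 * y,
                    matrix(stats::rnorm(n * 14), n, 14))
    sel <- selectTopK(X, y, kGrid = c(1, 2, 5, 15),
                      spec = boostSpec(nTrees = 20), seed = s)
    hits <- hits + (sel$bestK <= 5)
  }
  expect_gte(hits, 4L) # >= 80% of seeds
})

test_that("benchmark features expose 17 documented columns with logs", {
  tbl <- generateClinicalTable(rep(c(0L, 1L), 10), seed = 3)
  Xb <- prepareBenchmarkFeatures(tbl)
  expect_equal(ncol(Xb), 17)
  expect_true(all(c("log_wbc_baseline", "log_platelets_syndrome",
                    "anc_baseline", "blasts_baseline", "age", "sex")
                  %in% colnames(Xb)))
  expect_equal(unname(Xb[, "log_wbc_baseline"]), log(tbl$wbc_baseline))
  # the printed-median check: WBC 2.5 transforms to ln(2.5)
  one <- tbl[1, ]; one$wbc_baseline <- 2.5
  expect_equal(unname(prepareBenchmarkFeatures(one)[, "log_wbc_baseline"]),
               log(2.5))
  expect_equal(round(log(2.5), 3), 0.916)
  # flipping the sex coding changes no other column
  flipped <- tbl; flipped$sex <- 1L - flipped$sex
  Xf <- prepareBenchmarkFeatures(flipped)
  keep <- setdiff(colnames(Xb), "sex")
  expect_equal(Xf[, keep], Xb[, keep])
  neg <- tbl; neg$anc_baseline[1] <- -1
  expect_error(prepareBenchmarkFeatures(neg), "negative")
  zero <- tbl; zero$wbc_baseline[1] <- 0
  expect_warning(prepareBenchmarkFeatures(zero), "floored")
})

test_that("the cascade labels agreement and flags disagreement", {
  expect_identical(cascadePredict(0L, 0L), "pneumonia")
  expect_identical(cascadePredict(1L, 1L), "pneumonitis")
  expect_identical(cascadePredict(1L, 0L), "ambiguous")
  expect_identical(cascadePredict(0L, 1L), "ambiguous")
  a <- c(0L, 1L, 1L, 0L); b <- c(0L, 1L, 0L, 1L)
  out <- cascadePredict(a, b)
  expect_equal(mean(out == "ambiguous"), mean(a != b))
  expect_error(cascadePredict(c(0L, 1L), 0L), "length")
})

test_that("the composite model concatenates banks and degenerates cleanly", {
  set.seed(41)
  n <- 14
  y <- rep(c(0L, 1L), each = n / 2)
  Xmsi <- matrix(stats::rnorm(n * 88), n, 88,
                 dimnames = list(NULL, paste0("MSI", 1:88)))
  tbl <- generateClinicalTable(y, seed = 2)
  Xb <- prepareBenchmarkFeatures(tbl)
  comp <- fitComposite(Xmsi, Xb, y, kGrid = c(2, 5),
                       spec = boostSpec(nTrees = 10), seed = 1)
  expect_equal(comp$nFeatures, 88 + 17)
  expect_equal(nrow(comp$importance), 105)
  # zeroed-out MSI features leave only the benchmark signal: identical run
  Xzero <- Xmsi * 0
  compZ <- fitComposite(Xzero, Xb, y, kGrid = c(2, 5),
                        spec = boostSpec(nTrees = 10), seed = 1)
  benchOnly <- selectTopK(Xb, y, kGrid = c(2, 5),
                          spec = boostSpec(nTrees = 10), seed = 1)
  expect_equal(compZ$report$accuracy, benchOnly$report$accuracy)
  expect_error(fitComposite(Xmsi[1:10, ], Xb, y), "misaligned")
})

test_that("spatial-only signal favours the composite over the benchmark", {
  set.seed(51)
  n <- 20
  y <- rep(c(0L, 1L), each = n / 2)
  # imaging bank carries the class signal, clinical bank is pure noise
  Xmsi <- matrix(stats::rnorm(n * 20), n, 20,
                 dimnames = list(NULL, paste0("MSI", 1:20)))
  Xmsi[, 1] <- Xmsi[, 1] + 3 * y
  tbl <- generateClinicalTable(y, nullClinicalEffects(), seed = 5)
  Xb <- prepareBenchmarkFeatures(tbl)
  comp <- fitComposite(Xmsi, Xb, y, kGrid = c(1, 5),
                       spec = boostSpec(nTrees = 20), seed = 1)
  bench <- selectTopK(Xb, y, kGrid = c(1, 5),
                      spec = boostSpec(nTrees = 20), seed = 1)
  expect_gte(max(comp$report$accuracy), max(bench$report$accuracy))
})
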