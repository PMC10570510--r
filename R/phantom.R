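# Synthetic CT-like lung phantoms with planted habitats, and paired
# clinical-blood tables.  Tissue classes in the truth map:
#   0 outside lung, 1 parenchyma, 4 ground-glass opacity,
#   2 low-grade and 3 high-grade GGO-consolidation transition,
#   5 consolidation.
# Density (severity) order: parenchyma < GGO < transition-1 < transition-2 <
# consolidation; overlapping lesions resolve to the denser class.

# run expr with a fixed RNG seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Parameters of the synthetic lung phantom generator
#'
#' Defaults are the study conditions the generator emulates: 2.5 mm slices
#' with ~1 mm in-plane resolution, aerated parenchyma around -850 HU,
#' ground-glass opacity around -520 HU, consolidation near soft tissue
#' (+20 HU), and two GGO-consolidation transition grades in between
#' (-240 and -120 HU).  Per-class texture heterogeneity peaks in GGO.
#' The noise level (20 HU before class texture scaling) keeps the smallest
#' class-mean gap (120 HU or more) at least five times the largest class noise,
#' the separation regime under which the habitat count is recoverable.
#'
#' @param gridShape integer length-3 voxel grid (all >= 16).
#' @param spacingMm numeric length-3 voxel spacing in mm.
#' @param huParenchyma,huGGO,huConsolidation class mean HU values.
#' @param huTransition length-2 means of the two GGO-consolidation
#'   transition grades; must lie strictly between `huGGO` and
#'   `huConsolidation`.
#' @param noiseSd additive Gaussian noise standard deviation (HU).
#' @param textureScale length-5 multipliers on `noiseSd` per tissue class
#'   (parenchyma, the two transition grades, GGO, consolidation).  Emulates
#'   the elevated texture heterogeneity of ground-glass opacity relative to
#'   aerated parenchyma and the smoother appearance of consolidated
#'   airspace; a zero-noise phantom remains exactly piecewise-constant, and
#'   every multiplier stays at or below 1 so the stated noise level bounds
#'   all classes.
#' @param lesionCountRange integer pair, lesions drawn per phantom.
#' @param lesionRadiusRange numeric pair, in-plane lesion radius (voxels).
#' @param symmetry left/right placement symmetry knob in \[0,1\]: 0 = fully
#'   unilateral, 1 = mirror-symmetric.  `NULL` selects the class default
#'   (0 for pneumonia, 1 for pneumonitis).
#' @param signal `"condition"` plants class-typical lesions (pneumonia:
#'   unilateral, peripheral consolidation with GGO/transition rim;
#'   pneumonitis: bilateral mirrored GGO); `"asymmetry_only"` plants an
#'   identical lesion mix in both classes so that placement symmetry is the
#'   only class signal.
#' @param seed integer RNG seed.
#' @return A validated list of class `PhantomParams`.
#' @export
phantomParams <- function(gridShape = c(96L, 96L, 16L),
                          spacingMm = c(1, 1, 2.5),
                          huParenchyma = -850, huGGO = -520,
                          huConsolidation = 20,
                          huTransition = c(-240, -120),
                          noiseSd = 20,
                          textureScale = c(0.5, 0.3, 0.4, 1, 0.3),
                          lesionCountRange = c(3L, 4L),
                          lesionRadiusRange = c(8, 12),
                          symmetry = NULL,
                          signal = c("condition", "asymmetry_only"),
                          seed = 1L) {
  signal <- match.arg(signal)
  hu <- c(huParenchyma, huTransition, huGGO, huConsolidation)
  if (any(hu < -1024) || any(hu > 3071))
    stop("all HU class means must lie within [-1024, 3071]")
  if (length(huTransition) != 2L || huTransition[1] >= huTransition[2] ||
      any(huTransition <= huGGO) || any(huTransition >= huConsolidation))
    stop("transition means must lie strictly between huGGO and huConsolidation")
  if (length(gridShape) != 3L || any(gridShape < 16))
    stop("gridShape must be three integers, all >= 16 (grid too small to fit two lungs)")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(textureScale) != 5L || any(textureScale < 0))
    stop("textureScale must be 5 nonnegative multipliers")
  if (!is.null(symmetry) && (symmetry < 0 || symmetry > 1))
    stop("symmetry must lie in [0, 1]")
  p <- list(gridShape = as.integer(gridShape), spacingMm = as.numeric(spacingMm),
            huParenchyma = huParenchyma, huGGO = huGGO,
            huConsolidation = huConsolidation, huTransition = huTransition,
            noiseSd = noiseSd, textureScale = as.numeric(textureScale),
            lesionCountRange = as.integer(lesionCountRange),
            lesionRadiusRange = lesionRadiusRange,
            symmetry = symmetry, signal = signal, seed = as.integer(seed))
  class(p) <- "PhantomParams"
  p
}

# two mirror-symmetric ellipsoidal lung fields; left lung = smaller x
lungFieldMasks <- function(gridShape) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  cxL <- 0.29 * (nx + 1); cxR <- (nx + 1) - cxL
  cy <- 0.5 * (ny + 1); cz <- 0.5 * (nz + 1)
  a <- 0.17 * nx; b <- 0.32 * ny; cc <- 0.42 * nz
  x <- seq_len(nx); y <- seq_len(ny); z <- seq_len(nz)
  X <- array(x, dim = gridShape)
  Y <- array(rep(y, each = nx), dim = gridShape)
  Z <- array(rep(z, each = nx * ny), dim = gridShape)
  left <- ((X - cxL) / a)^2 + ((Y - cy) / b)^2 + ((Z - cz) / cc)^2 <= 1
  right <- ((X - cxR) / a)^2 + ((Y - cy) / b)^2 + ((Z - cz) / cc)^2 <= 1
  list(left = left, right = right,
       centers = list(left = c(cxL, cy, cz), right = c(cxR, cy, cz)),
       axes = c(a, b, cc))
}

# severity band thresholds on the radial Gaussian field of one lesion:
# list of (class, gmin, gmax].  Consolidation cores carry a high-grade
# transition ring; GGO and the transition grades occur as standalone
# patches.
lesionBands <- function(type) {
  switch(type,
    consolidation = list(c(5, 0.50, Inf), c(3, 0.28, 0.50)),
    ggo = list(c(4, 0.40, Inf)),
    trans2 = list(c(3, 0.40, Inf)),
    trans1 = list(c(2, 0.40, Inf)),
    stop("unknown lesion type"))
}

# density (severity) priority of truth classes 0..5: overlapping lesions
# resolve to the denser tissue
classPriority <- c(0, 1, 3, 4, 2, 5)

# paint one lesion into the truth array (severity-dominant overwrite),
# restricted to the lung mask; returns the updated truth
paintLesion <- function(truth, mask, center, r, rz, type, gridShape) {
  bands <- lesionBands(type)
  gmin <- min(vapply(bands, `[`, numeric(1), 2))
  reach <- ceiling(r * sqrt(-log(gmin))) + 1L
  reachZ <- ceiling(rz * sqrt(-log(gmin))) + 1L
  x <- max(1L, floor(center[1] - reach)):min(gridShape[1], ceiling(center[1] + reach))
  y <- max(1L, floor(center[2] - reach)):min(gridShape[2], ceiling(center[2] + reach))
  z <- max(1L, floor(center[3] - reachZ)):min(gridShape[3], ceiling(center[3] + reachZ))
  dx <- (x - center[1]) / r
  dy <- (y - center[2]) / r
  # columnar in z: full cross-section on every slice the lesion spans.
  # At 2.5 mm slices a blob's through-plane profile is effectively flat;
  # a smooth z-taper would create sub-superpixel partial-volume fringes
  # the scanner's slice averaging does not produce.
  dz <- as.numeric(abs(z - center[3]) <= rz)
  g <- outer(exp(-outer(dx^2, dy^2, `+`)), dz, `*`)
  sub <- truth[x, y, z, drop = FALSE]
  msub <- mask[x, y, z, drop = FALSE]
  for (b in bands) {
    hit <- msub & g > b[2] & g <= b[3] &
      classPriority[sub + 1L] < classPriority[b[1] + 1L]
    sub[hit] <- b[1]
  }
  truth[x, y, z] <- sub
  truth
}

# draw a lesion center inside an ellipsoidal lung at radial fraction
# within [fmin, fmax] of the semi-axes; placements keep some clearance from
# already-placed lesions so every planted class survives severity dominance
drawCenter <- function(lungCenter, axes, fmin = 0, fmax = 0.75,
                       placed = NULL, r = 0, zScale = 2.5, tries = 40L) {
  best <- NULL; bestClear <- -Inf
  for (t in seq_len(tries)) {
    repeat {
      u <- stats::runif(3, -1, 1)
      n2 <- sum(u^2)
      if (n2 <= 1 && n2 >= fmin^2) break
    }
    ctr <- lungCenter + u * axes * fmax
    if (is.null(placed) || !nrow(placed)) return(ctr)
    # anisotropic separation: z distances count at the slice-spacing ratio,
    # so lesions can stack in z without eating one another
    clear <- min(sqrt((placed$x - ctr[1])^2 + (placed$y - ctr[2])^2 +
                        (zScale * (placed$z - ctr[3]))^2) -
                   0.85 * (placed$r + r))
    if (clear >= 0) return(ctr)
    if (clear > bestClear) { bestClear <- clear; best <- ctr }
  }
  best
}

#' Generate one synthetic lung phantom
#'
#' Builds two disjoint mirror-symmetric ellipsoidal lung fields on the voxel
#' grid, plants lesions as radial-Gaussian blobs thresholded into concentric
#' severity bands (consolidation cores with a high-grade transition ring,
#' GGO cores with a low-grade transition ring, standalone transition
#' patches), and renders HU as class mean plus class-textured Gaussian
#' noise.  Pneumonia
#' (`condition = 0`) places lesions in one lung with peripheral,
#' border-touching consolidation; pneumonitis (`condition = 1`) places
#' mirrored ground-glass lesions in both lungs.
#'
#' @param params a [phantomParams()] object.
#' @param condition 0 (pneumonia) or 1 (pneumonitis).
#' @return list with components `scan` ([CTScan-class]), `mask` (logical
#'   array), `truth` (integer array of tissue classes), `leftMask`,
#'   `rightMask`, and `condition`.
#' @export
generatePhantom <- function(params = phantomParams(), condition = 0L) {
  stopifnot(inherits(params, "PhantomParams"))
  if (!condition %in% c(0L, 1L)) stop("condition must be 0 or 1")
  gs <- params$gridShape
  lungs <- lungFieldMasks(gs)
  mask <- lungs$left | lungs$right
  classHU <- c(params$huParenchyma, params$huTransition,
               params$huGGO, params$huConsolidation)

  withSeed(params$seed, {
    truth <- array(0L, dim = gs)
    truth[mask] <- 1L

    sym <- params$symmetry %||% (if (condition == 1L) 1 else 0)
    mirror <- function(center) {
      m <- center
      m[1] <- (gs[1] + 1) - m[1]
      # symmetry < 1 jitters the mirrored copy
      m + c(stats::runif(2, -1, 1) * (1 - sym) * lungs$axes[1:2] * 0.5, 0)
    }
    homeSide <- sample(c("left", "right"), 1L)
    homeCenter <- lungs$centers[[homeSide]]

    nLes <- sample(seq(params$lesionCountRange[1], params$lesionCountRange[2]), 1L)
    placed <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                         r = numeric(0))
    note <- function(ctr, r) {
      placed[nrow(placed) + 1L, ] <<- c(ctr[1], ctr[2], ctr[3], r)
    }
    if (params$signal == "asymmetry_only") {
      # identical lesion-mix draw for both classes; every drawn lesion is
      # planted twice so unilateral and bilateral phantoms carry the same
      # total burden
      types <- sample(c("consolidation", "ggo", "trans1", "trans2"), nLes,
                      replace = TRUE)
      for (i in seq_len(nLes)) {
        r <- stats::runif(1, params$lesionRadiusRange[1], params$lesionRadiusRange[2])
        rz <- max(1, min(2.5, r * params$spacingMm[1] / params$spacingMm[3]))
        zs <- params$spacingMm[3] / params$spacingMm[1]
        ctr <- drawCenter(homeCenter, lungs$axes, placed = placed, r = r,
                          zScale = zs)
        note(ctr, r)
        ctr2 <- if (condition == 1L) mirror(ctr)
                else drawCenter(homeCenter, lungs$axes, placed = placed, r = r,
                                zScale = zs)
        note(ctr2, r)
        truth <- paintLesion(truth, mask, ctr, r, rz, types[i], gs)
        truth <- paintLesion(truth, mask, ctr2, r, rz, types[i], gs)
      }
    } else if (condition == 0L) {
      # pneumonia: peripheral consolidation with GGO rim plus GGO and patchy
      # transition-grade opacities, all in the home lung (heavy unilateral
      # involvement)
      plant <- c(rep("consolidation", nLes), rep("ggo", nLes + 1L),
                 rep("trans1", nLes + 2L), rep("trans2", max(1L, nLes - 1L)))
      for (type in plant) {
        r <- stats::runif(1, params$lesionRadiusRange[1], params$lesionRadiusRange[2])
        rz <- max(1, min(2.5, r * params$spacingMm[1] / params$spacingMm[3]))
        fmin <- if (type == "consolidation") 0.45 else 0
        fmax <- if (type == "consolidation") 0.85 else 0.75
        ctr <- drawCenter(homeCenter, lungs$axes, fmin = fmin, fmax = fmax,
                          placed = placed, r = r,
                          zScale = params$spacingMm[3] / params$spacingMm[1])
        note(ctr, r)
        truth <- paintLesion(truth, mask, ctr, r, rz, type, gs)
      }
    } else {
      # pneumonitis: bilateral mirrored GGO plus patchy transition grades
      plant <- c(rep("ggo", nLes + 1L), rep("trans1", nLes + 2L),
                 rep("trans2", max(1L, nLes - 1L)))
      for (type in plant) {
        r <- stats::runif(1, params$lesionRadiusRange[1], params$lesionRadiusRange[2])
        rz <- max(1, min(2.5, r * params$spacingMm[1] / params$spacingMm[3]))
        ctr <- drawCenter(homeCenter, lungs$axes, placed = placed, r = r,
                          zScale = params$spacingMm[3] / params$spacingMm[1])
        note(ctr, r)
        m <- mirror(ctr)
        note(m, r)
        truth <- paintLesion(truth, mask, ctr, r, rz, type, gs)
        truth <- paintLesion(truth, mask, m, r, rz, type, gs)
      }
    }

    hu <- array(40, dim = gs) # soft tissue outside the lung fields
    hu[mask] <- classHU[truth[mask]]
    if (params$noiseSd > 0) {
      sdMap <- array(params$noiseSd, dim = gs)
      sdMap[mask] <- params$noiseSd * params$textureScale[truth[mask]]
      hu <- hu + stats::rnorm(length(hu)) * sdMap
    }
    hu <- pmin(pmax(hu, -1024), 3071)
    list(scan = new("CTScan", values = array(hu, dim = gs),
                    spacing = params$spacingMm),
         mask = mask, truth = truth,
         leftMask = lungs$left, rightMask = lungs$right,
         condition = as.integer(condition))
  })
}

#' Generate a synthetic cohort of lung phantoms
#'
#' Per-patient seeds are derived from the cohort seed, so the cohort is a
#' pure function of `(params, seed)`.
#'
#' @param nPneumonia,nPneumonitis patient counts per class (>= 1).
#' @param params shared [phantomParams()]; the per-patient seed is overridden.
#' @param seed cohort-level RNG seed.
#' @return Object of class `HabitatCohort`: list with `patients` (each a
#'   [generatePhantom()] result plus `id`), `labels` (0/1 vector) and the
#'   generation settings.
#' @export
generateCohort <- function(nPneumonia, nPneumonitis,
                           params = phantomParams(), seed = 1L) {
  stopifnot(nPneumonia >= 1, nPneumonitis >= 1)
  n <- nPneumonia + nPneumonitis
  labels <- c(rep(0L, nPneumonia), rep(1L, nPneumonitis))
  patientSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- patientSeeds[i]
    patients[[i]] <- c(generatePhantom(p, labels[i]),
                       list(id = sprintf("P%03d", i)))
  }
  structure(list(patients = patients, labels = labels,
                 params = params, seed = as.integer(seed)),
            class = "HabitatCohort")
}

#' @export
print.HabitatCohort <- function(x, ...) {
  cat(sprintf("HabitatCohort: %d patients (%d pneumonia, %d pneumonitis), grid %s\n",
              length(x$patients), sum(x$labels == 0), sum(x$labels == 1),
              paste(x$params$gridShape, collapse = " x ")))
  invisible(x)
}

#' Class-conditional distributions for the clinical-blood table
#'
#' Defaults follow the cohort characteristics of the diagnostic problem:
#' symptom prevalences at baseline and at time of syndrome, age means, and
#' median blood counts (e.g. baseline platelets 34 vs 29 x 10^3 cells/uL in
#' pneumonia vs pneumonitis; counts are drawn log-normally because cell
#' counts are positive and right-skewed).  `nullClinicalEffects()` removes
#' every class effect (class-1 parameters copied from class 0), which is the
#' null generator used for calibration checks.
#'
#' @return A list of class `ClinicalEffects` with elements `age`
#'   (means/sd), `sexFemale` (probability per class), `symptoms`
#'   (data.frame var/p0/p1) and `blood` (data.frame var/median0/median1/sdlog).
#' @export
clinicalEffectDefaults <- function() {
  eff <- list(
    age = list(mean = c(64, 69), sd = 10),
    sexFemale = c(0.38, 0.586),
    symptoms = data.frame(
      var = c("cough_baseline", "fever_baseline", "dyspnea_baseline",
              "cough_syndrome", "fever_syndrome", "dyspnea_syndrome"),
      p0 = c(0.227, 0.186, 0.227, 0.742, 0.794, 0.649),
      p1 = c(0.207, 0.241, 0.276, 0.655, 0.724, 0.759),
      stringsAsFactors = FALSE),
    blood = data.frame(
      var = c("wbc_baseline", "wbc_syndrome", "anc_baseline", "anc_syndrome",
              "alc_baseline", "alc_syndrome",
              "platelets_baseline", "platelets_syndrome", "blasts_baseline"),
      median0 = c(2.5, 2.4, 0.575, 0.528, 1.0, 0.6, 34, 22, 20),
      median1 = c(2.3, 1.4, 0.437, 0.42, 0.92, 0.35, 29, 14, 15),
      sdlog = c(0.6, 0.6, 0.8, 0.8, 0.8, 0.8, 0.6, 0.6, 0.7),
      stringsAsFactors = FALSE))
  class(eff) <- "ClinicalEffects"
  eff
}

#' @rdname clinicalEffectDefaults
#' @export
nullClinicalEffects <- function() {
  eff <- clinicalEffectDefaults()
  eff$age$mean[2] <- eff$age$mean[1]
  eff$sexFemale[2] <- eff$sexFemale[1]
  eff$symptoms$p1 <- eff$symptoms$p0
  eff$blood$median1 <- eff$blood$median0
  eff
}

#' Generate a class-conditional clinical-blood covariate table
#'
#' One row per patient: age, sex, three symptoms at two timepoints, and nine
#' blood measurements (WBC, neutrophils, lymphocytes and platelets at
#' baseline and at time of syndrome, plus baseline bone-marrow blasts).
#'
#' @param labels 0/1 condition labels (or a `HabitatCohort`).
#' @param effects a [clinicalEffectDefaults()]-style configuration.
#' @param seed RNG seed.
#' @return data.frame with 17 columns; zero rows (with the full header) when
#'   `labels` is empty.
#' @export
generateClinicalTable <- function(labels, effects = clinicalEffectDefaults(),
                                  seed = 1L) {
  if (inherits(labels, "HabitatCohort")) labels <- labels$labels
  stopifnot(inherits(effects, "ClinicalEffects"))
  if (any(effects$blood$median0 <= 0) || any(effects$blood$median1 <= 0) ||
      any(effects$blood$sdlog < 0) || effects$age$sd < 0)
    stop("negative or zero scale parameters rejected")
  n <- length(labels)
  cls <- as.integer(labels) + 1L # 1 = pneumonia, 2 = pneumonitis
  withSeed(seed, {
    tbl <- data.frame(
      age = pmax(18, stats::rnorm(n, effects$age$mean[cls], effects$age$sd)),
      sex = as.integer(stats::runif(n) < effects$sexFemale[cls]))
    for (i in seq_len(nrow(effects$symptoms)))
      tbl[[effects$symptoms$var[i]]] <-
        as.integer(stats::runif(n) <
                   c(effects$symptoms$p0[i], effects$symptoms$p1[i])[cls])
    for (i in seq_len(nrow(effects$blood))) {
      med <- c(effects$blood$median0[i], effects$blood$median1[i])[cls]
      tbl[[effects$blood$var[i]]] <-
        stats::rlnorm(n, meanlog = log(med), sdlog = effects$blood$sdlog[i])
    }
    if (n == 0) { # keep the full header on an empty request
      cols <- c("age", "sex", effects$symptoms$var, effects$blood$var)
      tbl <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    }
    tbl
  })
}
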