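# End-to-end orchestration: simulate -> preprocess -> habitat -> MSI ->
# models -> Bayes report, with per-stage caching keyed by a config hash and
# a reproducibility manifest.

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end run, with the package defaults.
#' The resolved configuration (and its hash) is written beside the outputs
#' of every stage.
#'
#' @param nPneumonia,nPneumonitis synthetic cohort composition.
#' @param phantom a [phantomParams()] object.
#' @param entropyRadius,entropyBins local entropy filter parameters; the
#'   pipeline default (radius 2, 64 bins) is matched to the phantom scale
#'   (96 px lung cross-section vs ~512 px clinical CT); for clinical-
#'   resolution volumes use the [localEntropy()] defaults (radius 4,
#'   32 bins).
#' @param nSuperpixels,compactness SLIC parameters (see [oversegment()]).
#' @param kRange,gapRefs,maxRows habitat clustering parameters.
#' @param kGrid candidate top-feature counts for model selection.
#' @param classifier a [boostSpec()].
#' @param smoteK SMOTE neighbour count.
#' @param seed master seed for the run.
#' @return list of class `RunConfig`.
#' @export
pipelineConfig <- function(nPneumonia = 8L, nPneumonitis = 4L,
                           phantom = phantomParams(),
                           entropyRadius = 2, entropyBins = 64L,
                           nSuperpixels = NULL, compactness = 0.1,
                           kRange = 2:8, gapRefs = 10L, maxRows = 20000L,
                           kGrid = c(2L, 5L, 10L),
                           classifier = boostSpec(), smoteK = 5L,
                           seed = 1L) {
  structure(list(nPneumonia = as.integer(nPneumonia),
                 nPneumonitis = as.integer(nPneumonitis),
                 phantom = phantom, entropyRadius = entropyRadius,
                 entropyBins = as.integer(entropyBins),
                 nSuperpixels = nSuperpixels, compactness = compactness,
                 kRange = as.integer(kRange), gapRefs = as.integer(gapRefs),
                 maxRows = as.integer(maxRows), kGrid = as.integer(kGrid),
                 classifier = classifier, smoteK = as.integer(smoteK),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

# strip S3 classes recursively so any config nests serialize plainly
unclassDeep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclassDeep) else x
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclassDeep(config), tmp, digits = NA,
                       auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

stageFresh <- function(dir, hash) {
  mf <- file.path(dir, "stage.json")
  if (!file.exists(mf)) return(FALSE)
  j <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
  identical(j$configHash, hash)
}

stampStage <- function(dir, stage, hash, files) {
  jsonlite::write_json(list(stage = stage, configHash = hash,
                            files = files,
                            checksums = as.list(tools::md5sum(files))),
                       file.path(dir, "stage.json"), auto_unbox = TRUE)
}

#' Run the full habitat-imaging pipeline
#'
#' Executes, in order: cohort simulation, composite-image preprocessing,
#' habitat model fitting and assignment, MSI / radiomics / clinical feature
#' extraction, model training and LOOCV evaluation (habitat, benchmark,
#' composite, radiomics, cascade), and the Bayesian diagnostic report.
#' Stage outputs are written to `outDir/<stage>/`; a stage whose outputs
#' already exist for the same configuration hash is not recomputed, so a
#' deleted stage is resumed from its cached upstream artefacts.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @param quiet suppress stage progress messages.
#' @return (invisibly) list with the key results: habitat model, per-model
#'   LOOCV reports, cascade table, Bayes reports, and `outDir`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  hash <- configHash(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(c(unclassDeep(config),
                         list(configHash = hash,
                              package = as.character(utils::packageVersion("HabitatCT")))),
                       file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  n <- config$nPneumonia + config$nPneumonitis
  ids <- sprintf("P%03d", seq_len(n))
  labels <- c(rep(0L, config$nPneumonia), rep(1L, config$nPneumonitis))

  ## -- simulate ------------------------------------------------------------
  simDir <- file.path(outDir, "simulate")
  dir.create(simDir, showWarnings = FALSE)
  scanFile <- function(id) file.path(simDir, paste0("ct_", id, ".nii.gz"))
  maskFile <- function(id) file.path(simDir, paste0("mask_", id, ".nii.gz"))
  truthFile <- function(id) file.path(simDir, paste0("truth_", id, ".nii.gz"))
  clinFile <- file.path(simDir, "clinical.csv")
  if (!stageFresh(simDir, hash)) {
    say("[simulate] generating %d phantoms", n)
    cohort <- generateCohort(config$nPneumonia, config$nPneumonitis,
                             params = config$phantom, seed = config$seed)
    for (i in seq_len(n)) {
      p <- cohort$patients[[i]]
      writeVolumeNifti(p$scan, scanFile(ids[i]))
      writeVolumeNifti(p$mask, maskFile(ids[i]), spacing = config$phantom$spacingMm)
      writeVolumeNifti(p$truth, truthFile(ids[i]), spacing = config$phantom$spacingMm)
    }
    clin <- generateClinicalTable(labels, seed = config$seed + 1L)
    utils::write.csv(cbind(patient = ids, label = labels, clin), clinFile,
                     row.names = FALSE)
    stampStage(simDir, "simulate", hash,
               c(vapply(ids, scanFile, ""), clinFile))
  } else say("[simulate] cached")

  ## -- preprocess ----------------------------------------------------------
  preDir <- file.path(outDir, "preprocess")
  dir.create(preDir, showWarnings = FALSE)
  compFile <- function(id) file.path(preDir, paste0("composite_", id, ".nii.gz"))
  sideFile <- function(id, s) file.path(preDir, paste0(s, "_", id, ".nii.gz"))
  if (!stageFresh(preDir, hash)) {
    say("[preprocess] building 4-channel composites")
    for (id in ids) {
      vol <- readVolumeNifti(scanFile(id))
      scan <- new("CTScan", values = pmin(pmax(vol, -1024), 3071),
                  spacing = as.numeric(attr(vol, "spacing")[1:3]))
      mask <- readVolumeNifti(maskFile(id)) > 0
      mask <- smoothMask(mask, radius = 1)
      comp <- makeComposite(scan, mask, entropyRadius = config$entropyRadius,
                            entropyBins = config$entropyBins)
      sides <- splitLungs(mask)
      writeCompositeNifti(comp, compFile(id))
      writeVolumeNifti(sides$left, sideFile(id, "left"), spacing = scan@spacing)
      writeVolumeNifti(sides$right, sideFile(id, "right"), spacing = scan@spacing)
    }
    stampStage(preDir, "preprocess", hash, vapply(ids, compFile, ""))
  } else say("[preprocess] cached")

  ## -- habitat -------------------------------------------------------------
  habDir <- file.path(outDir, "habitat")
  dir.create(habDir, showWarnings = FALSE)
  spFile <- function(id) file.path(habDir, paste0("superpixels_", id, ".nii.gz"))
  habFile <- function(id) file.path(habDir, paste0("habitats_", id, ".nii.gz"))
  modelFile <- file.path(habDir, "habitat_model.json")
  if (!stageFresh(habDir, hash)) {
    say("[habitat] SLIC oversegmentation + population clustering")
    spmaps <- list(); tables <- list()
    for (id in ids) {
      comp <- readCompositeNifti(compFile(id), entropyBins = config$entropyBins)
      mask <- (readVolumeNifti(sideFile(id, "left")) +
                 readVolumeNifti(sideFile(id, "right"))) > 0
      sp <- oversegment(comp, mask, nSuperpixels = config$nSuperpixels,
                        compactness = config$compactness)
      spmaps[[id]] <- sp
      tables[[id]] <- superpixelFeatures(comp, sp)
      writeVolumeNifti(sp, spFile(id), spacing = comp@spacing)
    }
    model <- fitPopulationClusters(tables, kRange = config$kRange,
                                   gapRefs = config$gapRefs,
                                   seed = config$seed,
                                   maxRows = config$maxRows)
    saveHabitatModel(model, modelFile)
    for (id in ids) {
      hm <- assignHabitats(spmaps[[id]], tables[[id]], model)
      writeVolumeNifti(hm, habFile(id), spacing = config$phantom$spacingMm)
    }
    stampStage(habDir, "habitat", hash,
               c(modelFile, vapply(ids, habFile, "")))
  } else say("[habitat] cached")
  model <- readHabitatModel(modelFile)

  ## -- msi -----------------------------------------------------------------
  msiDir <- file.path(outDir, "msi")
  dir.create(msiDir, showWarnings = FALSE)
  msiFile <- file.path(msiDir, "msi_features.csv")
  radFile <- file.path(msiDir, "radiomics_features.csv")
  dictFile <- file.path(msiDir, "feature_dictionary.json")
  if (!stageFresh(msiDir, hash)) {
    say("[msi] extracting the %d-feature MSI bank", 2 * (4 + 4 * model@K +
                                                           2 * choose(model@K, 2)))
    msiRows <- list(); radRows <- list()
    for (id in ids) {
      hm <- readVolumeNifti(habFile(id))
      left <- readVolumeNifti(sideFile(id, "left")) > 0
      right <- readVolumeNifti(sideFile(id, "right")) > 0
      msiRows[[id]] <- fullMSI(array(as.integer(hm), dim = dim(hm)),
                               left, right, K = model@K)
      comp <- readCompositeNifti(compFile(id), entropyBins = config$entropyBins)
      radRows[[id]] <- wholeLungRadiomics(comp, left | right)
    }
    msiMat <- do.call(rbind, msiRows)
    utils::write.csv(data.frame(patient = ids, label = labels, msiMat,
                                check.names = FALSE), msiFile, row.names = FALSE)
    utils::write.csv(data.frame(patient = ids, label = labels,
                                do.call(rbind, radRows), check.names = FALSE),
                     radFile, row.names = FALSE)
    jsonlite::write_json(msiDictionary(model@K), dictFile, digits = NA,
                         pretty = TRUE)
    stampStage(msiDir, "msi", hash, c(msiFile, radFile, dictFile))
  } else say("[msi] cached")

  ## -- models --------------------------------------------------------------
  modDir <- file.path(outDir, "models")
  dir.create(modDir, showWarnings = FALSE)
  reportFile <- file.path(modDir, "model_reports.json")
  predFile <- file.path(modDir, "predictions.csv")
  if (!stageFresh(modDir, hash)) {
    say("[models] SMOTE-nested LOOCV for 4 models")
    msiTab <- utils::read.csv(msiFile, check.names = FALSE)
    radTab <- utils::read.csv(radFile, check.names = FALSE)
    clin <- utils::read.csv(clinFile, check.names = FALSE)
    y <- msiTab$label
    Xmsi <- as.matrix(msiTab[, -(1:2)])
    Xrad <- as.matrix(radTab[, -(1:2)])
    Xbench <- prepareBenchmarkFeatures(clin)
    run <- function(X) selectTopK(X, y, kGrid = pmin(config$kGrid, ncol(X)),
                                  spec = config$classifier, seed = config$seed)
    habRun <- run(Xmsi)
    benchRun <- run(Xbench)
    radRun <- run(Xrad)
    compRun <- fitComposite(Xmsi, Xbench, y, kGrid = config$kGrid,
                            spec = config$classifier, seed = config$seed)
    cascade <- cascadePredict(benchRun$bestRun$predictions$predicted,
                              habRun$bestRun$predictions$predicted)
    rep1 <- function(r) list(bestK = r$bestK, grid = r$report,
                             confusion = as.list(r$bestRun$confusion),
                             metrics = as.list(r$bestRun$metrics))
    jsonlite::write_json(list(habitat = rep1(habRun),
                              benchmark = rep1(benchRun),
                              radiomics = rep1(radRun),
                              composite = rep1(compRun),
                              cascadeAmbiguousRate = mean(cascade == "ambiguous")),
                         reportFile, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    utils::write.csv(data.frame(patient = ids, truth = y,
                                habitat = habRun$bestRun$predictions$predicted,
                                benchmark = benchRun$bestRun$predictions$predicted,
                                radiomics = radRun$bestRun$predictions$predicted,
                                composite = compRun$bestRun$predictions$predicted,
                                cascade = cascade),
                     predFile, row.names = FALSE)
    stampStage(modDir, "models", hash, c(reportFile, predFile))
  } else say("[models] cached")

  ## -- eval ----------------------------------------------------------------
  evalDir <- file.path(outDir, "eval")
  dir.create(evalDir, showWarnings = FALSE)
  bayesFile <- file.path(evalDir, "bayes_report.json")
  if (!stageFresh(evalDir, hash)) {
    say("[eval] Bayesian pre-/post-test probabilities")
    reports <- jsonlite::read_json(reportFile, simplifyVector = TRUE)
    prev <- preTestProbability(labels)
    mkBayes <- function(r) {
      sens <- r$metrics$sensitivity; spc <- r$metrics$specificity
      post <- tryCatch(postTestPositive(prev, sens, spc),
                       error = function(e) NA_real_)
      list(preTest = prev, sensitivity = sens, specificity = spc,
           accuracy = r$metrics$accuracy, postTestPositive = post,
           percent = list(preTest = round(100 * prev),
                          postTest = if (is.na(post)) NA else round(100 * post)))
    }
    jsonlite::write_json(lapply(reports[c("habitat", "benchmark",
                                          "radiomics", "composite")], mkBayes),
                         bayesFile, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    stampStage(evalDir, "eval", hash, bayesFile)
  } else say("[eval] cached")

  invisible(list(outDir = outDir, configHash = hash, model = model,
                 reports = jsonlite::read_json(reportFile, simplifyVector = TRUE),
                 bayes = jsonlite::read_json(bayesFile, simplifyVector = TRUE)))
}
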