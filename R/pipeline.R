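# End-to-end orchestration: simulate -> dataset -> train -> infer -> filter
# -> measure -> fuse -> density, with a JSON manifest, per-stage derived
# seeds, stage toggles and hash-based idempotence.

pipelineStages <- c("simulate", "dataset", "train", "infer", "filter",
                    "measure", "fuse", "density")

#' Configuration for the end-to-end pipeline
#'
#' One top-level seed deterministically derives per-stage seeds, so stages
#' can be rerun independently yet reproducibly.
#'
#' @param outDir output directory (created if missing).
#' @param seed top-level integer seed.
#' @param synthetic a [SyntheticConfig-class] for the simulated tiles.
#' @param nTrainCases,tilesPerCase simulated training cases and tiles each.
#' @param testTiles tiles in the single held-out test case.
#' @param model a [bcnnConfig()] list.
#' @param epochs training epochs (overrides the model config).
#' @param augment,variants training-set augmentation settings.
#' @param stride,threshold inference lattice stride and decision threshold.
#' @param gaussianSigma,enhance discriminability preprocessing settings.
#' @param wavelet fusion wavelet family.
#' @param stages subset of stages to run.
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           synthetic = syntheticConfig(seed = seed),
                           nTrainCases = 1L, tilesPerCase = 2L,
                           testTiles = 2L, model = bcnnConfig(seed = seed),
                           epochs = model$epochs, augment = FALSE,
                           variants = 2L, stride = 10L, threshold = 0.5,
                           gaussianSigma = 1, enhance = TRUE,
                           wavelet = "haar", stages = pipelineStages) {
  stopifnot(all(stages %in% pipelineStages), stride >= 1L)
  structure(list(outDir = outDir, seed = as.integer(seed),
                 synthetic = synthetic, nTrainCases = as.integer(nTrainCases),
                 tilesPerCase = as.integer(tilesPerCase),
                 testTiles = as.integer(testTiles), model = model,
                 epochs = as.integer(epochs), augment = augment,
                 variants = as.integer(variants), stride = as.integer(stride),
                 threshold = threshold, gaussianSigma = gaussianSigma,
                 enhance = enhance, wavelet = wavelet, stages = stages),
            class = "pipelineConfig")
}

configEcho <- function(config) {
  syn <- config$synthetic
  list(seed = config$seed, nTrainCases = config$nTrainCases,
       tilesPerCase = config$tilesPerCase, testTiles = config$testTiles,
       epochs = config$epochs, augment = config$augment,
       variants = config$variants, stride = config$stride,
       threshold = config$threshold, gaussianSigma = config$gaussianSigma,
       enhance = config$enhance, wavelet = config$wavelet,
       model = unclass(config$model),
       synthetic = list(tileWidth = syn@tileWidth, tileHeight = syn@tileHeight,
                        nCells = syn@nCells,
                        cellRadiusRange = syn@cellRadiusRange,
                        haloRingWidth = syn@haloRingWidth,
                        stainIntensityRange = syn@stainIntensityRange,
                        nStrata = length(syn@intensityStrata),
                        backgroundNoiseSd = syn@backgroundNoiseSd,
                        nucleiDensity = syn@nucleiDensity,
                        nNegatives = syn@nNegatives,
                        micronsPerPixel = syn@micronsPerPixel,
                        seed = syn@seed))
}

stageInputHash <- function(config, inputFiles) {
  cfg <- jsonlite::toJSON(configEcho(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(c(as.character(cfg),
               vapply(inputFiles[file.exists(inputFiles)], md5OfFile, "")),
             tmp)
  md5OfFile(tmp)
}

readManifest <- function(outDir) {
  p <- file.path(outDir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE)
  else list(stages = list())
}

writeManifest <- function(outDir, manifest) {
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

stageUpToDate <- function(manifest, stage, hash) {
  st <- manifest$stages[[stage]]
  !is.null(st) && identical(st$input_hash, hash) &&
    all(file.exists(unlist(st$files)))
}

recordStage <- function(manifest, stage, hash, files) {
  manifest$stages[[stage]] <- list(
    input_hash = hash, files = as.list(files),
    md5 = as.list(stats::setNames(vapply(files, md5OfFile, ""), NULL)))
  manifest
}

caseCanvasDim <- function(tiles) {
  w <- max(vapply(tiles, function(t) t@origin[1] + dim(t@array)[2], 1))
  h <- max(vapply(tiles, function(t) t@origin[2] + dim(t@array)[1], 1))
  c(h, w)
}

# Paste per-tile rendered heatmaps onto one case canvas.
caseCellHeatmap <- function(grids, threshold, palette, canvasDim) {
  img <- array(0, dim = c(canvasDim, 3))
  for (ch in 1:3) img[, , ch] <- palette$negative[ch]
  for (g in grids) {
    r <- renderHeatmap(g, threshold, palette)
    oy <- g@tileOrigin[2] + g@originOffset - g@stride / 2
    ox <- g@tileOrigin[1] + g@originOffset - g@stride / 2
    ys <- (oy + 1):(oy + dim(r)[1])
    xs <- (ox + 1):(ox + dim(r)[2])
    img[ys, xs, ] <- r
  }
  img
}

#' Run the end-to-end workflow
#'
#' Executes the enabled stages in order, logging per-stage counts (marks
#' read, pairs built, detections, discarded by the acceptance threshold,
#' cells measured) and recording every artefact in
#' `<outDir>/manifest.json` together with input hashes and the fully
#' resolved configuration. Re-running a completed stage with unchanged
#' inputs is a no-op; a failing stage aborts with its name, keeping partial
#' artefacts.
#'
#' @param config a [pipelineConfig()] list.
#' @param verbose print per-stage progress.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipelineConfig"))
    stop("config must come from pipelineConfig()")
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- readManifest(out)
  manifest$config <- configEcho(config)
  say <- function(...) if (verbose) message(sprintf(...))

  runStage <- function(stage, inputs, body) {
    if (!stage %in% config$stages) return(invisible(NULL))
    hash <- stageInputHash(config, inputs)
    if (stageUpToDate(manifest, stage, hash)) {
      say("[%s] up to date, skipped", stage)
      return(invisible(NULL))
    }
    files <- tryCatch(body(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest <<- recordStage(manifest, stage, hash, files)
    writeManifest(out, manifest)
    invisible(NULL)
  }

  allCaseIds <- c(sprintf("train%d", seq_len(config$nTrainCases)), "test")
  tilePaths <- function() list.files(out, "^tile_.*\\.png$", full.names = TRUE)
  marksPath <- file.path(out, "marks.csv")
  fmapPath <- file.path(out, "feature_map.png")
  cpPath <- file.path(out, "control_points.csv")

  runStage("simulate", character(0), function() {
    files <- character(0)
    marks <- NULL
    syn <- config$synthetic
    for (ci in seq_along(allCaseIds)) {
      cid <- allCaseIds[ci]
      nT <- if (cid == "test") config$testTiles else config$tilesPerCase
      synCase <- syn
      synCase@seed <- deriveSeed(config$seed, 100L + ci)
      cs <- generateCase(synCase, nTiles = nT, caseId = cid)
      for (t in cs$tiles) {
        p <- file.path(out, sprintf("tile_%s_%s.png", t@caseId, t@tileId))
        writeTile(t, p)
        files <- c(files, p, paste0(p, ".json"))
      }
      marks <- rbind(marks, cs$marks)
      if (cid == "test") {
        writeFeatureMap(cs$featureMap, fmapPath)
        utils::write.csv(cs$controlPoints, cpPath, row.names = FALSE)
        files <- c(files, fmapPath, paste0(fmapPath, ".json"), cpPath)
      }
    }
    writeMarks(marks, marksPath)
    say("[simulate] %d tiles, %d marks (%d positive)",
        length(tilePaths()), nrow(marks), sum(marks$label == "positive"))
    c(files, marksPath)
  })

  loadTiles <- function(cases = NULL) {
    tl <- lapply(tilePaths(), readTile)
    if (!is.null(cases))
      tl <- Filter(function(t) t@caseId %in% cases, tl)
    tl
  }

  pairsPath <- file.path(out, "train_pairs.rds")
  runStage("dataset", c(tilePaths(), marksPath), function() {
    marks <- readMarks(marksPath)
    sp <- splitMarksByCase(marks, setdiff(allCaseIds, "test"), "test")
    pairs <- buildTrainingSet(loadTiles(setdiff(allCaseIds, "test")),
                              sp$train, augment = config$augment,
                              variants = config$variants,
                              seed = deriveSeed(config$seed, 2L))
    saveRDS(pairs, pairsPath)
    mf <- file.path(out, "dataset_manifest.json")
    jsonlite::write_json(list(n_pairs = length(pairs),
                              n_positive = sum(pairs@labels == "positive"),
                              cases = unique(pairs@caseIds),
                              augment = config$augment),
                         mf, auto_unbox = TRUE, digits = NA)
    say("[dataset] %d pairs built", length(pairs))
    c(pairsPath, mf)
  })

  modelPath <- file.path(out, "model.rds")
  runStage("train", pairsPath, function() {
    pairs <- readRDS(pairsPath)
    cfg <- config$model
    cfg$seed <- deriveSeed(config$seed, 3L)
    model <- buildModel(cfg)
    model <- trainModel(model, pairs, epochs = config$epochs,
                        verbose = verbose)
    saveModel(model, modelPath)
    hp <- file.path(out, "history.csv")
    utils::write.csv(model@history, hp, row.names = FALSE)
    say("[train] final loss %.4f after %d epochs",
        utils::tail(model@history$loss, 1), config$epochs)
    c(modelPath, sub("\\.rds$", ".json", modelPath), hp)
  })

  detPath <- file.path(out, "detections.csv")
  runStage("infer", c(modelPath, tilePaths()), function() {
    model <- loadModel(modelPath)
    tiles <- loadTiles("test")
    files <- character(0)
    det <- NULL
    for (t in tiles) {
      g <- slidingInference(model, t, stride = config$stride)
      gp <- file.path(out, sprintf("grid_%s_%s.rds", t@caseId, t@tileId))
      saveRDS(g, gp)
      jsonlite::write_json(list(case_id = g@caseId, tile_id = g@tileId,
                                stride = g@stride,
                                origin_offset = g@originOffset,
                                tile_origin = g@tileOrigin,
                                microns_per_pixel = g@micronsPerPixel),
                           paste0(gp, ".json"), auto_unbox = TRUE, digits = NA)
      hp <- file.path(out, sprintf("heatmap_%s_%s.png", t@caseId, t@tileId))
      writeImagePNG(renderHeatmap(g, config$threshold), hp)
      det <- rbind(det, mergeDetections(g, config$threshold))
      files <- c(files, gp, paste0(gp, ".json"), hp)
    }
    utils::write.csv(det, detPath, row.names = FALSE)
    say("[infer] %d detections on %d test tiles", nrow(det), length(tiles))
    c(files, detPath)
  })

  detFiltPath <- file.path(out, "detections_filtered.csv")
  runStage("filter", c(detPath, tilePaths()), function() {
    det <- utils::read.csv(detPath, stringsAsFactors = FALSE)
    fl <- filterDetections(loadTiles("test"), det,
                           gaussianSigma = config$gaussianSigma,
                           enhance = config$enhance)
    utils::write.csv(fl$detections, detFiltPath, row.names = FALSE)
    files <- detFiltPath
    for (cs in names(fl$summaries)) {
      sp <- file.path(out, sprintf("threshold_summary_%s.json", cs))
      writeThresholdSummary(fl$summaries[[cs]], sp)
      files <- c(files, sp)
    }
    say("[filter] %d detections, %d discarded by T",
        nrow(fl$detections), sum(!fl$detections$discriminable))
    files
  })

  morphPath <- file.path(out, "morphometry.csv")
  runStage("measure", c(detFiltPath, tilePaths()), function() {
    det <- utils::read.csv(detFiltPath, stringsAsFactors = FALSE)
    tiles <- loadTiles("test")
    cells <- measureDetections(tiles, det,
                               gaussianSigma = config$gaussianSigma,
                               enhance = config$enhance)
    utils::write.csv(cells, morphPath, row.names = FALSE)
    pxArea <- sum(vapply(tiles, function(t) prod(dim(t@array)[1:2]), 1))
    tissueMm2 <- pxArea * (mpp(tiles[[1]]) / 1000)^2
    cs <- caseSummary(cells, tissueMm2)
    sp <- file.path(out, "case_summary.json")
    jsonlite::write_json(as.list(cs), sp, auto_unbox = TRUE, digits = NA)
    say("[measure] %d cells measured", nrow(cells))
    c(morphPath, sp)
  })

  fusedPath <- file.path(out, "fused.png")
  runStage("fuse", c(fmapPath, cpPath, detPath), function() {
    fmap <- readFeatureMap(fmapPath)
    tiles <- loadTiles("test")
    canvas <- caseCanvasDim(tiles)
    grids <- lapply(tiles, function(t)
      readRDS(file.path(out, sprintf("grid_%s_%s.rds", t@caseId, t@tileId))))
    cellMap <- caseCellHeatmap(grids, config$threshold, heatmapPalette(),
                               canvas)
    heMap <- renderFeatureMap(fmap, caseWidth = canvas[2],
                              caseHeight = canvas[1])
    cp <- utils::read.csv(cpPath)
    fz <- fuseCase(heMap, cellMap, cp, wavelet = config$wavelet)
    writeImagePNG(fz$fused, fusedPath)
    cellPath <- file.path(out, "cell_heatmap.png")
    writeImagePNG(cellMap, cellPath)
    hePath <- file.path(out, "he_heatmap.png")
    writeImagePNG(heMap, hePath)
    tfPath <- file.path(out, "transform.json")
    jsonlite::write_json(list(matrix = as.data.frame(unclass(fz$transform)),
                              rmse = attr(fz$transform, "rmse")),
                         tfPath, digits = NA, auto_unbox = TRUE)
    say("[fuse] fused %d x %d canvas", canvas[1], canvas[2])
    c(fusedPath, cellPath, hePath, tfPath)
  })

  densPath <- file.path(out, "density.csv")
  runStage("density", c(detFiltPath, fmapPath, cpPath), function() {
    det <- utils::read.csv(detFiltPath, stringsAsFactors = FALSE)
    det <- det[det$discriminable, , drop = FALSE]
    fmap <- readFeatureMap(fmapPath)
    cp <- utils::read.csv(cpPath)
    M <- estimateTransform(cbind(cp$moving_x, cp$moving_y),
                           cbind(cp$fixed_x, cp$fixed_y))
    rep <- densityReport(assignClasses(det, fmap, M), fmap)
    utils::write.csv(rep, densPath, row.names = FALSE)
    say("[density] %d cells over %d feature classes", sum(rep$n_cells),
        nrow(rep))
    densPath
  })

  writeManifest(out, manifest)
  invisible(manifest)
}
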