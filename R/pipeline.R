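## End-to-end orchestration: simulate (or load) -> featurize -> reduce ->
## cluster -> geometry -> report, reproducible under a single seed.

#' PipelineConfig: one self-contained analysis configuration
#'
#' Defaults follow the reference workflow settings: picking stride 25,
#' 80% variance-explained threshold, K scanned over 2..8, 8 Angstrom
#' contact threshold.
#'
#' @slot ensembleSpec [EnsembleSpec-class] for synthetic input, or NULL.
#' @slot trajectoryFiles multi-model PDB paths (used when `ensembleSpec`
#'   is NULL); conditions are taken from `conditions`.
#' @slot conditions condition label per trajectory file.
#' @slot domainMap [DomainMap-class], or NULL to use the ensemble spec's
#'   map (synthetic input) / the seven-domain ORF2p map (file input).
#' @slot stride CA picking stride.
#' @slot varianceThreshold PCA variance-explained threshold.
#' @slot kRange inclusive K scan range.
#' @slot chosenK fixed cluster count, or NA to take the elbow K.
#' @slot distanceThreshold contact threshold, Angstrom (8; 10 as the
#'   looser alternative).
#' @slot contactDomains the two domains of the contact criterion.
#' @slot nInit EM restarts.
#' @slot seed master seed.
#' @slot outputDir output directory, or NA to skip writing.
#' @export
setClass("PipelineConfig",
  representation(ensembleSpec = "ANY", trajectoryFiles = "character",
                 conditions = "character", domainMap = "ANY",
                 stride = "integer", varianceThreshold = "numeric",
                 kRange = "integer", chosenK = "integer",
                 distanceThreshold = "numeric", contactDomains = "character",
                 nInit = "integer", seed = "integer",
                 outputDir = "character"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (is.null(object@ensembleSpec) && !length(object@trajectoryFiles))
    msg <- c(msg, "either an ensemble spec or trajectory files required")
  if (object@stride < 1L) msg <- c(msg, "stride must be >= 1")
  if (object@varianceThreshold <= 0 || object@varianceThreshold > 1)
    msg <- c(msg, "variance threshold must lie in (0, 1]")
  if (length(object@kRange) != 2L || object@kRange[1] > object@kRange[2])
    msg <- c(msg, "kRange must be c(kMin, kMax) with kMin <= kMax")
  if (object@distanceThreshold <= 0)
    msg <- c(msg, "distance threshold must be > 0")
  if (length(object@contactDomains) != 2L)
    msg <- c(msg, "contactDomains must name two domains")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param ensembleSpec,trajectoryFiles,conditions,domainMap,chosenK,outputDir
#'   see [PipelineConfig-class] slots.
#' @param stride CA picking stride (default 25).
#' @param varianceThreshold PCA threshold (default 0.80).
#' @param kRange K scan range (default c(2, 8)).
#' @param distanceThreshold contact threshold in Angstrom (default 8).
#' @param contactDomains contact criterion domains
#'   (default c("tower", "CTD")).
#' @param nInit EM restarts (default 10).
#' @param seed master seed (default 1).
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(ensembleSpec = NULL,
                           trajectoryFiles = character(),
                           conditions = character(), domainMap = NULL,
                           stride = 25L, varianceThreshold = 0.80,
                           kRange = c(2L, 8L), chosenK = NA_integer_,
                           distanceThreshold = 8,
                           contactDomains = c("tower", "CTD"),
                           nInit = 10L, seed = 1L,
                           outputDir = NA_character_) {
  new("PipelineConfig", ensembleSpec = ensembleSpec,
      trajectoryFiles = trajectoryFiles, conditions = conditions,
      domainMap = domainMap, stride = as.integer(stride),
      varianceThreshold = varianceThreshold, kRange = as.integer(kRange),
      chosenK = as.integer(chosenK),
      distanceThreshold = distanceThreshold,
      contactDomains = contactDomains, nInit = as.integer(nInit),
      seed = as.integer(seed), outputDir = outputDir)
}

#' Read / write a pipeline configuration as YAML
#'
#' Synthetic input is referenced by preset name (`open-like`,
#' `closed-like`, `three-mode`, `contact-switch`) plus frames/runs; file
#' input by trajectory paths and condition labels. The scalar settings
#' round-trip losslessly.
#'
#' @param path YAML file.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(y$ensemble)) {
    maker <- switch(y$ensemble$preset,
                    "open-like" = openLikeSpec,
                    "closed-like" = closedLikeSpec,
                    "three-mode" = threeModeSpec,
                    "contact-switch" = contactSwitchSpec,
                    stop("unknown ensemble preset: ", y$ensemble$preset))
    args <- list(seed = as.integer(y$seed %||% 1L))
    if (!is.null(y$ensemble$framesPerRun))
      args$framesPerRun <- as.integer(y$ensemble$framesPerRun)
    if (!is.null(y$ensemble$runsPerCondition))
      args$runsPerCondition <- unlist(y$ensemble$runsPerCondition)
    spec <- do.call(maker, args)
  }
  pipelineConfig(
    ensembleSpec = spec,
    trajectoryFiles = as.character(y$trajectories %||% character()),
    conditions = as.character(y$conditions %||% character()),
    stride = y$stride %||% 25L,
    varianceThreshold = y$varianceThreshold %||% 0.80,
    kRange = unlist(y$kRange %||% c(2L, 8L)),
    chosenK = y$chosenK %||% NA_integer_,
    distanceThreshold = y$distanceThreshold %||% 8,
    contactDomains = as.character(y$contactDomains %||% c("tower", "CTD")),
    nInit = y$nInit %||% 10L,
    seed = y$seed %||% 1L,
    outputDir = y$outputDir %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full conformational-landscape analysis
#'
#' Stages: simulate (or load) trajectories; strided CA distance
#' featurization; PCA with smallest-m variance-threshold selection; K scan
#' with elbow/silhouette diagnostics; mixture fit at the chosen K with
#' weights, per-condition populations and representative frames; rigid-core
#' alignment with per-domain RMSD against the initial and the iterated
#' average reference; minimum interdomain distance distribution and
#' open/closed-contact classification. Identical config and seed give
#' identical outputs.
#'
#' @param config a [PipelineConfig-class].
#' @return invisibly, a list with elements `trajectories`, `features`,
#'   `pca`, `m`, `space`, `selection`, `chosenK`, `clusters`
#'   ([ClusterReport-class]), `rmsd` (data.frame), `contactDistance`
#'   ([DistanceSeries-class]), `contactFraction`, `states` (factor),
#'   `groundTruth` (planted labels, synthetic input only) and `outputDir`.
#' @export
runPipeline <- function(config) {
  methods::validObject(config)
  synthetic <- !is.null(config@ensembleSpec)
  ens <- NULL
  trajs <- stage("simulate/load", {
    if (synthetic) {
      ens <- generateTrajectory(config@ensembleSpec)
      trajectories(ens)
    } else {
      if (length(config@conditions) != length(config@trajectoryFiles))
        stop("one condition label per trajectory file required")
      Map(function(f, cond) readTrajectory(f, condition = cond),
          config@trajectoryFiles, config@conditions)
    }
  })
  map <- config@domainMap %||%
    (if (synthetic) config@ensembleSpec@domainMap else orf2pDomainMap())
  topo <- topology(trajs[[1]])

  feats <- stage("featurize", {
    distanceFeatures(trajs, pickFeatureAtoms(topo, config@stride))
  })
  red <- stage("reduce", {
    pca <- fitPCA(feats)
    m <- nComponentsForThreshold(pca, config@varianceThreshold)
    list(pca = pca, m = m, space = projectScores(pca, feats, m))
  })
  clus <- stage("cluster", {
    sel <- scanK(red$space, config@kRange[1], config@kRange[2],
                 seed = config@seed, nInit = config@nInit)
    K <- config@chosenK
    if (is.na(K)) K <- elbowK(sel)
    if (is.na(K)) K <- bestSilhouetteK(sel)  # single-K scans have no elbow
    list(selection = sel, chosenK = K,
         report = buildClusterReport(selectedModel(sel, K), red$space))
  })
  geo <- stage("geometry", {
    pooled <- poolTrajectories(trajs)
    coreIdx <- backboneAtomIndices(pooled, domainResidues(map, "FPT"))
    aligned <- superposeOnCore(pooled, coreIdx, topo)
    avg <- averageStructure(aligned, coreIdx)
    alignedAvg <- superposeOnCore(pooled, coreIdx, avg)
    doms <- c(domainNames(map), "FPT")
    rmsd <- do.call(rbind, lapply(doms, function(d) {
      di <- backboneAtomIndices(pooled, domainResidues(map, d))
      rbind(
        summarizeSeries(domainRMSD(aligned, topo, di, d, "initial")),
        summarizeSeries(domainRMSD(alignedAvg, avg, di, d, "average")))
    }))
    iA <- domainAtomIndices(pooled, map, config@contactDomains[1])
    iB <- domainAtomIndices(pooled, map, config@contactDomains[2])
    dser <- minInterdomainDistance(pooled, iA, iB, config@contactDomains)
    list(pooled = pooled, aligned = aligned, average = avg, rmsd = rmsd,
         contact = dser,
         fraction = fractionBelow(dser, config@distanceThreshold),
         states = classifyOpenClosed(dser, config@distanceThreshold))
  })

  out <- list(trajectories = trajs, features = feats, pca = red$pca,
              m = red$m, space = red$space, selection = clus$selection,
              chosenK = clus$chosenK, clusters = clus$report,
              rmsd = geo$rmsd, contactDistance = geo$contact,
              contactFraction = geo$fraction, states = geo$states,
              groundTruth = if (synthetic) stateLabels(ens) else NULL,
              outputDir = config@outputDir)
  if (!is.na(config@outputDir))
    stage("report", writePipelineOutputs(out, config, geo$aligned))
  invisible(out)
}

#' Pool runs into one trajectory
#'
#' Concatenates the frames of several runs sharing one topology, in input
#' order (the same order the feature matrix uses); run/condition labels
#' stay in the feature metadata.
#'
#' @param trajs list of [MDTrajectory-class] with identical topologies.
#' @return One [MDTrajectory-class].
#' @export
poolTrajectories <- function(trajs) {
  if (length(trajs) == 1L) return(trajs[[1]])
  na <- nAtoms(trajs[[1]])
  nf <- sum(vapply(trajs, nFrames, integer(1)))
  arr <- array(NA_real_, dim = c(nf, na, 3))
  at <- 0L
  for (tr in trajs) {
    arr[at + seq_len(nFrames(tr)), , ] <- tr@coords
    at <- at + nFrames(tr)
  }
  MDTrajectory(topology(trajs[[1]]), arr, runId = "pooled",
               condition = "pooled", systemType = systemType(trajs[[1]]))
}

summarizeSeries <- function(s) {
  data.frame(domain = s@domain, reference = s@referenceKind,
             mean = seriesMean(s), sd = seriesSD(s))
}

writePipelineOutputs <- function(out, config, aligned) {
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config@outputDir, ...)
  writeClusterReport(out$clusters, p("clusters"))
  utils::write.csv(selectionTable(out$selection), p("selection.csv"),
                   row.names = FALSE)
  utils::write.csv(out$rmsd, p("rmsd.csv"), row.names = FALSE)
  writeSeries(out$contactDistance, p("contact_distance.csv"),
              meta = as.data.frame(frameMeta(out$space))[, c("run", "condition")])
  for (k in seq_along(out$clusters@representatives)) {
    f <- out$clusters@representatives[k]
    writePDB(ProteinStructure(atomData(aligned), coords(aligned, frame = f),
                              identifier = paste0("cluster", k)),
             p(sprintf("representative_cluster%d.pdb", k)))
  }
  cfgString <- paste(config@seed, config@stride, config@varianceThreshold,
                     paste(config@kRange, collapse = ","), config@chosenK,
                     config@distanceThreshold,
                     paste(config@contactDomains, collapse = ","),
                     config@nInit, sep = "|")
  ## polynomial rolling hash: a dependency-free config fingerprint
  h <- 0
  for (b in utf8ToInt(cfgString)) h <- (h * 31 + b) %% 2147483647

  manifest <- list(
    package = as.character(utils::packageVersion("DomainScape")),
    r = R.version.string,
    configHash = sprintf("%08x", h),
    seed = config@seed, stride = config@stride,
    varianceThreshold = config@varianceThreshold,
    kRange = config@kRange, chosenK = out$chosenK,
    distanceThreshold = config@distanceThreshold,
    contactDomains = config@contactDomains,
    nFrames = nFrames(out$space), m = out$m,
    contactFraction = out$contactFraction)
  jsonlite::write_json(manifest, p("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(config@outputDir)
}
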