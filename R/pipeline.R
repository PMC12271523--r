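# Run configuration and the subcommand pipeline tying the stages together
# with logging and master-seed control.

#' Default run configuration
#'
#' All knobs of the pipeline in one YAML-serializable list: paths, hierarchy
#' level, clustering policy, tuft thresholds (300/300 um defaults),
#' synthesis and connectivity parameters, and the master seed (every stage
#' derives its own substream from it).
#'
#' @param ... overrides of the defaults.
#' @return a named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    paths = list(atlas = NULL, morphologies = NULL, output = "synaxon-run"),
    level = "leaf",
    clustering = list(imposed_C = NULL, c_range = NULL,
                      covariance = "spherical", n_init = 10L),
    tufts = list(radial_max = 300, path_max = 300),
    synthesis = list(lattice_step = 2L, alpha = 0.5, trunk_step = 50,
                     noise_weight = 0.1, history_weight = 0.2,
                     tuft_step = 20, tuft_noise = 0.3, radius = 0.5,
                     retry_bound = 10L, n_axons = NULL),
    connectivity = list(touch_distance = NULL, interval = 5, density = 0.1),
    seed = 1L)
  overrides <- list(...)
  modifyList(cfg, overrides)
}

#' Read / validate a run configuration from YAML
#' @param path YAML file.
#' @return config list merged over the defaults.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(defaultRunConfig())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaultRunConfig(), raw)
  stopifnot(cfg$tufts$radial_max > 0, cfg$tufts$path_max > 0)
  cfg
}

logLine <- function(...) message("[synaxon] ", ...)

configHash <- function(cfg) {
  raw <- serialize(cfg, NULL)
  h <- 2166136261
  for (byte in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), byte)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Run a pipeline subcommand
#'
#' Subcommands \code{make-fixtures}, \code{project}, \code{cluster},
#' \code{synthesize}, \code{connect} and \code{validate} each consume and
#' produce the documented file artifacts under \code{paths$output}. Every
#' run logs the package version, config hash and master seed; identical
#' config + seed give identical artifacts.
#'
#' @param subcommand one of the subcommand names.
#' @param config a config list ([defaultRunConfig()]) or a YAML path.
#' @return invisible list of produced artifact paths.
#' @export
runPipeline <- function(subcommand, config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$paths$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logLine("synaxon ", as.character(utils::packageVersion("synaxon")),
          " | cmd=", subcommand, " | config=", configHash(config),
          " | seed=", config$seed)
  switch(subcommand,
         "make-fixtures" = pipelineMakeFixtures(config),
         "project" = pipelineProject(config),
         "cluster" = pipelineCluster(config),
         "synthesize" = pipelineSynthesize(config),
         "connect" = pipelineConnect(config),
         "validate" = pipelineValidate(config),
         stop("unknown subcommand: ", subcommand))
}

pipelineMakeFixtures <- function(cfg) {
  out <- cfg$paths$output
  atlas <- demoToyAtlas()
  writeBrainAtlas(atlas, file.path(out, "atlas"))
  pop <- generatePopulation(demoPopulationSpec(), atlas, seed = cfg$seed)
  mdir <- file.path(out, "morphologies")
  dir.create(mdir, showWarnings = FALSE)
  for (m in pop$morphologies) writeSWC(m, file.path(mdir, paste0(neuronId(m), ".swc")))
  utils::write.csv(pop$truth, file.path(out, "truth.csv"), row.names = FALSE)
  logLine("wrote ", length(pop$morphologies), " fixture morphologies")
  invisible(list(atlas = file.path(out, "atlas"), morphologies = mdir,
                 truth = file.path(out, "truth.csv")))
}

loadMorphologyDir <- function(dir) {
  files <- list.files(dir, pattern = "\\.swc$", full.names = TRUE)
  if (!length(files)) stop("no SWC files in ", dir)
  lapply(files, readSWC)
}

pipelineProject <- function(cfg) {
  out <- cfg$paths$output
  atlas <- readBrainAtlas(cfg$paths$atlas)
  morphs <- loadMorphologyDir(cfg$paths$morphologies)
  features <- lapply(morphs, computeProjectionFeatures, atlas = atlas,
                     level = cfg$level)
  excluded <- sum(vapply(features, is.null, TRUE))
  if (excluded) logLine(excluded, " morphologies excluded (soma outside atlas)")
  se <- stackPopulation(features)
  writeProjectionFeatures(se, file.path(out, "features.csv"))
  logLine("projected ", ncol(se), " axons over ", nrow(se), " regions")
  invisible(list(features = file.path(out, "features.csv")))
}

pipelineCluster <- function(cfg) {
  out <- cfg$paths$output
  se <- readProjectionFeatures(file.path(out, "features.csv"))
  X <- t(SummarizedExperiment::assay(se, "lengths"))
  src <- unique(SummarizedExperiment::colData(se)$source_region)
  model <- selectGMM(X, cRange = cfg$clustering$c_range,
                     imposedC = cfg$clustering$imposed_C,
                     covType = cfg$clustering$covariance,
                     seed = deriveSeed(cfg$seed, "gmm"),
                     nInit = cfg$clustering$n_init, sourceRegion = src)
  writeGMM(model, file.path(out, paste0("gmm_", src, ".json")))
  clusters <- classifyAxons(model, X)
  names(clusters) <- rownames(X)
  utils::write.csv(data.frame(neuron_id = names(clusters), cluster = clusters),
                   file.path(out, "assignments.csv"), row.names = FALSE)
  atlas <- readBrainAtlas(cfg$paths$atlas)
  morphs <- loadMorphologyDir(cfg$paths$morphologies)
  lib <- buildTuftLibrary(morphs, atlas, clusters, level = cfg$level,
                          radialMax = cfg$tufts$radial_max,
                          pathMax = cfg$tufts$path_max)
  writeTuftLibrary(lib, file.path(out, "tufts"))
  logLine("fitted C=", nClusters(model), " clusters; library of ",
          length(lib$tufts), " tufts")
  invisible(list(model = file.path(out, paste0("gmm_", src, ".json")),
                 assignments = file.path(out, "assignments.csv"),
                 tufts = file.path(out, "tufts")))
}

pipelineSynthesize <- function(cfg) {
  out <- cfg$paths$output
  atlas <- readBrainAtlas(cfg$paths$atlas)
  se <- readProjectionFeatures(file.path(out, "features.csv"))
  src <- unique(SummarizedExperiment::colData(se)$source_region)
  model <- readGMM(file.path(out, paste0("gmm_", src, ".json")))
  assignments <- utils::read.csv(file.path(out, "assignments.csv"))
  clusters <- stats::setNames(assignments$cluster, assignments$neuron_id)
  lib <- readTuftLibrary(file.path(out, "tufts"))
  stats <- targetStatistics(se, clusters, lib)
  nAxons <- if (is.null(cfg$synthesis$n_axons)) ncol(se) else cfg$synthesis$n_axons
  somata <- samplePointInRegion(atlas, src, n = nAxons, hemisphere = "left",
                                seed = deriveSeed(cfg$seed, "somata"))
  sc <- synthesisConfig(latticeStep = cfg$synthesis$lattice_step,
                        alpha = cfg$synthesis$alpha,
                        trunkStep = cfg$synthesis$trunk_step,
                        noiseWeight = cfg$synthesis$noise_weight,
                        historyWeight = cfg$synthesis$history_weight,
                        tuftStep = cfg$synthesis$tuft_step,
                        tuftNoise = cfg$synthesis$tuft_noise,
                        radius = cfg$synthesis$radius,
                        retryBound = cfg$synthesis$retry_bound)
  res <- synthesizePopulation(somata, model, stats, lib, atlas, sc,
                              seed = deriveSeed(cfg$seed, "synthesis"))
  sdir <- file.path(out, "synthesized")
  dir.create(sdir, showWarnings = FALSE)
  for (m in res$morphologies) writeSWC(m, file.path(sdir, paste0(neuronId(m), ".swc")))
  jsonlite::write_json(res$manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  logLine("synthesized ", length(res$morphologies), " long-range axons")
  invisible(list(synthesized = sdir, manifest = file.path(out, "manifest.json")))
}

pipelineConnect <- function(cfg) {
  out <- cfg$paths$output
  atlas <- readBrainAtlas(cfg$paths$atlas)
  pre <- loadMorphologyDir(file.path(out, "synthesized"))
  post <- generateScene(100L, atlas, seed = deriveSeed(cfg$seed, "scene"))
  touches <- detectTouches(pre, post, cfg$connectivity$touch_distance)
  touches <- filterInterbouton(touches, cfg$connectivity$interval)
  dendLen <- vapply(post, function(m)
    computeMorphometrics(m, "basal_dendrite")$total_length, 0)
  names(dendLen) <- vapply(post, neuronId, "")
  synapsesDf <- pruneToDensity(touches, cfg$connectivity$density, dendLen,
                               seed = deriveSeed(cfg$seed, "prune"))
  preRegions <- vapply(pre, function(m)
    regionAt(atlas, somaCenter(m), cfg$level), "")
  names(preRegions) <- vapply(pre, neuronId, "")
  cn <- buildConnectome(synapsesDf, atlas, cfg$level, preRegions)
  writeConnectome(cn, file.path(out, "connectome"))
  logLine(nrow(synapses(cn)), " synapses")
  invisible(list(connectome = file.path(out, "connectome")))
}

pipelineValidate <- function(cfg) {
  out <- cfg$paths$output
  atlas <- readBrainAtlas(cfg$paths$atlas)
  bio <- readProjectionFeatures(file.path(out, "features.csv"))
  synth <- loadMorphologyDir(file.path(out, "synthesized"))
  synthFeatures <- stackPopulation(lapply(synth, computeProjectionFeatures,
                                          atlas = atlas, level = cfg$level))
  report <- compareRegionLengths(bio, synthFeatures)
  writeComparisonReport(report, file.path(out, "validation"))
  logLine("validated ", nrow(report), " regions; max MVS = ",
          signif(max(report$mvs, na.rm = TRUE), 3))
  invisible(list(report = file.path(out, "validation.csv")))
}
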