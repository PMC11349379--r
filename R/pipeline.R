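#' @include assembly-io.R xlink-validation.R conformation-compare.R rigid-fit.R synthetic-data.R
NULL

## Polynomial rolling hash of the serialised effective config, for
## provenance logging (not cryptographic).
.configHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.need <- function(config, stage, field) {
  v <- config[[stage]][[field]]
  if (is.null(v))
    stop("invalid config: missing field '", stage, ".", field, "'")
  v
}

.opt <- function(config, stage, field, default) {
  config[[stage]][[field]] %||% default
}

.policyFromConfig <- function(config, stage) {
  thresholdPolicy(
    threshold = .opt(config, stage, "threshold", 35),
    confCutoff = .opt(config, stage, "plddtCutoff", 50),
    rescueWindow = .opt(config, stage, "rescueWindow", 0L))
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages as subcommands over one flat config (a
#' YAML file path or an equivalent nested list with per-stage sections);
#' `overrides` are merged on top of the stage section, so command-line flags
#' win over the config file. Every run writes its effective config
#' (`<out>/config.used.yaml`) and a log with package version, seed and a
#' config hash next to its outputs, so a run can be reproduced from its own
#' artifacts.
#'
#' Subcommands: `synth` (generate the two-state benchmark), `validate`
#' (map/classify cross-links on one model), `compare` (two-state distance
#' comparison + histograms), `burial` (two-state accessibility
#' differential), `fit` (fit-library + simulated annealing on a density
#' map).
#'
#' @param subcommand one of `"synth"`, `"validate"`, `"compare"`,
#'   `"burial"`, `"fit"`.
#' @param config YAML path or nested list.
#' @param overrides named list merged into the stage section.
#' @return invisibly, a list of the stage's in-memory results and output
#'   paths.
#' @export
runPipeline <- function(subcommand = c("synth", "validate", "compare",
                                       "burial", "fit"),
                        config = list(), overrides = list()) {
  subcommand <- match.arg(subcommand)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("invalid config: not a list or YAML path")
  config[[subcommand]] <- utils::modifyList(config[[subcommand]] %||% list(),
                                            overrides)
  outDir <- .opt(config, subcommand, "outDir", ".")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.used.yaml"))
  logLines <- c(
    sprintf("xlinkfit %s", as.character(utils::packageVersion("xlinkfit"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("config hash: %s", .configHash(config)),
    sprintf("seed: %s", .opt(config, subcommand, "seed", NA)),
    sprintf("R: %s", R.version.string))
  writeLines(logLines, file.path(outDir, "run.log"))
  res <- switch(subcommand,
                synth = .stageSynth(config, outDir),
                validate = .stageValidate(config, outDir),
                compare = .stageCompare(config, outDir),
                burial = .stageBurial(config, outDir),
                fit = .stageFit(config, outDir))
  invisible(res)
}

.stageSynth <- function(config, outDir) {
  sp <- syntheticSpec(
    nUnits = .opt(config, "synth", "nUnits", 5L),
    atomsPerDomain = .opt(config, "synth", "atomsPerDomain", 50L),
    nLinks = .opt(config, "synth", "nLinks", 40L),
    satFrac = c(A = .opt(config, "synth", "satFracA", 0.8),
                B = .opt(config, "synth", "satFracB", 0.95)),
    noise = .opt(config, "synth", "noise", 0),
    flexFrac = .opt(config, "synth", "flexFrac", 0.1),
    seed = .opt(config, "synth", "seed", 1L))
  g <- generateTwoState(sp)
  paths <- list(modelA = file.path(outDir, "modelA.cif"),
                modelB = file.path(outDir, "modelB.cif"),
                chainmap = file.path(outDir, "chainmap.yaml"),
                xlinks = file.path(outDir, "xlinks.csv"),
                truth = file.path(outDir, "truth.yaml"))
  writeStructure(g$modelA, paths$modelA)
  writeStructure(g$modelB, paths$modelB)
  writeChainMap(g$map, paths$chainmap)
  writeCrossLinks(g$xlinks, paths$xlinks)
  yaml::write_yaml(list(seed = sp@seed,
                        links = lapply(seq_len(nrow(g$truth)), function(i)
                          as.list(g$truth[i, ]))), paths$truth)
  c(g, list(paths = paths))
}

.stageValidate <- function(config, outDir) {
  model <- readStructure(.need(config, "validate", "model"))
  map <- readChainMap(.need(config, "validate", "chainmap"))
  xl <- readCrossLinks(.need(config, "validate", "xlinks"))
  rep <- validateCrossLinks(model, map, xl, .policyFromConfig(config, "validate"))
  out <- file.path(outDir, .opt(config, "validate", "out", "report.tsv"))
  writeReport(rep, out)
  pb <- file.path(outDir, .opt(config, "validate", "pb", "links.pb"))
  writePseudobonds(rep, pb)
  invisible(list(report = rep, paths = list(report = out, pb = pb)))
}

.stageCompare <- function(config, outDir) {
  mA <- readStructure(.need(config, "compare", "modelA"))
  mB <- readStructure(.need(config, "compare", "modelB"))
  mapA <- readChainMap(.need(config, "compare", "chainmapA"))
  mapB <- readChainMap(.opt(config, "compare", "chainmapB",
                            .need(config, "compare", "chainmapA")))
  xl <- readCrossLinks(.need(config, "compare", "xlinks"))
  pol <- .policyFromConfig(config, "compare")
  cmp <- compareStates(mA, mB, mapA, mapB, xl, pol)
  out <- file.path(outDir, "compare.tsv")
  writeReport(cmp, out)
  bw <- .opt(config, "compare", "binWidth", 5)
  hists <- list()
  for (st in c("A", "B")) {
    r <- data.frame(distance = cmp[[paste0("distance", st)]],
                    status = cmp[[paste0("status", st)]])
    hists[[st]] <- distanceHistogram(r, bw)
    hists[[st]]$state <- st
  }
  histOut <- file.path(outDir, "histogram.tsv")
  writeReport(do.call(rbind, hists), histOut)
  invisible(list(comparison = cmp, histograms = hists,
                 paths = list(comparison = out, histogram = histOut)))
}

.stageBurial <- function(config, outDir) {
  mA <- readStructure(.need(config, "burial", "modelA"))
  mB <- readStructure(.need(config, "burial", "modelB"))
  mapA <- readChainMap(.need(config, "burial", "chainmapA"))
  mapB <- readChainMap(.opt(config, "burial", "chainmapB",
                            .need(config, "burial", "chainmapA")))
  pA <- calcSASA(mA, nPoints = .opt(config, "burial", "nPoints", 960L))
  pB <- calcSASA(mB, nPoints = .opt(config, "burial", "nPoints", 960L))
  bd <- burialDifferential(pA, pB, mapA, mapB,
                           buriedCutoff = .opt(config, "burial", "buriedCutoff", 0.10),
                           accCutoff = .opt(config, "burial", "accCutoff", 0.25))
  paths <- list(AburiedB = file.path(outDir, "accessibleA_buriedB.tsv"),
                BburiedA = file.path(outDir, "accessibleB_buriedA.tsv"))
  writeReport(bd$accessibleAburiedB, paths$AburiedB)
  writeReport(bd$accessibleBburiedA, paths$BburiedA)
  invisible(list(differential = bd, profiles = list(A = pA, B = pB),
                 paths = paths))
}

.stageFit <- function(config, outDir) {
  bodyPaths <- .need(config, "fit", "bodies")
  bodies <- lapply(bodyPaths, readStructure)
  maps <- lapply(.need(config, "fit", "chainmaps"), readChainMap)
  grid <- readDensity(.need(config, "fit", "map"))
  resolution <- .need(config, "fit", "resolution")
  xl <- NULL
  if (!is.null(config$fit$xlinks)) xl <- readCrossLinks(config$fit$xlinks)
  seed <- .opt(config, "fit", "seed", 1L)
  libs <- lapply(seq_along(bodies), function(b)
    buildFitLibrary(bodies[[b]], grid, resolution,
                    nPositions = .opt(config, "fit", "nPositions", 80000L),
                    clusterAngle = .opt(config, "fit", "clusterAngle", 4),
                    clusterShift = .opt(config, "fit", "clusterShift", 3),
                    radius = .opt(config, "fit", "radius", 200),
                    insideThreshold = .opt(config, "fit", "insideThreshold", 0.3),
                    refine = .opt(config, "fit", "refine", 3L),
                    body = sprintf("body%d", b)))
  fit <- annealFit(bodies, maps, grid, resolution, xl, libs,
                   schedule = annealSchedule(), seed = seed,
                   policy = .policyFromConfig(config, "fit"))
  poseTab <- do.call(rbind, lapply(fit$poses, function(p)
    data.frame(body = p@body, qw = p@quat[1], qx = p@quat[2],
               qy = p@quat[3], qz = p@quat[4], tx = p@trans[1],
               ty = p@trans[2], tz = p@trans[3])))
  out <- file.path(outDir, "poses.tsv")
  writeReport(poseTab, out)
  scoreOut <- file.path(outDir, "score.yaml")
  yaml::write_yaml(list(total = totalScore(fit$score),
                        terms = as.list(scoreTerms(fit$score)),
                        weights = as.list(scoreWeights(fit$score))),
                   scoreOut)
  invisible(list(fit = fit, libraries = libs,
                 paths = list(poses = out, score = scoreOut)))
}
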