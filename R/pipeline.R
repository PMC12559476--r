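## End-to-end pipeline driver: mine -> ssn -> sites -> featurize ->
## train -> predict, with a strict config schema, per-stage seed fan-out
## and a checksummed artefact manifest.

.PIPELINE_STAGES <- c("mine", "ssn", "sites", "featurize", "train",
                      "predict")

.STAGE_KEYS <- list(
  mine = c("enabled", "min_identity", "min_coverage"),
  ssn = c("enabled", "cutoff", "repnode_threshold"),
  sites = c("enabled"),
  featurize = c("enabled", "embedder", "fingerprint"),
  train = c("enabled", "classifier", "folds", "repeats", "threshold"),
  predict = c("enabled", "runs"))

.INPUT_KEYS <- c("sequences", "queries", "substrates", "pairs",
                 "reference", "positions", "metadata")

#' Derive a per-stage seed from the global seed
#'
#' Stable hash of (global seed, stage name), so toggling one stage never
#' shifts another stage's randomness.
#'
#' @param globalSeed integer global seed.
#' @param stageName stage name string.
#' @return an integer seed in `[0, 2^31)`.
#' @export
stageSeed <- function(globalSeed, stageName)
  .mixSeed(as.integer(globalSeed), utf8ToInt(stageName))

#' Construct and validate a pipeline configuration
#'
#' The schema is strict: unknown keys at any level are rejected. The
#' config round-trips to YAML identically via [writePipelineConfig()].
#'
#' @param x a YAML file path or a nested list with elements `seed`
#'   (integer), `outdir` (path), `inputs` (paths keyed by `sequences`,
#'   `queries`, `substrates`, `pairs`, `reference`, `positions`,
#'   `metadata`) and `stages` (per-stage blocks keyed by `mine`, `ssn`,
#'   `sites`, `featurize`, `train`, `predict`, each with `enabled` plus
#'   stage parameters).
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x), c("seed", "outdir", "inputs", "stages"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(x$seed)) stop("config requires a 'seed'")
  if (is.null(x$outdir)) stop("config requires an 'outdir'")
  bad <- setdiff(names(x$inputs), .INPUT_KEYS)
  if (length(bad))
    stop("unknown input key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(x$stages), .PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (s in names(x$stages)) {
    bad <- setdiff(names(x$stages[[s]]), .STAGE_KEYS[[s]])
    if (length(bad))
      stop("unknown key(s) in stage '", s, "': ",
           paste(bad, collapse = ", "))
  }
  x$seed <- as.integer(x$seed)
  structure(x, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a `PipelineConfig`.
#' @param path output YAML path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.stageEnabled <- function(config, stage) {
  isTRUE(config$stages[[stage]]$enabled)
}

.stageParam <- function(config, stage, key, default) {
  v <- config$stages[[stage]][[key]]
  if (is.null(v)) default else v
}

.needInput <- function(config, key, stage) {
  p <- config$inputs[[key]]
  if (is.null(p))
    stop("stage '", stage, "' requires input '", key, "'")
  if (!file.exists(p))
    stop("stage '", stage, "': input '", key, "' not found at ", p)
  p
}

#' Run the pipeline
#'
#' Executes the enabled stages in order (mine, ssn, sites, featurize,
#' train, predict), writing every intermediate artefact under the
#' config's `outdir` and returning a manifest (stage, output path,
#' parameters, seed, md5 checksum). All randomness derives from
#' [stageSeed()] of the global seed, so a rerun with identical config
#' and inputs reproduces every artefact byte for byte.
#'
#' @param config a [pipelineConfig()] (or path/list accepted by it).
#' @return invisibly, the manifest `data.frame` (also written to
#'   `manifest.tsv` in `outdir`).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- pipelineConfig(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, paths, params) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, output = as.character(paths),
      seed = stageSeed(config$seed, stage),
      parameters = as.character(jsonlite::toJSON(params,
                                                 auto_unbox = TRUE)),
      md5 = unname(tools::md5sum(as.character(paths))))
  }

  seqs <- NULL
  getSeqs <- function(stage) {
    if (is.null(seqs))
      seqs <<- readSequences(.needInput(config, "sequences", stage))
    seqs
  }

  ## ---- mine ----
  if (.stageEnabled(config, "mine")) {
    queries <- readSequences(.needInput(config, "queries", "mine"))
    prot <- getSeqs("mine")
    par <- list(min_identity = .stageParam(config, "mine", "min_identity", 0.3),
                min_coverage = .stageParam(config, "mine", "min_coverage", 0.5))
    hits <- mineCandidates(queries, prot, par$min_identity, par$min_coverage)
    hp <- file.path(outdir, "hits.tsv")
    writeHits(hits, hp)
    seqs <- prot[hits$target_id]
    cp <- file.path(outdir, "candidates.fasta")
    writeSequences(seqs, cp)
    note("mine", c(hp, cp), par)
  }

  ## ---- ssn ----
  network <- NULL
  if (.stageEnabled(config, "ssn")) {
    par <- list(cutoff = .stageParam(config, "ssn", "cutoff", 0.8),
                repnode_threshold =
                  .stageParam(config, "ssn", "repnode_threshold", 0.95))
    network <- buildNetwork(getSeqs("ssn"), par$cutoff,
                            par$repnode_threshold)
    meta <- if (!is.null(config$inputs$metadata))
      readMetadata(config$inputs$metadata) else NULL
    paths <- writeNetwork(network, file.path(outdir, "ssn"), meta)
    note("ssn", paths, par)
  }

  ## ---- sites ----
  profile <- NULL
  if (.stageEnabled(config, "sites")) {
    ref <- readSequences(.needInput(config, "reference", "sites"))
    posmap <- if (!is.null(config$inputs$positions))
      positionMap(ref, config$inputs$positions) else positionMap(ref)
    profile <- activeSiteProfile(getSeqs("sites"), posmap)
    paths <- writeActiveSites(profile, file.path(outdir, "sites"))
    note("sites", paths, list(n_positions = nrow(posmap@positions)))
  }

  ## ---- featurize ----
  pairFeat <- NULL
  dataset <- NULL
  if (.stageEnabled(config, "featurize")) {
    par <- list(embedder = .stageParam(config, "featurize", "embedder",
                                       "fallback-physchem"),
                fingerprint = .stageParam(config, "featurize", "fingerprint",
                                          "maccs"))
    subs <- readSubstrateTable(.needInput(config, "substrates", "featurize"))
    ez <- featurizeEnzymes(getSeqs("featurize"), par$embedder)
    su <- featurizeSubstrates(subs, par$fingerprint)
    pairFeat <- buildPairFeatures(ez, su)
    fe <- file.path(outdir, "enzyme_features.csv")
    utils::write.csv(data.frame(seq_id = rownames(ez),
                                round(ez, 8), check.names = FALSE),
                     fe, row.names = FALSE, quote = FALSE)
    fs <- file.path(outdir, "substrate_fingerprints.csv")
    utils::write.csv(data.frame(substrate_id = rownames(su), su,
                                check.names = FALSE),
                     fs, row.names = FALSE, quote = FALSE)
    note("featurize", c(fe, fs), par)
  }

  ## ---- train ----
  report <- NULL
  trainCfg <- NULL
  if (.stageEnabled(config, "train")) {
    if (is.null(pairFeat))
      stop("stage 'train' needs features: enable stage 'featurize'")
    dataset <- readPairTable(.needInput(config, "pairs", "train"))
    par <- list(classifier = .stageParam(config, "train", "classifier",
                                         "random_forest"),
                folds = .stageParam(config, "train", "folds", 5L),
                repeats = .stageParam(config, "train", "repeats", 20L),
                threshold = .stageParam(config, "train", "threshold", 0.5))
    trainCfg <- modelConfig(classifier = par$classifier,
                            cvFolds = par$folds, cvRepeats = par$repeats,
                            decisionThreshold = par$threshold,
                            baseSeed = stageSeed(config$seed, "train"))
    report <- crossValidate(dataset, pairFeat, trainCfg)
    rp <- file.path(outdir, "report.json")
    writeReport(report, rp)
    note("train", rp, par)
  }

  ## ---- predict ----
  if (.stageEnabled(config, "predict")) {
    if (is.null(dataset) || is.null(trainCfg))
      stop("stage 'predict' needs a trained setup: enable stage 'train'")
    par <- list(runs = .stageParam(config, "predict", "runs", 100L))
    predCfg <- trainCfg
    predCfg@nPredictionRuns <- as.integer(par$runs)
    predCfg@baseSeed <- stageSeed(config$seed, "predict")
    pm <- predictMatrix(dataset, pairFeat, predCfg)
    pp <- file.path(outdir, "predictions.csv")
    probs <- probabilities(pm)
    utils::write.csv(data.frame(enzyme_id = rownames(probs),
                                matrix(sprintf("%.6f", probs),
                                       nrow = nrow(probs),
                                       dimnames = dimnames(probs)),
                                check.names = FALSE),
                     pp, row.names = FALSE, quote = FALSE)
    cp <- file.path(outdir, "calls.csv")
    utils::write.csv(data.frame(enzyme_id = rownames(probs),
                                binaryCalls(pm), check.names = FALSE),
                     cp, row.names = FALSE, quote = FALSE)
    note("predict", c(pp, cp), par)
  }

  manifest <- do.call(rbind, manifest)
  if (is.null(manifest))
    stop("no stage enabled; nothing to run")
  rel <- startsWith(manifest$output, paste0(outdir, "/"))
  manifest$output[rel] <- substring(manifest$output[rel],
                                    nchar(outdir) + 2L)
  mp <- file.path(outdir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}
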