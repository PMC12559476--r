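#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom Biostrings AAString AAStringSet
#' @importFrom stats setNames
NULL

#' SimilarityNetwork: a sequence similarity network with representative nodes
#'
#' A sequence similarity network (SSN) built from a collection of protein
#' sequences. Near-identical sequences (pairwise identity above
#' `repnodeThreshold`, by default 0.95) are collapsed into representative
#' nodes ("repnodes"); edges connect representatives whose global-alignment
#' identity is at least `cutoff`; clusters are the connected components of
#' the resulting graph, numbered by descending member count.
#'
#' @slot repnodes a [S4Vectors::DataFrame] with columns `rep_id` (character)
#'   and `members` (CharacterList); every input sequence id appears in
#'   exactly one repnode.
#' @slot edges a `data.frame` with columns `rep_a`, `rep_b`, `identity`;
#'   every `identity` is `>= cutoff`.
#' @slot clusters a `data.frame` with columns `rep_id`, `cluster_id`;
#'   cluster ids are `1..K` assigned by descending total member count, ties
#'   broken by the lexicographically smallest member id.
#' @slot cutoff edge identity cutoff, a fraction in (0, 1].
#' @slot repnodeThreshold repnode collapsing threshold, a fraction in (0, 1].
#'
#' @seealso [buildNetwork()], [clusterComposition()], [writeNetwork()]
#' @export
setClass("SimilarityNetwork",
  representation(
    repnodes = "DataFrame",
    edges = "data.frame",
    clusters = "data.frame",
    cutoff = "numeric",
    repnodeThreshold = "numeric"
  )
)

setValidity("SimilarityNetwork", function(object) {
  msg <- character()
  rn <- object@repnodes
  if (!all(c("rep_id", "members") %in% colnames(rn)))
    msg <- c(msg, "repnodes must have columns 'rep_id' and 'members'")
  else {
    members <- unlist(rn$members, use.names = FALSE)
    if (anyDuplicated(members))
      msg <- c(msg, "a member id appears in more than one repnode")
    if (!all(rn$rep_id %in% members))
      msg <- c(msg, "every representative must be among its own members")
  }
  if (length(object@cutoff) != 1L || object@cutoff <= 0 || object@cutoff > 1)
    msg <- c(msg, "cutoff must be a single fraction in (0, 1]")
  if (nrow(object@edges) > 0 && any(object@edges$identity < object@cutoff - 1e-12))
    msg <- c(msg, "all edge identities must be >= cutoff")
  cl <- object@clusters
  if (nrow(cl) > 0) {
    k <- sort(unique(cl$cluster_id))
    if (!identical(k, seq_along(k)))
      msg <- c(msg, "cluster ids must be 1..K")
    if (!setequal(cl$rep_id, rn$rep_id))
      msg <- c(msg, "clusters must cover exactly the repnode ids")
  }
  if (length(msg)) msg else TRUE
})

#' ActiveSitePositionMap: reference-numbered active-site positions
#'
#' Holds the reference protein (by convention the model plant chalcone
#' synthase MsCHS, UniProt P30074, supplied by the user) together with the
#' 1-based reference positions at which residues are to be read out, e.g.
#' the catalytic triad C164/H303/N336 and the substrate-pocket positions
#' 197, 256 and 265.
#'
#' @slot reference an [Biostrings::AAStringSet] of length 1 (the reference).
#' @slot positions a `data.frame` with columns `ref_position` (ascending
#'   1-based integers, each `<=` the reference length), `label` (character)
#'   and `expected_residue` (single letter or `""`).
#'
#' @seealso [positionMap()], [mapReferencePositions()], [flagTriad()]
#' @export
setClass("ActiveSitePositionMap",
  representation(reference = "AAStringSet", positions = "data.frame")
)

setValidity("ActiveSitePositionMap", function(object) {
  msg <- character()
  if (length(object@reference) != 1L)
    msg <- c(msg, "reference must contain exactly one sequence")
  p <- object@positions
  need <- c("ref_position", "label", "expected_residue")
  if (!all(need %in% colnames(p)))
    msg <- c(msg, sprintf("positions must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (is.unsorted(p$ref_position, strictly = TRUE))
      msg <- c(msg, "ref_position must be strictly ascending")
    if (length(object@reference) == 1L &&
        nrow(p) > 0 && max(p$ref_position) > Biostrings::width(object@reference))
      msg <- c(msg, "ref_position beyond reference length")
    if (any(p$ref_position < 1L))
      msg <- c(msg, "ref_position must be >= 1")
    if (!all(nchar(p$expected_residue) %in% c(0L, 1L)))
      msg <- c(msg, "expected_residue must be one letter or empty")
  }
  if (length(msg)) msg else TRUE
})

#' ActiveSiteProfile: residues observed at reference-numbered positions
#'
#' Per-sequence readout of the residues aligned to each mapped reference
#' position ("-" where the position is deleted in the query), plus an
#' optional grouping used when building frequency logos.
#'
#' @slot residues character matrix, sequences in rows (rownames are
#'   sequence ids), mapped reference positions in columns (colnames are the
#'   positions as character); entries are single residue letters or "-".
#' @slot groups named character vector assigning each sequence id to a
#'   group (e.g. an SSN cluster); may be empty.
#' @slot posmap the [ActiveSitePositionMap-class] object the profile was built from.
#'
#' @seealso [activeSiteProfile()], [residueLogo()], [flagTriad()]
#' @export
setClass("ActiveSiteProfile",
  representation(residues = "matrix", groups = "character",
                 posmap = "ActiveSitePositionMap")
)

setValidity("ActiveSiteProfile", function(object) {
  msg <- character()
  r <- object@residues
  if (nrow(r) > 0) {
    if (is.null(rownames(r)) || is.null(colnames(r)))
      msg <- c(msg, "residues matrix must have sequence ids and positions as dimnames")
    if (!all(nchar(r) == 1L))
      msg <- c(msg, "residue entries must be single characters")
  }
  if (length(object@groups) &&
      !all(rownames(r) %in% names(object@groups)))
    msg <- c(msg, "groups must cover all sequence ids when provided")
  if (length(msg)) msg else TRUE
})

#' PairDataset: binary enzyme-substrate activity labels
#'
#' The training/evaluation substrate for the activity classifiers: one row
#' per (enzyme, substrate) pair with a strictly binary activity label.
#' Synthetic datasets additionally carry the noise-free rule labels in a
#' `truth` column so recovery can be measured exactly.
#'
#' @slot pairs `data.frame` with columns `enzyme_id`, `substrate_id`,
#'   `label` (0/1) and optionally `truth` (0/1).
#' @slot provenance one of `"train"`, `"external"`, `"validation"`,
#'   `"synthetic"`.
#'
#' @seealso [pairDataset()], [activeFraction()], [crossValidate()]
#' @export
setClass("PairDataset",
  representation(pairs = "data.frame", provenance = "character")
)

setValidity("PairDataset", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("enzyme_id", "substrate_id", "label") %in% colnames(p)))
    msg <- c(msg, "pairs must have columns enzyme_id, substrate_id, label")
  else {
    if (anyDuplicated(paste(p$enzyme_id, p$substrate_id, sep = "\r")))
      msg <- c(msg, "duplicate (enzyme, substrate) pair")
    if (!all(p$label %in% c(0L, 1L)))
      msg <- c(msg, "labels must be strictly binary (0/1)")
    if ("truth" %in% colnames(p) && !all(p$truth %in% c(0L, 1L)))
      msg <- c(msg, "truth labels must be strictly binary (0/1)")
  }
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

#' ModelConfig: classifier and evaluation protocol settings
#'
#' @slot classifier one of `"decision_tree"`, `"random_forest"`, `"mlp"`.
#' @slot hyperparameters named list of classifier settings; unset values
#'   fall back to per-classifier defaults (see [trainClassifier()]).
#' @slot cvFolds number of stratified folds (>= 2).
#' @slot cvRepeats number of repeats of the whole CV (>= 1).
#' @slot nPredictionRuns number of seeded model runs averaged by
#'   [predictMatrix()] / [evaluateExternal()] (default 100).
#' @slot baseSeed base seed; run r uses seed `baseSeed + r - 1`.
#' @slot decisionThreshold probability threshold for binary calls.
#'
#' @seealso [modelConfig()], [crossValidate()], [predictMatrix()]
#' @export
setClass("ModelConfig",
  representation(
    classifier = "character",
    hyperparameters = "list",
    cvFolds = "integer",
    cvRepeats = "integer",
    nPredictionRuns = "integer",
    baseSeed = "integer",
    decisionThreshold = "numeric"
  ),
  prototype(
    classifier = "random_forest",
    hyperparameters = list(),
    cvFolds = 5L,
    cvRepeats = 20L,
    nPredictionRuns = 100L,
    baseSeed = 1L,
    decisionThreshold = 0.5
  )
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@classifier %in% c("decision_tree", "random_forest", "mlp"))
    msg <- c(msg, "classifier must be decision_tree, random_forest or mlp")
  if (object@cvFolds < 2L) msg <- c(msg, "cvFolds must be >= 2")
  if (object@cvRepeats < 1L) msg <- c(msg, "cvRepeats must be >= 1")
  if (object@nPredictionRuns < 1L) msg <- c(msg, "nPredictionRuns must be >= 1")
  if (object@decisionThreshold < 0 || object@decisionThreshold > 1)
    msg <- c(msg, "decisionThreshold must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: per-run classifier metrics
#'
#' One row per evaluation run (one CV fold fit, or one seeded external
#' evaluation), with accuracy and F1 of the active class, plus pooled
#' confusion counts over all runs.
#'
#' @slot metrics `data.frame` with columns `run`, `rep`, `fold`, `seed`,
#'   `accuracy`, `f1` (fold is `NA` for external evaluations).
#' @slot confusion named numeric vector `c(TP, FP, FN, TN)` pooled over runs.
#' @slot config the [ModelConfig-class] used.
#'
#' @seealso [crossValidate()], [evaluateExternal()], [compareModels()]
#' @export
setClass("EvaluationReport",
  representation(metrics = "data.frame", confusion = "numeric",
                 config = "ModelConfig")
)

setValidity("EvaluationReport", function(object) {
  msg <- character()
  m <- object@metrics
  need <- c("run", "rep", "fold", "seed", "accuracy", "f1")
  if (!all(need %in% colnames(m)))
    msg <- c(msg, sprintf("metrics must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    ok <- stats::complete.cases(m[, c("accuracy")])
    if (any(m$accuracy[ok] < 0 | m$accuracy[ok] > 1))
      msg <- c(msg, "accuracy out of [0, 1]")
    f <- m$f1[!is.na(m$f1)]
    if (any(f < 0 | f > 1)) msg <- c(msg, "f1 out of [0, 1]")
  }
  if (!all(c("TP", "FP", "FN", "TN") %in% names(object@confusion)))
    msg <- c(msg, "confusion must be named TP, FP, FN, TN")
  if (length(msg)) msg else TRUE
})

#' PredictionMatrix: seed-averaged enzyme x substrate activity predictions
#'
#' Mean predicted activity probability for every (enzyme, substrate) cell,
#' averaged over `nRuns` models trained with distinct seeds, together with
#' the binary calls at the decision threshold.
#'
#' @slot probabilities numeric matrix, enzymes in rows, substrates in
#'   columns; values in `[0, 1]`.
#' @slot calls integer 0/1 matrix of the same shape;
#'   `calls == (probabilities >= threshold)`.
#' @slot threshold decision threshold used for the calls.
#' @slot nRuns number of seeded model runs averaged.
#'
#' @seealso [predictMatrix()]
#' @export
setClass("PredictionMatrix",
  representation(probabilities = "matrix", calls = "matrix",
                 threshold = "numeric", nRuns = "integer")
)

setValidity("PredictionMatrix", function(object) {
  msg <- character()
  p <- object@probabilities
  if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities out of [0, 1]")
  if (!identical(dim(p), dim(object@calls)))
    msg <- c(msg, "probabilities and calls must have identical shape")
  else if (!all(object@calls == (p >= object@threshold)))
    msg <- c(msg, "calls inconsistent with threshold")
  if (object@nRuns < 1L) msg <- c(msg, "nRuns must be >= 1")
  if (length(msg)) msg else TRUE
})
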