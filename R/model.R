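## Binary enzyme-substrate activity classifiers: training, repeated
## stratified cross-validation, paired model comparison, seed-averaged
## prediction matrices, and external-set evaluation.

#' Construct a ModelConfig
#'
#' @param classifier `"decision_tree"` (rpart), `"random_forest"`
#'   (ranger) or `"mlp"` (single-hidden-layer network, nnet).
#' @param hyperparameters named list overriding per-classifier defaults:
#'   decision tree `minsplit` (10), `cp` (0.01), `maxdepth` (30); random
#'   forest `num_trees` (500), `min_node_size` (1), `mtry` (sqrt(p));
#'   mlp `hidden` (8), `decay` (0.01), `maxit` (100). All classifiers
#'   additionally accept `seed_offset` (default 0), which shifts the
#'   model-internal randomness stream while keeping the evaluation
#'   protocol (fold assignments, run seeds) fixed.
#' @param cvFolds stratified folds (default 5).
#' @param cvRepeats CV repeats (default 20; 5 x 20 = 100 runs, matching
#'   the 100-run averaging convention used for predictions).
#' @param nPredictionRuns seeded runs averaged by [predictMatrix()] and
#'   [evaluateExternal()] (default 100).
#' @param baseSeed base seed; every run derives its own seed from it.
#' @param decisionThreshold probability cutoff for binary calls
#'   (default 0.5).
#' @return a [ModelConfig-class] object.
#' @export
modelConfig <- function(classifier = c("random_forest", "decision_tree",
                                       "mlp"),
                        hyperparameters = list(), cvFolds = 5L,
                        cvRepeats = 20L, nPredictionRuns = 100L,
                        baseSeed = 1L, decisionThreshold = 0.5) {
  classifier <- match.arg(classifier)
  methods::new("ModelConfig", classifier = classifier,
               hyperparameters = hyperparameters,
               cvFolds = as.integer(cvFolds),
               cvRepeats = as.integer(cvRepeats),
               nPredictionRuns = as.integer(nPredictionRuns),
               baseSeed = as.integer(baseSeed),
               decisionThreshold = decisionThreshold)
}

## deterministic sub-seed in [0, 2^31): every run/fold mixes its indices
## into the base seed so seeds never collide across protocol axes
.mixSeed <- function(...) .hashInts(as.integer(c(...)))

## run expr under a private seed, restoring the caller's RNG state so
## library calls never perturb user-level random streams
.withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

.hp <- function(config, name, default) {
  v <- config@hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Train a single activity classifier
#'
#' Fits the configured classifier on all pairs of `dataset` using their
#' concatenated pair features. Deterministic given (data, config, seed).
#'
#' @param dataset a [PairDataset-class]; must contain both classes.
#' @param features pair feature matrix from [buildPairFeatures()]
#'   covering every dataset pair.
#' @param config a [ModelConfig-class].
#' @param seed integer seed for this fit.
#' @return a fitted model handle (list with class `"t3pksModel"`)
#'   supporting [predictProb()].
#' @export
trainClassifier <- function(dataset, features, config = modelConfig(),
                            seed = config@baseSeed) {
  stopifnot(is(dataset, "PairDataset"), is(config, "ModelConfig"))
  p <- dataset@pairs
  X <- .featuresForPairs(features, p$enzyme_id, p$substrate_id)
  y <- p$label
  if (length(unique(y)) < 2L)
    stop("trainClassifier: dataset contains a single class")
  if (nrow(X) != length(y))
    stop("trainClassifier: feature/label mismatch")

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  ## seed_offset shifts only the model-internal randomness stream,
  ## leaving the evaluation protocol (fold seeds) untouched -- useful
  ## for measuring sensitivity to fit randomness under identical splits
  off <- .hp(config, "seed_offset", 0L)
  seed <- if (off == 0L) seed else .mixSeed(seed, 7919L + as.integer(off))
  fit <- .withSeed(seed, switch(config@classifier,
    decision_tree = {
      d <- data.frame(.y = factor(y, levels = c(0, 1)), X,
                      check.names = FALSE)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     minsplit = .hp(config, "minsplit", 10L),
                     cp = .hp(config, "cp", 0.01),
                     maxdepth = .hp(config, "maxdepth", 30L)))
    },
    random_forest = {
      ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
        probability = TRUE,
        num.trees = .hp(config, "num_trees", 500L),
        min.node.size = .hp(config, "min_node_size", 1L),
        mtry = .hp(config, "mtry", NULL),
        seed = seed, num.threads = 1L)
    },
    mlp = {
      Xs <- scale(X, center = ctr, scale = scl)
      nnet::nnet(x = Xs, y = y, entropy = TRUE,
                 size = .hp(config, "hidden", 8L),
                 decay = .hp(config, "decay", 0.01),
                 maxit = .hp(config, "maxit", 100L),
                 MaxNWts = 200000L, trace = FALSE)
    }))
  structure(list(classifier = config@classifier, fit = fit,
                 center = ctr, scale = scl, seed = seed, config = config),
            class = "t3pksModel")
}

#' Predicted activity probability
#'
#' @param model a fitted handle from [trainClassifier()].
#' @param features pair feature matrix (rows are the pairs to score).
#' @return numeric vector of P(active) in `[0, 1]`, named by the feature
#'   row names.
#' @export
predictProb <- function(model, features) {
  stopifnot(inherits(model, "t3pksModel"))
  X <- features
  pr <- switch(model$classifier,
    decision_tree = {
      d <- as.data.frame(X, check.names = FALSE)
      stats::predict(model$fit, newdata = d, type = "prob")[, "1"]
    },
    random_forest = {
      stats::predict(model$fit, data = as.data.frame(X),
                     num.threads = 1L)$predictions[, "1"]
    },
    mlp = {
      Xs <- scale(X, center = model$center, scale = model$scale)
      as.numeric(stats::predict(model$fit, Xs))
    })
  stats::setNames(pmin(pmax(as.numeric(pr), 0), 1), rownames(X))
}

.confusion <- function(truth, call) {
  c(TP = sum(truth == 1 & call == 1), FP = sum(truth == 0 & call == 1),
    FN = sum(truth == 1 & call == 0), TN = sum(truth == 0 & call == 0))
}

.confusionMetrics <- function(cm) {
  acc <- (cm[["TP"]] + cm[["TN"]]) / sum(cm)
  denom <- 2 * cm[["TP"]] + cm[["FP"]] + cm[["FN"]]
  f1 <- if (denom == 0) NA_real_ else 2 * cm[["TP"]] / denom
  c(accuracy = acc, f1 = f1)
}

## stratified fold assignment; retries the draw when a fold misses a
## class (possible only near the class-count limit), then fails loudly
.stratifiedFolds <- function(y, k, seed) {
  if (min(table(y)) < k)
    stop("cannot stratify ", k, "-fold CV: a class has fewer than ", k,
         " examples")
  for (attempt in 1:20) {
    fold <- .withSeed(.mixSeed(seed, attempt), {
      f <- integer(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[fold == f])) == 2L, logical(1)))
    if (ok) return(fold)
  }
  stop("stratification failed: a fold lacked both classes in 20 draws")
}

#' Repeated stratified cross-validation
#'
#' Runs `cvFolds`-fold stratified CV `cvRepeats` times with distinct
#' seeds; every fold fit is one "run" (so the default 5 x 20 protocol
#' gives 100 runs). Pairs are split at random over (enzyme, substrate)
#' pairs; accuracy and F1 (positive class = active) are computed per run
#' and summarised as mean +/- sd across runs.
#'
#' @inheritParams trainClassifier
#' @return an [EvaluationReport-class].
#' @export
crossValidate <- function(dataset, features, config = modelConfig()) {
  stopifnot(is(dataset, "PairDataset"))
  p <- dataset@pairs
  if (nrow(p) < config@cvFolds)
    stop("dataset smaller than the number of folds")
  y <- p$label
  rows <- list()
  cm_total <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  run <- 0L
  for (r in seq_len(config@cvRepeats)) {
    rep_seed <- .mixSeed(config@baseSeed, r)
    fold <- .stratifiedFolds(y, config@cvFolds, rep_seed)
    for (f in seq_len(config@cvFolds)) {
      run <- run + 1L
      test <- fold == f
      tr <- pairDataset(p[!test, , drop = FALSE], dataset@provenance)
      fit_seed <- .mixSeed(config@baseSeed, r, f)
      model <- trainClassifier(tr, features, config, seed = fit_seed)
      prob <- predictProb(model, .featuresForPairs(
        features, p$enzyme_id[test], p$substrate_id[test]))
      call <- as.integer(prob >= config@decisionThreshold)
      cm <- .confusion(y[test], call)
      cm_total <- cm_total + cm
      met <- .confusionMetrics(cm)
      rows[[run]] <- data.frame(run = run, rep = r, fold = f,
                                seed = fit_seed,
                                accuracy = met[["accuracy"]],
                                f1 = met[["f1"]])
    }
  }
  methods::new("EvaluationReport", metrics = do.call(rbind, rows),
               confusion = cm_total, config = config)
}

#' Paired comparison of two evaluation reports
#'
#' Two-sided paired test on the per-run F1 scores of two reports sharing
#' the same run structure (same run count and matched seeds): Wilcoxon
#' signed-rank for six or more runs, paired t-test below that. Two
#' identical reports compare with p = 1.
#'
#' @param report_a,report_b [EvaluationReport-class] objects with matched
#'   runs.
#' @param alpha significance level (default 0.05).
#' @param metric `"f1"` (default) or `"accuracy"`.
#' @return a list with `statistic`, `p_value`, `significant`, `test`.
#' @export
compareModels <- function(report_a, report_b, alpha = 0.05, metric = "f1") {
  stopifnot(is(report_a, "EvaluationReport"),
            is(report_b, "EvaluationReport"))
  ma <- report_a@metrics
  mb <- report_b@metrics
  if (nrow(ma) != nrow(mb))
    stop("compareModels: reports have different run counts")
  if (!identical(ma$seed, mb$seed) ||
      !identical(ma$rep, mb$rep) || !identical(ma$fold, mb$fold))
    stop("compareModels: run structure (seeds/folds) not matched")
  a <- ma[[metric]]
  b <- mb[[metric]]
  d <- a - b
  d[is.na(d)] <- 0
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                test = "degenerate (all differences zero)"))
  if (stats::sd(d) == 0)
    ## constant nonzero difference: no within-pair variance, the
    ## direction is unanimous across every matched run
    return(list(statistic = mean(d), p_value = 0, significant = TRUE,
                test = "degenerate (constant nonzero difference)"))
  if (length(d) >= 6L) {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                              exact = FALSE,
                                              correct = TRUE))
    test <- "wilcoxon signed-rank"
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    test <- "paired t-test"
  }
  pv <- ht$p.value
  if (!is.finite(pv)) pv <- 1
  list(statistic = unname(ht$statistic), p_value = pv,
       significant = pv < alpha, test = test)
}

#' Seed-averaged prediction matrix
#'
#' Trains `nPredictionRuns` models on the full training dataset with
#' distinct seeds, averages the predicted activity probabilities for
#' every (target enzyme, target substrate) cell, and binarises at the
#' decision threshold -- the convention used for heatmap-style prediction
#' matrices averaged over 100 seeded runs.
#'
#' @inheritParams trainClassifier
#' @param targetEnzymes,targetSubstrates ids of the prediction grid;
#'   default to the ids present in `dataset`. Every target pair must have
#'   a row in `features`.
#' @return a [PredictionMatrix-class].
#' @export
predictMatrix <- function(dataset, features, config = modelConfig(),
                          targetEnzymes = NULL, targetSubstrates = NULL) {
  stopifnot(is(dataset, "PairDataset"))
  if (is.null(targetEnzymes))
    targetEnzymes <- sort(unique(dataset@pairs$enzyme_id))
  if (is.null(targetSubstrates))
    targetSubstrates <- sort(unique(dataset@pairs$substrate_id))
  grid <- expand.grid(enzyme_id = targetEnzymes,
                      substrate_id = targetSubstrates,
                      stringsAsFactors = FALSE)
  Xt <- .featuresForPairs(features, grid$enzyme_id, grid$substrate_id)
  acc <- numeric(nrow(grid))
  for (i in seq_len(config@nPredictionRuns)) {
    model <- trainClassifier(dataset, features, config,
                             seed = .mixSeed(config@baseSeed, i, 0L))
    acc <- acc + predictProb(model, Xt)
  }
  prob <- acc / config@nPredictionRuns
  pm <- matrix(prob, nrow = length(targetEnzymes),
               dimnames = list(targetEnzymes, targetSubstrates))
  calls <- matrix(as.integer(pm >= config@decisionThreshold),
                  nrow = nrow(pm), dimnames = dimnames(pm))
  methods::new("PredictionMatrix", probabilities = pm, calls = calls,
               threshold = config@decisionThreshold,
               nRuns = config@nPredictionRuns)
}

#' Evaluate on an external dataset
#'
#' Trains on the full training dataset repeatedly over
#' `nPredictionRuns` seeds and scores the external pairs each time,
#' reporting accuracy and F1 as mean +/- sd across the seeded runs. When
#' the two feature matrices are supplied separately, their embedder and
#' fingerprint tags must agree.
#'
#' @param training,external [PairDataset-class] objects.
#' @param features either one pair feature matrix covering both datasets,
#'   or `list(train = , external = )` of matrices built with the same
#'   embedder/fingerprint settings.
#' @param config a [ModelConfig-class].
#' @return an [EvaluationReport-class] (fold is `NA` per run).
#' @export
evaluateExternal <- function(training, external, features,
                             config = modelConfig()) {
  stopifnot(is(training, "PairDataset"), is(external, "PairDataset"))
  if (is.list(features) && !is.matrix(features)) {
    ta <- attr(features$train, "embedder_tag")
    tb <- attr(features$external, "embedder_tag")
    fa <- attr(features$train, "fingerprint_type")
    fb <- attr(features$external, "fingerprint_type")
    if (!identical(ta, tb))
      stop("embedder tag mismatch between feature caches: '",
           ta, "' vs '", tb, "'")
    if (!identical(fa, fb))
      stop("fingerprint type mismatch between feature caches: '",
           fa, "' vs '", fb, "'")
    common <- intersect(colnames(features$train),
                        colnames(features$external))
    features <- rbind(features$train[, common, drop = FALSE],
                      features$external[, common, drop = FALSE])
  }
  pe <- external@pairs
  Xe <- .featuresForPairs(features, pe$enzyme_id, pe$substrate_id)
  rows <- list()
  cm_total <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_len(config@nPredictionRuns)) {
    seed_i <- .mixSeed(config@baseSeed, i, 0L)
    model <- trainClassifier(training, features, config, seed = seed_i)
    prob <- predictProb(model, Xe)
    call <- as.integer(prob >= config@decisionThreshold)
    cm <- .confusion(pe$label, call)
    cm_total <- cm_total + cm
    met <- .confusionMetrics(cm)
    rows[[i]] <- data.frame(run = i, rep = i, fold = NA_integer_,
                            seed = seed_i, accuracy = met[["accuracy"]],
                            f1 = met[["f1"]])
  }
  methods::new("EvaluationReport", metrics = do.call(rbind, rows),
               confusion = cm_total, config = config)
}

#' Write an evaluation report to JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  s <- metricSummary(report)
  out <- list(
    classifier = report@config@classifier,
    n_runs = nrow(report@metrics),
    accuracy_mean = s$mean[s$metric == "accuracy"],
    accuracy_sd = s$sd[s$metric == "accuracy"],
    f1_mean = s$mean[s$metric == "f1"],
    f1_sd = s$sd[s$metric == "f1"],
    confusion = as.list(report@confusion),
    per_run = report@metrics)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", na = "null")
  invisible(path)
}
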