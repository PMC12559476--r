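# small helper: pair features from toy enzyme/substrate blocks
toyFeatures <- function(n_enz, n_sub, n_dim = 4, seed = 1) {
  set.seed(seed)
  ez <- matrix(rnorm(n_enz * n_dim), n_enz,
               dimnames = list(sprintf("e%02d", seq_len(n_enz)), NULL))
  su <- matrix(rbinom(n_sub * 3, 1, 0.5), n_sub,
               dimnames = list(sprintf("s%02d", seq_len(n_sub)), NULL))
  buildPairFeatures(ez, su)
}

test_that("F1 follows 2TP / (2TP + FP + FN)", {
  m <- t3pkskit:::.confusionMetrics(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unname(m["f1"]), 1.0)
  expect_equal(unname(m["accuracy"]), 1.0)
  m2 <- t3pkskit:::.confusionMetrics(c(TP = 3, FP = 1, FN = 2, TN = 4))
  expect_equal(unname(m2["f1"]), 2 * 3 / (2 * 3 + 1 + 2))
})

test_that("an expressive model fits a linearly separable rule exactly", {
  pf <- toyFeatures(10, 4)
  p <- attr(pf, "pairs")
  labels <- as.integer(pf[, 1] > 0)  # linear rule on one feature
  d <- pairDataset(data.frame(p, label = labels))
  for (clf in c("mlp", "random_forest")) {
    cfg <- modelConfig(clf, baseSeed = 5L)
    fit <- trainClassifier(d, pf, cfg, seed = 5L)
    pr <- predictProb(fit, pf)
    expect_equal(mean((pr >= 0.5) == (labels == 1)), 1.0)
  }
})

test_that("constant features predict the class prevalence", {
  pf <- toyFeatures(8, 4)
  pf[, ] <- 1
  p <- attr(pf, "pairs")
  set.seed(6)
  labels <- sample(c(rep(1L, 12), rep(0L, 20)))
  d <- pairDataset(data.frame(p, label = labels))
  fit <- trainClassifier(d, pf, modelConfig("decision_tree"), seed = 1L)
  pr <- predictProb(fit, pf)
  expect_true(all(abs(pr - mean(labels)) < 1e-9))
})

test_that("training is deterministic given the seed", {
  pf <- toyFeatures(8, 4)
  p <- attr(pf, "pairs")
  set.seed(7)
  d <- pairDataset(data.frame(p, label = rbinom(nrow(p), 1, 0.5)))
  for (clf in c("decision_tree", "random_forest", "mlp")) {
    cfg <- modelConfig(clf)
    p1 <- predictProb(trainClassifier(d, pf, cfg, seed = 99L), pf)
    p2 <- predictProb(trainClassifier(d, pf, cfg, seed = 99L), pf)
    expect_identical(p1, p2)
  }
})

test_that("degenerate training inputs are rejected", {
  pf <- toyFeatures(4, 3)
  p <- attr(pf, "pairs")
  d1 <- pairDataset(data.frame(p, label = 1L))
  expect_error(trainClassifier(d1, pf, modelConfig()), "single class")
  d2 <- pairDataset(data.frame(enzyme_id = "missing", substrate_id = "s01",
                               label = 1L))
  expect_error(trainClassifier(d2, pf, modelConfig()), "no feature vector")
})

test_that("cross-validation reports per-run metrics with matched seeds", {
  st <- studyFixture()
  cfg <- modelConfig("decision_tree", cvFolds = 4L, cvRepeats = 3L,
                     baseSeed = 3L)
  rep1 <- crossValidate(st$dataset, st$pairFeatures, cfg)
  m <- runMetrics(rep1)
  expect_equal(nrow(m), 12L)
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  ## summary equals recomputation from stored per-run values
  s <- metricSummary(rep1)
  expect_equal(s$mean[s$metric == "accuracy"], mean(m$accuracy))
  expect_equal(s$sd[s$metric == "f1"], stats::sd(m$f1))
  ## deterministic rerun
  rep2 <- crossValidate(st$dataset, st$pairFeatures, cfg)
  expect_identical(runMetrics(rep1), runMetrics(rep2))
  ## a class rarer than the fold count cannot be stratified
  p <- pairs(st$dataset)
  tiny <- pairDataset(rbind(head(p[p$label == 1L, ], 2),
                            head(p[p$label == 0L, ], 6)))
  expect_error(crossValidate(tiny, st$pairFeatures,
                             modelConfig(cvFolds = 5L)), "stratify")
})

test_that("a report compared with itself is never significant", {
  st <- studyFixture()
  cfg <- modelConfig("decision_tree", cvFolds = 3L, cvRepeats = 2L)
  rep1 <- crossValidate(st$dataset, st$pairFeatures, cfg)
  cmp <- compareModels(rep1, rep1)
  expect_equal(cmp$p_value, 1.0)
  expect_false(cmp$significant)
})

test_that("clearly separated per-run F1 vectors are significant", {
  mkrep <- function(f1) methods::new(
    "EvaluationReport",
    metrics = data.frame(run = 1:5, rep = 1L, fold = 1:5, seed = 1:5,
                         accuracy = f1, f1 = f1),
    confusion = c(TP = 1, FP = 0, FN = 0, TN = 1),
    config = modelConfig())
  cmp <- compareModels(mkrep(rep(0.9, 5)), mkrep(rep(0.5, 5)))
  expect_true(cmp$significant)
  expect_true(cmp$p_value < 0.05)
  ## mismatched run structure is rejected
  longer <- methods::new(
    "EvaluationReport",
    metrics = data.frame(run = 1:6, rep = 1L, fold = 1:6, seed = 1:6,
                         accuracy = 0.5, f1 = 0.5),
    confusion = c(TP = 1, FP = 0, FN = 0, TN = 1),
    config = modelConfig())
  expect_error(compareModels(mkrep(rep(0.9, 5)), longer), "run count")
})

test_that("prediction matrices are reproducible and threshold-consistent", {
  st <- studyFixture()
  cfg <- modelConfig("decision_tree", nPredictionRuns = 1L, baseSeed = 11L)
  pm1 <- predictMatrix(st$dataset, st$pairFeatures, cfg)
  pm2 <- predictMatrix(st$dataset, st$pairFeatures, cfg)
  expect_identical(probabilities(pm1), probabilities(pm2))
  expect_true(all(probabilities(pm1) >= 0 & probabilities(pm1) <= 1))
  expect_equal(binaryCalls(pm1),
               matrix(as.integer(probabilities(pm1) >= 0.5),
                      nrow(probabilities(pm1)),
                      dimnames = dimnames(probabilities(pm1))))
})

test_that("held-out enzymes from the planted rule are predicted correctly", {
  ## grow the families larger, train on a subset of enzymes, and predict
  ## the held-out members of the same families
  spec <- syntheticSpec(seed = 616, familySizes = c(8L, 13L, 6L, 12L))
  st <- syntheticStudy(spec)
  ez <- featurizeEnzymes(st$sequences)
  su <- featurizeSubstrates(st$substrates, "maccs")
  feats <- buildPairFeatures(ez, su)
  fam <- S4Vectors::mcols(st$sequences)$family
  held <- unlist(lapply(split(names(st$sequences), fam), head, 2))
  p <- pairs(st$dataset)
  train <- pairDataset(p[!p$enzyme_id %in% held, ], "synthetic")
  cfg <- modelConfig("random_forest", nPredictionRuns = 5L, baseSeed = 2L)
  pm <- predictMatrix(train, feats, cfg,
                      targetEnzymes = held,
                      targetSubstrates = st$substrates$substrate_id)
  calls <- binaryCalls(pm)
  tp <- p[p$enzyme_id %in% held, ]
  agree <- mean(calls[cbind(tp$enzyme_id, tp$substrate_id)] == tp$truth)
  expect_gte(agree, 0.9)
})

test_that("external evaluation matches resubstitution on the training set", {
  st <- studyFixture()
  cfg <- modelConfig("random_forest", nPredictionRuns = 3L, baseSeed = 9L)
  rep_ext <- evaluateExternal(st$dataset, st$dataset, st$pairFeatures, cfg)
  ## same pairs scored by the same full-data models: per-run accuracy
  ## equals resubstitution accuracy of each seeded model
  m <- runMetrics(rep_ext)
  p <- pairs(st$dataset)
  for (k in seq_len(nrow(m))) {
    fit <- trainClassifier(st$dataset, st$pairFeatures, cfg,
                           seed = m$seed[k])
    pr <- predictProb(fit, t3pkskit:::.featuresForPairs(
      st$pairFeatures, p$enzyme_id, p$substrate_id))
    expect_equal(m$accuracy[k],
                 mean(as.integer(pr >= 0.5) == p$label))
  }
})

test_that("an all-positive external set makes accuracy equal recall", {
  st <- studyFixture()
  pos <- pairs(st$dataset)[pairs(st$dataset)$label == 1L, ]
  ext <- pairDataset(pos, provenance = "external")
  cfg <- modelConfig("decision_tree", nPredictionRuns = 2L, baseSeed = 13L)
  rep_ext <- evaluateExternal(st$dataset, ext, st$pairFeatures, cfg)
  cm <- rep_ext@confusion
  expect_equal(cm[["FP"]] + cm[["TN"]], 0)
  s <- metricSummary(rep_ext)
  ## pooled accuracy equals pooled recall TP/(TP+FN)
  expect_equal((cm[["TP"]] + cm[["TN"]]) / sum(cm),
               cm[["TP"]] / (cm[["TP"]] + cm[["FN"]]))
})

test_that("feature caches with different embedders are rejected", {
  st <- studyFixture()
  f2 <- st$pairFeatures
  attr(f2, "embedder_tag") <- "prottrans-x5"
  expect_error(
    evaluateExternal(st$dataset, st$dataset,
                     list(train = st$pairFeatures, external = f2),
                     modelConfig(nPredictionRuns = 1L)),
    "embedder tag mismatch")
})

test_that("ablating substrate bits hurts a substrate-dependent rule", {
  st <- studyFixture()
  ## enzyme-only features: the substrate block is removed, so families
  ## accepting only one substrate class become indistinguishable
  ez <- st$enzymeFeatures
  ablated <- buildPairFeatures(
    ez, matrix(0L, nrow(st$substrateFeatures), 1,
               dimnames = list(rownames(st$substrateFeatures), NULL)),
    st$dataset)
  cfg <- modelConfig("random_forest", cvFolds = 5L, cvRepeats = 4L,
                     baseSeed = 19L)
  full <- crossValidate(st$dataset, st$pairFeatures, cfg)
  drop <- crossValidate(st$dataset, ablated, cfg)
  f_full <- runMetrics(full)$f1
  f_drop <- runMetrics(drop)$f1
  sep <- mean(f_full) - mean(f_drop)
  expect_gt(sep, 0)
  expect_gt(sep, 2 * max(stats::sd(f_full), stats::sd(f_drop)))
})
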