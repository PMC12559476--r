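# Shared fixtures, generated in code. The default synthetic study (31
# enzymes x 11 substrates, ~43% active) and its pair features are
# expensive enough to build once and reuse across test files.

.fixtureCache <- new.env(parent = emptyenv())

aaLetters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(L) paste(sample(aaLetters, L, TRUE),
                                   collapse = "")

mutateProtein <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aaLetters, ch[i]), 1)
  paste(ch, collapse = "")
}

# the study-shaped fixture: synthetic study + fallback/MACCS features
studyFixture <- function() {
  if (!is.null(.fixtureCache$study)) return(.fixtureCache$study)
  spec <- syntheticSpec(seed = 20260925)
  st <- syntheticStudy(spec)
  ez <- featurizeEnzymes(st$sequences)
  su <- featurizeSubstrates(st$substrates, "maccs")
  pf <- buildPairFeatures(ez, su, st$dataset)
  .fixtureCache$study <- c(st, list(spec = spec, enzymeFeatures = ez,
                                    substrateFeatures = su,
                                    pairFeatures = pf))
  .fixtureCache$study
}

# three well-separated families for SSN recovery checks
familyFixture <- function() {
  if (!is.null(.fixtureCache$fam)) return(.fixtureCache$fam)
  spec <- syntheticSpec(
    nFamilies = 3L, familySizes = c(6L, 6L, 6L),
    familyClasses = c("both", "aliphatic", "none"), seqLength = 150L,
    withinFamilyMutationRate = 0.05, betweenFamilyDivergence = 0.45,
    frozenResidues = c("40" = "C", "90" = "H", "120" = "N"),
    activityRule = list(
      motifs = list(aromatic = list(column = 60L, residues = "F"),
                    aliphatic = list(column = 75L, residues = "V")),
      substrate = list(aromatic = list(smarts = "c"),
                       aliphatic = list(smarts = "[CX4]"))),
    seed = 77L)
  .fixtureCache$fam <- list(spec = spec, seqs = generateFamilies(spec))
  .fixtureCache$fam
}

writeTempFasta <- function(seqs, path = tempfile(fileext = ".faa")) {
  writeSequences(seqs, path)
  path
}

# a small self-contained pipeline workspace on disk
pipelineWorkspace <- function(dir, seed = 303L, n_substrates = 4L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- syntheticSpec(nFamilies = 3L, familySizes = c(4L, 4L, 4L),
                        familyClasses = c("both", "aliphatic", "none"),
                        substratePanel = defaultSubstratePanel(n_substrates),
                        seed = 515L)
  st <- syntheticStudy(spec)
  paths <- list(
    sequences = file.path(dir, "seqs.faa"),
    queries = file.path(dir, "queries.faa"),
    reference = file.path(dir, "reference.faa"),
    substrates = file.path(dir, "substrates.csv"),
    pairs = file.path(dir, "pairs.csv"),
    positions = file.path(dir, "positions.tsv"))
  writeSequences(st$sequences, paths$sequences)
  writeSequences(st$sequences[c(1, 5, 9)], paths$queries)
  writeSequences(st$reference, paths$reference)
  utils::write.csv(st$substrates, paths$substrates, row.names = FALSE)
  writePairTable(st$dataset, paths$pairs, "long")
  utils::write.table(
    data.frame(ref_position = c(164L, 303L, 336L),
               label = c("cys", "his", "asn"),
               expected_residue = c("C", "H", "N")),
    paths$positions, sep = "\t", quote = FALSE, row.names = FALSE)
  config <- list(
    seed = seed,
    outdir = file.path(dir, "out"),
    inputs = paths,
    stages = list(
      mine = list(enabled = TRUE, min_identity = 0.2, min_coverage = 0.5),
      ssn = list(enabled = TRUE, cutoff = 0.8, repnode_threshold = 0.95),
      sites = list(enabled = TRUE),
      featurize = list(enabled = TRUE, embedder = "fallback-physchem",
                       fingerprint = "maccs"),
      train = list(enabled = TRUE, classifier = "decision_tree",
                   folds = 3L, repeats = 2L),
      predict = list(enabled = TRUE, runs = 3L)))
  list(config = config, study = st)
}

# a residue profile with a planted label-determining column
plantedProfile <- function(n_seq = 40, n_pos = 25, planted = 13,
                           planted2 = NULL, seed = 1) {
  set.seed(seed)
  res <- matrix(sample(c("A", "G", "S", "T"), n_seq * n_pos, TRUE),
                n_seq, n_pos,
                dimnames = list(sprintf("e%02d", 1:n_seq),
                                as.character(1:n_pos)))
  res[, 5] <- "C"  # a constant column carries no signal
  res[, planted] <- sample(c("V", "L"), n_seq, TRUE)
  lab <- as.integer(res[, planted] == "V")
  if (!is.null(planted2)) {
    res[, planted2] <- ifelse(lab == 1L, "W", "Y")  # redundant determinant
  }
  ref <- Biostrings::AAStringSet(c(ref = paste(rep("A", n_pos),
                                               collapse = "")))
  pm <- positionMap(ref, data.frame(ref_position = 1:n_pos,
                                    label = as.character(1:n_pos),
                                    expected_residue = ""))
  prof <- methods::new("ActiveSiteProfile", residues = res,
                       groups = stats::setNames(character(0), character(0)),
                       posmap = pm)
  ds <- pairDataset(data.frame(enzyme_id = rownames(res),
                               substrate_id = "sub01", label = lab),
                    provenance = "synthetic")
  list(profile = prof, dataset = ds, planted = planted,
       planted2 = planted2)
}
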