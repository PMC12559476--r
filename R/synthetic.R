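## Synthetic fixtures: homologous protein families at controlled
## divergence, a small-molecule substrate panel, and activity labels from
## a planted motif x substructure rule with configurable label noise.
## The defaults emulate the statistical shape of the experimental
## training data: 31 enzymes x 11 substrates = 341 pairs, ~43% active.

#' Default synthetic substrate panel
#'
#' Twelve small achiral carboxylic acids spanning aromatic, aliphatic and
#' branched classes (plus one deliberately inert dicarboxylic acid that
#' no planted acceptor class matches). The first eleven constitute the
#' default modelling panel.
#'
#' @param n number of substrates to return (default all 12).
#' @return a `data.frame` with columns `substrate_id`, `name`, `smiles`.
#' @export
defaultSubstratePanel <- function(n = 12L) {
  panel <- data.frame(
    substrate_id = sprintf("sub%02d", 1:12),
    name = c("benzoic acid", "4-hydroxybenzoic acid", "trans-cinnamic acid",
             "2-furoic acid", "nicotinic acid",
             "butyric acid", "hexanoic acid", "octanoic acid",
             "isovaleric acid", "trans-2-hexenoic acid",
             "cyclohexanecarboxylic acid", "oxalic acid"),
    smiles = c("c1ccccc1C(=O)O", "Oc1ccc(cc1)C(=O)O",
               "c1ccccc1/C=C/C(=O)O", "c1ccoc1C(=O)O", "c1ccncc1C(=O)O",
               "CCCC(=O)O", "CCCCCC(=O)O", "CCCCCCCC(=O)O",
               "CC(C)CC(=O)O", "CCC/C=C/C(=O)O", "C1CCCCC1C(=O)O",
               "OC(=O)C(=O)O"),
    stringsAsFactors = FALSE)
  panel[seq_len(n), , drop = FALSE]
}

#' Default planted activity rule
#'
#' Enzymes carrying `F` at reference column 197 accept aromatic
#' substrates (SMARTS `c`, any aromatic carbon); enzymes carrying `V` at
#' column 265 accept aliphatic substrates (SMARTS `[CX4]`, any sp3
#' carbon). A pair is active when either motif matches its substrate
#' class.
#'
#' @return the rule list consumed by [generateActivity()].
#' @export
defaultActivityRule <- function() {
  list(
    motifs = list(
      aromatic = list(column = 197L, residues = "F"),
      aliphatic = list(column = 265L, residues = "V")),
    substrate = list(
      aromatic = list(smarts = "c"),
      aliphatic = list(smarts = "[CX4]")))
}

#' Specify a synthetic study
#'
#' Collects every knob of the generator with defaults matching the shape
#' of the experimental dataset: 4 enzyme families of sizes 6/10/4/11
#' (31 enzymes) with acceptor classes both/aliphatic/aromatic/none, an
#' 11-substrate panel (5 aromatic, 6 aliphatic), which under the default
#' rule yields 341 pairs with 146 (42.8%) active.
#'
#' @param nFamilies number of families.
#' @param familySizes integer vector of per-family member counts.
#' @param familyClasses acceptor class per family: `"both"`,
#'   `"aliphatic"`, `"aromatic"` or `"none"`.
#' @param seqLength ancestor length (residues).
#' @param withinFamilyMutationRate per-position substitution rate from
#'   the family ancestor (0.05 gives ~90% within-family identity).
#' @param betweenFamilyDivergence per-position substitution rate of each
#'   family ancestor from the common root (0.45 gives ~30-40%
#'   between-family identity).
#' @param frozenResidues named character vector of positions never
#'   mutated, with their fixed residues (default the catalytic triad
#'   C164/H303/N336). Motif columns of the rule are frozen automatically.
#' @param substratePanel substrate `data.frame` (default the first 11 of
#'   [defaultSubstratePanel()]).
#' @param activityRule planted rule (default [defaultActivityRule()]).
#' @param labelNoiseRate probability of flipping each label (default 0).
#' @param seed mandatory integer seed; all generation is deterministic
#'   given it.
#' @return a validated spec list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nFamilies = 4L,
                          familySizes = c(6L, 10L, 4L, 11L),
                          familyClasses = c("both", "aliphatic",
                                            "aromatic", "none"),
                          seqLength = 389L,
                          withinFamilyMutationRate = 0.05,
                          betweenFamilyDivergence = 0.45,
                          frozenResidues = c("164" = "C", "303" = "H",
                                             "336" = "N"),
                          substratePanel = defaultSubstratePanel(11L),
                          activityRule = defaultActivityRule(),
                          labelNoiseRate = 0, seed) {
  if (missing(seed)) stop("syntheticSpec: a seed is mandatory")
  rates <- c(withinFamilyMutationRate, betweenFamilyDivergence,
             labelNoiseRate)
  if (any(rates < 0 | rates > 1))
    stop("syntheticSpec: rates must be fractions in [0, 1]")
  if (length(familySizes) != nFamilies || length(familyClasses) != nFamilies)
    stop("syntheticSpec: familySizes and familyClasses must have length ",
         nFamilies)
  if (!all(familyClasses %in% c("both", "aliphatic", "aromatic", "none")))
    stop("syntheticSpec: unknown family class")
  motif_cols <- vapply(activityRule$motifs, function(m)
    as.integer(m$column), integer(1))
  if (any(motif_cols > seqLength))
    stop("rule column beyond seqLength (", seqLength, "): ",
         paste(motif_cols[motif_cols > seqLength], collapse = ", "))
  if (any(as.integer(names(frozenResidues)) > seqLength))
    stop("frozen position beyond seqLength")
  structure(list(
    nFamilies = as.integer(nFamilies), familySizes = as.integer(familySizes),
    familyClasses = familyClasses, seqLength = as.integer(seqLength),
    withinFamilyMutationRate = withinFamilyMutationRate,
    betweenFamilyDivergence = betweenFamilyDivergence,
    frozenResidues = frozenResidues, substratePanel = substratePanel,
    activityRule = activityRule, labelNoiseRate = labelNoiseRate,
    seed = as.integer(seed)), class = "SyntheticSpec")
}

## substitute at `rate` per position, uniform over the 19 alternatives,
## never touching frozen positions
.mutateChars <- function(chars, rate, frozen) {
  hit <- which(stats::runif(length(chars)) < rate & !frozen)
  for (i in hit) {
    alt <- setdiff(.STANDARD_AA, chars[i])
    chars[i] <- alt[sample.int(19L, 1L)]
  }
  chars
}

#' Generate homologous protein families
#'
#' Grows `nFamilies` families from a common random root: each family
#' ancestor is the root point-mutated at `betweenFamilyDivergence`, each
#' member its ancestor point-mutated at `withinFamilyMutationRate`.
#' Frozen positions (catalytic triad and rule motif columns) are never
#' mutated; motif columns are set per the family's acceptor class.
#' Because no indels are introduced, reference numbering equals position.
#'
#' @param spec a [syntheticSpec()].
#' @return an [Biostrings::AAStringSet]; `mcols` carry `family` and
#'   `motif_class`, and `metadata(x)$reference` holds the root sequence
#'   (the synthetic numbering reference).
#' @export
generateFamilies <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, .generateFamiliesImpl(spec))
}

.generateFamiliesImpl <- function(spec) {
  L <- spec$seqLength
  frozen <- rep(FALSE, L)
  frozen_pos <- as.integer(names(spec$frozenResidues))
  frozen[frozen_pos] <- TRUE
  motif_cols <- vapply(spec$activityRule$motifs,
                       function(m) as.integer(m$column), integer(1))
  frozen[motif_cols] <- TRUE

  root <- sample(.STANDARD_AA, L, replace = TRUE)
  root[frozen_pos] <- spec$frozenResidues
  ## the root's motif columns carry non-accepting residues by convention
  for (k in seq_along(motif_cols)) {
    acc <- spec$activityRule$motifs[[k]]$residues
    root[motif_cols[k]] <- setdiff(.STANDARD_AA, acc)[1]
  }

  seqs <- character(0); fam <- character(0); cls <- character(0)
  for (f in seq_len(spec$nFamilies)) {
    anc <- .mutateChars(root, spec$betweenFamilyDivergence, frozen)
    class_f <- spec$familyClasses[f]
    for (k in seq_along(motif_cols)) {
      m <- spec$activityRule$motifs[[k]]
      accepts <- class_f == "both" || class_f == names(motif_cols)[k]
      anc[motif_cols[k]] <- if (accepts) m$residues[1] else
        setdiff(.STANDARD_AA, m$residues)[1]
    }
    for (i in seq_len(spec$familySizes[f])) {
      member <- .mutateChars(anc, spec$withinFamilyMutationRate, frozen)
      seqs <- c(seqs, paste(member, collapse = ""))
      fam <- c(fam, sprintf("F%d", f))
      cls <- c(cls, class_f)
    }
  }
  ids <- sprintf("%s_E%02d", fam, unlist(lapply(spec$familySizes, seq_len)))
  out <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(out)$family <- fam
  S4Vectors::mcols(out)$motif_class <- cls
  S4Vectors::metadata(out)$reference <- paste(root, collapse = "")
  out
}

.substrateMatches <- function(pred, smiles) {
  if (!is.null(pred$smarts)) {
    mol <- ChemmineOB::forEachMol("SMILES", smiles, identity)
    return(ChemmineOB::smartsSearch_OB(mol, pred$smarts) > 0)
  }
  if (!is.null(pred$bit)) {
    fp <- fingerprintSubstrate(smiles,
                               type = if (is.null(pred$fingerprint))
                                 "maccs" else pred$fingerprint)
    return(fp[pred$bit] == 1L)
  }
  stop("substrate predicate must specify 'smarts' or 'bit'")
}

#' Generate a planted-rule activity dataset
#'
#' Evaluates the planted motif x substructure rule for every (enzyme,
#' substrate) pair -- active when any motif the enzyme carries matches
#' the substrate's substructure class -- and flips each label
#' independently with probability `labelNoiseRate`. The noise-free rule
#' labels are kept in the `truth` column.
#'
#' @param spec a [syntheticSpec()].
#' @param sequences enzymes from [generateFamilies()] (defaults to
#'   generating them from `spec`).
#' @param substrates substrate `data.frame` (defaults to the spec panel).
#' @return a [PairDataset-class] with provenance `"synthetic"`.
#' @export
generateActivity <- function(spec, sequences = NULL, substrates = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (is.null(sequences)) sequences <- generateFamilies(spec)
  if (is.null(substrates)) substrates <- spec$substratePanel
  rule <- spec$activityRule
  motif_cols <- vapply(rule$motifs, function(m) as.integer(m$column),
                       integer(1))
  if (any(motif_cols > min(Biostrings::width(sequences))))
    stop("rule column beyond sequence length")

  chr <- as.character(sequences)
  enz_match <- do.call(cbind, lapply(rule$motifs, function(m)
    substring(chr, m$column, m$column) %in% m$residues))
  colnames(enz_match) <- names(rule$motifs)
  sub_match <- do.call(cbind, lapply(rule$substrate, function(pred)
    vapply(substrates$smiles, function(s)
      .substrateMatches(pred, s), logical(1), USE.NAMES = FALSE)))
  colnames(sub_match) <- names(rule$substrate)

  grid <- expand.grid(enzyme_id = names(sequences),
                      substrate_id = substrates$substrate_id,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$enzyme_id, grid$substrate_id), ]
  ei <- match(grid$enzyme_id, names(sequences))
  si <- match(grid$substrate_id, substrates$substrate_id)
  classes <- intersect(names(rule$motifs), colnames(sub_match))
  truth <- rep(FALSE, nrow(grid))
  for (k in classes)
    truth <- truth | (enz_match[ei, k] & sub_match[si, k])
  truth <- as.integer(truth)

  flip <- .withSeed(.mixSeed(spec$seed, 1001L),
                    stats::rbinom(length(truth), 1L, spec$labelNoiseRate))
  label <- as.integer(xor(truth, flip))
  pairDataset(data.frame(enzyme_id = grid$enzyme_id,
                         substrate_id = grid$substrate_id,
                         label = label, truth = truth),
              provenance = "synthetic")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: families, substrate panel and planted-rule
#' activity dataset in one call.
#'
#' @param spec a [syntheticSpec()].
#' @return a list with elements `sequences` ([Biostrings::AAStringSet]),
#'   `substrates` (`data.frame`), `dataset` ([PairDataset-class]) and
#'   `reference` (the synthetic numbering reference as a length-1
#'   [Biostrings::AAStringSet]).
#' @export
syntheticStudy <- function(spec) {
  sequences <- generateFamilies(spec)
  dataset <- generateActivity(spec, sequences, spec$substratePanel)
  reference <- Biostrings::AAStringSet(
    c(synthetic_ref = S4Vectors::metadata(sequences)$reference))
  list(sequences = sequences, substrates = spec$substratePanel,
       dataset = dataset, reference = reference)
}
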