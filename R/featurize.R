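## Pair feature construction: enzyme vector ++ substrate bits.

.pairKey <- function(enzyme_id, substrate_id)
  paste(enzyme_id, substrate_id, sep = "\r")

#' Build concatenated enzyme-substrate pair features
#'
#' Concatenates each pair's mean-pooled enzyme vector with its substrate
#' fingerprint bits, the representation used by the activity classifiers.
#' Pairs are ordered by enzyme id, then substrate id.
#'
#' @param enzymeFeatures matrix from [featurizeEnzymes()] (rownames
#'   enzyme ids).
#' @param substrateFeatures matrix from [featurizeSubstrates()] (rownames
#'   substrate ids).
#' @param pairs a [PairDataset-class], or a `data.frame` with columns
#'   `enzyme_id` and `substrate_id`; when omitted, the full cross product
#'   of enzymes and substrates is used.
#' @return a numeric matrix with one row per pair; `attr(x, "pairs")`
#'   holds the ordered pair table, `attr(x, "enzyme_dim")` /
#'   `attr(x, "substrate_dim")` the block sizes, and the embedder and
#'   fingerprint tags are carried through.
#' @examples
#' ez <- matrix(1:4, 2, 2, dimnames = list(c("e1", "e2"), NULL))
#' su <- matrix(0:1, 1, 2, dimnames = list("s1", NULL))
#' pf <- buildPairFeatures(ez, su)
#' dim(pf)  # 2 pairs x 4 features
#' @export
buildPairFeatures <- function(enzymeFeatures, substrateFeatures,
                              pairs = NULL) {
  if (is(pairs, "PairDataset")) pairs <- pairs@pairs
  if (is.null(pairs)) {
    pairs <- expand.grid(enzyme_id = rownames(enzymeFeatures),
                         substrate_id = rownames(substrateFeatures),
                         stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$enzyme_id, pairs$substrate_id), , drop = FALSE]
  rownames(pairs) <- NULL
  bad_e <- setdiff(unique(pairs$enzyme_id), rownames(enzymeFeatures))
  if (length(bad_e))
    stop("pair references unknown enzyme(s): ", paste(bad_e, collapse = ", "))
  bad_s <- setdiff(unique(pairs$substrate_id), rownames(substrateFeatures))
  if (length(bad_s))
    stop("pair references unknown substrate(s): ",
         paste(bad_s, collapse = ", "))
  m <- cbind(enzymeFeatures[pairs$enzyme_id, , drop = FALSE],
             substrateFeatures[pairs$substrate_id, , drop = FALSE])
  rownames(m) <- .pairKey(pairs$enzyme_id, pairs$substrate_id)
  colnames(m) <- c(paste0("E", seq_len(ncol(enzymeFeatures))),
                   paste0("S", seq_len(ncol(substrateFeatures))))
  attr(m, "pairs") <- pairs[c("enzyme_id", "substrate_id")]
  attr(m, "enzyme_dim") <- ncol(enzymeFeatures)
  attr(m, "substrate_dim") <- ncol(substrateFeatures)
  attr(m, "embedder_tag") <- attr(enzymeFeatures, "embedder_tag")
  attr(m, "fingerprint_type") <- attr(substrateFeatures, "fingerprint_type")
  m
}

.featuresForPairs <- function(features, enzyme_id, substrate_id) {
  keys <- .pairKey(enzyme_id, substrate_id)
  missing <- setdiff(keys, rownames(features))
  if (length(missing)) {
    p <- strsplit(missing[1], "\r", fixed = TRUE)[[1]]
    stop("no feature vector for pair (", p[1], ", ", p[2], ")",
         if (length(missing) > 1)
           paste0(" and ", length(missing) - 1, " more"))
  }
  features[keys, , drop = FALSE]
}
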