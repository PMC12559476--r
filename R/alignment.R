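## Alignment backends shared by the mining, ssn and active_site modules.
## Global (Needleman-Wunsch) parameters: BLOSUM62, gap open 10 / extend 1.
## Local (Smith-Waterman) parameters: BLOSUM62, gap open 11 / extend 1
## (BLAST defaults). Identity convention throughout: identical aligned
## columns / alignment length, gap columns included in the denominator.

.GLOBAL_GAP_OPEN <- 10
.LOCAL_GAP_OPEN <- 11
.GAP_EXTEND <- 1

## drop mcols before alignment (pairwiseAlignment warns otherwise)
.bareSet <- function(x) {
  if (is(x, "AAStringSet") && !is.null(S4Vectors::mcols(x)))
    S4Vectors::mcols(x) <- NULL
  x
}

.alignGlobal <- function(pattern, subject) {
  pattern <- .bareSet(pattern)
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = .GLOBAL_GAP_OPEN, gapExtension = .GAP_EXTEND)
}

.alignLocal <- function(pattern, subject) {
  pattern <- .bareSet(pattern)
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = "BLOSUM62",
    gapOpening = .LOCAL_GAP_OPEN, gapExtension = .GAP_EXTEND)
}

## identity of an alignment object: identical columns / alignment length
.alignmentIdentity <- function(aln) {
  len <- nchar(as.character(Biostrings::pattern(aln)))
  as.numeric(Biostrings::nmatch(aln)) / len
}

#' Pairwise sequence identity from a global alignment
#'
#' Aligns two amino-acid sequences globally (Needleman-Wunsch, BLOSUM62,
#' gap open 10 / extend 1) and returns the fraction of identical aligned
#' columns over the full alignment length, gap columns included in the
#' denominator. The value is symmetric and lies in `[0, 1]`.
#'
#' @param a,b single sequences: character strings, [Biostrings::AAString]
#'   objects, or length-1 [Biostrings::AAStringSet] objects.
#' @return a numeric fraction in `[0, 1]`.
#' @examples
#' pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKV")  # 0.9
#' @export
pairwiseIdentity <- function(a, b) {
  a <- .asAAString(a)
  b <- .asAAString(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("pairwiseIdentity: sequences must be non-empty")
  .alignmentIdentity(.alignGlobal(a, b))
}

.asAAString <- function(x) {
  if (is(x, "AAString")) return(x)
  if (is(x, "AAStringSet")) {
    if (length(x) != 1L)
      stop("expected a single sequence, got a set of length ", length(x))
    return(x[[1L]])
  }
  Biostrings::AAString(as.character(x))
}

#' All-vs-all identity matrix
#'
#' Computes the symmetric pairwise identity matrix of a sequence collection
#' using the same global-alignment convention as [pairwiseIdentity()].
#' Cost is quadratic in the number of sequences.
#'
#' @param seqs an [Biostrings::AAStringSet] with unique names.
#' @param prefilter skip alignment of pairs sharing fewer than
#'   `minKmerShare` of their k-mers, recording identity 0 instead. An
#'   approximation worth enabling for collections beyond a few thousand
#'   sequences: pairs dropped this way sit far below any useful network
#'   cutoff. Off by default.
#' @param k k-mer length for the prefilter (default 4).
#' @param minKmerShare minimum shared-k-mer fraction (relative to the
#'   smaller k-mer set; default 0.02).
#' @return a symmetric numeric matrix with unit diagonal, dimnames set to
#'   the sequence ids.
#' @export
identityMatrix <- function(seqs, prefilter = FALSE, k = 4L,
                           minKmerShare = 0.02) {
  stopifnot(is(seqs, "AAStringSet"))
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("identityMatrix: sequences must carry unique names")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n < 2L) return(m)
  kmers <- NULL
  if (prefilter) {
    chr <- as.character(seqs)
    kmers <- lapply(chr, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      unique(substring(s, 1:(L - k + 1L), k:L))
    })
  }
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    if (prefilter) {
      share <- vapply(js, function(j) {
        denom <- min(length(kmers[[i]]), length(kmers[[j]]))
        if (denom == 0L) 0 else
          length(intersect(kmers[[i]], kmers[[j]])) / denom
      }, numeric(1))
      js <- js[share >= minKmerShare]
      if (length(js) == 0L) next
    }
    aln <- .alignGlobal(seqs[js], seqs[[i]])
    len <- nchar(as.character(Biostrings::pattern(aln)))
    ident <- as.numeric(Biostrings::nmatch(aln)) / len
    m[i, js] <- ident
    m[js, i] <- ident
  }
  m
}
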