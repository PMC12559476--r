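## Candidate mining: local-alignment search of a proteome against a
## seed-query set, plus merge/dereplication of hit sets from several
## sources (e.g. different sequence databases).

#' Mine candidate sequences by similarity to seed queries
#'
#' Aligns every proteome sequence locally (Smith-Waterman, BLOSUM62, gap
#' open 11 / extend 1) against every query and reports each target whose
#' best alignment meets both the identity and the query-coverage
#' thresholds, once, with its best-scoring query. Identity is identical
#' aligned columns over the alignment length (gaps in the denominator);
#' query coverage is the aligned query span over the query length.
#'
#' @param queries seed-query sequences, an [Biostrings::AAStringSet] with
#'   unique names (e.g. experimentally characterised T3PKSs).
#' @param proteome target sequences to search, an
#'   [Biostrings::AAStringSet] with unique names.
#' @param minIdentity minimum identity fraction in `[0, 1]`.
#' @param minCoverage minimum query-coverage fraction in `[0, 1]`.
#' @return a `data.frame` of hits with columns `target_id`, `query_id`,
#'   `identity`, `coverage`, `score`, ordered by descending score then
#'   `target_id`.
#' @examples
#' q <- Biostrings::AAStringSet(c(q1 = "MKLVINGASFWQERTAAYGHPLMSDE"))
#' db <- Biostrings::AAStringSet(c(t1 = "MKLVINGASFWQERTAAYGHPLMSDE",
#'                                 t2 = "GGGGGGPPPPPPWWWWWWHHHHHHHH"))
#' mineCandidates(q, db, minIdentity = 0.4, minCoverage = 0.5)
#' @export
mineCandidates <- function(queries, proteome, minIdentity = 0.3,
                           minCoverage = 0.5) {
  stopifnot(is(queries, "AAStringSet"), is(proteome, "AAStringSet"))
  if (length(queries) == 0L) stop("mineCandidates: empty query collection")
  if (length(proteome) == 0L) stop("mineCandidates: empty proteome collection")
  if (minIdentity < 0 || minIdentity > 1 || minCoverage < 0 || minCoverage > 1)
    stop("mineCandidates: thresholds must be fractions in [0, 1]")
  queries <- normalizeResidues(queries)
  proteome <- normalizeResidues(proteome)
  if (is.null(names(queries)) || is.null(names(proteome)))
    stop("mineCandidates: sequences must carry names")

  nt <- length(proteome)
  best <- data.frame(
    target_id = names(proteome),
    query_id = NA_character_,
    identity = -Inf, coverage = NA_real_, score = -Inf,
    stringsAsFactors = FALSE)
  for (qi in seq_along(queries)) {
    aln <- .alignLocal(proteome, queries[[qi]])
    sc <- Biostrings::score(aln)
    len <- nchar(as.character(Biostrings::pattern(aln)))
    ident <- as.numeric(Biostrings::nmatch(aln)) / len
    qspan <- IRanges::width(Biostrings::subject(aln))
    cov <- qspan / Biostrings::width(queries[qi])
    upd <- sc > best$score
    best$query_id[upd] <- names(queries)[qi]
    best$identity[upd] <- ident[upd]
    best$coverage[upd] <- cov[upd]
    best$score[upd] <- sc[upd]
  }
  hits <- best[best$identity >= minIdentity & best$coverage >= minCoverage, ]
  hits <- hits[order(-hits$score, hits$target_id), ]
  rownames(hits) <- NULL
  hits
}

#' Merge hit sets and collapse exact duplicates
#'
#' Takes the union of several sequence collections (e.g. candidates mined
#' from different databases) and collapses records whose residue strings
#' are byte-identical to a single record. The first-seen id is kept; the
#' ids it absorbed are recorded in `mcols(x)$merged_ids` (comma-separated).
#' Dereplication here is exact-string only; collapsing near-duplicates is
#' the similarity-network module's job.
#'
#' @param hitSets a list of [Biostrings::AAStringSet] objects (or a single
#'   one).
#' @return a dereplicated [Biostrings::AAStringSet].
#' @examples
#' s <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKIV"))
#' length(mergeDereplicate(list(s, s)))  # 2
#' @export
mergeDereplicate <- function(hitSets) {
  if (is(hitSets, "AAStringSet")) hitSets <- list(hitSets)
  if (!is.list(hitSets) || length(hitSets) == 0L)
    stop("mergeDereplicate: need at least one sequence collection")
  ids <- unlist(lapply(hitSets, names), use.names = FALSE)
  seqs <- unlist(lapply(hitSets, as.character), use.names = FALSE)
  if (is.null(ids) || length(ids) != length(seqs))
    stop("mergeDereplicate: all collections must carry names")

  ## same id with different residues is a hard conflict
  byid <- split(seqs, ids)
  conflict <- names(byid)[vapply(byid, function(s)
    length(unique(s)) > 1L, logical(1))]
  if (length(conflict))
    stop("id collision with differing sequences: ",
         paste(conflict, collapse = ", "))

  first <- !duplicated(seqs)
  keep_ids <- ids[first]
  keep_seqs <- seqs[first]
  grp <- match(seqs, keep_seqs)
  merged <- vapply(seq_along(keep_seqs), function(g) {
    absorbed <- setdiff(unique(ids[grp == g]), keep_ids[g])
    paste(absorbed, collapse = ",")
  }, character(1))
  out <- Biostrings::AAStringSet(stats::setNames(keep_seqs, keep_ids))
  S4Vectors::mcols(out)$merged_ids <- merged
  out
}

#' Write a mining hit table
#'
#' Tab-separated with columns `target_id`, `query_id`, `identity`,
#' `coverage`, `score`.
#'
#' @param hits the hit `data.frame` from [mineCandidates()].
#' @param path output TSV path.
#' @export
writeHits <- function(hits, path) {
  out <- hits
  out$identity <- sprintf("%.6f", out$identity)
  out$coverage <- sprintf("%.6f", out$coverage)
  out$score <- sprintf("%.6g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
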