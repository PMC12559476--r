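## Shared parsing and writing: FASTA, metadata TSV, pair tables.

.STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AMBIGUOUS_AA <- c("B", "Z", "J", "U", "O")

#' Read protein sequences from FASTA
#'
#' Reads a multi-record amino-acid FASTA file (wrapped or unwrapped lines,
#' LF or CRLF endings) into an [Biostrings::AAStringSet]. The file is
#' structurally validated first: malformed headers and empty sequences are
#' reported with their line number, duplicate ids are an error. Residue
#' letters outside the 20 standard amino acids plus `X` are normalised to
#' `X` with a warning when they are the ambiguity letters B, Z, J, U, O
#' (or rejected when `strict = TRUE`); any other letter is always an error
#' naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param strict reject ambiguity letters instead of normalising to `X`.
#' @return an [Biostrings::AAStringSet] with record ids as names and the
#'   full header description stored in `mcols(x)$description`.
#' @seealso [writeSequences()], [normalizeResidues()]
#' @export
readSequences <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  hdr_at <- which(startsWith(lines, ">"))
  if (length(hdr_at) == 0L) stop("not a FASTA file (no '>' header): ", path)
  first_content <- match(TRUE, nzchar(trimws(lines)))
  if (first_content < hdr_at[1])
    stop("line ", first_content, ": sequence data before first header")
  rec_end <- c(hdr_at[-1] - 1L, length(lines))
  for (k in seq_along(hdr_at)) {
    i <- hdr_at[k]
    if (!nzchar(trimws(sub("^>", "", lines[i]))))
      stop("line ", i, ": malformed FASTA header (empty id)")
    body <- if (rec_end[k] > i) lines[(i + 1L):rec_end[k]] else character()
    rec_id <- strsplit(trimws(sub("^>", "", lines[i])), "\\s+")[[1]][1]
    if (!any(nzchar(trimws(body))))
      stop("line ", i, ": record '", rec_id, "' has an empty sequence")
    ## Biostrings silently drops invalid one-letter codes; reject them
    ## here so malformed residues never pass unnoticed
    bad_chars <- unique(strsplit(gsub("[A-Za-z]", "",
                                      paste(trimws(body), collapse = "")),
                                 "")[[1]])
    if (length(bad_chars))
      stop("record '", rec_id, "' contains non-amino-acid character(s): ",
           paste(bad_chars, collapse = ", "))
  }
  x <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  desc <- sub("^\\S+\\s*", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  normalizeResidues(x, strict = strict)
}

#' Normalise residue alphabets
#'
#' Restricts sequences to the 20 standard amino-acid letters plus `X`.
#' Ambiguity letters B, Z, J, U, O are replaced by `X` with a warning
#' (rejected when `strict = TRUE`); any other character is an error naming
#' the offending record. Empty sequences are rejected.
#'
#' @param seqs an [Biostrings::AAStringSet].
#' @param strict reject ambiguity letters instead of normalising.
#' @return the normalised [Biostrings::AAStringSet].
#' @export
normalizeResidues <- function(seqs, strict = FALSE) {
  stopifnot(is(seqs, "AAStringSet"))
  chr <- as.character(seqs)
  if (any(!nzchar(chr)))
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(chr)], collapse = ", "))
  allowed <- c(.STANDARD_AA, "X")
  letters_used <- lapply(strsplit(toupper(chr), ""), unique)
  bad <- vapply(letters_used, function(l)
    any(!l %in% c(allowed, .AMBIGUOUS_AA)), logical(1))
  if (any(bad)) {
    off <- letters_used[[which(bad)[1]]]
    stop("record '", names(seqs)[which(bad)[1]], "' contains non-amino-acid ",
         "character(s): ", paste(setdiff(off, c(allowed, .AMBIGUOUS_AA)),
                                 collapse = ", "))
  }
  amb <- vapply(letters_used, function(l) any(l %in% .AMBIGUOUS_AA), logical(1))
  if (any(amb)) {
    if (strict)
      stop("record '", names(seqs)[which(amb)[1]],
           "' contains ambiguity letter(s) (strict mode): ",
           paste(intersect(letters_used[[which(amb)[1]]], .AMBIGUOUS_AA),
                 collapse = ", "))
    warning("ambiguity letters (B/Z/J/U/O) normalised to X in ",
            sum(amb), " record(s)")
    chr <- toupper(chr)
    for (a in .AMBIGUOUS_AA) chr <- gsub(a, "X", chr, fixed = TRUE)
    old <- S4Vectors::mcols(seqs)
    seqs <- Biostrings::AAStringSet(stats::setNames(chr, names(seqs)))
    S4Vectors::mcols(seqs) <- old
  }
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs an [Biostrings::AAStringSet].
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @export
writeSequences <- function(seqs, path, width = 60L) {
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a per-sequence metadata table
#'
#' A TSV keyed by sequence id with arbitrary further columns (typically
#' `organism`, `genus`, `class`, `source`).
#'
#' @param path path to a tab-separated file whose first column is the
#'   sequence id (column name `id`).
#' @return a `data.frame` with one row per id.
#' @export
readMetadata <- function(path) {
  m <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"id" %in% colnames(m)) stop("metadata must have an 'id' column")
  if (anyDuplicated(m$id))
    stop("duplicate metadata id(s): ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  m
}

#' Construct a PairDataset
#'
#' @param pairs `data.frame` with columns `enzyme_id`, `substrate_id`,
#'   `label` (0/1) and optionally `truth`.
#' @param provenance dataset role tag: `"train"`, `"external"`,
#'   `"validation"` or `"synthetic"`.
#' @return a [PairDataset-class] object.
#' @export
pairDataset <- function(pairs, provenance = "train") {
  pairs$enzyme_id <- as.character(pairs$enzyme_id)
  pairs$substrate_id <- as.character(pairs$substrate_id)
  pairs$label <- as.integer(pairs$label)
  if ("truth" %in% colnames(pairs)) pairs$truth <- as.integer(pairs$truth)
  rownames(pairs) <- NULL
  methods::new("PairDataset", pairs = pairs, provenance = provenance)
}

#' Read/write enzyme-substrate pair tables
#'
#' Long format is a CSV with columns `enzyme_id`, `substrate_id`, `label`.
#' Wide format is a CSV binary matrix with enzymes in rows (first column
#' `enzyme_id`) and one column per substrate. Both are converted to a
#' [PairDataset-class] internally.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @param provenance dataset role tag.
#' @return `readPairTable()` returns a [PairDataset-class];
#'   `writePairTable()` returns the path invisibly.
#' @export
readPairTable <- function(path, format = c("long", "wide"),
                          provenance = "train") {
  format <- match.arg(format)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "long") {
    need <- c("enzyme_id", "substrate_id", "label")
    if (!all(need %in% colnames(d)))
      stop("long pair table must have columns ", paste(need, collapse = ", "))
    return(pairDataset(d[need], provenance))
  }
  if (colnames(d)[1] != "enzyme_id")
    stop("wide pair table must have 'enzyme_id' as its first column")
  long <- data.frame(
    enzyme_id = rep(d$enzyme_id, times = ncol(d) - 1L),
    substrate_id = rep(colnames(d)[-1], each = nrow(d)),
    label = as.integer(unlist(d[-1], use.names = FALSE)))
  long <- long[order(long$enzyme_id, long$substrate_id), ]
  pairDataset(long, provenance)
}

#' @rdname readPairTable
#' @param dataset a [PairDataset-class].
#' @export
writePairTable <- function(dataset, path, format = c("long", "wide")) {
  format <- match.arg(format)
  p <- pairs(dataset)
  if (format == "long") {
    utils::write.csv(p[c("enzyme_id", "substrate_id", "label")], path,
                     row.names = FALSE, quote = FALSE)
  } else {
    wide <- stats::xtabs(label ~ enzyme_id + substrate_id, data = p)
    d <- data.frame(enzyme_id = rownames(wide),
                    as.data.frame.matrix(wide), check.names = FALSE)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a substrate table
#'
#' CSV with columns `substrate_id`, `name`, `smiles` (line-notation
#' structure strings).
#'
#' @param path CSV file path.
#' @return a `data.frame`.
#' @export
readSubstrateTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate_id", "name", "smiles")
  if (!all(need %in% colnames(d)))
    stop("substrate table must have columns ", paste(need, collapse = ", "))
  d$substrate_id <- as.character(d$substrate_id)
  if (anyDuplicated(d$substrate_id)) stop("duplicate substrate_id")
  d
}
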