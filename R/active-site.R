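## Active-site residue mapping onto reference (chalcone-synthase)
## numbering, frequency logos, and catalytic-triad substitution flags.

#' Default active-site positions (MsCHS numbering)
#'
#' The conventional readout positions of the chalcone-synthase reference:
#' the catalytic triad C164/H303/N336 and the substrate- and
#' product-specificity pocket positions 197, G256 and F265.
#'
#' @return a `data.frame` with columns `ref_position`, `label`,
#'   `expected_residue` suitable for [positionMap()].
#' @export
defaultActiveSitePositions <- function() {
  data.frame(
    ref_position = c(164L, 197L, 256L, 265L, 303L, 336L),
    label = c("catalytic_cys", "pocket_197", "pocket_gly", "pocket_phe",
              "catalytic_his", "catalytic_asn"),
    expected_residue = c("C", "", "G", "F", "H", "N"),
    stringsAsFactors = FALSE)
}

#' Construct an ActiveSitePositionMap
#'
#' @param reference the reference sequence: an [Biostrings::AAStringSet]
#'   of length 1 (or a named character string). MsCHS (UniProt P30074) is
#'   the documented default reference id, supplied by the user; it is not
#'   bundled.
#' @param positions a `data.frame` with columns `ref_position`, `label`,
#'   `expected_residue`, or a TSV path with those columns. Defaults to
#'   [defaultActiveSitePositions()].
#' @return an [ActiveSitePositionMap-class] object. Positions beyond the
#'   reference length are rejected here, at construction.
#' @export
positionMap <- function(reference, positions = defaultActiveSitePositions()) {
  if (is.character(reference) && length(reference) == 1L && !is.null(names(reference)))
    reference <- Biostrings::AAStringSet(reference)
  stopifnot(is(reference, "AAStringSet"))
  if (is.character(positions)) {
    positions <- utils::read.delim(positions, sep = "\t",
                                   stringsAsFactors = FALSE)
    positions$expected_residue[is.na(positions$expected_residue)] <- ""
  }
  positions <- positions[order(positions$ref_position), ]
  positions$ref_position <- as.integer(positions$ref_position)
  rownames(positions) <- NULL
  methods::new("ActiveSitePositionMap", reference = reference,
               positions = positions)
}

#' Map a sequence onto reference-numbered positions
#'
#' Globally aligns `seq` to the reference and reads out the query
#' character aligned to each mapped reference column; `"-"` where the
#' reference position is deleted in the query. Insertions in the query
#' never shift the reference numbering, which is anchored to the
#' reference columns.
#'
#' @param seq a single sequence (character, [Biostrings::AAString], or
#'   length-1 [Biostrings::AAStringSet]).
#' @param posmap an [ActiveSitePositionMap-class].
#' @return a named character vector, names the reference positions.
#' @export
mapReferencePositions <- function(seq, posmap) {
  stopifnot(is(posmap, "ActiveSitePositionMap"))
  seq <- .asAAString(seq)
  if (length(seq) == 0L) stop("mapReferencePositions: empty sequence")
  ref <- posmap@reference[[1L]]
  aln <- .alignGlobal(seq, ref)
  qcols <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  rcols <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  refidx <- cumsum(rcols != "-")
  want <- posmap@positions$ref_position
  out <- vapply(want, function(p) {
    ## first alignment column carrying reference position p
    col <- match(p, refidx)
    qcols[col]
  }, character(1))
  names(out) <- as.character(want)
  out
}

#' Extract an ActiveSiteProfile for a sequence collection
#'
#' Runs [mapReferencePositions()] for every sequence and assembles the
#' per-sequence residue matrix.
#'
#' @param seqs an [Biostrings::AAStringSet] with unique names.
#' @param posmap an [ActiveSitePositionMap-class].
#' @param groups optional named character vector (sequence id to group,
#'   e.g. SSN cluster) used by [residueLogo()].
#' @return an [ActiveSiteProfile-class].
#' @export
activeSiteProfile <- function(seqs, posmap, groups = character()) {
  stopifnot(is(seqs, "AAStringSet"))
  if (length(seqs) == 0L) stop("activeSiteProfile: empty sequence collection")
  rows <- t(vapply(seq_along(seqs),
                   function(i) mapReferencePositions(seqs[[i]], posmap),
                   character(nrow(posmap@positions))))
  rownames(rows) <- names(seqs)
  colnames(rows) <- as.character(posmap@positions$ref_position)
  if (length(groups)) {
    groups <- stats::setNames(as.character(groups[rownames(rows)]),
                              rownames(rows))
    if (anyNA(groups)) stop("activeSiteProfile: groups missing for ",
                            paste(rownames(rows)[is.na(groups)], collapse = ", "))
  } else {
    groups <- stats::setNames(character(0), character(0))
  }
  methods::new("ActiveSiteProfile", residues = rows, groups = groups,
               posmap = posmap)
}

#' Residue frequency logo table
#'
#' Per-group, per-position frequency of every observed residue (the gap
#' symbol `"-"` participates as its own category). Frequencies at each
#' position sum to 1.
#'
#' @param profile an [ActiveSiteProfile-class].
#' @param by `"group"` to use the profile's groups (error if absent),
#'   `"all"` to pool every sequence into one group.
#' @return a `data.frame` with columns `group`, `ref_position`, `residue`,
#'   `frequency`.
#' @export
residueLogo <- function(profile, by = c("all", "group")) {
  stopifnot(is(profile, "ActiveSiteProfile"))
  by <- match.arg(by)
  r <- profile@residues
  if (nrow(r) == 0L) stop("residueLogo: empty profile")
  grp <- if (by == "group") {
    if (!length(profile@groups)) stop("residueLogo: profile has no groups")
    stats::setNames(profile@groups, rownames(r))
  } else stats::setNames(rep("all", nrow(r)), rownames(r))
  out <- do.call(rbind, lapply(split(rownames(r), grp[rownames(r)]), function(ids) {
    if (length(ids) == 0L) stop("residueLogo: empty group")
    sub <- r[ids, , drop = FALSE]
    do.call(rbind, lapply(colnames(sub), function(p) {
      tab <- table(sub[, p])
      data.frame(group = grp[[ids[1]]], ref_position = as.integer(p),
                 residue = names(tab),
                 frequency = as.numeric(tab) / length(ids))
    }))
  }))
  rownames(out) <- NULL
  out[order(out$group, out$ref_position, -out$frequency, out$residue), ]
}

#' Flag catalytic-triad substitutions
#'
#' Compares each sequence's residues at the catalytic-triad positions
#' against the expected Cys-His-Asn and reports substitutions in the
#' conventional `expected + position + observed` notation (e.g. `H303D`,
#' `N336S`); a deleted position is reported as e.g. `C164-`.
#'
#' @param profile an [ActiveSiteProfile-class] whose position map covers
#'   the triad positions.
#' @param triad named character vector: expected residue per position
#'   (names are reference positions). Default `c("164" = "C", "303" = "H",
#'   "336" = "N")`.
#' @return a named list: per sequence id, a character vector of
#'   substitution strings (empty when the triad is conserved).
#' @export
flagTriad <- function(profile, triad = c("164" = "C", "303" = "H",
                                         "336" = "N")) {
  stopifnot(is(profile, "ActiveSiteProfile"))
  r <- profile@residues
  missing_pos <- setdiff(names(triad), colnames(r))
  if (length(missing_pos))
    stop("triad position(s) not in the position map: ",
         paste(missing_pos, collapse = ", "))
  lapply(stats::setNames(rownames(r), rownames(r)), function(id) {
    obs <- r[id, names(triad)]
    sub <- obs != triad
    paste0(triad[sub], names(triad)[sub], obs[sub])
  })
}

#' Write active-site outputs
#'
#' Writes the per-sequence extraction table (`sites.tsv`, sequences x
#' positions) and the logo frequency table (`logo.tsv`).
#'
#' @param profile an [ActiveSiteProfile-class].
#' @param dir output directory.
#' @param by grouping passed to [residueLogo()].
#' @return invisibly, the paths written.
#' @export
writeActiveSites <- function(profile, dir, by = "all") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- data.frame(seq_id = rownames(profile@residues),
                      profile@residues, check.names = FALSE)
  p1 <- file.path(dir, "sites.tsv")
  utils::write.table(sites, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  logo <- residueLogo(profile, by = by)
  logo$frequency <- sprintf("%.6f", logo$frequency)
  p2 <- file.path(dir, "logo.tsv")
  utils::write.table(logo, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
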