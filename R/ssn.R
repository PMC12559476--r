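## Sequence similarity network: representative-node collapsing, identity
## edges at a cutoff, connected-component clusters.

#' Build a sequence similarity network
#'
#' Reproduces the usual SSN construction: (1) sequences whose identity to
#' an existing representative exceeds `repnodeThreshold` are collapsed
#' into that representative's node, greedily in descending-length order
#' (ties by lexicographic id), so the longest member of each repnode is
#' its representative; (2) edges connect representatives whose pairwise
#' global-alignment identity is at least `cutoff`; (3) clusters are the
#' connected components, numbered `1..K` by descending total member
#' count, ties broken by the lexicographically smallest member id.
#'
#' A new sequence joins the best-matching existing representative above
#' the threshold, or founds a new repnode. At `repnodeThreshold = 1` no
#' pair can exceed the threshold, so the network is built on the raw
#' sequences.
#'
#' @param seqs an [Biostrings::AAStringSet] with unique names.
#' @param cutoff edge identity cutoff, a fraction in (0, 1]. Typical
#'   values for T3PKS family separation are 0.57 (phylogenetic clades)
#'   and 0.80 (fine functional groups).
#' @param repnodeThreshold repnode collapsing identity threshold
#'   (default 0.95, i.e. ">95% identity" nodes).
#' @param idm optional precomputed identity matrix from
#'   [identityMatrix()]; computed when missing.
#' @param prefilter passed to [identityMatrix()]: skip alignments of
#'   pairs sharing almost no 4-mers. Off by default; worth enabling
#'   beyond a few thousand sequences.
#' @return a [SimilarityNetwork-class] object.
#' @export
buildNetwork <- function(seqs, cutoff, repnodeThreshold = 0.95,
                         idm = NULL, prefilter = FALSE) {
  stopifnot(is(seqs, "AAStringSet"))
  if (length(seqs) == 0L) stop("buildNetwork: empty sequence collection")
  if (cutoff <= 0 || cutoff > 1) stop("buildNetwork: cutoff must be in (0, 1]")
  if (repnodeThreshold <= 0 || repnodeThreshold > 1)
    stop("buildNetwork: repnodeThreshold must be in (0, 1]")
  if (cutoff > repnodeThreshold)
    warning("cutoff > repnodeThreshold: edges are finer than repnodes, ",
            "which inverts the expected regime")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("buildNetwork: sequences must carry unique names")
  if (is.null(idm)) idm <- identityMatrix(seqs, prefilter = prefilter)
  stopifnot(identical(rownames(idm), ids))

  ## greedy incremental collapsing, descending length then id
  ord <- order(-Biostrings::width(seqs), ids)
  rep_of <- character(0)                 # representative id per repnode
  assign <- stats::setNames(character(length(seqs)), ids)
  for (i in ord) {
    id <- ids[i]
    if (length(rep_of)) {
      sim <- idm[id, rep_of]
      j <- which.max(sim)
      if (sim[j] > repnodeThreshold) {
        assign[id] <- rep_of[j]
        next
      }
    }
    rep_of <- c(rep_of, id)
    assign[id] <- id
  }
  members <- split(ids, factor(assign, levels = rep_of))
  rn <- S4Vectors::DataFrame(
    rep_id = rep_of,
    members = IRanges::CharacterList(unname(members)))

  ## edges between representatives at identity >= cutoff
  edges <- data.frame(rep_a = character(), rep_b = character(),
                      identity = numeric())
  if (length(rep_of) > 1L) {
    sub <- idm[rep_of, rep_of, drop = FALSE]
    iu <- which(upper.tri(sub) & sub >= cutoff, arr.ind = TRUE)
    if (nrow(iu)) {
      edges <- data.frame(rep_a = rep_of[iu[, 1]], rep_b = rep_of[iu[, 2]],
                          identity = sub[iu])
      edges <- edges[order(edges$rep_a, edges$rep_b), ]
      rownames(edges) <- NULL
    }
  }

  ## connected components -> clusters, numbered by size then smallest member
  g <- igraph::graph_from_data_frame(
    edges[c("rep_a", "rep_b")], directed = FALSE,
    vertices = data.frame(name = rep_of))
  comp <- igraph::components(g)$membership
  comp <- comp[rep_of]
  msize <- lengths(members)
  comp_members <- split(names(assign), comp[assign[names(assign)]])
  csize <- vapply(split(msize, comp), sum, numeric(1))
  cmin <- vapply(comp_members, function(m) min(m), character(1))
  corder <- order(-csize, cmin[names(csize)])
  newid <- stats::setNames(seq_along(corder), names(csize)[corder])
  clusters <- data.frame(rep_id = rep_of,
                         cluster_id = as.integer(newid[as.character(comp)]))
  rownames(clusters) <- NULL

  methods::new("SimilarityNetwork", repnodes = rn, edges = edges,
               clusters = clusters, cutoff = cutoff,
               repnodeThreshold = repnodeThreshold)
}

#' Per-cluster taxon composition
#'
#' Tallies the members of every cluster by a metadata attribute (genus,
#' class, ...) and flags clusters whose members all share one value.
#' Member ids missing from the metadata are counted as `"unknown"`.
#'
#' @param network a [SimilarityNetwork-class].
#' @param metadata either a named character vector mapping member id to a
#'   taxon value, or a metadata `data.frame` from [readMetadata()]
#'   together with `column`.
#' @param column metadata column to tally when `metadata` is a data frame.
#' @return a `data.frame` with columns `cluster_id`, `taxon`, `count`,
#'   `monotaxon`; counts within a cluster sum to its member count.
#' @export
clusterComposition <- function(network, metadata, column = "genus") {
  stopifnot(is(network, "SimilarityNetwork"))
  if (is.data.frame(metadata)) {
    if (!column %in% colnames(metadata))
      stop("metadata has no column '", column, "'")
    metadata <- stats::setNames(as.character(metadata[[column]]), metadata$id)
  }
  rn <- network@repnodes
  cl <- network@clusters
  cluster_of_rep <- stats::setNames(cl$cluster_id, cl$rep_id)
  rows <- lapply(seq_len(nrow(rn)), function(i) {
    data.frame(member = rn$members[[i]],
               cluster_id = cluster_of_rep[[rn$rep_id[i]]])
  })
  d <- do.call(rbind, rows)
  tax <- metadata[d$member]
  tax[is.na(tax)] <- "unknown"
  tab <- as.data.frame(table(cluster_id = d$cluster_id, taxon = tax),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  tab$cluster_id <- as.integer(tab$cluster_id)
  names(tab)[names(tab) == "Freq"] <- "count"
  mono <- tapply(tab$taxon, tab$cluster_id, function(x) length(unique(x)) == 1L)
  tab$monotaxon <- unname(mono[as.character(tab$cluster_id)])
  tab <- tab[order(tab$cluster_id, -tab$count, tab$taxon), ]
  rownames(tab) <- NULL
  tab
}

#' Export a similarity network
#'
#' Writes three files into `dir`: `edges.tsv` (rep_a, rep_b, identity),
#' `nodes.tsv` (rep_id, member_count, cluster_id, plus any metadata
#' columns for the representative), and `network.graphml` for network
#' viewers such as Cytoscape.
#'
#' @param network a [SimilarityNetwork-class].
#' @param dir output directory (created if needed).
#' @param metadata optional metadata `data.frame` from [readMetadata()].
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(network, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ed <- network@edges
  ed$identity <- sprintf("%.6f", ed$identity)
  edge_path <- file.path(dir, "edges.tsv")
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  rn <- network@repnodes
  nodes <- data.frame(rep_id = rn$rep_id,
                      member_count = lengths(rn$members),
                      cluster_id = network@clusters$cluster_id[
                        match(rn$rep_id, network@clusters$rep_id)])
  if (!is.null(metadata)) {
    extra <- metadata[match(nodes$rep_id, metadata$id),
                      setdiff(colnames(metadata), "id"), drop = FALSE]
    nodes <- cbind(nodes, extra)
  }
  node_path <- file.path(dir, "nodes.tsv")
  utils::write.table(nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  g <- igraph::graph_from_data_frame(
    network@edges, directed = FALSE,
    vertices = nodes)
  gml_path <- file.path(dir, "network.graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edge_path, node_path, gml_path))
}
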