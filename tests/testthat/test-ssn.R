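test_that("pairwise identity follows the gaps-in-denominator convention", {
  expect_equal(pairwiseIdentity("MKLV", "MKLV"), 1.0)
  ## 9 identical of 10 aligned columns, no gaps
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  expect_error(pairwiseIdentity("", "MKLV"), "non-empty")
})

test_that("pairwise identity agrees with the DP oracle, reverse included", {
  set.seed(21)
  for (k in 1:25) {
    L <- sample(10:50, 1)
    a <- randomProtein(L)
    b <- mutateProtein(a, runif(1, 0.05, 0.45))
    o <- oracleGlobal(a, b)
    expect_equal(pairwiseIdentity(a, b), o$identity)
    expect_equal(pairwiseIdentity(b, a), o$identity)  # symmetry
  }
  ## a sequence against its own reversal (equal composition): co-optimal
  ## alignments of such pairs can differ in identity, so the unambiguous
  ## check is that the alignment the identity is read from is optimal
  a <- randomProtein(30)
  rv <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  aln <- t3pkskit:::.alignGlobal(Biostrings::AAString(a),
                                 Biostrings::AAString(rv))
  expect_equal(Biostrings::score(aln), oracleGlobal(a, rv)$score)
  expect_true(pairwiseIdentity(a, rv) >= 0 && pairwiseIdentity(a, rv) <= 1)
})

test_that("dissimilar sequences give singleton repnodes and clusters", {
  set.seed(22)
  seqs <- Biostrings::AAStringSet(
    stats::setNames(replicate(5, randomProtein(60)), paste0("s", 1:5)))
  net <- buildNetwork(seqs, cutoff = 0.8)
  expect_equal(nrow(repnodes(net)), 5L)
  expect_equal(nrow(networkEdges(net)), 0L)
  expect_equal(sort(unique(clusterTable(net)$cluster_id)), 1:5)
})

test_that("byte-identical sequences collapse into one repnode", {
  seqs <- Biostrings::AAStringSet(c(a = "MKLVINGAWQER", b = "MKLVINGAWQER"))
  net <- buildNetwork(seqs, cutoff = 0.8)
  expect_equal(nrow(repnodes(net)), 1L)
  expect_setequal(repnodes(net)$members[[1]], c("a", "b"))
  ## representative is the longest member, tie broken lexicographically
  expect_equal(repnodes(net)$rep_id, "a")
})

test_that("synthetic families are recovered as clusters at cutoff 0.8", {
  fam <- familyFixture()
  net <- buildNetwork(fam$seqs, cutoff = 0.8)
  cl <- clusterTable(net)
  rn <- repnodes(net)
  member_cluster <- do.call(rbind, lapply(seq_len(nrow(rn)), function(i)
    data.frame(id = rn$members[[i]],
               cluster = cl$cluster_id[cl$rep_id == rn$rep_id[i]])))
  fam_of <- S4Vectors::mcols(fam$seqs)$family[
    match(member_cluster$id, names(fam$seqs))]
  expect_equal(length(unique(member_cluster$cluster)), 3L)
  ## cluster labels are a bijection of family labels
  expect_true(all(table(fam_of, member_cluster$cluster) %in%
                    c(0L, 6L)))
})

test_that("raising the cutoff only splits clusters (monotone refinement)", {
  fam <- familyFixture()
  idm <- identityMatrix(fam$seqs)
  cuts <- c(0.5, 0.57, 0.8, 0.95)
  nets <- lapply(cuts, function(ct)
    buildNetwork(fam$seqs, ct, idm = idm))
  sizes <- vapply(nets, function(n)
    length(unique(clusterTable(n)$cluster_id)), integer(1))
  expect_false(is.unsorted(sizes))  # cluster count non-decreasing
  for (k in seq_len(length(nets) - 1)) {
    coarse <- nets[[k]]; fine <- nets[[k + 1]]
    cc <- stats::setNames(clusterTable(coarse)$cluster_id,
                          clusterTable(coarse)$rep_id)
    cf <- stats::setNames(clusterTable(fine)$cluster_id,
                          clusterTable(fine)$rep_id)
    ## every fine cluster maps into exactly one coarse cluster
    agree <- tapply(cc[names(cf)], cf, function(x) length(unique(x)))
    expect_true(all(agree == 1L))
  }
})

test_that("repnode threshold 1 reproduces the raw-sequence network", {
  fam <- familyFixture()
  seqs <- fam$seqs[c(1:3, 7:9)]
  idm <- identityMatrix(seqs)
  net <- buildNetwork(seqs, 0.8, repnodeThreshold = 1.0, idm = idm)
  expect_equal(nrow(repnodes(net)), length(seqs))
  ## edges equal thresholded identity matrix entries
  expected_edges <- sum(idm[upper.tri(idm)] >= 0.8)
  expect_equal(nrow(networkEdges(net)), expected_edges)
  expect_true(all(networkEdges(net)$identity >= networkCutoff(net)))
})

test_that("cutoff coarser than the repnode threshold warns", {
  seqs <- Biostrings::AAStringSet(c(a = "MKLVINGAWQER", b = "MKLVINGAWQEK"))
  expect_warning(buildNetwork(seqs, cutoff = 0.99,
                              repnodeThreshold = 0.5), "regime")
})

test_that("cluster composition tallies taxa and conserves counts", {
  fam <- familyFixture()
  net <- buildNetwork(fam$seqs, cutoff = 0.8)
  genus <- stats::setNames(
    c(rep("Aspergillus", 6), rep("Fusarium", 3), rep("Neurospora", 3),
      rep("Penicillium", 6)),
    names(fam$seqs))
  comp <- clusterComposition(net, genus)
  ## per-cluster tallies sum to member counts
  rn <- repnodes(net)
  cl <- clusterTable(net)
  msize <- tapply(lengths(rn$members),
                  cl$cluster_id[match(rn$rep_id, cl$rep_id)], sum)
  tsize <- tapply(comp$count, comp$cluster_id, sum)
  expect_equal(as.numeric(tsize[names(msize)]), as.numeric(msize))
  ## the all-Aspergillus family is monogeneric, the split one is not
  mono <- tapply(comp$monotaxon, comp$cluster_id, unique)
  n_taxa <- tapply(comp$taxon, comp$cluster_id, function(x)
    length(unique(x)))
  expect_equal(unname(mono), unname(n_taxa == 1L))
  expect_true(any(comp$monotaxon) && !all(comp$monotaxon))
  ## ids without metadata count as unknown
  comp2 <- clusterComposition(net, genus[1:10])
  expect_true("unknown" %in% comp2$taxon)
})

test_that("network export round-trips and is Cytoscape-loadable", {
  fam <- familyFixture()
  net <- buildNetwork(fam$seqs[1:9], cutoff = 0.8)
  d <- file.path(tempdir(), "ssn-export")
  paths <- writeNetwork(net, d)
  ed <- utils::read.delim(file.path(d, "edges.tsv"))
  expect_equal(nrow(ed), nrow(networkEdges(net)))
  expect_equal(ed$identity, as.numeric(sprintf("%.6f",
                                               networkEdges(net)$identity)))
  nd <- utils::read.delim(file.path(d, "nodes.tsv"))
  expect_setequal(nd$rep_id, repnodes(net)$rep_id)
  g <- igraph::read_graph(file.path(d, "network.graphml"),
                          format = "graphml")
  expect_equal(igraph::vcount(g), nrow(repnodes(net)))
  expect_equal(igraph::ecount(g), nrow(networkEdges(net)))
})

test_that("the k-mer prefilter preserves all above-cutoff edges", {
  fam <- familyFixture()
  full <- buildNetwork(fam$seqs, cutoff = 0.8)
  fast <- buildNetwork(fam$seqs, cutoff = 0.8, prefilter = TRUE)
  expect_equal(networkEdges(fast), networkEdges(full))
  expect_equal(clusterTable(fast), clusterTable(full))
  ## the prefilter only zeroes pairs, never raises identities
  idm_full <- identityMatrix(fam$seqs)
  idm_fast <- identityMatrix(fam$seqs, prefilter = TRUE)
  expect_true(all(idm_fast <= idm_full + 1e-12))
})
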