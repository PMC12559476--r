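test_that("a verbatim query is recovered at identity and coverage 1", {
  set.seed(11)
  q <- Biostrings::AAStringSet(c(q1 = randomProtein(80)))
  prot <- Biostrings::AAStringSet(c(t1 = as.character(q[[1]]),
                                    t2 = randomProtein(120)))
  hits <- mineCandidates(q, prot, minIdentity = 0.9, minCoverage = 0.9)
  expect_equal(hits$target_id, "t1")
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
})

test_that("unrelated proteomes yield no hits and match a local DP oracle", {
  set.seed(12)
  q <- Biostrings::AAStringSet(c(q1 = randomProtein(40)))
  prot <- Biostrings::AAStringSet(
    stats::setNames(replicate(20, randomProtein(120)),
                    sprintf("t%02d", 1:20)))
  ## random local alignments are short: no target covers half the query
  ## at 40% identity, confirmed below by the brute-force oracle
  expect_equal(nrow(mineCandidates(q, prot, minIdentity = 0.4,
                                   minCoverage = 0.5)), 0L)
  ## the unfiltered best alignments agree with the brute-force
  ## Smith-Waterman oracle
  all_hits <- mineCandidates(q, prot, minIdentity = 0, minCoverage = 0)
  expect_equal(nrow(all_hits), 20L)
  for (t in all_hits$target_id[1:5]) {
    o <- oracleLocal(as.character(prot[[t]]), as.character(q[[1]]))
    expect_equal(all_hits$score[all_hits$target_id == t], o$score)
  }
  ## oracle agrees that no alignment passes both thresholds
  passes <- vapply(names(prot), function(t) {
    o <- oracleLocal(as.character(prot[[t]]), as.character(q[[1]]))
    hit <- all_hits[all_hits$target_id == t, ]
    o$identity >= 0.4 && hit$coverage >= 0.5
  }, logical(1))
  expect_false(any(passes))
})

test_that("each target reports only its best-scoring query", {
  set.seed(13)
  target <- randomProtein(100)
  q_exact <- substr(target, 10, 70)          # strong match
  set.seed(14)
  q_weak <- mutateProtein(q_exact, 0.4)      # weaker match
  qs <- Biostrings::AAStringSet(c(strong = q_exact, weak = q_weak))
  prot <- Biostrings::AAStringSet(c(t1 = target))
  single <- vapply(c("strong", "weak"), function(qn)
    mineCandidates(qs[qn], prot, 0, 0)$score, numeric(1))
  combined <- mineCandidates(qs, prot, 0, 0)
  expect_equal(nrow(combined), 1L)
  expect_equal(combined$query_id, names(which.max(single)))
  expect_equal(combined$score, max(single))
})

test_that("raising thresholds never adds hits and self-mining is total", {
  fam <- familyFixture()
  prot <- fam$seqs[1:8]
  q <- fam$seqs[1]
  loose <- mineCandidates(q, prot, minIdentity = 0.2, minCoverage = 0.2)
  tight_i <- mineCandidates(q, prot, minIdentity = 0.6, minCoverage = 0.2)
  tight_c <- mineCandidates(q, prot, minIdentity = 0.2, minCoverage = 0.9)
  expect_true(all(tight_i$target_id %in% loose$target_id))
  expect_true(all(tight_c$target_id %in% loose$target_id))

  self <- mineCandidates(prot, prot, minIdentity = 1, minCoverage = 1)
  expect_setequal(self$target_id, names(prot))
  expect_true(all(self$identity == 1))
})

test_that("hits are ordered by descending score then target id", {
  fam <- familyFixture()
  hits <- mineCandidates(fam$seqs[1], fam$seqs, 0, 0)
  expect_false(is.unsorted(rev(hits$score)))
  ties <- split(hits$target_id, hits$score)
  expect_true(all(vapply(ties, function(x) !is.unsorted(x), logical(1))))
})

test_that("empty collections and bad thresholds are rejected", {
  s <- Biostrings::AAStringSet(c(a = "MKLV"))
  empty <- Biostrings::AAStringSet()
  expect_error(mineCandidates(empty, s), "empty query")
  expect_error(mineCandidates(s, empty), "empty proteome")
  expect_error(mineCandidates(s, s, minIdentity = 1.2), "thresholds")
})

test_that("dereplication collapses exact duplicates only", {
  s1 <- Biostrings::AAStringSet(c(a = "MKLVINGA", b = "MKIVINGA"))
  s2 <- Biostrings::AAStringSet(c(b2 = "MKIVINGA", c = "WWLVINGA"))

  ## idempotence on a duplicated collection
  expect_equal(as.character(mergeDereplicate(list(s1, s1))),
               as.character(s1))

  ## {a,b} + {b,c} with b byte-identical -> 3 records, merged id recorded
  m <- mergeDereplicate(list(s1, s2))
  expect_equal(length(m), 3L)
  expect_equal(names(m), c("a", "b", "c"))
  expect_equal(S4Vectors::mcols(m)$merged_ids[2], "b2")

  ## order-insensitivity up to the first-seen tie-break
  m2 <- mergeDereplicate(list(s2, s1))
  expect_setequal(unname(as.character(m)), unname(as.character(m2)))

  ## id collision with differing sequences errors, naming the id
  bad <- Biostrings::AAStringSet(c(a = "YYYY"))
  expect_error(mergeDereplicate(list(s1, bad)), "id collision.*a")
})

test_that("dereplicating 100 records with 10 duplicates keeps 90", {
  set.seed(15)
  base <- replicate(90, randomProtein(30))
  seqs <- c(base, base[1:10])
  names(seqs) <- sprintf("r%03d", seq_along(seqs))
  out <- mergeDereplicate(Biostrings::AAStringSet(seqs))
  expect_equal(length(out), 90L)
  expect_equal(length(unique(as.character(out))), 90L)
})
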