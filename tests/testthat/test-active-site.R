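test_that("position maps reject positions beyond the reference", {
  ref <- Biostrings::AAStringSet(c(ref = "MKLVINGAWQER"))
  pos <- data.frame(ref_position = c(3L, 20L), label = c("a", "b"),
                    expected_residue = c("L", ""))
  expect_error(positionMap(ref, pos), "beyond reference length")
  pm <- positionMap(ref, pos[1, ])
  expect_s4_class(pm, "ActiveSitePositionMap")
})

test_that("the reference maps onto itself at every position", {
  set.seed(31)
  refseq <- randomProtein(120)
  ref <- Biostrings::AAStringSet(c(ref = refseq))
  pos <- data.frame(ref_position = c(10L, 40L, 80L, 120L),
                    label = paste0("p", 1:4), expected_residue = "")
  pm <- positionMap(ref, pos)
  got <- mapReferencePositions(refseq, pm)
  want <- strsplit(refseq, "")[[1]][pos$ref_position]
  expect_equal(unname(got), want)
  expect_equal(names(got), as.character(pos$ref_position))
})

test_that("insertions in the query never shift reference numbering", {
  set.seed(32)
  refseq <- randomProtein(100)
  ref <- Biostrings::AAStringSet(c(ref = refseq))
  pm <- positionMap(ref, data.frame(ref_position = c(5L, 50L, 99L),
                                    label = c("a", "b", "c"),
                                    expected_residue = ""))
  ## five residues prepended: extraction unchanged
  ins <- paste0("WWWWW", refseq)
  expect_equal(mapReferencePositions(ins, pm),
               mapReferencePositions(refseq, pm))
  ## internal insertion after position 20: positions 50/99 unchanged
  ins2 <- paste0(substr(refseq, 1, 20), "GGGGG", substr(refseq, 21, 100))
  expect_equal(mapReferencePositions(ins2, pm),
               mapReferencePositions(refseq, pm))
})

test_that("a deleted reference position reads as the gap symbol", {
  set.seed(33)
  refseq <- randomProtein(80)
  ref <- Biostrings::AAStringSet(c(ref = refseq))
  pm <- positionMap(ref, data.frame(ref_position = c(10L, 40L),
                                    label = c("a", "b"),
                                    expected_residue = ""))
  ## delete positions 8..12 (containing mapped position 10)
  del <- paste0(substr(refseq, 1, 7), substr(refseq, 13, 80))
  got <- mapReferencePositions(del, pm)
  expect_equal(unname(got["10"]), "-")
  expect_equal(unname(got["40"]), substr(refseq, 40, 40))
})

test_that("residue logos are per-position probability distributions", {
  ## 10 members: 3 x A and 7 x G at the second position
  res <- cbind(rep("C", 10), c(rep("A", 3), rep("G", 7)))
  rownames(res) <- sprintf("e%02d", 1:10)
  colnames(res) <- c("164", "256")
  ref <- Biostrings::AAStringSet(c(ref = randomProtein(300)))
  pm <- positionMap(ref, data.frame(ref_position = c(164L, 256L),
                                    label = c("cys", "gly"),
                                    expected_residue = c("C", "G")))
  prof <- methods::new("ActiveSiteProfile", residues = res,
                       groups = stats::setNames(character(0), character(0)),
                       posmap = pm)
  logo <- residueLogo(prof)
  expect_equal(logo$frequency[logo$ref_position == 164 &
                                logo$residue == "C"], 1.0)
  expect_equal(sort(logo$frequency[logo$ref_position == 256]),
               c(0.3, 0.7))
  sums <- tapply(logo$frequency, logo$ref_position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  ## two members split 50/50
  res2 <- matrix(c("F", "V"), 2, 1,
                 dimnames = list(c("a", "b"), "265"))
  pm2 <- positionMap(ref, data.frame(ref_position = 265L, label = "phe",
                                     expected_residue = "F"))
  prof2 <- methods::new("ActiveSiteProfile", residues = res2,
                        groups = stats::setNames(character(0), character(0)),
                        posmap = pm2)
  logo2 <- residueLogo(prof2)
  expect_equal(logo2$frequency, c(0.5, 0.5))
})

test_that("triad substitutions are flagged in standard notation", {
  set.seed(34)
  refseq <- strsplit(randomProtein(389), "")[[1]]
  refseq[c(164, 303, 336)] <- c("C", "H", "N")
  refstr <- paste(refseq, collapse = "")
  ref <- Biostrings::AAStringSet(c(ref = refstr))
  pm <- positionMap(ref)

  conserved <- refstr
  sub <- refseq; sub[303] <- "D"; sub[336] <- "S"
  substituted <- paste(sub, collapse = "")
  gapped <- paste(refseq[-(160:170)], collapse = "")  # deletes C164

  prof <- activeSiteProfile(Biostrings::AAStringSet(
    c(ok = conserved, mut = substituted, del = gapped)), pm)
  flags <- flagTriad(prof)
  expect_equal(flags$ok, character(0))
  expect_equal(flags$mut, c("H303D", "N336S"))
  expect_true("C164-" %in% flags$del)
})

test_that("frozen-triad synthetic families all pass the triad check", {
  st <- studyFixture()
  pm <- positionMap(st$reference,
                    data.frame(ref_position = c(164L, 303L, 336L),
                               label = c("cys", "his", "asn"),
                               expected_residue = c("C", "H", "N")))
  prof <- activeSiteProfile(st$sequences, pm)
  flags <- flagTriad(prof)
  expect_true(all(lengths(flags) == 0L))
})

test_that("active-site outputs are written and re-readable", {
  st <- studyFixture()
  pm <- positionMap(st$reference,
                    data.frame(ref_position = c(164L, 197L),
                               label = c("cys", "pocket"),
                               expected_residue = c("C", "")))
  prof <- activeSiteProfile(st$sequences[1:5], pm)
  d <- file.path(tempdir(), "sites-out")
  writeActiveSites(prof, d)
  tab <- utils::read.delim(file.path(d, "sites.tsv"),
                           check.names = FALSE)
  expect_equal(tab$seq_id, names(st$sequences[1:5]))
  expect_equal(colnames(tab), c("seq_id", "164", "197"))
})
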