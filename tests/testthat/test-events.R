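test_that("same-region reproduces the printed NF1 interval pattern", {
  # starred squid pair: 87-residue overlap of the shorter 85-residue hit
  expect_true(sameRegion(c(1523, 1609), c(1572, 1656)))
  # unstarred nautilus hit vs starred one: disjoint regions
  expect_false(sameRegion(c(35, 318), c(1597, 1919)))
  expect_true(sameRegion(c(10, 20), c(10, 20)))
  expect_error(sameRegion(c(20, 10), c(1, 5)), "degenerate")
})

test_that("same-region is symmetric and reflexive on random intervals", {
  set.seed(801)
  for (i in 1:50) {
    a <- sort(sample.int(500, 2)); b <- sort(sample.int(500, 2))
    expect_identical(sameRegion(a, b), sameRegion(b, a))
    expect_true(sameRegion(a, a))
  }
})

test_that("interval mapping through a homologue alignment handles gaps", {
  # identical homologues: the mapping is the identity
  aln <- list(human = "MKVLITGAGA", fly = "MKVLITGAGA")
  expect_equal(mapToCommonFrame(c(3, 7), aln), c(3, 7))
  # a 4-column insertion in the fly before the interval shifts it down
  aln2 <- list(human = "----MKVLITGAGA", fly = "WWWWMKVLITGAGA")
  expect_equal(mapToCommonFrame(c(5, 8), aln2), c(1, 4))
  # an interval entirely opposite human gaps is unmappable
  expect_warning(r <- mapToCommonFrame(c(1, 4), aln2), "unmappable")
  expect_true(all(is.na(r)))
  # endpoints opposite gaps slide inward
  aln3 <- list(human = "MK--LI", fly = "MKVVLI")
  expect_equal(mapToCommonFrame(c(3, 6), aln3), c(3, 4))
})

test_that("indel-free synthetic homologue pairs map as the identity", {
  set.seed(802)
  for (i in 1:10) {
    anc <- randomAA(120)
    a <- evolveProtein(anc, 0.25)
    b <- evolveProtein(anc, 0.25)
    g <- globalAlign(a, b)
    iv <- sort(sample.int(120, 2))
    expect_equal(mapToCommonFrame(iv, list(human = g$a, fly = g$b)), iv)
  }
})

test_that("window conservation measures identity inside the interval", {
  a <- "MKVLITGAGAMKVLITGAGA"
  expect_equal(windowConservation(a, a, c(1, 20)), 1.0)
  b <- paste0("MKVLITGAGA", "WWWWWWWWWW")   # second half fully diverged
  expect_equal(windowConservation(a, b, c(1, 10)), 1.0)
  expect_equal(windowConservation(a, b, c(11, 20),
                                  aln = list(human = a, fly = b)), 0.0)
  expect_error(windowConservation(a, b, c(10, 5)), "degenerate")
})

test_that("near-identical contigs are not called duplications", {
  set.seed(803)
  p <- randomAA(80)
  ref <- Biostrings::AAStringSet(stats::setNames(p, "HSA_F1"))
  fly <- Biostrings::AAStringSet(stats::setNames(evolveProtein(p, 0.5),
                                                 "DME_F1"))
  dnaA <- reverseTranslate(p)
  dnaB <- dnaA
  substr(dnaB, 10, 12) <- "AAA"   # ~99% identical: same transcript
  contigs <- Biostrings::DNAStringSet(c(c1 = dnaA, c2 = dnaB))
  asg <- data.frame(contig_id = c("c1", "c2"), subject_id = "HSA_F1",
                    origin = "human", bits = c(100, 99),
                    evalue = c(1e-40, 1e-39), sstart = 1L, send = 80L,
                    stringsAsFactors = FALSE)
  hm <- data.frame(human_protein_id = "HSA_F1", fly_protein_id = "DME_F1",
                   family_id = "F1", stringsAsFactors = FALSE)
  out <- detectDuplications(asg, contigs, hm, ref, fly,
                            species = "squid")
  expect_equal(nrow(out), 0L)
  # a genuinely diverged pair is reported, with same-region evidence
  dnaC <- reverseTranslate(cephoscope:::.mutateExact(p, 16))   # 80% identity
  contigs2 <- Biostrings::DNAStringSet(c(c1 = dnaA, c3 = dnaC))
  asg$contig_id <- c("c1", "c3")
  out2 <- detectDuplications(asg, contigs2, hm, ref, fly,
                             species = "squid")
  expect_equal(nrow(out2), 1L)
  expect_false(out2$dual_origin)
  expect_true(out2$same_region)
  expect_lt(out2$max_pairwise_identity, 0.95)
})

test_that("planted events are recovered with correct evidence end to end", {
  d <- sharedDataset()
  run <- sharedRun()
  ev <- truthEvents(d)
  m <- scoreDetection(run$duplications, run$selections, ev)
  expect_gte(m$sensitivity[m$kind == "duplication"], 2 / 3)
  expect_gte(m$precision[m$kind == "duplication"], 0.9)
  expect_gte(m$sensitivity[m$kind == "selection"], 2 / 3)
  expect_gte(m$precision[m$kind == "selection"], 0.9)
  # every emitted candidate satisfies its invariants
  if (nrow(run$duplications)) {
    expect_true(all(run$duplications$max_pairwise_identity < 0.95))
    lens <- Biostrings::width(c(nautilusContigs(d), squidContigs(d)))
    names(lens) <- c(names(nautilusContigs(d)), names(squidContigs(d)))
    for (ids in strsplit(run$duplications$contig_ids, ";"))
      expect_true(all(lens[ids] > 100))
  }
  if (nrow(run$selections)) {
    expect_true(all(run$selections$nautilus_origin !=
                    run$selections$squid_origin))
    expect_true(all(run$selections$window_identity < 0.60))
    expect_true(all(run$selections$overlap_fraction >= 0.4))
  }
  # conserved decoy families are rejected by the conservation filter
  consFams <- ev$family_id[ev$event_kind == "conserved_decoy"]
  expect_false(any(run$selections$family_id %in% consFams))
  # selection orientation matches the planted truth
  sel <- run$selections
  for (k in seq_len(nrow(sel))) {
    tr <- ev[ev$family_id == sel$family_id[k] &
             ev$event_kind == "selection", ]
    if (!nrow(tr)) next
    org <- strsplit(tr$origins, ";")[[1]]   # nautilus;squid
    expect_equal(sel$nautilus_origin[k], org[1])
    expect_equal(sel$squid_origin[k], org[2])
  }
})
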