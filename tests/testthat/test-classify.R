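test_that("eye protein selection by keyword substring and by flag", {
  gm <- data.frame(protein_id = c("P1", "P2", "P3"),
                   go_id = c("G1", "G2", "G3"),
                   go_name = c("lens development", "ribosome biogenesis",
                               "Photoreceptor maintenance"),
                   eye_flag = c(TRUE, FALSE, FALSE))
  expect_equal(selectEyeProteins(gm, c("lens", "photoreceptor")),
               c("P1", "P3"))   # case-insensitive substring
  expect_equal(selectEyeProteins(gm), "P1")   # flag mode
  expect_error(selectEyeProteins(gm, character(0)), "non-empty")
  gm$eye_flag <- NULL
  expect_error(selectEyeProteins(gm), "eye_flag")
})

test_that("raw eye contigs require a qualifying hit to an eye protein", {
  h <- rbind(mkHits("c1", "EYE1", 1e-20), mkHits("c2", "OTHER", 1e-20),
             mkHits("c3", "EYE1", 1e-6))
  expect_equal(rawEyeContigs(h, "EYE1"), "c1")
  expect_equal(rawEyeContigs(h, "EYE1", eCutoff = 1e-3), c("c1", "c3"))
  expect_error(rawEyeContigs(h, character(0)), "non-empty")
})

test_that("QC drops contigs whose whole-proteome best hit is not eye", {
  # c1: best hit (50 bits) is a non-eye protein, eye hit only 30 bits
  h <- rbind(mkHits("c1", "EYE1", 1e-12), mkHits("c1", "BUSY", 1e-20),
             mkHits("c2", "EYE2", 1e-25))
  h$bits <- c(30, 50, 60)
  qc <- qcBestHits(h, rawSet = c("c1", "c2"), eyeProteins = c("EYE1", "EYE2"))
  expect_false(qc$qc_pass[qc$contig_id == "c1"])
  expect_true(qc$qc_pass[qc$contig_id == "c2"])
  expect_equal(qc$subject_id[qc$contig_id == "c1"], "BUSY")
  # strict mode additionally requires best hit == best eye hit
  h2 <- rbind(mkHits("c3", "EYE1", 1e-30), mkHits("c3", "EYE2", 1e-20))
  h2$bits <- c(80, 40)
  strict <- qcBestHits(h2, "c3", c("EYE1", "EYE2"), strict = TRUE)
  expect_true(strict$qc_pass)
})

test_that("synthetic eye truth is recovered and decoys rejected end to end", {
  d <- sharedDataset()
  run <- sharedRun()
  gm <- goMap(d)
  hm <- homologueMap(d)
  eye <- selectEyeProteins(gm)
  # the selected set is exactly the proteins of eye-flagged families
  eyeFams <- unique(gm$protein_id[gm$eye_flag])
  expect_setequal(eye, eyeFams)

  tbl <- run$eye
  raw <- tbl$contig_id
  final <- tbl$contig_id[tbl$qc_pass]
  allIds <- c(names(nautilusContigs(d)), names(squidContigs(d)))
  expect_true(all(final %in% raw))
  expect_true(all(raw %in% allIds))

  ev <- truthEvents(d)
  decoys <- ev$contig_ids[ev$event_kind == "qc_decoy"]
  expect_true(all(decoys %in% raw))          # decoys do hit eye proteins
  expect_false(any(decoys %in% final))       # but fail best-hit QC
  # contigs of eye families are retained
  fam <- cephoscope:::.famLookup(hm)
  tc <- truthContigs(d)
  eyeFamIds <- unique(fam[eyeFams])
  trueEye <- tc$contig_id[tc$family_id %in% eyeFamIds &
                          tc$role == "ortholog"]
  expect_gte(mean(trueEye %in% final), 0.95)
})
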