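test_that("protein evolution respects the substitution probability", {
  expect_equal(evolveProtein("MKV", 0), "MKV")
  set.seed(301)
  one <- evolveProtein("M", 1)
  expect_true(nchar(one) == 1 && one != "M")
  expect_error(evolveProtein("MKB", 0.1), "non-amino-acid")
  # binomial check: fraction changed over 100 replicates of length 1000
  base <- paste(rep("A", 1000), collapse = "")
  fr <- vapply(1:100, function(i) {
    x <- strsplit(evolveProtein(base, 0.2), "")[[1]]
    mean(x != "A")
  }, numeric(1))
  sdPool <- sqrt(0.2 * 0.8 / (1000 * 100))
  expect_lt(abs(mean(fr) - 0.2), 3 * sdPool)
  expect_true(all(abs(fr - 0.2) < 5 * sqrt(0.2 * 0.8 / 1000)))
})

test_that("planted selection windows are non-conserved and tracked", {
  set.seed(302)
  cfg <- SimulationConfig()
  for (i in 1:10) {
    L <- sample(80:200, 1)
    anc <- randomAA(L)
    human <- evolveProtein(anc, 0.3)
    fly <- evolveProtein(anc, 0.3)
    ps <- plantSelectionEvent(human, fly, cfg)
    w <- ps$window
    idw <- mean(strsplit(substring(ps$human, w[1], w[2]), "")[[1]] !=
                strsplit(substring(ps$fly, w[1], w[2]), "")[[1]])
    expect_gte(idw, 0.70)   # window identity <= 0.30
    expect_true(all(c(ps$nautOrigin, ps$squidOrigin) %in% c("human", "fly")))
    expect_false(ps$nautOrigin == ps$squidOrigin)
  }
  # zero window noise: the tracking copy equals its reference window exactly
  cfg0 <- SimulationConfig(pWindowBias = 0)
  ps <- plantSelectionEvent(randomAA(100), randomAA(100), cfg0)
  w <- ps$window
  ref <- if (ps$squidOrigin == "human") ps$human else ps$fly
  expect_identical(substring(ps$squid, w[1], w[2]),
                   substring(ref, w[1], w[2]))
})

test_that("planted duplications respect their identity intervals", {
  set.seed(303)
  cfg <- SimulationConfig()
  for (i in 1:10) {
    L <- sample(80:300, 1)
    anc <- randomAA(L)
    human <- evolveProtein(anc, 0.3)
    fly <- evolveProtein(anc, 0.3)
    nd <- plantDuplication(human, fly, cfg, dualOrigin = FALSE)
    expect_gte(nd$identity, 0.70)
    expect_lte(nd$identity, 0.90)
    expect_equal(nd$origins[1], nd$origins[2])
    dd <- plantDuplication(human, fly, cfg, dualOrigin = TRUE)
    expect_lt(dd$identity, 0.95)
    expect_setequal(dd$origins, c("human", "fly"))
  }
})

test_that("coverage simulation is degenerate at sigma zero and boosts work", {
  set.seed(304)
  cfg0 <- SimulationConfig(coverageMu = log(50), coverageSigma = 0)
  cov <- simulateCoverage(c("c1", "c2"), c(300, 600), c("none", "none"), cfg0)
  expect_true(all(cov$aligned_bases / cov$contig_length == 50))
  cfg <- SimulationConfig()
  cov2 <- simulateCoverage(paste0("c", 1:200), rep(300, 200),
                           rep(c("nautilus", "none"), 100), cfg)
  wide <- merge(cov2[cov2$sample == "nautilus", ],
                cov2[cov2$sample == "squid", ], by = "contig_id")
  boosted <- wide$contig_id %in% paste0("c", seq(1, 199, 2))
  ratio <- wide$aligned_bases.x / wide$aligned_bases.y
  # boost factor >= 2.5 by construction; small correlated sample noise
  expect_gt(mean(ratio[boosted] > 2), 0.9)
  expect_gt(stats::median(ratio[boosted]), 2.5)
  expect_lt(mean(ratio[!boosted] > 2), 0.05)
})

test_that("dataset generation is deterministic and honors the config", {
  cfg <- smallConfig(seed = 99)
  d1 <- generateDataset(cfg)
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  writeSyntheticData(d1, t1)
  writeSyntheticData(generateDataset(cfg), t2)
  for (f in list.files(t1))
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)), label = f)
  expect_true(validObject(d1))
  expect_equal(nrow(homologueMap(d1)), 60L)
  expect_true(all(Biostrings::width(c(nautilusContigs(d1),
                                      squidContigs(d1))) > 100))
  # GO terms are shared across a family's copies via its two proteins
  gm <- goMap(d1)
  hm <- homologueMap(d1)
  for (k in sample.int(nrow(hm), 5)) {
    th <- sort(gm$go_id[gm$protein_id == hm$human_protein_id[k]])
    tf <- sort(gm$go_id[gm$protein_id == hm$fly_protein_id[k]])
    expect_identical(th, tf)
  }
})

test_that("planted-pair identities land in their intervals across seeds", {
  for (s in 401:410) {
    d <- generateDataset(SimulationConfig(
      nFamilies = 12, nDuplications = 3, nDualOriginDuplications = 1,
      nSelectionEvents = 0, nQcDecoys = 0, nConservedDecoys = 0, seed = s))
    ev <- truthEvents(d)
    cs <- c(nautilusContigs(d), squidContigs(d))
    tr <- function(dna) {
      x <- sixFrameTranslate(as.character(dna))
      x$segment[x$frame == 1 & x$aa_start == 1][1]
    }
    for (k in seq_len(nrow(ev))) {
      ids <- strsplit(ev$contig_ids[k], ";")[[1]]
      idy <- cephoscope:::.seqIdentity(tr(cs[[ids[1]]]), tr(cs[[ids[2]]]))
      if (ev$event_kind[k] == "duplication") {
        expect_gte(idy, 0.70); expect_lte(idy, 0.90)
      } else {
        expect_lt(idy, 0.95)
      }
    }
  }
})

test_that("detection scoring implements the set-matching conventions", {
  truth <- data.frame(
    family_id = c("F1", "F2"), event_kind = c("duplication", "selection"),
    species = c("squid", NA), contig_ids = c("a;b", "n1;s1"),
    origins = c("human;human", "human;fly"),
    window_start = NA, window_end = NA)
  dup <- data.frame(contig_ids = "b;a", dual_origin = FALSE)
  sel <- data.frame(nautilus_contig = "n1", squid_contig = "s1")
  m <- scoreDetection(dup, sel, truth)
  expect_equal(m$sensitivity[m$kind == "duplication"], 1)
  expect_equal(m$precision[m$kind == "selection"], 1)
  # empty candidates: sensitivity 0, precision 1 by convention, warned
  expect_warning(
    scoreDetection(NULL, NULL, truth[truth$event_kind == "duplication", ]),
    "precision")
  m0 <- suppressWarnings(scoreDetection(NULL, NULL, truth))
  expect_equal(m0$sensitivity[m0$kind == "duplication"], 0)
  expect_equal(m0$precision[m0$kind == "duplication"], 1)
  # one spurious extra among 10 true
  truth10 <- data.frame(
    family_id = paste0("F", 1:10), event_kind = "duplication", species = "x",
    contig_ids = paste0("a", 1:10, ";b", 1:10), origins = "human;human",
    window_start = NA, window_end = NA)
  cand <- data.frame(contig_ids = c(truth10$contig_ids, "z1;z2"),
                     dual_origin = FALSE)
  m10 <- suppressWarnings(scoreDetection(cand, NULL, truth10))
  expect_equal(m10$precision[m10$kind == "duplication"], 10 / 11)
  expect_equal(m10$sensitivity[m10$kind == "duplication"], 1)
})
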