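test_that("local alignment scores match the BLOSUM62 examples", {
  r <- localAlign("MKV", "MKV")
  expect_equal(r$score, 14)         # 5 + 5 + 4 on the diagonal
  expect_equal(r$identity, 1.0)
  expect_equal(c(r$qstart, r$qend, r$sstart, r$send), c(1, 3, 1, 3))
  expect_equal(localAlign("MKV", "WWW")$score, 0)
  expect_error(localAlign("", "MKV"), "non-empty")
  expect_error(localAlign("MK1", "MKV"), "alphabet")
})

test_that("dynamic program equals the brute-force enumeration oracle", {
  set.seed(202)
  for (i in 1:60) {
    a <- randomAA(sample.int(12, 1))
    b <- randomAA(sample.int(12, 1))
    expect_equal(localAlign(a, b)$score, cephoscope:::bruteLocalScore(a, b),
                 info = paste(a, b))
  }
})

test_that("local alignment is symmetric and monotone under extension", {
  set.seed(203)
  for (i in 1:25) {
    a <- randomAA(sample(3:10, 1))
    b <- randomAA(sample(3:10, 1))
    expect_equal(localAlign(a, b)$score, localAlign(b, a)$score)
    ext <- paste0(a, randomAA(3))
    expect_gte(localAlign(ext, b)$score, localAlign(a, b)$score)
  }
})

test_that("tie-breaks pick the smallest subject start, then query start", {
  # "KK" against "AKKA": both K's align at subject 2-3 uniquely; against
  # "KKKK" several optima exist and the first subject window must win
  r <- localAlign("KK", "KKKK")
  expect_equal(c(r$sstart, r$send), c(1, 2))
  r2 <- localAlign("AKA", "KKK")   # single-residue optima tie everywhere
  expect_equal(c(r2$sstart, r2$qstart), c(1, 2))
})

test_that("bit scores and e-values follow the Karlin-Altschul formulas", {
  r <- bitScoreEvalue(100, 300, 1e5)
  expect_equal(r$bit, (0.267 * 100 - log(0.041)) / log(2), tolerance = 1e-12)
  expect_equal(r$bit, 43.13, tolerance = 1e-3)
  # with lambda = ln 2 and K = 1, bit == raw: bit 10 at m = n = 100
  s <- ScoringScheme(lambda = log(2), K = 1)
  expect_equal(bitScoreEvalue(10, 100, 100, s)$evalue, 10000 / 1024,
               tolerance = 1e-12)
  expect_equal(bitScoreEvalue(0, 100, 100, s)$evalue, 100 * 100)
  expect_error(bitScoreEvalue(10, 0, 100), "positive")
})

test_that("six-frame translation follows the genetic code and splits stops", {
  x <- sixFrameTranslate("ATGAAA")
  expect_equal(x$segment[x$frame == 1], "MK")
  y <- sixFrameTranslate("TTTCAT")   # reverse complement is ATGAAA
  expect_equal(y$segment[y$frame == -1], "MK")
  z <- sixFrameTranslate("ATGTAAATG")
  expect_equal(z$segment[z$frame == 1], c("M", "M"))
  expect_equal(z$nt_start[z$frame == 1], c(1, 7))
  expect_equal(nrow(sixFrameTranslate("AT")), 0L)
  n <- sixFrameTranslate("ATGNNN")
  expect_equal(n$segment[n$frame == 1], "MX")
  expect_error(sixFrameTranslate("ACGU"), "non-ACGTN")
})

test_that("reverse translation uses synonymous codons and round-trips", {
  expect_equal(reverseTranslate("M"), "ATG")
  set.seed(204)
  expect_true(reverseTranslate("MK") %in% c("ATGAAA", "ATGAAG"))
  for (i in 1:100) {
    p <- randomAA(sample(10:60, 1))
    dna <- reverseTranslate(p)
    expect_equal(nchar(dna), 3 * nchar(p))
    tr <- sixFrameTranslate(dna)
    expect_equal(tr$segment[tr$frame == 1 & tr$aa_start == 1][1], p)
  }
  expect_error(reverseTranslate("MKZ"), "invalid residue")
})

test_that("trimming a contig to a hit recovers the translated fragment", {
  set.seed(205)
  p <- randomAA(40)
  dna <- reverseTranslate(p)
  full <- trimToHit(dna, list(frame = 1, qstart = 1, qend = 120))
  expect_equal(full, p)
  frag <- trimToHit(dna, list(frame = 1, qstart = 13, qend = 30))
  expect_equal(frag, substring(p, 5, 10))   # codons 5-10, 6 residues
  expect_error(trimToHit(dna, list(frame = 1, qstart = 2, qend = 9)),
               "codon-aligned")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  expect_equal(trimToHit(rc, list(frame = -1, qstart = 1, qend = 120)), p)
})

test_that("contig identity reflects shared sequence, not alignment islands", {
  set.seed(206)
  p <- randomAA(60)
  a <- reverseTranslate(p)
  b <- a
  substr(b, 10, 12) <- "AAA"
  substr(b, 40, 41) <- "CC"
  expect_gt(contigIdentity(a, b), 0.95)
  # unrelated sequences must not look near-identical via a short island
  q <- randomAA(60)
  expect_lt(contigIdentity(a, reverseTranslate(q)), 0.6)
})
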