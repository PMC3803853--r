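test_that("pairwise distances match the correction formulas", {
  expect_equal(pairwiseDistance("MKV", "MKV"), 0)
  expect_equal(pairwiseDistance("MKV", "MKV", kimura = FALSE), 0)
  p1 <- alignedPairWithD(0.1)
  expect_equal(pairwiseDistance(p1$a, p1$b, kimura = FALSE), 0.1)
  expect_equal(pairwiseDistance(p1$a, p1$b), -log(1 - 0.1 - 0.2 * 0.01),
               tolerance = 1e-12)
  expect_lt(abs(pairwiseDistance(p1$a, p1$b) - 0.10758), 1e-5)
  p5 <- alignedPairWithD(0.5)
  expect_lt(abs(pairwiseDistance(p5$a, p5$b) - 0.79851), 1e-5)
  p9 <- alignedPairWithD(0.9)
  expect_error(pairwiseDistance(p9$a, p9$b), "0.85")
  # gapped columns are excluded
  expect_equal(pairwiseDistance("MK-V", "MKAV"), 0)
  expect_error(pairwiseDistance("---", "MKV"), "zero compared")
  expect_error(pairwiseDistance("MK", "MKV"), "equal length")
})

test_that("neighbor joining solves the three-leaf worked example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  expect_s3_class(tr, "phylo")
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
  expect_equal(leafDistance(tr, "A", "C"), 4)
  expect_equal(leafDistance(tr, "A", "A"), 0)
  expect_error(leafDistance(tr, "A", "Z"), "unknown leaf")
  expect_error(neighborJoining(d[1:2, 1:2]), "at least 3")
  dbad <- d; dbad[1, 2] <- 99
  expect_error(neighborJoining(dbad), "symmetric")
})

test_that("additive matrices are reconstructed exactly", {
  set.seed(901)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, br = stats::runif)
    d <- stats::cophenetic(tr0)
    d <- d[order(rownames(d)), order(colnames(d))]
    tr <- neighborJoining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
    cm <- stats::cophenetic(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(cm - d)), 1e-9)
    # tree path length equals the input matrix entry (additivity)
    expect_equal(leafDistance(tr, rownames(d)[1], rownames(d)[2]),
                 d[1, 2], tolerance = 1e-9)
  }
})

test_that("our NJ agrees with the ape reference implementation", {
  set.seed(902)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    d <- stats::cophenetic(ape::rtree(n, br = stats::runif))
    t1 <- neighborJoining(d)
    t2 <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(t1, ape::unroot(t2))), 0)
  }
})

test_that("equidistant matrices resolve deterministically", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- neighborJoining(d)
  t2 <- neighborJoining(d)
  expect_identical(writeNewick(t1), writeNewick(t2))
})

test_that("negative branch estimates are clamped with the deficit moved", {
  d <- matrix(c(0, 1, 2, 1, 0, 4, 2, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # three-point formulas give A the branch (1 + 2 - 4) / 2 = -0.5
  expect_message(tr <- neighborJoining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
  # the deficit moves to the sibling, so the total length is preserved
  expect_equal(sum(tr$edge.length), (1 + 2 + 4) / 2, tolerance = 1e-9)
})

test_that("newick and PHYLIP writers emit parseable output", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  s <- writeNewick(tr)
  back <- ape::read.tree(text = s)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  expect_equal(sort(back$edge.length), c(1, 1, 3))
  tf <- withr::local_tempfile(fileext = ".phy")
  writePhylip(d, tf)
  lines <- readLines(tf)
  expect_equal(length(lines), 4L)
  expect_equal(as.integer(trimws(lines[1])), 3L)
})

test_that("candidate trees cluster contigs with their seeding reference", {
  set.seed(903)
  anc <- randomAA(150)
  human <- evolveProtein(anc, 0.3)
  fly <- evolveProtein(anc, 0.3)
  a <- evolveProtein(human, 0.15)   # human-seeded copy
  b <- evolveProtein(fly, 0.15)     # fly-seeded copy
  tr <- candidateTree(c(cA = a, cB = b, HSA = human, DME = fly))
  expect_true(splitsWith(tr, c("cA", "HSA")))
  expect_true(splitsWith(tr, c("cB", "DME")))
  expect_false(splitsWith(tr, c("cA", "DME")))
})
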