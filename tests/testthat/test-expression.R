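covTable <- function(nBases, sBases, len = 100) {
  n <- length(nBases)
  data.frame(contig_id = rep(paste0("c", seq_len(n)), 2),
             sample = rep(c("nautilus", "squid"), each = n),
             aligned_bases = c(nBases, sBases),
             contig_length = rep(len, 2 * n))
}

test_that("normalized coverage preserves mass and matches the arithmetic", {
  # equal sample totals: normalization factor 1, coverage = bases / length
  cov <- covTable(c(1000, 500), c(500, 1000))
  nn <- normalizedCoverage(cov)
  expect_equal(nn$normalized_coverage, nn$coverage)
  expect_equal(nn$normalized_coverage[1], 10)
  # rescaling one sample's counts leaves cross-sample ratios unchanged
  cov2 <- cov
  dbl <- cov2$sample == "nautilus"
  cov2$aligned_bases[dbl] <- cov2$aligned_bases[dbl] * 2
  n2 <- normalizedCoverage(cov2)
  r1 <- nn$normalized_coverage[1] / nn$normalized_coverage[3]
  r2 <- n2$normalized_coverage[1] / n2$normalized_coverage[3]
  expect_equal(r1, r2, tolerance = 1e-12)
  # total normalized mass is equal across samples
  tot <- tapply(n2$normalized_coverage * n2$contig_length, n2$sample, sum)
  expect_equal(unname(tot[1]), unname(tot[2]))
  expect_error(normalizedCoverage(covTable(c(0, 0), c(1, 1))), "zero total")
  expect_error(normalizedCoverage(cov[cov$sample == "squid", ]),
               "both samples")
})

test_that("candidate selection applies the >=10 and strictly >2-fold rules", {
  # equal sample totals (6900 each) keep the normalization factor at 1
  cov <- covTable(c(3000, 2000, 900, 1000), c(1000, 1000, 300, 4600))
  sel <- selectCandidates(normalizedCoverage(cov))
  expect_equal(sel$nautilus, "c1")   # 30 vs 10: in
  # c2 is exactly 2-fold (20 vs 10): in neither; c3 fails min coverage
  expect_false(any(c("c2", "c3") %in% c(sel$nautilus, sel$squid)))
  expect_equal(sel$squid, "c4")      # 46 vs 10
  expect_length(intersect(sel$nautilus, sel$squid), 0)
})

test_that("selection is invariant under global rescaling and 0-fills gaps", {
  set.seed(601)
  cov <- covTable(sample(500:5000, 30), sample(500:5000, 30))
  s1 <- selectCandidates(normalizedCoverage(cov))
  cov2 <- cov
  cov2$aligned_bases <- cov2$aligned_bases * 7
  s2 <- selectCandidates(normalizedCoverage(cov2))
  expect_identical(s1$nautilus, s2$nautilus)
  expect_identical(s1$squid, s2$squid)
  expect_length(intersect(s1$nautilus, s1$squid), 0)
  # a contig missing from one sample counts as zero coverage there
  cov3 <- rbind(cov, data.frame(contig_id = "only", sample = "nautilus",
                                aligned_bases = 5000, contig_length = 100))
  s3 <- selectCandidates(normalizedCoverage(cov3))
  expect_true("only" %in% s3$nautilus)
})

test_that("the expression filter recovers planted differential contigs", {
  d <- sharedDataset()
  run <- sharedRun()
  tc <- truthContigs(d)
  selOf <- stats::setNames(run$expression$table$selected_sample,
                           run$expression$table$contig_id)
  got <- unname(selOf[tc$contig_id]); got[is.na(got)] <- "none"
  planted <- tc$direction != "none"
  expect_gte(mean(got[planted] == tc$direction[planted]), 0.9)
  expect_lte(mean(got[!planted] != "none"), 0.05)
})
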