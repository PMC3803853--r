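## Normalized average coverage and selection of adequately expressed,
## differentially expressed contigs. The study design has one sample per
## species, so no dispersion model is fit: expression is represented as
## per-base coverage rescaled by sequencing depth, and selection uses the
## coverage >= 10 and strictly-more-than-2-fold rules.

#' Normalized average coverage per contig per sample
#'
#' Raw coverage is \code{aligned_bases / contig_length}; the normalized
#' value rescales sample s by \code{mean(totals) / total_s}, where totals
#' are each sample's summed aligned bases. Total normalized mass is thus
#' preserved across samples, and cross-sample coverage ratios are
#' invariant under rescaling the aligned-base counts of either sample.
#'
#' @param coverage data.frame with columns \code{contig_id, sample,
#'   aligned_bases, contig_length}
#' @return the same table with raw \code{coverage} and
#'   \code{normalized_coverage} columns appended
#' @export
normalizedCoverage <- function(coverage) {
  need <- c("contig_id", "sample", "aligned_bases", "contig_length")
  miss <- setdiff(need, names(coverage))
  if (length(miss))
    stop("missing coverage column(s): ", paste(miss, collapse = ", "))
  samples <- unique(coverage$sample)
  if (length(samples) < 2L)
    stop("both samples must be present, got: ",
         paste(samples, collapse = ", "))
  if (any(coverage$contig_length <= 0)) stop("contig_length must be > 0")
  totals <- tapply(coverage$aligned_bases, coverage$sample, sum)
  if (any(totals == 0))
    stop("zero total aligned bases in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  fac <- stats::setNames(as.numeric(mean(totals) / totals), names(totals))
  coverage$coverage <- coverage$aligned_bases / coverage$contig_length
  coverage$normalized_coverage <-
    coverage$coverage * unname(fac[coverage$sample])
  coverage
}

#' Select up-regulated contigs per sample
#'
#' A contig enters sample A's set iff its normalized coverage there is at
#' least \code{minCov} ("10 or more", non-strict) and strictly exceeds
#' \code{fold} times its coverage in the other sample ("more than two
#' times", strict) -- so an exactly 2-fold contig is selected in neither
#' set, and the two sets are disjoint by construction. A contig absent
#' from one sample is treated as coverage 0 there.
#'
#' @param normalized output of \code{\link{normalizedCoverage}}
#' @param minCov minimum normalized coverage (inclusive)
#' @param fold fold-change threshold (exclusive)
#' @return list with the per-sample up-regulated id vectors (named by
#'   sample) and \code{table}, the wide per-contig table with a
#'   \code{selected_sample} column ("none" when unselected)
#' @export
selectCandidates <- function(normalized, minCov = 10, fold = 2) {
  if (!"normalized_coverage" %in% names(normalized))
    stop("input must come from normalizedCoverage()")
  samples <- sort(unique(normalized$sample))
  if (length(samples) != 2L) stop("exactly two samples expected")
  ids <- unique(normalized$contig_id)
  getcov <- function(s) {
    v <- stats::setNames(rep(0, length(ids)), ids)
    sub <- normalized[normalized$sample == s, ]
    v[sub$contig_id] <- sub$normalized_coverage
    v
  }
  cA <- getcov(samples[1])
  cB <- getcov(samples[2])
  upA <- cA >= minCov & cA > fold * cB
  upB <- cB >= minCov & cB > fold * cA
  sel <- ifelse(upA, samples[1], ifelse(upB, samples[2], "none"))
  tab <- data.frame(contig_id = ids, stringsAsFactors = FALSE)
  tab[[samples[1]]] <- unname(cA)
  tab[[samples[2]]] <- unname(cB)
  tab$selected_sample <- unname(sel)
  out <- list(ids[upA], ids[upB], tab)
  names(out) <- c(samples, "table")
  out
}
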