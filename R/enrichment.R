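## Homology transfer of GO annotations and Fisher/FDR term enrichment
## between the two species' up-regulated contig sets. Annotations are used
## flat (no GO-graph propagation).

#' Transfer GO annotations to contigs by homology
#'
#' A contig inherits the union of GO terms of every subject it hits at
#' e-value at most \code{eCutoff}; contigs with no qualifying hit stay
#' unannotated.
#'
#' @param hits a hit table from \code{\link{searchContigs}}
#' @param goMap protein-to-GO table (\code{protein_id, go_id, go_name,
#'   eye_flag})
#' @param eCutoff annotation-transfer e-value cutoff
#' @return data.frame \code{contig_id, go_id, go_name, eye_flag}, one row
#'   per contig-term pair
#' @export
transferAnnotations <- function(hits, goMap, eCutoff = 1e-10) {
  q <- hits[hits$evalue <= eCutoff, c("contig_id", "subject_id")]
  m <- merge(q, goMap, by.x = "subject_id", by.y = "protein_id")
  m <- unique(m[, c("contig_id", "go_id", "go_name", "eye_flag")])
  m <- m[order(m$contig_id, m$go_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' One-sided Fisher's exact test for term over-representation
#'
#' Hypergeometric upper-tail probability \code{P[X >= a]} with the table
#' margins fixed, for the 2x2 table (a = term-and-test, b =
#' term-and-reference, c = non-term-and-test, d = non-term-and-reference).
#'
#' @param a,b,c,d non-negative integer cell counts
#' @return the one-sided p-value (1 for the all-zero table)
#' @examples
#' fisherTerm(5, 0, 0, 5)  # 1 / choose(10, 5)
#' @export
fisherTerm <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up rule \code{q_(i) = min over j >= i of p_(j) * m / j}, clipped at
#' 1 and mapped back to input order.
#'
#' @param p p-values in [0, 1]
#' @return q-values, same length and order
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' GO term enrichment between two contig sets
#'
#' For each GO term annotated in either set, builds the 2x2 table over
#' annotated contigs and tests the direction with the higher test-set
#' frequency one-sidedly ("over" = over-represented in the test set,
#' "under" = over-represented in the reference set); q-values are BH
#' across terms. Swapping the sets turns "over" into "under" with
#' identical p-values.
#'
#' @param testSet,refSet disjoint contig id vectors
#' @param contigGo contig annotation table from
#'   \code{\link{transferAnnotations}}
#' @param alpha FDR significance level
#' @return data.frame \code{go_id, a, b, c, d, direction, p, q,
#'   significant}, ordered by q then go_id; empty (with a warning) when a
#'   set has no annotated contig
#' @export
enrichGO <- function(testSet, refSet, contigGo, alpha = 0.05) {
  if (length(intersect(testSet, refSet)))
    stop("test and reference sets must be disjoint")
  ann <- contigGo[contigGo$contig_id %in% c(testSet, refSet), , drop = FALSE]
  nTest <- length(intersect(testSet, unique(ann$contig_id)))
  nRef <- length(intersect(refSet, unique(ann$contig_id)))
  empty <- data.frame(go_id = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), direction = character(),
                      p = numeric(), q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (nTest == 0L || nRef == 0L) {
    warning("a set has zero annotated contigs; returning no results")
    return(empty)
  }
  terms <- sort(unique(ann$go_id))
  rows <- lapply(terms, function(g) {
    withTerm <- unique(ann$contig_id[ann$go_id == g])
    a <- length(intersect(withTerm, testSet))
    b <- length(intersect(withTerm, refSet))
    cc <- nTest - a
    d <- nRef - b
    over <- a / nTest >= b / nRef
    p <- if (over) fisherTerm(a, b, cc, d) else fisherTerm(b, a, d, cc)
    data.frame(go_id = g, a = a, b = b, c = cc, d = d,
               direction = if (over) "over" else "under", p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhFdr(res$p)
  res$significant <- res$q <= alpha
  res <- res[order(res$q, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
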