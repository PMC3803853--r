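## Eye-related contig extraction: GO-term-selected reference proteins, raw
## eye contigs by qualifying hit, and whole-proteome best-hit quality
## control assigning each retained contig a human-best or fly-best origin.

#' Select eye-related reference proteins
#'
#' With synthetic annotations (an \code{eye_flag} column and no term list)
#' a protein is eye-related iff any of its terms carries the flag. With a
#' term list, matching is case-insensitive substring search on term names,
#' emulating keyword selection such as "eye", "lens", "retina",
#' "photoreceptor".
#'
#' @param goMap protein-to-GO table
#' @param termList optional character vector of keywords; must be
#'   non-empty when given
#' @return character vector of eye-related protein ids
#' @export
selectEyeProteins <- function(goMap, termList = NULL) {
  if (!is.null(termList)) {
    if (!length(termList)) stop("term list must be non-empty")
    pat <- tolower(termList)
    hit <- vapply(tolower(goMap$go_name), function(nm)
      any(vapply(pat, function(p) grepl(p, nm, fixed = TRUE), logical(1))),
      logical(1))
  } else {
    if (!"eye_flag" %in% names(goMap))
      stop("goMap has no eye_flag column; supply a term list")
    hit <- goMap$eye_flag
  }
  sort(unique(goMap$protein_id[hit]))
}

#' Raw eye-related contigs
#'
#' Contigs with at least one qualifying hit (e-value at most
#' \code{eCutoff}) to an eye-related protein of either organism.
#'
#' @param hits a hit table
#' @param eyeProteins eye-related protein ids
#' @param eCutoff e-value cutoff
#' @return character vector of contig ids
#' @export
rawEyeContigs <- function(hits, eyeProteins, eCutoff = 1e-10) {
  if (!length(eyeProteins)) stop("eye protein set must be non-empty")
  sort(unique(hits$contig_id[hits$subject_id %in% eyeProteins &
                             hits$evalue <= eCutoff]))
}

#' Quality-control raw eye contigs against whole-proteome best hits
#'
#' A raw eye contig passes QC iff its whole-proteome best hit is itself an
#' eye-related protein; the retained record carries that best hit and its
#' origin label. Chimeric or promiscuous contigs whose strongest homology
#' is to a non-eye protein are dropped, even though they hit an eye
#' protein. With \code{strict = TRUE} the whole-proteome best hit must
#' additionally equal the contig's best eye-subset hit.
#'
#' @param hits whole-proteome hit table
#' @param rawSet raw eye contig ids from \code{\link{rawEyeContigs}}
#' @param eyeProteins eye-related protein ids
#' @param strict require identity of best hit and best eye hit
#' @return data.frame of assignment records (\code{contig_id, subject_id,
#'   origin, bits, evalue, sstart, send, eye_related, qc_pass})
#' @export
qcBestHits <- function(hits, rawSet, eyeProteins, strict = FALSE) {
  best <- bestHits(hits)
  best <- best[best$contig_id %in% rawSet, , drop = FALSE]
  qc <- best$subject_id %in% eyeProteins
  if (strict) {
    eyeBest <- bestHits(hits[hits$subject_id %in% eyeProteins, ,
                             drop = FALSE])
    top <- stats::setNames(eyeBest$subject_id, eyeBest$contig_id)
    qc <- qc & best$subject_id == unname(top[best$contig_id])
  }
  out <- data.frame(contig_id = best$contig_id,
                    subject_id = best$subject_id, origin = best$origin,
                    bits = best$bits, evalue = best$evalue,
                    sstart = best$sstart, send = best$send,
                    eye_related = rep(TRUE, nrow(best)), qc_pass = qc,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
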