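## Six-frame translation and reverse translation under the standard genetic
## code (translation table 1). Codons containing N translate to X; frame
## translations are split into segments at stop codons, keeping offsets so
## protein positions map back to nucleotide positions on the input strand.

.codonTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- gc
    }
    tab
  }
})

.aaToCodons <- local({
  lst <- NULL
  function() {
    if (is.null(lst)) {
      gc <- Biostrings::GENETIC_CODE
      lst <<- split(names(gc), unname(gc))
    }
    lst
  }
})

.translateCodons <- function(codons) {
  gc <- .codonTable()
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"  # N-containing codons
  aa
}

.revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Six-frame translation with stop-codon segmentation
#'
#' Translates all six reading frames, splitting each frame at stop codons.
#' For every segment the nucleotide interval on the \emph{original} strand
#' is reported (1-based inclusive; for negative frames the interval still
#' refers to input coordinates, with the segment read off the reverse
#' complement), so protein positions map back to nucleotide positions.
#'
#' @param dna nucleotide string over ACGTN
#' @return data.frame with columns \code{frame} (+1..+3, -1..-3),
#'   \code{segment} (protein string), \code{aa_start} (position of the
#'   segment's first residue within the frame translation),
#'   \code{nt_start}, \code{nt_end}
#' @examples
#' sixFrameTranslate("ATGAAA")          # frame +1 gives "MK"
#' sixFrameTranslate("ATGTAAATG")       # "M", "M" split at the stop
#' @export
sixFrameTranslate <- function(dna) {
  dna <- toupper(as.character(dna))
  bad <- setdiff(unique(strsplit(dna, "")[[1]]), .DNA_ALPHABET)
  if (length(bad))
    stop("non-ACGTN character(s): ", paste(bad, collapse = ""))
  L <- nchar(dna)
  rc <- if (L) .revcomp(dna) else ""
  out <- list()
  for (fr in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    off <- abs(fr) - 1L
    s <- if (fr > 0) dna else rc
    ncod <- (L - off) %/% 3L
    if (ncod < 1L) next
    starts <- off + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    aa <- .translateCodons(codons)
    # split at stops
    isStop <- aa == "*"
    runs <- rle(isStop)
    pos <- 1L
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (!runs$values[k]) {
        aaIdx <- pos:(pos + len - 1L)
        ntA <- starts[aaIdx[1]]
        ntB <- starts[aaIdx[len]] + 2L
        if (fr < 0) {  # map back to original-strand coordinates
          tmp <- c(L - ntB + 1L, L - ntA + 1L)
          ntA <- tmp[1]; ntB <- tmp[2]
        }
        out[[length(out) + 1L]] <- data.frame(
          frame = fr, segment = paste(aa[aaIdx], collapse = ""),
          aa_start = aaIdx[1], nt_start = ntA, nt_end = ntB,
          stringsAsFactors = FALSE)
      }
      pos <- pos + len
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), segment = character(),
                      aa_start = integer(), nt_start = integer(),
                      nt_end = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reverse translation with uniformly sampled synonymous codons
#'
#' Each residue is encoded by a codon drawn uniformly from its synonymous
#' codons, so translating frame +1 recovers the input protein exactly and
#' the output length is 3x the protein length. Uses the current RNG state.
#'
#' @param protein string over the 20-residue alphabet
#' @return nucleotide string
#' @examples
#' reverseTranslate("M")  # "ATG", the unique methionine codon
#' @export
reverseTranslate <- function(protein) {
  aa <- strsplit(as.character(protein), "")[[1]]
  bad <- setdiff(unique(aa), .AA_ALPHABET)
  if (length(bad))
    stop("invalid residue(s): ", paste(bad, collapse = ""))
  cods <- .aaToCodons()
  paste(vapply(aa, function(r) {
    ch <- cods[[r]]
    if (length(ch) == 1L) ch else ch[sample.int(length(ch), 1L)]
  }, character(1)), collapse = "")
}

#' Trim a contig to the translated region of a hit
#'
#' Extracts the hit's query interval, reads it in the hit's frame (reverse
#' complement for negative frames) and translates it, reproducing the
#' protein fragment that matched the reference.
#'
#' @param contig nucleotide sequence
#' @param hit one-row data.frame (or list) with \code{frame},
#'   \code{qstart}, \code{qend} in contig coordinates
#' @return protein string
#' @export
trimToHit <- function(contig, hit) {
  contig <- toupper(as.character(contig))
  qs <- min(hit$qstart, hit$qend)
  qe <- max(hit$qstart, hit$qend)
  if (qs < 1 || qe > nchar(contig))
    stop("hit interval outside contig bounds")
  if ((qe - qs + 1L) %% 3L != 0L)
    stop("hit interval is not codon-aligned with its frame")
  frag <- substring(contig, qs, qe)
  if (hit$frame < 0) frag <- .revcomp(frag)
  starts <- seq(1L, nchar(frag), 3L)
  aa <- .translateCodons(substring(frag, starts, starts + 2L))
  if (any(aa == "*"))
    stop("hit interval crosses a stop codon: frame/segment mismatch")
  paste(aa, collapse = "")
}
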