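## Translated homology search of nucleotide contigs against the combined
## reference proteomes. The heavy lifting (six-frame translated local
## alignment over every contig x protein pair) is delegated to NCBI BLAST+
## (blastx), the field-standard tool; the package owns the hit-table
## contract, the e-value thresholding and the deterministic best-hit rules.

.findBlast <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p))
    stop(tool, " not found on PATH; NCBI BLAST+ is required for ",
         "translated search")
  p
}

.emptyHits <- function() {
  data.frame(contig_id = character(), subject_id = character(),
             organism = character(), frame = integer(), qstart = integer(),
             qend = integer(), sstart = integer(), send = integer(),
             raw = numeric(), bits = numeric(), evalue = numeric(),
             identity = numeric(), stringsAsFactors = FALSE)
}

.sortHits <- function(hits) {
  hits[order(hits$contig_id, -hits$bits, hits$evalue, hits$subject_id), ,
       drop = FALSE]
}

#' Translated search of contigs against reference proteomes
#'
#' Runs blastx (BLOSUM62 by default, affine gaps from the scheme, SEG and
#' composition-based statistics off so scores follow the plain scheme) of
#' the length-filtered contigs against the combined proteomes, keeping the
#' single best HSP per contig-protein pair. Hits above the e-value cutoff
#' are dropped and the table is sorted deterministically: contig, then
#' descending bit score, then subject id.
#'
#' @param contigs named \code{DNAStringSet} (or named character vector)
#' @param proteomes named list of \code{AAStringSet}s, one per reference
#'   organism, e.g. \code{list(human = ..., fly = ...)}
#' @param scheme a \linkS4class{ScoringScheme}; gap penalties are passed to
#'   blastx
#' @param eCutoff e-value cutoff; hits with larger e-values are dropped
#' @param minLen contigs must be strictly longer than this many nucleotides
#' @return hit table data.frame with columns \code{contig_id, subject_id,
#'   organism, frame, qstart, qend, sstart, send, raw, bits, evalue,
#'   identity} (coordinates 1-based inclusive, \code{qstart <= qend})
#' @export
searchContigs <- function(contigs, proteomes, scheme = ScoringScheme(),
                          eCutoff = 1e-10, minLen = 100) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names")
  keep <- Biostrings::width(contigs) > minLen
  contigs <- contigs[keep]
  nprot <- sum(vapply(proteomes, length, integer(1)))
  if (nprot == 0L || length(contigs) == 0L) {
    if (nprot == 0L) warning("empty proteome: returning an empty hit table")
    return(.emptyHits())
  }
  if (eCutoff <= 0) return(.emptyHits())   # nothing can pass the filter
  orgOf <- rep(names(proteomes), vapply(proteomes, length, integer(1)))
  names(orgOf) <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (anyDuplicated(names(orgOf)))
    stop("protein ids must be unique across proteomes")

  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  dbFa <- file.path(td, "db.fasta")
  qFa <- file.path(td, "query.fasta")
  all <- do.call(c, unname(proteomes))
  writeFasta(all, dbFa)
  writeFasta(contigs, qFa)
  out <- file.path(td, "hits.tsv")
  system2(.findBlast("makeblastdb"),
          c("-in", dbFa, "-dbtype", "prot", "-out", file.path(td, "db")),
          stdout = FALSE, stderr = FALSE)
  status <- system2(.findBlast("blastx"),
    c("-query", qFa, "-db", file.path(td, "db"),
      "-evalue", format(eCutoff, scientific = TRUE),
      "-matrix", "BLOSUM62",
      "-gapopen", as.integer(scheme@gapOpen),
      "-gapextend", as.integer(scheme@gapExtend),
      "-seg", "no", "-comp_based_stats", "0",
      "-max_hsps", "1", "-max_target_seqs", "100000",
      "-num_threads", "1",
      "-outfmt",
      shQuote(paste("6 qseqid sseqid qstart qend sstart send qframe",
                    "score bitscore evalue pident")),
      "-out", out),
    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("blastx failed with status ", status)
  if (!file.size(out)) return(.emptyHits())
  raw <- utils::read.delim(out, header = FALSE, stringsAsFactors = FALSE)
  names(raw) <- c("contig_id", "subject_id", "qstart", "qend", "sstart",
                  "send", "frame", "raw", "bits", "evalue", "pident")
  hits <- data.frame(
    contig_id = raw$contig_id, subject_id = raw$subject_id,
    organism = unname(orgOf[raw$subject_id]), frame = as.integer(raw$frame),
    qstart = pmin(raw$qstart, raw$qend), qend = pmax(raw$qstart, raw$qend),
    sstart = as.integer(raw$sstart), send = as.integer(raw$send),
    raw = as.numeric(raw$raw), bits = as.numeric(raw$bits),
    evalue = as.numeric(raw$evalue), identity = raw$pident / 100,
    stringsAsFactors = FALSE)
  hits <- hits[hits$evalue <= eCutoff, , drop = FALSE]
  rownames(hits) <- NULL
  .sortHits(hits)
}

#' Best hit per contig
#'
#' The highest bit score wins; ties are broken by lower e-value, then
#' lexicographic subject id, so assignments are reproducible regardless of
#' input order. The origin label is the organism of the winning subject.
#'
#' @param hits a hit table from \code{\link{searchContigs}}
#' @return one-row-per-contig data.frame of assignment records
#' @export
bestHits <- function(hits) {
  if (!nrow(hits)) {
    names(hits)[names(hits) == "organism"] <- "origin"
    return(hits)
  }
  hits <- hits[order(hits$contig_id, -hits$bits, hits$evalue,
                     hits$subject_id), , drop = FALSE]
  out <- hits[!duplicated(hits$contig_id), , drop = FALSE]
  names(out)[names(out) == "organism"] <- "origin"
  rownames(out) <- NULL
  out
}

#' Best hit for one contig
#'
#' @param hits a hit table
#' @param contigId contig id
#' @return a one-row assignment record, or NULL (with a warning) when the
#'   contig has no hit in the table
#' @export
bestHit <- function(hits, contigId) {
  sub <- hits[hits$contig_id == contigId, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no hits for contig ", contigId)
    return(NULL)
  }
  bestHits(sub)
}
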