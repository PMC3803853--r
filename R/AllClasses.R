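#' @import methods
#' @importFrom Biostrings AAStringSet DNAStringSet
NULL

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties and Karlin-Altschul
#' constants used to convert raw local-alignment scores to bit scores and
#' e-values. The default mirrors common gapped protein-search practice:
#' BLOSUM62, gap open 11, gap extend 1, lambda = 0.267 nats, K = 0.041.
#'
#' @slot matrix integer substitution matrix with residue dimnames (symmetric)
#' @slot gapOpen positive gap-opening penalty; a gap of length L costs
#'   \code{gapOpen + L * gapExtend}
#' @slot gapExtend positive per-residue gap-extension penalty
#' @slot lambda Karlin-Altschul scale, nats per raw-score unit
#' @slot K Karlin-Altschul search-space constant
#' @export
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "numeric",
                 gapExtend = "numeric", lambda = "numeric", K = "numeric"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  m <- object@matrix
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    msg <- c(msg, "substitution matrix must have matching dimnames")
  else if (!isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "substitution matrix must be symmetric")
  if (object@gapOpen < object@gapExtend || object@gapExtend < 1)
    msg <- c(msg, "need gapOpen >= gapExtend >= 1")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a scoring scheme
#'
#' @param matrix substitution matrix (defaults to BLOSUM62)
#' @param gapOpen,gapExtend affine gap penalties
#' @param lambda,K Karlin-Altschul constants for gapped BLOSUM62/11/1
#' @return a \linkS4class{ScoringScheme}
#' @examples
#' ScoringScheme()
#' @export
ScoringScheme <- function(matrix = NULL, gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) matrix <- blosum62Matrix()
  new("ScoringScheme", matrix = matrix, gapOpen = as.numeric(gapOpen),
      gapExtend = as.numeric(gapExtend), lambda = lambda, K = K)
}

blosum62Matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "integer"
  m
}

#' Synthetic four-lineage dataset configuration
#'
#' Parameters of the synthetic transcriptome generator: homologue families
#' are evolved from random ancestors into a human and a fly reference
#' protein, then into nautilus and squid transcript contigs, with planted
#' duplication, dual-origin duplication, differential-selection, and decoy
#' events, plus per-sample coverage.
#'
#' @slot nFamilies number of homologue families
#' @slot familyLengthRange min/max family length, residues (min >= 40 so
#'   reverse-translated contigs clear the 100 bp length filter)
#' @slot pGlobal compound per-site substitution probability between the
#'   human and fly homologues (split symmetrically over the two branches)
#' @slot pFocal per-site substitution probability from the nearest
#'   reference to a focal-species contig
#' @slot nDuplications planted duplication events (total)
#' @slot nDualOriginDuplications of which dual-origin (one copy seeded from
#'   each reference, the NF1-style pattern)
#' @slot nSelectionEvents planted differential-selection events
#' @slot windowFrac planted window length as a fraction of family length
#' @slot pWindowBias per-site substitution probability between a planted
#'   window and the focal copy that tracks it
#' @slot coverageMu,coverageSigma lognormal parameters of family base
#'   coverage (log scale)
#' @slot coverageNoiseFrac per-contig-per-sample log-noise sd as a fraction
#'   of coverageSigma (keeps the two samples correlated; 0 when
#'   coverageSigma = 0)
#' @slot fracDifferential fraction of families with a planted >= 2.5-fold
#'   expression difference
#' @slot boostRange uniform range of the planted differential fold change
#' @slot nQcDecoys families whose host-species contig carries an eye-protein
#'   tail window (raw eye hit, non-eye best hit)
#' @slot nConservedDecoys families with highly conserved references and
#'   deliberately split contig origins (conservation-filter controls)
#' @slot enrichedTermFreqUp,enrichedTermFreqBase planted frequency of the
#'   enriched GO term in nautilus-up families vs all others (5-fold)
#' @slot seed RNG seed; identical configs generate byte-identical bundles
#' @export
setClass("SimulationConfig",
  representation(nFamilies = "integer", familyLengthRange = "integer",
                 pGlobal = "numeric", pFocal = "numeric",
                 nDuplications = "integer", nDualOriginDuplications = "integer",
                 nSelectionEvents = "integer", windowFrac = "numeric",
                 pWindowBias = "numeric", coverageMu = "numeric",
                 coverageSigma = "numeric", coverageNoiseFrac = "numeric",
                 fracDifferential = "numeric", boostRange = "numeric",
                 nQcDecoys = "integer", nConservedDecoys = "integer",
                 enrichedTermFreqUp = "numeric", enrichedTermFreqBase = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pr <- c(pGlobal = object@pGlobal, pFocal = object@pFocal,
          windowFrac = object@windowFrac, pWindowBias = object@pWindowBias,
          fracDifferential = object@fracDifferential,
          enrichedTermFreqUp = object@enrichedTermFreqUp,
          enrichedTermFreqBase = object@enrichedTermFreqBase)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, paste("probabilities must lie in [0,1]:",
                        paste(names(pr)[pr < 0 | pr > 1], collapse = ", ")))
  if (length(object@familyLengthRange) != 2L ||
      object@familyLengthRange[1] > object@familyLengthRange[2])
    msg <- c(msg, "familyLengthRange must be (min, max)")
  else if (object@familyLengthRange[1] < 40L)
    msg <- c(msg, "minimum family length must be >= 40 residues")
  nev <- object@nDuplications + object@nSelectionEvents +
    object@nQcDecoys + object@nConservedDecoys
  if (object@nFamilies < nev)
    msg <- c(msg, "nFamilies must cover all planted events and decoys")
  if (object@nDualOriginDuplications > object@nDuplications)
    msg <- c(msg, "dual-origin duplications cannot exceed nDuplications")
  if (length(object@boostRange) != 2L || object@boostRange[1] < 2.5)
    msg <- c(msg, "boostRange must be (lo, hi) with lo >= 2.5")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults define the reference study conditions: 200 families of 80-400
#' residues, human-fly divergence 0.5, focal divergence 0.15, 10 planted
#' duplications (3 dual-origin), 10 selection events with windows covering
#' 30\% of the family at 0.05 window noise, lognormal(log 50, 1) coverage
#' with half the families differential, and 5 + 5 decoy families.
#'
#' @param nFamilies,familyLengthRange,pGlobal,pFocal see slots
#' @param nDuplications,nDualOriginDuplications,nSelectionEvents see slots
#' @param windowFrac,pWindowBias,coverageMu,coverageSigma see slots
#' @param coverageNoiseFrac,fracDifferential,boostRange see slots
#' @param nQcDecoys,nConservedDecoys see slots
#' @param enrichedTermFreqUp,enrichedTermFreqBase see slots
#' @param seed integer RNG seed
#' @return a \linkS4class{SimulationConfig}
#' @examples
#' SimulationConfig(nFamilies = 50, seed = 7)
#' @export
SimulationConfig <- function(nFamilies = 200, familyLengthRange = c(80, 400),
                             pGlobal = 0.5, pFocal = 0.15,
                             nDuplications = 10, nDualOriginDuplications = 3,
                             nSelectionEvents = 10, windowFrac = 0.3,
                             pWindowBias = 0.05, coverageMu = log(50),
                             coverageSigma = 1, coverageNoiseFrac = 0.15,
                             fracDifferential = 0.5, boostRange = c(2.5, 6),
                             nQcDecoys = 5, nConservedDecoys = 5,
                             enrichedTermFreqUp = 0.75,
                             enrichedTermFreqBase = 0.15, seed = 1) {
  new("SimulationConfig", nFamilies = as.integer(nFamilies),
      familyLengthRange = as.integer(familyLengthRange), pGlobal = pGlobal,
      pFocal = pFocal, nDuplications = as.integer(nDuplications),
      nDualOriginDuplications = as.integer(nDualOriginDuplications),
      nSelectionEvents = as.integer(nSelectionEvents), windowFrac = windowFrac,
      pWindowBias = pWindowBias, coverageMu = coverageMu,
      coverageSigma = coverageSigma, coverageNoiseFrac = coverageNoiseFrac,
      fracDifferential = fracDifferential, boostRange = as.numeric(boostRange),
      nQcDecoys = as.integer(nQcDecoys),
      nConservedDecoys = as.integer(nConservedDecoys),
      enrichedTermFreqUp = enrichedTermFreqUp,
      enrichedTermFreqBase = enrichedTermFreqBase, seed = as.integer(seed))
}

#' Pipeline thresholds and constants
#'
#' Houses every downstream threshold: the 100 bp contig length filter, the
#' coverage >= 10 and > 2-fold expression rules, the 1e-10 e-value cutoff
#' for annotation transfer and search, the < 95\% duplicate-identity
#' criterion, the same-region overlap fraction, the < 0.60 human-fly
#' conservation ceiling for selection candidates, and FDR alpha 0.05.
#'
#' @slot minContigLen contigs must be strictly longer than this (bp)
#' @slot minCoverage minimum normalized average coverage (inclusive)
#' @slot foldChange expression ratio must strictly exceed this
#' @slot searchEvalue e-value cutoff for retained hits
#' @slot annotationEvalue e-value cutoff for GO annotation transfer
#' @slot duplicationIdentityMax contig pairs at or above this nucleotide
#'   identity are treated as the same transcript, not duplicates
#' @slot sameRegionMinOverlap overlap fraction of the shorter interval
#'   required to call two hits the same region (default 0.4, calibrated to
#'   reproduce the NF1 reference interval pattern; see
#'   \code{\link{sameRegion}})
#' @slot conservationMaxIdentity human-fly identity ceiling in the shared
#'   hit region for a selection candidate
#' @slot fdrAlpha BH-adjusted significance level
#' @slot strictQc if TRUE the whole-proteome best hit must equal the best
#'   eye-subset hit; default only requires it to be eye-related
#' @slot kimura use Kimura-corrected protein distances
#' @slot scheme the \linkS4class{ScoringScheme} used throughout
#' @export
setClass("PipelineConfig",
  representation(minContigLen = "numeric", minCoverage = "numeric",
                 foldChange = "numeric", searchEvalue = "numeric",
                 annotationEvalue = "numeric", duplicationIdentityMax = "numeric",
                 sameRegionMinOverlap = "numeric",
                 conservationMaxIdentity = "numeric", fdrAlpha = "numeric",
                 strictQc = "logical", kimura = "logical",
                 scheme = "ScoringScheme"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c(minContigLen = object@minContigLen, minCoverage = object@minCoverage,
           foldChange = object@foldChange, searchEvalue = object@searchEvalue,
           annotationEvalue = object@annotationEvalue)
  if (any(pos <= 0)) msg <- c(msg, "thresholds must be positive")
  fr <- c(object@duplicationIdentityMax, object@sameRegionMinOverlap,
          object@conservationMaxIdentity, object@fdrAlpha)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "identity/overlap/alpha fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a pipeline configuration
#'
#' @param minContigLen,minCoverage,foldChange,searchEvalue see slots
#' @param annotationEvalue,duplicationIdentityMax,sameRegionMinOverlap see slots
#' @param conservationMaxIdentity,fdrAlpha,strictQc,kimura,scheme see slots
#' @return a \linkS4class{PipelineConfig}
#' @examples
#' PipelineConfig(fdrAlpha = 0.01)
#' @export
PipelineConfig <- function(minContigLen = 100, minCoverage = 10,
                           foldChange = 2, searchEvalue = 1e-10,
                           annotationEvalue = 1e-10,
                           duplicationIdentityMax = 0.95,
                           sameRegionMinOverlap = 0.4,
                           conservationMaxIdentity = 0.60, fdrAlpha = 0.05,
                           strictQc = FALSE, kimura = TRUE,
                           scheme = ScoringScheme()) {
  new("PipelineConfig", minContigLen = minContigLen, minCoverage = minCoverage,
      foldChange = foldChange, searchEvalue = searchEvalue,
      annotationEvalue = annotationEvalue,
      duplicationIdentityMax = duplicationIdentityMax,
      sameRegionMinOverlap = sameRegionMinOverlap,
      conservationMaxIdentity = conservationMaxIdentity, fdrAlpha = fdrAlpha,
      strictQc = strictQc, kimura = kimura, scheme = scheme)
}

#' Synthetic four-lineage dataset
#'
#' In-memory bundle produced by \code{\link{generateDataset}}: reference
#' proteomes, focal-species contigs, coverage and annotation tables, the
#' homologue map, and the truth ledger of planted events.
#'
#' @slot humanProteins,flyProteins reference proteomes (AAStringSet)
#' @slot nautilusContigs,squidContigs transcript contigs (DNAStringSet)
#' @slot coverage long-format coverage table
#'   (contig_id, sample, aligned_bases, contig_length)
#' @slot goMap protein-to-GO table (protein_id, go_id, go_name, eye_flag)
#' @slot homologueMap family table (human_protein_id, fly_protein_id, family_id)
#' @slot truthEvents one row per planted event with contig ids, origins and
#'   window interval
#' @slot truthContigs one row per contig with family, expected origin and
#'   differential flag
#' @slot config the generating \linkS4class{SimulationConfig}
#' @export
setClass("SyntheticEyeData",
  representation(humanProteins = "AAStringSet", flyProteins = "AAStringSet",
                 nautilusContigs = "DNAStringSet", squidContigs = "DNAStringSet",
                 coverage = "data.frame", goMap = "data.frame",
                 homologueMap = "data.frame", truthEvents = "data.frame",
                 truthContigs = "data.frame", config = "SimulationConfig"))

setValidity("SyntheticEyeData", function(object) {
  msg <- character()
  ids <- c(names(object@nautilusContigs), names(object@squidContigs))
  if (anyDuplicated(ids)) msg <- c(msg, "contig ids must be unique")
  if (nrow(object@homologueMap) != object@config@nFamilies)
    msg <- c(msg, "homologue map must have one row per family")
  tc <- object@truthContigs$contig_id
  if (!all(tc %in% ids))
    msg <- c(msg, "truth ledger references unknown contigs")
  ev <- unlist(strsplit(object@truthEvents$contig_ids, ";", fixed = TRUE))
  if (!all(ev %in% ids))
    msg <- c(msg, "truth events reference unknown contigs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticEyeData", function(object) {
  cat("SyntheticEyeData\n")
  cat(sprintf("  families            : %d\n", object@config@nFamilies))
  cat(sprintf("  human / fly proteins: %d / %d\n",
              length(object@humanProteins), length(object@flyProteins)))
  cat(sprintf("  nautilus / squid contigs: %d / %d\n",
              length(object@nautilusContigs), length(object@squidContigs)))
  tab <- table(object@truthEvents$event_kind)
  cat("  planted events      :",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("  seed                : %d\n", object@config@seed))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d families, %d-%d aa, pGlobal=%.2f, pFocal=%.2f, seed=%d\n",
              object@nFamilies, object@familyLengthRange[1],
              object@familyLengthRange[2], object@pGlobal, object@pFocal,
              object@seed))
  cat(sprintf("  events: %d duplications (%d dual-origin), %d selection; decoys: %d qc, %d conserved\n",
              object@nDuplications, object@nDualOriginDuplications,
              object@nSelectionEvents, object@nQcDecoys,
              object@nConservedDecoys))
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: %dx%d matrix, gap %g/%g, lambda=%g, K=%g\n",
              nrow(object@matrix), ncol(object@matrix), object@gapOpen,
              object@gapExtend, object@lambda, object@K))
})
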