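## Duplication and differential-selection detection. Both detectors reason
## on a common coordinate frame: the human homologue's protein coordinates,
## onto which hits against the fly homologue are mapped through the global
## alignment of the homologue pair.

#' Map a fly-protein interval onto human coordinates
#'
#' Each fly position maps to its aligned human column in the global
#' alignment of the homologue pair; endpoints that fall opposite gaps
#' slide inward to the nearest aligned column. Intervals entirely opposite
#' gaps are unmappable (returned as NA with a warning).
#'
#' @param interval c(start, end), 1-based inclusive on the fly protein
#' @param aln list with gapped strings \code{human} and \code{fly} from a
#'   global alignment of the homologue pair
#' @return c(start, end) on the human protein, or c(NA, NA)
#' @export
mapToCommonFrame <- function(interval, aln) {
  h <- strsplit(aln$human, "")[[1]]
  f <- strsplit(aln$fly, "")[[1]]
  stopifnot(length(h) == length(f))
  hpos <- cumsum(h != "-")
  fpos <- cumsum(f != "-")
  cols <- which(f != "-" & fpos >= interval[1] & fpos <= interval[2] &
                h != "-")
  if (!length(cols)) {
    warning("interval aligns entirely opposite gaps; unmappable")
    return(c(NA_integer_, NA_integer_))
  }
  c(hpos[min(cols)], hpos[max(cols)])
}

#' Same-region test for two intervals on a common frame
#'
#' TRUE iff the overlap length is at least \code{minOverlap} times the
#' length of the shorter interval. Symmetric and reflexive on valid
#' intervals.
#'
#' The default fraction 0.4 is calibrated to reproduce the NF1 reference
#' same-region pattern from its hit coordinates (the starred pair
#' 1523-1609 / 1572-1656 overlaps by 38 of the shorter 85 residues, a
#' fraction of 0.447).
#'
#' @param a,b intervals c(start, end), 1-based inclusive, start <= end
#' @param minOverlap required overlap fraction of the shorter interval
#' @return logical
#' @examples
#' sameRegion(c(1523, 1609), c(1572, 1656))  # TRUE
#' sameRegion(c(35, 318), c(1597, 1919))     # FALSE
#' @export
sameRegion <- function(a, b, minOverlap = 0.4) {
  if (anyNA(c(a, b))) return(NA)
  if (a[1] > a[2] || b[1] > b[2]) stop("degenerate interval (start > end)")
  ov <- min(a[2], b[2]) - max(a[1], b[1]) + 1
  shorter <- min(a[2] - a[1] + 1, b[2] - b[1] + 1)
  ov >= minOverlap * shorter
}

#' Human-fly conservation within a common-frame window
#'
#' Identity over the alignment columns of the homologue pair whose human
#' coordinate lies in the interval; columns where the fly homologue is
#' gapped count as mismatches. High values flag regions where a shared hit
#' carries no lineage-specific signal (the basis for discarding conserved
#' candidate pairs).
#'
#' @param human,fly homologue protein sequences
#' @param interval c(start, end) on human coordinates
#' @param scheme a \linkS4class{ScoringScheme}
#' @param aln optional precomputed global alignment (list human/fly)
#' @return identity fraction in [0, 1]
#' @export
windowConservation <- function(human, fly, interval,
                               scheme = ScoringScheme(), aln = NULL) {
  if (anyNA(interval) || interval[1] > interval[2])
    stop("empty or degenerate window")
  if (is.null(aln)) {
    g <- globalAlign(human, fly, scheme, type = "global")
    aln <- list(human = g$a, fly = g$b)
  }
  h <- strsplit(aln$human, "")[[1]]
  f <- strsplit(aln$fly, "")[[1]]
  hpos <- cumsum(h != "-")
  cols <- which(h != "-" & hpos >= interval[1] & hpos <= interval[2])
  if (!length(cols)) stop("window has no aligned columns")
  mean(h[cols] == f[cols])
}

.famLookup <- function(homologueMap) {
  stats::setNames(rep(homologueMap$family_id, 2L),
                  c(homologueMap$human_protein_id,
                    homologueMap$fly_protein_id))
}

.homAln <- function(famRow, humanProteins, flyProteins, scheme, cache) {
  fam <- famRow$family_id
  if (!is.null(cache[[fam]])) return(cache[[fam]])
  g <- globalAlign(as.character(humanProteins[[famRow$human_protein_id]]),
                   as.character(flyProteins[[famRow$fly_protein_id]]),
                   scheme, type = "global")
  cache[[fam]] <- list(human = g$a, fly = g$b)
  cache[[fam]]
}

.commonInterval <- function(rec, famRow, humanProteins, flyProteins, scheme,
                            cache) {
  iv <- c(rec$sstart, rec$send)
  if (rec$origin == "human") return(iv)
  mapToCommonFrame(iv, .homAln(famRow, humanProteins, flyProteins, scheme,
                               cache))
}

#' Detect gene-duplication candidates within one species
#'
#' Groups the species' contigs whose best hits fall in the same homologue
#' family and emits a candidate when at least two members are longer than
#' \code{minContigLen} and every within-group pairwise nucleotide identity
#' (free-end-gap global alignment) is below
#' \code{duplicationIdentityMax}: near-identical contigs are treated as the
#' same transcript, not a duplication. \code{dual_origin} is set when the
#' members' origin labels differ (one human-best, one fly-best, the
#' NF1-style pattern); \code{same_region} tests all pairwise hit intervals
#' on the common (human) frame.
#'
#' @param assignments best-hit assignment records for one species
#' @param contigs the species' contig \code{DNAStringSet}
#' @param homologueMap family table
#' @param humanProteins,flyProteins reference proteomes
#' @param config a \linkS4class{PipelineConfig}
#' @param species label recorded on candidates
#' @return data.frame of duplication candidates (one row per event,
#'   ";"-joined contig lists)
#' @export
detectDuplications <- function(assignments, contigs, homologueMap,
                               humanProteins, flyProteins,
                               config = PipelineConfig(),
                               species = "unknown") {
  empty <- data.frame(species = character(), family_id = character(),
                      contig_ids = character(), origins = character(),
                      max_pairwise_identity = numeric(),
                      same_region = logical(), dual_origin = logical(),
                      intervals = character(), stringsAsFactors = FALSE)
  if (is.null(assignments) || !nrow(assignments)) return(empty)
  lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
  asg <- assignments[lens[assignments$contig_id] > config@minContigLen, ,
                     drop = FALSE]
  fam <- .famLookup(homologueMap)
  asg$family_id <- unname(fam[asg$subject_id])
  asg <- asg[!is.na(asg$family_id), , drop = FALSE]
  grp <- split(asg, asg$family_id)
  grp <- grp[vapply(grp, nrow, integer(1)) >= 2L]
  if (!length(grp)) return(empty)
  cache <- new.env()
  out <- lapply(names(grp), function(famid) {
    g <- grp[[famid]]
    g <- g[order(-g$bits, g$evalue, g$contig_id), , drop = FALSE]
    pairs <- utils::combn(nrow(g), 2)
    ident <- apply(pairs, 2, function(p)
      contigIdentity(as.character(contigs[[g$contig_id[p[1]]]]),
                     as.character(contigs[[g$contig_id[p[2]]]])))
    if (any(ident >= config@duplicationIdentityMax)) return(NULL)
    famRow <- homologueMap[homologueMap$family_id == famid, , drop = FALSE]
    ivs <- lapply(seq_len(nrow(g)), function(k)
      .commonInterval(g[k, ], famRow, humanProteins, flyProteins,
                      config@scheme, cache))
    sr <- all(apply(pairs, 2, function(p)
      isTRUE(sameRegion(ivs[[p[1]]], ivs[[p[2]]],
                        config@sameRegionMinOverlap))))
    data.frame(species = species, family_id = famid,
               contig_ids = paste(g$contig_id, collapse = ";"),
               origins = paste(g$origin, collapse = ";"),
               max_pairwise_identity = max(ident), same_region = sr,
               dual_origin = length(unique(g$origin)) > 1L,
               intervals = paste(vapply(ivs, function(v)
                 paste(v, collapse = "-"), character(1)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect differential-selection candidate pairs across species
#'
#' For each homologue family with exactly one qualifying contig in each
#' species (length filter passed, best hit in the family; families with
#' several qualifying contigs in one species carry a duplication signature
#' and are excluded), a candidate is emitted iff the two origin
#' labels differ (one human-best, one fly-best), the two hit intervals
#' fall in the same region of the common frame, and the human-fly identity
#' within the shared region is below \code{conservationMaxIdentity} --
#' a shared hit in a region conserved between the references carries no
#' lineage-specific signal and is discarded.
#'
#' @param assignNaut,assignSquid per-species best-hit assignment records
#' @param nautContigs,squidContigs the species' contig sets (for lengths)
#' @param homologueMap family table
#' @param humanProteins,flyProteins reference proteomes
#' @param config a \linkS4class{PipelineConfig}
#' @return data.frame of selection candidates with evidence fields
#' @export
detectSelectionPairs <- function(assignNaut, assignSquid, nautContigs,
                                 squidContigs, homologueMap, humanProteins,
                                 flyProteins, config = PipelineConfig()) {
  empty <- data.frame(family_id = character(), nautilus_contig = character(),
                      squid_contig = character(), nautilus_origin = character(),
                      squid_origin = character(), nautilus_interval = character(),
                      squid_interval = character(), overlap_fraction = numeric(),
                      window_identity = numeric(), stringsAsFactors = FALSE)
  fam <- .famLookup(homologueMap)
  prep <- function(asg, contigs) {
    if (is.null(asg) || !nrow(asg))
      return(data.frame(contig_id = character(), subject_id = character(),
                        origin = character(), bits = numeric(),
                        evalue = numeric(), sstart = integer(),
                        send = integer(), family_id = character(),
                        stringsAsFactors = FALSE))
    lens <- stats::setNames(Biostrings::width(contigs), names(contigs))
    asg <- asg[lens[asg$contig_id] > config@minContigLen, , drop = FALSE]
    asg$family_id <- unname(fam[asg$subject_id])
    asg <- asg[!is.na(asg$family_id), , drop = FALSE]
    asg <- asg[order(asg$family_id, -asg$bits, asg$evalue, asg$contig_id), ,
               drop = FALSE]
    ## families with several qualifying contigs in one species carry a
    ## duplication signature and are not clean selection candidates
    single <- names(which(table(asg$family_id) == 1L))
    asg[asg$family_id %in% single, , drop = FALSE]
  }
  an <- prep(assignNaut, nautContigs)
  as_ <- prep(assignSquid, squidContigs)
  common <- intersect(an$family_id, as_$family_id)
  if (!length(common)) return(empty)
  cache <- new.env()
  out <- lapply(sort(common), function(famid) {
    rn <- an[an$family_id == famid, ]
    rs <- as_[as_$family_id == famid, ]
    if (rn$origin == rs$origin) return(NULL)
    famRow <- homologueMap[homologueMap$family_id == famid, , drop = FALSE]
    ivN <- .commonInterval(rn, famRow, humanProteins, flyProteins,
                           config@scheme, cache)
    ivS <- .commonInterval(rs, famRow, humanProteins, flyProteins,
                           config@scheme, cache)
    sr <- sameRegion(ivN, ivS, config@sameRegionMinOverlap)
    if (!isTRUE(sr)) return(NULL)
    shared <- c(max(ivN[1], ivS[1]), min(ivN[2], ivS[2]))
    wid <- windowConservation(
      as.character(humanProteins[[famRow$human_protein_id]]),
      as.character(flyProteins[[famRow$fly_protein_id]]), shared,
      config@scheme, aln = .homAln(famRow, humanProteins, flyProteins,
                                   config@scheme, cache))
    if (wid >= config@conservationMaxIdentity) return(NULL)
    ov <- min(ivN[2], ivS[2]) - max(ivN[1], ivS[1]) + 1
    shorter <- min(ivN[2] - ivN[1] + 1, ivS[2] - ivS[1] + 1)
    data.frame(family_id = famid, nautilus_contig = rn$contig_id,
               squid_contig = rs$contig_id, nautilus_origin = rn$origin,
               squid_origin = rs$origin,
               nautilus_interval = paste(ivN, collapse = "-"),
               squid_interval = paste(ivS, collapse = "-"),
               overlap_fraction = ov / shorter, window_identity = wid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}
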