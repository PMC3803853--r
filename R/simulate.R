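## Synthetic four-lineage generator: homologue families evolve from a random
## ancestor into human and fly reference proteins (symmetric branches whose
## compound substitution probability is pGlobal), then into nautilus and
## squid transcript contigs, with planted duplication, dual-origin
## duplication, differential-selection and decoy events, simulated coverage,
## and a machine-readable truth ledger.

randomProtein <- function(n) {
  paste(sample(.AA_ALPHABET, n, replace = TRUE), collapse = "")
}

.seqIdentity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}

#' Evolve a protein by i.i.d. per-site substitution
#'
#' Each site is independently replaced with probability \code{pSub} by a
#' uniformly chosen \emph{different} residue. This is deliberately not a
#' rate-matrix CTMC: the downstream detectors depend only on identity
#' levels, not on realistic exchangeabilities.
#'
#' @param seq protein string over the 20-residue alphabet
#' @param pSub per-site substitution probability
#' @return protein string of the same length
#' @examples
#' evolveProtein("MKV", 0)    # identity at probability zero
#' @export
evolveProtein <- function(seq, pSub) {
  aa <- strsplit(as.character(seq), "")[[1]]
  if (!length(aa)) stop("sequence must be non-empty")
  idx <- match(aa, .AA_ALPHABET)
  if (anyNA(idx))
    stop("non-amino-acid character(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ""))
  hit <- which(stats::runif(length(aa)) < pSub)
  if (length(hit)) {
    shift <- sample.int(19L, length(hit), replace = TRUE)
    idx[hit] <- (idx[hit] - 1L + shift) %% 20L + 1L
  }
  paste(.AA_ALPHABET[idx], collapse = "")
}

## substitute exactly k distinct sites (guarantees identity = 1 - k/L)
.mutateExact <- function(seq, k) {
  aa <- strsplit(seq, "")[[1]]
  if (k == 0L) return(seq)
  sites <- sample.int(length(aa), k)
  idx <- match(aa[sites], .AA_ALPHABET)
  shift <- sample.int(19L, k, replace = TRUE)
  aa[sites] <- .AA_ALPHABET[(idx - 1L + shift) %% 20L + 1L]
  paste(aa, collapse = "")
}

#' Plant a differential-selection event in a homologue family
#'
#' Inside a planted window the human and fly references are regenerated
#' independently (window identity forced to at most 0.30, the
#' "not conserved between Human and Drosophila" premise); one focal copy
#' then tracks the human window and the other the fly window at
#' \code{pWindowBias} noise (orientation randomized and recorded). Outside
#' the window both focal copies derive from a common origin-neutral
#' intermediate (a 50/50 per-site mosaic of the two references) at
#' \code{pFocal}, so the window alone decides each contig's best hit.
#'
#' @param human,fly reference proteins, already diverged at \code{pGlobal}
#' @param config a \linkS4class{SimulationConfig}
#' @return list with modified \code{human} and \code{fly}, the
#'   \code{nautilus} and \code{squid} contig proteins, \code{window}
#'   (start, end; 1-based protein coordinates), and the expected origins
#'   \code{nautOrigin}, \code{squidOrigin}
#' @export
plantSelectionEvent <- function(human, fly, config) {
  L <- nchar(human)
  stopifnot(nchar(fly) == L)
  w <- max(10L, round(config@windowFrac * L))
  if (w > L) stop("window longer than family")
  ws <- sample.int(L - w + 1L, 1L)
  we <- ws + w - 1L
  repeat {
    hw <- randomProtein(w)
    fw <- randomProtein(w)
    if (.seqIdentity(hw, fw) <= 0.30) break
  }
  splice <- function(s, win) {
    paste0(substring(s, 1L, ws - 1L), win, substring(s, we + 1L, L))
  }
  human2 <- splice(human, hw)
  fly2 <- splice(fly, fw)
  hx <- strsplit(human2, "")[[1]]
  fx <- strsplit(fly2, "")[[1]]
  useH <- stats::runif(L) < 0.5
  inter <- paste(ifelse(useH, hx, fx), collapse = "")
  nautOut <- evolveProtein(inter, config@pFocal)
  squidOut <- evolveProtein(inter, config@pFocal)
  squidTracksHuman <- stats::runif(1) < 0.5
  if (squidTracksHuman) {
    squidWin <- evolveProtein(hw, config@pWindowBias)
    nautWin <- evolveProtein(fw, config@pWindowBias)
    origins <- c(naut = "fly", squid = "human")
  } else {
    squidWin <- evolveProtein(fw, config@pWindowBias)
    nautWin <- evolveProtein(hw, config@pWindowBias)
    origins <- c(naut = "human", squid = "fly")
  }
  list(human = human2, fly = fly2,
       nautilus = splice(nautOut, nautWin),
       squid = splice(squidOut, squidWin),
       window = c(ws, we),
       nautOrigin = unname(origins["naut"]),
       squidOrigin = unname(origins["squid"]))
}

#' Plant a gene duplication in one focal species
#'
#' Non-dual duplications seed both copies from the family's nearest
#' reference; the second copy is derived from the first by substituting an
#' exact number of sites, so the pairwise identity lands in [0.70, 0.90] by
#' construction (below the 95\% duplicate criterion, clearly homologous).
#' Dual-origin duplications seed copy A from the human homologue and copy B
#' from the fly homologue (the NF1-style pattern), so their pairwise
#' identity reflects the reference divergence and is only guaranteed to
#' stay below the duplicate criterion.
#'
#' @param human,fly reference proteins of the family
#' @param config a \linkS4class{SimulationConfig}
#' @param dualOrigin logical
#' @param ref "human" or "fly": the nearest reference for non-dual copies
#' @return list with \code{copyA}, \code{copyB}, expected \code{origins}
#'   (length 2) and the realized protein \code{identity} of the pair
#' @export
plantDuplication <- function(human, fly, config, dualOrigin = FALSE,
                             ref = c("human", "fly")) {
  ref <- match.arg(ref)
  if (dualOrigin) {
    a <- evolveProtein(human, config@pFocal)
    b <- evolveProtein(fly, config@pFocal)
    origins <- c("human", "fly")
  } else {
    refSeq <- if (ref == "human") human else fly
    a <- evolveProtein(refSeq, config@pFocal)
    L <- nchar(a)
    k <- round((1 - stats::runif(1, 0.72, 0.88)) * L)
    b <- .mutateExact(a, k)
    origins <- c(ref, ref)
  }
  list(copyA = a, copyB = b, origins = origins,
       identity = .seqIdentity(a, b))
}

#' Simulate per-sample coverage for a set of contigs
#'
#' Base coverage is lognormal per contig; the two samples share the base
#' and differ by a small correlated log-noise
#' (sd = \code{coverageSigma * coverageNoiseFrac}), so non-differential
#' contigs rarely exceed the 2-fold rule by chance. Contigs with a planted
#' direction have that sample's value multiplied by a factor drawn from
#' \code{boostRange} (always >= 2.5). \code{aligned_bases} is the rounded
#' product of coverage and contig length, matching the normalized average
#' coverage representation downstream.
#'
#' @param contigIds character vector
#' @param contigLengths nucleotide lengths
#' @param direction per-contig planted direction: "none", "nautilus" or
#'   "squid"
#' @param config a \linkS4class{SimulationConfig}
#' @return long-format data.frame (contig_id, sample, aligned_bases,
#'   contig_length), two rows per contig
#' @export
simulateCoverage <- function(contigIds, contigLengths, direction, config) {
  n <- length(contigIds)
  stopifnot(length(contigLengths) == n, length(direction) == n)
  base <- exp(config@coverageMu +
              config@coverageSigma * stats::rnorm(n))
  noiseSd <- config@coverageSigma * config@coverageNoiseFrac
  covN <- base * exp(noiseSd * stats::rnorm(n))
  covS <- base * exp(noiseSd * stats::rnorm(n))
  boost <- stats::runif(n, config@boostRange[1], config@boostRange[2])
  covN[direction == "nautilus"] <- covN[direction == "nautilus"] *
    boost[direction == "nautilus"]
  covS[direction == "squid"] <- covS[direction == "squid"] *
    boost[direction == "squid"]
  data.frame(
    contig_id = rep(contigIds, 2L),
    sample = rep(c("nautilus", "squid"), each = n),
    aligned_bases = pmax(1, round(c(covN, covS) * rep(contigLengths, 2L))),
    contig_length = rep(contigLengths, 2L),
    stringsAsFactors = FALSE)
}

.goVocabulary <- function() {
  eye <- c("eye photoreceptor cell development", "lens fiber cell differentiation",
           "retina morphogenesis", "photoreceptor cell maintenance",
           "compound eye development", "lens crystallin assembly")
  other <- c("ribosome biogenesis", "glycolytic process", "DNA replication",
             "proteolysis", "microtubule-based movement", "ion transport",
             "tRNA aminoacylation", "lipid biosynthetic process",
             "oxidative phosphorylation", "mRNA splicing", "cell adhesion",
             "chromatin remodeling", "protein folding", "autophagy",
             "vesicle-mediated transport", "cilium assembly",
             "actin cytoskeleton organization", "apoptotic process",
             "signal transduction", "carbohydrate metabolic process",
             "nucleotide excision repair", "translation initiation",
             "fatty acid beta-oxidation", "protein glycosylation",
             "RNA polymerase II transcription", "ubiquitin-dependent catabolism")
  nm <- c(eye, other, "cellular response to stress")
  data.frame(go_id = sprintf("GO:S%06d", seq_along(nm)), go_name = nm,
             eye_flag = c(rep(TRUE, length(eye)),
                          rep(FALSE, length(other) + 1L)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic four-lineage dataset
#'
#' Builds the full bundle the pipeline consumes: human and fly reference
#' proteomes, nautilus and squid contig FASTA (nucleotide, obtained by
#' reverse translation so reading frame +1 recovers each contig protein),
#' a protein-to-GO table (1-3 terms per family from a 33-term vocabulary
#' with an eye-flagged subset, shared across the four lineage copies), the
#' homologue map, a coverage table, and the truth ledger. Deterministic
#' given the config (including its seed).
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param outdir optional directory; when given, the bundle is also written
#'   with \code{\link{writeSyntheticData}}
#' @return a \linkS4class{SyntheticEyeData}
#' @examples
#' d <- generateDataset(SimulationConfig(nFamilies = 12, nDuplications = 1,
#'   nDualOriginDuplications = 1, nSelectionEvents = 1, nQcDecoys = 0,
#'   nConservedDecoys = 0, seed = 42))
#' d
#' @export
generateDataset <- function(config, outdir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nFamilies
  rng <- config@familyLengthRange
  lens <- sample(rng[1]:rng[2], n, replace = TRUE)

  ## family roles
  role <- rep("ortholog", n)
  shuffled <- sample.int(n)
  take <- function(k) {
    out <- shuffled[seq_len(k)]
    shuffled <<- shuffled[-seq_len(k)]
    out
  }
  dupIdx <- take(config@nDuplications)
  dualIdx <- dupIdx[seq_len(config@nDualOriginDuplications)]
  selIdx <- take(config@nSelectionEvents)
  qcIdx <- take(config@nQcDecoys)
  consIdx <- take(config@nConservedDecoys)
  role[dupIdx] <- "duplication"
  role[dualIdx] <- "dual_origin_duplication"
  role[selIdx] <- "selection"
  role[qcIdx] <- "qc_decoy"
  role[consIdx] <- "conserved_decoy"
  if (length(qcIdx)) {
    if (rng[2] < 200L)
      stop("qc decoys need a maximum family length of at least 200 residues")
    lens[qcIdx] <- sample(max(200L, rng[1]):rng[2], length(qcIdx),
                          replace = TRUE)
  }

  famId <- sprintf("FAM%04d", seq_len(n))
  humanId <- paste0("HSA_", famId)
  flyId <- paste0("DME_", famId)

  ## planted expression direction, per family (contigs of a family share it)
  fd <- config@fracDifferential
  dirFam <- sample(c("none", "nautilus", "squid"), n, replace = TRUE,
                   prob = c(1 - fd, fd / 2, fd / 2))

  ## GO terms per family; decoy families stay non-eye so the eye truth set
  ## is exactly the eye-flagged families
  voc <- .goVocabulary()
  eyeTermIdx <- which(voc$eye_flag)
  baseTermIdx <- seq_len(nrow(voc) - 1L)           # term 33 is planted only
  nonEyeTermIdx <- setdiff(baseTermIdx, eyeTermIdx)
  famTerms <- vector("list", n)
  for (i in seq_len(n)) {
    pool <- if (role[i] %in% c("qc_decoy", "conserved_decoy"))
      nonEyeTermIdx else baseTermIdx
    famTerms[[i]] <- sample(pool, sample.int(3L, 1L))
    pUp <- if (dirFam[i] == "nautilus") config@enrichedTermFreqUp
           else config@enrichedTermFreqBase
    if (stats::runif(1) < pUp)
      famTerms[[i]] <- c(famTerms[[i]], nrow(voc))
  }
  famEye <- vapply(famTerms, function(t) any(t %in% eyeTermIdx), logical(1))

  ## pass 1: reference proteins (selection events modify them in pass 2)
  qBranch <- 1 - sqrt(1 - config@pGlobal)
  refLabel <- sample(c("human", "fly"), n, replace = TRUE)
  humanSeq <- character(n)
  flySeq <- character(n)
  for (i in seq_len(n)) {
    anc <- randomProtein(lens[i])
    humanSeq[i] <- evolveProtein(anc, qBranch)
    flySeq[i] <- if (role[i] == "conserved_decoy")
      evolveProtein(humanSeq[i], 0.10) else evolveProtein(anc, qBranch)
  }

  ## pass 2: contigs and truth
  events <- list()
  contigs <- list()   # rows: contig_id, species, family, origin
  seqsN <- character(0); seqsS <- character(0)
  addContig <- function(id, species, fam, origin, prot) {
    contigs[[length(contigs) + 1L]] <<- data.frame(
      contig_id = id, species = species, family_id = fam,
      expected_origin = origin, stringsAsFactors = FALSE)
    if (species == "nautilus") seqsN[id] <<- prot else seqsS[id] <<- prot
  }
  cid <- function(i, species, k) {
    sprintf("%scomp%04d_c0_seq%d", if (species == "nautilus") "n" else "s",
            i, k)
  }
  selOrder <- order(match(role, c("selection"), nomatch = 2L))
  eyeSourcePool <- which(role == "ortholog" & famEye)
  for (i in selOrder) {
    refSeq <- if (refLabel[i] == "human") humanSeq[i] else flySeq[i]
    switch(role[i],
      ortholog = {
        addContig(cid(i, "nautilus", 1), "nautilus", famId[i], refLabel[i],
                  evolveProtein(refSeq, config@pFocal))
        addContig(cid(i, "squid", 1), "squid", famId[i], refLabel[i],
                  evolveProtein(refSeq, config@pFocal))
      },
      conserved_decoy = {
        idN <- cid(i, "nautilus", 1); idS <- cid(i, "squid", 1)
        addContig(idN, "nautilus", famId[i], "human",
                  evolveProtein(humanSeq[i], config@pFocal))
        addContig(idS, "squid", famId[i], "fly",
                  evolveProtein(flySeq[i], config@pFocal))
        events[[length(events) + 1L]] <- data.frame(
          family_id = famId[i], event_kind = "conserved_decoy", species = NA,
          contig_ids = paste(idN, idS, sep = ";"),
          origins = "human;fly", window_start = NA_integer_,
          window_end = NA_integer_, stringsAsFactors = FALSE)
      },
      selection = {
        ps <- plantSelectionEvent(humanSeq[i], flySeq[i], config)
        humanSeq[i] <- ps$human; flySeq[i] <- ps$fly
        idN <- cid(i, "nautilus", 1); idS <- cid(i, "squid", 1)
        addContig(idN, "nautilus", famId[i], ps$nautOrigin, ps$nautilus)
        addContig(idS, "squid", famId[i], ps$squidOrigin, ps$squid)
        events[[length(events) + 1L]] <- data.frame(
          family_id = famId[i], event_kind = "selection", species = NA,
          contig_ids = paste(idN, idS, sep = ";"),
          origins = paste(ps$nautOrigin, ps$squidOrigin, sep = ";"),
          window_start = ps$window[1], window_end = ps$window[2],
          stringsAsFactors = FALSE)
      },
      duplication = ,
      dual_origin_duplication = {
        dual <- role[i] == "dual_origin_duplication"
        host <- sample(c("nautilus", "squid"), 1L)
        other <- setdiff(c("nautilus", "squid"), host)
        pd <- plantDuplication(humanSeq[i], flySeq[i], config,
                               dualOrigin = dual, ref = refLabel[i])
        idA <- cid(i, host, 1); idB <- cid(i, host, 2)
        addContig(idA, host, famId[i], pd$origins[1], pd$copyA)
        addContig(idB, host, famId[i], pd$origins[2], pd$copyB)
        addContig(cid(i, other, 1), other, famId[i], refLabel[i],
                  evolveProtein(refSeq, config@pFocal))
        events[[length(events) + 1L]] <- data.frame(
          family_id = famId[i], event_kind = role[i], species = host,
          contig_ids = paste(idA, idB, sep = ";"),
          origins = paste(pd$origins, collapse = ";"),
          window_start = NA_integer_, window_end = NA_integer_,
          stringsAsFactors = FALSE)
      },
      qc_decoy = {
        host <- sample(c("nautilus", "squid"), 1L)
        other <- setdiff(c("nautilus", "squid"), host)
        base <- evolveProtein(refSeq, config@pFocal)
        L <- lens[i]
        wd <- round(0.3 * L)
        if (!length(eyeSourcePool))
          stop("no eye-flagged ortholog family available as qc-decoy source")
        srcOk <- eyeSourcePool[lens[eyeSourcePool] >= wd]
        if (!length(srcOk)) srcOk <- eyeSourcePool
        src <- if (length(srcOk) == 1L) srcOk else sample(srcOk, 1L)
        wd <- min(wd, lens[src])
        srcRef <- if (refLabel[src] == "human") humanSeq[src] else flySeq[src]
        s0 <- sample.int(nchar(srcRef) - wd + 1L, 1L)
        seg <- evolveProtein(substring(srcRef, s0, s0 + wd - 1L),
                             config@pFocal)
        decoy <- paste0(substring(base, 1L, L - wd), seg)
        idD <- cid(i, host, 1)
        addContig(idD, host, famId[i], refLabel[i], decoy)
        addContig(cid(i, other, 1), other, famId[i], refLabel[i],
                  evolveProtein(refSeq, config@pFocal))
        events[[length(events) + 1L]] <- data.frame(
          family_id = famId[i], event_kind = "qc_decoy", species = host,
          contig_ids = idD, origins = refLabel[i],
          window_start = L - wd + 1L, window_end = L,
          stringsAsFactors = FALSE)
      })
  }
  truthContigs <- do.call(rbind, contigs)
  truthContigs$differential <-
    dirFam[match(truthContigs$family_id, famId)] != "none"
  truthContigs$direction <- dirFam[match(truthContigs$family_id, famId)]
  truthContigs$role <- role[match(truthContigs$family_id, famId)]
  truthEvents <- if (length(events)) do.call(rbind, events) else
    data.frame(family_id = character(), event_kind = character(),
               species = character(), contig_ids = character(),
               origins = character(), window_start = integer(),
               window_end = integer(), stringsAsFactors = FALSE)

  ## reverse-translate contig proteins (order: nautilus then squid)
  dnaN <- vapply(seqsN, reverseTranslate, character(1))
  dnaS <- vapply(seqsS, reverseTranslate, character(1))

  covDir <- truthContigs$direction
  allIds <- truthContigs$contig_id
  allLen <- 3L * nchar(c(seqsN, seqsS)[allIds])
  coverage <- simulateCoverage(allIds, allLen, covDir, config)

  goRows <- do.call(rbind, lapply(seq_len(n), function(i) {
    t <- famTerms[[i]]
    data.frame(protein_id = rep(c(humanId[i], flyId[i]), each = length(t)),
               go_id = rep(voc$go_id[t], 2L),
               go_name = rep(voc$go_name[t], 2L),
               eye_flag = rep(voc$eye_flag[t], 2L), stringsAsFactors = FALSE)
  }))

  hset <- Biostrings::AAStringSet(humanSeq); names(hset) <- humanId
  fset <- Biostrings::AAStringSet(flySeq); names(fset) <- flyId
  nset <- Biostrings::DNAStringSet(dnaN)
  sset <- Biostrings::DNAStringSet(dnaS)

  x <- new("SyntheticEyeData", humanProteins = hset, flyProteins = fset,
           nautilusContigs = nset, squidContigs = sset, coverage = coverage,
           goMap = goRows,
           homologueMap = data.frame(human_protein_id = humanId,
                                     fly_protein_id = flyId,
                                     family_id = famId,
                                     stringsAsFactors = FALSE),
           truthEvents = truthEvents, truthContigs = truthContigs,
           config = config)
  if (!is.null(outdir)) writeSyntheticData(x, outdir)
  x
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits human/fly protein FASTA, nautilus/squid contig FASTA, the
#' coverage, GO-map and homologue-map TSVs, and the truth ledger as JSON.
#'
#' @param x a \linkS4class{SyntheticEyeData}
#' @param outdir output directory (created if needed)
#' @return invisibly, the vector of written paths
#' @export
writeSyntheticData <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  writeFasta(x@humanProteins, p("human_proteins.fasta"))
  writeFasta(x@flyProteins, p("fly_proteins.fasta"))
  writeFasta(x@nautilusContigs, p("nautilus_contigs.fasta"))
  writeFasta(x@squidContigs, p("squid_contigs.fasta"))
  writeTable(x@coverage, p("coverage.tsv"))
  writeTable(x@goMap, p("go_map.tsv"))
  writeTable(x@homologueMap, p("homologue_map.tsv"))
  jsonlite::write_json(list(events = x@truthEvents, contigs = x@truthContigs),
                       p("truth.json"), dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(vapply(c("human_proteins.fasta", "fly_proteins.fasta",
                     "nautilus_contigs.fasta", "squid_contigs.fasta",
                     "coverage.tsv", "go_map.tsv", "homologue_map.tsv",
                     "truth.json"), p, character(1)))
}

.idSetKey <- function(ids) {
  vapply(strsplit(ids, ";", fixed = TRUE),
         function(v) paste(sort(v), collapse = ";"), character(1))
}

#' Score detected events against the truth ledger
#'
#' Events match when their contig-id sets are equal. Sensitivity is
#' recovered planted events over planted; precision is recovered over
#' reported. With no reported events precision is returned as 1 by
#' convention, with a warning.
#'
#' @param duplications data.frame of duplication candidates (needs a
#'   \code{contig_ids} column, ";"-joined); may be empty or NULL
#' @param selections data.frame of selection candidates (needs
#'   \code{nautilus_contig} and \code{squid_contig} or \code{contig_ids})
#' @param truth the \code{truthEvents} table of the generating dataset
#' @return data.frame with one row per event kind ("duplication" covers
#'   dual-origin too; "dual_origin_duplication" is the subset;
#'   "selection"): counts, sensitivity and precision
#' @export
scoreDetection <- function(duplications, selections, truth) {
  candKey <- function(df, cols = "contig_ids") {
    if (is.null(df) || !nrow(df)) return(character(0))
    if ("contig_ids" %in% names(df)) .idSetKey(df$contig_ids)
    else .idSetKey(paste(df$nautilus_contig, df$squid_contig, sep = ";"))
  }
  dupKey <- candKey(duplications)
  selKey <- candKey(selections)
  one <- function(kind, truthKinds, repKey) {
    tr <- truth[truth$event_kind %in% truthKinds, , drop = FALSE]
    trKey <- .idSetKey(tr$contig_ids)
    matched <- sum(trKey %in% repKey)
    if (!length(repKey) && nrow(tr) > 0)
      warning("no reported ", kind,
              " candidates; precision set to 1 by convention")
    data.frame(kind = kind, n_truth = nrow(tr), n_reported = length(repKey),
               n_matched = matched,
               sensitivity = if (nrow(tr)) matched / nrow(tr) else NA_real_,
               precision = if (length(repKey))
                 sum(repKey %in% trKey) / length(repKey) else 1,
               stringsAsFactors = FALSE)
  }
  rbind(
    one("duplication", c("duplication", "dual_origin_duplication"), dupKey),
    one("dual_origin_duplication", "dual_origin_duplication",
        if (!is.null(duplications) && nrow(duplications))
          dupKey[duplications$dual_origin] else character(0)),
    one("selection", "selection", selKey))
}
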