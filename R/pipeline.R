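## End-to-end orchestration: length filter -> translated search ->
## expression filter -> annotation transfer -> enrichment -> eye
## classification -> event detection -> per-candidate phylogenetics,
## with a run report (per-stage counts, truth metrics when available,
## file manifest with checksums).

.loadBundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- NULL
  if (file.exists(p("truth.json"))) {
    tj <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
    truth <- list(events = as.data.frame(tj$events),
                  contigs = as.data.frame(tj$contigs))
  }
  list(human = readFasta(p("human_proteins.fasta"), "protein"),
       fly = readFasta(p("fly_proteins.fasta"), "protein"),
       nautilus = readFasta(p("nautilus_contigs.fasta"), "dna"),
       squid = readFasta(p("squid_contigs.fasta"), "dna"),
       coverage = readTable(p("coverage.tsv"), "coverage"),
       goMap = readTable(p("go_map.tsv"), "go_map"),
       homologueMap = readTable(p("homologue_map.tsv"), "homologue_map"),
       truth = truth)
}

.asBundle <- function(x) {
  if (is(x, "SyntheticEyeData"))
    return(list(human = x@humanProteins, fly = x@flyProteins,
                nautilus = x@nautilusContigs, squid = x@squidContigs,
                coverage = x@coverage, goMap = x@goMap,
                homologueMap = x@homologueMap,
                truth = list(events = x@truthEvents,
                             contigs = x@truthContigs)))
  if (is.character(x) && length(x) == 1L && dir.exists(x))
    return(.loadBundle(x))
  stop("input must be a SyntheticEyeData or a bundle directory")
}

.expressionMetrics <- function(sel, truthContigs) {
  tc <- truthContigs
  selOf <- stats::setNames(sel$table$selected_sample, sel$table$contig_id)
  got <- unname(selOf[tc$contig_id])
  got[is.na(got)] <- "none"
  planted <- tc$direction != "none"
  list(differential_recall = if (any(planted))
         mean(got[planted] == tc$direction[planted]) else NA_real_,
       false_selection_rate = if (any(!planted))
         mean(got[!planted] != "none") else NA_real_)
}

.originAccuracy <- function(assignments, truthContigs) {
  tc <- truthContigs[truthContigs$role == "ortholog", , drop = FALSE]
  m <- merge(tc, assignments[, c("contig_id", "origin")], by = "contig_id")
  if (!nrow(m)) return(NA_real_)
  mean(m$origin == m$expected_origin)
}

#' Run the full comparative-homology pipeline
#'
#' Executes all stages on a dataset bundle (a
#' \linkS4class{SyntheticEyeData} or a directory written by
#' \code{\link{writeSyntheticData}}): contig length filter, translated
#' best-hit search against the combined human+fly proteome, normalized
#' coverage and up-regulated contig selection, GO annotation transfer and
#' enrichment between the two up-sets, eye-related contig extraction with
#' whole-proteome QC, duplication and differential-selection detection,
#' and an NJ tree per dual-origin duplication and selection candidate.
#' When a truth ledger is available, detection metrics are added to the
#' report. Outputs are deterministic given the inputs.
#'
#' @param x dataset bundle (object or directory)
#' @param config a \linkS4class{PipelineConfig}
#' @param outdir optional output directory; when given, all result tables,
#'   trees and the JSON report are written and checksummed
#' @return list with \code{report} plus all stage results (\code{hits},
#'   \code{assignments}, \code{expression}, \code{enrichment}, \code{eye},
#'   \code{duplications}, \code{selections}, \code{trees})
#' @export
runPipeline <- function(x, config = PipelineConfig(), outdir = NULL) {
  b <- .asBundle(x)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  allContigs <- c(b$nautilus, b$squid)
  nPass <- sum(Biostrings::width(allContigs) > config@minContigLen)

  hits <- stage("search", searchContigs(
    allContigs, list(human = b$human, fly = b$fly), config@scheme,
    eCutoff = config@searchEvalue, minLen = config@minContigLen))
  assignments <- bestHits(hits)
  assignments$species <- ifelse(assignments$contig_id %in% names(b$nautilus),
                                "nautilus", "squid")

  norm <- stage("expression", normalizedCoverage(b$coverage))
  sel <- selectCandidates(norm, config@minCoverage, config@foldChange)

  contigGo <- stage("annotation",
                    transferAnnotations(hits, b$goMap,
                                        config@annotationEvalue))
  enr <- stage("enrichment", enrichGO(sel$nautilus, sel$squid, contigGo,
                                      config@fdrAlpha))

  eyeProteins <- stage("classify", selectEyeProteins(b$goMap))
  rawEye <- rawEyeContigs(hits, eyeProteins, config@annotationEvalue)
  eye <- qcBestHits(hits, rawEye, eyeProteins, strict = config@strictQc)
  eye$species <- ifelse(eye$contig_id %in% names(b$nautilus), "nautilus",
                        "squid")

  asgN <- assignments[assignments$species == "nautilus", , drop = FALSE]
  asgS <- assignments[assignments$species == "squid", , drop = FALSE]
  dups <- stage("detect", rbind(
    detectDuplications(asgN, b$nautilus, b$homologueMap, b$human, b$fly,
                       config, species = "nautilus"),
    detectDuplications(asgS, b$squid, b$homologueMap, b$human, b$fly,
                       config, species = "squid")))
  sels <- stage("detect", detectSelectionPairs(
    asgN, asgS, b$nautilus, b$squid, b$homologueMap, b$human, b$fly,
    config))

  trees <- stage("tree", .candidateTrees(dups, sels, assignments, b, config))

  counts <- list(
    contigs_total = length(allContigs), contigs_pass_length = nPass,
    hits = nrow(hits), contigs_with_hits = length(unique(hits$contig_id)),
    annotated_contigs = length(unique(contigGo$contig_id)),
    up_nautilus = length(sel$nautilus), up_squid = length(sel$squid),
    enrichment_tests = nrow(enr),
    enrichment_significant = sum(enr$significant),
    eye_raw = length(rawEye), eye_final = sum(eye$qc_pass),
    duplication_candidates = nrow(dups),
    selection_candidates = nrow(sels), trees = length(trees))

  metrics <- NULL
  if (!is.null(b$truth) && nrow(b$truth$events) >= 0) {
    det <- scoreDetection(dups, sels, b$truth$events)
    em <- .expressionMetrics(sel, b$truth$contigs)
    metrics <- list(detection = det,
                    differential_recall = em$differential_recall,
                    false_selection_rate = em$false_selection_rate,
                    origin_accuracy = .originAccuracy(assignments,
                                                      b$truth$contigs))
  }

  report <- list(schema = "cephoscope-report/1",
                 config = .configEcho(config), counts = counts,
                 metrics = metrics)
  out <- list(report = report, hits = hits, assignments = assignments,
              expression = sel, enrichment = enr, eye = eye,
              duplications = dups, selections = sels, trees = trees)
  if (!is.null(outdir)) out <- .writeRun(out, outdir)
  out
}

.configEcho <- function(config) {
  list(min_contig_len = config@minContigLen,
       min_coverage = config@minCoverage, fold_change = config@foldChange,
       search_evalue = config@searchEvalue,
       annotation_evalue = config@annotationEvalue,
       duplication_identity_max = config@duplicationIdentityMax,
       same_region_min_overlap = config@sameRegionMinOverlap,
       conservation_max_identity = config@conservationMaxIdentity,
       fdr_alpha = config@fdrAlpha, strict_qc = config@strictQc,
       kimura = config@kimura)
}

## one NJ tree per dual-origin duplication (contig pair + both references)
## and per selection candidate (cross-species pair + both references);
## contigs are trimmed to their best-hit region first
.candidateTrees <- function(dups, sels, assignments, b, config) {
  trees <- list()
  contigSeq <- c(b$nautilus, b$squid)
  frag <- function(id) {
    rec <- assignments[assignments$contig_id == id, ][1, ]
    trimToHit(as.character(contigSeq[[id]]), rec)
  }
  famRow <- function(famid)
    b$homologueMap[b$homologueMap$family_id == famid, , drop = FALSE]
  addTree <- function(key, ids, origins, famid) {
    fr <- famRow(famid)
    seqs <- c(vapply(ids, frag, character(1)),
              stats::setNames(as.character(b$human[[fr$human_protein_id]]),
                              fr$human_protein_id),
              stats::setNames(as.character(b$fly[[fr$fly_protein_id]]),
                              fr$fly_protein_id))
    tr <- tryCatch(candidateTree(seqs, config@scheme, config@kimura),
                   error = function(e) NULL)
    if (is.null(tr)) return()
    trees[[key]] <<- list(tree = tr, family_id = famid, contig_ids = ids,
                          origins = origins,
                          human_id = fr$human_protein_id,
                          fly_id = fr$fly_protein_id,
                          contig_distance = leafDistance(tr, ids[1], ids[2]))
  }
  if (nrow(dups)) {
    dd <- dups[dups$dual_origin, , drop = FALSE]
    for (k in seq_len(nrow(dd))) {
      ids <- strsplit(dd$contig_ids[k], ";", fixed = TRUE)[[1]]
      org <- strsplit(dd$origins[k], ";", fixed = TRUE)[[1]]
      addTree(paste0("dup_", dd$family_id[k]), ids, org, dd$family_id[k])
    }
  }
  if (nrow(sels)) {
    for (k in seq_len(nrow(sels))) {
      addTree(paste0("sel_", sels$family_id[k]),
              c(sels$nautilus_contig[k], sels$squid_contig[k]),
              c(sels$nautilus_origin[k], sels$squid_origin[k]),
              sels$family_id[k])
    }
  }
  trees
}

.writeRun <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  writeTable(out$hits, p("hits.tsv"))
  writeTable(out$assignments, p("assignments.tsv"))
  writeTable(out$expression$table, p("expression.tsv"))
  writeTable(out$enrichment, p("enrichment.tsv"))
  writeTable(out$eye, p("eye_contigs.tsv"))
  writeTable(out$duplications, p("duplications.tsv"))
  writeTable(out$selections, p("selections.tsv"))
  jsonlite::write_json(out$duplications, p("duplications.json"),
                       dataframe = "rows", na = "null", digits = NA)
  jsonlite::write_json(out$selections, p("selections.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (length(out$trees)) {
    nwk <- vapply(out$trees, function(t) writeNewick(t$tree), character(1))
    writeLines(paste0(names(out$trees), "\t", nwk), p("trees.nwk"))
  } else {
    writeLines(character(0), p("trees.nwk"))
  }
  files <- c("hits.tsv", "assignments.tsv", "expression.tsv",
             "enrichment.tsv", "eye_contigs.tsv", "duplications.tsv",
             "selections.tsv", "duplications.json", "selections.json",
             "trees.nwk")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(vapply(files, p,
                                                           character(1)))),
                         stringsAsFactors = FALSE)
  out$report$manifest <- manifest
  jsonlite::write_json(out$report, p("report.json"), dataframe = "rows",
                       na = "null", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out
}
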