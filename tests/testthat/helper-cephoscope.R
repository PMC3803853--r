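## Shared fixtures, generated in code. The small dataset and its pipeline
## run are cached per session because several files inspect them.

.fixtures <- new.env()

smallConfig <- function(seed = 101) {
  SimulationConfig(nFamilies = 60, familyLengthRange = c(80, 300),
                   nDuplications = 3, nDualOriginDuplications = 1,
                   nSelectionEvents = 3, nQcDecoys = 2, nConservedDecoys = 2,
                   seed = seed)
}

sharedDataset <- function() {
  if (is.null(.fixtures$dataset))
    .fixtures$dataset <- generateDataset(smallConfig())
  .fixtures$dataset
}

sharedRun <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- suppressWarnings(suppressMessages(
      runPipeline(sharedDataset())))
  .fixtures$run
}

randomAA <- function(n, alphabet = cephoscope:::.AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mkHits <- function(contig, subject, evalue) {
  data.frame(contig_id = contig, subject_id = subject, organism = "human",
             frame = 1L, qstart = 1L, qend = 30L, sstart = 1L, send = 10L,
             raw = 50, bits = 25, evalue = evalue, identity = 0.9,
             stringsAsFactors = FALSE)
}

mkGoMap <- function(protein, go) {
  data.frame(protein_id = protein, go_id = go, go_name = go,
             eye_flag = FALSE, stringsAsFactors = FALSE)
}

## independent hypergeometric enumeration of the one-sided Fisher p-value
enumFisherP <- function(a, b, c, d) {
  K <- a + b          # contigs with the term
  n <- a + c          # test-set size
  N <- a + b + c + d
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

## gapped strings with an exact mismatch fraction d over 20 columns
alignedPairWithD <- function(d) {
  n <- 20L
  k <- as.integer(round(d * n))
  a <- strsplit(paste(rep("A", n), collapse = ""), "")[[1]]
  b <- a
  if (k > 0) b[seq_len(k)] <- "R"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
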