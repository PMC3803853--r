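## Readers/writers for the external formats the pipeline touches. All
## coordinates downstream are 1-based inclusive (protein subjects and contig
## nucleotides, the tabular-BLAST convention); ids are the FASTA token before
## the first whitespace.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read a FASTA file with strict validation
#'
#' Sequences are upper-cased and multi-line records joined; record order is
#' preserved. Duplicate ids, characters outside the declared alphabet
#' (DNA: ACGTN; protein: the 20 residues plus X and *) and empty files are
#' each reported as errors.
#'
#' @param path file path
#' @param alphabet "dna" or "protein"
#' @return a \code{DNAStringSet} or \code{AAStringSet} named by id
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT"), tf)
#' readFasta(tf, "dna")
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines) || !any(startsWith(lines, ">")))
    stop("empty or headerless FASTA file: ", path)
  hdr <- which(startsWith(lines, ">"))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < hdr[i] + 1L) return("")
    toupper(paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
  }, character(1))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  ok <- if (alphabet == "dna") .DNA_ALPHABET else c(.AA_ALPHABET, "X", "*")
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), ok)
  if (length(bad))
    stop("illegal ", alphabet, " character(s) in ", path, ": ",
         paste(bad, collapse = ""))
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences as FASTA
#'
#' @param seqs a named XStringSet or named character vector
#' @param path output path
#' @param width line width
#' @return invisibly, \code{path}
#' @export
writeFasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(seqs)) {
      writeLines(paste0(">", names(seqs)[i]), con)
      s <- seqs[[i]]
      writeLines(substring(s, seq(1, nchar(s), width),
                           pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
                 con)
    }
  } else {
    Biostrings::writeXStringSet(seqs, path, width = width)
  }
  invisible(path)
}

## column schemas for the pipeline's TSV contracts
.SCHEMAS <- list(
  coverage = c(contig_id = "character", sample = "character",
               aligned_bases = "numeric", contig_length = "numeric"),
  go_map = c(protein_id = "character", go_id = "character",
             go_name = "character", eye_flag = "logical"),
  homologue_map = c(human_protein_id = "character",
                    fly_protein_id = "character", family_id = "character"),
  hits = c(contig_id = "character", subject_id = "character",
           organism = "character", frame = "integer", qstart = "integer",
           qend = "integer", sstart = "integer", send = "integer",
           raw = "numeric", bits = "numeric", evalue = "numeric",
           identity = "numeric")
)

#' Read a typed TSV table against a named schema
#'
#' @param path file path
#' @param schema one of \code{"coverage"}, \code{"go_map"},
#'   \code{"homologue_map"}, \code{"hits"}, or a named character vector of
#'   column classes
#' @return a data.frame with typed columns; header-only files yield an
#'   empty data.frame with the schema's columns
#' @export
readTable <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!schema %in% names(.SCHEMAS)) stop("unknown schema: ", schema)
    schema <- .SCHEMAS[[schema]]
  }
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df <- df[names(schema)]
  for (col in names(schema)) {
    cls <- schema[[col]]
    v <- df[[col]]
    conv <- switch(cls, character = as.character(v), logical = as.logical(v),
                   integer = suppressWarnings(as.integer(v)),
                   numeric = suppressWarnings(as.numeric(v)),
                   stop("unsupported class: ", cls))
    bad <- which(is.na(conv) & !is.na(v))
    if (length(bad))
      stop("unparseable ", cls, " in ", path, " column '", col, "', row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    df[[col]] <- conv
  }
  df
}

#' Write a table as TSV
#'
#' @param df data.frame
#' @param path output path
#' @return invisibly, \code{path}
#' @export
writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys mirror the \code{\link{PipelineConfig}} constructor arguments;
#' unknown keys are rejected.
#'
#' @param path YAML file
#' @return a \linkS4class{PipelineConfig}
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  fml <- names(formals(PipelineConfig))
  bad <- setdiff(names(vals), fml)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(PipelineConfig, vals)
}
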