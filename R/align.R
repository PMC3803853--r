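#' @useDynLib cephoscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.encodeSeq <- function(x, scheme) {
  alpha <- rownames(scheme@matrix)
  chars <- strsplit(x, "")[[1]]
  idx <- match(chars, alpha)
  if (anyNA(idx))
    stop("character(s) not in the scoring alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ""))
  idx - 1L
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' Computes the optimal local alignment score under the scheme. A gap of
#' length L costs \code{gapOpen + L * gapExtend}. When no positive-scoring
#' alignment exists the score is 0 and the intervals are NA. Ties among
#' equal-score optima are broken by smallest subject start, then smallest
#' query start, so results are reproducible.
#'
#' @param query,subject protein strings
#' @param scheme a \linkS4class{ScoringScheme}
#' @return list with \code{score}, \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send} (1-based inclusive), \code{identity}
#'   (fraction of aligned columns with equal residues) and \code{ncol}
#' @examples
#' localAlign("MKV", "MKV")$score  # 5 + 5 + 4 on the BLOSUM62 diagonal
#' @export
localAlign <- function(query, subject, scheme = ScoringScheme()) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty")
  .sw_local(.encodeSeq(query, scheme), .encodeSeq(subject, scheme),
            scheme@matrix, as.integer(scheme@gapOpen),
            as.integer(scheme@gapExtend))
}

## Reference scorer: exhaustive enumeration over every increasing matching of
## query/subject positions (exponential; short sequences only). Kept separate
## from the dynamic program so the two can check each other.
bruteLocalScore <- function(query, subject, scheme = ScoringScheme()) {
  .sw_brute_score(.encodeSeq(query, scheme), .encodeSeq(subject, scheme),
                  scheme@matrix, as.integer(scheme@gapOpen),
                  as.integer(scheme@gapExtend))
}

#' Karlin-Altschul bit score and e-value
#'
#' \code{bit = (lambda * raw - ln K) / ln 2} and
#' \code{e = m * n * 2^-bit}, with the plain m x n search space (no length
#' corrections): e-values here are used for thresholding and ranking only.
#'
#' @param raw raw alignment score
#' @param m query length
#' @param n database length (total residues)
#' @param scheme a \linkS4class{ScoringScheme}
#' @return list with \code{bit} and \code{evalue}
#' @examples
#' bitScoreEvalue(100, 300, 1e5)$bit  # about 43.13
#' @export
bitScoreEvalue <- function(raw, m, n, scheme = ScoringScheme()) {
  if (m <= 0 || n <= 0) stop("m and n must be positive")
  bit <- (scheme@lambda * raw - log(scheme@K)) / log(2)
  list(bit = bit, evalue = m * n * 2^(-bit))
}

#' Global alignment of two sequences
#'
#' Thin wrapper around \code{Biostrings::pairwiseAlignment} returning the
#' two gapped strings. \code{type = "global"} aligns end to end;
#' \code{type = "overlap"} leaves end gaps free (used for contig-contig
#' comparison of fragments of unequal length).
#'
#' @param a,b sequences (character or XString); for \code{dna = TRUE} a
#'   nucleotide match/mismatch matrix is used instead of the protein matrix
#' @param scheme a \linkS4class{ScoringScheme} (protein mode)
#' @param type "global" or "overlap"
#' @param dna logical
#' @return list of gapped strings \code{a} and \code{b}
#' @export
globalAlign <- function(a, b, scheme = ScoringScheme(),
                        type = c("global", "overlap"), dna = FALSE) {
  type <- match.arg(type)
  if (dna) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(as.character(a)),
      Biostrings::DNAString(as.character(b)),
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2, type = type)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(as.character(a)),
      Biostrings::AAString(as.character(b)),
      substitutionMatrix = scheme@matrix, gapOpening = scheme@gapOpen,
      gapExtension = scheme@gapExtend, type = type)
  }
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)))
}

#' Identity of two contigs from a global alignment with free end gaps
#'
#' Contigs are fragments of unequal length, so the shorter contig is
#' aligned end to end within the longer one (overhangs of the longer
#' contig are free and excluded); identity is matches over aligned
#' columns, internal gaps counting as mismatch columns. A fully free
#' overlap alignment is deliberately avoided: for dissimilar pairs it
#' degenerates to short perfect islands and overstates identity.
#'
#' @param a,b nucleotide sequences
#' @return identity fraction in [0, 1]
#' @export
contigIdentity <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2,
    type = "global-local")
  x <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(x == y & x != "-") / length(x)
}
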