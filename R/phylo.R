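## Corrected protein distances and neighbor-joining trees for candidate
## gene sets. Candidates involve at most a handful of short fragments, so
## distances come from pairwise global alignments under the package scheme
## rather than a progressive multiple alignment.

#' Kimura-corrected protein distance of an aligned pair
#'
#' Columns where either sequence has a gap are excluded; the observed
#' mismatch fraction d over the compared columns is returned as is, or
#' corrected as \code{D = -ln(1 - d - 0.2 d^2)} (the classic protein
#' distance correction, undefined for d >= 0.85).
#'
#' @param a,b equal-length aligned (gapped) strings
#' @param kimura apply the correction (default, matching common
#'   protein-distance practice)
#' @return the distance
#' @examples
#' pairwiseDistance("MKV", "MKV")           # 0
#' @export
pairwiseDistance <- function(a, b, kimura = TRUE) {
  x <- strsplit(as.character(a), "")[[1]]
  y <- strsplit(as.character(b), "")[[1]]
  if (length(x) != length(y)) stop("aligned strings must have equal length")
  keep <- x != "-" & y != "-"
  if (!sum(keep)) stop("zero compared columns")
  d <- mean(x[keep] != y[keep])
  if (!kimura) return(d)
  if (d >= 0.85)
    stop("observed distance ", round(d, 3),
         " >= 0.85: Kimura correction undefined")
  -log(1 - d - 0.2 * d^2)
}

#' Pairwise distance matrix for a set of protein sequences
#'
#' Globally aligns every pair under the scheme and applies
#' \code{\link{pairwiseDistance}}.
#'
#' @param seqs named \code{AAStringSet} or named character vector
#' @param scheme a \linkS4class{ScoringScheme}
#' @param kimura apply the Kimura correction
#' @return symmetric matrix with zero diagonal, labeled by sequence name
#' @export
distanceMatrix <- function(seqs, scheme = ScoringScheme(), kimura = TRUE) {
  nm <- names(seqs)
  seqs <- as.character(seqs)   # strips names for character input
  names(seqs) <- nm
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- globalAlign(seqs[[i]], seqs[[j]], scheme, type = "global")
      d[i, j] <- d[j, i] <- pairwiseDistance(al$a, al$b, kimura)
    }
  }
  d
}

.checkDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    stop("distance matrix needs unique labels")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  invisible(TRUE)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimizing
#' \code{Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)}, with branch
#' lengths from the standard two-point formulas. Ties on Q are broken by
#' the lexicographically smallest label pair (each cluster represented by
#' its smallest leaf label), so output is deterministic. Negative branch
#' estimates are clamped to zero with the deficit pushed to the sibling
#' branch, and reported via \code{message()}.
#'
#' @param d symmetric distance matrix with labels (>= 3 leaves)
#' @return an unrooted \code{ape::phylo} tree
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' neighborJoining(d)$edge.length  # branches 1, 1, 3
#' @export
neighborJoining <- function(d) {
  .checkDistanceMatrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 leaves")
  labels <- rownames(d)
  ## active clusters as newick substrings; rep = smallest leaf label
  sub <- labels
  rep_ <- labels
  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(li, lj) {
    if (li < 0) {
      message("negative branch estimate ", fmt(li),
              " clamped to 0; deficit moved to sibling")
      lj <- lj + li
      li <- 0
    }
    c(li, lj)
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(p) {
      pr <- sort(c(rep_[p[1]], rep_[p[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    v <- clamp(li, lj); v <- rev(clamp(v[2], v[1]))
    li <- v[1]; lj <- v[2]
    newSub <- sprintf("(%s:%s,%s:%s)", sub[i], fmt(li), sub[j], fmt(lj))
    newRep <- min(rep_[i], rep_[j])
    dk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk),
               c(dk, 0))
    sub <- c(sub[keep], newSub)
    rep_ <- c(rep_[keep], newRep)
    rn <- c(rownames(d)[seq_along(keep)], newRep)
    rownames(d) <- colnames(d) <- NULL
  }
  ## final three-point resolution
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- c(l1, l2, l3)
  if (any(ls < 0)) {
    for (k in which(ls < 0)) {
      message("negative branch estimate ", fmt(ls[k]),
              " clamped to 0; deficit moved to sibling")
      sib <- which.max(ls)
      ls[sib] <- ls[sib] + ls[k]
      ls[k] <- 0
    }
  }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[1], fmt(ls[1]), sub[2],
                 fmt(ls[2]), sub[3], fmt(ls[3]))
  ape::read.tree(text = nwk)
}

#' Path length between two leaves
#'
#' Sum of branch lengths on the unique path; a metric on any tree with
#' non-negative branches, and equal to the input matrix entry when the
#' matrix is additive.
#'
#' @param tree an \code{ape::phylo}
#' @param a,b leaf labels
#' @return numeric path length (0 for a leaf to itself)
#' @export
leafDistance <- function(tree, a, b) {
  if (!all(c(a, b) %in% tree$tip.label))
    stop("unknown leaf label(s): ",
         paste(setdiff(c(a, b), tree$tip.label), collapse = ", "))
  if (a == b) return(0)
  cm <- stats::cophenetic(tree)
  cm[a, b]
}

#' Serialize a tree as plain newick with fixed precision
#'
#' @param tree an \code{ape::phylo}
#' @param path optional output file
#' @param digits branch-length decimals (default 6)
#' @return the newick string (invisibly when writing to file)
#' @export
writeNewick <- function(tree, path = NULL, digits = 6) {
  rec <- function(node) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (!length(kids)) return(tree$tip.label[node])
    parts <- vapply(kids, function(k) {
      el <- tree$edge.length[which(tree$edge[, 1] == node &
                                   tree$edge[, 2] == k)]
      sprintf("%s:%.*f", rec(k), digits, el)
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d labeled symmetric matrix
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writePhylip <- function(d, path) {
  .checkDistanceMatrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
  invisible(path)
}

#' Neighbor-joining tree for a candidate gene set
#'
#' Builds the Kimura-corrected distance matrix of the supplied fragments
#' and references and returns the NJ tree; the classic use is the four
#' leaves of a dual-origin duplication (two same-species contig fragments
#' plus the human and fly homologues), where each contig is expected to
#' cluster with its seeding reference.
#'
#' @param seqs named \code{AAStringSet} or named character vector
#'   (>= 3 sequences)
#' @param scheme a \linkS4class{ScoringScheme}
#' @param kimura apply the Kimura correction
#' @return an \code{ape::phylo}
#' @export
candidateTree <- function(seqs, scheme = ScoringScheme(), kimura = TRUE) {
  neighborJoining(distanceMatrix(seqs, scheme, kimura))
}

#' Do two leaves form a cherry-side split against the other two?
#'
#' For a 4-leaf unrooted tree, TRUE iff the tree's internal split
#' separates \code{pair} from the remaining two leaves (checked by the
#' four-point condition on tree path lengths).
#'
#' @param tree a 4-leaf \code{ape::phylo}
#' @param pair two leaf labels
#' @return logical
#' @export
splitsWith <- function(tree, pair) {
  tips <- tree$tip.label
  stopifnot(length(tips) == 4L, all(pair %in% tips))
  oth <- setdiff(tips, pair)
  cm <- stats::cophenetic(tree)
  s1 <- cm[pair[1], pair[2]] + cm[oth[1], oth[2]]
  s2 <- cm[pair[1], oth[1]] + cm[pair[2], oth[2]]
  s3 <- cm[pair[1], oth[2]] + cm[pair[2], oth[1]]
  s1 < s2 - 1e-12 && s1 < s3 - 1e-12
}
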