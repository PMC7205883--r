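# Progressive multiple alignment of telomere sequences: all-pairs global
# alignment for the guide distances, UPGMA guide tree, profile-profile
# merges. Scoring is match +1 / mismatch -1, affine gaps -5 open / -1
# extend; a gap of length g costs open + g * extend. Deterministic.

.aln_score <- list(match = 1, mismatch = -1, gap_open = -5, gap_extend = -1)

# Column score between two profiles (character matrices, rows = sequences):
# mean pairwise residue score; pairs involving an existing gap score 0.
.col_score_matrix <- function(A, B, sc) {
  # A, B: character matrices; returns |colsA| x |colsB| score matrix
  bases <- c("A", "C", "G", "T")
  fa <- sapply(bases, function(b) colMeans(A == b))
  fb <- sapply(bases, function(b) colMeans(B == b))
  if (is.null(dim(fa))) fa <- matrix(fa, nrow = 1)
  if (is.null(dim(fb))) fb <- matrix(fb, nrow = 1)
  # expected score: match for identical bases, mismatch for different
  m <- fa %*% t(fb)            # sum of p_a(x) p_b(x) terms
  tot <- rowSums(fa) %o% rowSums(fb)
  sc$match * m + sc$mismatch * (tot - m)
}

# Global affine alignment of two profiles; returns the merged character
# matrix. Vectorised per DP column (the vertical-gap recurrence is solved
# with a cummax transform).
.align_profiles <- function(A, B, sc = .aln_score) {
  n <- ncol(A); m <- ncol(B)
  S <- .col_score_matrix(A, B, sc)
  NEG <- -1e9
  go <- sc$gap_open; ge <- sc$gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in A (consume B column)
  Y <- matrix(NEG, n + 1, m + 1) # gap in B (consume A column)
  M[1, 1] <- 0
  if (m > 0) X[1, 2:(m + 1)] <- go + ge * (1:m)
  if (n > 0) Y[2:(n + 1), 1] <- go + ge * (1:n)
  for (j in 2:(m + 1)) {
    prev <- pmax(M[, j - 1], X[, j - 1], Y[, j - 1])
    if (n > 0) M[2:(n + 1), j] <- prev[1:n] + S[, j - 1]
    X[, j] <- pmax(M[, j - 1] + go + ge, X[, j - 1] + ge)
    # Y[i, j] = max(M[i-1, j] + go + ge, Y[i-1, j] + ge)
    base <- pmax(M[, j], X[, j]) + go + ge
    z <- cummax(base - ge * seq_len(n + 1))
    Y[2:(n + 1), j] <- pmax(Y[2:(n + 1), j], z[1:n] + ge * (1:n))
  }
  # traceback
  gapA <- matrix("-", nrow(A), 1); gapB <- matrix("-", nrow(B), 1)
  i <- n + 1; j <- m + 1
  colsA <- list(); colsB <- list()
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) { # M: consume both
      colsA[[length(colsA) + 1]] <- A[, i - 1]
      colsB[[length(colsB) + 1]] <- B[, j - 1]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2) { # X: gap in A, consume B
      colsA[[length(colsA) + 1]] <- gapA[, 1]
      colsB[[length(colsB) + 1]] <- B[, j - 1]
      from_m <- M[i, j - 1] + go + ge
      from_x <- X[i, j - 1] + ge
      j <- j - 1
      state <- if (from_m >= from_x) 1 else 2
    } else { # Y: gap in B, consume A
      colsA[[length(colsA) + 1]] <- A[, i - 1]
      colsB[[length(colsB) + 1]] <- gapB[, 1]
      from_m <- pmax(M[i - 1, j], X[i - 1, j]) + go + ge
      from_y <- Y[i - 1, j] + ge
      prev_mx <- if (M[i - 1, j] >= X[i - 1, j]) 1 else 2
      i <- i - 1
      state <- if (from_m >= from_y) prev_mx else 3
    }
  }
  out <- rbind(
    do.call(cbind, rev(colsA)),
    do.call(cbind, rev(colsB)))
  out
}

# Pairwise global alignment of two sequences via the profile machinery.
nw_align <- function(a, b, sc = .aln_score) {
  A <- matrix(strsplit(a, "", fixed = TRUE)[[1]], nrow = 1)
  B <- matrix(strsplit(b, "", fixed = TRUE)[[1]], nrow = 1)
  al <- .align_profiles(A, B, sc)
  list(a = paste(al[1, ], collapse = ""),
       b = paste(al[2, ], collapse = ""))
}

nw_identity <- function(a, b) {
  al <- nw_align(a, b)
  va <- strsplit(al$a, "", fixed = TRUE)[[1]]
  vb <- strsplit(al$b, "", fixed = TRUE)[[1]]
  mean(va == vb)
}

#' Progressive multiple alignment of telomere sequences
#'
#' Aligns two or more sequences progressively: all-pairs global alignments
#' give identity-based guide distances, a UPGMA guide tree orders the
#' merges, and profiles are merged by global affine profile-profile
#' alignment (match +1, mismatch -1, gap open -5, gap extend -1). The
#' procedure is deterministic.
#'
#' @param seqs named character vector of DNA sequences (>= 2).
#' @return a `telomere_alignment`: list with `taxa`, `matrix` (character
#'   matrix, rows = taxa), `site_coverage` (per-column non-gap fraction).
#' @export
align_telomeres <- function(seqs) {
  if (length(seqs) < 2) stop("alignment needs at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  profiles <- lapply(seqs, function(s) {
    matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1)
  })
  members <- as.list(seq_len(n))
  if (n == 2) {
    merged <- .align_profiles(profiles[[1]], profiles[[2]])
    ord <- c(1L, 2L)
  } else {
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - nw_identity(seqs[[i]], seqs[[j]])
    }
    hc <- hclust(as.dist(d), method = "average")
    node_prof <- profiles
    node_members <- members
    merged <- NULL; ord <- NULL
    cl_prof <- list(); cl_members <- list()
    for (s in seq_len(nrow(hc$merge))) {
      pick <- function(k) {
        if (k < 0) list(p = node_prof[[-k]], m = node_members[[-k]])
        else list(p = cl_prof[[k]], m = cl_members[[k]])
      }
      L <- pick(hc$merge[s, 1]); R <- pick(hc$merge[s, 2])
      pr <- .align_profiles(L$p, R$p)
      cl_prof[[s]] <- pr
      cl_members[[s]] <- c(L$m, R$m)
    }
    merged <- cl_prof[[nrow(hc$merge)]]
    ord <- unlist(cl_members[[nrow(hc$merge)]])
  }
  mat <- merged
  rownames(mat) <- names(seqs)[ord]
  mat <- mat[names(seqs), , drop = FALSE]
  structure(list(taxa = names(seqs), matrix = mat,
                 site_coverage = colMeans(mat != "-")),
            class = "telomere_alignment")
}

#' Drop low-coverage alignment columns
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `min_coverage` (columns with strictly less are eliminated); retained
#' columns keep their order and content.
#'
#' @param alignment a `telomere_alignment`.
#' @param min_coverage minimum per-column non-gap fraction.
#' @export
filter_sites <- function(alignment, min_coverage = 0.80) {
  keep <- alignment$site_coverage >= min_coverage
  if (!any(keep)) stop("all alignment columns removed by coverage filter")
  mat <- alignment$matrix[, keep, drop = FALSE]
  structure(list(taxa = alignment$taxa, matrix = mat,
                 site_coverage = colMeans(mat != "-")),
            class = "telomere_alignment")
}

#' @export
print.telomere_alignment <- function(x, ...) {
  cat(sprintf("telomere alignment: %d taxa, %d columns\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Pairwise percent identity between two sequences
#'
#' Global alignment; identity is matches over the aligned columns with
#' terminal gap runs excluded from the denominator, so sequences
#' recovered to different lengths are compared over their mutual extent
#' without penalising the missing ends. A local/overlap alignment is
#' deliberately not used: for largely dissimilar sequences it collapses
#' onto any short shared repeat and reports a meaningless near-100%.
#'
#' @param a,b DNA strings.
#' @return percent identity in [0, 100].
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = sm, gapOpening = 5, gapExtension = 1)
  va <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  vb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  first <- max(min(which(va != "-")), min(which(vb != "-")))
  last <- min(max(which(va != "-")), max(which(vb != "-")))
  keep <- first:last
  100 * mean(va[keep] == vb[keep])
}
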