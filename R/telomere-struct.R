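#' Extract the terminal window of a replicon end
#'
#' Returns the terminal `n` bases of one end, oriented so that the physical
#' terminus reads last: the right end is returned verbatim, the left end is
#' reverse-complemented. Both ends of a replicon are thereby comparable in a
#' single canonical orientation.
#'
#' @param sequence DNA string (or a `replicon`).
#' @param n window size in bp (default 180, the classical extent of a
#'   Streptomyces telomere).
#' @param end `"left"` or `"right"`.
#' @param replicon_id optional id recorded in the result.
#' @return a `telomere` object (list with `replicon_id`, `end`, `sequence`).
#' @export
extract_terminal <- function(sequence, n = 180, end = c("right", "left"),
                             replicon_id = NA_character_) {
  end <- match.arg(end)
  if (inherits(sequence, "replicon")) {
    replicon_id <- sequence$id
    sequence <- sequence$sequence
  }
  len <- nchar(sequence)
  stopifnot(len >= 1)
  m <- min(n, len)
  s <- if (end == "right") {
    substr(sequence, len - m + 1, len)
  } else {
    revcomp(substr(sequence, 1, m))
  }
  structure(list(replicon_id = replicon_id, end = end, sequence = s),
            class = "telomere")
}

.tel_seq <- function(x) {
  if (inherits(x, "telomere")) x$sequence else as.character(x)
}

# Pair category for one stem position: 2 = canonical Watson-Crick,
# 1 = tolerated non-canonical ("sheared"; G.A and its complementary-strand
# image T.C), 0 = mismatch.
.pair_class <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (!is.na(comp[a]) && comp[[a]] == b) return(2L)
  p <- paste(sort(c(a, b)), collapse = "")
  if (p == "AG" || p == "CT") return(1L)
  0L
}

#' Enumerate candidate hairpins in a telomere window
#'
#' Exhaustively enumerates every inverted repeat (stem-loop) with arm length
#' at least `min_arm`, loop length in `loop_lens`, and at most
#' `max_stem_mismatch` mismatched stem positions. Sheared purine-purine G.A
#' pairs (and their complementary-strand image T.C) are tolerated without
#' counting as mismatches when `allow_sheared_GA` is TRUE, and are counted
#' separately.
#'
#' @param telomere a `telomere` object or DNA string.
#' @param min_arm minimum stem arm length in bp.
#' @param loop_lens permitted loop lengths (3-nt GNA/GCA and 4-nt CTTG loops
#'   are the classes observed in Streptomyces telomeres).
#' @param max_stem_mismatch maximum mismatched stem positions per hairpin.
#' @param allow_sheared_GA tolerate sheared pairs in stems.
#' @param sheared_max_depth deepest stem position (1 = loop-proximal) at
#'   which a sheared pair is tolerated; sheared pairing is a loop-adjacent
#'   phenomenon, and further out a purine-purine pair is a plain mismatch.
#' @param max_arm cap on enumerated arm length.
#' @return data.frame of candidates: `start`, `end` (0-based half-open span
#'   of the whole hairpin), `arm_len`, `loop_start`, `loop_len`, `loop_seq`,
#'   `mismatches`, `sheared`, `paired` (canonically paired stem positions:
#'   arm length minus mismatched and sheared positions).
#' @export
find_hairpins <- function(telomere, min_arm = 3, loop_lens = c(3, 4),
                          max_stem_mismatch = 1, allow_sheared_GA = TRUE,
                          sheared_max_depth = 2, max_arm = Inf) {
  s <- .tel_seq(telomere)
  n <- nchar(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  out <- list()
  for (l in loop_lens) {
    for (ls in seq_len(max(0, n - l + 1))) {
      # arms extend outward from the loop at [ls, ls + l - 1]
      mm <- 0L; sh <- 0L; d <- 0L
      rows <- list()
      repeat {
        i <- ls - d - 1L
        j <- ls + l + d
        if (i < 1L || j > n || d + 1L > max_arm) break
        pc <- .pair_class(v[i], v[j])
        if (pc == 1L && (!allow_sheared_GA || d + 1L > sheared_max_depth)) {
          pc <- 0L
        }
        if (pc == 0L) mm <- mm + 1L
        if (pc == 1L) sh <- sh + 1L
        if (mm > max_stem_mismatch) break
        d <- d + 1L
        if (d >= min_arm) {
          rows[[length(rows) + 1L]] <- data.frame(
            start = i - 1L, end = j, arm_len = d,
            loop_start = ls - 1L, loop_len = l,
            loop_seq = substr(s, ls, ls + l - 1L),
            mismatches = mm, sheared = sh, paired = d - mm - sh,
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      arm_len = integer(0), loop_start = integer(0),
                      loop_len = integer(0), loop_seq = character(0),
                      mismatches = integer(0), sheared = integer(0),
                      paired = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$loop_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fold a telomere by base-pair-maximising hairpin selection
#'
#' Selects the non-overlapping subset of candidate hairpins maximising the
#' total number of paired stem bases (weighted interval scheduling dynamic
#' program; ties resolved toward fewer hairpins, remaining ties by scan
#' order over candidates sorted by hairpin end). This combinatorial model
#' stands in for thermodynamic folding: it exhibits the stems and loop
#' motifs that type a telomere, without free-energy ranking.
#'
#' @param telomere a `telomere` object or DNA string.
#' @param candidates candidate hairpins from [find_hairpins()]; computed
#'   with defaults when NULL.
#' @param ... passed to [find_hairpins()] when `candidates` is NULL.
#' @return a `telomere_structure`: list with `hairpins` (ordered
#'   data.frame), `total_paired_bases`, `loop_class`.
#' @export
fold_telomere <- function(telomere, candidates = NULL, ...) {
  s <- .tel_seq(telomere)
  if (is.null(candidates)) candidates <- find_hairpins(s, ...)
  if (!nrow(candidates)) {
    return(structure(list(hairpins = candidates, total_paired_bases = 0L,
                          loop_class = "other"),
                     class = "telomere_structure"))
  }
  cand <- candidates[order(candidates$end, candidates$start), , drop = FALSE]
  k <- nrow(cand)
  # p[i]: last candidate (in end order) wholly left of candidate i
  p <- findInterval(cand$start, cand$end)
  V <- numeric(k + 1L)  # best paired bases using candidates 1..i
  C <- integer(k + 1L)  # hairpin count of that optimum
  take <- logical(k)
  for (i in seq_len(k)) {
    tv <- V[p[i] + 1L] + cand$paired[i]
    tc <- C[p[i] + 1L] + 1L
    sv <- V[i]
    sc <- C[i]
    if (tv > sv || (tv == sv && tc < sc)) {
      V[i + 1L] <- tv; C[i + 1L] <- tc; take[i] <- TRUE
    } else {
      V[i + 1L] <- sv; C[i + 1L] <- sc
    }
  }
  sel <- integer(0)
  i <- k
  while (i > 0L) {
    if (take[i]) {
      sel <- c(i, sel)
      i <- p[i]
    } else {
      i <- i - 1L
    }
  }
  hp <- cand[sel, , drop = FALSE]
  hp <- hp[order(hp$start), , drop = FALSE]
  rownames(hp) <- NULL
  st <- structure(list(hairpins = hp,
                       total_paired_bases = sum(hp$paired),
                       loop_class = NA_character_),
                  class = "telomere_structure")
  st$loop_class <- classify_loops(st)
  st
}

#' Classify a telomere by its dominant loop motif
#'
#' The loop class is the strict majority motif among the selected hairpin
#' loops, restricted to the known classes GCA, GGA and CTTG; anything else
#' (including structures with no hairpins or no majority) is `"other"`.
#' With `collapse_gna = TRUE` (default), GNA loops other than GCA count
#' toward the GGA class, following the observation that GNA-looped
#' telomeres are mostly GGA-capped.
#'
#' @param structure a `telomere_structure` from [fold_telomere()].
#' @param collapse_gna collapse GAA/GTA loops into the GGA class.
#' @return one of `"GCA"`, `"GGA"`, `"CTTG"`, `"other"`.
#' @export
classify_loops <- function(structure, collapse_gna = TRUE) {
  loops <- structure$hairpins$loop_seq
  n <- length(loops)
  if (n == 0L) return("other")
  if (collapse_gna) loops[grepl("^G[AGT]A$", loops)] <- "GGA"
  for (cls in c("GCA", "GGA", "CTTG")) {
    if (sum(loops == cls) > n / 2) return(cls)
  }
  "other"
}

#' Dot-bracket-style text rendering of a folded telomere
#'
#' @param telomere a `telomere` object or DNA string.
#' @param structure matching `telomere_structure`; computed when NULL.
#' @return character vector of two lines (sequence, annotation).
#' @export
render_structure <- function(telomere, structure = NULL) {
  s <- .tel_seq(telomere)
  if (is.null(structure)) structure <- fold_telomere(s)
  ann <- rep(".", nchar(s))
  hp <- structure$hairpins
  if (nrow(hp)) {
    for (i in seq_len(nrow(hp))) {
      a5 <- (hp$start[i] + 1):(hp$start[i] + hp$arm_len[i])
      lp <- (hp$loop_start[i] + 1):(hp$loop_start[i] + hp$loop_len[i])
      a3 <- (hp$end[i] - hp$arm_len[i] + 1):hp$end[i]
      ann[a5] <- "("
      ann[lp] <- "-"
      ann[a3] <- ")"
    }
  }
  c(s, paste(ann, collapse = ""))
}

#' @export
print.telomere_structure <- function(x, ...) {
  cat(sprintf("telomere structure: %d hairpin(s), %d paired bases, loop class %s\n",
              nrow(x$hairpins), x$total_paired_bases, x$loop_class))
  if (nrow(x$hairpins)) print(x$hairpins, ...)
  invisible(x)
}
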