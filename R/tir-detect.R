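#' Map reads onto an assembly and build a coverage profile
#'
#' Seed-and-extend mapping of each read (either strand) against a single
#' reference, keeping the placement with fewest mismatches over the full
#' read; ties are broken by leftmost position, then forward strand, so the
#' profile is deterministic. Depth is incremented over the aligned span of
#' every mapped read. Large duplications collapsed in the assembly (TIRs)
#' attract the reads of both physical copies and show doubled depth.
#'
#' @param reads a `read_set` or character vector of read sequences.
#' @param assembly a `replicon` or DNA string.
#' @param k exact seed length (bp); reads shorter than `k` stay unmapped.
#' @param max_mismatch maximum mismatches for a valid placement.
#' @param window_size window for the summarised depth track (bp).
#' @return a `coverage_profile`: list with `replicon_id`, `depth`
#'   (per-position integer), `window_means`, `window_size`, `n_reads`,
#'   `n_mapped`, `mapping_rate`.
#' @export
map_reads <- function(reads, assembly, k = 21, max_mismatch = 5,
                      window_size = 500) {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  seq <- if (inherits(assembly, "replicon")) assembly$sequence else assembly
  id <- if (inherits(assembly, "replicon")) assembly$id else "assembly"
  stopifnot(nchar(seq) > 0)
  res <- if (length(rd) == 0) {
    list(depth = integer(nchar(seq)), n_mapped = 0L, n_reads = 0L)
  } else {
    .map_reads_cpp(unname(rd), seq, as.integer(k), as.integer(max_mismatch))
  }
  structure(list(
    replicon_id = id, depth = res$depth,
    window_means = window_means(res$depth, window_size),
    window_size = window_size,
    read_length = if (length(rd)) as.integer(median(nchar(rd))) else
      NA_integer_,
    n_reads = res$n_reads, n_mapped = res$n_mapped,
    mapping_rate = if (res$n_reads > 0) res$n_mapped / res$n_reads else NA),
    class = "coverage_profile")
}

window_means <- function(depth, window_size) {
  n <- length(depth)
  if (n == 0) return(numeric(0))
  idx <- (seq_len(n) - 1L) %/% window_size
  as.numeric(tapply(depth, idx, mean))
}

#' Build a coverage profile from an external per-position depth table
#'
#' Accepts a two-column TSV (position, depth; 1-based positions) produced
#' by any production mapper, so [detect_tir()] can run on real pileups.
#'
#' @param path TSV file.
#' @param replicon_id id recorded in the profile.
#' @param window_size summarising window (bp).
#' @export
read_depth_tsv <- function(path, replicon_id = "assembly",
                           window_size = 500) {
  tab <- read.table(path, header = FALSE, sep = "\t")
  depth <- integer(max(tab[[1]]))
  depth[tab[[1]]] <- tab[[2]]
  structure(list(replicon_id = replicon_id, depth = depth,
                 window_means = window_means(depth, window_size),
                 window_size = window_size,
                 n_reads = NA_integer_, n_mapped = NA_integer_,
                 mapping_rate = NA_real_),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "coverage profile of %s: %d bp, mean depth %.1f, mapping rate %s\n",
    x$replicon_id, length(x$depth), mean(x$depth),
    ifelse(is.na(x$mapping_rate), "NA",
           sprintf("%.1f%%", 100 * x$mapping_rate))))
  invisible(x)
}

# Least-squares single change-point on a numeric vector: the split j
# (1..n-1) minimising the two-segment residual sum of squares of
# x[1..j] | x[j+1..n]. Returns the split index.
.best_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_integer_)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  j <- seq_len(n - 1)
  sse_left <- cs2[j] - cs[j]^2 / j
  nr <- n - j
  sse_right <- (cs2[n] - cs2[j]) - (cs[n] - cs[j])^2 / nr
  which.min(sse_left + sse_right)
}

#' Delimit terminal inverted repeats from the read-depth doubling signal
#'
#' Operationalises the rule that TIRs are the terminal regions attracting
#' twice the reads of the central region: the baseline is the median
#' window mean over the central 50% of the assembly; for each end a single
#' change-point is fit on the window means between that end and the
#' midpoint (two-segment least-squares mean model), the boundary is
#' refined to base resolution by a local per-base change-point scan, and
#' the terminal segment is called `detected` when its mean depth relative
#' to baseline falls inside `ratio_window` and its length reaches
#' `min_tir_length`. Undetected ends report size 0.
#'
#' Reads spanning the removed-copy junction cannot map, so the depth does
#' not step but ramps from twofold to baseline over one read length; a
#' step fit lands mid-ramp. When the profile records its read length the
#' detected boundary is therefore shifted outward by half a read length —
#' a correction derived from the mapping geometry, not a tuning knob.
#' Profiles loaded from external depth tables carry no read length and
#' receive no correction.
#'
#' @param profile a `coverage_profile`.
#' @param ratio_window accepted depth-ratio interval around the twofold
#'   signal.
#' @param min_tir_length minimum callable TIR length (bp).
#' @return a `tir_calls` data.frame with one row per end: `replicon_id`,
#'   `end`, `start`, `stop` (0-based half-open), `size`, `depth_ratio`,
#'   `baseline`, `status`.
#' @export
detect_tir <- function(profile, ratio_window = c(1.6, 2.4),
                       min_tir_length = 1000) {
  wm <- profile$window_means
  w <- profile$window_size
  n <- length(wm)
  L <- length(profile$depth)
  central <- wm[max(1, floor(n * 0.25)):min(n, ceiling(n * 0.75))]
  baseline <- median(central)
  if (!is.finite(baseline) || baseline <= 0) {
    stop("no central coverage: baseline is zero")
  }
  one_end <- function(end) {
    half <- max(2L, n %/% 2L)
    x <- if (end == "left") wm[seq_len(half)] else rev(wm)[seq_len(half)]
    j <- .best_split(x)
    term_mean <- mean(x[seq_len(j)])
    ratio <- term_mean / baseline
    # refine the boundary on per-base depth around the coarse window edge
    coarse <- j * w
    lo <- max(1L, coarse - 2L * w)
    hi <- min(L, coarse + 2L * w)
    d <- if (end == "left") profile$depth[lo:hi] else
      rev(profile$depth)[lo:hi]
    jj <- .best_split(d)
    size <- if (is.na(jj)) coarse else lo - 1L + jj
    # junction-ramp correction: the step fit sits half a read length
    # inside the true boundary (see Details)
    rl <- profile$read_length
    if (!is.null(rl) && length(rl) == 1 && is.finite(rl)) {
      size <- min(size + rl %/% 2L, L)
    }
    detected <- is.finite(ratio) && ratio >= ratio_window[1] &&
      ratio <= ratio_window[2] && size >= min_tir_length
    data.frame(
      replicon_id = profile$replicon_id, end = end,
      start = if (end == "left") 0L else as.integer(L - size),
      stop = if (end == "left") as.integer(size) else as.integer(L),
      size = if (detected) as.integer(size) else 0L,
      depth_ratio = ratio, baseline = baseline,
      status = if (detected) "detected" else "undetected",
      stringsAsFactors = FALSE)
  }
  out <- rbind(one_end("left"), one_end("right"))
  out$start[out$status == "undetected"] <- NA_integer_
  out$stop[out$status == "undetected"] <- NA_integer_
  class(out) <- c("tir_calls", "data.frame")
  out
}

#' Write TIR calls as BED and TSV report
#'
#' @param calls a `tir_calls` data.frame.
#' @param bed_path,tsv_path output paths (NULL to skip).
#' @export
write_tir_calls <- function(calls, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    det <- calls[calls$status == "detected", , drop = FALSE]
    bed <- data.frame(chrom = det$replicon_id, start = det$start,
                      end = det$stop, name = paste0("TIR_", det$end))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    write.table(as.data.frame(calls), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(calls)
}
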