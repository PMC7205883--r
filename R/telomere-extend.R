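#' Extend an assembly terminus by greedy consensus read walking
#'
#' Walks off the given terminal sequence toward the physical telomere: at
#' each step, reads overlapping the current terminus by at least
#' `min_overlap` with at most `max_mismatch` mismatches (either strand,
#' anchored on an exact terminal `anchor_k`-mer) vote on the next base,
#' which is appended only when its support and agreement clear the
#' thresholds. The walk reports why it stopped rather than guessing: at a
#' physical molecule end, read support thins out and the very last
#' nucleotides may remain unrecoverable.
#'
#' @param terminal_seq DNA string holding the current terminus (terminus
#'   last); must be at least `anchor_k` long.
#' @param reads a `read_set` or character vector of reads.
#' @param anchor_k exact anchor k-mer length.
#' @param min_overlap minimum read-terminus overlap (bp).
#' @param max_mismatch maximum mismatches in the overlap.
#' @param min_support minimum reads voting for the accepted base.
#' @param min_agreement minimum fraction of votes for the accepted base.
#' @param max_extension cap on the number of appended bases.
#' @return an `extension_result`: list with `added_sequence`,
#'   `per_base_support`, `stop_reason` (`no_overlap`, `low_support`,
#'   `ambiguous` or `max_length`), `extended_terminal`.
#' @export
extend_end <- function(terminal_seq, reads, anchor_k = 31,
                       min_overlap = 31, max_mismatch = 1,
                       min_support = 5, min_agreement = 0.8,
                       max_extension = 1000) {
  rd <- if (inherits(reads, "read_set")) reads$reads else reads
  if (nchar(terminal_seq) < anchor_k) {
    stop("terminal sequence shorter than anchor_k")
  }
  if (!length(rd)) stop("empty read set")
  res <- .extend_walk_cpp(terminal_seq, unname(rd), as.integer(anchor_k),
                          as.integer(min_overlap),
                          as.integer(max_mismatch),
                          as.integer(min_support), min_agreement,
                          as.integer(max_extension))
  structure(list(added_sequence = res$added_sequence,
                 per_base_support = res$per_base_support,
                 stop_reason = res$stop_reason,
                 extended_terminal = res$extended),
            class = "extension_result")
}

#' Extend one end of an assembly
#'
#' Convenience wrapper around [extend_end()]: the left end is extended as
#' the right end of the reverse complement, and the result is reported in
#' the assembly's own orientation.
#'
#' @param assembly a `replicon` or DNA string.
#' @param reads a `read_set` or character vector of reads.
#' @param end `"left"` or `"right"`.
#' @param anchor_window how much terminal sequence to hand the walker (bp).
#' @param ... parameters passed to [extend_end()].
#' @return an `extension_result` with an `end` field; `extended_terminal`
#'   reads terminus-last regardless of the end.
#' @export
extend_replicon_end <- function(assembly, reads,
                                end = c("right", "left"),
                                anchor_window = 2000, ...) {
  end <- match.arg(end)
  seq <- if (inherits(assembly, "replicon")) assembly$sequence else assembly
  L <- nchar(seq)
  w <- min(anchor_window, L)
  terminal <- if (end == "right") substr(seq, L - w + 1L, L) else
    revcomp(substr(seq, 1, w))
  out <- extend_end(terminal, reads, ...)
  out$end <- end
  out
}

#' @export
print.extension_result <- function(x, ...) {
  cat(sprintf("extension: +%d base(s), stop reason %s\n",
              nchar(x$added_sequence), x$stop_reason))
  invisible(x)
}
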