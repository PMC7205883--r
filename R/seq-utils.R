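#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GATC")
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  if (length(x) > 100 || any(nchar(x) > 10000)) {
    return(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x))))
  }
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Random DNA sequence at a given GC content
#'
#' @param n length in bp.
#' @param gc GC fraction in [0, 1].
#' @param alphabet bases to draw from (GC weighting only applies to the
#'   default full alphabet).
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  if (identical(alphabet, c("A", "C", "G", "T"))) {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  } else {
    p <- rep(1 / length(alphabet), length(alphabet))
  }
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage / per-replicate seed derivation from a user seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65536) * 31013 + 7919 * k) %% 2147483647L
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write a read set to FASTQ
#'
#' Quality strings are constant placeholders; downstream depth analysis
#' ignores base quality.
#'
#' @param reads a `read_set` (see [simulate_reads()]) or named character
#'   vector of read sequences.
#' @param path output FASTQ file.
#' @export
write_fastq <- function(reads, path) {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  ss <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    paste(rep("I", n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(ss), names(ss))
}

# Substitute random positions of a DNA string at a per-site probability,
# always to a different base. Returns the mutated string.
substitute_sites <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    v[i] <- sample(setdiff(bases, v[i]), 1)
  }
  paste(v, collapse = "")
}

# Replace a substring by position (1-based, inclusive), without regex.
str_assign <- function(s, from, to, value) {
  stopifnot(nchar(value) == to - from + 1)
  paste0(substr(s, 1, from - 1), value,
         substr(s, to + 1, nchar(s)))
}
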