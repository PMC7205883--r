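#' Find open reading frames on both strands
#'
#' Reports every ORF starting at a permitted start codon, running to the
#' next in-frame stop, with at least `min_len_codons` coding codons.
#' Overlapping ORFs are allowed; coordinates are 0-based half-open on the
#' forward strand and include the stop codon. GTG-initiated proteins
#' start with M, as translated in vivo.
#'
#' @param replicon a `replicon` or DNA string.
#' @param min_len_codons minimum protein length in codons.
#' @param starts permitted start codons.
#' @return data.frame of `OrfRecord`s: `replicon_id`, `start`, `end`,
#'   `strand`, `protein`.
#' @export
find_orfs <- function(replicon, min_len_codons = 100,
                      starts = c("ATG", "GTG")) {
  seq <- if (inherits(replicon, "replicon")) replicon$sequence else replicon
  id <- if (inherits(replicon, "replicon")) replicon$id else "replicon"
  L <- nchar(seq)
  gcode <- Biostrings::GENETIC_CODE
  scan_strand <- function(s, strand) {
    sl <- nchar(s)
    rows <- list()
    for (frame in 0:2) {
      ncod <- (sl - frame) %/% 3
      if (ncod < 2) next
      cod <- substring(s, frame + 3 * (seq_len(ncod) - 1) + 1,
                       frame + 3 * seq_len(ncod))
      is_stop <- cod %in% c("TAA", "TAG", "TGA")
      is_start <- cod %in% starts
      # segments between stops
      stop_idx <- c(0L, which(is_stop))
      for (si in seq_len(length(stop_idx) - 1L)) {
        if (stop_idx[si + 1L] - stop_idx[si] - 1L < min_len_codons) next
        seg <- (stop_idx[si] + 1L):(stop_idx[si + 1L] - 1L)
        st <- seg[is_start[seg]][1]
        if (is.na(st)) next
        n_cod <- stop_idx[si + 1L] - st
        if (n_cod < min_len_codons) next
        aa <- unname(gcode[cod[st:(stop_idx[si + 1L] - 1L)]])
        aa[1] <- "M"
        from0 <- frame + 3L * (st - 1L)          # 0-based CDS start
        to0 <- frame + 3L * stop_idx[si + 1L]    # 0-based end incl. stop
        rows[[length(rows) + 1L]] <- data.frame(
          replicon_id = id,
          start = if (strand == "+") from0 else L - to0,
          end = if (strand == "+") to0 else L - from0,
          strand = strand, protein = paste(aa, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    rows
  }
  rows <- c(scan_strand(seq, "+"), scan_strand(revcomp(seq), "-"))
  if (!length(rows)) {
    return(data.frame(replicon_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load ORFs from GFF3 plus protein FASTA
#'
#' Bypass for [find_orfs()] when gene calls already exist: CDS features
#' are read from the GFF3 and joined to proteins by the `ID` attribute
#' matching the FASTA headers.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param protein_fasta protein FASTA whose headers are CDS IDs.
#' @return data.frame in the [find_orfs()] layout.
#' @export
read_orfs_gff3 <- function(gff_path, protein_fasta) {
  lines <- readLines(gff_path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[vapply(parts, length, integer(1)) == 9]
  cds <- Filter(function(p) p[3] == "CDS", parts)
  prot <- {
    ss <- Biostrings::readAAStringSet(protein_fasta)
    setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  }
  rows <- lapply(cds, function(p) {
    idm <- regmatches(p[9], regexpr("ID=[^;]+", p[9]))
    cid <- sub("^ID=", "", idm)
    data.frame(replicon_id = p[1], start = as.integer(p[4]) - 1L,
               end = as.integer(p[5]), strand = p[7],
               protein = unname(prot[cid]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Find terminal-protein homologues at identity/coverage cutoffs
#'
#' Local alignment (BLOSUM62, gap open -11 / extend -1) of every query
#' against every predicted protein; identity is computed over aligned
#' columns and coverage as the aligned fraction of the query. Hits
#' passing both cutoffs are kept; near-miss hits inside `review_band`
#' percent identity (meeting coverage) are reported in a separate
#' `review` tier rather than silently dropped, since genuine terminal
#' proteins have been reported just below the 50% line.
#'
#' @param queries named character vector of query proteins.
#' @param orfs data.frame from [find_orfs()] / [read_orfs_gff3()].
#' @param id_cutoff percent identity cutoff (default 50).
#' @param cov_cutoff query coverage cutoff as a fraction (default 0.98).
#' @param review_band percent-identity band reported as `review`.
#' @return data.frame of `HomologyHit`s: `query_id`, orf coordinates,
#'   `percent_identity`, `query_coverage`, `aligned_length`, `tier`.
#' @export
find_homologues <- function(queries, orfs, id_cutoff = 50,
                            cov_cutoff = 0.98, review_band = c(45, 50)) {
  stopifnot(length(queries) > 0, nrow(orfs) > 0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (q in names(queries)) {
    qa <- Biostrings::AAString(queries[[q]])
    for (i in seq_len(nrow(orfs))) {
      pa <- tryCatch(Biostrings::pairwiseAlignment(
        qa, Biostrings::AAString(orfs$protein[i]), type = "local",
        substitutionMatrix = B62, gapOpening = 11, gapExtension = 1),
        error = function(e) NULL)
      if (is.null(pa)) next
      va <- as.character(Biostrings::alignedPattern(pa))
      alen <- nchar(va)
      if (alen == 0) next
      ident <- 100 * Biostrings::nmatch(pa) / alen
      cov <- nchar(gsub("-", "", va, fixed = TRUE)) / nchar(queries[[q]])
      tier <- if (ident >= id_cutoff && cov >= cov_cutoff) "pass"
        else if (ident >= review_band[1] && ident < review_band[2] &&
                 cov >= cov_cutoff) "review"
        else NA_character_
      if (is.na(tier)) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q, replicon_id = orfs$replicon_id[i],
        start = orfs$start[i], end = orfs$end[i],
        strand = orfs$strand[i], percent_identity = ident,
        query_coverage = cov, aligned_length = alen, tier = tier,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(query_id = character(0), replicon_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), percent_identity = numeric(0),
                      query_coverage = numeric(0),
                      aligned_length = integer(0), tier = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Family of a query id: tap/tpg with optional _I/_II suffix, gtpA, gtpB.
.query_family <- function(query_id) {
  q <- tolower(query_id)
  if (grepl("gtpa", q)) return("gtpA")
  if (grepl("gtpb", q)) return("gtpB")
  type <- if (grepl("ii|_2", q)) "II" else "I"
  if (grepl("tap", q)) return(paste0("tap_", type))
  if (grepl("tpg", q)) return(paste0("tpg_", type))
  "other"
}

#' Pair terminal-protein hits into operons
#'
#' Adjacent same-strand, same-replicon tap+tpg (same type) or gtpB+gtpA
#' hits within `max_gap` bp are paired into operon calls; remaining hits
#' are reported unpaired.
#'
#' @param hits data.frame from [find_homologues()] (tier `pass`).
#' @param max_gap maximum intergenic gap in bp.
#' @return data.frame of operon calls: `replicon_id`, `classification`
#'   (`type_I_tap_tpg`, `type_II_tap_tpg`, `gtpBA`, `unpaired`), member
#'   coordinates and families, `gap`.
#' @export
call_operons <- function(hits, max_gap = 200) {
  out <- data.frame(replicon_id = character(0),
                    classification = character(0),
                    family1 = character(0), family2 = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), gap = integer(0),
                    stringsAsFactors = FALSE)
  if (!nrow(hits)) return(out)
  h <- hits[hits$tier == "pass", , drop = FALSE]
  if (!nrow(h)) return(out)
  h$family <- vapply(h$query_id, .query_family, character(1))
  # one record per locus: best query per (replicon, start, end, strand)
  key <- paste(h$replicon_id, h$start, h$end, h$strand)
  h <- h[order(key, -h$percent_identity), , drop = FALSE]
  h <- h[!duplicated(paste(h$replicon_id, h$start, h$end, h$strand)), ,
         drop = FALSE]
  h <- h[order(h$replicon_id, h$start), , drop = FALSE]
  used <- rep(FALSE, nrow(h))
  pair_rule <- function(f1, f2) {
    fs <- sort(c(f1, f2))
    if (identical(fs, c("gtpA", "gtpB"))) return("gtpBA")
    if (identical(fs, c("tap_I", "tpg_I"))) return("type_I_tap_tpg")
    if (identical(fs, c("tap_II", "tpg_II"))) return("type_II_tap_tpg")
    NA_character_
  }
  for (i in seq_len(nrow(h) - 1L)) {
    if (used[i]) next
    j <- i + 1L
    while (j <= nrow(h) && !used[i]) {
      gap <- h$start[j] - h$end[i]
      if (used[j] || h$replicon_id[j] != h$replicon_id[i] ||
          gap > max_gap) break
      if (h$strand[j] == h$strand[i]) {
        cls <- pair_rule(h$family[i], h$family[j])
        if (!is.na(cls) && gap >= 0) {
          out <- rbind(out, data.frame(
            replicon_id = h$replicon_id[i], classification = cls,
            family1 = h$family[i], family2 = h$family[j],
            start = h$start[i], end = h$end[j], strand = h$strand[i],
            gap = gap, stringsAsFactors = FALSE))
          used[i] <- used[j] <- TRUE
        }
      }
      j <- j + 1L
    }
  }
  for (i in which(!used)) {
    out <- rbind(out, data.frame(
      replicon_id = h$replicon_id[i], classification = "unpaired",
      family1 = h$family[i], family2 = NA_character_,
      start = h$start[i], end = h$end[i], strand = h$strand[i],
      gap = NA_integer_, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Build a position-weight matrix from example motifs
#'
#' @param seqs equal-length amino-acid strings.
#' @param pseudocount added to every cell before log-odds.
#' @return numeric matrix (20 rows, motif-length columns) of log-odds
#'   scores against a uniform background.
#' @export
make_pwm <- function(seqs, pseudocount = 0.5) {
  stopifnot(length(unique(nchar(seqs))) == 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- nchar(seqs[1])
  mat <- matrix(pseudocount, 20, w, dimnames = list(aa, NULL))
  for (s in seqs) {
    v <- strsplit(s, "")[[1]]
    for (p in seq_len(w)) mat[v[p], p] <- mat[v[p], p] + 1
  }
  freq <- sweep(mat, 2, colSums(mat), "/")
  log2(freq / (1 / 20))
}

#' Flag a helix-turn-helix-like motif in a protein
#'
#' Scores every window of the protein against a position-weight pattern
#' and flags the protein when the best window reaches `score_frac` of the
#' pattern's maximum achievable score. Purely advisory.
#'
#' @param protein amino-acid string (>= 40 aa).
#' @param pwm log-odds matrix from [make_pwm()] (or a single consensus
#'   string, converted internally).
#' @param score_frac fraction of the maximum score required.
#' @return list with `flagged`, `position` (1-based best window start),
#'   `score`, `max_score`.
#' @export
hth_flag <- function(protein, pwm, score_frac = 0.8) {
  if (nchar(protein) < 40) stop("protein shorter than 40 aa")
  if (is.character(pwm)) pwm <- make_pwm(pwm)
  w <- ncol(pwm)
  v <- strsplit(protein, "")[[1]]
  n <- length(v)
  if (n < w) return(list(flagged = FALSE, position = NA, score = -Inf,
                         max_score = sum(apply(pwm, 2, max))))
  best <- -Inf; bpos <- NA_integer_
  for (i in seq_len(n - w + 1L)) {
    sc <- sum(pwm[cbind(match(v[i:(i + w - 1L)], rownames(pwm)),
                        seq_len(w))], na.rm = TRUE)
    if (sc > best) { best <- sc; bpos <- i }
  }
  mx <- sum(apply(pwm, 2, max))
  list(flagged = best >= score_frac * mx, position = bpos, score = best,
       max_score = mx)
}
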