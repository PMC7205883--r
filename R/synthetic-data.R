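#' Population simulator configuration
#'
#' Defines the study conditions for a conspecific population of linear
#' replicons: chromosome and TIR sizes, GC content, sub-clade structure,
#' per-sub-clade telomere loop motifs, per-branch substitution rate, and an
#' ordered list of rearrangement events. Defaults are desk-scale (200-kb
#' chromosome, 20-kb TIRs); `preset = "full"` switches to the real scale
#' of Streptomyces chromosomes (8 Mb, 450-kb TIRs).
#'
#' @param n_strains number of strains.
#' @param chromosome_length chromosome length in bp.
#' @param tir_length terminal inverted repeat length in bp (0 for a
#'   TIR-less replicon; otherwise at least 180 so the telomere fits).
#' @param gc_content ancestral GC fraction (Streptomyces-like 0.72).
#' @param telomere_motif named character vector of loop motifs per
#'   sub-clade.
#' @param ancestral_motif loop motif of the population ancestor.
#' @param n_stems stems per telomere (five to eight observed; default 6).
#' @param stem_range,spacer_range arm and spacer length ranges (bp) for
#'   telomere construction.
#' @param subclade_assignment character vector (length `n_strains`) of
#'   sub-clade labels; default mirrors a 4+3+2+2 split.
#' @param substitution_rate per-site substitution probability per tree
#'   branch.
#' @param clade_divergence per-position telomere divergence applied
#'   compensatorily between sub-clades (kept moderate so that downstream
#'   K2P distances stay inside the model's validity domain).
#' @param event_list ordered list of rearrangement events; each element a
#'   list with a `kind` field (one of `substitution_burst`,
#'   `terminal_indel`, `bir_homogenize`, `telomere_swap`, `hgt_insert`,
#'   `translocation`, `inversion`) plus kind-specific fields.
#' @param plasmids list of plasmid specs (lists with `id`, `length`,
#'   `tir_length`, `motif`, `n_stems`).
#' @param plant_tp_genes plant terminal-protein operons (gtpB-gtpA in all
#'   strains, a tap-tpg pair in the first sub-clade) inside the left TIR.
#' @param tp_divergence per-site substitution rate applied per strain to
#'   planted TP genes (they are otherwise protected, emulating purifying
#'   selection).
#' @param homogenize_final run a final TIR homogenization on every strain
#'   after the event list.
#' @param seed integer seed; all simulator randomness derives from it.
#' @param preset `"desk"` or `"full"` (real chromosome) scale.
#' @return a `population_config` list.
#' @export
population_config <- function(n_strains = 11,
                              chromosome_length = 200000,
                              tir_length = 20000,
                              gc_content = 0.72,
                              telomere_motif = c(I = "CTTG", II = "GGA",
                                                 III = "GGA", IV = "GCA"),
                              ancestral_motif = "GGA",
                              n_stems = 6,
                              stem_range = c(4, 8),
                              spacer_range = c(2, 12),
                              subclade_assignment = NULL,
                              substitution_rate = 1e-3,
                              clade_divergence = 0.2,
                              event_list = list(),
                              plasmids = list(),
                              plant_tp_genes = NULL,
                              tp_divergence = 1e-3,
                              homogenize_final = FALSE,
                              seed = 1,
                              preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    chromosome_length <- 8e6
    tir_length <- 450000
  }
  if (is.null(subclade_assignment)) {
    subclade_assignment <- default_subclades(n_strains)
  }
  stopifnot(n_strains >= 1, length(subclade_assignment) == n_strains,
            gc_content >= 0, gc_content <= 1,
            2 * tir_length < chromosome_length)
  if (tir_length > 0 && tir_length < 180) {
    stop("tir_length must be 0 or at least 180 (the telomere window)")
  }
  if (is.null(plant_tp_genes)) {
    plant_tp_genes <- tir_length >= 9000 && chromosome_length >= 50000
  }
  structure(list(
    n_strains = n_strains, chromosome_length = chromosome_length,
    tir_length = tir_length, gc_content = gc_content,
    telomere_motif = telomere_motif, ancestral_motif = ancestral_motif,
    n_stems = n_stems, stem_range = stem_range,
    spacer_range = spacer_range,
    subclade_assignment = subclade_assignment,
    substitution_rate = substitution_rate,
    clade_divergence = clade_divergence,
    event_list = event_list, plasmids = plasmids,
    plant_tp_genes = plant_tp_genes, tp_divergence = tp_divergence,
    homogenize_final = homogenize_final, seed = seed),
    class = "population_config")
}

#' Default sub-clade assignment
#'
#' Eleven strains are split 4+3+2+2 across sub-clades I-IV; other strain
#' counts are split into up to four near-equal contiguous blocks.
#'
#' @param n number of strains.
#' @export
default_subclades <- function(n) {
  labs <- c("I", "II", "III", "IV")
  if (n == 11) {
    sizes <- c(4, 3, 2, 2)
  } else {
    g <- min(4, n)
    sizes <- diff(round(seq(0, n, length.out = g + 1)))
  }
  rep(labs[seq_along(sizes)], times = sizes)
}

strain_ids <- function(n) sprintf("s%02d", seq_len(n))

# ---- telomere construction -------------------------------------------------

# Draw a telomere layout: stem arms over {G,C}, spacers poly-A. The
# alphabet split makes spacer self-pairing impossible and spacer-arm
# pairing rare, so the assembled 180-mer carries exactly the planted stems
# (verified by folding, with resampling on the rare failure).
.telomere_layout <- function(n_stems, stem_range, spacer_range,
                             motif_len = 3, total_length = 180) {
  arms <- character(n_stems)
  lens <- integer(0)
  if (n_stems > 0) {
    rng <- seq(stem_range[1], stem_range[2])
    lens <- if (length(rng) == 1) rep(rng, n_stems) else
      sample(rng, n_stems, replace = TRUE)
    # shrink arms toward the range minimum until the stems fit the budget
    budget <- total_length - (n_stems + 1) * spacer_range[1]
    while (sum(2 * lens + motif_len) > budget &&
           any(lens > stem_range[1])) {
      k <- which.max(lens)
      lens[k] <- lens[k] - 1L
    }
    arms <- vapply(lens, function(l) random_dna(l, alphabet = c("G", "C")),
                   character(1))
  }
  # spend the remaining slack on spacer lengths, in order
  slack <- total_length - sum(2 * lens + rep(motif_len, n_stems)) -
    (n_stems + 1) * spacer_range[1]
  spacers <- vapply(seq_len(n_stems + 1), function(i) {
    extra_max <- min(spacer_range[2] - spacer_range[1], slack)
    extra <- if (extra_max > 0) sample.int(extra_max + 1L, 1L) - 1L else 0L
    slack <<- slack - extra
    paste(rep("A", spacer_range[1] + extra), collapse = "")
  }, character(1))
  pad <- paste(rep("A", 200), collapse = "")
  list(arms = arms, spacers = spacers, pad = pad)
}

.assemble_telomere <- function(layout, motif, total_length = 180) {
  n <- length(layout$arms)
  parts <- layout$spacers[1]
  for (i in seq_len(n)) {
    parts <- c(parts, layout$arms[i], motif, revcomp(layout$arms[i]),
               layout$spacers[i + 1])
  }
  body <- paste(parts, collapse = "")
  over <- nchar(body) - total_length
  if (over > 0) {
    # absorb a small excess into the trailing spacer
    trail <- nchar(layout$spacers[n + 1])
    if (over > trail) {
      stop("telomere construction overflow: stems do not fit in ",
           total_length, " nt")
    }
    body <- substr(body, 1, total_length)
  }
  paste0(body, substr(layout$pad, 1, total_length - nchar(body)))
}

.verify_telomere <- function(seq, motif, n_stems) {
  st <- fold_telomere(seq)
  nrow(st$hairpins) == n_stems && all(st$hairpins$loop_seq == motif)
}

#' Construct a synthetic 180-nt telomere
#'
#' Builds a telomere of `n_stems` palindromic stems whose arms are exact
#' reverse complements, each capped by the given loop motif, separated by
#' non-pairing spacers and padded to 180 nt. The construction is verified
#' by folding (the sequence must contain exactly the planted hairpins, all
#' loops equal to the motif) and resampled on the rare spurious-structure
#' draw, so the postcondition holds deterministically for a fixed seed.
#'
#' @param motif loop motif, 3 or 4 nt (e.g. "GCA", "GGA", "CTTG").
#' @param n_stems number of stems (0 to 12).
#' @param stem_range arm length range in bp.
#' @param spacer_range spacer length range in bp.
#' @param seed integer seed.
#' @param total_length telomere length (default 180 nt).
#' @return DNA string of length `total_length`, with the construction
#'   layout attached as attribute `"layout"` and motif as `"motif"`.
#' @export
#' @examples
#' tel <- build_telomere("GGA", 6, seed = 1)
#' fold_telomere(tel)
build_telomere <- function(motif, n_stems, stem_range = c(4, 8),
                           spacer_range = c(2, 12), seed = 1,
                           total_length = 180) {
  stopifnot(nchar(motif) %in% c(3, 4), n_stems >= 0, n_stems <= 12,
            stem_range[1] >= 1, stem_range[2] >= stem_range[1])
  minimal <- n_stems * (2 * stem_range[1] + nchar(motif)) +
    (n_stems + 1) * spacer_range[1]
  if (minimal > total_length) {
    stop("telomere construction overflow: stems do not fit in ",
         total_length, " nt")
  }
  for (attempt in seq_len(100)) {
    res <- with_seed(derive_seed(seed, attempt - 1L), {
      layout <- .telomere_layout(n_stems, stem_range, spacer_range,
                                 nchar(motif), total_length)
      seq <- tryCatch(.assemble_telomere(layout, motif, total_length),
                      error = function(e) NULL)
      if (!is.null(seq) && .verify_telomere(seq, motif, n_stems)) {
        structure(seq, layout = layout, motif = motif)
      } else NULL
    })
    if (!is.null(res)) return(res)
  }
  stop("failed to construct a clean telomere in 100 attempts")
}

#' Derive a diverged telomere from an existing layout
#'
#' Applies compensatory substitutions to the stem arms (G<->C flips,
#' mirrored in the opposite arm so pairing is preserved), substitutions to
#' the spacers, and optionally replaces the loop motif - emulating the
#' divergence of related telomere families whose stem architecture is
#' conserved.
#'
#' @param telomere a telomere built by [build_telomere()] (layout attached).
#' @param rate per-position substitution probability.
#' @param motif replacement loop motif (NULL keeps the original).
#' @param seed integer seed.
#' @return a new telomere string with updated layout attributes.
#' @export
mutate_telomere <- function(telomere, rate, motif = NULL, seed = 1) {
  layout <- attr(telomere, "layout")
  if (is.null(layout)) stop("telomere carries no construction layout")
  old_motif <- attr(telomere, "motif")
  if (is.null(motif)) motif <- old_motif
  n_stems <- length(layout$arms)
  total_length <- nchar(telomere)
  flip <- function(s, pair) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- ifelse(v[hit] == pair[1], pair[2], pair[1])
    paste(v, collapse = "")
  }
  # a longer replacement motif needs room: trim spacers evenly
  delta <- (nchar(motif) - nchar(old_motif)) * n_stems
  if (delta > 0) {
    lens <- nchar(layout$spacers)
    while (delta > 0 && max(lens) > 1) {
      k <- which.max(lens)
      lens[k] <- lens[k] - 1L
      delta <- delta - 1L
    }
    if (delta > 0) stop("cannot fit the replacement loop motif")
    layout$spacers <- vapply(lens, function(l) {
      paste(rep("A", l), collapse = "")
    }, character(1))
  }
  for (attempt in seq_len(100)) {
    res <- with_seed(derive_seed(seed, 500L + attempt), {
      lay <- layout
      lay$arms <- vapply(lay$arms, flip, character(1), pair = c("G", "C"),
                         USE.NAMES = FALSE)
      lay$spacers <- vapply(lay$spacers, flip, character(1),
                            pair = c("A", "C"), USE.NAMES = FALSE)
      lay$pad <- flip(lay$pad, c("A", "C"))
      seq <- tryCatch(.assemble_telomere(lay, motif, total_length),
                      error = function(e) NULL)
      if (!is.null(seq) && .verify_telomere(seq, motif, n_stems)) {
        structure(seq, layout = lay, motif = motif)
      } else NULL
    })
    if (!is.null(res)) return(res)
  }
  stop("failed to derive a clean mutated telomere in 100 attempts")
}

# ---- truth helpers ---------------------------------------------------------

# Exact terminal inverted repeat length of a sequence: the largest t such
# that the first t bases equal the reverse complement of the last t.
.tir_truth <- function(seq) {
  L <- nchar(seq)
  h <- L %/% 2
  if (h == 0) return(0L)
  a <- utf8ToInt(substr(seq, 1, h))
  b <- utf8ToInt(revcomp(substr(seq, L - h + 1, L)))
  neq <- which(a != b)
  if (!length(neq)) h else neq[1] - 1L
}

.make_truth <- function(seq, subclade = NA_character_,
                        tree = NA_character_) {
  tirl <- .tir_truth(seq)
  L <- nchar(seq)
  list(
    tir_length = tirl,
    tir_interval_left = c(0L, tirl),
    tir_interval_right = c(L - tirl, L),
    telomere_left = revcomp(substr(seq, 1, min(180, L))),
    telomere_right = substr(seq, max(1, L - 179), L),
    subclade = subclade, true_tree = tree, event_log = list())
}

.refresh_truth <- function(truth, seq) {
  t2 <- .make_truth(seq, truth$subclade, truth$true_tree)
  t2$event_log <- truth$event_log
  for (nm in setdiff(names(truth),
                     c(names(t2)))) t2[[nm]] <- truth[[nm]]
  t2
}

new_replicon <- function(id, sequence, truth = NULL) {
  structure(list(id = id, sequence = sequence, topology = "linear",
                 truth = truth), class = "replicon")
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("linear replicon %s: %d bp", x$id, nchar(x$sequence)))
  if (!is.null(x$truth)) cat(sprintf(", TIR %d bp", x$truth$tir_length))
  cat("\n")
  invisible(x)
}

# ---- tree construction and sequence evolution ------------------------------

.ladder_newick <- function(tips) {
  if (length(tips) == 1) return(tips)
  paste0("(", tips[1], ":1,", .ladder_newick(tips[-1]), ":1)")
}

#' Default strain tree for a configuration
#'
#' A caterpillar of sub-clades, each sub-clade itself a caterpillar of its
#' strains; every branch has length 1 (one unit of per-branch substitution).
#'
#' @param config a `population_config`.
#' @return Newick string.
#' @export
subclade_tree <- function(config) {
  ids <- strain_ids(config$n_strains)
  if (config$n_strains == 1) return(paste0("(", ids, ":1);"))
  cl <- split(ids, factor(config$subclade_assignment,
                          levels = unique(config$subclade_assignment)))
  sub <- vapply(cl, .ladder_newick, character(1))
  if (length(sub) == 1) return(paste0(sub[[1]], ";"))
  paste0(.ladder_newick(unname(sub)), ";")
}

# Evolve a sequence down a tree: each edge applies per-site substitutions at
# rate * edge.length. Returns a named list of tip sequences.
.evolve_along_tree <- function(ancestor, phy, rate) {
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + phy$Nnode)
  seqs[[root]] <- ancestor
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    el <- if (is.null(ord$edge.length)) 1 else ord$edge.length[e]
    seqs[[child]] <- substitute_sites(seqs[[par]], rate * el)
  }
  setNames(seqs[seq_len(n_tip)], phy$tip.label)
}

# ---- terminal-protein gene planting ----------------------------------------

.aa_alphabet <- function() {
  setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
}

random_protein <- function(n) {
  paste(sample(.aa_alphabet(), n, replace = TRUE), collapse = "")
}

# Reverse-translate a protein with GC-biased codon choice.
reverse_translate <- function(protein, gc_bias = TRUE) {
  gc_tab <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc_tab), unname(gc_tab))
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    cands <- by_aa[[a]]
    if (gc_bias) {
      gc <- vapply(cands, function(cd) {
        sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
      }, numeric(1))
      cands <- cands[gc == max(gc)]
    }
    if (length(cands) == 1) cands else sample(cands, 1)
  }, character(1), USE.NAMES = FALSE)
  paste0("ATG", paste(codons, collapse = ""), "TGA")
}

# Archetype-like terminal protein query set (synthetic stand-ins for the
# Tap/Tpg and GtpB/GtpA archetypes; generated, not derived from any
# database sequence).
.make_tp_queries <- function(seed) {
  with_seed(seed, list(
    gtpB = random_protein(250), gtpA = random_protein(180),
    tap_I = random_protein(300), tpg_I = random_protein(175)))
}

.plant_gene <- function(seq, at, cds) {
  str_assign(seq, at, at + nchar(cds) - 1L, cds)
}

# Substitute sites in a CDS under purifying selection against nonsense
# changes: substitutions that would create an internal stop codon are
# reverted to the original codon.
.substitute_cds <- function(cds, rate) {
  mut <- substitute_sites(cds, rate)
  if (identical(mut, cds)) return(mut)
  ncod <- nchar(mut) %/% 3
  for (i in seq_len(ncod - 1L)) {
    cod <- substr(mut, 3 * i - 2, 3 * i)
    if (cod %in% c("TAA", "TAG", "TGA")) {
      mut <- str_assign(mut, 3 * i - 2, 3 * i,
                        substr(cds, 3 * i - 2, 3 * i))
    }
  }
  mut
}

# ---- events ----------------------------------------------------------------

.ev_bir <- function(seq, p, template = c("left", "right")) {
  template <- match.arg(template)
  L <- nchar(seq)
  if (p < 1 || p > L %/% 2) stop("bir breakpoint outside bounds")
  if (template == "left") {
    str_assign(seq, L - p + 1L, L, revcomp(substr(seq, 1, p)))
  } else {
    str_assign(seq, 1L, p, revcomp(substr(seq, L - p + 1L, L)))
  }
}

.ev_telomere_swap <- function(seq, end, donor_tel, homogenize_p) {
  L <- nchar(seq)
  stopifnot(nchar(donor_tel) == 180, L > 360)
  if (end == "left") {
    seq <- str_assign(seq, 1L, 180L, revcomp(donor_tel))
    if (homogenize_p > 0) seq <- .ev_bir(seq, homogenize_p, "left")
  } else {
    seq <- str_assign(seq, L - 179L, L, donor_tel)
    if (homogenize_p > 0) seq <- .ev_bir(seq, homogenize_p, "right")
  }
  seq
}

.apply_event <- function(seq, ev, pop_env) {
  L <- nchar(seq)
  kind <- ev$kind
  if (kind == "substitution_burst") {
    rate <- if (is.null(ev$rate)) 0.05 else ev$rate
    from <- max(1L, ev$position + 1L)
    to <- min(L, ev$position + ev$length)
    if (from > to) stop("substitution_burst outside bounds")
    str_assign(seq, from, to, substitute_sites(substr(seq, from, to), rate))
  } else if (kind == "terminal_indel") {
    op <- ev$op
    end <- if (is.null(ev$end)) "right" else ev$end
    if (op == "del") {
      if (ev$length >= L %/% 2) stop("indel would destroy linearity")
      from <- if (end == "right") L - ev$position - ev$length + 1L else
        ev$position + 1L
      to <- from + ev$length - 1L
      if (from < 1 || to > L) stop("indel outside bounds")
      paste0(substr(seq, 1, from - 1L), substr(seq, to + 1L, L))
    } else {
      payload <- if (!is.null(ev$payload)) ev$payload else
        random_dna(ev$length, 0.72)
      at <- if (end == "right") L - ev$position else ev$position
      if (at < 0 || at > L) stop("indel outside bounds")
      paste0(substr(seq, 1, at), payload, substr(seq, at + 1L, L))
    }
  } else if (kind == "bir_homogenize") {
    .ev_bir(seq, ev$breakpoint,
            if (is.null(ev$template)) "left" else ev$template)
  } else if (kind == "telomere_swap") {
    donor_tel <- if (!is.null(ev$payload)) {
      ev$payload
    } else if (!is.null(pop_env$plasmids[[ev$donor]])) {
      pop_env$plasmids[[ev$donor]]$truth$telomere_right
    } else if (!is.null(pop_env$seqs[[ev$donor]])) {
      # inter-strain telomere transfer: take the donor's current
      # right-end telomere
      don <- pop_env$seqs[[ev$donor]]
      substr(don, nchar(don) - 179L, nchar(don))
    } else {
      stop("unknown telomere_swap donor: ", ev$donor)
    }
    p <- if (!is.null(ev$breakpoint)) ev$breakpoint else .tir_truth(seq)
    .ev_telomere_swap(seq, if (is.null(ev$end)) "left" else ev$end,
                      donor_tel, p)
  } else if (kind == "hgt_insert") {
    payload <- if (!is.null(ev$payload) && nchar(ev$payload) > 1) {
      ev$payload
    } else {
      don <- pop_env$seqs[[ev$donor]]
      if (is.null(don)) stop("unknown hgt donor: ", ev$donor)
      substr(don, ev$donor_position + 1L, ev$donor_position + ev$length)
    }
    if (ev$position < 0 || ev$position > L) stop("hgt position out of bounds")
    paste0(substr(seq, 1, ev$position), payload,
           substr(seq, ev$position + 1L, L))
  } else if (kind == "translocation") {
    from <- ev$position + 1L; to <- ev$position + ev$length
    if (from < 1 || to > L) stop("translocation outside bounds")
    seg <- substr(seq, from, to)
    rest <- paste0(substr(seq, 1, from - 1L), substr(seq, to + 1L, L))
    at <- min(ev$to, nchar(rest))
    paste0(substr(rest, 1, at), seg, substr(rest, at + 1L, nchar(rest)))
  } else if (kind == "inversion") {
    from <- ev$position + 1L; to <- ev$position + ev$length
    if (from < 1 || to > L) stop("inversion outside bounds")
    str_assign(seq, from, to, revcomp(substr(seq, from, to)))
  } else {
    stop("unknown event kind: ", kind)
  }
}

# ---- the population simulator ----------------------------------------------

#' Simulate a conspecific population of linear replicons
#'
#' Generates an ancestor at the configured GC content, evolves it along a
#' fixed sub-clade tree with per-branch substitutions, installs per-sub-
#' clade telomeres and terminal-protein operons, homogenizes the terminal
#' inverted repeats (the arms are exact reverse complements, as maintained
#' in vivo by break-induced replication between chromosome arms), applies
#' the configured rearrangement events, and returns replicons with
#' complete ground-truth annotation.
#'
#' @param config a [population_config()].
#' @return a `population`: list with `replicons` (named list of `replicon`
#'   objects), `plasmids`, `tree` (Newick), `tp_queries` (the synthetic
#'   terminal-protein archetype set), and `config`.
#' @export
simulate_population <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    L <- cfg$chromosome_length
    tirl <- cfg$tir_length
    ids <- strain_ids(cfg$n_strains)
    nw <- subclade_tree(cfg)

    anc <- random_dna(L, cfg$gc_content)

    # per-sub-clade telomeres derived from one ancestral layout
    clades <- unique(cfg$subclade_assignment)
    clade_tel <- list()
    if (tirl > 0) {
      anc_tel <- build_telomere(cfg$ancestral_motif, cfg$n_stems,
                                cfg$stem_range, cfg$spacer_range,
                                seed = derive_seed(cfg$seed, 101L))
      for (i in seq_along(clades)) {
        motif <- cfg$telomere_motif[[clades[i]]]
        if (is.null(motif) || is.na(motif)) motif <- cfg$ancestral_motif
        clade_tel[[clades[i]]] <-
          if (cfg$clade_divergence > 0 || motif != cfg$ancestral_motif) {
            mutate_telomere(anc_tel, cfg$clade_divergence, motif,
                            seed = derive_seed(cfg$seed, 200L + i))
          } else anc_tel
      }
    }

    # evolve along the tree
    if (cfg$n_strains == 1) {
      seqs <- setNames(list(anc), ids)
    } else {
      phy <- ape::read.tree(text = nw)
      seqs <- .evolve_along_tree(anc, phy, cfg$substitution_rate)
      seqs <- seqs[ids]
    }

    # terminal-protein operons
    tp_queries <- NULL
    tp_genes <- list()
    if (cfg$plant_tp_genes) {
      tp_queries <- .make_tp_queries(derive_seed(cfg$seed, 301L))
      cds <- lapply(tp_queries, reverse_translate)
      first_clade <- clades[1]
      for (s in ids) {
        genes <- list(list(gene = "gtpB", at = 3000L),
                      list(gene = "gtpA",
                           at = 3000L + nchar(cds$gtpB) + 51L))
        if (cfg$subclade_assignment[match(s, ids)] == first_clade) {
          genes <- c(genes, list(
            list(gene = "tap_I", at = 6500L),
            list(gene = "tpg_I", at = 6500L + nchar(cds$tap_I) + 81L)))
        }
        rows <- list()
        for (g in genes) {
          cd <- .substitute_cds(cds[[g$gene]], cfg$tp_divergence)
          seqs[[s]] <- .plant_gene(seqs[[s]], g$at + 1L, cd)
          rows[[length(rows) + 1L]] <- data.frame(
            strain = s, gene = g$gene, start = g$at,
            end = g$at + nchar(cd), strand = "+",
            stringsAsFactors = FALSE)
        }
        tp_genes[[s]] <- do.call(rbind, rows)
      }
    }

    # telomeres + TIR homogenization
    if (tirl > 0) {
      for (s in ids) {
        cl <- cfg$subclade_assignment[match(s, ids)]
        tel <- as.character(clade_tel[[cl]])
        seqs[[s]] <- str_assign(seqs[[s]], 1L, 180L, revcomp(tel))
        seqs[[s]] <- .ev_bir(seqs[[s]], tirl, "left")
      }
    }

    # plasmids
    plasmids <- list()
    for (i in seq_along(cfg$plasmids)) {
      ps <- cfg$plasmids[[i]]
      pl_len <- ps$length
      pl_tir <- if (is.null(ps$tir_length)) 2000L else ps$tir_length
      pseq <- random_dna(pl_len, cfg$gc_content)
      if (pl_tir >= 180) {
        ptel <- if (tirl > 0) {
          # plasmid telomeres are related telomere-family members too
          mutate_telomere(anc_tel, ps$divergence %||% 0.3, ps$motif,
                          seed = derive_seed(cfg$seed, 400L + i))
        } else build_telomere(ps$motif,
                              if (is.null(ps$n_stems)) cfg$n_stems else
                                ps$n_stems,
                              cfg$stem_range, cfg$spacer_range,
                              seed = derive_seed(cfg$seed, 400L + i))
        pseq <- str_assign(pseq, 1L, 180L, revcomp(as.character(ptel)))
        pseq <- .ev_bir(pseq, pl_tir, "left")
      }
      plasmids[[ps$id]] <- new_replicon(ps$id, pseq, .make_truth(pseq))
    }

    # truth before events
    replicons <- list()
    for (s in ids) {
      tr <- .make_truth(seqs[[s]],
                        cfg$subclade_assignment[match(s, ids)], nw)
      if (!is.null(tp_genes[[s]])) tr$tp_genes <- tp_genes[[s]]
      replicons[[s]] <- new_replicon(s, seqs[[s]], tr)
    }

    # events
    pop_env <- list(seqs = seqs, plasmids = plasmids)
    for (ev in cfg$event_list) {
      s <- ev$strain
      if (is.null(replicons[[s]])) stop("event targets unknown strain: ", s)
      newseq <- .apply_event(replicons[[s]]$sequence, ev, pop_env)
      replicons[[s]]$sequence <- newseq
      replicons[[s]]$truth <- .refresh_truth(replicons[[s]]$truth, newseq)
      replicons[[s]]$truth$event_log <-
        c(replicons[[s]]$truth$event_log, list(ev))
      pop_env$seqs[[s]] <- newseq
    }

    if (cfg$homogenize_final && tirl > 0) {
      for (s in ids) {
        newseq <- .ev_bir(replicons[[s]]$sequence, tirl, "left")
        replicons[[s]]$sequence <- newseq
        replicons[[s]]$truth <- .refresh_truth(replicons[[s]]$truth, newseq)
      }
    }

    structure(list(replicons = replicons, plasmids = plasmids, tree = nw,
                   tp_queries = tp_queries, config = cfg),
              class = "population")
  })
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("simulated population: %d strain(s), %d plasmid(s)\n",
              length(x$replicons), length(x$plasmids)))
  for (r in x$replicons) print(r)
  invisible(x)
}

#' Collapse a replicon to a single-TIR assembly
#'
#' Removes one terminal-inverted-repeat copy, emulating an NGS assembly in
#' which large terminal duplications are represented once (and therefore
#' attract twice the read depth).
#'
#' @param replicon a `replicon` with truth annotation.
#' @param drop which copy to remove (`"right"` or `"left"`).
#' @return a `replicon` whose truth records `collapsed_end`,
#'   `retained_tir` (0-based half-open interval) and `original_length`.
#' @export
collapse_assembly <- function(replicon, drop = c("right", "left")) {
  drop <- match.arg(drop)
  if (is.null(replicon$truth)) stop("collapse requires truth annotation")
  tirl <- replicon$truth$tir_length
  seq <- replicon$sequence
  L <- nchar(seq)
  if (tirl == 0) {
    out <- replicon
    out$truth$collapsed_end <- NA_character_
    out$truth$retained_tir <- c(0L, 0L)
    out$truth$original_length <- L
    return(out)
  }
  newseq <- if (drop == "right") substr(seq, 1, L - tirl) else
    substr(seq, tirl + 1L, L)
  tr <- replicon$truth
  tr$collapsed_end <- drop
  tr$original_length <- L
  tr$retained_tir <- if (drop == "right") c(0L, tirl) else
    c(L - 2L * tirl, L - tirl)
  new_replicon(paste0(replicon$id, "_collapsed"), newseq, tr)
}

#' Simulate uniform short reads from a linear replicon
#'
#' Fragment start positions are uniform over the extended range
#' `[-read_length+1, L]` and reads are clipped at the physical molecule
#' ends (fragment ends pile up at the termini of a sheared linear
#' molecule); clipped reads shorter than 31 nt are discarded. Interior
#' coverage is uniform at the requested fold and the termini stay covered,
#' which is what makes telomere read-walking possible. Strand is
#' Bernoulli(0.5); substitution errors are i.i.d. per base.
#'
#' @param replicon a `replicon` or DNA string.
#' @param coverage target fold coverage.
#' @param read_length read length in bp.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed; a fixed seed reproduces the read set exactly.
#' @return a `read_set`: list with `reads` (named character vector),
#'   `read_length`, `coverage_target`, `seed`.
#' @export
simulate_reads <- function(replicon, coverage, read_length = 300,
                           error_rate = 0.001, seed = 1) {
  seq <- if (inherits(replicon, "replicon")) replicon$sequence else replicon
  id <- if (inherits(replicon, "replicon")) replicon$id else "replicon"
  L <- nchar(seq)
  stopifnot(coverage > 0)
  if (read_length > L) stop("read_length exceeds replicon length")
  with_seed(seed, {
    n <- rpois(1, coverage * (L + read_length - 1) / read_length)
    starts <- sample.int(L + read_length - 1L, n, replace = TRUE) -
      read_length + 1L
    from <- pmax(1L, starts)
    to <- pmin(L, starts + read_length - 1L)
    keep <- (to - from + 1L) >= 31L
    from <- from[keep]; to <- to[keep]
    reads <- substring(seq, from, to)
    # sequencing errors
    if (error_rate > 0) {
      nerr <- rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(nerr > 0)) {
        reads[i] <- substitute_sites_fixed(reads[i], nerr[i])
      }
    }
    rev <- runif(length(reads)) < 0.5
    reads[rev] <- revcomp(reads[rev])
    names(reads) <- sprintf("%s_r%06d", id, seq_along(reads))
    structure(list(reads = reads, read_length = read_length,
                   coverage_target = coverage, seed = seed),
              class = "read_set")
  })
}

# Substitute exactly k random positions of a string to a different base.
substitute_sites_fixed <- function(s, k) {
  n <- nchar(s)
  pos <- sample.int(n, min(k, n))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in pos) v[i] <- sample(setdiff(bases, v[i]), 1)
  paste(v, collapse = "")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read set: %d reads, read length %d, target %.0fx\n",
              length(x$reads), x$read_length, x$coverage_target))
  invisible(x)
}

#' Write population artifacts to a directory
#'
#' Writes replicon and plasmid FASTA, per-strain truth JSON, TIR intervals
#' as BED (0-based half-open), and the true tree as Newick.
#'
#' @param pop a `population`.
#' @param dir output directory (created if needed).
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(pop$replicons, function(r) r$sequence, character(1))
  write_fasta(seqs, file.path(dir, "replicons.fasta"))
  if (length(pop$plasmids)) {
    write_fasta(vapply(pop$plasmids, function(r) r$sequence, character(1)),
                file.path(dir, "plasmids.fasta"))
  }
  truth <- lapply(pop$replicons, function(r) {
    tr <- r$truth
    tr$event_log <- lapply(tr$event_log, function(e)
      e[!vapply(e, is.null, logical(1))])
    tr
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  bed <- do.call(rbind, lapply(pop$replicons, function(r) {
    tr <- r$truth
    data.frame(chrom = r$id,
               start = c(tr$tir_interval_left[1], tr$tir_interval_right[1]),
               end = c(tr$tir_interval_left[2], tr$tir_interval_right[2]),
               name = c("TIR_left", "TIR_right"))
  }))
  write.table(bed, file.path(dir, "tirs.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(pop$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
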