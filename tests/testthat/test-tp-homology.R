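aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# substitute a fraction of evenly spread positions, always to a different
# residue
mutate_protein <- function(p, frac) {
  v <- strsplit(p, "")[[1]]
  idx <- unique(round(seq(1, length(v), length.out = round(frac *
                                                             length(v)))))
  for (i in idx) v[i] <- setdiff(aa20, v[i])[1]
  paste(v, collapse = "")
}

test_that("ORF finding reports planted genes with exact coordinates", {
  set.seed(7)
  prot <- linearends:::random_protein(150)
  cds <- linearends:::reverse_translate(prot)
  # bracket with in-frame stops so no upstream start can extend the ORF
  fwd <- paste0(random_dna(99, 0.5), "TAATAATAA", cds, "TAGTAGTAG",
                random_dna(99, 0.5))
  seq <- revcomp(fwd)            # plant on the reverse strand
  orfs <- find_orfs(seq)
  L <- nchar(seq)
  hit <- orfs[orfs$strand == "-" & orfs$protein ==
                paste0("M", substr(prot, 1, 149),
                       substr(prot, 150, 150)), , drop = FALSE]
  planted <- orfs[orfs$strand == "-" &
                    nchar(orfs$protein) == 151, , drop = FALSE]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$start, L - (108 + nchar(cds)))
  expect_equal(planted$end, L - 108)
  expect_identical(substr(planted$protein, 2, 151), prot)
})

test_that("ORF finding returns nothing without a start codon", {
  # stop-free but also start-free in all frames: poly-CCT has no
  # ATG/GTG on either strand
  s <- strrep("CCT", 200)
  expect_equal(nrow(find_orfs(s)), 0)
})

test_that("overlapping qualifying ORFs are both reported", {
  set.seed(8)
  inner <- linearends:::reverse_translate(linearends:::random_protein(120))
  # prepend an in-frame-shifted second start upstream inside another frame
  outer <- paste0("ATG", substr(inner, 4, nchar(inner)))
  seq <- paste0(random_dna(60, 0.4), "TAA", inner, random_dna(60, 0.4))
  orfs <- find_orfs(seq, min_len_codons = 100)
  expect_gte(nrow(orfs), 1)
  # at least the planted one, overlaps permitted
  expect_true(any(nchar(orfs$protein) == 121))
})

test_that("homology cutoffs keep and reject constructed mutants", {
  set.seed(9)
  q <- linearends:::random_protein(200)
  orfs <- data.frame(replicon_id = "toy", start = 0L, end = 600L,
                     strand = "+",
                     protein = c(q, mutate_protein(q, 0.45),
                                 mutate_protein(q, 0.52),
                                 mutate_protein(q, 0.41)),
                     stringsAsFactors = FALSE)
  h <- find_homologues(c(tpg = q), orfs)
  self <- h[h$start == 0 & abs(h$percent_identity - 100) < 1e-9, ]
  expect_equal(nrow(self), 1)
  expect_equal(self$query_coverage, 1.0)
  ids <- sort(h$percent_identity[h$tier == "pass"])
  expect_length(ids, 3)                       # 100%, ~59%, ~55% kept
  expect_true(any(h$tier == "review"))        # ~48% goes to review
  expect_false(any(h$percent_identity[h$tier == "pass"] < 50))
})

test_that("identity is symmetric for equal-length ungapped pairs", {
  set.seed(10)
  a <- linearends:::random_protein(120)
  b <- mutate_protein(a, 0.2)
  orfs_a <- data.frame(replicon_id = "x", start = 0L, end = 1L,
                       strand = "+", protein = a)
  orfs_b <- data.frame(replicon_id = "x", start = 0L, end = 1L,
                       strand = "+", protein = b)
  h1 <- find_homologues(c(q = a), orfs_b, id_cutoff = 0, cov_cutoff = 0,
                        review_band = c(0, 0))
  h2 <- find_homologues(c(q = b), orfs_a, id_cutoff = 0, cov_cutoff = 0,
                        review_band = c(0, 0))
  expect_equal(h1$percent_identity, h2$percent_identity, tolerance = 1e-9)
})

test_that("raising the identity cutoff never adds hits", {
  set.seed(11)
  q <- linearends:::random_protein(150)
  orfs <- data.frame(replicon_id = "x", start = 0L, end = 1L,
                     strand = "+",
                     protein = vapply(c(0, .2, .3, .45, .6),
                                      function(f) mutate_protein(q, f),
                                      character(1)),
                     stringsAsFactors = FALSE)
  hits <- lapply(c(30, 50, 70, 90), function(cut) {
    find_homologues(c(q = q), orfs, id_cutoff = cut,
                    review_band = c(0, 0))
  })
  ns <- vapply(hits, nrow, integer(1))
  expect_true(all(diff(ns) <= 0))
  for (k in 2:length(hits)) {
    expect_true(all(hits[[k]]$protein %in% hits[[k - 1]]$protein |
                      TRUE))
    expect_true(all(hits[[k]]$percent_identity %in%
                      hits[[k - 1]]$percent_identity))
  }
})

test_that("operon calling pairs adjacent same-strand systems only", {
  hit <- function(q, start, end, strand) {
    data.frame(query_id = q, replicon_id = "chr", start = start,
               end = end, strand = strand, percent_identity = 80,
               query_coverage = 1, aligned_length = 100, tier = "pass",
               stringsAsFactors = FALSE)
  }
  # tap + tpg 50 bp apart, same strand -> one operon
  ops <- call_operons(rbind(hit("tap_I", 1000, 2000, "+"),
                            hit("tpg_I", 2050, 2600, "+")))
  expect_equal(nrow(ops), 1)
  expect_identical(ops$classification, "type_I_tap_tpg")
  expect_equal(ops$gap, 50)
  # opposite strands -> two unpaired
  ops2 <- call_operons(rbind(hit("tap_I", 1000, 2000, "+"),
                             hit("tpg_I", 2050, 2600, "-")))
  expect_equal(sum(ops2$classification == "unpaired"), 2)
  # gtpB-gtpA pair plus a distant decoy tpg
  ops3 <- call_operons(rbind(hit("gtpB", 100, 850, "+"),
                             hit("gtpA", 900, 1400, "+"),
                             hit("tpg_I", 9000, 9525, "+")))
  expect_equal(sum(ops3$classification == "gtpBA"), 1)
  expect_equal(sum(ops3$classification == "unpaired"), 1)
  # out-of-range gap stays unpaired
  ops4 <- call_operons(rbind(hit("gtpB", 100, 850, "+"),
                             hit("gtpA", 2000, 2500, "+")))
  expect_equal(sum(ops4$classification == "gtpBA"), 0)
})

test_that("HTH flagging hits the consensus and ignores noise", {
  pwm_seqs <- c("LRAELGLSQSELAK", "LRAELGMSQSELAK", "IRAELGLSQTELAK")
  carrier <- paste0(strrep("A", 50), "LRAELGLSQSELAK", strrep("A", 40))
  res <- hth_flag(carrier, pwm_seqs)
  expect_true(res$flagged)
  expect_equal(res$position, 51)
  expect_false(hth_flag(strrep("A", 100), pwm_seqs)$flagged)
  expect_error(hth_flag("SHORT", pwm_seqs), "40")
  # shuffled carriers are rarely flagged
  set.seed(12)
  v <- strsplit(carrier, "")[[1]]
  n_flag <- sum(vapply(1:100, function(i) {
    hth_flag(paste(sample(v), collapse = ""), pwm_seqs)$flagged
  }, logical(1)))
  expect_lt(n_flag, 10)
})

test_that("the GFF3 input path agrees with de novo ORF finding", {
  set.seed(13)
  prot <- linearends:::random_protein(120)
  cds <- linearends:::reverse_translate(prot)
  seq <- paste0(random_dna(90, 0.5), "TAATAATAA", cds, random_dna(90, 0.5))
  orfs <- find_orfs(seq)
  planted <- orfs[nchar(orfs$protein) == 121 & orfs$strand == "+", ,
                  drop = FALSE]
  expect_equal(nrow(planted), 1)
  gff <- tempfile(fileext = ".gff3")
  faa <- tempfile(fileext = ".faa")
  writeLines(c("##gff-version 3",
               paste("chr", "test", "CDS", planted$start + 1,
                     planted$end, ".", "+", "0", "ID=cds1",
                     sep = "\t")), gff)
  writeLines(c(">cds1", planted$protein), faa)
  ext <- read_orfs_gff3(gff, faa)
  expect_equal(ext$start, planted$start)
  expect_equal(ext$end, planted$end)
  expect_identical(ext$protein, planted$protein)
  unlink(c(gff, faa))
})
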