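test_that("reverse complement is an involution over random sequences", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(1:200, 1), runif(1))
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_identical(revcomp("GATC"), "GATC")
  expect_identical(revcomp(c("A", "ACG")), c("T", "CGT"))
})

test_that("single-stem construction yields exactly one enumerable hairpin", {
  tel <- build_telomere("CTTG", 1, stem_range = c(5, 5),
                        spacer_range = c(0, 0), seed = 4)
  expect_equal(nchar(tel), 180)
  cand <- naive_hairpins(as.character(tel))
  arm5 <- cand[cand$arm_len >= 5 & cand$mismatches == 0 &
                 cand$sheared == 0, ]
  expect_equal(nrow(arm5), 1)
  expect_equal(arm5$loop_seq, "CTTG")
  st <- fold_telomere(tel)
  expect_equal(nrow(st$hairpins), 1)
  expect_equal(st$hairpins$arm_len, 5)
})

test_that("zero-stem construction folds to nothing and overflow errors", {
  tel0 <- build_telomere("GGA", 0, seed = 2)
  expect_equal(nchar(tel0), 180)
  expect_equal(nrow(fold_telomere(tel0)$hairpins), 0)
  # 12 stems of arm exactly 8 with a 4-nt loop cannot fit 180 nt
  expect_error(build_telomere("CTTG", 12, stem_range = c(8, 8),
                              spacer_range = c(2, 12), seed = 1),
               "overflow")
})

test_that("zero-rate, zero-event simulation yields identical strains", {
  cfg <- population_config(n_strains = 3, chromosome_length = 30000,
                           tir_length = 3000, substitution_rate = 0,
                           clade_divergence = 0,
                           subclade_assignment = rep("I", 3),
                           telomere_motif = c(I = "GGA"),
                           plant_tp_genes = FALSE, seed = 9)
  pop <- simulate_population(cfg)
  seqs <- vapply(pop$replicons, function(r) r$sequence, character(1))
  expect_identical(unname(seqs[1]), unname(seqs[2]))
  expect_identical(unname(seqs[1]), unname(seqs[3]))
  tirs <- vapply(pop$replicons, function(r) r$truth$tir_length, integer(1))
  expect_true(all(tirs == tirs[1]))
  expect_true(all(tirs >= 3000))
})

test_that("TIR arms are exact reverse complements after homogenization", {
  cfg <- population_config(n_strains = 2, chromosome_length = 30000,
                           tir_length = 3000, plant_tp_genes = FALSE,
                           seed = 21)
  pop <- simulate_population(cfg)
  for (r in pop$replicons) {
    L <- nchar(r$sequence)
    t <- r$truth$tir_length
    expect_gte(t, 3000)
    expect_identical(substr(r$sequence, 1, t),
                     revcomp(substr(r$sequence, L - t + 1, L)))
  }
})

test_that("a breakpoint upstream of the TIR grows both homogenized arms", {
  cfg <- population_config(n_strains = 1, chromosome_length = 50000,
                           tir_length = 5000, plant_tp_genes = FALSE,
                           seed = 5,
                           event_list = list(
                             list(kind = "bir_homogenize", strain = "s01",
                                  breakpoint = 7000, template = "left")))
  pop <- simulate_population(cfg)
  r <- pop$replicons[[1]]
  expect_gte(r$truth$tir_length, 7000)
  L <- nchar(r$sequence)
  expect_identical(substr(r$sequence, 1, 7000),
                   revcomp(substr(r$sequence, L - 6999, L)))
})

test_that("a telomere swap installs the donor telomere at both ends", {
  cfg <- population_config(
    n_strains = 4, chromosome_length = 40000, tir_length = 4000,
    plant_tp_genes = FALSE, seed = 13,
    subclade_assignment = c("I", "I", "II", "II"),
    plasmids = list(list(id = "pX", length = 15000, tir_length = 1500,
                         motif = "GCA")),
    event_list = list(list(kind = "telomere_swap", strain = "s02",
                           donor = "pX")))
  pop <- simulate_population(cfg)
  donor_tel <- pop$plasmids$pX$truth$telomere_right
  tr <- pop$replicons$s02$truth
  expect_gte(pairwise_identity(tr$telomere_right, donor_tel), 97)
  expect_gte(pairwise_identity(tr$telomere_left, donor_tel), 97)
  # non-terminal sequence identical to the sister strain away from TIRs
  mid <- function(r) substr(r$sequence, 10000, 30000)
  expect_identical(nchar(mid(pop$replicons$s02)), 20001L)
  d <- sum(utf8ToInt(mid(pop$replicons$s02)) !=
             utf8ToInt(mid(pop$replicons$s01)))
  # only tree substitutions separate the sisters in the core
  expect_lt(d / 20001, 0.02)
})

test_that("collapse removes exactly one TIR copy and keeps truth", {
  cfg <- population_config(n_strains = 1, chromosome_length = 100000,
                           tir_length = 10000, plant_tp_genes = FALSE,
                           seed = 31)
  pop <- simulate_population(cfg)
  r <- pop$replicons[[1]]
  col <- collapse_assembly(r)
  expect_equal(nchar(col$sequence),
               nchar(r$sequence) - r$truth$tir_length)
  expect_identical(col$truth$collapsed_end, "right")
  expect_equal(col$truth$retained_tir[1], 0)
  # TIR-less replicon collapses to itself
  cfg0 <- population_config(n_strains = 1, chromosome_length = 20000,
                            tir_length = 0, plant_tp_genes = FALSE,
                            seed = 32)
  r0 <- simulate_population(cfg0)$replicons[[1]]
  expect_lt(r0$truth$tir_length, 50)
  r0$truth$tir_length <- 0L
  col0 <- collapse_assembly(r0)
  expect_identical(col0$sequence, r0$sequence)
})

test_that("read simulation hits its coverage expectation", {
  seq <- random_dna(300000, 0.72)
  rep_ <- linearends:::new_replicon("toy", seq)
  rs <- simulate_reads(rep_, 50, 300, 0, seed = 8)
  expect_true(abs(length(rs$reads) - 50000) < 5 * sqrt(50000))
  # error-free reads are exact substrings of the replicon or its
  # reverse complement
  idx <- sample(length(rs$reads), 50)
  rc <- revcomp(seq)
  for (rd in rs$reads[idx]) {
    expect_true(grepl(rd, seq, fixed = TRUE) ||
                  grepl(rd, rc, fixed = TRUE))
  }
})

test_that("read simulation is seed-reproducible and FASTQ round-trips", {
  seq <- random_dna(20000, 0.6)
  rs1 <- simulate_reads(seq, 10, 150, 0.01, seed = 77)
  rs2 <- simulate_reads(seq, 10, 150, 0.01, seed = 77)
  expect_identical(rs1$reads, rs2$reads)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_fastq(rs1, f1); write_fastq(rs2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_identical(unname(back), unname(rs1$reads))
  expect_identical(names(back), names(rs1$reads))
  unlink(c(f1, f2))
})

test_that("structural events preserve length bookkeeping", {
  cfg <- population_config(
    n_strains = 1, chromosome_length = 30000, tir_length = 3000,
    plant_tp_genes = FALSE, seed = 41,
    event_list = list(
      list(kind = "inversion", strain = "s01", position = 10000,
           length = 2000),
      list(kind = "hgt_insert", strain = "s01", position = 15000,
           payload = strrep("ACGT", 250)),
      list(kind = "terminal_indel", strain = "s01", end = "right",
           op = "del", position = 4000, length = 500)))
  pop <- simulate_population(cfg)
  expect_equal(nchar(pop$replicons[[1]]$sequence), 30000 + 1000 - 500)
  expect_equal(length(pop$replicons[[1]]$truth$event_log), 3)
  # event outside bounds is rejected
  bad <- population_config(
    n_strains = 1, chromosome_length = 20000, tir_length = 2000,
    plant_tp_genes = FALSE, seed = 42,
    event_list = list(list(kind = "hgt_insert", strain = "s01",
                           position = 30000, payload = "ACGT")))
  expect_error(simulate_population(bad), "bounds")
})
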