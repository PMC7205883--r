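test_that("identical sequences align without gaps", {
  s <- random_dna(80, 0.6)
  aln <- align_telomeres(c(a = s, b = s))
  expect_equal(ncol(aln$matrix), 80)
  expect_true(all(aln$matrix != "-"))
  expect_error(align_telomeres(c(a = s)), "at least 2")
})

test_that("pairwise alignment is optimal against brute-force enumeration", {
  al <- linearends:::nw_align("ACGT", "AGT")
  expect_equal(aligned_score(al), brute_align_score("ACGT", "AGT"))
  expect_equal(nchar(al$a), 4)
  expect_equal(lengths(regmatches(al$b, gregexpr("-", al$b))), 1)
  set.seed(31)
  for (i in 1:8) {
    a <- random_dna(sample(3:7, 1), 0.5)
    b <- random_dna(sample(3:7, 1), 0.5)
    al <- linearends:::nw_align(a, b)
    expect_equal(aligned_score(al), brute_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment of a simulated population is deterministic", {
  set.seed(41)
  seqs <- setNames(vapply(1:6, function(i) random_dna(100, 0.6),
                          character(1)), paste0("t", 1:6))
  a1 <- align_telomeres(seqs)
  a2 <- align_telomeres(seqs)
  expect_identical(a1$matrix, a2$matrix)
  expect_identical(rownames(a1$matrix), names(seqs))
})

test_that("site filtering applies the strict sub-80% rule", {
  mat <- matrix("A", nrow = 10, ncol = 4,
                dimnames = list(paste0("t", 1:10), NULL))
  mat[1:3, 1] <- "-"   # coverage 0.70 -> removed
  mat[1:2, 2] <- "-"   # coverage 0.80 -> kept (boundary)
  mat[1, 3] <- "-"     # coverage 0.90 -> kept
  aln <- structure(list(taxa = rownames(mat), matrix = mat,
                        site_coverage = colMeans(mat != "-")),
                   class = "telomere_alignment")
  f <- filter_sites(aln, 0.80)
  expect_equal(ncol(f$matrix), 3)
  expect_identical(f$matrix[, 1], mat[, 2])
  # gapless alignment is unchanged
  g <- structure(list(taxa = rownames(mat),
                      matrix = matrix("C", 10, 5,
                                      dimnames = list(rownames(mat),
                                                      NULL)),
                      site_coverage = rep(1, 5)),
                 class = "telomere_alignment")
  expect_equal(ncol(filter_sites(g)$matrix), 5)
  aln$matrix[] <- "-"
  aln$site_coverage <- rep(0, 4)
  expect_error(filter_sites(aln), "removed")
})

test_that("K2P matches the closed form and flags saturation", {
  mk <- function(b) {
    m <- rbind(a = rep("A", 100), b = b)
    structure(list(taxa = c("a", "b"), matrix = m,
                   site_coverage = rep(1, 100)),
              class = "telomere_alignment")
  }
  b <- rep("A", 100); b[1:10] <- "G"; b[11:15] <- "C"
  dm <- k2p_distance(mk(b))
  expect_equal(dm$P["a", "b"], 0.10)
  expect_equal(dm$Q["a", "b"], 0.05)
  expect_equal(dm$d["a", "b"], -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
  # identical rows
  expect_equal(k2p_distance(mk(rep("A", 100)))$d["a", "b"], 0)
  # P = 0, Q = 0.5 saturates the second logarithm
  b2 <- rep("A", 100); b2[1:50] <- "C"
  dm2 <- k2p_distance(mk(b2))
  expect_true(dm2$saturated["a", "b"])
  expect_true(is.na(dm2$d["a", "b"]))
  expect_error(nj_tree(k2p_distance(mk(b2))), "needs at least 3|saturated")
})

test_that("K2P correction never undershoots the raw p-distance", {
  set.seed(51)
  for (i in 1:10) {
    a <- strsplit(random_dna(200, 0.5), "")[[1]]
    b <- a
    idx <- sample(200, sample(5:60, 1))
    b[idx] <- vapply(b[idx], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    aln <- structure(list(taxa = c("a", "b"), matrix = rbind(a = a, b = b),
                          site_coverage = rep(1, 200)),
                     class = "telomere_alignment")
    dm <- k2p_distance(aln)
    if (!dm$saturated["a", "b"]) {
      p <- dm$P["a", "b"] + dm$Q["a", "b"]
      expect_gte(dm$d["a", "b"] + 1e-12, p)
    }
  }
})

test_that("NJ resolves three taxa additively", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  pd <- cophenetic(tr)
  expect_equal(pd["A", "B"], 5)
  expect_equal(pd["A", "C"], 9)
  expect_equal(pd["B", "C"], 10)
})

test_that("NJ recovers a four-taxon additive matrix exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  expect_identical(names(linearends:::tree_bipartitions(tr)), "C|D")
  expect_equal(unname(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]),
               unname(D), tolerance = 1e-12)
})

test_that("NJ recovers random additive trees and agrees with ape", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (i in 1:25) {
    nt <- sample(4:8, 1)
    rt <- ape::rtree(nt, br = function(n) runif(n, 0.3, 2))
    D <- cophenetic(rt)
    tr <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rt)), 0,
                 info = i)
    expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                   ape::unroot(ape::nj(D))), 0, info = i)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("bootstrap supports are bounded, reproducible and decisive", {
  set.seed(71)
  clade1 <- random_dna(200, 0.6)
  clade2 <- strsplit(clade1, "")[[1]]
  idx <- sample(200, 40)
  clade2[idx] <- vapply(clade2[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, character(1))
  clade2 <- paste(clade2, collapse = "")
  jitter <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    paste(v, collapse = "")
  }
  seqs <- c(a1 = jitter(clade1, 2), a2 = jitter(clade1, 2),
            a3 = jitter(clade1, 2), b1 = jitter(clade2, 2),
            b2 = jitter(clade2, 2), b3 = jitter(clade2, 2))
  aln <- align_telomeres(seqs)
  bs1 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  bs2 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 100))
  clade_split <- vapply(names(bs1$support), function(s) {
    setequal(strsplit(s, "|", fixed = TRUE)[[1]],
             c("a1", "a2", "a3")) ||
      setequal(strsplit(s, "|", fixed = TRUE)[[1]], c("b1", "b2", "b3"))
  }, logical(1))
  expect_true(any(clade_split))
  expect_gte(max(bs1$support[clade_split]), 95)
})

test_that("topology comparison finds the conflicts of a leaf swap", {
  t1 <- ape::read.tree(text = "((A,B),C,(D,E));")
  expect_equal(compare_topologies(t1, t1)$rf_distance, 0)
  expect_length(compare_topologies(t1, t1)$conflicting_telomere, 0)
  t2 <- ape::read.tree(text = "((A,D),C,(B,E));")
  cmp <- compare_topologies(t1, t2)
  expect_setequal(cmp$conflicting_genome, names(
    linearends:::tree_bipartitions(t1)))
  expect_setequal(cmp$conflicting_telomere, names(
    linearends:::tree_bipartitions(t2)))
  expect_true(all(c("A", "B", "D", "E") %in% cmp$incongruent_leaves))
  expect_false("C" %in% cmp$incongruent_leaves)
  t3 <- ape::read.tree(text = "((A,B),C,(D,X));")
  expect_error(compare_topologies(t1, t3), "leaf sets")
})

test_that("a planted telomere swap clusters with its donor lineage", {
  cfg <- population_config(
    n_strains = 8, chromosome_length = 30000, tir_length = 3000,
    plant_tp_genes = FALSE, seed = 303,
    subclade_assignment = rep(c("I", "II", "III", "IV"), each = 2),
    plasmids = list(list(id = "pD", length = 12000, tir_length = 1200,
                         motif = "GCA")),
    event_list = list(list(kind = "telomere_swap", strain = "s07",
                           donor = "pD")))
  pop <- simulate_population(cfg)
  tels <- vapply(pop$replicons, function(r) r$truth$telomere_right,
                 character(1))
  aln <- filter_sites(align_telomeres(tels), 0.80)
  tr <- nj_tree(k2p_distance(aln), allow_saturated = TRUE)
  cmp <- compare_topologies(ape::read.tree(text = pop$tree), tr)
  expect_true("s07" %in% cmp$incongruent_leaves)
  # the recombinant no longer pairs with its genome sister
  expect_gt(cophenetic(tr)["s07", "s08"],
            cophenetic(tr)["s01", "s02"])
})

test_that("percent identity uses overlap columns only", {
  s <- random_dna(180, 0.6)
  expect_equal(pairwise_identity(s, s), 100)
  # 93 matches in a 100-column gapless overlap
  v <- strsplit(random_dna(100, 0.5), "")[[1]]
  w <- v
  w[seq(5, 95, length.out = 7)] <- vapply(
    w[seq(5, 95, length.out = 7)], function(x) {
      setdiff(c("A", "C", "G", "T"), x)[1]
    }, character(1))
  expect_equal(pairwise_identity(paste(v, collapse = ""),
                                 paste(w, collapse = "")), 93)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("compensatory stem substitutions keep the fold class", {
  tel <- build_telomere("GGA", 6, seed = 404)
  mut <- mutate_telomere(tel, 0.02, seed = 405)
  ident <- pairwise_identity(as.character(tel), as.character(mut))
  expect_gt(ident, 90)
  expect_lt(ident, 100)
  expect_identical(fold_telomere(as.character(mut))$loop_class,
                   fold_telomere(as.character(tel))$loop_class)
})
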