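mk_profile <- function(states, positions = seq_along(states)) {
  structure(list(triplet = c(recombinant = "rec", parent_a = "pA",
                             parent_b = "pB"),
                 site_positions = positions, site_states = states),
            class = "informative_profile")
}

test_that("identical triplets carry no informative sites and no events", {
  s <- strsplit(random_dna(500, 0.6), "")[[1]]
  mat <- rbind(rec = s, pA = s, pB = s)
  pr <- informative_sites(mat, "rec", "pA", "pB")
  expect_length(pr$site_positions, 0)
  expect_equal(nrow(maxchi_scan(pr)), 0)
  expect_equal(nrow(chimaera_scan(pr)), 0)
  expect_equal(nrow(triplet_descent_scan(pr)), 0)
})

test_that("informative-site states follow the triplet definition", {
  mat <- rbind(rec = c("A", "C", "G", "T", "A"),
               pA  = c("A", "C", "T", "T", "C"),
               pB  = c("A", "G", "G", "T", "C"))
  pr <- informative_sites(mat, "rec", "pA", "pB")
  # col1: invariant; col2: rec==pA; col3: rec==pB; col4: invariant;
  # col5: rec matches neither (biallelic)
  expect_equal(pr$site_positions, c(2L, 3L, 5L))
  expect_equal(pr$site_states, c("A", "B", "other"))
})

test_that("a half-and-half mosaic is localised by all three detectors", {
  for (s in 1:3) {
    mat <- simulate_recombination_triplet(1000, 0.1, breakpoint = 500,
                                          seed = s)
    pr <- informative_sites(mat, "rec", "pA", "pB")
    e <- rbind(maxchi_scan(pr, n_perm = 500, seed = s),
               chimaera_scan(pr, n_perm = 500, seed = s + 10),
               triplet_descent_scan(pr, n_perm = 500, seed = s + 20))
    expect_equal(nrow(e), 3, info = s)
    expect_true(all(abs((e$bp_start + e$bp_end) / 2 - 500) <= 50),
                info = s)
    expect_true(all(e$p <= 0.05))
  }
})

test_that("the descent statistic equals the hand count on block data", {
  states <- c(rep("A", 30), rep("B", 30))
  pr <- mk_profile(states)
  obs <- linearends:::.descent_stat(pr$site_states == "A")
  expect_equal(obs$stat, 30)
  ev <- triplet_descent_scan(pr, n_perm = 1000, seed = 3)
  expect_equal(nrow(ev), 1)
  expect_lte(ev$p, 0.05)
  # alternating states never accumulate a descent
  alt <- mk_profile(rep(c("A", "B"), 30))
  obs2 <- linearends:::.descent_stat(alt$site_states == "A")
  expect_lte(obs2$stat, 2)
  expect_equal(nrow(triplet_descent_scan(alt, n_perm = 300, seed = 4)), 0)
})

test_that("a pure-parent recombinant yields no event", {
  mat <- simulate_recombination_triplet(800, 0.1, seed = 9)
  mat["rec", ] <- mat["pA", ]
  pr <- informative_sites(mat, "rec", "pA", "pB")
  expect_true(all(pr$site_states != "B"))
  expect_equal(nrow(triplet_descent_scan(pr, n_perm = 300, seed = 1)), 0)
})

test_that("permutation p-values are seed-reproducible", {
  mat <- simulate_recombination_triplet(600, 0.08, breakpoint = 300,
                                        seed = 5)
  pr <- informative_sites(mat, "rec", "pA", "pB")
  e1 <- maxchi_scan(pr, n_perm = 300, seed = 42)
  e2 <- maxchi_scan(pr, n_perm = 300, seed = 42)
  expect_identical(e1$p, e2$p)
})

test_that("consensus voting drops lone-method events and merges support", {
  one <- data.frame(recombinant = "rec", parent_a = "pA", parent_b = "pB",
                    method = "maxchi", stat = 30, p = 0.001,
                    bp_start = 480L, bp_end = 500L,
                    stringsAsFactors = FALSE)
  expect_equal(nrow(consensus_events(one, min_methods = 2)), 0)
  three <- rbind(one,
                 transform(one, method = "chimaera", bp_start = 500L,
                           bp_end = 520L),
                 transform(one, method = "triplet_descent",
                           bp_start = 470L, bp_end = 490L))
  ce <- consensus_events(three, min_methods = 2)
  expect_equal(nrow(ce), 1)
  expect_equal(ce$n_methods, 3)
  # order independence
  ce2 <- consensus_events(three[c(3, 1, 2), ], min_methods = 2)
  expect_identical(ce, ce2)
})

test_that("per-strain counts include requested zeros and sort by burden", {
  ev <- data.frame(recombinant = c("x", "x", "x", "y", "y"))
  tab <- per_strain_event_counts(ev, strains = c("x", "y", "z"))
  expect_equal(tab$n_events[tab$strain == "x"], 3L)
  expect_equal(tab$n_events[tab$strain == "y"], 2L)
  expect_equal(tab$n_events[tab$strain == "z"], 0L)
  expect_identical(tab$strain[1], "x")
  empty <- per_strain_event_counts(ev[0, , drop = FALSE],
                                   strains = c("a", "b"))
  expect_true(all(empty$n_events == 0))
})

test_that("planted transfers are recovered with donors in a population", {
  # five strains; s05 receives a large block from s03
  set.seed(88)
  n <- 1500
  mat <- simulate_recombination_triplet(n, 0.1, n_extra = 2, seed = 88)
  rownames(mat) <- c("s01", "s02", "s03", "s04", "s05")
  mat["s05", 600:1500] <- mat["s03", 600:1500]
  sc <- scan_triplets(mat, n_perm = 400, n_perm_explore = 150, seed = 7)
  ev <- sc$events
  expect_gte(nrow(ev), 1)
  hit <- ev[ev$recombinant == "s05", , drop = FALSE]
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$donor == "s03"))
  # transfer-free control stays clean
  ctrl <- simulate_recombination_triplet(n, 0.08, n_extra = 2, seed = 89)
  rownames(ctrl) <- rownames(mat)
  sc0 <- scan_triplets(ctrl, n_perm = 400, n_perm_explore = 150, seed = 8)
  expect_equal(nrow(sc0$events), 0)
})
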