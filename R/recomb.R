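#' Informative-site profile of a recombination triplet
#'
#' For a putative recombinant and two candidate parents, extracts the
#' alignment columns that are variable and biallelic among the triplet and
#' assigns each the state `A` (recombinant matches parent A), `B`
#' (matches parent B) or `other` (matches neither).
#'
#' @param alignment a `telomere_alignment` or character matrix (rows =
#'   taxa).
#' @param recombinant,parent_a,parent_b taxon names.
#' @return an `informative_profile`: list with `triplet`,
#'   `site_positions` (1-based alignment columns), `site_states`.
#' @export
informative_sites <- function(alignment, recombinant, parent_a, parent_b) {
  mat <- if (inherits(alignment, "telomere_alignment")) alignment$matrix
         else alignment
  r <- mat[recombinant, ]; a <- mat[parent_a, ]; b <- mat[parent_b, ]
  ok <- r != "-" & a != "-" & b != "-"
  states <- rep(NA_character_, length(r))
  n_alleles <- vapply(seq_along(r), function(i) {
    length(unique(c(r[i], a[i], b[i])))
  }, integer(1))
  variable <- ok & n_alleles == 2L
  states[variable & r == a & r != b] <- "A"
  states[variable & r == b & r != a] <- "B"
  states[variable & r != a & r != b] <- "other"
  keep <- which(!is.na(states))
  structure(list(
    triplet = c(recombinant = recombinant, parent_a = parent_a,
                parent_b = parent_b),
    site_positions = keep, site_states = states[keep]),
    class = "informative_profile")
}

.chi2_2x2 <- function(a, b, c2, d) {
  # chi-square statistic of the 2x2 table [a b; c2 d] without continuity
  # correction; 0 on degenerate margins
  n <- a + b + c2 + d
  r1 <- a + b; r2 <- c2 + d; c1 <- a + c2; cc2 <- b + d
  den <- r1 * r2 * c1 * cc2
  ifelse(den == 0, 0, n * (a * d - b * c2)^2 / den)
}

# Max chi-square over breakpoints for a +/- state vector (A = 1, B = 0,
# NA = uninformative filler). Returns list(stat, k) with k the site index
# left of the maximizing breakpoint.
.maxchi_stat <- function(is_a, window) {
  n <- length(is_a)
  if (n < 2 * window) return(list(stat = NA_real_, k = NA_integer_))
  ca <- cumsum(!is.na(is_a) & is_a)
  cb <- cumsum(!is.na(is_a) & !is_a)
  k <- window:(n - window)
  aL <- ca[k] - c(0, ca)[pmax(k - window + 1L, 1L)]
  bL <- cb[k] - c(0, cb)[pmax(k - window + 1L, 1L)]
  aR <- ca[k + window] - ca[k]
  bR <- cb[k + window] - cb[k]
  stat <- .chi2_2x2(aL, bL, aR, bR)
  best <- which.max(stat)
  list(stat = stat[best], k = k[best])
}

.descent_stat <- function(is_a) {
  # random walk: +1 on B-matching, -1 on A-matching sites
  z <- ifelse(is_a, -1L, 1L)
  walk <- cumsum(z)
  run_max <- cummax(c(0L, walk))[-1]
  drop <- run_max - walk
  j <- which.max(drop)
  # descent start: last position (0 = before the first site) where the
  # running maximum was attained before j
  pre <- c(0L, walk)[seq_len(j)]
  i <- max(which(pre == run_max[j])) - 1L
  list(stat = drop[j], start = i, end = j)
}

.perm_pvalue <- function(obs, x, n_perm, stat_fun) {
  if (!is.finite(obs)) return(NA_real_)
  ge <- 0L
  for (p in seq_len(n_perm)) {
    s <- stat_fun(sample(x))
    if (is.finite(s) && s >= obs) ge <- ge + 1L
  }
  (1 + ge) / (n_perm + 1)
}

.scan_result <- function(profile, method, stat, p, alpha, bp_start,
                         bp_end) {
  if (!is.finite(stat) || is.na(p) || p > alpha) {
    return(NULL)
  }
  data.frame(recombinant = profile$triplet[["recombinant"]],
             parent_a = profile$triplet[["parent_a"]],
             parent_b = profile$triplet[["parent_b"]],
             method = method, stat = stat, p = p,
             bp_start = bp_start, bp_end = bp_end,
             stringsAsFactors = FALSE)
}

#' MaxChi-style recombination scan on a triplet
#'
#' Slides a breakpoint over the informative sites; at each breakpoint a
#' 2x2 chi-square compares A-matching vs B-matching counts in the two
#' flanking windows of `window` sites. The maximum chi-square is tested by
#' permuting the site order `n_perm` times (seeded); a significant maximum
#' becomes an event with the breakpoint at the maximizing site interval.
#'
#' @param profile an `informative_profile`.
#' @param window flanking window in informative sites.
#' @param n_perm permutations for the null.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data.frame of events (possibly empty, with attribute `reason`).
#' @export
maxchi_scan <- function(profile, window = 20, n_perm = 1000,
                        alpha = 0.05, seed = 1) {
  st <- profile$site_states
  use <- st %in% c("A", "B", "other")
  is_a <- ifelse(st[use] == "A", TRUE,
                 ifelse(st[use] == "B", FALSE, NA))
  pos <- profile$site_positions[use]
  if (length(is_a) < 2 * window) {
    ev <- .empty_events()
    attr(ev, "reason") <- "too few informative sites"
    return(ev)
  }
  obs <- .maxchi_stat(is_a, window)
  p <- with_seed(seed, .perm_pvalue(obs$stat, is_a, n_perm, function(x) {
    .maxchi_stat(x, window)$stat
  }))
  ev <- .scan_result(profile, "maxchi", obs$stat, p, alpha,
                     pos[obs$k], pos[min(obs$k + 1L, length(pos))])
  if (is.null(ev)) .empty_events() else ev
}

#' Chimaera-style recombination scan on a triplet
#'
#' As [maxchi_scan()], but restricted to the sites where the recombinant
#' differs from exactly one parent (the `A`/`B` states).
#'
#' @inheritParams maxchi_scan
#' @export
chimaera_scan <- function(profile, window = 20, n_perm = 1000,
                          alpha = 0.05, seed = 1) {
  use <- profile$site_states %in% c("A", "B")
  is_a <- profile$site_states[use] == "A"
  pos <- profile$site_positions[use]
  if (length(is_a) < 2 * window) {
    ev <- .empty_events()
    attr(ev, "reason") <- "too few informative sites"
    return(ev)
  }
  obs <- .maxchi_stat(is_a, window)
  p <- with_seed(seed, .perm_pvalue(obs$stat, is_a, n_perm, function(x) {
    .maxchi_stat(x, window)$stat
  }))
  ev <- .scan_result(profile, "chimaera", obs$stat, p, alpha,
                     pos[obs$k], pos[min(obs$k + 1L, length(pos))])
  if (is.null(ev)) .empty_events() else ev
}

#' Maximum-descent recombination scan on a triplet
#'
#' Orders the A/B-matching informative sites and walks +1 for B and -1
#' for A; the statistic is the maximum drop from the running maximum -
#' large when A-matching sites cluster on one side. Significance is by
#' site-order permutation; the breakpoint is placed at the descent's end.
#'
#' @inheritParams maxchi_scan
#' @export
triplet_descent_scan <- function(profile, n_perm = 1000, alpha = 0.05,
                                 seed = 1) {
  use <- profile$site_states %in% c("A", "B")
  is_a <- profile$site_states[use] == "A"
  pos <- profile$site_positions[use]
  if (length(is_a) < 4) {
    ev <- .empty_events()
    attr(ev, "reason") <- "too few informative sites"
    return(ev)
  }
  obs <- .descent_stat(is_a)
  p <- with_seed(seed, .perm_pvalue(obs$stat, is_a, n_perm, function(x) {
    .descent_stat(x)$stat
  }))
  ev <- .scan_result(profile, "triplet_descent", obs$stat, p, alpha,
                     pos[max(obs$end, 1L)],
                     pos[min(obs$end + 1L, length(pos))])
  if (is.null(ev)) .empty_events() else ev
}

.empty_events <- function() {
  data.frame(recombinant = character(0), parent_a = character(0),
             parent_b = character(0), method = character(0),
             stat = numeric(0), p = numeric(0), bp_start = integer(0),
             bp_end = integer(0), stringsAsFactors = FALSE)
}

#' Two-phase consensus recombination scan over all triplets
#'
#' Phase one is exploratory: all three detectors run over every ordered
#' triplet (recombinant x unordered parent pair) at the nominal alpha with
#' a reduced permutation count. Phase two rescans the flagged triplets
#' with a Bonferroni correction across the flagged set (the confirmatory
#' family of tests); its permutation count is raised beyond `n_perm` when
#' needed so that the corrected threshold stays above the permutation
#' p-value floor. Events are then merged by [consensus_events()].
#'
#' @param alignment a `telomere_alignment` or character matrix.
#' @param window MaxChi/Chimaera flanking window (informative sites).
#' @param n_perm full permutation count (phase two).
#' @param n_perm_explore reduced permutation count (phase one).
#' @param alpha nominal significance level before Bonferroni.
#' @param min_methods detectors that must support a consensus event.
#' @param merge_tol breakpoint merge tolerance (alignment columns).
#' @param donor_floor minimum segment identity for donor attribution.
#' @param seed integer seed.
#' @return list with `events` (unique consensus events) and `raw`
#'   (per-method events from phase two).
#' @export
scan_triplets <- function(alignment, window = 20, n_perm = 1000,
                          n_perm_explore = 200, alpha = 0.05,
                          min_methods = 2, merge_tol = 50,
                          donor_floor = 0.9, seed = 1) {
  mat <- if (inherits(alignment, "telomere_alignment")) alignment$matrix
         else alignment
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")
  trip <- list()
  for (r in taxa) {
    others <- setdiff(taxa, r)
    cmb <- utils::combn(others, 2)
    for (k in seq_len(ncol(cmb))) {
      trip[[length(trip) + 1]] <- c(r, cmb[1, k], cmb[2, k])
    }
  }
  run_one <- function(t3, np, a, sd) {
    pr <- informative_sites(mat, t3[1], t3[2], t3[3])
    rbind(
      maxchi_scan(pr, window, np, a, seed = derive_seed(sd, 1)),
      chimaera_scan(pr, window, np, a, seed = derive_seed(sd, 2)),
      triplet_descent_scan(pr, np, a, seed = derive_seed(sd, 3)))
  }
  flagged <- list()
  for (i in seq_along(trip)) {
    ev <- run_one(trip[[i]], n_perm_explore, alpha,
                  derive_seed(seed, 10L + i))
    if (nrow(ev)) flagged[[length(flagged) + 1]] <- trip[[i]]
  }
  a_conf <- if (length(flagged)) alpha / length(flagged) else alpha
  # keep the corrected threshold resolvable: the permutation p-value
  # floor is 1/(n_perm + 1), so the confirmatory count grows with the
  # size of the flagged family
  np_conf <- max(n_perm, ceiling(5 / a_conf))
  raw <- .empty_events()
  for (i in seq_along(flagged)) {
    raw <- rbind(raw, run_one(flagged[[i]], np_conf, a_conf,
                              derive_seed(seed, 5000L + i)))
  }
  list(events = consensus_events(raw, mat, min_methods = min_methods,
                                 merge_tol = merge_tol,
                                 donor_floor = donor_floor),
       raw = raw)
}

#' Merge per-method events into unique consensus events
#'
#' Events from different detectors on the same recombinant are merged when
#' their breakpoints lie within `merge_tol` alignment columns, kept only
#' when supported by at least `min_methods` detectors, attributed to the
#' candidate donor with maximal identity over the recombinant segment (or
#' `"unknown"` below `donor_floor`), and deduplicated across triplets
#' sharing the recombinant and overlapping breakpoints. The result is
#' independent of the input event order.
#'
#' @param events data.frame of per-method events.
#' @param alignment alignment matrix used for donor attribution (optional;
#'   donor is `"unknown"` without it).
#' @param min_methods minimum number of supporting detectors.
#' @param merge_tol breakpoint merge tolerance (columns).
#' @param donor_floor minimum donor segment identity (fraction).
#' @return data.frame of unique events: `recombinant`, `donor`,
#'   `bp_start`, `bp_end`, `methods`, `n_methods`, `p_min`, `merged_from`.
#' @export
consensus_events <- function(events, alignment = NULL, min_methods = 2,
                             merge_tol = 50, donor_floor = 0.9) {
  out <- data.frame(recombinant = character(0), donor = character(0),
                    bp_start = integer(0), bp_end = integer(0),
                    methods = character(0), n_methods = integer(0),
                    p_min = numeric(0), merged_from = integer(0),
                    stringsAsFactors = FALSE)
  if (!nrow(events)) return(out)
  mat <- if (inherits(alignment, "telomere_alignment")) alignment$matrix
         else alignment
  # canonical order for order-independence
  ev <- events[order(events$recombinant, events$bp_start, events$bp_end,
                     events$method, events$p), , drop = FALSE]
  for (r in sort(unique(ev$recombinant))) {
    er <- ev[ev$recombinant == r, , drop = FALSE]
    mid <- (er$bp_start + er$bp_end) / 2
    o <- order(mid)
    er <- er[o, , drop = FALSE]; mid <- mid[o]
    grp <- cumsum(c(1L, as.integer(diff(mid) > merge_tol)))
    for (g in unique(grp)) {
      eg <- er[grp == g, , drop = FALSE]
      methods <- sort(unique(eg$method))
      if (length(methods) < min_methods) next
      bs <- as.integer(round(median(eg$bp_start)))
      be <- as.integer(round(median(eg$bp_end)))
      donor <- "unknown"
      if (!is.null(mat)) {
        donor <- .attribute_donor(mat, r, unique(c(eg$parent_a,
                                                   eg$parent_b)),
                                  bs, donor_floor)
      }
      out <- rbind(out, data.frame(
        recombinant = r, donor = donor, bp_start = bs, bp_end = be,
        methods = paste(methods, collapse = ","),
        n_methods = length(methods), p_min = min(eg$p),
        merged_from = nrow(eg), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

# Donor = candidate with maximal identity to the recombinant over the
# post-breakpoint segment (falling back to the pre-breakpoint segment if
# it is longer), or "unknown" below the identity floor.
.attribute_donor <- function(mat, recombinant, candidates, bp,
                             donor_floor) {
  nc <- ncol(mat)
  seg <- if (nc - bp >= bp) (bp + 1):nc else 1:bp
  r <- mat[recombinant, seg]
  ids <- vapply(candidates, function(cnd) {
    x <- mat[cnd, seg]
    ok <- r != "-" & x != "-"
    if (!any(ok)) return(0)
    mean(r[ok] == x[ok])
  }, numeric(1))
  if (!length(ids) || max(ids) < donor_floor) return("unknown")
  names(ids)[which.max(ids)]
}

#' Per-strain counts of unique recombination events
#'
#' @param events consensus event data.frame.
#' @param strains strain ids to report (zeros included); defaults to the
#'   strains present in `events`.
#' @return data.frame with `strain` and `n_events`, sorted by count.
#' @export
per_strain_event_counts <- function(events, strains = NULL) {
  if (is.null(strains)) strains <- sort(unique(events$recombinant))
  counts <- vapply(strains, function(s) {
    sum(events$recombinant == s)
  }, integer(1))
  out <- data.frame(strain = strains, n_events = counts,
                    stringsAsFactors = FALSE)
  out[order(-out$n_events, out$strain), , drop = FALSE]
}

#' Simulate a recombination triplet alignment
#'
#' Two parents diverge independently from a common ancestor to the given
#' pairwise divergence; the recombinant copies parent A up to the
#' breakpoint and parent B after it (or diverges independently when
#' `breakpoint` is NULL - a no-recombination null triplet). Extra taxa
#' diverge independently.
#'
#' @param n_col alignment columns.
#' @param divergence expected pairwise parent divergence (fraction).
#' @param breakpoint 1-based column after which the recombinant switches
#'   to parent B, or NULL for the null.
#' @param n_extra additional independently diverged taxa.
#' @param gc GC content of the ancestor.
#' @param seed integer seed.
#' @return character matrix with rows `rec`, `pA`, `pB` (and `xN`).
#' @export
simulate_recombination_triplet <- function(n_col = 1000, divergence = 0.1,
                                           breakpoint = NULL, n_extra = 0,
                                           gc = 0.72, seed = 1) {
  with_seed(seed, {
    anc <- strsplit(random_dna(n_col, gc), "")[[1]]
    mut <- function(v, rate) {
      hit <- runif(length(v)) < rate
      bases <- c("A", "C", "G", "T")
      v[hit] <- vapply(v[hit], function(x) sample(setdiff(bases, x), 1),
                       character(1))
      v
    }
    half <- divergence / 2
    pa <- mut(anc, half)
    pb <- mut(anc, half)
    rec <- if (is.null(breakpoint)) {
      mut(anc, half)
    } else {
      c(pa[seq_len(breakpoint)], pb[(breakpoint + 1):n_col])
    }
    rows <- list(rec = rec, pA = pa, pB = pb)
    for (i in seq_len(n_extra)) rows[[paste0("x", i)]] <- mut(anc, half)
    do.call(rbind, rows)
  })
}
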