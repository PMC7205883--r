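#' Kimura two-parameter distances from an alignment
#'
#' Pairwise-deletion K2P: for each taxon pair, only mutually ungapped
#' sites are compared; P is the transition proportion, Q the transversion
#' proportion, and d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q). Pairs where
#' either logarithm's argument is non-positive are flagged saturated
#' (distance NA); [nj_tree()] refuses saturated matrices unless overridden.
#'
#' @param alignment a `telomere_alignment` (ideally after
#'   [filter_sites()]).
#' @return a `k2p_dist`: list with `taxa`, `d`, `P`, `Q`, `saturated`
#'   (logical matrix).
#' @export
k2p_distance <- function(alignment) {
  mat <- alignment$matrix
  n <- nrow(mat)
  taxa <- rownames(mat)
  d <- P <- Q <- matrix(0, n, n, dimnames = list(taxa, taxa))
  sat <- matrix(FALSE, n, n, dimnames = list(taxa, taxa))
  transitions <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- mat[i, ]; b <- mat[j, ]
    ok <- a != "-" & b != "-"
    if (!any(ok)) { sat[i, j] <- sat[j, i] <- TRUE; next }
    a <- a[ok]; b <- b[ok]
    diff <- a != b
    pair <- paste0(a[diff], b[diff])
    p <- sum(pair %in% names(transitions)) / length(a)
    q <- (sum(diff) / length(a)) - p
    P[i, j] <- P[j, i] <- p
    Q[i, j] <- Q[j, i] <- q
    if (1 - 2 * p - q <= 0 || 1 - 2 * q <= 0) {
      sat[i, j] <- sat[j, i] <- TRUE
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      dd <- -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
      d[i, j] <- d[j, i] <- dd
    }
  }
  structure(list(taxa = taxa, d = d, P = P, Q = Q, saturated = sat),
            class = "k2p_dist")
}

.dist_matrix <- function(x) {
  if (inherits(x, "k2p_dist")) x$d else as.matrix(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Q criterion; ties in Q are broken
#' by lexicographic order of the joined labels. Negative branch lengths
#' are clamped to zero with the deficit moved to the adjacent (sister)
#' branch, preserving path lengths through the new node.
#'
#' @param dm a `k2p_dist` or symmetric distance matrix with dimnames
#'   (>= 3 taxa).
#' @param allow_saturated proceed despite saturated (NA) distances by
#'   substituting the largest finite distance; off by default.
#' @return an unrooted `phylo` object (ape).
#' @export
nj_tree <- function(dm, allow_saturated = FALSE) {
  D <- .dist_matrix(dm)
  if (any(is.na(D))) {
    if (!allow_saturated) {
      stop("saturated distances present; rerun with allow_saturated ",
           "or drop the offending taxa")
    }
    mx <- max(D, na.rm = TRUE)
    D[is.na(D)] <- mx * 1.05
  }
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  # node bookkeeping for the ape edge matrix: tips 1..n, internals n+1..
  active_ids <- seq_len(n)        # ape node numbers of active clusters
  next_internal <- 2L * n - 2L    # internal ids assigned downward
  edges <- NULL; elens <- NULL
  repeat {
    m <- nrow(D)
    if (m == 2) break
    r <- rowSums(D)
    Qm <- (m - 2) * D - outer(r, r, "+")
    diag(Qm) <- Inf
    best <- which(Qm == min(Qm), arr.ind = TRUE)
    if (nrow(best) > 1) {
      lab_pairs <- apply(best, 1, function(ij) {
        paste(sort(rownames(D)[ij]), collapse = "\r")
      })
      best <- best[order(lab_pairs)[1], , drop = FALSE]
    }
    i <- min(best[1, ]); j <- max(best[1, ])
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_id <- next_internal
    next_internal <- next_internal - 1L
    edges <- rbind(edges, c(new_id, active_ids[i]),
                   c(new_id, active_ids[j]))
    elens <- c(elens, vi, vj)
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(D)[keep], paste0("#", new_id))
    dimnames(D2) <- list(nm, nm)
    D <- D2
    active_ids <- c(active_ids[keep], new_id)
  }
  # join the last two clusters with a single edge
  edges <- rbind(edges, c(active_ids[2], active_ids[1]))
  elens <- c(elens, max(D[1, 2], 0))
  # renumber internals in preorder from the root so the object is a valid
  # ape phylo (root = n + 1)
  root_old <- setdiff(unique(edges[, 1]), edges[, 2])
  map <- integer(2L * n)
  map[seq_len(n)] <- seq_len(n)
  counter <- n
  stack <- root_old
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    counter <- counter + 1L
    map[v] <- counter
    kids <- edges[edges[, 1] == v, 2]
    stack <- c(kids[kids > n], stack)
  }
  edges2 <- cbind(map[edges[, 1]], map[edges[, 2]])
  phy <- list(edge = edges2, edge.length = elens,
              tip.label = labels, Nnode = counter - n)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# Non-trivial bipartitions of an unrooted tree as canonical signatures:
# each internal edge splits the leaves; the side not containing the
# alphabetically first leaf is sorted and joined with "|". Edges of
# (near-)zero length are treated as unresolved and skipped when the tree
# carries branch lengths.
tree_bipartitions <- function(phy, min_length = 1e-9) {
  n <- length(phy$tip.label)
  anchor <- sort(phy$tip.label)[1]
  adj <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  sigs <- character(0)
  sides <- list()
  for (e in seq_len(nrow(phy$edge))) {
    if (!is.null(phy$edge.length) && phy$edge.length[e] < min_length) next
    a <- phy$edge[e, 1]; b <- phy$edge[e, 2]
    # leaves on the b side of edge (a, b)
    seen <- rep(FALSE, n + phy$Nnode)
    seen[a] <- TRUE
    stack <- b; leaves <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) next
      seen[v] <- TRUE
      if (v <= n) leaves <- c(leaves, v)
      stack <- c(stack, adj[[v]])
    }
    if (length(leaves) < 2 || length(leaves) > n - 2) next
    side <- sort(phy$tip.label[leaves])
    if (anchor %in% side) {
      side <- sort(setdiff(phy$tip.label, side))
    }
    sig <- paste(side, collapse = "|")
    if (!(sig %in% sigs)) {
      sigs <- c(sigs, sig)
      sides[[length(sides) + 1]] <- side
    }
  }
  setNames(sides, sigs)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the full-data
#' tree the percentage of replicates containing it. Within replicates,
#' saturated distances fall back to the largest finite replicate distance
#' so that no replicate aborts.
#'
#' @param alignment a `telomere_alignment`.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed; supports are seed-reproducible.
#' @param dist_fun distance function (default [k2p_distance()]).
#' @return list with `tree` (the full-data NJ `phylo`), `support` (named
#'   percentage vector per bipartition signature), and `n_reps`.
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1,
                              dist_fun = k2p_distance) {
  main <- nj_tree(dist_fun(alignment), allow_saturated = TRUE)
  splits <- tree_bipartitions(main)
  counts <- setNames(numeric(length(splits)), names(splits))
  with_seed(seed, {
    nc <- ncol(alignment$matrix)
    for (b in seq_len(n_reps)) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rep_aln <- structure(list(
        taxa = alignment$taxa,
        matrix = alignment$matrix[, cols, drop = FALSE],
        site_coverage = alignment$site_coverage[cols]),
        class = "telomere_alignment")
      rp <- tryCatch(nj_tree(dist_fun(rep_aln), allow_saturated = TRUE),
                     error = function(e) NULL)
      if (is.null(rp)) next
      rs <- names(tree_bipartitions(rp))
      hit <- names(counts) %in% rs
      counts[hit] <- counts[hit] + 1
    }
  })
  list(tree = main, support = 100 * counts / n_reps, n_reps = n_reps)
}

# Two bipartitions (leaf-name vectors, same leaf universe) are
# incompatible iff all four side intersections are non-empty.
.splits_conflict <- function(s1, s2, all_leaves) {
  c1 <- setdiff(all_leaves, s1)
  c2 <- setdiff(all_leaves, s2)
  length(intersect(s1, s2)) > 0 && length(intersect(s1, c2)) > 0 &&
    length(intersect(c1, s2)) > 0 && length(intersect(c1, c2)) > 0
}

#' Compare genome and telomere tree topologies
#'
#' Reports shared and conflicting non-trivial bipartitions between the two
#' trees (the symmetric-difference count is the Robinson-Foulds distance)
#' and lists leaf pairs grouped in the telomere tree but separated in the
#' genome tree - the operational signal of telomere exchange.
#'
#' When bootstrap supports for the telomere tree are supplied, telomere
#' splits below `min_support` are treated as unresolved and excluded from
#' the conflict bookkeeping: short telomere alignments rarely resolve the
#' deep between-clade order, and an arbitrary resolution of a no-signal
#' split is not evidence of exchange.
#'
#' @param genome_tree,telomere_tree `phylo` objects over identical leaf
#'   sets.
#' @param telomere_support optional named support vector (percent) from
#'   [bootstrap_support()], keyed by split signature.
#' @param min_support minimum support for a telomere split to count.
#' @return a `topology_comparison`: list with `shared`,
#'   `conflicting_genome`, `conflicting_telomere` (split signatures),
#'   `rf_distance`, `incongruent_pairs` (two-column matrix of leaf pairs),
#'   `incongruent_leaves`.
#' @export
compare_topologies <- function(genome_tree, telomere_tree,
                               telomere_support = NULL,
                               min_support = 70) {
  lg <- sort(genome_tree$tip.label)
  lt <- sort(telomere_tree$tip.label)
  if (!identical(lg, lt)) stop("leaf sets differ between the trees")
  sg <- tree_bipartitions(genome_tree)
  st <- tree_bipartitions(telomere_tree)
  if (!is.null(telomere_support)) {
    sup <- telomere_support[names(st)]
    sup[is.na(sup)] <- 0
    st <- st[sup >= min_support]
  }
  shared <- intersect(names(sg), names(st))
  conf_g <- names(sg)[vapply(sg, function(s) {
    any(vapply(st, .splits_conflict, logical(1), s2 = s,
               all_leaves = lg))
  }, logical(1))]
  conf_t <- names(st)[vapply(st, function(s) {
    any(vapply(sg, .splits_conflict, logical(1), s2 = s,
               all_leaves = lg))
  }, logical(1))]
  pairs <- NULL
  for (sig in conf_t) {
    side <- st[[sig]]
    other <- setdiff(lg, side)
    grp <- if (length(side) <= length(other)) side else other
    if (length(grp) < 2) next
    cmb <- utils::combn(sort(grp), 2)
    for (k in seq_len(ncol(cmb))) {
      x <- cmb[1, k]; y <- cmb[2, k]
      separated <- any(vapply(sg[conf_g], function(s) {
        (x %in% s) != (y %in% s)
      }, logical(1)))
      if (separated) pairs <- rbind(pairs, c(x, y))
    }
  }
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    colnames(pairs) <- c("leaf1", "leaf2")
  }
  structure(list(
    shared = shared, conflicting_genome = conf_g,
    conflicting_telomere = conf_t,
    rf_distance = length(setdiff(names(sg), names(st))) +
      length(setdiff(names(st), names(sg))),
    incongruent_pairs = pairs,
    incongruent_leaves = sort(unique(as.vector(pairs)))),
    class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf(
    "topology comparison: %d shared, %d/%d conflicting splits, RF = %d\n",
    length(x$shared), length(x$conflicting_genome),
    length(x$conflicting_telomere), x$rf_distance))
  if (length(x$incongruent_leaves)) {
    cat("incongruent leaves:", paste(x$incongruent_leaves, collapse = ", "),
        "\n")
  }
  invisible(x)
}
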