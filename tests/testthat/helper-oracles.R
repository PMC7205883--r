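# Independent oracles and shared fixtures for the test suite. These
# deliberately re-derive results by brute force / naive enumeration and
# never call the implementation paths they check.

# Naive exhaustive hairpin enumeration: triple loop over (arm5 start,
# arm length, loop length), counting canonical, sheared (G.A / T.C,
# loop-proximal only) and mismatched stem positions pair by pair.
naive_hairpins <- function(s, min_arm = 3, loop_lens = c(3, 4),
                           max_stem_mismatch = 1, allow_sheared = TRUE,
                           sheared_max_depth = 2) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (i in seq_len(n)) {          # arm5 start (1-based)
    for (a in min_arm:floor(n / 2)) {
      for (l in loop_lens) {
        j_end <- i + 2 * a + l - 1 # arm3 end
        if (j_end > n) next
        mm <- 0; sh <- 0
        for (d in seq_len(a)) {    # d = 1 outermost ... a innermost
          x <- v[i + d - 1]
          y <- v[j_end - d + 1]
          depth <- a - d + 1       # 1 = loop-proximal
          if (comp[[x]] == y) {
          } else if (allow_sheared && depth <= sheared_max_depth &&
                     paste(sort(c(x, y)), collapse = "") %in%
                       c("AG", "CT")) {
            sh <- sh + 1
          } else {
            mm <- mm + 1
          }
        }
        if (mm <= max_stem_mismatch) {
          out[[length(out) + 1]] <- data.frame(
            start = i - 1L, end = j_end, arm_len = a,
            loop_start = i + a - 1L, loop_len = l,
            loop_seq = paste(v[(i + a):(i + a + l - 1)], collapse = ""),
            mismatches = mm, sheared = sh, paired = a - mm - sh)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$loop_len), ]
}

# Maximum total paired bases over all non-overlapping candidate subsets.
# Small sets are enumerated exhaustively over the power set; larger ones
# fall back to top-down recursion over start-sorted candidates (an
# independent code path from the package's bottom-up scheduler).
brute_best_packing <- function(cand) {
  k <- nrow(cand)
  if (k == 0) return(0)
  if (k <= 16) {
    best <- 0
    for (mask in 0:(2^k - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
      if (length(idx) >= 2) {
        o <- idx[order(cand$start[idx])]
        if (any(cand$start[o][-1] < cand$end[o][-length(o)])) next
      }
      best <- max(best, sum(cand$paired[idx]))
    }
    return(best)
  }
  cand <- cand[order(cand$start), ]
  memo <- rep(NA_real_, k + 1)
  rec <- function(i) {
    if (i > k) return(0)
    if (!is.na(memo[i])) return(memo[i])
    nxt <- which(cand$start >= cand$end[i])
    nxt <- nxt[nxt > i]
    take <- cand$paired[i] + if (length(nxt)) rec(min(nxt)) else 0
    val <- max(rec(i + 1), take)
    memo[i] <<- val
    val
  }
  rec(1)
}

# Brute-force global affine alignment score by recursive enumeration
# (match +1, mismatch -1, gap of length g costs open + g * extend).
brute_align_score <- function(a, b, match = 1, mismatch = -1,
                              open = -5, extend = -1) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  # state: (i, j, last move: 0 none/diag, 1 gap-in-b, 2 gap-in-a)
  memo <- new.env()
  rec <- function(i, j, last) {
    if (i > length(va) && j > length(vb)) return(0)
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(va) && j <= length(vb)) {
      sc <- if (va[i] == vb[j]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1, 0))
    }
    if (i <= length(va)) {
      pen <- if (last == 1) extend else open + extend
      best <- max(best, pen + rec(i + 1, j, 1))
    }
    if (j <= length(vb)) {
      pen <- if (last == 2) extend else open + extend
      best <- max(best, pen + rec(i, j + 1, 2))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, 0)
}

aligned_score <- function(al, match = 1, mismatch = -1, open = -5,
                          extend = -1) {
  va <- strsplit(al$a, "")[[1]]; vb <- strsplit(al$b, "")[[1]]
  sc <- 0; ga <- FALSE; gb <- FALSE
  for (k in seq_along(va)) {
    if (va[k] == "-") {
      sc <- sc + if (ga) extend else open + extend
      ga <- TRUE; gb <- FALSE
    } else if (vb[k] == "-") {
      sc <- sc + if (gb) extend else open + extend
      gb <- TRUE; ga <- FALSE
    } else {
      sc <- sc + if (va[k] == vb[k]) match else mismatch
      ga <- gb <- FALSE
    }
  }
  sc
}

# Shared cache for expensive simulation batches reused across test files.
.fixture_cache <- new.env(parent = emptyenv())

# 50 seeded TIR-recovery replicates at the study conditions (200-kb
# replicon, 20-kb TIRs, 50x coverage, 300-bp reads).
tir_recovery_batch <- function(n_rep = 50) {
  key <- paste0("tir_batch_", n_rep)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  res <- lapply(seq_len(n_rep), function(i) {
    cfg <- population_config(n_strains = 1, seed = i)
    pop <- simulate_population(cfg)
    r <- pop$replicons[[1]]
    col <- collapse_assembly(r)
    rs <- simulate_reads(r, 50, 300, 0.001, seed = i + 10000)
    prof <- map_reads(rs, col)
    call <- detect_tir(prof)
    left <- call[call$end == "left", ]
    tirseg <- prof$depth[seq_len(r$truth$tir_length)]
    central <- prof$depth[seq(floor(length(prof$depth) * 0.25),
                              ceiling(length(prof$depth) * 0.75))]
    list(true_size = r$truth$tir_length, est_size = left$size,
         status = left$status, depth_ratio = mean(tirseg) / mean(central))
  })
  .fixture_cache[[key]] <- res
  res
}
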