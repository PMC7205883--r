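#' Default pipeline run configuration
#'
#' Assembles the per-stage parameter blocks and the global seed. Stage
#' seeds are derived deterministically from the global seed so any stage
#' can be rerun in isolation.
#'
#' @param seed global integer seed.
#' @param stages stages to run, in dependency order.
#' @param population a [population_config()] (its seed is overridden by
#'   the derived stage seed unless `keep_population_seed` is TRUE).
#' @param keep_population_seed keep the seed inside `population`.
#' @param reads read-simulation block: `coverage`, `read_length`,
#'   `error_rate`.
#' @param tir TIR-detection block: `ratio_window`, `min_tir_length`,
#'   `window_size`, `k`, `max_mismatch`.
#' @param extend extension block: `truncate_bp` (bases clipped off the
#'   terminus before walking, emulating an incomplete assembly) plus
#'   [extend_end()] parameters.
#' @param phylo phylogeny block: `n_boot`.
#' @param recomb recombination block: `region`, `window`, `n_perm`,
#'   `n_perm_explore`, `alpha`, `min_methods`.
#' @param tp terminal-protein block: `region`, `id_cutoff`, `cov_cutoff`,
#'   `max_gap`.
#' @return a `run_config` list.
#' @export
default_run_config <- function(seed = 1,
                               stages = c("simulate", "tir", "extend",
                                          "fold", "phylo", "recomb",
                                          "tp"),
                               population = population_config(),
                               keep_population_seed = FALSE,
                               reads = list(coverage = 50,
                                            read_length = 300,
                                            error_rate = 0.001),
                               tir = list(),
                               extend = list(truncate_bp = 60),
                               phylo = list(n_boot = 100),
                               recomb = list(region = 6000, window = 20,
                                             n_perm = 500,
                                             n_perm_explore = 100,
                                             alpha = 0.05,
                                             min_methods = 2),
                               tp = list(region = 12000)) {
  structure(list(seed = seed, stages = stages, population = population,
                 keep_population_seed = keep_population_seed,
                 reads = reads, tir = tir, extend = extend, phylo = phylo,
                 recomb = recomb, tp = tp),
            class = "run_config")
}

.stage_msg <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Cluster sequences by pairwise identity
#'
#' Single-linkage grouping at an identity threshold (percent), mirroring
#' the grouping of strains by near-identical telomere sequences.
#'
#' @param seqs named character vector.
#' @param threshold percent identity joining two sequences.
#' @return integer cluster ids named by sequence.
#' @export
cluster_by_identity <- function(seqs, threshold = 92) {
  n <- length(seqs)
  grp <- seq_len(n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (pairwise_identity(seqs[[i]], seqs[[j]]) >= threshold) {
        old <- grp[j]; grp[grp == old] <- grp[i]
      }
    }
  }
  setNames(match(grp, unique(grp)), names(seqs))
}

#' Run the full terminal-region analysis pipeline
#'
#' Executes the configured stages in dependency order on a simulated
#' population: simulate, TIR detection (collapse + read mapping + depth
#' change-point), terminal extension (after clipping `truncate_bp` bases,
#' emulating an incomplete assembly), telomere folding and loop typing,
#' telomere phylogeny and congruence against the true genome tree,
#' consensus recombination scanning over a colinear terminal region, and
#' terminal-protein inventory. Identical config and seed reproduce every
#' artifact and the manifest checksums exactly.
#'
#' @param config a [default_run_config()].
#' @param out_dir directory for artifacts and the manifest (NULL for none).
#' @param quiet suppress progress messages.
#' @return a `pipeline_result` list with per-stage outputs, the joined
#'   `report` (see [emit_report()]) and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         quiet = TRUE) {
  seed <- config$seed
  stages <- config$stages
  res <- list(config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }

  stopifnot("simulate" %in% stages)
  pcfg <- config$population
  if (!config$keep_population_seed) pcfg$seed <- derive_seed(seed, 1L)
  pop <- simulate_population(pcfg)
  res$population <- pop
  strains <- names(pop$replicons)
  .stage_msg(quiet, "simulate", "%d strains of %d bp", length(strains),
             pcfg$chromosome_length)
  if (!is.null(out_dir)) write_population(pop, file.path(out_dir, "sim"))

  needs_reads <- any(c("tir", "extend") %in% stages)
  collapsed <- lapply(pop$replicons, collapse_assembly)
  read_sets <- NULL
  if (needs_reads) {
    read_sets <- lapply(seq_along(strains), function(i) {
      simulate_reads(pop$replicons[[i]], config$reads$coverage,
                     config$reads$read_length, config$reads$error_rate,
                     seed = derive_seed(seed, 100L + i))
    })
    names(read_sets) <- strains
  }

  if ("tir" %in% stages) {
    tirp <- config$tir
    calls <- lapply(strains, function(s) {
      prof <- map_reads(read_sets[[s]], collapsed[[s]],
                        k = tirp$k %||% 21,
                        max_mismatch = tirp$max_mismatch %||% 5,
                        window_size = tirp$window_size %||% 500)
      detect_tir(prof, ratio_window = tirp$ratio_window %||% c(1.6, 2.4),
                 min_tir_length = tirp$min_tir_length %||% 1000)
    })
    res$tir <- do.call(rbind, calls)
    .stage_msg(quiet, "tir", "%d/%d ends detected",
               sum(res$tir$status == "detected"), nrow(res$tir))
    if (!is.null(out_dir)) {
      write_tir_calls(res$tir, file.path(out_dir, "tirs_detected.bed"),
                      file.path(out_dir, "tir_report.tsv"))
    }
  }

  if ("extend" %in% stages) {
    ext <- config$extend
    t_bp <- ext$truncate_bp %||% 60
    res$extend <- lapply(strains, function(s) {
      seqc <- collapsed[[s]]$sequence
      truncated <- substr(seqc, t_bp + 1L, nchar(seqc))
      er <- extend_replicon_end(truncated, read_sets[[s]], end = "left",
                                anchor_k = ext$anchor_k %||% 31,
                                min_overlap = ext$min_overlap %||% 31,
                                max_mismatch = ext$max_mismatch %||% 1,
                                min_support = ext$min_support %||% 5,
                                min_agreement = ext$min_agreement %||% 0.8,
                                max_extension = ext$max_extension %||% 1000)
      er$recovered_terminal_180 <-
        substr(er$extended_terminal,
               max(1L, nchar(er$extended_terminal) - 179L),
               nchar(er$extended_terminal))
      er
    })
    names(res$extend) <- strains
    .stage_msg(quiet, "extend", "median extension %d nt",
               as.integer(median(vapply(res$extend, function(e)
                 nchar(e$added_sequence), numeric(1)))))
  }

  if ("fold" %in% stages) {
    tels <- vapply(strains, function(s) {
      if (!is.null(res$extend)) res$extend[[s]]$recovered_terminal_180
      else extract_terminal(collapsed[[s]]$sequence, 180, "left")$sequence
    }, character(1))
    res$telomeres <- tels
    res$fold <- lapply(tels, fold_telomere)
    .stage_msg(quiet, "fold", "loop classes: %s",
               paste(vapply(res$fold, function(f) f$loop_class,
                            character(1)), collapse = " "))
  }

  if ("phylo" %in% stages && length(strains) >= 4 &&
      !is.null(res$telomeres)) {
    aln <- align_telomeres(res$telomeres)
    aln <- filter_sites(aln, 0.80)
    bs <- bootstrap_support(aln, n_reps = config$phylo$n_boot %||% 100,
                            seed = derive_seed(seed, 300L))
    genome_tree <- ape::read.tree(text = pop$tree)
    res$phylo <- list(alignment = aln, tree = bs$tree,
                      support = bs$support,
                      comparison = compare_topologies(
                        genome_tree, bs$tree,
                        telomere_support = bs$support),
                      telomere_group = cluster_by_identity(res$telomeres))
    .stage_msg(quiet, "phylo", "RF distance to genome tree: %d",
               res$phylo$comparison$rf_distance)
    if (!is.null(out_dir)) {
      ape::write.tree(bs$tree,
                      file.path(out_dir, "telomere_tree.nwk"))
    }
  }

  if ("recomb" %in% stages && length(strains) >= 3) {
    rc <- config$recomb
    region <- rc$region %||% 6000
    mat <- do.call(rbind, lapply(strains, function(s) {
      strsplit(substr(collapsed[[s]]$sequence, 1, region), "")[[1]]
    }))
    rownames(mat) <- strains
    sc <- scan_triplets(mat, window = rc$window %||% 20,
                        n_perm = rc$n_perm %||% 500,
                        n_perm_explore = rc$n_perm_explore %||% 100,
                        alpha = rc$alpha %||% 0.05,
                        min_methods = rc$min_methods %||% 2,
                        seed = derive_seed(seed, 400L))
    res$recomb <- sc
    res$recomb$per_strain <- per_strain_event_counts(sc$events, strains)
    .stage_msg(quiet, "recomb", "%d unique events", nrow(sc$events))
  }

  if ("tp" %in% stages && !is.null(pop$tp_queries)) {
    tpc <- config$tp
    region <- tpc$region %||% 12000
    hits <- lapply(strains, function(s) {
      sub <- new_replicon(s, substr(collapsed[[s]]$sequence, 1, region))
      orfs <- find_orfs(sub)
      if (!nrow(orfs)) return(NULL)
      find_homologues(unlist(pop$tp_queries), orfs,
                      id_cutoff = tpc$id_cutoff %||% 50,
                      cov_cutoff = tpc$cov_cutoff %||% 0.98)
    })
    hits <- do.call(rbind, hits)
    res$tp <- list(hits = hits,
                   operons = call_operons(hits,
                                          max_gap = tpc$max_gap %||% 200))
    .stage_msg(quiet, "tp", "%d operon calls",
               sum(res$tp$operons$classification != "unpaired"))
  }

  res$report <- emit_report(res)
  if (!is.null(out_dir)) {
    write.table(res$report, file.path(out_dir, "population_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- list(seed = seed, stages = stages,
                     checksums = as.list(tools::md5sum(files)))
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Join stage outputs into a per-strain population report
#'
#' One row per strain; stages that did not run leave their columns as
#' em-dashes, never fabricated values. TIR size columns refer to the
#' retained copy on the collapsed assembly; an undetected TIR is reported
#' as an em-dash.
#'
#' @param res a (possibly partial) `pipeline_result` list.
#' @return data.frame report.
#' @export
emit_report <- function(res) {
  pop <- res$population
  strains <- names(pop$replicons)
  dash <- "—"
  rep_row <- function(s) {
    truth <- pop$replicons[[s]]$truth
    tir_size <- dash; tir_ratio <- dash; tir_status <- dash
    if (!is.null(res$tir)) {
      tc <- res$tir[res$tir$replicon_id == paste0(s, "_collapsed") &
                      res$tir$end == "left", , drop = FALSE]
      if (nrow(tc) == 1) {
        tir_status <- tc$status
        tir_ratio <- sprintf("%.2f", tc$depth_ratio)
        tir_size <- if (tc$status == "detected")
          as.character(tc$size) else dash
      }
    }
    loop_class <- dash; n_hairpins <- dash
    if (!is.null(res$fold)) {
      loop_class <- res$fold[[s]]$loop_class
      n_hairpins <- as.character(nrow(res$fold[[s]]$hairpins))
    }
    tel_group <- dash; incong <- dash
    if (!is.null(res$phylo)) {
      tel_group <- as.character(res$phylo$telomere_group[[s]])
      incong <- if (s %in% res$phylo$comparison$incongruent_leaves)
        "yes" else "no"
    }
    tp_sys <- dash
    if (!is.null(res$tp)) {
      op <- res$tp$operons
      op <- op[op$replicon_id == s &
                 op$classification != "unpaired", , drop = FALSE]
      tp_sys <- if (nrow(op)) {
        paste(sort(unique(op$classification)), collapse = ";")
      } else dash
    }
    n_ev <- dash
    if (!is.null(res$recomb)) {
      n_ev <- as.character(sum(res$recomb$events$recombinant == s))
    }
    data.frame(strain = s, subclade = truth$subclade,
               true_tir = truth$tir_length, tir_size = tir_size,
               tir_status = tir_status, depth_ratio = tir_ratio,
               loop_class = loop_class, n_hairpins = n_hairpins,
               telomere_group = tel_group, incongruent = incong,
               tp_systems = tp_sys, recomb_events = n_ev,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(strains, rep_row))
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run, stages:", paste(x$config$stages, collapse = " "),
      "\n")
  print(x$report, ...)
  invisible(x)
}
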