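#!/usr/bin/env Rscript
# Walk reads off the clipped assembly termini, fold the recovered
# terminal 180 nt, and type each telomere by its dominant loop motif.

source(file.path("analysis", "00_config.R"))

res <- run_pipeline(run_config(c("simulate", "tir", "extend", "fold")),
                    quiet = FALSE)

tab <- do.call(rbind, lapply(names(res$fold), function(s) {
  st <- res$fold[[s]]
  ext <- res$extend[[s]]
  data.frame(strain = s,
             added_nt = nchar(ext$added_sequence),
             stop_reason = ext$stop_reason,
             n_hairpins = nrow(st$hairpins),
             paired_bases = st$total_paired_bases,
             loop_class = st$loop_class)
}))
write.table(tab, file.path(RESULTS, "telomere_structures.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)

# dot-bracket renderings
rend <- unlist(lapply(names(res$fold), function(s) {
  c(paste0(">", s), render_structure(res$telomeres[[s]], res$fold[[s]]))
}))
writeLines(rend, file.path(RESULTS, "telomere_folds.txt"))
message("structures in results/telomere_structures.tsv; folds in ",
        "results/telomere_folds.txt")
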