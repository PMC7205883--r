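#!/usr/bin/env Rscript
# Inventory terminal-protein homologues (gtpB-gtpA and tap-tpg) in the
# terminal regions at the 50% identity / 98% coverage cutoffs, and pair
# them into operons.

source(file.path("analysis", "00_config.R"))

res <- run_pipeline(run_config(c("simulate", "tp")), quiet = FALSE)

write.table(res$tp$hits, file.path(RESULTS, "tp_hits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$tp$operons, file.path(RESULTS, "tp_operons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

ops <- res$tp$operons[res$tp$operons$classification != "unpaired", ]
message(sprintf("%d operon calls across %d strains", nrow(ops),
                length(unique(ops$replicon_id))))
print(table(ops$classification))
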