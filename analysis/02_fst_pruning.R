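#!/usr/bin/env Rscript
# Pairwise Weir-Cockerham F_ST over the panel and threshold pruning.
#
# Every Balding-Nichols satellite sits close to its base group (expected
# pairwise theta roughly F/2 = 0.0025 against the base, since only one side
# drifted), while unrelated bases are far apart. Pruning at the study's
# threshold of 0.005 removes the genetically redundant member of each
# base/satellite pair one at a time: the pair with the lowest F_ST loses a
# random member until every remaining pair exceeds the threshold.

suppressPackageStartupMessages(library(dnamixr))

out_dir <- "results"
manifest <- jsonlite::fromJSON(file.path(out_dir, "panel", "manifest.json"))
panel <- lapply(seq_len(nrow(manifest)), function(i)
  read_frequency_table(file.path(out_dir, "panel", manifest$file[i]), "wide",
                       group_id = manifest$group_id[i]))

m <- fst_matrix(panel)
write_fst_matrix(m, file.path(out_dir, "fst_matrix.tsv"))
off <- m[upper.tri(m)]
message(sprintf("pairwise F_ST: min %.5f, median %.5f, max %.5f",
                min(off), median(off), max(off)))

pruned <- prune_by_fst(panel, threshold = 0.005, seed = 7L)
write_pruned_panel(pruned, file.path(out_dir, "pruned_panel.json"))
message("threshold 0.005: kept ", length(pruned$kept), " of ", nrow(manifest),
        " groups; removed ",
        paste(pruned$removed$group_id, collapse = ", "))

# a stricter threshold removes more of the densely spaced diversity ladder
strict <- prune_by_fst(panel, threshold = 0.02, seed = 7L)
message("threshold 0.02:  kept ", length(strict$kept), " groups")

# exempting the satellites forces their base partners out instead
ex <- prune_by_fst(panel, threshold = 0.005,
                   exempt = manifest$group_id[grepl("bn", manifest$group_id)],
                   seed = 7L)
message("with satellites exempt: removed ",
        paste(ex$removed$group_id, collapse = ", "))
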