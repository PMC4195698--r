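#!/usr/bin/env Rscript
# Stage 2: amplification efficiencies and efficiency-corrected quantities.
#
# Fits each assay's dilution series (Cq vs log10 input) to estimate its
# amplification efficiency, flags anything outside 90-110%, then collapses
# replicates and converts every experiment's Cq table to relative
# quantities Q = F^(minCq - Cq).

suppressMessages(library(erenorm))

ind <- "results/simulated"
out <- "results/quantified"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- reference_panel()
eff <- do.call(rbind, lapply(panel$target, function(t) {
  efficiency_from_dilution(read_cq_tsv(file.path(ind, paste0("dilution_", t, ".tsv"))))
}))
eff <- rbind(eff, efficiency_table(c("zorba", "pax6a", "acta2"), rep(100, 3),
                                   source = "assumed"))
write_efficiency_tsv(eff, file.path(out, "efficiencies.tsv"))
cat(sprintf("estimated %d efficiencies; %d outside [90, 110]%%\n",
            nrow(eff), sum(!eff$in_range)))
cat(sprintf("range: %.1f%% .. %.1f%%\n",
            min(eff$efficiency_percent), max(eff$efficiency_percent)))

experiments <- c("time_series", "organs", "mo_slc2a10", "mo_chordin",
                 "tgfbri", "warfarin")
for (nm in experiments) {
  cq <- read_cq_tsv(file.path(ind, paste0("cq_", nm, ".tsv")))
  Q <- cq_to_relative_quantity(collapse_replicates(cq), eff)
  tab <- data.frame(sample = rownames(Q), group = rq_groups(Q),
                    as.data.frame(Q, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, file.path(out, paste0("q_", nm, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-12s Q matrix %d x %d written\n", nm, nrow(Q), ncol(Q)))
}
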