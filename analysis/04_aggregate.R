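#!/usr/bin/env Rscript
# Stage 4: cross-experiment rank aggregation.
#
# Combines the six per-experiment rankings into one consensus ordering,
# first by Borda count (mean rank), then by cross-entropy Monte Carlo
# minimisation of the weighted Spearman footrule objective (M-values as
# stability weights). The optimiser is seeded with the Borda solution, so
# its objective can only improve on it.

suppressMessages(library(erenorm))

ind <- "results/stability"
out <- "results/aggregated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

experiments <- c("time_series", "organs", "mo_slc2a10", "mo_chordin",
                 "tgfbri", "warfarin")
rankings <- lapply(experiments, function(nm) {
  utils::read.table(file.path(ind, paste0("ranking_", nm, ".tsv")),
                    sep = "\t", header = TRUE)
})
rls <- ranked_lists(lapply(rankings, `[[`, "target"),
                    lapply(rankings, function(r) setNames(r$M, r$target)))

b <- borda(rls)
ce <- aggregate_ce(rls, seed = seed)
cat(sprintf("Borda objective: %.3f; cross-entropy objective: %.3f (%d iterations)\n",
            b$phi, ce$phi, nrow(ce$trace)))
cat("consensus (most stable first):\n")
cat(" ", paste(ce$consensus, collapse = " > "), "\n")

fam <- setNames(reference_panel()$family, reference_panel()$target)
cat(sprintf("EREs in the top half of the consensus: %d of 10\n",
            sum(fam[ce$consensus[1:10]] == "ERE")))

med_m <- apply(vapply(rankings, function(r) {
  setNames(r$M, r$target)[rls$universe]
}, numeric(20)), 1, median)
cons <- data.frame(target = ce$consensus,
                   consensus_rank = seq_along(ce$consensus),
                   mean_rank = unname(b$mean_rank[ce$consensus]),
                   median_M = unname(med_m[ce$consensus]))
utils::write.table(cons, file.path(out, "consensus.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(ce$trace, file.path(out, "convergence_trace.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
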