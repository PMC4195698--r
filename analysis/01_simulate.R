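#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic inputs.
#
# Six Cq experiments emulating a zebrafish qPCR validation study (a
# developmental time series, adult organs, two morpholino injections, two
# compound treatments) over a 20-target reference panel (10 expressed-repeat
# assays, 10 classic reference genes), plus per-assay standard dilution
# series and a repeat-bearing genome/transcriptome with recorded truth.

suppressMessages(library(erenorm))

seed <- 1L
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

designs <- demo_designs(seed)
for (nm in names(designs)) {
  sim <- generate_cq_dataset(designs[[nm]])
  write_cq_tsv(sim$cq, file.path(out, paste0("cq_", nm, ".tsv")))
  write_truth_json(sim$truth[c("sigma_bio", "stable_targets", "content_log2")],
                   file.path(out, paste0("truth_", nm, ".json")))
  cat(sprintf("%-12s %3d samples x %2d targets\n", nm,
              length(unique(sim$cq$sample)), length(unique(sim$cq$target))))
}

panel <- reference_panel()
for (i in seq_len(nrow(panel))) {
  s <- make_dilution_series(1 + panel$efficiency_percent[i] / 100,
                            sigma_tech = 0.05, n_replicates = 2L,
                            seed = seed * 131L + i, target = panel$target[i])
  write_cq_tsv(cbind(sample = sprintf("dil%d", seq_len(nrow(s))), s),
               file.path(out, paste0("dilution_", panel$target[i], ".tsv")))
}
cat("wrote", nrow(panel), "dilution series\n")

seqdes <- sequence_design(consensus_length = 300, n_copies = 150,
                          substitution_rate = 0.05, n_transcripts = 100,
                          transcript_length = 900, repeat_fraction = 0.4,
                          seed = seed)
gen <- generate_repeat_sequences(seqdes)
write_fasta(gen$consensus, file.path(out, "repeat_consensus.fa"))
write_fasta(gen$genome, file.path(out, "genome.fa"))
write_fasta(gen$transcripts, file.path(out, "transcripts.fa"))
write_truth_json(gen$truth, file.path(out, "sequence_truth.json"))
cat(sprintf("sequence set: %d bp genome, %d planted copies, %d/%d transcripts carry the repeat\n",
            seqdes$genome_length, nrow(gen$truth$genome_copies),
            nrow(gen$truth$transcript_carriers), seqdes$n_transcripts))
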