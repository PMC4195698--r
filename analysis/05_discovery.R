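#!/usr/bin/env Rscript
# Stage 5: candidate-ERE discovery on the synthetic sequence set.
#
# Scans the repeat consensus against the genome (copy number) and the
# transcripts (expressed hits, conservation), applies the three filters
# (> 100 genomic copies, > 30 combined transcript hits, > 85% mean
# conservation) and delineates the conserved region used as the primer
# template, then checks everything against the generator's truth record.

suppressMessages(library(erenorm))

ind <- "results/simulated"
out <- "results/discovery"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_fasta(file.path(ind, "repeat_consensus.fa"))
genome <- read_fasta(file.path(ind, "genome.fa"))
tx <- read_fasta(file.path(ind, "transcripts.fa"))
truth <- jsonlite::read_json(file.path(ind, "sequence_truth.json"),
                             simplifyVector = TRUE)

res <- filter_candidates(lib, genome, list(refseq = tx))
utils::write.table(res, file.path(out, "candidates.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(res)

cat(sprintf("\nplanted copies: %d, recovered: %d\n",
            nrow(truth$genome_copies), res$copies))
cat(sprintf("transcripts carrying the repeat: %d, expressed hits: %d\n",
            nrow(truth$transcript_carriers), res$hits_combined))
cat(sprintf("designed mean identity: %.1f%%, recovered conservation: %.1f%%\n",
            mean(truth$transcript_carriers$identity), res$conservation))
cat(sprintf("conserved region on the consensus: [%d, %d)\n",
            res$region_start, res$region_end))
cat(if (res$pass) "-> candidate PASSES all three filters\n" else
    "-> candidate fails at least one filter\n")
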