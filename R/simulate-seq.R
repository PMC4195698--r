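#' Design of a synthetic repeat-bearing sequence set
#'
#' Describes a genome with planted copies of a repeat consensus (each copy an
#' independently mutated instance) and a transcriptome in which a fraction of
#' transcripts carry the repeat embedded in their final third, emulating
#' repeat instances residing predominantly in 3'UTRs.
#'
#' @param consensus_length length of the repeat consensus (bp, >= 50).
#' @param n_copies genomic copies to plant (>= 0).
#' @param substitution_rate per-base substitution probability applied
#'   independently to every planted copy, in `[0, 0.5)`.
#' @param genome_length genome size (bp); default leaves a ~200 bp spacer per
#'   copy. Copies are planted in disjoint equal-width slots, so the genome
#'   must be long enough that each slot exceeds the consensus length.
#' @param n_transcripts number of transcripts.
#' @param transcript_length transcript length (bp, >= 3x consensus length so
#'   the final third can host a copy).
#' @param repeat_fraction fraction of transcripts carrying the repeat.
#' @param seed integer seed.
#' @return An object of class `sequence_design`.
#' @export
sequence_design <- function(consensus_length = 300, n_copies = 150,
                            substitution_rate = 0.05,
                            genome_length = NULL,
                            n_transcripts = 100, transcript_length = 1000,
                            repeat_fraction = 0.4, seed = 1L) {
  consensus_length <- check_count(consensus_length, "consensus_length", min = 50L)
  n_copies <- check_count(n_copies, "n_copies", min = 0L)
  check_scalar_number(substitution_rate, "substitution_rate", lower = 0)
  if (substitution_rate >= 0.5) stop_field("substitution_rate", "must be < 0.5")
  if (is.null(genome_length)) {
    genome_length <- max(n_copies, 1L) * (consensus_length + 200L) + 1000L
  }
  genome_length <- check_count(genome_length, "genome_length", min = 1000L)
  if (n_copies > 0L && genome_length %/% n_copies <= consensus_length) {
    stop_field("genome_length",
               sprintf("too short to host %d disjoint copies of %d bp",
                       n_copies, consensus_length))
  }
  n_transcripts <- check_count(n_transcripts, "n_transcripts", min = 1L)
  transcript_length <- check_count(transcript_length, "transcript_length",
                                   min = 3L * consensus_length)
  check_scalar_number(repeat_fraction, "repeat_fraction", lower = 0, upper = 1)
  seed <- check_count(seed, "seed", min = 0L)

  structure(list(consensus_length = consensus_length, n_copies = n_copies,
                 substitution_rate = substitution_rate,
                 genome_length = genome_length,
                 n_transcripts = n_transcripts,
                 transcript_length = transcript_length,
                 repeat_fraction = repeat_fraction, seed = seed),
            class = "sequence_design")
}

random_dna_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

## Mutate a character vector copy; returns the vector plus realized identity.
mutate_copy <- function(chars, rate) {
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  list(chars = chars, identity = 100 * (1 - length(hit) / length(chars)))
}

#' Generate a genome and transcriptome with planted repeat copies
#'
#' Plants independently mutated instances of a random consensus at recorded
#' 0-based half-open coordinates: genomic copies in disjoint slots along a
#' single chromosome, transcript copies within the final third of each
#' carrier transcript. The truth record lists every planted copy with its
#' realized percent identity to the consensus.
#'
#' @param design a [sequence_design()] object.
#' @return list with `consensus` (`Biostrings::DNAStringSet`, one entry),
#'   `genome` (`DNAStringSet`, one chromosome), `transcripts`
#'   (`DNAStringSet`), and `truth` (list of data.frames `genome_copies` and
#'   `transcript_carriers`, coordinates 0-based half-open, plus the design).
#' @export
generate_repeat_sequences <- function(design) {
  if (!inherits(design, "sequence_design")) {
    stop("design must be a sequence_design object")
  }
  L <- design$consensus_length
  withr::with_seed(design$seed, {
    consensus <- random_dna_chars(L)
    genome <- random_dna_chars(design$genome_length)

    gcopies <- data.frame(copy = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          identity = numeric(0), stringsAsFactors = FALSE)
    if (design$n_copies > 0L) {
      slot <- design$genome_length %/% design$n_copies
      offs <- sample.int(slot - L, design$n_copies, replace = TRUE) - 1L
      starts <- (seq_len(design$n_copies) - 1L) * slot + offs   # 0-based
      ident <- numeric(design$n_copies)
      for (i in seq_len(design$n_copies)) {
        m <- mutate_copy(consensus, design$substitution_rate)
        genome[(starts[i] + 1L):(starts[i] + L)] <- m$chars
        ident[i] <- m$identity
      }
      gcopies <- data.frame(copy = sprintf("copy%04d", seq_len(design$n_copies)),
                            start = starts, end = starts + L, strand = "+",
                            identity = ident, stringsAsFactors = FALSE)
    }

    tx_names <- sprintf("tx%04d", seq_len(design$n_transcripts))
    n_carriers <- round(design$repeat_fraction * design$n_transcripts)
    carriers <- sort(sample.int(design$n_transcripts, n_carriers))
    TL <- design$transcript_length
    lo <- floor(2 * TL / 3)                 # final third, 0-based start range
    tx_seqs <- character(design$n_transcripts)
    tcar <- data.frame(transcript = character(0), start = integer(0),
                       end = integer(0), identity = numeric(0),
                       stringsAsFactors = FALSE)
    for (i in seq_len(design$n_transcripts)) {
      chars <- random_dna_chars(TL)
      if (i %in% carriers) {
        s <- lo + sample.int(TL - L - lo + 1L, 1L) - 1L
        m <- mutate_copy(consensus, design$substitution_rate)
        chars[(s + 1L):(s + L)] <- m$chars
        tcar <- rbind(tcar, data.frame(transcript = tx_names[i], start = s,
                                       end = s + L, identity = m$identity,
                                       stringsAsFactors = FALSE))
      }
      tx_seqs[i] <- paste(chars, collapse = "")
    }
  })

  list(consensus = Biostrings::DNAStringSet(
         stats::setNames(paste(consensus, collapse = ""), "consensus")),
       genome = Biostrings::DNAStringSet(
         stats::setNames(paste(genome, collapse = ""), "chr1")),
       transcripts = Biostrings::DNAStringSet(stats::setNames(tx_seqs, tx_names)),
       truth = list(genome_copies = gcopies, transcript_carriers = tcar,
                    design = design))
}
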