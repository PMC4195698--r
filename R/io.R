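#' Read and write Cq tables
#'
#' Cq matrices travel as TSV with columns `sample`, `group`, `target`,
#' `replicate`, `cq` (`group` and `replicate` optional on input).
#'
#' @param path file path.
#' @return `read_cq_tsv`: the Cq data.frame.
#' @export
read_cq_tsv <- function(path) {
  cq <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  check_cq_frame(cq)
  cq
}

#' @rdname read_cq_tsv
#' @param cq Cq data.frame.
#' @return `write_cq_tsv`: the path, invisibly.
#' @export
write_cq_tsv <- function(cq, path) {
  check_cq_frame(cq)
  write_tsv(cq, path)
  invisible(path)
}

#' Read and write efficiency tables
#'
#' @param path file path.
#' @return `read_efficiency_tsv`: the efficiency data.frame.
#' @export
read_efficiency_tsv <- function(path) {
  eff <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("target", "efficiency_percent")
  if (!all(need %in% names(eff))) {
    stop("efficiency table needs columns target, efficiency_percent")
  }
  if (is.null(eff$amplification_factor)) {
    eff$amplification_factor <- 1 + eff$efficiency_percent / 100
  }
  eff
}

#' @rdname read_efficiency_tsv
#' @param eff efficiency data.frame ([efficiency_table()] layout).
#' @export
write_efficiency_tsv <- function(eff, path) {
  write_tsv(eff, path)
  invisible(path)
}

#' Write a simulation truth record as JSON
#'
#' @param truth truth list from [generate_cq_dataset()] or
#'   [generate_repeat_sequences()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  truth$design <- unclass(truth$design)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor", force = TRUE)
  invisible(path)
}

#' Write sequence sets to FASTA
#'
#' Thin wrapper over `Biostrings::writeXStringSet` so generated genomes,
#' transcriptomes and repeat libraries round-trip through standard files.
#'
#' @param seqs a `Biostrings::DNAStringSet`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
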