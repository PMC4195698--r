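#' Seeded ungapped local alignment of a repeat consensus against sequences
#'
#' A self-contained seed-and-extend scanner for locating repeat instances:
#' exact k-mer seeds between the consensus (query) and each subject are
#' grouped by alignment diagonal, each diagonal's full overlap is compared
#' base-by-base, and the maximal-scoring ungapped segment (match +1,
#' mismatch -2) is kept. Both strands are scanned. Hits on the same subject
#' and strand whose subject intervals overlap by more than half of the
#' shorter hit are merged, keeping the higher-scoring one. Hits below the
#' identity or length floor are discarded.
#'
#' Because extension is ungapped, instances that diverged by substitutions
#' only are recovered on a single diagonal; indel-containing instances may be
#' reported as split or truncated hits.
#'
#' @param consensus the repeat consensus: a single-sequence
#'   `Biostrings::DNAStringSet`/`DNAString` or a character scalar.
#' @param subjects named `DNAStringSet` or named character vector of subject
#'   sequences (genome chromosomes, transcripts, ...).
#' @param k seed k-mer length (>= 8).
#' @param min_identity minimum percent identity of a reported hit, in
#'   `[50, 100]`.
#' @param min_hit_length minimum alignment length (bp).
#' @return data.frame of hits, one row each: `subject`, `strand` (+/-),
#'   `sstart`, `send`, `qstart`, `qend` (0-based half-open; subject
#'   coordinates always on the forward strand), `length`, `identity`
#'   (percent), `score`.
#' @export
scan_sequences <- function(consensus, subjects, k = 11L,
                           min_identity = 70, min_hit_length = 50L) {
  k <- check_count(k, "k", min = 8L)
  check_scalar_number(min_identity, "min_identity", lower = 50, upper = 100)
  min_hit_length <- check_count(min_hit_length, "min_hit_length", min = 1L)
  qchars <- as_dna_chars(consensus, "consensus")[[1]]
  subj <- as_dna_chars(subjects, "subjects")
  empty <- data.frame(subject = character(0), strand = character(0),
                      sstart = integer(0), send = integer(0),
                      qstart = integer(0), qend = integer(0),
                      length = integer(0), identity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(subj) == 0L) return(empty)
  if (length(qchars) < k) stop("consensus shorter than the seed length")

  qkmers <- kmer_strings(qchars, k)
  hits <- list()
  for (sname in names(subj)) {
    for (strand in c("+", "-")) {
      schars <- subj[[sname]]
      if (strand == "-") schars <- revcomp_chars(schars)
      h <- scan_one(qchars, qkmers, schars, k, min_identity, min_hit_length)
      if (nrow(h) == 0L) next
      if (strand == "-") {
        # map subject coordinates back to the forward strand
        slen <- length(schars)
        tmp <- slen - h$send
        h$send <- slen - h$sstart
        h$sstart <- tmp
      }
      h$subject <- sname
      h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0L) return(empty)
  h <- do.call(rbind, hits)
  h <- merge_overlapping_hits(h)
  h <- h[order(h$subject, h$sstart), c("subject", "strand", "sstart", "send",
                                       "qstart", "qend", "length", "identity",
                                       "score")]
  rownames(h) <- NULL
  h
}

as_dna_chars <- function(x, what) {
  if (methods::is(x, "DNAString")) x <- Biostrings::DNAStringSet(x)
  if (methods::is(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (is.character(x)) {
    s <- x
  } else stop(sprintf("%s must be a DNAStringSet or character vector", what))
  if (length(s) >= 1L && is.null(names(s))) {
    names(s) <- if (length(s) == 1L) what else sprintf("%s%d", what, seq_along(s))
  }
  lapply(s, function(one) strsplit(toupper(one), "", fixed = TRUE)[[1]])
}

revcomp_chars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}

kmer_strings <- function(chars, k) {
  n <- length(chars) - k + 1L
  if (n < 1L) return(character(0))
  s <- paste(chars, collapse = "")
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

## One subject strand: seed matches -> diagonals -> best ungapped segment.
scan_one <- function(qchars, qkmers, schars, k, min_identity, min_hit_length) {
  out <- data.frame(sstart = integer(0), send = integer(0),
                    qstart = integer(0), qend = integer(0),
                    length = integer(0), identity = numeric(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  skmers <- kmer_strings(schars, k)
  if (length(skmers) == 0L) return(out)
  m <- match(skmers, qkmers)              # first query position per subject kmer
  spos <- which(!is.na(m))
  if (length(spos) == 0L) return(out)
  # a subject kmer can seed several query positions; collect them all
  qidx <- split(seq_along(qkmers), qkmers)
  seeds_q <- qidx[skmers[spos]]
  reps <- lengths(seeds_q)
  qpos <- unlist(seeds_q, use.names = FALSE)
  spos <- rep(spos, reps)
  diags <- unique(spos - qpos)            # subject offset of the query origin

  qlen <- length(qchars)
  slen <- length(schars)
  for (d in diags) {
    qlo <- max(1L, 1L - d)                # aligned query range on this diagonal
    qhi <- min(qlen, slen - d)
    if (qhi - qlo + 1L < min_hit_length) next
    qseg <- qchars[qlo:qhi]
    sseg <- schars[(qlo + d):(qhi + d)]
    x <- ifelse(qseg == sseg, 1, -2)
    cs <- cumsum(x)
    lo_run <- cummin(c(0, cs[-length(cs)]))  # best prefix sum before each end
    gain <- cs - lo_run
    j <- which.max(gain)                     # segment end
    # segment start: position after the latest prefix minimum before j
    pre <- c(0, cs[-length(cs)])
    i <- max(which(pre == lo_run[j] & seq_along(pre) <= j))
    score <- gain[j]
    len <- j - i + 1L
    if (len < min_hit_length) next
    matches <- sum(qseg[i:j] == sseg[i:j])
    identity <- 100 * matches / len
    if (identity < min_identity) next
    qstart0 <- qlo + i - 2L                  # 0-based
    out <- rbind(out, data.frame(
      sstart = qstart0 + d, send = qstart0 + d + len,
      qstart = qstart0, qend = qstart0 + len,
      length = len, identity = identity, score = score,
      stringsAsFactors = FALSE))
  }
  out
}

## Greedy merge: keep best-scoring hit; drop/absorb hits on the same subject
## and strand overlapping it by > 50% of the shorter hit.
merge_overlapping_hits <- function(h) {
  o <- order(-h$score, -h$identity, h$subject, h$sstart)
  h <- h[o, , drop = FALSE]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (h$subject[j] != h$subject[i] || h$strand[j] != h$strand[i]) next
      ov <- min(h$send[i], h$send[j]) - max(h$sstart[i], h$sstart[j])
      if (ov > 0.5 * min(h$length[i], h$length[j])) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  h[keep, , drop = FALSE]
}

#' Genomic copy number of a repeat consensus
#'
#' Number of merged genomic hits found by [scan_sequences()].
#'
#' @inheritParams scan_sequences
#' @param genome genome sequences (`DNAStringSet` or named character).
#' @param ... passed to [scan_sequences()].
#' @return integer copy count.
#' @export
copy_number <- function(consensus, genome, ...) {
  nrow(scan_sequences(consensus, genome, ...))
}

#' Expressed-hit counts of a repeat across transcript collections
#'
#' Counts transcripts (not hit segments) containing at least one hit, per
#' collection (e.g. RefSeq and non-RefSeq annotated transcripts) and
#' combined.
#'
#' @inheritParams scan_sequences
#' @param collections named list of transcript sequence sets.
#' @param ... passed to [scan_sequences()].
#' @return list with `per_collection` (named integer vector), `combined`
#'   (their sum) and `hits` (all hits with a `collection` column).
#' @export
expressed_hits <- function(consensus, collections, ...) {
  if (!is.list(collections) || length(collections) < 1L) {
    stop("need >= 1 transcript collection")
  }
  if (is.null(names(collections))) {
    names(collections) <- sprintf("collection%d", seq_along(collections))
  }
  per <- integer(length(collections))
  names(per) <- names(collections)
  all_hits <- list()
  for (nm in names(collections)) {
    h <- scan_sequences(consensus, collections[[nm]], ...)
    per[[nm]] <- length(unique(h$subject))
    if (nrow(h)) { h$collection <- nm; all_hits[[nm]] <- h }
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else NULL
  list(per_collection = per, combined = sum(per), hits = hits)
}

#' Mean conservation rate of a set of hits
#'
#' Arithmetic mean of the hits' percent identities to the consensus.
#'
#' @param hits hit data.frame from [scan_sequences()].
#' @return percent in `[0, 100]`.
#' @export
conservation_rate <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("conservation rate undefined for an empty hit list")
  }
  mean(hits$identity)
}

#' Most frequently expressed (conserved) region of a consensus
#'
#' Scores every consensus position by (number of hits covering it) x (mean
#' identity of those hits) and returns the fixed-length window with the
#' highest total score — the template region for primer design. Ties resolve
#' to the earliest window.
#'
#' @param hits hit data.frame (consensus coordinates `qstart`/`qend`).
#' @param consensus_length length of the consensus (bp).
#' @param window window length (bp, <= consensus length).
#' @return list with `start`, `end` (0-based half-open) and `score`.
#' @export
conserved_region <- function(hits, consensus_length, window = 100L) {
  if (is.null(hits) || nrow(hits) == 0L) stop("need >= 1 hit")
  window <- check_count(window, "window", min = 1L)
  consensus_length <- check_count(consensus_length, "consensus_length", min = 1L)
  if (window > consensus_length) stop_field("window", "exceeds consensus length")
  cov <- numeric(consensus_length)
  idsum <- numeric(consensus_length)
  for (i in seq_len(nrow(hits))) {
    span <- (hits$qstart[i] + 1L):hits$qend[i]
    cov[span] <- cov[span] + 1
    idsum[span] <- idsum[span] + hits$identity[i]
  }
  score <- ifelse(cov > 0, cov * (idsum / pmax(cov, 1)), 0)
  cs <- cumsum(c(0, score))
  wins <- cs[(window + 1L):(consensus_length + 1L)] -
    cs[1:(consensus_length - window + 1L)]
  s <- which.max(wins) - 1L                # earliest max, 0-based
  list(start = s, end = s + window, score = wins[s + 1L])
}

#' Apply the candidate-ERE filters to a repeat library
#'
#' For every consensus in the library, computes the genomic copy number, the
#' expressed-hit counts over the transcript collections, and the mean
#' conservation rate, then applies three strict filters: more than
#' `min_copies` genomic copies, more than `min_combined_hits` transcript
#' hits (summed over collections) and a mean conservation rate above
#' `min_conservation` percent. For passing (or all) repeats with transcript
#' hits, the conserved region is delineated.
#'
#' @param library named `DNAStringSet` (or named character vector) of repeat
#'   consensus sequences.
#' @param genome genome sequences.
#' @param collections named list of transcript sequence sets.
#' @param min_copies,min_combined_hits,min_conservation filter thresholds
#'   (strict `>` comparisons).
#' @param conservation_from compute the conservation rate from
#'   `"transcripts"` (expressed instances; default) or `"genome"` hits.
#' @param region_window conserved-region window length (bp).
#' @param ... aligner parameters passed to [scan_sequences()].
#' @return data.frame, one row per repeat: `repeat_id`, `copies`, per-
#'   collection hit counts (`hits_<collection>`), `hits_combined`,
#'   `conservation`, `pass_copies`, `pass_hits`, `pass_conservation`,
#'   `pass`, `region_start`, `region_end` (NA when no transcript hits).
#' @export
filter_candidates <- function(library, genome, collections,
                              min_copies = 100, min_combined_hits = 30,
                              min_conservation = 85,
                              conservation_from = c("transcripts", "genome"),
                              region_window = 100L, ...) {
  conservation_from <- match.arg(conservation_from)
  if (min_copies <= 0 || min_combined_hits <= 0 || min_conservation <= 0) {
    stop("thresholds must be positive")
  }
  lib <- if (methods::is(library, "DNAStringSet")) as.character(library) else library
  if (is.null(names(lib))) stop("library sequences must be named")
  rows <- vector("list", length(lib))
  for (i in seq_along(lib)) {
    cons <- lib[[i]]
    ghits <- scan_sequences(cons, genome, ...)
    ehits <- expressed_hits(cons, collections, ...)
    cons_hits <- if (conservation_from == "transcripts") ehits$hits else ghits
    conservation <- if (is.null(cons_hits) || nrow(cons_hits) == 0L) NA_real_
                    else conservation_rate(cons_hits)
    region <- c(NA_integer_, NA_integer_)
    if (!is.null(ehits$hits) && nrow(ehits$hits) > 0L) {
      r <- conserved_region(ehits$hits, nchar(cons),
                            min(region_window, nchar(cons)))
      region <- c(r$start, r$end)
    }
    row <- data.frame(repeat_id = names(lib)[i], copies = nrow(ghits),
                      stringsAsFactors = FALSE)
    for (nm in names(ehits$per_collection)) {
      row[[paste0("hits_", nm)]] <- ehits$per_collection[[nm]]
    }
    row$hits_combined <- ehits$combined
    row$conservation <- conservation
    row$pass_copies <- row$copies > min_copies
    row$pass_hits <- row$hits_combined > min_combined_hits
    row$pass_conservation <- !is.na(conservation) & conservation > min_conservation
    row$pass <- row$pass_copies & row$pass_hits & row$pass_conservation
    row$region_start <- region[1]
    row$region_end <- region[2]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read hits from a standard 12-column tabular alignment file
#'
#' Adapter for external aligners emitting the conventional tab-separated
#' format (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, e-value, bit score;
#' 1-based inclusive coordinates). Converted to this package's 0-based
#' half-open convention with explicit strand.
#'
#' @param path file path.
#' @return hit data.frame compatible with [scan_sequences()] output.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("expected 12 tab-separated columns")
  names(tab)[1:12] <- c("query", "subject", "identity", "length", "mismatch",
                        "gapopen", "qstart1", "qend1", "sstart1", "send1",
                        "evalue", "bitscore")
  minus <- tab$sstart1 > tab$send1
  sstart <- ifelse(minus, tab$send1, tab$sstart1) - 1L
  send <- ifelse(minus, tab$sstart1, tab$send1)
  data.frame(subject = tab$subject,
             strand = ifelse(minus, "-", "+"),
             sstart = sstart, send = send,
             qstart = tab$qstart1 - 1L, qend = tab$qend1,
             length = tab$length, identity = tab$identity,
             score = tab$bitscore, stringsAsFactors = FALSE)
}
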