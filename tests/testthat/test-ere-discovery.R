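plant <- function(consensus, flank5, flank3) paste0(flank5, consensus, flank3)

rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

test_that("a verbatim planted consensus is found once at its coordinates", {
  cons <- rand_seq(200, 1)
  subject <- plant(cons, rand_seq(150, 2), rand_seq(100, 3))
  h <- scan_sequences(cons, c(s1 = subject), min_hit_length = 50)
  expect_equal(nrow(h), 1)
  expect_equal(h$sstart, 150)
  expect_equal(h$send, 350)
  expect_equal(h$qstart, 0)
  expect_equal(h$qend, 200)
  expect_equal(h$identity, 100)
  expect_equal(h$strand, "+")
})

test_that("a reverse-complement subject is reported on the minus strand", {
  cons <- rand_seq(150, 4)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  subject <- plant(rc, rand_seq(80, 5), rand_seq(60, 6))
  h <- scan_sequences(cons, c(s1 = subject))
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$identity, 100)
  expect_equal(h$sstart, 80)     # forward-strand coordinates
  expect_equal(h$send, 230)
})

test_that("recall is complete on a synthetic genome and identities track truth", {
  des <- sequence_design(consensus_length = 250, n_copies = 40,
                         substitution_rate = 0.05, n_transcripts = 5,
                         transcript_length = 800, repeat_fraction = 0.4,
                         seed = 21)
  gen <- generate_repeat_sequences(des)
  h <- scan_sequences(gen$consensus, gen$genome)
  expect_equal(nrow(h), 40)
  truth <- gen$truth$genome_copies[order(gen$truth$genome_copies$start), ]
  h <- h[order(h$sstart), ]
  # ungapped extension may trim a mutated copy edge; identity within 2 points
  expect_true(all(abs(h$identity - truth$identity) <= 2))
  expect_true(all(h$sstart >= truth$start - 1 & h$send <= truth$end + 1))
})

test_that("heavily overlapping hits are merged to the best-scoring one", {
  cons <- rand_seq(120, 7)
  # two overlapping plantings: tandem with 60 bp shift -> overlapping hits
  subject <- paste0(rand_seq(100, 8), substr(cons, 1, 120),
                    substr(cons, 61, 120), rand_seq(100, 9))
  h <- scan_sequences(cons, c(s1 = subject), min_hit_length = 50)
  # the two candidate alignments overlap by more than half the shorter one
  expect_lte(nrow(h), 2)
  expect_equal(h$identity[1], 100)
})

test_that("copy number is monotone in the planted copy count", {
  counts <- c(0L, 5L, 15L)
  found <- vapply(counts, function(nc) {
    des <- sequence_design(consensus_length = 150, n_copies = nc,
                           genome_length = 20000, substitution_rate = 0.03,
                           n_transcripts = 2, transcript_length = 500,
                           repeat_fraction = 0, seed = 30 + nc)
    gen <- generate_repeat_sequences(des)
    copy_number(gen$consensus, gen$genome)
  }, 1L)
  expect_equal(found, counts)
})

test_that("expressed hits count transcripts, not hit segments", {
  cons <- rand_seq(100, 10)
  # one transcript containing two well-separated copies
  two <- paste0(rand_seq(60, 11), cons, rand_seq(200, 12), cons, rand_seq(60, 13))
  none <- rand_seq(500, 14)
  eh <- expressed_hits(cons, list(refseq = c(tx1 = two, tx2 = none)))
  expect_equal(unname(eh$per_collection["refseq"]), 1L)
  expect_equal(eh$combined, 1L)
  expect_equal(nrow(eh$hits), 2)     # two segments, one transcript
  # counts split per collection and summed
  eh2 <- expressed_hits(cons, list(refseq = c(tx1 = two),
                                   nonrefseq = c(tx3 = two, tx4 = none)))
  expect_equal(unname(eh2$per_collection), c(1L, 1L))
  expect_equal(eh2$combined, 2L)
})

test_that("conservation rate is the arithmetic mean of hit identities", {
  hits <- data.frame(identity = c(80, 90))
  expect_equal(conservation_rate(hits), 85)
  expect_equal(conservation_rate(data.frame(identity = rep(100, 4))), 100)
  expect_error(conservation_rate(NULL), "empty|undefined")
  expect_error(conservation_rate(data.frame(identity = numeric(0))), "empty|undefined")
})

test_that("candidate filters use strict greater-than thresholds", {
  boundary_case <- function(n_copies, seed) {
    des <- sequence_design(consensus_length = 60, n_copies = n_copies,
                           genome_length = n_copies * 100 + 1000,
                           substitution_rate = 0, n_transcripts = 40,
                           transcript_length = 200, repeat_fraction = 0.8,
                           seed = seed)
    generate_repeat_sequences(des)
  }
  at <- boundary_case(100, 61)    # exactly 100 copies: fails "more than 100"
  above <- boundary_case(101, 62) # 101 copies: passes
  res_at <- filter_candidates(at$consensus, at$genome,
                              list(refseq = at$transcripts),
                              min_hit_length = 50)
  res_above <- filter_candidates(above$consensus, above$genome,
                                 list(refseq = above$transcripts),
                                 min_hit_length = 50)
  expect_equal(res_at$copies, 100)
  expect_false(res_at$pass_copies)
  expect_equal(res_above$copies, 101)
  expect_true(res_above$pass_copies)
  # 32 carriers > 30 with conservation 100 > 85: the other filters pass
  expect_true(res_above$pass_hits && res_above$pass_conservation)
  expect_true(res_above$pass)
  expect_false(res_at$pass)
})

test_that("a designed pass/fail library filters to exactly the designed set", {
  # passer: many genomic copies, widely expressed, high conservation
  des_pass <- sequence_design(consensus_length = 150, n_copies = 120,
                              substitution_rate = 0.03, n_transcripts = 40,
                              transcript_length = 500, repeat_fraction = 0.9,
                              seed = 51)
  pass <- generate_repeat_sequences(des_pass)
  # failer 1: too few genomic copies
  des_few <- sequence_design(consensus_length = 150, n_copies = 20,
                             genome_length = pass$truth$design$genome_length,
                             substitution_rate = 0.03, n_transcripts = 40,
                             transcript_length = 500, repeat_fraction = 0.9,
                             seed = 52)
  few <- generate_repeat_sequences(des_few)
  # failer 2: enough copies but barely expressed
  des_silent <- sequence_design(consensus_length = 150, n_copies = 120,
                                substitution_rate = 0.03, n_transcripts = 40,
                                transcript_length = 500, repeat_fraction = 0.1,
                                seed = 53)
  silent <- generate_repeat_sequences(des_silent)
  genome <- c(pass$genome, few$genome, silent$genome)
  names(genome) <- c("chrA", "chrB", "chrC")
  tx <- c(pass$transcripts, few$transcripts, silent$transcripts)
  names(tx) <- sprintf("tx%03d", seq_along(tx))
  lib <- c(pass$consensus, few$consensus, silent$consensus)
  names(lib) <- c("passer", "few_copies", "silent")
  res <- filter_candidates(lib, genome, list(refseq = tx))
  expect_equal(res$repeat_id[res$pass], "passer")
  expect_false(res$pass_copies[res$repeat_id == "few_copies"])
  expect_true(res$pass_hits[res$repeat_id == "few_copies"])
  expect_false(res$pass_hits[res$repeat_id == "silent"])
  # ordering invariance of the pass set
  res2 <- filter_candidates(rev(lib), genome, list(refseq = tx))
  expect_setequal(res2$repeat_id[res2$pass], res$repeat_id[res$pass])
})

test_that("the conserved region stays inside the hit support and breaks ties early", {
  hits <- data.frame(qstart = c(100, 120, 110), qend = c(250, 240, 230),
                     identity = c(95, 98, 92))
  r <- conserved_region(hits, consensus_length = 300, window = 100)
  expect_gte(r$start, 100)
  expect_lte(r$end, 250)
  # uniform coverage: earliest window wins
  uni <- data.frame(qstart = 0, qend = 300, identity = 100)
  r2 <- conserved_region(uni, 300, 80)
  expect_equal(r2$start, 0)
  expect_equal(r2$end, 80)
  # a designed high-coverage block attracts the window
  block <- data.frame(qstart = c(rep(150, 8), 0), qend = c(rep(260, 8), 300),
                      identity = 97)
  r3 <- conserved_region(block, 300, 60)
  expect_gte(r3$start, 150)
  expect_lte(r3$end, 260)
  expect_error(conserved_region(uni, 300, 400), "window")
})

test_that("external 12-column hit tables are converted to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("cons", "tx1", "97.5", "200", "5", "0",
                     "1", "200", "301", "500", "1e-50", "350"),
                   collapse = "\t"), f)
  h <- read_hit_table(f)
  expect_equal(h$sstart, 300)
  expect_equal(h$send, 500)
  expect_equal(h$qstart, 0)
  expect_equal(h$strand, "+")
  # minus-strand rows have sstart > send in the input
  writeLines(paste(c("cons", "tx2", "90", "100", "10", "0",
                     "1", "100", "400", "301", "1e-20", "120"),
                   collapse = "\t"), f)
  h2 <- read_hit_table(f)
  expect_equal(h2$strand, "-")
  expect_equal(h2$sstart, 300)
  expect_equal(h2$send, 400)
})
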