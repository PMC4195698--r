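simple_targets <- function(sigma_bio = 0, F = 2) {
  data.frame(target = c("t1", "t2", "t3", "t4", "t5"),
             amplification_factor = F,
             baseline_cq = c(20, 22, 24, 26, 28),
             sigma_bio = sigma_bio)
}

test_that("noiseless design with unit fold changes gives constant Cq at baseline", {
  d <- cq_design(simple_targets(), groups = c("a", "b"), n_per_group = 3)
  sim <- generate_cq_dataset(d)
  for (t in d$targets$target) {
    cqs <- sim$cq$cq[sim$cq$target == t]
    expect_equal(cqs, rep(d$targets$baseline_cq[d$targets$target == t],
                          length(cqs)))
  }
  expect_true(all(sim$truth$quantities == 1))
})

test_that("a designed 4-fold change with F = 2 shifts Cq by exactly 2 cycles", {
  tg <- simple_targets()
  fc <- matrix(1, 5, 2, dimnames = list(tg$target, c("a", "b")))
  fc["t3", "a"] <- 4
  d <- cq_design(tg, c("a", "b"), n_per_group = 3, fold_changes = fc)
  sim <- generate_cq_dataset(d)
  cq_a <- sim$cq$cq[sim$cq$target == "t3" & sim$cq$group == "a"]
  cq_b <- sim$cq$cq[sim$cq$target == "t3" & sim$cq$group == "b"]
  expect_equal(unique(cq_b) - unique(cq_a), 2)
})

test_that("Cq generation is deterministic given the design seed", {
  d <- cq_design(simple_targets(sigma_bio = 0.5), c("a", "b"), 3,
                 sigma_content = 0.4, sigma_tech = 0.2, n_replicates = 2,
                 seed = 1)
  s1 <- generate_cq_dataset(d)
  s2 <- generate_cq_dataset(d)
  expect_identical(s1$cq, s2$cq)
  expect_identical(s1$truth$quantities, s2$truth$quantities)
  d2 <- cq_design(simple_targets(sigma_bio = 0.5), c("a", "b"), 3,
                  sigma_content = 0.4, sigma_tech = 0.2, n_replicates = 2,
                  seed = 2)
  expect_false(identical(generate_cq_dataset(d2)$cq$cq, s1$cq$cq))
})

test_that("design validation names the offending field", {
  tg <- simple_targets()
  expect_error(cq_design(tg, c("a", "a"), 3), "groups")
  expect_error(cq_design(tg, "a", 0), "n_per_group")
  expect_error(cq_design(tg, "a", 3, sigma_tech = -1), "sigma_tech")
  bad <- tg; bad$amplification_factor <- 1
  expect_error(cq_design(bad, "a", 3), "amplification_factor")
  fc <- matrix(-1, 5, 1, dimnames = list(tg$target, "a"))
  expect_error(cq_design(tg, "a", 3, fold_changes = fc), "fold_changes")
})

test_that("technical replicates share the true quantity and differ only by noise", {
  d <- cq_design(simple_targets(sigma_bio = 0.8), "a", 4,
                 sigma_tech = 0, n_replicates = 3, seed = 5)
  sim <- generate_cq_dataset(d)
  per_well <- tapply(sim$cq$cq, interaction(sim$cq$sample, sim$cq$target),
                     function(x) diff(range(x)))
  expect_true(all(per_well == 0))   # sigma_tech 0: replicates identical
})

test_that("dilution series is spaced exactly per dilution step when noiseless", {
  s <- make_dilution_series(2, top_cq = 20)
  expect_equal(s$cq, c(20, 22, 24, 26, 28))   # 2 cycles per 4-fold step
  expect_error(make_dilution_series(1), "amplification_factor")
  expect_error(make_dilution_series(2, quantities = c(1, 2)), "quantities")
  expect_error(make_dilution_series(2, quantities = c(1, 2, -1)), "quantities")
})

test_that("planted copies are exact consensus instances at substitution rate 0", {
  des <- sequence_design(consensus_length = 120, n_copies = 5,
                         substitution_rate = 0, n_transcripts = 4,
                         transcript_length = 400, repeat_fraction = 0.5,
                         seed = 3)
  gen <- generate_repeat_sequences(des)
  expect_equal(gen$truth$genome_copies$identity, rep(100, 5))
  cons <- as.character(gen$consensus[[1]])
  g <- as.character(gen$genome[[1]])
  for (i in seq_len(5)) {
    s <- gen$truth$genome_copies$start[i]
    expect_identical(substr(g, s + 1, s + 120), cons)
  }
  expect_equal(nrow(gen$truth$transcript_carriers), 2)
})

test_that("zero planted copies leave the genome clean and the truth empty", {
  des <- sequence_design(n_copies = 0, genome_length = 5000, n_transcripts = 3,
                         repeat_fraction = 0, seed = 1)
  gen <- generate_repeat_sequences(des)
  expect_equal(nrow(gen$truth$genome_copies), 0)
  expect_equal(nrow(gen$truth$transcript_carriers), 0)
  expect_equal(copy_number(gen$consensus, gen$genome), 0)
})

test_that("realized identity matches the binomial expectation of the mutation process", {
  des <- sequence_design(consensus_length = 200, n_copies = 200,
                         substitution_rate = 0.1, n_transcripts = 1,
                         transcript_length = 600, repeat_fraction = 0,
                         seed = 7)
  gen <- generate_repeat_sequences(des)
  ident <- gen$truth$genome_copies$identity
  expect_equal(length(ident), 200)
  # mean identity within 1 point of 90% and within 3 SE of the binomial mean
  expect_lt(abs(mean(ident) - 90), 1)
  se <- 100 * sqrt(0.1 * 0.9 / 200) / sqrt(200)
  expect_lt(abs(mean(ident) - 90), 3 * se + 1e-9)
})

test_that("transcript copies land inside the final third", {
  des <- sequence_design(consensus_length = 100, n_copies = 1,
                         genome_length = 2000, n_transcripts = 30,
                         transcript_length = 600, repeat_fraction = 1,
                         substitution_rate = 0.02, seed = 11)
  gen <- generate_repeat_sequences(des)
  tc <- gen$truth$transcript_carriers
  expect_equal(nrow(tc), 30)
  expect_true(all(tc$start >= floor(2 * 600 / 3)))
  expect_true(all(tc$end <= 600))
})

test_that("sequence design rejects impossible layouts", {
  expect_error(sequence_design(consensus_length = 300, n_copies = 100,
                               genome_length = 20000), "genome_length")
  expect_error(sequence_design(substitution_rate = 0.6), "substitution_rate")
  expect_error(sequence_design(consensus_length = 10), "consensus_length")
})
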