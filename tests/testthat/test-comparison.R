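geomean_ref <- function(x) exp(mean(log(x)))

noiseless_fc_data <- function(goi_fc = 20, ref_fcs = c(r1 = 1, r2 = 1, r3 = 1),
                              seed = 1) {
  tg <- data.frame(target = c("goi", names(ref_fcs)),
                   amplification_factor = 2,
                   baseline_cq = c(24, 20, 21, 22),
                   sigma_bio = 0)
  fc <- matrix(1, 4, 2, dimnames = list(tg$target, c("A", "B")))
  fc["goi", "A"] <- goi_fc
  fc[names(ref_fcs), "A"] <- ref_fcs
  d <- cq_design(tg, c("A", "B"), 3, fold_changes = fc, sigma_content = 0.4,
                 seed = seed)
  sim <- generate_cq_dataset(d)
  cq_to_relative_quantity(collapse_replicates(sim$cq), NULL)
}

test_that("noiseless fold change with flat references is recovered exactly", {
  Q <- noiseless_fc_data(goi_fc = 20)
  fc <- fold_change(Q, "goi", c("r1", "r2", "r3"), "A", "B")
  expect_equal(fc$fold_change, 20)
})

test_that("a changing reference biases the fold change by the ratio law", {
  # single reference with its own fold change f: measured FC = 20 / f
  for (f in c(2, 6.7, 10)) {
    Q <- noiseless_fc_data(goi_fc = 20, ref_fcs = c(r1 = f, r2 = 1, r3 = 1))
    fc1 <- fold_change(Q, "goi", "r1", "A", "B")
    expect_equal(fc1$fold_change, 20 / f)
  }
  # reference set: bias is the geometric mean of the references' fold changes
  Q <- noiseless_fc_data(goi_fc = 20, ref_fcs = c(r1 = 10, r2 = 6, r3 = 5))
  fc3 <- fold_change(Q, "goi", c("r1", "r2", "r3"), "A", "B")
  expect_equal(fc3$fold_change, 20 / (10 * 6 * 5)^(1 / 3))
})

test_that("the bias law holds across random noiseless designs", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      goi_fc <- runif(1, 0.2, 30)
      ref_fcs <- runif(3, 0.5, 8)
    })
    names(ref_fcs) <- c("r1", "r2", "r3")
    Q <- noiseless_fc_data(goi_fc, ref_fcs, seed = seed)
    fc <- fold_change(Q, "goi", names(ref_fcs), "A", "B")
    expect_equal(fc$fold_change, goi_fc / geomean_ref(ref_fcs),
                 tolerance = 1e-10)
  }
})

test_that("fold change is invariant to per-sample global scaling", {
  Q <- noiseless_fc_data(goi_fc = 5, ref_fcs = c(r1 = 2, r2 = 1, r3 = 1))
  groups <- rq_groups(Q)
  Qs <- Q * 2^seq(-2, 3, length.out = nrow(Q))
  fc1 <- fold_change(Q, "goi", c("r1", "r2"), "A", "B")
  fc2 <- fold_change(Qs, "goi", c("r1", "r2"), "A", "B", groups = groups)
  expect_equal(fc1$fold_change, fc2$fold_change, tolerance = 1e-12)
})

test_that("fold-change preconditions are enforced", {
  Q <- noiseless_fc_data()
  expect_error(fold_change(Q, "goi", character(0), "A", "B"), "reference")
  expect_error(fold_change(Q, "goi", c("goi", "r1"), "A", "B"), "reference")
  expect_error(fold_change(Q, "goi", "r1", "A", "Z"), "group")
})

test_that("with stable references and realistic noise the FC error is small", {
  errs <- vapply(1:40, function(seed) {
    tg <- data.frame(target = c("goi", "r1", "r2", "r3"),
                     amplification_factor = 2, baseline_cq = c(24, 20, 21, 22),
                     sigma_bio = c(0.1, 0.1, 0.1, 0.1))
    fc <- matrix(1, 4, 2, dimnames = list(tg$target, c("A", "B")))
    fc["goi", "A"] <- 4
    d <- cq_design(tg, c("A", "B"), 4, fold_changes = fc, sigma_content = 0.3,
                   sigma_tech = 0.2, n_replicates = 2, seed = seed)
    sim <- generate_cq_dataset(d)
    Q <- cq_to_relative_quantity(collapse_replicates(sim$cq), NULL)
    abs(fold_change(Q, "goi", c("r1", "r2", "r3"), "A", "B")$fold_change - 4) / 4
  }, 1)
  expect_lt(median(errs), 0.10)
})

test_that("group stability tests separate designed stable and unstable families", {
  withr::with_seed(8, {
    m_ere <- 0.2 + rnorm(10, 0, 0.02)
    m_classic <- 0.8 + rnorm(10, 0, 0.05)
  })
  M <- setNames(c(m_ere, m_classic), paste0("t", 1:20))
  membership <- setNames(rep(c("ERE", "classic"), each = 10), names(M))
  res <- group_stability_test(M, membership)
  expect_lt(res$location$p.value, 0.001)
  expect_lt(res$summary$median_M[res$summary$group == "ERE"],
            res$summary$median_M[res$summary$group == "classic"])
  # identical distributions: t near 0, p near 1
  M2 <- setNames(rep(c(0.3, 0.4, 0.5), 4), paste0("u", 1:12))
  mem2 <- setNames(rep(c("a", "b"), each = 6), names(M2))
  res2 <- group_stability_test(M2, mem2)
  expect_equal(unname(res2$location$statistic), 0, tolerance = 1e-12)
  expect_gt(res2$location$p.value, 0.99)
  # one tight, one dispersed group: the spread test flags it
  withr::with_seed(9, {
    M3 <- setNames(c(0.3 + rnorm(12, 0, 0.005), abs(0.5 + rnorm(12, 0, 0.4))),
                   paste0("v", 1:24))
  })
  mem3 <- setNames(rep(c("tight", "wide"), each = 12), names(M3))
  res3 <- group_stability_test(M3, mem3)
  expect_lt(res3$spread$p.value, 0.01)
  expect_error(group_stability_test(M, membership[1:5]), "membership")
})

test_that("the report writer emits a deterministic, complete file set", {
  Q <- random_Q(8, 5, seed = 3)
  r <- rank_targets(Q)
  vc <- suppressWarnings(v_curve(Q, r))
  rls <- ranked_lists(list(r$ranking$target, r$ranking$target))
  cons <- aggregate_ce(rls, seed = 1)
  fc_tab <- data.frame(experiment = "e1", goi = "g", reference_set = "ERE",
                       group_a = "A", group_b = "B", fold_change = 2.5)
  d1 <- withr::local_tempdir()
  files <- write_report(d1, rankings = list(e1 = r, e2 = r),
                        vcurves = list(e1 = vc, e2 = vc), consensus = cons,
                        fold_changes = fc_tab, metadata = list(seed = 1))
  expect_setequal(basename(files),
                  c("stability_rankings.tsv", "v_curves.tsv",
                    "consensus_ranking.tsv", "aggregation_trace.tsv",
                    "fold_change_comparison.tsv", "run_metadata.json"))
  expect_true(all(file.exists(files)))
  # rerun into a second directory: byte-identical tables
  d2 <- withr::local_tempdir()
  files2 <- write_report(d2, rankings = list(e1 = r, e2 = r),
                         vcurves = list(e1 = vc, e2 = vc), consensus = cons,
                         fold_changes = fc_tab, metadata = list(seed = 1))
  for (f in setdiff(basename(files), "run_metadata.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # degraded mode: missing aggregation -> partial report with a gap note
  d3 <- withr::local_tempdir()
  files3 <- write_report(d3, rankings = list(e1 = r), vcurves = list(e1 = vc))
  expect_false("consensus_ranking.tsv" %in% basename(files3))
  meta <- jsonlite::read_json(file.path(d3, "run_metadata.json"))
  expect_match(meta$gaps, "aggregation")
})

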