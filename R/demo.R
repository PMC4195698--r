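#' The packaged 20-target reference panel
#'
#' Ten expressed-repeat-element (ERE) assays and ten classic protein-coding
#' reference genes commonly used in zebrafish work, with their designed
#' per-assay amplification efficiencies (percent) and the biological SDs
#' (log2 units) used by the demo generator. Two SD columns reflect the two
#' regimes the demo emulates: `sigma_dispersed` for conditions with strong
#' global expression remodelling (developmental time series, adult organs)
#' and `sigma_perturbation` for milder treatment experiments (morpholino
#' injections, compound exposure). EREs are designed stable in both regimes;
#' classic genes drift in the dispersed regime, with `gapdh` deliberately
#' the least stable assay of the panel.
#'
#' @return data.frame with columns `target`, `family` (`"ERE"`/`"classic"`),
#'   `efficiency_percent`, `sigma_dispersed`, `sigma_perturbation`.
#' @export
reference_panel <- function() {
  data.frame(
    target = c("tc1n1", "dna11ta1", "tdr7", "dna15ta1", "cr1-1",
               "hatn8", "hatn10", "hatn4", "loopern4", "sine3",
               "tuba1", "tbp", "b2m", "elfa", "cyp19a1b",
               "bactin2", "rpl13a", "hprt1", "rps18", "gapdh"),
    family = rep(c("ERE", "classic"), each = 10L),
    efficiency_percent = c(103.5, 107.6, 102.2, 101.1, 101.2,
                           102.4, 104.3, 105.0, 109.5, 101.4,
                           107.7, 95.4, 94.6, 106.0, 101.5,
                           99.3, 91.2, 95.7, 98.7, 102.5),
    sigma_dispersed = c(0.18, 0.20, 0.20, 0.12, 0.22,
                        0.22, 0.10, 0.25, 0.13, 0.45,
                        0.65, 0.55, 0.70, 0.50, 0.75,
                        0.45, 0.60, 0.60, 0.40, 1.30),
    sigma_perturbation = c(0.10, 0.12, 0.12, 0.08, 0.14,
                           0.14, 0.06, 0.15, 0.09, 0.22,
                           0.28, 0.22, 0.30, 0.20, 0.30,
                           0.18, 0.25, 0.24, 0.16, 0.35),
    stringsAsFactors = FALSE)
}

demo_targets <- function(regime = c("dispersed", "perturbation"),
                         goi = NULL, goi_sigma = 0.1) {
  regime <- match.arg(regime)
  panel <- reference_panel()
  tg <- data.frame(target = panel$target,
                   amplification_factor = 1 + panel$efficiency_percent / 100,
                   baseline_cq = seq(18, 28, length.out = nrow(panel)),
                   sigma_bio = if (regime == "dispersed") panel$sigma_dispersed
                               else panel$sigma_perturbation,
                   stable = panel$family == "ERE",
                   stringsAsFactors = FALSE)
  if (!is.null(goi)) {
    tg <- rbind(tg, data.frame(target = goi, amplification_factor = 2,
                               baseline_cq = 24, sigma_bio = goi_sigma,
                               stable = FALSE, stringsAsFactors = FALSE))
  }
  tg
}

#' Experiment designs for the six-experiment demo emulation
#'
#' Builds the six [cq_design()] objects the demo pipeline runs: a
#' developmental time series (10 time points, triplicate pools) with a
#' maternally deposited gene of interest (`zorba`-like, 20-fold higher at
#' the first time point) and maternally elevated classic reference genes; a
#' set of adult organs (7 organs, duplicate fish) with an eye-enriched gene
#' of interest (`pax6a`-like, 1.25-fold eye over brain); two morpholino
#' experiments and two compound experiments (3 treated vs 3 control pools)
#' with an `acta2`-like response gene. See [reference_panel()] for the
#' stability design of the 20 reference targets.
#'
#' @param seed master seed; each experiment derives its own sub-seed.
#' @return named list of six `cq_design` objects with attribute `goi`
#'   (gene-of-interest name or NA) on each element.
#' @export
demo_designs <- function(seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  sub <- function(i) (seed * 101L + i) %% .Machine$integer.max

  ts_groups <- c("t000", "t008", "t024", "t048", "t072", "t096",
                 "d06", "d08", "d10", "d12")
  ts_tg <- demo_targets("dispersed", goi = "zorba")
  ts_fc <- matrix(1, nrow(ts_tg), length(ts_groups),
                  dimnames = list(ts_tg$target, ts_groups))
  ts_fc["zorba", "t000"] <- 20     # maternal transcript, gone after MBT
  ts_fc["gapdh", "t000"] <- 10     # maternally elevated classic references
  ts_fc["bactin2", "t000"] <- 6
  ts_fc["elfa", "t000"] <- 5
  time_series <- cq_design(ts_tg, ts_groups, n_per_group = 3L,
                           fold_changes = ts_fc, sigma_content = 0.5,
                           sigma_tech = 0.15, n_replicates = 2L,
                           seed = sub(1L))
  attr(time_series, "goi") <- "zorba"

  organ_groups <- c("eye", "brain", "skin", "testis", "liver",
                    "intestine", "ovary")
  org_tg <- demo_targets("dispersed", goi = "pax6a")
  org_fc <- matrix(1, nrow(org_tg), length(organ_groups),
                   dimnames = list(org_tg$target, organ_groups))
  org_fc["pax6a", "eye"] <- 1.25
  organs <- cq_design(org_tg, organ_groups, n_per_group = 2L,
                      fold_changes = org_fc, sigma_content = 0.8,
                      sigma_tech = 0.15, n_replicates = 2L, seed = sub(2L))
  attr(organs, "goi") <- "pax6a"

  pert <- function(goi_fc, i) {
    tg <- demo_targets("perturbation", goi = "acta2")
    fc <- matrix(1, nrow(tg), 2L,
                 dimnames = list(tg$target, c("treated", "control")))
    fc["acta2", "treated"] <- goi_fc
    d <- cq_design(tg, c("treated", "control"), n_per_group = 3L,
                   fold_changes = fc, sigma_content = 0.3,
                   sigma_tech = 0.15, n_replicates = 2L, seed = sub(i))
    attr(d, "goi") <- "acta2"
    d
  }
  list(time_series = time_series,
       organs = organs,
       mo_slc2a10 = pert(1.3, 3L),
       mo_chordin = pert(1.0, 4L),
       tgfbri = pert(3.0, 5L),
       warfarin = pert(1.2, 6L))
}

#' Run the full demo pipeline: simulate, quantify, rank, aggregate, compare
#'
#' Chains every stage of the package on the six-experiment emulation:
#' per-assay dilution series and efficiency estimation, Cq simulation,
#' replicate collapse, efficiency-corrected quantification, geNorm ranking
#' and V curve per experiment, cross-experiment rank aggregation (Borda and
#' cross-entropy), the ERE-vs-classic stability comparison, and the
#' normalization-bias fold-change table. Deterministic given `seed`.
#'
#' @param seed master seed.
#' @param dir optional report directory; when given, [write_report()] emits
#'   the full table set there.
#' @param ce_args list of overrides passed to [aggregate_ce()].
#' @return list with `efficiencies`, `experiments` (per experiment: `cq`,
#'   `truth`, `Q`, `ranking`, `vcurve`), `lists` (the [ranked_lists()]
#'   input), `borda`, `consensus` (cross-entropy result), `stability_test`,
#'   `median_m` (per target across experiments), `fold_changes`
#'   (data.frame), `files` (report files or NULL), `seed`.
#' @export
run_demo <- function(seed = 1L, dir = NULL, ce_args = list()) {
  seed <- check_count(seed, "seed", min = 0L)
  panel <- reference_panel()
  refs <- panel$target

  # efficiency estimation from simulated dilution series, one per assay
  eff <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    s <- make_dilution_series(1 + panel$efficiency_percent[i] / 100,
                              top_cq = 20, sigma_tech = 0.05,
                              n_replicates = 2L,
                              seed = (seed * 131L + i) %% .Machine$integer.max,
                              target = panel$target[i])
    efficiency_from_dilution(s)
  }))
  # genes of interest quantified at assumed perfect doubling
  eff <- rbind(eff, efficiency_table(c("zorba", "pax6a", "acta2"),
                                     rep(100, 3L), source = "assumed"))

  designs <- demo_designs(seed)
  experiments <- lapply(designs, function(d) {
    sim <- generate_cq_dataset(d)
    collapsed <- collapse_replicates(sim$cq)
    Q <- cq_to_relative_quantity(collapsed, eff)
    ranking <- rank_targets(Q[, refs])
    vc <- v_curve(Q[, refs], ranking)
    list(cq = sim$cq, truth = sim$truth, Q = Q, ranking = ranking,
         vcurve = vc, goi = attr(d, "goi"))
  })

  lists <- ranked_lists(
    lapply(experiments, function(e) e$ranking$ranking$target),
    lapply(experiments, function(e) {
      stats::setNames(e$ranking$ranking$M, e$ranking$ranking$target)
    }))
  borda_res <- borda(lists)
  consensus <- do.call(aggregate_ce,
                       c(list(rls = lists, seed = seed), ce_args))

  med_m <- aggregate_median_m(lapply(experiments, function(e) e$ranking))
  # family comparison pools every per-experiment M-value, so both the
  # location and the across-condition dispersion of each family are compared
  m_pooled <- unlist(lapply(names(experiments), function(nm) {
    r <- experiments[[nm]]$ranking$ranking
    stats::setNames(r$M, paste(r$target, nm, sep = "@"))
  }))
  fam <- stats::setNames(panel$family, panel$target)
  membership <- stats::setNames(fam[sub("@.*", "", names(m_pooled))],
                                names(m_pooled))
  stab <- group_stability_test(m_pooled, membership)

  ere_refs <- c("hatn10", "dna15ta1", "loopern4")
  classic_refs <- c("gapdh", "bactin2", "elfa")
  fc_rows <- list()
  cases <- list(list("time_series", "zorba", "t000", "t008"),
                list("organs", "pax6a", "eye", "brain"),
                list("mo_slc2a10", "acta2", "treated", "control"),
                list("tgfbri", "acta2", "treated", "control"))
  for (cs in cases) {
    Q <- experiments[[cs[[1]]]]$Q
    for (set_name in c("ERE", "classic")) {
      r <- if (set_name == "ERE") ere_refs else classic_refs
      fc <- fold_change(Q, cs[[2]], r, cs[[3]], cs[[4]])
      fc_rows[[length(fc_rows) + 1L]] <- data.frame(
        experiment = cs[[1]], goi = cs[[2]], reference_set = set_name,
        group_a = cs[[3]], group_b = cs[[4]],
        fold_change = fc$fold_change, stringsAsFactors = FALSE)
    }
  }
  fold_changes <- do.call(rbind, fc_rows)

  files <- NULL
  if (!is.null(dir)) {
    files <- write_report(dir,
                          rankings = lapply(experiments, `[[`, "ranking"),
                          vcurves = lapply(experiments, `[[`, "vcurve"),
                          consensus = consensus,
                          fold_changes = fold_changes,
                          metadata = list(seed = seed,
                                          design = "six-experiment synthetic emulation"))
  }
  list(efficiencies = eff, experiments = experiments, lists = lists,
       borda = borda_res, consensus = consensus, stability_test = stab,
       median_m = med_m, fold_changes = fold_changes, files = files,
       seed = seed)
}
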