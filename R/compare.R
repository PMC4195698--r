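#' Fold change of a gene of interest between two groups under a reference set
#'
#' Normalizes the gene of interest by the per-sample geometric mean of the
#' reference targets' quantities, summarises each group (geometric mean by
#' default) and returns the ratio of the two group summaries. On noiseless
#' data with references whose own expression changes, the measured fold
#' change obeys the bias law
#' \eqn{FC_{meas} = FC_{true}(goi) / \mathrm{geomean}_{ref}(FC_{true}(ref))}
#' — an unstable reference set silently rescales every result.
#'
#' @param Q relative-quantity matrix with group labels
#'   (`attr(Q, "groups")`), or pass `groups` explicitly.
#' @param goi gene-of-interest target name (not among `refs`).
#' @param refs nonempty character vector of reference targets.
#' @param group_a,group_b group labels; the fold change is A over B.
#' @param groups optional per-sample group labels overriding the attribute.
#' @param summary group summary on the normalized quantities:
#'   `"geometric"` (default) or `"arithmetic"` mean.
#' @return list with `fold_change`, `goi`, `refs`, `groups` (the pair) and
#'   `normalized` (per-sample normalized quantities).
#' @export
fold_change <- function(Q, goi, refs, group_a, group_b, groups = NULL,
                        summary = c("geometric", "arithmetic")) {
  Q <- as_rq_matrix(Q)
  summary <- match.arg(summary)
  if (length(refs) < 1L) stop("need >= 1 reference target")
  if (goi %in% refs) stop("gene of interest must not be a reference")
  if (is.null(groups)) groups <- rq_groups(Q)
  if (is.null(groups)) stop("no group labels available")
  if (!all(c(group_a, group_b) %in% groups)) stop("empty group")
  gi <- resolve_target(Q, goi)
  ri <- vapply(refs, function(t) resolve_target(Q, t), 1L)
  nf <- apply(Q[, ri, drop = FALSE], 1L, geomean)
  normalized <- Q[, gi] / nf
  summarise <- if (summary == "geometric") geomean else mean
  fc <- summarise(normalized[groups == group_a]) /
    summarise(normalized[groups == group_b])
  list(fold_change = fc, goi = goi, refs = refs,
       groups = c(group_a, group_b), normalized = normalized)
}

#' Compare M-value location and spread between two reference-target groups
#'
#' Tests whether one family of reference targets (e.g. expressed repeats) is
#' more stable than another (e.g. classic protein-coding reference genes):
#' an equal-variance two-sample t-test on the M-values for location, and a
#' Brown-Forsythe-style equal-variance t-test on absolute deviations from
#' each group's median for spread. Medians, IQRs and SDs are reported per
#' group.
#'
#' @param M named numeric vector of M-values (pooled across experiments).
#' @param membership named character vector assigning each target to one of
#'   exactly two groups.
#' @return list with `summary` (per-group data.frame: n, median, IQR, SD),
#'   `location` (htest) and `spread` (htest).
#' @export
group_stability_test <- function(M, membership) {
  if (is.null(names(M)) || is.null(names(membership))) {
    stop("M and membership must be named by target")
  }
  membership <- membership[names(M)]
  if (anyNA(membership)) stop("every M-value needs a group membership")
  groups <- unique(membership)
  if (length(groups) != 2L) stop("membership must define exactly two groups")
  split_m <- split(unname(M), factor(membership, levels = groups))
  if (any(lengths(split_m) < 2L)) stop("need >= 2 targets per group")
  loc <- stats::t.test(split_m[[1]], split_m[[2]], var.equal = TRUE)
  absdev <- lapply(split_m, function(x) abs(x - stats::median(x)))
  spr <- stats::t.test(absdev[[1]], absdev[[2]], var.equal = TRUE)
  summ <- data.frame(group = groups,
                     n = lengths(split_m),
                     median_M = vapply(split_m, stats::median, 1),
                     iqr_M = vapply(split_m, stats::IQR, 1),
                     sd_M = vapply(split_m, stats::sd, 1),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(summary = summ, location = loc, spread = spr)
}

#' Write the run's report tables
#'
#' Emits a deterministic file set: one ranking table per experiment, their V
#' curves, the aggregated consensus, the fold-change comparison table, and a
#' run-metadata JSON (inputs, configuration, seed, package version). When
#' the aggregation result is absent a partial report is written and the gap
#' recorded in the metadata.
#'
#' @param dir output directory (created if needed).
#' @param rankings named list of `genorm_ranking` objects, one per
#'   experiment.
#' @param vcurves named list of [v_curve()] results aligned to `rankings`.
#' @param consensus an `aggregated_ranking`, or `NULL` (degraded mode).
#' @param fold_changes data.frame of fold-change comparisons, or `NULL`.
#' @param metadata named list merged into the metadata file (e.g. seed,
#'   design description).
#' @return invisibly, the character vector of files written.
#' @export
write_report <- function(dir, rankings, vcurves = NULL, consensus = NULL,
                         fold_changes = NULL, metadata = list()) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create report directory '%s'", dir))
  }
  files <- character(0)
  rank_tab <- do.call(rbind, lapply(names(rankings), function(nm) {
    cbind(experiment = nm, rankings[[nm]]$ranking)
  }))
  f <- file.path(dir, "stability_rankings.tsv")
  write_tsv(rank_tab, f); files <- c(files, f)

  if (!is.null(vcurves)) {
    v_tab <- do.call(rbind, lapply(names(vcurves), function(nm) {
      data.frame(experiment = nm, pair = names(vcurves[[nm]]$v),
                 v = unname(vcurves[[nm]]$v),
                 optimal_n = vcurves[[nm]]$optimal_n,
                 stringsAsFactors = FALSE)
    }))
    f <- file.path(dir, "v_curves.tsv")
    write_tsv(v_tab, f); files <- c(files, f)
  }

  gap <- NULL
  if (!is.null(consensus)) {
    cons_tab <- data.frame(target = consensus$consensus,
                           consensus_rank = seq_along(consensus$consensus),
                           stringsAsFactors = FALSE)
    med_m <- aggregate_median_m(rankings)
    cons_tab$median_M <- unname(med_m[cons_tab$target])
    f <- file.path(dir, "consensus_ranking.tsv")
    write_tsv(cons_tab, f); files <- c(files, f)
    if (!is.null(consensus$trace)) {
      f <- file.path(dir, "aggregation_trace.tsv")
      write_tsv(consensus$trace, f); files <- c(files, f)
    }
  } else {
    gap <- "aggregation result missing: consensus tables not written"
  }

  if (!is.null(fold_changes)) {
    f <- file.path(dir, "fold_change_comparison.tsv")
    write_tsv(fold_changes, f); files <- c(files, f)
  }

  meta <- c(list(package = "erenorm",
                 version = as.character(utils::packageVersion("erenorm")),
                 experiments = names(rankings),
                 files = basename(files)),
            if (!is.null(gap)) list(gaps = gap),
            metadata)
  f <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, f, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, f)
  invisible(files)
}

aggregate_median_m <- function(rankings) {
  all_m <- lapply(rankings, function(r) {
    stats::setNames(r$ranking$M, r$ranking$target)
  })
  targets <- unique(unlist(lapply(all_m, names)))
  vapply(targets, function(t) {
    stats::median(unlist(lapply(all_m, function(m) m[[t]])), na.rm = TRUE)
  }, 1)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
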