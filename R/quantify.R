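#' Collapse technical replicates on the Cq scale
#'
#' Averages replicate wells per (sample, target) arithmetically on the Cq
#' scale (the near-Gaussian scale for qPCR noise) and retains the replicate
#' SD and count as quality metadata.
#'
#' @param cq long-format Cq data.frame with columns `sample`, `target`, `cq`,
#'   and optionally `group` and `replicate`.
#' @return data.frame with one row per (sample, target): columns `sample`,
#'   `group` (if present), `target`, `cq`, `cq_sd` (NA for single wells),
#'   `n_replicates`.
#' @export
collapse_replicates <- function(cq) {
  check_cq_frame(cq)
  keys <- c("sample", if ("group" %in% names(cq)) "group", "target")
  agg <- stats::aggregate(cq$cq, by = cq[keys], FUN = mean)
  names(agg)[ncol(agg)] <- "cq"
  sds <- stats::aggregate(cq$cq, by = cq[keys],
                          FUN = function(x) if (length(x) > 1L) stats::sd(x) else NA_real_)
  ns <- stats::aggregate(cq$cq, by = cq[keys], FUN = length)
  agg$cq_sd <- sds$x
  agg$n_replicates <- ns$x
  agg[order(agg$target, agg$sample), , drop = FALSE]
}

check_cq_frame <- function(cq) {
  if (!is.data.frame(cq) || !all(c("sample", "target", "cq") %in% names(cq))) {
    stop("Cq data must be a data.frame with columns sample, target, cq")
  }
  if (any(!is.finite(cq$cq))) stop("all Cq values must be finite")
  invisible(cq)
}

#' Estimate amplification efficiency from a standard dilution series
#'
#' Fits the least-squares slope \eqn{b} of Cq versus \eqn{\log_{10}} input
#' quantity and converts it to a percent efficiency
#' \eqn{e = (10^{-1/b} - 1) \times 100}; a slope of \eqn{-3.3219} corresponds
#' to perfect doubling (100%). Values outside the conventional 90--110%
#' acceptance window are flagged.
#'
#' @param series data.frame with columns `quantity` (ng, > 0) and `cq`;
#'   replicate rows per quantity are allowed. An optional `target` column
#'   names the assay.
#' @param range acceptance window for the efficiency flag (percent).
#' @return one-row data.frame: `target`, `slope`, `r2`,
#'   `efficiency_percent`, `amplification_factor`, `in_range`, `source`.
#' @export
efficiency_from_dilution <- function(series, range = c(90, 110)) {
  if (!is.data.frame(series) || !all(c("quantity", "cq") %in% names(series))) {
    stop("series must have columns quantity and cq")
  }
  if (any(!is.finite(series$cq))) stop("all Cq values must be present and finite")
  if (any(series$quantity <= 0)) stop_field("quantity", "must be > 0")
  if (length(unique(series$quantity)) < 3L) {
    stop("need >= 3 distinct dilution points")
  }
  fit <- stats::lm(cq ~ log10(quantity), data = series)
  b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || b >= 0) {
    stop("non-amplifying series: slope of Cq vs log10(quantity) must be negative")
  }
  eff <- (10^(-1 / b) - 1) * 100
  # R^2 computed directly; summary.lm warns on exactly collinear (noiseless) fits
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((series$cq - mean(series$cq))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  data.frame(target = if ("target" %in% names(series)) series$target[1] else "assay",
             slope = b, r2 = r2,
             efficiency_percent = eff,
             amplification_factor = 1 + eff / 100,
             in_range = eff >= range[1] & eff <= range[2],
             source = "dilution-series", stringsAsFactors = FALSE)
}

#' Assemble an efficiency table from externally supplied percentages
#'
#' @param target target names.
#' @param efficiency_percent per-target efficiencies (percent; 100 =
#'   doubling).
#' @param source provenance tag recorded per row.
#' @param range acceptance window for the `in_range` flag.
#' @return data.frame with the same columns as [efficiency_from_dilution()]
#'   (slope and r2 are NA for external values).
#' @export
efficiency_table <- function(target, efficiency_percent, source = "external",
                             range = c(90, 110)) {
  if (length(target) != length(efficiency_percent)) {
    stop("target and efficiency_percent lengths differ")
  }
  if (any(!is.finite(efficiency_percent)) || any(efficiency_percent <= 0)) {
    stop_field("efficiency_percent", "must be finite and > 0 (F_t > 1)")
  }
  data.frame(target = as.character(target), slope = NA_real_, r2 = NA_real_,
             efficiency_percent = efficiency_percent,
             amplification_factor = 1 + efficiency_percent / 100,
             in_range = efficiency_percent >= range[1] &
               efficiency_percent <= range[2],
             source = source, stringsAsFactors = FALSE)
}

#' Convert Cq values to efficiency-corrected relative quantities
#'
#' Applies the standard transformation
#' \eqn{Q_{s,t} = F_t^{\min_{s'} Cq_{s',t} - Cq_{s,t}}}: the sample with the
#' lowest Cq per target gets quantity 1 and every other sample a fraction of
#' it. The min-Cq reference keeps \eqn{Q \le 1} and is irrelevant for
#' downstream ratio statistics. Efficiency-corrected Cq values produced by
#' per-well tools can be converted with `efficiencies = NULL`, which applies
#' \eqn{F_t = 2} throughout.
#'
#' @param cq collapsed Cq data.frame (one row per sample x target; see
#'   [collapse_replicates()]).
#' @param efficiencies an efficiency table ([efficiency_table()] or rows of
#'   [efficiency_from_dilution()]) covering every target, or `NULL` for
#'   \eqn{F_t = 2}.
#' @param missing policy for (sample, target) cells with no Cq: `"error"`
#'   (default; a complete matrix is required for geNorm) or `"drop_sample"`
#'   (remove samples with any missing cell).
#' @return numeric matrix (samples x targets) of relative quantities in
#'   (0, 1], with per-sample group labels in `attr(,"groups")` when the input
#'   has a `group` column.
#' @export
cq_to_relative_quantity <- function(cq, efficiencies = NULL,
                                    missing = c("error", "drop_sample")) {
  check_cq_frame(cq)
  missing <- match.arg(missing)
  if (anyDuplicated(cq[c("sample", "target")])) {
    stop("multiple rows per (sample, target): collapse replicates first")
  }
  samples <- unique(cq$sample)
  targets <- unique(cq$target)
  M <- matrix(NA_real_, length(samples), length(targets),
              dimnames = list(samples, targets))
  M[cbind(match(cq$sample, samples), match(cq$target, targets))] <- cq$cq
  if (anyNA(M)) {
    if (missing == "error") {
      bad <- which(is.na(M), arr.ind = TRUE)
      stop(sprintf("missing Cq for %d (sample, target) cells, e.g. %s / %s",
                   nrow(bad), samples[bad[1, 1]], targets[bad[1, 2]]))
    }
    keep <- rowSums(is.na(M)) == 0L
    if (!any(keep)) stop("no complete samples left after dropping")
    M <- M[keep, , drop = FALSE]
    samples <- samples[keep]
  }
  if (is.null(efficiencies)) {
    Fv <- rep(2, length(targets))
  } else {
    idx <- match(targets, efficiencies$target)
    if (anyNA(idx)) {
      stop(sprintf("no efficiency for target(s): %s",
                   paste(targets[is.na(idx)], collapse = ", ")))
    }
    Fv <- efficiencies$amplification_factor[idx]
  }
  Q <- vapply(seq_along(targets),
              function(j) Fv[j]^(min(M[, j]) - M[, j]),
              numeric(nrow(M)))
  if (nrow(M) == 1L) Q <- matrix(Q, nrow = 1L)
  dimnames(Q) <- list(samples, targets)
  groups <- NULL
  if ("group" %in% names(cq)) {
    groups <- cq$group[match(samples, cq$sample)]
  }
  as_rq_matrix(Q, groups)
}
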