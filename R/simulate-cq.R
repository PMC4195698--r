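#' Design of a synthetic RT-qPCR experiment
#'
#' Describes a Cq-level simulation: a panel of targets (each with its own
#' amplification factor, baseline Cq, biological variability and group-wise
#' fold changes), a group layout, and noise levels. The generative model is
#'
#' \deqn{Q_{s,t} = FC_{g(s),t} \cdot 2^{u_s} \cdot 2^{b_{s,t}}, \quad
#'       Cq_{s,t,r} = c_t - \log_{F_t}(Q_{s,t}) + \epsilon_{s,t,r}}
#'
#' with \eqn{u_s \sim N(0, \sigma_{content})} a shared per-sample mRNA-content
#' factor (the global input variation a good normalizer must cancel),
#' \eqn{b_{s,t} \sim N(0, \sigma_{bio,t})} target-specific biological
#' variability, both in log2 units, and \eqn{\epsilon \sim N(0, \sigma_{tech})}
#' technical well noise in cycles. Technical replicates share \eqn{Q_{s,t}} and
#' differ only by \eqn{\epsilon}, mirroring replicate wells of one cDNA.
#'
#' @param targets data.frame with columns `target` (unique names),
#'   `amplification_factor` (per-cycle gain \eqn{F_t > 1}; 2 = perfect
#'   doubling, realistic assays fall in roughly 1.9--2.1), `baseline_cq`
#'   (cycles) and `sigma_bio` (per-target biological SD, log2 units). An
#'   optional logical column `stable` marks the designed stable set; if
#'   absent, targets with `sigma_bio <= 0.2` are recorded as stable.
#' @param groups character vector of group labels.
#' @param n_per_group samples per group (single count, >= 1).
#' @param fold_changes optional numeric matrix (targets x groups) of positive
#'   expression fold changes relative to the panel baseline; defaults to 1.
#' @param sigma_content SD of the shared per-sample content factor (log2
#'   units, >= 0).
#' @param sigma_tech technical replicate SD (cycles, >= 0).
#' @param n_replicates technical replicates per well (>= 1).
#' @param seed integer seed making the dataset reproducible.
#' @return An object of class `cq_design`.
#' @export
cq_design <- function(targets, groups, n_per_group,
                      fold_changes = NULL,
                      sigma_content = 0, sigma_tech = 0,
                      n_replicates = 1L, seed = 1L) {
  if (!is.data.frame(targets) ||
      !all(c("target", "amplification_factor", "baseline_cq", "sigma_bio")
           %in% names(targets))) {
    stop_field("targets",
               "need columns target, amplification_factor, baseline_cq, sigma_bio")
  }
  targets$target <- as.character(targets$target)
  if (anyDuplicated(targets$target)) stop_field("targets", "target names must be unique")
  if (any(!is.finite(targets$amplification_factor)) ||
      any(targets$amplification_factor <= 1)) {
    stop_field("amplification_factor", "every F_t must be > 1")
  }
  if (any(!is.finite(targets$sigma_bio)) || any(targets$sigma_bio < 0)) {
    stop_field("sigma_bio", "must be >= 0")
  }
  if (any(!is.finite(targets$baseline_cq))) {
    stop_field("baseline_cq", "must be finite")
  }
  groups <- as.character(groups)
  if (length(groups) < 1L || anyDuplicated(groups)) {
    stop_field("groups", "need >= 1 unique group label")
  }
  n_per_group <- check_count(n_per_group, "n_per_group", min = 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  check_scalar_number(sigma_content, "sigma_content", lower = 0)
  check_scalar_number(sigma_tech, "sigma_tech", lower = 0)
  seed <- check_count(seed, "seed", min = 0L)

  nt <- nrow(targets)
  if (is.null(fold_changes)) {
    fold_changes <- matrix(1, nt, length(groups),
                           dimnames = list(targets$target, groups))
  } else {
    if (!is.matrix(fold_changes) || nrow(fold_changes) != nt ||
        ncol(fold_changes) != length(groups)) {
      stop_field("fold_changes", "must be a targets x groups matrix")
    }
    if (is.null(rownames(fold_changes))) rownames(fold_changes) <- targets$target
    if (is.null(colnames(fold_changes))) colnames(fold_changes) <- groups
    fold_changes <- fold_changes[targets$target, groups, drop = FALSE]
    if (any(!is.finite(fold_changes)) || any(fold_changes <= 0)) {
      stop_field("fold_changes", "must be finite and > 0")
    }
  }
  if (is.null(targets$stable)) targets$stable <- targets$sigma_bio <= 0.2

  structure(list(targets = targets, groups = groups,
                 n_per_group = n_per_group, fold_changes = fold_changes,
                 sigma_content = sigma_content, sigma_tech = sigma_tech,
                 n_replicates = n_replicates, seed = seed),
            class = "cq_design")
}

#' Generate a synthetic Cq dataset with recorded ground truth
#'
#' Draws per-sample content factors, per-(sample, target) biological effects
#' and per-well technical noise under the model documented in [cq_design()],
#' and returns both the long-format Cq table and a truth record holding the
#' designed quantities.
#'
#' @param design a [cq_design()] object.
#' @return A list with components
#'   \describe{
#'     \item{cq}{data.frame with columns `sample`, `group`, `target`,
#'       `replicate`, `cq`.}
#'     \item{truth}{list with `quantities` (true \eqn{Q_{s,t}} matrix, samples
#'       x targets), `content_log2` (the per-sample factors \eqn{u_s}),
#'       `sigma_bio`, `stable_targets`, `fold_changes` and the `design`.}
#'   }
#' @export
generate_cq_dataset <- function(design) {
  if (!inherits(design, "cq_design")) stop("design must be a cq_design object")
  tg <- design$targets
  nt <- nrow(tg)
  samples <- sprintf("%s_s%02d",
                     rep(design$groups, each = design$n_per_group),
                     rep(seq_len(design$n_per_group), length(design$groups)))
  grp <- rep(design$groups, each = design$n_per_group)
  ns <- length(samples)

  withr::with_seed(design$seed, {
    u <- stats::rnorm(ns, 0, design$sigma_content)
    b <- vapply(seq_len(nt),
                function(j) stats::rnorm(ns, 0, tg$sigma_bio[j]),
                numeric(ns))
    Q <- t(design$fold_changes[, grp, drop = FALSE]) * 2^u * 2^b
    dimnames(Q) <- list(samples, tg$target)

    rows <- expand.grid(replicate = seq_len(design$n_replicates),
                        sample = seq_len(ns), target = seq_len(nt),
                        KEEP.OUT.ATTRS = FALSE)
    base_cq <- tg$baseline_cq[rows$target] -
      log(Q[cbind(rows$sample, rows$target)]) /
      log(tg$amplification_factor[rows$target])
    eps <- stats::rnorm(nrow(rows), 0, design$sigma_tech)
    cq <- data.frame(sample = samples[rows$sample],
                     group = grp[rows$sample],
                     target = tg$target[rows$target],
                     replicate = rows$replicate,
                     cq = base_cq + eps,
                     stringsAsFactors = FALSE)
  })

  truth <- list(quantities = Q,
                content_log2 = stats::setNames(u, samples),
                sigma_bio = stats::setNames(tg$sigma_bio, tg$target),
                stable_targets = tg$target[tg$stable],
                fold_changes = design$fold_changes,
                design = design)
  list(cq = cq, truth = truth)
}

#' Simulate a standard dilution series
#'
#' Emulates the serial dilution used to estimate amplification efficiency:
#' \eqn{Cq(q) = top\_cq - \log_F(q / \max q) + \epsilon}. With the default
#' four-fold ladder 16, 4, 1, 0.25, 0.0625 ng and \eqn{F = 2} the Cq values
#' are spaced exactly 2 cycles per step.
#'
#' @param amplification_factor per-cycle gain \eqn{F > 1}.
#' @param top_cq Cq of the most concentrated point (cycles).
#' @param quantities input quantities (ng); >= 3 distinct positive values.
#' @param sigma_tech technical noise SD (cycles).
#' @param n_replicates replicate wells per dilution point.
#' @param seed integer seed.
#' @param target assay name attached to the series.
#' @return data.frame with columns `target`, `quantity`, `replicate`, `cq`.
#' @export
make_dilution_series <- function(amplification_factor, top_cq = 20,
                                 quantities = c(16, 4, 1, 0.25, 0.0625),
                                 sigma_tech = 0, n_replicates = 1L,
                                 seed = 1L, target = "assay") {
  check_scalar_number(amplification_factor, "amplification_factor",
                      lower = 1, strict_lower = TRUE)
  if (!is.numeric(quantities) || any(!is.finite(quantities)) ||
      any(quantities <= 0)) {
    stop_field("quantities", "must be strictly positive")
  }
  if (length(unique(quantities)) < 3L) {
    stop_field("quantities", "need >= 3 distinct values")
  }
  check_scalar_number(sigma_tech, "sigma_tech", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)

  q <- rep(quantities, each = n_replicates)
  cq0 <- top_cq - log(q / max(quantities)) / log(amplification_factor)
  withr::with_seed(seed, {
    eps <- stats::rnorm(length(q), 0, sigma_tech)
  })
  data.frame(target = target, quantity = q,
             replicate = rep(seq_len(n_replicates), length(quantities)),
             cq = cq0 + eps, stringsAsFactors = FALSE)
}
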