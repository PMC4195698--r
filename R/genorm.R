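#' Pairwise variation between two reference targets
#'
#' The geNorm pairwise variation \eqn{V_{jk}}: the sample standard deviation
#' (n-1 denominator) across samples of the log2 ratio of the two targets'
#' relative quantities. Two targets with a constant expression ratio — the
#' hallmark of two good references — have \eqn{V_{jk} = 0}.
#'
#' @param Q relative-quantity matrix (samples x targets), e.g. from
#'   [cq_to_relative_quantity()].
#' @param j,k target names or column indices; `j != k`.
#' @return \eqn{V_{jk}} (non-negative, symmetric in its arguments).
#' @export
pairwise_variation <- function(Q, j, k) {
  Q <- as_rq_matrix(Q)
  if (nrow(Q) < 3L) stop("need >= 3 samples for a stable SD")
  jj <- resolve_target(Q, j); kk <- resolve_target(Q, k)
  if (jj == kk) stop("j and k must be different targets")
  log_ratio_sd(Q[, jj], Q[, kk])
}

## SD of log2(x/y) across samples. The ratio is formed before the log and
## centred on the first sample so that shared per-sample factors and
## constant per-target factors cancel exactly in floating point (for
## power-of-two factors), not just in exact arithmetic; the centring leaves
## the SD unchanged mathematically.
log_ratio_sd <- function(x, y) {
  r <- x / y
  stats::sd(log2(r / r[1]))
}

resolve_target <- function(Q, t) {
  if (is.character(t)) {
    i <- match(t, colnames(Q))
    if (is.na(i)) stop(sprintf("unknown target '%s'", t))
    i
  } else as.integer(t)
}

#' geNorm expression-stability measure M for every target
#'
#' \eqn{M_j} is the arithmetic mean of the pairwise variations of target
#' \eqn{j} with all other targets:
#' \eqn{M_j = \frac{1}{n-1}\sum_{k \ne j} V_{jk}}. Lower M means more stable
#' expression relative to the rest of the panel.
#'
#' @inheritParams pairwise_variation
#' @return named numeric vector of M-values.
#' @export
m_values <- function(Q) {
  Q <- as_rq_matrix(Q)
  n <- ncol(Q)
  if (n < 3L) stop("need >= 3 targets to compute M")
  if (nrow(Q) < 3L) stop("need >= 3 samples for a stable SD")
  V <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      V[j, k] <- V[k, j] <- log_ratio_sd(Q[, j], Q[, k])
    }
  }
  stats::setNames(rowSums(V) / (n - 1L), colnames(Q))
}

#' Rank reference targets by stepwise exclusion of the least stable
#'
#' The geNorm ranking procedure: compute M on the current target set, remove
#' the target with the highest M, and repeat until two targets remain. The
#' final two targets cannot be separated (their M values are identical by
#' construction) and share the best rank. Ties in the argmax are broken by
#' the later position in the input column order.
#'
#' @inheritParams pairwise_variation
#' @return An object of class `genorm_ranking`: a list with
#'   \describe{
#'     \item{ranking}{data.frame `target`, `rank` (1..n; positions 1 and 2
#'       are the tied best pair), `M` (M at the round the target was
#'       excluded; for the final pair, their mutual pairwise variation),
#'       `category` (see [classify_stability()]).}
#'     \item{rounds}{list of named M vectors, one per exclusion round.}
#'     \item{excluded}{targets in exclusion order (least stable first).}
#'   }
#' @export
rank_targets <- function(Q) {
  Q <- as_rq_matrix(Q)
  if (ncol(Q) < 3L) stop("need >= 3 targets to rank")
  remaining <- colnames(Q)
  rounds <- list()
  excluded <- character(0)
  m_at_exclusion <- numeric(0)
  while (length(remaining) > 2L) {
    M <- m_values(Q[, remaining, drop = FALSE])
    rounds[[length(rounds) + 1L]] <- M
    worst <- max(M)
    # later input position wins ties
    out <- remaining[max(which(M == worst))]
    excluded <- c(excluded, out)
    m_at_exclusion <- c(m_at_exclusion, worst)
    remaining <- setdiff(remaining, out)
  }
  v_pair <- pairwise_variation(Q, remaining[1], remaining[2])
  # the tied pair is reported in lexicographic order so the ranking does not
  # depend on the input column order
  best_first <- c(sort(remaining, method = "radix"), rev(excluded))
  M_final <- c(v_pair, v_pair, rev(m_at_exclusion))
  ranking <- data.frame(target = best_first, rank = seq_along(best_first),
                        M = M_final,
                        category = classify_stability(M_final),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, rounds = rounds, excluded = excluded),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm stability ranking (", nrow(x$ranking), " targets; ranks 1-2 tied)\n",
      sep = "")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Normalization factors from the n best-ranked reference targets
#'
#' The per-sample normalization factor is the geometric mean of the relative
#' quantities of the chosen reference targets.
#'
#' @inheritParams pairwise_variation
#' @param targets reference targets in ranked order (best first).
#' @param n how many of the top-ranked targets to use (2 <= n <= length
#'   of `targets`).
#' @return named numeric vector NF(s) > 0, one entry per sample.
#' @export
normalization_factors <- function(Q, targets, n = length(targets)) {
  Q <- as_rq_matrix(Q)
  n <- check_count(n, "n", min = 2L)
  if (n > length(targets)) stop_field("n", "exceeds number of ranked targets")
  use <- vapply(targets[seq_len(n)], function(t) resolve_target(Q, t), 1L)
  apply(Q[, use, drop = FALSE], 1L, geomean)
}

#' Pairwise variation curve V(n/n+1) and the optimal reference count
#'
#' For increasing n, compares the normalization factors built from the n and
#' n+1 best-ranked targets: \eqn{V_{n/n+1}} is the sample SD across samples of
#' \eqn{\log_2(NF_n / NF_{n+1})}. A small V means the (n+1)-th target adds
#' little, so the optimal count is the smallest n with \eqn{V_{n/n+1}} below
#' the cutoff (0.15 by convention). If no n qualifies, the full panel size is
#' returned with a warning.
#'
#' @inheritParams pairwise_variation
#' @param ranking a `genorm_ranking` (from [rank_targets()]) or a character
#'   vector of targets in ranked order, best first.
#' @param cutoff V threshold below which adding another reference is not
#'   required.
#' @return list with `v` (named vector, names `"2/3"`, `"3/4"`, ...),
#'   `optimal_n`, and `cutoff`.
#' @export
v_curve <- function(Q, ranking, cutoff = 0.15) {
  Q <- as_rq_matrix(Q)
  ord <- if (inherits(ranking, "genorm_ranking")) ranking$ranking$target
         else as.character(ranking)
  if (length(ord) < 3L) stop("need >= 3 ranked targets for a V curve")
  check_scalar_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  nmax <- length(ord)
  v <- numeric(nmax - 2L)
  idx <- vapply(ord, function(t) resolve_target(Q, t), 1L)
  for (n in 2L:(nmax - 1L)) {
    # log2(NF_n / NF_{n+1}) = mean_{t<=n} log2(Q_t / Q_{n+1}) / (n+1);
    # ratios against the entering target are taken first and centred on the
    # first sample so shared factors cancel exactly (see log_ratio_sd)
    R <- Q[, idx[seq_len(n)], drop = FALSE] / Q[, idx[n + 1L]]
    R <- sweep(R, 2L, R[1L, ], "/")
    v[n - 1L] <- stats::sd(rowMeans(log2(R)) / (n + 1L))
  }
  names(v) <- sprintf("%d/%d", 2L:(nmax - 1L), 3L:nmax)
  below <- which(v < cutoff)
  if (length(below)) {
    optimal_n <- unname(below[1]) + 1L
  } else {
    warning("no V(n/n+1) below cutoff; returning the full panel size")
    optimal_n <- nmax
  }
  list(v = v, optimal_n = optimal_n, cutoff = cutoff)
}

#' Qualitative stability category of an M-value
#'
#' M below 0.2 counts as very-high stability, below 0.5 as high, anything
#' else as low.
#'
#' @param M numeric vector of M-values (>= 0).
#' @return character vector in `{"very-high", "high", "low"}`.
#' @export
classify_stability <- function(M) {
  if (any(!is.finite(M)) || any(M < 0)) stop("M-values must be finite and >= 0")
  ifelse(M < 0.2, "very-high", ifelse(M < 0.5, "high", "low"))
}
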