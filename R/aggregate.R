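#' Bundle ranked reference-target lists from several experiments
#'
#' @param lists list of character vectors; every list must be a permutation
#'   of one common target universe (best-ranked first).
#' @param weights optional list of numeric vectors, one per list, giving a
#'   per-target stability weight (M-values: lower = more stable). Each vector
#'   must be named by target or aligned to its list's order. `NULL` means
#'   unweighted aggregation.
#' @return An object of class `ranked_lists` with elements `lists` (each a
#'   character vector), `weights` (named numeric vectors or `NULL`) and
#'   `universe` (targets in first-list order).
#' @export
ranked_lists <- function(lists, weights = NULL) {
  if (!is.list(lists) || length(lists) < 1L) stop("need >= 1 ranked list")
  lists <- lapply(lists, as.character)
  universe <- lists[[1]]
  if (anyDuplicated(universe)) stop("lists must not contain duplicates")
  for (l in lists) {
    if (length(l) != length(universe) || !setequal(l, universe)) {
      stop("all lists must be permutations of one common target universe")
    }
  }
  if (!is.null(weights)) {
    if (!is.list(weights) || length(weights) != length(lists)) {
      stop("need one weight vector per list")
    }
    weights <- lapply(seq_along(weights), function(i) {
      w <- weights[[i]]
      if (is.null(names(w))) names(w) <- lists[[i]]
      if (!setequal(names(w), universe)) {
        stop("weight names must match the target universe")
      }
      if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
      w[universe]
    })
  }
  structure(list(lists = lists, weights = weights, universe = universe),
            class = "ranked_lists")
}

## Element weights for one list: low M -> high importance, min-max normalized.
## A constant weight vector maps to 1 for every target (unweighted footrule).
normalized_importance <- function(w, universe) {
  if (is.null(w)) return(stats::setNames(rep(1, length(universe)), universe))
  rng <- range(w)
  if (rng[2] == rng[1]) return(stats::setNames(rep(1, length(w)), names(w)))
  (rng[2] - w) / (rng[2] - rng[1])
}

#' Weighted Spearman footrule distance between two orderings
#'
#' \eqn{d = \sum_t \tilde w(t)\,|r_{cand}(t) - r_{ref}(t)|} where the
#' element importance \eqn{\tilde w(t) = (w_{max} - w(t))/(w_{max} -
#' w_{min})} maps a low stability weight (low M) to high importance. With
#' constant weights this reduces to the classic unweighted footrule.
#'
#' @param candidate,reference character vectors: permutations of the same
#'   universe, best rank first.
#' @param weights named per-target weight vector (M-values) or `NULL` for
#'   the unweighted footrule.
#' @return non-negative distance; 0 iff the orderings agree (or every
#'   importance vanishes).
#' @export
ws_distance <- function(candidate, reference, weights = NULL) {
  if (!setequal(candidate, reference) ||
      length(candidate) != length(reference)) {
    stop("candidate and reference must be permutations of the same universe")
  }
  wt <- normalized_importance(weights, reference)
  r_cand <- match(names(wt), candidate)
  r_ref <- match(names(wt), reference)
  sum(wt * abs(r_cand - r_ref))
}

#' Aggregation objective: total footrule distance to all lists
#'
#' \eqn{\Phi(\delta) = \sum_i d(\delta, L_i; w_i)} — the quantity the
#' consensus ordering minimises.
#'
#' @param candidate character permutation of the universe.
#' @param rls a [ranked_lists()] object.
#' @return \eqn{\Phi \ge 0}.
#' @export
footrule_objective <- function(candidate, rls) {
  stopifnot(inherits(rls, "ranked_lists"))
  s <- 0
  for (i in seq_along(rls$lists)) {
    s <- s + ws_distance(candidate, rls$lists[[i]],
                         if (is.null(rls$weights)) NULL else rls$weights[[i]])
  }
  s
}

new_aggregated_ranking <- function(consensus, phi, method, trace = NULL,
                                   seed = NA_integer_) {
  structure(list(consensus = consensus, phi = phi, method = method,
                 trace = trace, seed = seed),
            class = "aggregated_ranking")
}

#' @export
print.aggregated_ranking <- function(x, ...) {
  cat(sprintf("Consensus ranking (%s), Phi = %.4g\n", x$method, x$phi))
  cat(paste(seq_along(x$consensus), x$consensus, collapse = " > "), "\n")
  invisible(x)
}

#' Borda-count consensus ranking
#'
#' Orders targets by their mean rank position across lists. Ties are broken
#' by ascending mean weight (more stable first) and then by universe order.
#'
#' @param rls a [ranked_lists()] object.
#' @return An `aggregated_ranking` with the Borda ordering and its
#'   [footrule_objective()] value.
#' @export
borda <- function(rls) {
  stopifnot(inherits(rls, "ranked_lists"))
  universe <- rls$universe
  ranks <- vapply(rls$lists, function(l) match(universe, l),
                  numeric(length(universe)))
  mean_rank <- if (is.matrix(ranks)) rowMeans(ranks) else ranks
  mean_w <- if (is.null(rls$weights)) rep(0, length(universe)) else
    rowMeans(vapply(rls$weights, function(w) w[universe],
                    numeric(length(universe))))
  ord <- order(mean_rank, mean_w, seq_along(universe))
  consensus <- universe[ord]
  res <- new_aggregated_ranking(consensus, footrule_objective(consensus, rls),
                                "borda")
  res$mean_rank <- stats::setNames(mean_rank, universe)[consensus]
  res
}

#' Consensus ranking by cross-entropy Monte Carlo optimisation
#'
#' Minimises the weighted-footrule objective over permutations with a
#' cross-entropy scheme: an item-by-position probability matrix (initialised
#' uniform) generates candidate orderings by sequential sampling without
#' replacement; each iteration the matrix is pulled toward the elite
#' (lowest-\eqn{\Phi}) fraction of the sample with smoothing. The Borda
#' solution is injected into the first sample pool, so the result is never
#' worse than Borda. Deterministic given `seed`.
#'
#' @param rls a [ranked_lists()] object.
#' @param n_samples permutations sampled per iteration (default
#'   `100 * n_targets`).
#' @param elite_frac elite fraction rho in (0, 1).
#' @param smoothing learning rate lambda in (0, 1].
#' @param max_iter iteration cap.
#' @param patience stop after this many iterations without improvement of
#'   the best objective.
#' @param seed integer seed.
#' @return An `aggregated_ranking` with convergence `trace`
#'   (data.frame `iteration`, `best_phi`).
#' @export
aggregate_ce <- function(rls, n_samples = NULL, elite_frac = 0.1,
                         smoothing = 0.1, max_iter = 100L, patience = 10L,
                         seed = 1L) {
  stopifnot(inherits(rls, "ranked_lists"))
  universe <- rls$universe
  n <- length(universe)
  if (n == 1L) {
    return(new_aggregated_ranking(universe, 0, "cross-entropy", seed = seed))
  }
  if (elite_frac <= 0 || elite_frac >= 1) stop_field("elite_frac", "must be in (0, 1)")
  if (smoothing <= 0 || smoothing > 1) stop_field("smoothing", "must be in (0, 1]")
  if (is.null(n_samples)) n_samples <- 100L * n
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  max_iter <- check_count(max_iter, "max_iter", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)

  # precompute per-list reference ranks and element importances, aligned to
  # the universe order, so scoring a block of permutations is matrix algebra
  imp <- lapply(seq_along(rls$lists), function(i) {
    normalized_importance(
      if (is.null(rls$weights)) NULL else rls$weights[[i]], universe)[universe]
  })
  ref_rank <- lapply(rls$lists, function(l) match(universe, l))
  score_perms <- function(P) { # P: N x n, items as universe indices by position
    N <- nrow(P)
    R <- matrix(0L, N, n)                       # R[i, item] = position
    R[cbind(rep(seq_len(N), n), as.vector(P))] <- rep(seq_len(n), each = N)
    phi <- numeric(N)
    for (i in seq_along(ref_rank)) {
      phi <- phi + abs(R - matrix(ref_rank[[i]], N, n, byrow = TRUE)) %*% imp[[i]]
    }
    drop(phi)
  }

  borda_sol <- borda(rls)
  borda_idx <- match(borda_sol$consensus, universe)
  n_elite <- max(1L, floor(elite_frac * n_samples))

  withr::with_seed(seed, {
    prob <- matrix(1 / n, n, n)                 # prob[item, position]
    best_perm <- borda_idx
    best_phi <- borda_sol$phi
    trace <- data.frame(iteration = integer(0), best_phi = numeric(0))
    stall <- 0L
    for (iter in seq_len(max_iter)) {
      P <- sample_permutations(prob, n_samples)
      if (iter == 1L) P[1, ] <- borda_idx
      phi <- score_perms(P)
      o <- order(phi)
      if (phi[o[1]] < best_phi) {
        best_phi <- phi[o[1]]
        best_perm <- P[o[1], ]
        stall <- 0L
      } else stall <- stall + 1L
      elite <- P[o[seq_len(n_elite)], , drop = FALSE]
      freq <- matrix(0, n, n)
      for (pos in seq_len(n)) {
        freq[, pos] <- tabulate(elite[, pos], nbins = n) / n_elite
      }
      prob <- (1 - smoothing) * prob + smoothing * freq
      trace <- rbind(trace, data.frame(iteration = iter, best_phi = best_phi))
      if (stall >= patience) break
    }
  })
  res <- new_aggregated_ranking(universe[best_perm], best_phi,
                                "cross-entropy", trace, seed)
  res
}

## Sample N permutations from an item x position probability matrix by
## sequential position sampling without replacement (vectorised over N).
sample_permutations <- function(prob, N) {
  n <- nrow(prob)
  perm <- matrix(0L, N, n)
  avail <- matrix(TRUE, N, n)
  for (pos in seq_len(n)) {
    w <- matrix(prob[, pos], N, n, byrow = TRUE)
    w[!avail] <- 0
    rs <- rowSums(w)
    zero <- rs <= 0                             # smoothing exhausted: uniform
    if (any(zero)) {
      w[zero, ] <- avail[zero, , drop = FALSE] + 0
      rs[zero] <- rowSums(w[zero, , drop = FALSE])
    }
    u <- stats::runif(N) * rs
    cw <- w
    if (n > 1L) for (j in 2:n) cw[, j] <- cw[, j - 1L] + w[, j]
    item <- max.col(cw >= u, ties.method = "first")
    perm[, pos] <- item
    avail[cbind(seq_len(N), item)] <- FALSE
  }
  perm
}

#' Exhaustive-search consensus (test oracle)
#'
#' Enumerates every permutation of the universe (refused above 8 targets)
#' and returns the lexicographically smallest minimiser of the objective.
#'
#' @param rls a [ranked_lists()] object with <= 8 targets.
#' @return An `aggregated_ranking` tagged `"brute-force"`.
#' @export
brute_force_aggregate <- function(rls) {
  stopifnot(inherits(rls, "ranked_lists"))
  n <- length(rls$universe)
  if (n > 8L) stop("brute force refused for > 8 targets")
  universe <- sort(rls$universe)                # lexicographic enumeration
  best <- NULL
  best_phi <- Inf
  for (p in all_permutations(n)) {
    cand <- universe[p]
    phi <- footrule_objective(cand, rls)
    if (phi < best_phi) { best_phi <- phi; best <- cand }
  }
  new_aggregated_ranking(best, best_phi, "brute-force")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (s in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[s])
    }
  }
  out
}
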