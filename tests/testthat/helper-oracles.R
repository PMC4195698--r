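# Independent first-principles oracles and fixture builders. Everything here
# recomputes geNorm quantities with plain loops and the textbook formulas,
# deliberately sharing no code with the package implementation.

sd_n1 <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_v <- function(Q, j, k) sd_n1(log2(Q[, j] / Q[, k]))

oracle_m <- function(Q) {
  n <- ncol(Q)
  out <- numeric(n)
  for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(n)) if (k != j) s <- s + oracle_v(Q, j, k)
    out[j] <- s / (n - 1)
  }
  names(out) <- colnames(Q)
  out
}

# stepwise exclusion, later input position wins ties; returns best-first order
oracle_exclusion_order <- function(Q) {
  remaining <- colnames(Q)
  excluded <- character(0)
  while (length(remaining) > 2) {
    M <- oracle_m(Q[, remaining, drop = FALSE])
    out <- remaining[max(which(M == max(M)))]
    excluded <- c(excluded, out)
    remaining <- setdiff(remaining, out)
  }
  c(sort(remaining, method = "radix"), rev(excluded))
}

oracle_nf <- function(Q, targets) {
  apply(Q[, targets, drop = FALSE], 1, function(x) prod(x)^(1 / length(x)))
}

oracle_v_curve <- function(Q, order_best_first) {
  nmax <- length(order_best_first)
  v <- numeric(nmax - 2)
  for (n in 2:(nmax - 1)) {
    a <- oracle_nf(Q, order_best_first[1:n])
    b <- oracle_nf(Q, order_best_first[1:(n + 1)])
    v[n - 1] <- sd_n1(log2(a / b))
  }
  v
}

# random positive quantity matrix, lognormal profiles, rescaled to max 1
random_Q <- function(n_samples = 8, n_targets = 5, seed = 1) {
  withr::with_seed(seed, {
    Q <- matrix(2^rnorm(n_samples * n_targets, 0, 1), n_samples, n_targets)
  })
  Q <- sweep(Q, 2, apply(Q, 2, max), "/")
  dimnames(Q) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("g%02d", seq_len(n_targets)))
  Q
}

# random ranked-list fixture with per-list weights (M-like, increasing in rank)
random_ranked_fixture <- function(n_targets = 5, n_lists = 3, seed = 1) {
  universe <- LETTERS[seq_len(n_targets)]
  withr::with_seed(seed, {
    lists <- lapply(seq_len(n_lists), function(i) sample(universe))
    weights <- lapply(lists, function(l) {
      w <- sort(runif(n_targets, 0.1, 1.5))   # best-ranked target lowest M
      names(w) <- l
      w
    })
  })
  ranked_lists(lists, weights)
}

# direct footrule objective evaluation, independent of the package's
oracle_phi <- function(candidate, rls) {
  total <- 0
  for (i in seq_along(rls$lists)) {
    ref <- rls$lists[[i]]
    w <- if (is.null(rls$weights)) NULL else rls$weights[[i]]
    if (is.null(w)) {
      imp <- setNames(rep(1, length(ref)), ref)
    } else {
      rng <- range(w)
      imp <- if (rng[1] == rng[2]) setNames(rep(1, length(w)), names(w))
             else (rng[2] - w) / (rng[2] - rng[1])
    }
    for (t in ref) {
      total <- total + imp[[t]] * abs(match(t, candidate) - match(t, ref))
    }
  }
  total
}
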