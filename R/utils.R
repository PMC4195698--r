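#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return The geometric mean of `x`.
#' @keywords internal
geomean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires finite, strictly positive values")
  }
  exp(mean(log(x)))
}

## internal validators ------------------------------------------------------

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %s", lower))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    stop_field(field, "must be a single integer")
  }
  if (x < min) stop_field(field, sprintf("must be >= %d", min))
  invisible(as.integer(x))
}

## Quantity matrices are plain numeric matrices (samples x targets) with an
## optional per-sample group label kept in attr(Q, "groups").

as_rq_matrix <- function(Q, groups = NULL) {
  if (!is.matrix(Q) || !is.numeric(Q)) stop("Q must be a numeric matrix")
  if (is.null(rownames(Q)) || is.null(colnames(Q))) {
    stop("Q must have sample rownames and target colnames")
  }
  if (any(!is.finite(Q)) || any(Q <= 0)) {
    stop("relative quantities must be finite and > 0")
  }
  if (!is.null(groups)) {
    if (length(groups) != nrow(Q)) stop("groups must have one label per sample")
    attr(Q, "groups") <- as.character(groups)
  }
  Q
}

#' Per-sample group labels of a quantity matrix
#'
#' @param Q a relative-quantity matrix as produced by
#'   [cq_to_relative_quantity()].
#' @return Character vector of group labels (one per row), or `NULL`.
#' @export
rq_groups <- function(Q) attr(Q, "groups")
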