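#' Plug-in mutual information between two discrete vectors
#'
#' Maximum-likelihood ("plug-in") estimate of
#' \eqn{MI(X;Y) = \sum_{x,y} p(x,y) \log \frac{p(x,y)}{p(x)p(y)}}
#' with empirical cell frequencies, in nats. Empty cells contribute zero
#' (the \eqn{0 \log 0} convention) and the result is clamped to be
#' non-negative against floating-point noise. No bias correction is applied
#' by default; `miller_madow = TRUE` adds the Miller-Madow correction
#' \eqn{(K_{xy} - K_x - K_y + 1)/(2n)} over occupied cells.
#'
#' @param x,y Equal-length vectors of discrete codes (any atomic type).
#' @param miller_madow Apply the Miller-Madow small-sample bias correction?
#'   Default `FALSE`.
#' @return MI estimate in nats (>= 0).
#' @examples
#' empirical_mi(c(1, 1, 2, 2), c(1, 1, 2, 2)) # = log(2)
#' @export
empirical_mi <- function(x, y, miller_madow = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  n <- length(x)
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  cells <- joint > 0
  outer_p <- outer(px, py)
  mi <- sum(joint[cells] * log(joint[cells] / outer_p[cells]))
  if (miller_madow) {
    mi <- mi + (sum(cells) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
  }
  max(mi, 0)
}

#' Pairwise mutual-information matrix of a discrete dataset
#'
#' @param data Sample-by-gene data frame or matrix of discrete codes, at
#'   least two columns and two rows.
#' @inheritParams empirical_mi
#' @return Symmetric named numeric matrix of MI values in nats; the diagonal
#'   holds each column's empirical entropy (MI of a column with itself).
#' @export
mi_matrix <- function(data, miller_madow = FALSE) {
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("need at least two variables to compute pairwise MI", call. = FALSE)
  if (nrow(data) < 2) stop("need at least two samples", call. = FALSE)
  vars <- names(data)
  n <- length(vars)
  m <- matrix(0, n, n, dimnames = list(vars, vars))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- empirical_mi(data[[i]], data[[j]], miller_madow = miller_madow)
    }
  }
  m
}

# Pairwise marginal from an exact joint table.
pair_marginal <- function(joint, i, j) {
  tapply(joint$prob, list(joint[[i]], joint[[j]]), sum, default = 0)
}

mi_from_table <- function(p) {
  p <- p / sum(p)
  px <- rowSums(p)
  py <- colSums(p)
  cells <- p > 0
  outer_p <- outer(px, py)
  max(sum(p[cells] * log(p[cells] / outer_p[cells])), 0)
}

#' Exact mutual information under a known network
#'
#' Computes MI between two nodes from the network's enumerated joint
#' distribution — the error-free MI oracle. For `i == j` the node's exact
#' entropy is returned.
#'
#' @param bn A [bn_model()] whose state space fits [exact_joint()]'s cap.
#' @param i,j Node names.
#' @param joint Optional precomputed [exact_joint()] table (saves repeated
#'   enumeration).
#' @return Exact MI in nats (>= 0).
#' @export
exact_mi <- function(bn, i, j, joint = NULL) {
  stopifnot(i %in% bn$structure$nodes, j %in% bn$structure$nodes)
  if (is.null(joint)) joint <- exact_joint(bn)
  if (i == j) {
    p <- tapply(joint$prob, joint[[i]], sum, default = 0)
    p <- p[p > 0]
    return(-sum(p * log(p)))
  }
  mi_from_table(pair_marginal(joint, i, j))
}

#' Exact pairwise MI matrix of a network
#'
#' @inheritParams exact_mi
#' @return Symmetric matrix as in [mi_matrix()], computed from the exact
#'   joint distribution instead of data. Useful for injecting error-free MIs
#'   into the neighbour-selection phase.
#' @export
exact_mi_matrix <- function(bn) {
  joint <- exact_joint(bn)
  vars <- bn$structure$nodes
  n <- length(vars)
  m <- matrix(0, n, n, dimnames = list(vars, vars))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- exact_mi(bn, vars[i], vars[j], joint = joint)
    }
  }
  attr(m, "exact_mi") <- TRUE
  m
}

#' Write / read a square MI matrix as TSV
#'
#' @param m Symmetric MI matrix with dimnames.
#' @param path File path.
#' @return `read_mi_matrix()` returns the matrix; `write_mi_matrix()` its
#'   path, invisibly.
#' @export
write_mi_matrix <- function(m, path) {
  df <- tibble::as_tibble(as.data.frame(m), rownames = "node")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_mi_matrix
#' @export
read_mi_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$node
  m
}
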