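#' Random tree-skeleton DAG
#'
#' Random recursive tree: node `i` (in order) attaches to a uniformly
#' chosen earlier node, edges directed parent to child. Tree skeletons are
#' the regime where DPI-based pruning is provably exact, so these are the
#' primary benchmark structures.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Integer seed.
#' @return A [bn_structure()] with `n - 1` edges whose skeleton is a tree.
#' @export
random_tree <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  nodes <- paste0("X", seq_len(n))
  build <- function() {
    pa <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
    bn_structure(nodes, tibble::tibble(from = nodes[pa], to = nodes[2:n]))
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Random sparse DAG
#'
#' Draws a random topological order, then gives each node edges from its
#' predecessors independently with probability `edge_prob`, truncated to at
#' most `max_parents` (a uniform subset is kept when over the cap).
#'
#' @param n Number of nodes (>= 2).
#' @param max_parents In-degree cap (>= 1).
#' @param edge_prob Per-predecessor edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return An acyclic [bn_structure()].
#' @export
random_dag <- function(n, max_parents = 3, edge_prob = 0.2, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("n must be >= 2", call. = FALSE)
  if (max_parents < 1) stop("max_parents must be >= 1", call. = FALSE)
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must be in [0, 1]", call. = FALSE)
  nodes <- paste0("X", seq_len(n))
  build <- function() {
    ord <- sample(nodes)
    from <- character(0)
    to <- character(0)
    for (i in seq_along(ord)[-1]) {
      pre <- ord[seq_len(i - 1)]
      pa <- pre[stats::runif(length(pre)) < edge_prob]
      if (length(pa) > max_parents) pa <- sample(pa, max_parents)
      from <- c(from, pa)
      to <- c(to, rep(ord[i], length(pa)))
    }
    bn_structure(nodes, tibble::tibble(from = from, to = to))
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Structural motifs with duplicate paths and canonical relations
#'
#' The small directed-graph fixtures used throughout to probe how duplicate
#' paths distort DPI Levels: feed-forward, feedback (cyclic — for
#' cycle-detection and documentation only, not sampleable), parallel
#' control channel, and duplicate parents (two shared causes, the classic
#' sibling false positive); plus the canonical target-relation cases:
#' direct link, indirect chain, v-structure separation, and common cause.
#'
#' @return Named list of [bn_structure()] objects.
#' @export
motif_fixtures <- function() {
  list(
    feed_forward = bn_structure(
      c("T", "A", "B"),
      tibble::tibble(from = c("T", "T", "A"), to = c("A", "B", "B"))
    ),
    feedback = bn_structure(
      c("T", "A", "B"),
      tibble::tibble(from = c("T", "A", "B"), to = c("A", "B", "T"))
    ),
    parallel_control = bn_structure(
      c("T", "A", "B", "Z"),
      tibble::tibble(from = c("T", "T", "A", "B"), to = c("A", "B", "Z", "Z"))
    ),
    duplicate_parents = bn_structure(
      c("P1", "P2", "T", "S"),
      tibble::tibble(from = c("P1", "P1", "P2", "P2"), to = c("T", "S", "T", "S"))
    ),
    relation_direct = bn_structure(
      c("T", "A"),
      tibble::tibble(from = "T", to = "A")
    ),
    relation_indirect = bn_structure(
      c("T", "A", "B"),
      tibble::tibble(from = c("T", "A"), to = c("A", "B"))
    ),
    relation_v_structure = bn_structure(
      c("T", "Y", "Z"),
      tibble::tibble(from = c("T", "Y"), to = c("Z", "Z"))
    ),
    relation_common_cause = bn_structure(
      c("P", "T", "S"),
      tibble::tibble(from = c("P", "P"), to = c("T", "S"))
    )
  )
}

#' Random CPTs for a structure (Dirichlet rows)
#'
#' Parameterizes a structure into a full [bn_model()] by drawing every CPT
#' row from a symmetric Dirichlet. Small `concentration` values put most
#' mass on few states per row, giving strong parent-child dependencies
#' (high edge MI); large values approach uniform rows (weak dependence).
#'
#' @param structure An acyclic [bn_structure()].
#' @param cardinalities Scalar or named vector of state counts (default 3,
#'   the under/normal/over-expressed convention for expression data).
#' @param concentration Dirichlet concentration (> 0), default 1.
#' @param seed Integer seed.
#' @return A [bn_model()].
#' @export
random_cpts <- function(structure, cardinalities = 3, concentration = 1, seed = NULL) {
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  nodes <- structure$nodes
  if (length(cardinalities) == 1) {
    cardinalities <- stats::setNames(rep(as.integer(cardinalities), length(nodes)), nodes)
  }
  build <- function() {
    cpts <- lapply(nodes, function(v) {
      pa <- parents(structure, v)
      q <- if (length(pa) == 0) 1L else prod(cardinalities[pa])
      r <- cardinalities[[v]]
      rows <- t(vapply(seq_len(q), function(i) {
        g <- stats::rgamma(r, shape = concentration)
        if (sum(g) <= 0) g <- rep(1, r)
        g / sum(g)
      }, numeric(r)))
      matrix(rows, nrow = q, ncol = r)
    })
    names(cpts) <- nodes
    bn_model(structure, cardinalities, cpts)
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

#' Discretize a continuous expression matrix
#'
#' Per-column independent binning into integer codes `1..bins`.
#' `"quantile"` balances bin counts to within one sample (rank-based;
#' invariant under strictly monotone transforms); `"width"` uses equal-width
#' intervals over the column's range. A constant column cannot be
#' quantile-binned and is returned as a single-bin column with a warning.
#'
#' @param data Sample-by-gene numeric data frame or matrix.
#' @param bins Number of bins (>= 2), default 3.
#' @param method `"quantile"` (default) or `"width"`.
#' @return Tibble of integer codes with the input's column names.
#' @export
discretize <- function(data, bins = 3, method = c("quantile", "width")) {
  method <- match.arg(method)
  bins <- as.integer(bins)
  if (bins < 2) stop("bins must be >= 2", call. = FALSE)
  data <- as.data.frame(data)
  n <- nrow(data)
  out <- lapply(names(data), function(v) {
    x <- data[[v]]
    distinct <- length(unique(x))
    if (method == "quantile") {
      if (distinct == 1) {
        warning(sprintf("column '%s' is constant; returning a single bin", v))
        return(rep(1L, n))
      }
      if (distinct < bins) {
        stop(sprintf(
          "column '%s' has %d distinct values, fewer than %d bins (quantile mode)",
          v, distinct, bins
        ), call. = FALSE)
      }
      as.integer(ceiling(rank(x, ties.method = "first") * bins / n))
    } else {
      if (distinct == 1) {
        warning(sprintf("column '%s' is constant; returning a single bin", v))
        return(rep(1L, n))
      }
      br <- seq(min(x), max(x), length.out = bins + 1)
      as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
    }
  })
  names(out) <- names(data)
  tibble::as_tibble(out)
}
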