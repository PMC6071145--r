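#' Discrete Bayesian network: structure, cardinalities, CPTs
#'
#' Couples an acyclic [bn_structure()] with per-node state counts and
#' conditional probability tables. A node's CPT is a numeric matrix with one
#' row per configuration of its parents (first parent varying fastest, as in
#' [expand.grid()]) and one column per state of the node; each row is a
#' probability vector. Parentless nodes have a single-row CPT.
#'
#' @param structure An acyclic [bn_structure()].
#' @param cardinalities Named integer vector: number of states (>= 2) per node.
#' @param cpts Named list of CPT matrices, one per node.
#' @param state_labels Optional named list of per-node state label vectors;
#'   defaults to `"s1" ... "sr"`.
#' @return An object of class `bn_model`.
#' @examples
#' g <- bn_structure(c("A", "B"), data.frame(from = "A", to = "B"))
#' bn <- bn_model(g,
#'   cardinalities = c(A = 2, B = 2),
#'   cpts = list(A = matrix(c(0.5, 0.5), 1), B = matrix(c(0.9, 0.1, 0.1, 0.9), 2))
#' )
#' exact_joint(bn)
#' @export
bn_model <- function(structure, cardinalities, cpts, state_labels = NULL) {
  stopifnot(inherits(structure, "bn_structure"))
  if (!is_acyclic(structure)) stop("a Bayesian network must be acyclic", call. = FALSE)
  nodes <- structure$nodes
  if (!setequal(names(cardinalities), nodes)) {
    stop("cardinalities must be named for exactly the nodes of the structure", call. = FALSE)
  }
  cardinalities <- vapply(nodes, function(v) as.integer(cardinalities[[v]]), integer(1))
  if (any(cardinalities < 2)) stop("all cardinalities must be >= 2", call. = FALSE)
  if (!setequal(names(cpts), nodes)) stop("cpts must be named for exactly the nodes", call. = FALSE)
  if (is.null(state_labels)) {
    state_labels <- lapply(cardinalities, function(r) paste0("s", seq_len(r)))
  }
  state_labels <- state_labels[nodes]
  for (v in nodes) {
    pa <- parents(structure, v)
    q <- if (length(pa) == 0) 1L else prod(cardinalities[pa])
    r <- cardinalities[[v]]
    tab <- cpts[[v]]
    if (!is.matrix(tab) || nrow(tab) != q || ncol(tab) != r) {
      stop(sprintf(
        "CPT for node '%s' must be a %d x %d matrix (parent configurations x states)",
        v, q, r
      ), call. = FALSE)
    }
    if (any(tab < 0)) stop(sprintf("CPT for node '%s' has negative entries", v), call. = FALSE)
    if (any(abs(rowSums(tab) - 1) > 1e-12)) {
      stop(sprintf("CPT rows for node '%s' must each sum to 1 (tolerance 1e-12)", v), call. = FALSE)
    }
    if (length(state_labels[[v]]) != r) {
      stop(sprintf("state labels for node '%s' must have length %d", v, r), call. = FALSE)
    }
  }
  structure(
    list(
      structure = structure, cardinalities = cardinalities,
      cpts = cpts[nodes], state_labels = state_labels
    ),
    class = "bn_model"
  )
}

#' @export
print.bn_model <- function(x, ...) {
  cat("<bn_model> ", length(x$structure$nodes), " nodes, ",
    nrow(x$structure$edges), " edges, states: ",
    paste(range(x$cardinalities), collapse = "-"), "\n",
    sep = ""
  )
  invisible(x)
}

# 1-based index of each sample's parent configuration; first parent fastest.
parent_config_index <- function(values, cards) {
  if (length(cards) == 0) return(rep(1L, if (is.matrix(values)) nrow(values) else 1L))
  values <- as.matrix(values)
  idx <- rep(1L, nrow(values))
  mult <- 1L
  for (j in seq_along(cards)) {
    idx <- idx + (values[, j] - 1L) * mult
    mult <- mult * cards[j]
  }
  idx
}

#' Exact joint distribution of a discrete Bayesian network
#'
#' Enumerates every configuration of the network's variables and computes its
#' probability as the product of the conditional probabilities, i.e. the
#' factorized joint \eqn{P(x_1,\dots,x_n) = \prod_i P(x_i \mid pa_i)}.
#'
#' @param bn A [bn_model()].
#' @param max_cells Refuse enumeration when the state space exceeds this many
#'   configurations (default `2^20`).
#' @return A tibble with one integer-coded column per node (states `1..r`)
#'   and a `prob` column; probabilities sum to 1.
#' @export
exact_joint <- function(bn, max_cells = 2^20) {
  stopifnot(inherits(bn, "bn_model"))
  nodes <- bn$structure$nodes
  total <- prod(as.numeric(bn$cardinalities))
  if (total > max_cells) {
    stop(sprintf(
      "state space has %.0f configurations, above the cap of %.0f; raise max_cells to force enumeration",
      total, max_cells
    ), call. = FALSE)
  }
  grid <- do.call(expand.grid, lapply(bn$cardinalities, seq_len))
  names(grid) <- nodes
  grid <- as.matrix(grid)
  prob <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- parents(bn$structure, v)
    row <- parent_config_index(grid[, pa, drop = FALSE], bn$cardinalities[pa])
    prob <- prob * bn$cpts[[v]][cbind(row, grid[, v])]
  }
  out <- tibble::as_tibble(as.data.frame(grid))
  out$prob <- prob
  out
}

#' Forward (ancestral) sampling from a discrete Bayesian network
#'
#' Draws i.i.d. samples by visiting nodes in topological order and sampling
#' each from its CPT row given the already-sampled parent states. A single
#' RNG stream is consumed node by node in topological order, so identical
#' `(bn, n_samples, seed)` yield bit-identical output.
#'
#' @param bn A [bn_model()].
#' @param n_samples Number of samples (>= 1).
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return Tibble of integer state codes (`1..r`), one column per node in
#'   the network's node order, one row per sample.
#' @export
forward_sample <- function(bn, n_samples, seed = NULL) {
  stopifnot(inherits(bn, "bn_model"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  draw <- function() {
    ord <- topo_sort_nodes(bn$structure)
    nodes <- bn$structure$nodes
    out <- matrix(NA_integer_, nrow = n_samples, ncol = length(nodes),
      dimnames = list(NULL, nodes)
    )
    for (v in ord) {
      pa <- parents(bn$structure, v)
      row <- parent_config_index(out[, pa, drop = FALSE], bn$cardinalities[pa])
      cpt <- bn$cpts[[v]]
      cum <- cpt
      for (k in seq_len(ncol(cpt))[-1]) cum[, k] <- cum[, k - 1] + cpt[, k]
      u <- stats::runif(n_samples)
      val <- 1L + as.integer(rowSums(cum[row, , drop = FALSE] < u))
      out[, v] <- pmin(val, ncol(cpt))
    }
    tibble::as_tibble(as.data.frame(out))
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}
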