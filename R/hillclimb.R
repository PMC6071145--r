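path_exists <- function(adj, from, to) {
  # BFS over logical adjacency matrix
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

adj_from_structure <- function(dag) {
  n <- length(dag$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$edges) > 0) adj[cbind(dag$edges$from, dag$edges$to)] <- TRUE
  adj
}

structure_from_adj <- function(adj) {
  idx <- which(adj, arr.ind = TRUE)
  bn_structure(
    rownames(adj),
    tibble::tibble(from = rownames(adj)[idx[, 1]], to = colnames(adj)[idx[, 2]])
  )
}

#' Enumerate legal search operators on a DAG
#'
#' Candidate moves for the greedy search: `add` for every allowed, absent,
#' acyclicity-preserving ordered pair; `delete` for every current edge;
#' `reverse` for every current edge whose reversal leaves the graph acyclic.
#' Add moves are restricted by the (undirected) neighbour mask; delete and
#' reverse are always permitted on existing edges, since reversal stays
#' within the mask (neighbour selection does not distinguish parents from
#' children).
#'
#' @param dag An acyclic [bn_structure()].
#' @param allowed Symmetric logical matrix over the nodes (see
#'   [allowed_mask()]), or `NULL` for unrestricted search.
#' @return Tibble with columns `op` (`"add"`, `"delete"`, `"reverse"`),
#'   `from`, `to`, in the search's deterministic tie-break order.
#' @export
legal_moves <- function(dag, allowed = NULL) {
  if (!is_acyclic(dag)) stop("legal_moves requires an acyclic structure", call. = FALSE)
  nodes <- dag$nodes
  n <- length(nodes)
  adj <- adj_from_structure(dag)
  if (is.null(allowed)) {
    allowed <- matrix(TRUE, n, n, dimnames = list(nodes, nodes))
  } else {
    allowed <- allowed[nodes, nodes]
  }
  moves <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (allowed[i, j] && !adj[i, j] && !adj[j, i] && !path_exists(adj, j, i)) {
        moves[[length(moves) + 1]] <- c("add", nodes[i], nodes[j])
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) moves[[length(moves) + 1]] <- c("delete", nodes[i], nodes[j])
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!adj[i, j]) next
      adj2 <- adj
      adj2[i, j] <- FALSE
      if (!path_exists(adj2, i, j)) moves[[length(moves) + 1]] <- c("reverse", nodes[i], nodes[j])
    }
  }
  if (length(moves) == 0) {
    return(tibble::tibble(op = character(), from = character(), to = character()))
  }
  m <- do.call(rbind, moves)
  tibble::tibble(op = m[, 1], from = m[, 2], to = m[, 3])
}

#' Greedy BDeu hill climbing over DAGs
#'
#' Starts from the empty graph and repeatedly applies the single add-edge,
#' delete-edge or reverse-edge operator with the largest score improvement,
#' stopping when no operator improves the total BDeu score by more than
#' `tol`. With `allowed = NULL` this is plain hill climbing; with a
#' neighbour mask from [allowed_mask()] the search is restricted to the
#' selected candidate edges. Ties between equally good moves go to the
#' first move in (operator, from, to) order, so the search is
#' deterministic.
#'
#' @param data Sample-by-gene data frame of integer codes `1..r`.
#' @param allowed Symmetric logical neighbour mask, or `NULL`.
#' @param ess Equivalent sample size for the BDeu score (default 1).
#' @param max_iter Iteration cap (default 500).
#' @param tol Minimal score improvement to accept a move (default `1e-9`).
#' @param levels Optional named cardinality vector (see [bdeu_local()]).
#' @return Object of class `bn_search`: `structure` (learned DAG), `score`,
#'   `trace` (tibble of accepted moves with deltas), `iterations`,
#'   `converged`, `ess`.
#' @export
hill_climb <- function(data, allowed = NULL, ess = 1, max_iter = 500, tol = 1e-9,
                       levels = NULL) {
  data <- as.data.frame(data)
  nodes <- names(data)
  if (!is.null(allowed)) {
    if (!setequal(rownames(allowed), nodes)) {
      stop("allowed mask nodes must match data columns", call. = FALSE)
    }
  }
  local <- score_cache(data, ess = ess, levels = levels)
  dag <- bn_structure(nodes)
  score <- sum(vapply(nodes, function(v) local(v, character()), numeric(1)))
  trace <- list()
  iter <- 0
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1
    moves <- legal_moves(dag, allowed)
    best_delta <- tol
    best <- NULL
    for (k in seq_len(nrow(moves))) {
      op <- moves$op[k]
      i <- moves$from[k]
      j <- moves$to[k]
      delta <- switch(op,
        add = local(j, c(parents(dag, j), i)) - local(j, parents(dag, j)),
        delete = local(j, setdiff(parents(dag, j), i)) - local(j, parents(dag, j)),
        reverse = (local(j, setdiff(parents(dag, j), i)) - local(j, parents(dag, j))) +
          (local(i, c(parents(dag, i), j)) - local(i, parents(dag, i)))
      )
      if (delta > best_delta) {
        best_delta <- delta
        best <- moves[k, ]
      }
    }
    if (is.null(best)) {
      converged <- TRUE
      iter <- iter - 1
      break
    }
    dag <- switch(best$op,
      add = add_edge(dag, best$from, best$to),
      delete = drop_edge(dag, best$from, best$to),
      reverse = add_edge(drop_edge(dag, best$from, best$to), best$to, best$from)
    )
    score <- score + best_delta
    trace[[length(trace) + 1]] <- tibble::tibble(
      iteration = iter, op = best$op, from = best$from, to = best$to,
      delta = best_delta, score = score
    )
  }
  structure(
    list(
      structure = dag, score = score,
      trace = dplyr::bind_rows(trace),
      iterations = iter, converged = converged, ess = ess
    ),
    class = "bn_search"
  )
}

#' @export
print.bn_search <- function(x, ...) {
  cat("<bn_search> ", nrow(x$structure$edges), " edges, BDeu score ",
    format(x$score), if (!x$converged) " (not converged)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.bn_search <- function(x, ...) x$structure$edges

#' @export
glance.bn_search <- function(x, ...) {
  tibble::tibble(
    score = x$score, n_edges = nrow(x$structure$edges),
    iterations = x$iterations, converged = x$converged, ess = x$ess
  )
}

#' @export
autoplot.bn_search <- function(object, ...) {
  autoplot(object$structure, ...) +
    ggplot2::labs(title = sprintf("Learned network (BDeu = %.2f)", object$score))
}

#' Flooding-Pruning Hill-Climbing: full structure learning
#'
#' The complete pipeline: [fpns()] neighbour selection followed by
#' [hill_climb()] restricted to the symmetrized candidate edges. With
#' `restricted = FALSE` the neighbour sets are ignored and the plain hill
#' climbing baseline is run instead.
#'
#' @inheritParams fpns
#' @inheritParams hill_climb
#' @param rule Symmetrization rule for the mask, `"union"` (default) or
#'   `"and"`; see [neighbor_pairs()].
#' @param restricted Set `FALSE` for the unrestricted baseline.
#' @return A `bn_search` object (subclass `fphc_fit`) with the `fpns`
#'   result attached as `$selection` (when restricted).
#' @examples
#' bn <- random_cpts(random_tree(5, seed = 1), cardinalities = 3, concentration = 0.25, seed = 1)
#' d <- forward_sample(bn, 1000, seed = 2)
#' fit <- fphc(d, theta = 1)
#' tidy(fit)
#' glance(fit)
#' @export
fphc <- function(data, theta = "mode", ess = 1, rule = c("union", "and"),
                 restricted = TRUE, max_iter = 500, tol = 1e-9, levels = NULL,
                 miller_madow = FALSE) {
  rule <- match.arg(rule)
  sel <- NULL
  mask <- NULL
  if (restricted) {
    sel <- fpns(data, theta = theta, miller_madow = miller_madow)
    mask <- allowed_mask(sel, rule)
  }
  fit <- hill_climb(data, allowed = mask, ess = ess, max_iter = max_iter, tol = tol,
    levels = levels
  )
  fit$selection <- sel
  class(fit) <- c("fphc_fit", class(fit))
  fit
}
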