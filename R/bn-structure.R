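#' Directed network structure over named variables
#'
#' `bn_structure()` builds the directed-graph object that structure learning
#' operates on: a set of named nodes and a set of directed edges. Acyclicity
#' is *not* enforced at construction (use [is_acyclic()]); this permits
#' representing cyclic motifs such as feedback loops for diagnostic purposes.
#' Operations that require Bayesian-network semantics ([bn_model()],
#' [forward_sample()], [exact_joint()]) do require a DAG and check it.
#'
#' @param nodes Character vector of unique variable (gene) names.
#' @param edges Directed edges: a data frame with columns `from` and `to`,
#'   a 2-column character matrix, or `NULL` for an edgeless graph.
#' @return An object of class `bn_structure`: a list with elements `nodes`
#'   (character) and `edges` (tibble with columns `from`, `to`).
#' @examples
#' g <- bn_structure(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("B", "C")))
#' is_acyclic(g)
#' parents(g, "B")
#' @export
bn_structure <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0) stop("at least one node is required", call. = FALSE)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character())
  } else if (is.matrix(edges)) {
    edges <- tibble::tibble(from = as.character(edges[, 1]), to = as.character(edges[, 2]))
  } else {
    edges <- tibble::as_tibble(edges[, c("from", "to")])
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
  }
  bad <- setdiff(c(edges$from, edges$to), nodes)
  if (length(bad) > 0) {
    stop("edge endpoint(s) not in node set: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate edges", call. = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "bn_structure")
}

#' @export
print.bn_structure <- function(x, ...) {
  cat("<bn_structure> ", length(x$nodes), " nodes, ", nrow(x$edges), " edges",
    if (!is_acyclic(x)) " (cyclic)" else "", "\n",
    sep = ""
  )
  invisible(x)
}

as_igraph <- function(structure) {
  igraph::graph_from_data_frame(structure$edges,
    directed = TRUE,
    vertices = data.frame(name = structure$nodes)
  )
}

#' Test whether a directed structure is acyclic
#'
#' @param structure A [bn_structure()].
#' @return `TRUE` iff the directed graph contains no cycle.
#' @export
is_acyclic <- function(structure) {
  stopifnot(inherits(structure, "bn_structure"))
  if (nrow(structure$edges) == 0) return(TRUE)
  igraph::is_dag(as_igraph(structure))
}

#' Topological order of a DAG's nodes
#'
#' @param structure An acyclic [bn_structure()].
#' @return Character vector of node names, parents before children.
#' @export
topo_sort_nodes <- function(structure) {
  if (!is_acyclic(structure)) stop("structure is cyclic; no topological order exists", call. = FALSE)
  as.character(names(igraph::topo_sort(as_igraph(structure), mode = "out")))
}

#' Parents and children of a node
#'
#' @param structure A [bn_structure()].
#' @param node Node name.
#' @return Character vector of parent (resp. child) node names, in edge order.
#' @export
parents <- function(structure, node) {
  stopifnot(node %in% structure$nodes)
  structure$edges$from[structure$edges$to == node]
}

#' @rdname parents
#' @export
children <- function(structure, node) {
  stopifnot(node %in% structure$nodes)
  structure$edges$to[structure$edges$from == node]
}

#' Undirected skeleton of a structure as unordered node pairs
#'
#' @param structure A [bn_structure()].
#' @return Tibble with columns `a`, `b` (`a` < `b` in node order), one row
#'   per adjacent pair.
#' @export
skeleton_pairs <- function(structure) {
  e <- structure$edges
  if (nrow(e) == 0) return(tibble::tibble(a = character(), b = character()))
  idx_from <- match(e$from, structure$nodes)
  idx_to <- match(e$to, structure$nodes)
  a <- ifelse(idx_from < idx_to, e$from, e$to)
  b <- ifelse(idx_from < idx_to, e$to, e$from)
  dplyr::distinct(tibble::tibble(a = a, b = b))
}

has_edge <- function(structure, from, to) {
  any(structure$edges$from == from & structure$edges$to == to)
}

add_edge <- function(structure, from, to) {
  structure$edges <- tibble::add_row(structure$edges, from = from, to = to)
  structure
}

drop_edge <- function(structure, from, to) {
  keep <- !(structure$edges$from == from & structure$edges$to == to)
  structure$edges <- structure$edges[keep, ]
  structure
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.bn_structure <- function(x, ...) x$edges

#' Plot a network structure
#'
#' Draws the directed graph with a deterministic force-directed layout.
#'
#' @param object A [bn_structure()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_structure <- function(object, ...) {
  g <- as_igraph(object)
  lay <- withr::with_seed(1L, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = object$nodes, x = lay[, 1], y = lay[, 2])
  seg <- dplyr::left_join(object$edges, nodes, by = c("from" = "name"))
  seg <- dplyr::left_join(seg, nodes, by = c("to" = "name"), suffix = c("", "end"))
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(seg) > 0) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = grid::arrow(length = grid::unit(2.5, "mm")),
      colour = "grey40"
    )
  }
  p +
    ggplot2::geom_point(size = 8, colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$name)) +
    ggplot2::theme_void()
}
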