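#' BDeu local score of a child given a parent set
#'
#' Bayesian Dirichlet equivalent uniform (BDeu) marginal log-likelihood of
#' one node's conditional distribution:
#' \deqn{\sum_{j=1}^{q} \Big[\log\Gamma(\alpha_j) - \log\Gamma(\alpha_j + N_j)
#'   + \sum_{k=1}^{r} \log\Gamma(\alpha_{jk} + N_{jk}) - \log\Gamma(\alpha_{jk})\Big]}
#' with \eqn{\alpha_{jk} = \mathrm{ess}/(q\,r)}, \eqn{\alpha_j = \mathrm{ess}/q},
#' where `q` is the number of parent configurations (full cartesian product,
#' including unobserved ones) and `r` the child's cardinality. The default
#' equivalent sample size is 1.
#'
#' @param data Sample-by-gene data frame of integer codes `1..r`.
#' @param child Child node (column name).
#' @param parents Character vector of parent columns (possibly empty).
#' @param ess Equivalent sample size (> 0), default 1.
#' @param levels Optional named integer vector of cardinalities; defaults to
#'   the observed maximum code per column.
#' @return Scalar log score.
#' @examples
#' d <- data.frame(A = c(1, 2))
#' bdeu_local(d, "A") # log(1/8): Beta(1/2, 1/2) marginal likelihood of one head, one tail
#' @export
bdeu_local <- function(data, child, parents = character(), ess = 1, levels = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  if (child %in% parents) stop("child cannot be its own parent", call. = FALSE)
  cols <- c(child, parents)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) stop("columns not in data: ", paste(missing, collapse = ", "), call. = FALSE)
  if (ess <= 0) stop("ess must be positive", call. = FALSE)
  if (is.null(levels)) levels <- data_levels(data)
  r <- levels[[child]]
  q <- if (length(parents) == 0) 1 else prod(levels[parents])
  cfg <- parent_config_index(
    as.matrix(data[, parents, drop = FALSE]),
    as.integer(levels[parents])
  )
  cell <- (cfg - 1L) * r + as.integer(data[[child]])
  n_jk <- tabulate(cell, nbins = q * r)
  n_j <- tabulate(cfg, nbins = q)
  a_jk <- ess / (q * r)
  a_j <- ess / q
  sum(lgamma(a_j) - lgamma(a_j + n_j)) +
    sum(lgamma(a_jk + n_jk) - lgamma(a_jk))
}

# observed cardinalities (max integer code per column)
data_levels <- function(data) {
  vapply(as.data.frame(data), function(x) as.integer(max(x)), integer(1))
}

#' Memoizing BDeu local-score function
#'
#' Returns a closure `f(child, parents)` that caches local scores by
#' (child, sorted parent set); cache hits are bit-identical to
#' recomputation.
#'
#' @inheritParams bdeu_local
#' @return Function of `(child, parents)`.
#' @export
score_cache <- function(data, ess = 1, levels = NULL) {
  if (is.null(levels)) levels <- data_levels(data)
  env <- new.env(parent = emptyenv())
  function(child, parents = character()) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (is.null(env[[key]])) {
      env[[key]] <- bdeu_local(data, child, parents, ess = ess, levels = levels)
    }
    env[[key]]
  }
}

#' Total BDeu score of a DAG
#'
#' Decomposable sum of local scores, \eqn{\sum_i \mathrm{bdeu}(X_i, Pa(X_i))}.
#'
#' @inheritParams bdeu_local
#' @param dag An acyclic [bn_structure()] over the data's columns.
#' @param local Optional [score_cache()] closure (built from `data` if
#'   omitted).
#' @return Scalar log score.
#' @export
total_score <- function(data, dag, ess = 1, levels = NULL, local = NULL) {
  if (!is_acyclic(dag)) stop("total_score requires an acyclic structure", call. = FALSE)
  if (is.null(local)) local <- score_cache(data, ess = ess, levels = levels)
  sum(vapply(dag$nodes, function(v) local(v, parents(dag, v)), numeric(1)))
}
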