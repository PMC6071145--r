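#' Gaussian log-likelihood of an MI segment at its MLE
#'
#' The flooding phase models the MI values on either side of a candidate
#' breakpoint as draws from normal distributions. This evaluates the
#' log-likelihood of a segment at the maximum-likelihood mean and variance,
#' with the variance floored at `var_floor` so that single-point and
#' constant segments (typical for the near-zero MI cluster of unrelated
#' genes) stay finite.
#'
#' @param values Numeric vector, length >= 1.
#' @param var_floor Lower bound on the MLE variance (default `1e-12`).
#' @return Scalar log-likelihood.
#' @export
normal_segment_loglik <- function(values, var_floor = 1e-12) {
  if (length(values) == 0) stop("empty segment", call. = FALSE)
  mu <- mean(values)
  v <- max(mean((values - mu)^2), var_floor)
  sum(stats::dnorm(values, mean = mu, sd = sqrt(v), log = TRUE))
}

#' Likelihood-ratio breakpoint statistic Q at a candidate position
#'
#' For an ascending MI vector `M` of length m and a split position `k`,
#' \eqn{Q = 2[\ell(M_{1:k}) + \ell(M_{k+1:m}) - \ell(M_{1:m})]}
#' where each \eqn{\ell} is the Gaussian segment log-likelihood at its MLE.
#' Large Q indicates that the two segments are better described by two
#' distributions than by one — i.e. a breakpoint between unrelated and
#' related genes.
#'
#' @param M Numeric MI vector (ascending order expected).
#' @param k Split position, `1 <= k <= length(M) - 1`.
#' @inheritParams normal_segment_loglik
#' @return Scalar Q.
#' @export
q_statistic <- function(M, k, var_floor = 1e-12) {
  m <- length(M)
  if (k < 1 || k > m - 1) stop("k must be in [1, length(M) - 1]", call. = FALSE)
  2 * (normal_segment_loglik(M[1:k], var_floor) +
    normal_segment_loglik(M[(k + 1):m], var_floor) -
    normal_segment_loglik(M, var_floor))
}

#' Locate the breakpoint in an ascending MI vector
#'
#' Scans every split position `k` in `[1, m - 1]`, computes the Q statistic,
#' and returns the argmax. Ties are broken toward the smallest `k`, which
#' yields the larger related set (flooding aims to include every reachable
#' gene). No significance threshold is applied: a breakpoint is always
#' declared at the maximizing position.
#'
#' The variance floor used for the scan is scale-aware by default:
#' \eqn{\max(10^{-12}, (0.05\,\mathrm{sd}(M))^2)}. An absolute floor alone
#' leaves the Gaussian likelihood effectively unbounded on one- and
#' two-point segments (a singleton fit contributes
#' \eqn{-\tfrac12\log(2\pi\epsilon)} per point), which drives the argmax to
#' a degenerate end split that keeps only the single highest-MI gene —
#' the opposite of flooding's over-inclusive intent. Flooring at a small
#' fraction of the vector's overall spread removes that artefact while
#' leaving genuinely tight clusters (including exact-zero noise groups)
#' dominant.
#'
#' @param M Ascending numeric MI vector of length >= 3.
#' @param var_floor Variance floor for the segment fits; `NULL` (default)
#'   uses the scale-aware floor described above.
#' @return A list of class `breakpoint`: `k` (chosen split), `q_values`
#'   (Q at each candidate `k`), the fitted segment parameters
#'   `delta1`, `delta2` (left/right mean and variance at `k`) and `delta`
#'   (whole-vector parameters), and `var_floor` (the floor used).
#' @export
detect_breakpoint <- function(M, var_floor = NULL) {
  m <- length(M)
  if (m < 3) {
    stop("need at least 3 MI values to detect a breakpoint; treat all nodes as related",
      call. = FALSE
    )
  }
  if (is.null(var_floor)) var_floor <- max(1e-12, (0.05 * stats::sd(M))^2)
  q <- vapply(seq_len(m - 1), function(k) q_statistic(M, k, var_floor), numeric(1))
  k <- which.max(q) # first maximum = smallest k on ties
  seg_par <- function(x) {
    c(mean = mean(x), var = max(mean((x - mean(x))^2), var_floor))
  }
  structure(
    list(
      k = k, q_values = q,
      delta1 = seg_par(M[1:k]), delta2 = seg_par(M[(k + 1):m]),
      delta = seg_par(M), var_floor = var_floor
    ),
    class = "breakpoint"
  )
}

#' Flooding phase: related set of a target gene
#'
#' Builds the target's MI vector against every other gene, sorts it in
#' ascending order (ties broken by node order), locates the breakpoint with
#' [detect_breakpoint()], and returns the genes to the right of the
#' breakpoint — the related set \eqn{R_t} — ordered by MI descending.
#'
#' For an *exact* MI matrix (one produced by [exact_mi_matrix()], or any
#' matrix carrying attribute `exact_mi = TRUE`), MIs carry no estimation
#' error, so the related set is identified analytically: exactly the genes
#' with nonzero MI to the target (d-separated and disconnected genes have
#' MI exactly 0). The breakpoint test is the finite-sample procedure for
#' estimated MIs, where the unrelated group is a noise cluster rather than
#' exact zeros.
#'
#' @param target Target node name.
#' @param mi Symmetric MI matrix covering all nodes (from [mi_matrix()] or
#'   [exact_mi_matrix()]).
#' @param exact Treat the MIs as error-free (zero/nonzero rule) instead of
#'   running breakpoint detection; defaults to the matrix's `exact_mi`
#'   attribute.
#' @param zero_tol Threshold below which an exact MI counts as zero
#'   (default `1e-14`).
#' @return A list of class `related_set`: `target`, `members` (character,
#'   MI-descending), `mi` (aligned MI values), `breakpoint` (`NULL` on the
#'   exact path).
#' @export
flood <- function(target, mi, exact = isTRUE(attr(mi, "exact_mi")), zero_tol = 1e-14) {
  nodes <- colnames(mi)
  stopifnot(target %in% nodes)
  others <- setdiff(nodes, target)
  if (length(others) < 3) {
    stop("need at least 3 other nodes to identify a related set; treat all nodes as related",
      call. = FALSE
    )
  }
  vals <- mi[target, others]
  ord <- order(vals, match(others, nodes)) # ascending; node-order tie-break
  M <- vals[ord]
  if (exact) {
    bp <- NULL
    keep <- rev(which(M > zero_tol))
    if (length(keep) == 0) {
      stop(sprintf("node '%s' has zero exact MI to every other node (disconnected)", target),
        call. = FALSE
      )
    }
  } else {
    bp <- detect_breakpoint(M)
    keep <- rev(seq(bp$k + 1, length(M))) # right of k, re-ordered MI-descending
  }
  structure(
    list(
      target = target,
      members = others[ord][keep],
      mi = unname(M[keep]),
      breakpoint = bp
    ),
    class = "related_set"
  )
}

#' Pruning phase ranking: DPI Levels of a related set
#'
#' Implements the DPI Level: walking the related set in MI-descending order,
#' the first (highest-MI) gene gets level 1; each subsequent gene `Xi` is
#' tested against every preceding gene `Xa` with the data processing
#' inequality \eqn{MI(T;X_i) \le \min(MI(T;X_a), MI(X_a;X_i))}; its level is
#' 1 plus the maximum level among the `Xa` that satisfy it, or 1 if none
#' does. Level 1 marks candidate direct neighbours; higher levels mark
#' relations mediated by closer genes.
#'
#' @param target Target node name.
#' @param related A `related_set` from [flood()], or a character vector of
#'   member names already ordered by MI descending.
#' @param mi Symmetric MI matrix covering target and members.
#' @return Tibble of class `dpi_ranking` with columns `node`, `mi`,
#'   `dpi_level`, in related-set order; the target name is attached as
#'   attribute `target`.
#' @export
dpi_levels <- function(target, related, mi) {
  members <- if (inherits(related, "related_set")) related$members else as.character(related)
  if (length(members) == 0) stop("related set is empty", call. = FALSE)
  missing <- setdiff(c(target, members), colnames(mi))
  if (length(missing) > 0) {
    stop("MI matrix does not cover: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lev <- integer(length(members))
  lev[1] <- 1L
  for (i in seq_along(members)[-1]) {
    xi <- members[i]
    sat <- integer(0)
    for (a in seq_len(i - 1)) {
      xa <- members[a]
      if (mi[target, xi] <= min(mi[target, xa], mi[xa, xi])) sat <- c(sat, lev[a])
    }
    lev[i] <- if (length(sat) > 0) max(sat) + 1L else 1L
  }
  out <- tibble::tibble(node = members, mi = unname(mi[target, members]), dpi_level = lev)
  class(out) <- c("dpi_ranking", class(out))
  attr(out, "target") <- target
  out
}

#' Choose the pruning depth theta
#'
#' With `policy = "mode"` the threshold is the mode of the DPI Levels in the
#' related set, but never less than 2 (ties between equally frequent levels
#' go to the smallest level). A numeric `policy` is used as a fixed depth.
#'
#' @param ranking A `dpi_ranking` from [dpi_levels()] (or an integer vector
#'   of levels).
#' @param policy `"mode"` or a fixed integer >= 1.
#' @return Integer theta.
#' @export
choose_theta <- function(ranking, policy = "mode") {
  if (is.numeric(policy)) {
    theta <- as.integer(policy)
    if (theta < 1) stop("fixed theta must be >= 1", call. = FALSE)
    return(theta)
  }
  if (!identical(policy, "mode")) stop("policy must be \"mode\" or a number", call. = FALSE)
  levels <- if (is.data.frame(ranking)) ranking$dpi_level else as.integer(ranking)
  if (length(levels) == 0) {
    warning("empty DPI ranking; falling back to theta = 2")
    return(2L)
  }
  tab <- table(levels)
  mode_val <- min(as.integer(names(tab)[tab == max(tab)]))
  max(mode_val, 2L)
}

#' Pruning phase: cut indirect relations
#'
#' Keeps the members of the related set whose DPI Level is at most `theta`.
#'
#' @param ranking A `dpi_ranking` from [dpi_levels()].
#' @param theta Pruning depth (integer >= 1).
#' @return Character vector of retained neighbour candidates, in ranking
#'   order.
#' @export
prune <- function(ranking, theta) {
  stopifnot(theta >= 1)
  ranking$node[ranking$dpi_level <= theta]
}

#' Flooding-Pruning Neighbour Selection over a whole dataset
#'
#' Runs the two-phase neighbour selection for every gene: compute the
#' pairwise MI matrix (unless one is supplied), then per target gene flood
#' (breakpoint over the sorted MI vector), rank the related set by DPI
#' Level, choose theta, and prune. The result restricts the search space of
#' the subsequent hill climb. The procedure is deterministic: identical
#' inputs give identical outputs.
#'
#' @param data Sample-by-gene data frame of discrete codes (>= 2 samples,
#'   >= 4 genes). Ignored when `mi` is supplied.
#' @param theta `"mode"` (per-target mode rule, >= 2) or a fixed integer
#'   pruning depth.
#' @param mi Optional precomputed symmetric MI matrix — e.g. an exact-MI
#'   matrix from [exact_mi_matrix()] — overriding estimation from `data`.
#' @param miller_madow Passed to [mi_matrix()].
#' @return Object of class `fpns`: list with `neighbors` (tibble: `target`,
#'   `neighbor`, `mi`, `dpi_level`), `rankings` (tibble over all related
#'   sets, with `kept` flag), `thetas` (tibble: `target`, `theta`),
#'   `breakpoints` (per-target `breakpoint` objects), `nodes`, `policy`,
#'   and `failures` (named list of per-target errors, normally empty).
#' @examples
#' bn <- random_cpts(random_tree(6, seed = 1), cardinalities = 3, concentration = 0.25, seed = 1)
#' d <- forward_sample(bn, 500, seed = 2)
#' sel <- fpns(d, theta = 1)
#' tidy(sel)
#' @export
fpns <- function(data = NULL, theta = "mode", mi = NULL, miller_madow = FALSE) {
  if (is.null(mi)) {
    if (is.null(data)) stop("supply data or a precomputed MI matrix", call. = FALSE)
    if (ncol(data) < 4) stop("need at least 4 variables", call. = FALSE)
    if (nrow(data) < 2) stop("need at least 2 samples", call. = FALSE)
    mi <- mi_matrix(data, miller_madow = miller_madow)
  }
  nodes <- colnames(mi)
  if (length(nodes) < 4) stop("need at least 4 variables", call. = FALSE)
  neigh <- list()
  ranks <- list()
  thetas <- integer(0)
  bps <- list()
  failures <- list()
  for (t in nodes) {
    res <- tryCatch(
      {
        rel <- flood(t, mi)
        ranking <- dpi_levels(t, rel, mi)
        th <- choose_theta(ranking, theta)
        kept <- prune(ranking, th)
        list(rel = rel, ranking = ranking, theta = th, kept = kept)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[t]] <- conditionMessage(res)
      next
    }
    thetas[t] <- res$theta
    bps[[t]] <- res$rel$breakpoint
    r <- res$ranking
    ranks[[t]] <- tibble::tibble(
      target = t, node = r$node, mi = r$mi, dpi_level = r$dpi_level,
      kept = r$node %in% res$kept
    )
    keep <- r$dpi_level <= res$theta
    neigh[[t]] <- tibble::tibble(
      target = t, neighbor = r$node[keep], mi = r$mi[keep], dpi_level = r$dpi_level[keep]
    )
  }
  structure(
    list(
      neighbors = dplyr::bind_rows(neigh),
      rankings = dplyr::bind_rows(ranks),
      thetas = tibble::tibble(target = names(thetas), theta = unname(thetas)),
      breakpoints = bps,
      nodes = nodes,
      policy = theta,
      failures = failures
    ),
    class = "fpns"
  )
}

#' @export
print.fpns <- function(x, ...) {
  cat("<fpns> ", length(x$nodes), " genes, ",
    nrow(neighbor_pairs(x)), " candidate undirected edges (union rule)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.fpns <- function(x, ...) x$neighbors

#' @export
glance.fpns <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_candidate_pairs = nrow(neighbor_pairs(x)),
    mean_theta = mean(x$thetas$theta),
    n_failures = length(x$failures)
  )
}

#' Symmetrized candidate edges of an FPNS result
#'
#' Neighbour sets are per-target and need not be mutually consistent; the
#' search phase works on unordered pairs. Under the `"union"` rule a pair
#' is allowed if either endpoint selected the other; under `"and"` both
#' must agree.
#'
#' @param x An `fpns` object.
#' @param rule `"union"` (default) or `"and"`.
#' @return Tibble of unordered pairs `a`, `b` (`a` before `b` in node
#'   order).
#' @export
neighbor_pairs <- function(x, rule = c("union", "and")) {
  rule <- match.arg(rule)
  nb <- x$neighbors
  if (nrow(nb) == 0) return(tibble::tibble(a = character(), b = character()))
  ia <- match(nb$target, x$nodes)
  ib <- match(nb$neighbor, x$nodes)
  pairs <- tibble::tibble(
    a = ifelse(ia < ib, nb$target, nb$neighbor),
    b = ifelse(ia < ib, nb$neighbor, nb$target)
  )
  counts <- dplyr::count(pairs, .data$a, .data$b)
  if (rule == "and") counts <- dplyr::filter(counts, .data$n == 2)
  dplyr::select(dplyr::arrange(counts, match(.data$a, x$nodes), match(.data$b, x$nodes)), -"n")
}

#' Allowed-edge mask for restricted search
#'
#' @inheritParams neighbor_pairs
#' @return Symmetric logical matrix over the nodes; `TRUE` where an edge
#'   (either direction) may be considered by the hill climb.
#' @export
allowed_mask <- function(x, rule = c("union", "and")) {
  pairs <- neighbor_pairs(x, rule)
  m <- matrix(FALSE, length(x$nodes), length(x$nodes), dimnames = list(x$nodes, x$nodes))
  if (nrow(pairs) > 0) {
    m[cbind(pairs$a, pairs$b)] <- TRUE
    m[cbind(pairs$b, pairs$a)] <- TRUE
  }
  m
}

#' Plot a target's sorted MI vector and detected breakpoint
#'
#' @param object An `fpns` object.
#' @param target Node whose flooding diagnostics to show; default first node.
#' @param ... Unused.
#' @return A ggplot: ascending MI values, breakpoint as a dashed line,
#'   kept neighbours highlighted.
#' @export
autoplot.fpns <- function(object, target = object$nodes[1], ...) {
  r <- dplyr::filter(object$rankings, .data$target == !!target)
  if (nrow(r) == 0) stop("no ranking for target ", target, call. = FALSE)
  bp <- object$breakpoints[[target]]
  others <- setdiff(object$nodes, target)
  # related members sit to the right of the breakpoint in the ascending vector
  asc <- dplyr::arrange(r, .data$mi)
  m <- length(others)
  df <- tibble::tibble(
    rank = seq(m - nrow(asc) + 1, m),
    mi = asc$mi,
    kept = asc$kept,
    node = asc$node
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$mi, colour = .data$kept)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "rank in ascending MI vector", y = "MI (nats)",
      title = paste0("Flooding phase for ", target),
      colour = "kept"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(bp)) {
    p <- p + ggplot2::geom_vline(xintercept = bp$k + 0.5, linetype = "dashed")
  }
  p
}
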