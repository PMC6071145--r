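#' Completed PDAG (equivalence class) of a DAG
#'
#' Converts a DAG to its completed partially directed graph: edges taking
#' part in a v-structure (collider with non-adjacent parents) are compelled
#' and stay directed, the orientation closure is completed with the Meek
#' rules R1-R3, and every remaining (reversible) edge becomes undirected.
#' Two DAGs are Markov equivalent iff their CPDAGs are identical, so
#' structural comparisons ([shd()]) are made on this representation.
#'
#' @param dag An acyclic [bn_structure()].
#' @return Object of class `cpdag`: `nodes`, `directed` (tibble `from`,
#'   `to`), `undirected` (tibble `a`, `b`, unordered), and `amat`
#'   (matrix; `amat[i, j]` is `TRUE` when i->j is present or i-j is
#'   undirected).
#' @export
dag_to_cpdag <- function(dag) {
  if (!is_acyclic(dag)) stop("dag_to_cpdag requires an acyclic structure", call. = FALSE)
  nodes <- dag$nodes
  n <- length(nodes)
  adj <- adj_from_structure(dag)
  skel <- adj | t(adj)
  m <- skel # TRUE in both directions = undirected
  # v-structures: x -> z <- y with x, y non-adjacent are compelled
  for (z in seq_len(n)) {
    pa <- which(adj[, z])
    if (length(pa) < 2) next
    for (x in pa) {
      for (y in pa) {
        if (x < y && !skel[x, y]) {
          m[z, x] <- FALSE
          m[z, y] <- FALSE
        }
      }
    }
  }
  directed <- function(i, j) m[i, j] && !m[j, i]
  undirected <- function(i, j) m[i, j] && m[j, i]
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b || !undirected(a, b)) next
        orient <- FALSE
        # R1: c -> a, a - b, c and b non-adjacent  =>  a -> b
        for (c in seq_len(n)) {
          if (c != b && directed(c, a) && !skel[c, b]) {
            orient <- TRUE
            break
          }
        }
        # R2: a -> c -> b with a - b  =>  a -> b
        if (!orient) {
          for (c in seq_len(n)) {
            if (c != a && c != b && directed(a, c) && directed(c, b)) {
              orient <- TRUE
              break
            }
          }
        }
        # R3: a - c, a - d, c -> b, d -> b, c and d non-adjacent  =>  a -> b
        if (!orient) {
          cand <- which(vapply(seq_len(n), function(c) {
            c != a && c != b && undirected(a, c) && directed(c, b)
          }, logical(1)))
          if (length(cand) >= 2) {
            for (c in cand) {
              for (d in cand) {
                if (c < d && !skel[c, d]) orient <- TRUE
              }
            }
          }
        }
        if (orient) {
          m[b, a] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dir_idx <- which(m & !t(m), arr.ind = TRUE)
  und_idx <- which(m & t(m) & upper.tri(m), arr.ind = TRUE)
  structure(
    list(
      nodes = nodes,
      directed = tibble::tibble(
        from = nodes[dir_idx[, 1]], to = nodes[dir_idx[, 2]]
      ),
      undirected = tibble::tibble(
        a = nodes[und_idx[, 1]], b = nodes[und_idx[, 2]]
      ),
      amat = m
    ),
    class = "cpdag"
  )
}

#' @export
print.cpdag <- function(x, ...) {
  cat("<cpdag> ", nrow(x$directed), " compelled, ", nrow(x$undirected),
    " reversible edges\n",
    sep = ""
  )
  invisible(x)
}

check_same_nodes <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) stop("graphs are over different node sets", call. = FALSE)
}

#' Structural Hamming distance between two DAGs
#'
#' Both DAGs are converted to their CPDAGs; each unordered node pair then
#' contributes one unit when the pair's status differs — present in one
#' graph only (extra/missing edge), directed in one and undirected in the
#' other, or directed oppositely.
#'
#' @param learned,truth Acyclic [bn_structure()] objects over the same
#'   nodes.
#' @return Non-negative integer count.
#' @export
shd <- function(learned, truth) {
  check_same_nodes(learned, truth)
  truth_m <- dag_to_cpdag(truth)$amat
  learned_m <- dag_to_cpdag(learned)$amat[truth$nodes, truth$nodes]
  n <- length(truth$nodes)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- c(learned_m[i, j], learned_m[j, i])
      b <- c(truth_m[i, j], truth_m[j, i])
      if (!identical(a, b)) count <- count + 1L
    }
  }
  count
}

#' Undirected structural Hamming distance (skeleton difference)
#'
#' Size of the symmetric difference of the two skeletons, counted over
#' unordered pairs; orientation is ignored.
#'
#' @inheritParams shd
#' @return Non-negative integer count.
#' @export
ushd <- function(learned, truth) {
  check_same_nodes(learned, truth)
  pa <- skeleton_pairs(learned)
  pb <- skeleton_pairs(truth)
  ka <- paste(pa$a, pa$b, sep = "\r")
  kb <- paste(pb$a, pb$b, sep = "\r")
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Edge F-score of a learned network
#'
#' Precision, recall and F-score (`2PR/(P+R)`; 0 when `P + R = 0`) of the
#' learned edges against the gold standard, comparing either unordered
#' adjacencies (`"skeleton"`, default) or ordered directed edges
#' (`"directed"`).
#'
#' @inheritParams shd
#' @param mode `"skeleton"` or `"directed"`.
#' @return One-row tibble: `precision`, `recall`, `f_score`, `mode`.
#' @export
edge_fscore <- function(learned, truth, mode = c("skeleton", "directed")) {
  mode <- match.arg(mode)
  check_same_nodes(learned, truth)
  key <- function(g) {
    if (mode == "skeleton") {
      p <- skeleton_pairs(g)
      paste(p$a, p$b, sep = "\r")
    } else {
      paste(g$edges$from, g$edges$to, sep = "\r")
    }
  }
  ka <- key(learned)
  kb <- key(truth)
  tp <- length(intersect(ka, kb))
  precision <- if (length(ka) == 0) 0 else tp / length(ka)
  recall <- if (length(kb) == 0) 0 else tp / length(kb)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f_score = f, mode = mode)
}

#' Confusion counts of neighbour selection against a true skeleton
#'
#' Symmetrizes the predicted neighbour sets with the union rule and counts
#' true/false positives and negatives over all `n(n-1)/2` unordered node
#' pairs against the true network's skeleton. Sensitivity (`TP/(TP+FN)`,
#' recall of true adjacencies) bounds what the search phase can recover;
#' specificity (`TN/(TN+FP)`) measures how tightly the search space was
#' restricted.
#'
#' @param predicted An `fpns` object, or a tibble of unordered pairs with
#'   columns `a`, `b`.
#' @param truth A [bn_structure()] over the same nodes.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`.
#' @export
neighbor_confusion <- function(predicted, truth) {
  if (inherits(predicted, "fpns")) {
    if (!setequal(predicted$nodes, truth$nodes)) {
      stop("predicted and truth are over different node sets", call. = FALSE)
    }
    pairs <- neighbor_pairs(predicted, rule = "union")
  } else {
    pairs <- predicted
    bad <- setdiff(c(pairs$a, pairs$b), truth$nodes)
    if (length(bad) > 0) stop("unknown nodes in prediction: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(truth$nodes)
  total <- n * (n - 1) / 2
  idx <- function(x, y) {
    i <- pmin(match(x, truth$nodes), match(y, truth$nodes))
    j <- pmax(match(x, truth$nodes), match(y, truth$nodes))
    paste(i, j)
  }
  pred_k <- unique(idx(pairs$a, pairs$b))
  tr <- skeleton_pairs(truth)
  true_k <- idx(tr$a, tr$b)
  tp <- length(intersect(pred_k, true_k))
  fp <- length(setdiff(pred_k, true_k))
  fn <- length(setdiff(true_k, pred_k))
  tn <- total - tp - fp - fn
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  )
}

#' Full structural evaluation report
#'
#' @inheritParams shd
#' @param learned A learned [bn_structure()] or a `bn_search` fit.
#' @return One-row tibble: skeleton and directed F-scores, `shd`, `ushd`,
#'   `n_edges`.
#' @export
evaluate_structure <- function(learned, truth) {
  if (inherits(learned, "bn_search")) learned <- learned$structure
  fs <- edge_fscore(learned, truth, "skeleton")
  fd <- edge_fscore(learned, truth, "directed")
  tibble::tibble(
    f_score = fs$f_score, precision = fs$precision, recall = fs$recall,
    f_score_directed = fd$f_score,
    shd = shd(learned, truth), ushd = ushd(learned, truth),
    n_edges = nrow(learned$edges)
  )
}

#' Normalize evaluation metrics against a baseline
#'
#' Divides each numeric metric column by the corresponding baseline value
#' (e.g. plain hill climbing on the same data), yielding ratios where > 1
#' means larger than the baseline.
#'
#' @param report,baseline One-row metric tibbles with matching columns.
#' @return Tibble of ratios over the shared numeric columns.
#' @export
normalize_report <- function(report, baseline) {
  cols <- intersect(names(report), names(baseline))
  cols <- cols[vapply(report[cols], is.numeric, logical(1))]
  out <- purrr::map2(report[cols], baseline[cols], `/`)
  tibble::as_tibble(out)
}
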