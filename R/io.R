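#' Write and read a discrete network as JSON
#'
#' The native network format is a JSON object with fields `nodes`
#' (array of names, in order), `cardinalities` (name -> integer),
#' `states` (name -> array of state labels), `edges` (array of
#' `{"from":, "to":}` objects) and `cpts` (name -> `{"parents": [...],
#' "probs": [[row], ...]}` with one row per parent configuration, first
#' parent varying fastest). Probabilities round-trip to within 1e-12.
#'
#' @param bn A [bn_model()].
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   a validated [bn_model()].
#' @export
write_network <- function(bn, path) {
  stopifnot(inherits(bn, "bn_model"))
  nodes <- bn$structure$nodes
  obj <- list(
    nodes = nodes,
    cardinalities = as.list(stats::setNames(bn$cardinalities, nodes)),
    states = bn$state_labels,
    edges = lapply(seq_len(nrow(bn$structure$edges)), function(i) {
      list(from = bn$structure$edges$from[i], to = bn$structure$edges$to[i])
    }),
    cpts = stats::setNames(lapply(nodes, function(v) {
      list(
        parents = parents(bn$structure, v),
        probs = unname(apply(bn$cpts[[v]], 1, function(r) r, simplify = FALSE))
      )
    }), nodes)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @param format `"json"` (native) or `"bif"` (read-only BIF 0.15 subset).
#' @rdname write_network
#' @export
read_network <- function(path, format = c("json", "bif")) {
  format <- match.arg(format)
  if (format == "bif") return(read_bif(path))
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("nodes", "cardinalities", "cpts")) {
    if (is.null(obj[[field]])) stop("network JSON is missing field '", field, "'", call. = FALSE)
  }
  nodes <- unlist(obj$nodes)
  edges <- if (length(obj$edges) == 0) {
    NULL
  } else {
    tibble::tibble(
      from = vapply(obj$edges, function(e) e$from, character(1)),
      to = vapply(obj$edges, function(e) e$to, character(1))
    )
  }
  st <- bn_structure(nodes, edges)
  if (!is_acyclic(st)) stop("network JSON defines a cyclic structure", call. = FALSE)
  cards <- vapply(obj$cardinalities, as.integer, integer(1))
  cpts <- lapply(nodes, function(v) {
    rows <- obj$cpts[[v]]$probs
    do.call(rbind, lapply(rows, unlist))
  })
  names(cpts) <- nodes
  labels <- if (is.null(obj$states)) NULL else lapply(obj$states, unlist)
  bn_model(st, cards, cpts, state_labels = labels)
}

# Read-only subset of the BIF 0.15 interchange format: `variable` blocks with
# discrete types and `probability` blocks with `table` (no parents) or
# per-parent-configuration rows. Variables must be declared before use.
read_bif <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("//[^\n]*", "", txt)
  vars <- character(0)
  cards <- integer(0)
  states <- list()
  var_pat <- "variable\\s+([A-Za-z0-9_.-]+)\\s*\\{\\s*type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}\\s*;\\s*\\}"
  prob_pat <- "probability\\s*\\(\\s*([A-Za-z0-9_.-]+)\\s*(\\|([^)]*))?\\)\\s*\\{([^}]*)\\}"
  match_positions <- function(pat) {
    m <- gregexpr(pat, txt, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(start = as.integer(m), len = attr(m, "match.length"))
  }
  mv <- match_positions(var_pat)
  mp <- match_positions(prob_pat)
  if (is.null(mv)) stop("no variable declarations found in BIF file", call. = FALSE)
  if (is.null(mp)) stop("no probability blocks found in BIF file", call. = FALSE)
  # blocks are processed in file order: a probability block may only
  # reference variables already declared above it (dialect rule)
  blocks <- rbind(
    cbind(mv, kind = "variable"),
    cbind(mp, kind = "probability")
  )
  blocks <- blocks[order(blocks$start), ]
  edges <- NULL
  cpts <- list()
  for (bi in seq_len(nrow(blocks))) {
    piece <- substr(txt, blocks$start[bi], blocks$start[bi] + blocks$len[bi] - 1)
    if (blocks$kind[bi] == "variable") {
      g <- regmatches(piece, regexec(var_pat, piece, perl = TRUE))[[1]]
      v <- g[2]
      r <- as.integer(g[3])
      labs <- trimws(strsplit(g[4], ",")[[1]])
      if (length(labs) != r) {
        stop(sprintf("BIF variable '%s': %d state labels for cardinality %d", v, length(labs), r),
          call. = FALSE
        )
      }
      vars <- c(vars, v)
      cards[v] <- r
      states[[v]] <- labs
      next
    }
    g <- regmatches(piece, regexec(prob_pat, piece, perl = TRUE))[[1]]
    child <- g[2]
    if (!child %in% vars) {
      stop(sprintf("BIF probability block uses variable '%s' before its declaration", child),
        call. = FALSE
      )
    }
    pa <- if (nchar(trimws(g[4])) > 0 || nchar(g[3]) > 0) trimws(strsplit(g[4], ",")[[1]]) else character(0)
    pa <- pa[nchar(pa) > 0]
    bad <- setdiff(pa, vars)
    if (length(bad) > 0) {
      stop(sprintf("BIF probability block for '%s' uses undeclared parent(s): %s", child,
        paste(bad, collapse = ", ")
      ), call. = FALSE)
    }
    body <- g[5]
    r <- cards[[child]]
    q <- if (length(pa) == 0) 1L else prod(cards[pa])
    tab <- matrix(NA_real_, q, r)
    if (length(pa) == 0) {
      tm <- regmatches(body, regexec("table\\s+([^;]*);", body))[[1]]
      if (length(tm) == 0) stop(sprintf("BIF block for '%s': expected 'table ...;'", child), call. = FALSE)
      vals <- as.numeric(trimws(strsplit(tm[2], ",")[[1]]))
      if (length(vals) != r) stop(sprintf("BIF block for '%s': wrong number of probabilities", child), call. = FALSE)
      tab[1, ] <- vals
    } else {
      row_pat <- "\\(([^)]*)\\)\\s*([^;]*);"
      rm_ <- gregexpr(row_pat, body, perl = TRUE)[[1]]
      if (rm_[1] == -1) stop(sprintf("BIF block for '%s': no rows", child), call. = FALSE)
      for (k in seq_along(rm_)) {
        row_piece <- substr(body, rm_[k], rm_[k] + attr(rm_, "match.length")[k] - 1)
        rg <- regmatches(row_piece, regexec(row_pat, row_piece, perl = TRUE))[[1]]
        labs <- trimws(strsplit(rg[2], ",")[[1]])
        if (length(labs) != length(pa)) {
          stop(sprintf("BIF block for '%s': row with %d parent states, expected %d", child,
            length(labs), length(pa)
          ), call. = FALSE)
        }
        codes <- vapply(seq_along(pa), function(j) {
          idx <- match(labs[j], states[[pa[j]]])
          if (is.na(idx)) {
            stop(sprintf("BIF block for '%s': unknown state '%s' of parent '%s'", child,
              labs[j], pa[j]
            ), call. = FALSE)
          }
          idx
        }, integer(1))
        rowi <- parent_config_index(matrix(codes, nrow = 1), cards[pa])
        vals <- as.numeric(trimws(strsplit(rg[3], ",")[[1]]))
        if (length(vals) != r) stop(sprintf("BIF block for '%s': wrong number of probabilities", child), call. = FALSE)
        tab[rowi, ] <- vals
      }
      if (anyNA(tab)) stop(sprintf("BIF block for '%s': missing parent configurations", child), call. = FALSE)
    }
    cpts[[child]] <- tab
    if (length(pa) > 0) {
      edges <- rbind(edges, data.frame(from = pa, to = child))
    }
  }
  missing_cpt <- setdiff(vars, names(cpts))
  if (length(missing_cpt) > 0) {
    stop("BIF file lacks probability blocks for: ", paste(missing_cpt, collapse = ", "), call. = FALSE)
  }
  st <- bn_structure(vars, edges)
  if (!is_acyclic(st)) stop("BIF file defines a cyclic structure", call. = FALSE)
  bn_model(st, cards, cpts[vars], state_labels = states)
}

#' Write and read a discrete sample matrix as TSV
#'
#' Header row of variable names, one sample per row, integer state codes.
#'
#' @param data Sample-by-gene data frame.
#' @param path File path.
#' @return `read_samples()` returns a tibble of integer columns.
#' @export
write_samples <- function(data, path) {
  readr::write_tsv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = readr::col_integer()))
}

#' Serialize an FPNS result
#'
#' `write_neighbors()` stores per-target neighbour sets, DPI Levels and
#' thetas as JSON; `write_neighbor_edges()` stores the symmetrized
#' candidate pairs as an undirected edge-list TSV.
#'
#' @param x An `fpns` object.
#' @param path File path.
#' @inheritParams neighbor_pairs
#' @return `path`, invisibly.
#' @export
write_neighbors <- function(x, path) {
  obj <- list(
    nodes = x$nodes,
    policy = if (is.numeric(x$policy)) x$policy else as.character(x$policy),
    thetas = stats::setNames(as.list(x$thetas$theta), x$thetas$target),
    neighbors = lapply(stats::setNames(x$nodes, x$nodes), function(t) {
      nb <- x$neighbors[x$neighbors$target == t, ]
      list(neighbors = nb$neighbor, mi = nb$mi, dpi_level = nb$dpi_level)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_neighbors
#' @export
write_neighbor_edges <- function(x, path, rule = c("union", "and")) {
  readr::write_tsv(neighbor_pairs(x, rule), path)
  invisible(path)
}

#' Write a learned structure as directed edge list or SIF
#'
#' @param structure A [bn_structure()] (or `bn_search` fit).
#' @param path File path.
#' @param format `"tsv"` (columns `from`, `to`) or `"sif"`
#'   (`from<TAB>regulates<TAB>to`).
#' @return `path`, invisibly.
#' @export
write_edges <- function(structure, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (inherits(structure, "bn_search")) structure <- structure$structure
  e <- structure$edges
  if (format == "tsv") {
    readr::write_tsv(e, path)
  } else {
    writeLines(paste(e$from, "regulates", e$to, sep = "\t"), path)
  }
  invisible(path)
}
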