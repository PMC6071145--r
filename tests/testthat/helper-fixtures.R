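# Shared fixtures and independent oracles for the test suite.

# Binary chain T -> A -> B with P(T=1)=0.5, P(A=x|T=x)=0.9, P(B=x|A=x)=0.9.
# Its 8-state joint and pairwise MIs are known in closed form (frozen below).
chain_bn <- function() {
  g <- bn_structure(c("T", "A", "B"), data.frame(from = c("T", "A"), to = c("A", "B")))
  noisy_copy <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  bn_model(g,
    cardinalities = c(T = 2, A = 2, B = 2),
    cpts = list(T = matrix(c(0.5, 0.5), 1), A = noisy_copy, B = noisy_copy)
  )
}

# Hand enumeration of the chain joint: p(t,a,b) = 0.5 * P(a|t) * P(b|a).
chain_joint_byhand <- function() {
  p <- function(x, y) if (x == y) 0.9 else 0.1
  out <- expand.grid(T = 1:2, A = 1:2, B = 1:2)
  out$prob <- apply(out, 1, function(r) 0.5 * p(r[1], r[2]) * p(r[2], r[3]))
  out
}

# Exact chain MIs, hand-derived from the 2x2 pair marginals:
#   MI(T;A) = MI(A;B) = 0.9*log(1.8) + 0.1*log(0.2)
#   MI(T;B) = 0.82*log(1.64) + 0.18*log(0.36)
CHAIN_MI_TA <- 0.9 * log(1.8) + 0.1 * log(0.2)
CHAIN_MI_TB <- 0.82 * log(1.64) + 0.18 * log(0.36)

# Chain T->A->B->C->D plus `n_isolated` disconnected binary nodes: the
# Theorem-1 scenario (d-separated/disconnected nodes have exact MI zero).
chain_plus_isolated_bn <- function(n_isolated = 5) {
  chain <- c("T", "A", "B", "C", "D")
  iso <- paste0("Z", seq_len(n_isolated))
  nodes <- c(chain, iso)
  g <- bn_structure(nodes, data.frame(from = chain[-5], to = chain[-1]))
  noisy_copy <- matrix(c(0.85, 0.15, 0.15, 0.85), 2, byrow = TRUE)
  cpts <- c(
    list(T = matrix(c(0.5, 0.5), 1)),
    stats::setNames(rep(list(noisy_copy), 4), chain[-1]),
    stats::setNames(rep(list(matrix(c(0.6, 0.4), 1)), n_isolated), iso)
  )
  bn_model(g, stats::setNames(rep(2L, length(nodes)), nodes), cpts)
}

# --- independent breakpoint oracle -----------------------------------------
# Exhaustive scan of the likelihood-ratio statistic, coded with the explicit
# closed-form Gaussian log-likelihood rather than dnorm().
oracle_breakpoint_k <- function(M, var_floor = max(1e-12, (0.05 * stats::sd(M))^2)) {
  ll <- function(x) {
    mu <- sum(x) / length(x)
    v <- sum((x - mu)^2) / length(x)
    if (v < var_floor) v <- var_floor
    -length(x) / 2 * log(2 * pi * v) - sum((x - mu)^2) / (2 * v)
  }
  m <- length(M)
  qs <- vapply(seq_len(m - 1), function(k) {
    2 * (ll(M[1:k]) + ll(M[(k + 1):m]) - ll(M))
  }, numeric(1))
  which.max(qs)
}

# --- independent CPDAG oracle ----------------------------------------------
# Enumerate every orientation of the DAG's skeleton; keep those that are
# acyclic with the same v-structures; an edge is compelled iff it has the
# same direction in every member of the class.
oracle_vstructures <- function(edges, nodes) {
  adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) adj[cbind(edges$from, edges$to)] <- TRUE
  skel <- adj | t(adj)
  out <- character(0)
  for (z in nodes) {
    pa <- nodes[adj[, z]]
    if (length(pa) < 2) next
    for (x in pa) {
      for (y in pa) {
        if (match(x, nodes) < match(y, nodes) && !skel[x, y]) {
          out <- c(out, paste(x, y, z))
        }
      }
    }
  }
  sort(out)
}

oracle_is_acyclic <- function(edges, nodes) {
  if (nrow(edges) == 0) return(TRUE)
  igraph::is_dag(igraph::graph_from_data_frame(edges, vertices = data.frame(name = nodes)))
}

oracle_cpdag_amat <- function(dag) {
  nodes <- dag$nodes
  sk <- skeleton_pairs(dag)
  e <- nrow(sk)
  target_v <- oracle_vstructures(dag$edges, nodes)
  members <- list()
  for (mask in 0:(2^e - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(max(e, 1))]
    from <- ifelse(bits[seq_len(e)] == 1, sk$a, sk$b)
    to <- ifelse(bits[seq_len(e)] == 1, sk$b, sk$a)
    cand <- tibble::tibble(from = from, to = to)
    if (!oracle_is_acyclic(cand, nodes)) next
    if (!identical(oracle_vstructures(cand, nodes), target_v)) next
    members[[length(members) + 1]] <- cand
  }
  amat <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(e)) {
    dirs <- vapply(members, function(mem) {
      any(mem$from == sk$a[i] & mem$to == sk$b[i])
    }, logical(1))
    if (all(dirs)) {
      amat[sk$a[i], sk$b[i]] <- TRUE
    } else if (all(!dirs)) {
      amat[sk$b[i], sk$a[i]] <- TRUE
    } else {
      amat[sk$a[i], sk$b[i]] <- TRUE
      amat[sk$b[i], sk$a[i]] <- TRUE
    }
  }
  amat
}

# --- exhaustive DAG enumeration (3 nodes) ----------------------------------
# All 25 DAGs over three labelled nodes, as bn_structure objects.
all_3node_dags <- function(nodes = c("A", "B", "C")) {
  pairs <- utils::combn(nodes, 2)
  out <- list()
  # each unordered pair is absent (0), forward (1) or backward (2)
  for (s1 in 0:2) {
    for (s2 in 0:2) {
      for (s3 in 0:2) {
        states <- c(s1, s2, s3)
        from <- character(0)
        to <- character(0)
        for (i in 1:3) {
          if (states[i] == 1) {
            from <- c(from, pairs[1, i])
            to <- c(to, pairs[2, i])
          } else if (states[i] == 2) {
            from <- c(from, pairs[2, i])
            to <- c(to, pairs[1, i])
          }
        }
        edges <- tibble::tibble(from = from, to = to)
        if (oracle_is_acyclic(edges, nodes)) {
          out[[length(out) + 1]] <- bn_structure(nodes, edges)
        }
      }
    }
  }
  out
}
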