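test_that("flood requires at least three other nodes", {
  m <- exact_mi_matrix(chain_bn()) # only 3 nodes -> 2 others
  expect_error(flood("T", m), "at least 3 other nodes")
})

test_that("flood with exact MIs keeps exactly the nonzero-MI nodes", {
  bn <- chain_plus_isolated_bn(3)
  m <- exact_mi_matrix(bn)
  rel <- flood("T", m)
  expect_s3_class(rel, "related_set")
  expect_setequal(rel$members, c("A", "B", "C", "D"))
  expect_null(rel$breakpoint)
  # MI-descending order with the closest chain member first
  expect_equal(rel$members[1], "A")
  expect_equal(rel$mi, sort(rel$mi, decreasing = TRUE))
  # a fully disconnected node has no related set
  expect_error(flood("Z1", m), "zero exact MI")
})

test_that("flood on sampled data returns a breakpoint and MI-descending members", {
  bn <- random_cpts(random_tree(7, seed = 3), cardinalities = 3, concentration = 0.25, seed = 3)
  d <- forward_sample(bn, 400, seed = 5)
  m <- mi_matrix(d)
  rel <- flood("X1", m)
  expect_s3_class(rel$breakpoint, "breakpoint")
  expect_equal(rel$mi, sort(rel$mi, decreasing = TRUE))
  expect_equal(length(rel$members), length(bn$structure$nodes) - 1 - rel$breakpoint$k)
  expect_equal(unname(rel$mi), unname(m["X1", rel$members]))
})

test_that("dpi_levels reproduces the chain ranking by hand", {
  # target T, related {A, B} with MI(T;A) > MI(T;B) and
  # MI(T;B) <= min(MI(T;A), MI(A;B)): A is level 1, B level 2
  bn <- chain_bn()
  nodes <- c("T", "A", "B")
  m <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  m["T", "A"] <- m["A", "T"] <- CHAIN_MI_TA
  m["A", "B"] <- m["B", "A"] <- CHAIN_MI_TA
  m["T", "B"] <- m["B", "T"] <- CHAIN_MI_TB
  r <- dpi_levels("T", c("A", "B"), m)
  expect_equal(r$node, c("A", "B"))
  expect_equal(r$dpi_level, c(1L, 2L))
  expect_equal(attr(r, "target"), "T")
  # and the exact pipeline agrees
  m2 <- exact_mi_matrix(bn)
  r2 <- dpi_levels("T", c("A", "B"), m2)
  expect_equal(r2$dpi_level, c(1L, 2L))
})

test_that("dpi_levels validates its inputs and starts at level 1", {
  m <- exact_mi_matrix(chain_bn())
  expect_error(dpi_levels("T", character(0), m), "empty")
  expect_error(dpi_levels("T", c("A", "nope"), m), "does not cover")
  r <- dpi_levels("T", "A", m)
  expect_equal(r$dpi_level, 1L)
})

test_that("dpi_levels never exceeds one plus the running maximum", {
  withr::with_seed(17, {
    for (rep in 1:15) {
      st <- random_dag(7, edge_prob = 0.4, seed = rep)
      bn <- random_cpts(st, cardinalities = 2, concentration = 0.5, seed = rep + 100)
      m <- exact_mi_matrix(bn)
      t <- st$nodes[1]
      others <- setdiff(st$nodes, t)
      related <- others[order(-m[t, others])]
      related <- related[m[t, related] > 1e-14]
      if (length(related) == 0) next
      lev <- dpi_levels(t, related, m)$dpi_level
      expect_equal(lev[1], 1L)
      for (i in seq_along(lev)[-1]) {
        expect_lte(lev[i], max(lev[seq_len(i - 1)]) + 1L)
      }
    }
  })
})

test_that("choose_theta implements the mode rule with a floor of 2", {
  expect_equal(choose_theta(c(1L, 1L, 2L, 2L, 2L, 3L)), 2L)
  # mode 1 is raised to the floor
  expect_equal(choose_theta(c(1L, 1L, 1L, 2L)), 2L)
  # tie between 2 and 3 goes to the smaller level
  expect_equal(choose_theta(c(2L, 2L, 3L, 3L)), 2L)
  expect_equal(choose_theta(c(3L, 3L, 3L, 4L)), 3L)
  expect_equal(choose_theta(c(1L, 2L, 3L), policy = 3), 3L)
  expect_equal(choose_theta(c(1L, 2L, 3L), policy = 1), 1L)
  expect_error(choose_theta(1:3, policy = 0), ">= 1")
  expect_error(choose_theta(1:3, policy = "median"), "policy")
  expect_warning(th <- choose_theta(integer(0)), "empty")
  expect_equal(th, 2L)
})

test_that("prune keeps members at or below theta, in ranking order", {
  m <- exact_mi_matrix(chain_bn())
  r <- dpi_levels("T", c("A", "B"), m)
  expect_equal(prune(r, 1), "A")
  expect_equal(prune(r, 2), c("A", "B"))
  expect_equal(prune(r, 5), c("A", "B"))
  expect_error(prune(r, 0))
})

test_that("fpns is deterministic and records per-target thetas", {
  bn <- random_cpts(random_tree(7, seed = 2), cardinalities = 3, concentration = 0.25, seed = 2)
  d <- forward_sample(bn, 300, seed = 9)
  s1 <- fpns(d, theta = "mode")
  s2 <- fpns(d, theta = "mode")
  expect_identical(s1$neighbors, s2$neighbors)
  expect_identical(s1$thetas, s2$thetas)
  expect_true(all(s1$thetas$theta >= 2))
  expect_setequal(s1$thetas$target, names(d))
  expect_equal(length(s1$failures), 0)
  expect_error(fpns(d[, 1:3]), "at least 4")
  expect_error(fpns(NULL), "supply data")
})

test_that("fpns neighbour sets are nested in theta", {
  bn <- random_cpts(random_tree(8, seed = 6), cardinalities = 3, concentration = 0.25, seed = 6)
  d <- forward_sample(bn, 500, seed = 7)
  prev <- NULL
  for (th in 1:4) {
    sel <- fpns(d, theta = th)
    cur <- paste(sel$neighbors$target, sel$neighbors$neighbor)
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("fpns with exact MIs and theta = 1 recovers tree skeletons", {
  for (seed in 1:5) {
    st <- random_tree(7, seed = seed)
    bn <- random_cpts(st, cardinalities = 3, concentration = 0.25, seed = seed + 50)
    sel <- fpns(mi = exact_mi_matrix(bn), theta = 1)
    got <- neighbor_pairs(sel, rule = "union")
    want <- skeleton_pairs(st)
    expect_equal(
      sort(paste(got$a, got$b)),
      sort(paste(want$a, want$b))
    )
  }
})

test_that("direct neighbours rank level 1 and mediated nodes deeper (tree, exact MIs)", {
  st <- random_tree(8, seed = 11)
  bn <- random_cpts(st, cardinalities = 3, concentration = 0.25, seed = 61)
  sel <- fpns(mi = exact_mi_matrix(bn), theta = "mode")
  sk <- skeleton_pairs(st)
  true_pair <- paste(sk$a, sk$b)
  r <- sel$rankings
  is_true <- ifelse(match(r$target, st$nodes) < match(r$node, st$nodes),
    paste(r$target, r$node), paste(r$node, r$target)
  ) %in% true_pair
  expect_true(all(r$dpi_level[is_true] == 1L))
  expect_true(all(r$dpi_level[!is_true] >= 2L))
})

test_that("duplicate parents produce the sibling false positive at level 1", {
  # P1 and P2 each regulate both T and S: T-S are non-adjacent but share
  # two causes, so DPI with a single mediator cannot separate them and S
  # typically lands at level 1 for target T. This documents why pruning at
  # theta = 1 is exact only on tree skeletons.
  st <- motif_fixtures()$duplicate_parents
  found_fp <- FALSE
  for (seed in 1:10) {
    bn <- random_cpts(st, cardinalities = 3, concentration = 0.25, seed = seed)
    m <- exact_mi_matrix(bn)
    if (all(m["T", c("P1", "P2", "S")] > 1e-14)) {
      r <- dpi_levels("T", flood("T", m), m)
      if (r$dpi_level[r$node == "S"] == 1L) found_fp <- TRUE
    }
  }
  expect_true(found_fp)
})

test_that("fpns records failures instead of aborting the whole run", {
  bn <- chain_plus_isolated_bn(1) # Z1 disconnected -> zero exact MI everywhere
  sel <- fpns(mi = exact_mi_matrix(bn), theta = "mode")
  expect_named(sel$failures, "Z1")
  expect_match(sel$failures$Z1, "zero exact MI")
  expect_false("Z1" %in% sel$neighbors$target)
  expect_setequal(unique(sel$neighbors$target), c("T", "A", "B", "C", "D"))
})

test_that("neighbor_pairs union and and rules behave as documented", {
  sel <- structure(
    list(
      neighbors = tibble::tibble(
        target = c("A", "B", "C"),
        neighbor = c("B", "A", "A"),
        mi = c(0.3, 0.3, 0.1),
        dpi_level = c(1L, 1L, 1L)
      ),
      nodes = c("A", "B", "C")
    ),
    class = "fpns"
  )
  u <- neighbor_pairs(sel, "union")
  expect_equal(paste(u$a, u$b), c("A B", "A C"))
  a <- neighbor_pairs(sel, "and")
  expect_equal(paste(a$a, a$b), "A B") # C chose A but A did not choose C
  mask <- allowed_mask(sel, "union")
  expect_true(mask["A", "B"] && mask["B", "A"] && mask["A", "C"])
  expect_false(mask["B", "C"])
  expect_identical(mask, t(mask))
})

test_that("fpns print, tidy, glance and autoplot methods work", {
  bn <- random_cpts(random_tree(6, seed = 4), cardinalities = 3, concentration = 0.25, seed = 4)
  d <- forward_sample(bn, 200, seed = 4)
  sel <- fpns(d, theta = 1)
  expect_output(print(sel), "<fpns>")
  expect_identical(tidy(sel), sel$neighbors)
  g <- glance(sel)
  expect_equal(g$n_nodes, 6)
  expect_equal(g$n_failures, 0)
  expect_s3_class(autoplot(sel), "ggplot")
  # exact path (breakpoint NULL) must also plot
  sel2 <- fpns(mi = exact_mi_matrix(bn), theta = 1)
  expect_s3_class(autoplot(sel2, target = "X2"), "ggplot")
})

test_that("fpns cost grows polynomially in the number of genes", {
  sizes <- c(10, 20, 40)
  times <- vapply(sizes, function(nv) {
    st <- random_tree(nv, seed = nv)
    bn <- random_cpts(st, cardinalities = 2, concentration = 0.25, seed = nv)
    d <- forward_sample(bn, 200, seed = nv)
    t0 <- proc.time()[["elapsed"]]
    fpns(d, theta = "mode")
    max(proc.time()[["elapsed"]] - t0, 0.02)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(times) ~ log(sizes)))[[2]]
  expect_lt(slope, 4.5)
})
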