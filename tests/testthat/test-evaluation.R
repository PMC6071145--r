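test_that("dag_to_cpdag keeps colliders directed and frees chains", {
  nodes <- c("A", "B", "C")
  collider <- bn_structure(nodes, data.frame(from = c("A", "C"), to = c("B", "B")))
  cp <- dag_to_cpdag(collider)
  expect_equal(nrow(cp$undirected), 0)
  expect_setequal(paste(cp$directed$from, cp$directed$to), c("A B", "C B"))

  chain <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  cp <- dag_to_cpdag(chain)
  expect_equal(nrow(cp$directed), 0)
  expect_equal(nrow(cp$undirected), 2)

  expect_error(dag_to_cpdag(motif_fixtures()$feedback), "acyclic")
})

test_that("Meek rule R1 orients the tail of a compelled collider", {
  # A -> C <- B plus C - D: R1 compels C -> D (else a new v-structure)
  g <- bn_structure(
    c("A", "B", "C", "D"),
    data.frame(from = c("A", "B", "C"), to = c("C", "C", "D"))
  )
  cp <- dag_to_cpdag(g)
  expect_true(any(cp$directed$from == "C" & cp$directed$to == "D"))
  expect_equal(nrow(cp$undirected), 0)
})

test_that("dag_to_cpdag matches the brute-force equivalence-class oracle", {
  for (seed in 1:20) {
    dag <- random_dag(6, max_parents = 3, edge_prob = 0.35, seed = seed)
    expect_identical(
      dag_to_cpdag(dag)$amat,
      oracle_cpdag_amat(dag),
      info = paste("seed", seed)
    )
  }
})

test_that("Markov-equivalent DAGs share a CPDAG; non-equivalent ones do not", {
  nodes <- c("A", "B", "C")
  chain <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  fork <- bn_structure(nodes, data.frame(from = c("B", "B"), to = c("A", "C")))
  collider <- bn_structure(nodes, data.frame(from = c("A", "C"), to = c("B", "B")))
  expect_identical(dag_to_cpdag(chain)$amat, dag_to_cpdag(fork)$amat)
  expect_false(identical(dag_to_cpdag(chain)$amat, dag_to_cpdag(collider)$amat))
})

test_that("shd counts pairwise CPDAG disagreements", {
  nodes <- c("A", "B", "C")
  truth <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("C", "C")))
  same_class <- truth
  expect_equal(shd(same_class, truth), 0)
  # learned single edge A -> B vs the collider: all three pairs disagree
  learned <- bn_structure(nodes, data.frame(from = "A", to = "B"))
  expect_equal(shd(learned, truth), 3)
  # chain and fork are equivalent, so shd = 0 despite different edge lists
  chain <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  fork <- bn_structure(nodes, data.frame(from = c("B", "B"), to = c("A", "C")))
  expect_equal(shd(chain, fork), 0)
  # empty vs e-edge truth counts every missing adjacency
  expect_equal(shd(bn_structure(nodes), truth), 2)
  expect_error(shd(bn_structure(c("X", "Y")), truth), "different node sets")
})

test_that("shd is symmetric and ushd never exceeds shd", {
  for (seed in 1:15) {
    a <- random_dag(6, edge_prob = 0.3, seed = seed)
    b <- random_dag(6, edge_prob = 0.3, seed = seed + 100)
    expect_equal(shd(a, b), shd(b, a))
    expect_equal(ushd(a, b), ushd(b, a))
    expect_lte(ushd(a, b), shd(a, b))
  }
})

test_that("ushd is the size of the skeleton symmetric difference", {
  nodes <- c("A", "B", "C")
  truth <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  # same skeleton, different orientations: ushd 0
  reor <- bn_structure(nodes, data.frame(from = c("B", "C"), to = c("A", "B")))
  expect_equal(ushd(reor, truth), 0)
  # one extra, one missing: ushd 2
  other <- bn_structure(nodes, data.frame(from = c("A", "A"), to = c("B", "C")))
  expect_equal(ushd(other, truth), 2)
})

test_that("edge_fscore computes precision, recall and F in both modes", {
  nodes <- c("A", "B", "C", "D")
  truth <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  perfect <- edge_fscore(truth, truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_score, 1)
  # learned: true A-B (reversed), false A-D -> skeleton P = 1/2, R = 1/2
  learned <- bn_structure(nodes, data.frame(from = c("B", "A"), to = c("A", "D")))
  sk <- edge_fscore(learned, truth, "skeleton")
  expect_equal(sk$precision, 0.5)
  expect_equal(sk$recall, 0.5)
  expect_equal(sk$f_score, 0.5)
  # directed mode does not credit the reversed edge
  dr <- edge_fscore(learned, truth, "directed")
  expect_equal(dr$precision, 0)
  expect_equal(dr$f_score, 0)
  # empty learned graph
  empty <- edge_fscore(bn_structure(nodes), truth)
  expect_equal(empty$f_score, 0)
})

test_that("neighbor_confusion reproduces hand counts on 4 nodes", {
  nodes <- c("A", "B", "C", "D")
  truth <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  # predicted pairs: A-B (true), B-C (true), A-D (false)
  pred <- tibble::tibble(a = c("A", "B", "A"), b = c("B", "C", "D"))
  cm <- neighbor_confusion(pred, truth)
  expect_equal(cm$tp, 2)
  expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 0)
  expect_equal(cm$tn, 3) # 6 unordered pairs in total
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 3 / 4)
  # empty prediction: nothing found, nothing falsely claimed
  none <- neighbor_confusion(tibble::tibble(a = character(), b = character()), truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_error(
    neighbor_confusion(tibble::tibble(a = "Z", b = "A"), truth),
    "unknown nodes"
  )
})

test_that("neighbor_confusion symmetrizes fpns objects with the union rule", {
  st <- random_tree(7, seed = 13)
  bn <- random_cpts(st, cardinalities = 3, concentration = 0.25, seed = 63)
  sel <- fpns(mi = exact_mi_matrix(bn), theta = 1)
  cm <- neighbor_confusion(sel, st)
  expect_identical(cm, neighbor_confusion(neighbor_pairs(sel, "union"), st))
  expect_equal(cm$sensitivity, 1) # exact-MI tree recovery
  expect_equal(cm$fp, 0)
})

test_that("evaluate_structure and normalize_report assemble the metric table", {
  nodes <- c("A", "B", "C")
  truth <- bn_structure(nodes, data.frame(from = c("A", "B"), to = c("B", "C")))
  learned <- bn_structure(nodes, data.frame(from = "A", to = "B"))
  rep_ <- evaluate_structure(learned, truth)
  expect_equal(rep_$f_score, edge_fscore(learned, truth)$f_score)
  expect_equal(rep_$shd, shd(learned, truth))
  expect_equal(rep_$ushd, ushd(learned, truth))
  expect_equal(rep_$n_edges, 1)
  # a bn_search fit is unwrapped to its structure
  d <- forward_sample(chain_bn(), 200, seed = 26)
  fit <- hill_climb(d)
  expect_equal(
    evaluate_structure(fit, bn_structure(names(d))),
    evaluate_structure(fit$structure, bn_structure(names(d)))
  )
  base <- evaluate_structure(truth, truth)
  ratio <- normalize_report(rep_, base)
  expect_equal(ratio$f_score, rep_$f_score / 1)
  expect_equal(ratio$n_edges, 1 / 2)
})
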