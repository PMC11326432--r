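test_that("a constant character costs nothing and is unambiguous", {
  tr <- parse_trees(text = "((A:1,B:1):1,(C:1,D:1):1);")
  asr <- sankoff_ordered(tr, c(A = 3, B = 3, C = 3, D = 3), K = 5)
  expect_equal(asr$total_cost, 0)
  for (s in asr$mpr) expect_equal(s, 3L)
  expect_true(all(asr$transitions$class == "unambiguous_none"))
  expect_equal(nrow(enumerate_mprs(asr)), 1)
})

test_that("tips without states are rejected", {
  tr <- parse_trees(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(sankoff_ordered(tr, c(A = 1, B = 1, C = 5), K = 5), "D")
})

test_that("the split 1,1,5,5 cherry case matches full enumeration", {
  tr <- parse_trees(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = 1, B = 1, C = 5, D = 5)
  asr <- sankoff_ordered(tr, states, K = 5)
  oracle <- brute_force_sankoff(tr, states, K = 5)
  expect_equal(asr$total_cost, 4)
  expect_equal(asr$total_cost, oracle$min_cost)
  # root may take any state 1..5 in some MPR
  expect_equal(asr$mpr[[5]], 1:5)
  mprs <- enumerate_mprs(asr)
  # exhaustive, duplicate-free, and every one re-scores to the minimum
  expect_equal(nrow(unique(mprs)), nrow(mprs))
  expect_equal(nrow(mprs), nrow(oracle$assignments))
  for (r in seq_len(nrow(mprs))) {
    expect_equal(score_assignment(asr, mprs[r, ]), 4)
  }
  # the enumerated set equals the brute-force optimal set
  key <- function(m) sort(apply(m, 1, paste, collapse = "-"))
  expect_equal(key(mprs), key(oracle$assignments))
  expect_error(enumerate_mprs(asr, cap = 1), "cap = 1")
})

test_that("DP cost and MPR sets match enumeration on random instances", {
  set.seed(61)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    tr <- random_tree(n)
    states <- setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    asr <- sankoff_ordered(tr, states, K = 5)
    oracle <- brute_force_sankoff(tr, states, K = 5)
    expect_equal(asr$total_cost, oracle$min_cost)
    mprs <- enumerate_mprs(asr, cap = 1e5)
    expect_equal(nrow(mprs), nrow(unique(mprs)))
    expect_true(all(apply(mprs, 1, score_assignment, asr = asr) == oracle$min_cost))
    # MPR state sets equal the union over enumerated MPRs, node by node
    for (v in seq_len(n + tr$Nnode)) {
      expect_equal(asr$mpr[[v]], sort(unique(mprs[, v])))
    }
  }
})

test_that("cost is invariant under the order-reversing state relabeling", {
  set.seed(67)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    tr <- random_tree(n)
    states <- setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    a1 <- sankoff_ordered(tr, states, K = 5)
    a2 <- sankoff_ordered(tr, 6L - states, K = 5)
    expect_equal(a1$total_cost, a2$total_cost)
  }
})

test_that("polytomies are handled as hard multifurcations", {
  tr <- parse_trees(text = "(A:1,B:1,C:1,D:1,E:1);")
  asr <- sankoff_ordered(tr, c(A = 1, B = 1, C = 1, D = 2, E = 3), K = 5)
  oracle <- brute_force_sankoff(tr, c(A = 1, B = 1, C = 1, D = 2, E = 3), K = 5)
  expect_equal(asr$total_cost, oracle$min_cost)
  expect_equal(asr$total_cost, 3)  # root at 1: |1-2| + |1-3|
})

test_that("acquisition and loss counts agree with MPR enumeration", {
  tr <- parse_trees(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states <- c(A = 1, B = 1, C = 5, D = 5)
  asr <- sankoff_ordered(tr, states, K = 5)
  mprs <- enumerate_mprs(asr)
  e <- asr$tree$edge
  for (level in 2:5) {
    per_mpr_up <- apply(mprs, 1, function(s)
      s[e[, 1]] < level & s[e[, 2]] >= level)
    per_mpr_dn <- apply(mprs, 1, function(s)
      s[e[, 1]] >= level & s[e[, 2]] < level)
    counts <- count_acquisitions(asr, level)
    expect_equal(counts$unambiguous_count, sum(apply(per_mpr_up, 1, all)))
    expect_equal(counts$possible_count, sum(apply(per_mpr_up, 1, any)))
    expect_equal(counts$loss_unambiguous, sum(apply(per_mpr_dn, 1, all)))
    expect_equal(counts$loss_possible, sum(apply(per_mpr_dn, 1, any)))
    expect_lte(counts$unambiguous_count, counts$possible_count)
  }
  # all tips at state 1: no acquisitions of any higher level
  asr1 <- sankoff_ordered(tr, c(A = 1, B = 1, C = 1, D = 1), K = 5)
  for (level in 2:5) {
    expect_equal(count_acquisitions(asr1, level)$possible_count, 0)
  }
})

test_that("acquisition counts match enumeration on random instances", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    tr <- random_tree(n)
    states <- setNames(sample(1:5, n, replace = TRUE), tr$tip.label)
    asr <- sankoff_ordered(tr, states, K = 5)
    mprs <- enumerate_mprs(asr, cap = 1e5)
    e <- tr$edge
    for (level in c(2, 4)) {
      up <- apply(mprs, 1, function(s) s[e[, 1]] < level & s[e[, 2]] >= level)
      if (is.null(dim(up))) up <- matrix(up, nrow = nrow(e))
      counts <- count_acquisitions(asr, level)
      expect_equal(counts$unambiguous_count, sum(apply(up, 1, all)))
      expect_equal(counts$possible_count, sum(apply(up, 1, any)))
    }
  }
})

test_that("squared-change parsimony solves the textbook cases", {
  tr <- parse_trees(text = "(A:1,B:1);")
  asr <- squared_change_asr(tr, c(A = 0, B = 2))
  expect_equal(unname(asr$node_values[3]), 1)   # midpoint at the root
  expect_equal(asr$objective, 2)                # 1^2/1 + 1^2/1

  set.seed(73)
  tr2 <- random_tree(8)
  asr2 <- squared_change_asr(tr2, setNames(rep(4.2, 8), tr2$tip.label))
  expect_equal(unname(asr2$node_values), rep(4.2, 8 + tr2$Nnode))
  expect_equal(asr2$objective, 0)
})

test_that("internal values are the weighted means of their neighbours", {
  set.seed(79)
  for (weighted in c(TRUE, FALSE)) {
    tr <- random_tree(10)
    vals <- setNames(rnorm(10, 0, 2), tr$tip.label)
    asr <- squared_change_asr(tr, vals, weighted = weighted)
    x <- asr$node_values
    w <- if (weighted) tr$edge.length else rep(1, nrow(tr$edge))
    for (v in 11:(10 + tr$Nnode)) {
      inc <- which(tr$edge[, 1] == v | tr$edge[, 2] == v)
      nb <- ifelse(tr$edge[inc, 1] == v, tr$edge[inc, 2], tr$edge[inc, 1])
      expect_equal(unname(x[v]), sum(x[nb] / w[inc]) / sum(1 / w[inc]),
                   tolerance = 1e-9)
    }
    # generic numerical minimizer cannot beat the linear-solve objective
    obj <- function(z) {
      full <- c(vals[tr$tip.label], z)
      sum((full[tr$edge[, 1]] - full[tr$edge[, 2]])^2 / w)
    }
    opt <- optim(rep(mean(vals), tr$Nnode), obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 2000))
    expect_lt(asr$objective, opt$value + 1e-6)
  }
})

test_that("weighted squared-change equals BM-ML ancestral states", {
  set.seed(83)
  for (rep in 1:10) {
    tr <- random_tree(9, fossil = TRUE)
    vals <- setNames(rnorm(9), tr$tip.label)
    asr <- squared_change_asr(tr, vals, weighted = TRUE)
    ml <- bm_ml_states(tr, vals)
    expect_equal(unname(asr$node_values[10:(9 + tr$Nnode)]), ml,
                 tolerance = 1e-8)
  }
})

test_that("weighted mode refuses zero-length branches", {
  expect_warning(tr <- parse_trees(text = "((A:1,B:1):0,C:2);"),
                 "zero-length")
  expect_error(squared_change_asr(tr, c(A = 1, B = 2, C = 3), weighted = TRUE),
               "positive branch lengths")
  collapsed <- collapse_zero_edges(tr)
  expect_equal(collapsed$Nnode, 1)
  asr <- squared_change_asr(collapsed, c(A = 1, B = 2, C = 3), weighted = TRUE)
  expect_equal(length(asr$node_values), 4)
})

test_that("annotated trees carry MPR sets and node values", {
  tr <- parse_trees(text = "((A:1,B:1):1,(C:1,D:1):1);")
  asr <- sankoff_ordered(tr, c(A = 1, B = 1, C = 5, D = 5), K = 5)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_annotated_tree(asr, f)
  back <- ape::read.tree(f)
  expect_equal(back$node.label[1], "1|2|3|4|5")
  casr <- squared_change_asr(tr, c(A = 0, B = 0, C = 1, D = 1))
  write_annotated_tree(casr, f)
  expect_equal(as.numeric(ape::read.tree(f)$node.label[1]), 0.5, tolerance = 1e-6)
})
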