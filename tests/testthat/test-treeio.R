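test_that("Newick parsing handles small and degenerate trees", {
  tr <- parse_trees(text = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3)
  root_children <- tr$edge[tr$edge[, 1] == 4, 2]
  expect_length(root_children, 2)

  one <- parse_trees(text = "(A:1);")
  expect_s3_class(one, "phylo")
  expect_equal(one$tip.label, "A")
})

test_that("malformed and invalid trees fail informatively", {
  expect_error(parse_trees(text = "((A:1,B:1:1,C:2);"), "offset")
  expect_error(parse_trees(text = "((A:1,B:1)):1,C:2);;"), "offset")
  expect_error(parse_trees(text = "((A:1,A:1):1,C:2);"), "duplicate tip")
})

test_that("parse/write round trip is lossless for 60 simulated trees", {
  set.seed(11)
  trees <- lapply(1:60, function(i) simulate_tree(12, fossil = TRUE))
  class(trees) <- "multiPhylo"
  for (fmt in c("newick", "nexus")) {
    f <- withr::local_tempfile(fileext = ".trees")
    write_trees(trees, f, format = fmt)
    back <- parse_trees(f)
    expect_length(back, 60)
    for (i in seq_along(trees)) {
      expect_true(ape::all.equal.phylo(trees[[i]], back[[i]],
                                       use.edge.length = FALSE))
      d0 <- patristic_distances(trees[[i]])
      d1 <- patristic_distances(back[[i]])
      expect_lt(max(abs(d0 - d1[rownames(d0), colnames(d0)])), 1e-9)
    }
  }
})

test_that("consensus of a unanimous set returns the input tree exactly", {
  set.seed(2)
  base <- simulate_tree(10, fossil = TRUE)
  trees <- rep(list(base), 60)
  cons <- consensus_with_lengths(trees)
  expect_true(ape::all.equal.phylo(cons, base, use.edge.length = FALSE))
  # branch lengths are bit-identical (compare the length multisets, since
  # edge ordering differs between the rebuilt and the input tree)
  expect_identical(sort(cons$edge.length), sort(base$edge.length))
  d0 <- patristic_distances(base)
  d1 <- patristic_distances(cons)[rownames(d0), colnames(d0)]
  expect_equal(unname(d0), unname(d1), tolerance = 1e-12)
})

test_that("consensus keeps majority clades with mean supporting lengths", {
  # ((A,B),C) x2 vs ((A,C),B) x1; AB clade supported 2/3, lengths 1 and 3
  t1 <- parse_trees(text = "((A:1,B:1):1,C:2);")
  t2 <- parse_trees(text = "((A:1,B:1):3,C:2);")
  t3 <- parse_trees(text = "((A:1,C:1):1,B:2);")
  cons <- consensus_with_lengths(list(t1, t2, t3))
  expect_setequal(cons$tip.label, c("A", "B", "C"))
  ab_node <- ape::getMRCA(cons, c("A", "B"))
  expect_false(ab_node == ape::Ntip(cons) + 1)  # AB is a proper clade
  ab_edge <- which(cons$edge[, 2] == ab_node)
  expect_equal(cons$edge.length[ab_edge], mean(c(1, 3)))  # supporting trees only
  # tip A edge length: mean over all three trees
  a_edge <- which(cons$edge[, 2] == match("A", cons$tip.label))
  expect_equal(cons$edge.length[a_edge], 1)
})

test_that("consensus clades recounted independently always exceed threshold", {
  set.seed(31)
  base <- simulate_tree(12)
  trees <- lapply(1:60, function(i) {
    tr <- base
    if (i %% 3 == 0) {  # perturb a third of the trees
      tips <- sample(tr$tip.label, 4)
      tr <- ape::keep.tip(tr, setdiff(tr$tip.label, tips))
      for (tp in tips) {
        target <- sample(tr$tip.label, 1)
        ages <- node_ages(tr)
        ei <- which(tr$edge[, 2] == match(target, tr$tip.label))
        span <- c(ages[tr$edge[ei, 2]], ages[tr$edge[ei, 1]])
        tr <- graft_tip(tr, tp, target,
                        stem_attach_age = mean(span), tip_age = span[1] / 2)
      }
    }
    tr$edge.length <- tr$edge.length * runif(length(tr$edge.length), 0.5, 1.5)
    tr
  })
  cons <- consensus_with_lengths(trees)
  # independent bipartition counter: ape::prop.part
  pp <- ape::prop.part(trees)
  labs <- attr(pp, "labels")
  freq_of <- function(tips) {
    hit <- vapply(pp, function(p) setequal(labs[p], tips), logical(1))
    if (any(hit)) attr(pp, "number")[hit] / length(trees) else 0
  }
  n <- ape::Ntip(cons)
  for (node in (n + 2):(n + cons$Nnode)) {
    tips <- ape::extract.clade(cons, node)$tip.label
    expect_gt(freq_of(tips), 0.5)
  }
})

test_that("consensus rejects mismatched tip sets", {
  t1 <- parse_trees(text = "((A:1,B:1):1,C:2);")
  t2 <- parse_trees(text = "((A:1,B:1):1,D:2);")
  expect_error(consensus_with_lengths(list(t1, t2)), "tip-set mismatch.*[CD]")
})

test_that("pruning collapses paths and preserves patristic distances", {
  tr <- parse_trees(text = "((A:1,B:1):1,C:2);")
  pr <- prune_tree(tr, c("A", "C"))
  expect_setequal(pr$tip.label, c("A", "C"))
  expect_equal(patristic_distances(pr)["A", "C"], 4)

  expect_identical(prune_tree(tr, c("A", "B", "C")), tr)
  expect_error(prune_tree(tr, c("A", "Z")), "unknown taxa.*Z")

  set.seed(5)
  big <- simulate_tree(20, fossil = TRUE)
  keep <- sample(big$tip.label, 8)
  sub <- prune_tree(big, keep)
  d_big <- patristic_distances(big)[keep, keep]
  d_sub <- patristic_distances(sub)[keep, keep]
  expect_lt(max(abs(d_big - d_sub)), 1e-9)
})

test_that("grafting splits the edge at the requested age", {
  tr <- parse_trees(text = "((A:2,B:2):1,C:3);")
  g <- graft_tip(tr, "X", "A", stem_attach_age = 1, tip_age = 0)
  expect_setequal(g$tip.label, c("A", "B", "C", "X"))
  d <- patristic_distances(g)
  expect_equal(d["A", "X"], 2)        # 1 up + 1 down
  expect_equal(d["A", "B"], 4)        # unchanged
  ages <- node_ages(g)
  expect_equal(unname(ages[match("X", g$tip.label)]), 0)

  # graft then prune recovers the original tree
  back <- prune_tree(g, c("A", "B", "C"))
  d0 <- patristic_distances(tr)
  expect_lt(max(abs(d0 - patristic_distances(back)[rownames(d0), colnames(d0)])),
            1e-9)

  expect_error(graft_tip(tr, "X", "A", stem_attach_age = 5, tip_age = 0),
               "outside edge span")
  expect_error(graft_tip(tr, "X", "A", stem_attach_age = 1, tip_age = 2),
               "tip_age")
})

test_that("grafting preserves all pre-existing node ages", {
  set.seed(9)
  tr <- simulate_tree(15, fossil = TRUE)
  ages0 <- node_ages(tr)
  child <- "t4"
  ei <- which(tr$edge[, 2] == match(child, tr$tip.label))
  span <- sort(c(ages0[tr$edge[ei, 1]], ages0[tr$edge[ei, 2]]))
  attach_age <- mean(span)
  g <- graft_tip(tr, "new_tip", child, attach_age, tip_age = attach_age / 2)
  ages1 <- node_ages(g)
  for (tp in tr$tip.label) {
    expect_equal(unname(ages1[match(tp, g$tip.label)]),
                 unname(ages0[match(tp, tr$tip.label)]), tolerance = 1e-9)
  }
})
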