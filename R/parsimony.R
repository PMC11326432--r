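#' Ordered-character (Sankoff) parsimony ancestral-state reconstruction
#'
#' Dynamic program over a rooted tree (polytomies allowed) with linear step
#' costs: changing from state i to state j costs `|i - j|`, the ordered-
#' character assumption that all levels are equally spaced. The bottom-up
#' pass computes per-node cost vectors; a top-down pass computes, for every
#' node, the MPR state set — the states the node takes in at least one
#' most-parsimonious reconstruction — and classifies every branch as an
#' unambiguous increase, unambiguous decrease, unambiguous no-change, or
#' ambiguous over all MPRs.
#'
#' @param tree Rooted `phylo`.
#' @param tip_states Named integer vector (taxon -> state in `1..K`)
#'   covering every tip.
#' @param K Number of ordered states (default 5).
#' @return An object of class `ordered_asr` with elements `tree`, `K`,
#'   `cost` (node x state matrix), `mpr` (list of state sets per node id),
#'   `total_cost`, and `transitions` (per-edge data frame with the
#'   classification and the feasible parent/child state pairs).
#' @export
sankoff_ordered <- function(tree, tip_states, K = 5L) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing))
    stop("validation error: tips missing a state: ",
         paste(missing, collapse = ", "))
  st <- tip_states[tree$tip.label]
  if (any(st < 1 | st > K | st != round(st)))
    stop("validation error: states must be integers in 1..", K)
  step <- abs(outer(seq_len(K), seq_len(K), "-"))  # step[i, j] = |i - j|

  cost <- matrix(Inf, nn, K)
  cost[cbind(seq_len(n), st)] <- 0
  po <- stats::reorder(tree, "postorder")$edge
  # bottom-up: S_v(s) = sum over children c of min_t(|s - t| + S_c(t))
  child_min <- matrix(NA_real_, nn, K)  # min_t(step[s, t] + S_c(t)) cache per child
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    inc <- apply(step + rep(cost[ch, ], each = K), 1, min)
    child_min[ch, ] <- inc
    if (is.infinite(cost[p, 1]) && all(is.infinite(cost[p, ]))) cost[p, ] <- 0
    cost[p, ] <- cost[p, ] + inc
  }
  root <- n + 1L
  total <- min(cost[root, ])

  # top-down MPR sets: s feasible at child c iff some feasible parent state t
  # has s optimal in min_t'(|t - t'| + S_c(t'))
  mpr <- vector("list", nn)
  mpr[[root]] <- which(abs(cost[root, ] - total) < 1e-9)
  co <- po[rev(seq_len(nrow(po))), , drop = FALSE]  # preorder on edges
  opt_child <- function(t, ch) which(step[t, ] + cost[ch, ] <=
                                       min(step[t, ] + cost[ch, ]) + 1e-9)
  pairs <- vector("list", nrow(co))
  for (i in seq_len(nrow(co))) {
    p <- co[i, 1]; ch <- co[i, 2]
    pr <- do.call(rbind, lapply(mpr[[p]], function(t)
      cbind(parent_state = t, child_state = opt_child(t, ch))))
    pairs[[i]] <- pr
    mpr[[ch]] <- sort(unique(pr[, "child_state"]))
  }
  classify <- function(pr) {
    d <- pr[, "child_state"] - pr[, "parent_state"]
    if (all(d > 0)) "unambiguous_increase"
    else if (all(d < 0)) "unambiguous_decrease"
    else if (all(d == 0)) "unambiguous_none"
    else "ambiguous"
  }
  transitions <- data.frame(
    parent = co[, 1], child = co[, 2],
    child_label = ifelse(co[, 2] <= n, tree$tip.label[co[, 2]], NA_character_),
    class = vapply(pairs, classify, character(1)),
    row.names = NULL)
  structure(list(tree = tree, K = K, cost = cost, mpr = mpr,
                 total_cost = total, transitions = transitions,
                 edge_order = co, edge_pairs = pairs,
                 tip_states = st),
            class = "ordered_asr")
}

#' @export
print.ordered_asr <- function(x, ...) {
  cat("Ordered-parsimony ancestral-state reconstruction\n")
  cat("  states: 1..", x$K, "   tips: ", ape::Ntip(x$tree), "\n", sep = "")
  cat("  minimum total cost:", x$total_cost, "steps\n")
  amb <- sum(x$transitions$class == "ambiguous")
  cat("  branches with ambiguous change:", amb, "\n")
  invisible(x)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Depth-first enumeration in deterministic (preorder, ascending-state)
#' order. Every returned assignment achieves the minimum cost; the list is
#' exhaustive and duplicate-free.
#'
#' @param asr An `ordered_asr`.
#' @param cap Maximum number of MPRs to return; exceeding it is an error
#'   reporting the bound.
#' @return Integer matrix, one row per MPR, columns = node ids 1..(tips +
#'   internal).
#' @export
enumerate_mprs <- function(asr, cap = 10000L) {
  tree <- asr$tree
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  co <- asr$edge_order  # preorder edges
  step <- abs(outer(seq_len(asr$K), seq_len(asr$K), "-"))
  children <- split(co[, 2], factor(co[, 1], levels = seq_len(nn)))
  out <- list()
  assign_vec <- integer(nn)
  recurse <- function(stack) {
    # stack: nodes whose state is assigned but children not yet expanded
    if (!length(stack)) {
      if (length(out) >= cap)
        stop("MPR count exceeds cap = ", cap,
             " (at least ", cap + 1, " reconstructions)")
      out[[length(out) + 1L]] <<- assign_vec
      return(invisible())
    }
    v <- stack[[1]]
    rest <- stack[-1]
    kids <- children[[v]]
    if (!length(kids)) return(recurse(rest))
    # expand children one at a time, branching over their optimal states
    expand <- function(ki, stack2) {
      if (ki > length(kids)) return(recurse(stack2))
      ch <- kids[ki]
      t <- assign_vec[v]
      opts <- which(step[t, ] + asr$cost[ch, ] <=
                      min(step[t, ] + asr$cost[ch, ]) + 1e-9)
      for (s in opts) {
        assign_vec[ch] <<- s
        expand(ki + 1L, c(stack2, ch))
      }
    }
    expand(1L, rest)
  }
  for (r in sort(asr$mpr[[root]])) {
    assign_vec[root] <- r
    recurse(list(root))
  }
  do.call(rbind, out)
}

#' Re-score a complete node-state assignment
#'
#' @param asr An `ordered_asr`.
#' @param states Integer vector of states over all node ids.
#' @return Total ordered-parsimony cost of the assignment.
#' @export
score_assignment <- function(asr, states) {
  e <- asr$tree$edge
  sum(abs(states[e[, 1]] - states[e[, 2]]))
}

#' Count acquisitions and losses of a complexity level
#'
#' A branch (u, v) is an acquisition of `level` when the state crosses the
#' threshold upward along it: `state(u) < level <= state(v)`. It is
#' unambiguous when that holds in every most-parsimonious reconstruction and
#' possible when it holds in at least one; losses are the downward mirror
#' (`state(u) >= level > state(v)`). Counting uses the per-branch feasible
#' parent/child state pairs, which is exact because the Sankoff cost
#' decomposes over children: any feasible pair occurs in some MPR.
#'
#' @param asr An `ordered_asr`.
#' @param level Threshold state.
#' @return List `unambiguous_count`, `possible_count`, `loss_unambiguous`,
#'   `loss_possible`.
#' @export
count_acquisitions <- function(asr, level) {
  if (level < 1 || level > asr$K) stop("level must be in 1..K")
  acq_all <- acq_any <- loss_all <- loss_any <- 0L
  for (pr in asr$edge_pairs) {
    up <- pr[, "parent_state"] < level & pr[, "child_state"] >= level
    dn <- pr[, "parent_state"] >= level & pr[, "child_state"] < level
    if (all(up)) acq_all <- acq_all + 1L
    if (any(up)) acq_any <- acq_any + 1L
    if (all(dn)) loss_all <- loss_all + 1L
    if (any(dn)) loss_any <- loss_any + 1L
  }
  list(unambiguous_count = acq_all, possible_count = acq_any,
       loss_unambiguous = loss_all, loss_possible = loss_any)
}

#' Squared-change parsimony for a continuous character
#'
#' Finds internal-node values minimizing the sum over edges of
#' `(x_parent - x_child)^2 / w_e`, with `w_e` the branch length (weighted
#' mode; all lengths must then be positive) or 1 (unweighted). The optimum
#' is the unique solution of the first-order system in which every internal
#' value is the weighted mean of its neighbours' values; the weighted mode
#' coincides with Brownian-motion maximum-likelihood ancestral states.
#'
#' @param tree Rooted `phylo` (polytomies allowed).
#' @param tip_values Named numeric vector (taxon -> value) covering all tips.
#' @param weighted Divide squared changes by branch lengths (default TRUE).
#' @return An object of class `continuous_asr` with `node_values` over all
#'   node ids (tips fixed at their observations), `objective`, `weighted`.
#' @export
squared_change_asr <- function(tree, tip_values, weighted = TRUE) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  missing <- setdiff(tree$tip.label, names(tip_values))
  if (length(missing))
    stop("validation error: tips missing a value: ",
         paste(missing, collapse = ", "))
  x <- numeric(nn)
  x[seq_len(n)] <- tip_values[tree$tip.label]
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  if (weighted && any(w <= 0))
    stop("validation error: weighted mode needs positive branch lengths; ",
         "collapse zero-length edges first (collapse_zero_edges)")
  internal <- (n + 1L):nn
  idx <- stats::setNames(seq_along(internal), internal)
  A <- matrix(0, length(internal), length(internal))
  b <- numeric(length(internal))
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    wi <- 1 / w[i]
    pi <- idx[[as.character(p)]]
    A[pi, pi] <- A[pi, pi] + wi
    if (ch > n) {
      ci <- idx[[as.character(ch)]]
      A[ci, ci] <- A[ci, ci] + wi
      A[pi, ci] <- A[pi, ci] - wi
      A[ci, pi] <- A[ci, pi] - wi
    } else {
      b[pi] <- b[pi] + wi * x[ch]
    }
  }
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("singular squared-change system (should not occur on a tree): ",
         conditionMessage(e)))
  x[internal] <- sol
  obj <- sum((x[tree$edge[, 1]] - x[tree$edge[, 2]])^2 / w)
  structure(list(tree = tree, node_values = x, objective = obj,
                 weighted = weighted),
            class = "continuous_asr")
}

#' @export
print.continuous_asr <- function(x, ...) {
  cat("Squared-change parsimony reconstruction (",
      if (x$weighted) "branch-length weighted" else "unweighted", ")\n", sep = "")
  cat("  objective (sum of scaled squared changes):",
      format(x$objective, digits = 6), "\n")
  rng <- range(x$node_values)
  cat("  node value range:", format(rng[1], digits = 4), "to",
      format(rng[2], digits = 4), "\n")
  invisible(x)
}

#' Write a tree annotated with per-node values or MPR sets
#'
#' Node annotations are placed in the Newick node-label position so any
#' standard viewer can display them.
#'
#' @param asr An `ordered_asr` or `continuous_asr`.
#' @param file Output path (Newick).
#' @return `file`, invisibly.
#' @export
write_annotated_tree <- function(asr, file) {
  tree <- asr$tree
  n <- ape::Ntip(tree)
  if (inherits(asr, "ordered_asr")) {
    lab <- vapply(asr$mpr[(n + 1):(n + tree$Nnode)], function(s)
      paste(s, collapse = "|"), character(1))
  } else {
    lab <- sprintf("%.6g", asr$node_values[(n + 1):(n + tree$Nnode)])
  }
  tree$node.label <- lab
  ape::write.tree(tree, file = file)
  invisible(file)
}
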