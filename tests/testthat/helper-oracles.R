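# Independent oracles and small fixture builders. Everything here is kept
# deliberately naive (enumeration, explicit formulas, generic optimizers) and
# separate from the package's own algorithms.

random_tree <- function(n, fossil = FALSE) {
  tr <- ape::rtree(n)                      # random topology, U(0,1) lengths
  tr$edge.length <- tr$edge.length + 0.1   # keep lengths comfortably positive
  if (fossil) {
    term <- which(tr$edge[, 2] <= n)
    tr$edge.length[term] <- tr$edge.length[term] * runif(length(term), 0.2, 1)
  }
  tr
}

# exhaustive ordered-parsimony minimum: try every internal-state assignment
brute_force_sankoff <- function(tree, tip_states, K) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  st <- tip_states[tree$tip.label]
  grids <- do.call(expand.grid, rep(list(seq_len(K)), m))
  full <- cbind(matrix(rep(st, each = nrow(grids)), nrow(grids), n),
                as.matrix(grids))
  costs <- rep(0, nrow(grids))
  for (i in seq_len(nrow(tree$edge))) {
    costs <- costs + abs(full[, tree$edge[i, 1]] - full[, tree$edge[i, 2]])
  }
  list(min_cost = min(costs),
       assignments = full[costs == min(costs), , drop = FALSE])
}

# pairwise MRCA-depth covariance by explicit path-to-root intersection
brute_force_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- toothpos::node_depths(tree)
  path_to_root <- function(v) {
    p <- v
    while (v != n + 1L) {
      v <- parent[v]
      p <- c(p, v)
    }
    p
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      anc <- intersect(path_to_root(i), path_to_root(j))
      C[i, j] <- max(depth[anc])
    }
  }
  C
}

# axial landmark positions by perpendicular-foot line intersection: solve the
# 2x2 system for midline and perpendicular through the landmark, then measure
foot_positions <- function(lm) {
  A <- lm[1, ]; B <- lm[2, ]
  d <- B - A
  nvec <- c(-d[2], d[1])
  vapply(seq_len(nrow(lm)), function(k) {
    P <- lm[k, ]
    if (anyNA(P)) return(NA_real_)
    # A + s d = P + r nvec
    sr <- solve(cbind(d, -nvec), P - A)
    foot <- A + sr[1] * d
    sign(sum((foot - A) * d)) * sqrt(sum((foot - A)^2))
  }, numeric(1))
}

# BM maximum-likelihood ancestral states via the conditional-normal formula,
# using covariances between internal nodes and tips (MRCA depths)
bm_ml_states <- function(tree, tip_values) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  y <- tip_values[tree$tip.label]
  depth <- toothpos::node_depths(tree)
  M <- ape::mrca(tree, full = TRUE)     # MRCA for every node pair
  Cfull <- matrix(depth[M], nn, nn)
  Ct <- Cfull[seq_len(n), seq_len(n)]
  ones <- rep(1, n)
  Ct_inv <- solve(Ct)
  mu <- as.numeric((t(ones) %*% Ct_inv %*% y) / (t(ones) %*% Ct_inv %*% ones))
  vapply((n + 1L):nn, function(k) {
    mu + as.numeric(Cfull[k, seq_len(n)] %*% Ct_inv %*% (y - mu))
  }, numeric(1))
}

rigid_motion <- function(xy, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  ok <- stats::complete.cases(xy)
  xy[ok, ] <- sweep(xy[ok, , drop = FALSE] %*% t(R), 2, shift, "+")
  xy
}

# symmetric cranium-like configuration for geometry tests
random_config <- function(id = "spec", with_postmax = TRUE, scale = 1) {
  cr <- runif(1, 100, 300)
  lens <- sort(runif(4, 0.2, 0.95)) * cr    # four paired lengths, ascending
  xy <- matrix(NA_real_, 10, 2)
  xy[1, ] <- c(0, 0)
  xy[2, ] <- c(cr, 0)
  for (k in 1:4) {
    off <- runif(1, 3, 0.25 * cr)
    xy[2 * k + 1, ] <- c(lens[k], off)
    xy[2 * k + 2, ] <- c(lens[k], -runif(1, 3, 0.25 * cr))
  }
  if (!with_postmax) xy[9:10, ] <- NA_real_
  toothpos::landmark_config(id, xy, scale = scale)
}
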