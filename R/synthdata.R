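#' Configuration for a synthetic comparative study
#'
#' The defaults state the world the analysis is built for: 60 fossil taxa on
#' a non-ultrametric tree, natural-log mm length variables with
#' phylogenetically structured residual noise (Brownian motion attenuated by
#' lambda = 0.8, residual sd 0.1 on the log scale), an ordered five-state
#' complexity character evolving by unit steps, a complexity effect of 0.07
#' log-mm per level on the length to post-dentition, and 2 of 60 taxa
#' missing the post-maxilla measurement.
#'
#' @param n_taxa Number of tips (>= 4).
#' @param seed Integer seed; all randomness derives from it.
#' @param lambda_true Pagel's lambda of the residual noise, in `[0, 1]`.
#' @param sigma2_true Residual variance at unit tree height (log-mm scale).
#' @param beta_complexity Effect of one complexity level on log length to
#'   post-dentition.
#' @param slope_reference Slope of the reference (cranial) log length.
#' @param intercept Intercept of the post-dentition model.
#' @param complexity_step_rate Expected +/-1 state events per unit tree
#'   height.
#' @param fraction_missing_post_maxilla Fraction of taxa with `NA`
#'   post-maxilla length.
#' @return A `study_config` list.
#' @export
study_config <- function(n_taxa = 60L, seed = 1L, lambda_true = 0.8,
                         sigma2_true = 0.01, beta_complexity = 0.07,
                         slope_reference = 1.0, intercept = -0.9,
                         complexity_step_rate = 3,
                         fraction_missing_post_maxilla = 2 / 60) {
  stopifnot(n_taxa >= 4, sigma2_true > 0, complexity_step_rate > 0,
            lambda_true >= 0, lambda_true <= 1,
            fraction_missing_post_maxilla >= 0,
            fraction_missing_post_maxilla <= 1)
  structure(list(n_taxa = as.integer(n_taxa), seed = as.integer(seed),
                 lambda_true = lambda_true, sigma2_true = sigma2_true,
                 beta_complexity = beta_complexity,
                 slope_reference = slope_reference, intercept = intercept,
                 complexity_step_rate = complexity_step_rate,
                 fraction_missing_post_maxilla = fraction_missing_post_maxilla),
            class = "study_config")
}

#' Simulate a rooted time-scaled tree
#'
#' Pure-birth tree; in fossil mode each terminal branch is shortened by an
#' independent uniform fraction so tips end at different ages and the tree
#' is non-ultrametric, as for extinct taxa sampled through time.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed; omit to use the current RNG stream.
#' @param fossil Truncate tips at independent uniform ages.
#' @return A rooted `phylo` with branch lengths; tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, seed = NULL, fossil = FALSE) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  if (fossil) {
    term <- which(tree$edge[, 2] <= n_tips)
    cut <- stats::runif(length(term), 0, 0.8)
    tree$edge.length[term] <- tree$edge.length[term] * (1 - cut)
  }
  tree
}

#' Rescale a tree to unit root-to-deepest-tip height
#'
#' @param tree A `phylo` with branch lengths.
#' @return The rescaled tree.
#' @export
scale_tree_height <- function(tree) {
  h <- max(node_depths(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Simulate a Brownian-motion trait with lambda attenuation
#'
#' One draw from the multivariate normal with mean `root_value` and
#' covariance `sigma2 * C(lambda)`, where `C` is the phylogenetic covariance
#' of the tree and `lambda` multiplies its off-diagonal entries (see
#' [apply_lambda()]); drawn through the Cholesky square root.
#'
#' @param tree Rooted `phylo`.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param root_value Trait value at the root.
#' @param lambda Phylogenetic-signal attenuation in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, root_value = 0, lambda = 1, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  z <- stats::rnorm(n)
  if (sigma2 == 0)
    return(stats::setNames(rep(root_value, n), tree$tip.label))
  S <- sigma2 * apply_lambda(phylo_covariance(tree), lambda)
  y <- root_value + as.numeric(t(chol(S)) %*% z)
  stats::setNames(y, tree$tip.label)
}

#' Simulate an ordered character by a reflected unit-step walk
#'
#' The root starts at state 1; along each branch, a Poisson(`step_rate` x
#' length) number of events each move the state by +/-1 with reflection at
#' the boundaries 1 and `K`.
#'
#' @param tree Rooted `phylo`.
#' @param step_rate Events per unit branch length (> 0).
#' @param K Number of states (>= 2).
#' @param seed Optional integer seed.
#' @return Named integer vector of tip states, with attributes
#'   `node_states` (state at every node id) and `n_changes` (total realized
#'   state changes along all branches).
#' @export
simulate_ordered_walk <- function(tree, step_rate, K = 5L, seed = NULL) {
  if (K < 2) stop("K must be >= 2")
  if (step_rate <= 0) stop("step_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  state <- integer(nn)
  state[n + 1L] <- 1L
  n_changes <- 0L
  edges <- stats::reorder(tree, "cladewise")
  for (i in seq_len(nrow(edges$edge))) {
    p <- edges$edge[i, 1]; ch <- edges$edge[i, 2]
    s <- state[p]
    n_ev <- stats::rpois(1, step_rate * edges$edge.length[i])
    if (n_ev > 0) {
      for (d in sample(c(-1L, 1L), n_ev, replace = TRUE)) {
        s_new <- s + d
        if (s_new < 1L || s_new > K) s_new <- s - d  # reflect at boundary
        if (s_new != s) n_changes <- n_changes + 1L
        s <- s_new
      }
    }
    state[ch] <- s
  }
  structure(stats::setNames(state[seq_len(n)], tree$tip.label),
            node_states = state, n_changes = n_changes)
}

#' Synthesize a complete comparative study
#'
#' Generates, under one seed: a fossil pure-birth tree rescaled to unit
#' height; a Brownian cranial log length (root ln 150 mm); the three jaw
#' reference log lengths as anatomical offsets from cranial length plus
#' small Brownian noise; an ordered five-state complexity character; and
#' the log length to post-dentition as
#' `intercept + slope_reference * cranial + beta_complexity * level +
#' lambda-structured noise`. A stated fraction of taxa lose their
#' post-maxilla measurement. The generator and the PGLS estimator share the
#' same likelihood family, so parameter recovery is a fair test of the
#' estimator.
#'
#' @param config A [study_config()].
#' @return List `tree` (`phylo`), `records` (measurement table), `truth`
#'   (generating parameters, node states of the complexity walk, and the
#'   noise-free expectations).
#' @export
synthesize_study <- function(config = study_config()) {
  set.seed(config$seed)
  tree <- scale_tree_height(simulate_tree(config$n_taxa, fossil = TRUE))
  cranial <- simulate_bm(tree, sigma2 = 0.05, root_value = log(150), lambda = 1)
  # anatomical offsets (log scale): ante-palatine ~40%, post-palatine ~70%,
  # post-maxilla ~80% of cranial length, each with small independent BM noise
  ante <- cranial - 0.9 + simulate_bm(tree, 0.005)
  postpal <- cranial - 0.35 + simulate_bm(tree, 0.005)
  postmax <- cranial - 0.20 + simulate_bm(tree, 0.005)
  walk <- simulate_ordered_walk(tree, config$complexity_step_rate, K = 5L)
  eps <- simulate_bm(tree, config$sigma2_true, 0, config$lambda_true)
  postdent <- config$intercept + config$slope_reference * cranial +
    config$beta_complexity * as.numeric(walk) + eps
  n_miss <- round(config$fraction_missing_post_maxilla * config$n_taxa)
  miss <- if (n_miss > 0) sample(tree$tip.label, n_miss) else character(0)
  postmax[miss] <- NA_real_
  records <- data.frame(taxon = tree$tip.label,
                        len_post_dentition = unname(postdent),
                        len_ante_palatine = unname(ante),
                        len_post_palatine = unname(postpal),
                        len_post_maxilla = unname(postmax),
                        len_cranial = unname(cranial),
                        complexity = as.integer(walk),
                        row.names = NULL)
  list(tree = tree,
       records = validate_measurements(records),
       truth = list(config = config,
                    complexity_node_states = attr(walk, "node_states"),
                    complexity_changes = attr(walk, "n_changes"),
                    residual_noise = eps,
                    missing_post_maxilla = miss))
}

#' Emit landmark sheets consistent with a measurement table
#'
#' Inverse of the measurement step, for end-to-end tests: places the 10
#' landmarks of each taxon on a cranium-like configuration whose midline
#' projections reproduce the (back-transformed) lengths, applies a random
#' rigid motion per specimen, and attaches the cranial length as the scale
#' proxy.
#'
#' @param records Measurement table.
#' @param jitter Half-width of the lateral (off-midline) landmark offsets,
#'   as a fraction of cranial length.
#' @param seed Optional integer seed for the rigid motions.
#' @return List of [landmark_config()] objects.
#' @export
emit_landmarks <- function(records, jitter = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    cr <- exp(r$len_cranial)
    lens <- c(exp(r$len_post_dentition), exp(r$len_ante_palatine),
              exp(r$len_post_palatine),
              if (is.na(r$len_post_maxilla)) NA_real_ else exp(r$len_post_maxilla))
    xy <- matrix(NA_real_, 10, 2)
    xy[1, ] <- c(0, 0)
    xy[2, ] <- c(cr, 0)
    for (k in seq_len(4)) {
      off <- stats::runif(1, 0.02, jitter) * cr
      xy[2 * k + 1, ] <- c(lens[k], off)
      xy[2 * k + 2, ] <- c(lens[k], -off)
    }
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shift <- stats::runif(2, -100, 100)
    u <- stats::runif(1, 0.5, 2)  # arbitrary illustration scale
    ok <- stats::complete.cases(xy)
    xy[ok, ] <- sweep(u * xy[ok, , drop = FALSE] %*% t(R), 2, -shift)
    landmark_config(r$taxon, xy, proxy_skull_length = cr)
  })
}
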