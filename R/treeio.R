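#' Parse rooted time-scaled trees from Newick or NEXUS text
#'
#' Reads one or more rooted trees with branch lengths from a file or a
#' character string. NEXUS input is detected by a leading `#NEXUS` token;
#' anything else is treated as (possibly multi-line, multi-tree) Newick.
#' Before handing the text to the parser, parenthesis balance is checked so
#' that malformed input fails with the character offset of the first
#' imbalance rather than an opaque downstream error.
#'
#' @param file Path to a tree file (Newick or NEXUS with a TREES block).
#' @param text Serialized tree text, used instead of `file` when given.
#' @return A `phylo` object for single-tree input, or a `multiPhylo` list for
#'   multi-tree input.
#' @export
parse_trees <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  }
  if (grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(text, tf)
    trees <- ape::read.nexus(tf)
  } else {
    .check_newick_syntax(text)
    trees <- ape::read.tree(text = text)
    if (is.null(trees)) stop("parse error: no tree found in input text")
  }
  if (inherits(trees, "phylo")) {
    .validate_tree(trees)
  } else {
    lapply(trees, .validate_tree)
    class(trees) <- "multiPhylo"
  }
  trees
}

# Balanced-parenthesis scan; reports 1-based character offset of the first
# unmatched parenthesis so malformed Newick fails with a location.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("parse error: unmatched ')' at character offset %d", i))
    }
  }
  if (depth > 0L) {
    last_open <- max(which(chars == "("))
    stop(sprintf("parse error: unclosed '(' at character offset %d", last_open))
  }
  invisible(TRUE)
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("validation error: duplicate tip label(s): ", paste(dup, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("validation error: negative branch length")
  if (!is.null(tree$edge.length) && any(tree$edge.length == 0))
    warning("tree contains zero-length branches; consider collapse_zero_edges()")
  invisible(tree)
}

#' Write trees to Newick or NEXUS
#'
#' @param trees A `phylo` or `multiPhylo` object.
#' @param file Output path; the format is chosen by `format`.
#' @param format `"newick"` or `"nexus"`.
#' @return `file`, invisibly.
#' @export
write_trees <- function(trees, file, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "newick") {
    ape::write.tree(trees, file = file, digits = 17)  # exact double round trip
  } else {
    # write the TREES block directly: ape::write.nexus truncates lengths to
    # its default precision, which breaks lossless round trips
    nwk <- ape::write.tree(trees, digits = 17)
    lines <- c("#NEXUS", "BEGIN TREES;",
               sprintf("\tTREE tree%d = [&R] %s", seq_along(nwk), nwk),
               "END;")
    writeLines(lines, file)
  }
  invisible(file)
}

## ---- node ages and depths -------------------------------------------------

#' Root-to-node depths (time since the root)
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Numeric vector over all node ids (tips then internals); root = 0.
#' @export
node_depths <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  depth <- numeric(n + tree$Nnode)
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  for (i in seq_len(nrow(tr$edge))) {
    depth[tr$edge[i, 2]] <- depth[tr$edge[i, 1]] + tr$edge.length[i]
  }
  depth[root] <- 0
  depth
}

#' Node ages (time before present)
#'
#' The present is defined as the deepest tip; fossil tips have positive age.
#'
#' @inheritParams node_depths
#' @return Numeric vector of ages over all node ids.
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

## ---- consensus with branch lengths ----------------------------------------

# Rooted clades of a tree as sorted tip-label sets, with the subtending edge
# length for each. The root clade (full tip set) carries no edge.
.rooted_clades <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  tips_below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) tips_below[[i]] <- tree$tip.label[i]
  tr <- stats::reorder(tree, "postorder")
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1]; ch <- tr$edge[i, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }
  ids <- setdiff(seq_len(n + tree$Nnode), root)
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  list(
    keys = vapply(ids, function(v) paste(sort(tips_below[[v]]), collapse = "\r"),
                  character(1)),
    lengths = elen[ids]
  )
}

#' Majority-rule consensus tree with branch lengths
#'
#' Computes the rooted majority-rule consensus of a set of trees sharing one
#' tip set. A clade is retained when its frequency strictly exceeds
#' `threshold`; each retained edge's length is the arithmetic mean of that
#' edge's length over the trees that contain the clade. Edges absent from the
#' consensus produce polytomies, so the output may be non-binary.
#'
#' @param trees A `multiPhylo` (or list) of rooted trees with branch lengths,
#'   all sharing the same tip labels.
#' @param threshold Clade-retention threshold in `(0.5, 1]`; default `0.5`
#'   keeps clades present in more than half the trees.
#' @return A rooted `phylo`, possibly with polytomies.
#' @export
consensus_with_lengths <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (threshold < 0.5 || threshold > 1)
    stop("threshold must be in [0.5, 1]")
  ntree <- length(trees)
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  base <- tipsets[[1]]
  for (k in seq_along(tipsets)) {
    if (!identical(tipsets[[k]], base)) {
      bad <- c(setdiff(tipsets[[k]], base), setdiff(base, tipsets[[k]]))
      stop("validation error: tip-set mismatch in tree ", k, ": ",
           paste(bad, collapse = ", "))
    }
  }
  counts <- new.env(parent = emptyenv())
  sums <- new.env(parent = emptyenv())
  firsts <- new.env(parent = emptyenv())   # to short-circuit unanimous means
  same <- new.env(parent = emptyenv())
  for (t in trees) {
    cl <- .rooted_clades(t)
    for (j in seq_along(cl$keys)) {
      k <- cl$keys[j]; len <- cl$lengths[j]
      if (is.null(counts[[k]])) {
        counts[[k]] <- 1L; sums[[k]] <- len; firsts[[k]] <- len; same[[k]] <- TRUE
      } else {
        counts[[k]] <- counts[[k]] + 1L
        sums[[k]] <- sums[[k]] + len
        if (same[[k]] && len != firsts[[k]]) same[[k]] <- FALSE
      }
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1)) / ntree
  keep <- keys[freq > threshold]
  # mean length over supporting trees; exact value when unanimous within clade
  mean_len <- vapply(keep, function(k) {
    if (same[[k]]) firsts[[k]] else sums[[k]] / counts[[k]]
  }, numeric(1))
  names(mean_len) <- keep
  clade_sets <- lapply(strsplit(keep, "\r", fixed = TRUE), sort)
  names(clade_sets) <- keep
  sizes <- lengths(clade_sets)

  build <- function(members) {
    # children: maximal retained proper subsets of `members`
    inside <- keep[vapply(keep, function(k)
      sizes[[k]] < length(members) && all(clade_sets[[k]] %in% members),
      logical(1))]
    inside <- inside[order(-sizes[inside])]
    children <- character(0)
    covered <- character(0)
    for (k in inside) {
      if (!any(clade_sets[[k]] %in% covered)) {
        children <- c(children, k)
        covered <- c(covered, clade_sets[[k]])
      }
    }
    parts <- vapply(children, function(k) {
      sub <- if (sizes[[k]] == 1L) .quote_label(clade_sets[[k]])
             else build(clade_sets[[k]])
      sprintf("%s:%.17g", sub, mean_len[[k]])
    }, character(1))
    stray <- setdiff(members, covered)  # tips directly under this node
    parts <- c(parts, vapply(stray, function(tp)
      sprintf("%s:%.17g", .quote_label(tp), mean_len[[tp]]), character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  if (length(base) == 1L) {
    nwk <- sprintf("(%s:%.17g);", .quote_label(base), mean_len[[base]])
  } else {
    nwk <- paste0(build(base), ";")
  }
  ape::read.tree(text = nwk)
}

.quote_label <- function(x) {
  if (grepl("[ ():,;\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

## ---- pruning and grafting -------------------------------------------------

#' Prune a tree to a set of taxa
#'
#' Unbranched internal nodes left by the pruning are collapsed with branch
#' lengths summed, so patristic distances among the kept tips are unchanged.
#'
#' @param tree A rooted `phylo`.
#' @param keep Character vector of tip labels to retain (at least 2, or 1 to
#'   reduce to a single-tip tree is not supported).
#' @return The pruned `phylo`.
#' @export
prune_tree <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("validation error: unknown taxa in keep: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("keep must contain at least 2 taxa")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Graft a new tip onto an edge at a specified age
#'
#' Splits the edge above `edge_child` at `stem_attach_age` (time before
#' present, where the present is the deepest tip) and attaches a new tip of
#' age `tip_age`. All pre-existing node ages are unchanged.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param new_taxon Label for the new tip (must not already be present).
#' @param edge_child Tip label or node id identifying the child end of the
#'   attachment edge.
#' @param stem_attach_age Age at which the new lineage diverges; must lie
#'   strictly within the ages spanned by the attachment edge.
#' @param tip_age Age of the new tip; `0 <= tip_age < stem_attach_age`.
#' @return A `phylo` with one more tip.
#' @export
graft_tip <- function(tree, new_taxon, edge_child, stem_attach_age, tip_age = 0) {
  if (new_taxon %in% tree$tip.label)
    stop("validation error: tip label already present: ", new_taxon)
  n <- ape::Ntip(tree)
  if (is.character(edge_child)) {
    idx <- match(edge_child, tree$tip.label)
    if (is.na(idx)) stop("validation error: unknown edge_child taxon: ", edge_child)
    child <- idx
  } else {
    child <- as.integer(edge_child)
    if (child < 1L || child > n + tree$Nnode || child == n + 1L)
      stop("validation error: edge_child is not a non-root node id")
  }
  age <- node_ages(tree)
  ei <- which(tree$edge[, 2] == child)
  parent <- tree$edge[ei, 1]
  if (!(stem_attach_age > age[child] && stem_attach_age < age[parent]))
    stop(sprintf(
      "validation error: stem_attach_age %.6g outside edge span (%.6g, %.6g)",
      stem_attach_age, age[child], age[parent]))
  if (!(tip_age >= 0 && tip_age < stem_attach_age))
    stop("validation error: tip_age must satisfy 0 <= tip_age < stem_attach_age")

  # renumber: tips 1..n keep ids, new tip n+1; internals shift by 1; the new
  # internal node takes the last id so the old root stays at Ntip+1
  shift <- function(v) ifelse(v > n, v + 1L, v)
  new_tip <- n + 1L
  new_node <- n + tree$Nnode + 2L
  edge <- cbind(shift(tree$edge[, 1]), shift(tree$edge[, 2]))
  elen <- tree$edge.length
  child_new <- shift(child)
  # split the attachment edge
  edge[ei, ] <- c(shift(parent), new_node)
  elen[ei] <- age[parent] - stem_attach_age
  edge <- rbind(edge,
                c(new_node, child_new),
                c(new_node, new_tip))
  elen <- c(elen,
            stem_attach_age - age[child],
            stem_attach_age - tip_age)
  out <- list(edge = edge,
              edge.length = elen,
              tip.label = c(tree$tip.label, new_taxon),
              Nnode = tree$Nnode + 1L)
  class(out) <- "phylo"
  stats::reorder(out, "cladewise")
}

#' Collapse zero-length internal edges into polytomies
#'
#' Weighted squared-change parsimony and the phylogenetic covariance both
#' assume strictly positive internal branch lengths; this collapses
#' zero-length internal edges (within `tol`) into hard polytomies.
#'
#' @param tree A `phylo`.
#' @param tol Lengths `<= tol` are treated as zero.
#' @return A `phylo`, possibly multifurcating.
#' @export
collapse_zero_edges <- function(tree, tol = 0) {
  # di2multi collapses edges strictly below its tolerance, so nudge it to
  # make the comparison effectively <= tol
  ape::di2multi(tree, tol = tol + 1e-300)
}

#' Pairwise patristic distances between tips
#'
#' @param tree A `phylo` with branch lengths.
#' @return A symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}
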