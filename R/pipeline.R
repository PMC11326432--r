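.references <- c("ante_palatine", "post_palatine", "post_maxilla", "cranial")
.model_labels <- stats::setNames(c("(a)", "(b)", "(c)", "(d)"), .references)

#' Run the full comparative study
#'
#' Orchestrates the whole analysis from trees and a measurement table to the
#' reporting surface: (1) majority-rule consensus with branch lengths when
#' several trees are supplied; (2) pruning to the measured taxa (plus
#' optional tip grafts); (3) per-taxon complexity levels, either from the
#' measurement table or scored from a tooth-descriptor table; (4) dentition
#' position as PGLS residuals against each of the four reference lengths;
#' (5) ordered-parsimony ancestral states of complexity with
#' acquisition/loss counts per level, and squared-change ancestral states of
#' the four residual characters; (6) the four PGLS correlation models of
#' complexity on length to post-dentition controlling for each reference
#' length, reported as one coefficient block per model labelled (a)-(d).
#'
#' @param trees A `phylo`, `multiPhylo`, or path to a tree file.
#' @param measurements Measurement data frame or CSV path (see
#'   [read_measurements()]).
#' @param descriptors Optional tooth-descriptor data frame or CSV path; when
#'   given, complexity levels are (re)scored from it.
#' @param grafts Optional data frame with columns `new_taxon`, `edge_child`,
#'   `stem_attach_age`, `tip_age` of tips to graft before pruning.
#' @param consensus_threshold Clade-retention threshold for the consensus.
#' @param weighted_asr Use branch-length-weighted squared-change parsimony.
#' @param out_dir Optional output directory; when given, writes the
#'   regression table, residual tables, annotated trees and a JSON manifest.
#' @return List with `tree`, `records`, `regression` (long coefficient
#'   table), `fits`, `residuals`, `ordered_asr`, `gain_loss`,
#'   `continuous_asr`, `manifest`. Deterministic given its inputs.
#' @export
run_study <- function(trees, measurements, descriptors = NULL, grafts = NULL,
                      consensus_threshold = 0.5, weighted_asr = TRUE,
                      out_dir = NULL) {
  if (is.character(trees)) trees <- parse_trees(trees)
  tree <- if (inherits(trees, "phylo")) trees
          else consensus_with_lengths(trees, threshold = consensus_threshold)
  records <- if (is.character(measurements)) read_measurements(measurements)
             else validate_measurements(measurements)
  if (!is.null(descriptors)) {
    if (is.character(descriptors))
      descriptors <- utils::read.csv(descriptors, stringsAsFactors = FALSE)
    sc <- score_descriptor_table(descriptors)
    records$complexity <- sc$complexity[match(records$taxon, sc$taxon)]
    records <- validate_measurements(records)
  }
  if (!is.null(grafts)) {
    for (i in seq_len(nrow(grafts))) {
      tree <- graft_tip(tree, grafts$new_taxon[i], grafts$edge_child[i],
                        grafts$stem_attach_age[i], grafts$tip_age[i])
    }
  }
  absent <- setdiff(records$taxon, tree$tip.label)
  if (length(absent))
    stop("stage prune: measured taxa absent from tree: ",
         paste(absent, collapse = ", "))
  tree <- prune_tree(tree, records$taxon)
  tree <- collapse_zero_edges(tree)

  # dentition position residuals and correlation models, one per reference
  resids <- list(); fits <- list(); reg_rows <- list()
  for (ref in .references) {
    pr <- position_residuals(records, ref, tree)
    resids[[ref]] <- pr
    fit <- correlation_model(records, ref, tree)
    fits[[ref]] <- fit
    ct <- coef_table(fit)
    ct$model <- .model_labels[[ref]]
    ct$reference <- ref
    ct$lambda <- fit$lambda
    ct$n <- fit$n
    reg_rows[[ref]] <- ct[, c("model", "reference", "term", "estimate",
                              "se", "t", "p", "lambda", "n")]
  }
  regression <- do.call(rbind, reg_rows)
  rownames(regression) <- NULL

  # ancestral states: ordered complexity + continuous residual characters
  lv <- stats::setNames(records$complexity, records$taxon)
  oasr <- sankoff_ordered(tree, lv, K = 5L)
  gain_loss <- lapply(stats::setNames(2:5, paste0("level_", 2:5)),
                      function(l) count_acquisitions(oasr, l))
  casr <- lapply(resids, function(pr) {
    sub <- prune_tree(tree, names(pr$residuals))
    squared_change_asr(sub, pr$residuals, weighted = weighted_asr)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("toothpos")),
    n_taxa = nrow(records),
    consensus_threshold = consensus_threshold,
    weighted_continuous_asr = weighted_asr,
    lambda_hat = lapply(fits, function(f) f$lambda),
    complexity_cost = oasr$total_cost,
    gain_loss = gain_loss,
    dropped_post_maxilla = setdiff(records$taxon,
                                   names(resids$post_maxilla$residuals)))
  out <- list(tree = tree, records = records, regression = regression,
              fits = fits, residuals = resids, ordered_asr = oasr,
              gain_loss = gain_loss, continuous_asr = casr,
              manifest = manifest)
  if (!is.null(out_dir)) .write_report(out, out_dir)
  out
}

.write_report <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$regression, file.path(out_dir, "regression_table.csv"),
                   row.names = FALSE, quote = FALSE)
  res_tab <- do.call(rbind, lapply(out$residuals, function(pr)
    data.frame(taxon = names(pr$residuals), reference = pr$reference,
               residual = unname(pr$residuals), row.names = NULL)))
  utils::write.csv(res_tab, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE, quote = FALSE)
  write_annotated_tree(out$ordered_asr,
                       file.path(out_dir, "asr_complexity.nwk"))
  for (ref in names(out$continuous_asr)) {
    write_annotated_tree(out$continuous_asr[[ref]],
                         file.path(out_dir, paste0("asr_position_", ref, ".nwk")))
  }
  write_trees(out$tree, file.path(out_dir, "analysis_tree.nwk"))
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
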