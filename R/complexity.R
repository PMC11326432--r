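#' Structured descriptor of one tooth's cusp pattern
#'
#' Captures what the five-level complexity rubric needs: the cusp count, the
#' view the tooth was scored from, the largest perpendicular deviation of any
#' cusp from the mesio-distal cusp row (in units of cusp width), and whether
#' cusp rows are present on both the lingual and buccal sides. A tooth known
#' only from a lateral view cannot show deviation or double rows, so those
#' fields must be 0 / FALSE there.
#'
#' @param cusp_count Positive integer.
#' @param view `"occlusal"` or `"lateral_only"`.
#' @param max_deviation Non-negative real, largest deviation in cusp widths
#'   (0 when unknown or inapplicable).
#' @param both_rows Logical: rows of cusps on both lingual and buccal sides.
#' @return An object of class `tooth_descriptor`.
#' @export
tooth_descriptor <- function(cusp_count, view = c("occlusal", "lateral_only"),
                             max_deviation = 0, both_rows = FALSE) {
  view <- match.arg(view)
  if (!is.numeric(cusp_count) || cusp_count < 1 || cusp_count != round(cusp_count))
    stop("validation error: cusp_count must be a positive integer")
  if (max_deviation < 0)
    stop("validation error: max_deviation must be non-negative")
  if (view == "lateral_only" && (max_deviation != 0 || isTRUE(both_rows)))
    stop("validation error: lateral-only views cannot record deviation or double rows")
  structure(list(cusp_count = as.integer(cusp_count), view = view,
                 max_deviation = as.numeric(max_deviation),
                 both_rows = isTRUE(both_rows)),
            class = "tooth_descriptor")
}

#' Classify one tooth into a complexity level
#'
#' The rubric, applied in order of decreasing complexity:
#' level 5 — cusp rows on both lingual and buccal sides (an added lingual
#' cusp row); level 4 — more than two cusps with one deviated from the cusp
#' row by strictly more than one cusp width (triangular arrangement); level
#' 1 — a single cusp; level 2 — two or three cusps in a mesio-distal row;
#' level 3 — more than three cusps in a row (including along a cingulum).
#' Lateral-only views are assumed linear, so they can only score 1-3.
#'
#' @param tooth A [tooth_descriptor()].
#' @return Integer level in 1..5.
#' @export
classify_tooth <- function(tooth) {
  if (!inherits(tooth, "tooth_descriptor"))
    tooth <- do.call(tooth_descriptor, as.list(tooth))
  if (tooth$both_rows) return(5L)
  if (tooth$cusp_count > 2L && tooth$max_deviation > 1) return(4L)
  if (tooth$cusp_count == 1L) return(1L)
  if (tooth$cusp_count <= 3L) return(2L)
  3L
}

#' Score a taxon from its teeth
#'
#' A taxon's complexity level is the highest level found among its teeth.
#'
#' @param teeth Non-empty list of [tooth_descriptor()] objects.
#' @return Integer level in 1..5.
#' @export
score_taxon <- function(teeth) {
  if (!length(teeth)) stop("validation error: empty tooth list")
  max(vapply(teeth, classify_tooth, integer(1)))
}

#' Score a descriptor table into per-taxon levels
#'
#' @param df Data frame with columns `taxon`, `cusp_count`, `view`,
#'   `max_deviation`, `both_rows` (one row per tooth).
#' @return Data frame `taxon`, `complexity`, one row per taxon.
#' @export
score_descriptor_table <- function(df) {
  need <- c("taxon", "cusp_count", "view", "max_deviation", "both_rows")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation error: descriptor table missing columns: ",
         paste(miss, collapse = ", "))
  levels <- vapply(split(df, df$taxon), function(d) {
    score_taxon(lapply(seq_len(nrow(d)), function(i)
      tooth_descriptor(d$cusp_count[i], d$view[i], d$max_deviation[i],
                       as.logical(d$both_rows[i]))))
  }, integer(1))
  data.frame(taxon = names(levels), complexity = unname(levels),
             row.names = NULL)
}
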