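#' Landmark configuration for one cranium
#'
#' Ten named 2-D landmarks digitized on a ventral-view cranium illustration:
#' (1) anterior end of the premaxilla and (2) basion define the midline;
#' the paired landmarks (3,4) posterior end of the dentition, (5,6) anterior
#' end of the palatine, (7,8) posterior end of the palatine and (9,10)
#' posterior end of the maxilla sit left/right of it. Pair (9,10) may be
#' absent (`NA` coordinates) when the posterior end of the maxilla cannot be
#' identified in the available illustration.
#'
#' @param specimen_id Specimen/taxon label.
#' @param landmarks A 10 x 2 numeric matrix of (x, y) coordinates in
#'   illustration units; rows 9 and 10 may be `NA`.
#' @param scale Optional mm-per-illustration-unit factor.
#' @param proxy_skull_length Optional published skull length in mm, used as a
#'   scale proxy when `scale` is absent.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(specimen_id, landmarks, scale = NULL,
                            proxy_skull_length = NULL) {
  landmarks <- as.matrix(landmarks)
  if (nrow(landmarks) != 10L || ncol(landmarks) != 2L)
    stop("landmarks must be a 10 x 2 matrix")
  if (anyNA(landmarks[1:2, ]))
    stop("validation error: landmarks 1 and 2 (midline) must be present")
  if (anyNA(landmarks[3:8, ]))
    stop("validation error: landmarks 3-8 must be present (only pair 9,10 may be absent)")
  if (all(landmarks[1, ] == landmarks[2, ]))
    stop("degenerate-midline error: landmarks 1 and 2 coincide")
  if (!is.null(scale) && scale <= 0) stop("scale must be positive")
  if (!is.null(proxy_skull_length) && proxy_skull_length <= 0)
    stop("proxy_skull_length must be positive")
  structure(list(specimen_id = specimen_id, landmarks = unname(landmarks),
                 scale = scale, proxy_skull_length = proxy_skull_length),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration:", x$specimen_id, "\n")
  cat("  present landmarks:", sum(stats::complete.cases(x$landmarks)), "of 10\n")
  if (!is.null(x$scale)) cat("  scale:", x$scale, "mm/unit\n")
  if (!is.null(x$proxy_skull_length))
    cat("  proxy skull length:", x$proxy_skull_length, "mm\n")
  invisible(x)
}

#' Project landmarks onto the cranial midline
#'
#' The midline is the line through landmark 1 (anterior end of the premaxilla)
#' and landmark 2 (basion). Each landmark's anteroposterior position is the
#' foot of its perpendicular to the midline, expressed as a signed distance
#' from landmark 1 (positive toward landmark 2). Equivalently, the scalar
#' projection of (Lk - L1) onto the unit vector from L1 to L2.
#'
#' @param config A [landmark_config()].
#' @return Named numeric vector of axial positions indexed "1".."10" (`NA`
#'   for absent landmarks); position 1 is 0 and position 2 is the L1-L2
#'   distance.
#' @export
project_to_midline <- function(config) {
  lm <- config$landmarks
  v <- lm[2, ] - lm[1, ]
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate-midline error: landmarks 1 and 2 coincide")
  u <- v / len
  pos <- as.numeric((lm[, 1] - lm[1, 1]) * u[1] + (lm[, 2] - lm[1, 2]) * u[2])
  names(pos) <- as.character(1:10)
  pos
}

#' Resolve the mm-per-unit scale factor for a configuration
#'
#' If a digitized scale is available it is used directly; otherwise the
#' published skull length of the taxon serves as a proxy, divided by the
#' illustration-unit midline length L1-L2.
#'
#' @param config A [landmark_config()].
#' @return Positive scalar, mm per illustration unit.
#' @export
calibrate_scale <- function(config) {
  if (!is.null(config$scale)) return(config$scale)
  if (!is.null(config$proxy_skull_length)) {
    d12 <- sqrt(sum((config$landmarks[2, ] - config$landmarks[1, ])^2))
    return(config$proxy_skull_length / d12)
  }
  stop("calibration error: neither scale nor proxy skull length available for ",
       config$specimen_id)
}

# landmark pairs defining each anteroposterior length
.length_pairs <- list(
  len_post_dentition = c(3L, 4L),
  len_ante_palatine  = c(5L, 6L),
  len_post_palatine  = c(7L, 8L),
  len_post_maxilla   = c(9L, 10L)
)

#' Compute the five anteroposterior lengths from a configuration
#'
#' Each paired length is the mean of the left and right axial positions,
#' converted to mm with the calibrated scale factor and then natural-logged.
#' Cranial length is the axial position of landmark 2 (basion). The absent
#' pair (9,10) yields an `NA` post-maxilla length.
#'
#' @param config A [landmark_config()].
#' @param complexity Integer tooth-complexity level 1-5 for the taxon.
#' @return One-row data frame: taxon, the five natural-log mm lengths, and
#'   the complexity level.
#' @export
compute_lengths <- function(config, complexity = NA_integer_) {
  pos <- project_to_midline(config)
  s <- calibrate_scale(config)
  out <- lapply(.length_pairs, function(pr) {
    p <- pos[pr]
    if (anyNA(p)) {
      if (!identical(pr, c(9L, 10L)))
        stop("validation error: landmarks ", pr[1], ",", pr[2],
             " absent in ", config$specimen_id)
      return(NA_real_)
    }
    len_mm <- mean(p) * s
    if (len_mm <= 0)
      stop("validation error: non-positive pre-log length for landmarks ",
           pr[1], ",", pr[2], " in ", config$specimen_id,
           " (landmark behind landmark 1?)")
    log(len_mm)
  })
  cranial_mm <- pos["2"] * s
  if (cranial_mm <= 0) stop("validation error: non-positive cranial length")
  data.frame(taxon = config$specimen_id,
             len_post_dentition = out$len_post_dentition,
             len_ante_palatine = out$len_ante_palatine,
             len_post_palatine = out$len_post_palatine,
             len_post_maxilla = out$len_post_maxilla,
             len_cranial = as.numeric(log(cranial_mm)),
             complexity = as.integer(complexity),
             row.names = NULL)
}

#' Measure a batch of configurations into a measurement table
#'
#' @param configs List of [landmark_config()] objects.
#' @param complexity Named integer vector of complexity levels, indexed by
#'   specimen id (optional).
#' @return Measurement table (one row per taxon) as produced by
#'   [compute_lengths()].
#' @export
measure_specimens <- function(configs, complexity = NULL) {
  rows <- lapply(configs, function(cf) {
    lev <- if (!is.null(complexity) && cf$specimen_id %in% names(complexity))
      complexity[[cf$specimen_id]] else NA_integer_
    compute_lengths(cf, lev)
  })
  do.call(rbind, rows)
}

## ---- TPS and tabular I/O --------------------------------------------------

#' Read landmark configurations from a TPS file
#'
#' Supports the dialect written by standard 2-D digitizing tools: `LM=`
#' starts a record and gives the landmark count, `ID=` names the specimen,
#' `SCALE=` gives mm per unit; `IMAGE=` lines are ignored. Coordinates are
#' y-up. Absent landmarks are encoded as `NA NA` coordinate lines.
#'
#' @param file Path to a TPS file with 10-landmark records.
#' @param proxy_skull_lengths Optional named vector of published skull
#'   lengths (mm) by specimen id, used when a record carries no `SCALE=`.
#' @return List of [landmark_config()] objects.
#' @export
read_tps <- function(file, proxy_skull_lengths = NULL) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (!length(starts)) stop("parse error: no LM= records in TPS file")
  ends <- c(starts[-1] - 1L, length(lines))
  configs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    nlm <- as.integer(sub("^LM\\s*=\\s*", "", block[1]))
    if (is.na(nlm) || nlm != 10L)
      stop("parse error: expected LM=10, got '", block[1], "'")
    coord_lines <- block[2:(1 + nlm)]
    xy <- t(vapply(coord_lines, function(ln) {
      parts <- strsplit(ln, "\\s+")[[1]]
      if (length(parts) != 2L)
        stop("parse error: bad coordinate line '", ln, "'")
      suppressWarnings(as.numeric(parts))
    }, numeric(2)))
    rest <- if (length(block) > 1 + nlm) block[(2 + nlm):length(block)] else character(0)
    id <- sub("^ID\\s*=\\s*", "", grep("^ID\\s*=", rest, value = TRUE))
    scale_line <- grep("^SCALE\\s*=", rest, value = TRUE)
    scale <- if (length(scale_line))
      as.numeric(sub("^SCALE\\s*=\\s*", "", scale_line[1])) else NULL
    id <- if (length(id)) id[1] else paste0("specimen_", r)
    proxy <- if (!is.null(proxy_skull_lengths) && id %in% names(proxy_skull_lengths))
      unname(proxy_skull_lengths[[id]]) else NULL
    configs[[r]] <- landmark_config(id, xy, scale = scale,
                                    proxy_skull_length = proxy)
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs List of [landmark_config()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_tps <- function(configs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines("LM=10", con)
    apply(cf$landmarks, 1, function(p)
      writeLines(paste(format(p[1], digits = 12), format(p[2], digits = 12)), con))
    writeLines(paste0("ID=", cf$specimen_id), con)
    if (!is.null(cf$scale)) writeLines(paste0("SCALE=", format(cf$scale, digits = 12)), con)
  }
  invisible(file)
}

#' Read landmark configurations from a long-format table
#'
#' Expected columns: `specimen`, `landmark` (1-10), `x`, `y`, and optionally
#' `scale` and `proxy_skull_length` (constant within specimen).
#'
#' @param file Path to a delimited file readable by [utils::read.csv()].
#' @param ... Passed to [utils::read.csv()].
#' @return List of [landmark_config()] objects.
#' @export
read_landmark_table <- function(file, ...) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, ...)
  need <- c("specimen", "landmark", "x", "y")
  if (!all(need %in% names(df)))
    stop("parse error: landmark table needs columns ", paste(need, collapse = ", "))
  lapply(split(df, df$specimen), function(d) {
    xy <- matrix(NA_real_, 10, 2)
    xy[d$landmark, ] <- cbind(d$x, d$y)
    sc <- if ("scale" %in% names(d) && !all(is.na(d$scale))) d$scale[1] else NULL
    px <- if ("proxy_skull_length" %in% names(d) && !all(is.na(d$proxy_skull_length)))
      d$proxy_skull_length[1] else NULL
    landmark_config(d$specimen[1], xy, scale = sc, proxy_skull_length = px)
  })
}

#' Read a measurement table
#'
#' The table mirrors the layout of a per-taxon supplementary data sheet:
#' columns `taxon`, `len_post_dentition`, `len_ante_palatine`,
#' `len_post_palatine`, `len_post_maxilla`, `len_cranial` (natural-log mm;
#' post-maxilla may be `NA`) and `complexity` (integer 1-5).
#'
#' @param file CSV path.
#' @return Validated measurement data frame.
#' @export
read_measurements <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' Validate a measurement table
#'
#' @param df Data frame in the [read_measurements()] layout.
#' @return The data frame, invisibly usable, with checked invariants.
#' @export
validate_measurements <- function(df) {
  need <- c("taxon", "len_post_dentition", "len_ante_palatine",
            "len_post_palatine", "len_post_maxilla", "len_cranial",
            "complexity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation error: measurement table missing columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$taxon))
    stop("validation error: duplicate taxa in measurement table")
  core <- c("len_post_dentition", "len_ante_palatine", "len_post_palatine",
            "len_cranial")
  if (anyNA(df[core]))
    stop("validation error: missing values in required length columns")
  lv <- df$complexity
  if (any(!is.na(lv) & (lv < 1 | lv > 5 | lv != round(lv))))
    stop("validation error: complexity levels must be integers in 1..5")
  df$complexity <- as.integer(df$complexity)
  df
}

#' Write a measurement table
#' @param df Measurement data frame.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_measurements <- function(df, file) {
  # full-precision numeric output so write -> read round trips exactly
  for (cl in names(df)) {
    if (is.double(df[[cl]])) {
      v <- sprintf("%.17g", df[[cl]])
      v[is.na(df[[cl]])] <- "NA"
      df[[cl]] <- v
    }
  }
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(file)
}
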