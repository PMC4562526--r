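#' Write a contour set to JSON
#'
#' Serializes a phantom or a named list of contours to the package's contour
#' schema: \code{\{units: "mm", center: [x, y], coverage_deg,
#' contours: [\{name, points: [[x, y], ...]\}]\}}.
#'
#' @param x An \code{airway_phantom}, or a list with elements
#'   \code{contours} (named list of n x 2 matrices), \code{center},
#'   \code{coverage_deg}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_contours <- function(x, path) {
  if (inherits(x, "airway_phantom")) {
    contours <- c(list(lumen = x$lumen_contour), x$interface_contours)
    center <- x$center
    coverage <- x$coverage_deg
  } else {
    contours <- x$contours
    center <- x$center
    coverage <- if (is.null(x$coverage_deg)) 360 else x$coverage_deg
  }
  obj <- list(
    units = "mm",
    center = as.numeric(center),
    coverage_deg = as.numeric(coverage),
    contours = lapply(names(contours), function(nm)
      list(name = nm, points = unname(apply(contours[[nm]], 1L, c,
                                            simplify = FALSE))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour set from JSON
#'
#' Validates and parses a contour file written by \code{\link{write_contours}}.
#' Units must be mm (pixel files need a separate mm-per-px conversion before
#' import); non-finite points and malformed schemas are rejected with an
#' error naming the offending field.
#'
#' @param path Input file path.
#' @return List with \code{center}, \code{coverage_deg}, \code{contours}
#'   (named list of n x 2 matrices).
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed contour JSON: ", conditionMessage(e)))
  if (is.null(obj$units)) stop("contour schema error: missing field 'units'")
  if (!identical(obj$units, "mm"))
    stop("contour schema error: field 'units' must be \"mm\", got \"",
         obj$units, "\"")
  if (is.null(obj$center) || length(obj$center) != 2L)
    stop("contour schema error: field 'center' must be [x, y]")
  if (is.null(obj$contours) || !length(obj$contours))
    stop("contour schema error: missing field 'contours'")
  contours <- list()
  for (ct in obj$contours) {
    if (is.null(ct$name) || is.null(ct$points))
      stop("contour schema error: each contour needs 'name' and 'points'")
    pts <- do.call(rbind, lapply(ct$points, function(p) {
      p <- unlist(p)
      if (length(p) != 2L)
        stop("contour schema error: 'points' entries must be [x, y]")
      as.numeric(p)
    }))
    if (anyNA(pts) || any(!is.finite(pts)))
      stop("contour schema error: non-finite point in contour '", ct$name, "'")
    contours[[ct$name]] <- pts
  }
  list(center = as.numeric(unlist(obj$center)),
       coverage_deg = if (is.null(obj$coverage_deg)) 360 else
         as.numeric(obj$coverage_deg),
       contours = contours)
}

.record_columns <- c("modality", "pi_mm", "d_mm", "la_mm2", "l1_mm", "l2_mm",
                     "l2_area_mm2", "a_asm_mm2", "a_ecm_mm2",
                     "missing_angle_deg", "quality_score", "l2_area_over_pi",
                     "l2_area_over_pi2", "a_asm_over_pi2", "excluded",
                     "exclude_reason")
.record_mandatory <- c("modality", "pi_mm", "missing_angle_deg")

#' Write a morphometry record table to CSV
#'
#' Fixed-schema, comma-separated, UTF-8 CSV with a mandatory header and "."
#' decimals; numbers keep full precision (15 significant digits), so a
#' write/read round trip preserves values to better than 1e-9 relative.
#' Extra key columns (group/subject/airway/image) are written first when
#' present.
#'
#' @param records Data frame in the record schema (see
#'   \code{\link{measure_phantom}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_records <- function(records, path) {
  miss <- setdiff(.record_mandatory, names(records))
  if (length(miss))
    stop("records are missing mandatory columns: ",
         paste(miss, collapse = ", "))
  for (cn in setdiff(.record_columns, names(records)))
    records[[cn]] <- NA
  keys <- intersect(c("group", "subject", "airway", "image"), names(records))
  records <- records[, c(keys, .record_columns)]
  utils::write.csv(format(records, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a morphometry record table from CSV
#'
#' @param path Input file path.
#' @return Data frame with the standard record columns; unknown columns are
#'   kept with a warning, missing mandatory columns are an error.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.record_mandatory, names(df))
  if (length(miss))
    stop("record file is missing mandatory columns: ",
         paste(miss, collapse = ", "))
  keys <- c("group", "subject", "airway", "image")
  unknown <- setdiff(names(df), c(keys, .record_columns))
  if (length(unknown))
    warning("unknown record columns kept as-is: ",
            paste(unknown, collapse = ", "))
  if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
  num <- setdiff(.record_columns,
                 c("modality", "excluded", "exclude_reason"))
  for (cn in intersect(num, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Analysis run configuration
#'
#' Collects the thresholds and options of a pipeline run: significance
#' level, the ultrasound missing-angle exclusion threshold, histology
#' score-2 angle threshold, size-class boundaries, the composition Pi
#' cutoff, simulation sizes and the master seed. Values can be overridden
#' individually or loaded from a YAML file whose keys mirror the argument
#' names.
#'
#' @param path Optional YAML file; its entries override the defaults, and
#'   \code{...} overrides the file.
#' @param ... Named overrides.
#' @return List of class \code{run_config}.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 20150908L,
    units = "mm",
    alpha = 0.05,
    missing_angle_max = 180,
    score2_angle_max = 90,
    size_bounds = c(16, 31),
    composition_pi_max = 26,
    n_phantoms = 8L,
    paired = list(n_airways = 60L, n_subjects = 8L, pi_bias_slope = 0.18,
                  pi_bias_intercept = 0, shrink_fraction = 0.44,
                  noise_cv = 0.05),
    hierarchy = list(n_subjects_per_group = 7L, n_airways_per_subject = 10L,
                     n_images_per_airway = 4L, group_effect_pct = 30,
                     total_cv = 0.25),
    power = list(effect_pcts = c(30, 60), n_grid = c(4, 6, 10), reps = 100L),
    out_dir = NULL,
    verbose = TRUE
  )
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, y)
  }
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$alpha <= 0 || cfg$missing_angle_max <= 0)
    stop("thresholds must be positive")
  if (is.unsorted(cfg$size_bounds))
    stop("size-class bounds must be ordered")
  class(cfg) <- "run_config"
  cfg
}
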