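# Specimen-table schema, validation and CSV I/O.
#
# The canonical table has one row per herbarium sheet:
#   id, year, doy, latitude, longitude, elevation, spring_tmax, winter_ppt,
#   manual_buds, manual_flowers, manual_immature, manual_mature,
#   and optionally (as a complete block)
#   pred_buds, pred_flowers, pred_immature, pred_mature.

.meta_cols <- c("id", "year", "doy", "latitude", "longitude", "elevation",
                "spring_tmax", "winter_ppt")

#' Canonical specimen-table column names
#'
#' @param predicted If \code{TRUE}, include the optional predicted-count
#'   block.
#' @return Character vector of column names.
#' @export
specimen_columns <- function(predicted = TRUE) {
  cols <- c(.meta_cols, .count_cols("manual"))
  if (predicted) cols <- c(cols, .count_cols("predicted"))
  cols
}

#' Does a specimen table carry predicted counts?
#'
#' @param specimens Specimen table.
#' @return \code{TRUE} if the full \code{pred_*} block is present.
#' @export
has_predicted <- function(specimens) {
  all(.count_cols("predicted") %in% names(specimens))
}

.check_counts <- function(x, cols, what) {
  for (cl in cols) {
    v <- x[[cl]]
    bad <- which(is.na(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop(what, " column '", cl, "' must hold non-negative whole numbers; ",
           "offending row(s): ", paste(utils::head(bad, 10L), collapse = ", "),
           call. = FALSE)
  }
}

#' Validate a specimen table
#'
#' Checks the canonical schema: required columns present, counts
#' non-negative whole numbers, day-of-year within 1–366 (366 admits
#' Dec 31 of leap years), collection year within a plausible window.
#' The predicted-count block is optional but must be complete if present.
#'
#' @param specimens Specimen table (data.frame).
#' @param year_window Plausible calendar-year range, default 1800–2100.
#' @return The validated table, invisibly; errors name offending columns
#'   and row numbers.
#' @export
validate_specimens <- function(specimens, year_window = c(1800, 2100)) {
  if (!is.data.frame(specimens))
    stop("specimens must be a data.frame", call. = FALSE)
  need <- c(.meta_cols, .count_cols("manual"))
  missing_cols <- setdiff(need, names(specimens))
  if (length(missing_cols))
    stop("specimen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  pred_cols <- .count_cols("predicted")
  n_pred <- sum(pred_cols %in% names(specimens))
  if (n_pred > 0 && n_pred < 4L)
    stop("incomplete predicted-count block: need all of ",
         paste(pred_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(specimens$id))
    stop("duplicate specimen id(s): ",
         paste(unique(specimens$id[duplicated(specimens$id)]),
               collapse = ", "), call. = FALSE)
  bad_doy <- which(is.na(specimens$doy) | specimens$doy < 1 |
                     specimens$doy > 366 |
                     abs(specimens$doy - round(specimens$doy)) > 1e-8)
  if (length(bad_doy))
    stop("doy must be a whole number in [1, 366]; offending row(s): ",
         paste(utils::head(bad_doy, 10L), collapse = ", "), call. = FALSE)
  bad_year <- which(is.na(specimens$year) |
                      specimens$year < year_window[1] |
                      specimens$year > year_window[2])
  if (length(bad_year))
    stop("year outside plausible window [", year_window[1], ", ",
         year_window[2], "]; offending row(s): ",
         paste(utils::head(bad_year, 10L), collapse = ", "), call. = FALSE)
  for (cl in c("latitude", "longitude", "elevation", "spring_tmax",
               "winter_ppt")) {
    if (!is.numeric(specimens[[cl]]))
      stop("column '", cl, "' must be numeric", call. = FALSE)
  }
  .check_counts(specimens, .count_cols("manual"), "manual count")
  if (n_pred == 4L)
    .check_counts(specimens, pred_cols, "predicted count")
  invisible(specimens)
}

#' Read a specimen table from CSV
#'
#' Reads the canonical comma-separated, UTF-8, header-first schema
#' (see \code{\link{specimen_columns}}).  Lines starting with \code{#}
#' (e.g., a recorded simulation seed) are ignored.  Because column naming
#' in external deposits varies, a rename map can translate foreign
#' headers to the canonical ones before validation.
#'
#' @param path Path to the CSV file.
#' @param rename Optional named character vector mapping canonical names
#'   to the names used in the file, e.g.
#'   \code{c(doy = "dayOfYear", manual_buds = "bud_count")}.
#' @param year_window Passed to \code{\link{validate_specimens}}.
#' @return Validated specimen table.
#' @export
read_specimens <- function(path, rename = NULL, year_window = c(1800, 2100)) {
  if (!file.exists(path))
    stop("specimen file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(rename)) {
    for (canon in names(rename)) {
      idx <- match(rename[[canon]], names(x))
      if (!is.na(idx)) names(x)[idx] <- canon
    }
  }
  x$id <- as.character(x$id)
  validate_specimens(x, year_window = year_window)
  x
}

#' Write a specimen table to CSV
#'
#' Canonical CSV output (comma, UTF-8, "." decimal, header).  Optional
#' comment lines (e.g., the simulation seed) are written as \code{#}
#' headers that \code{\link{read_specimens}} skips.
#'
#' @param specimens Specimen table.
#' @param path Output path.
#' @param comments Character vector of comment lines to record (without
#'   the leading \code{"# "}).
#' @return \code{path}, invisibly.
#' @export
write_specimens <- function(specimens, path, comments = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste("#", comments), con)
  utils::write.csv(specimens, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
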