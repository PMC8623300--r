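# Organ classes, count validation, and the Phenological Index.

#' Reproductive organ classes and their phenological index values
#'
#' The four classes of reproductive structures scored on a herbarium sheet,
#' each with its index value on the phenological progression scale:
#' buds = 1, flowers = 2, immature fruits = 3, mature fruits = 4.
#'
#' @return Named integer vector of index values, in progression order.
#' @export
#' @examples
#' organ_classes()
organ_classes <- function() {
  c(buds = 1L, flowers = 2L, immature_fruits = 3L, mature_fruits = 4L)
}

# Short column stems used in specimen tables (manual_buds, pred_immature, ...)
.class_stems <- c("buds", "flowers", "immature", "mature")
.class_names <- names(organ_classes())

# Column names holding counts for a given source ("manual" or "predicted").
.count_cols <- function(source = c("manual", "predicted")) {
  source <- match.arg(source)
  prefix <- if (source == "manual") "manual_" else "pred_"
  paste0(prefix, .class_stems)
}

# Coerce counts to a validated n x 4 matrix of non-negative whole numbers.
# Accepts a length-4 numeric vector, or a matrix/data.frame with 4 columns
# ordered buds, flowers, immature fruits, mature fruits.
.as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.numeric(counts) && is.null(dim(counts))) {
    if (length(counts) != 4L)
      stop("counts must have 4 elements (buds, flowers, immature fruits, ",
           "mature fruits), got ", length(counts), call. = FALSE)
    counts <- matrix(counts, nrow = 1L)
  }
  if (!is.numeric(counts) || ncol(counts) != 4L)
    stop("counts must be a numeric vector of length 4 or a 4-column ",
         "matrix/data.frame", call. = FALSE)
  if (anyNA(counts))
    stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be whole numbers (organ counts)", call. = FALSE)
  colnames(counts) <- .class_names
  counts
}

#' Phenological Index (PI) of organ counts
#'
#' The PI summarises a specimen's reproductive progression as the
#' proportion-weighted mean of the class index values:
#' \deqn{PI = \sum_{i=1}^{4} P_i \, i}
#' where \eqn{P_i} is the proportion of reproductive structures in class
#' \eqn{i} (buds = 1, flowers = 2, immature fruits = 3, mature fruits = 4).
#' A sheet bearing only buds scores 1 (earliest stage); one bearing only
#' mature fruits scores 4 (latest stage).  The PI is dimensionless, lies in
#' \[1, 4\], and is invariant under uniform scaling of all counts — it
#' depends on the composition, not the abundance, of organs.
#'
#' The PI is undefined for a sheet with no reproductive structures
#' (total count zero); such input is an error.
#'
#' @param counts A numeric vector of length 4 (buds, flowers, immature
#'   fruits, mature fruits), or an n x 4 matrix / data.frame of counts,
#'   one row per specimen.
#' @param ids Optional character vector of specimen identifiers (length n)
#'   used in error messages when a zero-total row is encountered.
#' @return Numeric vector of PI values, one per row of \code{counts}.
#' @export
#' @examples
#' phenological_index(c(25, 0, 0, 0))  # only buds -> 1
#' phenological_index(c(0, 0, 0, 12))  # only mature fruits -> 4
#' phenological_index(c(5, 5, 5, 5))   # equal mixture -> 2.5
phenological_index <- function(counts, ids = NULL) {
  m <- .as_count_matrix(counts)
  total <- rowSums(m)
  if (any(total == 0)) {
    bad <- which(total == 0)
    lab <- if (!is.null(ids)) ids[bad] else paste0("row ", bad)
    stop("undefined PI: zero-total organ counts for specimen(s) ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  as.numeric(m %*% organ_classes()) / total
}

#' PI table for a specimen collection
#'
#' Computes one Phenological Index per specimen from either the manual
#' (human-observer) or the predicted (detector-derived) counts.
#' Specimens with a zero organ total have an undefined PI; by default they
#' are skipped with a warning (a scored collection normally contains
#' fertile sheets only), or \code{zero_total = "error"} makes them fatal.
#'
#' @param specimens Specimen table as returned by
#'   \code{\link{read_specimens}} or \code{\link{simulate_collection}}.
#' @param source \code{"manual"} or \code{"predicted"} counts.
#' @param zero_total Policy for zero-total specimens: \code{"skip"}
#'   (drop with a warning naming the ids) or \code{"error"}.
#' @return A data.frame with columns \code{id} and \code{pi}, one row per
#'   retained specimen; attribute \code{"n_skipped"} records how many
#'   zero-total specimens were dropped.
#' @export
pi_table <- function(specimens, source = c("manual", "predicted"),
                     zero_total = c("skip", "error")) {
  source <- match.arg(source)
  zero_total <- match.arg(zero_total)
  cols <- .count_cols(source)
  missing_cols <- setdiff(cols, names(specimens))
  if (length(missing_cols))
    stop("no ", source, " counts: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- .as_count_matrix(specimens[cols])
  ids <- as.character(specimens$id)
  if (source == "predicted" && anyNA(specimens[cols]))
    stop("predicted counts missing for specimen(s) ",
         paste(ids[apply(is.na(specimens[cols]), 1L, any)], collapse = ", "),
         call. = FALSE)
  total <- rowSums(m)
  zero <- total == 0
  if (any(zero)) {
    if (zero_total == "error")
      stop("undefined PI: zero-total organ counts for specimen(s) ",
           paste(ids[zero], collapse = ", "), call. = FALSE)
    warning("skipping ", sum(zero), " zero-total specimen(s) with ",
            "undefined PI: ", paste(ids[zero], collapse = ", "),
            call. = FALSE)
    m <- m[!zero, , drop = FALSE]
    ids <- ids[!zero]
  }
  out <- data.frame(id = ids, pi = phenological_index(m, ids = ids),
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(zero)
  out
}
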