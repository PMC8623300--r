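# Agreement between detector-predicted and manual organ counts:
# signed counting errors, per-class MAE, concordance regressions,
# abundance-binned error distributions, and specimen-age effects.

.need_predicted <- function(specimens) {
  if (!has_predicted(specimens))
    stop("specimen table has no predicted-count block (pred_* columns)",
         call. = FALSE)
  bad <- apply(is.na(specimens[.count_cols("predicted")]), 1L, any)
  if (any(bad))
    stop("predicted counts missing for specimen(s) ",
         paste(specimens$id[bad], collapse = ", "), call. = FALSE)
  invisible(specimens)
}

#' Per-sheet, per-class counting errors
#'
#' The counting error for organ class k on sheet i is the signed
#' difference e = predicted − manual, so positive errors mean the
#' detector overestimates the number of structures and negative errors
#' mean it underestimates.
#'
#' @param specimens Specimen table with both count sources.
#' @return data.frame with columns \code{id}, \code{e_buds},
#'   \code{e_flowers}, \code{e_immature}, \code{e_mature}.
#' @export
counting_errors <- function(specimens) {
  .need_predicted(specimens)
  manual <- as.matrix(specimens[.count_cols("manual")])
  pred <- as.matrix(specimens[.count_cols("predicted")])
  e <- pred - manual
  colnames(e) <- paste0("e_", .class_stems)
  cbind(data.frame(id = as.character(specimens$id),
                   stringsAsFactors = FALSE),
        as.data.frame(e))
}

#' Mean absolute counting error per organ class
#'
#' MAE_k = (1/N) * sum_i |e_{i,k}| over the N sheets, per class.
#'
#' @param errors Error table from \code{\link{counting_errors}}, or a
#'   specimen table with both count sources (errors are derived first).
#' @return Named numeric vector of MAEs (organs), one per class.
#' @export
mae_per_class <- function(errors) {
  if (!is.data.frame(errors) || nrow(errors) == 0L)
    stop("need at least one sheet to compute MAE", call. = FALSE)
  ecols <- paste0("e_", .class_stems)
  if (!all(ecols %in% names(errors)))
    errors <- counting_errors(errors)
  out <- colMeans(abs(as.matrix(errors[ecols])))
  names(out) <- .class_names
  out
}

.target_vectors <- function(specimens, target) {
  if (target == "pi") {
    manual <- pi_table(specimens, "manual", zero_total = "skip")
    pred <- pi_table(specimens, "predicted", zero_total = "skip")
    keep <- intersect(manual$id, pred$id)
    list(manual = manual$pi[match(keep, manual$id)],
         pred = pred$pi[match(keep, pred$id)],
         ids = keep)
  } else {
    k <- match(target, .class_names)
    list(manual = specimens[[.count_cols("manual")[k]]],
         pred = specimens[[.count_cols("predicted")[k]]],
         ids = as.character(specimens$id))
  }
}

#' Concordance between predicted and manual values
#'
#' For one organ class (counts) or for the Phenological Index, computes
#' the Pearson correlation between predicted and manual values and an
#' ordinary least-squares regression of predicted on manual values:
#' slope (predicted per manual unit), its standard error, intercept,
#' R-squared, and the two-sided p-value for slope = 0.  The MAE column
#' is the mean absolute predicted-minus-manual difference.
#'
#' For the PI target, sheets whose manual or predicted total is zero
#' (undefined PI) are dropped before pairing.
#'
#' @param specimens Specimen table with both count sources.
#' @param target One of \code{"buds"}, \code{"flowers"},
#'   \code{"immature_fruits"}, \code{"mature_fruits"}, \code{"pi"}.
#' @return One-row data.frame: \code{target}, \code{n}, \code{mae},
#'   \code{pearson_r}, \code{slope}, \code{slope_se}, \code{intercept},
#'   \code{r2}, \code{p_value}.
#' @export
concordance <- function(specimens,
                        target = c("buds", "flowers", "immature_fruits",
                                   "mature_fruits", "pi")) {
  target <- match.arg(target)
  .need_predicted(specimens)
  v <- .target_vectors(specimens, target)
  n <- length(v$manual)
  if (n < 3L)
    stop("need at least 3 sheets for a concordance regression", call. = FALSE)
  if (stats::var(v$manual) == 0)
    stop("degenerate regressor: manual ", target,
         " values have zero variance", call. = FALSE)
  fit <- stats::lm(pred ~ manual, data = data.frame(v))
  s <- summary(fit)
  data.frame(target = target,
             n = n,
             mae = mean(abs(v$pred - v$manual)),
             pearson_r = stats::cor(v$manual, v$pred),
             slope = unname(stats::coef(fit)[2L]),
             slope_se = s$coefficients["manual", "Std. Error"],
             intercept = unname(stats::coef(fit)[1L]),
             r2 = s$r.squared,
             p_value = s$coefficients["manual", "Pr(>|t|)"],
             stringsAsFactors = FALSE)
}

#' Manual organs per detected organ
#'
#' The reciprocal of a concordance slope: a slope of 0.16 predicted buds
#' per manually counted bud means the detector finds 1 bud for every
#' 6.25 manual buds.  Full precision is returned; round only for report
#' output.
#'
#' @param slope Positive concordance slope (predicted per manual organ).
#' @return Manual organs per predicted organ (1/slope).
#' @export
detection_ratio <- function(slope) {
  if (!is.numeric(slope) || any(is.na(slope)) || any(slope <= 0))
    stop("detection ratio requires a positive slope", call. = FALSE)
  1 / slope
}

#' Counting-error distributions by organ abundance
#'
#' Bins sheets by their manual count of one organ class into
#' fixed-width abundance ranges (default 0–9, 10–19, 20–29, 30–39, 40+)
#' and summarises the signed counting error in each bin with a
#' five-number summary.  Empty bins are retained with n = 0.
#'
#' @param specimens Specimen table with both count sources.
#' @param target Organ class.
#' @param bin_width Width of each abundance bin (organs).
#' @param n_bins Number of bins; the last bin is open above.
#' @return data.frame with one row per bin: \code{lower} (inclusive),
#'   \code{upper} (exclusive; \code{Inf} for the top bin), \code{n},
#'   and \code{min}, \code{q1}, \code{median}, \code{q3}, \code{max}
#'   of the error (NA when n = 0).
#' @export
bin_errors_by_abundance <- function(specimens,
                                    target = c("buds", "flowers",
                                               "immature_fruits",
                                               "mature_fruits"),
                                    bin_width = 10, n_bins = 5) {
  target <- match.arg(target)
  .need_predicted(specimens)
  if (nrow(specimens) == 0L)
    stop("need at least one sheet", call. = FALSE)
  k <- match(target, .class_names)
  manual <- specimens[[.count_cols("manual")[k]]]
  e <- specimens[[.count_cols("predicted")[k]]] - manual
  lower <- (seq_len(n_bins) - 1L) * bin_width
  upper <- c(lower[-1L], Inf)
  bin <- pmin(manual %/% bin_width, n_bins - 1L) + 1L
  summarise_bin <- function(b) {
    ei <- e[bin == b]
    if (!length(ei)) return(c(n = 0, rep(NA_real_, 5L)))
    q <- stats::quantile(ei, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    c(length(ei), q)
  }
  s <- t(vapply(seq_len(n_bins), summarise_bin, numeric(6L)))
  out <- data.frame(target = target, lower = lower, upper = upper,
                    n = as.integer(s[, 1L]), min = s[, 2L], q1 = s[, 3L],
                    median = s[, 4L], q3 = s[, 5L], max = s[, 6L],
                    stringsAsFactors = FALSE)
  if (any(out$n == 0L))
    warning("empty abundance bin(s) for ", target, ": ",
            paste(which(out$n == 0L), collapse = ", "), call. = FALSE)
  out
}

#' Effect of specimen age on counting or PI-estimation error
#'
#' Regresses a transformed error magnitude on the year of specimen
#' collection, asking whether older sheets are scored less accurately.
#' For an organ class the response is \code{log10(|e| + 1)} (the +1
#' rescues zero errors before the log); for the Phenological Index it is
#' \code{sqrt(|PI_pred - PI_manual|)} (bounded in \[0, 3\], no offset
#' needed).  The slope is in transformed units per year; a negative
#' slope means larger errors on older specimens.
#'
#' @param specimens Specimen table with both count sources.
#' @param response Organ class, or \code{"pi"} for the PI estimation
#'   error.
#' @return One-row data.frame: \code{response}, \code{transform},
#'   \code{slope}, \code{se}, \code{t}, \code{p_value}, \code{r2},
#'   \code{n}.
#' @export
age_effect <- function(specimens,
                       response = c("buds", "flowers", "immature_fruits",
                                    "mature_fruits", "pi")) {
  response <- match.arg(response)
  .need_predicted(specimens)
  if (response == "pi") {
    v <- .target_vectors(specimens, "pi")
    year <- specimens$year[match(v$ids, specimens$id)]
    y <- sqrt(abs(v$pred - v$manual))
    transform <- "sqrt(|dPI|)"
  } else {
    k <- match(response, .class_names)
    e <- specimens[[.count_cols("predicted")[k]]] -
      specimens[[.count_cols("manual")[k]]]
    year <- specimens$year
    y <- log10(abs(e) + 1)
    transform <- "log10(|e|+1)"
  }
  if (length(y) < 3L)
    stop("need at least 3 sheets for an age-effect regression",
         call. = FALSE)
  if (stats::var(year) == 0)
    stop("degenerate regressor: collection year is constant", call. = FALSE)
  fit <- stats::lm(y ~ year)
  s <- summary(fit)
  data.frame(response = response, transform = transform,
             slope = unname(stats::coef(fit)[2L]),
             se = s$coefficients["year", "Std. Error"],
             t = s$coefficients["year", "t value"],
             p_value = s$coefficients["year", "Pr(>|t|)"],
             r2 = s$r.squared, n = length(y),
             stringsAsFactors = FALSE)
}

#' Detector evaluation report
#'
#' One row per organ class plus one for the Phenological Index:
#' n, MAE, Pearson r, concordance slope and SE, intercept, R-squared,
#' and slope p-value — the standard summary of detector-vs-manual
#' agreement for a scored collection.
#'
#' @param specimens Specimen table with both count sources.
#' @return data.frame with five rows (four classes + PI).
#' @export
evaluation_report <- function(specimens) {
  targets <- c(.class_names, "pi")
  do.call(rbind, lapply(targets, function(t) concordance(specimens, t)))
}
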