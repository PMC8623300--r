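# PI-controlled linear models of collection day-of-year, their
# comparison by confidence-interval overlap, and the derived ecological
# quantities (days/century of flowering shift, days/PI unit of
# phenological progression).

.build_model_data <- function(specimens, pi_source) {
  pit <- pi_table(specimens, pi_source, zero_total = "skip")
  idx <- match(pit$id, as.character(specimens$id))
  data.frame(doy = specimens$doy[idx],
             year = specimens$year[idx],
             pi = pit$pi,
             elevation = specimens$elevation[idx],
             latitude = specimens$latitude[idx],
             longitude = specimens$longitude[idx],
             winter_ppt = specimens$winter_ppt[idx],
             spring_tmax = specimens$spring_tmax[idx])
}

# Fit DOY ~ <terms> by OLS and package the per-term summary.
# Partial R^2 for a single-df term equals t^2 / (t^2 + df_res), the
# squared partial correlation; equivalently the SSE drop from adding the
# term to the otherwise-full model divided by the reduced-model SSE.
.fit_doy_model <- function(data, terms, pi_source, model_name) {
  if (nrow(data) < length(terms) + 2L)
    stop("need at least ", length(terms) + 2L,
         " complete specimens to fit ", model_name, call. = FALSE)
  const <- terms[vapply(terms, function(t) stats::var(data[[t]]) == 0,
                        logical(1L))]
  if (length(const))
    stop("rank-deficient design for ", model_name,
         ": constant regressor(s) ", paste(const, collapse = ", "),
         call. = FALSE)
  f <- stats::reformulate(terms, response = "doy")
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design for ", model_name, ": collinear term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  s <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  cf <- s$coefficients
  df_res <- fit$df.residual
  tvals <- cf[, "t value"]
  partial <- tvals^2 / (tvals^2 + df_res)
  partial["(Intercept)"] <- NA_real_
  tab <- data.frame(term = rownames(cf),
                    estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"],
                    ci_low = ci[, 1L],
                    ci_high = ci[, 2L],
                    t_ratio = tvals,
                    p_value = cf[, "Pr(>|t|)"],
                    partial_r2 = partial,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(list(model = model_name,
                 pi_source = pi_source,
                 terms = tab,
                 full_model_r2 = s$r.squared,
                 n = nrow(data),
                 residual_df = df_res,
                 formula = f,
                 fit = fit),
            class = "pheno_model")
}

#' @export
print.pheno_model <- function(x, ...) {
  cat(x$model, " (PI source: ", x$pi_source, ")\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  tab <- x$terms
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], signif, digits = 4L)
  print(tab, row.names = FALSE)
  cat(sprintf("n = %d, residual df = %d, full-model R2 = %.3f\n",
              x$n, x$residual_df, x$full_model_r2))
  invisible(x)
}

#' Temporal-shift model of flowering date
#'
#' OLS model \code{doy ~ year + pi + elevation + latitude + longitude},
#' estimating the rate of temporal shift in flowering date (days/year,
#' the \code{year} coefficient) while controlling for the specimen's
#' phenological status (PI) and collection-site geography.  Predictors
#' enter untransformed and uncentred, so coefficients are in raw units
#' (e.g., days per metre of elevation).  95% confidence intervals use t
#' quantiles with residual degrees of freedom; partial R-squared per
#' term is the squared partial correlation (SSE comparison of the full
#' vs the term-dropped model).
#'
#' Specimens whose selected count source has a zero organ total
#' (undefined PI) are skipped with a warning.
#'
#' @param specimens Specimen table.
#' @param pi_source Which counts the PI covariate is derived from:
#'   \code{"manual"} or \code{"predicted"}.
#' @return A \code{pheno_model} object: a per-term summary data.frame
#'   (\code{$terms}: estimate, SE, 95% CI, t, p, partial R2) plus
#'   \code{$full_model_r2}, \code{$n}, \code{$residual_df} and the
#'   underlying \code{lm} fit.
#' @export
temporal_shift_model <- function(specimens,
                                 pi_source = c("manual", "predicted")) {
  pi_source <- match.arg(pi_source)
  data <- .build_model_data(specimens, pi_source)
  .fit_doy_model(data,
                 c("year", "pi", "elevation", "latitude", "longitude"),
                 pi_source, "temporal shift model")
}

#' Phenoclimatic model of flowering date
#'
#' OLS model \code{doy ~ pi + winter_ppt + spring_tmax}, estimating the
#' sensitivity of flowering date to cumulative winter precipitation
#' (days/mm) and spring maximum temperature (days/degree C) while
#' controlling for phenological status (PI).  See
#' \code{\link{temporal_shift_model}} for conventions.
#'
#' @inheritParams temporal_shift_model
#' @return A \code{pheno_model} object.
#' @export
phenoclimatic_model <- function(specimens,
                                pi_source = c("manual", "predicted")) {
  pi_source <- match.arg(pi_source)
  data <- .build_model_data(specimens, pi_source)
  .fit_doy_model(data, c("pi", "winter_ppt", "spring_tmax"),
                 pi_source, "phenoclimatic model")
}

#' 95% confidence interval of one model term
#'
#' @param model \code{pheno_model} object.
#' @param term Term name, e.g. \code{"year"} or \code{"pi"}.
#' @return Numeric c(low, high).
#' @export
term_ci <- function(model, term) {
  stopifnot(inherits(model, "pheno_model"))
  i <- match(term, model$terms$term)
  if (is.na(i))
    stop("term '", term, "' not in model ", model$model, call. = FALSE)
  c(model$terms$ci_low[i], model$terms$ci_high[i])
}

# Collect coefficient bounds (in days per unit) from models or bare
# numeric CI bounds.
.collect_bounds <- function(args, term) {
  bounds <- lapply(args, function(a) {
    if (inherits(a, "pheno_model")) term_ci(a, term) else as.numeric(a)
  })
  unlist(bounds)
}

#' Flowering-date shift per century
#'
#' Converts the confidence bounds of the year coefficient (days/year)
#' into the magnitude of flowering-date shift over 100 years.  Given
#' several fitted models (or bare CI bounds), returns the range of
#' |bound| x 100 across all supplied bounds — e.g., year-coefficient CIs
#' of (−0.15, −0.048) and (−0.16, −0.058) give a shift of 4.8 to 16
#' days per century.
#'
#' @param ... \code{pheno_model} objects (their \code{year} CIs are
#'   used) and/or numeric coefficient bounds in days/year.
#' @return Numeric c(low, high) in days per 100 years (c(x, x) for a
#'   single bound).
#' @export
shift_per_century <- function(...) {
  bounds <- .collect_bounds(list(...), "year")
  range(abs(bounds) * 100)
}

#' Rate of phenological progression in days
#'
#' Converts the confidence bounds of the PI coefficient (days per PI
#' unit) into the interval spanned across all supplied models — the
#' number of days a plant takes to advance one PI unit — and the
#' full-cycle duration, 3 x that interval, since the PI spans three
#' units from all-buds (1) to all-mature-fruits (4).
#'
#' @param ... \code{pheno_model} objects (their \code{pi} CIs are used)
#'   and/or numeric coefficient bounds in days/PI unit.
#' @return List with \code{days_per_pi_unit} = c(low, high) and
#'   \code{full_cycle_days} = 3 x that interval.
#' @export
progression_days <- function(...) {
  bounds <- .collect_bounds(list(...), "pi")
  per_unit <- range(bounds)
  list(days_per_pi_unit = per_unit,
       full_cycle_days = 3 * per_unit)
}

#' Compare two fitted models by confidence-interval overlap
#'
#' For every substantive term shared by two model fits (the intercept is
#' excluded), tests whether the 95% confidence intervals overlap as
#' closed intervals — touching endpoints count as overlap.  Two models
#' whose intervals all overlap are statistically indistinguishable at
#' this (conservative) criterion; this is how a manual-PI and a
#' machine-PI fit of the same formula are judged equivalent.
#'
#' @param model_a,model_b \code{pheno_model} objects.
#' @return data.frame with one row per shared term (\code{term},
#'   \code{ci_a_low}, \code{ci_a_high}, \code{ci_b_low},
#'   \code{ci_b_high}, \code{overlap}) and attribute
#'   \code{"all_overlap"} (also column-wise reachable via
#'   \code{all(x$overlap)}).
#' @export
compare_models <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "pheno_model"),
            inherits(model_b, "pheno_model"))
  shared <- setdiff(intersect(model_a$terms$term, model_b$terms$term),
                    "(Intercept)")
  if (!length(shared))
    stop("models share no substantive terms", call. = FALSE)
  rows <- lapply(shared, function(tm) {
    a <- term_ci(model_a, tm)
    b <- term_ci(model_b, tm)
    data.frame(term = tm, ci_a_low = a[1L], ci_a_high = a[2L],
               ci_b_low = b[1L], ci_b_high = b[2L],
               overlap = ci_overlap(a, b), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "all_overlap") <- all(out$overlap)
  out
}

#' Closed-interval overlap test
#'
#' @param a,b Numeric intervals c(low, high).
#' @return \code{TRUE} if the closed intervals intersect (touching
#'   endpoints overlap).
#' @export
ci_overlap <- function(a, b) {
  a <- sort(as.numeric(a))
  b <- sort(as.numeric(b))
  a[1L] <= b[2L] && b[1L] <= a[2L]
}
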