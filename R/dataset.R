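# Data model operations: monthly resampling, linear interpolation of
# missing time nodes, the year-based train/validation/test split protocol,
# growth-stage / prefix time-window subsetting, normalization, and
# covariate encoding (time, one-hot region, normalized planting area).

# Growth stages of winter wheat mapped to season-month indices (1-based):
# T1 emergence-tillering (Oct-Nov), T2 winter dormancy (Dec-Feb),
# T3 jointing-heading (Mar-Apr), T4 heading-maturity (May-Jun).
GROWTH_STAGES <- list(
  T1 = c("oct", "nov"),
  T2 = c("dec", "jan", "feb"),
  T3 = c("mar", "apr"),
  T4 = c("may", "jun"))

#' Aggregate sub-monthly samples to monthly means
#'
#' Resamples irregular within-season observations (e.g. 16-day satellite
#' composites) to the 9-month Oct-Jun grid by arithmetic mean per month.
#' Months with no samples are returned as `NA` (to be filled by
#' [interpolate_missing()]).
#'
#' @param timestamps `Date` vector, or integer calendar months (1-12), one
#'   per sample; all must fall inside the Oct-Jun season window.
#' @param values numeric vector of samples.
#' @return named 9-vector of monthly means (NA where empty).
#' @export
monthly_aggregate <- function(timestamps, values) {
  stopifnot(length(timestamps) == length(values))
  out <- stats::setNames(rep(NA_real_, 9L), SEASON_MONTHS)
  if (length(values) == 0L) return(out)
  cal <- if (inherits(timestamps, "Date")) {
    as.integer(format(timestamps, "%m"))
  } else as.integer(timestamps)
  pos <- match(cal, SEASON_CAL)
  if (anyNA(pos)) stop("timestamps outside the Oct-Jun season window")
  agg <- tapply(values, pos, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Fill missing monthly values by linear interpolation
#'
#' Interior runs of `NA` are filled on the straight line between the
#' flanking present months; missing season boundaries are extended from the
#' nearest present value (flat extrapolation).
#'
#' @param series numeric vector (typically length 9) with `NA` gaps.
#' @return the completed series; errors if every value is missing.
#' @export
interpolate_missing <- function(series) {
  ok <- !is.na(series)
  if (!any(ok)) stop("all values missing: series unusable")
  if (all(ok)) return(series)
  filled <- stats::approx(x = which(ok), y = series[ok],
                          xout = seq_along(series), rule = 2)$y
  names(filled) <- names(series)
  filled
}

# Interpolate every dynamic series of every record in place.
complete_records <- function(dataset) {
  records <- if (inherits(dataset, "wf_dataset")) dataset$records else dataset
  records <- lapply(records, function(r) {
    for (s in c("rs", "climate", "soil_dyn")) {
      if (anyNA(r[[s]])) r[[s]] <- apply(r[[s]], 2L, interpolate_missing)
    }
    r
  })
  if (inherits(dataset, "wf_dataset")) {
    dataset$records <- records
    dataset
  } else records
}

#' Split records by the year-based test protocol
#'
#' All records from `test_years` form the test set; the remaining records
#' are split into training and validation in an 8:2 ratio (to within one
#' record), stratified by region so every region contributes about 20% of
#' its non-test seasons to validation. The split is a pure function of
#' `seed`.
#'
#' @param dataset `wf_dataset` or list of `season_record`.
#' @param test_years integer years held out for testing.
#' @param seed integer seed for the train/validation draw.
#' @return object of class `wf_split` with integer id vectors `train`,
#'   `val`, `test` (indices into the record list).
#' @export
split_dataset <- function(dataset, test_years = c(2021L, 2022L), seed = 1L) {
  records <- if (inherits(dataset, "wf_dataset")) dataset$records else dataset
  if (length(records) == 0L) stop("no records to split")
  years <- vapply(records, `[[`, 0L, "year")
  regions <- vapply(records, `[[`, 0L, "region_id")
  test <- which(years %in% test_years)
  rest <- setdiff(seq_along(records), test)
  if (length(rest) == 0L) stop("all records fall in test years")
  n_val_target <- round(0.2 * length(rest))
  val <- integer(0)
  with_seed(seed, {
    by_region <- split(rest, regions[rest])
    quota <- vapply(by_region, function(ids) 0.2 * length(ids), 0)
    base <- floor(quota)
    # largest-remainder allocation to hit the global 8:2 target exactly
    extra <- n_val_target - sum(base)
    frac <- quota - base
    ord <- order(-frac, stats::runif(length(frac)))
    add <- rep(0L, length(base))
    if (extra > 0) add[ord[seq_len(min(extra, length(ord)))]] <- 1L
    take <- base + add
    val <- unlist(lapply(seq_along(by_region), function(i) {
      ids <- by_region[[i]]
      k <- min(take[i], length(ids))
      if (k > 0) sample(ids, k) else integer(0)
    }), use.names = FALSE)
  })
  val <- sort(val)
  train <- setdiff(rest, val)
  structure(list(train = train, val = val, test = sort(test),
                 seed = as.integer(seed)), class = "wf_split")
}

#' @export
print.wf_split <- function(x, ...) {
  cat(sprintf("<wf_split> train %d / val %d / test %d (seed %d)\n",
              length(x$train), length(x$val), length(x$test), x$seed))
  invisible(x)
}

#' Truncate a record to a contiguous month window
#'
#' Slices every monthly matrix to the requested months (static soil,
#' covariates and the label are untouched). Windows must be contiguous in
#' season order: prefix windows ("first k months") and the growth stages
#' T1-T4 are both contiguous.
#'
#' @param record a `season_record`.
#' @param months contiguous vector of month labels (subset of
#'   `oct..jun`), or a stage name `"T1".."T4"`, or an integer count `k`
#'   meaning the first `k` months.
#' @return the truncated record.
#' @export
window_subset <- function(record, months) {
  if (is.character(months) && length(months) == 1L &&
      months %in% names(GROWTH_STAGES)) {
    months <- GROWTH_STAGES[[months]]
  }
  if (is.numeric(months) && length(months) == 1L) {
    if (months < 1 || months > 9) stop("prefix length must be in 1..9")
    months <- SEASON_MONTHS[seq_len(months)]
  }
  idx <- match(months, SEASON_MONTHS)
  if (length(idx) == 0L || anyNA(idx)) stop("unknown month labels")
  if (!identical(idx, seq(idx[1], idx[length(idx)])))
    stop("month selection must be contiguous in season order")
  for (s in c("rs", "climate", "soil_dyn")) {
    record[[s]] <- record[[s]][idx, , drop = FALSE]
  }
  record
}

# Apply window_subset to every record of a dataset.
window_subset_all <- function(dataset, months) {
  records <- if (inherits(dataset, "wf_dataset")) dataset$records else dataset
  records <- lapply(records, window_subset, months = months)
  if (inherits(dataset, "wf_dataset")) {
    dataset$records <- records
    dataset
  } else records
}

## ---- normalization -----------------------------------------------------

#' Fit normalization statistics on training records only
#'
#' Computes per-feature location/scale on the training subset. In `global`
#' mode every dynamic cell (variable x month) is z-scored with train
#' statistics; in `instance` mode (reversible instance normalization)
#' dynamic series are instead normalized per sample and per variable over
#' the months, and the per-sample statistics are re-injected into the model
#' so no information is discarded. Static soil, planting area, year and the
#' yield label always use train z-scores. Constant features get scale 1.
#'
#' @param records list of `season_record` (the training records).
#' @param mode `"instance"` (default) or `"global"`.
#' @return object of class `wf_normalizer`.
#' @export
fit_normalizer <- function(records, mode = c("instance", "global")) {
  mode <- match.arg(mode)
  stopifnot(length(records) >= 1L)
  safe_sd <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) 1 else s
  }
  dyn_stats <- lapply(c("rs", "climate", "soil_dyn"), function(s) {
    A <- vapply(records, function(r) r[[s]], records[[1]][[s]]) # m x v x n
    list(mean = apply(A, c(1, 2), mean),
         sd = apply(A, c(1, 2), function(x) safe_sd(x)))
  })
  names(dyn_stats) <- c("rs", "climate", "soil_dyn")
  ss <- do.call(rbind, lapply(records, `[[`, "soil_static"))
  areas <- vapply(records, `[[`, 0, "planting_area")
  yields <- vapply(records, `[[`, 0, "yield")
  years <- vapply(records, `[[`, 0L, "year")
  structure(list(
    mode = mode,
    dyn = dyn_stats,
    static_mean = colMeans(ss), static_sd = apply(ss, 2L, safe_sd),
    area_mean = mean(areas), area_sd = safe_sd(areas),
    yield_mean = mean(yields), yield_sd = safe_sd(yields),
    year_min = min(years), year_span = max(1L, max(years) - min(years))),
    class = "wf_normalizer")
}

# Normalize one dynamic series matrix (months x vars). Returns the
# normalized matrix plus, in instance mode, the per-variable (mean, sd)
# statistics for re-injection.
normalize_series <- function(ns, mat, source) {
  if (ns$mode == "global") {
    st <- ns$dyn[[source]]
    k <- nrow(mat)
    list(x = (mat - st$mean[seq_len(k), , drop = FALSE]) /
           st$sd[seq_len(k), , drop = FALSE],
         stats = NULL)
  } else {
    mu <- colMeans(mat)
    sg <- apply(mat, 2L, stats::sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    list(x = sweep(sweep(mat, 2L, mu), 2L, sg, "/"),
         stats = c(mu, sg))
  }
}

#' Invert normalization
#'
#' Maps normalized values back to the original scale; with `what =
#' "yield"` this de-normalizes model predictions to kg/hm^2. The
#' apply-then-invert round trip is exact to floating-point precision.
#'
#' @param ns a `wf_normalizer`.
#' @param x numeric vector of normalized values.
#' @param what one of `"yield"`, `"area"`.
#' @return de-normalized values.
#' @export
normalizer_invert <- function(ns, x, what = c("yield", "area")) {
  what <- match.arg(what)
  switch(what,
         yield = x * ns$yield_sd + ns$yield_mean,
         area = x * ns$area_sd + ns$area_mean)
}

## ---- covariate encoding ------------------------------------------------

#' Encode spatio-temporal covariates
#'
#' Time is a linear map of the year onto `[0, 1]` over the training span,
#' region is a one-hot vector of length `n_regions` (sums to exactly 1),
#' and planting area is z-scored with training statistics.
#'
#' @param record a `season_record`.
#' @param ns a `wf_normalizer` fitted on training records.
#' @param n_regions total number of region codes.
#' @return list with `time` (scalar), `region` (one-hot vector), `area`
#'   (scalar).
#' @export
encode_covariates <- function(record, ns, n_regions) {
  if (record$region_id < 0 || record$region_id >= n_regions)
    stop("region_id out of range")
  onehot <- rep(0, n_regions)
  onehot[record$region_id + 1L] <- 1
  list(time = (record$year - ns$year_min) / ns$year_span,
       region = onehot,
       area = (record$planting_area - ns$area_mean) / ns$area_sd)
}
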