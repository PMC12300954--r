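# Seeded generator of multi-source winter-wheat season records.
#
# The real study data (statistical yearbooks + satellite/reanalysis
# extractions for 196 regions, 2001-2022) are private, so this module
# produces a synthetic stand-in with the same schema and a *known*
# ground-truth yield function, which makes every downstream stage testable:
# smooth unimodal vegetation-index curves peaking at jointing-heading,
# sinusoidal-plus-noise climate, static per-region soil draws, and a yield
# response with a remote-sensing x precipitation cross-source interaction.

SEASON_MONTHS <- c("oct", "nov", "dec", "jan", "feb", "mar", "apr", "may", "jun")
# calendar month number for each season position (Oct..Jun)
SEASON_CAL <- c(10, 11, 12, 1, 2, 3, 4, 5, 6)

RS_VARS <- c("ndvi", "evi")
CLIMATE_VARS <- c("evap", "lwrad", "swrad", "pressure", "precip", "temp", "wind")
SOILDYN_VARS <- c("moist10", "moist40", "stemp10", "stemp40")
SOILSTATIC_VARS <- as.vector(outer(
  c("bd", "oc", "ph", "sand", "clay", "silt", "cec", "cec_clay"),
  c("surf", "deep"), paste, sep = "_"))

#' Simulation configuration
#'
#' Defines the synthetic world: number of regions, the span of growing
#' seasons, which years are held out for testing, observation noise on the
#' yield, and the strength of the remote-sensing x water cross-source
#' interaction in the ground-truth yield function.
#'
#' @param n_regions number of regions (default 196).
#' @param years inclusive vector of harvest years (default 2001:2022).
#' @param test_years years whose records form the test set.
#' @param noise_sd standard deviation (kg/hm^2) of the additive yield noise.
#' @param interaction_weight multiplier on the NDVI x precipitation
#'   interaction term of the yield function; 0 makes the response purely
#'   additive across sources.
#' @param seed integer seed; the generated dataset is a pure function of
#'   this configuration.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 196L, years = 2001:2022,
                       test_years = c(2021L, 2022L), noise_sd = 300,
                       interaction_weight = 1, seed = 42L) {
  if (n_regions < 1) stop("n_regions must be a positive integer")
  if (length(years) < 1 || any(years != round(years)))
    stop("years must be integers")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!all(test_years %in% years) && length(test_years) > 0)
    warning("some test_years are outside the simulated year range")
  structure(list(
    n_regions = as.integer(n_regions), years = as.integer(years),
    test_years = as.integer(test_years), season_months = SEASON_MONTHS,
    noise_sd = noise_sd, interaction_weight = interaction_weight,
    seed = as.integer(seed)), class = "sim_config")
}

# Ground-truth yield coefficients. Magnitudes are calibrated once so that
# the simulated yield has mean ~6000 kg/hm^2 and sd ~1500 kg/hm^2,
# comparable to the error scales of published county-level studies.
.yield_coef <- function(cfg, region_effect) {
  list(
    b0 = -4420,             # intercept (kg/hm^2)
    b1_ndvi = 2000,         # per unit season-summed NDVI
    ct_temp = 60,           # penalty per (degC)^2 deviation of spring temp
    t_opt = 14,             # optimal mean Mar-Jun air temperature (degC)
    cp_precip = 1200,       # per mm/day season-mean precipitation
    c_inter = 500,          # scale of sum_m NDVI_m * precip_m
    interaction_weight = cfg$interaction_weight,
    year_trend = 40,        # kg/hm^2 per year since the first season
    year0 = min(cfg$years),
    region_effect = region_effect,
    noise_sd = cfg$noise_sd)
}

#' Deterministic part of the ground-truth yield function
#'
#' Recomputes, from a season record and the generator coefficients, the
#' yield the generator would assign before noise. Used by recovery tests
#' and by the zero-noise exactness check.
#'
#' @param record a `season_record`.
#' @param coef coefficient list as returned in `generate_dataset()$coef`.
#' @return deterministic yield in kg/hm^2.
#' @export
yield_closed_form <- function(record, coef) {
  ndvi <- record$rs[, "ndvi"]
  precip <- record$climate[, "precip"]
  temp <- record$climate[, "temp"]
  t_spring <- mean(temp[6:9]) # Mar..Jun
  coef$b0 +
    coef$b1_ndvi * sum(ndvi) -
    coef$ct_temp * (t_spring - coef$t_opt)^2 +
    coef$cp_precip * mean(precip) +
    coef$interaction_weight * coef$c_inter * sum(ndvi * precip) +
    coef$region_effect[record$region_id + 1L] +
    coef$year_trend * (record$year - coef$year0)
}

#' Generate a synthetic multi-source season dataset
#'
#' Produces one record per region-year with monthly remote-sensing, climate
#' and dynamic-soil series, a static per-region soil vector, planting area,
#' and a yield drawn from the known ground-truth response. Identical
#' configurations (including the seed) give bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with class `wf_dataset`: `records` (list of
#'   `season_record`), `coef` (generator coefficients, see
#'   [yield_closed_form()]), and `config`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    R <- cfg$n_regions
    m_idx <- 0:8 # season month index, Oct = 0

    # region-level latent structure
    reg <- list(
      peak_pos = stats::runif(R, 5, 6),          # Mar..Apr in month index
      peak_h   = stats::rnorm(R, 0.65, 0.06),
      base     = stats::runif(R, 0.12, 0.18),
      width    = stats::runif(R, 1.6, 2.2),
      effect   = stats::rnorm(R, 0, 450),
      precip_off = stats::rnorm(R, 0, 0.25),
      temp_off = stats::rnorm(R, 0, 1.0),
      area     = exp(stats::rnorm(R, log(20000), 0.5)))
    soil_static <- sapply(seq_along(SOILSTATIC_VARS), function(j) {
      mu <- c(1.35, 1.0, 7.5, 40, 25, 35, 15, 40)[(j - 1L) %% 8L + 1L]
      sd_ <- c(0.10, 0.30, 0.50, 10, 8, 8, 5, 10)[(j - 1L) %% 8L + 1L]
      stats::rnorm(R, mu, sd_)
    })
    if (!is.matrix(soil_static)) soil_static <- matrix(soil_static, nrow = R)
    colnames(soil_static) <- SOILSTATIC_VARS

    coef <- .yield_coef(cfg, reg$effect)

    cl_mean <- c(evap = 2.2, lwrad = -60, swrad = 160, pressure = 92,
                 precip = 1.4, temp = 9, wind = 2.4)
    cl_amp <- c(evap = 1.5, lwrad = 25, swrad = 70, pressure = 0.5,
                precip = 1.1, temp = 12, wind = 0.5)
    cl_sd <- c(evap = 0.2, lwrad = 5, swrad = 10, pressure = 0.3,
               precip = 0.35, temp = 1.2, wind = 0.3)
    # annual cycle: each variable peaks in July (month 7)
    phase <- cos(2 * pi * (SEASON_CAL - 7) / 12)

    records <- vector("list", R * length(cfg$years))
    k <- 0L
    for (r in seq_len(R)) {
      for (yr in cfg$years) {
        k <- k + 1L
        # vegetation: unimodal Gaussian bump over the season index with a
        # region-specific peak (jointing-heading, Mar-Apr) and a yearly
        # vigor multiplier; smooth by construction so unimodality holds.
        vigor <- max(stats::rnorm(1, 1, 0.08), 0.5)
        h <- reg$base[r] +
          (reg$peak_h[r] * vigor - reg$base[r]) *
            exp(-(m_idx - reg$peak_pos[r])^2 / (2 * reg$width[r]^2))
        ndvi <- pmin(pmax(h, -1), 1)
        evi <- pmin(pmax(0.04 + 0.78 * ndvi, -1), 1)
        rs <- cbind(ndvi = ndvi, evi = evi)
        rownames(rs) <- SEASON_MONTHS

        climate <- sapply(CLIMATE_VARS, function(v) {
          off <- switch(v, precip = reg$precip_off[r],
                        temp = reg$temp_off[r], 0)
          x <- cl_mean[[v]] + off + cl_amp[[v]] * phase +
            stats::rnorm(9, 0, cl_sd[[v]])
          if (v == "precip") x <- pmax(x, 0)
          x
        })
        rownames(climate) <- SEASON_MONTHS

        soil_dyn <- cbind(
          moist10 = pmin(pmax(0.24 - 0.03 * phase +
            0.05 * (climate[, "precip"] - cl_mean[["precip"]]) +
            stats::rnorm(9, 0, 0.015), 0.05), 0.45),
          moist40 = pmin(pmax(0.26 - 0.02 * phase +
            0.03 * (climate[, "precip"] - cl_mean[["precip"]]) +
            stats::rnorm(9, 0, 0.010), 0.05), 0.45),
          stemp10 = 0.8 * climate[, "temp"] + 2 + stats::rnorm(9, 0, 0.5),
          stemp40 = 0.6 * climate[, "temp"] + 4 + stats::rnorm(9, 0, 0.3))
        rownames(soil_dyn) <- SEASON_MONTHS

        rec <- structure(list(
          region_id = r - 1L, year = as.integer(yr),
          rs = rs, climate = climate, soil_dyn = soil_dyn,
          soil_static = stats::setNames(soil_static[r, ], SOILSTATIC_VARS),
          planting_area = reg$area[r], yield = NA_real_),
          class = "season_record")
        y_det <- yield_closed_form(rec, coef)
        rec$yield <- max(y_det + stats::rnorm(1, 0, cfg$noise_sd), 100)
        records[[k]] <- rec
      }
    }
    structure(list(records = records, coef = coef, config = cfg),
              class = "wf_dataset")
  })
}

#' @export
print.wf_dataset <- function(x, ...) {
  ys <- vapply(x$records, `[[`, 0, "yield")
  cat(sprintf(
    "<wf_dataset> %d records (%d regions x %d years); yield mean %.0f, sd %.0f kg/hm^2\n",
    length(x$records), x$config$n_regions, length(x$config$years),
    mean(ys), stats::sd(ys)))
  invisible(x)
}

#' Inject missing monthly cells
#'
#' Masks exactly `floor(rate * n_cells)` monthly cells (a cell is one month
#' of one variable's series in one record) as `NA`, emulating the small
#' number of severely missing time nodes in raw satellite/reanalysis
#' extractions. The first and last month of a series are never masked, so
#' interior linear interpolation is always defined.
#'
#' @param dataset a `wf_dataset` (or plain list of `season_record`).
#' @param rate fraction of cells to mask, in `[0, 1)`.
#' @param seed seed controlling which cells are masked.
#' @return the dataset with masked cells set to `NA`.
#' @export
inject_missing <- function(dataset, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  records <- if (inherits(dataset, "wf_dataset")) dataset$records else dataset
  sources <- c("rs", "climate", "soil_dyn")
  n_vars <- sum(vapply(sources, function(s) ncol(records[[1]][[s]]), 0L))
  n_series <- length(records) * n_vars
  n_cells <- n_series * 9L
  k <- floor(rate * n_cells)
  if (k > n_series * 7L)
    stop("rate too high: boundary months cannot be masked")
  if (k > 0) {
    with_seed(seed, {
      # enumerate interior cells: series index x month 2..8 (1-based)
      pick <- sample.int(n_series * 7L, k)
      series_i <- (pick - 1L) %/% 7L + 1L
      month_i <- (pick - 1L) %% 7L + 2L # in 2..8, never 1 or 9
      for (j in seq_len(k)) {
        si <- series_i[j]
        rec_i <- (si - 1L) %/% n_vars + 1L
        vi <- (si - 1L) %% n_vars + 1L
        for (s in sources) {
          nc <- ncol(records[[rec_i]][[s]])
          if (vi <= nc) {
            records[[rec_i]][[s]][month_i[j], vi] <- NA_real_
            break
          }
          vi <- vi - nc
        }
      }
    })
  }
  if (inherits(dataset, "wf_dataset")) {
    dataset$records <- records
    dataset
  } else records
}

## ---- CSV / JSON round trip --------------------------------------------

.flat_colnames <- function() {
  c("region_id", "year", "planting_area", "yield",
    as.vector(t(outer(paste0("rs_", RS_VARS), SEASON_MONTHS, paste, sep = "_"))),
    as.vector(t(outer(paste0("cl_", CLIMATE_VARS), SEASON_MONTHS, paste, sep = "_"))),
    as.vector(t(outer(paste0("sd_", SOILDYN_VARS), SEASON_MONTHS, paste, sep = "_"))),
    paste0("ss_", SOILSTATIC_VARS))
}

#' Write season records to the canonical CSV layout
#'
#' One row per region-year; monthly series flatten to
#' `<source>_<var>_<month>` columns. A sidecar `<path>.coef.json` with the
#' generator coefficients is written when `dataset` carries them.
#'
#' @param dataset `wf_dataset` or list of `season_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_season_csv <- function(dataset, path) {
  records <- if (inherits(dataset, "wf_dataset")) dataset$records else dataset
  rows <- lapply(records, function(r) {
    c(r$region_id, r$year, r$planting_area, r$yield,
      as.numeric(r$rs), as.numeric(r$climate), as.numeric(r$soil_dyn),
      as.numeric(r$soil_static))
  })
  dt <- data.table::as.data.table(do.call(rbind, rows))
  data.table::setnames(dt, .flat_colnames())
  data.table::fwrite(dt, path)
  if (inherits(dataset, "wf_dataset") && !is.null(dataset$coef)) {
    jsonlite::write_json(dataset$coef, paste0(path, ".coef.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read season records from the canonical CSV layout
#'
#' @param path CSV path written by [write_season_csv()].
#' @return a `wf_dataset` (with `coef` when the sidecar JSON exists).
#' @export
read_season_csv <- function(path) {
  dt <- data.table::fread(path)
  stopifnot(identical(names(dt), .flat_colnames()))
  mat <- as.matrix(dt)
  grab <- function(row, prefix, vars) {
    m <- matrix(row[paste0(prefix, "_", rep(vars, each = 9), "_",
                           rep(SEASON_MONTHS, length(vars)))],
                nrow = 9, dimnames = list(SEASON_MONTHS, vars))
    m
  }
  records <- lapply(seq_len(nrow(mat)), function(i) {
    row <- mat[i, ]
    structure(list(
      region_id = as.integer(row[["region_id"]]),
      year = as.integer(row[["year"]]),
      rs = grab(row, "rs", RS_VARS),
      climate = grab(row, "cl", CLIMATE_VARS),
      soil_dyn = grab(row, "sd", SOILDYN_VARS),
      soil_static = stats::setNames(row[paste0("ss_", SOILSTATIC_VARS)],
                                    SOILSTATIC_VARS),
      planting_area = row[["planting_area"]],
      yield = row[["yield"]]), class = "season_record")
  })
  coef_path <- paste0(path, ".coef.json")
  coef <- if (file.exists(coef_path)) {
    cf <- jsonlite::read_json(coef_path, simplifyVector = TRUE)
    cf$region_effect <- as.numeric(cf$region_effect)
    cf
  } else NULL
  structure(list(records = records, coef = coef, config = NULL),
            class = "wf_dataset")
}
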