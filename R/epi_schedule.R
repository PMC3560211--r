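# Epidemiological input schedules --------------------------------------------
#
# Age x sex grids of IHD and stroke incidence, case fatality, background
# (non-CVD) mortality and utility weights, with annual proportional trends in
# incidence and case fatality.  The defaults are synthetic log-linear-in-age
# stand-ins for national hospital/mortality-register rates: rates are
# exponential in age by construction, so `rate(age) = base * exp(slope *
# (age - ref_age))`, which makes the grid easy to reason about and to override.

#' Default configuration for the synthetic epi schedule
#'
#' Baseline rates at the reference age of 60 with log-linear age slopes.
#' Incidence and background mortality are person-year rates; case fatality is
#' a probability per incident event (capped checkable at age 100).  Trends
#' default to a 2% annual decline in both incidence and case fatality.
#' Utility weights decline linearly with age; disability weights for time
#' lived with IHD and stroke are scalar.  All values are illustrative
#' synthetic defaults and user-overridable.
#'
#' @return Config list for [generate_epi_schedule()].
#' @export
default_epi_config <- function() {
  list(
    ref_age = 60,
    ages = 35:100,
    incidence_ihd = list(male = c(base = 0.008, slope = 0.085),
                         female = c(base = 0.004, slope = 0.090)),
    incidence_stroke = list(male = c(base = 0.0030, slope = 0.095),
                            female = c(base = 0.0025, slope = 0.095)),
    case_fatality_ihd = list(male = c(base = 0.25, slope = 0.030),
                             female = c(base = 0.25, slope = 0.030)),
    case_fatality_stroke = list(male = c(base = 0.30, slope = 0.025),
                                female = c(base = 0.30, slope = 0.025)),
    background_mortality = list(male = c(base = 0.006, slope = 0.090),
                                female = c(base = 0.004, slope = 0.095)),
    trend_incidence = c(ihd = -0.02, stroke = -0.02),
    trend_case_fatality = c(ihd = -0.02, stroke = -0.02),
    utility_weight = list(male = c(at35 = 0.95, slope = -0.0028),
                          female = c(at35 = 0.95, slope = -0.0028)),
    disability_weight_ihd = 0.15,
    disability_weight_stroke = 0.30
  )
}

#' Generate an epidemiological schedule
#'
#' Builds the age (35-100) by sex grid of incidence, case fatality,
#' background mortality and utility weights from the log-linear configuration,
#' plus the trend and disability-weight scalars.  The generator is
#' deterministic given its configuration; `seed` is accepted for interface
#' symmetry with the population generator.
#'
#' @param seed Integer seed (unused by the deterministic default shapes).
#' @param config Shape settings, see [default_epi_config()].
#' @return An object of class `epi_schedule`: list with `grid` (data frame by
#'   `age`, `sex`), `trend_incidence`, `trend_case_fatality` (named per
#'   disease), and `disability` (named per disease).
#' @export
generate_epi_schedule <- function(seed = 1, config = default_epi_config()) {
  ages <- config$ages
  expc <- function(par, age) par[["base"]] * exp(par[["slope"]] * (age - config$ref_age))
  grid <- do.call(rbind, lapply(c("male", "female"), function(s) {
    cf_ihd <- expc(config$case_fatality_ihd[[s]], ages)
    cf_str <- expc(config$case_fatality_stroke[[s]], ages)
    if (max(cf_ihd, cf_str) > 1) {
      stop_config("case_fatality", "slope produces probability > 1 by age 100")
    }
    u <- config$utility_weight[[s]]
    util <- pmin(pmax(u[["at35"]] + u[["slope"]] * (ages - 35), 0), 1)
    data.frame(
      age = ages, sex = s,
      incidence_ihd = expc(config$incidence_ihd[[s]], ages),
      incidence_stroke = expc(config$incidence_stroke[[s]], ages),
      case_fatality_ihd = cf_ihd,
      case_fatality_stroke = cf_str,
      background_mortality = expc(config$background_mortality[[s]], ages),
      utility_weight = util,
      stringsAsFactors = FALSE
    )
  }))
  rownames(grid) <- NULL
  structure(list(
    grid = grid,
    trend_incidence = config$trend_incidence,
    trend_case_fatality = config$trend_case_fatality,
    disability = c(ihd = config$disability_weight_ihd,
                   stroke = config$disability_weight_stroke)
  ), class = "epi_schedule")
}

#' @export
print.epi_schedule <- function(x, ...) {
  cat("<epi_schedule> ages", min(x$grid$age), "-", max(x$grid$age),
      "| trends (incidence):", paste(sprintf("%s %+0.1f%%/yr",
        names(x$trend_incidence), 100 * x$trend_incidence), collapse = ", "),
      "\n")
  invisible(x)
}

#' Look up schedule quantities
#'
#' Vectorised lookup of one grid column at given ages and sexes; ages beyond
#' the grid are clamped to its last row (extrapolation by carry-forward).
#'
#' @param schedule An `epi_schedule`.
#' @param quantity Grid column name, e.g. `"incidence_ihd"`.
#' @param age,sex Vectors (recycled to common length).
#' @return Numeric vector.
#' @export
schedule_lookup <- function(schedule, quantity, age, sex) {
  grid <- schedule$grid
  amin <- min(grid$age); amax <- max(grid$age)
  age <- pmin(pmax(round(age), amin), amax)
  n <- max(length(age), length(sex))
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  pos_m <- pos_f <- rep(NA_integer_, amax - amin + 1)
  im <- grid$sex == "male"
  pos_m[grid$age[im] - amin + 1] <- which(im)
  pos_f[grid$age[!im] - amin + 1] <- which(!im)
  idx <- ifelse(sex == "male", pos_m[age - amin + 1], pos_f[age - amin + 1])
  if (anyNA(idx)) stop("schedule lookup failed for some (age, sex)")
  grid[[quantity]][idx]
}

#' Write / read an epi schedule as long-format CSV
#'
#' The grid is serialised as `(age, sex, year, quantity, value)` with
#' `year = NA` (base-year rates; trends are multiplicative scalars serialised
#' as `age = NA, sex = NA` rows named `trend_*` and `disability_*`).
#'
#' @param schedule An `epi_schedule`.
#' @param path File path.
#' @return `read_epi_schedule()` returns the reconstructed `epi_schedule`.
#' @export
write_epi_schedule <- function(schedule, path) {
  grid <- schedule$grid
  long <- do.call(rbind, lapply(setdiff(names(grid), c("age", "sex")),
    function(q) data.frame(age = grid$age, sex = grid$sex, year = NA,
                           quantity = q, value = grid[[q]])))
  scalars <- data.frame(
    age = NA, sex = NA, year = NA,
    quantity = c(paste0("trend_incidence_", names(schedule$trend_incidence)),
                 paste0("trend_case_fatality_", names(schedule$trend_case_fatality)),
                 paste0("disability_", names(schedule$disability))),
    value = c(schedule$trend_incidence, schedule$trend_case_fatality,
              schedule$disability))
  utils::write.csv(rbind(long, scalars), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epi_schedule
#' @export
read_epi_schedule <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  cells <- long[!is.na(long$age), ]
  grid <- stats::reshape(cells[, c("age", "sex", "quantity", "value")],
                         idvar = c("age", "sex"), timevar = "quantity",
                         direction = "wide")
  names(grid) <- sub("^value\\.", "", names(grid))
  grid <- grid[order(grid$sex, grid$age), ]
  rownames(grid) <- NULL
  sc <- long[is.na(long$age), ]
  val <- function(nm) sc$value[match(nm, sc$quantity)]
  structure(list(
    grid = grid,
    trend_incidence = c(ihd = val("trend_incidence_ihd"),
                        stroke = val("trend_incidence_stroke")),
    trend_case_fatality = c(ihd = val("trend_case_fatality_ihd"),
                            stroke = val("trend_case_fatality_stroke")),
    disability = c(ihd = val("disability_ihd"),
                   stroke = val("disability_stroke"))
  ), class = "epi_schedule")
}
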