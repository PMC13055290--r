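#' Gas constants for closed-chamber CH4 flux computation
#'
#' CH4 density at standard conditions (0 degC, 101 kPa) is 0.717 mg cm^-3,
#' numerically equal to kg m^-3; with headspace concentrations in ppmv the
#' product rho x H x slope lands directly in mg m^-2 h^-1.
#'
#' @param rho CH4 gas density, mg cm^-3 (equivalently kg m^-3).
#' @param kelvin_offset additive offset converting degC to K in the
#'   temperature correction `kelvin_offset / (kelvin_offset + T)`.
#' @return A list with elements `rho` and `kelvin_offset`.
#' @export
gas_constants <- function(rho = 0.717, kelvin_offset = 273) {
  stopifnot(rho > 0, kelvin_offset > 0)
  list(rho = rho, kelvin_offset = kelvin_offset)
}

#' Slope of a timed chamber concentration series
#'
#' Ordinary least squares of concentration (ppmv) on closure time (minutes),
#' reported per hour. With exactly two points the slope is the endpoint
#' difference over the interval and r^2 is recorded as 1; a zero-variance
#' (constant) series also reports r^2 = 1 by convention.
#'
#' @param times_min closure times in minutes, strictly increasing, length >= 2.
#' @param conc_ppm CH4 mixing ratios (ppmv), one per time point.
#' @param method `"ols"` (default) or `"endpoint"` (last minus first over
#'   elapsed time).
#' @return A list with `slope_ppm_h` and `r2`.
#' @export
fit_slope <- function(times_min, conc_ppm, method = c("ols", "endpoint")) {
  method <- match.arg(method)
  n <- length(times_min)
  if (n < 2) abort("invalid chamber series: need at least 2 timed concentrations")
  if (length(conc_ppm) != n) abort("invalid chamber series: times and concentrations differ in length")
  if (anyDuplicated(times_min)) abort("invalid chamber series: duplicate closure times")
  if (is.unsorted(times_min, strictly = TRUE)) abort("invalid chamber series: times must be strictly increasing")
  t_h <- times_min / 60
  if (method == "endpoint" || n == 2) {
    slope <- (conc_ppm[n] - conc_ppm[1]) / (t_h[n] - t_h[1])
    return(list(slope_ppm_h = slope, r2 = 1))
  }
  tc <- t_h - mean(t_h)
  cc <- conc_ppm - mean(conc_ppm)
  slope <- sum(tc * cc) / sum(tc^2)
  sst <- sum(cc^2)
  r2 <- if (sst == 0) 1 else sum(tc * cc)^2 / (sum(tc^2) * sst)
  list(slope_ppm_h = slope, r2 = r2)
}

#' CH4 flux from a concentration slope
#'
#' Closed-chamber flux `F = rho * H * slope * 273 / (273 + T)`: density times
#' chamber headspace height times the ppmv h^-1 accumulation rate, corrected
#' to chamber temperature. Negative slopes (net CH4 uptake) give negative
#' fluxes.
#'
#' @param slope_ppm_h concentration slope, ppmv h^-1 (vectorised).
#' @param height_m chamber height above the water layer, m (> 0).
#' @param temp_c mean in-chamber temperature, degC (> -273).
#' @param constants see [gas_constants()].
#' @return Flux in mg CH4 m^-2 h^-1.
#' @export
compute_flux <- function(slope_ppm_h, height_m, temp_c, constants = gas_constants()) {
  if (any(height_m <= 0)) abort("chamber height must be positive")
  if (any(temp_c <= -constants$kelvin_offset)) abort("temperature below absolute zero")
  constants$rho * height_m * slope_ppm_h *
    constants$kelvin_offset / (constants$kelvin_offset + temp_c)
}

#' Per-closure fluxes from a field sheet
#'
#' Takes the vial-level field sheet (one row per gas sample) and returns one
#' flux per chamber closure (plot x date). Concentration slopes come from
#' [fit_slope()]; the in-chamber temperature used in the flux equation is the
#' mean over the closure's readings.
#'
#' @param field_sheet data frame with columns `plot_id`, `date`, `t_min`,
#'   `conc_ppm`, `chamber_height_m`, `temp_c` and optionally `treatment`.
#' @param constants see [gas_constants()].
#' @param slope_method passed to [fit_slope()].
#' @param qc_r2 optional minimum slope r^2; closures below it are flagged
#'   (`qc_pass = FALSE`), never dropped.
#' @param conc_unit `"ppmv"` (default) or `"mg_m3"`; the latter divides the
#'   density back out so the same equation applies to mass concentrations.
#' @return A tibble with one row per closure: `plot_id`, `treatment` (if
#'   present), `date`, `slope_ppm_h`, `slope_r2`, `flux`, `qc_pass`.
#' @export
chamber_fluxes <- function(field_sheet, constants = gas_constants(),
                           slope_method = c("ols", "endpoint"),
                           qc_r2 = NULL, conc_unit = c("ppmv", "mg_m3")) {
  slope_method <- match.arg(slope_method)
  conc_unit <- match.arg(conc_unit)
  need <- c("plot_id", "date", "t_min", "conc_ppm", "chamber_height_m", "temp_c")
  miss <- setdiff(need, names(field_sheet))
  if (length(miss)) abort(paste0("field sheet missing columns: ", paste(miss, collapse = ", ")))
  conv <- if (conc_unit == "mg_m3") 1 / constants$rho else 1
  keys <- c("plot_id", intersect("treatment", names(field_sheet)), "date")
  field_sheet |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::summarise(
      fit = list(fit_slope(.data$t_min, .data$conc_ppm * conv, method = slope_method)),
      height_m = .data$chamber_height_m[1],
      temp_c = mean(.data$temp_c),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      slope_ppm_h = purrr::map_dbl(.data$fit, "slope_ppm_h"),
      slope_r2 = purrr::map_dbl(.data$fit, "r2"),
      flux = compute_flux(.data$slope_ppm_h, .data$height_m, .data$temp_c, constants),
      qc_pass = if (is.null(qc_r2)) TRUE else .data$slope_r2 >= qc_r2
    ) |>
    dplyr::select(-"fit", -"height_m", -"temp_c")
}

#' Seasonal cumulative CH4 emission by trapezoid integration
#'
#' `S = sum (F_i + F_{i+1}) / 2 * (t_{i+1} - t_i) * 24` over consecutive
#' sampling dates, with day intervals taken from calendar dates; units
#' mg CH4 m^-2. Also reports the arithmetic mean flux over the season and the
#' "cumulative / number of samplings" average (units mg m^-2).
#'
#' @param fluxes tibble with `plot_id`, `date`, `flux` (one row per closure),
#'   e.g. from [chamber_fluxes()]; extra grouping columns such as `treatment`
#'   are carried through.
#' @return One row per plot: `cumulative_S` (mg m^-2), `n_samplings`,
#'   `mean_flux_arithmetic` (mg m^-2 h^-1), `mean_flux_paper_literal`
#'   (cumulative / n, mg m^-2).
#' @export
cumulative_emission <- function(fluxes) {
  need <- c("plot_id", "date", "flux")
  miss <- setdiff(need, names(fluxes))
  if (length(miss)) abort(paste0("flux table missing columns: ", paste(miss, collapse = ", ")))
  keys <- c("plot_id", intersect("treatment", names(fluxes)))
  fluxes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      cumulative_S = trapezoid_emission(.data$date, .data$flux),
      n_samplings = dplyr::n(),
      mean_flux_arithmetic = mean(.data$flux),
      mean_flux_paper_literal = .data$cumulative_S / .data$n_samplings,
      .groups = "drop"
    )
}

trapezoid_emission <- function(dates, flux) {
  if (anyDuplicated(dates)) abort("duplicate sampling dates within a plot")
  n <- length(flux)
  if (n < 2) return(0)
  dt_days <- as.numeric(diff(as.Date(dates)), units = "days")
  if (any(dt_days <= 0)) abort("sampling dates must be strictly increasing")
  sum((flux[-n] + flux[-1]) / 2 * dt_days * 24)
}

#' Average flux over a date window
#'
#' @param fluxes flux tibble (`plot_id`, `date`, `flux`).
#' @param window optional length-2 date range (inclusive); default all dates.
#' @param method `"arithmetic"` — mean of fluxes in the window (mg m^-2 h^-1);
#'   `"paper_literal"` — trapezoid cumulative over the window divided by the
#'   number of records (mg m^-2).
#' @return Tibble with one row per plot and a `mean_flux` column.
#' @export
mean_flux <- function(fluxes, window = NULL,
                      method = c("arithmetic", "paper_literal")) {
  method <- match.arg(method)
  if (!is.null(window)) {
    window <- as.Date(window)
    fluxes <- dplyr::filter(fluxes, as.Date(.data$date) >= window[1],
                            as.Date(.data$date) <= window[2])
  }
  if (nrow(fluxes) == 0) abort("no flux records in the requested window")
  keys <- c("plot_id", intersect("treatment", names(fluxes)))
  fluxes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$date, .by_group = TRUE) |>
    dplyr::summarise(
      mean_flux = if (method == "arithmetic") mean(.data$flux)
                  else trapezoid_emission(.data$date, .data$flux) / dplyr::n(),
      n_records = dplyr::n(),
      .groups = "drop"
    )
}

#' Percent reduction of a treated value relative to a reference
#'
#' `100 * (reference - treated) / reference`; exceeds 100% when the treated
#' value is negative (net CH4 uptake).
#'
#' @param reference,treated numeric (vectorised); `reference` must be nonzero.
#' @return Percent reduction.
#' @export
percent_reduction <- function(reference, treated) {
  if (any(reference == 0)) abort("percent reduction undefined for a zero reference")
  100 * (reference - treated) / reference
}
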