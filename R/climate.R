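# month lengths of a non-leap civil year; daily resolution is out of scope
# so all years use the 365-day calendar
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

# mid-month day of year, used for solar declination
MID_MONTH_DOY <- cumsum(c(0L, DAYS_IN_MONTH[-12])) + DAYS_IN_MONTH %/% 2L

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classic temperature-based PET estimator from monthly mean temperature
#' and latitude (for the mean day-length correction).  Months with mean
#' temperature at or below 0 degC contribute 0.
#'
#' @param tmean numeric vector of 12 monthly mean temperatures (degC),
#'   January first.
#' @param lat latitude in decimal degrees (default 54, mid-Britain).
#' @return vector of 12 monthly PET values (mm).
#' @export
thornthwaite_pet <- function(tmean, lat = 54) {
  stopifnot(length(tmean) == 12)
  tpos <- pmax(tmean, 0)
  I <- sum((tpos / 5)^1.514)
  if (I == 0) return(rep(0, 12))
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  decl <- 0.409 * sin(2 * pi / 365 * MID_MONTH_DOY - 1.39)
  x <- pmin(1, pmax(-1, -tan(lat * pi / 180) * tan(decl)))
  daylen <- 24 / pi * acos(x)
  16 * (10 * tpos / I)^a * (daylen / 12) * (DAYS_IN_MONTH / 30)
}

#' Annualize a monthly climate series for one cell
#'
#' Derives the three yearly climate attributes from monthly records:
#' * minimum temperature — the mean daily minimum of the coldest month;
#' * drought — potential evapotranspiration minus total annual
#'   precipitation (mm), PET from a pluggable estimator (default
#'   [thornthwaite_pet()]);
#' * growing degree days — accumulated mean temperature above 5.5 degC,
#'   monthly means weighted by month length.
#'
#' @param monthly data.frame for a single cell with columns `year`,
#'   `month`, `tmin_c`, `tmean_c`, `precip_mm`; every year must have all
#'   12 months.
#' @param lat latitude passed to the PET estimator.
#' @param pet_fun function(tmean12, lat) -> 12 monthly PET values (mm).
#' @param gdd_base GDD threshold in degC (default 5.5).
#' @return data.frame with columns `year`, `min_temp`, `drought`, `gdd`.
#' @export
annualize <- function(monthly, lat = 54, pet_fun = thornthwaite_pet,
                      gdd_base = 5.5) {
  need <- c("year", "month", "tmin_c", "tmean_c", "precip_mm")
  stopifnot(all(need %in% names(monthly)))
  monthly <- monthly[order(monthly$year, monthly$month), ]
  years <- sort(unique(monthly$year))
  tab <- table(factor(monthly$year, years))
  if (any(tab != 12)) {
    bad <- years[tab != 12]
    stop("missing months in year(s): ", paste(bad, collapse = ", "))
  }
  out <- lapply(years, function(y) {
    m <- monthly[monthly$year == y, ]
    gdd <- sum(pmax(0, m$tmean_c - gdd_base) * DAYS_IN_MONTH)
    pet <- sum(pet_fun(m$tmean_c, lat))
    data.frame(year = y, min_temp = min(m$tmin_c),
               drought = pet - sum(m$precip_mm), gdd = gdd)
  })
  do.call(rbind, out)
}

#' Time-series summary measures
#'
#' The five yearly-series summaries applied to each climate attribute:
#' mean, ordinary-least-squares trend slope (per year), detrended variance
#' (residual variance about the OLS line, divisor n - 2), lag-1
#' autocorrelation (Pearson correlation of the series with itself shifted
#' one year), and the fat-tail statistic
#' (Q(0.975) - Q(0.025)) / (Q(0.875) - Q(0.125)) measuring the relative
#' weight of extreme values.
#'
#' @param x numeric series (one value per year, consecutive years).
#' @return scalar summary (NA with a warning for degenerate input).
#' @name ts_measures
NULL

#' @rdname ts_measures
#' @export
ts_mean <- function(x) mean(x)

#' @rdname ts_measures
#' @export
ts_trend <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  t <- seq_len(n)
  sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
}

#' @rdname ts_measures
#' @export
ts_detrended_var <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  t <- seq_len(n)
  b <- ts_trend(x)
  r <- x - mean(x) - b * (t - mean(t))
  sum(r^2) / (n - 2)
}

#' @rdname ts_measures
#' @export
ts_lag1 <- function(x) {
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  if (stats::sd(x[-1]) == 0 || stats::sd(x[-n]) == 0) {
    warning("constant series: lag-1 autocorrelation undefined")
    return(NA_real_)
  }
  stats::cor(x[-1], x[-n])
}

#' @rdname ts_measures
#' @param type quantile interpolation type passed to [stats::quantile()]
#'   (default 7, the common linear convention; the statistic is sensitive
#'   to this choice at n = 30, so it is recorded in pipeline metadata).
#' @export
ts_fat_tail <- function(x, type = 7) {
  if (length(x) < 8) stop("need at least 8 values")
  q <- stats::quantile(x, c(0.025, 0.125, 0.875, 0.975), type = type,
                       names = FALSE)
  den <- q[3] - q[2]
  if (den == 0) {
    warning("fat-tail denominator 0")
    return(NA_real_)
  }
  (q[4] - q[1]) / den
}

#' The 15 climate covariates per grid cell
#'
#' Applies the five summary measures to each of the three annualized
#' attributes (minimum temperature T, drought D, growing degree days G)
#' for every cell of a monthly climate table.  Column names follow the
#' usual abbreviations: `Min.temp`, `Drought`, `GDD` for the means, then
#' `var*`, `auto*`, `LTT*` (long-term trend) and `Ftail*` for each of
#' T/D/G.
#'
#' @param climate data.frame with columns `cell_id`, `year`, `month`,
#'   `tmin_c`, `tmean_c`, `precip_mm` (e.g. from [simulate_climate()] or
#'   [read_climate()]).
#' @inheritParams annualize
#' @param quantile_type passed to [ts_fat_tail()].
#' @return data.frame with `cell_id` plus 15 covariate columns.
#' @export
climate_covariates <- function(climate, lat = 54,
                               pet_fun = thornthwaite_pet,
                               quantile_type = 7) {
  cells <- unique(climate$cell_id)
  rows <- lapply(cells, function(cl) {
    ann <- annualize(climate[climate$cell_id == cl, , drop = FALSE],
                     lat = lat, pet_fun = pet_fun)
    one <- function(x) c(ts_mean(x), ts_detrended_var(x), ts_lag1(x),
                         ts_trend(x), ts_fat_tail(x, type = quantile_type))
    m <- vapply(ann[c("min_temp", "drought", "gdd")], one, numeric(5))
    data.frame(cell_id = cl,
               Min.temp = m[1, 1], Drought = m[1, 2], GDD = m[1, 3],
               varT = m[2, 1], varD = m[2, 2], varG = m[2, 3],
               autoT = m[3, 1], autoD = m[3, 2], autoG = m[3, 3],
               LTTT = m[4, 1], LTTD = m[4, 2], LTTG = m[4, 3],
               FtailT = m[5, 1], FtailD = m[5, 2], FtailG = m[5, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a monthly climate table
#'
#' @param path CSV with columns `cell_id,year,month,tmin_c,tmean_c,
#'   precip_mm`.
#' @return data.frame.
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "year", "month", "tmin_c", "tmean_c", "precip_mm")
  if (!all(need %in% names(df)))
    stop("climate CSV must contain columns ", paste(need, collapse = ", "))
  df
}
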