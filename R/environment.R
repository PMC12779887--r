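#' @title Exogenous drivers: grass growth, light, weights, populations
#'
#' @description
#' Weather-driven daily grass growth (a light-use-efficiency formulation
#' driven by daily mean temperature and global solar radiation, optionally
#' modulated by a grass-height-dependent growth factor), an astronomical
#' day/night and moonlight calendar, species weight calendars, and the
#' quadratic seasonal population trajectories that set how many flocks are
#' present on each simulation day.
#'
#' @name environment-drivers
NULL

#' Grass growth parameters
#'
#' @param g_max maximal daily growth (cm/day) under saturating light and
#'   optimal temperature.
#' @param t_base,t_opt base and optimal temperature (deg C); growth scales
#'   linearly between them and is zero at or below \code{t_base}.
#' @param r_ref reference global radiation (MJ m-2 day-1) at which the light
#'   term saturates.
#' @param ghdgg_enabled enable the grass-height-dependent growth factor.
#' @param h_opt sward height (m) at which the height factor peaks.
#' @param ghdgg_width Gaussian width (m) of the height factor.
#' @return list of class \code{grass_growth_params}.
#' @export
grass_growth_params <- function(g_max = 0.15, t_base = 5, t_opt = 18,
                                r_ref = 15, ghdgg_enabled = FALSE,
                                h_opt = 0.07, ghdgg_width = 0.08) {
  stopifnot(g_max > 0, t_base < t_opt, r_ref > 0, ghdgg_width > 0)
  structure(list(g_max = g_max, t_base = t_base, t_opt = t_opt,
                 r_ref = r_ref, ghdgg_enabled = ghdgg_enabled,
                 h_opt = h_opt, ghdgg_width = ghdgg_width),
            class = "grass_growth_params")
}

#' Daily grass growth increment
#'
#' Light-use-efficiency form: the daily height increment (cm) is
#' \code{g_max * min(1, R/r_ref) * clamp((T - t_base)/(t_opt - t_base), 0, 1)},
#' optionally multiplied by a unimodal Gaussian height factor peaking at
#' \code{h_opt} when \code{ghdgg_enabled}. Deterministic; returns metres.
#'
#' @param height current sward height (m), scalar or vector.
#' @param weather list or one-row data.frame with \code{temperature} (deg C)
#'   and \code{radiation} (MJ m-2 day-1).
#' @param params a \code{\link{grass_growth_params}}.
#' @return height increment (m), same length as \code{height}; always >= 0.
#' @export
grass_growth <- function(height, weather, params = grass_growth_params()) {
  if (any(height < 0)) stop("negative grass height")
  light <- min(1, weather$radiation / params$r_ref)
  temp <- (weather$temperature - params$t_base) / (params$t_opt - params$t_base)
  temp <- min(1, max(0, temp))
  d_cm <- params$g_max * light * temp
  if (isTRUE(params$ghdgg_enabled))
    d_cm <- d_cm * exp(-((height - params$h_opt) / params$ghdgg_width)^2)
  else
    d_cm <- rep(d_cm, length(height))
  d_cm / 100
}

#' Quadratic seasonal population trajectory
#'
#' Goose numbers over the wintering season follow a downward-opening
#' quadratic with its vertex (the estimated seasonal maximum) in
#' January-February, clipped at zero. The curvature is set so that the
#' trajectory falls to \code{edge_frac * peak_count} at the season edge
#' farther from the peak.
#'
#' @param peak_count maximal number of geese.
#' @param peak_day simulation day (1-based) of the maximum; the default
#'   day 92 is February 1 for a November 1 start.
#' @param n_days season length in days.
#' @param edge_frac fraction of the peak at the far season edge.
#' @return object of class \code{population_trajectory}.
#' @export
population_trajectory <- function(peak_count, peak_day = 92L,
                                  n_days = 195L, edge_frac = 0.1) {
  stopifnot(peak_count >= 0, peak_day >= 1, peak_day <= n_days)
  far <- max(peak_day - 1, n_days - peak_day)
  k <- if (far > 0) (1 - edge_frac) / far^2 else 0
  structure(list(peak_count = peak_count, peak_day = peak_day,
                 n_days = n_days, k = k),
            class = "population_trajectory")
}

#' Population size on a simulation day
#'
#' @param trajectory a \code{\link{population_trajectory}}.
#' @param day simulation day in \code{1..n_days}.
#' @return non-negative integer count; equals \code{peak_count} at
#'   \code{peak_day}.
#' @export
population_size <- function(trajectory, day) {
  if (any(day < 1 | day > trajectory$n_days))
    stop("day outside the simulation window")
  n <- trajectory$peak_count *
    (1 - trajectory$k * (day - trajectory$peak_day)^2)
  as.integer(round(pmax(0, n)))
}

#' Weight calendar
#'
#' Daily mean body weight (g) for each of the \code{n_days} simulation days
#' plus the species' maximal additional weight. The maximum weight a goose
#' can attain on a day is the daily mean plus the additional weight.
#'
#' @param species species code.
#' @param daily_mean numeric vector of daily mean weights (g), length
#'   \code{n_days}.
#' @param max_additional maximal additional weight (g).
#' @param min_weight starvation threshold (g).
#' @return object of class \code{weight_calendar}.
#' @export
weight_calendar <- function(species, daily_mean, max_additional, min_weight) {
  stopifnot(all(daily_mean > min_weight), max_additional >= 0)
  structure(list(species = species, daily_mean = daily_mean,
                 max_additional = max_additional, min_weight = min_weight,
                 n_days = length(daily_mean)),
            class = "weight_calendar")
}

#' Maximum attainable weight on a day
#'
#' @param calendar a \code{\link{weight_calendar}}.
#' @param day simulation day.
#' @return daily mean weight plus the maximal additional weight (g).
#' @export
max_weight <- function(calendar, day) {
  if (any(day < 1 | day > calendar$n_days))
    stop("day outside the calendar window")
  calendar$daily_mean[day] + calendar$max_additional
}

#' Mean expected weight on a day
#'
#' @inheritParams max_weight
#' @export
mean_weight <- function(calendar, day) {
  if (any(day < 1 | day > calendar$n_days))
    stop("day outside the calendar window")
  calendar$daily_mean[day]
}

## --- day/night and moonlight -------------------------------------------

#' Sunrise and sunset hours
#'
#' Standard solar-declination approximation: declination
#' \code{delta = -23.44 * cos(2*pi*(doy + 10)/365)} degrees and hour angle
#' \code{omega = acos(-tan(lat) tan(delta))}; sunrise/sunset are
#' \code{12 -/+ omega * 12/pi} in local solar hours.
#'
#' @param doy day of year (1-366).
#' @param latitude degrees north.
#' @return list with \code{sunrise} and \code{sunset} (decimal hours).
#' @export
sun_times <- function(doy, latitude = 53.2) {
  rad <- pi / 180
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * rad
  x <- -tan(latitude * rad) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  omega <- acos(x)
  list(sunrise = 12 - omega * 12 / pi, sunset = 12 + omega * 12 / pi)
}

#' Is a given hour in daylight?
#'
#' @param doy day of year.
#' @param hour decimal hour in [0, 24).
#' @param latitude degrees north.
#' @return logical.
#' @export
is_daylight <- function(doy, hour, latitude = 53.2) {
  if (any(hour < 0 | hour >= 24)) stop("hour must be in [0, 24)")
  st <- sun_times(doy, latitude)
  hour >= st$sunrise & hour < st$sunset
}

# moon age in days since new moon, from a fixed epoch (2000-01-06, a new
# moon), folded into the 29.53-day synodic cycle. doy is mapped to a
# nominal non-leap civil date in the 2000/2001 winter.
.moon_age <- function(doy) {
  days_since_epoch <- ifelse(doy >= 183, doy - 6, doy + 360)
  days_since_epoch %% 29.530588
}

#' Illuminated moon fraction
#'
#' Phase approximation on the 29.53-day synodic cycle:
#' \code{(1 - cos(2*pi*age/29.53))/2}, 0 at new moon, 1 at full moon.
#'
#' @param doy day of year.
#' @return fraction in [0, 1].
#' @export
moon_fraction <- function(doy) {
  (1 - cos(2 * pi * .moon_age(doy) / 29.530588)) / 2
}

#' Is moonlight sufficient for night foraging?
#'
#' TRUE when the illuminated fraction reaches \code{threshold} and the moon
#' is plausibly above the horizon: the lunar transit is approximated as
#' advancing through the night with phase (transit at solar midnight at
#' full moon), and the moon is taken as up within +/- 6.2 h of transit.
#'
#' @param doy day of year.
#' @param hour decimal hour in [0, 24).
#' @param threshold required illuminated fraction; 0 always suffices,
#'   values above 1 never do.
#' @return logical.
#' @export
moonlight_sufficient <- function(doy, hour, threshold = 0.5) {
  if (any(hour < 0 | hour >= 24)) stop("hour must be in [0, 24)")
  if (threshold <= 0) return(rep(TRUE, max(length(hour), length(doy))))
  frac <- moon_fraction(doy)
  ok_frac <- frac >= threshold  # never TRUE for threshold > 1
  transit <- (12 + 24 * .moon_age(doy) / 29.530588) %% 24
  dh <- pmin(abs(hour - transit), 24 - abs(hour - transit))
  ok_frac & dh <= 6.2
}
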