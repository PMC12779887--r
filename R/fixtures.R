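#' @title Synthetic-data generators
#'
#' @description
#' Deterministic (seeded) generators for every input the model consumes:
#' clustered landscapes with realistic patch-type proportions, seasonal
#' weather series, species weight calendars, and GPS tracks with known
#' movement parameters for calibration-recovery testing. All generators
#' are pure functions of their arguments and the RNG state.
#'
#' @name fixtures
NULL

#' Default landscape composition
#'
#' Patch-type fractions proportional to the study region's composition:
#' scaring 139324, accommodation 15533, nature 12546 and roost 7881 out of
#' 490000 one-ha patches; the remainder is "other".
#' @export
default_landscape_fractions <- function() {
  c(scaring = 139324, accommodation = 15533, nature = 12546,
    roost = 7881) / 490000
}

#' Generate a clustered synthetic landscape
#'
#' Seeded region-growing: for each patch type, circular blobs of
#' exponentially distributed radius are grown from random nuclei until the
#' target cell count is met exactly. Roosts are placed first; nature-area
#' nuclei are biased to lie near roost cells (nature areas are close to
#' roost sites); accommodation and scaring areas fill in afterwards.
#'
#' @param width,height grid size in patches.
#' @param fractions named fractions for scaring, accommodation, nature and
#'   roost (must sum to < 1; remainder is "other").
#' @param cluster_radius mean blob radius (patches).
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @param initial_height initial grass height (m).
#' @return a \code{goose_landscape}.
#' @export
gen_landscape <- function(width = 100L, height = 100L,
                          fractions = default_landscape_fractions(),
                          cluster_radius = 4, seed = NULL,
                          initial_height = 0.094) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(fractions) > 1) stop("infeasible fractions (sum > 1)")
  n <- width * height
  targets <- round(fractions * n)
  grid <- rep(0L, n)  # column-major: id = row + 1 + col*height
  col_of <- (seq_len(n) - 1L) %/% height
  row_of <- (seq_len(n) - 1L) %% height
  grow_type <- function(grid, code, target, near = NULL) {
    placed <- sum(grid == code)
    guard <- 0L
    while (placed < target && guard < 10000L) {
      guard <- guard + 1L
      free <- which(grid == 0L)
      if (length(free) == 0L) break
      nucleus <- if (!is.null(near) && length(near) > 0L) {
        anchor <- near[sample.int(length(near), 1L)]
        cand <- c(col_of[anchor] + round(stats::rnorm(1L, 0, 4)),
                  row_of[anchor] + round(stats::rnorm(1L, 0, 4)))
        cand <- pmin(pmax(cand, 0L), c(width - 1L, height - 1L))
        id <- cand[2L] + 1L + cand[1L] * height
        if (grid[id] != 0L) free[sample.int(length(free), 1L)] else id
      } else free[sample.int(length(free), 1L)]
      r <- pmax(1, stats::rexp(1L, 1 / cluster_radius))
      d2 <- (col_of - col_of[nucleus])^2 + (row_of - row_of[nucleus])^2
      blob <- which(d2 <= r^2 & grid == 0L)
      need <- target - placed
      if (length(blob) > need)
        blob <- blob[order(d2[blob])][seq_len(need)]
      grid[blob] <- code
      placed <- placed + length(blob)
    }
    grid
  }
  grid <- grow_type(grid, -1L, targets[["roost"]])
  grid <- grow_type(grid, 3L, targets[["nature"]], near = which(grid == -1L))
  grid <- grow_type(grid, 2L, targets[["accommodation"]])
  grid <- grow_type(grid, 1L, targets[["scaring"]])
  new_landscape(matrix(grid, height, width), initial_height = initial_height)
}

#' Generate a synthetic daily weather series
#'
#' Seasonal sinusoids for daily mean temperature and global radiation over
#' the wintering season (November 1 start by default) plus optional
#' Gaussian noise; radiation is clipped at zero.
#'
#' @param n_days number of days (195 = Nov 1 to May 15).
#' @param start_doy day of year of the first day.
#' @param noise_sd named noise standard deviations for
#'   \code{temperature} (deg C) and \code{radiation} (MJ m-2 day-1).
#' @param seed optional seed.
#' @return data.frame with \code{day}, \code{doy}, \code{temperature},
#'   \code{radiation}.
#' @export
gen_weather <- function(n_days = 195L, start_doy = 305L,
                        noise_sd = c(temperature = 1.5, radiation = 1.5),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  day <- seq_len(n_days)
  doy <- (start_doy - 1L + day - 1L) %% 365L + 1L
  temp <- 9.5 + 7 * cos(2 * pi * (doy - 196) / 365)
  rad <- 10.5 + 8.5 * cos(2 * pi * (doy - 172) / 365)
  if (noise_sd[["temperature"]] > 0)
    temp <- temp + stats::rnorm(n_days, 0, noise_sd[["temperature"]])
  if (noise_sd[["radiation"]] > 0)
    rad <- rad + stats::rnorm(n_days, 0, noise_sd[["radiation"]])
  data.frame(day = day, doy = doy, temperature = temp,
             radiation = pmax(0, rad))
}

#' Generate a species weight calendar
#'
#' Smooth daily mean weights: anchored at the species' initial weight over
#' the first days of November, with a sigmoidal spring gain (fattening
#' before migration) reaching ~60% of the maximal additional weight by the
#' season's end. Always above the species minimum weight.
#'
#' @param sp a \code{goose_species}.
#' @param n_days season length.
#' @param gain_frac fraction of \code{max_additional} gained by spring.
#' @param midpoint_day sigmoid midpoint (simulation day).
#' @param seed optional seed (the default curve is deterministic).
#' @return a \code{\link{weight_calendar}}.
#' @export
gen_weight_calendar <- function(sp, n_days = 195L, gain_frac = 0.6,
                                midpoint_day = 130, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  day <- seq_len(n_days)
  daily <- sp$initial_weight + gain_frac * sp$max_additional *
    stats::plogis((day - midpoint_day) / 12)
  weight_calendar(sp$name, daily, sp$max_additional, sp$min_weight)
}

#' Generate synthetic GPS tracks with known movement parameters
#'
#' Hourly fixes for \code{n_animals} geese over \code{n_days} days: nights
#' (0:00-4:00 local) are spent exactly at the animal's roost; during the
#' day the animal relocates with probability \code{p_move} per hour by one
#' composite-random-walk step on a uniform bearing. Relocations emit a
#' take-off and a landing fix at the species flight speed, separated by
#' the modelled flight duration, so flight segmentation, hourly
#' displacements and roost detection can all recover the planted truth.
#' The evening return to the roost is timed off the hourly grid so it does
#' not contaminate hourly displacement samples.
#'
#' @param sp a \code{goose_species} (provides CRW and flight parameters).
#' @param n_animals number of animals.
#' @param n_days tracking days (>= 4 so roosts qualify).
#' @param roosts matrix with columns x, y: roost centres in metres; one is
#'   assigned per animal (recycled).
#' @param p_move probability of relocating in a daytime hour.
#' @param seed optional seed.
#' @return data.frame with \code{animal}, \code{species}, \code{time}
#'   (POSIXct, local), \code{x}, \code{y} (m), \code{speed} (m/s); the
#'   generating parameters are attached as attribute \code{"truth"}.
#' @export
gen_tracks <- function(sp, n_animals = 5L, n_days = 10L,
                       roosts = cbind(x = c(5050, 25050),
                                      y = c(5050, 15050)),
                       p_move = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_animals == 0L)
    return(structure(data.frame(animal = integer(0), species = character(0),
                                time = as.POSIXct(character(0), tz = "UTC"),
                                x = numeric(0), y = numeric(0),
                                speed = numeric(0)),
                     truth = list(crw = sp$crw, flight = sp$flight,
                                  roosts = roosts)))
  t0 <- as.POSIXct("2018-11-01 00:00:00", tz = "UTC")
  rows <- vector("list", 0L)
  add <- function(animal, time, x, y, speed)
    rows[[length(rows) + 1L]] <<- list(animal = animal, time = time,
                                       x = x, y = y, speed = speed)
  for (a in seq_len(n_animals)) {
    home <- roosts[(a - 1L) %% nrow(roosts) + 1L, ]
    pos <- c(home[["x"]], home[["y"]])
    for (d in seq_len(n_days)) {
      base <- t0 + (d - 1L) * 86400
      for (h in 0:4) add(a, base + h * 3600, home[["x"]], home[["y"]],
                         stats::runif(1L, 0, 1))
      pos <- c(home[["x"]], home[["y"]])
      for (h in 5:22) {
        if (stats::runif(1L) < p_move) {
          len_m <- sample_step(sp$crw, 1L) * 100
          theta <- stats::runif(1L, 0, 2 * pi)
          new_pos <- pos + len_m * c(cos(theta), sin(theta))
          t_dep <- base + h * 3600
          dur <- flight_duration(len_m / sp$flight$patch_length, sp$flight)
          add(a, t_dep, pos[1L], pos[2L], sp$flight_speed)
          add(a, t_dep + dur, new_pos[1L], new_pos[2L], sp$flight_speed)
          pos <- new_pos
        } else {
          add(a, base + h * 3600, pos[1L], pos[2L], stats::runif(1L, 0, 1))
        }
      }
      # off-grid-timed return to the roost
      add(a, base + 23 * 3600 + 1800, home[["x"]], home[["y"]],
          sp$flight_speed)
    }
  }
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(animal = r$animal, species = sp$name, time = r$time,
               x = r$x, y = r$y, speed = r$speed)))
  df <- df[order(df$animal, df$time), ]
  rownames(df) <- NULL
  structure(df, truth = list(crw = sp$crw, flight = sp$flight,
                             roosts = roosts))
}
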