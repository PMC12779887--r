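#' @title Season simulation: scheduler, recorders, damage economics
#'
#' @description
#' The simulator runs the hourly decision tree for every flock from
#' November 1 to May 15 (day of year 305 to 135; 195 days, 4680 hourly
#' steps at full length) over a landscape of 1-ha patches. Grass grows once
#' a day from weather; flock numbers track a quadratic seasonal population
#' trajectory per species (arrivals spawn at the species' initial roost
#' sites, departures retire the most recently arrived flocks). Recorders
#' accumulate goose pressure per grassland type and species, scaring
#' events, affected patches, deaths, and grass state, from which yield loss
#' (height deficit vs an ungrazed reference, at 150 kg dry matter per cm
#' per ha and EUR 0.25 per kg) and total management costs are computed.
#'
#' @name simulation
NULL

# internal: one flock's decision tree for one hour; returns an effect list,
# mutates only the flock environment. ctx carries hour-level context and
# read-only views of the world state. Written for the hot loop: scalar
# arithmetic, no generic dispatch, conspecific positions snapshotted at the
# start of the hour.
.flock_hour <- function(f, ctx) {
  sp <- f$sp
  beh <- ctx$behaviour
  nr <- ctx$nr
  t_fly <- 0
  forage_now <- if (ctx$daylight) {
    f$mass < ctx$max_w_v[f$spi]
  } else {
    f$mass < ctx$mean_w_v[f$spi] &&
      (ctx$sunrise_gap - 1) >= beh$night_rest_hours &&
      ctx$moon_ok
  }
  if (!forage_now) {
    if (!(f$state == "roosting" && ctx$type[f$cell] == -1L)) {
      dest <- .roost_fast(f, ctx)
      if (dest != f$cell) {
        dcol <- (dest - 1L) %/% nr; drow <- (dest - 1L) %% nr
        d <- sqrt((f$col - dcol)^2 + (f$row - drow)^2)
        t_fly <- .flight_fast(max(d, 1e-9), sp$flight)
        f$cell <- dest; f$col <- dcol; f$row <- drow
      }
      f$prev_roost <- f$cell
      f$state <- "roosting"
    }
    t_fly <- min(t_fly, 3600)
    return(list(event = "roost", t_forage = 0, t_fly = t_fly,
                t_rest = 3600 - t_fly, scare_type = NA_integer_))
  }
  event <- if (ctx$daylight) "forage" else "night_forage"
  dest <- .select_mem(f, ctx$time, beh, ctx$gain_factor)
  if (is.null(dest)) dest <- .crw_dest(f, ctx)
  dest <- .join_fast(f, dest, ctx)
  moves <- 0L
  repeat {
    if (dest != f$cell) {
      dcol <- (dest - 1L) %/% nr; drow <- (dest - 1L) %% nr
      d <- sqrt((f$col - dcol)^2 + (f$row - drow)^2)
      t_fly <- t_fly + .flight_fast(max(d, 1e-9), sp$flight)
      f$cell <- dest; f$col <- dcol; f$row <- drow
    }
    if (moves >= beh$max_relocations ||
        stats::runif(1L) < beh$p_max_forage *
          .intake_fast(ctx$height[f$cell], sp) / sp$rate_opt) break
    moves <- moves + 1L
    dest <- .crw_dest(f, ctx)
  }
  scare_type <- NA_integer_
  ty <- ctx$type[f$cell]
  if (ty > 0L && stats::runif(1L) < ctx$dist_p[ty]) {
    scare_type <- ty
    event <- "scare"
    # scaring: zero the memory of this patch, displace ~2 km
    j <- match(f$cell, f$mem_cell)
    if (is.na(j)) {
      remember(f, f$cell, 0, time = ctx$time, land = ctx$land,
               memory_size = beh$memory_size)
    } else f$mem_h[j] <- 0
    landing <- .displace_fast(f, ctx, 20)
    dcol <- (landing - 1L) %/% nr; drow <- (landing - 1L) %% nr
    d <- sqrt((f$col - dcol)^2 + (f$row - drow)^2)
    t_fly <- t_fly + .flight_fast(max(d, 1), sp$flight)
    f$cell <- landing; f$col <- dcol; f$row <- drow
    if (ctx$type[f$cell] <= 0L) {
      dest <- .crw_dest(f, ctx)
      dcol <- (dest - 1L) %/% nr; drow <- (dest - 1L) %% nr
      d <- sqrt((f$col - dcol)^2 + (f$row - drow)^2)
      t_fly <- t_fly + .flight_fast(max(d, 1e-9), sp$flight)
      f$cell <- dest; f$col <- dcol; f$row <- drow
    }
  }
  f$state <- "foraging"
  t_fly <- min(t_fly, 3600)
  list(event = event, t_forage = 3600 - t_fly, t_fly = t_fly,
       t_rest = 0, scare_type = scare_type)
}

# random-search destination: composite-random-walk length on a uniform
# bearing, re-drawn until the landing cell is on-grid grassland (20 tries,
# then a uniform random grassland cell).
.crw_dest <- function(f, ctx) {
  p <- f$sp$crw
  nr <- ctx$nr
  for (i in seq_len(20L)) {
    len <- if (stats::runif(1L) < p$p_bw)
      p$x_min + stats::rexp(1L, p$lambda)
    else
      (p$x_min^(p$mu - 1) / (1 - stats::runif(1L) * p$denom))^(1 / (p$mu - 1))
    theta <- stats::runif(1L, 0, 2 * pi)
    col <- round(f$col + len * cos(theta))
    row <- round(f$row + len * sin(theta))
    if (col < 0 || col >= ctx$ncl || row < 0 || row >= nr) next
    id <- row + 1 + col * nr
    if (ctx$type[id] > 0L) return(as.integer(id))
  }
  ctx$grass_cells[sample.int(length(ctx$grass_cells), 1L)]
}

# previous roost if within 10 km, else distance-weighted random roost
.roost_fast <- function(f, ctx) {
  pr <- f$prev_roost
  if (!is.null(pr)) {
    pcol <- (pr - 1L) %/% ctx$nr; prow <- (pr - 1L) %% ctx$nr
    if ((f$col - pcol)^2 + (f$row - prow)^2 <= 10000) return(pr)
  }
  d <- sqrt((ctx$roost_col - f$col)^2 + (ctx$roost_row - f$row)^2)
  ctx$roosts[sample.int(length(ctx$roosts), 1L, prob = 1 / (d + 1))]
}

# join the largest conspecific aggregation within the join radius of dest
.join_fast <- function(f, dest, ctx) {
  cj <- ctx$consp[[f$spi]]
  if (is.null(cj) || length(cj$n) == 0L) return(dest)
  nr <- ctx$nr
  dcol <- (dest - 1L) %/% nr; drow <- (dest - 1L) %% nr
  dc <- cj$col - dcol; dr <- cj$row - drow
  ok <- (dc * dc + dr * dr) <= ctx$join_r2 & cj$id != f$id
  if (!any(ok)) return(dest)
  b <- which(ok)[which.max(cj$n[ok])]
  if (stats::runif(1L) <
      stats::plogis(f$sp$a1 + ctx$beta_join * log10(cj$n[b] + 1)))
    cj$cell[b]
  else dest
}

# ~2 km displacement on a uniform random bearing (bounded redraws). On
# grids too small to hold the full displacement the landing point is
# clipped to the grid edge along the last bearing (the flock flies to the
# boundary); the exported scare_displacement keeps the strict error.
.displace_fast <- function(f, ctx, distance = 20) {
  nr <- ctx$nr
  theta <- 0
  for (i in seq_len(100L)) {
    theta <- stats::runif(1L, 0, 2 * pi)
    col <- round(f$col + distance * cos(theta))
    row <- round(f$row + distance * sin(theta))
    if (col >= 0 && col < ctx$ncl && row >= 0 && row < nr)
      return(as.integer(row + 1 + col * nr))
  }
  col <- min(max(round(f$col + distance * cos(theta)), 0), ctx$ncl - 1)
  row <- min(max(round(f$row + distance * sin(theta)), 0), nr - 1)
  as.integer(row + 1 + col * nr)
}

# assemble the hour context used by .flock_hour
.build_ctx <- function(land, flocks, behaviour, energetics, time, daylight,
                       sunrise_gap, moon_ok, max_w_v, mean_w_v,
                       type = as.vector(land$type),
                       height = as.vector(land$height),
                       grass_cells = which(type > 0L)) {
  roosts <- land$roost_index
  nr <- land$height_patches
  consp <- vector("list", 4L)
  for (g in flocks) {
    if (!g$alive || g$state != "foraging") next
    i <- g$spi
    consp[[i]]$col <- c(consp[[i]]$col, g$col)
    consp[[i]]$row <- c(consp[[i]]$row, g$row)
    consp[[i]]$n <- c(consp[[i]]$n, g$n_geese)
    consp[[i]]$cell <- c(consp[[i]]$cell, g$cell)
    consp[[i]]$id <- c(consp[[i]]$id, g$id)
  }
  list(land = land, type = type, height = height,
       grass_cells = grass_cells,
       nr = nr, ncl = land$width,
       roosts = roosts,
       roost_col = (roosts - 1L) %/% nr, roost_row = (roosts - 1L) %% nr,
       flocks = flocks, consp = consp,
       behaviour = behaviour, energetics = energetics,
       gain_factor = 3600 * energetics$e_grass * energetics$q_assim,
       dist_p = unname(behaviour$disturbance[
         c("scaring", "accommodation", "nature")]),
       join_r2 = behaviour$join_radius^2,
       beta_join = behaviour$beta_join,
       time = time, daylight = daylight, sunrise_gap = sunrise_gap,
       moon_ok = moon_ok, max_w_v = max_w_v, mean_w_v = mean_w_v)
}

#' Step one flock through one hour (functional wrapper)
#'
#' Runs the hourly decision tree for a single flock against a landscape,
#' applies grazing and the energy budget, and returns the updated
#' landscape together with the hour's ledger. The flock environment is
#' modified in place. Intended for testing and stepwise inspection; the
#' season runner inlines the same logic.
#'
#' @param flock a \code{goose_flock}.
#' @param land a \code{goose_landscape}.
#' @param time simulation hour (0-based).
#' @param doy day of year.
#' @param calendar the species' \code{weight_calendar}.
#' @param day simulation day (1-based, indexes the calendar).
#' @param flocks all flocks (for joining); defaults to just this flock.
#' @param behaviour,energetics constant lists.
#' @param latitude degrees north.
#' @return list: \code{land} (updated), \code{ledger} (t_forage, t_fly,
#'   t_rest, grams, dE, event).
#' @export
step_flock <- function(flock, land, time, doy, calendar, day,
                       flocks = list(flock),
                       behaviour = .default_behaviour(),
                       energetics = .default_energetics(),
                       latitude = 53.2) {
  if (!flock$alive) stop("cannot step a dead flock")
  hod <- time %% 24
  st <- sun_times(doy, latitude)
  gap <- if (hod < st$sunrise) st$sunrise - hod else 24 - hod + st$sunrise
  mw <- mv <- numeric(4L)
  mw[flock$spi] <- max_weight(calendar, day)
  mv[flock$spi] <- mean_weight(calendar, day)
  ctx <- .build_ctx(land, flocks, behaviour, energetics,
                    time = time,
                    daylight = is_daylight(doy, hod + 0.5, latitude),
                    sunrise_gap = gap,
                    moon_ok = moonlight_sufficient(
                      doy, hod + 0.5, behaviour$moonlight_threshold),
                    max_w_v = mw, mean_w_v = mv)
  eff <- .flock_hour(flock, ctx)
  grams <- 0
  if (eff$t_forage > 0 && land$type[flock$cell] %in% GRASS_CODES) {
    gz <- graze(land, flock$cell, flock$sp, flock$n_geese, eff$t_forage)
    land <- gz$land
    grams <- gz$grams_total
    remember(flock, flock$cell, land$height[flock$cell], time = time,
             land = land, memory_size = behaviour$memory_size)
  }
  dE <- hourly_budget(eff$t_forage, eff$t_fly, eff$t_rest,
                      grams / flock$n_geese, flock$sp, energetics)
  uw <- update_weight(flock$mass, dE, flock$sp,
                      max_w = max_weight(calendar, day), energetics)
  flock$mass <- uw$mass
  if (!uw$alive) flock$alive <- FALSE
  list(land = land,
       ledger = list(event = eff$event, t_forage = eff$t_forage,
                     t_fly = eff$t_fly, t_rest = eff$t_rest,
                     grams = grams, dE = dE,
                     scare_type = eff$scare_type))
}

#' Run a season simulation
#'
#' @param land a \code{goose_landscape}.
#' @param config a \code{goosesim_config} from \code{\link{load_config}}.
#' @param seed integer seed; the run is deterministic given
#'   (landscape, config, seed).
#' @param n_days season length in days (default from config; 195 = Nov 1
#'   to May 15).
#' @param weather data.frame with \code{temperature} and \code{radiation}
#'   columns, one row per day; generated synthetically when \code{NULL}.
#' @param calendars named list of \code{weight_calendar}s per species;
#'   generated when \code{NULL}.
#' @param peak_day simulation day of the population maximum.
#' @param record_events keep a per-event log (slower).
#' @param progress print a line every 30 days.
#' @return a \code{goosesim_result}: recorders described above plus the
#'   final grass state and the ungrazed reference height.
#' @export
run_simulation <- function(land, config = load_config(), seed = 1L,
                           n_days = NULL, weather = NULL, calendars = NULL,
                           peak_day = NULL, record_events = FALSE,
                           progress = FALSE) {
  set.seed(seed)
  n_days <- as.integer(n_days %||% config$n_days)
  start_doy <- as.integer(config$start_doy)
  species <- config$species
  beh <- config$behaviour
  ener <- config$energetics
  if (is.null(weather)) weather <- gen_weather(n_days = n_days)
  stopifnot(nrow(weather) >= n_days)
  if (is.null(calendars))
    calendars <- lapply(species, function(sp)
      gen_weight_calendar(sp, n_days = n_days))
  peak_day <- as.integer(peak_day %||% min(92L, n_days))
  trajectories <- lapply(SPECIES_CODES, function(code)
    population_trajectory(
      peak_count = species[[code]]$max_population *
        config$population_scalars[[code]],
      peak_day = peak_day, n_days = n_days))
  names(trajectories) <- SPECIES_CODES

  n_cells <- land$width * land$height_patches
  type <- as.vector(land$type)
  height <- as.vector(land$height)
  grazed <- numeric(n_cells)
  fh <- matrix(0, n_cells, 4L, dimnames = list(NULL, SPECIES_CODES))
  grass_cells <- which(type %in% GRASS_CODES)
  roosts <- land$roost_index
  if (length(roosts) == 0L)
    stop("config/landscape error: no roost cells")
  # Arrival sites: the species' initial-distribution site counts refer to
  # the full 700x700 study region. On smaller landscapes the counts are
  # scaled with area so the number of flocks per active roost site (the
  # crowding that saturates near-roost grasslands) is preserved, and the
  # scaled sites are drawn from a shared pool because roost sites are
  # shared between species.
  area_factor <- min(1, n_cells / 490000)
  n_eff <- vapply(SPECIES_CODES, function(code)
    max(1L, min(length(roosts),
                as.integer(round(species[[code]]$n_sites * area_factor)))),
    integer(1L))
  if (area_factor < 1) {
    pool <- sample(roosts, min(length(roosts), max(n_eff)))
    arrival_sites <- lapply(n_eff, function(k)
      pool[sample.int(length(pool), min(k, length(pool)))])
  } else {
    arrival_sites <- lapply(SPECIES_CODES, function(code)
      sample(roosts, n_eff[[code]]))
  }
  names(arrival_sites) <- SPECIES_CODES

  # recorders
  tnames <- c("scaring", "accommodation", "nature")
  pressure <- matrix(0, 3L, 4L, dimnames = list(tnames, SPECIES_CODES))
  scares <- matrix(0L, 3L, 4L, dimnames = list(tnames, SPECIES_CODES))
  deaths <- stats::setNames(integer(4L), SPECIES_CODES)
  grams_eaten <- stats::setNames(numeric(4L), SPECIES_CODES)
  fly_seconds <- stats::setNames(numeric(4L), SPECIES_CODES)
  forage_seconds <- stats::setNames(numeric(4L), SPECIES_CODES)
  daily_pop <- matrix(0, n_days, 4L, dimnames = list(NULL, SPECIES_CODES))
  events <- if (record_events) vector("list", 0L) else NULL

  flocks <- list()           # all ever created, arrival order
  next_id <- 1L
  ref_h <- land$initial_height
  n_steps <- 0L
  max_w_v <- mean_w_v <- numeric(4L)
  nr <- land$height_patches
  roost_col <- (roosts - 1L) %/% nr
  roost_row <- (roosts - 1L) %% nr
  gain_factor <- 3600 * ener$e_grass * ener$q_assim
  dist_p <- unname(beh$disturbance[c("scaring", "accommodation", "nature")])
  join_r2 <- beh$join_radius^2

  for (hr in 0:(24L * n_days - 1L)) {
    day <- hr %/% 24L + 1L
    hod <- hr %% 24L
    doy <- (start_doy - 1L + day - 1L) %% 365L + 1L
    if (hod == 0L) {
      # daily grass growth (and the ungrazed reference twin)
      w <- list(temperature = weather$temperature[day],
                radiation = weather$radiation[day])
      if (isTRUE(config$grass$ghdgg_enabled)) {
        height[grass_cells] <- height[grass_cells] +
          grass_growth(height[grass_cells], w, config$grass)
      } else {
        height[grass_cells] <- height[grass_cells] +
          grass_growth(0, w, config$grass)
      }
      ref_h <- ref_h + grass_growth(ref_h, w, config$grass)
      # population adjustment
      for (si in seq_along(SPECIES_CODES)) {
        code <- SPECIES_CODES[si]
        sp <- species[[code]]
        target <- as.integer(round(
          population_size(trajectories[[code]], day) / sp$flock_size))
        mine <- Filter(function(f) f$species == code && f$alive, flocks)
        cur <- length(mine)
        if (cur < target) {
          for (k in seq_len(target - cur)) {
            site <- arrival_sites[[code]][
              sample.int(length(arrival_sites[[code]]), 1L)]
            f <- new_flock(sp, site, land,
                           mass = mean_weight(calendars[[code]], day),
                           id = next_id)
            next_id <- next_id + 1L
            flocks[[length(flocks) + 1L]] <- f
          }
        } else if (cur > target) {
          for (f in rev(mine)[seq_len(cur - target)]) {
            f$alive <- FALSE
            f$departed <- TRUE
          }
        }
        daily_pop[day, si] <- target * sp$flock_size
        max_w_v[si] <- max_weight(calendars[[code]], day)
        mean_w_v[si] <- mean_weight(calendars[[code]], day)
      }
      if (progress && (day %% 30L == 0L))
        message(sprintf("day %d/%d: %d flocks active", day, n_days,
                        sum(vapply(flocks, function(f) f$alive, TRUE))))
    }
    st <- sun_times(doy, config$latitude)
    gap <- if (hod < st$sunrise) st$sunrise - hod else 24 - hod + st$sunrise
    active <- Filter(function(f) f$alive, flocks)
    if (length(active) == 0L) { n_steps <- n_steps + 1L; next }
    consp <- vector("list", 4L)
    for (g in active) {
      if (g$state != "foraging") next
      i <- g$spi
      consp[[i]]$col <- c(consp[[i]]$col, g$col)
      consp[[i]]$row <- c(consp[[i]]$row, g$row)
      consp[[i]]$n <- c(consp[[i]]$n, g$n_geese)
      consp[[i]]$cell <- c(consp[[i]]$cell, g$cell)
      consp[[i]]$id <- c(consp[[i]]$id, g$id)
    }
    ctx <- list(
      land = land, type = type, height = height, grass_cells = grass_cells,
      nr = nr, ncl = land$width,
      roosts = roosts, roost_col = roost_col, roost_row = roost_row,
      flocks = active, consp = consp,
      behaviour = beh, energetics = ener,
      gain_factor = gain_factor, dist_p = dist_p,
      join_r2 = join_r2, beta_join = beh$beta_join,
      time = hr, daylight = hod + 0.5 >= st$sunrise & hod + 0.5 < st$sunset,
      sunrise_gap = gap,
      moon_ok = moonlight_sufficient(doy, hod + 0.5,
                                     beh$moonlight_threshold),
      max_w_v = max_w_v, mean_w_v = mean_w_v)
    for (f in active[sample.int(length(active))]) {
      si <- match(f$species, SPECIES_CODES)
      eff <- .flock_hour(f, ctx)
      grams <- 0
      cell <- f$cell
      ty <- type[cell]
      if (eff$t_forage > 0 && ty > 0L) {
        h0 <- ctx$height[cell]           # start-of-hour height
        demand <- .intake_fast(h0, f$sp) * eff$t_forage * f$n_geese
        standing <- height[cell] * 100 * 150000
        grams <- min(demand, standing)
        dh_cm <- grams / 150000
        height[cell] <- max(0, height[cell] - dh_cm / 100)
        grazed[cell] <- grazed[cell] + dh_cm
        hrs <- f$n_geese * eff$t_forage / 3600
        fh[cell, si] <- fh[cell, si] + hrs
        pressure[ty, si] <- pressure[ty, si] + hrs
        grams_eaten[si] <- grams_eaten[si] + grams
        forage_seconds[si] <- forage_seconds[si] + eff$t_forage
        remember(f, cell, height[cell], time = hr, land = land,
                 memory_size = beh$memory_size)
      }
      if (!is.na(eff$scare_type))
        scares[eff$scare_type, si] <- scares[eff$scare_type, si] + 1L
      fly_seconds[si] <- fly_seconds[si] + eff$t_fly
      dE <- grams / f$n_geese * ener$e_grass * ener$q_assim -
        (f$sp$fmr * eff$t_forage + f$sp$flight_mr * eff$t_fly +
           f$sp$rmr * eff$t_rest)
      f$mass <- min(f$mass + dE / ener$e_tissue, max_w_v[si])
      if (f$mass < f$sp$min_weight) {
        f$alive <- FALSE
        deaths[si] <- deaths[si] + 1L
      }
      if (record_events)
        events[[length(events) + 1L]] <- data.frame(
          hour = hr, flock = f$id, species = f$species,
          event = if (!f$alive) "death" else eff$event,
          cell = f$cell, mass = f$mass)
    }
    n_steps <- n_steps + 1L
  }

  land$height <- matrix(height, land$height_patches, land$width)
  land$grazed_cm <- matrix(grazed, land$height_patches, land$width)
  for (si in seq_along(SPECIES_CODES))
    land$flock_hours[[SPECIES_CODES[si]]] <-
      matrix(fh[, si], land$height_patches, land$width)
  structure(list(
    pressure = pressure, scares = scares, deaths = deaths,
    grams_eaten = grams_eaten, fly_seconds = fly_seconds,
    forage_seconds = forage_seconds,
    daily_pop = daily_pop, n_steps = n_steps, n_days = n_days,
    seed = seed, type = type, fh = fh, grazed = grazed,
    height_final = height, ref_height_final = ref_h,
    land = land,
    events = if (record_events) do.call(rbind, events) else NULL
  ), class = "goosesim_result")
}

#' @export
print.goosesim_result <- function(x, ...) {
  cat(sprintf("<goosesim_result> %d hourly steps over %d days (seed %d)\n",
              x$n_steps, x$n_days, x$seed))
  cat(sprintf("  goose pressure (h): %s\n",
              paste(sprintf("%s %.0f", SPECIES_CODES, colSums(x$pressure)),
                    collapse = ", ")))
  cat(sprintf("  scaring events: %d | deaths: %d | yield loss: EUR %.2f\n",
              sum(x$scares), sum(x$deaths), yield_loss(x)))
  invisible(x)
}

#' Yield loss in euro
#'
#' Monetizes the grass-height deficit of agricultural grassland against an
#' ungrazed reference: per patch, \code{max(0, dh_cm) * 150 kg/cm/ha *
#' 0.25 EUR/kg} (i.e. EUR 37.50 per cm per ha). Nature-area patches are
#' excluded from the monetary sum unless \code{include_nature}.
#'
#' @param x a \code{goosesim_result}, or a final \code{goose_landscape}
#'   (with \code{reference} the ungrazed twin of identical geometry).
#' @param reference ungrazed reference landscape (landscape method only).
#' @param economics economics constants.
#' @param include_nature include nature-area patches in the sum.
#' @return euro amount.
#' @export
yield_loss <- function(x, reference = NULL,
                       economics = .default_economics(),
                       include_nature = FALSE) {
  per_cm <- economics$dm_per_cm_ha * economics$price_per_kg
  codes <- if (include_nature) c(1L, 2L, 3L) else c(1L, 2L)
  if (inherits(x, "goosesim_result")) {
    idx <- x$type %in% codes
    dh_cm <- pmax(0, (x$ref_height_final - x$height_final[idx]) * 100)
    return(sum(dh_cm) * per_cm)
  }
  if (!inherits(x, "goose_landscape") ||
      !inherits(reference, "goose_landscape"))
    stop("x must be a goosesim_result or a goose_landscape with reference")
  if (x$width != reference$width ||
      x$height_patches != reference$height_patches ||
      !identical(x$type, reference$type))
    stop("geometry mismatch between final and reference landscape")
  idx <- which(x$type %in% codes)
  dh_cm <- pmax(0, (reference$height[idx] - x$height[idx]) * 100)
  sum(dh_cm) * per_cm
}

#' Total management costs
#'
#' Yield loss plus scaring costs (EUR per scaring event) plus appraisal
#' costs (EUR per affected agricultural patch); each term also returned
#' separately.
#'
#' @param result a \code{goosesim_result}.
#' @param economics economics constants.
#' @return list with \code{yield_loss}, \code{scaring_costs},
#'   \code{appraisal_costs}, \code{total}.
#' @export
total_costs <- function(result, economics = .default_economics()) {
  yl <- yield_loss(result, economics = economics)
  n_scares <- sum(result$scares)
  affected <- sum(rowSums(result$fh)[result$type %in% c(1L, 2L)] > 0)
  sc <- economics$cost_per_scare * n_scares
  ap <- economics$cost_per_appraised_patch * affected
  list(yield_loss = yl, scaring_costs = sc, appraisal_costs = ap,
       n_scare_events = n_scares, affected_patches = affected,
       total = yl + sc + ap)
}

#' Goose pressure per goose
#'
#' Average hours per day a goose of the species spent foraging in the
#' given scope: \code{"agricultural"} counts scaring + accommodation
#' grassland, \code{"all-grassland"} adds nature areas.
#'
#' @param result a \code{goosesim_result}.
#' @param species species code.
#' @param scope \code{"agricultural"} or \code{"all-grassland"}.
#' @return hours per goose per day, or \code{NA} when the species had zero
#'   mean population.
#' @export
pressure_per_goose <- function(result, species,
                               scope = c("agricultural", "all-grassland")) {
  scope <- match.arg(scope)
  rows <- if (scope == "agricultural") c("scaring", "accommodation")
          else c("scaring", "accommodation", "nature")
  hours <- sum(result$pressure[rows, species])
  mean_pop <- mean(result$daily_pop[, species])
  if (mean_pop == 0) return(NA_real_)
  hours / (mean_pop * result$n_days)
}

#' Additional foraging relative to the sweep minimum
#'
#' For each run, the per-goose-normalized total goose pressure (all
#' grassland) minus the across-runs minimum for the species.
#'
#' @param results list of \code{goosesim_result} (>= 2).
#' @param species species code.
#' @return numeric vector, one value per run; 0 for the minimizing run.
#' @export
additional_foraging <- function(results, species) {
  if (length(results) < 2L) stop("need at least two results")
  p <- vapply(results, pressure_per_goose, numeric(1L),
              species = species, scope = "all-grassland")
  p - min(p, na.rm = TRUE)
}
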