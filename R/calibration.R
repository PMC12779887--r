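#' @title Calibration: GPS-track and count-data parameter estimation
#'
#' @description
#' The data-to-parameter procedures that turn tracking and count data into
#' model parameters: roost detection from night-time fixes, flight
#' segmentation by recorded velocity, flight-time coefficient fitting,
#' hourly displacement extraction feeding the composite-random-walk fit,
#' and the flock-size quantile rule. All operate on plain data.frames of
#' GPS fixes with columns \code{animal}, \code{time} (POSIXct, local time,
#' or with an optional \code{utc_offset} hours column), \code{x}, \code{y}
#' (projected metres) and \code{speed} (m/s); \code{species} is optional
#' and used by roost detection.
#'
#' @name calibration
NULL

.local_hour <- function(fixes) {
  h <- as.numeric(format(fixes$time, "%H")) +
    as.numeric(format(fixes$time, "%M")) / 60
  if (!is.null(fixes$utc_offset)) h <- (h + fixes$utc_offset) %% 24
  h
}

#' Detect roost cells from night-time GPS fixes
#'
#' A 100-m grid cell is a roost when a goose species visited it during at
#' least \code{min_nights} distinct nights within the night window
#' (0:00-4:00 local by default); the output pools all species, since
#' roosts are shared. Repeated fixes within one night count once.
#'
#' @param fixes GPS fix data.frame (see \code{\link{calibration}}).
#' @param cell_size grid cell size (m).
#' @param min_nights minimum distinct nights.
#' @param window numeric length-2 half-open local-hour window.
#' @return data.frame of roost cells with integer columns \code{cx},
#'   \code{cy} (cell indices: \code{floor(x / cell_size)}).
#' @export
detect_roosts <- function(fixes, cell_size = 100, min_nights = 4L,
                          window = c(0, 4)) {
  empty <- data.frame(cx = integer(0), cy = integer(0))
  if (nrow(fixes) == 0L) return(empty)
  h <- .local_hour(fixes)
  night <- fixes[h >= window[1L] & h < window[2L], , drop = FALSE]
  if (nrow(night) == 0L) return(empty)
  cx <- floor(night$x / cell_size)
  cy <- floor(night$y / cell_size)
  night_id <- format(night$time, "%Y-%m-%d")
  sp <- if (!is.null(night$species)) night$species else "all"
  key <- paste(cx, cy, sp, sep = "/")
  nights_per <- tapply(night_id, key, function(v) length(unique(v)))
  hit <- names(nights_per)[nights_per >= min_nights]
  if (length(hit) == 0L) return(empty)
  parts <- do.call(rbind, strsplit(hit, "/", fixed = TRUE))
  cells <- unique(data.frame(cx = as.integer(parts[, 1L]),
                             cy = as.integer(parts[, 2L])))
  rownames(cells) <- NULL
  cells[order(cells$cx, cells$cy), , drop = FALSE]
}

#' Segment flights from GPS fixes
#'
#' A goose is flying when its recorded velocity exceeds \code{v_min}
#' (strictly); consecutive flying fixes are chained into maximal segments
#' when their time gap is at most \code{max_gap}. Each segment carries its
#' along-track distance and duration.
#'
#' @param fixes GPS fix data.frame.
#' @param v_min flight speed threshold (m/s), exceeded strictly.
#' @param max_gap maximal usable fix interval (s).
#' @return data.frame with \code{animal}, \code{n_fixes},
#'   \code{distance_m}, \code{duration_s}, one row per segment.
#' @export
flight_segments <- function(fixes, v_min = 12, max_gap = 15 * 60) {
  out <- list()
  for (a in unique(fixes$animal)) {
    fa <- fixes[fixes$animal == a, , drop = FALSE]
    fa <- fa[order(fa$time), , drop = FALSE]
    n <- nrow(fa)
    if (n < 2L) next
    gap <- as.numeric(difftime(fa$time[-1L], fa$time[-n], units = "secs"))
    usable <- fa$speed[-n] > v_min & fa$speed[-1L] > v_min & gap <= max_gap
    if (!any(usable)) next
    r <- rle(usable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]:ends[k]     # pair indices
      d <- sum(sqrt((fa$x[i + 1L] - fa$x[i])^2 +
                    (fa$y[i + 1L] - fa$y[i])^2))
      out[[length(out) + 1L]] <- data.frame(
        animal = a, n_fixes = length(i) + 1L,
        distance_m = d, duration_s = sum(gap[i]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(animal = integer(0), n_fixes = integer(0),
                      distance_m = numeric(0), duration_s = numeric(0)))
  do.call(rbind, out)
}

#' Fit flight-time sigmoid coefficients to observed segments
#'
#' Nonlinear least squares of the flight-duration model
#' \code{T = exp(10 / (1 + c1 * d^c2)) * d / v} on (distance, duration)
#' segments, fitted on the sigmoid scale \code{log(T v / d)}.
#'
#' @param segments data.frame from \code{\link{flight_segments}} (needs
#'   \code{distance_m} and \code{duration_s}); at least 30 segments
#'   spanning at least one decade of distances.
#' @param v species flight speed (m/s).
#' @return list with \code{c1}, \code{c2}, \code{residual_sd}, \code{n}.
#' @export
fit_flight_time <- function(segments, v) {
  if (nrow(segments) < 30L) stop("need at least 30 flight segments")
  d <- segments$distance_m
  if (max(d) / min(d) < 10) stop("segments must span a decade of distances")
  y <- log(segments$duration_s * v / d)
  fit <- tryCatch(
    stats::nls(y ~ 10 / (1 + c1 * d^c2),
               start = list(c1 = 0.3, c2 = 0.5),
               lower = c(c1 = 1e-4, c2 = 0.01),
               upper = c(c1 = 100, c2 = 2), algorithm = "port",
               control = stats::nls.control(maxiter = 200)),
    error = function(e)
      stop("fit_flight_time failed to converge: ", conditionMessage(e)))
  est <- stats::coef(fit)
  list(c1 = unname(est[["c1"]]), c2 = unname(est[["c2"]]),
       residual_sd = stats::sigma(fit), n = nrow(segments))
}

#' Hourly displacements from GPS fixes
#'
#' For every fix, the distance to the first subsequent fix about one hour
#' later (60 +/- 5 min), in hm; displacements below \code{x_min} (the
#' within-patch scale) are dropped. The output feeds
#' \code{\link{fit_crw}}.
#'
#' @param fixes GPS fix data.frame.
#' @param tol_min pairing tolerance around one hour (minutes).
#' @param x_min minimum displacement retained (hm).
#' @return numeric vector of displacements in hm.
#' @export
hourly_displacements <- function(fixes, tol_min = 5, x_min = 1) {
  out <- numeric(0)
  lo <- 3600 - tol_min * 60; hi <- 3600 + tol_min * 60
  for (a in unique(fixes$animal)) {
    fa <- fixes[fixes$animal == a, , drop = FALSE]
    fa <- fa[order(fa$time), , drop = FALSE]
    t <- as.numeric(fa$time)
    j <- findInterval(t + lo - 1e-9, t) + 1L
    ok <- j <= length(t)
    ok[ok] <- (t[j[ok]] - t[which(ok)]) <= hi
    i <- which(ok)
    if (length(i) == 0L) next
    d <- sqrt((fa$x[j[i]] - fa$x[i])^2 + (fa$y[j[i]] - fa$y[i])^2) / 100
    out <- c(out, d[d >= x_min])
  }
  out
}

#' Model flock size from observed flock sizes
#'
#' The fixed model flock size is the 20th percentile of observed flock
#' sizes (inverse-ECDF quantile, type 1), rounded to a granularity.
#'
#' @param sizes observed flock sizes (>= 20 observations).
#' @param q quantile level.
#' @param granularity rounding unit (geese).
#' @return flock size in geese.
#' @export
flock_size_model <- function(sizes, q = 0.20, granularity = 1) {
  if (length(sizes) < 20L) stop("need at least 20 observations")
  v <- unname(stats::quantile(sizes, probs = q, type = 1))
  max(granularity, round(v / granularity) * granularity)
}
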