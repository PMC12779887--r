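#' @title Movement: step lengths, flight duration, displacement, roosts
#'
#' @description
#' Random foraging moves follow a composite random walk: with probability
#' \code{P_BW} a flight length is drawn from an exponential (Brownian)
#' distribution, otherwise from a truncated-Levy (bounded Pareto)
#' distribution on \code{[x_min, x_max]} (lengths in hm = patch units).
#' Flight duration over a distance \code{d} patches is the straight-line
#' time inflated by a logarithmic sigmoid that accounts for circling before
#' landing. Scared flocks are displaced 2 km on a uniform random bearing.
#'
#' @name movement
NULL

#' Composite-random-walk step-length parameters
#'
#' @param p_bw probability of drawing from the exponential (Brownian)
#'   component.
#' @param lambda exponential rate (1/hm).
#' @param mu Levy (bounded-Pareto) exponent, > 1.
#' @param x_min,x_max support bounds in hm (patch units).
#' @return list of class \code{crw_params}.
#' @export
crw_params <- function(p_bw, lambda, mu, x_max, x_min = 1) {
  stopifnot(p_bw >= 0, p_bw <= 1, lambda > 0, x_min < x_max)
  if (mu <= 1) stop("mu must exceed 1 (degenerate Levy exponent)")
  structure(list(p_bw = p_bw, lambda = lambda, mu = mu,
                 x_min = x_min, x_max = x_max,
                 denom = 1 - (x_min / x_max)^(mu - 1)),
            class = "crw_params")
}

# bounded-Pareto CDF on [x_min, x_max]
.pareto_cdf <- function(x, p) {
  (1 - p$x_min^(p$mu - 1) * x^(1 - p$mu)) /
    (1 - (p$x_min / p$x_max)^(p$mu - 1))
}

#' Survival function of the composite random walk
#'
#' \code{form = "printed"} evaluates the mixture survival exactly as the
#' inverse cumulative frequency distribution is written:
#' \deqn{P_x = P_{BW} e^{-\lambda x} + (1-P_{BW})\left(1 -
#'   \frac{1 - x_{min}^{\mu-1} x^{1-\mu}}{1 - (x_{min}/x_{max})^{\mu-1}}\right)}
#' This form is slightly improper at \code{x_min} (the exponential term is
#' not conditioned on \code{x >= x_min}). \code{form = "sampling"} is the
#' exact survival of \code{\link{sample_step}}, whose exponential component
#' is shifted to start at \code{x_min}; use it as the Monte-Carlo oracle.
#'
#' @param x flight length (hm), \code{x >= x_min}.
#' @param p a \code{\link{crw_params}}.
#' @param form \code{"printed"} or \code{"sampling"}.
#' @return survival probability, monotone non-increasing in \code{x}.
#' @export
crw_survival <- function(x, p, form = c("printed", "sampling")) {
  form <- match.arg(form)
  if (any(x < p$x_min)) stop("x below x_min")
  pareto_surv <- 1 - .pareto_cdf(pmin(x, p$x_max), p)
  pareto_surv[x >= p$x_max] <- 0
  if (form == "printed")
    p$p_bw * exp(-p$lambda * x) + (1 - p$p_bw) * pareto_surv
  else
    p$p_bw * exp(-p$lambda * (x - p$x_min)) + (1 - p$p_bw) * pareto_surv
}

#' Sample flight lengths from the composite random walk
#'
#' With probability \code{p_bw} an exponential draw of rate \code{lambda}
#' shifted to start at \code{x_min}; otherwise an inverse-CDF bounded-Pareto
#' draw on \code{[x_min, x_max]}. All draws are \code{>= x_min}. Uses R's
#' global RNG stream; seed with \code{set.seed}.
#'
#' @param p a \code{\link{crw_params}}.
#' @param n number of draws.
#' @return numeric vector of lengths in hm.
#' @export
sample_step <- function(p, n = 1L) {
  brownian <- stats::runif(n) < p$p_bw
  out <- numeric(n)
  nb <- sum(brownian)
  if (nb > 0)
    out[brownian] <- p$x_min + stats::rexp(nb, rate = p$lambda)
  np <- n - nb
  if (np > 0) {
    u <- stats::runif(np)
    # invert the bounded-Pareto CDF
    denom <- 1 - (p$x_min / p$x_max)^(p$mu - 1)
    out[!brownian] <- (p$x_min^(p$mu - 1) / (1 - u * denom))^(1 / (p$mu - 1))
  }
  out
}

# mixture log-density of the sampler, used by fit_crw
.crw_loglik <- function(x, p_bw, lambda, mu, x_min, x_max) {
  f_exp <- lambda * exp(-lambda * (x - x_min))
  denom <- 1 - (x_min / x_max)^(mu - 1)
  f_par <- ifelse(x <= x_max,
                  (mu - 1) * x_min^(mu - 1) * x^(-mu) / denom, 0)
  sum(log(p_bw * f_exp + (1 - p_bw) * f_par))
}

#' Fit composite-random-walk parameters to observed step lengths
#'
#' Maximum likelihood on the mixture density of the composite walk
#' (exponential component shifted to \code{x_min}; bounded Pareto on
#' \code{[x_min, x_max]}). \code{x_max} is fixed at the sample maximum;
#' \code{(P_BW, lambda, mu)} are estimated by L-BFGS-B on transformed
#' coordinates (logit/log/log). A least-squares fit of the model survival
#' to the empirical survival on log scale is available as an alternative
#' criterion.
#'
#' @param samples observed hourly flight lengths (hm), all \code{>= x_min};
#'   at least 200 values.
#' @param x_min minimum flight distance (hm).
#' @param method \code{"mle"} (mixture likelihood) or \code{"ls_icfd"}
#'   (least squares on the log empirical survival).
#' @return a \code{\link{crw_params}} with attributes \code{objective}
#'   (achieved criterion value), \code{n} and \code{method}.
#' @export
fit_crw <- function(samples, x_min = 1, method = c("mle", "ls_icfd")) {
  method <- match.arg(method)
  if (length(samples) < 200) stop("need at least 200 samples")
  if (any(samples < x_min)) stop("samples below x_min")
  x_max <- max(samples) * (1 + 1e-9)
  obj <- function(th) {
    p_bw <- stats::plogis(th[1L]); lambda <- exp(th[2L]); mu <- 1 + exp(th[3L])
    if (method == "mle") {
      -.crw_loglik(samples, p_bw, lambda, mu, x_min, x_max)
    } else {
      q <- sort(samples)
      emp <- 1 - (seq_along(q) - 0.5) / length(q)
      p <- crw_params(p_bw, lambda, mu, x_max, x_min)
      mod <- crw_survival(q, p, form = "sampling")
      keep <- emp > 0 & mod > 1e-12
      sum((log(emp[keep]) - log(mod[keep]))^2)
    }
  }
  starts <- list(c(0, log(0.1), log(1)), c(1, log(0.05), log(0.5)),
                 c(-1, log(0.2), log(1.5)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("fit_crw failed to converge: all starts rejected; ",
         "n = ", length(samples), ", range = [",
         signif(min(samples), 3), ", ", signif(max(samples), 3), "]")
  th <- best$par
  out <- crw_params(p_bw = stats::plogis(th[1L]), lambda = exp(th[2L]),
                    mu = 1 + exp(th[3L]), x_max = x_max, x_min = x_min)
  attr(out, "objective") <- best$value
  attr(out, "n") <- length(samples)
  attr(out, "method") <- method
  out
}

#' Flight-time sigmoid coefficients
#'
#' @param c1,c2 species-specific dimensionless sigmoid coefficients.
#' @param v flight speed (m/s).
#' @param c3 unit-normalizing constant (1/m).
#' @param patch_length patch side (m).
#' @return list of class \code{flight_coeffs}.
#' @export
flight_coeffs <- function(c1, c2, v, c3 = 1, patch_length = 100) {
  stopifnot(c1 > 0, c2 > 0, v > 0)
  structure(list(c1 = c1, c2 = c2, c3 = c3, v = v,
                 patch_length = patch_length),
            class = "flight_coeffs")
}

#' Flight duration over a distance
#'
#' \deqn{T = e^S \cdot d L_{patch} / v,\qquad
#'       S = \frac{10}{1 + c_1 (d L_{patch} c_3)^{c_2}}}
#' Geese circle a patch before landing, so modelled duration always exceeds
#' the straight-line time \code{d*L/v} and converges to it as \code{d}
#' grows.
#'
#' @param d flight distance in patches, > 0.
#' @param f a \code{\link{flight_coeffs}}.
#' @return duration in seconds.
#' @export
flight_duration <- function(d, f) {
  if (any(d <= 0)) stop("flight distance must be positive")
  s <- 10 / (1 + f$c1 * (d * f$patch_length * f$c3)^f$c2)
  exp(s) * d * f$patch_length / f$v
}

# scalar/vector fast path of flight_duration, no argument checks
.flight_fast <- function(d, f) {
  dm <- d * f$patch_length
  exp(10 / (1 + f$c1 * (dm * f$c3)^f$c2)) * dm / f$v
}

#' Displace a scared flock about 2 km on a random bearing
#'
#' Draws a uniform bearing and returns the grid cell nearest the point
#' 20 patches (2 km) away; bearings taking the flock off-grid are re-drawn
#' (up to 100 times).
#'
#' @param land a \code{goose_landscape}.
#' @param origin cell (\code{c(col, row)} 0-based or linear id).
#' @param distance displacement distance in patches.
#' @return linear cell id of the landing cell.
#' @export
scare_displacement <- function(land, origin, distance = 20) {
  o <- as_cell(land, origin)
  for (i in seq_len(100L)) {
    theta <- stats::runif(1L, 0, 2 * pi)
    col <- as.integer(round(o[1L] + distance * cos(theta)))
    row <- as.integer(round(o[2L] + distance * sin(theta)))
    if (col >= 0L && col < land$width && row >= 0L &&
        row < land$height_patches)
      return(cell_id(land, col, row))
  }
  stop("scare_displacement: no on-grid cell reachable from origin")
}

#' Choose a roost cell
#'
#' The previous roost is reused when it lies within 100 patches (10 km) of
#' the current position; otherwise a roost is sampled with probability
#' proportional to \code{1/(distance + 1)}.
#'
#' @param land a \code{goose_landscape}.
#' @param current current cell.
#' @param prev_roost previous roost cell id, or \code{NULL}.
#' @param roosts integer vector of roost cell ids (defaults to the
#'   landscape's roost index).
#' @return linear cell id of the chosen roost.
#' @export
choose_roost <- function(land, current, prev_roost = NULL,
                         roosts = land$roost_index) {
  if (length(roosts) == 0L) stop("no roost cells configured in landscape")
  cur <- as_cell(land, current)
  if (!is.null(prev_roost)) {
    pr <- as_cell(land, prev_roost)
    if (sqrt(sum((cur - pr)^2)) <= 100) return(as.integer(prev_roost))
  }
  cr <- cell_colrow(land, roosts)
  d <- sqrt((cr[, "col"] - cur[1L])^2 + (cr[, "row"] - cur[2L])^2)
  w <- 1 / (d + 1)
  roosts[sample.int(length(roosts), 1L, prob = w)]
}
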