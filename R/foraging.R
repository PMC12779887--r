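#' @title Foraging energetics: intake, energy budget, mass, grazing
#'
#' @description
#' Per-goose intake on a sward of height \code{h} follows a bite-based
#' functional response: bite mass grows with sward height but is discounted
#' in tall swards (accessibility/bite-quality factor) and capped by a
#' digestive-feasible maximum; bite time is the larger of the minimal
#' cropping time and the chewing time, plus a height-dependent handling
#' term. The instantaneous rate is bite mass over bite time, never above
#' the species' maximal instantaneous rate \code{i_max}. Hourly energy
#' budgets combine metabolizable intake with activity-specific expenditure
#' (foraging, flight, resting); body mass follows the energy balance and a
#' flock dies when per-goose mass falls below the species minimum.
#'
#' @name foraging
NULL

#' Instantaneous dry-matter intake rate
#'
#' Default functional response, per goose:
#' \deqn{m(h) = \min(b_1 h\, e^{-h/h_{access}},\; b_2 h_{cap})}
#' \deqn{\tau(h) = \max(t_{crop},\; m(h)/r_{chew}) + c\,h}
#' \deqn{rate(h) = \min(i_{max},\; m(h)/\tau(h))}
#' with \code{h} in metres, \code{m} the bite mass (g dry matter),
#' \code{tau} the time per bite (s). The exponential factor represents
#' reduced bite quality and accessibility in tall dense swards and makes
#' the response unimodal for small-billed species; \code{h_cap} (default
#' 0.01 m) scales the provisional digestive cap \code{b2}. The functional
#' form sits behind this single function so an alternative response is a
#' one-line swap.
#'
#' @param h sward height (m), scalar or vector, >= 0.
#' @param sp a \code{goose_species}.
#' @param h_cap cap reference height (m).
#' @return intake rate in g dry matter per second per goose; 0 at
#'   \code{h = 0} and never above \code{sp$i_max}.
#' @export
intake_rate <- function(h, sp, h_cap = NULL) {
  if (any(h < 0)) stop("negative sward height")
  cap <- if (is.null(h_cap)) (sp$b2cap %||% (sp$b2 * 0.01)) else sp$b2 * h_cap
  m <- pmin(sp$b1 * h * exp(-h / sp$h_access), cap)
  tau <- pmax(sp$t_crop, m / sp$r_chew) + sp$c_handling * h
  pmin(sp$i_max, ifelse(tau > 0, m / tau, 0))
}

# scalar fast path of the same formula, for the simulation hot loop
.intake_fast <- function(h, sp) {
  m <- sp$b1 * h * exp(-h / sp$h_access)
  if (m > sp$b2cap) m <- sp$b2cap
  ch <- m / sp$r_chew
  tau <- (if (ch > sp$t_crop) ch else sp$t_crop) + sp$c_handling * h
  if (tau <= 0) return(0)
  r <- m / tau
  if (r > sp$i_max) sp$i_max else r
}

#' Sward height maximizing intake rate
#'
#' Grid argmax of \code{\link{intake_rate}} over [0, 0.5] m at 1-mm
#' resolution. Because intake curves can plateau at \code{i_max}, the
#' convention is the \emph{smallest} height attaining the maximum: the
#' shortest sward delivering full intake. Under default parameters the
#' barnacle optimum is below the greylag optimum, the ordering behind
#' sward-height facilitation between species.
#'
#' @param sp a \code{goose_species}.
#' @param h_grid candidate heights (m).
#' @return optimal height (m).
#' @export
optimal_height <- function(sp, h_grid = seq(0, 0.5, by = 0.001)) {
  r <- intake_rate(h_grid, sp)
  h_grid[which.max(r)]
}

#' Hourly energy balance
#'
#' \deqn{\Delta E = g\, e_{grass}\, q_{assim} -
#'   (FMR\, t_{forage} + flightMR\, t_{fly} + RMR\, t_{rest})}
#' with \code{g} grams of dry matter eaten per goose and the three activity
#' durations summing to 3600 s.
#'
#' @param t_forage,t_fly,t_rest seconds of foraging, flying and resting in
#'   the hour; must be non-negative and sum to 3600.
#' @param grams_eaten dry matter eaten per goose (g).
#' @param sp a \code{goose_species}.
#' @param energetics list with \code{e_grass} (J/g), \code{q_assim},
#'   \code{e_tissue} (J/g).
#' @return net energy change per goose (J).
#' @export
hourly_budget <- function(t_forage, t_fly, t_rest, grams_eaten, sp,
                          energetics = .default_energetics()) {
  if (grams_eaten < 0) stop("negative intake")
  if (any(c(t_forage, t_fly, t_rest) < 0))
    stop("negative activity duration")
  if (abs(t_forage + t_fly + t_rest - 3600) > 1e-6 &&
      (t_forage + t_fly + t_rest) != 0)
    stop("activity durations must sum to 3600 s")
  grams_eaten * energetics$e_grass * energetics$q_assim -
    (sp$fmr * t_forage + sp$flight_mr * t_fly + sp$rmr * t_rest)
}

#' Update flock body mass from an energy balance
#'
#' Per-goose mass changes by \code{dE / e_tissue}, is capped at the day's
#' maximum weight, and the flock dies when mass falls below the species
#' minimum weight.
#'
#' @param mass current per-goose mass (g).
#' @param dE net energy change per goose (J).
#' @param sp a \code{goose_species}.
#' @param max_w maximum attainable weight today (g); \code{Inf} to disable
#'   the cap.
#' @param energetics energetic constants (see \code{\link{hourly_budget}}).
#' @return list with \code{mass} (g) and \code{alive} (logical).
#' @export
update_weight <- function(mass, dE, sp, max_w = Inf,
                          energetics = .default_energetics()) {
  if (!is.finite(dE)) stop("non-finite energy change")
  m <- min(mass + dE / energetics$e_tissue, max_w)
  list(mass = m, alive = m >= sp$min_weight)
}

#' Graze a patch
#'
#' A flock foraging \code{t_forage} seconds removes
#' \code{intake_rate(h) * t_forage * n_geese} grams of dry matter (start-of-
#' hour height), bounded by the standing crop so grass mass is conserved;
#' 150 000 g corresponds to 1 cm height over the 1-ha patch. The patch's
#' goose-attributed height loss and flock-hour ledgers are updated.
#'
#' @param land a \code{goose_landscape} (modified copy returned).
#' @param cell linear cell id of a grassland patch.
#' @param sp a \code{goose_species}.
#' @param n_geese geese in the flock.
#' @param t_forage foraging seconds, <= 3600.
#' @param dm_per_cm_ha grams of dry matter per cm height per ha (150 000).
#' @return list with the updated landscape and \code{grams_total} actually
#'   eaten by the flock.
#' @export
graze <- function(land, cell, sp, n_geese, t_forage,
                  dm_per_cm_ha = 150000) {
  if (!(land$type[cell] %in% GRASS_CODES))
    stop("graze called on a non-grassland patch")
  if (t_forage > 3600) stop("t_forage exceeds one hour")
  h <- land$height[cell]
  demand <- intake_rate(h, sp) * t_forage * n_geese
  standing <- h * 100 * dm_per_cm_ha          # g available above 0
  grams <- min(demand, standing)
  dh_cm <- grams / dm_per_cm_ha
  land$height[cell] <- max(0, h - dh_cm / 100)
  land$grazed_cm[cell] <- land$grazed_cm[cell] + dh_cm
  land$flock_hours[[sp$name]][cell] <-
    land$flock_hours[[sp$name]][cell] + n_geese * t_forage / 3600
  list(land = land, grams_total = grams)
}
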