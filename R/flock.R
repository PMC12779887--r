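#' @title Flock agents: memory, joining, acceptance, scaring, decision tree
#'
#' @description
#' The model's agents are single-species flocks of fixed size (1000
#' barnacle, 100 greylag, 200 pink-footed, 400 white-fronted geese). A
#' flock carries a per-goose body mass, a FIFO memory of up to 100
#' (location, grass height) entries, and its previous roost. Each hour a
#' flock follows a decision tree: in daylight it roosts once the day's
#' maximum weight is reached and otherwise forages, picking a patch from
#' memory (by age-discounted expected net energy gain) or by a composite
#' random walk, possibly joining conspecifics en route, accepting the patch
#' according to its sward height, and being displaced ~2 km when scaring
#' occurs. At night, under-weight flocks may forage if at least eight
#' hours of rest remain before sunrise and moonlight suffices; otherwise
#' they roost, returning to the previous roost when it is within 10 km.
#'
#' Flock objects are environments and are modified in place (and returned
#' invisibly-compatible for chaining).
#'
#' @name flock
NULL

#' Create a flock
#'
#' @param sp a \code{goose_species}.
#' @param cell starting linear cell id.
#' @param land the \code{goose_landscape} (for coordinates).
#' @param mass initial per-goose mass (g); default the species initial
#'   weight.
#' @param id integer flock identifier.
#' @return an environment of class \code{goose_flock}.
#' @export
new_flock <- function(sp, cell, land, mass = sp$initial_weight, id = 1L) {
  f <- new.env(parent = emptyenv())
  f$id <- id
  f$sp <- sp
  f$species <- sp$name
  f$spi <- match(sp$name, SPECIES_CODES)
  f$n_geese <- sp$flock_size
  f$cell <- as.integer(cell)
  cr <- cell_colrow(land, f$cell)
  f$col <- cr[1L, 1L]; f$row <- cr[1L, 2L]
  f$mass <- mass
  f$mem_cell <- integer(0)
  f$mem_col <- integer(0)
  f$mem_row <- integer(0)
  f$mem_h <- numeric(0)
  f$mem_t <- numeric(0)   # insertion time (h); age = now - mem_t
  f$prev_roost <- if (land$type[f$cell] == -1L) f$cell else NULL
  f$alive <- TRUE
  f$state <- "roosting"
  class(f) <- "goose_flock"
  f
}

#' @export
print.goose_flock <- function(x, ...) {
  cat(sprintf("<goose_flock #%d> %s x%d, %.0f g, cell %d, %s, memory %d\n",
              x$id, x$species, x$n_geese, x$mass, x$cell, x$state,
              length(x$mem_cell)))
  invisible(x)
}

#' Insert or refresh a memory entry
#'
#' Appends a (cell, height) entry with age zero; when the flock already
#' remembers the cell the entry is updated in place (height refreshed, age
#' reset) rather than duplicated. When the memory is full (100 entries) the
#' oldest entry is evicted.
#'
#' @param flock a \code{goose_flock} (modified in place).
#' @param cell linear cell id.
#' @param height grass height to remember (m).
#' @param time current time (h) used as the entry timestamp.
#' @param land the landscape (for coordinates).
#' @param memory_size FIFO capacity.
#' @return the flock, invisibly.
#' @export
remember <- function(flock, cell, height, time = 0, land = NULL,
                     memory_size = 100L) {
  j <- match(cell, flock$mem_cell)
  if (!is.na(j)) {
    flock$mem_h[j] <- height
    flock$mem_t[j] <- time
    return(invisible(flock))
  }
  if (length(flock$mem_cell) >= memory_size) {
    old <- which.min(flock$mem_t)
    flock$mem_cell <- flock$mem_cell[-old]
    flock$mem_col <- flock$mem_col[-old]
    flock$mem_row <- flock$mem_row[-old]
    flock$mem_h <- flock$mem_h[-old]
    flock$mem_t <- flock$mem_t[-old]
  }
  if (is.null(land)) {
    col <- NA_integer_; row <- NA_integer_
  } else {
    cr <- cell_colrow(land, cell)
    col <- cr[1L, 1L]; row <- cr[1L, 2L]
  }
  flock$mem_cell <- c(flock$mem_cell, as.integer(cell))
  flock$mem_col <- c(flock$mem_col, col)
  flock$mem_row <- c(flock$mem_row, row)
  flock$mem_h <- c(flock$mem_h, height)
  flock$mem_t <- c(flock$mem_t, time)
  invisible(flock)
}

# memory scores: age-discounted expected one-hour net gain (J per goose)
.memory_scores <- function(flock, time, behaviour, energetics) {
  sp <- flock$sp
  age <- pmax(0, time - flock$mem_t)
  gain <- intake_rate(flock$mem_h, sp) * 3600 *
    energetics$e_grass * energetics$q_assim
  d <- sqrt((flock$mem_col - flock$col)^2 + (flock$mem_row - flock$row)^2)
  cost <- numeric(length(d))
  nz <- d > 0
  if (any(nz)) cost[nz] <- sp$flight_mr * .flight_fast(d[nz], sp$flight)
  exp(-behaviour$lambda_memory * age) * (gain - cost)
}

# fast memory selection for the hot loop; gain_factor = 3600*e_grass*q_assim
.select_mem <- function(f, time, beh, gain_factor) {
  m <- length(f$mem_cell)
  if (m == 0L) return(NULL)
  sp <- f$sp
  h <- f$mem_h
  bm <- sp$b1 * h * exp(-h / sp$h_access)
  bm[bm > sp$b2cap] <- sp$b2cap
  tau <- pmax(sp$t_crop, bm / sp$r_chew) + sp$c_handling * h
  r <- pmin(sp$i_max, bm / tau)
  dc <- f$mem_col - f$col; dr <- f$mem_row - f$row
  d <- sqrt(dc * dc + dr * dr)
  cost <- numeric(m)
  nz <- d > 0
  if (any(nz)) cost[nz] <- sp$flight_mr * .flight_fast(d[nz], sp$flight)
  sc <- exp(-beh$lambda_memory * (time - f$mem_t)) *
    (r * gain_factor - cost)
  b <- which.max(sc)
  if (sc[b] <= 0) return(NULL)
  if (stats::runif(1L) < beh$p_max_memory * r[b] / sp$rate_opt)
    f$mem_cell[b]
  else NULL
}

#' Select a foraging patch from memory
#'
#' Scores each remembered patch as
#' \code{exp(-lambda_mem * age) * (expected one-hour intake energy at the
#' remembered height - flight energy to reach it)} and proposes the best
#' one. The proposal is used with probability \code{P_maxM} scaled by the
#' quality of the best memory (its intake rate relative to the species
#' optimum); otherwise, or when no score is positive, \code{NULL} is
#' returned and the caller falls back to random search.
#'
#' @param flock a \code{goose_flock}.
#' @param time current time (h).
#' @param behaviour behaviour constants (see \code{load_config}).
#' @param energetics energetic constants.
#' @return linear cell id or \code{NULL}.
#' @export
select_memory_patch <- function(flock, time = 0,
                                behaviour = .default_behaviour(),
                                energetics = .default_energetics()) {
  if (length(flock$mem_cell) == 0L) return(NULL)
  sc <- .memory_scores(flock, time, behaviour, energetics)
  best <- which.max(sc)
  if (sc[best] <= 0) return(NULL)
  quality <- intake_rate(flock$mem_h[best], flock$sp) / flock$sp$rate_opt
  if (stats::runif(1L) < behaviour$p_max_memory * quality)
    flock$mem_cell[best]
  else NULL
}

#' Probability of joining conspecifics already on a patch
#'
#' Logistic in the log10 number of geese present:
#' \code{plogis(a1 + beta_join * log10(n + 1))}.
#'
#' @param n geese already present.
#' @param sp a \code{goose_species}.
#' @param beta_join slope on \code{log10(n+1)}.
#' @return probability.
#' @export
join_probability <- function(n, sp, beta_join = 2.0) {
  stats::plogis(sp$a1 + beta_join * log10(n + 1))
}

#' Possibly join a conspecific flock near the destination
#'
#' Scans foraging flocks of the same species within \code{join_radius}
#' patches of the destination; the largest such aggregation is joined with
#' probability \code{\link{join_probability}}.
#'
#' @param flock the moving \code{goose_flock}.
#' @param dest intended destination cell id.
#' @param flocks list of all flocks (the candidates are the other foraging
#'   conspecifics).
#' @param land the landscape.
#' @param behaviour behaviour constants.
#' @return destination cell id (possibly changed to the joined patch).
#' @export
maybe_join <- function(flock, dest, flocks, land,
                       behaviour = .default_behaviour()) {
  dcr <- cell_colrow(land, dest)
  best_n <- 0L; best_cell <- NA_integer_
  for (g in flocks) {
    if (!g$alive || g$state != "foraging" || g$species != flock$species ||
        identical(g$id, flock$id)) next
    if (sqrt((g$col - dcr[1L, 1L])^2 + (g$row - dcr[1L, 2L])^2) >
        behaviour$join_radius) next
    if (g$n_geese > best_n) { best_n <- g$n_geese; best_cell <- g$cell }
  }
  if (best_n > 0L &&
      stats::runif(1L) < join_probability(best_n, flock$sp,
                                          behaviour$beta_join))
    best_cell
  else dest
}

#' Accept or reject a foraging patch by sward height
#'
#' Acceptance probability is \code{P_maxF} scaled by the intake rate at the
#' patch relative to the species' optimal-sward rate; the optimal sward is
#' accepted with probability exactly \code{P_maxF}, a bare patch never.
#'
#' @param h sward height (m).
#' @param sp a \code{goose_species}.
#' @param p_max_forage maximum acceptance probability.
#' @return logical.
#' @export
accept_patch <- function(h, sp, p_max_forage = 0.9) {
  if (h < 0) stop("negative sward height")
  stats::runif(1L) < p_max_forage * intake_rate(h, sp) / sp$rate_opt
}

#' Hourly disturbance draw
#'
#' Bernoulli with a per-patch-type hourly probability; scaring areas carry
#' the highest probability by configuration contract.
#'
#' @param patch_type patch type code (1 scaring, 2 accommodation,
#'   3 nature).
#' @param probs named per-type probabilities.
#' @return logical.
#' @export
disturbance <- function(patch_type,
                        probs = .default_behaviour()$disturbance) {
  key <- c(`1` = "scaring", `2` = "accommodation", `3` = "nature")[
    as.character(patch_type)]
  if (is.na(key)) stop("disturbance is defined on grassland types 1-3")
  stats::runif(1L) < probs[[key]]
}

#' Scare a flock off its patch
#'
#' Sets the remembered grass height of the origin patch to zero (making a
#' return unlikely), displaces the flock ~2 km on a random bearing, and
#' charges the corresponding flight time.
#'
#' @param flock a \code{goose_flock} (modified in place).
#' @param land the landscape.
#' @param time current time (h).
#' @return list with the landing \code{cell} and the \code{t_fly} seconds
#'   charged for the displacement.
#' @export
handle_scaring <- function(flock, land, time = 0) {
  remember(flock, flock$cell, 0, time = time, land = land)
  j <- match(flock$cell, flock$mem_cell)
  flock$mem_h[j] <- 0
  landing <- scare_displacement(land, flock$cell)
  d <- cell_distance(land, flock$cell, landing)
  cr <- cell_colrow(land, landing)
  flock$cell <- landing; flock$col <- cr[1L, 1L]; flock$row <- cr[1L, 2L]
  list(cell = landing, t_fly = flight_duration(max(d, 1), flock$sp$flight))
}
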