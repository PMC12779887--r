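#' @title Species parameter registry
#'
#' @description
#' All species-level parameters for the four study species: barnacle goose
#' (BAG, \emph{Branta leucopsis}), greylag goose (GLG, \emph{Anser anser}),
#' pink-footed goose (PFG, \emph{Anser brachyrhynchus}) and greater
#' white-fronted goose (WFG, \emph{Anser albifrons}). The registry covers
#' metabolic rates, the functional-response coefficients, body-weight
#' bounds, flock sizes, population maxima, flight-time coefficients, the
#' composite-random-walk step-length parameters, and the behavioural
#' coefficients (joining, memory, patch acceptance).
#'
#' @name species
NULL

#' Species codes
#' @export
SPECIES_CODES <- c("BAG", "GLG", "PFG", "WFG")

# Core species-by-parameter table. One column per species, in
# SPECIES_CODES order. b2 is provisional: the source table typography is
# ambiguous (see bundled config notes); under the default functional
# response the b2 cap rarely binds.
.species_table <- function() {
  list(
    flight_speed   = c(19.0, 19.2, 18.8, 15.0),    # m/s
    fmr            = c(9.84, 17.14, 16.51, 13.97), # J/s foraging
    b1             = c(0.33, 0.25, 0.23, 0.25),    # g/m bite-mass slope
    b2             = c(7, 6, 102, 129),            # g/m bite-mass cap coeff (provisional)
    c_handling     = c(1.0, 0.0, 0.5, 0.5),        # s/m per-bite handling vs height
    t_crop         = c(0.48, 0.80, 0.59, 0.59),    # s minimal cropping time
    r_chew         = c(0.02, 0.08, 0.04, 0.03),    # g/s maximal chewing rate
    i_max          = c(0.005, 0.02, 0.009, 0.008), # g/s max instantaneous intake
    rmr            = c(7.25, 12.63, 12.17, 10.29), # J/s resting
    flight_mr      = c(60.80, 123.70, 97.70, 76.10), # J/s flying
    initial_weight = c(1771, 3401, 2170, 2127),    # g
    min_weight     = c(1080, 2040, 1600, 1400),    # g
    max_additional = c(600, 900, 600, 400),        # g above daily mean
    max_population = c(500000, 70000, 15000, 300000), # geese
    flock_size     = c(1000, 100, 200, 400),       # geese per flock
    n_sites        = c(61, 65, 9, 59),             # initial spatial distribution
    a1             = c(-2.17, -2.19, -1.41, -2.17),# joining intercept (logit)
    c1             = c(0.20, 0.25, 0.18, 0.57),    # flight-time sigmoid
    c2             = c(0.52, 0.52, 0.48, 0.44),    # flight-time sigmoid
    crw_lambda     = c(0.08, 0.116, 0.052, 0.05),  # 1/hm exponential rate
    crw_mu         = c(1.74, 2.08, 2.25, 1.64),    # Levy exponent
    crw_xmax       = c(200, 84, 200, 200),         # hm
    crw_pbw        = c(0.32, 0.46, 0.40, 0.18),    # P(Brownian component)
    # sward-accessibility scale of the default functional response (m);
    # not a literature value - see the methods vignette.
    h_access       = c(0.03, 0.25, 0.10, 0.10)
  )
}

# Behavioural constants shared across species, inherited from the
# single-species predecessor's role; all overridable through the config.
.default_behaviour <- function() {
  list(
    p_max_memory = 0.9,        # max probability to forage on memory
    p_max_forage = 0.9,        # max patch-acceptance probability
    lambda_memory = 0.2,       # 1/h memory decay
    memory_size = 100L,
    beta_join = 2.0,           # joining slope on log10(n+1)
    join_radius = 10,          # patches scanned for conspecifics
    disturbance = c(scaring = 0.3, accommodation = 0.02, nature = 0.02),
    moonlight_threshold = 0.5, # illuminated fraction
    night_rest_hours = 8,
    max_relocations = 3L       # patch rejections before settling
  )
}

# Energetic conversion constants (configurable; standard waterfowl values).
.default_energetics <- function() {
  list(
    e_grass = 17800,  # J per g grass dry matter
    q_assim = 0.35,   # assimilation efficiency
    e_tissue = 34300  # J per g body reserve
  )
}

.default_economics <- function() {
  list(
    price_per_kg = 0.25,        # EUR per kg dry grass
    dm_per_cm_ha = 150,         # kg dry matter in 1 cm over 1 ha
    cost_per_scare = 10,        # EUR per scaring event
    cost_per_appraised_patch = 0 # EUR per affected agricultural patch
  )
}

#' Construct the parameter set of one species
#'
#' @param code one of \code{"BAG"}, \code{"GLG"}, \code{"PFG"}, \code{"WFG"}.
#' @param overrides named list of parameter overrides.
#' @return an object of class \code{goose_species}: a named list of all
#'   parameters plus derived quantities (\code{crw} parameter list,
#'   \code{flight} coefficient list, cached \code{h_opt} and
#'   \code{rate_opt}).
#' @export
goose_species <- function(code, overrides = list()) {
  code <- match.arg(code, SPECIES_CODES)
  i <- match(code, SPECIES_CODES)
  tab <- .species_table()
  sp <- lapply(tab, `[`, i)
  sp$name <- code
  for (nm in names(overrides)) sp[[nm]] <- overrides[[nm]]
  sp$crw <- crw_params(p_bw = sp$crw_pbw, lambda = sp$crw_lambda,
                       mu = sp$crw_mu, x_max = sp$crw_xmax)
  sp$flight <- flight_coeffs(c1 = sp$c1, c2 = sp$c2, v = sp$flight_speed)
  sp$h_cap <- sp$h_cap %||% 0.01          # cap reference height (m)
  sp$b2cap <- sp$b2 * sp$h_cap            # digestive bite-mass cap (g)
  class(sp) <- "goose_species"
  sp$h_opt <- optimal_height(sp)
  sp$rate_opt <- intake_rate(sp$h_opt, sp)
  sp
}

#' @export
print.goose_species <- function(x, ...) {
  cat(sprintf("<goose_species> %s: flock %d geese, %.0f g initial, i_max %.3f g/s, h* = %.3f m\n",
              x$name, x$flock_size, x$initial_weight, x$i_max, x$h_opt))
  invisible(x)
}

#' Default parameter sets for all four species
#'
#' @param overrides optional named list (by species code) of override lists.
#' @return named list of \code{goose_species}.
#' @export
default_species <- function(overrides = list()) {
  out <- lapply(SPECIES_CODES, function(code)
    goose_species(code, overrides = if (code %in% names(overrides))
      overrides[[code]] else list()))
  names(out) <- SPECIES_CODES
  out
}

#' Load a configuration file
#'
#' Reads a YAML configuration holding species-parameter overrides,
#' behaviour, energetics and economics constants, landscape/weather sources
#' and population scalars; missing entries fall back to package defaults.
#' The bundled default config (\code{system.file("extdata",
#' "default_config.yaml", package = "goosesim")}) reproduces the full
#' species table verbatim.
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return a validated config list (class \code{goosesim_config}).
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  behaviour <- merge_into(.default_behaviour(), cfg$behaviour %||% list())
  # disturbance may arrive as a named list from YAML
  if (is.list(behaviour$disturbance))
    behaviour$disturbance <- unlist(behaviour$disturbance)
  stopifnot(behaviour$disturbance[["scaring"]] >
              behaviour$disturbance[["accommodation"]],
            behaviour$disturbance[["accommodation"]] >=
              behaviour$disturbance[["nature"]])
  out <- list(
    species = default_species(cfg$species %||% list()),
    behaviour = behaviour,
    energetics = merge_into(.default_energetics(), cfg$energetics %||% list()),
    economics = merge_into(.default_economics(), cfg$economics %||% list()),
    grass = do.call(grass_growth_params, cfg$grass %||% list()),
    latitude = cfg$latitude %||% 53.2,
    population_scalars = {
      ps <- c(BAG = 1, GLG = 1, PFG = 1, WFG = 1)
      if (!is.null(cfg$population_scalars))
        ps[names(cfg$population_scalars)] <- unlist(cfg$population_scalars)
      ps
    },
    start_doy = cfg$start_doy %||% 305L,  # Nov 1
    n_days = cfg$n_days %||% 195L         # through May 15
  )
  class(out) <- "goosesim_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
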