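#' @title Population sweeps and relative-importance analysis
#'
#' @description
#' Factorial experiments over the four species' population sizes (the full
#' design is 11 evenly spaced levels between 0 and 200% of the wintering
#' maxima per species, 11^4 = 14641 combinations; desk-scale sweeps use
#' fewer levels on a smaller landscape with proportionally scaled
#' populations), response summarization per run, and the
#' normalized-coefficient linear-model importance analysis.
#'
#' @name experiments
NULL

#' Build a full-factorial population design
#'
#' Cartesian product of the level fractions per species, in deterministic
#' lexicographic order (first species varies fastest).
#'
#' @param levels numeric vector of population fractions (of each species'
#'   maximum), or a named list per species.
#' @param species species codes.
#' @return data.frame with one fraction column per species
#'   (\code{frac_BAG}, ...).
#' @export
build_design <- function(levels = seq(0, 2, length.out = 11),
                         species = SPECIES_CODES) {
  if (!is.list(levels))
    levels <- stats::setNames(rep(list(levels), length(species)), species)
  if (any(lengths(levels) < 1L)) stop("need at least one level per species")
  g <- do.call(expand.grid, c(levels[species], KEEP.OUT.ATTRS = FALSE))
  names(g) <- paste0("frac_", species)
  g
}

#' Normalized-coefficient importance of population sizes
#'
#' Ordinary least squares of a response on the four species' population
#' sizes; coefficients are normalized by the maximum absolute coefficient
#' so the most important predictor has magnitude 1 and all others lie in
#' [-1, 1]. The reported R-squared is the adjusted R-squared.
#'
#' @param table data.frame holding the response and predictor columns.
#' @param response response column name.
#' @param predictors predictor column names (default the four
#'   \code{N_<species>} columns).
#' @return list of class \code{importance_result}: \code{coefficients}
#'   (raw), \code{normalized}, \code{intercept}, \code{r_squared}
#'   (adjusted), \code{n}.
#' @export
fit_importance <- function(table, response = "y",
                           predictors = paste0("N_", SPECIES_CODES)) {
  if (nrow(table) < length(predictors) + 2L)
    stop("need at least ", length(predictors) + 2L, " rows")
  keep <- stats::complete.cases(table[, c(response, predictors)])
  dat <- table[keep, , drop = FALSE]
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta))
    stop("rank-deficient design: predictors ",
         paste(names(beta)[is.na(beta)], collapse = ", "),
         " are not estimable")
  slopes <- beta[predictors]
  m <- max(abs(slopes))
  normalized <- if (m > 0) slopes / m else slopes
  structure(list(coefficients = slopes, normalized = normalized,
                 intercept = unname(beta[["(Intercept)"]]),
                 r_squared = summary(fit)$adj.r.squared,
                 n = nrow(dat), response = response),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("<importance_result> %s ~ %s (n = %d, adj R2 = %.3f)\n",
              x$response, paste(names(x$coefficients), collapse = " + "),
              x$n, x$r_squared))
  print(round(x$normalized, 2))
  invisible(x)
}

#' Summarize one simulation run into response rows
#'
#' @param result a \code{goosesim_result}.
#' @return one-row data.frame with, per species, the fraction of foraging
#'   on agricultural grassland (\code{frac_agri_*}), the fraction in the
#'   scaring area (\code{frac_scaring_*}), goose pressure per goose on
#'   agricultural grassland (\code{ppg_*}) and on all grassland
#'   (\code{tppg_*}); plus \code{yield_loss}, \code{n_scares},
#'   \code{pct_scaring_affected} and \code{deaths}. Species with zero mean
#'   population yield \code{NA} responses.
#' @export
summarize_run <- function(result) {
  row <- list()
  for (code in SPECIES_CODES) {
    tot <- sum(result$pressure[, code])
    agri <- sum(result$pressure[c("scaring", "accommodation"), code])
    present <- mean(result$daily_pop[, code]) > 0 && tot > 0
    row[[paste0("frac_agri_", code)]] <-
      if (present) agri / tot else NA_real_
    row[[paste0("frac_scaring_", code)]] <-
      if (present) result$pressure["scaring", code] / tot else NA_real_
    row[[paste0("ppg_", code)]] <-
      pressure_per_goose(result, code, "agricultural")
    row[[paste0("tppg_", code)]] <-
      pressure_per_goose(result, code, "all-grassland")
  }
  scaring_cells <- result$type == 1L
  row$yield_loss <- yield_loss(result)
  row$n_scares <- sum(result$scares)
  row$pct_scaring_affected <-
    100 * sum(rowSums(result$fh)[scaring_cells] > 0) / sum(scaring_cells)
  row$deaths <- sum(result$deaths)
  as.data.frame(row)
}

#' Summarize a set of simulation runs
#'
#' @param results list of \code{goosesim_result}.
#' @return data.frame with one \code{\link{summarize_run}} row per run.
#' @export
summarize_responses <- function(results) {
  out <- do.call(rbind, lapply(results, summarize_run))
  rownames(out) <- NULL
  out
}

#' Run a population sweep
#'
#' Runs the simulator once per (design row, seed) with the design's
#' population fractions applied on top of the config's population
#' scalars, and returns the stacked response table.
#'
#' @param design data.frame from \code{\link{build_design}}.
#' @param land a \code{goose_landscape}.
#' @param config a \code{goosesim_config}; its \code{population_scalars}
#'   act as the overall scale (e.g. 0.01 for a 1/100-scale desk sweep).
#' @param seeds integer vector of replicate seeds.
#' @param n_days season length per run.
#' @param ... further arguments to \code{\link{run_simulation}}.
#' @return data.frame: design columns, \code{seed}, population sizes
#'   \code{N_<species>} (mean daily geese), and the
#'   \code{\link{summarize_run}} responses; one row per run.
#' @export
sweep_populations <- function(design, land, config, seeds = 1L,
                              n_days = config$n_days, ...) {
  out <- vector("list", nrow(design) * length(seeds))
  k <- 0L
  for (i in seq_len(nrow(design))) {
    for (s in seeds) {
      cfg <- config
      cfg$population_scalars <- config$population_scalars *
        unlist(design[i, paste0("frac_", SPECIES_CODES)])
      names(cfg$population_scalars) <- SPECIES_CODES
      res <- run_simulation(land, cfg, seed = s, n_days = n_days, ...)
      k <- k + 1L
      row <- cbind(design[i, , drop = FALSE], seed = s,
                   as.data.frame(as.list(stats::setNames(
                     colMeans(res$daily_pop), paste0("N_", SPECIES_CODES)))),
                   summarize_run(res))
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
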