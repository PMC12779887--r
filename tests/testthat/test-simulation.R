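small_cfg <- function(scalar = 0.002) {
  cfg <- load_config()
  cfg$population_scalars[] <- scalar
  cfg
}

test_that("a gooseless run produces no pressure, damage or events", {
  land <- gen_landscape(30, 30, seed = 5)
  res <- run_simulation(land, small_cfg(0), seed = 1, n_days = 10)
  expect_equal(sum(res$pressure), 0)
  expect_equal(sum(res$scares), 0)
  expect_equal(yield_loss(res), 0)
  expect_equal(res$n_steps, 240)
})

test_that("runs are deterministic given the seed", {
  land <- gen_landscape(30, 30, seed = 5)
  r1 <- run_simulation(land, small_cfg(0.005), seed = 42, n_days = 8)
  r2 <- run_simulation(land, small_cfg(0.005), seed = 42, n_days = 8)
  expect_identical(r1$pressure, r2$pressure)
  expect_identical(r1$height_final, r2$height_final)
  expect_identical(r1$scares, r2$scares)
  r3 <- run_simulation(land, small_cfg(0.005), seed = 43, n_days = 8)
  expect_false(identical(r1$height_final, r3$height_final))
})

test_that("season structure: hourly steps, days, population counts", {
  # full-length season bookkeeping without running the full season
  cfg <- load_config()
  expect_equal(cfg$n_days * 24L, 4680L)            # 195 days of hourly steps
  expect_equal(70 * 1000 / 100, 700)               # 70 km at 100-m patches
  # flock counts at the species' population maxima
  n_flocks <- sapply(default_sp, function(sp)
    round(sp$max_population / sp$flock_size))
  expect_equal(unname(n_flocks), c(500, 700, 75, 750))
  # short run executes exactly 24 * n_days steps
  land <- gen_landscape(25, 25, seed = 2)
  res <- run_simulation(land, small_cfg(0.002), seed = 3, n_days = 5)
  expect_equal(res$n_steps, 120)
})

test_that("grass-mass and goose-hour ledgers balance over a run", {
  land <- gen_landscape(50, 50, seed = 9)
  cfg <- small_cfg(0.004)   # ~20 flocks at peak
  res <- run_simulation(land, cfg, seed = 11, n_days = 30)
  # grams eaten equal 150 000 g per goose-attributed cm lost
  expect_equal(sum(res$grams_eaten), 150000 * sum(res$grazed),
               tolerance = 1e-9)
  # per-cell flock-hours sum to the per-type pressure ledger
  for (code in SPECIES_CODES) {
    si <- match(code, SPECIES_CODES)
    for (ty in 1:3) {
      nm <- c("scaring", "accommodation", "nature")[ty]
      expect_equal(sum(res$fh[res$type == ty, si]),
                   res$pressure[nm, code], tolerance = 1e-9)
    }
  }
  # pressure equals recorded foraging time
  expect_equal(sum(res$pressure),
               sum(sapply(SPECIES_CODES, function(code) {
                 si <- match(code, SPECIES_CODES)
                 sum(res$fh[, si])
               })), tolerance = 1e-9)
})

test_that("the event log records flock activity when requested", {
  land <- gen_landscape(30, 30, seed = 5)
  res <- run_simulation(land, small_cfg(0.005), seed = 9, n_days = 4,
                        record_events = TRUE)
  expect_s3_class(res$events, "data.frame")
  expect_true(all(c("hour", "flock", "species", "event", "cell", "mass")
                  %in% names(res$events)))
  expect_true(all(res$events$event %in%
                  c("forage", "night_forage", "roost", "scare", "death")))
  # per-cell ledger export covers every cell once
  tab <- landscape_table(res$land)
  expect_equal(nrow(tab), 900)
  expect_true(all(paste0("hours_", SPECIES_CODES) %in% names(tab)))
})

test_that("yield loss prices height deficits at EUR 37.50 per cm per ha", {
  # hand-built one-patch case
  final <- tiny_land(); ref <- tiny_land()
  cell <- cells_of_type(final, 1L)[1]
  final$height[cell] <- ref$height[cell] - 0.01     # 1 cm lower
  expect_equal(yield_loss(final, ref), 37.50)
  # linear in the deficit
  final2 <- tiny_land()
  final2$height[cell] <- ref$height[cell] - 0.02
  expect_equal(yield_loss(final2, ref), 75)
  expect_equal(yield_loss(tiny_land(), ref), 0)     # no grazing
  # nature-area deficits are excluded by default, included on request
  final3 <- tiny_land()
  nat <- cells_of_type(final3, 3L)[1]
  final3$height[nat] <- ref$height[nat] - 0.01
  expect_equal(yield_loss(final3, ref), 0)
  expect_equal(yield_loss(final3, ref, include_nature = TRUE), 37.50)
  bad <- new_landscape(matrix(1L, 3, 3))
  expect_error(yield_loss(bad, ref), "geometry")
})

test_that("total costs decompose into yield, scaring and appraisal terms", {
  res <- structure(list(
    type = c(1L, 1L, 2L, 3L),
    height_final = c(0.084, 0.094, 0.094, 0.094),
    ref_height_final = 0.094,
    scares = matrix(c(100, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), 3, 4,
                    dimnames = list(c("scaring", "accommodation", "nature"),
                                    SPECIES_CODES)),
    fh = matrix(c(5, 0, 0, 0), 4, 4,
                dimnames = list(NULL, SPECIES_CODES))
  ), class = "goosesim_result")
  tc <- total_costs(res)
  expect_equal(tc$yield_loss, 37.50)
  expect_equal(tc$scaring_costs, 1000)   # 100 events at EUR 10
  expect_equal(tc$appraisal_costs, 0)
  expect_equal(tc$total, 1037.50)
  eco <- goosesim:::.default_economics()
  eco$cost_per_appraised_patch <- 5
  tc2 <- total_costs(res, eco)
  expect_equal(tc2$appraisal_costs, 5)   # one affected agricultural patch
  expect_gt(tc2$total, tc$total)         # monotone in every counter
})

test_that("pressure per goose divides goose-hours by population-days", {
  res <- structure(list(
    pressure = matrix(c(300, 200, 100, rep(0, 9)), 3, 4,
                      dimnames = list(c("scaring", "accommodation", "nature"),
                                      SPECIES_CODES)),
    daily_pop = matrix(rep(c(100, 0, 0, 0), each = 1), 1, 4,
                       dimnames = list(NULL, SPECIES_CODES)),
    n_days = 1
  ), class = "goosesim_result")
  expect_equal(pressure_per_goose(res, "BAG", "agricultural"), 5)
  expect_equal(pressure_per_goose(res, "BAG", "all-grassland"), 6)
  expect_true(is.na(pressure_per_goose(res, "GLG", "agricultural")))
  # all-grassland never below agricultural
  expect_gte(pressure_per_goose(res, "BAG", "all-grassland"),
             pressure_per_goose(res, "BAG", "agricultural"))
})

test_that("additional foraging is measured against the sweep minimum", {
  mk <- function(total) structure(list(
    pressure = matrix(c(total, 0, 0, rep(0, 9)), 3, 4,
                      dimnames = list(c("scaring", "accommodation", "nature"),
                                      SPECIES_CODES)),
    daily_pop = matrix(c(100, 0, 0, 0), 1, 4,
                       dimnames = list(NULL, SPECIES_CODES)),
    n_days = 1), class = "goosesim_result")
  af <- additional_foraging(list(mk(400), mk(600)), "BAG")
  expect_equal(af, c(0, 2))
  expect_equal(additional_foraging(list(mk(500), mk(500)), "BAG"), c(0, 0))
  expect_error(additional_foraging(list(mk(1)), "BAG"), "at least two")
})
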