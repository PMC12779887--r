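make_flock <- function(land = grass_land(21), sp = default_sp$BAG,
                       cell = cell_id(land, 10, 10), id = 1L)
  new_flock(sp, cell, land, id = id)

test_that("memory is a deduplicating FIFO capped at 100 locations", {
  land <- grass_land(21)
  f <- make_flock(land)
  remember(f, cell_id(land, 1, 1), 0.05, time = 0, land = land)
  expect_length(f$mem_cell, 1)
  # 101 distinct inserts: size stays 100 and the first entry is evicted
  f2 <- make_flock(land)
  cells <- sample(seq_len(21 * 21), 101)
  for (i in seq_along(cells))
    remember(f2, cells[i], 0.05, time = i, land = land)
  expect_length(f2$mem_cell, 100)
  expect_false(cells[1] %in% f2$mem_cell)
  expect_true(all(cells[2:101] %in% f2$mem_cell))
  # re-inserting updates in place
  n_before <- length(f2$mem_cell)
  remember(f2, cells[50], 0.08, time = 200, land = land)
  expect_length(f2$mem_cell, n_before)
  j <- match(cells[50], f2$mem_cell)
  expect_equal(f2$mem_h[j], 0.08)
  expect_equal(f2$mem_t[j], 200)
})

test_that("memory never exceeds capacity under random operation streams", {
  land <- grass_land(31)
  f <- make_flock(land)
  set.seed(77)
  ops_cells <- sample(seq_len(31 * 31), 5000, replace = TRUE)
  max_size <- 0L
  for (i in seq_along(ops_cells)) {
    remember(f, ops_cells[i], runif(1, 0, 0.2), time = i, land = land)
    max_size <- max(max_size, length(f$mem_cell))
  }
  expect_lte(max_size, 100)
  expect_length(f$mem_cell, 100)
})

test_that("memory selection prefers near, tall-remembered patches", {
  land <- grass_land(101)
  beh <- goosesim:::.default_behaviour()
  beh$p_max_memory <- 1   # deterministic proposal
  f <- new_flock(default_sp$BAG, cell_id(land, 0, 0), land)
  expect_null(select_memory_patch(f, 0, beh))
  near <- cell_id(land, 1, 0); far <- cell_id(land, 50, 0)
  remember(f, near, 0.02, time = 0, land = land)
  remember(f, far, 0.02, time = 0, land = land)
  picks <- replicate(50, select_memory_patch(f, 1, beh))
  expect_true(all(unlist(picks) == near))
  # a scared (zero-height) memory never beats a positive-gain one
  f2 <- new_flock(default_sp$BAG, cell_id(land, 0, 0), land)
  remember(f2, near, 0, time = 0, land = land)
  remember(f2, far, 0.03, time = 0, land = land)
  picks2 <- unlist(replicate(50, select_memory_patch(f2, 1, beh)))
  expect_true(all(picks2 == far))
})

test_that("joining probability rises with conspecific numbers", {
  expect_equal(join_probability(0, default_sp$BAG), plogis(-2.17),
               tolerance = 1e-12)
  expect_equal(plogis(-2.17), 0.102, tolerance = 0.01)
  n <- c(0, 10, 100, 1000)
  p <- join_probability(n, default_sp$BAG)
  expect_true(all(diff(p) > 0))
  # empirical joining frequency increases with aggregation size
  land <- grass_land(21)
  f <- make_flock(land, id = 1L)
  mk_other <- function(n_geese, id) {
    g <- make_flock(land, cell = cell_id(land, 12, 10), id = id)
    g$state <- "foraging"; g$n_geese <- n_geese
    g
  }
  set.seed(5)
  freq <- sapply(c(10, 5000), function(ng) {
    other <- mk_other(ng, 2L)
    mean(replicate(400, maybe_join(f, cell_id(land, 10, 10),
                                   list(f, other), land) == other$cell))
  })
  expect_gt(freq[2], freq[1])
  # no conspecifics anywhere: destination unchanged
  expect_equal(maybe_join(f, cell_id(land, 3, 3), list(f), land),
               cell_id(land, 3, 3))
})

test_that("patch acceptance scales with intake rate and P_maxF", {
  sp <- default_sp$BAG
  set.seed(13)
  expect_false(any(replicate(200, accept_patch(0, sp))))
  acc <- mean(replicate(4000, accept_patch(sp$h_opt, sp, p_max_forage = 0.9)))
  expect_equal(acc, 0.9, tolerance = 0.03)   # binomial check at h*
  # acceptance probability inherits the intake-rate shape
  h <- seq(0, 0.5, by = 0.01)
  p_acc <- 0.9 * intake_rate(h, sp) / sp$rate_opt
  expect_equal(which.max(p_acc), which.max(intake_rate(h, sp)))
})

test_that("disturbance respects per-type probabilities and their ordering", {
  set.seed(3)
  expect_false(any(replicate(100, disturbance(1, c(scaring = 0,
    accommodation = 0, nature = 0)))))
  expect_true(all(replicate(100, disturbance(1, c(scaring = 1,
    accommodation = 0, nature = 0)))))
  expect_error(disturbance(0), "grassland")
  d <- goosesim:::.default_behaviour()$disturbance
  expect_gt(d[["scaring"]], d[["accommodation"]])
  expect_gte(d[["accommodation"]], d[["nature"]])
  # config loader enforces the ordering
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("behaviour:", "  disturbance:", "    scaring: 0.01",
               "    accommodation: 0.5", "    nature: 0.02"), bad)
  expect_error(load_config(bad))
})

test_that("scaring zeroes the patch memory and charges the 2-km flight", {
  land <- grass_land(101)
  f <- new_flock(default_sp$BAG, cell_id(land, 50, 50), land)
  origin <- f$cell
  remember(f, origin, 0.08, time = 0, land = land)
  set.seed(21)
  res <- handle_scaring(f, land, time = 1)
  j <- match(origin, f$mem_cell)
  expect_equal(f$mem_h[j], 0)
  expect_false(f$cell == origin)
  d <- cell_distance(land, origin, f$cell)
  expect_equal(res$t_fly, flight_duration(d, default_sp$BAG$flight))
  expect_true(d >= 19 && d <= 21)
})

test_that("the hourly decision tree follows daylight, weight and rest rules", {
  land <- grass_land(21)
  cal <- gen_weight_calendar(default_sp$BAG)
  # daylight at the weight cap: move to a roost and rest
  f <- new_flock(default_sp$BAG, cell_id(land, 10, 10), land,
                 mass = max_weight(cal, 50))
  f$state <- "foraging"
  set.seed(1)
  st <- step_flock(f, land, time = 12, doy = 20, calendar = cal, day = 50)
  expect_equal(st$ledger$event, "roost")
  expect_equal(land$type[f$cell], -1L)
  expect_equal(st$ledger$t_forage + st$ledger$t_fly + st$ledger$t_rest, 3600)
  # night, under the expected weight, 9 h to sunrise, bright moon: forage
  f2 <- new_flock(default_sp$BAG, cell_id(land, 10, 10), land,
                  mass = mean_weight(cal, 50) - 200)
  doy_full <- which.max(moon_fraction(1:365))
  st_n <- sun_times(doy_full)
  hour9 <- floor(st_n$sunrise) - 9         # 9 h before sunrise
  if (hour9 < 0) hour9 <- hour9 + 24
  set.seed(2)
  beh <- goosesim:::.default_behaviour()
  beh$disturbance[] <- 0
  st2 <- step_flock(f2, land, time = hour9, doy = doy_full, calendar = cal,
                    day = 50, behaviour = beh)
  expect_equal(st2$ledger$event, "night_forage")
  expect_gt(st2$ledger$t_forage, 0)
  # night with only 7 h to sunrise: roost regardless of mass
  f3 <- new_flock(default_sp$BAG, cell_id(land, 10, 10), land,
                  mass = mean_weight(cal, 50) - 200)
  hour7 <- floor(st_n$sunrise) - 7
  if (hour7 < 0) hour7 <- hour7 + 24
  set.seed(3)
  st3 <- step_flock(f3, land, time = hour7, doy = doy_full, calendar = cal,
                    day = 50, behaviour = beh)
  expect_equal(st3$ledger$event, "roost")
  expect_error(step_flock({f$alive <- FALSE; f}, land, 12, 20, cal, 50),
               "dead")
})

test_that("with no disturbance a lone flock locks onto a good nearby patch", {
  land <- grass_land(15, initial_height = 0.003)   # poor swards everywhere
  good <- cell_id(land, 1, 1)
  land$height[good] <- default_sp$BAG$h_opt   # one optimal patch near roost
  beh <- goosesim:::.default_behaviour()
  beh$disturbance[] <- 0
  cal <- gen_weight_calendar(default_sp$BAG)
  f <- new_flock(default_sp$BAG, land$roost_index[1], land)
  f$mass <- 1500
  remember(f, good, default_sp$BAG$h_opt, time = 9, land = land)
  set.seed(4)
  visited <- integer(0)
  for (h in 10:17) {   # consecutive daylight hours
    st <- step_flock(f, land, time = h, doy = 100, calendar = cal, day = 150,
                     behaviour = beh)
    land <- st$land
    visited <- c(visited, f$cell)
  }
  # the good patch is used repeatedly (a random walk over the 224
  # grassland cells would visit it ~0.25 times in expectation)
  expect_gte(sum(visited == good), 3)
})
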