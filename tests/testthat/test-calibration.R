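mk_fix <- function(animal, hours, x, y, speed = 0.5, species = "BAG",
                   day = 1) {
  data.frame(animal = animal, species = species,
             time = as.POSIXct("2018-11-01", tz = "UTC") +
               (day - 1) * 86400 + hours * 3600,
             x = x, y = y, speed = speed)
}

test_that("roost detection needs four distinct nights in the night window", {
  # same cell, 2:00 fixes on 4 distinct nights
  f4 <- do.call(rbind, lapply(1:4, function(d)
    mk_fix(1, 2, 150, 150, day = d)))
  expect_equal(detect_roosts(f4), data.frame(cx = 1L, cy = 1L))
  # only 3 nights: not a roost
  expect_equal(nrow(detect_roosts(f4[1:3, ])), 0)
  # 10 fixes within one night count as a single night
  f10 <- mk_fix(1, seq(0, 3.9, length.out = 10), 150, 150)
  expect_equal(nrow(detect_roosts(f10)), 0)
  # fixes outside 0:00-4:00 never qualify
  fday <- do.call(rbind, lapply(1:6, function(d)
    mk_fix(1, 13, 150, 150, day = d)))
  expect_equal(nrow(detect_roosts(fday)), 0)
  expect_equal(nrow(detect_roosts(f4[0, ])), 0)
})

test_that("roost detection is invariant to fix order", {
  set.seed(91)
  f <- do.call(rbind, lapply(1:6, function(d)
    mk_fix(1, sample(0:3, 1), 950, 2050, day = d)))
  shuffled <- f[sample(nrow(f)), ]
  expect_equal(detect_roosts(f), detect_roosts(shuffled))
})

test_that("flight segmentation uses strict speed and gap thresholds", {
  # slow fixes: nothing
  slow <- mk_fix(1, seq(10, 12, by = 0.25), seq(0, 2000, length.out = 9),
                 0, speed = 5)
  expect_equal(nrow(flight_segments(slow)), 0)
  # fast run with a 20-min hole: two segments
  hours <- c(10, 10.1, 10.2, 10.6, 10.7, 10.8)
  fast <- mk_fix(1, hours, seq(0, 5000, length.out = 6), 0, speed = 15)
  seg <- flight_segments(fast)
  expect_equal(nrow(seg), 2)
  expect_equal(sum(seg$n_fixes), 6)
  expect_equal(sum(seg$distance_m), 4000)  # the hole's 1000 m is excluded
  # exactly 12 m/s is not flying
  at12 <- mk_fix(1, c(10, 10.1), c(0, 1000), 0, speed = 12)
  expect_equal(nrow(flight_segments(at12)), 0)
})

test_that("flight-time coefficients are recovered from synthetic segments", {
  sp <- default_sp$WFG    # c1 = 0.57, c2 = 0.44
  set.seed(92)
  d <- exp(runif(500, log(300), log(30000)))   # 0.3-30 km
  t_true <- flight_duration(d / 100, sp$flight)
  seg <- data.frame(distance_m = d,
                    duration_s = t_true * exp(rnorm(500, 0, 0.05)))
  fit <- fit_flight_time(seg, v = sp$flight_speed)
  expect_lt(abs(fit$c1 - 0.57) / 0.57, 0.15)
  expect_lt(abs(fit$c2 - 0.44) / 0.44, 0.15)
  # noiseless data: near-exact recovery
  seg0 <- data.frame(distance_m = d, duration_s = t_true)
  fit0 <- fit_flight_time(seg0, v = sp$flight_speed)
  expect_equal(fit0$c1, 0.57, tolerance = 1e-4)
  expect_equal(fit0$c2, 0.44, tolerance = 1e-4)
  # residuals uncorrelated with distance under the true model
  resid <- log(seg$duration_s) - log(flight_duration(d / 100, flight_coeffs(
    c1 = fit$c1, c2 = fit$c2, v = sp$flight_speed)))
  expect_gt(cor.test(resid, d, method = "spearman")$p.value, 0.01)
  expect_error(fit_flight_time(seg[1:10, ], v = 15), "at least 30")
})

test_that("hourly displacements convert paired fixes to hm", {
  # stationary animal: nothing at or above x_min
  still <- mk_fix(1, 8:18, 500, 500)
  expect_length(hourly_displacements(still), 0)
  # two fixes one hour and 1500 m apart: a single 15-hm sample
  two <- mk_fix(1, c(8, 9), c(0, 1500), 0)
  expect_equal(hourly_displacements(two), 15)
  # fixes 2 h apart are not paired
  twoh <- mk_fix(1, c(8, 10), c(0, 1500), 0)
  expect_length(hourly_displacements(twoh), 0)
})

test_that("the GPS pipeline recovers planted roosts and CRW parameters", {
  sp <- default_sp$GLG    # mu = 2.08
  roosts <- cbind(x = c(5050, 25050, 12050), y = c(5050, 15050, 30050))
  tracks <- gen_tracks(sp, n_animals = 12, n_days = 30, roosts = roosts,
                       seed = 93)
  found <- detect_roosts(tracks)
  expect_equal(nrow(found), nrow(roosts))
  expect_setequal(paste(found$cx, found$cy),
                  paste(floor(roosts[, "x"] / 100),
                        floor(roosts[, "y"] / 100)))
  # displacement distribution feeds the CRW fit; mu recovered within 0.15
  disp <- hourly_displacements(tracks)
  expect_gt(length(disp), 1000)
  fit <- fit_crw(disp)
  expect_lt(abs(fit$mu - sp$crw$mu), 0.15)
  # flight segments from the same tracks recover the flight-time curve
  seg <- flight_segments(tracks)
  expect_gt(nrow(seg), 30)
  ft <- fit_flight_time(seg, v = sp$flight_speed)
  expect_lt(abs(ft$c1 - sp$c1) / sp$c1, 0.15)
  expect_lt(abs(ft$c2 - sp$c2) / sp$c2, 0.15)
})

test_that("flock sizes come from the 20th percentile of observations", {
  expect_equal(flock_size_model(1:100), 20)
  expect_equal(flock_size_model(rep(7, 25)), 7)
  # a catch distribution whose 20th percentile sits at the model flock size
  set.seed(94)
  obs <- round(1000 * exp(rnorm(500, 0.8, 0.6)))
  q <- unname(quantile(obs, 0.2, type = 1))
  expect_equal(flock_size_model(obs, granularity = 100),
               round(q / 100) * 100)
  expect_error(flock_size_model(1:10), "at least 20")
})
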