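test_that("composite-random-walk survival matches the printed mixture", {
  bag <- default_sp$BAG$crw
  # barnacle defaults at x = 1: 0.32 e^-0.08 + 0.68
  expect_equal(crw_survival(1, bag), 0.32 * exp(-0.08) + 0.68,
               tolerance = 1e-12)
  # pure Pareto endpoints
  par_only <- crw_params(p_bw = 0, lambda = 1, mu = 2, x_max = 50)
  expect_equal(crw_survival(1, par_only), 1)
  expect_equal(crw_survival(50, par_only), 0)
  x <- seq(1, 200, by = 0.5)
  expect_true(all(diff(crw_survival(x, bag)) <= 1e-12))
  expect_error(crw_survival(0.5, bag), "x_min")
  expect_error(crw_params(p_bw = 0.3, lambda = 0.1, mu = 1, x_max = 100),
               "mu")
})

test_that("sampled steps agree with the sampling-form survival (MC oracle)", {
  set.seed(101)
  p <- default_sp$BAG$crw
  n <- 1e5
  draws <- sample_step(p, n)
  expect_true(all(draws >= p$x_min))
  for (x0 in c(1, 5, 20)) {
    emp <- mean(draws > x0)
    th <- crw_survival(x0, p, form = "sampling")
    se <- sqrt(max(th * (1 - th), 1e-12) / n)
    expect_lt(abs(emp - th), 3 * se + 1e-9)
  }
  # Brownian-dominated limit concentrates near x_min
  pb <- crw_params(p_bw = 1, lambda = 10, mu = 2, x_max = 100)
  expect_lt(max(sample_step(pb, 1000)), 3)
  # pure Pareto respects the upper truncation
  pp <- crw_params(p_bw = 0, lambda = 1, mu = 2.25, x_max = 200)
  expect_lte(max(sample_step(pp, 10000)), 200)
})

test_that("fit_crw recovers generating parameters from simulated steps", {
  set.seed(202)
  truth <- default_sp$PFG$crw   # lambda 0.052, mu 2.25, x_max 200, P_BW 0.4
  fit <- fit_crw(sample_step(truth, 5000))
  expect_lt(abs(fit$mu - truth$mu), 0.15)
  expect_lt(abs(fit$p_bw - truth$p_bw), 0.07)
  # degenerate mixture: a pure exponential sample is attributed to the
  # Brownian component
  set.seed(203)
  fit_exp <- fit_crw(1 + rexp(3000, 0.2))
  expect_gte(fit_exp$p_bw, 0.9)
  expect_error(fit_crw(c(0.5, rep(2, 300))), "x_min")
  expect_error(fit_crw(rep(2, 50)), "at least 200")
})

test_that("flight duration exceeds straight-line time and converges to it", {
  bag <- default_sp$BAG$flight
  # barnacle, 1 km: S ~ 1.21, T ~ 1.8e2 s
  s <- 10 / (1 + 0.20 * 1000^0.52)
  expect_equal(flight_duration(10, bag), exp(s) * 1000 / 19, tolerance = 1e-12)
  expect_equal(flight_duration(10, bag), 176.6, tolerance = 0.01)
  d <- 1:500
  for (sp in default_sp) {
    t_mod <- flight_duration(d, sp$flight)
    t_line <- d * 100 / sp$flight_speed
    expect_true(all(t_mod > t_line))
    # monotone in distance beyond the within-patch scale (the circling
    # overhead makes very short hops slightly non-monotone)
    expect_true(all(diff(t_mod[-1]) > 0))
    ratio <- t_mod / t_line
    expect_true(all(diff(ratio) < 0))            # circling overhead shrinks
  }
  far <- flight_duration(1e6, bag) / (1e6 * 100 / 19)
  expect_equal(far, 1, tolerance = 0.005)
  expect_error(flight_duration(0, bag), "positive")
})

test_that("scare displacement lands ~2 km away on a uniform bearing", {
  land <- new_landscape(matrix(0L, 100, 100))
  origin <- cell_id(land, 50, 50)
  set.seed(7)
  d <- replicate(200, cell_distance(land, origin,
                                    scare_displacement(land, origin)))
  expect_true(all(d >= 19 & d <= 21))
  # bearings uniform by chi-square over 8 sectors
  set.seed(8)
  cells <- replicate(1000, scare_displacement(land, origin))
  cr <- t(sapply(cells, function(id) c((id - 1) %/% 100, (id - 1) %% 100)))
  theta <- atan2(cr[, 2] - 50, cr[, 1] - 50) %% (2 * pi)
  bins <- table(cut(theta, breaks = seq(0, 2 * pi, length.out = 9)))
  expect_gt(chisq.test(bins)$p.value, 0.01)
  # different seeds give different bearings
  set.seed(1); a <- scare_displacement(land, origin)
  set.seed(2); b <- scare_displacement(land, origin)
  expect_false(identical(a, b))
  expect_error(scare_displacement(new_landscape(matrix(0L, 3, 3)),
                                  cell_id(new_landscape(matrix(0L, 3, 3)), 1, 1)),
               "no on-grid cell")
})

test_that("roost choice honours the 10-km fidelity rule and distance weights", {
  g <- matrix(0L, 200, 200)
  g[1, 1] <- -1L; g[11, 11] <- -1L; g[101, 101] <- -1L
  land <- new_landscape(g)
  near <- cell_id(land, 0, 0)      # 10*sqrt(2) ~ 14 patches from current
  mid <- cell_id(land, 10, 10)
  far <- cell_id(land, 100, 100)
  cur <- c(10, 20)
  # previous roost within 10 km is always reused
  expect_equal(choose_roost(land, cur, prev_roost = near), near)
  # previous roost beyond 10 km: distance-weighted sampling prefers near
  set.seed(9)
  cur2 <- c(0, 30)
  picks <- replicate(1000, choose_roost(land, cur2, prev_roost = far))
  expect_false(far %in% names(sort(table(picks), decreasing = TRUE))[1])
  expect_gt(sum(picks == near), sum(picks == far))
  # single roost set
  g1 <- matrix(0L, 5, 5); g1[3, 3] <- -1L
  l1 <- new_landscape(g1)
  expect_equal(choose_roost(l1, c(0, 0), prev_roost = NULL), l1$roost_index)
  expect_error(choose_roost(land, cur, roosts = integer(0)), "roost")
})
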