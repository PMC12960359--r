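test_that("covered area matches the analytic disk area for a single platelet", {
  frac <- covered_area_fraction(matrix(c(40, 20), 1), diameter = 0.6,
                                floor_x = c(0, 80), floor_z = c(0, 40),
                                resolution = 0.05)
  expect_equal(frac, pi * 0.3^2 / (80 * 40), tolerance = 0.02)
  expect_identical(covered_area_fraction(matrix(0, 0, 2), 0.6,
                                         c(0, 80), c(0, 40)), 0)
})

test_that("covered area saturates under dense paving and rejects bad input", {
  g <- as.matrix(expand.grid(seq(0.1, 4.9, by = 0.25), seq(0.1, 4.9, by = 0.25)))
  frac <- covered_area_fraction(g, diameter = 0.6, floor_x = c(0, 5),
                                floor_z = c(0, 5), resolution = 0.05)
  expect_gt(frac, 0.97)
  expect_error(covered_area_fraction(g, 0.6, c(2, 2), c(0, 5)), "non-empty")
  expect_error(covered_area_fraction(g, 0.6, c(0, 5), c(0, 5), resolution = 0.2),
               "resolution")
})

test_that("covered area converges to the Monte-Carlo union-of-disks area", {
  set.seed(31)
  pts <- cbind(runif(12, 1, 7), runif(12, 1, 7))
  d <- 1.2
  # Monte-Carlo oracle for the union-of-disks area fraction
  m <- 2e5
  q <- cbind(runif(m, 0, 8), runif(m, 0, 8))
  inside <- rep(FALSE, m)
  for (k in seq_len(nrow(pts)))
    inside <- inside | ((q[, 1] - pts[k, 1])^2 + (q[, 2] - pts[k, 2])^2 <= (d / 2)^2)
  oracle <- mean(inside)
  err <- vapply(c(0.2, 0.1, 0.05), function(res) {
    abs(covered_area_fraction(pts, d, c(0, 8), c(0, 8), resolution = res) - oracle)
  }, 0)
  expect_lt(err[3], 0.02 * oracle + 3 * sqrt(oracle / m))
  # finer rasters do not get worse
  expect_lte(err[3], err[1] + 1e-3)
})

test_that("aggregate partition equals the transitive-closure oracle", {
  closure_components <- function(pos, cutoff) {
    n <- nrow(pos)
    adj <- as.matrix(dist(pos)) <= cutoff
    diag(adj) <- TRUE
    # O(n^2) reachability by repeated boolean multiplication
    reach <- adj
    repeat {
      nxt <- (reach %*% adj) > 0
      if (identical(nxt, reach > 0)) break
      reach <- nxt
    }
    comp <- integer(n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (comp[i] == 0L) {
        cid <- cid + 1L
        comp[reach[i, ] > 0] <- cid
      }
    }
    comp
  }
  set.seed(17)
  pos <- cbind(runif(20, 0, 6), runif(20, 0, 2), runif(20, 0, 6))
  agg <- platelet_aggregates(pos, diameter = 0.6)
  comp <- closure_components(pos, 1.1 * 0.6)
  sizes_oracle <- sort(as.integer(table(comp)), decreasing = TRUE)
  expect_identical(sort(agg$n_platelets, decreasing = TRUE), sizes_oracle)
  expect_equal(sum(agg$n_platelets), 20)
})

test_that("aggregates follow the contact relation in the simple cases", {
  d <- 0.6
  two_close <- rbind(c(1, 0.3, 1), c(1 + 0.5 * d, 0.3, 1))
  a1 <- platelet_aggregates(two_close, d)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$n_platelets, 2)
  two_far <- rbind(c(1, 0.3, 1), c(1 + 3 * d, 0.3, 1))
  a2 <- platelet_aggregates(two_far, d)
  expect_equal(nrow(a2), 2)
  expect_equal(a2$n_platelets, c(1, 1))
  # max height is measured from the floor
  stack <- rbind(c(1, 0.3, 1), c(1, 0.9, 1))
  a3 <- platelet_aggregates(stack, d)
  expect_equal(a3$max_height, 0.9)
  # projected area of one disk (fine raster)
  one <- platelet_aggregates(matrix(c(1, 0.3, 1), 1), d, resolution = d / 40)
  expect_equal(one$projected_area, pi * (d / 2)^2, tolerance = 0.02)
})

test_that("aggregate partition is invariant to ordering and translation", {
  set.seed(23)
  pos <- cbind(runif(15, 0, 5), runif(15, 0, 2), runif(15, 0, 5))
  a <- platelet_aggregates(pos, 0.6)
  perm <- sample(15)
  b <- platelet_aggregates(pos[perm, ], 0.6)
  expect_identical(a$n_platelets, b$n_platelets)
  shifted <- sweep(pos, 2, c(3.2, 0, -1.7), `+`)
  c_ <- platelet_aggregates(shifted, 0.6, floor_level = 0)
  expect_identical(a$n_platelets, c_$n_platelets)
  expect_equal(a$projected_area, c_$projected_area, tolerance = 0.05)
})

test_that("monolayer fraction distinguishes stacked from flat configurations", {
  flat <- cbind(seq(1, 5), 0.3, 1)
  expect_equal(monolayer_fraction(flat, 0.6), 1)
  stacked <- rbind(c(1, 0.3, 1), c(1, 0.9, 1), c(3, 0.3, 1))
  expect_equal(monolayer_fraction(stacked, 0.6), 2 / 3)
  expect_true(is.na(monolayer_fraction(matrix(0, 0, 3), 0.6)))
})

test_that("velocity profile recovers prescribed fields", {
  set.seed(9)
  n <- 6000
  H <- 10
  x <- cbind(runif(n, 0, 10), runif(n, 0, H), runif(n, 0, 10))
  # uniform field -> flat profile
  v <- cbind(rep(2, n), 0, 0)
  sys <- particle_system(x, v, 0L, box = c(10, H, 10))
  pr <- velocity_profile(sys, n_bins = 10)
  expect_equal(pr$mean_vx, rep(2, 10), tolerance = 1e-12)
  # parabolic field sampled on particles
  umax <- 5
  vpar <- cbind(umax * (1 - (2 * x[, 2] / H - 1)^2), 0, 0)
  sys2 <- particle_system(x, vpar, 0L, box = c(10, H, 10))
  pr2 <- velocity_profile(sys2, n_bins = 20)
  expected <- umax * (1 - (2 * pr2$y / H - 1)^2)
  expect_equal(pr2$mean_vx, expected, tolerance = 0.05)
  expect_error(velocity_profile(sys2, n_bins = 2), "at least 4")
})

test_that("empty bins are flagged missing, not zero", {
  x <- cbind(runif(50, 0, 5), runif(50, 0, 2), runif(50, 0, 5))  # only y < 2
  sys <- particle_system(x, cbind(1, 0, 0)[rep(1, 50), ], 0L, box = c(5, 10, 5))
  pr <- velocity_profile(sys, n_bins = 10)
  expect_true(any(is.na(pr$mean_vx)))
  expect_true(all(pr$n[is.na(pr$mean_vx)] == 0))
})

test_that("shear fit on an exact parabola recovers 4 Umax / H exactly", {
  H <- 20
  y <- seq(0.5, H - 0.5, by = 1)
  umax <- 35
  profile <- data.frame(y = y, mean_vx = umax * (1 - (2 * y / H - 1)^2),
                        se = 0, n = 100)
  fit <- fit_profile_shear(profile, degree = 2, H = H)
  expect_equal(fit$wall_shear_rate, 4 * umax / H, tolerance = 1e-10)
  u <- table1_units()
  fit2 <- fit_profile_shear(profile, degree = 2, H = H, units = u)
  expect_equal(fit2$wall_shear_rate_per_s, 4 * umax / H / u$time, tolerance = 1e-10)
  # flat profile -> zero shear
  flat <- data.frame(y = y, mean_vx = rep(3, length(y)), se = 0, n = 100)
  expect_equal(fit_profile_shear(flat, H = H)$wall_shear_rate, 0, tolerance = 1e-10)
  expect_error(fit_profile_shear(profile[1:3, ], degree = 2), "valid bins")
})

test_that("shear fit under noise stays within propagated bounds", {
  H <- 20
  y <- seq(0.5, H - 0.5, by = 1)
  umax <- 35
  truth <- umax * (1 - (2 * y / H - 1)^2)
  sigma <- 0.5
  set.seed(4)
  shears <- replicate(100, {
    pr <- data.frame(y = y, mean_vx = truth + rnorm(length(y), sd = sigma),
                     se = sigma, n = 100)
    fit_profile_shear(pr, degree = 2, H = H)$wall_shear_rate
  })
  expect_equal(mean(shears), 4 * umax / H, tolerance = 0.05)
  # spread consistent with least-squares error propagation (loose 3x bound)
  expect_lt(sd(shears), 3 * sigma)
})

test_that("near-wall speed histogram matches direct counting", {
  x <- rbind(cbind(1:6, 0.5, 1), cbind(1:3, 5, 1))  # 6 near wall, 3 far
  v <- matrix(0, 9, 3)
  v[1:6, 1] <- c(0.05, 0.15, 0.15, 0.45, 0.8, 2.0)
  sys <- particle_system(x, v, 3L, box = c(10, 10, 10))
  h <- near_wall_speed_histogram(sys, wall_distance = 1, edges = c(0.1, 0.5, 1))
  expect_equal(sum(h$percent), 100)
  expect_equal(h$percent, 100 * c(1, 3, 1, 1) / 6)
  # stationary platelets all fall in the lowest class
  sys0 <- particle_system(x, matrix(0, 9, 3), 3L, box = c(10, 10, 10))
  h0 <- near_wall_speed_histogram(sys0, edges = c(0.1, 0.5, 1))
  expect_equal(h0$percent[1], 100)
  # no platelets in the band: empty result, not an error
  sysfar <- particle_system(cbind(1:3, 5, 1), matrix(0, 3, 3), 3L,
                            box = c(10, 10, 10))
  expect_equal(nrow(near_wall_speed_histogram(sysfar, edges = c(1))), 0)
})

test_that("speed-class edges convert consistently through the unit system", {
  u <- table1_units()
  x <- matrix(c(1, 0.5, 1), 1)
  v <- matrix(c(to_dpd(100e-6, "velocity", u), 0, 0), 1)  # 100 um/s
  sys <- particle_system(x, v, 3L, box = c(10, 10, 10))
  h <- near_wall_speed_histogram(sys, edges = c(50e-6, 200e-6), units = u)
  expect_equal(h$percent, c(0, 100, 0))
})

test_that("coarse fields recover uniform and linear-shear flows", {
  set.seed(12)
  n <- 8000
  x <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  vuni <- cbind(rep(3, n), 0, 0)
  sys <- particle_system(x, vuni, 0L, box = c(10, 10, 10))
  f <- coarse_field(sys, nx = 5, ny = 5, mu_eff = 1)
  expect_equal(max(abs(f$shear_stress), na.rm = TRUE), 0, tolerance = 1e-10)
  expect_equal(mean(f$speed), 3, tolerance = 1e-10)
  # linear shear: vx = g * y
  g <- 0.7
  sys2 <- particle_system(x, cbind(g * x[, 2], 0, 0), 0L, box = c(10, 10, 10))
  f2 <- coarse_field(sys2, nx = 5, ny = 5, mu_eff = 2)
  expect_equal(mean(f2$shear_stress), 2 * g, tolerance = 0.05)
})
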