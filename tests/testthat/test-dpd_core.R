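test_that("weight functions follow the soft-repulsion form with a sharp cutoff", {
  expect_equal(weight_conservative(0.5, 25, 1), 12.5)
  expect_identical(weight_conservative(1, 25, 1), 0)
  expect_equal(weight_conservative(0, 25, 1), 25)
  expect_error(weight_conservative(-0.1, 25), "non-negative")
  r <- runif(100, 0, 2)
  expect_equal(weight_dissipative(r), weight_random(r)^2)
  expect_true(all(weight_random(r[r >= 1]) == 0))
})

test_that("fluctuation-dissipation fixes the random force amplitude", {
  tab <- interaction_table(kBT = 1)
  expect_equal(tab$phi[1, 1], 3)       # sqrt(2 * 4.5 * 1)
  expect_equal(tab$phi, sqrt(2 * tab$gamma * tab$kBT))
  # derived plasma-wall conservative coefficient 75 kBT / (n_s r_c)
  expect_equal(tab$a["plasma", "wall"], 25)
  expect_equal(tab$a["plasma", "plasma"], 10)
  expect_error(interaction_table(a = matrix(1:16, 4)), "symmetric")
})

test_that("compiled forces agree with the O(n^2) reference without noise", {
  for (seed in 1:3) {
    sys <- bulk_fluid(n = 60, L = 4, seed = seed)
    # mix in wall and platelet kinds
    sys$kind[1:5] <- 1L
    sys$kind[6:8] <- 3L
    sys$v[1:5, ] <- 0
    tab0 <- interaction_table(kBT = 0)
    f_cpp <- dpd_forces(sys, tab0)$force
    f_ref <- dpd_pair_forces_ref(sys, tab0)
    expect_equal(f_cpp, f_ref, tolerance = 1e-10)
  }
})

test_that("pair forces obey Newton's third law including the random term", {
  sys <- bulk_fluid(n = 150, L = 5, seed = 11)
  f <- dpd_forces(sys, interaction_table(), dt = 0.01, seed = 3, step = 17)$force
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-11)
  # two-particle system: exactly equal and opposite
  x <- rbind(c(2, 2, 2), c(2.4, 2.3, 2.1))
  v <- rbind(c(0.3, -0.1, 0), c(-0.2, 0.2, 0.1))
  two <- particle_system(x, v, 0L, box = c(5, 5, 5))
  f2 <- dpd_forces(two, interaction_table(), seed = 8, step = 5)$force
  expect_equal(f2[1, ], -f2[2, ])
})

test_that("dissipative force opposes approach and vanishes for transverse motion", {
  tab0 <- interaction_table(kBT = 0, a = matrix(0, 4, 4))
  # head-on approach: dissipative force must push the particles apart less,
  # i.e. oppose the approach (decelerate particle 1 moving in +x)
  x <- rbind(c(2, 2, 2), c(2.5, 2, 2))
  v <- rbind(c(1, 0, 0), c(-1, 0, 0))
  sys <- particle_system(x, v, 0L, box = c(5, 5, 5))
  f <- dpd_forces(sys, tab0)$force
  expect_lt(f[1, 1], 0)
  expect_gt(f[2, 1], 0)
  # perpendicular relative velocity: no dissipative force at all
  v2 <- rbind(c(0, 1, 0), c(0, 1, 0))  # zero relative velocity
  sys2 <- particle_system(x, v2, 0L, box = c(5, 5, 5))
  expect_equal(dpd_forces(sys2, tab0)$force, matrix(0, 2, 3))
  v3 <- rbind(c(0, 1, 0), c(0, -1, 0))  # relative velocity perpendicular to e
  sys3 <- particle_system(x, v3, 0L, box = c(5, 5, 5))
  expect_equal(dpd_forces(sys3, tab0)$force, matrix(0, 2, 3))
})

test_that("a force-free particle moves in a straight line", {
  x <- matrix(c(1, 2, 3), 1)
  v <- matrix(c(0.3, 0.1, -0.2), 1)
  sys <- particle_system(x, v, 0L, box = c(10, 10, 10))
  run <- dpd_run(sys, interaction_table(kBT = 0), n_steps = 100, dt = 0.01)
  expect_equal(run$x[1, ], c(1, 2, 3) + 100 * 0.01 * c(0.3, 0.1, -0.2),
               tolerance = 1e-12)
  expect_equal(run$v[1, ], c(0.3, 0.1, -0.2))
})

test_that("periodic force-free ideal gas conserves planar momentum to machine precision", {
  sys <- bulk_fluid(n = 100, L = 5, seed = 2)
  run <- dpd_run(sys, interaction_table(), n_steps = 1000, dt = 0.01, seed = 4)
  p0 <- colSums(sys$v)
  p1 <- colSums(run$v)
  # x and z are periodic; y reflections flip vy but preserve |p_y| pairwise
  expect_equal(p1[c(1, 3)], p0[c(1, 3)], tolerance = 1e-10)
})

test_that("two-particle conservative-only dynamics conserve energy within 1%", {
  x <- rbind(c(2, 2.5, 2.5), c(2.6, 2.5, 2.5))
  v <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
  sys <- particle_system(x, v, 0L, box = c(5, 5, 5))
  tab0 <- interaction_table(kBT = 0, gamma = matrix(0, 4, 4))
  pot <- function(s) {
    d <- s$x[1, ] - s$x[2, ]
    for (ax in c(1, 3)) {
      if (d[ax] > 2.5) d[ax] <- d[ax] - 5
      if (d[ax] < -2.5) d[ax] <- d[ax] + 5
    }
    r <- sqrt(sum(d^2))
    if (r < 1) 10 / 2 * (1 - r)^2 else 0  # integral of a (1 - r) from r to r_c
  }
  e0 <- 0.5 * sum(sys$v^2) + pot(sys)
  run <- dpd_run(sys, tab0, n_steps = 1e4, dt = 0.01)
  e1 <- 0.5 * sum(run$v^2) + pot(run$system)
  expect_lt(abs(e1 - e0) / e0, 0.01)
})

test_that("the thermostat holds the equilibrium temperature within 5%", {
  sys <- bulk_fluid(n = 3 * 6^3, L = 6, seed = 5)
  run <- dpd_run(sys, interaction_table(), n_steps = 1500, dt = 0.01, seed = 6,
                 metrics_every = 100)
  temps <- tail(run$metrics$temperature, 10)
  expect_equal(mean(temps), 1, tolerance = 0.05)
})

test_that("kinetic temperature diagnostics behave at the edges", {
  v0 <- matrix(0, 5, 3)
  expect_identical(kinetic_temperature(v0), 0)
  set.seed(1)
  v <- matrix(rnorm(3 * 20000), ncol = 3)
  expect_equal(kinetic_temperature(v), 1, tolerance = 0.05)
  sys <- particle_system(matrix(1, 2, 3), kind = c(1L, 2L), box = c(5, 5, 5))
  expect_error(kinetic_temperature(sys), "mobile")
})

test_that("wall reflection is specular and wall particles never move", {
  x <- matrix(c(5, 0.05, 5), 1)
  v <- matrix(c(0, -20, 0), 1)
  sys <- particle_system(x, v, 0L, box = c(10, 10, 10))
  run <- dpd_run(sys, interaction_table(kBT = 0), n_steps = 1, dt = 0.01)
  expect_equal(run$x[1, 2], 0.15)   # mirrored about y = 0
  expect_equal(run$v[1, 2], 20)     # wall-normal velocity negated
  expect_equal(run$x[1, c(1, 3)], c(5, 5))
  # interior particle untouched
  sys2 <- particle_system(matrix(c(5, 5, 5), 1), matrix(c(0, 0.5, 0), 1), 0L,
                          box = c(10, 10, 10))
  run2 <- dpd_run(sys2, interaction_table(kBT = 0), n_steps = 1, dt = 0.01)
  expect_equal(run2$x[1, 2], 5.005)
  # breaching the wall by more than r_c in one step is an instability
  sys3 <- particle_system(matrix(c(5, 0.5, 5), 1), matrix(c(0, -300, 0), 1), 0L,
                          box = c(10, 10, 10))
  expect_error(dpd_run(sys3, interaction_table(kBT = 0), n_steps = 1, dt = 0.01),
               "instability")
})

test_that("no mobile particle ends outside the walls after a driven run", {
  sys <- build_channel(channel_spec(Lx = 6, Ly = 6, Lz = 6, coating = "generic"),
                       seed = 3)
  run <- dpd_run(sys, interaction_table(), n_steps = 2000, dt = 0.01, seed = 3,
                 body_force = 0.45)
  mobile <- run$kind %in% c(0L, 3L)
  expect_true(all(run$x[mobile, 2] >= 0 & run$x[mobile, 2] <= 6))
  expect_true(all(run$x[mobile, c(1, 3)] >= 0 & run$x[mobile, c(1, 3)] < 6))
  # immobile wall particles exactly where they started
  wall0 <- sys$x[sys$kind %in% c(1L, 2L), ]
  wall1 <- run$x[run$kind %in% c(1L, 2L), ]
  expect_equal(wall1, wall0)
})

test_that("the body force injects momentum at rate f per mobile particle", {
  sys <- bulk_fluid(n = 50, L = 5, seed = 7)
  tab0 <- interaction_table(kBT = 0, a = matrix(0, 4, 4), gamma = matrix(0, 4, 4))
  run <- dpd_run(sys, tab0, n_steps = 10, dt = 0.01, body_force = 0.45)
  dp <- sum(run$v[, 1]) - sum(sys$v[, 1])
  expect_equal(dp, 0.45 * 50 * 10 * 0.01, tolerance = 1e-10)
  run0 <- dpd_run(sys, tab0, n_steps = 10, dt = 0.01, body_force = 0)
  expect_equal(sum(run0$v[, 1]), sum(sys$v[, 1]), tolerance = 1e-12)
})

test_that("runs are reproducible from the seed", {
  sys <- bulk_fluid(n = 120, L = 5, seed = 1)
  r1 <- dpd_run(sys, interaction_table(), n_steps = 200, dt = 0.01, seed = 42)
  r2 <- dpd_run(sys, interaction_table(), n_steps = 200, dt = 0.01, seed = 42)
  expect_identical(r1$x, r2$x)
  expect_identical(r1$v, r2$v)
  r3 <- dpd_run(sys, interaction_table(), n_steps = 200, dt = 0.01, seed = 43)
  expect_false(identical(r1$x, r3$x))
})
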