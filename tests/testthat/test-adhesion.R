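test_that("elastic bond force switches from attraction to repulsion at r_a", {
  p <- visco_params(a0 = 400, gamma_p = 80)
  expect_equal(elastic_bond_force(5 / 6, p), -400 * (1 - 5 / 6))
  p2 <- visco_params(a0 = 400, gamma_p = 80, a1 = 1200)
  expect_equal(elastic_bond_force(0.5, p2), 1200 * 0.5)
  expect_identical(elastic_bond_force(1, p), 0)
  expect_identical(elastic_bond_force(2, p), 0)
  # attraction everywhere in (r_a, r_c), repulsion at or below r_a
  r <- seq(0.01, 0.99, by = 0.01)
  f <- elastic_bond_force(r, p)
  expect_true(all(f[r > p$r_a] < 0))
  expect_true(all(f[r <= p$r_a] > 0))
})

test_that("viscous bond force opposes relative motion along the bond", {
  p <- visco_params(a0 = 0, gamma_p = 80)
  expect_equal(viscous_bond_force(0.5, 0.1, p), -80 * 0.25 * 0.1)
  expect_identical(viscous_bond_force(0.5, 0, p), 0)
  expect_identical(viscous_bond_force(1, 0.3, p), 0)
  # sign always opposite to the relative velocity
  v <- seq(-2, 2, by = 0.25)
  expect_true(all(viscous_bond_force(0.4, v, p) * v <= 0))
})

test_that("visco_params validates the switch radius", {
  expect_error(visco_params(50, 4.5, r_a = 1.2), "r_a")
  expect_error(visco_params(-1, 4.5), "non-negative")
  expect_equal(visco_params(50, 4.5)$r_a, 2 / 3)
})

test_that("Bell detachment rate matches its closed form and is monotone", {
  s <- stoch_params(k0 = 120, F0 = 1000)
  expect_equal(detachment_rate(0, s), 120)
  s2 <- stoch_params(k0 = 100, F0 = 1000)
  expect_equal(detachment_rate(1000, s2), 100 * exp(1))
  expect_error(detachment_rate(-1, s), "non-negative")
  F <- sort(runif(100, 0, 5000))
  expect_true(all(diff(detachment_rate(F, s)) >= 0))
})

test_that("detachment probability has the right limits and monotonicity", {
  s <- stoch_params(k0 = 100, F0 = 1000, dt = 0.01)
  expect_equal(detachment_probability(0, s), 1 - exp(-1), tolerance = 1e-10)
  expect_true(detachment_probability(0, s) >= 0.62)  # printed band lower bound
  expect_equal(detachment_probability(0, s, dt = 1e-12), 0, tolerance = 1e-9)
  expect_identical(detachment_probability(500, stoch_params(k0 = 0, F0 = 1000)), 0)
  # bounds and monotonicity over grids
  F <- seq(0, 8000, length.out = 50)
  p <- detachment_probability(F, s)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
  k0s <- c(1, 10, 100, 500)
  pk <- vapply(k0s, function(k) detachment_probability(100, stoch_params(k, 1000)), 0)
  expect_true(all(diff(pk) > 0))
  dts <- c(1e-4, 1e-3, 1e-2, 1e-1)
  pd <- vapply(dts, function(d) detachment_probability(100, s, dt = d), 0)
  expect_true(all(diff(pd) > 0))
})

test_that("bond survival over n sweeps follows (1 - P_dis)^n", {
  s <- stoch_params(k0 = 30, F0 = 1000, dt = 0.01)
  p <- detachment_probability(0, s)
  set.seed(42)
  n_sweeps <- 5
  trials <- 1e4
  # a bond survives a sweep when its uniform draw is not below P_dis
  survived <- colSums(matrix(runif(n_sweeps * trials) < p, n_sweeps)) == 0
  expected <- (1 - p)^n_sweeps
  se <- sqrt(expected * (1 - expected) / trials)
  expect_lt(abs(mean(survived) - expected), 3 * se)
})

test_that("reference sweep reproduces a hand-enumerated 3-particle scenario", {
  # platelet 1 near coated 10 (class 1) and near adhered platelet 2 (class 0);
  # platelets 1-2 also a candidate pair
  pairs <- data.frame(a = c(1, 1, 2), b = c(10, 2, 10), class = c(1, 0, 1))
  bonded <- c(FALSE, FALSE, TRUE)
  stage <- c(NA, NA, 1)
  p_dis <- c(0.4, 0.7, 0.9)
  p_r <- c(0.5, 0.6, 0.2)
  adhered_a <- c(FALSE, FALSE, TRUE)
  adhered_b <- c(TRUE, TRUE, TRUE)
  out <- bond_sweep_ref(pairs, bonded, stage, p_dis, p_r, adhered_a, adhered_b)
  # pair 1: unbonded, surface class, 0.5 >= 0.4 -> forms
  # pair 2: unbonded, pp class with adhered partner, 0.6 < 0.7 -> no bond
  # pair 3: bonded stage 1, 0.2 < 0.9 -> breaks
  expect_identical(out, c(TRUE, FALSE, FALSE))
  # stage-2 bonds survive any draw
  out2 <- bond_sweep_ref(pairs, bonded, c(NA, NA, 2), p_dis, p_r,
                         adhered_a, adhered_b)
  expect_true(out2[3])
})

test_that("engine sweep with stubbed P_dis matches the all-or-nothing limits", {
  sys <- adhesion_fixture()
  n <- nrow(sys$x)
  adh0 <- adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80),
                          k0 = c(120, 120), p_dis_override = 0)
  run <- dpd_run(sys, interaction_table(), n_steps = 1, dt = 0.01, seed = 5,
                 adhesion = adh0)
  # P_dis = 0: every platelet-coated candidate pair bonds (P_r >= 0 always)
  expect_gt(nrow(run$bonds), 0)
  platelet_id <- n  # fixture places the platelet last
  expect_true(all(run$bonds[, "b"] == platelet_id))
  expect_equal(run$activation[run$kind == 3L], 1L)
  # P_dis = 1: all stage-1 bonds break and none form
  adh1 <- adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80),
                          k0 = c(120, 120), p_dis_override = 1)
  run2 <- dpd_run(sys, interaction_table(), n_steps = 2, dt = 0.01, seed = 5,
                  adhesion = adh1, bonds = run$bonds)
  expect_equal(nrow(run2$bonds), 0)
})

test_that("stage-2 bonds are permanent and confer adhered_stage2 state", {
  sys <- adhesion_fixture()
  n <- nrow(sys$x)
  # pre-existing stage-2 bond platelet <-> coated particle
  b0 <- matrix(c(31, n, 1, 2, 0), 1)
  adh1 <- adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80),
                          k0 = c(120, 120), p_dis_override = 1)
  run <- dpd_run(sys, interaction_table(), n_steps = 50, dt = 0.01, seed = 9,
                 adhesion = adh1, bonds = b0)
  expect_equal(nrow(run$bonds), 1)
  expect_equal(unname(run$bonds[1, "stage"]), 2)
  expect_equal(run$activation[run$id == n], 2L)
})

test_that("stage-1 bonds older than t_stage2 are promoted", {
  sys <- adhesion_fixture()
  n <- nrow(sys$x)
  b0 <- matrix(c(31, n, 1, 1, 0), 1)  # stage 1, formed at t = 0
  adh <- adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80),
                         k0 = c(120, 120), t_stage2 = 0.05, p_dis_override = 0)
  run <- dpd_run(sys, interaction_table(), n_steps = 10, dt = 0.01, seed = 9,
                 adhesion = adh, bonds = b0)
  b <- run$bonds
  expect_equal(unname(b[b[, "a"] == 31 & b[, "b"] == n, "stage"]), 2)
  ev <- run$events
  expect_true(any(ev[, "type"] == 3))  # a promotion event was logged
})

test_that("bond forces are equal and opposite and replace the DPD pair force", {
  # two platelets bonded at r = 0.8 (attractive range), at rest
  x <- rbind(c(5, 5, 5), c(5.8, 5, 5))
  sys <- particle_system(x, matrix(0, 2, 3), c(3L, 3L), box = c(10, 10, 10))
  tab0 <- interaction_table(kBT = 0)
  adh <- adhesion_params(a0 = c(50, 400), gamma_p = c(4.5, 80), k0 = c(0, 0))
  b0 <- matrix(c(1, 2, 0, 1, 0), 1)
  f <- dpd_forces(sys, tab0, adhesion = adh, bonds = b0)$force
  expect_equal(f[1, ], -f[2, ])
  # magnitude equals the elastic law (viscous term zero at rest); the
  # negative signed magnitude pulls particle 1 toward its partner at +x
  expect_equal(f[1, 1], -elastic_bond_force(0.8, visco_params(50, 4.5)),
               tolerance = 1e-12)
  # unbonded: plain DPD repulsion instead
  f2 <- dpd_forces(sys, tab0)$force
  expect_equal(f2[1, 1], -weight_conservative(0.8, 10), tolerance = 1e-12)
})

test_that("the detachment load on an isolated platelet is the body force", {
  x <- matrix(c(5, 5, 5), 1)
  sys <- particle_system(x, matrix(0, 1, 3), 3L, box = c(10, 10, 10))
  f <- dpd_forces(sys, interaction_table(kBT = 0), body_force = 0.45)
  expect_equal(f$nonbond_force[1, ], c(0.45, 0, 0))
})
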