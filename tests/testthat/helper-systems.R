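# Small fixture systems built in code.

# random periodic bulk fluid (reflective y but wall-free: used where the y
# boundary is irrelevant or the test tracks x/z momentum only)
bulk_fluid <- function(n = 200, L = 5, seed = 1, kBT = 1) {
  set.seed(seed)
  x <- cbind(runif(n, 0, L), runif(n, 0, L), runif(n, 0, L))
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  v <- sweep(v, 2, colMeans(v))
  particle_system(x, v, 0L, box = c(L, L, L), wall_pad = 0)
}

# a platelet hovering over a few coated particles, with plasma around it
adhesion_fixture <- function(seed = 1) {
  set.seed(seed)
  coated <- cbind(c(4.5, 5.0, 5.5, 5.0), -0.25, c(5.0, 4.6, 5.0, 5.4))
  platelet <- matrix(c(5, 0.4, 5), 1)
  plasma <- cbind(runif(30, 0, 10), runif(30, 0.5, 9.5), runif(30, 0, 10))
  x <- rbind(plasma, coated, platelet)
  kind <- c(rep(0L, 30), rep(2L, 4), 3L)
  particle_system(x, matrix(0, nrow(x), 3), kind, box = c(10, 10, 10))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_equal(object, expected, tolerance = tol)
}

table1_units <- function() dpd_units(5e-6, 4.14e-21, 4.17e-14)
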