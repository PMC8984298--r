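test_that("density binning conserves mass and assigns the nearest node", {
  grid <- spheroid_grid(11, 200)  # h = 20
  expect_equal(sum(bin_density(agent_table(), grid)), 0)

  # one agent exactly at a node
  a <- agent_table(0, 0, 0, "R", 1)
  v <- bin_density(a, grid)
  expect_equal(v[6, 6, 6], 1 / 20^3)
  expect_equal(sum(v) * 20^3, 1)

  # nearest-node assignment is locally constant: nudges < h/2 do nothing
  set.seed(5)
  n <- 200
  base <- agent_table(runif(n, -90, 90), runif(n, -90, 90),
                      runif(n, -90, 90), rep("R", n), 1)
  v1 <- bin_density(base, grid)
  nudged <- base
  # move each agent 40% of the way toward its assigned node
  near <- function(u) round(u / 20) * 20
  nudged$x <- base$x + 0.4 * (near(base$x) - base$x)
  nudged$y <- base$y + 0.4 * (near(base$y) - base$y)
  nudged$z <- base$z + 0.4 * (near(base$z) - base$z)
  expect_identical(bin_density(nudged, grid), v1)
  expect_equal(sum(v1) * 20^3, n)
})

test_that("trivial nutrient solves: no consumption means c = 1 everywhere", {
  grid <- spheroid_grid(9, 160)
  v0 <- array(0, dim = c(9, 9, 9))
  expect_equal(max(abs(solve_nutrient(v0, 0.15, grid) - 1)), 0,
               tolerance = 1e-9)
  set.seed(1)
  a <- agent_table(runif(50, -60, 60), runif(50, -60, 60),
                   runif(50, -60, 60), rep("R", 50), 1)
  v <- bin_density(a, grid)
  expect_equal(max(abs(solve_nutrient(v, 0, grid) - 1)), 0, tolerance = 1e-9)
})

test_that("solver matches a dense direct solve to 1e-10 on small grids", {
  skip_if_not_installed("Matrix")
  set.seed(21)
  for (I in c(9, 21)) {
    grid <- spheroid_grid(I, 400)
    n <- 400
    a <- agent_table(runif(n, -150, 150), runif(n, -150, 150),
                     runif(n, -150, 150), rep("R", n), 1)
    v <- bin_density(a, grid)
    alpha <- 0.02
    cc <- solve_nutrient(v, alpha, grid, tol = 1e-14, maxit = 5000)
    sys <- dense_nutrient_system(v, grid, alpha)
    ref <- as.numeric(Matrix::solve(sys$A, sys$b))
    expect_lt(max(abs(cc[sys$lin] - ref)) / max(abs(ref)), 1e-10)
  }
})

test_that("uniform consumption ball matches the 1-D radial oracle within 2%", {
  # compact ball of uniform density, far-field boundary; the oracle is
  # resolved finely (dr = 1 um) so its own truncation error at the
  # consumption discontinuity does not pollute the comparison
  grid <- spheroid_grid(41, 2000)            # h = 50 um
  R <- 200
  v0 <- 5e-4
  nodes <- grid$nodes
  rr <- sqrt(outer(outer(nodes^2, nodes^2, `+`), nodes^2, `+`))
  v <- array(ifelse(rr <= R, v0, 0), dim = dim(rr))
  alpha <- 0.15
  cc <- solve_nutrient(v, alpha, grid, tol = 1e-10)
  ora <- radial_nutrient_oracle(function(r) ifelse(r <= R, v0, 0),
                                alpha, rmax = 1000, dr = 1)
  # compare along the +x axis (node centre to face)
  axis_vals <- cc[21:41, 21, 21]
  osub <- ora[seq(1, 1001, by = grid$h)]
  expect_equal(length(axis_vals), length(osub))
  expect_lt(max(abs(axis_vals - osub) / osub), 0.02)
})

test_that("maximum principle and comparison principle hold", {
  set.seed(31)
  grid <- spheroid_grid(9, 160)
  n <- 150
  a <- agent_table(runif(n, -60, 60), runif(n, -60, 60),
                   runif(n, -60, 60), rep("R", n), 1)
  v <- bin_density(a, grid)
  c1 <- solve_nutrient(v, 0.15, grid, tol = 1e-12)
  expect_gt(min(c1), 0)
  expect_equal(max(c1), 1)  # attained on the boundary
  # more consumption never raises c anywhere
  c2 <- solve_nutrient(v, 0.30, grid, tol = 1e-12)
  expect_true(all(c2 <= c1 + 1e-9))
  # more agents never raise c anywhere
  extra <- agent_table(runif(50, -60, 60), runif(50, -60, 60),
                       runif(50, -60, 60), rep("R", 50), 1)
  v2 <- v + bin_density(extra, grid)
  c3 <- solve_nutrient(v2, 0.15, grid, tol = 1e-12)
  expect_true(all(c3 <= c1 + 1e-9))
})

test_that("warm-started and cold-started solves agree to solver tolerance", {
  set.seed(41)
  grid <- spheroid_grid(13, 260)
  a <- agent_table(runif(300, -100, 100), runif(300, -100, 100),
                   runif(300, -100, 100), rep("R", 300), 1)
  v <- bin_density(a, grid)
  cold <- solve_nutrient(v, 0.15, grid, tol = 1e-12)
  warm <- solve_nutrient(v, 0.15, grid, warm_start = cold * 0.9 + 0.05,
                         tol = 1e-12)
  expect_equal(as.numeric(warm), as.numeric(cold), tolerance = 1e-8)
})

test_that("trilinear sampling reproduces nodal, constant and edge-midpoint values", {
  grid <- spheroid_grid(5, 400)  # h = 100, nodes at -200,-100,0,100,200
  cc <- array(runif(125), dim = c(5, 5, 5))
  # exactly at a node
  expect_equal(sample_field(cbind(0, -100, 100), cc, grid), cc[3, 2, 4])
  # constant field anywhere
  c0 <- array(0.37, dim = c(5, 5, 5))
  expect_equal(sample_field(cbind(13.7, -42.1, 99.9), c0, grid), 0.37)
  # midpoint of an edge averages the endpoints
  cc[3, 3, 3] <- 0.2
  cc[4, 3, 3] <- 0.6
  expect_equal(sample_field(cbind(50, 0, 0), cc, grid), 0.4)
  # outside the grid is an error
  expect_error(sample_field(cbind(201, 0, 0), cc, grid), "outside")
})

test_that("a nearer far-field boundary enriches the spheroid core", {
  # same late-stage cell ball solved on a reduced and an extended domain
  # (identical 20-um spacing): the closer c = 1 boundary must raise the
  # core concentration, the mechanism that delays starvation-driven death
  # on reduced domains
  ball <- annulus_spec(0, 0, 250, density_outer = 1e-3, seed = 12)
  a <- make_annulus_spheroid(ball)
  g_small <- spheroid_grid(61, 1200)
  g_large <- spheroid_grid(121, 2400)
  c_small <- solve_nutrient(bin_density(a, g_small), 0.15, g_small)
  c_large <- solve_nutrient(bin_density(a, g_large), 0.15, g_large)
  expect_gt(min(c_small), min(c_large))
  # centre values, sampled at the same physical point
  ctr_small <- sample_field(cbind(0, 0, 0), c_small, g_small)
  ctr_large <- sample_field(cbind(0, 0, 0), c_large, g_large)
  expect_gt(ctr_small, ctr_large)
})

test_that("equatorial plane export round-trips node values", {
  grid <- spheroid_grid(9, 160)
  f <- make_radial_field(function(r) pmin(r / 200, 1), grid)
  path <- withr::local_tempfile(fileext = ".csv")
  export_equatorial_plane(f, grid, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 81)
  got <- df$c[df$x_um == 40 & df$y_um == -20]
  expect_equal(got, sqrt(40^2 + 20^2) / 200)
})
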