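test_that("rasterization maps agents to discs in the right channel and place", {
  p <- spheroid_params(L = 200, ro_init = 50, I = 5)
  # empty slab -> background only
  a0 <- agent_table(0, 0, 40, "R", 1)  # outside the +-6 um equatorial slab
  img0 <- rasterize_cross_section(a0, p, "equator")
  expect_equal(sum(img0), 0)
  # one red agent at the origin -> a ~12 px disc centred mid-image
  a1 <- agent_table(0, 0, 0, "R", 1)
  img1 <- rasterize_cross_section(a1, p, "equator")
  expect_equal(sum(img1[, , c("yellow", "green", "dead")]), 0)
  red <- img1[, , "red"]
  on <- which(red > 0, arr.ind = TRUE)
  expect_equal(colMeans(on), c(row = 101, col = 101), tolerance = 0.01)
  expect_equal(sum(red > 0), pi * 6^2, tolerance = 0.05)
  # overlapping discs cover less than twice the single-disc area
  a2 <- agent_table(c(0, 6), c(0, 0), c(0, 0), c("R", "R"), 1)
  img2 <- rasterize_cross_section(a2, p, "equator")
  expect_lt(sum(img2[, , "red"] > 0), 2 * sum(red > 0))
  # dead channel
  imgd <- rasterize_cross_section(a0, p, "equator",
                                  deaths = tibble::tibble(x = 0, y = 0, z = 0))
  expect_gt(sum(imgd[, , "dead"]), 0)
})

test_that("radii recovery on the three-zone fixture across 20 seeds", {
  p <- spheroid_params(L = 600, ro_init = 200, I = 5)
  for (seed in 1:20) {
    spec <- annulus_spec(r_necrotic = 50, r_arrested = 100, r_outer = 200,
                         seed = seed)
    a <- make_annulus_spheroid(spec)
    img <- rasterize_cross_section(a, p, "equator")
    est <- estimate_radii(img)
    expect_lt(abs(est$ro_um - 200), 8)
    expect_lt(abs(est$ra_um - 100), 8)
    expect_lt(abs(est$rn_um - 50), 8)
    expect_true(est$ro_um > est$ra_um && est$ra_um >= est$rn_um)
  }
})

test_that("degenerate images: full mixed ball and a single disc", {
  p <- spheroid_params(L = 600, ro_init = 200, I = 5)
  spec <- annulus_spec(r_necrotic = 0, r_arrested = 0, r_outer = 150,
                       seed = 7)
  a <- make_annulus_spheroid(spec)
  est <- estimate_radii(rasterize_cross_section(a, p, "equator"))
  expect_equal(est$ro_um, 150, tolerance = 0.07)
  expect_equal(est$rn_um, 0)
  expect_true(is.na(est$ra_um))  # no arrested region in a mixed ball

  single <- agent_table(0, 0, 0, "G", 1)
  est1 <- estimate_radii(rasterize_cross_section(single, p, "equator"))
  expect_lt(est1$ro_um, 8)
  expect_equal(est1$rn_um, 0)

  empty <- rasterize_cross_section(agent_table(), p, "equator")
  expect_error(estimate_radii(empty), "empty image")
})

test_that("radial profiles: normalization, nutrient passthrough, conservation", {
  # all-green ball: the green profile has maximum exactly 1
  p <- spheroid_params(L = 600, ro_init = 150, I = 9,
                       Ng0 = 30000, Nr0 = 0, Ny0 = 0, alpha = 0)
  set.seed(8)
  st <- initialize_spheroid(p)
  sim <- structure(list(snapshots = list("0" = st$agents), params = p),
                   class = "spheroid_sim")
  prof <- radial_profiles(sim, times = 0, bin_width = 25,
                          ro_method = "max_radius")
  green <- prof[prof$subpopulation == "green", ]
  expect_equal(max(green$mean), 1)
  # with alpha = 0 the nutrient profile is constant 1
  nut <- prof[prof$subpopulation == "nutrient", ]
  expect_equal(nut$mean, rep(1, nrow(nut)), tolerance = 1e-7)
  # counts conserved before normalization
  cons <- attr(prof, "conserved_counts")
  expect_equal(cons$n, p$N0)
})

test_that("layered fixture profiles order subpopulations with depth", {
  p <- spheroid_params(L = 600, ro_init = 200, I = 9)
  spec <- annulus_spec(r_necrotic = 0, r_arrested = 120, r_outer = 200,
                       density_mid = 8e-4, density_outer = 8e-4, seed = 3)
  a <- make_annulus_spheroid(spec)
  a$cached_c <- 0.2  # deep interior: red agents count as arrested
  sim <- structure(list(snapshots = list("0" = a), params = p),
                   class = "spheroid_sim")
  prof <- radial_profiles(sim, times = 0, bin_width = 20,
                          ro_method = "max_radius")
  arr <- prof[prof$subpopulation == "red_arrested", ]
  grn <- prof[prof$subpopulation == "green", ]
  # arrested red peaks deep, green peaks near the periphery
  expect_gt(arr$p_um[which.max(arr$mean)], 100)
  expect_lt(grn$p_um[which.max(grn$mean)], 60)
})

test_that("ensemble statistics are pointwise mean and n-1 sd", {
  t1 <- tibble::tibble(time_h = 0:3, n_living = c(1, 2, 3, 4))
  t2 <- tibble::tibble(time_h = 0:3, n_living = c(3, 2, 1, 0))
  st <- ensemble_stats(list(t1, t2))
  expect_equal(st$n_living_mean, c(2, 2, 2, 2))
  expect_equal(st$n_living_sd, c(sd(c(1, 3)), 0, sd(c(3, 1)), sd(c(4, 0))))
  # identical tables -> zero sd
  st2 <- ensemble_stats(list(t1, t1, t1))
  expect_equal(st2$n_living_sd, rep(0, 4))
  # misaligned grids are rejected
  t3 <- tibble::tibble(time_h = c(0, 1, 2, 4), n_living = 1:4)
  expect_error(ensemble_stats(list(t1, t3)), "misaligned")
  # sample sd of standard normal draws stays within chi-square bounds
  set.seed(10)
  tabs <- lapply(1:10, function(i)
    tibble::tibble(time_h = 1:25, v = rnorm(25)))
  stn <- ensemble_stats(tabs)
  expect_true(all(stn$v_sd > 0.4 & stn$v_sd < 1.9))
})

test_that("radial field fixture: shell averages follow a linear ramp", {
  grid <- spheroid_grid(41, 400)
  ramp <- function(r) pmin(r / 200, 1)
  f <- make_radial_field(ramp, grid)
  pos <- cbind(c(50, 100, 150), 0, 0)
  expect_equal(sample_field(pos, f, grid), c(0.25, 0.5, 0.75),
               tolerance = 0.02)
  step <- function(r) ifelse(r < 100, 0.2, 0.9)
  fs <- make_radial_field(step, grid)
  expect_equal(sample_field(cbind(c(50, 150), 0, 0), fs, grid), c(0.2, 0.9))
  expect_error(make_radial_field(function(r) r, grid), "\\[0, 1\\]")
})
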