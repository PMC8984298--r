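test_that("initialization reproduces the requested composition and geometry", {
  p <- tiny_params()
  set.seed(1)
  s <- initialize_spheroid(p)
  a <- s$agents
  expect_equal(nrow(a), p$N0)
  expect_equal(sum(a$phase == "R"), p$Nr0)
  expect_equal(sum(a$phase == "Y"), p$Ny0)
  expect_equal(sum(a$phase == "G"), p$Ng0)
  r <- sqrt(a$x^2 + a$y^2 + a$z^2)
  expect_true(all(r <= p$ro_init))
  expect_true(all(a$cached_c >= 0 & a$cached_c <= 1))
  expect_equal(a$cached_c, sample_field(a, s$field, s$grid))
})

test_that("initial positions are volume-uniform in the ball", {
  p <- spheroid_params(N0 = 30000, Nr0 = 20911, Ny0 = 995, Ng0 = 8094,
                       ro_init = 245, L = 600, I = 5)
  set.seed(2)
  s <- initialize_spheroid(p, solve_field = FALSE)
  r <- sqrt(s$agents$x^2 + s$agents$y^2 + s$agents$z^2)
  ks <- suppressWarnings(stats::ks.test(r, function(q) (q / 245)^3))
  expect_gt(ks$p.value, 0.01)
})

test_that("an empty window leaves the state unchanged except time", {
  p <- tiny_params()
  set.seed(3)
  s <- initialize_spheroid(p)
  s$agents <- s$agents[0, ]
  s2 <- gillespie_window(s, p, 1)
  expect_equal(s2$time, 1)
  expect_equal(nrow(s2$agents), 0)
  expect_true(is.na(attr(s2, "t_first_event")))
})

test_that("all-zero rates freeze positions and phases", {
  p <- spheroid_params(Rr_max = 0, Ry = 0, Rg = 0, m_max = 0, m_min = 0,
                       d_max = 0, d_min = 0,
                       N0 = 200, Nr0 = 100, Ny0 = 50, Ng0 = 50,
                       L = 600, I = 9, ro_init = 80, T = 2,
                       validate = FALSE)
  set.seed(4)
  s <- initialize_spheroid(p)
  before <- s$agents
  s2 <- gillespie_window(s, p, 2)
  expect_equal(s2$time, 2)
  expect_identical(s2$agents$x, before$x)
  expect_identical(s2$agents$phase, before$phase)
  expect_equal(unname(s2$events), rep(0, 5))
})

test_that("single-agent waiting times are exponential with the frozen rate", {
  # G1 commitment clock: everything else switched off
  p <- spheroid_params(Ry = 0, Rg = 0, m_max = 0, m_min = 0,
                       d_max = 0, d_min = 0, L = 600, I = 5, ro_init = 80,
                       validate = FALSE)
  grid <- grid_from_params(p)
  field <- array(1, dim = rep(5, 3))
  base <- structure(list(
    time = 0,
    agents = agent_table(0, 0, 0, "R", 1),
    deaths = tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                            time_h = numeric()),
    field = field, grid = grid,
    events = c(n_r2y = 0, n_y2g = 0, n_mitosis = 0, n_death = 0,
               n_migration = 0)), class = "spheroid_state")
  set.seed(5)
  waits <- replicate(1e4, {
    attr(gillespie_window(base, p, 500), "t_first_event")
  })
  expect_true(all(!is.na(waits)))
  rate <- rate_red_to_yellow(1, p)
  expect_gt(suppressWarnings(stats::ks.test(waits, "pexp",
                                            rate = rate))$p.value, 0.01)

  # death clock at an arbitrary frozen concentration
  p2 <- spheroid_params(Rr_max = 1e-12, Ry = 1e-12, Rg = 1e-12,
                        m_max = 0, m_min = 0, d_max = 0.3, d_min = 0.3,
                        L = 600, I = 5, ro_init = 80, validate = FALSE)
  base2 <- base
  base2$agents$cached_c <- 0.5
  set.seed(6)
  waits2 <- replicate(1e4, {
    attr(gillespie_window(base2, p2, 500), "t_first_event")
  })
  expect_gt(suppressWarnings(stats::ks.test(waits2, "pexp",
                                            rate = 0.3))$p.value, 0.01)
})

test_that("bookkeeping conservation and phase-order event counts hold", {
  p <- tiny_params(T = 8)
  sim <- simulate_spheroid(p, snapshot_every = Inf)
  ev <- sim$final$events
  last <- sim$series[nrow(sim$series), ]
  expect_equal(last$n_living + last$n_dead,
               p$N0 + unname(ev["n_mitosis"]))
  # agents traverse phases in order; initial Y and G stocks offset the counts
  expect_lte(ev[["n_y2g"]], ev[["n_r2y"]] + p$Ny0)
  expect_lte(ev[["n_mitosis"]], ev[["n_y2g"]] + p$Ng0)
  # series partitions
  expect_equal(sim$series$n_red + sim$series$n_yellow + sim$series$n_green,
               sim$series$n_living)
  expect_equal(sim$series$n_arrested + sim$series$n_cycling_red,
               sim$series$n_red)
})

test_that("identical seeds give bit-identical runs", {
  p <- tiny_params(T = 3)
  s1 <- simulate_spheroid(p)
  s2 <- simulate_spheroid(p)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$final$agents, s2$final$agents)
  expect_identical(s1$deaths, s2$deaths)
  p2 <- tiny_params(T = 3, seed = 43)
  s3 <- simulate_spheroid(p2)
  expect_false(identical(s1$final$agents, s3$final$agents))
})

test_that("well-mixed ensemble mean tracks the linear compartment ODE", {
  nrep <- 20
  p <- well_mixed_params(N0 = 1000, T = 48)
  finals <- matrix(NA_real_, nrep, 3)
  for (i in seq_len(nrep)) {
    pi <- well_mixed_params(N0 = 1000, T = 48, seed = 100 + i)
    sim <- simulate_spheroid(pi, snapshot_every = Inf)
    last <- sim$series[nrow(sim$series), ]
    finals[i, ] <- c(last$n_red, last$n_yellow, last$n_green)
  }
  expected <- wm_ode_mean(c(p$Nr0, p$Ny0, p$Ng0), 48, p)
  se <- apply(finals, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(finals) - expected) <= 3 * se))
})

test_that("growth dominates at high nutrient: living population increases", {
  p <- well_mixed_params(N0 = 500, T = 24, seed = 9)
  sim <- simulate_spheroid(p, snapshot_every = Inf)
  expect_gt(sim$series$n_living[nrow(sim$series)], p$N0)
})
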