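# Small consistent configurations used across tests.

# a light, fast-to-simulate spheroid
tiny_params <- function(...) {
  spheroid_params(N0 = 500, Nr0 = 350, Ny0 = 20, Ng0 = 130,
                  L = 600, I = 16, ro_init = 80, T = 4, seed = 42, ...)
}

# well-mixed configuration: no consumption, so c = 1 everywhere
well_mixed_params <- function(N0 = 1000, T = 48, seed = 1, ...) {
  frac <- c(20911, 995, 8094) / 30000
  counts <- floor(frac * N0)
  counts[1] <- counts[1] + (N0 - sum(counts))
  spheroid_params(N0 = N0, Nr0 = counts[1], Ny0 = counts[2],
                  Ng0 = counts[3], alpha = 0,
                  L = 2400, I = 9, ro_init = 120, T = T, seed = seed, ...)
}

# independent brute-force evaluation of the five rate laws, written with
# exp/log arithmetic so it shares no code path with the package functions
oracle_rates <- function(c, p) {
  pw <- function(base, e) ifelse(base > 0, exp(e * log(base)), 0)
  hr <- pw(c, p$eta1) / (pw(p$c_a, p$eta1) + pw(c, p$eta1))
  hm <- pw(c, p$eta2) / (pw(p$c_m, p$eta2) + pw(c, p$eta2))
  hd <- pw(c, p$eta3) / (pw(p$c_d, p$eta3) + pw(c, p$eta3))
  list(r2y = p$Rr_max * hr,
       y2g = rep(p$Ry, length(c)),
       g2r = rep(p$Rg, length(c)),
       mig = (p$m_max - p$m_min) * hm + p$m_min,
       dth = (p$d_max - p$d_min) * (1 - hd) + p$d_min)
}

# mean of the well-mixed branching process: linear ODE solved by
# eigen-decomposition. Compartments (Nr, Ny, Ng); mitosis converts one
# green into two reds; each compartment loses mass at the death rate d1.
wm_ode_mean <- function(n0, t, p) {
  Rr1 <- rate_red_to_yellow(1, p)
  d1 <- rate_death(1, p)
  A <- matrix(c(-Rr1 - d1, 0,          2 * p$Rg,
                Rr1,       -p$Ry - d1, 0,
                0,         p$Ry,       -p$Rg - d1),
              nrow = 3, byrow = TRUE)
  e <- eigen(A)
  co <- solve(e$vectors, n0)
  Re(e$vectors %*% (co * exp(e$values * t)))[, 1]
}

# build the nutrient linear system densely (same stencil) for direct-solve
# oracles on small grids; returns list(A, b, interior_index)
dense_nutrient_system <- function(v, grid, alpha) {
  I <- grid$I; h <- grid$h
  ih2 <- 1 / h^2
  interior <- expand.grid(i = 2:(I - 1), j = 2:(I - 1), k = 2:(I - 1))
  id <- function(i, j, k) (i - 1) + I * (j - 1) + I * I * (k - 1) + 1
  n <- nrow(interior)
  lin <- id(interior$i, interior$j, interior$k)
  pos <- integer(I^3); pos[lin] <- seq_len(n)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  b <- numeric(n)
  for (q in seq_len(n)) {
    i <- interior$i[q]; j <- interior$j[q]; k <- interior$k[q]
    trip_i <- c(trip_i, q); trip_j <- c(trip_j, q)
    trip_x <- c(trip_x, 6 * ih2 + alpha * v[id(i, j, k)])
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      if (ii %in% c(1, I) || jj %in% c(1, I) || kk %in% c(1, I)) {
        b[q] <- b[q] + ih2
      } else {
        trip_i <- c(trip_i, q)
        trip_j <- c(trip_j, pos[id(ii, jj, kk)])
        trip_x <- c(trip_x, -ih2)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n, n))
  list(A = A, b = b, lin = lin)
}

# 1-D spherically symmetric finite-difference oracle for a radial
# consumption profile: (1/r^2) (r^2 c')' = alpha * v(r) * c, c'(0) = 0,
# c(rmax) = 1. Conservative discretization; returns c on nodes r = i*dr.
radial_nutrient_oracle <- function(vfun, alpha, rmax, dr) {
  r <- seq(0, rmax, by = dr)
  n <- length(r)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (q in 1:(n - 1)) {
    if (q == 1) {
      # r = 0: symmetric limit, laplacian -> 6 (c_2 - c_1) / dr^2
      A[1, 1] <- -6 / dr^2 - alpha * vfun(0)
      A[1, 2] <- 6 / dr^2
    } else {
      rp <- (r[q] + dr / 2)^2 / (r[q]^2 * dr^2)
      rm <- (r[q] - dr / 2)^2 / (r[q]^2 * dr^2)
      A[q, q - 1] <- rm
      A[q, q] <- -(rp + rm) - alpha * vfun(r[q])
      A[q, q + 1] <- rp
    }
  }
  A[n, n] <- 1
  b[n] <- 1
  drop(solve(A, b))
}
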