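#' Synthetic three-zone spheroid fixtures
#'
#' Deterministic generators of point clouds with known internal structure,
#' used to exercise the image-quantification layer without running full
#' simulations. The generated spheroid mirrors the layered anatomy of a
#' late-stage spheroid: an empty (necrotic) core at radii below
#' `r_necrotic`, a red-only (arrested) shell for
#' `r_necrotic <= r < r_arrested`, and a colour-mixed proliferative rim for
#' `r_arrested <= r < r_outer`.
#'
#' @param r_necrotic,r_arrested,r_outer region breakpoints, um, with
#'   `0 <= r_necrotic <= r_arrested < r_outer`.
#' @param density_mid,density_outer agent densities of the red-only shell
#'   and of the mixed rim, cells per cubic um. The default 1e-3 matches
#'   the cell density a mature simulated spheroid reaches, which is the
#'   anatomy the fixture emulates.
#' @param mix named proportions of `R`, `Y`, `G` in the rim.
#' @param seed RNG seed making the fixture reproducible bit-for-bit.
#' @return An `annulus_spec` list.
#' @export
annulus_spec <- function(r_necrotic = 50, r_arrested = 100, r_outer = 200,
                         density_mid = 1e-3, density_outer = 1e-3,
                         mix = c(R = 0.5, Y = 0.15, G = 0.35), seed = 1) {
  stopifnot(0 <= r_necrotic, r_necrotic <= r_arrested, r_arrested < r_outer,
            density_mid >= 0, density_outer >= 0,
            abs(sum(mix) - 1) < 1e-9)
  structure(list(r_necrotic = r_necrotic, r_arrested = r_arrested,
                 r_outer = r_outer, density_mid = density_mid,
                 density_outer = density_outer, mix = mix, seed = seed),
            class = "annulus_spec")
}

#' @rdname annulus_spec
#' @param spec an `annulus_spec`.
#' @return `make_annulus_spheroid()`: an [agent_table()] with positions
#'   volume-uniform within each region at the stated densities.
#' @export
make_annulus_spheroid <- function(spec) {
  stopifnot(inherits(spec, "annulus_spec"))
  set.seed(spec$seed)
  shell_points <- function(r_lo, r_hi, density) {
    vol <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
    n <- round(density * vol)
    if (n == 0) return(NULL)
    dirs <- random_unit_direction(n)
    r <- (runif(n, r_lo^3, r_hi^3))^(1 / 3)  # volume-uniform in the shell
    list(x = r * dirs[, 1], y = r * dirs[, 2], z = r * dirs[, 3], n = n)
  }
  mid <- shell_points(spec$r_necrotic, spec$r_arrested, spec$density_mid)
  rim <- shell_points(spec$r_arrested, spec$r_outer, spec$density_outer)
  xs <- c(mid$x, rim$x); ys <- c(mid$y, rim$y); zs <- c(mid$z, rim$z)
  ph <- c(rep("R", mid$n %||% 0),
          if (!is.null(rim))
            sample(names(spec$mix), rim$n, replace = TRUE, prob = spec$mix))
  agent_table(xs %||% numeric(), ys %||% numeric(), zs %||% numeric(),
              ph %||% character())
}

#' Radially symmetric nodal field
#'
#' Builds a nutrient-like field whose nodal values are `profile(r)` with
#' `r` the distance from the domain centre; used to test interpolation and
#' shell averaging against closed forms.
#'
#' @param profile a function mapping radius (um) to a value in \[0, 1\]
#'   (vectorized).
#' @param grid a [spheroid_grid()].
#' @return An `I x I x I` numeric array.
#' @export
make_radial_field <- function(profile, grid) {
  nodes <- grid$nodes
  r <- sqrt(outer(outer(nodes^2, nodes^2, `+`), nodes^2, `+`))
  vals <- profile(r)
  if (any(vals < 0 | vals > 1))
    stop("profile values must lie in [0, 1]")
  array(vals, dim = c(grid$I, grid$I, grid$I))
}
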