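#' Ten measured initial spheroid radii
#'
#' The default sample of experimentally measured initial outer radii (um)
#' shipped for the variable-initial-radius ensemble experiment; their mean
#' is 245 um, matching the fixed-radius protocol.
#'
#' @return Numeric vector of length 10, um.
#' @export
initial_radius_sample <- function() {
  c(232.75, 235.47, 238.97, 242.19, 244.89,
    247.76, 247.93, 251.23, 251.48, 260.13)
}

#' Rescale the initial population to a new radius at constant density
#'
#' For the variable-initial-radius experiment, the initial agent density is
#' held constant, so a spheroid of radius `radius` starts with
#' `N0 * (radius / ro_init)^3` agents (rounded). The phase composition is
#' scaled proportionally with a largest-remainder correction so the three
#' counts are integers summing exactly to the new total.
#'
#' @param p a [spheroid_params()] object (the reference composition).
#' @param radius new initial radius, um.
#' @return A new `spheroid_params` with rescaled `N0`, `Nr0`, `Ny0`, `Ng0`
#'   and `ro_init = radius`.
#' @export
rescale_initial_population <- function(p, radius) {
  stopifnot(radius > 0)
  n_new <- round(p$N0 * (radius / p$ro_init)^3)
  frac <- c(p$Nr0, p$Ny0, p$Ng0) / p$N0
  raw <- frac * n_new
  base <- floor(raw)
  rem <- n_new - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  do.call(spheroid_params, utils::modifyList(unclass(p), list(
    N0 = n_new, Nr0 = base[1], Ny0 = base[2], Ng0 = base[3],
    ro_init = radius)))
}

#' Simulate an ensemble of spheroids
#'
#' Two protocols:
#'
#' * **identical initial conditions** (`radii = NULL`): `n` realizations of
#'   the same parameter set, differing only through the RNG — realization
#'   `i` uses seed `p$seed + i - 1`. Quantifies the variability intrinsic
#'   to the stochastic growth process.
#' * **variable initial radius** (`radii` given): one realization per
#'   radius, each rescaled to constant initial agent density via
#'   [rescale_initial_population()], mimicking measured spheroid-to-spheroid
#'   variability at the start of an experiment. The shipped default list is
#'   [initial_radius_sample()].
#'
#' @param p a [spheroid_params()] object.
#' @param n number of realizations (identical-conditions mode).
#' @param radii optional vector of initial radii (um) selecting the
#'   variable-radius mode; overrides `n`.
#' @param ... passed to [simulate_spheroid()].
#' @return An object of class `spheroid_ensemble`: list with `sims` (the
#'   realizations), `mode`, and `params`.
#' @export
simulate_ensemble <- function(p, n = 10, radii = NULL, ...) {
  mode <- if (is.null(radii)) "identical" else "variable_radius"
  if (mode == "variable_radius") {
    stopifnot(all(radii > 0))
    plist <- lapply(radii, function(r) rescale_initial_population(p, r))
  } else {
    plist <- rep(list(p), n)
  }
  sims <- purrr::imap(plist, function(pi, i) {
    pi$seed <- p$seed + i - 1
    simulate_spheroid(pi, ...)
  })
  structure(list(sims = sims, mode = mode, params = p, radii = radii),
            class = "spheroid_ensemble")
}

#' @export
print.spheroid_ensemble <- function(x, ...) {
  cat(sprintf("<spheroid_ensemble> %d realizations, %s initial conditions\n",
              length(x$sims),
              if (x$mode == "identical") "identical" else "variable-radius"))
  invisible(x)
}

#' Tidy an ensemble into stacked population series
#'
#' @param x a `spheroid_ensemble`.
#' @param ... unused.
#' @return All realizations' population series stacked with a
#'   `realization` column.
#' @export
tidy.spheroid_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$sims, function(s, i)
    dplyr::mutate(s$series, realization = i))
}

#' @rdname tidy.spheroid_ensemble
#' @return `glance()`: one row per realization (see
#'   [glance.spheroid_sim()]).
#' @export
glance.spheroid_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$sims, function(s, i)
    dplyr::mutate(glance(s), realization = i))
}

#' Ensemble mean/sd of the population series
#'
#' @param x a `spheroid_ensemble`.
#' @return Pointwise mean and sd of every population column (see
#'   [ensemble_stats()]).
#' @export
ensemble_series_stats <- function(x) {
  ensemble_stats(lapply(x$sims, function(s) s$series))
}

#' Ensemble mean/sd of the radii time series
#'
#' @param x a `spheroid_ensemble`.
#' @param plane cross-section selector.
#' @param ... passed to [radii_time_series()].
#' @return Pointwise mean and sd of `ro_um`, `ra_um`, `rn_um`.
#' @export
ensemble_radii_stats <- function(x, plane = "equator", ...) {
  ensemble_stats(lapply(x$sims, radii_time_series, plane = plane, ...))
}
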