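#' Rasterize a cross-section of the spheroid
#'
#' Mimics confocal cross-section imaging of the simulated spheroid: agents
#' within a thin slab around the chosen plane are drawn as filled discs of
#' one cell diameter (12 um = 12 pixels) into an `(L+1) x (L+1)` image at
#' 1 um per pixel, one channel per FUCCI phase plus a channel for recorded
#' death locations. Pixel (1, 1) maps to the domain corner
#' `(-L/2, -L/2)` in the plane.
#'
#' The equatorial plane is `z = 0`; the upper and lower planes default to
#' `z = +/- ro / 2`, with `ro` taken from `ro_hint` or, failing that, the
#' 99th percentile of the agents' radial distances.
#'
#' @param agents an [agent_table()].
#' @param p a [spheroid_params()] object (only `L` is used).
#' @param plane `"equator"`, `"upper"`, `"lower"`, or a numeric z (um).
#' @param deaths optional tibble of death locations (columns `x,y,z`).
#' @param slab_halfwidth half-thickness of the imaged slab, um (default
#'   6, half a cell diameter).
#' @param disc_diameter drawn agent diameter in pixels.
#' @param ro_hint outer radius used to position the upper/lower planes.
#' @return An `(L+1) x (L+1) x 4` integer count array (channels
#'   `red`, `yellow`, `green`, `dead`) of class `spheroid_image`, with the
#'   plane height stored in attribute `z_plane`.
#' @export
rasterize_cross_section <- function(agents, p, plane = "equator",
                                    deaths = NULL, slab_halfwidth = 6,
                                    disc_diameter = 12, ro_hint = NULL) {
  if (is.character(plane)) {
    plane <- match.arg(plane, c("equator", "upper", "lower"))
    zp <- if (plane == "equator") 0 else {
      ro <- ro_hint %||%
        unname(quantile(sqrt(agents$x^2 + agents$y^2 + agents$z^2), 0.99))
      if (plane == "upper") ro / 2 else -ro / 2
    }
  } else {
    zp <- as.numeric(plane)
  }
  npix <- as.integer(p$L) + 1L
  keep <- abs(agents$z - zp) <= slab_halfwidth
  px <- agents$x[keep]
  py <- agents$y[keep]
  ch <- phase_to_int(agents$phase[keep])
  if (!is.null(deaths) && nrow(deaths)) {
    dk <- abs(deaths$z - zp) <= slab_halfwidth
    px <- c(px, deaths$x[dk])
    py <- c(py, deaths$y[dk])
    ch <- c(ch, rep(3L, sum(dk)))
  }
  img <- cpp_rasterize(px, py, ch, npix, 4L, disc_diameter)
  dimnames(img) <- list(NULL, NULL, c("red", "yellow", "green", "dead"))
  attr(img, "z_plane") <- zp
  attr(img, "disc_diameter") <- disc_diameter
  class(img) <- c("spheroid_image", class(img))
  img
}

#' Estimate outer, arrested and necrotic radii from a cross-section image
#'
#' Edge detection on the rasterized cross-section, assuming approximate
#' circular symmetry of the slice:
#'
#' * **outer radius `ro`** — for 360 evenly spaced rays cast from the
#'   centroid of the living-cell foreground, the outermost foreground
#'   crossing; `ro` is the median over rays.
#' * **necrotic radius `rn`** — the radius of the largest central disc
#'   whose living-cell pixel coverage stays below `rn_coverage` (default
#'   10%). Viable tissue at typical densities covers roughly half of every
#'   central pixel with cell discs, whereas a genuine necrotic core is
#'   empty apart from the occasional straggler cell that has wandered in
#'   and not yet died, so the cumulative coverage separates the two regimes
#'   cleanly (a per-ray innermost-crossing rule is defeated by a single
#'   straggler disc near the centroid). A detected radius smaller than
#'   `rn_min` (default 14 um, just above one cell diameter) is reported as
#'   0: a "core" smaller than one cell is not a necrotic core.
#' * **arrested radius `ra`** — the cycling signal (yellow + green
#'   channels) is averaged over concentric annuli half a disc diameter
#'   wide; the rim level is the maximum coverage within two cell diameters
#'   of `ro`, and `ra` is the outer edge of the contiguous central run of
#'   annuli whose coverage is below half of that rim level. The
#'   half-maximum crossing localizes the arrest boundary without bias
#'   under the symmetric smearing that drawing cells as discs introduces.
#'   When no such central run exists (no arrested region), `ra` is `NA`.
#'
#' The ordering `ro > ra >= rn` is enforced on the returned estimate;
#' violations before enforcement are reported via a warning.
#'
#' @param img a `spheroid_image` from [rasterize_cross_section()].
#' @param n_rays number of rays.
#' @param rn_min,ra_min minimum detectable necrotic / arrested radius, um
#'   (a region smaller than one cell diameter is noise, not anatomy).
#' @param rn_coverage living coverage below which a central disc counts as
#'   necrotic.
#' @param ra_threshold fraction of the rim cycling coverage below which an
#'   annulus counts as non-cycling (half-maximum by default).
#' @return A one-row tibble: `ro_um`, `ra_um`, `rn_um`, `z_plane`.
#' @export
estimate_radii <- function(img, n_rays = 360, rn_min = 14, ra_min = 14,
                           rn_coverage = 0.1, ra_threshold = 0.5) {
  npix <- dim(img)[1]
  living <- img[, , "red"] + img[, , "yellow"] + img[, , "green"]
  fg <- living > 0
  if (!any(fg)) stop("cannot estimate radii from an empty image")
  idx <- which(fg, arr.ind = TRUE)
  cx <- mean(idx[, 1]) - 1  # 0-based pixel coordinates
  cy <- mean(idx[, 2]) - 1

  cross <- cpp_ray_crossings(as.vector(fg), npix, cx, cy, as.integer(n_rays))
  outer <- cross[, 1]
  ro <- median(outer[outer >= 0])

  dd <- attr(img, "disc_diameter") %||% 12
  gx <- (seq_len(npix) - 1) - cx
  gy <- (seq_len(npix) - 1) - cy
  dist <- sqrt(outer(gx^2, gy^2, `+`))

  # necrotic radius: largest central disc mostly devoid of living pixels
  rbin <- pmin(floor(dist) + 1L, npix)  # 1 um radial bins
  npx_tot <- tabulate(rbin, nbins = npix)
  npx_liv <- tabulate(rbin[fg], nbins = npix)
  cumcov <- cumsum(npx_liv) / pmax(cumsum(npx_tot), 1)
  rmax_idx <- max(1L, floor(ro))
  ok <- which(cumcov[seq_len(rmax_idx)] < rn_coverage)
  rn <- if (length(ok)) max(ok) else 0
  if (!is.finite(rn) || rn < rn_min) rn <- 0

  # annular cycling coverage for the arrested radius
  cyc <- (img[, , "yellow"] + img[, , "green"]) > 0
  wa <- dd / 2                   # annulus width: half a cell diameter
  bin <- floor(dist / wa)
  nb <- floor(ro / wa)           # annuli fully inside the spheroid
  ra <- NA_real_
  if (nb >= 1) {
    sel <- bin < nb
    cov <- tapply(cyc[sel], bin[sel], mean)
    cov <- cov[order(as.integer(names(cov)))]
    rim <- max(cov[max(1, nb - 3):nb], na.rm = TRUE)
    below <- cov < ra_threshold * rim
    if (isTRUE(below[1])) {
      k <- which(!below)[1]
      run <- if (is.na(k)) length(below) else k - 1
      ra <- run * wa
      if (ra < ra_min) ra <- NA_real_
    }
  }

  # ordering invariant ro > ra >= rn
  if (!is.na(ra) && ra < rn) {
    warning("radii ordering violated before enforcement (ra < rn); clamping")
    ra <- rn
  }
  if (!is.na(ra) && ra >= ro) {
    warning("radii ordering violated before enforcement (ra >= ro); clamping")
    ra <- ro - 1
  }
  tibble::tibble(ro_um = ro, ra_um = ra, rn_um = rn,
                 z_plane = attr(img, "z_plane") %||% NA_real_)
}

#' Radii time series from simulation snapshots
#'
#' Runs the rasterization and edge-detection pipeline on each stored agent
#' snapshot of a simulation.
#'
#' @param sim a `spheroid_sim` from [simulate_spheroid()].
#' @param plane cross-section selector (see [rasterize_cross_section()]).
#' @param times snapshot times (h) to use; defaults to all snapshots.
#' @param ... passed to [estimate_radii()].
#' @return A tibble with one row per snapshot: `time_h`, `cross_section`,
#'   `ro_um`, `ra_um`, `rn_um`.
#' @export
radii_time_series <- function(sim, plane = "equator", times = NULL, ...) {
  snaps <- sim$snapshots
  tt <- as.numeric(names(snaps))
  if (!is.null(times)) {
    keep <- tt %in% times
    snaps <- snaps[keep]
    tt <- tt[keep]
  }
  purrr::map2_dfr(snaps, tt, function(a, t) {
    img <- rasterize_cross_section(a, sim$params, plane = plane)
    est <- estimate_radii(img, ...)
    tibble::tibble(time_h = t,
                   cross_section = if (is.character(plane)) plane else "custom",
                   ro_um = est$ro_um, ra_um = est$ra_um, rn_um = est$rn_um)
  })
}

#' Periphery-referenced radial profiles
#'
#' Radial structure of the spheroid expressed against depth from the
#' periphery, `p = ro - r`, so profiles of growing spheroids can be
#' overlaid. For each realization and requested time, living agents are
#' counted into spherical shells of the given width and divided by shell
#' volume; the subpopulations are cycling red, arrested red (see
#' [is_arrested()]), yellow and green. Profiles are averaged across
#' realizations, and all agent profiles are normalized by the one global
#' maximum over subpopulations, shells and requested times. The nutrient
#' profile is the shell average of `c` (already in \[0, 1\], not
#' renormalized); the field is re-solved from each snapshot's density, which
#' reproduces it exactly since the field is a deterministic function of the
#' agent positions.
#'
#' @param sims a list of `spheroid_sim` objects (identically prepared
#'   realizations) or a single `spheroid_sim`.
#' @param times snapshot times (h) to profile; default all shared snapshots.
#' @param bin_width shell width, um.
#' @param ro_method `"raster"` (edge-detection [estimate_radii()] outer
#'   radius at the equator) or `"max_radius"` (maximum agent distance).
#' @return A tibble: `time_h`, `p_um` (shell centre depth), `subpopulation`,
#'   `mean`, `sd` (across realizations; `NA` for a single realization).
#' @export
radial_profiles <- function(sims, times = NULL, bin_width = 10,
                            ro_method = c("raster", "max_radius")) {
  if (inherits(sims, "spheroid_sim")) sims <- list(sims)
  ro_method <- match.arg(ro_method)
  p <- sims[[1]]$params
  grid <- grid_from_params(p)
  if (is.null(times))
    times <- as.numeric(names(sims[[1]]$snapshots))

  one <- function(sim, t) {
    a <- sim$snapshots[[format(t, trim = TRUE)]]
    if (is.null(a)) stop("no snapshot at t = ", t, " h")
    ro <- if (ro_method == "raster") {
      img <- rasterize_cross_section(a, p, "equator")
      estimate_radii(img)$ro_um
    } else max(sqrt(a$x^2 + a$y^2 + a$z^2))
    r <- sqrt(a$x^2 + a$y^2 + a$z^2)
    depth <- pmax(ro - r, 0)
    nb <- max(1L, ceiling(ro / bin_width))
    shell <- pmin(floor(depth / bin_width), nb - 1L)  # 0-based from periphery
    sub <- dplyr::case_when(
      a$phase == "Y" ~ "yellow",
      a$phase == "G" ~ "green",
      is_arrested(a, p) ~ "red_arrested",
      TRUE ~ "red_cycling")
    # shell volumes: shell k spans radius [ro-(k+1)w, ro-kw]
    hi <- ro - (0:(nb - 1)) * bin_width
    lo <- pmax(ro - (1:nb) * bin_width, 0)
    vol <- 4 / 3 * pi * (hi^3 - lo^3)
    counts <- table(factor(shell, levels = 0:(nb - 1)), factor(
      sub, levels = c("red_cycling", "red_arrested", "yellow", "green")))
    dens <- sweep(unclass(counts), 1, vol, "/")
    # nutrient: deterministic re-solve from this snapshot's density
    field <- solve_nutrient(bin_density(a, grid), p$alpha, grid)
    rmid <- pmax(ro - (0:(nb - 1) + 0.5) * bin_width, 0)
    dirs <- fibonacci_sphere(50)
    cbar <- vapply(rmid, function(rr) {
      pos <- cbind(rr * dirs[, 1], rr * dirs[, 2], rr * dirs[, 3])
      mean(sample_field(pos, field, grid))
    }, numeric(1))
    tibble::tibble(
      time_h = t,
      p_um = rep((0:(nb - 1) + 0.5) * bin_width, times = 5),
      subpopulation = rep(c("red_cycling", "red_arrested", "yellow",
                            "green", "nutrient"), each = nb),
      value = c(dens, cbar),
      n_in_shell = c(unclass(counts), rep(NA_real_, nb)))
  }

  raw <- purrr::imap_dfr(sims, function(sim, i)
    dplyr::bind_rows(lapply(times, function(t) one(sim, t))) |>
      dplyr::mutate(realization = i))

  # one global normalization over every agent subpopulation, shell and time
  agent_max <- max(raw$value[raw$subpopulation != "nutrient"], na.rm = TRUE)
  raw <- raw |>
    dplyr::mutate(value = ifelse(.data$subpopulation == "nutrient",
                                 .data$value, .data$value / agent_max))
  out <- raw |>
    dplyr::group_by(.data$time_h, .data$p_um, .data$subpopulation) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
                     .groups = "drop")
  attr(out, "normalization") <- agent_max
  attr(out, "conserved_counts") <- raw |>
    dplyr::filter(.data$subpopulation != "nutrient") |>
    dplyr::group_by(.data$realization, .data$time_h) |>
    dplyr::summarise(n = sum(.data$n_in_shell), .groups = "drop")
  out
}

#' Population time series of a simulation
#'
#' @param sim a `spheroid_sim`.
#' @return The per-window population tibble (see [tidy.spheroid_sim()]).
#' @export
time_series <- function(sim) sim$series

#' Pointwise ensemble mean and standard deviation
#'
#' Aligns a collection of per-realization tables on their `time_h` column
#' and returns the pointwise sample mean and sample standard deviation
#' (n - 1 denominator) of every other numeric column.
#'
#' @param tables a list of tibbles sharing an identical `time_h` grid.
#' @return A tibble in long-by-column layout: `time_h`, one `<col>_mean`
#'   and `<col>_sd` per input column.
#' @export
ensemble_stats <- function(tables) {
  stopifnot(length(tables) >= 2)
  t0 <- tables[[1]]$time_h
  for (tb in tables[-1])
    if (!isTRUE(all.equal(tb$time_h, t0)))
      stop("misaligned time grids across realizations")
  cols <- setdiff(names(tables[[1]]),
                  c("time_h", "cross_section", "realization"))
  cols <- cols[vapply(tables[[1]][cols], is.numeric, logical(1))]
  out <- tibble::tibble(time_h = t0)
  for (cl in cols) {
    m <- vapply(tables, function(tb) as.numeric(tb[[cl]]),
                numeric(length(t0)))
    m <- matrix(m, nrow = length(t0))
    out[[paste0(cl, "_mean")]] <- rowMeans(m)
    out[[paste0(cl, "_sd")]] <- apply(m, 1, sd)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic, approximately even directions for shell averaging
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  cth <- 1 - 2 * i / n
  sth <- sqrt(pmax(0, 1 - cth^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(sth * cos(phi), sth * sin(phi), cth)
}
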