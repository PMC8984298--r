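#' Initialize an in-silico spheroid
#'
#' Draws `N0` agent positions uniformly in the ball of radius `ro_init`
#' centred at the origin (radius proportional to the cube root of a uniform
#' variate, so density is uniform in volume), assigns exactly `Nr0`, `Ny0`
#' and `Ng0` agents to the red, yellow and green phases by a uniformly
#' random permutation, solves the initial nutrient field from the initial
#' density, and caches the interpolated concentration on every agent.
#'
#' Uses the current R random number stream; call `set.seed()` (or let
#' [simulate_spheroid()] do it from `p$seed`) for reproducibility.
#'
#' @param p a [spheroid_params()] object.
#' @param solve_field if `FALSE`, skip the initial nutrient solve and leave
#'   `field` `NULL` and `cached_c` `NA` — useful when only the initial
#'   agent table is wanted.
#' @return A `spheroid_state`: list with fields `time` (h), `agents`
#'   ([agent_table()]), `deaths` (tibble of death locations and times),
#'   `field` (nutrient array), `grid`, and cumulative `events` counters.
#' @export
initialize_spheroid <- function(p, solve_field = TRUE) {
  n <- as.integer(p$N0)
  dirs <- random_unit_direction(n)
  r <- p$ro_init * runif(n)^(1 / 3)
  phase <- sample(rep(c("R", "Y", "G"),
                      times = c(p$Nr0, p$Ny0, p$Ng0)))
  agents <- agent_table(x = r * dirs[, 1], y = r * dirs[, 2],
                        z = r * dirs[, 3], phase = phase)
  grid <- grid_from_params(p)
  field <- NULL
  if (solve_field) {
    v <- bin_density(agents, grid)
    field <- solve_nutrient(v, p$alpha, grid)
    agents$cached_c <- sample_field(agents, field, grid)
  }
  structure(
    list(time = 0, agents = agents,
         deaths = tibble::tibble(x = numeric(), y = numeric(),
                                 z = numeric(), time_h = numeric()),
         field = field, grid = grid,
         events = c(n_r2y = 0, n_y2g = 0, n_mitosis = 0,
                    n_death = 0, n_migration = 0)),
    class = "spheroid_state")
}

#' Resolve agent-level events over one update window
#'
#' Runs the exact Gillespie algorithm from the state's current time to
#' `window_end` with every agent's propensities frozen at its cached
#' nutrient concentration: cycle progression (rate depending on phase),
#' migration and death compete as independent exponential clocks.
#' Daughters born by mitosis sample the frozen field at their own birth
#' positions. The waiting-time draw that overshoots the window end is
#' discarded, which is exact for this frozen-rate process by
#' memorylessness. The nutrient field itself is not updated here — that is
#' the caller's job (see [simulate_spheroid()]).
#'
#' @param state a `spheroid_state`.
#' @param p a [spheroid_params()] object.
#' @param window_end absolute end time of the window, h.
#' @return The updated `spheroid_state` (time equal to `window_end`), with
#'   attribute `t_first_event` carrying the absolute time of the first
#'   event in the window (`NA` if none fired).
#' @export
gillespie_window <- function(state, p, window_end) {
  stopifnot(state$time < window_end)
  res <- cpp_gillespie_window(
    state$agents$x, state$agents$y, state$agents$z,
    phase_to_int(state$agents$phase), state$agents$cached_c,
    state$time, window_end, unclass(p), state$field, state$grid$I)
  state$agents <- agent_table(res$x, res$y, res$z, int_to_phase(res$phase),
                              res$cached_c)
  if (length(res$death_x))
    state$deaths <- dplyr::bind_rows(
      state$deaths,
      tibble::tibble(x = res$death_x, y = res$death_y, z = res$death_z,
                     time_h = res$death_time))
  state$time <- res$time
  state$events <- state$events +
    c(n_r2y = res$n_r2y, n_y2g = res$n_y2g, n_mitosis = res$n_mitosis,
      n_death = res$n_death, n_migration = res$n_migration)
  attr(state, "t_first_event") <- res$t_first_event
  state
}

series_row <- function(state, p) {
  a <- state$agents
  arrested <- is_arrested(a, p)
  n_red <- sum(a$phase == "R")
  tibble::tibble(
    time_h = state$time,
    n_living = nrow(a),
    n_dead = nrow(state$deaths),
    n_red = n_red,
    n_yellow = sum(a$phase == "Y"),
    n_green = sum(a$phase == "G"),
    n_arrested = sum(arrested),
    n_cycling_red = n_red - sum(arrested))
}

#' Simulate spheroid growth
#'
#' The hybrid simulation loop: `M = T / t_star` times, resolve all
#' agent-level events over a window of duration `t_star` with the exact
#' Gillespie algorithm (propensities frozen at each agent's cached nutrient
#' concentration), then re-bin the agent density, re-solve the quasi-steady
#' nutrient field (warm-started from the previous window) and re-sample the
#' concentration at every agent position.
#'
#' The RNG is seeded from `p$seed`, so a given parameter set yields a
#' bit-identical realization.
#'
#' @param p a [spheroid_params()] object.
#' @param snapshot_every interval (h) at which full agent tables are kept
#'   (`Inf` keeps only the initial and final tables). Must be a multiple of
#'   `t_star`.
#' @param observers optional list of functions called as `f(state, window)`
#'   after every window (window 0 is the initial state).
#' @param record_fields if `TRUE`, keep the nutrient array alongside each
#'   snapshot.
#' @param progress print one line per simulated day.
#' @return An object of class `spheroid_sim`: list with the per-window
#'   population `series` (tibble), `snapshots` (named by time in h),
#'   `field_snapshots` (if recorded), the death ledger `deaths`, the
#'   `final` state, `params`, and a `solver_log` tibble (iterations and
#'   residual per window).
#' @export
simulate_spheroid <- function(p, snapshot_every = 24, observers = NULL,
                              record_fields = FALSE, progress = FALSE) {
  validate_params(p)
  set.seed(as.integer(p$seed))
  simulate_spheroid_impl(p, snapshot_every, observers, record_fields,
                         progress)
}

# Same loop without validation/seeding; used by tests that need degenerate
# rate settings and by the ensemble driver.
simulate_spheroid_impl <- function(p, snapshot_every = 24, observers = NULL,
                                   record_fields = FALSE, progress = FALSE) {
  state <- initialize_spheroid(p)
  m <- n_windows(p)
  snap_every <- if (is.finite(snapshot_every))
    as.integer(round(snapshot_every / p$t_star)) else NA_integer_
  series <- vector("list", m + 1)
  series[[1]] <- series_row(state, p)
  snapshots <- list()
  field_snapshots <- list()
  keep_snap <- function(w) {
    !is.na(snap_every) && snap_every > 0 && (w %% snap_every == 0)
  }
  snapshots[["0"]] <- state$agents
  if (record_fields) field_snapshots[["0"]] <- state$field
  for (f in observers) f(state, 0L)
  log <- vector("list", m)
  field_prev <- NULL

  for (w in seq_len(m)) {
    t_end <- w * p$t_star
    state <- gillespie_window(state, p, t_end)
    v <- bin_density(state$agents, state$grid)
    # warm start: linear extrapolation of the slowly drifting field
    warm <- if (is.null(field_prev)) state$field else
      pmin(pmax(2 * state$field - field_prev, 0), 1)
    field_prev <- state$field
    state$field <- solve_nutrient(v, p$alpha, state$grid,
                                  warm_start = warm)
    state$agents$cached_c <- sample_field(state$agents, state$field,
                                          state$grid)
    series[[w + 1]] <- series_row(state, p)
    log[[w]] <- tibble::tibble(
      window = w, time_h = t_end,
      iterations = attr(state$field, "iterations"),
      relres = attr(state$field, "relres"))
    nm <- format(t_end, trim = TRUE)
    if (keep_snap(w) || w == m) {
      snapshots[[nm]] <- state$agents
      if (record_fields) field_snapshots[[nm]] <- state$field
    }
    for (f in observers) f(state, w)
    if (progress && (t_end %% 24 == 0))
      message(sprintf("t = %5.0f h: %d living, %d dead", t_end,
                      nrow(state$agents), nrow(state$deaths)))
  }

  structure(
    list(series = dplyr::bind_rows(series),
         snapshots = snapshots,
         field_snapshots = if (record_fields) field_snapshots else NULL,
         deaths = state$deaths,
         final = state,
         params = p,
         solver_log = dplyr::bind_rows(log)),
    class = "spheroid_sim")
}

#' @export
print.spheroid_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat("<spheroid_sim>\n")
  cat(sprintf("  T = %g h (%d windows), seed %d\n", x$params$T,
              n_windows(x$params), as.integer(x$params$seed)))
  cat(sprintf("  final: %d living (R %d / Y %d / G %d), %d dead\n",
              last$n_living, last$n_red, last$n_yellow, last$n_green,
              last$n_dead))
  invisible(x)
}

#' Tidy a simulation into its population time series
#'
#' @param x a `spheroid_sim`.
#' @param ... unused.
#' @return The per-window population tibble: `time_h`, `n_living`,
#'   `n_dead`, `n_red`, `n_yellow`, `n_green`, `n_arrested`,
#'   `n_cycling_red`. Red agents are partitioned as
#'   `n_red = n_arrested + n_cycling_red`, and
#'   `n_living = n_red + n_yellow + n_green`.
#' @export
tidy.spheroid_sim <- function(x, ...) x$series

#' @rdname tidy.spheroid_sim
#' @export
glance.spheroid_sim <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  ev <- x$final$events
  tibble::tibble(
    t_final_h = last$time_h,
    n_living = last$n_living, n_dead = last$n_dead,
    n_mitosis = unname(ev["n_mitosis"]),
    n_migration = unname(ev["n_migration"]),
    seed = as.integer(x$params$seed))
}
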