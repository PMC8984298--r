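#' Agent tables
#'
#' Agents are point cells carried as a tibble with one row per living cell
#' and columns `x`, `y`, `z` (um, relative to the domain centre), `phase`
#' (`"R"` = G1, `"Y"` = early S, `"G"` = S/G2/M, following FUCCI colours)
#' and `cached_c`, the non-dimensional nutrient concentration sampled at the
#' last field update.
#'
#' @param x,y,z numeric coordinates in micrometres.
#' @param phase character vector of `"R"`, `"Y"`, `"G"`.
#' @param cached_c nutrient values in \[0, 1\] (default `NA`).
#' @return A tibble of class `agent_table`.
#' @export
agent_table <- function(x = numeric(), y = numeric(), z = numeric(),
                        phase = character(), cached_c = NA_real_) {
  phase <- as.character(phase)
  if (length(phase) && !all(phase %in% c("R", "Y", "G")))
    stop("phase must be one of 'R', 'Y', 'G'")
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        z = as.numeric(z), phase = phase,
                        cached_c = rep_len(as.numeric(cached_c),
                                           length.out = length(x)))
  class(out) <- c("agent_table", class(out))
  out
}

phase_to_int <- function(phase) match(phase, c("R", "Y", "G")) - 1L
int_to_phase <- function(i) c("R", "Y", "G")[i + 1L]

#' Uniform random directions on the unit sphere
#'
#' Directions are drawn isotropically: the azimuthal angle uniform on
#' \[0, 2 pi) and the cosine of the polar angle uniform on \[-1, 1\], so no
#' direction is favoured (naive uniform sampling of the polar angle itself
#' would concentrate directions at the poles).
#'
#' @param n number of directions.
#' @return An `n x 3` matrix of unit vectors.
#' @export
random_unit_direction <- function(n = 1) {
  cpp_random_unit_directions(as.integer(n))
}

#' Displace agents along given directions
#'
#' Moves each agent a distance `mu` (the migration step length) along its
#' direction; phases and cached nutrient are unchanged. A displacement that
#' leaves the cubic domain is an error: the domain is chosen large enough
#' that cells never reach its edge, so a breach indicates a mis-sized run.
#'
#' @param agents an [agent_table()].
#' @param directions an `n x 3` matrix of unit vectors (one row per agent).
#' @param p a [spheroid_params()] object.
#' @return The displaced agent table.
#' @export
apply_migration <- function(agents, directions, p) {
  directions <- matrix(directions, ncol = 3)
  stopifnot(nrow(directions) == nrow(agents))
  agents$x <- agents$x + p$mu * directions[, 1]
  agents$y <- agents$y + p$mu * directions[, 2]
  agents$z <- agents$z + p$mu * directions[, 3]
  check_inside_domain(agents, p$L)
  agents
}

#' Divide a green agent into two red daughters
#'
#' Mitosis replaces one S/G2/M (green) agent by two G1 (red) daughters
#' placed `sigma / 2` on either side of the parent along a random (or
#' supplied) direction, so the daughters are `sigma` apart and their
#' midpoint is the parent position. If a nutrient field is supplied each
#' daughter caches the concentration interpolated at its own birth
#' position; otherwise it inherits `NA`.
#'
#' @param agent a single-row [agent_table()] with `phase == "G"`.
#' @param direction a unit 3-vector; drawn uniformly if missing.
#' @param p a [spheroid_params()] object.
#' @param field optional nutrient array (see [solve_nutrient()]).
#' @param grid the [spheroid_grid()] of `field`.
#' @return A two-row agent table of red daughters.
#' @export
apply_mitosis <- function(agent, direction = NULL, p = default_params(),
                          field = NULL, grid = NULL) {
  if (nrow(agent) != 1) stop("apply_mitosis expects a single agent")
  if (agent$phase != "G")
    stop("mitosis requires a green (S/G2/M) agent")
  if (is.null(direction)) direction <- drop(random_unit_direction(1))
  off <- p$sigma / 2 * direction
  out <- agent_table(
    x = agent$x + c(off[1], -off[1]),
    y = agent$y + c(off[2], -off[2]),
    z = agent$z + c(off[3], -off[3]),
    phase = c("R", "R"))
  check_inside_domain(out, p$L)
  if (!is.null(field)) {
    out$cached_c <- sample_field(out, field, grid)
  }
  out
}

#' Classify G1-arrested agents
#'
#' An agent is considered G1-arrested when it is red (G1) and its local
#' nutrient concentration lies below the arrest concentration `c_a` — the
#' level at which the G1-to-eS commitment rate has fallen to half its
#' maximum.
#'
#' @param agents an [agent_table()].
#' @param p a [spheroid_params()] object.
#' @return Logical vector, one entry per agent.
#' @export
is_arrested <- function(agents, p) {
  agents$phase == "R" & agents$cached_c < p$c_a
}

check_inside_domain <- function(agents, L) {
  half <- L / 2
  if (nrow(agents) &&
      any(abs(agents$x) >= half | abs(agents$y) >= half |
          abs(agents$z) >= half))
    stop("boundary breach: an agent reached the edge of the domain; ",
         "increase the domain length L", call. = FALSE)
  invisible(agents)
}
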