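#' Model parameters for the FUCCI spheroid simulator
#'
#' Constructs the full parameter set of the individual-based spheroid model:
#' initial composition, domain geometry, per-capita event rates, Hill-function
#' shape constants and the nutrient consumption-to-diffusion ratio. All
#' quantities are in micrometres, hours and cells; nutrient concentration is
#' non-dimensional on \[0, 1\].
#'
#' The default values reproduce the calibrated WM793B melanoma spheroid
#' conditions: 30 000 agents seeded uniformly in a ball of radius 245 um,
#' split 20 911 / 995 / 8 094 between red (G1), yellow (eS) and green
#' (S/G2/M), simulated for 240 h with the nutrient field re-solved every
#' hour on a 201^3 grid over a 4000-um cube.
#'
#' @param ... named overrides of any default field (see
#'   [default_params()] for the full list).
#' @param validate if `TRUE` (the default) the invariants linking the fields
#'   are checked and a violation is an error. Setting `FALSE` is intended
#'   only for degenerate configurations in tests (e.g. switching death off
#'   entirely, which violates the strict `d_max > d_min` ordering).
#'
#' @return An object of class `spheroid_params`: a named list of numeric
#'   fields.
#' @examples
#' p <- spheroid_params(T = 24, N0 = 1000, Nr0 = 700, Ny0 = 100, Ng0 = 200)
#' p$Rr_max
#' @export
spheroid_params <- function(..., validate = TRUE) {
  p <- default_params()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad))
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- lapply(over, as.numeric)
  }
  class(p) <- "spheroid_params"
  if (validate) validate_params(p)
  p
}

#' Default parameter values
#'
#' The calibrated constants of the spheroid model (see
#' [spheroid_params()] for field meanings and units).
#'
#' @return A named list (class `spheroid_params`).
#' @export
default_params <- function() {
  p <- list(
    # initial composition (cells)
    N0 = 30000, Nr0 = 20911, Ny0 = 995, Ng0 = 8094,
    # geometry (um) and grid
    L = 4000, I = 201, ro_init = 245,
    # event length scales (um)
    sigma = 12, mu = 12,
    # time horizon and nutrient update interval (h)
    T = 240, t_star = 1,
    # cycle progression rates (h^-1)
    Rr_max = 0.047, Ry = 0.50, Rg = 0.062,
    # death and migration rate bounds (h^-1)
    d_max = 2, d_min = 0.0005, m_max = 0.12, m_min = 0.06,
    # Hill indices (dimensionless)
    eta1 = 5, eta2 = 5, eta3 = 15,
    # inflection concentrations (dimensionless)
    c_a = 0.4, c_m = 0.5, c_d = 0.1,
    # consumption-to-diffusion ratio (um / cell)
    alpha = 0.15,
    # RNG master seed
    seed = 1
  )
  class(p) <- "spheroid_params"
  p
}

#' Reduced-domain desk preset
#'
#' The full calibrated configuration keeps a 4000-um domain on a 201^3
#' grid so the far-field boundary is far from the spheroid. For desk-scale
#' work this preset shrinks the domain to `L = 1500` um with `I = 76`
#' nodes — the same 20-um node spacing — and leaves every biological
#' parameter untouched. The Dirichlet `c = 1` boundary then sits nearer
#' the spheroid (750 um from the centre against a final outer radius
#' around 300 um), which slightly enriches the nutrient supply relative to
#' the full domain.
#'
#' @param ... overrides passed to [spheroid_params()].
#' @return A `spheroid_params` object.
#' @export
desk_preset <- function(...) {
  spheroid_params(L = 1500, I = 76, ...)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and throws an
#' error naming the first violated constraint.
#'
#' @param p a `spheroid_params` object.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameters: ", msg,
                                                 call. = FALSE)
  chk(p$N0 == p$Nr0 + p$Ny0 + p$Ng0, "N0 must equal Nr0 + Ny0 + Ng0")
  chk(all(c(p$N0, p$Nr0, p$Ny0, p$Ng0) >= 0), "agent counts must be >= 0")
  chk(p$d_max > p$d_min, "d_max must exceed d_min")
  chk(p$d_min >= 0, "d_min must be >= 0")
  chk(p$m_max > p$m_min, "m_max must exceed m_min")
  chk(p$m_min >= 0, "m_min must be >= 0")
  chk(p$Rr_max > 0, "Rr_max must be > 0")
  chk(p$Ry > 0, "Ry must be > 0")
  chk(p$Rg > 0, "Rg must be > 0")
  for (f in c("c_a", "c_m", "c_d"))
    chk(p[[f]] > 0 && p[[f]] <= 1, paste(f, "must lie in (0, 1]"))
  for (f in c("eta1", "eta2", "eta3"))
    chk(p[[f]] > 0, paste(f, "must be > 0"))
  chk(p$alpha >= 0, "alpha must be >= 0")
  chk(p$L > 2 * p$ro_init, "L must exceed twice the initial radius")
  chk(p$I >= 3 && p$I == round(p$I), "I must be an integer >= 3")
  chk(p$T > 0, "T must be > 0")
  chk(p$t_star > 0, "t_star must be > 0")
  m <- p$T / p$t_star
  chk(abs(m - round(m)) < 1e-9 && round(m) >= 1,
      "T / t_star must be a positive integer")
  chk(p$sigma >= 0 && p$mu >= 0, "sigma and mu must be >= 0")
  invisible(p)
}

#' Derived quantities
#'
#' `grid_spacing()` is the node spacing `h = L / (I - 1)` in micrometres;
#' `n_windows()` is the number `M = T / t_star` of nutrient update windows.
#'
#' @param p a `spheroid_params` object.
#' @return A scalar.
#' @export
grid_spacing <- function(p) p$L / (p$I - 1)

#' @rdname grid_spacing
#' @export
n_windows <- function(p) as.integer(round(p$T / p$t_star))

#' @export
print.spheroid_params <- function(x, ...) {
  cat("<spheroid_params>\n")
  cat(sprintf("  N0 = %d (R %d / Y %d / G %d), ro(0) = %g um\n",
              x$N0, x$Nr0, x$Ny0, x$Ng0, x$ro_init))
  cat(sprintf("  domain L = %g um, grid I = %d (h = %g um)\n",
              x$L, as.integer(x$I), grid_spacing(x)))
  cat(sprintf("  T = %g h, t* = %g h (M = %d windows), alpha = %g um/cell\n",
              x$T, x$t_star, n_windows(x), x$alpha))
  cat(sprintf("  rates: Rr_max %g, Ry %g, Rg %g; m [%g, %g]; d [%g, %g] h^-1\n",
              x$Rr_max, x$Ry, x$Rg, x$m_min, x$m_max, x$d_min, x$d_max))
  cat(sprintf("  Hill: eta (%g, %g, %g), c_a %g, c_m %g, c_d %g; seed %d\n",
              x$eta1, x$eta2, x$eta3, x$c_a, x$c_m, x$c_d, as.integer(x$seed)))
  invisible(x)
}

#' Read or write a parameter configuration file
#'
#' The configuration format is flat `key = value` text, one field per line,
#' with `#` comments and blank lines ignored. Keys absent from the file keep
#' their default values; the assembled set is re-validated.
#'
#' @param path file path.
#' @param validate passed on to [spheroid_params()].
#' @return `read_params()` returns a `spheroid_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed configuration line: '", ln, "'")
    key <- trimws(kv[1])
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value for key '", key, "'")
    over[[key]] <- val
  }
  do.call(spheroid_params, c(over, list(validate = validate)))
}

#' @rdname read_params
#' @param p a `spheroid_params` object to write.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "spheroid_params"))
  lines <- vapply(names(unclass(p)), function(k)
    sprintf("%s = %.17g", k, p[[k]]), character(1))
  writeLines(c("# spheroid model configuration", lines), path)
  invisible(path)
}
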