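# Initial-condition generators.  All randomness flows through the `seed`
# argument; the caller's RNG state is left untouched.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Band-pass filtered Gaussian white noise
#'
#' Draws independent complex (or real) Gaussian amplitudes on the annulus
#' of lattice modes with \eqn{|k/k_c - 1| \le bandwidth/2}, zero elsewhere,
#' and rescales so the realized power \eqn{\langle |z|^2 \rangle} equals
#' `target_power` exactly.  This is the standard low-selectivity initial
#' condition for the OP field; an ensemble of such maps has mean pinwheel
#' density slightly above the Gaussian-random-map lower bound \eqn{\pi}.
#'
#' @param grid a [grid_spec()].
#' @param kc critical wavenumber the annulus is centred on (default
#'   \eqn{2\pi}, the OP circle).
#' @param bandwidth relative annulus width (in (0, 1)).
#' @param target_power desired \eqn{\langle |z|^2 \rangle}.
#' @param seed RNG seed (fields are deterministic in (arguments, seed)).
#' @param real if `TRUE` return a real field (conjugate-symmetrized
#'   spectrum) instead of a complex one.
#' @return `ny x nx` complex (or real) matrix.
#' @export
bandpass_gwn <- function(grid, kc = 2 * pi, bandwidth = 0.2, target_power,
                         seed = NULL, real = FALSE) {
  stopifnot(inherits(grid, "grid_spec"), bandwidth > 0, bandwidth < 1,
            target_power >= 0)
  kk <- sqrt(grid$k2)
  mask <- abs(kk / kc - 1) <= bandwidth / 2
  if (sum(mask) < 12)
    stop("band-pass annulus contains fewer than 12 lattice modes; enlarge the grid")
  with_seed(seed, {
    n <- grid$nx * grid$ny
    a <- matrix(complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
                grid$ny, grid$nx)
    a[!mask] <- 0
    z <- ifft2(a)
    if (real) z <- matrix(Re(z) * sqrt(2), grid$ny, grid$nx)
    p <- mean(Mod(z)^2)
    if (p > 0) z <- z * sqrt(target_power / p)
    z
  })
}

#' Pinwheel-free stripe pattern
#'
#' \eqn{z = A e^{i(k \cdot x + \phi)}} with `k` on the grid's wavenumber
#' lattice.  Stripes carry no pinwheels; with \eqn{A = \sqrt{r_z}} and
#' \eqn{|k| = k_c} the stripe is a stationary state of the uncoupled flow.
#'
#' @param grid a [grid_spec()].
#' @param k wavevector `c(kx, ky)`; must lie on the lattice
#'   \eqn{2\pi(m/l_x, n/l_y)}.
#' @param amplitude stripe amplitude A.
#' @param phase phase offset \eqn{\phi}.
#' @return complex `ny x nx` matrix with \eqn{\langle |z|^2 \rangle = A^2}.
#' @export
stripes <- function(grid, k = c(2 * pi, 0), amplitude = 1, phase = 0) {
  stopifnot(inherits(grid, "grid_spec"), length(k) == 2)
  mn <- c(k[1] * grid$lx, k[2] * grid$ly) / (2 * pi)
  if (any(abs(mn - round(mn)) > 1e-8))
    stop("stripe wavevector is not on the grid's wavenumber lattice")
  xy <- grid_coords(grid)
  ph <- outer(xy$y * k[2], xy$x * k[1], `+`) + phase
  amplitude * exp(1i * ph)
}

#' Hexagonal pattern
#'
#' \eqn{o = \delta + A \sum_{j=1}^3 \cos(k_j \cdot x + \phi_j)} with three
#' wavevectors at mutual 120 degrees summing to zero, each snapped to the
#' nearest lattice mode near radius `kc`.  The spatial mean equals
#' `mean_offset` exactly.  The standard ocular-dominance initial condition
#' is such a hexagon (plus band-pass noise) with a positive mean offset
#' representing contralateral bias.
#'
#' @param grid a [grid_spec()].
#' @param kc target wavenumber magnitude of the triad.
#' @param amplitude mode amplitude A.
#' @param phases three phases \eqn{\phi_j} (resonant convention: summing
#'   to 0).
#' @param mean_offset uniform offset \eqn{\delta}.
#' @param angle_tol maximum tolerated deviation (degrees) of the snapped
#'   triad angles from 120 degrees.
#' @return real `ny x nx` matrix.
#' @export
hexagons <- function(grid, kc = 2 * pi, amplitude, phases = c(0, 0, 0),
                     mean_offset = 0, angle_tol = 4) {
  stopifnot(inherits(grid, "grid_spec"), length(phases) == 3)
  snap <- function(k) round(c(k[1] * grid$lx, k[2] * grid$ly) / (2 * pi))
  mn1 <- snap(kc * c(1, 0))
  mn2 <- snap(kc * c(-0.5, sqrt(3) / 2))
  mn3 <- -mn1 - mn2                       # exact closure on the lattice
  ks <- lapply(list(mn1, mn2, mn3), function(mn)
    2 * pi * c(mn[1] / grid$lx, mn[2] / grid$ly))
  ang <- function(a, b)
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  angles <- c(ang(ks[[1]], ks[[2]]), ang(ks[[2]], ks[[3]]), ang(ks[[1]], ks[[3]]))
  if (any(abs(angles - 120) > angle_tol))
    stop(sprintf(
      "lattice cannot host a near-120 degree triad at kc = %g (achieved angles: %s)",
      kc, paste(sprintf("%.1f", angles), collapse = ", ")))
  xy <- grid_coords(grid)
  o <- matrix(mean_offset, grid$ny, grid$nx)
  for (j in 1:3) {
    k <- ks[[j]]
    o <- o + amplitude * cos(outer(xy$y * k[2], xy$x * k[1], `+`) + phases[j])
  }
  o
}
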