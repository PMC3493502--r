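#' Periodic simulation grid
#'
#' Defines the doubly periodic rectangular domain on which all fields live.
#' Lengths are measured in units of the orientation-preference (OP) column
#' spacing \eqn{\Lambda_z}, so the OP critical wavenumber is \eqn{k_c = 2\pi}
#' by construction.  The side lengths must accommodate an integer number of
#' wavelengths of every field in the model (checked by [model_spec()]), which
#' keeps the active Fourier modes balanced on the discrete critical circle.
#'
#' @param nx,ny number of mesh points in x and y (at least 16).
#' @param lx,ly physical side lengths in units of \eqn{\Lambda_z}.
#' @return An object of class `grid_spec` with the mesh, the wavenumber
#'   lattice (`kx`, `ky`, `k2` as `ny x nx` matrices in FFT layout, DC at
#'   index \[1,1\]) and cell spacings `hx`, `hy`.
#' @examples
#' g <- grid_spec(64, 64, 8, 8)
#' g
#' @export
grid_spec <- function(nx, ny, lx = nx / 8, ly = ny / 8) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 16L, ny >= 16L, lx > 0, ly > 0)
  # resolve the critical circle: at least 8 mesh points per OP wavelength
  if (nx / lx < 8 - 1e-9 || ny / ly < 8 - 1e-9)
    stop("mesh too coarse: need >= 8 points per wavelength (nx/lx, ny/ly)")
  fx <- fft_freq(nx) * (2 * pi / lx)   # kx for column index 1..nx
  fy <- fft_freq(ny) * (2 * pi / ly)
  kx <- matrix(fx, ny, nx, byrow = TRUE)
  ky <- matrix(fy, ny, nx)
  # derivative operators drop the (one-sided) Nyquist mode so that the
  # spectral derivative is an exactly antisymmetric real-linear map; this
  # makes the divergence-form coupling forces the exact discrete gradients
  # of the coupling energies
  fxd <- fx; if (nx %% 2 == 0) fxd[nx / 2 + 1] <- 0
  fyd <- fy; if (ny %% 2 == 0) fyd[ny / 2 + 1] <- 0
  structure(list(nx = nx, ny = ny, lx = lx, ly = ly,
                 hx = lx / nx, hy = ly / ny,
                 kx = kx, ky = ky, k2 = kx^2 + ky^2,
                 kxd = matrix(fxd, ny, nx, byrow = TRUE),
                 kyd = matrix(fyd, ny, nx),
                 periodic = TRUE),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Periodic grid: %d x %d mesh over %g x %g Lambda^2 (%.2g pts/Lambda)\n",
              x$nx, x$ny, x$lx, x$ly, min(x$nx / x$lx, x$ny / x$ly)))
  invisible(x)
}

# integer FFT frequencies 0, 1, ..., n/2-1, -n/2, ..., -1 (half-open convention)
fft_freq <- function(n) {
  f <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  f[seq_len(n)]
}

#' Real-space mesh coordinates
#'
#' @param grid a [grid_spec()].
#' @return list with `x` (length nx) and `y` (length ny) coordinates of the
#'   mesh points, starting at 0.
#' @export
grid_coords <- function(grid) {
  list(x = (seq_len(grid$nx) - 1) * grid$hx,
       y = (seq_len(grid$ny) - 1) * grid$hy)
}

# forward/inverse 2d transforms with the unitary-in-round-trip convention
# used throughout: fft2 unnormalized, ifft2 carries the 1/(nx ny)
fft2 <- function(a) stats::fft(a)
ifft2 <- function(a) stats::fft(a, inverse = TRUE) / length(a)

# spectral partial derivatives of a (complex or real) field (Nyquist-free)
spectral_grad <- function(a, grid) {
  ah <- fft2(a)
  list(x = ifft2(1i * grid$kxd * ah), y = ifft2(1i * grid$kyd * ah))
}
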