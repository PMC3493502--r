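#' Swift-Hohenberg growth spectrum
#'
#' Linear growth rate \eqn{\lambda(k) = r - (k_c^2 - k^2)^2 / k_c^4} of the
#' Swift-Hohenberg operator.  The maximum over \eqn{k \ge 0} is \eqn{r},
#' attained on the critical circle \eqn{|k| = k_c}; the homogeneous mode has
#' rate \eqn{r - 1}.
#'
#' @param k2 squared wavenumber(s) (any numeric array).
#' @param r bifurcation parameter (distance from threshold).
#' @param kc critical wavenumber (> 0).
#' @return growth rates, same shape as `k2`.
#' @examples
#' linear_spectrum((2 * pi)^2, r = 0.05, kc = 2 * pi)  # r at the circle
#' linear_spectrum(0, r = 0.05, kc = 2 * pi)           # r - 1 at DC
#' @export
linear_spectrum <- function(k2, r, kc) {
  if (!is.numeric(kc) || length(kc) != 1L || kc <= 0)
    stop("critical wavenumber kc must be a positive scalar")
  r - (kc^2 - k2)^2 / kc^4
}

#' Apply the linear Swift-Hohenberg operator
#'
#' Applies \eqn{\hat L = r - (k_c^2 + \Delta)^2 / k_c^4} to a field,
#' diagonally in Fourier space on the grid's wavenumber lattice.
#'
#' @param field complex or real `ny x nx` matrix.
#' @param r,kc bifurcation parameter and critical wavenumber.
#' @param grid a [grid_spec()].
#' @return the transformed field (complex if input complex, real otherwise).
#' @export
apply_linear <- function(field, r, kc, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!all(dim(field) == c(grid$ny, grid$nx)))
    stop("field shape does not match grid")
  out <- ifft2(linear_spectrum(grid$k2, r, kc) * fft2(field))
  if (is.complex(field)) out else Re(out)
}

#' Inter-map coupling term
#'
#' One pairwise coupling energy from the symmetry-classified family.  With
#' \eqn{S = \nabla z \cdot \nabla o} (a complex scalar; for real-real pairs
#' the plain product of gradients) the energy densities are
#' \describe{
#'   \item{`product2`}{\eqn{\alpha\, o^2 |z|^2}}
#'   \item{`product4`}{\eqn{\tau\, o^4 |z|^4}}
#'   \item{`gradient2`}{\eqn{\beta\, |S|^2}}
#'   \item{`gradient4`}{\eqn{\epsilon\, |S|^4}}
#' }
#' Field index 0 denotes the complex OP field, 1..m the real fields.
#'
#' @param kind one of `"product2"`, `"product4"`, `"gradient2"`, `"gradient4"`.
#' @param strength nonnegative coupling constant.
#' @param pair integer vector of the two (distinct) coupled field indices.
#' @return a `coupling_spec` object.
#' @export
coupling <- function(kind = c("gradient4", "gradient2", "product2", "product4"),
                     strength, pair = c(0L, 1L)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(strength), length(strength) == 1L, strength >= 0)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2] || any(pair < 0L))
    stop("pair must be two distinct nonnegative field indices")
  structure(list(kind = kind, strength = strength, pair = sort(pair)),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("coupling %s(strength = %g) between fields %d and %d\n",
              x$kind, x$strength, x$pair[1], x$pair[2]))
  invisible(x)
}

#' Coupled-map model specification
#'
#' Collects everything that defines the coupled gradient-flow dynamics: the
#' OP bifurcation parameter `r_z`, one entry per real field (bifurcation
#' parameter `r`, constant contralateral bias `gamma`, wavelength ratio
#' `w = k_c,i / k_c,z`, timescale constant `c`), and the list of pairwise
#' couplings.  Time is measured in intrinsic units \eqn{\tau = 1/r_z}: the
#' whole right-hand side is rescaled by \eqn{1/r_z}, so the fastest OP modes
#' grow at unit rate.
#'
#' @param grid a [grid_spec()].
#' @param r_z OP bifurcation parameter (> 0).
#' @param fields list of real-field descriptors, each a list with elements
#'   `r`, `gamma` (default 0), `w` (default 1) and `c` (default 1); a single
#'   descriptor may be passed directly.
#' @param couplings list of [coupling()] objects (a single one may be passed
#'   directly).
#' @return a `model_spec` object.
#' @examples
#' g <- grid_spec(64, 64, 8, 8)
#' m <- model_spec(g, r_z = 0.05,
#'                 fields = list(list(r = 0.25, gamma = 0.15)),
#'                 couplings = coupling("gradient4", 2000))
#' m
#' @export
model_spec <- function(grid, r_z, fields = list(), couplings = list()) {
  stopifnot(inherits(grid, "grid_spec"), r_z > 0)
  if (length(fields) && !is.null(fields$r)) fields <- list(fields)
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  fields <- lapply(fields, function(f) {
    f <- utils::modifyList(list(gamma = 0, w = 1, c = 1), f)
    stopifnot(f$r > -1, f$w > 0, f$c > 0)
    f[c("r", "gamma", "w", "c")]
  })
  m <- length(fields)
  # integer-wavelength rule for every field, so active modes sit on the lattice
  for (w in c(1, vapply(fields, `[[`, 1, "w"))) {
    for (L in c(grid$lx, grid$ly)) {
      if (abs(L * w - round(L * w)) > 1e-8)
        stop(sprintf(
          "domain length %g does not hold an integer number of wavelengths at ratio w = %g",
          L, w))
    }
  }
  for (cp in couplings) {
    if (!inherits(cp, "coupling_spec")) stop("couplings must be coupling() objects")
    if (any(cp$pair > m)) stop("coupling pair references a field beyond the model")
  }
  structure(list(grid = grid, r_z = r_z, fields = fields,
                 couplings = couplings, kc_z = 2 * pi),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Coupled Swift-Hohenberg model: OP field (r_z = %g) + %d real field(s)\n",
              x$r_z, length(x$fields)))
  for (i in seq_along(x$fields)) {
    f <- x$fields[[i]]
    cat(sprintf("  o_%d: r = %g, gamma = %g, w = %g, c = %g\n",
                i, f$r, f$gamma, f$w, f$c))
  }
  for (cp in x$couplings) cat("  ", format_coupling(cp), "\n", sep = "")
  print(x$grid)
  invisible(x)
}

format_coupling <- function(cp)
  sprintf("%s(strength = %g) on (%d,%d)", cp$kind, cp$strength,
          cp$pair[1], cp$pair[2])

# ---- precomputed operator tables consumed by the C++ kernels ----------------
# lam[[f]]: growth spectrum of field f (1 = z, 2.. = real fields), already on
# the wavenumber lattice; mu[f]: time-unit multiplier 1/(r_z c_f).
model_tables <- function(model) {
  g <- model$grid
  lam <- c(list(linear_spectrum(g$k2, model$r_z, model$kc_z)),
           lapply(model$fields, function(f)
             linear_spectrum(g$k2, f$r, 2 * pi * f$w)))
  mu <- c(1, vapply(model$fields, `[[`, 1, "c")) # c_0 = 1 for the OP field
  mu <- 1 / (model$r_z * mu)
  cps <- model$couplings
  cmat <- if (length(cps)) {
    t(vapply(cps, function(cp) c(match(cp$kind, coupling_kinds), cp$pair),
             integer(3)))
  } else matrix(integer(0), 0, 3)
  list(lam = lam, mu = mu,
       gamma = vapply(model$fields, `[[`, 1, "gamma"),
       kx = g$kxd, ky = g$kyd,
       ckind = as.integer(cmat[, 1L]), ca = as.integer(cmat[, 2L]),
       cb = as.integer(cmat[, 3L]),
       cstr = vapply(cps, `[[`, 1, "strength"))
}

coupling_kinds <- c("product2", "product4", "gradient2", "gradient4")

#' Snapshot of all fields at one time
#'
#' @param z complex `ny x nx` matrix (OP field).
#' @param o list of real `ny x nx` matrices, one per real field (may be
#'   empty; a single matrix may be passed directly).
#' @param t time in intrinsic units \eqn{\tau = 1/r_z}.
#' @param grid the [grid_spec()] the fields live on.
#' @return a `field_state` object.
#' @export
field_state <- function(z, o = list(), t = 0, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.matrix(o)) o <- list(o)
  z <- as_complex_matrix(z)
  dims <- c(grid$ny, grid$nx)
  if (!all(dim(z) == dims)) stop("z shape does not match grid")
  for (oi in o) if (!all(dim(oi) == dims)) stop("real field shape mismatch")
  structure(list(z = z, o = o, t = t, grid = grid), class = "field_state")
}

as_complex_matrix <- function(z) {
  if (!is.complex(z)) z <- matrix(complex(real = z, imaginary = 0), nrow(z), ncol(z))
  z
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf("field_state at t = %g: z (power %.4g) + %d real field(s)\n",
              x$t, mean(Mod(x$z)^2), length(x$o)))
  invisible(x)
}

# ---- packed real state vector [Re z, Im z, o_1, ..., o_m] -------------------
pack_state <- function(state) {
  c(as.numeric(Re(state$z)), as.numeric(Im(state$z)),
    unlist(lapply(state$o, as.numeric), use.names = FALSE))
}

unpack_state <- function(u, grid, m, t = 0) {
  n <- grid$nx * grid$ny
  z <- matrix(complex(real = u[seq_len(n)], imaginary = u[n + seq_len(n)]),
              grid$ny, grid$nx)
  o <- lapply(seq_len(m), function(i)
    matrix(u[(1 + i) * n + seq_len(n)], grid$ny, grid$nx))
  field_state(z, o, t, grid)
}
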