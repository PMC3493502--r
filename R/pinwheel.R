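#' Locate pinwheels as zero-contour crossings
#'
#' Pinwheel centres are the common zeros of Re z and Im z.  Within every
#' grid cell whose corners show a sign change in both parts, the two
#' bilinear interpolants are intersected exactly (their elimination is a
#' quadratic), giving subcell positions; periodic wraparound is handled by
#' closing the cells across the domain edges.  Each accepted crossing is
#' assigned a topological charge by [pinwheel_charge()]; simple zeros carry
#' \eqn{q = \pm 1/2}, anything else is kept but flagged.
#'
#' @param z complex `ny x nx` matrix.
#' @param grid the [grid_spec()] `z` lives on.
#' @param t frame time stored with the result.
#' @param lambda column spacing used for distances/densities (default 1,
#'   the OP wavelength unit; see [estimate_wavelength()]).
#' @return a `pinwheel_set`: data frame with columns `x`, `y` (positions in
#'   \eqn{\Lambda_z} units), `q` (signed charge) and `flagged`; grid
#'   metadata in attributes.
#' @export
find_pinwheels <- function(z, grid, t = NA_real_, lambda = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  a <- Re(z); b <- Im(z)
  if (all(a == 0) && all(b == 0)) stop("find_pinwheels: field is identically zero")
  ny <- grid$ny; nx <- grid$nx
  ixp <- c(2:nx, 1L); iyp <- c(2:ny, 1L)
  f00a <- a;            f10a <- a[, ixp]
  f01a <- a[iyp, ];     f11a <- a[iyp, ixp]
  f00b <- b;            f10b <- b[, ixp]
  f01b <- b[iyp, ];     f11b <- b[iyp, ixp]
  sgn_change <- function(p, q, r, s)
    (pmin(p, q, r, s) <= 0) & (pmax(p, q, r, s) >= 0)
  cand <- which(sgn_change(f00a, f10a, f01a, f11a) &
                  sgn_change(f00b, f10b, f01b, f11b))
  res <- list()
  for (idx in cand) {
    a0 <- f00a[idx]; a1 <- f10a[idx] - a0; a2 <- f01a[idx] - a0
    a3 <- f11a[idx] - f10a[idx] - f01a[idx] + a0
    b0 <- f00b[idx]; b1 <- f10b[idx] - b0; b2 <- f01b[idx] - b0
    b3 <- f11b[idx] - f10b[idx] - f01b[idx] + b0
    degenerate <- all(abs(c(a0, a1, a2, a3, b0, b1, b2, b3)) <
                        .Machine$double.eps * 4)
    if (degenerate) {
      iy <- (idx - 1) %% ny + 1; ix <- (idx - 1) %/% ny + 1
      res[[length(res) + 1L]] <- c((ix - 0.5) * grid$hx, (iy - 0.5) * grid$hy,
                                   NA_real_, 1)
      next
    }
    c2 <- a1 * b3 - b1 * a3
    c1 <- a0 * b3 + a1 * b2 - b0 * a3 - b1 * a2
    c0 <- a0 * b2 - b0 * a2
    xs <- quad_roots(c2, c1, c0)
    for (x in xs) {
      if (is.na(x) || x < 0 || x >= 1) next
      den_a <- a2 + a3 * x; den_b <- b2 + b3 * x
      y <- if (abs(den_a) >= abs(den_b)) -(a0 + a1 * x) / den_a
           else -(b0 + b1 * x) / den_b
      if (!is.finite(y) || y < 0 || y >= 1) next
      iy <- (idx - 1) %% ny + 1; ix <- (idx - 1) %/% ny + 1
      res[[length(res) + 1L]] <- c((ix - 1 + x) * grid$hx,
                                   (iy - 1 + y) * grid$hy, NA_real_, 0)
    }
  }
  if (!length(res)) {
    pw <- data.frame(x = numeric(0), y = numeric(0), q = numeric(0),
                     flagged = logical(0))
    return(as_pinwheel_set(pw, grid, t, lambda))
  }
  pw <- do.call(rbind, res)
  pw <- data.frame(x = pw[, 1], y = pw[, 2], q = pw[, 3],
                   flagged = pw[, 4] > 0)
  pw <- merge_close(pw, min(grid$hx, grid$hy) / 10, grid)
  ch <- pinwheel_charge(z, pw$x, pw$y, grid)
  pw$q <- ch$q
  pw$flagged <- pw$flagged | ch$flagged
  as_pinwheel_set(pw[order(pw$x, pw$y), , drop = FALSE], grid, t, lambda)
}

#' Construct a pinwheel set from positions and charges
#'
#' Mostly useful for testing statistics on hand-built point patterns;
#' [find_pinwheels()] is the usual producer.
#'
#' @param x,y positions in \eqn{\Lambda_z} units (inside the domain).
#' @param q signed charges.
#' @param grid the [grid_spec()] defining the periodic domain.
#' @param t frame time.
#' @param lambda column spacing.
#' @param flagged logical vector (default none flagged).
#' @return a `pinwheel_set`.
#' @export
pinwheel_set <- function(x, y, q, grid, t = NA_real_, lambda = 1,
                         flagged = logical(length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(q),
            inherits(grid, "grid_spec"),
            all(x >= 0 & x < grid$lx), all(y >= 0 & y < grid$ly))
  as_pinwheel_set(data.frame(x = x, y = y, q = q, flagged = flagged),
                  grid, t, lambda)
}

as_pinwheel_set <- function(pw, grid, t, lambda) {
  rownames(pw) <- NULL
  structure(pw, grid = grid, t = t, lambda = lambda,
            class = c("pinwheel_set", "data.frame"))
}

#' @export
print.pinwheel_set <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("pinwheel_set: %d pinwheels (%d flagged), density %.3g per Lambda^2\n",
              nrow(x), sum(x$flagged), pinwheel_density(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

quad_roots <- function(c2, c1, c0) {
  if (abs(c2) < 1e-14 * max(abs(c1), abs(c0), 1)) {
    if (c1 == 0) return(numeric(0))
    return(-c0 / c1)
  }
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) return(numeric(0))
  # numerically stable pair
  qq <- -(c1 + sign(c1 + (c1 == 0)) * sqrt(disc)) / 2
  unique(c(qq / c2, if (qq != 0) c0 / qq else -c1 / c2))
}

merge_close <- function(pw, eps, grid) {
  if (nrow(pw) < 2) return(pw)
  keep <- rep(TRUE, nrow(pw))
  for (i in seq_len(nrow(pw) - 1)) {
    if (!keep[i]) next
    dx <- torus_diff(pw$x[-seq_len(i)], pw$x[i], grid$lx)
    dy <- torus_diff(pw$y[-seq_len(i)], pw$y[i], grid$ly)
    dup <- which(sqrt(dx^2 + dy^2) < eps) + i
    keep[dup] <- FALSE
  }
  pw[keep, , drop = FALSE]
}

torus_diff <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

# periodic bilinear interpolation of a real matrix at arbitrary points
interp_periodic <- function(f, xq, yq, grid) {
  gx <- xq / grid$hx; gy <- yq / grid$hy
  ix <- floor(gx); iy <- floor(gy)
  tx <- gx - ix; ty <- gy - iy
  i0 <- (ix %% grid$nx) + 1; i1 <- ((ix + 1) %% grid$nx) + 1
  j0 <- (iy %% grid$ny) + 1; j1 <- ((iy + 1) %% grid$ny) + 1
  f[cbind(j0, i0)] * (1 - tx) * (1 - ty) + f[cbind(j0, i1)] * tx * (1 - ty) +
    f[cbind(j1, i0)] * (1 - tx) * ty + f[cbind(j1, i1)] * tx * ty
}

#' Topological charge of pinwheels
#'
#' The winding number of \eqn{\arg z} along a small closed loop around each
#' centre, halved: the orientation \eqn{\theta = \arg z / 2} advances by
#' \eqn{q \cdot 2\pi} around a pinwheel of charge q.  Simple zeros give
#' \eqn{q = \pm 1/2}; ambiguous loops are retried at half the radius (the
#' loop may have enclosed a close opposite-charge pair) and then at twice
#' the radius, and flagged if the result remains non-simple.
#'
#' @param z complex field matrix.
#' @param x,y pinwheel positions in \eqn{\Lambda_z} units.
#' @param grid the [grid_spec()].
#' @param loop_radius loop radius in mesh cells (default 1.5; retried at 3).
#' @param nsamp number of loop sample points.
#' @return list with `q` (signed, in units of 1/2) and `flagged`.
#' @export
pinwheel_charge <- function(z, x, y, grid, loop_radius = 1.5, nsamp = 24) {
  re <- Re(z); im <- Im(z)
  wind <- function(xc, yc, rad_cells) {
    th <- seq(0, 2 * pi, length.out = nsamp + 1)[-(nsamp + 1)]
    px <- xc + rad_cells * grid$hx * cos(th)
    py <- yc + rad_cells * grid$hy * sin(th)
    ph <- atan2(interp_periodic(im, px, py, grid),
                interp_periodic(re, px, py, grid))
    d <- diff(c(ph, ph[1]))
    d <- (d + pi) %% (2 * pi) - pi
    sum(d) / (2 * pi)
  }
  q <- numeric(length(x)); flagged <- logical(length(x))
  for (i in seq_along(x)) {
    w <- wind(x[i], y[i], loop_radius)
    if (abs(abs(w) - 1) > 0.25) {
      for (fac in c(0.5, 2)) {
        w2 <- wind(x[i], y[i], fac * loop_radius)
        if (abs(abs(w2) - 1) <= 0.25) { w <- w2; break }
      }
      flagged[i] <- abs(abs(w) - 1) > 0.25
    }
    q[i] <- round(w) / 2
  }
  list(q = q, flagged = flagged)
}

#' Orientation preference and selectivity maps
#'
#' \eqn{\theta = \arg z / 2 \in [0, \pi)} (cyclic) and the selectivity
#' \eqn{|z|}.  Where \eqn{z = 0} the orientation is undefined and returned
#' as `NA`.
#'
#' @param z complex field matrix.
#' @return list with matrices `theta` and `selectivity`.
#' @export
orientation_and_selectivity <- function(z) {
  theta <- (Arg(z) / 2) %% pi
  theta[z == 0] <- NA_real_
  list(theta = theta, selectivity = Mod(z))
}

#' Pinwheel density per hypercolumn
#'
#' \eqn{\rho = N \Lambda^2 / (l_x l_y)}: the number of pinwheels per unit
#' area \eqn{\Lambda^2}, dimensionless and independent of the column
#' spacing.
#'
#' @param pws a `pinwheel_set` (from [find_pinwheels()]).
#' @param lambda column spacing \eqn{\Lambda}; defaults to the value stored
#'   in the set.
#' @return scalar density.
#' @export
pinwheel_density <- function(pws, lambda = attr(pws, "lambda")) {
  g <- attr(pws, "grid")
  if (g$lx * g$ly == 0) stop("zero-area domain")
  nrow(pws) * lambda^2 / (g$lx * g$ly)
}

#' Estimate the column spacing from the spectrum
#'
#' \eqn{\Lambda = 2\pi / \bar k} with \eqn{\bar k} the power-weighted mean
#' radial wavenumber of the field's spectrum (DC excluded).
#'
#' @param z complex or real field matrix.
#' @param grid the [grid_spec()].
#' @return estimated wavelength in \eqn{\Lambda_z} units.
#' @export
estimate_wavelength <- function(z, grid) {
  p <- Mod(fft2(z))^2
  p[1, 1] <- 0
  kbar <- sum(sqrt(grid$k2) * p) / sum(p)
  2 * pi / kbar
}
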