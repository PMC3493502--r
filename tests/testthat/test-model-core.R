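test_that("linear spectrum peaks at the critical circle with value r", {
  kc <- 2 * pi
  expect_equal(linear_spectrum(kc^2, r = 0.05, kc = kc), 0.05)
  expect_equal(linear_spectrum(0, r = 0.05, kc = kc), 0.05 - 1)
  k <- seq(0, 4 * kc, length.out = 2000)
  lam <- linear_spectrum(k^2, r = 0.3, kc = kc)
  expect_equal(max(lam), 0.3, tolerance = 1e-4)   # k sampled on a grid
  expect_equal(k[which.max(lam)], kc, tolerance = 1e-2)
  expect_lt(linear_spectrum((4 * kc)^2, 0.3, kc), -100)
  expect_error(linear_spectrum(1, 0.1, kc = -1), "positive")
})

test_that("apply_linear is diagonal with the spectrum on plane waves", {
  g <- tiny_grid()
  r <- 0.05
  pw <- stripes(g, c(2 * pi, 0), amplitude = 1)      # |k| = kc
  expect_rel_equal(apply_linear(pw, r, 2 * pi, g), r * pw, 1e-10)
  const <- matrix(1 + 0i, g$ny, g$nx)
  expect_rel_equal(apply_linear(const, r, 2 * pi, g), (r - 1) * const, 1e-10)
  expect_error(apply_linear(matrix(0i, 4, 4), r, 2 * pi, g), "shape")
})

test_that("spectral linear operator agrees with finite differences to O(h^2)", {
  # oracle: r - (kc^2 + D)^2 / kc^4 with D the 5-point Laplacian, applied to
  # a smooth (band-limited) field; error must shrink ~4x per mesh doubling
  r <- 0.1; kc <- 2 * pi
  errs <- vapply(c(32, 64, 128), function(n) {
    g <- grid_spec(n, n, 4, 4)
    z <- bandpass_gwn(g, target_power = 1, seed = 3)
    lap5 <- function(f) {
      (f[, c(2:g$nx, 1)] + f[, c(g$nx, 1:(g$nx - 1))] - 2 * f) / g$hx^2 +
        (f[c(2:g$ny, 1), ] + f[c(g$ny, 1:(g$ny - 1)), ] - 2 * f) / g$hy^2
    }
    fd <- r * z - (kc^4 * z + 2 * kc^2 * lap5(z) + lap5(lap5(z))) / kc^4
    max(Mod(apply_linear(z, r, kc, g) - fd)) / max(Mod(z))
  }, 0)
  expect_lt(errs[2] / errs[1], 1 / 3)
  expect_lt(errs[3] / errs[2], 1 / 3)
})

test_that("single-field energies: zero state and analytic stripe", {
  g <- tiny_grid()
  m <- model_spec(g, r_z = 0.05, fields = list(list(r = 0.25, gamma = 0)))
  zero <- field_state(matrix(0i, g$ny, g$nx),
                      list(matrix(0, g$ny, g$nx)), 0, g)
  expect_equal(unname(single_field_energy(zero, m)), c(0, 0))
  # uncoupled OP stripe z = sqrt(r) e^{i kc x}: E = -r^2/2 per unit area
  for (r_z in c(0.05, 0.2)) {
    mz <- model_spec(g, r_z = r_z)
    st <- field_state(stripes(g, c(2 * pi, 0), sqrt(r_z)), list(), 0, g)
    expect_equal(unname(single_field_energy(st, mz)["z"]), -r_z^2 / 2,
                 tolerance = 1e-10)
  }
})

test_that("coupling energies vanish for perpendicular stripes and zero strength", {
  g <- tiny_grid()
  xy <- grid_coords(g)
  z <- stripes(g, c(2 * pi, 0), 1)                       # along x
  o <- cos(outer(xy$y * 2 * pi, rep(0, g$nx), `+`))      # cos(2 pi y)
  st <- field_state(z, list(o), 0, g)
  for (kind in c("gradient2", "gradient4")) {
    m <- model_spec(g, 0.05, list(list(r = 0.25)), coupling(kind, 5))
    expect_lt(coupling_energy(st, m), 1e-20)
    f <- coupling_force(st, m)
    expect_lt(max(Mod(f$fz)), 1e-10)
    expect_lt(max(abs(f$fo[[1]])), 1e-10)
  }
  m0 <- model_spec(g, 0.05, list(list(r = 0.25)), coupling("gradient4", 0))
  stc <- random_state(g, seed = 5)
  expect_identical(coupling_energy(stc, m0), 0)
  f0 <- coupling_force(stc, m0)
  expect_equal(max(Mod(f0$fz)), 0)
})

test_that("gradient4 coupling energy matches brute-force quadrature for parallel stripes", {
  # z = A e^{ikx}, o = B cos(kx + phi): S = -A B k^2 e^{ikx} sin(kx + phi),
  # |S|^4 averaged by direct quadrature on a fine 1d mesh
  g <- tiny_grid(64, 4)
  A <- 0.7; B <- 0.4; phi <- 0.3; k <- 2 * pi; eps <- 2
  xy <- grid_coords(g)
  z <- stripes(g, c(k, 0), A)
  o <- B * matrix(cos(k * xy$x + phi), g$ny, g$nx, byrow = TRUE)
  st <- field_state(z, list(o), 0, g)
  m <- model_spec(g, 0.05, list(list(r = 0.25)), coupling("gradient4", eps))
  xs <- (seq_len(4096) - 1) / 4096 * g$lx
  oracle <- eps * (A * B * k^2)^4 * mean(sin(k * xs + phi)^4)
  expect_equal(coupling_energy(st, m), oracle, tolerance = 1e-10)
})

test_that("coupling forces are the exact discrete gradients of the energies", {
  g <- tiny_grid()
  st <- random_state(g, seed = 2)
  set.seed(11)
  pts <- cbind(sample(g$ny, 3), sample(g$nx, 3))
  for (kind in c("product2", "product4", "gradient2", "gradient4")) {
    m <- model_spec(g, 0.05, list(list(r = 0.25, gamma = 0.15)),
                    coupling(kind, 0.01))
    f <- coupling_force(st, m)
    f_un <- coupling_force(st, model_spec(g, 0.05,
                                          list(list(r = 0.25, gamma = 0.15))))
    rr <- rhs(st, m)
    for (p in seq_len(nrow(pts))) {
      i <- pts[p, 1]; j <- pts[p, 2]
      # complex field: FD w.r.t. Re and Im parts carries the Wirtinger factor 2
      fd_re <- fd_energy_grad(st, m, 0, i, j, "re")
      expect_equal(Re(rr$dz[i, j]) * m$r_z, -fd_re / 2, tolerance = 1e-5)
      fd_im <- fd_energy_grad(st, m, 0, i, j, "im")
      expect_equal(Im(rr$dz[i, j]) * m$r_z, -fd_im / 2, tolerance = 1e-5)
      fd_o <- fd_energy_grad(st, m, 1, i, j)
      expect_equal(rr$do[[1]][i, j] * m$r_z, -fd_o, tolerance = 1e-5)
    }
  }
})

test_that("finite-difference force error scales as h^2", {
  g <- tiny_grid()
  st <- random_state(g, seed = 9)
  m <- od_model(g, kind = "gradient4", strength = 0.02)
  rr <- rhs(st, m)
  i <- 5; j <- 17
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(h) {
    fd <- fd_energy_grad(st, m, 1, i, j, h = h)
    abs(rr$do[[1]][i, j] * m$r_z + fd)
  }, 0)
  # halving h must reduce the error ~4x (allow slack for the cubic term)
  expect_lt(errs[2] / errs[1], 0.4)
  expect_lt(errs[3] / errs[2], 0.4)
})

test_that("rhs: stripe fixed point, bias response, energy descent", {
  g <- tiny_grid()
  mz <- model_spec(g, r_z = 0.05)
  st <- field_state(stripes(g, c(2 * pi, 0), sqrt(0.05)), list(), 0, g)
  expect_lt(max(Mod(rhs(st, mz)$dz)), 1e-10)

  # z = 0, o = 0, gamma > 0: do/dt = gamma / (c r_z) in intrinsic time units
  m <- model_spec(g, 0.05, list(list(r = 0.25, gamma = 0.12, c = 2)))
  zero <- field_state(matrix(0i, g$ny, g$nx), list(matrix(0, g$ny, g$nx)), 0, g)
  expect_rel_equal(rhs(zero, m)$do[[1]],
                   matrix(0.12 / (2 * 0.05), g$ny, g$nx), 1e-12)

  # dE/dt <= 0 along the flow on random states (all couplings on)
  for (seed in 1:3) {
    stc <- random_state(g, seed = seed)
    mc <- od_model(g, strength = 0.02)
    rr <- rhs(stc, mc)
    dedt <- function(h) {
      st2 <- stc
      st2$z <- st2$z + h * rr$dz
      st2$o[[1]] <- st2$o[[1]] + h * rr$do[[1]]
      (total_energy(st2, mc) - total_energy(stc, mc)) / h
    }
    expect_lt(dedt(1e-6), 0)
  }
})

test_that("rhs is equivariant under lattice translation and transposition", {
  g <- tiny_grid()
  st <- random_state(g, seed = 4)
  m <- od_model(g, strength = 0.01)
  rr <- rhs(st, m)
  # translate by (3, 5) lattice vectors
  sh <- function(a) a[c(4:g$ny, 1:3), c(6:g$nx, 1:5)]
  st2 <- field_state(sh(st$z), list(sh(st$o[[1]])), 0, g)
  rr2 <- rhs(st2, m)
  expect_rel_equal(rr2$dz, sh(rr$dz), 1e-10)
  expect_rel_equal(rr2$do[[1]], sh(rr$do[[1]]), 1e-10)
  # rotate by 90 degrees (transpose on the square grid)
  st3 <- field_state(t(st$z), list(t(st$o[[1]])), 0, g)
  rr3 <- rhs(st3, m)
  expect_rel_equal(rr3$dz, t(rr$dz), 1e-10)
})

test_that("real fields stay real and multi-field couplings work", {
  g <- tiny_grid()
  m <- model_spec(g, 0.05,
                  fields = list(list(r = 0.25, gamma = 0.1),
                                list(r = 0.25, gamma = 0)),
                  couplings = list(coupling("gradient4", 0.01, c(0, 1)),
                                   coupling("gradient4", 0.01, c(0, 2)),
                                   coupling("gradient4", 0.01, c(1, 2))))
  st <- random_state(g, seed = 6, m = 2)
  rr <- rhs(st, m)
  expect_true(is.numeric(rr$do[[1]]) && is.numeric(rr$do[[2]]))
  # real-real coupling force is also an exact discrete energy gradient
  fd <- fd_energy_grad(st, m, 2, 7, 7)
  expect_equal(rr$do[[2]][7, 7] * m$r_z, -fd, tolerance = 1e-5)
})

test_that("model validation enforces the integer-wavelength rule", {
  g <- tiny_grid()
  expect_error(model_spec(g, 0.05, list(list(r = 0.25, w = 0.55))),
               "integer number of wavelengths")
  m <- model_spec(g, 0.05, list(list(r = 0.25, w = 0.5)))
  expect_equal(m$fields[[1]]$w, 0.5)
  expect_error(coupling("gradient4", -1), "strength")
  expect_error(coupling("gradient4", 1, c(1, 1)), "distinct")
  expect_error(model_spec(g, 0.05, couplings = coupling("gradient4", 1)),
               "beyond")
})
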