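test_that("Crank-Nicolson residual vanishes at fixed points and is O(dt^2) at the Euler guess", {
  g <- tiny_grid()
  mz <- model_spec(g, r_z = 0.05)
  tab <- mapcrystal:::model_tables(mz)
  u_fix <- mapcrystal:::pack_state(
    field_state(stripes(g, c(2 * pi, 0), sqrt(0.05)), list(), 0, g))
  expect_lt(max(abs(cn_residual(u_fix, u_fix, dt = 0.3, mz))), 1e-10)

  st <- random_state(g, seed = 3)
  m <- od_model(g, strength = 0.01)
  u <- mapcrystal:::pack_state(st)
  n0 <- mapcrystal:::cpp_rhs(u, mapcrystal:::model_tables(m))
  res <- vapply(c(0.1, 0.05, 0.025), function(dt)
    max(abs(cn_residual(u + dt * n0, u, dt, m, n_curr = n0))), 0)
  expect_lt(res[2] / res[1], 0.3)          # ~ dt^2
  expect_lt(res[3] / res[2], 0.3)
})

test_that("CN integration converges at order 2 to the exact linear propagator", {
  # nonlinearity negligible at tiny amplitude: exact solution is the
  # diagonal exponential exp(lambda(k) t / r_z) in Fourier space
  g <- tiny_grid()
  r_z <- 0.05
  mz <- model_spec(g, r_z = r_z)
  z0 <- bandpass_gwn(g, target_power = 1e-14, seed = 8)
  t_end <- 2
  lam <- linear_spectrum(g$k2, r_z, 2 * pi)
  exact <- ifft2(exp(lam * t_end / r_z) * fft2(z0))
  errs <- vapply(c(0.25, 0.125, 0.0625), function(dt) {
    u <- mapcrystal:::pack_state(field_state(z0, list(), 0, g))
    tab <- mapcrystal:::model_tables(mz)
    cfg <- integrator_config(newton_tol = 1e-16)
    pre <- make_preconditioner(mz, dt, 0.01)
    for (k in seq_len(round(t_end / dt))) {
      n0 <- mapcrystal:::cpp_rhs(u, tab)
      u <- newton_step(u + dt * n0, u, dt, mz, cfg, pre, n0)$u
    }
    st <- mapcrystal:::unpack_state(u, g, 0)
    max(Mod(st$z - exact)) / max(Mod(exact))
  }, 0)
  order <- log2(errs[1] / errs[2])
  order2 <- log2(errs[2] / errs[3])
  expect_gt(order, 1.9); expect_lt(order, 2.1)
  expect_gt(order2, 1.9); expect_lt(order2, 2.1)
})

test_that("jvp is exact on linear maps, O(eps) on the cubic, and rejects v = 0", {
  set.seed(2)
  A <- matrix(rnorm(100), 10, 10)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(jvp(function(x) A %*% x, u, v), A %*% v, tolerance = 1e-6)
  expect_error(jvp(function(x) x, u, rep(0, 10)), "zero direction")
  # cubic: analytic Jacobian action is 3 u^2 v; forward difference error O(eps)
  f <- function(x) x^3
  err <- abs(jvp(f, u, v) - 3 * u^2 * v)
  expect_lt(max(err), 1e-5)
})

test_that("GMRES solves small systems to the dense-solver answer", {
  set.seed(4)
  n <- 50
  A <- diag(n) + 0.1 * matrix(rnorm(n * n), n)
  b <- rnorm(n)
  sol <- gmres(function(v) A %*% v, b, m = n, tol = 1e-12)
  expect_true(sol$converged)
  expect_rel_equal(sol$x, solve(A, b), 1e-8)
  # identity: one iteration
  si <- gmres(function(v) v, b, tol = 1e-12)
  expect_equal(si$iterations, 1L)
  expect_rel_equal(si$x, b, 1e-12)
  # reported residual equals the true residual recomputed from scratch
  true_res <- sqrt(sum((b - A %*% sol$x)^2))
  expect_equal(utils::tail(sol$resnorms, 1), true_res, tolerance = 1e-8)
  # residual norms never increase over inner iterations
  expect_true(all(diff(sol$resnorms) <= 1e-12))
})

test_that("GMRES with an (inverse-)diagonal preconditioner converges in <= 2 iterations", {
  set.seed(5)
  d <- runif(40, 0.5, 50)
  b <- rnorm(40)
  sol <- gmres(function(v) d * v, b, tol = 1e-6,
               precond = function(v) v / (d + 1e-4))
  expect_true(sol$converged)
  expect_lte(sol$iterations, 2L)
})

test_that("Fourier preconditioner has the specified diagonal and accelerates GMRES", {
  g <- tiny_grid()
  m <- od_model(g, strength = 0.01)
  tab <- mapcrystal:::model_tables(m)
  dt <- 0.5; shift <- 0.01
  P <- make_preconditioner(m, dt, shift)
  mults <- attr(P, "mults")
  # mode at kc for the OP field: denominator 1 - (dt/2) r_z / r_z + shift
  i_kc <- which.min(abs(sqrt(g$k2) - 2 * pi))
  expect_equal(mults[[1]][i_kc],
               1 / (1 - (dt / 2) * tab$mu[1] * linear_spectrum(g$k2[i_kc], m$r_z, 2 * pi) + shift),
               tolerance = 1e-12)
  P0 <- make_preconditioner(m, 1e-12, shift)
  expect_equal(attr(P0, "mults")[[1]][1, 1], 1 / (1 + shift), tolerance = 1e-6)

  # measured acceleration on a standard stiff implicit step: a partly
  # saturated mid-run state of the coupled dynamics, dt of order the
  # intrinsic time
  cfgb <- kinetics_config(seed = 11, epsilon = eps_strong(), nx = 64, L = 8,
                          t_end = 30, frame_count = 3, step_rtol = 3e-4)
  fsb <- run_simulation(cfgb)
  mb <- fsb$model
  tabb <- mapcrystal:::model_tables(mb)
  u <- mapcrystal:::pack_state(fsb$frames[[length(fsb$frames)]])
  n0 <- mapcrystal:::cpp_rhs(u, tabb)
  dtb <- 2
  fn <- function(x) cn_residual(x, u, dtb, tabb, n0)
  FF <- -dtb * n0
  Pb <- make_preconditioner(mb, dtb, 0.01, state = u)
  it_plain <- gmres(function(v) jvp(fn, u, v, FF), -FF, m = 400, tol = 1e-3,
                    max_restarts = 1)$iterations
  it_pre <- gmres(function(v) jvp(fn, u, v, FF), -FF, m = 400, tol = 1e-3,
                  precond = Pb, max_restarts = 1)$iterations
  expect_gte(it_plain / it_pre, 2)
})

test_that("Newton-Krylov step: zero iterations at the solution, monotone line search at huge dt", {
  g <- tiny_grid()
  m <- od_model(g, strength = 1e-3)
  cfg <- integrator_config()
  st <- random_state(g, seed = 3)
  u <- mapcrystal:::pack_state(st)
  dt <- 0.05
  sol <- newton_step(u + dt * mapcrystal:::cpp_rhs(u, mapcrystal:::model_tables(m)),
                     u, dt, m, cfg)
  expect_true(sol$converged)
  # restart from the converged solution: declared done with zero iterations
  again <- newton_step(sol$u, u, dt, m, cfg)
  expect_identical(again$iterations, 0L)

  # deliberately huge dt from a bad guess: line search must engage yet the
  # residual history stays monotone
  big <- newton_step(u, u, 1e4, m, integrator_config(newton_max = 25))
  expect_true(any(big$line_search_s < 1))
})

test_that("adaptive integration matches a closed-form decay and is self-convergent", {
  g <- tiny_grid()
  mz <- model_spec(g, r_z = 0.05)
  z0 <- bandpass_gwn(g, target_power = 1e-12, seed = 6) *
    exp(2i * pi * 0)   # linear regime
  run <- function(rtol) {
    # the test field is deliberately tiny (amplitude ~1e-6), so both the
    # stationarity threshold and the absolute Newton tolerance must be
    # rescaled far below it
    cfg <- integrator_config(t_end = 3, frame_count = 4, step_rtol = rtol,
                             step_atol = 1e-16, stationary_tol = 1e-300,
                             newton_tol = 1e-18, gmres_tol = 1e-6)
    adaptive_integrate(field_state(z0, list(), 0, g), mz, cfg)
  }
  fs <- run(1e-4)
  lam <- linear_spectrum(g$k2, 0.05, 2 * pi)
  exact <- ifft2(exp(lam * 3 / 0.05) * fft2(z0))
  zf <- fs$frames[[length(fs$frames)]]$z
  expect_rel_equal(zf, exact, 2e-3)
  # halving the tolerance shrinks the defect
  fs2 <- run(5e-5)
  zf2 <- fs2$frames[[length(fs2$frames)]]$z
  e1 <- max(Mod(zf - exact)); e2 <- max(Mod(zf2 - exact))
  expect_lt(e2, e1 * 1.05)
})

test_that("energy is non-increasing across accepted frames and runs are deterministic", {
  g <- tiny_grid()
  m <- od_model(g, strength = 5e-4)
  ic <- random_state(g, seed = 21, zp = 0.001, op = 0.002, o_offset = 0.05)
  cfg <- integrator_config(t_end = 60, frame_count = 15)
  fs <- adaptive_integrate(ic, m, cfg)
  en <- fs$diagnostics$energy
  expect_true(all(diff(en) <= 10 * cfg$step_rtol * (abs(en[-length(en)]) + 1)))
  fs2 <- adaptive_integrate(ic, m, cfg)
  expect_identical(fs$frames[[length(fs$frames)]]$z,
                   fs2$frames[[length(fs2$frames)]]$z)
  # frame schedule: stored times match the exponential schedule
  expect_equal(fs$times[1], 0)
  expect_gt(min(diff(fs$times)), 0)
})
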