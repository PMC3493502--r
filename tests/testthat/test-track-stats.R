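test_that("power series and maturation time follow their definitions", {
  g <- tiny_grid()
  st <- field_state(stripes(g, c(2 * pi, 0), 0.3), list(matrix(0.2, g$ny, g$nx)),
                    1.5, g)
  p <- power_series(list(st))
  expect_equal(p$power_z, 0.09, tolerance = 1e-12)
  expect_equal(p$power_o1, 0.04, tolerance = 1e-12)
  expect_equal(power_series(list(field_state(matrix(0i, g$ny, g$nx),
                                             list(), 0, g)))$power_z, 0)

  # saturating curve P = 1 - exp(-t): T at the 90% crossing = -log(0.1)
  t <- seq(0, 12, by = 0.002)
  expect_equal(maturation_time(1 - exp(-t), t), -log(0.1), tolerance = 1e-2)
  # interior peak wins over the 90% rule
  pk <- exp(-(t - 3)^2) + 0.5
  expect_equal(maturation_time(pk, t), 3, tolerance = 1e-2)
  expect_error(maturation_time(t, t), "saturated")
})

test_that("nearest-neighbour distances use the torus metric and charge classes", {
  g <- tiny_grid(64, 8)
  pw <- pinwheel_set(c(1, 1.3), c(1, 1), c(0.5, -0.5), g)
  expect_equal(nn_distances(pw, "any"), c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(nn_distances(pw, "opposite"), c(0.3, 0.3), tolerance = 1e-12)
  expect_error(nn_distances(pw, "same"), "empty")
  # wraparound pair
  pw2 <- pinwheel_set(c(0.1, 7.9), c(0.1, 7.9), c(0.5, 0.5), g)
  expect_equal(nn_distances(pw2, "same"), rep(sqrt(0.08), 2), tolerance = 1e-12)
  # distances reported in units of Lambda
  pw3 <- pinwheel_set(c(1, 2), c(1, 1), c(0.5, -0.5), g, lambda = 2)
  expect_equal(nn_distances(pw3, "any"), c(0.5, 0.5))
})

test_that("density variability recovers the Poisson exponent 1/2 and is deterministic", {
  g <- grid_spec(160, 160, 20, 20)
  set.seed(3)
  rho <- 3
  gammas <- vapply(1:4, function(rep) {
    n <- rpois(1, rho * g$lx * g$ly)
    pw <- pinwheel_set(runif(n, 0, g$lx), runif(n, 0, g$ly),
                       sample(c(-0.5, 0.5), n, TRUE), g)
    density_variability(pw, n_regions = 6000, seed = 11 + rep)$gamma_v
  }, 0)
  expect_equal(mean(gammas), 0.5, tolerance = 0.05)
  # crystalline lattice: stronger suppression of large-area fluctuations
  xs <- as.vector(outer(seq(0.25, 19.75, 0.5), rep(1, 40)))
  ys <- as.vector(outer(rep(1, 40), seq(0.25, 19.75, 0.5)))
  pwl <- pinwheel_set(xs, ys, rep(c(0.5, -0.5), length.out = length(xs)), g)
  dv <- density_variability(pwl, n_regions = 6000, seed = 5)
  expect_gt(dv$gamma_v, 0.5)
  # determinism under a fixed region seed
  dv2 <- density_variability(pwl, n_regions = 6000, seed = 5)
  expect_identical(dv$gamma_v, dv2$gamma_v)
})

test_that("tracking: identity, pair annihilation, and the conservation law", {
  g <- tiny_grid(64, 8)
  p1 <- pinwheel_set(c(1, 2, 3, 5), c(1, 1, 2, 4),
                     c(0.5, -0.5, 0.5, -0.5), g, t = 0)
  tt <- track_pinwheels(list(p1, p1), times = c(0, 1))
  expect_equal(sum(tt$created), 0)
  expect_equal(sum(tt$annihilated), 0)
  expect_equal(length(tt$first), 4L)

  # remove one +/- pair: exactly two annihilations, zero creations
  p2 <- pinwheel_set(c(3, 5), c(2, 4), c(0.5, -0.5), g, t = 1)
  tt2 <- track_pinwheels(list(p1, p2), times = c(0, 1))
  expect_equal(tt2$annihilated[2], 2L)
  expect_equal(tt2$created[2], 0L)
  # conservation: N(t2) = N(t1) + created - annihilated
  expect_equal(tt2$counts[2], tt2$counts[1] + tt2$created[2] - tt2$annihilated[2])

  # matching is charge-restricted: swapped charges cannot match
  p3 <- pinwheel_set(c(1, 2), c(1, 1), c(-0.5, 0.5), g, t = 1)
  tt3 <- track_pinwheels(list(p1[1:2, ], p3), times = c(0, 1))
  # nearest same-charge candidates are 1 Lambda apart > radius 0.2
  expect_equal(tt3$created[2], 2L)
  expect_equal(tt3$annihilated[2], 2L)
})

test_that("a drifting pinwheel forms one unbroken lineage over 50 frames", {
  g <- tiny_grid(64, 8)
  sets <- lapply(0:49, function(j)
    pinwheel_set((1 + 0.05 * j) %% 8, 4, 0.5, g, t = j))
  tt <- track_pinwheels(sets, match_radius = 0.2, times = 0:49)
  expect_equal(length(tt$first), 1L)
  expect_equal(unname(tt$last[1]), 50)
  expect_equal(sum(tt$created), 0)
})

test_that("event rates and survival fractions follow their definitions", {
  g <- grid_spec(32, 32, 4, 2)    # area 8 Lambda^2
  p0 <- pinwheel_set(c(1, 2, 3), c(1, 1, 1), c(0.5, -0.5, 0.5), g, t = 0)
  p1 <- pinwheel_set(c(1, 2, 3, 0.5, 2.5, 3.5, 1.5), rep(1, 7),
                     c(0.5, -0.5, 0.5, 0.5, -0.5, 0.5, -0.5), g, t = 2)
  tt <- track_pinwheels(list(p0, p1), times = c(0, 2))
  r <- event_rates(tt)
  expect_equal(r$creation, 4 / (2 * 8))            # 4 creations, dt 2, 8 Lambda^2
  expect_equal(r$annihilation, 0)

  # survival: all lineages span the run -> s == 1
  tta <- track_pinwheels(list(p0, p0, p0), times = 0:2)
  sv <- survival_fractions(tta)
  expect_true(all(sv$s$s == 1))
  expect_equal(tail(sv$preserved$p, 1), 1)         # p(t_f) = 1 by definition

  # half the initial pinwheels die: s(t0, t_f) = expected fraction
  pb <- pinwheel_set(c(1, 2), c(1, 1), c(0.5, -0.5), g, t = 1)
  ttb <- track_pinwheels(list(p0, pb), times = c(0, 1))
  svb <- survival_fractions(ttb)
  expect_equal(tail(svb$s$s, 1), 2 / 3, tolerance = 1e-12)
  expect_error(survival_fractions(ttb, t0 = 99), "beyond")
})
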