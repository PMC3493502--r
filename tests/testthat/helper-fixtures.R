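# Shared fixtures: small grids and models used across the suite.
# Everything is built in code; no stored data.

tiny_grid <- function(n = 32, L = 4) grid_spec(n, n, L, L)

od_model <- function(grid = tiny_grid(), r_z = 0.05, r_o = 0.25,
                     gamma = 0.15, kind = "gradient4", strength = 0.01) {
  model_spec(grid, r_z,
             fields = list(list(r = r_o, gamma = gamma, w = 1, c = 1)),
             couplings = if (strength > 0) coupling(kind, strength) else list())
}

random_state <- function(grid = tiny_grid(), seed = 1, zp = 0.02, op = 0.05,
                         o_offset = 0.1, m = 1) {
  z <- bandpass_gwn(grid, target_power = zp, seed = seed)
  o <- lapply(seq_len(m), function(i)
    bandpass_gwn(grid, target_power = op, seed = seed + 10 * i, real = TRUE) +
      o_offset)
  field_state(z, o, 0, grid)
}

# numeric gradient of the total energy with respect to one grid point,
# converted to the force convention used by rhs (see the FD contract):
# d(E_avg)/d(u_p) * N equals the (doubled, for complex z) negative force
fd_energy_grad <- function(state, model, field, i, j, part = "re", h = 1e-6) {
  n <- model$grid$nx * model$grid$ny
  bump <- function(s) {
    st <- state
    if (field == 0) {
      d <- if (part == "re") complex(real = s) else complex(imaginary = s)
      st$z[i, j] <- st$z[i, j] + d
    } else st$o[[field]][i, j] <- st$o[[field]][i, j] + s
    st
  }
  (total_energy(bump(h), model) - total_energy(bump(-h), model)) / (2 * h) * n
}

expect_rel_equal <- function(x, y, tol = 1e-6) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-300), tol)
}
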