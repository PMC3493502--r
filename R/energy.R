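#' Single-field (uncoupled) energies per unit area
#'
#' Area-averaged Swift-Hohenberg energies whose gradient descent gives the
#' uncoupled dynamics: \eqn{E_z = \langle -\bar z \hat L_z z + |z|^4/2
#' \rangle} for the OP field and \eqn{E_{o_i} = \langle -o \hat L_i o / 2 +
#' o^4/4 - \gamma_i o \rangle} for each real field.
#'
#' @param state a [field_state()].
#' @param model a [model_spec()].
#' @return named numeric vector, one entry per field (`z`, `o1`, ...).
#' @examples
#' g <- grid_spec(32, 32, 4, 4)
#' m <- model_spec(g, r_z = 0.05)
#' xy <- grid_coords(g)
#' stripe <- sqrt(0.05) * exp(2i * pi * outer(rep(1, 32), xy$x))
#' single_field_energy(field_state(stripe, t = 0, grid = g), m)  # -r_z^2/2
#' @export
single_field_energy <- function(state, model) {
  e <- cpp_energy(pack_state(state), model_tables(model))
  m <- length(model$fields)
  stats::setNames(as.numeric(e$single),
                  c("z", if (m) paste0("o", seq_len(m))))
}

#' Inter-map coupling energy per unit area
#'
#' Sum of all configured pairwise coupling energies (see [coupling()] for
#' the family).  Nonnegative; zero when any coupled field is uniform
#' (gradient kinds) or zero (all kinds).
#'
#' @inheritParams single_field_energy
#' @param total if `FALSE`, return the per-coupling breakdown instead.
#' @return scalar (or vector with `total = FALSE`).
#' @export
coupling_energy <- function(state, model, total = TRUE) {
  e <- cpp_energy(pack_state(state), model_tables(model))
  if (total) sum(e$coupling) else as.numeric(e$coupling)
}

#' Total energy per unit area
#'
#' @inheritParams single_field_energy
#' @return scalar: sum of single-field and coupling energies.
#' @export
total_energy <- function(state, model)
  cpp_energy(pack_state(state), model_tables(model))$total

#' Right-hand side of the coupled gradient flow
#'
#' Evaluates the time derivatives of all fields in intrinsic time units
#' \eqn{\tau = 1/r_z}:
#' \deqn{\partial_t z = \frac{1}{r_z}\left[\hat L_z z - |z|^2 z -
#'   \frac{\delta U}{\delta \bar z}\right], \qquad
#'   \partial_t o_i = \frac{1}{c_i r_z}\left[\hat L_i o_i - o_i^3 + \gamma_i
#'   - \frac{\delta U}{\delta o_i}\right].}
#' Coupling forces are the exact (spectral) functional derivatives of the
#' discrete coupling energy, so the flow is a true gradient descent of
#' [total_energy()] on the discrete torus.
#'
#' @inheritParams single_field_energy
#' @return list with `dz` (complex matrix) and `do` (list of real matrices).
#' @export
rhs <- function(state, model) {
  tab <- model_tables(model)
  du <- cpp_rhs(pack_state(state), tab)
  st <- unpack_state(du, model$grid, length(model$fields))
  list(dz = st$z, do = st$o)
}

#' Coupling forces on each field
#'
#' The negative functional derivatives \eqn{-\delta U / \delta \bar z} and
#' \eqn{-\delta U / \delta o_i} of the total coupling energy, i.e. exactly
#' the terms the couplings add to the uncoupled right-hand side (before the
#' \eqn{1/(c_i r_z)} time-unit factors).
#'
#' @inheritParams single_field_energy
#' @return list with `fz` (complex matrix) and `fo` (list of real matrices).
#' @export
coupling_force <- function(state, model) {
  tab_full <- model_tables(model)
  tab_off <- tab_full
  tab_off$cstr <- numeric(length(tab_off$cstr))
  u <- pack_state(state)
  dd <- cpp_rhs(u, tab_full) - cpp_rhs(u, tab_off)
  # undo the per-field time-unit multipliers to expose the bare forces
  n <- model$grid$nx * model$grid$ny
  mu <- tab_full$mu
  dd[seq_len(2 * n)] <- dd[seq_len(2 * n)] / mu[1]
  for (i in seq_along(model$fields))
    dd[(1 + i) * n + seq_len(n)] <- dd[(1 + i) * n + seq_len(n)] / mu[1 + i]
  st <- unpack_state(dd, model$grid, length(model$fields))
  list(fz = st$z, fo = st$o)
}
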