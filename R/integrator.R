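#' Implicit integrator configuration
#'
#' Settings for the fully implicit Crank-Nicolson / Newton-Krylov scheme
#' with step-doubling adaptive step control.  Defaults are tuned for the
#' stiff coupled Swift-Hohenberg dynamics in intrinsic time units.
#'
#' @param dt0 initial step size.
#' @param newton_tol RMS residual tolerance declaring Newton convergence.
#' @param newton_max maximum Newton iterations before the time step is
#'   rejected and retried with a smaller `dt`.
#' @param gmres_dim Krylov subspace dimension (restart length).
#' @param gmres_tol relative residual target per linear solve (inexact
#'   Newton).
#' @param gmres_restarts maximum GMRES restart cycles per Newton iteration.
#' @param precond_shift small positive shift \eqn{\eta} in the Fourier-space
#'   preconditioner, avoiding singular mode factors.
#' @param step_rtol local-error tolerance (relative, RMS norm) for the
#'   step-doubling controller.
#' @param step_atol absolute floor added to the error scale.
#' @param grow,shrink bounds on the per-step change of `dt`.
#' @param dt_min smallest admissible step (underflow aborts the run).
#' @param dt_max largest admissible step.
#' @param t_end final time in units \eqn{\tau = 1/r_z}.
#' @param frame_count total number of stored snapshots, including the
#'   initial condition at t = 0.
#' @param frame_t0 time of the first frame of the exponential schedule.
#' @param stationary_tol RMS right-hand-side norm below which the state
#'   counts as stationary; the run stops once this is sustained for one
#'   \eqn{\tau}.
#' @param verbose print per-step progress (step, t, dt, Newton/GMRES
#'   iterations, energy).
#' @return an `integrator_config` object.
#' @export
integrator_config <- function(dt0 = 0.01, newton_tol = 1e-8, newton_max = 12,
                              gmres_dim = 30, gmres_tol = 1e-4,
                              gmres_restarts = 2, precond_shift = 0.01,
                              step_rtol = 1e-4, step_atol = 1e-9,
                              grow = 1.5, shrink = 0.5, dt_min = 1e-12,
                              dt_max = Inf,
                              t_end = 1e4, frame_count = 150, frame_t0 = 0.1,
                              stationary_tol = 1e-6, verbose = FALSE) {
  cfg <- list(dt0 = dt0, newton_tol = newton_tol, newton_max = newton_max,
              gmres_dim = as.integer(gmres_dim), gmres_tol = gmres_tol,
              gmres_restarts = as.integer(gmres_restarts),
              precond_shift = precond_shift, step_rtol = step_rtol,
              step_atol = step_atol, grow = grow, shrink = shrink,
              dt_min = dt_min, dt_max = dt_max, t_end = t_end,
              frame_count = as.integer(frame_count), frame_t0 = frame_t0,
              stationary_tol = stationary_tol, verbose = verbose)
  with(cfg, stopifnot(dt0 > 0, newton_tol > 0, gmres_dim >= 1, gmres_tol > 0,
                      precond_shift > 0, step_rtol > 0, grow > 1,
                      shrink < 1, shrink > 0, t_end > frame_t0,
                      frame_count >= 2))
  structure(cfg, class = "integrator_config")
}

rms <- function(x) sqrt(mean(x^2))

#' Crank-Nicolson residual
#'
#' \eqn{F(u') = u' - u - \frac{dt}{2}\left[N(u') + N(u)\right]} where
#' \eqn{N} is the full right-hand side ([rhs()]) on the packed state vector.
#' The Crank-Nicolson update is the root \eqn{F(u') = 0}.
#'
#' @param u_next,u_curr packed state vectors (see [pack_state()]).
#' @param dt time step.
#' @param model a [model_spec()] (or a precomputed table from the internal
#'   `model_tables()`).
#' @param n_curr optionally the cached value of `N(u_curr)`.
#' @return residual vector, same length as the state.
#' @export
cn_residual <- function(u_next, u_curr, dt, model, n_curr = NULL) {
  tab <- if (inherits(model, "model_spec")) model_tables(model) else model
  if (is.null(n_curr)) n_curr <- cpp_rhs(u_curr, tab)
  u_next - u_curr - (dt / 2) * (cpp_rhs(u_next, tab) + n_curr)
}

#' Matrix-free Jacobian-vector product
#'
#' Forward-difference approximation \eqn{[F(u + \epsilon v) - F(u)] /
#' \epsilon} of the directional derivative, with the standard matrix-free
#' step \eqn{\epsilon = \sqrt{\epsilon_{mach}} (1 + \|u\|) / \|v\|}.
#'
#' @param fn residual function of one vector argument.
#' @param u linearization point.
#' @param v direction (must be nonzero).
#' @param f0 optionally the cached value `fn(u)`.
#' @return approximate Jacobian action on `v`.
#' @export
jvp <- function(fn, u, v, f0 = fn(u)) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("jvp: zero direction vector")
  eps <- sqrt(.Machine$double.eps) * (1 + sqrt(sum(u^2))) / nv
  (fn(u + eps * v) - f0) / eps
}

#' Restarted GMRES
#'
#' Generalized Minimum Residual solver for `A x = b` with a matrix-free
#' operator, Arnoldi orthogonalization (modified Gram-Schmidt) and a
#' Hessenberg least-squares update.  An optional left preconditioner `P` is
#' composed with the operator, i.e. the method solves \eqn{P A x = P b} and
#' reports residual norms of the preconditioned system.
#'
#' @param apply_A function: the linear operator.
#' @param b right-hand side vector.
#' @param x0 initial guess (default zero).
#' @param m Krylov subspace dimension per restart cycle.
#' @param tol relative residual target (w.r.t. the initial residual).
#' @param precond optional left preconditioner function.
#' @param max_restarts maximum number of restart cycles.
#' @return list with `x`, `resnorms` (one per inner iteration, starting with
#'   the initial residual), `iterations` and `converged`.
#' @export
gmres <- function(apply_A, b, x0 = NULL, m = 30, tol = 1e-8,
                  precond = NULL, max_restarts = 10) {
  P <- if (is.null(precond)) identity else precond
  op <- function(v) P(apply_A(v))
  x <- if (is.null(x0)) numeric(length(b)) else x0
  Pb <- P(b)
  r <- Pb - if (any(x != 0)) op(x) else 0
  beta0 <- sqrt(sum(r^2))
  resnorms <- beta0
  if (beta0 == 0)
    return(list(x = x, resnorms = resnorms, iterations = 0L, converged = TRUE))
  target <- tol * beta0
  iters <- 0L
  for (cycle in seq_len(max_restarts)) {
    beta <- sqrt(sum(r^2))
    V <- matrix(0, length(b), m + 1)
    H <- matrix(0, m + 1, m)
    V[, 1] <- r / beta
    # Givens-rotation bookkeeping for the running least-squares residual
    cs <- sn <- numeric(m)
    g <- c(beta, numeric(m))
    j_used <- 0L
    for (j in seq_len(m)) {
      w <- op(V[, j])
      for (i in seq_len(j)) {           # modified Gram-Schmidt
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1, j] <- sqrt(sum(w^2))
      happy <- H[j + 1, j] < 1e-14 * beta
      if (!happy) V[, j + 1] <- w / H[j + 1, j]
      # apply previous rotations, then form the new one
      for (i in seq_len(j - 1)) {
        t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
        H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
        H[i, j] <- t1
      }
      d <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
      cs[j] <- H[j, j] / d; sn[j] <- H[j + 1, j] / d
      H[j, j] <- d; H[j + 1, j] <- 0
      g[j + 1] <- -sn[j] * g[j]; g[j] <- cs[j] * g[j]
      iters <- iters + 1L
      j_used <- j
      resnorms <- c(resnorms, abs(g[j + 1]))
      if (abs(g[j + 1]) <= target || happy) break
    }
    y <- backsolve(H[seq_len(j_used), seq_len(j_used), drop = FALSE],
                   g[seq_len(j_used)])
    x <- x + V[, seq_len(j_used), drop = FALSE] %*% y
    x <- as.numeric(x)
    if (utils::tail(resnorms, 1) <= target) break
    r <- Pb - op(x)
  }
  list(x = x, resnorms = resnorms, iterations = iters,
       converged = utils::tail(resnorms, 1) <= target)
}

#' Fourier-space preconditioner for the Crank-Nicolson Jacobian
#'
#' The inverse of the linearized Crank-Nicolson operator, diagonal in
#' Fourier space, with a small shift to avoid singular factors: mode
#' \eqn{k} of field \eqn{f} is multiplied by
#' \eqn{\left[1 - \frac{dt}{2}\mu_f\lambda_f(k) + \eta\right]^{-1}}, where
#' \eqn{\mu_f = 1/(c_f r_z)} is the field's time-unit factor.
#'
#' When a current state is supplied, the mean-field stiffness of the cubic
#' saturation (\eqn{2\langle|z|^2\rangle} for the complex field,
#' \eqn{3\langle o^2\rangle} for real fields) is folded into the diagonal,
#' which keeps the Krylov iteration effective once the pattern amplitudes
#' have saturated.
#'
#' @param model a [model_spec()].
#' @param dt time step the preconditioner is built for.
#' @param shift small positive shift \eqn{\eta}.
#' @param state optional packed state vector (or [field_state()]) whose
#'   mean square amplitudes augment the diagonal.
#' @return function acting on packed state vectors.
#' @export
make_preconditioner <- function(model, dt, shift = 0.01, state = NULL) {
  stopifnot(shift > 0)
  tab <- model_tables(model)
  g <- model$grid
  m <- length(model$fields)
  damp <- rep(list(0), m + 1)     # per-field damping added to -lambda(k)
  if (!is.null(state)) {
    if (is.numeric(state)) state <- unpack_state(state, model$grid, m)
    damp[[1]] <- 2 * mean(Mod(state$z)^2)
    for (i in seq_len(m)) damp[[1 + i]] <- 3 * mean(state$o[[i]]^2)
    # mean-field stiffness of the couplings: gradient kinds act like an
    # effective diffusion ~ k^2, product kinds like a uniform shift
    if (length(model$couplings)) {
      fields <- c(list(state$z), state$o)
      grads <- vector("list", m + 1)
      for (cp in model$couplings) {
        a <- cp$pair[1] + 1L; b <- cp$pair[2] + 1L
        s <- cp$strength
        if (s == 0) next
        if (cp$kind %in% c("gradient2", "gradient4")) {
          for (f in c(a, b)) if (is.null(grads[[f]]))
            grads[[f]] <- spectral_grad(fields[[f]], g)
          S <- grads[[a]]$x * grads[[b]]$x + grads[[a]]$y * grads[[b]]$y
          gb2 <- mean(Mod(grads[[b]]$x)^2 + Mod(grads[[b]]$y)^2)
          ga2 <- mean(Mod(grads[[a]]$x)^2 + Mod(grads[[a]]$y)^2)
          # prefactor set empirically: Krylov iteration counts on saturated
          # strong-coupling states keep improving up to ~4x the naive
          # mean-field estimate
          kap <- if (cp$kind == "gradient2") 4 * s else 8 * s * mean(Mod(S)^2)
          damp[[a]] <- damp[[a]] + kap * gb2 * g$k2
          damp[[b]] <- damp[[b]] + kap * ga2 * g$k2
        } else {
          fb2 <- mean(Mod(fields[[b]])^2); fa2 <- mean(Mod(fields[[a]])^2)
          kap <- if (cp$kind == "product2") s else 2 * s * fa2 * fb2
          damp[[a]] <- damp[[a]] + kap * fb2
          damp[[b]] <- damp[[b]] + kap * fa2
        }
      }
    }
  }
  mults <- lapply(seq_along(tab$lam), function(f)
    1 / (1 - (dt / 2) * tab$mu[f] * (tab$lam[[f]] - damp[[f]]) + shift))
  structure(function(u) cpp_fourier_diag(u, mults, g$ny, g$nx),
            mults = mults)
}

#' Solve one implicit Crank-Nicolson step by Newton-Krylov iteration
#'
#' Finds the root of the Crank-Nicolson residual by an inexact Newton
#' method: each linear system is solved matrix-free with preconditioned
#' [gmres()], and a backtracking line search on
#' \eqn{g(s) = \|F(u + s\,\delta u)\|^2 / 2} guarantees monotone residual
#' decrease.  Convergence is declared when the RMS residual drops below
#' `config$newton_tol`.
#'
#' @param u_guess starting iterate (packed state vector).
#' @param u_curr state at the beginning of the step.
#' @param dt time step.
#' @param model a [model_spec()].
#' @param config an [integrator_config()].
#' @param precond optional preconditioner (rebuilt from `dt` if missing).
#' @param n_curr optional cached right-hand side at `u_curr`.
#' @return list with `u`, `converged`, `iterations`, `resnorm` (RMS),
#'   `gmres_iters`, and `line_search_s` (step fractions per iteration).
#' @export
newton_step <- function(u_guess, u_curr, dt, model, config = integrator_config(),
                        precond = NULL, n_curr = NULL) {
  tab <- model_tables(model)
  if (is.null(n_curr)) n_curr <- cpp_rhs(u_curr, tab)
  if (is.null(precond)) precond <- make_preconditioner(model, dt, config$precond_shift)
  fn <- function(u) cn_residual(u, u_curr, dt, tab, n_curr)
  u <- u_guess
  FF <- fn(u)
  if (any(!is.finite(FF))) stop("newton_step: non-finite residual")
  # discard a predictor that is worse than the trivial guess u_curr, whose
  # residual is exactly -dt * N(u_curr)
  if (rms(FF) > dt * rms(n_curr)) {
    u <- u_curr
    FF <- -dt * n_curr
  }
  gmres_iters <- integer(0); svec <- numeric(0)
  for (it in seq_len(config$newton_max)) {
    if (rms(FF) < config$newton_tol)
      return(list(u = u, converged = TRUE, iterations = it - 1L,
                  resnorm = rms(FF), gmres_iters = gmres_iters,
                  line_search_s = svec))
    sol <- gmres(function(v) jvp(fn, u, v, FF), -FF,
                 m = config$gmres_dim, tol = config$gmres_tol,
                 precond = precond,
                 max_restarts = if (is.null(config$gmres_restarts)) 1
                                else config$gmres_restarts)
    gmres_iters <- c(gmres_iters, sol$iterations)
    du <- sol$x
    g0 <- 0.5 * sum(FF^2)
    s <- 1
    repeat {
      Fnew <- fn(u + s * du)
      if (all(is.finite(Fnew)) && 0.5 * sum(Fnew^2) < g0) break
      s <- s / 2
      if (s < 2^-12)
        return(list(u = u, converged = FALSE, iterations = it,
                    resnorm = rms(FF), gmres_iters = gmres_iters,
                    line_search_s = c(svec, s)))
    }
    svec <- c(svec, s)
    u <- u + s * du
    FF <- Fnew
  }
  list(u = u, converged = rms(FF) < config$newton_tol,
       iterations = as.integer(config$newton_max), resnorm = rms(FF),
       gmres_iters = gmres_iters, line_search_s = svec)
}

#' Integrate the coupled dynamics with adaptive implicit time stepping
#'
#' Advances a [field_state()] under the coupled gradient flow using
#' Crank-Nicolson steps solved by Newton-Krylov iteration, with
#' step-doubling local error control (one full step against two half
#' steps; the half-step solution is kept).  Snapshots are stored on an
#' exponential schedule \eqn{t_j = t_0 (t_f/t_0)^{j/(J-2)}} preceded by the
#' initial condition at \eqn{t = 0}; the step size is clamped so frame
#' times are hit exactly.  The run stops at `t_end` or once the RMS
#' right-hand side stays below `stationary_tol` for one \eqn{\tau}.
#'
#' @param ic initial [field_state()].
#' @param model a [model_spec()].
#' @param config an [integrator_config()].
#' @return a `frame_set`: list with `frames` (list of [field_state()]),
#'   `times`, `diagnostics` (per-frame data frame with power per field,
#'   energy and step statistics), `model`, `config`, and `stop_reason`.
#' @export
adaptive_integrate <- function(ic, model, config = integrator_config()) {
  stopifnot(inherits(ic, "field_state"), inherits(model, "model_spec"))
  tab <- model_tables(model)
  m <- length(model$fields)
  J <- config$frame_count
  sched <- c(0, config$frame_t0 *
               (config$t_end / config$frame_t0)^((0:(J - 2)) / max(1, J - 2)))
  u <- pack_state(ic)
  t <- 0
  dt <- config$dt0
  frames <- list(); times <- numeric(0); diag_rows <- list()
  emit <- function(u, t, dt, nwt, gmr, err) {
    st <- unpack_state(u, model$grid, m, t)
    frames[[length(frames) + 1L]] <<- st
    times[length(times) + 1L] <<- t
    en <- cpp_energy(u, tab)
    pw <- c(mean(Mod(st$z)^2), vapply(st$o, function(o) mean(o^2), 0))
    diag_rows[[length(diag_rows) + 1L]] <<- data.frame(
      t = t, dt = dt, energy = en$total,
      t(stats::setNames(pw, c("power_z", if (m) paste0("power_o", seq_len(m))))),
      newton_iters = nwt, gmres_iters = gmr, local_err = err)
  }
  emit(u, 0, 0, 0L, 0L, 0)
  next_frame <- 2L
  stat_since <- NA_real_
  stop_reason <- "t_end"
  nsteps <- 0L
  while (t < config$t_end - 1e-12) {
    n0 <- cpp_rhs(u, tab)
    if (rms(n0) < config$stationary_tol) {
      if (is.na(stat_since)) stat_since <- t
      if (t - stat_since >= 1) { stop_reason <- "stationary"; break }
    } else stat_since <- NA_real_
    if (next_frame <= length(sched))
      dt <- min(dt, sched[next_frame] - t)
    dt <- min(dt, config$t_end - t, config$dt_max)
    dt <- max(dt, config$dt_min)
    pre_full <- make_preconditioner(model, dt, config$precond_shift, u)
    pre_half <- make_preconditioner(model, dt / 2, config$precond_shift, u)
    big <- newton_step(u + dt * n0, u, dt, model, config, pre_full, n0)
    ok <- big$converged
    if (ok) {
      h1 <- newton_step(u + (dt / 2) * n0, u, dt / 2, model, config, pre_half, n0)
      ok <- h1$converged
    }
    if (ok) {
      nh <- cpp_rhs(h1$u, tab)
      h2 <- newton_step(h1$u + (dt / 2) * nh, h1$u, dt / 2, model, config,
                        pre_half, nh)
      ok <- h2$converged
    }
    if (!ok) {
      if (config$verbose)
        message(sprintf("  reject (newton) at t = %.4g dt = %.3g", t, dt))
      dt <- dt * config$shrink
      if (dt < config$dt_min) stop("adaptive_integrate: step size underflow")
      next
    }
    err <- rms(big$u - h2$u) / 3
    scale <- config$step_rtol * rms(u) + config$step_atol
    ratio <- err / scale
    fac <- if (ratio > 0) 0.9 * ratio^(-1 / 3) else config$grow
    if (ratio <= 1) {
      u <- h2$u
      t <- t + dt
      nsteps <- nsteps + 1L
      if (config$verbose)
        message(sprintf("step %d: t = %.4g dt = %.3g newton = %d err = %.2g",
                        nsteps, t, dt, big$iterations, err))
      while (next_frame <= length(sched) && t >= sched[next_frame] - 1e-9) {
        emit(u, t, dt, big$iterations, sum(big$gmres_iters), err)
        next_frame <- next_frame + 1L
      }
      dt <- dt * min(config$grow, max(config$shrink, fac))
    } else {
      if (config$verbose)
        message(sprintf("  reject (err %.2g) at t = %.4g dt = %.3g", err, t, dt))
      dt <- dt * max(config$shrink, min(1, fac))
      if (dt < config$dt_min) stop("adaptive_integrate: step size underflow")
    }
  }
  if (utils::tail(times, 1) < t - 1e-9) emit(u, t, dt, 0L, 0L, 0)
  structure(list(frames = frames, times = times,
                 diagnostics = do.call(rbind, diag_rows),
                 model = model, config = config,
                 stop_reason = stop_reason, n_steps = nsteps),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames over t = [%g, %g] (%d accepted steps, stop: %s)\n",
              length(x$frames), x$times[1], utils::tail(x$times, 1),
              x$n_steps, x$stop_reason))
  invisible(x)
}

#' @export
summary.frame_set <- function(object, ...) {
  d <- object$diagnostics
  cat(sprintf("frames: %d, t in [%g, %g]\n", nrow(d), d$t[1], utils::tail(d$t, 1)))
  cat(sprintf("final OP power: %.5g, final energy: %.5g\n",
              utils::tail(d$power_z, 1), utils::tail(d$energy, 1)))
  invisible(d)
}
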