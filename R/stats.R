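#' Power time series
#'
#' Spatially averaged power \eqn{P = \langle |z|^2 \rangle} (and
#' \eqn{\langle o_i^2 \rangle}) per stored frame.  For the uncoupled OP
#' flow the stripe attractor has \eqn{P = r_z}.
#'
#' @param frames a `frame_set` from [adaptive_integrate()], or a list of
#'   [field_state()] objects.
#' @return data frame with `t`, `power_z` and one `power_oi` column per
#'   real field.
#' @export
power_series <- function(frames) {
  if (inherits(frames, "frame_set")) {
    d <- frames$diagnostics
    return(d[, c("t", grep("^power_", names(d), value = TRUE)), drop = FALSE])
  }
  stopifnot(length(frames) >= 1)
  rows <- lapply(frames, function(st) {
    pw <- c(mean(Mod(st$z)^2), vapply(st$o, function(o) mean(o^2), 0))
    data.frame(t = st$t, t(stats::setNames(
      pw, c("power_z", if (length(st$o)) paste0("power_o", seq_along(st$o))))))
  })
  do.call(rbind, rows)
}

#' Maturation time of the OP power
#'
#' The time T at which the OP power reaches its peak value or, for curves
#' without an interior peak, first reaches 90% of its final value.
#' Developmental time is \eqn{t' = t / T}.
#'
#' @param p numeric power series (sampled to saturation).
#' @param t frame times (same length).
#' @return the maturation time T.
#' @export
maturation_time <- function(p, t) {
  stopifnot(length(p) == length(t), length(p) >= 3)
  pf <- p[length(p)]
  imax <- which.max(p)
  if (imax < length(p) && p[imax] > 1.02 * pf) return(t[imax])
  if (pf <= 0) stop("maturation_time: final power is not positive")
  # saturation check over the last 10% of the sampled time span
  t90 <- t[1] + 0.9 * (t[length(t)] - t[1])
  i90 <- which(t >= t90)[1]
  tail_dev <- abs(pf - p[i90]) / pf
  if (tail_dev > 0.05)
    stop(sprintf("maturation_time: power not saturated (relative change %.3g over the last 10%% of the run)",
                 tail_dev))
  t[which(p >= 0.9 * pf)[1]]
}

torus_dist_matrix <- function(x1, y1, x2, y2, lx, ly) {
  dx <- abs(outer(x1, x2, `-`)); dx <- pmin(dx, lx - dx)
  dy <- abs(outer(y1, y2, `-`)); dy <- pmin(dy, ly - dy)
  sqrt(dx^2 + dy^2)
}

#' Nearest-neighbour pinwheel distances
#'
#' Minimal-image (torus metric) distance from each pinwheel to its nearest
#' neighbour of arbitrary, equal, or opposite topological charge, in units
#' of the column spacing \eqn{\Lambda}.  The map is implicitly continued
#' periodically, so border pinwheels are treated correctly.
#'
#' @param pws a `pinwheel_set`.
#' @param mode `"any"`, `"same"` or `"opposite"`.
#' @param lambda column spacing (default from the set).
#' @return numeric vector of distances (one per pinwheel with a nonempty
#'   neighbour class).
#' @export
nn_distances <- function(pws, mode = c("any", "same", "opposite"),
                         lambda = attr(pws, "lambda")) {
  mode <- match.arg(mode)
  g <- attr(pws, "grid")
  n <- nrow(pws)
  if (n < 2) stop("nn_distances: need at least two pinwheels")
  D <- torus_dist_matrix(pws$x, pws$y, pws$x, pws$y, g$lx, g$ly)
  diag(D) <- Inf
  same <- outer(sign(pws$q), sign(pws$q), `==`)
  keep <- switch(mode, any = matrix(TRUE, n, n), same = same, opposite = !same)
  D[!keep] <- Inf
  d <- apply(D, 1, min)
  d <- d[is.finite(d)]
  if (!length(d)) stop(sprintf("nn_distances: empty '%s' neighbour class", mode))
  d / lambda
}

#' Pinwheel density variability over circular regions
#'
#' Samples circular regions of uniformly distributed area with uniformly
#' random centres (torus geometry), computes the standard deviation of the
#' pinwheel density over regions falling in each area bin, and fits the
#' power law \eqn{SD(A) = c\, A^{-\gamma}} on log-log axes.  A homogeneous
#' Poisson point pattern gives \eqn{\gamma = 1/2}; crystalline patterns
#' suppress large-area fluctuations and give larger exponents.
#'
#' @param pws a `pinwheel_set` (positions in \eqn{\Lambda_z} units).
#' @param n_regions total number of sampled regions.
#' @param area_range range of region areas in \eqn{\Lambda^2} (the maximum
#'   should not exceed a quarter of the domain).
#' @param bins number of log-spaced area bins.
#' @param max_per_bin cap on regions used per bin.
#' @param min_per_bin bins with fewer regions are excluded.
#' @param seed RNG seed for the region sample.
#' @return list with `table` (area, SD, n per bin), `c`, `gamma_v` and the
#'   RMS `residual` of the log-log fit.
#' @export
density_variability <- function(pws, n_regions = 10000,
                                area_range = c(0.25, 9), bins = 30,
                                max_per_bin = 1000, min_per_bin = 10,
                                seed = NULL) {
  g <- attr(pws, "grid")
  lambda <- attr(pws, "lambda")
  if (max(area_range) * lambda^2 > g$lx * g$ly / 4)
    stop("largest region area exceeds a quarter of the domain")
  with_seed(seed, {
    A <- stats::runif(n_regions, area_range[1], area_range[2]) * lambda^2
    cx <- stats::runif(n_regions, 0, g$lx)
    cy <- stats::runif(n_regions, 0, g$ly)
    rad <- sqrt(A / pi)
    counts <- integer(n_regions)
    if (nrow(pws)) {
      D <- torus_dist_matrix(cx, cy, pws$x, pws$y, g$lx, g$ly)
      counts <- as.integer(rowSums(sweep(D, 1, rad, `<=`)))
    }
    dens <- counts / (A / lambda^2)                 # per Lambda^2
    brks <- exp(seq(log(area_range[1]), log(area_range[2]),
                    length.out = bins + 1)) * lambda^2
    bin <- cut(A, brks, include.lowest = TRUE, labels = FALSE)
    tab <- lapply(seq_len(bins), function(b) {
      i <- which(bin == b)
      if (length(i) > max_per_bin) i <- i[seq_len(max_per_bin)]
      if (length(i) < min_per_bin) return(NULL)
      data.frame(area = sqrt(brks[b] * brks[b + 1]) / lambda^2,
                 sd = stats::sd(dens[i]), n = length(i))
    })
    tab <- do.call(rbind, tab)
    tab <- tab[tab$sd > 0, , drop = FALSE]
    if (is.null(tab) || nrow(tab) < 3)
      stop("density_variability: too few usable area bins")
    fit <- stats::lm(log(sd) ~ log(area), data = tab)
    list(table = tab,
         c = exp(unname(stats::coef(fit)[1])),
         gamma_v = -unname(stats::coef(fit)[2]),
         residual = sqrt(mean(stats::residuals(fit)^2)))
  })
}

#' Track pinwheels across frames
#'
#' Matches pinwheels between consecutive frames if they carry the same
#' topological charge and their (torus) positions differ by less than
#' `match_radius` \eqn{\times \Lambda}; matching is greedy by increasing
#' distance and one-to-one.  Unmatched old pinwheels count as annihilated,
#' unmatched new ones as created, so the conservation identity
#' \eqn{N_{j+1} = N_j + c_j - a_j} holds for every frame pair by
#' construction.
#'
#' @param pinwheel_sets time-ordered list of `pinwheel_set` objects.
#' @param match_radius matching threshold in units of \eqn{\Lambda}.
#' @param lambda column spacing.
#' @param times frame times (default: the `t` attribute of each set).
#' @return a `track_table`: list with `lineages` (data frame id, frame, t,
#'   x, y, q), `first`/`last` frame per lineage, `counts`, `created`,
#'   `annihilated` per frame, `times`, `match_radius`.
#' @export
track_pinwheels <- function(pinwheel_sets, match_radius = 0.2, lambda = 1,
                            times = NULL) {
  J <- length(pinwheel_sets)
  stopifnot(J >= 1)
  if (is.null(times))
    times <- vapply(pinwheel_sets, function(p) attr(p, "t"), 0)
  if (is.unsorted(times)) stop("frames must be time-ordered")
  g <- attr(pinwheel_sets[[1]], "grid")
  thr <- match_radius * lambda
  ids <- vector("list", J)
  next_id <- nrow(pinwheel_sets[[1]])
  ids[[1]] <- seq_len(next_id)
  created <- annihilated <- integer(J)
  for (j in seq_len(J - 1)) {
    p1 <- pinwheel_sets[[j]]; p2 <- pinwheel_sets[[j + 1]]
    n1 <- nrow(p1); n2 <- nrow(p2)
    id2 <- rep(NA_integer_, n2)
    if (n1 && n2) {
      D <- torus_dist_matrix(p1$x, p1$y, p2$x, p2$y, g$lx, g$ly)
      D[outer(p1$q, p2$q, `!=`)] <- Inf
      D[D > thr] <- Inf
      ord <- order(D)
      used1 <- logical(n1); used2 <- logical(n2)
      for (k in ord) {
        if (!is.finite(D[k])) break
        i <- (k - 1) %% n1 + 1; jj <- (k - 1) %/% n1 + 1
        if (used1[i] || used2[jj]) next
        used1[i] <- TRUE; used2[jj] <- TRUE
        id2[jj] <- ids[[j]][i]
      }
    }
    new <- which(is.na(id2))
    id2[new] <- next_id + seq_along(new)
    next_id <- next_id + length(new)
    ids[[j + 1]] <- id2
    created[j + 1] <- length(new)
    annihilated[j + 1] <- n1 - (n2 - length(new))
  }
  lineages <- do.call(rbind, lapply(seq_len(J), function(j) {
    p <- pinwheel_sets[[j]]
    if (!nrow(p)) return(NULL)
    data.frame(id = ids[[j]], frame = j, t = times[j],
               x = p$x, y = p$y, q = p$q)
  }))
  first <- tapply(lineages$frame, lineages$id, min)
  last <- tapply(lineages$frame, lineages$id, max)
  structure(list(lineages = lineages,
                 first = first, last = last,
                 counts = vapply(pinwheel_sets, nrow, 0L),
                 created = created, annihilated = annihilated,
                 times = times, match_radius = match_radius,
                 lambda = lambda, grid = g),
            class = "track_table")
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf(
    "track_table: %d frames, %d lineages, %d creations, %d annihilations\n",
    length(x$times), length(x$first), sum(x$created), sum(x$annihilated)))
  invisible(x)
}

#' @export
summary.track_table <- function(object, ...) {
  data.frame(frame = seq_along(object$times), t = object$times,
             n = object$counts, created = object$created,
             annihilated = object$annihilated)
}

#' Pinwheel creation and annihilation rates
#'
#' Rates per hypercolumn per unit time between consecutive frames:
#' \eqn{rate_j = N_j / (\Delta t_j \cdot l_x l_y / \Lambda^2)} with
#' \eqn{N_j} the created (annihilated) count in the interval.
#'
#' @param tracks a `track_table`.
#' @return data frame with `t` (interval midpoint in log time), `dt`,
#'   `creation`, `annihilation`.
#' @export
event_rates <- function(tracks) {
  J <- length(tracks$times)
  stopifnot(J >= 2)
  dt <- diff(tracks$times)
  if (any(dt <= 0)) stop("event_rates: zero-length frame interval")
  area <- tracks$grid$lx * tracks$grid$ly / tracks$lambda^2
  data.frame(t = sqrt(pmax(tracks$times[-J], 1e-12) * tracks$times[-1]),
             dt = dt,
             creation = tracks$created[-1] / (dt * area),
             annihilation = tracks$annihilated[-1] / (dt * area))
}

#' Pinwheel survival fractions
#'
#' For the pinwheels present at a reference time \eqn{t_0}, the fraction
#' \eqn{s(t_0, t)} whose lineages persist (without interruption) until
#' time \eqn{t}; and the preserved fraction \eqn{p(t) = s(t, t_f)}, the
#' fraction of pinwheels present at \eqn{t} that survive to the final
#' frame.
#'
#' @param tracks a `track_table`.
#' @param t0 reference time (snapped to the nearest frame at or after it).
#' @return list with `s` (data frame t, s) and `preserved` (data frame t,
#'   p over all frames).
#' @export
survival_fractions <- function(tracks, t0 = tracks$times[1]) {
  J <- length(tracks$times)
  j0 <- which(tracks$times >= t0 - 1e-9)[1]
  if (is.na(j0)) stop("t0 beyond the frame range")
  lin <- tracks$lineages
  ids0 <- lin$id[lin$frame == j0]
  if (!length(ids0)) stop("no pinwheels at t0")
  last0 <- tracks$last[as.character(ids0)]
  s <- vapply(j0:J, function(j) mean(last0 >= j), 0)
  preserved <- vapply(seq_len(J), function(j) {
    idsj <- lin$id[lin$frame == j]
    if (!length(idsj)) return(NA_real_)
    mean(tracks$last[as.character(idsj)] == J)
  }, 0)
  list(s = data.frame(t = tracks$times[j0:J], s = s),
       preserved = data.frame(t = tracks$times, p = preserved))
}
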