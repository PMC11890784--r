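# Nudged-elastic-band minimum-energy-path optimization over pluggable
# analytic potentials, including a partial-band (coordinate-mask)
# variant.
#
# Improved-tangent NEB (uphill-neighbour tangent) with a deterministic
# FIRE-style quenched-descent optimizer; climbing image available by
# flag. With a partial mask, the tangent and spring act only on masked
# coordinates while unmasked coordinates feel the bare potential force.

#' Define an analytic potential
#'
#' @param dimension Configuration-space dimension.
#' @param energy Function `x -> scalar`.
#' @param gradient Function `x -> gradient vector`.
#' @param name Display name.
#' @return A `potential_function` object.
#' @export
potential_function <- function(dimension, energy, gradient, name = "custom") {
  structure(list(dimension = as.integer(dimension), energy = energy,
                 gradient = gradient, name = name),
            class = "potential_function")
}

#' The Mueller-Brown two-dimensional benchmark surface
#'
#' Sum of four anisotropic Gaussians; the standard test surface for
#' minimum-energy-path methods, with two deep minima separated by two
#' saddle points.
#'
#' @return A `potential_function` of dimension 2.
#' @export
mueller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7)
  bb <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy <- function(x) {
    dx <- x[1] - x0
    dy <- x[2] - y0
    sum(A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2))
  }
  gradient <- function(x) {
    dx <- x[1] - x0
    dy <- x[2] - y0
    e <- A * exp(aa * dx^2 + bb * dx * dy + cc * dy^2)
    c(sum(e * (2 * aa * dx + bb * dy)), sum(e * (bb * dx + 2 * cc * dy)))
  }
  potential_function(2, energy, gradient, "mueller-brown")
}

#' Vectorized Mueller-Brown energies over a coordinate grid
#'
#' @param x,y Numeric vectors of equal length.
#' @return Energies at `(x, y)`.
#' @export
mueller_brown_energy <- function(x, y) {
  A <- c(-200, -100, -170, 15)
  aa <- c(-1, -1, -6.5, 0.7)
  bb <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  e <- 0
  for (k in 1:4) {
    e <- e + A[k] * exp(aa[k] * (x - x0[k])^2 + bb[k] * (x - x0[k]) *
                          (y - y0[k]) + cc[k] * (y - y0[k])^2)
  }
  e
}

#' Isotropic harmonic well potential
#'
#' @param dimension Configuration-space dimension (default 2).
#' @param k Force constant (default 1).
#' @return A `potential_function`.
#' @export
harmonic_well <- function(dimension = 2, k = 1) {
  potential_function(dimension,
                     function(x) 0.5 * k * sum(x^2),
                     function(x) k * x,
                     sprintf("harmonic-%dd", dimension))
}

#' Initialize an elastic band between two endpoints
#'
#' @param start,end Endpoint configuration vectors (pinned during
#'   optimization).
#' @param n_replicas Number of replicas `R >= 3`, endpoints included.
#' @param k Spring constant between adjacent replicas (energy /
#'   length^2; default 10, the value conventional for molecular-scale
#'   coordinates in kcal mol^-1 A^-2).
#' @param mask Logical vector over coordinates: the band-coordinate
#'   subset for partial NEB (default: all coordinates).
#' @return A `neb_band`: list with `replicas` (R x d matrix), `k`,
#'   `mask`.
#' @export
make_band <- function(start, end, n_replicas, k = 10, mask = NULL) {
  if (n_replicas < 3) stop_dccnet("a band needs at least 3 replicas")
  d <- length(start)
  if (length(end) != d) stop_dccnet("endpoint dimensions differ")
  mask <- mask %||% rep(TRUE, d)
  if (length(mask) != d || !any(mask)) {
    stop_dccnet("mask must be a non-empty logical over coordinates")
  }
  t <- seq(0, 1, length.out = n_replicas)
  reps <- outer(1 - t, start) + outer(t, end)
  structure(list(replicas = reps, k = k, mask = as.logical(mask)),
            class = "neb_band")
}

#' NEB forces on every replica
#'
#' Interior replicas feel the potential force projected perpendicular
#' to the local (improved, uphill-neighbour) tangent plus a spring
#' force `k (|d_next| - |d_prev|)` along the tangent. Endpoints feel
#' zero force. With `climbing`, the highest-energy interior replica
#' instead feels the full potential force with its tangent component
#' inverted and no spring.
#'
#' @param band A `neb_band`.
#' @param potential A `potential_function` of matching dimension.
#' @param climbing Apply the climbing-image force to the
#'   highest-energy interior replica (default `FALSE`).
#' @return List with `forces` (R x d matrix) and `energies` (length R).
#' @export
neb_force <- function(band, potential, climbing = FALSE) {
  reps <- band$replicas
  r <- nrow(reps)
  d <- ncol(reps)
  if (potential$dimension != d) {
    stop_dccnet("potential dimension (", potential$dimension,
                ") does not match band dimension (", d, ")")
  }
  mask <- band$mask
  energies <- apply(reps, 1, potential$energy)
  forces <- matrix(0, r, d)
  i_climb <- if (climbing && r > 2) {
    interior <- 2:(r - 1)
    interior[which.max(energies[interior])]
  } else 0L
  for (i in 2:(r - 1)) {
    g <- potential$gradient(reps[i, ])
    tau <- improved_tangent(reps[i - 1, mask], reps[i, mask],
                            reps[i + 1, mask],
                            energies[i - 1], energies[i], energies[i + 1])
    f <- numeric(d)
    f[!mask] <- -g[!mask]  # unmasked coordinates: bare potential force
    gm <- g[mask]
    if (i == i_climb) {
      f[mask] <- -gm + 2 * sum(gm * tau) * tau
    } else {
      d_next <- sqrt(sum((reps[i + 1, mask] - reps[i, mask])^2))
      d_prev <- sqrt(sum((reps[i, mask] - reps[i - 1, mask])^2))
      f[mask] <- -(gm - sum(gm * tau) * tau) +
        band$k * (d_next - d_prev) * tau
    }
    forces[i, ] <- f
  }
  list(forces = forces, energies = energies)
}

#' Optimize an elastic band to a minimum-energy path
#'
#' Damped steepest descent with FIRE-style velocity quenching on the
#' NEB forces; endpoints stay pinned. Convergence is declared when the
#' maximum per-replica displacement in an iteration falls below `tol`.
#' Non-convergence at `max_iter` flags the result rather than raising
#' an error.
#'
#' @param band A `neb_band`.
#' @param potential A `potential_function`.
#' @param tol Convergence tolerance on the per-iteration maximum
#'   replica displacement (default `1e-6`).
#' @param max_iter Iteration budget (default 20000).
#' @param dt Initial time step (default `1e-4`; adapted by FIRE).
#' @param max_step Per-coordinate displacement cap per iteration
#'   (default 0.05).
#' @param climbing Climbing-image mode (default `FALSE`).
#' @return A `neb_result`: list with `replicas`, `energies`,
#'   `i_max` (highest-energy replica index), `converged`, `iterations`
#'   and `trace` (data frame `iter`, `max_disp`, `mean_replica_rmsd`).
#' @export
optimize_band <- function(band, potential, tol = 1e-6, max_iter = 20000,
                          dt = 1e-4, max_step = 0.05, climbing = FALSE) {
  reps <- band$replicas
  r <- nrow(reps)
  d <- ncol(reps)
  v <- matrix(0, r, d)
  # FIRE parameters (standard values)
  alpha0 <- 0.1
  alpha <- alpha0
  f_inc <- 1.1
  f_dec <- 0.5
  f_alpha <- 0.99
  n_min <- 5
  dt_max <- dt * 50
  n_good <- 0
  trace_iter <- integer(0)
  trace_disp <- double(0)
  trace_rmsd <- double(0)
  converged <- FALSE
  iter <- 0
  n_small <- 0L
  work <- band
  while (iter < max_iter) {
    iter <- iter + 1
    nf <- neb_force(work, potential, climbing = climbing)
    f <- nf$forces
    p <- sum(f * v)
    if (p > 0) {
      n_good <- n_good + 1
      fn <- sqrt(sum(f^2))
      vn <- sqrt(sum(v^2))
      if (fn > 0) v <- (1 - alpha) * v + alpha * (f / fn) * vn
      if (n_good > n_min) {
        dt <- min(dt * f_inc, dt_max)
        alpha <- alpha * f_alpha
      }
    } else {
      v[] <- 0
      dt <- dt * f_dec
      alpha <- alpha0
      n_good <- 0
    }
    v <- v + dt * f
    step <- dt * v
    step <- pmin(pmax(step, -max_step), max_step)
    step[c(1, r), ] <- 0  # endpoints pinned
    work$replicas <- work$replicas + step
    max_disp <- max(abs(step))
    # steps are transiently tiny while FIRE rebuilds velocity (start-up
    # and after every reset), so convergence requires a run of
    # consecutive sub-tolerance displacements
    n_small <- if (max_disp < tol) n_small + 1L else 0L
    if (iter %% 25 == 0 || n_small >= 10L) {
      seg <- diff(work$replicas)
      trace_iter <- c(trace_iter, iter)
      trace_disp <- c(trace_disp, max_disp)
      trace_rmsd <- c(trace_rmsd, mean(sqrt(rowSums(seg^2) / d)))
    }
    if (n_small >= 10L) {
      converged <- TRUE
      break
    }
  }
  energies <- apply(work$replicas, 1, potential$energy)
  structure(list(replicas = work$replicas, energies = energies,
                 i_max = which.max(energies), converged = converged,
                 iterations = iter,
                 trace = data.frame(iter = trace_iter,
                                    max_disp = trace_disp,
                                    mean_replica_rmsd = trace_rmsd)),
            class = "neb_result")
}

#' Arc-length energy profile of an optimized path
#'
#' @param result A `neb_result`.
#' @return Data frame with `arc_length` (cumulative Euclidean) and
#'   `energy`; `attr(, "barrier")` is the maximum energy minus the
#'   energy of the start replica.
#' @export
path_profile <- function(result) {
  seg <- sqrt(rowSums(diff(result$replicas)^2))
  out <- data.frame(arc_length = c(0, cumsum(seg)),
                    energy = result$energies)
  attr(out, "barrier") <- max(result$energies) - result$energies[1]
  out
}

# -- internals ----------------------------------------------------------

# Improved (uphill-neighbour) tangent of Henkelman & Jonsson; returns a
# unit vector over the masked coordinates.
improved_tangent <- function(prev, here, nxt, e_prev, e_here, e_next) {
  t_plus <- nxt - here
  t_minus <- here - prev
  if (e_next > e_here && e_here > e_prev) {
    tau <- t_plus
  } else if (e_next < e_here && e_here < e_prev) {
    tau <- t_minus
  } else {
    dv_max <- max(abs(e_next - e_here), abs(e_prev - e_here))
    dv_min <- min(abs(e_next - e_here), abs(e_prev - e_here))
    tau <- if (e_next >= e_prev) {
      t_plus * dv_max + t_minus * dv_min
    } else {
      t_plus * dv_min + t_minus * dv_max
    }
  }
  nrm <- sqrt(sum(tau^2))
  if (nrm == 0) {
    tau <- t_plus + t_minus
    nrm <- sqrt(sum(tau^2))
    if (nrm == 0) return(rep(0, length(tau)))
  }
  tau / nrm
}

#' @export
print.neb_result <- function(x, ...) {
  cat("neb_result:", nrow(x$replicas), "replicas,",
      if (x$converged) "converged" else "NOT converged", "after",
      x$iterations, "iterations; barrier =",
      round(max(x$energies) - x$energies[1], 4), "\n")
  invisible(x)
}
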