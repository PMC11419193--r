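# Advection-reaction transport of the DCACl/Lipiodol bolus on the solved
# flow field. The bolus saturation so obeys
#   d so/dt + d(u so)/dx = -lambda so,   lambda = gamma_t eps rho_DCACl/rho_o
# discretized with a backward Euler upwind scheme on the graph: each node
# receives flux-weighted upstream saturation, loses its advective outflux,
# and decays at rate lambda. The temperature rise obeys the matching energy
# equation with source h eps gamma_t rho_DCACl / (W rho_b cp_b) * so.

#' Per-node control volumes
#'
#' Each node owns half of every incident branch cylinder:
#' `dV_x = sum over incident edges of pi R^2 L / 2` (m^3). Summed over all
#' nodes this equals the total cylinder volume of the network.
#'
#' @param g A `vessel_graph` with edge geometry.
#' @return Numeric vector of node volumes, m^3.
#' @export
node_volumes <- function(g) {
  stopifnot(inherits(g, "vessel_graph"))
  e <- g$edges
  if (is.null(e$radius) || is.null(e$length))
    stop("edge geometry missing; run edge_geometry() first")
  half <- pi * (e$radius * 1e-3)^2 * (e$length * 1e-3) / 2
  v <- numeric(nrow(g$nodes))
  for (k in seq_len(nrow(e))) {
    v[e$from[k]] <- v[e$from[k]] + half[k]
    v[e$to[k]] <- v[e$to[k]] + half[k]
  }
  v
}

#' Simulate bolus transport, reaction and heating
#'
#' Injects the bolus as a saturated plug at the root (inlet saturation 1
#' for a duration `V_injected / q_root`, i.e. the pure bolus temporarily
#' displaces blood at the catheterized inlet), advects it passively on the
#' static blood-flow field, reacts it at first-order rate
#' `lambda = gamma_t * epsilon * rho_DCACl / rho_o`, and accumulates the
#' per-node cumulative reacted fraction
#' `D_x = lambda / V_injected * sum_t so(x,t) dt dV_x` together with the
#' escaped unreacted fraction `beta` (terminal sink outflux of saturation,
#' integrated over time). Time stepping is implicit (unconditionally
#' stable); the default step is `courant * min(L/|u|)` over flowing edges.
#' The run stops when the bolus volume still in the network falls below
#' `stop_frac * V_injected` (after the injection has ended) or at
#' `n_max` steps.
#'
#' @param g A `vessel_graph` with roles and geometry.
#' @param sol The matching `flow_solution`.
#' @param bp A [bolus_params()] (supplies `gamma_t`, `epsilon`, densities,
#'   injected volume and the energy-equation constants).
#' @param dt Time step, s; default `courant * min(L/|u|)`.
#' @param courant Courant number used for the default step.
#' @param inj_duration Injection duration, s; default `V_injected / q_root`.
#'   `Inf` keeps the inlet saturated for the whole run (used for
#'   steady-state benchmarks together with `n_steps`).
#' @param n_steps If given, run exactly this many steps (no stop criterion).
#' @param n_max Step cap; hitting it issues a warning with the residual.
#' @param stop_frac Remaining-bolus fraction below which the run stops.
#' @param temperature Track the temperature-rise equation (slightly slower).
#' @return An object of class `transport_result`: per-node damage `D`,
#'   escaped fraction `beta`, residual fraction, per-node final saturation
#'   `so`, per-node peak temperature rise `dT` (K) and scalar `T_max`,
#'   elapsed time `t_end`, steps `n_steps`, time step `dt` and the node
#'   volumes used.
#' @export
simulate_transport <- function(g, sol, bp, dt = NULL, courant = 0.5,
                               inj_duration = NULL, n_steps = NULL,
                               n_max = 1e6, stop_frac = 1e-6,
                               temperature = TRUE) {
  stopifnot(inherits(g, "vessel_graph"), inherits(sol, "flow_solution"),
            inherits(bp, "bolus_params"))
  n <- nrow(g$nodes)
  V <- node_volumes(g)
  lambda <- bp$gamma_t * bp$epsilon * bp$rho_dcacl / bp$rho_o
  v_inj <- bp$v_dcacl_ul * 1e-9  # uL -> m^3

  qa <- abs(sol$q)
  flowing <- qa > 1e-18
  if (!any(flowing) || sol$q_total <= 1e-16)
    stop("flow field is stagnant; bolus transport is undefined")
  up <- ifelse(sol$q >= 0, g$edges$from, g$edges$to)
  dn <- ifelse(sol$q >= 0, g$edges$to, g$edges$from)

  if (is.null(dt)) {
    tau <- (g$edges$length * 1e-3) / abs(sol$u)
    dt <- courant * min(tau[flowing])
  }
  stopifnot(dt > 0)

  out <- numeric(n)
  for (e in which(flowing)) out[up[e]] <- out[up[e]] + qa[e]
  out[sol$terminals] <- out[sol$terminals] + sol$sink_flow
  root <- sol$root
  q_root <- out[root]
  if (q_root <= 0) stop("no outflow at the root; cannot inject")
  if (is.null(inj_duration)) inj_duration <- v_inj / q_root

  fe <- which(flowing)
  M <- Matrix::sparseMatrix(i = dn[fe], j = up[fe], x = -qa[fe],
                            dims = c(n, n)) +
    Matrix::Diagonal(n, V / dt + out + lambda * V)
  lu <- Matrix::lu(M)
  if (temperature) {
    Mt <- Matrix::sparseMatrix(i = dn[fe], j = up[fe], x = -qa[fe],
                               dims = c(n, n)) +
      Matrix::Diagonal(n, V / dt + out)
    lut <- Matrix::lu(Mt)
    src <- bp$h * bp$epsilon * bp$gamma_t * bp$rho_dcacl /
      (bp$molar_mass * bp$rho_b * bp$cp_b)
  }

  so <- numeric(n)
  so_min <- 0; so_max <- 0
  Tn <- numeric(n)
  dT_max <- numeric(n)
  reacted <- numeric(n)
  injected <- 0; escaped <- 0
  t <- 0; step <- 0L
  term <- sol$terminals
  cap_hit <- FALSE

  repeat {
    step <- step + 1L
    frac <- max(0, min(t + dt, inj_duration) - t) / dt  # inlet duty cycle
    rhs <- V * so / dt
    rhs[root] <- rhs[root] + q_root * frac
    so <- as.numeric(Matrix::solve(lu, rhs))
    so_min <- min(so_min, min(so)); so_max <- max(so_max, max(so))
    injected <- injected + q_root * frac * dt
    reacted <- reacted + lambda * V * so * dt
    escaped <- escaped + sum(sol$sink_flow * so[term]) * dt
    if (temperature) {
      rhs_t <- V * Tn / dt + src * V * so
      Tn <- as.numeric(Matrix::solve(lut, rhs_t))
      dT_max <- pmax(dT_max, Tn)
    }
    t <- t + dt
    residual <- sum(V * so)
    if (!is.null(n_steps)) {
      if (step >= n_steps) break
    } else {
      if (t >= inj_duration && residual < stop_frac * v_inj) break
      if (step >= n_max) { cap_hit <- TRUE; break }
    }
  }
  if (cap_hit)
    warning(sprintf("step cap %d reached; residual bolus fraction %.3g",
                    n_max, residual / v_inj))

  structure(list(D = reacted / v_inj, beta = escaped / v_inj,
                 residual_frac = residual / v_inj,
                 injected_frac = injected / v_inj,
                 so = so, so_min = so_min, so_max = so_max,
                 dT = dT_max, T_max = max(dT_max),
                 t_end = t, n_steps = step, dt = dt, lambda = lambda,
                 node_volume = V, q_root = q_root),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(
    "transport_result: %d steps (dt = %.3g s, t_end = %.3g s)\n  reacted %.4f, escaped (beta) %.4f, residual %.2g; max dT = %.3g K\n",
    x$n_steps, x$dt, x$t_end, sum(x$D), x$beta, x$residual_frac, x$T_max))
  invisible(x)
}

#' Tag predicted embolization sites
#'
#' A vascular element is tagged when its cumulative reacted fraction
#' reaches the damage threshold: `tagged(x) = D_x >= delta`.
#'
#' @param res A `transport_result`.
#' @param delta Damage threshold, fraction in (0, 1).
#' @return An object of class `embolization_prediction` with logical
#'   `tagged` per node and the threshold used.
#' @export
tag_embolization <- function(res, delta) {
  stopifnot(inherits(res, "transport_result"), delta > 0, delta < 1)
  structure(list(tagged = res$D >= delta, delta = delta),
            class = "embolization_prediction")
}
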