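# Steady Hagen-Poiseuille network flow. Each edge is a resistive branch
# with conductance k = pi R^4 / (8 mu L); mass balance holds at interior
# nodes, the root carries a Dirichlet pressure (mean arterial pressure) and
# every terminal drains through a lumped conductance gamma_a / mu to the
# central venous sink pressure.

#' Hagen-Poiseuille edge conductance
#'
#' `k = pi R^4 / (8 mu L)` in m^3/(Pa s): laminar fully developed flow in a
#' cylindrical branch of radius `R` and length `L`.
#'
#' @param radius_m Edge radius, m.
#' @param length_m Edge length, m.
#' @param mu Dynamic viscosity, Pa s.
#' @return Conductance, m^3/(Pa s).
#' @export
conductance <- function(radius_m, length_m, mu) {
  if (any(radius_m <= 0) || any(length_m <= 0) || any(mu <= 0))
    stop("radius, length and viscosity must be positive")
  pi * radius_m^4 / (8 * mu * length_m)
}

#' Solve the network pressure and flow field
#'
#' Assembles the sparse node balance system: at interior nodes
#' `sum_j k_ij (P_i - P_j) = 0`; at the root `P = P_MAP`; at terminals
#' `sum_j k_ij (P_i - P_j) + (gamma_a/mu) (P_CVP - P_i) = 0`. The Dirichlet
#' row is eliminated and the remaining symmetric positive-definite system is
#' solved with a sparse direct method.
#'
#' @param g A `vessel_graph` with roles and edge geometry.
#' @param p A [flow_params()].
#' @return An object of class `flow_solution`: node pressures `P` (Pa),
#'   directed edge flows `q` (m^3/s, positive from `from` to `to`), mean
#'   velocities `u` (m/s), per-terminal `sink_flow` (m^3/s), total perfusion
#'   `q_total` (m^3/s) and `q_total_mlmin`, plus the edge orientation and
#'   conductances used.
#' @export
solve_pressures <- function(g, p) {
  stopifnot(inherits(g, "vessel_graph"), inherits(p, "flow_params"))
  nodes <- g$nodes; edges <- g$edges
  if (!any(nodes$role == "root", na.rm = TRUE))
    stop("graph has no root; run classify_nodes() first")
  if (sum(nodes$role == "root", na.rm = TRUE) != 1L)
    stop("graph must have exactly one root")
  if (is.null(edges$radius) || is.null(edges$length))
    stop("edge geometry missing; run edge_geometry() first")

  n <- nrow(nodes)
  root <- which(nodes$role == "root")
  term <- which(nodes$role == "terminal")
  p_map <- p$p_map * MMHG_TO_PA
  p_cvp <- p$p_cvp * MMHG_TO_PA
  k <- conductance(edges$radius * 1e-3, edges$length * 1e-3, p$mu)
  g_term <- p$gamma_a / p$mu

  free <- setdiff(seq_len(n), root)
  idx <- integer(n); idx[free] <- seq_along(free)

  ef <- edges$from; et <- edges$to
  ii <- c(idx[ef], idx[et], idx[ef], idx[et])
  jj <- c(idx[ef], idx[et], idx[et], idx[ef])
  xx <- c(k, k, -k, -k)
  keep <- ii > 0 & jj > 0
  A <- Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = xx[keep],
                            dims = c(n - 1L, n - 1L))
  # sink conductance on terminals; Dirichlet contributions to the rhs
  diag_add <- numeric(n - 1L)
  diag_add[idx[term]] <- g_term
  A <- A + Matrix::Diagonal(n - 1L, diag_add)
  b <- numeric(n - 1L)
  b[idx[term]] <- b[idx[term]] + g_term * p_cvp
  on_root <- ef == root | et == root
  if (any(on_root)) {
    other <- ifelse(ef[on_root] == root, et[on_root], ef[on_root])
    b[idx[other]] <- b[idx[other]] + k[on_root] * p_map
  }

  P <- numeric(n)
  P[root] <- p_map
  sol <- tryCatch(Matrix::solve(A, b),
                  error = function(e) stop("flow system is singular: ",
                                           conditionMessage(e)))
  P[free] <- as.numeric(sol)

  q <- k * (P[ef] - P[et])          # positive: from -> to
  u <- q / (pi * (edges$radius * 1e-3)^2)
  sink_flow <- g_term * (P[term] - p_cvp)
  names(sink_flow) <- term
  q_total <- sum(sink_flow)
  structure(list(P = P, q = q, u = u, k = k,
                 sink_flow = sink_flow, terminals = term, root = root,
                 q_total = q_total, q_total_mlmin = q_total * M3S_TO_MLMIN,
                 p_map_pa = p_map, p_cvp_pa = p_cvp, gamma_a = p$gamma_a,
                 mu = p$mu),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "flow_solution: %d nodes, q_total = %.4g mL/min, P in [%.2f, %.2f] mmHg\n",
    length(x$P), x$q_total_mlmin, min(x$P) / MMHG_TO_PA,
    max(x$P) / MMHG_TO_PA))
  invisible(x)
}

#' Total simulated perfusion in mL/min
#'
#' Sum of terminal sink outfluxes `(gamma_a/mu) (P_i - P_CVP)`; equals the
#' root influx by mass balance.
#'
#' @param sol A `flow_solution`.
#' @return Perfusion, mL/min.
#' @export
total_perfusion <- function(sol) {
  stopifnot(inherits(sol, "flow_solution"))
  sol$q_total_mlmin
}

# Interior-node mass-balance residuals (m^3/s), for diagnostics and tests.
flow_residuals <- function(g, sol) {
  n <- nrow(g$nodes)
  res <- numeric(n)
  ef <- g$edges$from; et <- g$edges$to
  for (e in seq_along(sol$q)) {
    res[ef[e]] <- res[ef[e]] - sol$q[e]
    res[et[e]] <- res[et[e]] + sol$q[e]
  }
  res[sol$terminals] <- res[sol$terminals] - sol$sink_flow
  res
}
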