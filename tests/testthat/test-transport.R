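test_that("node control volumes partition the branch cylinders", {
  # single edge R = 1 mm, L = 10 mm: each endpoint gets half the cylinder
  nodes <- data.frame(id = 1:2, x = c(0, 10), y = 0, z = 0, radius = 1)
  g <- edge_geometry(classify_nodes(
    vessel_graph(nodes, data.frame(from = 1L, to = 2L)), 1L))
  v <- node_volumes(g)
  expect_equal(v, rep(pi * (1e-3)^2 * 1e-2 / 2, 2), tolerance = 1e-12)
  expect_equal(v[1], 1.5708e-8, tolerance = 1e-4)

  # two identical edges in a path: middle node holds twice an end node
  g3 <- pipe_graph(3, dx_mm = 10, r_mm = 1)
  v3 <- node_volumes(g3)
  expect_equal(v3[2], 2 * v3[1])

  g5 <- fx_small_graph()
  expect_equal(sum(node_volumes(g5)),
               sum(pi * (g5$edges$radius * 1e-3)^2 *
                     (g5$edges$length * 1e-3)), tolerance = 1e-12)
})

test_that("steady pipe saturation matches the analytic exponential profile", {
  n <- 400
  g <- pipe_graph(n, dx_mm = 0.5, r_mm = 0.5)
  u_target <- 0.3  # m/s
  q_target <- u_target * pi * (0.5e-3)^2 * 6e7  # mL/min
  cal <- calibrate_gamma_a(g, flow_params(), q_target)
  sol <- solve_pressures(g, flow_params(gamma_a = cal$gamma_a))
  bp <- bolus_params(gamma_t = 13)
  expect_equal(bp$gamma_t * bp$epsilon * bp$rho_dcacl / bp$rho_o, 2.986,
               tolerance = 1e-3)
  res <- simulate_transport(g, sol, bp, inj_duration = Inf, n_steps = 1500,
                            temperature = FALSE)
  u <- mean(sol$u)
  lambda <- res$lambda
  x <- (g$nodes$x - g$nodes$x[1]) * 1e-3
  expected <- exp(-lambda * x / u)
  probe <- which(expected > 0.1)[-1]  # skip the inlet node itself
  expect_equal(res$so[probe] / res$so[2] * expected[2], expected[probe],
               tolerance = 0.01)
})

test_that("halving the time step changes total damage by less than 1%", {
  n <- 150
  g <- pipe_graph(n, dx_mm = 0.5, r_mm = 0.5)
  cal <- calibrate_gamma_a(g, flow_params(),
                           0.3 * pi * (0.5e-3)^2 * 6e7)
  sol <- solve_pressures(g, flow_params(gamma_a = cal$gamma_a))
  bp <- bolus_params(gamma_t = 13, v_dcacl_ul = 30)
  r1 <- simulate_transport(g, sol, bp, temperature = FALSE)
  r2 <- simulate_transport(g, sol, bp, dt = r1$dt / 2, temperature = FALSE)
  expect_lt(abs(sum(r2$D) - sum(r1$D)) / sum(r1$D), 0.01)
})

test_that("mass is conserved: injected = reacted + escaped + residual", {
  sub <- fx_subject()
  bp0 <- bolus_params(v_dcacl_ul = sub$injected_ul)
  for (gt in c(0, 5, 14)) {
    bp <- bp0; bp$gamma_t <- gt
    res <- simulate_transport(sub$graph, sub$sol, bp, temperature = FALSE)
    expect_equal(res$injected_frac, 1, tolerance = 1e-9)
    expect_lt(abs(sum(res$D) + res$beta + res$residual_frac -
                    res$injected_frac), 1e-6)
    expect_gte(res$so_min, -1e-12)
    expect_lte(res$so_max, 1 + 1e-9)
  }
})

test_that("reaction-rate limits behave physically", {
  sub <- fx_subject()
  # no reaction: all bolus escapes unreacted
  bp <- bolus_params(gamma_t = 0, v_dcacl_ul = sub$injected_ul)
  res0 <- simulate_transport(sub$graph, sub$sol, bp, temperature = FALSE)
  expect_equal(res0$beta, 1, tolerance = 1e-6)
  expect_true(all(res0$D == 0))

  # instant reaction: everything reacts at/near the injection site
  bp$gamma_t <- 1e4
  res_inf <- simulate_transport(sub$graph, sub$sol, bp, temperature = FALSE)
  expect_lt(res_inf$beta, 1e-3)
  root <- which(sub$graph$nodes$role == "root")
  near <- c(root, sub$graph$edges$to[sub$graph$edges$from == root],
            sub$graph$edges$from[sub$graph$edges$to == root])
  expect_gt(sum(res_inf$D[unique(near)]), 0.5)
})

test_that("damage reach extends downstream as hydrolysis slows", {
  sub <- fx_subject()
  g <- sub$graph
  root <- which(g$nodes$role == "root")
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$from, to = g$edges$to,
               weight = g$edges$length),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(g$nodes))))
  dist_root <- as.numeric(igraph::distances(ig, v = as.character(root)))
  reach <- vapply(c(8, 11, 14, 17, 20), function(gt) {
    bp <- bolus_params(gamma_t = gt, v_dcacl_ul = sub$injected_ul)
    res <- simulate_transport(g, sub$sol, bp, temperature = FALSE)
    max(dist_root[tag_embolization(res, 0.01)$tagged])
  }, numeric(1))
  expect_true(all(diff(reach) <= 1e-9))
  expect_lt(reach[5], reach[1])
})

test_that("temperature rise is non-negative, linear in the reaction enthalpy, and absent without reaction", {
  g <- fx_small_graph()
  cal <- calibrate_gamma_a(g, flow_params(), 10)
  sol <- solve_pressures(g, flow_params(gamma_a = cal$gamma_a))
  bp <- bolus_params(gamma_t = 13, v_dcacl_ul = 100)
  r1 <- simulate_transport(g, sol, bp)
  expect_true(all(r1$dT >= 0))
  expect_gt(r1$T_max, 0)
  bp2 <- bp; bp2$h <- 2 * bp$h
  r2 <- simulate_transport(g, sol, bp2)
  expect_equal(r2$T_max, 2 * r1$T_max, tolerance = 1e-9)
  bp0 <- bolus_params(gamma_t = 0, v_dcacl_ul = 100)
  expect_equal(simulate_transport(g, sol, bp0)$T_max, 0)
})

test_that("stagnant flow fields are rejected and thresholds act as written", {
  g <- fx_small_graph()
  sol <- solve_pressures(g, flow_params(gamma_a = 1e-30))
  expect_error(simulate_transport(g, sol, bolus_params()), "stagnant")

  res <- structure(list(D = c(0.02, 0.005)), class = "transport_result")
  expect_equal(tag_embolization(res, 0.01)$tagged, c(TRUE, FALSE))
  expect_equal(tag_embolization(res, 1e-9)$tagged, c(TRUE, TRUE))
  expect_equal(tag_embolization(res, 0.5)$tagged, c(FALSE, FALSE))
})
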