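# Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

# Default depth-5 study fixture with forward-simulated labels at
# gamma_t = 14, delta = 1%.
fx_subject <- function() {
  if (is.null(.fx$subject))
    .fx$subject <- make_observed(synthetic_subject(),
                                 gamma_t_true = 14, delta_true = 0.01)
  .fx$subject
}

# Small, fast depth-3 tree graph for flow/transport unit tests.
fx_small_graph <- function() {
  if (is.null(.fx$small)) {
    tree <- make_tree(tree_spec(depth = 3, segment_length = 12))
    .fx$small <- build_vessel_graph(tree$volume)
  }
  .fx$small
}

# A straight pipe graph built directly (no rasterization): n nodes,
# spacing dx_mm, constant radius r_mm, root at node 1.
pipe_graph <- function(n, dx_mm = 0.5, r_mm = 0.5) {
  nodes <- data.frame(id = seq_len(n), x = (seq_len(n) - 1) * dx_mm,
                      y = 0, z = 0, radius = r_mm)
  edges <- data.frame(from = seq_len(n - 1), to = 2:n)
  g <- vessel_graph(nodes, edges)
  edge_geometry(classify_nodes(g, 1L))
}

# A two-node root--terminal graph whose single edge has a prescribed
# conductance k (m^3/(Pa s)) under viscosity mu, via the radius/length.
two_node_graph <- function(k, mu, length_mm = 10) {
  r_m <- (k * 8 * mu * length_mm * 1e-3 / pi)^0.25
  nodes <- data.frame(id = 1:2, x = c(0, length_mm), y = 0, z = 0,
                      radius = r_m * 1e3)
  g <- vessel_graph(nodes, data.frame(from = 1L, to = 2L))
  edge_geometry(classify_nodes(g, 1L))
}

# Random tree graph for solver oracle tests: node 1 is the root (degree 1,
# child node 2); later nodes attach to a random earlier non-root node.
random_tree_graph <- function(n, seed) {
  set.seed(seed)
  stopifnot(n >= 3)
  parent <- c(NA_integer_, 1L,
              vapply(3:n, function(i) (2:(i - 1))[sample.int(i - 2, 1)],
                     integer(1)))
  nodes <- data.frame(id = seq_len(n),
                      x = runif(n, 0, 50), y = runif(n, 0, 50),
                      z = runif(n, 0, 50),
                      radius = runif(n, 0.3, 1.5))
  edges <- data.frame(from = parent[-1], to = 2:n,
                      length = runif(n - 1, 0.5, 2))
  g <- vessel_graph(nodes, edges)
  edge_geometry(classify_nodes(g, 1L))
}

# Small volume helpers: an empty 3D array with given voxels set.
volume_with_voxels <- function(dims, ijk0, values = 1, spacing = c(1, 1, 1)) {
  arr <- array(0, dim = dims)
  if (!is.matrix(ijk0)) ijk0 <- matrix(ijk0, ncol = 3L, byrow = TRUE)
  for (r in seq_len(nrow(ijk0)))
    arr[ijk0[r, 1] + 1L, ijk0[r, 2] + 1L, ijk0[r, 3] + 1L] <-
      if (length(values) == 1) values else values[r]
  centerline_volume(arr, spacing = spacing)
}
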