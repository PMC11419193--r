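test_that("NIfTI round trip preserves voxel counts, radii and spacing", {
  vol <- volume_with_voxels(c(5, 5, 5), c(1, 1, 1, 2, 1, 1, 3, 1, 1),
                            values = c(1, 1.5, 2))
  path <- tempfile(fileext = ".nii.gz")
  write_centerline(vol, path)
  rt <- read_centerline(path)
  expect_equal(n_centerline_voxels(rt), 3L)
  expect_equal(sort(rt$values[rt$values > 0]), c(1, 1.5, 2))

  aniso <- volume_with_voxels(c(4, 4, 4), c(1, 1, 1),
                              spacing = c(0.8, 0.8, 0.5))
  path2 <- tempfile(fileext = ".nii.gz")
  write_centerline(aniso, path2)
  expect_equal(read_centerline(path2)$spacing, c(0.8, 0.8, 0.5),
               tolerance = 1e-6)
})

test_that("degenerate volumes are rejected", {
  zero <- array(0, dim = c(4, 4, 4))
  path <- tempfile(fileext = ".nii.gz")
  write_centerline(zero, path)
  expect_error(read_centerline(path), "empty")
  expect_error(centerline_volume(array(1, dim = c(3, 3))), "3D")
  expect_error(centerline_volume(array(-1, dim = c(3, 3, 3))),
               "non-negative")
})

test_that("26-neighbourhood connectivity produces the expected components", {
  # three collinear voxels, 1 mm spacing: one chain, two unit edges
  chain <- volume_with_voxels(c(5, 5, 5), c(1, 2, 2, 2, 2, 2, 3, 2, 2))
  comps <- build_components(chain)
  expect_length(comps, 1L)
  expect_equal(nrow(comps[[1]]$edges), 2L)
  expect_equal(comps[[1]]$edges$length, c(1, 1))

  # in-plane diagonal contact at 0.8 mm spacing: connected, length 0.8*sqrt(2)
  diag2 <- volume_with_voxels(c(5, 5, 5), c(1, 1, 1, 2, 2, 1),
                              spacing = c(0.8, 0.8, 0.8))
  comps <- build_components(diag2)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$edges$length, 0.8 * sqrt(2), tolerance = 1e-12)

  # two clusters separated by >= 2 voxels: sizes [5, 3], largest first
  two <- volume_with_voxels(c(12, 5, 5), rbind(
    cbind(0:4, 1, 1),        # 5-voxel chain
    cbind(8:10, 1, 1)))      # 3-voxel chain
  comps <- build_components(two)
  expect_equal(vapply(comps, function(g) nrow(g$nodes), integer(1)),
               c(5L, 3L))
})

test_that("no voxel is lost or duplicated and adjacency is symmetric", {
  set.seed(42)
  for (rep in 1:5) {
    arr <- array(0, dim = c(8, 8, 8))
    arr[sample(length(arr), 40)] <- runif(40, 0.5, 2)
    vol <- centerline_volume(arr, spacing = c(0.8, 0.8, 0.5))
    comps <- build_components(vol)
    expect_equal(sum(vapply(comps, function(g) nrow(g$nodes), integer(1))),
                 n_centerline_voxels(vol))
    for (g in comps) {
      # undirected symmetry: each unordered pair appears exactly once
      if (nrow(g$edges) > 0) {
        key <- paste(pmin(g$edges$from, g$edges$to),
                     pmax(g$edges$from, g$edges$to))
        expect_equal(anyDuplicated(key), 0L)
        expect_true(all(g$edges$length >= min(vol$spacing) - 1e-12))
        expect_true(all(g$edges$length <=
                          sqrt(sum(vol$spacing^2)) + 1e-12))
      }
    }
  }
})

test_that("component builds are deterministic", {
  vol <- fx_small_graph()  # warm the cache; rebuild from the same volume
  tree <- make_tree(tree_spec(depth = 3, segment_length = 12))
  a <- build_components(tree$volume)
  b <- build_components(tree$volume)
  expect_identical(a, b)
})

test_that("largest-component selection and its tie-break are deterministic", {
  two <- volume_with_voxels(c(12, 5, 5), rbind(
    cbind(0:4, 1, 1), cbind(8:10, 1, 1)))
  sel <- select_largest(build_components(two))
  expect_equal(nrow(sel$nodes), 5L)

  # equal sizes: the component holding the smallest linear index wins
  eq <- volume_with_voxels(c(12, 5, 5), rbind(
    cbind(6:8, 3, 3), cbind(0:2, 1, 1)))
  sel <- select_largest(build_components(eq))
  expect_equal(min(sel$nodes$lin), min(which(eq$values > 0)))
  expect_error(select_largest(list()), "no components")
})

test_that("node roles follow degree and the chosen root", {
  # 4-node path, root at one end
  path4 <- volume_with_voxels(c(6, 3, 3), cbind(0:3, 1, 1))
  g <- classify_nodes(select_largest(build_components(path4)), 1L)
  expect_equal(sum(g$nodes$role == "root"), 1L)
  expect_equal(sum(g$nodes$role == "interior"), 2L)
  expect_equal(sum(g$nodes$role == "terminal"), 1L)

  # Y tree: root + junction + 2 tips
  y <- volume_with_voxels(c(7, 7, 3), rbind(
    cbind(0:2, 3, 1), c(3, 4, 1), c(3, 2, 1), c(4, 5, 1), c(4, 1, 1)))
  gy <- select_largest(build_components(y))
  root <- which(gy$nodes$i == 0 & gy$nodes$j == 3)
  gy <- classify_nodes(gy, root)
  expect_equal(sum(gy$nodes$role == "root"), 1L)
  expect_equal(sum(gy$nodes$role == "terminal"), 2L)

  # a junction node cannot be the root
  junction <- which(gy$nodes$degree >= 3)[1]
  expect_error(classify_nodes(gy, junction), "degree 1")
})

test_that("edge geometry uses mean endpoint radii and physical lengths", {
  vol <- volume_with_voxels(c(5, 3, 3), rbind(c(1, 1, 1), c(2, 1, 1)),
                            values = c(1, 2))
  g <- edge_geometry(select_largest(build_components(vol)))
  expect_equal(g$edges$radius, 1.5)

  same <- volume_with_voxels(c(5, 3, 3), rbind(c(1, 1, 1), c(2, 1, 1)),
                             values = c(0.7, 0.7))
  expect_equal(edge_geometry(select_largest(
    build_components(same)))$edges$radius, 0.7)

  # axis-aligned neighbours at 0.5 mm slice spacing
  thin <- volume_with_voxels(c(3, 3, 5), rbind(c(1, 1, 1), c(1, 1, 2)),
                             spacing = c(0.8, 0.8, 0.5))
  expect_equal(edge_geometry(select_largest(
    build_components(thin)))$edges$length, 0.5, tolerance = 1e-12)
})
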