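test_that("rasterized trees rebuild with the designed terminal count", {
  for (d in 1:3) {
    tr <- make_tree(tree_spec(depth = d, segment_length = 12))
    g <- build_vessel_graph(tr$volume)
    expect_equal(sum(g$nodes$role == "terminal"), 2^d)
    expect_equal(sum(g$nodes$role == "root"), 1L)
    # total rebuilt length within one voxel diagonal per segment
    n_seg <- 2^(d + 1) - 1
    expect_lt(abs(sum(g$edges$length) - tr$total_length_mm),
              n_seg * sqrt(3) * 0.5 + 1)
  }
})

test_that("Murray's law sets the symmetric child radius ratio", {
  tr <- make_tree(tree_spec(depth = 1, segment_length = 12,
                            split_jitter = 0, length_jitter = 0))
  rads <- sort(unique(vapply(tr$segments, function(s) s$radius,
                             numeric(1))), decreasing = TRUE)
  expect_length(rads, 2L)
  expect_equal(rads[2] / rads[1], 2^(-1 / 3), tolerance = 1e-12)
  expect_equal(2^(-1 / 3), 0.7937, tolerance = 1e-4)
})

test_that("tree generation is deterministic per seed and varies across seeds", {
  spec <- tree_spec(depth = 3, segment_length = 12, seed = 4)
  a <- make_tree(spec, verify = FALSE)
  b <- make_tree(spec, verify = FALSE)
  expect_identical(a$volume$values, b$volume$values)
  c_ <- make_tree(tree_spec(depth = 3, segment_length = 12, seed = 5),
                  verify = FALSE)
  expect_false(identical(a$volume$values, c_$volume$values))
})

test_that("noise-free observation masks reproduce the generating prediction", {
  sub <- fx_subject()  # flip_rate 0
  bp <- bolus_params(gamma_t = sub$truth$gamma_t_true,
                     v_dcacl_ul = sub$injected_ul)
  res <- simulate_transport(sub$graph, sub$sol, bp, temperature = FALSE)
  pred <- tag_embolization(res, sub$truth$delta_true)
  root <- which(sub$graph$nodes$role == "root")
  rep <- score_prediction(pred, sub$obs, exclude = root)
  expect_equal(rep$balanced_accuracy, 1)
  expect_gt(sum(sub$obs), 0)
})

test_that("label flips are seeded, reproducible and degrade accuracy as expected", {
  base <- fx_subject()
  sub1 <- make_observed(synthetic_subject(), 14, 0.01,
                        flip_rate = 0.2, seed = 7)
  sub2 <- make_observed(synthetic_subject(), 14, 0.01,
                        flip_rate = 0.2, seed = 7)
  expect_identical(sub1$mask$values, sub2$mask$values)
  expect_false(identical(sub1$obs, base$obs))

  # flipping each label with probability f dilutes both classes; with p
  # true positives and n true negatives the expected balanced accuracy is
  #   [ p(1-f)/(p(1-f)+nf) + n(1-f)/(n(1-f)+pf) ] / 2
  # (0.5 exactly at f = 0.5, regardless of imbalance)
  f <- 0.4
  root <- which(base$graph$nodes$role == "root")
  bp <- bolus_params(gamma_t = 14, v_dcacl_ul = base$injected_ul)
  res <- simulate_transport(base$graph, base$sol, bp, temperature = FALSE)
  pred <- tag_embolization(res, 0.01)
  keep <- setdiff(seq_along(pred$tagged), root)
  p <- sum(pred$tagged[keep]); n <- sum(!pred$tagged[keep])
  expected <- (p * (1 - f) / (p * (1 - f) + n * f) +
                 n * (1 - f) / (n * (1 - f) + p * f)) / 2
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    flip <- runif(length(base$obs)) < f
    score_prediction(pred, xor(pred$tagged, flip),
                     exclude = root)$balanced_accuracy
  }, numeric(1))
  expect_equal(mean(accs), expected, tolerance = 0.05)
})
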