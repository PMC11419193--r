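# Synthetic voxelized vascular trees and forward-simulated observation
# masks, so every pipeline stage is testable without animal imaging data.
# Trees are planar H-fractals with Murray's-law radius tapering: symmetric
# bifurcations with r_parent^m = 2 r_child^m, alternating perpendicular
# branch directions, and per-generation length shrinkage.

#' Specification of a synthetic bifurcating tree
#'
#' @param depth Number of bifurcation generations (>= 1); the rebuilt graph
#'   has `2^depth` terminals.
#' @param root_radius Trunk radius, mm.
#' @param murray_exponent Radius rule exponent `m` in
#'   `r_parent^m = 2 r_child^m`; the classical value 3 gives
#'   `r_child = 2^(-1/3) r_parent`.
#' @param segment_length Trunk length, mm.
#' @param length_shrink Per-generation length factor; the default 0.65
#'   (just under `1/sqrt(2)`) keeps the planar layout collision-free
#'   with margin for the length jitter.
#' @param spacing Isotropic voxel size, mm.
#' @param jitter Positional noise amplitude on branch endpoints, voxels.
#' @param length_jitter Relative branch-length heterogeneity: each child
#'   length is multiplied by `U(1 - length_jitter, 1 + length_jitter)`.
#'   Real vascular trees are strongly asymmetric; a perfectly symmetric
#'   tree makes all root-to-tip transit times identical, which is both
#'   unrealistic and degenerate for reaction-parameter estimation.
#' @param split_jitter Flow-split asymmetry at bifurcations: the Murray
#'   split fraction is drawn as `w ~ U(0.5 - split_jitter,
#'   0.5 + split_jitter)` and child radii follow `r = w^(1/m) r_parent`,
#'   `r = (1-w)^(1/m) r_parent`.
#' @param seed Seed for all random draws.
#' @return A list of class `tree_spec`.
#' @export
tree_spec <- function(depth = 5, root_radius = 1.5, murray_exponent = 3,
                      segment_length = 16, length_shrink = 0.65,
                      spacing = 0.5, jitter = 0, length_jitter = 0.2,
                      split_jitter = 0.12, seed = 1L) {
  stopifnot(depth >= 1, root_radius > 0, segment_length > 0,
            length_shrink > 0, length_shrink < 1, spacing > 0,
            jitter >= 0, murray_exponent > 0,
            length_jitter >= 0, length_jitter < 0.5,
            split_jitter >= 0, split_jitter < 0.5)
  structure(list(depth = depth, root_radius = root_radius,
                 murray_exponent = murray_exponent,
                 segment_length = segment_length,
                 length_shrink = length_shrink, spacing = spacing,
                 jitter = jitter, length_jitter = length_jitter,
                 split_jitter = split_jitter, seed = as.integer(seed)),
            class = "tree_spec")
}

# Continuous-space segment list of the (jittered) H-fractal tree.
tree_segments <- function(spec) {
  set.seed(spec$seed)
  m <- spec$murray_exponent
  segs <- list()
  recurse <- function(p0, dir, gen, rad) {
    len <- spec$segment_length * spec$length_shrink^gen
    if (spec$length_jitter > 0 && gen > 0)
      len <- len * stats::runif(1, 1 - spec$length_jitter,
                                1 + spec$length_jitter)
    p1 <- p0 + dir * len
    if (spec$jitter > 0 && gen > 0)
      p1 <- p1 + stats::runif(3, -1, 1) * spec$jitter * spec$spacing *
        c(1, 1, 0)
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, radius = rad,
                                       gen = gen)
    if (gen < spec$depth) {
      w <- if (spec$split_jitter > 0)
        stats::runif(1, 0.5 - spec$split_jitter, 0.5 + spec$split_jitter)
      else 0.5
      perp <- if (abs(dir[1]) > abs(dir[2])) c(0, 1, 0) else c(1, 0, 0)
      recurse(p1, perp, gen + 1L, rad * w^(1 / m))
      recurse(p1, -perp, gen + 1L, rad * (1 - w)^(1 / m))
    }
  }
  recurse(c(0, 0, 0), c(1, 0, 0), 0L, spec$root_radius)
  segs
}

#' Rasterize a synthetic tree into a centerline volume
#'
#' Walks each branch in sub-voxel steps and marks the visited voxels with
#' the branch radius (junction voxels keep the larger parent radius).
#' The rebuilt graph is verified to have exactly `2^depth` terminals; a
#' mismatch means branches collided in the raster and raises an error
#' advising a larger volume or smaller depth.
#'
#' @param spec A [tree_spec()].
#' @param verify Check the round trip (terminal count) after rasterizing.
#' @return List with `volume` (a [centerline_volume()]), `segments`
#'   (continuous-space ground truth), `n_terminals`, `total_length_mm`.
#' @export
make_tree <- function(spec = tree_spec(), verify = TRUE) {
  stopifnot(inherits(spec, "tree_spec"))
  segs <- tree_segments(spec)
  pts <- do.call(rbind, lapply(segs, function(s) rbind(s$p0, s$p1)))
  pad <- 3 * spec$spacing
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(ceiling((hi - lo) / spec$spacing) + 1L, 5L)
  arr <- array(0, dim = dims)
  for (s in segs) {
    len <- sqrt(sum((s$p1 - s$p0)^2))
    nstep <- max(2L, ceiling(len / (0.3 * spec$spacing)))
    tt <- seq(0, 1, length.out = nstep)
    for (f in tt) {
      p <- s$p0 + f * (s$p1 - s$p0)
      ijk <- round((p - lo) / spec$spacing) + 1L
      arr[ijk[1], ijk[2], ijk[3]] <- max(arr[ijk[1], ijk[2], ijk[3]],
                                         s$radius)
    }
  }
  vol <- centerline_volume(arr, spacing = rep(spec$spacing, 3))
  if (verify) {
    g <- build_vessel_graph(vol)
    n_term <- sum(g$nodes$role == "terminal")
    if (n_term != 2^spec$depth)
      stop(sprintf(paste0("rasterization collision: expected %d terminals, ",
                          "got %d; use a larger volume or smaller depth"),
                   2^spec$depth, n_term))
  }
  list(volume = vol, segments = segs, n_terminals = 2^spec$depth,
       total_length_mm = sum(vapply(segs, function(s)
         sqrt(sum((s$p1 - s$p0)^2)), numeric(1))))
}

#' Assemble a synthetic study subject
#'
#' Builds the tree volume and graph, derives the weight-based reference
#' perfusion, calibrates the terminal conductance to the chosen reference
#' (the scaled mean by default) and solves the flow field — everything the
#' transport and calibration stages need.
#'
#' A desk-scale synthetic tree stands for a small subtree of the hepatic
#' arterial bed, not the whole organ's vasculature, so it carries only a
#' fraction of the whole-liver reference perfusion: `perfusion_scale`
#' multiplies the weight-derived bounds. The default 0.04 puts the bolus
#' transit time through the default tree (a few seconds) on the same scale as the
#' hydrolysis time 1/lambda (~0.3 s), the operating regime of the therapy,
#' where most of the bolus reacts inside the segmented network.
#'
#' @param spec A [tree_spec()].
#' @param weight_kg Body weight, kg.
#' @param injected_ul Injected bolus volume, microlitres.
#' @param perfusion_scale Fraction of the whole-liver reference perfusion
#'   carried by the synthetic subtree.
#' @param q_ref Reference perfusion, mL/min; default the scaled
#'   weight-derived mean.
#' @param flow A [flow_params()] template.
#' @return A list of class `synthetic_subject` with fields `volume`,
#'   `graph`, `ref` (whole-liver perfusion reference), `q_min`/`q_max`
#'   (scaled bounds for the subtree), `flow` (calibrated), `sol`,
#'   `weight_kg`, `injected_ul`.
#' @export
synthetic_subject <- function(spec = tree_spec(), weight_kg = 54,
                              injected_ul = 200, perfusion_scale = 0.04,
                              q_ref = NULL, flow = flow_params()) {
  stopifnot(perfusion_scale > 0, perfusion_scale <= 1)
  tree <- make_tree(spec)
  g <- build_vessel_graph(tree$volume)
  ref <- reference_perfusion(weight_kg)
  if (is.null(q_ref)) q_ref <- perfusion_scale * ref$q_mean
  cal <- calibrate_gamma_a(g, flow, q_ref)
  flow$gamma_a <- cal$gamma_a
  sol <- solve_pressures(g, flow)
  structure(list(volume = tree$volume, graph = g, ref = ref,
                 q_min = perfusion_scale * ref$q_min,
                 q_max = perfusion_scale * ref$q_max,
                 perfusion_scale = perfusion_scale,
                 flow = flow, sol = sol, q_ref = q_ref,
                 weight_kg = weight_kg, injected_ul = injected_ul,
                 spec = spec),
            class = "synthetic_subject")
}

#' Paint per-node values back into the voxel grid
#'
#' @param g A `vessel_graph` with voxel indices.
#' @param vol The source [centerline_volume()] (defines the grid shape).
#' @param values Numeric or logical vector, one per node.
#' @return A 3D array of the volume's shape with node voxels set.
#' @export
paint_nodes <- function(g, vol, values) {
  stopifnot(length(values) == nrow(g$nodes))
  arr <- array(0, dim = dim(vol$values))
  lin <- g$nodes$i + 1L + g$nodes$j * dim(arr)[1] +
    g$nodes$k * dim(arr)[1] * dim(arr)[2]
  arr[lin] <- as.numeric(values)
  arr
}

#' Forward-simulated observation mask for a synthetic subject
#'
#' Runs the full forward pipeline at a known ground-truth time constant:
#' transport at `gamma_t_true`, damage tagging at `delta_true`, then paints
#' the tagged nodes into a binary mask in the subject's voxel space.
#' Optional label-flip noise emulates imperfect registration/observation.
#'
#' @param subject A [synthetic_subject()].
#' @param gamma_t_true Ground-truth hydrolysis time constant, 1/s.
#' @param delta_true Ground-truth damage threshold.
#' @param flip_rate Per-node label flip probability in `[0, 0.5)`.
#' @param seed Seed for the flips.
#' @return The subject with added fields `obs` (logical labels), `mask`
#'   (a [centerline_volume()] of 0/1 in the same space) and `truth`.
#' @export
make_observed <- function(subject, gamma_t_true = 14, delta_true = 0.01,
                          flip_rate = 0, seed = 1L) {
  stopifnot(inherits(subject, "synthetic_subject"),
            flip_rate >= 0, flip_rate < 0.5)
  bp <- bolus_params(gamma_t = gamma_t_true,
                     v_dcacl_ul = subject$injected_ul)
  res <- simulate_transport(subject$graph, subject$sol, bp,
                            temperature = FALSE)
  pred <- tag_embolization(res, delta_true)
  obs <- pred$tagged
  if (flip_rate > 0) {
    set.seed(seed)
    flip <- stats::runif(length(obs)) < flip_rate
    obs <- xor(obs, flip)
  }
  mask_arr <- paint_nodes(subject$graph, subject$volume, obs)
  subject$obs <- obs
  subject$mask <- centerline_volume(mask_arr, affine = subject$volume$affine)
  subject$truth <- list(gamma_t_true = gamma_t_true,
                        delta_true = delta_true, flip_rate = flip_rate,
                        seed = seed)
  subject
}
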