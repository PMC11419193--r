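# Confusion-matrix scoring against observed Lipiodol labels and
# calibration of the hydrolysis time constant gamma_t by minimizing
# g(gamma_t, delta) = beta + (1 - alpha), where beta is the escaped
# unreacted bolus fraction and alpha the balanced accuracy of the tagged
# sites against the observed labels.

#' Observed labels from a registered binary mask
#'
#' Looks up, for every graph node, the mask value at the node's voxel
#' (nearest-voxel lookup). The mask must live in the same voxel space as
#' the centerline the graph was built from.
#'
#' @param g A `vessel_graph` carrying voxel indices (`i`, `j`, `k`).
#' @param mask A [centerline_volume()] or plain 3D array of the same shape
#'   as the source centerline; values `> threshold` count as positive.
#' @param threshold Mask threshold; default 0.5 for binary masks.
#' @return Logical vector, one label per node.
#' @export
labels_from_mask <- function(g, mask, threshold = 0.5) {
  stopifnot(inherits(g, "vessel_graph"))
  arr <- if (inherits(mask, "centerline_volume")) mask$values else mask
  if (length(dim(arr)) != 3L) stop("mask must be a 3D volume")
  if (is.null(g$nodes$i)) stop("graph carries no voxel indices")
  if (any(g$nodes$i >= dim(arr)[1] | g$nodes$j >= dim(arr)[2] |
            g$nodes$k >= dim(arr)[3]))
    stop("mask shape does not cover the graph's voxel space")
  lin <- g$nodes$i + 1L + g$nodes$j * dim(arr)[1] +
    g$nodes$k * dim(arr)[1] * dim(arr)[2]
  arr[lin] > threshold
}

#' Confusion-matrix metrics for predicted vs observed embolization
#'
#' Counts TP/FP/TN/FN over the node set and reports recall
#' `TP/(TP+FN)`, precision `TP/(TP+FP)` and balanced accuracy
#' `(TP/(TP+FN) + TN/(TN+FP))/2`. The root (injection) node is excluded:
#' it trivially reacts. Ratios with a zero denominator are reported as `NA`
#' rather than 0.
#'
#' @param pred An `embolization_prediction` or logical vector.
#' @param obs Logical vector of observed labels (same node set).
#' @param exclude Node ids to drop from the counts (default: the root, if
#'   the prediction came from a graph with roles — pass explicitly
#'   otherwise).
#' @return An object of class `classification_report` with counts and the
#'   three metrics.
#' @export
score_prediction <- function(pred, obs, exclude = integer(0)) {
  tagged <- if (inherits(pred, "embolization_prediction")) pred$tagged else pred
  stopifnot(is.logical(tagged), is.logical(obs),
            length(tagged) == length(obs))
  keep <- setdiff(seq_along(tagged), exclude)
  tagged <- tagged[keep]; obs <- obs[keep]
  tp <- sum(tagged & obs); fp <- sum(tagged & !obs)
  tn <- sum(!tagged & !obs); fn <- sum(!tagged & obs)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  specificity <- ratio(tn, tn + fp)
  parts <- c(recall, specificity)
  bal_acc <- if (all(is.na(parts))) NA_real_ else mean(parts, na.rm = TRUE)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 recall = recall, precision = precision,
                 specificity = specificity, balanced_accuracy = bal_acc,
                 n = length(tagged)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "classification_report: TP %d, FP %d, TN %d, FN %d | recall %.3f, precision %.3f, balanced accuracy %.3f\n",
    x$TP, x$FP, x$TN, x$FN, x$recall, x$precision, x$balanced_accuracy))
  invisible(x)
}

#' Evaluation context for gamma_t calibration
#'
#' Packs everything `objective_g` needs: the graph, the solved flow field,
#' the bolus parameters and the observed labels.
#'
#' @param g A `vessel_graph` with roles and geometry.
#' @param sol The matching `flow_solution`.
#' @param bp A [bolus_params()].
#' @param obs Logical observed labels, one per node.
#' @return A list of class `calibration_context`.
#' @export
calibration_context <- function(g, sol, bp, obs) {
  stopifnot(inherits(g, "vessel_graph"), inherits(sol, "flow_solution"),
            inherits(bp, "bolus_params"),
            is.logical(obs), length(obs) == nrow(g$nodes))
  structure(list(g = g, sol = sol, bp = bp, obs = obs,
                 root = which(g$nodes$role == "root")),
            class = "calibration_context")
}

#' Calibration objective g = beta + (1 - alpha)
#'
#' Runs the transport simulation at the given hydrolysis time constant,
#' tags damage at `delta`, scores against the observed labels and returns
#' `beta + (1 - balanced accuracy)`. A good time constant lets little bolus
#' escape unreacted (small beta) while reproducing the observed
#' embolization pattern (alpha near 1). For a fixed reference perfusion,
#' beta depends on `gamma_t` alone; alpha also depends on `delta`.
#'
#' @param gamma_t Hydrolysis time constant, 1/s.
#' @param delta Damage threshold.
#' @param ctx A [calibration_context()].
#' @return Scalar objective value; attributes `beta`, `alpha` carry the
#'   components.
#' @export
objective_g <- function(gamma_t, delta, ctx) {
  stopifnot(inherits(ctx, "calibration_context"))
  bp <- ctx$bp
  bp$gamma_t <- gamma_t
  res <- simulate_transport(ctx$g, ctx$sol, bp, temperature = FALSE)
  rep <- score_prediction(tag_embolization(res, delta), ctx$obs,
                          exclude = ctx$root)
  alpha <- rep$balanced_accuracy
  g_val <- res$beta + (1 - ifelse(is.na(alpha), 0, alpha))
  structure(g_val, beta = res$beta, alpha = alpha)
}

#' Multi-start calibration of the hydrolysis time constant
#'
#' Draws `n_starts` initial guesses uniformly in `start_range` (default
#' (10, 20) 1/s) with the given seed, runs a Nelder-Mead minimization of
#' [objective_g()] from each, and returns the best converged `gamma_t`.
#' All starts are kept for audit. Negative trial values are rejected by a
#' penalty. The objective's accuracy term is piecewise constant in
#' `gamma_t` (labels flip at discrete thresholds), so the multi-start is
#' what guards against flat-plateau local minima.
#'
#' @param ctx A [calibration_context()].
#' @param delta Damage threshold.
#' @param n_starts Number of random starts.
#' @param seed Integer seed for the start draws.
#' @param start_range Range for the uniform start draws, 1/s.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return An object of class `gamma_t_calibration`: `gamma_t`, `g`,
#'   `beta`, `alpha`, and a `starts` data.frame (start, converged value,
#'   objective).
#' @export
calibrate_gamma_t <- function(ctx, delta, n_starts = 10, seed = 1L,
                              start_range = c(10, 20), maxit = 60) {
  stopifnot(inherits(ctx, "calibration_context"), n_starts >= 1)
  rng <- local({
    set.seed(seed)
    stats::runif(n_starts, start_range[1], start_range[2])
  })
  cache <- new.env(parent = emptyenv())
  f <- function(gt) {
    if (gt <= 0) return(2 + abs(gt))  # outside the physical domain
    key <- sprintf("%.12g", gt)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- as.numeric(objective_g(gt, delta, ctx))
    cache[[key]] <- val
    val
  }
  rows <- lapply(rng, function(g0) {
    fit <- suppressWarnings(stats::optim(
      g0, f, method = "Nelder-Mead",
      control = list(abstol = 1e-10, reltol = 1e-8, maxit = maxit,
                     warn.1d.NelderMead = FALSE)))
    data.frame(start = g0, gamma_t = fit$par, g = fit$value)
  })
  starts <- do.call(rbind, rows)
  if (all(!is.finite(starts$g))) stop("all calibration starts failed")
  best <- which.min(starts$g)
  g_best <- objective_g(starts$gamma_t[best], delta, ctx)
  structure(list(gamma_t = starts$gamma_t[best], g = as.numeric(g_best),
                 beta = attr(g_best, "beta"), alpha = attr(g_best, "alpha"),
                 delta = delta, starts = starts, seed = seed),
            class = "gamma_t_calibration")
}

#' @export
print.gamma_t_calibration <- function(x, ...) {
  cat(sprintf(
    "gamma_t_calibration: gamma_t = %.4f 1/s (g = %.4f, beta = %.4f, alpha = %.4f, delta = %g, %d starts)\n",
    x$gamma_t, x$g, x$beta, x$alpha, x$delta, nrow(x$starts)))
  invisible(x)
}
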