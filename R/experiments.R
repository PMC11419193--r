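# Study-level orchestration: uncertainty grids over (q_ref, delta),
# Pearson correlation summaries, and leave-one-out cross-validation of the
# hydrolysis time constant across subjects.

#' Uncertainty grid over reference perfusion and damage threshold
#'
#' For each grid cell the terminal conductance is first calibrated so that
#' simulated perfusion matches the cell's `q_ref`, then the hydrolysis time
#' constant is calibrated against the subject's observed labels at the
#' cell's `delta`. Cell failures are recorded and the grid continues.
#'
#' @param subject A [synthetic_subject()] carrying observed labels
#'   (see [make_observed()]), or any list with fields `graph`, `flow`,
#'   `obs`, `injected_ul` and `ref`.
#' @param n_qref Number of evenly spaced perfusion values in
#'   `[q_min, q_max]` (endpoints included).
#' @param delta_values Damage thresholds; default 1%..10% in steps of 1%.
#' @param n_starts Random starts per gamma_t calibration.
#' @param seed Base seed; each cell derives its own stream deterministically.
#' @return A data.frame of class `uncertainty_grid` with one row per cell:
#'   `qref`, `delta`, `gamma_a`, `gamma_t`, `alpha`, `beta`, `g`, `ok`.
#' @export
run_uncertainty <- function(subject, n_qref = 10,
                            delta_values = seq(0.01, 0.10, by = 0.01),
                            n_starts = 10, seed = 1L) {
  stopifnot(!is.null(subject$graph), !is.null(subject$obs))
  q_lo <- if (!is.null(subject$q_min)) subject$q_min else subject$ref$q_min
  q_hi <- if (!is.null(subject$q_max)) subject$q_max else subject$ref$q_max
  qref_values <- seq(q_lo, q_hi, length.out = n_qref)
  rows <- list()
  cell <- 0L
  for (iq in seq_along(qref_values)) {
    qref <- qref_values[iq]
    flow_cal <- tryCatch({
      cal <- calibrate_gamma_a(subject$graph, subject$flow, qref)
      fp <- subject$flow; fp$gamma_a <- cal$gamma_a
      list(fp = fp, sol = solve_pressures(subject$graph, fp),
           gamma_a = cal$gamma_a)
    }, error = function(e) e)
    for (id in seq_along(delta_values)) {
      cell <- cell + 1L
      delta <- delta_values[id]
      row <- data.frame(qref = qref, delta = delta, gamma_a = NA_real_,
                        gamma_t = NA_real_, alpha = NA_real_,
                        beta = NA_real_, g = NA_real_, ok = FALSE)
      if (!inherits(flow_cal, "error")) {
        out <- tryCatch({
          bp <- bolus_params(v_dcacl_ul = subject$injected_ul)
          ctx <- calibration_context(subject$graph, flow_cal$sol, bp,
                                     subject$obs)
          fit <- calibrate_gamma_t(ctx, delta, n_starts = n_starts,
                                   seed = seed + cell)
          row$gamma_a <- flow_cal$gamma_a
          row$gamma_t <- fit$gamma_t
          row$alpha <- fit$alpha
          row$beta <- fit$beta
          row$g <- fit$g
          row$ok <- TRUE
          row
        }, error = function(e) row)
        row <- out
      }
      rows[[cell]] <- row
    }
  }
  grid <- do.call(rbind, rows)
  class(grid) <- c("uncertainty_grid", "data.frame")
  grid
}

#' Sample Pearson correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined for zero-variance input")
  stats::cor(x, y, method = "pearson")
}

#' Correlation summary of an uncertainty grid
#'
#' Pearson correlations between the grid's optimal hydrolysis time constant
#' and (a) the reference perfusion, (b) the damage threshold.
#'
#' @param grid An `uncertainty_grid`.
#' @return List with `r_qref_gammat` and `r_delta_gammat`.
#' @export
grid_correlations <- function(grid) {
  ok <- grid$ok & is.finite(grid$gamma_t)
  if (sum(ok) < 3) stop("not enough successful cells for correlation")
  list(r_qref_gammat = pearson_r(grid$qref[ok], grid$gamma_t[ok]),
       r_delta_gammat = pearson_r(grid$delta[ok], grid$gamma_t[ok]))
}

#' Leave-one-out aggregation of per-subject time constants
#'
#' The cross-validated time constant for each held-out subject is the
#' arithmetic mean of the remaining subjects' optimal values.
#'
#' @param gamma_t Numeric vector of per-subject optimal time constants.
#' @return Numeric vector of the same length: `mean(gamma_t[-i])` per i.
#' @export
loocv_aggregate <- function(gamma_t) {
  stopifnot(is.numeric(gamma_t), length(gamma_t) >= 2)
  vapply(seq_along(gamma_t), function(i) mean(gamma_t[-i]), numeric(1))
}

#' Leave-one-out cross-validation across subjects
#'
#' Each subject's own-optimal time constant is first calibrated at its mean
#' reference perfusion and the given threshold. Each subject is then held
#' out in turn, simulated with the mean of the other subjects' optimal
#' values, and scored against its observed labels; own-optimal scores are
#' reported alongside for comparison. The aggregate is the mean balanced
#' accuracy of the held-out predictions.
#'
#' @param subjects List of >= 2 subjects (see [run_uncertainty()] for the
#'   required fields).
#' @param delta Damage threshold (the cross-validation operating point).
#' @param n_starts,seed Multi-start controls for the per-subject
#'   calibrations.
#' @return List of class `loocv_report`: per-subject data.frame `table`
#'   (id, own gamma_t, LOOCV gamma_t, own/LOOCV recall, precision,
#'   balanced accuracy) and `mean_balanced_accuracy`.
#' @export
loocv <- function(subjects, delta = 0.01, n_starts = 10, seed = 1L) {
  if (length(subjects) < 2) stop("LOOCV needs at least 2 subjects")
  fits <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    bp <- bolus_params(v_dcacl_ul = s$injected_ul)
    ctx <- calibration_context(s$graph, s$sol, bp, s$obs)
    list(ctx = ctx,
         fit = calibrate_gamma_t(ctx, delta, n_starts = n_starts,
                                 seed = seed + i))
  })
  gt_own <- vapply(fits, function(f) f$fit$gamma_t, numeric(1))
  gt_cv <- loocv_aggregate(gt_own)
  score_at <- function(ctx, gt) {
    bp <- ctx$bp; bp$gamma_t <- gt
    res <- simulate_transport(ctx$g, ctx$sol, bp, temperature = FALSE)
    score_prediction(tag_embolization(res, delta), ctx$obs,
                     exclude = ctx$root)
  }
  rows <- lapply(seq_along(fits), function(i) {
    own <- score_at(fits[[i]]$ctx, gt_own[i])
    cv <- score_at(fits[[i]]$ctx, gt_cv[i])
    data.frame(id = i, gamma_t_own = gt_own[i], gamma_t_loocv = gt_cv[i],
               recall_own = own$recall, precision_own = own$precision,
               bal_acc_own = own$balanced_accuracy,
               recall_loocv = cv$recall, precision_loocv = cv$precision,
               bal_acc_loocv = cv$balanced_accuracy)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 mean_balanced_accuracy = mean(tab$bal_acc_loocv,
                                               na.rm = TRUE)),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("loocv_report:\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("mean balanced accuracy (LOOCV): %.4f\n",
              x$mean_balanced_accuracy))
  invisible(x)
}
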