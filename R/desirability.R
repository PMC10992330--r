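#' Define a desirability goal for one response
#'
#' @param response Response name the goal applies to.
#' @param goal `"maximize"`, `"minimize"` or `"target"`.
#' @param y_min,y_max Acceptance bounds (`y_min < y_max`).
#' @param target Target value, required (and only allowed) for the
#'   `"target"` goal; must lie inside `[y_min, y_max]`.
#' @param weight Positive weight used by the weighted geometric mean in
#'   [composite_desirability()]; default 1 (the unweighted form).
#' @return Object of class `desirability_goal`.
#' @export
desirability_goal <- function(response, goal = c("maximize", "minimize", "target"),
                              y_min, y_max, target = NULL, weight = 1) {
  goal <- match.arg(goal)
  if (!is.finite(y_min) || !is.finite(y_max) || y_min >= y_max) {
    stop("need finite bounds with y_min < y_max", call. = FALSE)
  }
  if (goal == "target") {
    if (is.null(target) || !is.finite(target) || target < y_min || target > y_max) {
      stop("target goal needs a target inside [y_min, y_max]", call. = FALSE)
    }
  } else if (!is.null(target)) {
    stop("target is only meaningful for the 'target' goal", call. = FALSE)
  }
  stopifnot(is.finite(weight), weight > 0)
  structure(list(response = response, goal = goal, y_min = y_min,
                 y_max = y_max, target = target, weight = weight),
            class = "desirability_goal")
}

#' Individual desirability of a response value
#'
#' Linear (exponent-1) desirability ramps: for a maximized response,
#' 0 below `y_min`, `(y - y_min)/(y_max - y_min)` inside the bounds and
#' 1 above `y_max`; mirrored for minimization; a two-sided tent (1 at the
#' target, 0 at both bounds) for a target goal.
#'
#' @param y Numeric vector of response values.
#' @param goal A [desirability_goal()].
#' @return Desirabilities in `[0, 1]`, same length as `y`.
#' @export
individual_desirability <- function(y, goal) {
  stopifnot(inherits(goal, "desirability_goal"))
  span <- goal$y_max - goal$y_min
  d <- switch(goal$goal,
    maximize = (y - goal$y_min) / span,
    minimize = (goal$y_max - y) / span,
    target   = ifelse(y <= goal$target,
                      (y - goal$y_min) / (goal$target - goal$y_min),
                      (goal$y_max - y) / (goal$y_max - goal$target))
  )
  pmin(pmax(d, 0), 1)
}

#' Composite desirability
#'
#' Weighted geometric mean `D = (prod d_i^w_i)^(1/sum w_i)`; with equal
#' weights (the default) this is the m-th root of the m-fold product.
#' `D = 0` exactly when any individual desirability is 0.
#'
#' @param d Numeric vector of individual desirabilities in `[0, 1]`.
#' @param weights Optional positive weights, recycled to `length(d)`.
#' @return Composite desirability in `[0, 1]`.
#' @export
composite_desirability <- function(d, weights = NULL) {
  if (length(d) == 0L) stop("empty desirability vector", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("individual desirabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(d))
  stopifnot(all(weights > 0))
  weights <- rep_len(weights, length(d))
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

#' Run-wise desirability table over a design
#'
#' Predicts every response at every design run, converts predictions to
#' individual desirabilities and combines them into the composite
#' desirability `D`, then selects the run with maximal `D` (ties broken
#' by lowest run id).  Unless goals are supplied, each response is
#' maximized with bounds taken as the minimum and maximum of its
#' *predicted* values over the design runs, so the best and worst
#' predicted runs score exactly 1 and 0.
#'
#' @param models Named list of `rsm_fit` objects, one per response,
#'   all fitted on the same design.
#' @param design The `bbd_design` whose runs are scored.
#' @param goals Optional named list of [desirability_goal()]s overriding
#'   the per-response defaults.
#' @param weights Optional named numeric vector of per-response weights
#'   for the composite (defaults to equal weights).
#' @return Object of class `desirability_report`: `table` (one row per
#'   run: predictions `Y_*`, desirabilities `d_*`, `D`), `bounds`,
#'   `optimum` (run id, coded and natural coordinates, `D`, predicted
#'   responses) and the goals used.
#' @export
desirability_table <- function(models, design, goals = NULL, weights = NULL) {
  stopifnot(is.list(models), length(models) >= 2L)
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be a named list", call. = FALSE)
  }
  cm <- coded_matrix(design)
  preds <- vapply(models, function(m) predict(m, cm), numeric(nrow(cm)))
  resp <- names(models)

  if (is.null(goals)) {
    goals <- lapply(resp, function(nm) {
      rng <- range(preds[, nm])
      if (diff(rng) <= .Machine$double.eps^0.5 * max(1, abs(rng[2L]))) {
        stop("degenerate desirability bounds for '", nm,
             "': predicted values are constant", call. = FALSE)
      }
      desirability_goal(nm, "maximize", y_min = rng[1L], y_max = rng[2L])
    })
    names(goals) <- resp
  } else {
    stopifnot(all(resp %in% names(goals)))
    goals <- goals[resp]
  }
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1, length(resp)), resp)
  } else {
    stopifnot(all(resp %in% names(weights)))
    weights <- weights[resp]
  }

  d <- vapply(resp, function(nm) individual_desirability(preds[, nm], goals[[nm]]),
              numeric(nrow(cm)))
  D <- apply(d, 1L, composite_desirability, weights = unname(weights))

  run_id <- if (is.data.frame(design) && "run_id" %in% names(design)) {
    design$run_id
  } else {
    seq_len(nrow(cm))
  }
  tab <- data.frame(run_id = run_id, check.names = FALSE)
  for (nm in resp) tab[[paste0("Y_", nm)]] <- preds[, nm]
  for (nm in resp) tab[[paste0("d_", nm)]] <- d[, nm]
  tab$D <- D

  best <- which.max(D)  # first maximum = lowest run id
  factors <- .design_factors(design, default = models[[1L]]$factors)
  optimum <- list(
    run_id = run_id[best],
    coded = cm[best, ],
    natural = stats::setNames(decode_point(factors, cm[best, ]),
                              vapply(factors, function(f) f$name, character(1))),
    D = unname(D[best]),
    predicted = stats::setNames(preds[best, ], resp)
  )
  bounds <- t(vapply(goals, function(g) c(y_min = g$y_min, y_max = g$y_max),
                     numeric(2)))
  structure(list(table = tab, bounds = bounds, goals = goals,
                 weights = weights, optimum = optimum),
            class = "desirability_report")
}

#' @export
print.desirability_report <- function(x, digits = 2, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("optimum: run %d, D = %.2f, conditions (%s)\n",
              x$optimum$run_id, x$optimum$D,
              paste(sprintf("%s = %g", names(x$optimum$natural),
                            x$optimum$natural), collapse = ", ")))
  invisible(x)
}

.grid_levels <- function(resolution) {
  stopifnot(resolution >= 2, resolution == round(resolution))
  seq(-1, 1, length.out = resolution)
}

.grid_desirability <- function(models, grid, goals, weights) {
  resp <- names(models)
  preds <- vapply(models, function(m) predict(m, grid), numeric(nrow(grid)))
  d <- vapply(resp, function(nm) individual_desirability(preds[, nm], goals[[nm]]),
              numeric(nrow(grid)))
  D <- apply(d, 1L, composite_desirability, weights = unname(weights))
  list(preds = preds, d = d, D = D)
}

#' Continuous desirability optimization on a coded grid
#'
#' Extends the run-wise selection of [desirability_table()] to a uniform
#' `resolution^3` grid over the coded cube `[-1, 1]^3`, using the same
#' predicted-value bounds (derived from the design runs).  Ties are
#' broken by the lexicographically smallest coded point; because nested
#' resolutions contain each other's grids, the best `D` is monotone
#' non-decreasing as the resolution is refined over odd resolutions
#' (3, 5, 9, ...).
#'
#' @inheritParams desirability_table
#' @param resolution Number of grid levels per factor (>= 2).
#' @return List with `coded`, `natural`, `D`, `d` and `predicted` at the
#'   maximizing grid point.
#' @export
grid_optimize <- function(models, design, resolution = 21,
                          goals = NULL, weights = NULL) {
  rep0 <- desirability_table(models, design, goals = goals, weights = weights)
  lv <- .grid_levels(resolution)
  grid <- as.matrix(expand.grid(x3 = lv, x2 = lv, x1 = lv))[, c("x1", "x2", "x3")]
  gd <- .grid_desirability(models, grid, rep0$goals, rep0$weights)
  best <- which.max(gd$D)  # rows are lexicographic in (x1, x2, x3)
  factors <- .design_factors(design, default = models[[1L]]$factors)
  list(
    coded = grid[best, ],
    natural = stats::setNames(decode_point(factors, grid[best, ]),
                              vapply(factors, function(f) f$name, character(1))),
    D = gd$D[best],
    d = stats::setNames(gd$d[best, ], names(models)),
    predicted = stats::setNames(gd$preds[best, ], names(models))
  )
}

#' Desirability profile of one factor
#'
#' For each grid level of the chosen factor, reports the maximum
#' composite desirability over a grid of the other two factors — the
#' profile whose peak locates the factor's optimal setting.
#'
#' @inheritParams grid_optimize
#' @param factor_index Which factor to profile (1, 2 or 3).
#' @return Data frame with `level_coded`, `level_natural` and `D`.
#' @export
desirability_profiles <- function(models, design, factor_index, resolution = 21,
                                  goals = NULL, weights = NULL) {
  if (!factor_index %in% 1:3) stop("factor_index must be 1, 2 or 3", call. = FALSE)
  rep0 <- desirability_table(models, design, goals = goals, weights = weights)
  lv <- .grid_levels(resolution)
  others <- setdiff(1:3, factor_index)
  inner <- as.matrix(expand.grid(a = lv, b = lv))
  factors <- .design_factors(design, default = models[[1L]]$factors)
  prof <- vapply(lv, function(z) {
    grid <- matrix(0, nrow = nrow(inner), ncol = 3L,
                   dimnames = list(NULL, c("x1", "x2", "x3")))
    grid[, factor_index] <- z
    grid[, others] <- inner
    max(.grid_desirability(models, grid, rep0$goals, rep0$weights)$D)
  }, numeric(1))
  f <- factors[[factor_index]]
  data.frame(factor = f$name,
             level_coded = lv,
             level_natural = lv * .half_range(f) + f$center,
             D = prof)
}

#' Compare a model prediction with confirmation experiments
#'
#' Summarizes the confirmation runs carried out at the selected optimum:
#' experimental mean and standard deviation, and the relative error
#' `|mean - predicted| / predicted` (predicted-value denominator).
#'
#' @param predicted Model prediction at the optimum (non-zero).
#' @param replicates Numeric vector of confirmation measurements, or
#'   `NULL` if only the summary is available.
#' @param experimental_mean,experimental_sd Summary alternative to raw
#'   `replicates`.
#' @param response_name Label.
#' @return Object of class `optimum_validation` with fields
#'   `response_name`, `predicted`, `experimental_mean`,
#'   `experimental_sd`, `n` and `relative_error`.
#' @export
validate_optimum <- function(predicted, replicates = NULL,
                             experimental_mean = NULL, experimental_sd = NA_real_,
                             response_name = "") {
  if (!is.finite(predicted) || predicted == 0) {
    stop("predicted value must be finite and non-zero", call. = FALSE)
  }
  if (!is.null(replicates)) {
    stopifnot(length(replicates) >= 1L, all(is.finite(replicates)))
    experimental_mean <- mean(replicates)
    experimental_sd <- if (length(replicates) > 1L) stats::sd(replicates) else NA_real_
    n <- length(replicates)
  } else {
    if (is.null(experimental_mean)) {
      stop("supply replicates or an experimental mean", call. = FALSE)
    }
    n <- NA_integer_
  }
  structure(
    list(response_name = response_name,
         predicted = predicted,
         experimental_mean = experimental_mean,
         experimental_sd = experimental_sd,
         n = n,
         relative_error = abs(experimental_mean - predicted) / abs(predicted)),
    class = "optimum_validation"
  )
}

#' @export
print.optimum_validation <- function(x, ...) {
  cat(sprintf("%s: predicted %.2f, experimental %.2f +- %s, relative error %.2f\n",
              x$response_name, x$predicted, x$experimental_mean,
              ifelse(is.na(x$experimental_sd), "NA",
                     sprintf("%.2f", x$experimental_sd)),
              x$relative_error))
  invisible(x)
}
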